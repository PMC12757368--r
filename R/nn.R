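#' Specification of the diagnostic feed-forward network
#'
#' The diagnostic score is produced by a fully connected network with three
#' hidden layers, logistic activations throughout, a sigmoid output unit and
#' cross-entropy loss, trained by full-batch gradient descent with an L2
#' weight penalty.
#'
#' @param hidden_sizes Integer vector of three hidden-layer widths
#'   (default `c(16, 8, 4)`).
#' @param max_epochs Gradient-descent epochs (default 3000).
#' @param learning_rate Step size (default 0.5; training loss decreases
#'   monotonically for sufficiently small values).
#' @param l2_penalty L2 weight-decay coefficient (default 1e-4).
#' @param seed RNG seed for the weight initialisation.
#' @return A `net_spec` list.
#' @export
net_spec <- function(hidden_sizes = c(16, 8, 4), max_epochs = 3000,
                     learning_rate = 0.5, l2_penalty = 1e-4, seed = 1) {
  if (length(hidden_sizes) != 3 || any(hidden_sizes < 1)) {
    abort("`hidden_sizes` must be three positive integers.")
  }
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, l2_penalty = l2_penalty,
                 seed = as.integer(seed)),
            class = "net_spec")
}

#' Stratified train/validation split
#'
#' Samples `round(fraction * class size)` members of each class
#' (round-half-up) into the training set; the rest form the validation set.
#' The split is deterministic under `seed`.
#'
#' @param features A [feature_matrix()].
#' @param fraction Training fraction (default 0.6666).
#' @param seed RNG seed.
#' @param stratified Split per class (default) or over all samples at once.
#' @return A list with [feature_matrix()] elements `train` and `val`.
#' @export
split_train_val <- function(features, fraction = 0.6666, seed = 1,
                            stratified = TRUE) {
  stopifnot(inherits(features, "feature_matrix"))
  grp <- features$samples$group
  if (stratified) {
    if (any(table(grp) < 2)) abort("Every class needs >= 2 samples.")
    set.seed(seed)
    train_idx <- sort(unlist(lapply(unique(grp), function(g) {
      rows <- which(grp == g)
      sample(rows, floor(fraction * length(rows) + 0.5))
    })))
  } else {
    set.seed(seed)
    train_idx <- sort(sample(length(grp), floor(fraction * length(grp) + 0.5)))
  }
  val_idx <- setdiff(seq_along(grp), train_idx)
  if (!length(val_idx)) abort("Validation set is empty; lower `fraction`.")
  take <- function(idx) {
    feature_matrix(features$values[idx, , drop = FALSE],
                   features$samples[idx, ])
  }
  list(train = take(train_idx), val = take(val_idx))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

init_layers <- function(sizes, seed) {
  set.seed(seed)
  purrr::map(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

nn_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (l in seq_along(layers)) {
    acts[[l + 1]] <- sigmoid(sweep(acts[[l]] %*% layers[[l]]$W, 2,
                                   layers[[l]]$b, `+`))
  }
  acts
}

#' Train the three-hidden-layer diagnostic network
#'
#' Features are standardised with training-set means and SDs (frozen into
#' the model and reused for every later projection — no leakage from
#' validation data). Labels are `case` = 1, `control` = 0. Training is
#' full-batch gradient descent on the mean cross-entropy plus
#' `l2_penalty/2 * sum(W^2)`; an error is raised if the loss turns
#' non-finite.
#'
#' @param train A [feature_matrix()] without missing values.
#' @param spec A [net_spec()].
#' @return A `cflmd_model` with the layer weights, standardisation
#'   parameters, region ids and the per-epoch loss trace.
#' @export
train_nn <- function(train, spec = net_spec()) {
  stopifnot(inherits(train, "feature_matrix"), inherits(spec, "net_spec"))
  if (anyNA(train$values)) abort("Training features contain missing values.")
  X <- train$values
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  y <- as.numeric(train$samples$group == "case")
  sizes <- c(ncol(X), spec$hidden_sizes, 1L)
  layers <- init_layers(sizes, spec$seed)
  n <- nrow(Xs)
  loss_trace <- numeric(spec$max_epochs)
  eps <- 1e-12
  for (epoch in seq_len(spec$max_epochs)) {
    acts <- nn_forward(layers, Xs)
    p <- acts[[length(acts)]][, 1]
    l2 <- sum(vapply(layers, function(l) sum(l$W^2), numeric(1)))
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)) +
      spec$l2_penalty / 2 * l2
    if (!is.finite(loss)) {
      abort(paste0("Non-finite loss at epoch ", epoch, "."))
    }
    loss_trace[epoch] <- loss
    # backprop: output delta for sigmoid + cross-entropy is (p - y)/n
    delta <- matrix((p - y) / n, ncol = 1)
    for (l in rev(seq_along(layers))) {
      gW <- t(acts[[l]]) %*% delta + spec$l2_penalty * layers[[l]]$W
      gb <- colSums(delta)
      if (l > 1) {
        a <- acts[[l]]
        delta <- (delta %*% t(layers[[l]]$W)) * a * (1 - a)
      }
      layers[[l]]$W <- layers[[l]]$W - spec$learning_rate * gW
      layers[[l]]$b <- layers[[l]]$b - spec$learning_rate * gb
    }
  }
  structure(list(layers = layers, center = center, scale = scale,
                 region_ids = colnames(X), spec = spec,
                 loss_trace = loss_trace,
                 final_loss = if (spec$max_epochs) loss_trace[spec$max_epochs]
                 else NA_real_),
            class = "cflmd_model")
}

#' @export
print.cflmd_model <- function(x, ...) {
  cat(sprintf(
    "<cflmd_model> %d features -> [%s] -> score; %d epochs, final loss %.4g\n",
    length(x$region_ids), paste(x$spec$hidden_sizes, collapse = ", "),
    x$spec$max_epochs, x$final_loss))
  invisible(x)
}

#' Score samples with a trained diagnostic model
#'
#' Feature columns are aligned to the model's region ids by name (so column
#' order never matters), standardised with the frozen training parameters
#' and passed through the network; the sigmoid output is the diagnostic
#' score in \[0, 1\].
#'
#' @param model A `cflmd_model` from [train_nn()].
#' @param features A [feature_matrix()] containing all model regions.
#' @return A tibble with `sample_id`, `score`, `true_group`, `activity`.
#' @export
score_samples <- function(model, features) {
  stopifnot(inherits(model, "cflmd_model"),
            inherits(features, "feature_matrix"))
  missing_ids <- setdiff(model$region_ids, colnames(features$values))
  if (length(missing_ids)) {
    abort(paste0("Features lack model region(s): ",
                 paste(head(missing_ids, 3), collapse = ", "), "."))
  }
  X <- features$values[, model$region_ids, drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  p <- nn_forward(model$layers, Xs)
  tibble::tibble(sample_id = features$samples$sample_id,
                 score = p[[length(p)]][, 1],
                 true_group = features$samples$group,
                 activity = features$samples$activity)
}

#' @param x A `cflmd_model`.
#' @param ... Unused.
#' @describeIn train_nn Tidy the model weights (one row per weight).
#' @method tidy cflmd_model
#' @export
tidy.cflmd_model <- function(x, ...) {
  purrr::imap_dfr(x$layers, function(l, i) {
    tibble::tibble(layer = i,
                   from = rep(seq_len(nrow(l$W)), ncol(l$W)),
                   to = rep(seq_len(ncol(l$W)), each = nrow(l$W)),
                   weight = as.vector(l$W))
  })
}

#' @param x A `cflmd_model`.
#' @param ... Unused.
#' @describeIn train_nn One-row model summary (size, epochs, final loss).
#' @method glance cflmd_model
#' @export
glance.cflmd_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$region_ids),
                 hidden = paste(x$spec$hidden_sizes, collapse = "-"),
                 epochs = x$spec$max_epochs,
                 learning_rate = x$spec$learning_rate,
                 l2_penalty = x$spec$l2_penalty,
                 final_loss = x$final_loss)
}
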