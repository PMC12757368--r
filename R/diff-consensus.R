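#' k-nearest-probe imputation of missing beta values
#'
#' Replaces each missing cell by the mean (over the `k` nearest complete
#' probes) of that sample's values. Distance between two probes is the
#' root-mean-square difference over the samples where the incomplete probe
#' is observed. Probes with no observed value at all are dropped with a
#' warning.
#'
#' @param m A [beta_matrix()].
#' @param k Number of neighbour probes (default 10).
#' @return A [beta_matrix()] with no missing values.
#' @export
impute_missing <- function(m, k = 10) {
  stopifnot(inherits(m, "beta_matrix"))
  values <- m$values
  all_missing <- rowSums(!is.na(values)) == 0
  if (any(all_missing)) {
    warn(paste0("Dropping ", sum(all_missing),
                " probe(s) with no observed values."))
    values <- values[!all_missing, , drop = FALSE]
  }
  complete <- which(rowSums(is.na(values)) == 0)
  incomplete <- which(rowSums(is.na(values)) > 0)
  if (length(incomplete)) {
    if (k >= length(complete)) {
      abort("`k` must be smaller than the number of complete probes.")
    }
    comp_vals <- values[complete, , drop = FALSE]
    for (i in incomplete) {
      obs <- !is.na(values[i, ])
      d <- sqrt(rowMeans((comp_vals[, obs, drop = FALSE] -
                            rep(values[i, obs], each = nrow(comp_vals)))^2))
      nn <- complete[order(d)[seq_len(k)]]
      miss <- which(!obs)
      values[i, miss] <- colMeans(values[nn, miss, drop = FALSE])
    }
  }
  beta_matrix(values, m$samples)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-feature case-vs-control t-statistics with feature variances shrunk
#' toward a common prior. The prior (scale `s0^2`, degrees of freedom `d0`)
#' is estimated by method of moments on the across-feature distribution of
#' pooled sample variances, modelled as `s0^2` times a scaled F variate.
#' The moderated variance is `(d0 s0^2 + d s^2) / (d0 + d)` and two-sided
#' p-values use a t distribution with `d + d0` degrees of freedom. With
#' `prior_df = 0` this is exactly the classical pooled two-sample t-test.
#'
#' @param m A [beta_matrix()] or [expr_matrix()] with >= 2 samples per group.
#' @param prior_df Optional override of the prior degrees of freedom
#'   (`NULL` = estimate; `0` = classical t; `Inf` = fully shrunk).
#' @return A tibble with one row per feature: `feature_id`, `mean_case`,
#'   `mean_control`, `delta`, `sd_case`, `sd_control`, `t_stat`, `df`,
#'   `p_value`, `q_value`, `direction` (`up`/`down`) and `constant`
#'   (no variance and no difference anywhere).
#' @export
moderated_t_test <- function(m, prior_df = NULL) {
  stopifnot(inherits(m, "cohort_matrix"))
  ic <- group_index(m, "case")
  i0 <- group_index(m, "control")
  n1 <- length(ic); n0 <- length(i0)
  if (n1 < 2 || n0 < 2) abort("Need >= 2 samples per group.")
  if (anyNA(m$values)) {
    abort("Missing values present; run impute_missing() first.")
  }
  x1 <- m$values[, ic, drop = FALSE]
  x0 <- m$values[, i0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  d <- n1 + n0 - 2
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / d

  if (is.null(prior_df)) {
    fit <- fit_f_prior(s2, d)
    d0 <- fit$d0; s02 <- fit$s02
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2) else 0
  }
  s2_mod <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)

  delta <- unname(m1 - m0)
  m1 <- unname(m1); m0 <- unname(m0)
  v1 <- unname(v1); v0 <- unname(v0); s2_mod <- unname(s2_mod)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n0))
  t_stat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  df_tot <- d + d0
  p <- 2 * pt(-abs(t_stat), df = df_tot)
  constant <- v1 == 0 & v0 == 0 & delta == 0
  p[constant] <- 1

  tibble::tibble(
    feature_id = rownames(m$values),
    mean_case = m1, mean_control = m0, delta = delta,
    sd_case = sqrt(v1), sd_control = sqrt(v0),
    t_stat = t_stat, df = df_tot, p_value = p,
    q_value = p.adjust(p, method = "BH"),
    direction = dplyr::case_when(delta > 0 ~ "up", delta < 0 ~ "down",
                                 TRUE ~ NA_character_),
    constant = constant)
}

# method-of-moments fit of s^2 ~ s0^2 * F(d, d0) across features
fit_f_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 3) return(list(d0 = Inf, s02 = mean(s2)))
  m1 <- mean(s2)
  cv2 <- var(s2) / m1^2
  # F(d, d0) moments: CV^2 = 2 (d + d0 - 2) / (d (d0 - 4)); solve for d0
  if (cv2 * d <= 2) return(list(d0 = Inf, s02 = m1))
  d0 <- (4 * cv2 * d + 2 * d - 4) / (cv2 * d - 2)
  if (!is.finite(d0) || d0 <= 4) d0 <- 4.01
  s02 <- m1 * (d0 - 2) / d0
  list(d0 = d0, s02 = s02)
}

order_features <- function(stats, by = c("p", "delta")) {
  by <- match.arg(by)
  if (by == "p") {
    stats[order(stats$p_value, -abs(stats$t_stat), stats$feature_id), ]
  } else {
    stats[order(-abs(stats$delta), stats$p_value, stats$feature_id), ]
  }
}

#' Select differentially expressed genes from one dataset
#'
#' Keeps features with `p_value < p_max`, then takes the `top_n`
#' smallest-p features per direction (ties broken by |t|, then feature id).
#'
#' @param stats A tibble from [moderated_t_test()].
#' @param p_max P-value cutoff (default 0.05).
#' @param top_n Per-direction cap (default 1000).
#' @return A list with character vectors `up` and `down`.
#' @export
select_degs <- function(stats, p_max = 0.05, top_n = 1000) {
  sig <- stats[!is.na(stats$p_value) & stats$p_value < p_max &
                 !is.na(stats$direction), ]
  pick <- function(dir) {
    head(order_features(sig[sig$direction == dir, ], "p")$feature_id, top_n)
  }
  list(up = pick("up"), down = pick("down"))
}

#' Select differentially methylated probes from one dataset
#'
#' A probe is kept when the case/control mean difference passes
#' `delta_min`, the control-group SD is below `sd_control_max` and the
#' case-group SD is below `sd_case_max`; survivors are ranked by |delta|
#' (descending, ties by p then probe id) and capped at `top_n` per
#' direction. `hyper` means case mean > control mean.
#'
#' @param stats A tibble from [moderated_t_test()] on a [beta_matrix()].
#' @param delta_min Minimum |mean difference| (default 0.1).
#' @param sd_control_max,sd_case_max Group-SD ceilings (defaults 0.2 / 0.3).
#' @param top_n Per-direction cap (default 1000).
#' @param delta_rule `"min"` (default) keeps |delta| >= `delta_min`;
#'   `"max"` keeps |delta| <= `delta_min` (the literal small-difference
#'   reading, retained only for comparability).
#' @return A list with character vectors `hyper` and `hypo`.
#' @export
select_dmps <- function(stats, delta_min = 0.1, sd_control_max = 0.2,
                        sd_case_max = 0.3, top_n = 1000,
                        delta_rule = c("min", "max")) {
  delta_rule <- match.arg(delta_rule)
  keep_delta <- if (delta_rule == "min") abs(stats$delta) >= delta_min else
    abs(stats$delta) <= delta_min
  sig <- stats[keep_delta & stats$sd_control < sd_control_max &
                 stats$sd_case < sd_case_max & !is.na(stats$direction), ]
  pick <- function(dir) {
    head(order_features(sig[sig$direction == dir, ], "delta")$feature_id,
         top_n)
  }
  list(hyper = pick("up"), hypo = pick("down"))
}

#' Consensus feature selection across datasets
#'
#' A feature is selected when it is significant in at least `min_datasets`
#' datasets in the same direction. Features reaching the count only by
#' mixing directions are flagged `conflicting` and never selected.
#'
#' Each element of `selections` is a two-vector list as returned by
#' [select_degs()] (`up`/`down`) or [select_dmps()] (`hyper`/`hypo`);
#' the first element is treated as the positive direction.
#'
#' @param selections List of per-dataset selections.
#' @param min_datasets Minimum supporting datasets (default 3).
#' @return A tibble with `feature_id`, `n_up`, `n_down`, `direction`,
#'   `selected`, `conflicting`; direction labels follow the input naming.
#' @export
consensus_features <- function(selections, min_datasets = 3) {
  if (length(selections) < min_datasets) {
    abort("`min_datasets` exceeds the number of datasets supplied.")
  }
  dir_names <- names(selections[[1]])
  if (length(dir_names) != 2) {
    abort("Each selection must have two direction components.")
  }
  tab <- purrr::imap_dfr(selections, function(sel, i) {
    dplyr::bind_rows(
      tibble::tibble(feature_id = unique(sel[[1]]), dir = "pos"),
      tibble::tibble(feature_id = unique(sel[[2]]), dir = "neg"))
  })
  out <- dplyr::summarise(dplyr::group_by(tab, .data$feature_id),
                          n_up = sum(.data$dir == "pos"),
                          n_down = sum(.data$dir == "neg"),
                          .groups = "drop")
  out$direction <- dplyr::case_when(
    out$n_up >= min_datasets & out$n_down == 0 ~ dir_names[1],
    out$n_down >= min_datasets & out$n_up == 0 ~ dir_names[2],
    TRUE ~ NA_character_)
  out$conflicting <- out$n_up > 0 & out$n_down > 0
  out$selected <- !is.na(out$direction) & !out$conflicting
  out$direction[!out$selected] <- NA_character_
  dplyr::arrange(out, dplyr::desc(.data$selected), .data$feature_id)
}

#' Map selected probes to differentially methylated genes
#'
#' @param probes Character vector of probe ids.
#' @param ann Probe annotation tibble (see [read_probe_annotation()]).
#' @return Character vector of unique gene symbols; probes without a gene
#'   annotation are counted and dropped (message).
#' @export
map_probes_to_genes <- function(probes, ann) {
  hit <- ann[ann$probe_id %in% probes, ]
  n_empty <- sum(hit$gene == "" | is.na(hit$gene)) +
    length(setdiff(probes, ann$probe_id))
  if (n_empty) {
    inform(paste0(n_empty, " probe(s) without gene annotation dropped."))
  }
  sort(unique(hit$gene[hit$gene != "" & !is.na(hit$gene)]))
}
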