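#' Reference-based methylation deconvolution
#'
#' Estimates cell-type proportions of each bulk sample by non-negative
#' least squares of its marker methylation values on the signature columns,
#' followed by normalisation onto the probability simplex. Markers are
#' matched by id between matrix and signature; the signature must have full
#' column rank and at least as many shared markers as cell types.
#'
#' @param m A [beta_matrix()] of bulk profiles (markers x samples).
#' @param sig A [signature_matrix()].
#' @return A tibble with one row per sample: `sample_id`, one column per
#'   cell type (proportions summing to 1) and `.residual` (the NNLS
#'   residual norm before normalisation).
#' @export
deconvolve <- function(m, sig) {
  stopifnot(inherits(m, "beta_matrix"), inherits(sig, "signature_matrix"))
  shared <- intersect(rownames(m$values), sig$marker_ids)
  k <- length(sig$cell_types)
  if (length(shared) < k) {
    abort("Need at least as many shared markers as cell types.")
  }
  A <- sig$values[shared, , drop = FALSE]
  if (qr(A)$rank < k) abort("Signature matrix is rank deficient.")
  B <- m$values[shared, , drop = FALSE]
  res <- purrr::map_dfr(seq_len(ncol(B)), function(j) {
    b <- B[, j]
    ok <- is.finite(b)
    fit <- pracma::lsqnonneg(A[ok, , drop = FALSE], b[ok])
    x <- fit$x
    tot <- sum(x)
    prop <- if (tot > 0) x / tot else rep(1 / k, k)
    out <- tibble::as_tibble(as.list(setNames(prop, sig$cell_types)))
    out$.residual <- sqrt(sum(fit$resid.norm))
    out$sample_id <- colnames(B)[j]
    out
  })
  dplyr::relocate(res, "sample_id")
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Per sample, genes are ranked by expression (descending; ties get
#' mid-ranks) and a set's score is the integrated difference between the
#' weighted in-set ECDF (weights = rank^alpha, normalised) and the uniform
#' out-of-set ECDF. Scores are rank-based, hence invariant under any
#' strictly monotone transform of the expression values. With
#' `normalize = TRUE` the whole score matrix is divided by its range
#' (max minus min), the usual cross-sample normalisation.
#'
#' @param expr An [expr_matrix()].
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide all scores by the overall score range.
#' @return A tibble with `sample_id`, `set`, `score`; sets with fewer than
#'   2 member genes in the matrix get `NA` with a warning.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- rownames(expr$values)
  n <- length(genes)
  present <- purrr::map(sets, intersect, genes)
  too_small <- lengths(present) < 2
  if (any(too_small)) {
    warn(paste0("Gene set(s) with <2 genes in matrix scored NA: ",
                paste(names(sets)[too_small], collapse = ", ")))
  }
  memb <- purrr::map(present, function(g) genes %in% g)
  scores <- purrr::map_dfr(seq_len(ncol(expr$values)), function(j) {
    v <- rank(expr$values[, j])          # ascending mid-ranks
    pos <- rank(-expr$values[, j])       # descending mid-position
    w <- v^alpha
    set_scores <- purrr::imap_dbl(memb, function(in_set, nm) {
      if (too_small[[nm]]) return(NA_real_)
      n_in <- sum(in_set)
      # integral of (P_in - P_out) over list positions, closed form
      sum((w[in_set] / sum(w[in_set])) * (n - pos[in_set] + 1)) -
        sum((n - pos[!in_set] + 1)) / (n - n_in)
    })
    tibble::tibble(sample_id = colnames(expr$values)[j],
                   set = names(sets), score = unname(set_scores))
  })
  if (normalize && any(is.finite(scores$score))) {
    rng <- range(scores$score, na.rm = TRUE)
    if (diff(rng) > 0) scores$score <- scores$score / diff(rng)
  }
  scores
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the hit list and the set,
#' within the given universe; BH-adjusted across sets.
#'
#' @param hits Character vector of hit genes (non-empty).
#' @param universe Character vector, the background gene universe.
#' @param annotation Named list of gene sets.
#' @return A tibble sorted by p-value: `set`, `n_overlap`, `n_set`,
#'   `n_hits`, `expected`, `odds_ratio`, `p_value`, `q_value`.
#' @export
ora_hypergeometric <- function(hits, universe, annotation) {
  hits <- intersect(unique(hits), universe)
  if (!length(hits)) abort("`hits` must contain genes from the universe.")
  N <- length(unique(universe))
  n <- length(hits)
  res <- purrr::imap_dfr(annotation, function(set, nm) {
    K <- length(intersect(set, universe))
    k <- length(intersect(set, hits))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    orr <- (k * (N - K - n + k)) / (max(K - k, 0) * max(n - k, 0))
    tibble::tibble(set = nm, n_overlap = k, n_set = K, n_hits = n,
                   expected = n * K / N,
                   odds_ratio = ifelse(is.nan(orr), Inf, orr),
                   p_value = p)
  })
  res$q_value <- bh_adjust(res$p_value)
  dplyr::arrange(res, .data$p_value, .data$set)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
gsea_es <- function(stat_sorted, in_set) {
  n <- length(stat_sorted)
  n_in <- sum(in_set)
  w <- abs(stat_sorted)
  w_in <- sum(w[in_set])
  inc <- ifelse(in_set, if (w_in > 0) w / w_in else 1 / n_in,
                -1 / (n - n_in))
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Pre-ranked gene-set enrichment analysis
#'
#' The enrichment score (ES) is the maximum deviation of the weighted
#' Kolmogorov-Smirnov running sum over the ranking (weights = |rank
#' statistic|). Significance is assessed by randomly re-drawing the gene
#' set from the ranked universe `n_perm` times; the two-sided permutation
#' p-value is `(1 + #{|ES_perm| >= |ES|}) / (n_perm + 1)`. With several
#' sets, p-values are BH-adjusted across sets.
#'
#' @param ranking Named numeric vector (gene -> ranking statistic).
#' @param sets A single character vector or a named list of gene sets.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return A tibble with `set`, `n_genes`, `es`, `p_value`, `q_value`.
#' @export
gsea_preranked <- function(ranking, sets, n_perm = 1000, seed = 1) {
  if (!is.list(sets)) sets <- list(set = sets)
  ord <- order(ranking, decreasing = TRUE)
  stat_sorted <- ranking[ord]
  genes_sorted <- names(ranking)[ord]
  set.seed(seed)
  res <- purrr::imap_dfr(sets, function(set, nm) {
    in_set <- genes_sorted %in% set
    n_in <- sum(in_set)
    if (n_in < 1 || n_in >= length(genes_sorted)) {
      return(tibble::tibble(set = nm, n_genes = n_in, es = NA_real_,
                            p_value = NA_real_))
    }
    es <- gsea_es(stat_sorted, in_set)
    perm <- vapply(seq_len(n_perm), function(i) {
      gsea_es(stat_sorted,
              seq_along(genes_sorted) %in%
                sample.int(length(genes_sorted), n_in))
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
    tibble::tibble(set = nm, n_genes = n_in, es = es, p_value = p)
  })
  res$q_value <- bh_adjust(res$p_value)
  res
}
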