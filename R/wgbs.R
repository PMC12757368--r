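# windowed coverage-weighted sums over sorted positions (one chromosome)
# returns list(meth, total) window sums at each site
window_sums <- function(pos, n_meth, n_total, window_bp) {
  half <- window_bp / 2
  cm <- c(0, cumsum(n_meth)); ct <- c(0, cumsum(n_total))
  lo <- findInterval(pos - half - 0.5, pos) + 1L
  hi <- findInterval(pos + half + 0.5 - 1e-9, pos)
  list(meth = cm[hi + 1L] - cm[lo], total = ct[hi + 1L] - ct[lo])
}

#' Window-smoothed methylation fractions
#'
#' Per-site smoothed methylation: the coverage-weighted mean of
#' `n_meth / n_total` over all CpGs of the same chromosome within
#' `window_bp / 2` of the site (the site itself included). With
#' `window_bp = 0`, or for a CpG with no neighbours in range, this is the
#' raw per-site fraction.
#'
#' @param table A [cpg_counts()] object.
#' @param window_bp Full window width in bp (default 500).
#' @return A tibble `chrom`, `pos`, `frac_raw`, `frac_smooth`.
#' @export
smooth_methylation <- function(table, window_bp = 500) {
  stopifnot(inherits(table, "cpg_counts"))
  s <- table$sites
  out <- dplyr::group_modify(dplyr::group_by(s, .data$chrom), function(d, g) {
    w <- window_sums(d$pos, d$n_meth, d$n_total, window_bp)
    tibble::tibble(pos = d$pos,
                   frac_raw = ifelse(d$n_total > 0,
                                     d$n_meth / d$n_total, NA_real_),
                   frac_smooth = ifelse(w$total > 0,
                                        w$meth / w$total, NA_real_))
  })
  dplyr::ungroup(out)
}

# align a list of cpg_counts onto the union site grid; returns site tibble
# plus meth / total matrices (sites x samples)
align_count_tables <- function(tables) {
  sites <- dplyr::distinct(dplyr::bind_rows(
    purrr::map(tables, function(t) t$sites[, c("chrom", "pos")])))
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos)
  key <- paste(sites$chrom, sites$pos)
  n <- length(tables)
  X <- N <- matrix(0, nrow = nrow(sites), ncol = n)
  for (i in seq_len(n)) {
    idx <- match(paste(tables[[i]]$sites$chrom, tables[[i]]$sites$pos), key)
    X[idx, i] <- tables[[i]]$sites$n_meth
    N[idx, i] <- tables[[i]]$sites$n_total
  }
  colnames(X) <- colnames(N) <- purrr::map_chr(tables, "sample_id")
  list(sites = sites, meth = X, total = N)
}

#' Beta-binomial Wald test for per-CpG differential methylation
#'
#' For every site covered in at least one case and one control sample:
#' group methylation levels are coverage-weighted means of per-sample
#' window-smoothed fractions; a per-site beta-binomial dispersion is
#' estimated by method of moments and shrunk toward the chromosome-wide
#' median dispersion with weight `m/(m + n_samples)` (`m = 20`
#' pseudo-observations); the Wald statistic is `delta / se(delta)` with
#' beta-binomial group variances, and two-sided p-values come from the
#' normal reference. Sites covered in only one group are skipped.
#'
#' @param cases,controls Lists of [cpg_counts()] tables (>= 1 each).
#' @param window_bp Smoothing window passed to the per-sample smoother
#'   (default 500; use 0 for raw fractions).
#' @param shrink_m Pseudo-observation count of the dispersion shrinkage
#'   target (default 20).
#' @return A tibble of DMP records: `chrom`, `pos`, `pi_case`,
#'   `pi_control`, `delta`, `wald_stat`, `p_value`, `phi` (shrunk
#'   dispersion), sorted by (chrom, pos).
#' @export
bb_wald_test <- function(cases, controls, window_bp = 500, shrink_m = 20) {
  if (!length(cases) || !length(controls)) {
    abort("Need at least one case and one control table.")
  }
  al <- align_count_tables(c(controls, cases))
  grp <- rep(c("control", "case"), c(length(controls), length(cases)))
  X <- al$meth; N <- al$total
  tested <- rowSums(N[, grp == "case", drop = FALSE]) > 0 &
    rowSums(N[, grp == "control", drop = FALSE]) > 0
  if (!any(tested)) {
    warn("No site is covered in both groups.")
    return(tibble::tibble(chrom = character(), pos = integer(),
                          pi_case = numeric(), pi_control = numeric(),
                          delta = numeric(), wald_stat = numeric(),
                          p_value = numeric(), phi = numeric()))
  }

  # per-sample smoothed fractions on the union grid, per chromosome
  S <- matrix(NA_real_, nrow = nrow(al$sites), ncol = ncol(X))
  for (ch in unique(al$sites$chrom)) {
    ii <- which(al$sites$chrom == ch)
    for (j in seq_len(ncol(X))) {
      w <- window_sums(al$sites$pos[ii], X[ii, j], N[ii, j], window_bp)
      S[ii, j] <- ifelse(w$total > 0, w$meth / w$total, NA_real_)
    }
  }

  # group methylation level: the per-site pooled group fraction shrunk
  # toward the local smoothed level, with `prior_reads` pseudo-reads on the
  # smooth target. High per-site coverage lets the site data dominate (no
  # edge attenuation); sparse sites borrow strength from the window.
  prior_reads <- 20
  group_pi <- function(g) {
    Ng <- N[, grp == g, drop = FALSE]
    Xg <- X[, grp == g, drop = FALSE]
    Sg <- S[, grp == g, drop = FALSE]
    tot <- rowSums(Ng)
    # smooth target: per-sample smoothed fractions, site-coverage weighted
    wsum <- rowSums(Ng * !is.na(Sg))
    tg <- ifelse(wsum > 0, rowSums(Ng * Sg, na.rm = TRUE) / wsum, NA_real_)
    ifelse(tot > 0, (rowSums(Xg) + prior_reads * tg) / (tot + prior_reads),
           tg)
  }
  pi1 <- group_pi("case"); pi0 <- group_pi("control")

  # method-of-moments beta-binomial dispersion, pooled over both groups;
  # residuals are taken around the raw per-site pooled group fraction so
  # that smoothing-induced site heterogeneity does not inflate dispersion
  resid_d <- function(g) {
    Ng <- N[, grp == g, drop = FALSE]
    Xg <- X[, grp == g, drop = FALSE]
    tot <- rowSums(Ng)
    pg <- ifelse(tot > 0, rowSums(Xg) / tot, NA_real_)
    mu <- Ng * pg
    vb <- Ng * pg * (1 - pg)
    r <- rowSums(((Xg - mu)^2 - vb) * (Ng > 0))
    d <- rowSums(Ng * (Ng - 1) * pg * (1 - pg))
    list(r = r, d = d)
  }
  rc <- resid_d("case"); r0 <- resid_d("control")
  denom <- rc$d + r0$d
  phi_hat <- ifelse(denom > 0, pmin(pmax((rc$r + r0$r) / denom, 0), 0.95),
                    NA_real_)
  phi_med <- stats::ave(phi_hat, al$sites$chrom, FUN = function(z) {
    if (all(is.na(z))) 0 else median(z, na.rm = TRUE)
  })
  n_cov <- rowSums(N > 0)
  wsh <- shrink_m / (shrink_m + n_cov)
  phi <- wsh * phi_med + (1 - wsh) * ifelse(is.na(phi_hat), phi_med, phi_hat)

  # beta-binomial variance of the per-site pooled group fraction (the
  # shrinkage toward the smooth target only reduces variance, so this is
  # mildly conservative at sparse sites)
  bb_var <- function(g, pig) {
    Ng <- N[, grp == g, drop = FALSE]
    tot <- rowSums(Ng)
    pv <- pmin(pmax(pig, 1 / (tot + 2)), 1 - 1 / (tot + 2))
    pv * (1 - pv) * rowSums(Ng * (1 + (Ng - 1) * phi)) / tot^2
  }
  delta <- pi1 - pi0
  se <- sqrt(bb_var("case", pi1) + bb_var("control", pi0))
  z <- ifelse(delta == 0, 0, delta / se)
  p <- ifelse(delta == 0, 1, 2 * pnorm(-abs(z)))

  out <- tibble::tibble(chrom = al$sites$chrom, pos = al$sites$pos,
                        pi_case = pi1, pi_control = pi0, delta = delta,
                        wald_stat = z, p_value = p, phi = phi)
  dplyr::arrange(out[tested, ], .data$chrom, .data$pos)
}

#' Filter DMP records by significance and effect size
#'
#' Keeps sites with `p_value < p_max` and `|delta| > delta_min`.
#'
#' @param records Tibble from [bb_wald_test()].
#' @param p_max P-value cutoff (default 0.01).
#' @param delta_min Minimum |case - control| methylation difference
#'   (default 0.2, strict inequality).
#' @return The filtered tibble with a `direction` column
#'   (`hyper` = case above control, `hypo` = below).
#' @export
call_dmps <- function(records, p_max = 0.01, delta_min = 0.2) {
  out <- records[!is.na(records$p_value) & records$p_value < p_max &
                   abs(records$delta) > delta_min, ]
  out$direction <- ifelse(out$delta > 0, "hyper", "hypo")
  out
}

#' Merge DMPs into differentially methylated regions
#'
#' Chromosomes are processed independently. Consecutive same-direction
#' DMPs whose gap is at most `max_gap_bp` are merged greedily into
#' candidate regions; a region is reported when it contains at least
#' `min_dmps` member DMPs and its Stouffer-combined member p-value is
#' below `region_p_max`. Region bounds are the first and last member CpG
#' (1-based inclusive).
#'
#' @param dmps Tibble from [call_dmps()] (needs `direction`).
#' @param min_dmps Minimum member DMPs per region (default 6, i.e. more
#'   than five; set 5 for the inclusive reading).
#' @param max_gap_bp Maximum inter-DMP gap inside a region (default 1000).
#' @param region_p_max Region-level p cutoff (default 0.05).
#' @return A tibble of DMR records: `chrom`, `start`, `end`, `n_dmps`,
#'   `mean_delta`, `direction`, `region_p`, sorted by (chrom, start).
#' @export
call_dmrs <- function(dmps, min_dmps = 6, max_gap_bp = 1000,
                      region_p_max = 0.05) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_dmps = integer(),
                          mean_delta = numeric(), direction = character(),
                          region_p = numeric())
  if (!nrow(dmps)) return(empty)
  dmps <- dplyr::arrange(dmps, .data$chrom, .data$pos)
  new_run <- c(TRUE, dmps$chrom[-1] != dmps$chrom[-nrow(dmps)] |
                 dmps$direction[-1] != dmps$direction[-nrow(dmps)] |
                 diff(dmps$pos) > max_gap_bp)
  dmps$run <- cumsum(new_run)
  out <- dplyr::summarise(
    dplyr::group_by(dmps, .data$run),
    chrom = dplyr::first(.data$chrom),
    start = min(.data$pos), end = max(.data$pos),
    n_dmps = dplyr::n(), mean_delta = mean(.data$delta),
    direction = dplyr::first(.data$direction),
    region_p = stouffer_p(.data$p_value),
    .groups = "drop")
  out$run <- NULL
  out <- out[out$n_dmps >= min_dmps & out$region_p < region_p_max, ]
  dplyr::arrange(out, .data$chrom, .data$start)
}

# Stouffer combination of two-sided member p-values (common direction)
stouffer_p <- function(p) {
  z <- qnorm(pmin(pmax(p / 2, 1e-320), 1 - 1e-16), lower.tail = FALSE)
  2 * pnorm(-sum(z) / sqrt(length(z)))
}

#' Binomial subsample augmentation of WGBS samples
#'
#' Expands a small cohort by random subsampling: every input sample is
#' replicated `reps_control` (controls) or `reps_case` (cases) times, and
#' each replicate independently thins the parent's methylated and
#' unmethylated read counts site-by-site with a Binomial retention
#' probability of `thin_fraction`. With 3 controls and 3 cases at the
#' default replicate counts 7/20 this yields 21 control and 60 case
#' sub-samples. `thin_fraction = 1` reproduces each parent exactly.
#'
#' @param tables List of [cpg_counts()] tables.
#' @param reps_control,reps_case Replicates per control / case sample
#'   (defaults 7 / 20).
#' @param thin_fraction Read-retention probability in (0, 1\] (default 0.5).
#' @param seed RNG seed; the output is deterministic given the seed.
#' @return A list of [cpg_counts()] sub-samples (in parent order; replicate
#'   index appended to the sample id). Parent activity scores are inherited.
#' @export
augment_subsamples <- function(tables, reps_control = 7, reps_case = 20,
                               thin_fraction = 0.5, seed = 1) {
  if (!length(tables)) abort("`tables` must not be empty.")
  if (thin_fraction <= 0 || thin_fraction > 1) {
    abort("`thin_fraction` must lie in (0, 1].")
  }
  set.seed(seed)
  out <- list()
  for (t in tables) {
    reps <- if (t$group == "case") reps_case else reps_control
    for (r in seq_len(reps)) {
      meth <- rbinom(nrow(t$sites), t$sites$n_meth, thin_fraction)
      unmeth <- rbinom(nrow(t$sites), t$sites$n_total - t$sites$n_meth,
                       thin_fraction)
      sub <- tibble::tibble(chrom = t$sites$chrom, pos = t$sites$pos,
                            n_total = meth + unmeth, n_meth = meth)
      out[[length(out) + 1L]] <- cpg_counts(
        sub, sample_id = sprintf("%s_rep%02d", t$sample_id, r),
        group = t$group, activity = t$activity %||% NA_real_)
    }
  }
  out
}
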