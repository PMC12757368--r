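#' Construct a beta-value matrix
#'
#' A `beta_matrix` holds array-style methylation fractions (beta values) as a
#' probes-by-samples matrix together with per-sample metadata: a group label
#' (`"control"` or `"case"`) and an optional non-negative disease-activity
#' score (SLEDAI-like).
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). Values must lie in
#'   \[0, 1\] or be `NA`.
#' @param samples A data frame with columns `sample_id`, `group` and
#'   optionally `activity`, one row per matrix column.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, samples) {
  new_cohort_matrix(values, samples, class = "beta_matrix",
                    feature_label = "probe_id")
}

#' Construct a log-scale expression matrix
#'
#' An `expr_matrix` holds a genes-by-samples matrix of log-scale expression
#' values (e.g. log2 FPKM) with the same per-sample metadata as
#' [beta_matrix()]. Values may be any finite real number.
#'
#' @inheritParams beta_matrix
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples) {
  new_cohort_matrix(values, samples, class = "expr_matrix",
                    feature_label = "gene_id")
}

new_cohort_matrix <- function(values, samples, class, feature_label) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have rownames (features) and colnames (samples).")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    abort(paste0("Duplicate feature id: ", dup))
  }
  if (anyDuplicated(colnames(values))) {
    abort("Duplicate sample ids in `values`.")
  }
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("`samples` needs columns `sample_id` and `group`.")
  }
  if (!"activity" %in% names(samples)) samples$activity <- NA_real_
  samples <- samples[match(colnames(values), samples$sample_id), ]
  if (anyNA(samples$sample_id)) {
    abort("Every matrix column must have a row in `samples`.")
  }
  bad_grp <- setdiff(unique(samples$group[!is.na(samples$group)]),
                     c("control", "case"))
  if (length(bad_grp)) {
    abort(paste0("Unknown group label(s): ", paste(bad_grp, collapse = ", "),
                 " (expected 'control'/'case')."))
  }
  if (identical(class, "beta_matrix")) {
    rng <- range(values, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
      bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
      abort(paste0("Beta value out of [0,1] at probe ",
                   rownames(values)[bad[1]], ", sample ",
                   colnames(values)[bad[2]], "."))
    }
  } else {
    if (any(!is.finite(values[!is.na(values)]))) {
      abort("Expression values must be finite.")
    }
  }
  structure(
    list(values = values, samples = samples),
    feature_label = feature_label,
    class = c(class, "cohort_matrix")
  )
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d features x %d samples (%d control, %d case)\n",
              class(x)[1], nrow(x$values), ncol(x$values),
              sum(x$samples$group == "control", na.rm = TRUE),
              sum(x$samples$group == "case", na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$values)

#' Tidy a cohort matrix into long format
#'
#' @param x A [beta_matrix()] or [expr_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per feature/sample pair: feature id,
#'   `sample_id`, `value`, `group`, `activity`.
#' @method tidy cohort_matrix
#' @export
tidy.cohort_matrix <- function(x, ...) {
  lab <- attr(x, "feature_label")
  out <- tibble::as_tibble(x$values, rownames = lab)
  out <- tidyr::pivot_longer(out, -dplyr::all_of(lab),
                             names_to = "sample_id", values_to = "value")
  dplyr::left_join(out, x$samples, by = "sample_id")
}

group_index <- function(x, group) which(x$samples$group == group)

#' Construct a per-sample CpG count table
#'
#' Holds one WGBS sample's per-CpG methylated/total read counts. Positions
#' are 1-based (Bismark coverage convention); records are kept sorted by
#' (chrom, pos) and duplicates are an error.
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based integer),
#'   `n_total`, `n_meth`.
#' @param sample_id Sample identifier.
#' @param group `"control"` or `"case"`.
#' @param activity Optional non-negative disease-activity score.
#' @return An object of class `cpg_counts`.
#' @export
cpg_counts <- function(sites, sample_id, group, activity = NA_real_) {
  sites <- tibble::as_tibble(sites)[, c("chrom", "pos", "n_total", "n_meth")]
  if (nrow(sites)) {
    if (any(sites$n_meth < 0) || any(sites$n_total < 0)) {
      abort("Negative counts are not allowed.")
    }
    if (any(sites$n_meth > sites$n_total)) {
      abort("n_meth may not exceed n_total.")
    }
    ord <- order(sites$chrom, sites$pos)
    if (is.unsorted(ord) || any(ord != seq_along(ord))) {
      inform(paste0("Sorting CpG records of sample ", sample_id,
                    " by (chrom, pos)."))
      sites <- sites[ord, ]
    }
    key <- paste(sites$chrom, sites$pos)
    if (anyDuplicated(key)) {
      abort(paste0("Duplicate CpG record at ", key[duplicated(key)][1], "."))
    }
  }
  if (!group %in% c("control", "case")) {
    abort("`group` must be 'control' or 'case'.")
  }
  structure(list(sites = sites, sample_id = sample_id, group = group,
                 activity = activity),
            class = "cpg_counts")
}

#' @export
print.cpg_counts <- function(x, ...) {
  cat(sprintf("<cpg_counts> sample %s (%s): %d CpGs, mean depth %.1f\n",
              x$sample_id, x$group, nrow(x$sites),
              if (nrow(x$sites)) mean(x$sites$n_total) else 0))
  invisible(x)
}

#' @param x A `cpg_counts` object.
#' @param ... Unused.
#' @describeIn cpg_counts Tidy to a tibble with per-site methylation fraction.
#' @method tidy cpg_counts
#' @export
tidy.cpg_counts <- function(x, ...) {
  dplyr::mutate(x$sites,
                frac = ifelse(.data$n_total > 0,
                              .data$n_meth / .data$n_total, NA_real_),
                sample_id = x$sample_id, group = x$group)
}

#' Construct a methylation signature matrix for deconvolution
#'
#' Markers-by-cell-types reference methylation fractions used by
#' [deconvolve()]. Columns must be linearly independent (full column rank)
#' for the deconvolution to be identifiable.
#'
#' @param values Numeric matrix in \[0,1\], rownames = marker ids,
#'   colnames = cell types.
#' @return An object of class `signature_matrix`.
#' @export
signature_matrix <- function(values) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values))) {
    abort("`values` must be a matrix with marker rownames and cell-type colnames.")
  }
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    abort("Signature values must lie in [0,1].")
  }
  structure(list(values = values,
                 marker_ids = rownames(values),
                 cell_types = colnames(values)),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d markers x %d cell types\n",
              length(x$marker_ids), length(x$cell_types)))
  invisible(x)
}

#' Construct a samples-by-regions feature matrix
#'
#' Rows are samples, columns are model DMRs (named `chrom:start-end`);
#' cells hold mean methylation of the region in that sample.
#'
#' @param values Numeric matrix in \[0,1\] (or `NA`), rownames = sample ids,
#'   colnames = region ids.
#' @param samples Data frame with `sample_id`, `group`, optional `activity`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, samples) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values))) {
    abort("`values` must be a matrix with sample rownames and region colnames.")
  }
  if (anyDuplicated(colnames(values))) abort("Region ids must be unique.")
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    abort("Feature values must lie in [0,1].")
  }
  samples <- tibble::as_tibble(samples)
  if (!"activity" %in% names(samples)) samples$activity <- NA_real_
  samples <- samples[match(rownames(values), samples$sample_id), ]
  if (anyNA(samples$sample_id)) {
    abort("Every matrix row must have a row in `samples`.")
  }
  structure(list(values = values, samples = samples),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d regions\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @describeIn feature_matrix Tidy to long format.
#' @method tidy feature_matrix
#' @export
tidy.feature_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$values, rownames = "sample_id")
  out <- tidyr::pivot_longer(out, -"sample_id",
                             names_to = "region_id", values_to = "value")
  dplyr::left_join(out, x$samples, by = "sample_id")
}
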