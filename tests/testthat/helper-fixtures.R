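# small in-code fixtures shared across test files

mk_beta <- function(values, groups = NULL, activity = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cg%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(groups)) {
    groups <- rep(c("control", "case"), length.out = ncol(values))
  }
  samples <- tibble::tibble(sample_id = colnames(values), group = groups)
  if (!is.null(activity)) samples$activity <- activity
  beta_matrix(values, samples)
}

mk_expr <- function(values, groups = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(groups)) {
    groups <- rep(c("control", "case"), length.out = ncol(values))
  }
  expr_matrix(values, tibble::tibble(sample_id = colnames(values),
                                     group = groups))
}

mk_counts <- function(pos, n_total, n_meth, chrom = "chr1",
                      sample_id = "s1", group = "control") {
  cpg_counts(tibble::tibble(chrom = chrom, pos = as.integer(pos),
                            n_total = as.integer(n_total),
                            n_meth = as.integer(n_meth)),
             sample_id = sample_id, group = group)
}

# a null two-group expr matrix of iid normals
mk_null_expr <- function(n_features, n_per_group, seed) {
  set.seed(seed)
  v <- matrix(rnorm(n_features * 2 * n_per_group), nrow = n_features)
  mk_expr(v, groups = rep(c("control", "case"), each = n_per_group))
}
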