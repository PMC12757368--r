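#' Run the full cfDNA methylation diagnostic pipeline
#'
#' Chains every stage on already-loaded cohorts: consensus DEG screening
#' across the expression cohorts, consensus DMP screening and gene mapping
#' across the array cohorts, WGBS DMP/DMR calling on the parent samples,
#' cross-platform region screening, binomial subsample augmentation,
#' WGBS feature-matrix construction, stratified train/validation split,
#' network training and validation scoring.
#'
#' @param expr_cohorts List of [expr_matrix()] cohorts (>= `min_datasets`).
#' @param array_cohorts List of [beta_matrix()] cohorts (>= `min_datasets`).
#' @param wgbs_tables List of [cpg_counts()] tables (both groups).
#' @param ann Probe annotation tibble.
#' @param min_datasets Consensus support threshold (default 3).
#' @param reps_control,reps_case,thin_fraction Augmentation parameters
#'   (defaults 7 / 20 / 0.5).
#' @param split_fraction Training fraction (default 0.6666).
#' @param spec A [net_spec()].
#' @param seed Seed controlling augmentation and the split.
#' @param shuffle_labels Permute training labels before fitting (negative
#'   control; validation labels stay truthful).
#' @return A list: `deg_genes`, `dmg_genes`, `dmrs`, `model_regions`,
#'   `model`, `scores` (validation tibble), `all_scores` (every sub-sample
#'   scored with the trained model), `auc` (validation-only) and
#'   `activity_spearman` (over all scored samples with activity).
#' @export
cflmd_pipeline <- function(expr_cohorts, array_cohorts, wgbs_tables, ann,
                           min_datasets = 3, reps_control = 7,
                           reps_case = 20, thin_fraction = 0.5,
                           split_fraction = 0.6666, spec = net_spec(),
                           seed = 1, shuffle_labels = FALSE) {
  deg_sel <- purrr::map(expr_cohorts,
                        function(e) select_degs(moderated_t_test(e)))
  deg_cons <- consensus_features(deg_sel, min_datasets = min_datasets)
  deg_genes <- deg_cons$feature_id[deg_cons$selected]

  dmp_sel <- purrr::map(array_cohorts,
                        function(b) select_dmps(moderated_t_test(b)))
  dmp_cons <- consensus_features(dmp_sel, min_datasets = min_datasets)
  dmg_genes <- map_probes_to_genes(dmp_cons$feature_id[dmp_cons$selected],
                                   ann)

  groups <- purrr::map_chr(wgbs_tables, "group")
  records <- bb_wald_test(wgbs_tables[groups == "case"],
                          wgbs_tables[groups == "control"])
  dmrs <- call_dmrs(call_dmps(records))
  regions <- screen_model_regions(deg_genes, dmg_genes, dmrs, ann)
  if (!nrow(regions)) abort("No model regions survived screening.")

  subs <- augment_subsamples(wgbs_tables, reps_control = reps_control,
                             reps_case = reps_case,
                             thin_fraction = thin_fraction, seed = seed)
  features <- build_feature_matrix_wgbs(regions, subs)
  split <- split_train_val(features, fraction = split_fraction, seed = seed)
  train <- split$train
  if (shuffle_labels) {
    set.seed(seed + 1L)
    train$samples$group <- sample(train$samples$group)
  }
  model <- train_nn(train, spec)
  scores <- score_samples(model, split$val)
  auc <- roc_auc(scores$score, scores$true_group)
  # activity assessment uses every scored sample: the diagnostic claim is
  # held out, the severity correlation is a cohort-level description
  all_scores <- score_samples(model, features)
  rho <- if (any(is.finite(all_scores$activity))) {
    spearman_cor(all_scores$score, all_scores$activity)$rho
  } else NA_real_
  list(deg_genes = deg_genes, dmg_genes = dmg_genes, dmrs = dmrs,
       model_regions = regions, model = model, scores = scores,
       all_scores = all_scores, auc = auc, activity_spearman = rho)
}
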