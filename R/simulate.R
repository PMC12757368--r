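#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the simulators with defaults chosen to emulate a
#' small case/control cfDNA methylation study: hypo-methylation-dominant
#' planted signal, intermediate baseline methylation where differential
#' signal is detectable, and WGBS coverage typical of a plasma sequencing
#' run. For the array generator `n_true_hypo`/`n_true_hyper` count planted
#' probes; for the WGBS generator they count planted regions of
#' `dmr_width_cpgs` consecutive CpGs.
#'
#' @param seed Integer RNG seed.
#' @param n_control,n_case Samples per group (each >= 1).
#' @param n_probes Number of array probes (and paired genes).
#' @param n_cpgs Number of WGBS CpG sites (across all chromosomes).
#' @param n_true_hypo,n_true_hyper Planted hypo-/hyper-methylated features.
#' @param effect_size Planted methylation-fraction shift, in \[0, 1).
#' @param baseline_alpha,baseline_beta Beta shape parameters for per-feature
#'   baseline methylation.
#' @param precision Beta precision (alpha + beta) for per-sample array noise
#'   around the group mean.
#' @param depth_mean Mean WGBS per-site coverage (Poisson, floored at 1).
#' @param dmr_width_cpgs CpGs per planted WGBS region (>= 1).
#' @param cpg_gap_mean Mean inter-CpG gap in bp (geometric; default 100,
#'   between CpG-island and genome-background spacing).
#' @param n_chroms Number of synthetic chromosomes (1-3).
#' @param activity_slope Coupling between a sample's mean planted-signal
#'   deviation and its disease-activity score.
#' @param severity_spread Half-width of the per-case severity factor
#'   (uniform on `1 +- severity_spread`) scaling the planted shift;
#'   0 plants the same effect in every case.
#' @param expr_effect Log-expression shift for genes paired to planted
#'   probes (hypo-methylated gene -> up-regulated).
#' @param expr_sd Residual SD of log expression.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_control = 20, n_case = 20,
                       n_probes = 2000, n_cpgs = 3000,
                       n_true_hypo = 120, n_true_hyper = 80,
                       effect_size = 0.3,
                       baseline_alpha = 2, baseline_beta = 2,
                       precision = 30, depth_mean = 30,
                       dmr_width_cpgs = 8, cpg_gap_mean = 100,
                       n_chroms = 2, activity_slope = 10,
                       expr_effect = 1, expr_sd = 1,
                       severity_spread = 0.4) {
  if (effect_size < 0 || effect_size >= 1) {
    abort("`effect_size` must lie in [0, 1).")
  }
  if (n_control < 1 || n_case < 1) {
    abort("Need at least one control and one case sample.")
  }
  if (depth_mean < 1) abort("`depth_mean` must be >= 1.")
  if (dmr_width_cpgs < 1) abort("`dmr_width_cpgs` must be >= 1.")
  if (n_true_hypo + n_true_hyper > n_probes) {
    abort("More planted probes than probes.")
  }
  if (severity_spread < 0 || severity_spread >= 1) {
    abort("`severity_spread` must lie in [0, 1).")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a paired array methylation + expression cohort
#'
#' Per-feature baseline methylation is drawn from
#' `Beta(baseline_alpha, baseline_beta)`; planted case means are shifted by
#' `-effect_size` (hypo) or `+effect_size` (hyper) and clipped to \[0, 1\]
#' (a warning reports the clipped count when more than 10% of planted
#' features hit a boundary). Per-sample beta values are drawn from a Beta
#' distribution reparameterised by (group mean, `precision`); each case
#' carries a per-sample severity factor (uniform on `1 +- severity_spread`)
#' scaling the planted shift, so patients span a disease-activity spectrum. The paired
#' expression matrix shifts genes of planted hypo-methylated probes up by
#' `expr_effect` and hyper-methylated ones down, mirroring the inverse
#' promoter-methylation/expression relationship. A disease-activity score
#' is coupled to each sample's realised planted-signal deviation through
#' `activity_slope`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `beta` ([beta_matrix()]), `expr`
#'   ([expr_matrix()]) and `truth` (planted probe/gene sets and the
#'   per-sample activity values).
#' @export
simulate_array_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_control + cfg$n_case
  probe_ids <- sprintf("cg%05d", seq_len(cfg$n_probes))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_probes))
  planted <- sample.int(cfg$n_probes, cfg$n_true_hypo + cfg$n_true_hyper)
  hypo <- planted[seq_len(cfg$n_true_hypo)]
  hyper <- setdiff(planted, hypo)

  mu <- rbeta(cfg$n_probes, cfg$baseline_alpha, cfg$baseline_beta)
  mu_case <- mu
  mu_case[hypo] <- mu[hypo] - cfg$effect_size
  mu_case[hyper] <- mu[hyper] + cfg$effect_size
  clipped <- sum(mu_case[planted] < 0 | mu_case[planted] > 1)
  if (length(planted) && clipped > 0.1 * length(planted)) {
    warn(paste0(clipped, " of ", length(planted),
                " planted effects were clipped at the [0,1] boundary."))
  }
  mu_case <- pmin(pmax(mu_case, 0.001), 0.999)
  mu_ctrl <- pmin(pmax(mu, 0.001), 0.999)

  draw <- function(m, k) {
    matrix(rbeta(length(m) * k, rep(m, k) * cfg$precision,
                 rep(1 - m, k) * cfg$precision),
           nrow = length(m), ncol = k)
  }
  # per-sample disease severity scales the planted shift (cases only),
  # emulating an activity spectrum across patients
  severity <- runif(cfg$n_case, 1 - cfg$severity_spread,
                    1 + cfg$severity_spread)
  shift_vec <- mu_case - mu_ctrl
  case_vals <- vapply(seq_len(cfg$n_case), function(j) {
    mj <- pmin(pmax(mu_ctrl + severity[j] * shift_vec, 0.001), 0.999)
    rbeta(length(mj), mj * cfg$precision, (1 - mj) * cfg$precision)
  }, numeric(cfg$n_probes))
  values <- cbind(draw(mu_ctrl, cfg$n_control), case_vals)
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(cfg$n_control)),
                  sprintf("case_%02d", seq_len(cfg$n_case)))
  groups <- rep(c("control", "case"), c(cfg$n_control, cfg$n_case))
  dimnames(values) <- list(probe_ids, sample_ids)

  # deviation toward disease: hypo counts downward shifts, hyper upward
  sign_vec <- numeric(cfg$n_probes)
  sign_vec[hypo] <- -1
  sign_vec[hyper] <- 1
  dev <- if (length(planted)) {
    colMeans((values[planted, , drop = FALSE] - mu[planted]) *
               sign_vec[planted])
  } else rep(0, n)
  activity <- pmax(0, cfg$activity_slope * dev + rnorm(n, 0, 0.3))

  samples <- tibble::tibble(sample_id = sample_ids, group = groups,
                            activity = activity)
  beta <- beta_matrix(values, samples)

  shift <- numeric(cfg$n_probes)
  shift[hypo] <- cfg$expr_effect
  shift[hyper] <- -cfg$expr_effect
  expr_vals <- matrix(rnorm(cfg$n_probes * n, 0, cfg$expr_sd),
                      nrow = cfg$n_probes,
                      dimnames = list(gene_ids, sample_ids))
  expr_vals[, groups == "case"] <- expr_vals[, groups == "case"] + shift
  expr <- expr_matrix(expr_vals, samples)

  truth <- list(hypo_probes = probe_ids[hypo], hyper_probes = probe_ids[hyper],
                hypo_genes = gene_ids[hypo], hyper_genes = gene_ids[hyper],
                probe_gene = setNames(gene_ids, probe_ids),
                severity = severity,
                activity = setNames(activity, sample_ids))
  list(beta = beta, expr = expr, truth = truth)
}

# lay CpGs on n_chroms chromosomes with geometric gaps; returns tibble
lay_cpg_positions <- function(n_cpgs, n_chroms, gap_mean) {
  per <- diff(round(seq(0, n_cpgs, length.out = n_chroms + 1)))
  purrr::map2_dfr(sprintf("chr%d", seq_len(n_chroms)), per, function(ch, k) {
    gaps <- 1L + rgeom(k, 1 / gap_mean)
    tibble::tibble(chrom = ch, pos = 1000L + cumsum(gaps))
  })
}

#' Simulate a WGBS case/control cohort with planted DMRs
#'
#' CpG positions are laid on 1-3 synthetic chromosomes with geometric
#' inter-CpG gaps. Per-site baseline methylation comes from
#' `Beta(baseline_alpha, baseline_beta)`; planted DMRs are runs of
#' `dmr_width_cpgs` consecutive CpGs whose case-group methylation is
#' shifted by `effect_size` (down for hypo, up for hyper, clipped to
#' \[0, 1\]), scaled per case sample by a severity factor (uniform
#' on `1 +- severity_spread`) that also drives the activity score. Per-sample, per-site coverage is Poisson(`depth_mean`)
#' floored at 1 and methylated counts are Binomial(coverage, group pi).
#'
#' @param cfg A [sim_config()]; `n_true_hypo`/`n_true_hyper` are the planted
#'   region counts here.
#' @return A list with `tables` (list of [cpg_counts()], controls first) and
#'   `truth` (`dmr_intervals` tibble with chrom/start/end/direction, per-site
#'   group means, per-sample activity).
#' @export
simulate_wgbs_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$dmr_width_cpgs < 1) abort("`dmr_width_cpgs` must be >= 1.")
  set.seed(cfg$seed)
  sites <- lay_cpg_positions(cfg$n_cpgs, cfg$n_chroms, cfg$cpg_gap_mean)
  m <- nrow(sites)
  w <- cfg$dmr_width_cpgs
  n_reg <- cfg$n_true_hypo + cfg$n_true_hyper
  # candidate region starts: disjoint blocks of w CpGs with a w-CpG buffer,
  # never spanning a chromosome boundary
  block_start <- seq(1L, m - w + 1L, by = 2L * w)
  ok <- sites$chrom[block_start] == sites$chrom[block_start + w - 1L]
  block_start <- block_start[ok]
  if (n_reg > length(block_start)) {
    abort("Too many planted regions for the number of CpGs.")
  }
  starts <- sort(sample(block_start, n_reg))
  dir <- sample(rep(c("hypo", "hyper"), c(cfg$n_true_hypo, cfg$n_true_hyper)))

  pi0 <- rbeta(m, cfg$baseline_alpha, cfg$baseline_beta)
  pi_case <- pi0
  in_dmr <- integer(0)
  intervals <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), direction = character())
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + w - 1L)
    pi_case[idx] <- pi0[idx] + if (dir[j] == "hypo") -cfg$effect_size else
      cfg$effect_size
    in_dmr <- c(in_dmr, idx)
    intervals <- dplyr::bind_rows(intervals, tibble::tibble(
      chrom = sites$chrom[idx[1]], start = sites$pos[idx[1]],
      end = sites$pos[idx[w]], direction = dir[j]))
  }
  pi_case <- pmin(pmax(pi_case, 0), 1)
  dmr_sign <- numeric(m)
  dmr_sign[in_dmr] <- ifelse(pi_case[in_dmr] >= pi0[in_dmr], 1, -1)

  n <- cfg$n_control + cfg$n_case
  groups <- rep(c("control", "case"), c(cfg$n_control, cfg$n_case))
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(cfg$n_control)),
                  sprintf("case_%02d", seq_len(cfg$n_case)))
  tables <- vector("list", n)
  dev <- numeric(n)
  # per-patient severity scales the planted shift, giving cases a disease
  # spectrum whose activity score the diagnostic model can track
  severity <- ifelse(groups == "case",
                     runif(n, 1 - cfg$severity_spread,
                           1 + cfg$severity_spread), 0)
  for (i in seq_len(n)) {
    p <- pmin(pmax(pi0 + severity[i] * (pi_case - pi0), 0), 1)
    depth <- pmax(1L, rpois(m, cfg$depth_mean))
    x <- rbinom(m, depth, p)
    if (length(in_dmr)) {
      dev[i] <- mean((x[in_dmr] / depth[in_dmr] - pi0[in_dmr]) *
                       dmr_sign[in_dmr])
    }
    tables[[i]] <- cpg_counts(
      tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                     n_total = depth, n_meth = x),
      sample_id = sample_ids[i], group = groups[i])
  }
  activity <- pmax(0, cfg$activity_slope * dev + rnorm(n, 0, 0.3))
  for (i in seq_len(n)) tables[[i]]$activity <- activity[i]

  truth <- list(dmr_intervals = intervals, pi_control = pi0,
                pi_case = pi_case, sites = sites,
                severity = setNames(severity, sample_ids),
                activity = setNames(activity, sample_ids))
  list(tables = tables, truth = truth)
}

#' Simulate bulk methylation mixtures from a signature
#'
#' Mixes signature columns by known proportions and adds Gaussian noise,
#' clipping to \[0, 1\]: `values = sig %*% t(proportions) + noise`.
#'
#' @param sig A [signature_matrix()].
#' @param proportions Samples-by-cell-types matrix; every row must be on the
#'   probability simplex (entries >= 0, summing to 1 within 1e-8).
#' @param noise_sd Gaussian noise SD (0 for exact mixtures).
#' @param seed RNG seed.
#' @return A [beta_matrix()] of markers x samples (all labelled `control`).
#' @export
simulate_mixtures <- function(sig, proportions, noise_sd = 0, seed = 1) {
  stopifnot(inherits(sig, "signature_matrix"))
  proportions <- as.matrix(proportions)
  if (ncol(proportions) != length(sig$cell_types)) {
    abort("`proportions` must have one column per signature cell type.")
  }
  if (any(proportions < 0) ||
      any(abs(rowSums(proportions) - 1) > 1e-8)) {
    abort("Each proportion row must lie on the probability simplex.")
  }
  set.seed(seed)
  values <- sig$values %*% t(proportions)
  if (noise_sd > 0) {
    values <- values + matrix(rnorm(length(values), 0, noise_sd),
                              nrow = nrow(values))
  }
  values <- pmin(pmax(values, 0), 1)
  if (is.null(rownames(proportions))) {
    rownames(proportions) <- sprintf("mix_%02d", seq_len(nrow(proportions)))
  }
  colnames(values) <- rownames(proportions)
  rownames(values) <- sig$marker_ids
  beta_matrix(values, tibble::tibble(sample_id = colnames(values),
                                     group = "control"))
}

#' Generate a synthetic methylation signature matrix
#'
#' Each cell type gets a block of markers that are highly methylated in that
#' type (Beta(8, 2)) and lowly methylated elsewhere (Beta(2, 8)), giving a
#' well-conditioned, full-column-rank reference for deconvolution tests.
#'
#' @param n_markers Total markers (split evenly across cell types).
#' @param cell_types Character vector of cell-type names.
#' @param seed RNG seed.
#' @return A [signature_matrix()].
#' @export
synthetic_signature <- function(n_markers = 60,
                                cell_types = c("Tcell", "Bcell", "NK",
                                               "Mono", "Neutro"),
                                seed = 1) {
  set.seed(seed)
  k <- length(cell_types)
  values <- matrix(rbeta(n_markers * k, 2, 8), nrow = n_markers,
                   dimnames = list(sprintf("mk%03d", seq_len(n_markers)),
                                   cell_types))
  owner <- rep(seq_len(k), length.out = n_markers)
  values[cbind(seq_len(n_markers), owner)] <- rbeta(n_markers, 8, 2)
  signature_matrix(values)
}

#' Simulate an integrated multi-platform study
#'
#' Builds a linked synthetic world for the full pipeline: a WGBS cohort with
#' planted DMRs; a probe annotation placing probes of one gene inside each
#' planted region (plus null genes elsewhere); several array methylation
#' cohorts whose planted probes mirror the DMR directions; and several
#' expression cohorts where hypo-methylated genes are up-regulated. The
#' truth set names the genes/regions every stage should recover.
#'
#' @param cfg A [sim_config()] describing the WGBS cohort (its
#'   `n_true_hypo`/`n_true_hyper` count planted regions).
#' @param n_array_datasets,n_expr_datasets Number of array/expression
#'   cohorts to emit (consensus screening needs >= 3).
#' @param array_n_control,array_n_case Per-cohort sample sizes for the
#'   array/expression side.
#' @param n_null_genes Unplanted genes with probes outside planted regions.
#' @param probes_per_gene Probes annotated to each gene.
#' @return A list: `wgbs` (tables + truth), `ann` (probe annotation tibble),
#'   `tss` (per-gene TSS tibble), `array_cohorts`, `expr_cohorts`, `truth`.
#' @export
simulate_integrated_study <- function(cfg, n_array_datasets = 3,
                                      n_expr_datasets = 3,
                                      array_n_control = 20,
                                      array_n_case = 20,
                                      n_null_genes = 60,
                                      probes_per_gene = 3) {
  stopifnot(inherits(cfg, "sim_config"))
  wgbs <- simulate_wgbs_cohort(cfg)
  intervals <- wgbs$truth$dmr_intervals
  sites <- wgbs$truth$sites
  set.seed(cfg$seed + 1000L)

  k_reg <- nrow(intervals)
  genes <- sprintf("GENE%03d", seq_len(k_reg))
  ann_list <- purrr::map(seq_len(k_reg), function(j) {
    pos <- round(seq(intervals$start[j], intervals$end[j],
                     length.out = probes_per_gene))
    tibble::tibble(chrom = intervals$chrom[j], pos = as.integer(pos),
                   gene = genes[j], region_class = "promoter")
  })
  # null genes: runs of consecutive CpG positions outside planted regions
  in_reg <- rep(FALSE, nrow(sites))
  for (j in seq_len(k_reg)) {
    in_reg <- in_reg | (sites$chrom == intervals$chrom[j] &
                          sites$pos >= intervals$start[j] - 2000 &
                          sites$pos <= intervals$end[j] + 2000)
  }
  free_run <- which(!in_reg &
                      purrr::map_lgl(seq_len(nrow(sites)), function(s) {
                        e <- s + probes_per_gene - 1
                        e <= nrow(sites) && all(!in_reg[s:e]) &&
                          sites$chrom[s] == sites$chrom[e]
                      }))
  runs <- free_run[seq(1, length(free_run), by = probes_per_gene + 2)]
  runs <- sample(runs, min(n_null_genes, length(runs)))
  null_genes <- sprintf("NULLG%03d", seq_along(runs))
  null_ann <- purrr::map2_dfr(runs, null_genes, function(s, g) {
    idx <- s:(s + probes_per_gene - 1)
    tibble::tibble(chrom = sites$chrom[idx], pos = sites$pos[idx], gene = g,
                   region_class = sample(c("body", "intergenic"), 1))
  })
  ann <- dplyr::bind_rows(dplyr::bind_rows(ann_list), null_ann)
  ann$probe_id <- sprintf("cg%05d", seq_len(nrow(ann)))
  ann <- ann[, c("probe_id", "chrom", "pos", "gene", "region_class")]

  all_genes <- c(genes, null_genes)
  gene_dir <- setNames(c(intervals$direction, rep("null", length(null_genes))),
                       all_genes)
  tss <- dplyr::summarise(dplyr::group_by(ann, .data$gene),
                          chrom = dplyr::first(.data$chrom),
                          tss = min(.data$pos), .groups = "drop")

  probe_dir <- gene_dir[ann$gene]
  mk_cohort <- function(ds_seed) {
    set.seed(ds_seed)
    n <- array_n_control + array_n_case
    mu <- rbeta(nrow(ann), cfg$baseline_alpha, cfg$baseline_beta)
    mu_case <- mu + ifelse(probe_dir == "hypo", -cfg$effect_size,
                           ifelse(probe_dir == "hyper", cfg$effect_size, 0))
    mu_case <- pmin(pmax(mu_case, 0.001), 0.999)
    mu_ctrl <- pmin(pmax(mu, 0.001), 0.999)
    vals <- cbind(
      matrix(rbeta(nrow(ann) * array_n_control,
                   rep(mu_ctrl, array_n_control) * cfg$precision,
                   rep(1 - mu_ctrl, array_n_control) * cfg$precision),
             nrow = nrow(ann)),
      matrix(rbeta(nrow(ann) * array_n_case,
                   rep(mu_case, array_n_case) * cfg$precision,
                   rep(1 - mu_case, array_n_case) * cfg$precision),
             nrow = nrow(ann)))
    ids <- c(sprintf("c%02d", seq_len(array_n_control)),
             sprintf("p%02d", seq_len(array_n_case)))
    dimnames(vals) <- list(ann$probe_id, ids)
    beta_matrix(vals, tibble::tibble(
      sample_id = ids,
      group = rep(c("control", "case"), c(array_n_control, array_n_case))))
  }
  mk_expr <- function(ds_seed) {
    set.seed(ds_seed)
    n <- array_n_control + array_n_case
    shift <- ifelse(gene_dir == "hypo", cfg$expr_effect,
                    ifelse(gene_dir == "hyper", -cfg$expr_effect, 0))
    vals <- matrix(rnorm(length(all_genes) * n, 0, cfg$expr_sd),
                   nrow = length(all_genes),
                   dimnames = list(all_genes, c(
                     sprintf("c%02d", seq_len(array_n_control)),
                     sprintf("p%02d", seq_len(array_n_case)))))
    case_cols <- array_n_control + seq_len(array_n_case)
    vals[, case_cols] <- vals[, case_cols] + shift
    expr_matrix(vals, tibble::tibble(
      sample_id = colnames(vals),
      group = rep(c("control", "case"), c(array_n_control, array_n_case))))
  }
  array_cohorts <- purrr::map(seq_len(n_array_datasets),
                              function(i) mk_cohort(cfg$seed + 2000L + i))
  expr_cohorts <- purrr::map(seq_len(n_expr_datasets),
                             function(i) mk_expr(cfg$seed + 3000L + i))

  truth <- list(model_genes = genes, null_genes = null_genes,
                dmr_intervals = intervals,
                gene_direction = gene_dir,
                activity = wgbs$truth$activity)
  list(wgbs = wgbs, ann = ann, tss = tss, array_cohorts = array_cohorts,
       expr_cohorts = expr_cohorts, truth = truth)
}
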