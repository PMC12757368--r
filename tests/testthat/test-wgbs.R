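test_that("window smoothing pools neighbours and respects its limits", {
  # two CpGs 10 bp apart, fractions 0/1, equal depth -> both smoothed to 0.5
  t1 <- mk_counts(c(100, 110), c(10, 10), c(0, 10))
  sm <- smooth_methylation(t1, window_bp = 500)
  expect_equal(sm$frac_smooth, c(0.5, 0.5))
  # window 0 -> raw fractions
  sm0 <- smooth_methylation(t1, window_bp = 0)
  expect_equal(sm0$frac_smooth, c(0, 1))
  # isolated CpG keeps its raw fraction
  t2 <- mk_counts(c(100, 5000), c(10, 20), c(3, 10))
  sm2 <- smooth_methylation(t2, window_bp = 500)
  expect_equal(sm2$frac_smooth, c(0.3, 0.5))
  # smoothing never crosses chromosomes
  t3 <- cpg_counts(tibble::tibble(chrom = c("chr1", "chr2"),
                                  pos = c(100L, 120L),
                                  n_total = c(10L, 10L),
                                  n_meth = c(0L, 10L)), "s", "control")
  sm3 <- smooth_methylation(t3, window_bp = 500)
  expect_equal(sm3$frac_smooth, c(0, 1))
})

test_that("identical case and control tables give delta 0 and p 1 everywhere", {
  t1 <- mk_counts(seq(100, 2000, by = 100), rep(20, 20),
                  rbinom(20, 20, 0.4))
  rec <- bb_wald_test(list(t1), list(t1))
  expect_equal(rec$delta, rep(0, nrow(rec)))
  expect_equal(rec$p_value, rep(1, nrow(rec)))
})

test_that("the Wald test matches the two-proportion z-test in the large-depth limit", {
  pos <- seq(1000, 16000, by = 3000)  # isolated: no smoothing interaction
  x1 <- c(3000L, 5000L, 7000L, 4500L, 1000L, 9000L)
  x2 <- c(3300L, 5400L, 6800L, 4450L, 1100L, 8800L)
  ctrl <- mk_counts(pos, rep(10000, 6), x1)
  case <- mk_counts(pos, rep(10000, 6), x2, sample_id = "s2", group = "case")
  rec <- bb_wald_test(list(case), list(ctrl))
  p1 <- x1 / 1e4; p2 <- x2 / 1e4
  z <- (p2 - p1) / sqrt(p1 * (1 - p1) / 1e4 + p2 * (1 - p2) / 1e4)
  expect_equal(rec$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-3)
  expect_equal(rec$delta, p2 - p1, tolerance = 1e-6)
})

test_that("sites covered in only one group are skipped, none -> empty with warning", {
  ctrl <- mk_counts(c(100, 200), c(10, 10), c(5, 5))
  case <- mk_counts(c(300, 400), c(10, 10), c(5, 5),
                    sample_id = "s2", group = "case")
  expect_warning(rec <- bb_wald_test(list(case), list(ctrl)), "covered")
  expect_equal(nrow(rec), 0)
  case2 <- mk_counts(c(200, 300), c(10, 10), c(5, 5),
                     sample_id = "s2", group = "case")
  rec2 <- bb_wald_test(list(case2), list(ctrl))
  expect_equal(rec2$pos, 200L)
})

test_that("the null false-positive rate stays near the nominal 1% level", {
  fpr <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_control = 3, n_case = 3, n_cpgs = 500,
                      n_true_hypo = 0, n_true_hyper = 0, effect_size = 0,
                      depth_mean = 30)
    w <- simulate_wgbs_cohort(cfg)
    grp <- vapply(w$tables, function(t) t$group, "")
    rec <- bb_wald_test(w$tables[grp == "case"], w$tables[grp == "control"])
    mean(rec$p_value < 0.01)
  }, numeric(1))
  expect_lt(abs(mean(fpr) - 0.01), 0.01)
})

test_that("DMP filtering applies both significance and effect thresholds", {
  rec <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L, 3L),
                        pi_case = c(0.8, 0.6, 0.9),
                        pi_control = c(0.55, 0.45, 0.4),
                        delta = c(0.25, 0.15, 0.5),
                        wald_stat = 3, p_value = c(0.005, 0.005, 0.02),
                        phi = 0)
  kept <- call_dmps(rec)
  expect_equal(kept$pos, 1L)
  expect_equal(kept$direction, "hyper")
})

test_that("DMR merging respects gaps, direction runs and the member minimum", {
  mk_dmps <- function(pos, delta, p = 1e-6) {
    tibble::tibble(chrom = "chr1", pos = as.integer(pos),
                   pi_case = 0.5 + delta / 2, pi_control = 0.5 - delta / 2,
                   delta = delta, wald_stat = sign(delta) * 6, p_value = p,
                   phi = 0, direction = ifelse(delta > 0, "hyper", "hypo"))
  }
  # 7 hypo DMPs spaced 100 bp -> one DMR with 7 members
  d1 <- mk_dmps(seq(1000, 1600, by = 100), -0.3)
  r1 <- call_dmrs(d1)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$n_dmps, 7L)
  expect_equal(r1$direction, "hypo")
  expect_equal(c(r1$start, r1$end), c(1000L, 1600L))
  expect_lt(r1$region_p, 0.05)

  # a 5 kb gap after the third DMP splits the run; both fragments < 6
  d2 <- mk_dmps(c(1000, 1100, 1200, 6200, 6300, 6400, 6500), -0.3)
  expect_equal(nrow(call_dmrs(d2)), 0)

  # alternating directions never form a region
  d3 <- mk_dmps(seq(1000, 1700, by = 100), rep(c(0.3, -0.3), 4))
  expect_equal(nrow(call_dmrs(d3)), 0)

  # chromosomes are processed independently and order cannot matter
  d4 <- dplyr::bind_rows(mk_dmps(seq(1000, 1600, 100), 0.3),
                         dplyr::mutate(mk_dmps(seq(1000, 1600, 100), -0.3),
                                       chrom = "chr0"))
  r4 <- call_dmrs(d4)
  expect_equal(r4$chrom, c("chr0", "chr1"))
  r4b <- call_dmrs(d4[sample(nrow(d4)), ])
  expect_equal(r4, r4b)
})

test_that("subsample augmentation reproduces the 21/60 bookkeeping", {
  cfg <- sim_config(seed = 8, n_control = 3, n_case = 3, n_cpgs = 50,
                    n_true_hypo = 1, n_true_hyper = 1)
  w <- simulate_wgbs_cohort(cfg)
  subs <- augment_subsamples(w$tables, reps_control = 7, reps_case = 20,
                             thin_fraction = 0.5, seed = 1)
  grp <- vapply(subs, function(t) t$group, "")
  expect_equal(sum(grp == "control"), 21)
  expect_equal(sum(grp == "case"), 60)
  expect_equal(length(subs), 81)
})

test_that("augmentation is deterministic, identity at thin 1, unbiased in coverage", {
  t1 <- mk_counts(seq(100, 5000, by = 100), rep(30, 50),
                  rbinom(50, 30, 0.5))
  s1 <- augment_subsamples(list(t1), reps_control = 3, thin_fraction = 0.5,
                           seed = 42)
  s2 <- augment_subsamples(list(t1), reps_control = 3, thin_fraction = 0.5,
                           seed = 42)
  expect_identical(s1[[2]]$sites, s2[[2]]$sites)

  full <- augment_subsamples(list(t1), reps_control = 2, thin_fraction = 1,
                             seed = 1)
  expect_equal(full[[1]]$sites, t1$sites)
  expect_equal(full[[2]]$sites, t1$sites)

  # expected coverage = thin_fraction * parent coverage (within 5%)
  many <- augment_subsamples(list(t1), reps_control = 40,
                             thin_fraction = 0.5, seed = 3)
  mean_cov <- mean(vapply(many, function(t) mean(t$sites$n_total),
                          numeric(1)))
  expect_lt(abs(mean_cov - 0.5 * mean(t1$sites$n_total)) /
              (0.5 * mean(t1$sites$n_total)), 0.05)
  expect_error(augment_subsamples(list(), seed = 1), "empty")
  expect_error(augment_subsamples(list(t1), thin_fraction = 0), "thin")
})

test_that("planted DMRs are recovered end-to-end with correct directions", {
  res <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_control = 3, n_case = 3, n_cpgs = 800,
                      n_true_hypo = 4, n_true_hyper = 2, effect_size = 0.4,
                      depth_mean = 30, severity_spread = 0)
    w <- simulate_wgbs_cohort(cfg)
    grp <- vapply(w$tables, function(t) t$group, "")
    rec <- bb_wald_test(w$tables[grp == "case"], w$tables[grp == "control"])
    dmrs <- call_dmrs(call_dmps(rec))
    tr <- w$truth$dmr_intervals
    hit <- vapply(seq_len(nrow(tr)), function(i) {
      any(dmrs$chrom == tr$chrom[i] & dmrs$start <= tr$end[i] &
            dmrs$end >= tr$start[i] & dmrs$direction == tr$direction[i])
    }, logical(1))
    mean(hit)
  }, numeric(1))
  expect_gte(mean(res), 0.9)
})

test_that("DMP results are invariant to sample order within groups", {
  cfg <- sim_config(seed = 17, n_control = 3, n_case = 3, n_cpgs = 300,
                    n_true_hypo = 2, n_true_hyper = 1, effect_size = 0.4)
  w <- simulate_wgbs_cohort(cfg)
  grp <- vapply(w$tables, function(t) t$group, "")
  cases <- w$tables[grp == "case"]; ctrls <- w$tables[grp == "control"]
  r1 <- bb_wald_test(cases, ctrls)
  r2 <- bb_wald_test(rev(cases), rev(ctrls))
  expect_equal(r1, r2)
})
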