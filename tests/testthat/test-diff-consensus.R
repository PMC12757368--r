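test_that("imputation is the identity without missing values and copies nearest neighbours", {
  set.seed(3)
  v <- matrix(runif(40), 8)
  b <- mk_beta(v)
  expect_equal(impute_missing(b, k = 2)$values, b$values)

  # single missing cell, k = 1: value comes from the nearest complete probe
  v2 <- v
  v2[1, 3] <- NA
  b2 <- mk_beta(v2)
  imp <- impute_missing(b2, k = 1)
  obs <- !is.na(v2[1, ])
  d <- apply(v[-1, , drop = FALSE], 1,
             function(r) sqrt(mean((r[obs] - v2[1, obs])^2)))
  nearest <- (2:8)[which.min(d)]
  expect_equal(unname(imp$values[1, 3]), v[nearest, 3])
  expect_false(anyNA(imp$values))

  # all-missing probe dropped with a warning
  v3 <- v
  v3[2, ] <- NA
  expect_warning(imp3 <- impute_missing(mk_beta(v3), k = 1), "Dropping 1")
  expect_equal(nrow(imp3$values), 7)

  expect_error(impute_missing(b2, k = 10), "smaller")
})

test_that("moderated t reduces to the classical pooled t at zero prior df", {
  m <- mk_null_expr(50, 5, seed = 11)
  st <- moderated_t_test(m, prior_df = 0)
  grp <- m$samples$group
  for (i in c(1, 17, 50)) {
    ht <- t.test(m$values[i, grp == "case"], m$values[i, grp == "control"],
                 var.equal = TRUE)
    expect_equal(st$t_stat[i], unname(ht$statistic), tolerance = 1e-8)
    expect_equal(st$p_value[i], ht$p.value, tolerance = 1e-8)
  }
})

test_that("moderated t is antisymmetric under group swap and flags constants", {
  m <- mk_null_expr(30, 4, seed = 2)
  st <- moderated_t_test(m)
  swapped <- m
  swapped$samples$group <- ifelse(m$samples$group == "case",
                                  "control", "case")
  st2 <- moderated_t_test(swapped)
  expect_equal(st2$t_stat, -st$t_stat)
  expect_equal(st2$p_value, st$p_value)

  v <- matrix(1, 3, 6, dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  v[2, ] <- rnorm(6)
  cm <- mk_expr(v)
  stc <- moderated_t_test(cm)
  expect_true(stc$constant[1])
  expect_equal(stc$p_value[1], 1)
})

test_that("moderated t agrees with limma's moderated statistics on shared data", {
  skip_if_not_installed("limma")
  m <- mk_null_expr(200, 6, seed = 21)
  st <- moderated_t_test(m)
  design <- cbind(1, m$samples$group == "case")
  fit <- limma::eBayes(limma::lmFit(m$values, design))
  # same shrinkage family, different prior estimator: rankings must agree
  expect_gt(cor(st$t_stat, fit$t[, 2]), 0.99)
})

test_that("moderated t holds its nominal type-I error on null data", {
  fpr <- vapply(1:20, function(s) {
    mean(moderated_t_test(mk_null_expr(200, 5, seed = s))$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fpr) - 0.05), 0.03)
})

test_that("DEG selection filters then caps with deterministic tie-breaks", {
  st <- tibble::tibble(
    feature_id = c("a", "b", "c", "d", "e"),
    delta = c(1, 1, -1, 1, -1),
    t_stat = c(5, 3, -4, 2, -0.5),
    p_value = c(0.01, 0.01, 0.002, 0.03, 0.4),
    sd_case = 0.1, sd_control = 0.1,
    direction = c("up", "up", "down", "up", "down"))
  sel <- select_degs(st, p_max = 0.05, top_n = 1000)
  expect_equal(sel$up, c("a", "b", "d"))   # equal p: |t| breaks the tie
  expect_equal(sel$down, "c")
  sel2 <- select_degs(st, p_max = 0.05, top_n = 2)
  expect_equal(sel2$up, c("a", "b"))
  expect_equal(select_degs(dplyr::mutate(st, p_value = 0.9))$up,
               character(0))
})

test_that("DMP selection applies the effect and group-SD criteria", {
  row <- function(id, delta, sdc, sdt) {
    tibble::tibble(feature_id = id, delta = delta, t_stat = delta * 10,
                   p_value = 0.001, sd_control = sdc, sd_case = sdt,
                   direction = ifelse(delta > 0, "up", "down"))
  }
  st <- dplyr::bind_rows(
    row("keep_hyper", 0.15, 0.10, 0.20),
    row("small_delta", 0.05, 0.01, 0.01),
    row("noisy_control", 0.30, 0.25, 0.10),
    row("noisy_case", 0.30, 0.10, 0.35),
    row("keep_hypo", -0.40, 0.19, 0.29))
  sel <- select_dmps(st)
  expect_equal(sel$hyper, "keep_hyper")
  expect_equal(sel$hypo, "keep_hypo")
  # literal small-difference reading retained behind delta_rule
  sel_lit <- select_dmps(st, delta_rule = "max")
  expect_true("small_delta" %in% sel_lit$hyper)
  expect_false("keep_hypo" %in% sel_lit$hypo)
})

test_that("DMP selection is invariant to sample column order", {
  cfg <- sim_config(seed = 13, n_control = 8, n_case = 8, n_probes = 300,
                    n_true_hypo = 20, n_true_hyper = 10)
  sim <- suppressWarnings(simulate_array_cohort(cfg))
  perm <- sample(ncol(sim$beta$values))
  shuffled <- beta_matrix(sim$beta$values[, perm],
                          sim$beta$samples[perm, ])
  expect_equal(select_dmps(moderated_t_test(sim$beta)),
               select_dmps(moderated_t_test(shuffled)))
})

test_that("consensus selection needs agreement in direction across datasets", {
  sel <- list(
    list(up = c("a", "b", "x"), down = c("c")),
    list(up = c("a", "x"), down = c("c", "b")),
    list(up = c("a", "x"), down = c("c")),
    list(up = character(0), down = c("x", "b")),
    list(up = c("b"), down = character(0)))
  cons <- consensus_features(sel, min_datasets = 3)
  a <- cons[cons$feature_id == "a", ]
  expect_true(a$selected)
  expect_equal(a$direction, "up")
  # up in 3 but also down once -> conflicting, never selected
  x <- cons[cons$feature_id == "x", ]
  expect_false(x$selected)
  expect_true(x$conflicting)
  b <- cons[cons$feature_id == "b", ]
  expect_false(b$selected)
  expect_error(consensus_features(sel[1:2], min_datasets = 3), "exceeds")
  # single dataset, min 1: selection is that dataset's selection
  cons1 <- consensus_features(sel[3], min_datasets = 1)
  expect_setequal(cons1$feature_id[cons1$selected & cons1$direction == "up"],
                  c("a", "x"))
})

test_that("consensus is invariant to dataset order", {
  sel <- list(list(up = c("a", "b"), down = "c"),
              list(up = "a", down = c("c", "d")),
              list(up = c("a", "d"), down = "c"))
  c1 <- consensus_features(sel, 3)
  c2 <- consensus_features(rev(sel), 3)
  expect_equal(c1, c2)
})

test_that("probe-to-gene mapping deduplicates and drops unannotated probes", {
  ann <- tibble::tibble(probe_id = c("p1", "p2", "p3", "p4"),
                        chrom = "chr1", pos = 1:4 * 100L,
                        gene = c("G1", "G1", "", "G2"),
                        region_class = "promoter")
  expect_message(g <- map_probes_to_genes(c("p1", "p2", "p3"), ann),
                 "1 probe")
  expect_equal(g, "G1")
  expect_equal(suppressMessages(
    map_probes_to_genes(c("p1", "p4"), ann)), c("G1", "G2"))
})

test_that("planted probes are recovered with high precision and recall", {
  res <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, n_control = 20, n_case = 20,
                      n_probes = 2000, n_true_hypo = 120, n_true_hyper = 80,
                      effect_size = 0.3, severity_spread = 0)
    sim <- suppressWarnings(simulate_array_cohort(cfg))
    sel <- select_dmps(moderated_t_test(sim$beta))
    called <- c(sel$hyper, sel$hypo)
    truth <- c(sim$truth$hypo_probes, sim$truth$hyper_probes)
    good <- c(intersect(sel$hyper, sim$truth$hyper_probes),
              intersect(sel$hypo, sim$truth$hypo_probes))
    c(recall = length(good) / length(truth),
      precision = length(good) / length(called))
  }, numeric(2))
  expect_gte(mean(res["recall", ]), 0.9)
  expect_gte(mean(res["precision", ]), 0.9)
})
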