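test_that("deconvolution recovers pure samples and exact mixtures", {
  sig <- synthetic_signature(n_markers = 40,
                             cell_types = c("A", "B", "C", "D"))
  pure <- simulate_mixtures(sig, diag(4), noise_sd = 0)
  est <- deconvolve(pure, sig)
  expect_equal(unname(as.matrix(est[, c("A", "B", "C", "D")])),
               diag(4), tolerance = 1e-8)
  mix <- simulate_mixtures(sig, matrix(c(0.3, 0.7, 0, 0), 1), noise_sd = 0)
  est2 <- deconvolve(mix, sig)
  expect_equal(unname(as.matrix(est2[, c("A", "B", "C", "D")])),
               matrix(c(0.3, 0.7, 0, 0), 1), tolerance = 1e-6)
})

test_that("deconvolution stays on the simplex and permutes with samples", {
  sig <- synthetic_signature()
  set.seed(12)
  P <- t(apply(matrix(rexp(8 * 5), 8), 1, function(x) x / sum(x)))
  mix <- simulate_mixtures(sig, P, noise_sd = 0.05, seed = 4)
  est <- deconvolve(mix, sig)
  props <- as.matrix(est[, sig$cell_types])
  expect_true(all(props >= 0))
  expect_equal(unname(rowSums(props)), rep(1, 8), tolerance = 1e-6)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  mixp <- beta_matrix(mix$values[, perm], mix$samples[perm, ])
  estp <- deconvolve(mixp, sig)
  expect_equal(estp$sample_id, est$sample_id[perm])
  expect_equal(as.matrix(estp[, sig$cell_types]), props[perm, ],
               ignore_attr = TRUE)
})

test_that("deconvolution recovers noisy mixtures within RMSE 0.05", {
  sig <- synthetic_signature()
  rmse <- vapply(1:20, function(s) {
    set.seed(s)
    P <- t(apply(matrix(rexp(10 * 5), 10), 1, function(x) x / sum(x)))
    mix <- simulate_mixtures(sig, P, noise_sd = 0.02, seed = s + 500)
    est <- deconvolve(mix, sig)
    sqrt(mean((as.matrix(est[, sig$cell_types]) - P)^2))
  }, numeric(1))
  expect_lt(mean(rmse), 0.05)
})

test_that("deconvolution rejects rank-deficient or marker-poor signatures", {
  v <- matrix(runif(10), 5, 2, dimnames = list(sprintf("m%d", 1:5),
                                               c("A", "B")))
  v[, 2] <- v[, 1]
  expect_error(deconvolve(
    mk_beta(matrix(0.5, 5, 2, dimnames = list(rownames(v), c("s1", "s2"))),
            groups = rep("control", 2)),
    signature_matrix(v)), "rank")
})

test_that("ssGSEA scores follow the ranking: top sets positive, bottom negative", {
  v <- matrix(rep(10:1, 2), ncol = 2,
              dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2")))
  e <- mk_expr(v, groups = c("control", "case"))
  sets <- list(top = sprintf("g%02d", 1:5), bottom = sprintf("g%02d", 6:10))
  sc <- ssgsea(e, sets, normalize = FALSE)
  expect_gt(sc$score[sc$set == "top" & sc$sample_id == "s1"], 0)
  expect_lt(sc$score[sc$set == "bottom" & sc$sample_id == "s1"], 0)
})

test_that("constant expression degenerates to a zero ssGSEA score", {
  v <- matrix(1, 10, 1, dimnames = list(sprintf("g%02d", 1:10), "s1"))
  e <- mk_expr(v, groups = "control")
  sc <- ssgsea(e, list(s = sprintf("g%02d", c(2, 5, 9))), normalize = FALSE)
  expect_equal(sc$score, 0)
})

test_that("ssGSEA matches the brute-force running-sum computation", {
  set.seed(14)
  v <- matrix(rnorm(10), 10, 1, dimnames = list(sprintf("g%02d", 1:10), "s1"))
  e <- mk_expr(v, groups = "control")
  set_genes <- sprintf("g%02d", c(1, 4, 7))
  sc <- ssgsea(e, list(s = set_genes), alpha = 0.25, normalize = FALSE)
  # brute force: walk the descending-expression list, accumulate ECDFs
  ord <- order(v[, 1], decreasing = TRUE)
  genes <- rownames(v)[ord]
  w <- rank(v[, 1])[ord]^0.25
  in_set <- genes %in% set_genes
  p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
  p_out <- cumsum(!in_set) / sum(!in_set)
  expect_equal(sc$score, sum(p_in - p_out))
})

test_that("ssGSEA is invariant under monotone transforms and warns on tiny sets", {
  set.seed(15)
  v <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("g%02d", 1:20), c("s1", "s2")))
  e1 <- mk_expr(v, groups = c("control", "case"))
  e2 <- mk_expr(exp(v), groups = c("control", "case"))
  sets <- list(s = sprintf("g%02d", c(2, 3, 11, 17)))
  expect_equal(ssgsea(e1, sets, normalize = FALSE),
               ssgsea(e2, sets, normalize = FALSE))
  expect_warning(sc <- ssgsea(e1, list(tiny = c("g01", "nope"))), "<2")
  expect_true(all(is.na(sc$score)))
})

test_that("hypergeometric ORA matches exact enumeration on a small universe", {
  universe <- sprintf("u%02d", 1:20)
  annotation <- list(setA = universe[1:5], setB = universe[6:15])
  hits <- universe[c(1:4, 18)]
  res <- ora_hypergeometric(hits, universe, annotation)
  # oracle: sum hypergeometric point masses for counts >= observed
  p_exact <- function(set) {
    K <- length(set)
    k_obs <- length(intersect(hits, set))
    sum(vapply(k_obs:min(K, 5), function(k) {
      choose(K, k) * choose(20 - K, 5 - k) / choose(20, 5)
    }, numeric(1)))
  }
  expect_equal(res$p_value[res$set == "setA"], p_exact(annotation$setA),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "setB"], p_exact(annotation$setB),
               tolerance = 1e-12)
  expect_lt(res$p_value[res$set == "setA"], res$p_value[res$set == "setB"])
  expect_error(ora_hypergeometric(character(0), universe, annotation),
               "hits")
})

test_that("an overlap at its expected count is unremarkable", {
  universe <- sprintf("u%03d", 1:100)
  annotation <- list(s = universe[1:20])   # expect 20% of hits inside
  hits <- c(universe[1:2], universe[50:57])   # 2 of 10, exactly expected
  res <- ora_hypergeometric(hits, universe, annotation)
  expect_gt(res$p_value, 0.5)
})

test_that("pre-ranked GSEA: sign, hand-computed ES, null uniformity", {
  ranking <- setNames(c(4, 3, 2.5, 2, 1, -1, -2, -2.5), sprintf("g%d", 1:8))
  res <- gsea_preranked(ranking, list(top = c("g1", "g2", "g3")),
                        n_perm = 200, seed = 1)
  expect_gt(res$es, 0.9)
  # hand-computed weighted KS running sum for an 8-gene toy
  set_genes <- c("g2", "g5", "g7")
  in_set <- names(ranking) %in% set_genes
  w <- abs(ranking)
  inc <- ifelse(in_set, w / sum(w[in_set]), -1 / 5)
  running <- cumsum(inc)
  es_hand <- running[which.max(abs(running))]
  res2 <- gsea_preranked(ranking, list(s = set_genes), n_perm = 100,
                         seed = 2)
  expect_equal(res2$es, es_hand)
})

test_that("pre-ranked GSEA agrees with the fgsea enrichment statistic", {
  skip_if_not_installed("fgsea")
  set.seed(16)
  ranking <- sort(setNames(rnorm(50), sprintf("g%02d", 1:50)),
                  decreasing = TRUE)
  set_genes <- sample(names(ranking), 8)
  got <- gsea_preranked(ranking, list(s = set_genes), n_perm = 10, seed = 1)
  oracle <- fgsea::calcGseaStat(ranking,
                                which(names(ranking) %in% set_genes),
                                gseaParam = 1)
  expect_equal(got$es, oracle, tolerance = 1e-8)
})

test_that("random sets on a null ranking give roughly uniform GSEA p-values", {
  set.seed(17)
  ranking <- setNames(rnorm(60), sprintf("g%02d", 1:60))
  hits <- vapply(1:200, function(i) {
    g <- sample(names(ranking), 6)
    gsea_preranked(ranking, list(s = g), n_perm = 99,
                   seed = i)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.05)
})
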