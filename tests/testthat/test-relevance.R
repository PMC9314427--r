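# KL sensitivity analysis, evaluation metrics, validation-ligand split and
# feature-count optimization.

test_that("relevance scores normalize and ignore irrelevant features", {
  set.seed(11)
  x <- matrix(rnorm(160), 80, 2)
  y <- sin(2 * x[, 1]) + rnorm(80, 0, 0.05)
  m <- quick_fit(x, y)
  rel <- feature_relevance_kl(m)
  expect_equal(sum(rel$relevance), 1, tolerance = 1e-12)
  expect_true(all(rel$relevance >= 0))
  expect_equal(sort(rel$rank), 1:2)

  # manually inflating a length scale to 1e9 kills that feature's relevance
  m2 <- m
  m2$lengthscales[2] <- 1e9
  m2 <- stabcast:::.gpr_refit_subset(m2, seq_len(nrow(m$x)))
  rel2 <- feature_relevance_kl(m2)
  expect_lt(rel2$relevance[rel2$feature == "x2"], 1e-6)
})

test_that("relevance strictly decreases as a length scale is inflated", {
  set.seed(12)
  x <- matrix(rnorm(200), 100, 2)
  y <- x[, 1] + 0.8 * x[, 2] + rnorm(100, 0, 0.05)
  m <- quick_fit(x, y)
  vals <- vapply(c(1, 4, 16, 64), function(f) {
    m2 <- m
    m2$lengthscales[2] <- m$lengthscales[2] * f
    m2 <- stabcast:::.gpr_refit_subset(m2, seq_len(nrow(m$x)))
    rel <- feature_relevance_kl(m2)
    rel$relevance[rel$feature == "x2"]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("planted active features are recovered by the relevance ranking", {
  hits <- 0
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 140; d <- 8
    x <- matrix(rnorm(n * d), n, d)
    y <- 1.2 * sin(2 * x[, 1]) + x[, 2] - 0.8 * x[, 3]^2 + rnorm(n, 0, 0.1)
    m <- fit_gpr(x, y, restarts = 2, seed = s, maxit = 80)
    rel <- feature_relevance_kl(m)
    if (setequal(rel$feature[1:3], c("x1", "x2", "x3"))) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("permuting a feature column drives its relevance to the noise floor", {
  set.seed(13)
  n <- 150; d <- 6
  x <- matrix(rnorm(n * d), n, d)
  y <- sin(2 * x[, 1]) + x[, 2] + 0.9 * x[, 3] + rnorm(n, 0, 0.25)
  xp <- x
  xp[, 3] <- sample(xp[, 3])     # break the relationship, keep the marginal
  m <- fit_gpr(xp, y, restarts = 2, seed = 1, maxit = 80)
  rel <- feature_relevance_kl(m)
  floor_rel <- min(rel$relevance[rel$feature %in% c("x4", "x5", "x6")])
  expect_lt(rel$relevance[rel$feature == "x3"], 2 * max(floor_rel, 1e-6))
})

test_that("evaluation metrics match hand computations", {
  expect_equal(evaluate_predictions(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(mae = 0, rsq = 1))
  y <- c(2, 4, 9, 1)
  expect_equal(evaluate_predictions(y, rep(mean(y), 4))$rsq, 0)
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(ev$mae, 1 / 3)
  expect_equal(ev$rsq, 0.5)
  expect_error(evaluate_predictions(c(2, 2, 2), c(1, 2, 3)),
               regexp = "zero variance")
})

test_that("validation-ligand selection honors contract, determinism and strata", {
  recs <- small_synth()
  lig_tbl <- small_ligand_tbl(recs)
  sel <- select_validation_ligands(lig_tbl, count = 20, seed = 5)
  expect_length(sel, 20)
  expect_true(all(sel %in% lig_tbl$smiles))
  expect_equal(anyDuplicated(sel), 0)
  # determinism
  sel2 <- select_validation_ligands(lig_tbl, count = 20, seed = 5)
  expect_identical(as.character(sel), as.character(sel2))
  # the emitted distances confirm coverage of the far strata: at least 4
  # picks from the top quintile, and the top decile is represented
  strata <- attr(sel, "strata")
  picked <- strata[strata$smiles %in% sel, ]
  expect_gte(sum(picked$stratum == 5), 4)
  top_decile <- stats::quantile(strata$distance, 0.9)
  expect_true(any(picked$distance >= top_decile))
  # every stratum is represented
  expect_setequal(unique(picked$stratum), 1:5)
  expect_error(select_validation_ligands(lig_tbl, count = nrow(lig_tbl)),
               regexp = "smaller")
})

test_that("feature-count optimization follows the relevance order", {
  set.seed(14)
  n <- 90
  x <- matrix(rnorm(n * 6), n, 6)
  colnames(x) <- paste0("f", 1:6)
  y <- x[, 1] + 0.8 * x[, 2] + rnorm(n, 0, 0.1)
  tr <- 1:60; va <- 61:90
  m <- quick_fit(x[tr, ], y[tr])
  rel <- feature_relevance_kl(m)
  fc <- optimize_feature_count(x[tr, ], y[tr], rel, x[va, ], y[va],
                               restarts = 1, seed = 0, maxit = 50)
  # one curve entry per evaluated k, metrics present where the fit worked
  expect_equal(fc$curve$k, sort(unique(fc$curve$k)))
  expect_true(all(c("mae", "rsq", "failed") %in% names(fc$curve)))
  expect_true(all(is.finite(fc$curve$mae[!fc$curve$failed])))
  # the two active features suffice: best k stays small
  expect_lte(fc$best_k, 4)
  expect_gte(fc$best_k, 2)

  # single-feature edge case
  x1 <- x[, 1, drop = FALSE]
  fc1 <- optimize_feature_count(x1[tr, , drop = FALSE], y[tr], "f1",
                                x1[va, , drop = FALSE], y[va],
                                restarts = 1, seed = 0, maxit = 30)
  expect_equal(fc1$best_k, 1)
})
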