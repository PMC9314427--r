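# The beta_1 -> beta_n cascade, the universal inequality, and the
# predicted-beta_1 / beta_n correlation analysis.

cascade_fixture <- function() {
  cached("cascade_fixture", {
    recs <- small_synth()
    lig_tbl <- small_ligand_tbl(recs)
    model <- fit_cascade(recs, ligand_tbl = lig_tbl,
                         config = cascade_config(restarts = 2, seed = 0,
                                                 maxit = 60))
    list(recs = recs, lig_tbl = lig_tbl, model = model)
  })
}

test_that("beta_n descriptor carries the four cascade features exactly once", {
  fx <- cascade_fixture()
  nn <- dplyr::filter(fx$recs, n >= 2)
  dt <- assemble_betan_descriptor(nn, fx$model$beta1_model,
                                  ligand_tbl = fx$lig_tbl)
  cascade_cols <- names(dt$provenance)[dt$provenance == "cascade"]
  expect_setequal(cascade_cols, c("pred_beta1", "pred_beta1_std",
                                  "complex_charge", "n_minus_1"))
  # complex charge = cation charge + ligand molecular charge, n-1 arithmetic
  expect_equal(dt$features$complex_charge, nn$charge + nn$ligand_charge)
  expect_equal(dt$features$n_minus_1, as.numeric(nn$n - 1))
  # same (M, L) at different n: identical predicted-beta_1 features
  key <- paste(nn$cation, nn$charge, nn$smiles)
  dupkey <- key[duplicated(key)][1]
  idx <- which(key == dupkey)
  expect_equal(dt$features$pred_beta1[idx[1]], dt$features$pred_beta1[idx[2]])
  expect_equal(dt$features$pred_beta1_std[idx[1]],
               dt$features$pred_beta1_std[idx[2]])
  # n = 1 records are rejected
  expect_error(
    assemble_betan_descriptor(dplyr::filter(fx$recs, n == 1)[1, ],
                              fx$model$beta1_model, ligand_tbl = fx$lig_tbl),
    regexp = "n = 1")
})

test_that("cascade predicts pairs whose (M, L) never appears with n = 1", {
  fx <- cascade_fixture()
  # fabricate a beta_n query for a pair absent from the n = 1 stratum
  n1 <- dplyr::filter(fx$recs, n == 1)
  probe <- dplyr::filter(fx$recs, n >= 2)[1, ]
  probe$cation <- "Ni"; probe$charge <- 2
  probe$smiles <- fx$lig_tbl$smiles[1]
  stopifnot(!any(n1$cation == probe$cation & n1$smiles == probe$smiles))
  pred <- predict(fx$model, probe)
  expect_true(is.finite(pred$.pred))
  expect_gt(pred$.pred_std, 0)
})

test_that("cascade fitting requires both strata and is deterministic", {
  fx <- cascade_fixture()
  expect_error(fit_cascade(dplyr::filter(fx$recs, n == 1),
                           ligand_tbl = fx$lig_tbl),
               regexp = "n >= 2")
  expect_error(fit_cascade(dplyr::filter(fx$recs, n >= 2),
                           ligand_tbl = fx$lig_tbl),
               regexp = "n = 1")
  sub <- dplyr::bind_rows(
    head(dplyr::filter(fx$recs, n == 1), 60),
    head(dplyr::filter(fx$recs, n >= 2), 40)
  )
  cfg <- cascade_config(restarts = 1, seed = 2, maxit = 40)
  m1 <- fit_cascade(sub, ligand_tbl = fx$lig_tbl, config = cfg)
  m2 <- fit_cascade(sub, ligand_tbl = fx$lig_tbl, config = cfg)
  expect_identical(m1$beta1_model$lengthscales, m2$beta1_model$lengthscales)
  expect_identical(m1$betan_model$lengthscales, m2$betan_model$lengthscales)
})

test_that("check_inequality flags exactly the violating relations", {
  # consistent family: 5 < 8 < 2 * 5
  expect_equal(nrow(check_inequality(5, c(`2` = 8))), 0)
  # upper-bound violation: 7 >= 2 * 3
  v <- check_inequality(3, c(`2` = 7))
  expect_equal(v$type, "upper_bound")
  expect_equal(v$n, 2L)
  # monotonicity violation: beta_3 <= beta_2
  v2 <- check_inequality(5, c(`2` = 9, `3` = 8))
  expect_true("monotonicity" %in% v2$type)
  expect_equal(v2$n[v2$type == "monotonicity"], 3L)
  # boundary: beta_n = n beta_1 exactly is a violation (strict inequality)
  expect_equal(check_inequality(4, c(`2` = 8))$type, "upper_bound")
})

test_that("record-level inequality check works with duplicated orders", {
  recs <- dplyr::bind_rows(
    record_row(n = 1, beta = 6),
    record_row(n = 2, beta = 10, temp_c = 30),
    record_row(n = 2, beta = 9.5),
    record_row(n = 3, beta = 12)
  )
  expect_equal(nrow(check_records_inequality(recs)), 0)
  bad <- dplyr::bind_rows(recs, record_row(n = 3, beta = 30))
  v <- check_records_inequality(bad)
  expect_true("upper_bound" %in% v$type)
})

test_that("beta_1 / beta_n correlation behaves at the two extremes", {
  fx <- cascade_fixture()
  nn <- dplyr::filter(fx$recs, n == 2)
  base <- assemble_beta1_descriptor(nn, cation_features(), fx$lig_tbl)
  pred <- predict(fx$model$beta1_model, base)
  # beta_n an exact linear function of predicted beta_1 -> PCC = 1
  lin <- nn
  lin$beta <- 2 * pred$.pred + 1
  pcc <- beta1_betan_correlation(fx$model$beta1_model, lin,
                                 ligand_tbl = fx$lig_tbl)
  expect_equal(pcc$pcc[pcc$n == 2], 1, tolerance = 1e-9)
  # beta_n independent of beta_1 by construction -> |PCC| small
  set.seed(21)
  nulls <- nn[sample.int(nrow(nn), 500, replace = TRUE), ]
  nulls$beta <- rnorm(500)
  pcc0 <- beta1_betan_correlation(fx$model$beta1_model, nulls,
                                  ligand_tbl = fx$lig_tbl)
  expect_lt(abs(pcc0$pcc[pcc0$n == 2]), 0.2)
})

test_that("the fitted cascade shows the planted beta_1 -> beta_n structure", {
  fx <- cascade_fixture()
  nn <- dplyr::filter(fx$recs, n >= 2)
  pcc <- beta1_betan_correlation(fx$model$beta1_model, nn,
                                 ligand_tbl = fx$lig_tbl)
  expect_true(all(pcc$pcc[pcc$n %in% 2:4] > 0.7))
  # predicted beta_1 dominates the beta_n relevance report
  rel <- feature_relevance_kl(fx$model$betan_model)
  expect_equal(rel$feature[1], "pred_beta1")
})
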