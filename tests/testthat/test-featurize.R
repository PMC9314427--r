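# Descriptor generation, the three pruning filters, and descriptor-table
# assembly / standardization.

test_that("ligand descriptors match hand counts of structural features", {
  d <- ligand_descriptors(c(
    "C",                                       # methane
    "c1ccccc1",                                # benzene
    "NCCNCCN",                                 # diethylenetriamine
    "OC(=O)CN(CCN(CC(=O)O)CC(=O)O)CC(=O)O"     # EDTA (protonated form)
  ))
  expect_equal(d$nHeavy, c(1, 6, 7, 20))
  expect_equal(d$nRingAtoms, c(0, 6, 0, 0))
  expect_equal(d$nAromRings6, c(0, 1, 0, 0))
  # dien has two terminal -NH2 and exactly one internal -NH-
  expect_equal(d$NsNH2[3], 2)
  expect_equal(d$NssNH[3], 1)
  # EDTA: two tertiary amines, four carboxyls, no -NH-
  expect_equal(d$NsssN[4], 2)
  expect_equal(d$nCOOH[4], 4)
  expect_equal(d$NssNH[4], 0)
  # molecular charge is appended from input
  dc <- ligand_descriptors("NCC(=O)O", ligand_charge = -1)
  expect_equal(dc$molecular_charge, -1)
})

test_that("drop_degenerate removes constant and incomplete columns only", {
  df <- tibble::tibble(
    id = letters[1:4],
    all_zero = rep(0, 4),
    with_na = c(1, NA, 3, 4),
    two_valued = c(1, 1, 2, 2),
    varying = c(0.1, 0.4, 0.2, 0.9)
  )
  out <- drop_degenerate(df)
  expect_named(out, c("id", "two_valued", "varying"))
})

test_that("correlation_filter drops the later column of a too-correlated pair", {
  set.seed(42)
  base <- rnorm(50)
  df <- tibble::tibble(a = base, b = rnorm(50), a_copy = base)
  out <- correlation_filter(df)
  expect_named(out, c("a", "b"))

  # a pair at exactly |r| = 0.7 is retained (strict inequality)
  x <- as.numeric(1:40)
  z <- stats::residuals(stats::lm(rnorm(40) ~ x))
  xs <- as.numeric(scale(x)); zs <- as.numeric(scale(z))
  y <- 0.7 * xs + sqrt(1 - 0.7^2) * zs
  expect_equal(abs(cor(xs, y)), 0.7, tolerance = 1e-12)
  out2 <- correlation_filter(tibble::tibble(x = xs, y = y))
  expect_named(out2, c("x", "y"))

  # independent columns all survive, and no surviving pair exceeds 0.7
  set.seed(1)
  ind <- as.data.frame(matrix(rnorm(600), 100, 6))
  out3 <- correlation_filter(ind)
  expect_equal(ncol(out3), 6)
  r <- abs(cor(as.matrix(out3)))
  diag(r) <- 0
  expect_lt(max(r), 0.7 + 1e-10)
})

test_that("vif_filter matches an independent brute-force oracle", {
  # orthonormal columns: all VIF = 1, nothing removed
  q <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  dfq <- as.data.frame(q)
  expect_equal(ncol(vif_filter(dfq)), 5)

  # exact collinearity: C = A + B, exactly one of the set removed first
  set.seed(5)
  dfc <- tibble::tibble(a = rnorm(30), b = rnorm(30))
  dfc$c <- dfc$a + dfc$b
  out <- vif_filter(dfc)
  expect_equal(ncol(out), 2)

  # random 10-column table: output equals step-by-step oracle application
  set.seed(9)
  z <- matrix(rnorm(600), 60, 10)
  # plant correlation structure so something gets removed
  z[, 9] <- z[, 1] + z[, 2] + rnorm(60, 0, 0.4)
  z[, 10] <- z[, 3] - z[, 4] + rnorm(60, 0, 0.4)
  df <- as.data.frame(z)
  oracle_cols <- names(df)
  repeat {
    v <- oracle_vif(df[oracle_cols])
    if (all(v < 4)) break
    oracle_cols <- oracle_cols[-utils::tail(which(v == max(v)), 1)]
  }
  out <- vif_filter(df)
  expect_equal(names(out), oracle_cols)
  # post-condition re-checked with the oracle
  expect_true(all(oracle_vif(out) < 4))
})

test_that("beta_1 descriptor assembly concatenates cation, ligand, condition blocks", {
  recs <- small_synth()
  lig_tbl <- small_ligand_tbl(recs)
  dt <- assemble_beta1_descriptor(recs, cation_features(), lig_tbl)
  n_lig_cols <- sum(vapply(lig_tbl, is.numeric, logical(1)))
  expect_equal(ncol(dt$features), 12 + n_lig_cols + 2)
  expect_equal(as.integer(table(dt$provenance)[c("cation", "condition", "ligand")]),
               c(12L, 2L, n_lig_cols))
  expect_equal(nrow(dt$features), nrow(recs))
  # two records sharing a ligand carry identical ligand sub-vectors
  shared <- recs$smiles[duplicated(recs$smiles)][1]
  idx <- which(recs$smiles == shared)[1:2]
  lig_cols <- names(dt$provenance)[dt$provenance == "ligand"]
  expect_equal(dt$features[idx[1], lig_cols], dt$features[idx[2], lig_cols],
               ignore_attr = TRUE)
  # unknown cation is reported by name
  bad <- recs[1, ]; bad$cation <- "Xx"
  expect_error(assemble_beta1_descriptor(bad, cation_features(), lig_tbl),
               regexp = "Xx")
})

test_that("standardization uses fit-row statistics and round-trips", {
  dt <- new_dt <- NULL
  df <- tibble::tibble(f1 = c(0, 2, 5, 9), f2 = c(1, -1, 2, 0))
  dt <- stabcast:::new_descriptor_table(
    df, tibble::tibble(id = 1:4),
    provenance = c(f1 = "ligand", f2 = "ligand"))
  std <- standardize_descriptors(dt, fit_rows = 1:2)
  # column {0, 2} over the fit rows maps to {-1, +1} (population scale)
  expect_equal(std$features$f1[1:2], c(-1, 1))
  expect_equal(mean(std$features$f1[1:2]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(std$features$f1[1:2]^2)), 1, tolerance = 1e-9)
  # a held-out row is transformed with fit statistics, not its own
  expect_equal(std$features$f1[3], (5 - 1) / 1)
  # transforming new rows uses the stored metadata
  new_dt <- stabcast:::new_descriptor_table(
    tibble::tibble(f1 = 7, f2 = 0), tibble::tibble(id = 9L),
    provenance = c(f1 = "ligand", f2 = "ligand"))
  applied <- apply_standardization(new_dt, std)
  expect_equal(applied$features$f1, (7 - 1) / 1)
  # inverse(standardize(x)) = x
  back <- unstandardize_descriptors(std)
  expect_equal(as.matrix(back$features), as.matrix(df), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero-variance fit columns are an error
  expect_error(standardize_descriptors(dt, fit_rows = c(1, 1)),
               regexp = "zero-variance")
})
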