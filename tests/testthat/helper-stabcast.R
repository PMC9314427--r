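# Shared fixtures for the test suite.  Everything is generated in code;
# expensive objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a minimal valid record row, with overridable fields
record_row <- function(cation = "Cu", charge = 2, smiles = "NCCN",
                       ligand_charge = 0, n = 1, beta = 10.5, temp_c = 25,
                       ionic_strength = 0.1, source = "test") {
  tibble::tibble(cation = cation, charge = charge, smiles = smiles,
                 ligand_charge = ligand_charge, n = n, beta = beta,
                 temp_c = temp_c, ionic_strength = ionic_strength,
                 source = source)
}

# small curated synthetic dataset shared across tests
small_synth <- function(seed = 7) {
  cached(paste0("synth", seed), {
    spec <- synthetic_spec(n_cations = 20, n_ligands = 80, n_pairs = 350,
                           seed = seed)
    resolve_duplicates(apply_exclusions(generate_dataset(spec))$kept)
  })
}

# pruned ligand descriptor table for a record set
small_ligand_tbl <- function(records, key = "ligtbl") {
  cached(key, {
    lig <- dplyr::distinct(records, smiles, ligand_charge)
    ligand_descriptors(lig$smiles, lig$ligand_charge) |>
      drop_degenerate() |>
      correlation_filter() |>
      vif_filter()
  })
}

# quick GPR settings for tests
quick_fit <- function(x, y, ...) {
  fit_gpr(x, y, restarts = 2, seed = 0, maxit = 60, ...)
}

# independent brute-force VIF oracle: per-column lm regressions
oracle_vif <- function(df) {
  x <- as.matrix(df[vapply(df, is.numeric, logical(1))])
  vapply(seq_len(ncol(x)), function(k) {
    fit <- stats::lm(x[, k] ~ x[, -k, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

# independent GP posterior oracle: direct dense solve, no Cholesky
oracle_gp_posterior <- function(x_train, y_train, x_query, sigma,
                                lengthscales, noise_sd, jitter = 1e-8) {
  n <- nrow(x_train)
  kf <- function(a, b) matern32_ard(a, b, sigma, lengthscales)
  k <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) kf(x_train[i, ], x_train[j, ])))
  k <- k + diag(noise_sd^2 + jitter, n)
  ks <- outer(seq_len(n), seq_len(nrow(x_query)),
              Vectorize(function(i, j) kf(x_train[i, ], x_query[j, ])))
  kinv_y <- solve(k, y_train)
  mean <- drop(crossprod(ks, kinv_y))
  var <- sigma^2 + noise_sd^2 - diag(crossprod(ks, solve(k, ks)))
  list(mean = mean, var = var)
}
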