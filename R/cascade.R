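# Two-stage cascade: the beta_1 GPR model's out-of-fold prediction and
# 1-sigma uncertainty become features of the multi-order beta_n model,
# together with the complex charge, n-1, and the ligand features the final
# beta_1 model did not use.

# cascade feature names injected by assemble_betan_descriptor
.cascade_feature_names <- c("pred_beta1", "pred_beta1_std", "complex_charge",
                            "n_minus_1")

#' Configuration for cascade fitting
#'
#' @param restarts,seed,maxit,max_rows Passed to [fit_gpr()] for both
#'   stages.
#' @param feature_select Run KL-relevance feature-count optimization per
#'   stage (the workflow's full form).  When `FALSE` both stages use all
#'   available features.
#' @param relevance_delta Perturbation for [feature_relevance_kl()].
#' @param validation_count Ligands held out by
#'   [select_validation_ligands()] for feature-count optimization.
#' @param grid Feature-count grid (default as in
#'   [optimize_feature_count()]).
#' @param oof_folds Folds for out-of-fold beta_1 predictions feeding the
#'   beta_n training stage.
#' @return A named list of settings.
#' @export
cascade_config <- function(restarts = 5, seed = 0, maxit = 150,
                           max_rows = Inf, feature_select = FALSE,
                           relevance_delta = 0.001, validation_count = 20,
                           grid = NULL, oof_folds = 5) {
  list(restarts = restarts, seed = seed, maxit = maxit, max_rows = max_rows,
       feature_select = feature_select, relevance_delta = relevance_delta,
       validation_count = validation_count, grid = grid,
       oof_folds = oof_folds)
}

# ligand descriptor pipeline: descriptors for the unique ligands of a
# record set, then degenerate / correlation / VIF pruning
.ligand_pipeline <- function(records, corr_threshold = 0.7,
                             vif_threshold = 4) {
  lig <- dplyr::distinct(records, .data$smiles, .data$ligand_charge)
  tbl <- ligand_descriptors(lig$smiles, lig$ligand_charge)
  tbl |>
    drop_degenerate() |>
    correlation_filter(threshold = corr_threshold) |>
    vif_filter(threshold = vif_threshold)
}

# rebuild a GP posterior on a row subset with the fitted hyperparameters
# unchanged (used for out-of-fold beta_1 predictions)
.gpr_refit_subset <- function(model, rows) {
  out <- model
  out$x <- model$x[rows, , drop = FALSE]
  out$y_std <- model$y_std[rows]
  k <- .kernel_gram(out$x, NULL, out$sigma, out$lengthscales)
  diag(k) <- diag(k) + out$noise_sd^2 + out$jitter
  out$chol <- chol(k)
  out$alpha <- backsolve(out$chol, backsolve(out$chol, out$y_std,
                                             transpose = TRUE))
  out
}

#' Assemble the multi-order beta_n descriptor table
#'
#' Per record with coordination count n >= 2, runs the beta_1 model on the
#' record's (cation, ligand, conditions) descriptor - a prediction, never a
#' lookup of a measured beta_1, since not every (M, L) pair of the beta_n
#' stratum has a measured beta_1 - and emits the predicted beta_1, its
#' 1-sigma standard deviation, the complex charge (cation charge + ligand
#' molecular charge), n - 1, and the ligand features that the (possibly
#' feature-selected) beta_1 model did not use.
#'
#' @param records Records with `n >= 2` (a record with n = 1 is an error -
#'   it belongs to the beta_1 model).
#' @param beta1_model Fitted `stabcast_gpr` for beta_1.
#' @param cation_tbl Cation feature table.
#' @param ligand_tbl Pruned ligand descriptor table keyed by `smiles`.
#' @param beta1_pred Optional tibble (`.pred`, `.pred_std`, one row per
#'   record) overriding the beta_1 model's predictions - used internally to
#'   inject out-of-fold predictions during cascade training.
#' @return A `descriptor_table`; the four cascade columns carry provenance
#'   `"cascade"`, the unused ligand columns `"ligand"`.
#' @export
assemble_betan_descriptor <- function(records, beta1_model,
                                      cation_tbl = cation_features(),
                                      ligand_tbl, beta1_pred = NULL) {
  stopifnot(inherits(beta1_model, "stabcast_gpr"))
  if (any(records$n < 2)) {
    abort("records with n = 1 belong to the beta_1 model, not the cascade stage")
  }
  base <- assemble_beta1_descriptor(records, cation_tbl, ligand_tbl)
  if (is.null(beta1_pred)) {
    beta1_pred <- predict(beta1_model, base)
  }
  stopifnot(nrow(beta1_pred) == nrow(records))

  lig_cols <- names(base$provenance)[base$provenance == "ligand"]
  unused <- setdiff(lig_cols, beta1_model$feature_names)

  cascade_block <- tibble(
    pred_beta1 = beta1_pred$.pred,
    pred_beta1_std = beta1_pred$.pred_std,
    complex_charge = records$charge + records$ligand_charge,
    n_minus_1 = as.numeric(records$n - 1)
  )
  features <- dplyr::bind_cols(cascade_block,
                               base$features[unused])
  provenance <- c(
    setNames(rep("cascade", 4), .cascade_feature_names),
    setNames(rep("ligand", length(unused)), unused)
  )
  new_descriptor_table(features, base$info, provenance)
}

# one feature-selection pass: relevance on the fitted full model, then
# feature-count optimization on a held-out ligand split
.select_features <- function(x_tbl, y, records, full_model, config) {
  rel <- feature_relevance_kl(full_model, delta = config$relevance_delta)
  lig_feats <- dplyr::distinct(
    dplyr::bind_cols(tibble(smiles = records$smiles),
                     as_tibble(x_tbl$features)),
    .data$smiles, .keep_all = TRUE
  )
  n_lig <- dplyr::n_distinct(records$smiles)
  count <- min(config$validation_count, max(2, floor(n_lig / 3)))
  held <- select_validation_ligands(lig_feats, count = count,
                                    seed = config$seed,
                                    lengthscales = full_model$lengthscales)
  is_valid <- records$smiles %in% held
  fm <- feature_matrix(x_tbl)
  fc <- optimize_feature_count(
    fm[!is_valid, , drop = FALSE], y[!is_valid], rel,
    fm[is_valid, , drop = FALSE], y[is_valid],
    grid = config$grid, restarts = config$restarts, seed = config$seed,
    maxit = config$maxit, max_rows = config$max_rows
  )
  list(features = rel$feature[seq_len(fc$best_k)], relevance = rel,
       curve = fc)
}

#' Fit the beta_1 -> beta_n cascade
#'
#' Fits the beta_1 GPR on the n = 1 stratum, generates out-of-fold beta_1
#' predictions for the n >= 2 stratum (hyperparameters from the full beta_1
#' fit; the posterior is rebuilt per fold so a pair's own n = 1 record never
#' informs the beta_1 features of its beta_n rows), assembles the beta_n
#' descriptor via [assemble_betan_descriptor()], and fits the beta_n GPR.
#' With `feature_select = TRUE` each stage runs KL-relevance ranking plus
#' feature-count optimization on an applicability-domain ligand hold-out.
#'
#' @param records Validated records containing both n = 1 and n >= 2 strata.
#' @param cation_tbl Cation feature table.
#' @param ligand_tbl Pruned ligand descriptor table; `NULL` (default) runs
#'   the full ligand pipeline ([ligand_descriptors()] + the three filters)
#'   on the records' unique ligands.
#' @param config See [cascade_config()].
#' @return A `stabcast_cascade` object with `beta1_model`, `betan_model`,
#'   the feature partition, and (when feature selection ran) the relevance
#'   reports and feature curves.  Supports [predict()][predict.stabcast_cascade],
#'   [tidy()], [glance()].
#' @export
fit_cascade <- function(records, cation_tbl = cation_features(),
                        ligand_tbl = NULL, config = cascade_config()) {
  stopifnot(is.data.frame(records))
  n1 <- dplyr::filter(records, .data$n == 1)
  nn <- dplyr::filter(records, .data$n >= 2)
  if (nrow(n1) == 0) abort("no n = 1 records: cannot fit the beta_1 stage")
  if (nrow(nn) == 0) abort("no n >= 2 records: cannot fit the beta_n stage")
  if (is.null(ligand_tbl)) ligand_tbl <- .ligand_pipeline(records)

  # ---- stage 1: beta_1 -------------------------------------------------
  dt1 <- assemble_beta1_descriptor(n1, cation_tbl, ligand_tbl)
  dt1$features <- as_tibble(as.data.frame(
    .as_feature_matrix(drop_degenerate(dt1$features))))
  dt1$provenance <- dt1$provenance[names(dt1$features)]
  beta1_model <- fit_gpr(dt1, n1$beta, restarts = config$restarts,
                         seed = config$seed, maxit = config$maxit,
                         max_rows = config$max_rows)
  beta1_selection <- NULL
  if (isTRUE(config$feature_select)) {
    beta1_selection <- .select_features(dt1, n1$beta, n1, beta1_model, config)
    fm <- feature_matrix(dt1)[, beta1_selection$features, drop = FALSE]
    beta1_model <- fit_gpr(fm, n1$beta, restarts = config$restarts,
                           seed = config$seed, maxit = config$maxit,
                           max_rows = config$max_rows)
  }

  # ---- out-of-fold beta_1 features for the beta_n stratum --------------
  pair_key <- function(df) paste0(df$cation, "+", df$charge, "|", df$smiles)
  k1 <- pair_key(n1)[beta1_model$train_rows]
  kn <- pair_key(nn)
  folds <- config$oof_folds
  fold_of_pair <- .with_seed(config$seed, {
    pairs <- unique(k1)
    setNames(sample(rep_len(seq_len(folds), length(pairs))), pairs)
  })
  dtn_base <- assemble_beta1_descriptor(nn, cation_tbl, ligand_tbl)
  oof <- predict(beta1_model, dtn_base)  # full-model fallback
  fold_rows <- fold_of_pair[k1]
  for (f in seq_len(folds)) {
    target <- which(kn %in% names(fold_of_pair)[fold_of_pair == f])
    if (length(target) == 0) next
    sub <- .gpr_refit_subset(beta1_model, which(fold_rows != f))
    xs <- .standardize_new(sub, dtn_base)[target, , drop = FALSE]
    post <- .predict_std(sub, xs)
    oof$.pred[target] <- post$mean * sub$y_scale + sub$y_center
    oof$.pred_std[target] <- sqrt(post$var) * sub$y_scale
  }

  # ---- stage 2: beta_n -------------------------------------------------
  dtn <- assemble_betan_descriptor(nn, beta1_model, cation_tbl, ligand_tbl,
                                   beta1_pred = oof)
  dtn$features <- as_tibble(as.data.frame(
    .as_feature_matrix(drop_degenerate(dtn$features))))
  dtn$provenance <- dtn$provenance[names(dtn$features)]
  betan_model <- fit_gpr(dtn, nn$beta, restarts = config$restarts,
                         seed = config$seed, maxit = config$maxit,
                         max_rows = config$max_rows)
  betan_selection <- NULL
  if (isTRUE(config$feature_select)) {
    betan_selection <- .select_features(dtn, nn$beta, nn, betan_model, config)
    fm <- feature_matrix(dtn)[, betan_selection$features, drop = FALSE]
    betan_model <- fit_gpr(fm, nn$beta, restarts = config$restarts,
                           seed = config$seed, maxit = config$maxit,
                           max_rows = config$max_rows)
  }

  structure(
    list(
      beta1_model = beta1_model, betan_model = betan_model,
      beta1_feature_names = beta1_model$feature_names,
      betan_extra_feature_names = setdiff(betan_model$feature_names,
                                          names(dtn$provenance)[dtn$provenance == "ligand"]),
      beta1_selection = beta1_selection, betan_selection = betan_selection,
      cation_tbl = cation_tbl, ligand_tbl = ligand_tbl, config = config
    ),
    class = "stabcast_cascade"
  )
}

#' @export
print.stabcast_cascade <- function(x, ...) {
  cat("<stabcast_cascade>\n  beta_1 stage: ")
  cat(nrow(x$beta1_model$x), "records,",
      length(x$beta1_model$feature_names), "features\n")
  cat("  beta_n stage:", nrow(x$betan_model$x), "records,",
      length(x$betan_model$feature_names), "features\n")
  invisible(x)
}

#' Predict stability constants with a fitted cascade
#'
#' Records with n = 1 go through the beta_1 model; records with n >= 2 go
#' through the beta_n model with the full beta_1 model providing the
#' predicted-beta_1 features (always a prediction, even when the pair has a
#' measured beta_1).
#'
#' @param object A `stabcast_cascade`.
#' @param records Records to predict (the `beta` column is ignored and may
#'   be absent).
#' @param ... Unused.
#' @return A tibble with `.pred` and `.pred_std`, rows parallel to
#'   `records`.
#' @export
predict.stabcast_cascade <- function(object, records, ...) {
  stopifnot(is.data.frame(records))
  rec <- records
  if (!"beta" %in% names(rec)) rec$beta <- NA_real_
  out <- tibble(.pred = rep(NA_real_, nrow(rec)),
                .pred_std = rep(NA_real_, nrow(rec)))
  i1 <- which(rec$n == 1)
  if (length(i1) > 0) {
    dt <- assemble_beta1_descriptor(rec[i1, ], object$cation_tbl,
                                    object$ligand_tbl)
    out[i1, ] <- predict(object$beta1_model, dt)
  }
  i2 <- which(rec$n >= 2)
  if (length(i2) > 0) {
    dt <- assemble_betan_descriptor(rec[i2, ], object$beta1_model,
                                    object$cation_tbl, object$ligand_tbl)
    out[i2, ] <- predict(object$betan_model, dt)
  }
  out
}

#' @export
glance.stabcast_cascade <- function(x, ...) {
  tibble(
    n_beta1 = nrow(x$beta1_model$x), d_beta1 = ncol(x$beta1_model$x),
    n_betan = nrow(x$betan_model$x), d_betan = ncol(x$betan_model$x),
    beta1_loglik = x$beta1_model$log_marginal_likelihood,
    betan_loglik = x$betan_model$log_marginal_likelihood
  )
}

#' @export
tidy.stabcast_cascade <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$beta1_model), stage = "beta1"),
    dplyr::mutate(tidy(x$betan_model), stage = "betan")
  )
}

#' Check the universal stability-constant inequality
#'
#' For a family of overall stability constants of one M-L pair the stepwise
#' constants decrease (K_1 > K_2 > ...), which implies
#' beta_(n-1) < beta_n < n * beta_1.  `check_inequality()` flags every
#' consecutive pair violating monotonicity and every order violating the
#' upper bound; an empty result means the family is consistent.  Intended
#' both for data QC (real compilations obey it with few exceptions) and for
#' verifying the synthetic generator.
#'
#' @param beta1 The first overall stability constant (log10).
#' @param betas Named numeric vector of beta_n values, names = n (may be
#'   sparse; beta_1 is taken from `beta1` if not included).
#' @return A tibble of violations with columns `n`, `type`
#'   (`"monotonicity"` or `"upper_bound"`), `value` and `bound`.
#' @examples
#' check_inequality(5, c(`2` = 8))            # consistent -> 0 rows
#' check_inequality(3, c(`2` = 7))            # upper-bound violation
#' @export
check_inequality <- function(beta1, betas) {
  stopifnot(is.numeric(beta1), length(beta1) == 1, is.numeric(betas))
  nn <- as.integer(names(betas))
  if (anyNA(nn)) abort("betas must be named by their order n")
  if (!1 %in% nn) {
    betas <- c(setNames(beta1, "1"), betas)
    nn <- c(1L, nn)
  }
  ord <- order(nn)
  nn <- nn[ord]; betas <- betas[ord]
  out <- tibble(n = integer(), type = character(),
                value = numeric(), bound = numeric())
  if (length(nn) >= 2) {
    prev <- betas[-length(betas)]
    cur <- betas[-1]
    mono_bad <- which(prev >= cur)
    if (length(mono_bad) > 0) {
      out <- dplyr::bind_rows(out, tibble(
        n = nn[mono_bad + 1], type = "monotonicity",
        value = unname(cur[mono_bad]), bound = unname(prev[mono_bad])
      ))
    }
  }
  ub_bad <- which(nn > 1 & betas >= nn * beta1)
  if (length(ub_bad) > 0) {
    out <- dplyr::bind_rows(out, tibble(
      n = nn[ub_bad], type = "upper_bound",
      value = unname(betas[ub_bad]), bound = unname(nn[ub_bad] * beta1)
    ))
  }
  dplyr::arrange(out, .data$n, .data$type)
}

#' @rdname check_inequality
#' @param records A tibble of records; the check runs per
#'   (cation, charge, ligand) family (families lacking an n = 1 record are
#'   checked for monotonicity only).
#' @return `check_records_inequality()`: a tibble of violations with the
#'   family key columns prepended.
#' @export
check_records_inequality <- function(records) {
  stopifnot(is.data.frame(records))
  records |>
    dplyr::group_by(.data$cation, .data$charge, .data$smiles) |>
    dplyr::group_modify(function(df, key) {
      # duplicate measurements of one order are all checked: every recorded
      # beta_n must exceed every recorded beta_(n-1) and stay below
      # n * (every recorded beta_1)
      agg <- df |>
        dplyr::group_by(n = .data$n) |>
        dplyr::summarise(bmin = min(.data$beta), bmax = max(.data$beta),
                         .groups = "drop") |>
        dplyr::arrange(.data$n)
      out <- tibble(n = integer(), type = character(),
                    value = numeric(), bound = numeric())
      if (nrow(agg) >= 2) {
        prev_max <- agg$bmax[-nrow(agg)]
        cur_min <- agg$bmin[-1]
        bad <- which(prev_max >= cur_min)
        if (length(bad) > 0) {
          out <- dplyr::bind_rows(out, tibble(
            n = agg$n[bad + 1], type = "monotonicity",
            value = cur_min[bad], bound = prev_max[bad]))
        }
      }
      if (1 %in% agg$n) {
        b1 <- agg$bmin[agg$n == 1]
        bad <- which(agg$n > 1 & agg$bmax >= agg$n * b1)
        if (length(bad) > 0) {
          out <- dplyr::bind_rows(out, tibble(
            n = agg$n[bad], type = "upper_bound",
            value = agg$bmax[bad], bound = agg$n[bad] * b1))
        }
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Correlation between predicted beta_1 and measured beta_n
#'
#' For each coordination count n >= 2 with at least `min_records` records,
#' the Pearson correlation between the beta_1 model's prediction for the
#' record's (M, L) pair and the measured beta_n.  Strong positive
#' correlations motivate using the predicted beta_1 as a beta_n feature.
#'
#' @param beta1_model Fitted `stabcast_gpr` for beta_1.
#' @param records Records with n >= 2.
#' @param cation_tbl,ligand_tbl Feature tables as in
#'   [assemble_beta1_descriptor()].
#' @param min_records Minimum records per n stratum, default 3.
#' @return A tibble with `n`, `pcc` (NA with zero variance in either
#'   variable) and `n_records`.
#' @export
beta1_betan_correlation <- function(beta1_model, records,
                                    cation_tbl = cation_features(),
                                    ligand_tbl, min_records = 3) {
  stopifnot(all(records$n >= 2))
  dt <- assemble_beta1_descriptor(records, cation_tbl, ligand_tbl)
  pred <- predict(beta1_model, dt)
  tibble(n = records$n, pred_beta1 = pred$.pred, beta = records$beta) |>
    dplyr::group_by(.data$n) |>
    dplyr::filter(dplyr::n() >= min_records) |>
    dplyr::summarise(
      pcc = if (sd(.data$pred_beta1) == 0 || sd(.data$beta) == 0) NA_real_
            else cor(.data$pred_beta1, .data$beta),
      n_records = dplyr::n(),
      .groups = "drop"
    )
}
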