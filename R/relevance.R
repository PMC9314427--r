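# Feature relevance by Kullback-Leibler sensitivity analysis, evaluation
# metrics, relevance-ordered feature-count optimization, and the
# applicability-domain validation-ligand split.

#' Feature relevance via Kullback-Leibler sensitivity analysis
#'
#' For each feature m, every evaluation row's m-th (standardized) coordinate
#' is perturbed by `+delta` and the KL divergence
#' KL(unperturbed || perturbed) between the two univariate predictive
#' Gaussians is computed at each row; the raw relevance score of feature m
#' is the arithmetic mean KL over rows, and standardized relevances are the
#' raw scores normalized to sum to 1.  The perturbation is applied in
#' standardized feature units so that one delta is meaningful across
#' heterogeneous descriptors.
#'
#' @param model A fitted `stabcast_gpr`.
#' @param x_eval Evaluation rows in original units (matrix, data frame or
#'   `descriptor_table`); default `NULL` uses the model's own training rows
#'   (self-sensitivity).
#' @param delta Perturbation size in standardized units, default 0.001.
#' @return A `stabcast_relevance` object: a tibble with columns `feature`,
#'   `raw`, `relevance` (sums to 1) and `rank` (1 = most relevant), ordered
#'   by decreasing relevance, with the perturbation stored as attribute
#'   `delta`.  Supports [tidy()] and [autoplot()].
#' @export
feature_relevance_kl <- function(model, x_eval = NULL, delta = 0.001) {
  stopifnot(inherits(model, "stabcast_gpr"), delta > 0)
  xs <- if (is.null(x_eval)) model$x else .standardize_new(model, x_eval)
  base <- .predict_std(model, xs)
  d <- ncol(xs)
  raw <- vapply(seq_len(d), function(m) {
    xp <- xs
    xp[, m] <- xp[, m] + delta
    pert <- .predict_std(model, xp)
    kl <- 0.5 * log(pert$var / base$var) +
      (base$var + (base$mean - pert$mean)^2) / (2 * pert$var) - 0.5
    mean(kl)
  }, numeric(1))
  if (all(raw <= 0)) abort("model insensitive to all features")
  out <- tibble(
    feature = model$feature_names,
    raw = raw,
    relevance = raw / sum(raw)
  ) |>
    dplyr::arrange(dplyr::desc(.data$relevance)) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "delta") <- delta
  class(out) <- c("stabcast_relevance", class(out))
  out
}

#' @export
tidy.stabcast_relevance <- function(x, ...) {
  as_tibble(unclass(x)[c("feature", "raw", "relevance", "rank")])
}

#' @export
print.stabcast_relevance <- function(x, n_top = 10, ...) {
  cat("<stabcast_relevance> KL sensitivity, delta =",
      attr(x, "delta"), "\n")
  top <- head(x, n_top)
  cat(sprintf("  %2d. %-24s %.4f\n", top$rank, top$feature, top$relevance),
      sep = "")
  cat("  top-", min(n_top, nrow(x)), " relevance mass: ",
      round(sum(top$relevance), 3), "\n", sep = "")
  invisible(x)
}

#' Regression evaluation metrics
#'
#' Mean absolute error and coefficient of determination,
#' R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2).
#'
#' @param truth Observed values.
#' @param estimate Predicted values (same length, >= 2).
#' @return A one-row tibble with columns `mae` and `rsq`.
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
#' @export
evaluate_predictions <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) >= 2)
  if (var(truth) == 0) abort("R^2 undefined: truth has zero variance")
  tibble(
    mae = mean(abs(truth - estimate)),
    rsq = 1 - sum((truth - estimate)^2) / sum((truth - mean(truth))^2)
  )
}

#' Select validation ligands near the edge of the applicability domain
#'
#' Splits ligands by chemical distance: each ligand's mean distance to all
#' other ligands is computed in standardized descriptor space (optionally
#' rescaled by per-feature length scales from a fitted model, so distance
#' matches the kernel's ARD metric), ligands are stratified into quintiles
#' of that distance, and `count` ligands are sampled proportionally across
#' strata with at least `top_stratum_min` guaranteed from the most distant
#' stratum - the applicability-domain edge.  Holding out whole ligands (all
#' their records) avoids the optimistic bias of record-level
#' cross-validation when common ligands appear in both splits.
#'
#' @param ligand_tbl Tibble of ligand descriptors keyed by `smiles` (one row
#'   per ligand; numeric columns are features).
#' @param count Number of ligands to select, default 20.
#' @param seed Integer seed (selection is deterministic given the seed).
#' @param lengthscales Optional named vector of per-feature length scales
#'   used to rescale the standardized coordinates.
#' @param top_stratum_min Minimum picks from the most distant quintile.
#' @return Character vector of the selected ligand `smiles`, with the full
#'   per-ligand distance/stratum table attached as attribute `"strata"`.
#' @export
select_validation_ligands <- function(ligand_tbl, count = 20, seed = 0,
                                      lengthscales = NULL,
                                      top_stratum_min = 4) {
  stopifnot(is.data.frame(ligand_tbl), "smiles" %in% names(ligand_tbl))
  n <- nrow(ligand_tbl)
  if (count >= n) abort("count must be smaller than the number of ligands")
  feats <- setdiff(.numeric_cols(ligand_tbl), "smiles")
  x <- as.matrix(ligand_tbl[feats])
  keep <- apply(x, 2, function(col) sd(col) > 0)
  x <- scale(x[, keep, drop = FALSE])
  if (!is.null(lengthscales)) {
    ls <- lengthscales[intersect(names(lengthscales), colnames(x))]
    if (length(ls) > 0) {
      x[, names(ls)] <- sweep(x[, names(ls), drop = FALSE], 2, ls, "/")
    }
  }
  dmat <- as.matrix(stats::dist(x))
  mean_dist <- rowSums(dmat) / (n - 1)
  stratum <- dplyr::ntile(mean_dist, 5)

  alloc <- rep(floor(count / 5), 5)
  extra <- count - sum(alloc)
  if (extra > 0) alloc[5:(5 - extra + 1)] <- alloc[5:(5 - extra + 1)] + 1
  need <- min(top_stratum_min, count) - alloc[5]
  while (need > 0) {
    donor <- which.max(alloc[1:4])
    alloc[donor] <- alloc[donor] - 1
    alloc[5] <- alloc[5] + 1
    need <- need - 1
  }
  alloc <- pmin(alloc, tabulate(stratum, 5))
  while (sum(alloc) < count) {  # redistribute if a stratum ran short
    room <- tabulate(stratum, 5) - alloc
    donor <- which.max(room)
    alloc[donor] <- alloc[donor] + 1
  }

  selected <- .with_seed(seed, {
    unlist(lapply(5:1, function(s) {
      pool <- ligand_tbl$smiles[stratum == s]
      sample(pool, alloc[s])
    }))
  })
  structure(
    selected,
    strata = tibble(smiles = ligand_tbl$smiles, distance = mean_dist,
                    stratum = stratum)
  )
}

#' Optimize the number of features by relevance order
#'
#' Refits the GPR on the top-k features (k from `grid`, features taken in
#' decreasing relevance order) and evaluates mean absolute error and R^2 on
#' a held-out validation set; the best k minimizes MAE, with ties going to
#' the smaller k.  A k whose fit fails is recorded as failed and the search
#' continues.
#'
#' @param x_train,y_train Training features (data frame / matrix /
#'   `descriptor_table`) and targets.
#' @param ranking Features in decreasing relevance order: a character
#'   vector or a `stabcast_relevance` report.
#' @param x_valid,y_valid Validation features and targets (ligands held out
#'   from training in the intended workflow).
#' @param grid Integer vector of feature counts; default every k in
#'   1..min(d, 20) plus multiples of 5 up to d.
#' @param ... Passed to [fit_gpr()] (e.g. `restarts`, `seed`, `maxit`).
#' @return A `stabcast_feature_curve`: list with `best_k` and `curve` (a
#'   tibble with one row per evaluated k: `k`, `mae`, `rsq`, `failed`).
#' @export
optimize_feature_count <- function(x_train, y_train, ranking,
                                   x_valid, y_valid, grid = NULL, ...) {
  if (inherits(ranking, "stabcast_relevance")) ranking <- ranking$feature
  stopifnot(is.character(ranking), length(ranking) >= 1)
  xt <- .as_feature_matrix(x_train)
  xv <- .as_feature_matrix(x_valid)
  stopifnot(all(ranking %in% colnames(xt)))
  d <- length(ranking)
  if (is.null(grid)) {
    grid <- sort(unique(c(seq_len(min(d, 20)),
                          if (d >= 5) seq(5, d, by = 5), d)))
  }
  grid <- sort(unique(as.integer(grid)))
  stopifnot(all(grid >= 1), all(grid <= d))

  rows <- purrr::map(grid, function(k) {
    cols <- ranking[seq_len(k)]
    res <- tryCatch({
      mod <- fit_gpr(xt[, cols, drop = FALSE], y_train, ...)
      pred <- predict(mod, xv[, cols, drop = FALSE])
      ev <- evaluate_predictions(y_valid, pred$.pred)
      tibble(k = k, mae = ev$mae, rsq = ev$rsq, failed = FALSE)
    }, error = function(cnd) {
      tibble(k = k, mae = NA_real_, rsq = NA_real_, failed = TRUE)
    })
    res
  })
  curve <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(curve, !.data$failed)
  if (nrow(ok) == 0) abort("every feature count failed to fit")
  best_k <- ok$k[order(ok$mae, ok$k)][1]
  structure(list(best_k = best_k, curve = curve),
            class = "stabcast_feature_curve")
}

#' @export
print.stabcast_feature_curve <- function(x, ...) {
  cat("<stabcast_feature_curve> best k =", x$best_k, "\n")
  print(x$curve, n = 10)
  invisible(x)
}

#' @export
tidy.stabcast_feature_curve <- function(x, ...) x$curve

#' @export
glance.stabcast_feature_curve <- function(x, ...) {
  best <- dplyr::filter(x$curve, .data$k == x$best_k)
  tibble(best_k = x$best_k, mae = best$mae, rsq = best$rsq,
         n_evaluated = nrow(x$curve), n_failed = sum(x$curve$failed))
}
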