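# Exact Gaussian process regression with isotropic and
# automatic-relevance-determination (ARD) Matern-3/2 kernels.
#
# k(x_i, x_j) = sigma^2 (1 + sqrt(3) r) exp(-sqrt(3) r)
# isotropic:   r = ||x_i - x_j|| / l
# ARD:         r = sqrt( sum_m (x_im - x_jm)^2 / l_m^2 )
#
# Hyperparameters (log sigma, log l_m, log noise_sd) are fitted by
# multi-restart L-BFGS-B maximization of the log marginal likelihood with
# analytic gradients; the per-feature inverse length scales 1/l_m encode
# feature relevance.

#' Matern-3/2 kernel between two points
#'
#' `matern32()` is the isotropic form with a single length scale;
#' `matern32_ard()` rescales every coordinate by its own length scale
#' (automatic relevance determination) before taking the distance.  With all
#' ARD length scales equal the two agree exactly.
#'
#' @param x_i,x_j Numeric vectors of equal length (one point each).
#' @param sigma Signal amplitude (> 0); the kernel value at zero distance is
#'   `sigma^2`.
#' @param l Length scale (> 0).
#' @param lengthscales Vector of per-feature length scales (> 0), length
#'   `length(x_i)`.
#' @return The scalar kernel value.
#' @examples
#' matern32(c(0, 0), c(0, 0), sigma = 2, l = 1)   # = 4
#' matern32_ard(c(1, 0), c(0, 0), 1, c(2, 5))
#' @export
matern32 <- function(x_i, x_j, sigma, l) {
  stopifnot(length(x_i) == length(x_j), sigma > 0, l > 0)
  if (!all(is.finite(c(x_i, x_j)))) abort("non-finite input point")
  r <- sqrt(sum((x_i - x_j)^2)) / l
  sigma^2 * (1 + sqrt(3) * r) * exp(-sqrt(3) * r)
}

#' @rdname matern32
#' @export
matern32_ard <- function(x_i, x_j, sigma, lengthscales) {
  stopifnot(sigma > 0, all(lengthscales > 0))
  if (length(x_i) != length(x_j) || length(lengthscales) != length(x_i)) {
    abort("dimension mismatch between points and length scales")
  }
  if (!all(is.finite(c(x_i, x_j)))) abort("non-finite input point")
  r <- sqrt(sum(((x_i - x_j) / lengthscales)^2))
  sigma^2 * (1 + sqrt(3) * r) * exp(-sqrt(3) * r)
}

# ARD-scaled distance matrix between row sets (cross if xb given)
.ard_dist <- function(xa, xb = NULL, lengthscales) {
  a <- sweep(xa, 2, lengthscales, "/")
  b <- if (is.null(xb)) a else sweep(xb, 2, lengthscales, "/")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Gram (or cross) matrix of the ARD Matern-3/2 kernel
.kernel_gram <- function(xa, xb = NULL, sigma, lengthscales) {
  r <- .ard_dist(xa, xb, lengthscales)
  sigma^2 * (1 + sqrt(3) * r) * exp(-sqrt(3) * r)
}

# negative log marginal likelihood and its gradient in
# theta = (log sigma, log l_1..d [, log noise_sd]); a one-slot cache shares
# the Cholesky factor between optim's fn and gr calls
.make_gp_objective <- function(x, y, jitter, noise_fixed = NULL) {
  n <- nrow(x); d <- ncol(x)
  cache <- new.env(parent = emptyenv())
  compute <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    sigma <- exp(theta[1])
    ls <- exp(theta[2:(d + 1)])
    noise_sd <- if (is.null(noise_fixed)) exp(theta[d + 2]) else noise_fixed
    r <- .ard_dist(x, NULL, ls)
    e <- sigma^2 * exp(-sqrt(3) * r)
    k <- e * (1 + sqrt(3) * r)
    diag(k) <- diag(k) + noise_sd^2 + jitter
    ch <- tryCatch(chol(k), error = function(cnd) NULL)
    val <- if (is.null(ch)) {
      list(nll = 1e10, grad = rep(0, length(theta)))
    } else {
      alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
      nll <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + n / 2 * log(2 * pi)
      kinv <- chol2inv(ch)
      w <- kinv - tcrossprod(alpha)          # d nll / d theta = 0.5 tr(W dK)
      g <- numeric(length(theta))
      g[1] <- 0.5 * sum(w * (2 * (k - diag(noise_sd^2 + jitter, n))))
      for (m in seq_len(d)) {
        d2m <- outer(x[, m], x[, m], "-")^2
        g[1 + m] <- 0.5 * sum(w * (3 * e * d2m / ls[m]^2))
      }
      if (is.null(noise_fixed)) g[d + 2] <- 0.5 * sum(diag(w)) * 2 * noise_sd^2
      list(nll = nll, grad = g)
    }
    cache$key <- key
    cache$val <- val
    val
  }
  list(fn = function(theta) compute(theta)$nll,
       gr = function(theta) compute(theta)$grad)
}

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.as_feature_matrix <- function(x) {
  if (inherits(x, "descriptor_table")) return(feature_matrix(x))
  if (is.data.frame(x)) return(as.matrix(x[.numeric_cols(x)]))
  as.matrix(x)
}

#' Fit an exact Gaussian process regression model
#'
#' Fits a zero-mean GP with the ARD Matern-3/2 kernel and learned Gaussian
#' observation noise to (X, y).  Targets are standardized internally and all
#' reported predictions are de-standardized; features are z-scored with
#' statistics stored in the model (so prediction-time rows are transformed
#' with the training metadata).  Hyperparameters - signal amplitude, one
#' length scale per feature, and (unless fixed) the noise standard
#' deviation - are chosen by multi-restart L-BFGS-B maximization of the log
#' marginal likelihood with analytic gradients; restarts are drawn from
#' log-uniform ranges under the configured seed, so the fit is reproducible.
#'
#' Exact GPR factorizes a dense n x n covariance; fits beyond roughly 10^4
#' rows are impractical, and `max_rows` provides a uniform subsampling
#' switch for larger inputs.
#'
#' @param x Training features: numeric matrix, data frame, or
#'   `descriptor_table`.  Rows must be finite.
#' @param y Numeric target vector, `length(y) == nrow(x)` (log10 beta in the
#'   intended application).
#' @param noise `"fit"` (default) to learn the noise standard deviation, or
#'   `"fixed"` to pin it at `noise_value`.
#' @param noise_value Fixed noise standard deviation in the units of `y`
#'   (only used when `noise = "fixed"`); 0 gives exact interpolation up to
#'   jitter.
#' @param restarts Number of optimizer restarts (default 5; the first starts
#'   from neutral values, the rest from random draws).
#' @param seed Integer seed controlling restart draws and subsampling.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param jitter Diagonal jitter added for numerical positive definiteness
#'   (escalated automatically if the fitted covariance is barely positive
#'   definite).
#' @param max_rows Uniform subsampling cap on training rows (default `Inf`).
#' @param standardize_x Z-score features internally (default TRUE; set FALSE
#'   if `x` is already standardized and you want distances taken as given).
#' @return An object of class `stabcast_gpr` with fitted hyperparameters,
#'   training data, standardization metadata and the factorized covariance.
#'   Supports [predict()][predict.stabcast_gpr], [tidy()], [glance()].
#' @export
fit_gpr <- function(x, y, noise = c("fit", "fixed"), noise_value = 0,
                    restarts = 5, seed = 0, maxit = 150, jitter = 1e-8,
                    max_rows = Inf, standardize_x = TRUE) {
  noise <- match.arg(noise)
  xm <- .as_feature_matrix(x)
  feature_names <- colnames(xm) %||% paste0("x", seq_len(ncol(xm)))
  colnames(xm) <- feature_names
  y <- as.numeric(y)
  stopifnot(nrow(xm) == length(y), nrow(xm) >= 2)
  if (!all(is.finite(xm))) abort("training features must be finite")
  if (!all(is.finite(y))) abort("training targets must be finite")

  sub_idx <- seq_len(nrow(xm))
  if (nrow(xm) > max_rows) {
    sub_idx <- .with_seed(seed, sort(sample(nrow(xm), max_rows)))
    xm <- xm[sub_idx, , drop = FALSE]
    y <- y[sub_idx]
  }
  n <- nrow(xm); d <- ncol(xm)

  if (standardize_x) {
    x_center <- colMeans(xm)
    x_scale <- apply(xm, 2, sd)
    flat <- !is.finite(x_scale) | x_scale <= 0
    if (any(flat)) {
      # a constant column carries no information; keep it inert rather than
      # failing (it can arise from row subsetting of a clean table)
      warn(paste0("zero-variance feature column(s) kept inert: ",
                  paste(feature_names[flat], collapse = ", ")))
      x_scale[flat] <- 1
    }
  } else {
    x_center <- setNames(rep(0, d), feature_names)
    x_scale <- setNames(rep(1, d), feature_names)
  }
  xs <- sweep(sweep(xm, 2, x_center), 2, x_scale, "/")

  y_center <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale <= 0) y_scale <- 1
  ys <- (y - y_center) / y_scale

  noise_fixed <- if (noise == "fixed") noise_value / y_scale else NULL
  obj <- .make_gp_objective(xs, ys, jitter, noise_fixed)

  l0 <- sqrt(d)
  lower <- c(log(1e-3), rep(log(1e-2), d), if (is.null(noise_fixed)) log(1e-4))
  upper <- c(log(1e3), rep(log(1e4), d), if (is.null(noise_fixed)) log(10))
  starts <- .with_seed(seed, {
    lapply(seq_len(max(1, restarts)), function(i) {
      if (i == 1) {
        c(0, rep(log(l0), d), if (is.null(noise_fixed)) log(0.3))
      } else {
        c(runif(1, log(0.5), log(2)),
          log(l0) + runif(d, -1.5, 1.5),
          if (is.null(noise_fixed)) runif(1, log(0.05), log(0.7)))
      }
    })
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = maxit)),
      error = function(cnd) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) {
    abort("covariance matrix not positive definite for any restart; check for duplicated rows or increase jitter")
  }

  theta <- best$par
  sigma <- exp(theta[1])
  lengthscales <- setNames(exp(theta[2:(d + 1)]), feature_names)
  noise_sd <- if (is.null(noise_fixed)) exp(theta[d + 2]) else noise_fixed

  k <- .kernel_gram(xs, NULL, sigma, lengthscales)
  # escalate the jitter if the optimum sits at a barely-PD covariance
  ch <- NULL
  for (j in jitter * c(1, 1e2, 1e4, 1e6)) {
    kj <- k
    diag(kj) <- diag(kj) + noise_sd^2 + j
    ch <- tryCatch(chol(kj), error = function(cnd) NULL)
    if (!is.null(ch)) { jitter <- j; k <- kj; break }
  }
  if (is.null(ch)) {
    diag(k) <- diag(k) + noise_sd^2 + jitter
    abort(paste0("covariance not positive definite even after jitter ",
                 "escalation (reciprocal condition ~ ",
                 format(rcond(k), digits = 3), ")"))
  }
  alpha <- backsolve(ch, backsolve(ch, ys, transpose = TRUE))

  structure(
    list(
      sigma = sigma, lengthscales = lengthscales, noise_sd = noise_sd,
      jitter = jitter, feature_names = feature_names,
      x = xs, y_std = ys, chol = ch, alpha = alpha,
      x_center = x_center, x_scale = x_scale,
      y_center = y_center, y_scale = y_scale,
      log_marginal_likelihood = -best$value,
      train_rows = sub_idx,
      config = list(noise = noise, noise_value = noise_value,
                    restarts = restarts, seed = seed, maxit = maxit,
                    max_rows = max_rows, standardize_x = standardize_x)
    ),
    class = "stabcast_gpr"
  )
}

#' @export
print.stabcast_gpr <- function(x, ...) {
  cat("<stabcast_gpr> ARD Matern-3/2 Gaussian process\n")
  cat("  n =", nrow(x$x), " d =", ncol(x$x), "\n")
  cat("  sigma =", signif(x$sigma, 4),
      " noise_sd =", signif(x$noise_sd, 4),
      " logLik =", signif(x$log_marginal_likelihood, 6), "\n")
  inv <- sort(1 / x$lengthscales, decreasing = TRUE)
  cat("  top inverse length scales:",
      paste(names(head(inv, 5)), signif(head(inv, 5), 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

# standardized design matrix for new data, with column checking
.standardize_new <- function(object, newdata) {
  xm <- .as_feature_matrix(newdata)
  if (!is.null(colnames(xm))) {
    miss <- setdiff(object$feature_names, colnames(xm))
    if (length(miss) > 0) {
      abort(paste0("newdata is missing feature column(s): ",
                   paste(miss, collapse = ", ")))
    }
    xm <- xm[, object$feature_names, drop = FALSE]
  } else if (ncol(xm) != length(object$feature_names)) {
    abort("newdata has wrong number of columns and no column names")
  }
  if (!all(is.finite(xm))) abort("newdata features must be finite")
  sweep(sweep(xm, 2, object$x_center), 2, object$x_scale, "/")
}

#' Posterior predictions from a fitted GPR model
#'
#' Standard GP posterior mean and standard deviation at new inputs,
#' de-standardized to the target's original scale.  The predictive variance
#' includes the learned observation-noise variance, so far from all training
#' points it reverts to `sigma^2 + noise_sd^2` (on the standardized target
#' scale).
#'
#' @param object A `stabcast_gpr` model.
#' @param newdata New features (matrix, data frame or `descriptor_table`)
#'   with the training columns.
#' @param ... Unused.
#' @return A tibble with columns `.pred` and `.pred_std` (1-sigma).
#' @export
predict.stabcast_gpr <- function(object, newdata, ...) {
  xs <- .standardize_new(object, newdata)
  post <- .predict_std(object, xs)
  tibble(
    .pred = post$mean * object$y_scale + object$y_center,
    .pred_std = sqrt(post$var) * object$y_scale
  )
}

# posterior mean/variance on the standardized scales, for pre-standardized
# design rows (predictive variance includes the noise variance)
.predict_std <- function(object, xs) {
  ks <- .kernel_gram(object$x, xs, object$sigma, object$lengthscales)
  v <- backsolve(object$chol, ks, transpose = TRUE)
  list(
    mean = drop(crossprod(ks, object$alpha)),
    var = pmax(object$sigma^2 + object$noise_sd^2 - colSums(v^2),
               object$jitter)
  )
}

#' @export
tidy.stabcast_gpr <- function(x, ...) {
  tibble(
    feature = x$feature_names,
    lengthscale = unname(x$lengthscales),
    inv_lengthscale = unname(1 / x$lengthscales)
  ) |>
    dplyr::arrange(dplyr::desc(.data$inv_lengthscale))
}

#' @export
glance.stabcast_gpr <- function(x, ...) {
  tibble(
    n = nrow(x$x), d = ncol(x$x),
    sigma = x$sigma, noise_sd = x$noise_sd,
    log_marginal_likelihood = x$log_marginal_likelihood
  )
}

#' Serialize / restore a fitted GPR model
#'
#' Writes a versioned key-value (JSON) container with hyperparameters,
#' feature names, standardization metadata and the (standardized) training
#' arrays; the covariance factorization is rebuilt on read.
#'
#' @param object A `stabcast_gpr` model.
#' @param path JSON file path.
#' @return `write_gpr()` the model invisibly; `read_gpr()` the restored
#'   model.
#' @export
write_gpr <- function(object, path) {
  stopifnot(inherits(object, "stabcast_gpr"))
  payload <- list(
    schema = "stabcast/gpr/v1",
    sigma = object$sigma,
    lengthscales = as.list(object$lengthscales),
    noise_sd = object$noise_sd, jitter = object$jitter,
    feature_names = object$feature_names,
    x = apply(object$x, 1, as.numeric, simplify = FALSE),
    y_std = object$y_std,
    x_center = as.list(object$x_center), x_scale = as.list(object$x_scale),
    y_center = object$y_center, y_scale = object$y_scale,
    log_marginal_likelihood = object$log_marginal_likelihood,
    config = object$config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(object)
}

#' @rdname write_gpr
#' @export
read_gpr <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "stabcast/gpr/v1")) {
    abort(paste0("unrecognized model schema: ", p$schema %||% "<none>"))
  }
  xs <- if (is.matrix(p$x)) p$x else do.call(rbind, p$x)
  colnames(xs) <- p$feature_names
  lengthscales <- setNames(unlist(p$lengthscales), p$feature_names)
  k <- .kernel_gram(xs, NULL, p$sigma, lengthscales)
  diag(k) <- diag(k) + p$noise_sd^2 + p$jitter
  ch <- chol(k)
  alpha <- backsolve(ch, backsolve(ch, p$y_std, transpose = TRUE))
  structure(
    list(
      sigma = p$sigma, lengthscales = lengthscales, noise_sd = p$noise_sd,
      jitter = p$jitter, feature_names = p$feature_names,
      x = xs, y_std = p$y_std, chol = ch, alpha = alpha,
      x_center = setNames(unlist(p$x_center), p$feature_names),
      x_scale = setNames(unlist(p$x_scale), p$feature_names),
      y_center = p$y_center, y_scale = p$y_scale,
      log_marginal_likelihood = p$log_marginal_likelihood,
      train_rows = seq_len(nrow(xs)),
      config = p$config
    ),
    class = "stabcast_gpr"
  )
}
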