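# Kernel exactness, Gram-matrix properties, posterior correctness against a
# direct-solve oracle, and hyperparameter fitting behavior.

test_that("matern32 evaluates the kernel exactly", {
  # zero distance -> sigma^2
  expect_identical(matern32(c(1, 2), c(1, 2), sigma = 3, l = 0.5), 9)
  # sigma = 1, l = 1, r = 1/sqrt(3): sigma^2 (1 + 1) exp(-1) = 2/e
  x <- c(1 / sqrt(3), 0); y <- c(0, 0)
  expect_equal(matern32(x, y, 1, 1), 2 * exp(-1), tolerance = 1e-12)
  # symmetry on random points
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(matern32(a, b, 1.3, 0.7), matern32(b, a, 1.3, 0.7))
  }
  expect_error(matern32(c(1, NA), c(0, 0), 1, 1), regexp = "finite")
})

test_that("ARD kernel reduces to isotropic and matches a termwise oracle", {
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(5)
    # equal length scales reduce exactly to the isotropic kernel
    expect_equal(matern32_ard(a, b, 1.5, rep(0.8, 5)),
                 matern32(a, b, 1.5, 0.8), tolerance = 1e-14)
    # termwise scalar re-implementation of the ARD distance
    ls <- exp(runif(5, -1, 1))
    r <- 0
    for (m in 1:5) r <- r + (a[m] - b[m])^2 / ls[m]^2
    r <- sqrt(r)
    expect_equal(matern32_ard(a, b, 2, ls),
                 4 * (1 + sqrt(3) * r) * exp(-sqrt(3) * r), tolerance = 1e-12)
  }
  # a feature with a huge length scale cannot change the kernel value
  a <- c(0, 0); b1 <- c(0, 0); b2 <- c(0, 5)
  expect_equal(matern32_ard(a, b1, 1, c(1, 1e9)),
               matern32_ard(a, b2, 1, c(1, 1e9)), tolerance = 1e-9)
  expect_error(matern32_ard(c(1, 2), c(1, 2), 1, c(1, 1, 1)),
               regexp = "dimension")
})

test_that("Gram matrices are symmetric and positive semi-definite", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:25, 1); d <- sample(2:6, 1)
    x <- matrix(rnorm(n * d), n, d)
    ls <- exp(runif(d, -1, 1))
    k <- stabcast:::.kernel_gram(x, NULL, sigma = 1.2, lengthscales = ls)
    expect_equal(k, t(k), tolerance = 1e-12)
    expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("posterior mean and variance match the direct-solve oracle", {
  set.seed(4)
  for (s in 1:10) {
    n <- 50; d <- 5
    x <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n)
    q <- matrix(rnorm(8 * d), 8, d)
    sigma <- exp(runif(1, -0.5, 0.5))
    ls <- exp(runif(d, -0.5, 1))
    noise <- runif(1, 0.05, 0.4)
    # package posterior with the same fixed hyperparameters, bypassing the
    # optimizer: restart at the truth with 0 iterations would still move;
    # instead build the model object through the internal constructor path
    m <- quick_fit(x, y)
    m$sigma <- sigma; m$lengthscales[] <- ls; m$noise_sd <- noise
    m$x_center[] <- 0; m$x_scale[] <- 1
    m$y_center <- 0; m$y_scale <- 1
    m$x <- x; m$y_std <- y
    m <- stabcast:::.gpr_refit_subset(m, seq_len(n))
    pred <- predict(m, q)
    orac <- oracle_gp_posterior(x, y, q, sigma, ls, noise, jitter = m$jitter)
    expect_equal(pred$.pred, orac$mean, tolerance = 1e-8)
    expect_equal(pred$.pred_std, sqrt(orac$var), tolerance = 1e-8)
  }
})

test_that("noise-free GP interpolates its training targets", {
  set.seed(5)
  x <- matrix(runif(10), 5, 2)
  y <- sin(3 * x[, 1]) + x[, 2]^2
  m <- fit_gpr(x, y, noise = "fixed", noise_value = 0, restarts = 2,
               seed = 0, maxit = 80)
  pred <- predict(m, x)
  expect_equal(pred$.pred, y, tolerance = 1e-6)
})

test_that("predictions revert to the prior far from training data", {
  set.seed(6)
  x <- matrix(rnorm(60), 30, 2)
  y <- x[, 1] + rnorm(30, 0, 0.1)
  m <- quick_fit(x, y)
  far <- matrix(1e6, 1, 2)
  pred <- predict(m, far)
  # mean reverts to the (de-standardized) zero prior mean
  expect_equal(pred$.pred, mean(y), tolerance = 1e-6)
  # 1-sigma reverts to sqrt(sigma^2 + noise^2) on the target scale
  expect_equal(pred$.pred_std,
               sqrt(m$sigma^2 + m$noise_sd^2) * m$y_scale, tolerance = 1e-6)
})

test_that("constant targets give constant predictions with bounded variance", {
  x <- matrix(rnorm(40), 20, 2)
  m <- quick_fit(x, rep(5, 20))
  pred <- predict(m, matrix(rnorm(10), 5, 2))
  expect_equal(pred$.pred, rep(5, 5), tolerance = 1e-8)
  expect_true(all(pred$.pred_std^2 <= m$sigma^2 + m$noise_sd^2 + 1e-9))
})

test_that("adding a training point at the query never increases its variance", {
  set.seed(7)
  x <- matrix(rnorm(40), 20, 2)
  y <- x[, 1] + rnorm(20, 0, 0.2)
  q <- matrix(c(0.3, -0.2), 1, 2)
  m <- quick_fit(x, y)
  v1 <- predict(m, q)$.pred_std
  # same hyperparameters, training set augmented with the query point
  m2 <- m
  m2$x <- rbind(m$x, (c(q) - m$x_center) / m$x_scale)
  m2$y_std <- c(m$y_std, 0)
  m2 <- stabcast:::.gpr_refit_subset(m2, 1:21)
  v2 <- predict(m2, q)$.pred_std
  expect_lte(v2, v1 + 1e-10)
})

test_that("ARD fitting ranks planted active features first", {
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 70; d <- 5
    x <- matrix(rnorm(n * d), n, d)
    # two active features with short true length scales, three inert
    y <- sin(2 * x[, 1]) + 0.8 * cos(2 * x[, 2]) + rnorm(n, 0, 0.05)
    m <- fit_gpr(x, y, restarts = 2, seed = s, maxit = 100)
    top2 <- order(1 / m$lengthscales, decreasing = TRUE)[1:2]
    if (setequal(top2, 1:2)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("fitting is deterministic given seed and config", {
  set.seed(8)
  x <- matrix(rnorm(60), 30, 2)
  y <- x[, 1]^2 + rnorm(30, 0, 0.1)
  m1 <- fit_gpr(x, y, restarts = 2, seed = 3, maxit = 50)
  m2 <- fit_gpr(x, y, restarts = 2, seed = 3, maxit = 50)
  expect_identical(m1$sigma, m2$sigma)
  expect_identical(m1$lengthscales, m2$lengthscales)
  expect_identical(m1$noise_sd, m2$noise_sd)
})

test_that("models survive a serialization round trip", {
  set.seed(9)
  x <- matrix(rnorm(60), 30, 2); colnames(x) <- c("a", "b")
  y <- x[, 1] + rnorm(30, 0.1)
  m <- quick_fit(x, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_gpr(m, path)
  m2 <- read_gpr(path)
  q <- matrix(rnorm(10), 5, 2); colnames(q) <- c("a", "b")
  expect_equal(predict(m2, q), predict(m, q), tolerance = 1e-10)
  # column mismatch is reported by name
  colnames(q) <- c("a", "zz")
  expect_error(predict(m, q), regexp = "b")
})
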