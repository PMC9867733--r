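test_that("standardize centers/scales continuous and passes binary through", {
  x <- cbind(a = c(1, 2, 3), b = c(0, 1, 1))
  out <- standardize(x, c("continuous", "binary"))
  expect_equal(out$x[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(out$centers[1], 2)
  expect_equal(out$scales[1], 1)
  expect_equal(out$x[, "b"], x[, "b"])
  expect_error(standardize(cbind(c = c(5, 5, 5)), "continuous"),
               "zero variance.*c|c.*zero variance")
  expect_error(standardize(cbind(d = c(0, 2, 1)), "binary"), "0/1")
})

test_that("lambda_grid matches the stationarity closed form", {
  # single column with x'(y - ybar)/n = 0.8 exactly
  n <- 10
  x <- matrix(rep(c(1, -1), 5), ncol = 1)      # x'x = n, mean 0
  y <- 0.8 * x[, 1]                             # x'(y - ybar)/n = 0.8
  g <- lambda_grid(x, y, "gaussian", n_lambda = 2, min_ratio = 0.01)
  expect_equal(g, c(0.8, 0.008))
  g50 <- lambda_grid(x, y, "gaussian", n_lambda = 50, min_ratio = 1e-4)
  expect_length(g50, 50)
  expect_equal(g50[1], 0.8)
  expect_equal(g50[50], 0.8 * 1e-4)
  expect_true(all(diff(g50) < 0))
  expect_error(lambda_grid(x, rep(1, n), "gaussian"), "constant")
})

test_that("univariate soft-thresholding closed form is reproduced", {
  n <- 40
  x <- matrix(rep(c(1, -1), n / 2), ncol = 1, dimnames = list(NULL, "x"))
  y <- x[, 1]                                   # x'y/n = 1.0
  f <- fit_nodewise(x, y, "gaussian", lambda = 0.4)
  expect_equal(unname(f$coefficients["x"]), 0.6, tolerance = 1e-9)
  # at lambda >= lambda_max everything is zero
  f0 <- fit_nodewise(x, y, "gaussian", lambda = 1.0)
  expect_equal(unname(f0$coefficients["x"]), 0)
})

test_that("lambda = 0 gaussian fit equals least squares", {
  inst <- random_instance(1, n = 80, p = 5)
  f <- fit_nodewise(inst$x, inst$y, "gaussian", lambda = 0)
  ls <- lm.fit(cbind(1, inst$x), inst$y)$coefficients
  expect_equal(unname(f$intercept), unname(ls[1]), tolerance = 1e-6)
  expect_equal(unname(f$coefficients), unname(ls[-1]), tolerance = 1e-6)
})

test_that("every fit passes the KKT certificate at 1e-6", {
  for (s in 1:10) {
    for (fam in c("gaussian", "binomial")) {
      inst <- random_instance(s, n = 150, p = 7, family = fam)
      grid <- lambda_grid(inst$x, inst$y, fam, n_lambda = 12)
      fits <- fit_nodewise(inst$x, inst$y, fam, grid)
      for (f in fits) {
        k <- kkt_check(f, inst$x, inst$y, tol = 1e-6)
        expect_true(k$ok, label = sprintf(
          "KKT (%s, seed %d, lambda %.4g): violation %.2g",
          fam, s, f$lambda, k$max_violation))
      }
    }
  }
})

test_that("brute-force search never improves on the solver objective", {
  # coarse global grid plus a fine 1e-3 grid around the solution
  brute_best <- function(x, y, fam, lam, center, halfwidth, step) {
    grids <- lapply(seq_along(center), function(j)
      seq(center[j] - halfwidth, center[j] + halfwidth, by = step))
    best <- Inf
    cand <- as.matrix(expand.grid(grids))
    for (r in seq_len(nrow(cand))) {
      b <- cand[r, ]
      v <- lasso_objective(0, b, x, y, fam, lam)
      if (v < best) best <- v
    }
    best
  }
  set.seed(42)
  for (p in c(1, 2, 3)) {
    x <- matrix(rnorm(60 * p), 60, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    x <- scale(x); x <- x - rep(colMeans(x), each = nrow(x))
    beta <- c(0.8, -0.4, 0.2)[1:p]
    y <- as.numeric(x %*% beta + rnorm(60, sd = 0.3))
    y <- y - mean(y)                     # centered => intercept is 0
    lam <- 0.1
    f <- fit_nodewise(x, y, "gaussian", lam)
    obj <- lasso_objective(f$intercept, f$coefficients, x, y, "gaussian", lam)
    coarse <- brute_best(x, y, "gaussian", lam, rep(0, p), 1.5, 0.1)
    fine <- brute_best(x, y, "gaussian", lam, unname(f$coefficients),
                       0.01, 0.001)
    expect_gte(coarse - obj, -1e-5)
    expect_gte(fine - obj, -1e-5)
  }
})

test_that("solver agrees with an independent reference implementation", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(3, n = 200, p = 6)
  lam <- 0.07
  f <- fit_nodewise(inst$x, inst$y, "gaussian", lam)
  g <- glmnet::glmnet(inst$x, inst$y, family = "gaussian", lambda = lam,
                      standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(f$coefficients), as.numeric(g$beta), tolerance = 1e-5)
  expect_equal(unname(f$intercept), as.numeric(g$a0), tolerance = 1e-5)

  instb <- random_instance(4, n = 400, p = 6, family = "binomial")
  lamb <- 0.02
  fb <- fit_nodewise(instb$x, instb$y, "binomial", lamb)
  gb <- glmnet::glmnet(instb$x, instb$y, family = "binomial", lambda = lamb,
                       standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(fb$coefficients), as.numeric(gb$beta), tolerance = 1e-4)
  expect_equal(unname(fb$intercept), as.numeric(gb$a0), tolerance = 1e-4)
})

test_that("active set shrinks along increasing lambda on an orthogonal design", {
  # with orthonormal columns the lasso is exact soft-thresholding, so the
  # active set is provably nested along the path
  n <- 64
  x <- qr.Q(qr(matrix(rnorm(n * 5), n, 5))) * sqrt(n)
  colnames(x) <- paste0("x", 1:5)
  set.seed(9)
  y <- as.numeric(x %*% c(1, 0.5, 0.25, 0.1, 0) + rnorm(n, sd = 0.1))
  grid <- lambda_grid(x, y, "gaussian", n_lambda = 20)
  fits <- fit_nodewise(x, y, "gaussian", grid)   # descending order
  sizes <- vapply(fits, function(f) sum(f$coefficients != 0), integer(1))
  expect_true(all(diff(sizes) >= 0))   # descending lambda => growing sets
})

test_that("input validation errors fire", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(10)
  expect_error(fit_nodewise(x, y, "gaussian", lambda = -1), "lambda")
  x[1, 1] <- NA
  expect_error(fit_nodewise(x, y, "gaussian", lambda = 0.1), "non-finite")
})
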