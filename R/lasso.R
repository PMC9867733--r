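#' Standardize a mixed-type design matrix
#'
#' Continuous columns are centered and scaled to unit standard deviation
#' (denominator `n - 1`); binary 0/1 columns pass through unchanged so that
#' their coefficients stay on the interpretable per-group scale. Centers and
#' scales are returned for back-transformation.
#'
#' @param design numeric matrix with named columns.
#' @param kinds character vector (`"continuous"` or `"binary"`) per column.
#' @return `list(x, centers, scales)`; for binary columns the center is 0 and
#'   the scale 1.
#' @export
standardize <- function(design, kinds) {
  stopifnot(is.matrix(design), length(kinds) == ncol(design))
  centers <- numeric(ncol(design))
  scales <- rep(1, ncol(design))
  x <- design
  for (j in seq_len(ncol(design))) {
    if (kinds[j] == "binary") {
      bad <- !design[, j] %in% c(0, 1)
      if (any(bad))
        stop_("binary column %s contains values other than 0/1",
              colnames(design)[j] %||% j)
    } else {
      s <- sd(design[, j])
      if (!is.finite(s) || s == 0)
        stop_("continuous column %s has zero variance",
              colnames(design)[j] %||% j)
      centers[j] <- mean(design[, j])
      scales[j] <- s
      x[, j] <- (design[, j] - centers[j]) / s
    }
  }
  list(x = x, centers = centers, scales = scales)
}

#' Penalty grid for an L1 path
#'
#' Log-spaced descending grid from `lambda_max` (the smallest penalty at which
#' all penalized coefficients are zero) down to `lambda_max * min_ratio`. For
#' the gaussian family `lambda_max = max_j |x_j'(y - mean(y))| / n`; for the
#' binomial family the mean response replaces the fitted null probability.
#'
#' @param predictors standardized predictor matrix.
#' @param response numeric response (0/1 for binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param n_lambda number of grid points (>= 2).
#' @param min_ratio ratio of smallest to largest penalty, in (0, 1).
#' @return Descending numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(predictors, response, family = c("gaussian", "binomial"),
                        n_lambda = 50L, min_ratio = 1e-4) {
  family <- match.arg(family)
  stopifnot(n_lambda >= 2, min_ratio > 0, min_ratio < 1)
  n <- length(response)
  if (var(response) == 0) stop_("response is constant")
  center <- mean(response)
  lmax <- max(abs(crossprod(predictors, response - center))) / n
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Fit one nodewise L1-penalized regression
#'
#' Minimizes `(1/2n) sum (y - b0 - x'b)^2 + lambda ||b||_1` (gaussian) or the
#' mean logistic negative log-likelihood plus `lambda ||b||_1` (binomial),
#' intercept unpenalized, by coordinate descent (compiled). Solutions satisfy
#' the subgradient (KKT) optimality conditions at tolerance 1e-6, checked by
#' [kkt_check()].
#'
#' @param predictors standardized predictor matrix (columns named).
#' @param response numeric response; 0/1 for binomial.
#' @param family `"gaussian"` or `"binomial"`.
#' @param lambda penalty value(s) >= 0; a descending vector is solved as a
#'   warm-started path.
#' @return For a single `lambda`, a `nodewise_fit` list with `intercept`,
#'   `coefficients`, `lambda`, `family`; for a vector, a list of such fits.
#' @export
fit_nodewise <- function(predictors, response,
                         family = c("gaussian", "binomial"), lambda) {
  family <- match.arg(family)
  if (any(!is.finite(predictors)) || any(!is.finite(response)))
    stop_("non-finite values in inputs")
  if (any(lambda < 0)) stop_("lambda must be >= 0")
  path <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  n <- length(response)
  p <- ncol(predictors)

  if (family == "gaussian") {
    xbar <- colMeans(predictors)
    ybar <- mean(response)
    G <- crossprod(predictors) / n - tcrossprod(xbar)
    cvec <- as.numeric(crossprod(predictors, response) / n - xbar * ybar)
    B <- cd_gauss_path(G, cvec, path)
    b0 <- ybar - as.numeric(xbar %*% B)
  } else {
    if (!all(response %in% c(0, 1))) stop_("binomial response must be 0/1")
    fit <- cd_logis_path(predictors, response, path)
    B <- fit$beta
    b0 <- fit$beta0
  }
  mk <- function(k) {
    structure(list(
      intercept = b0[k],
      coefficients = setNames(B[, k], colnames(predictors)),
      lambda = path[k],
      family = family
    ), class = "nodewise_fit")
  }
  if (length(path) == 1L) mk(1L) else lapply(seq_along(path), mk)
}

#' Subgradient (KKT) certificate for an L1 fit
#'
#' Computes the penalized-objective gradient at the fitted coefficients and
#' checks stationarity: `|g_j| <= lambda + tol` for zero coefficients and
#' `g_j = -sign(b_j) * lambda` within `tol` for active ones. This is the
#' machine-checkable proof that a fit is the exact minimizer.
#'
#' @param fit a `nodewise_fit`.
#' @param predictors,response the data the fit was computed on.
#' @param tol tolerance (default 1e-6).
#' @return `list(ok, max_violation, gradient)`.
#' @export
kkt_check <- function(fit, predictors, response, tol = 1e-6) {
  n <- length(response)
  eta <- fit$intercept + as.numeric(predictors %*% fit$coefficients)
  if (fit$family == "gaussian") {
    g <- -as.numeric(crossprod(predictors, response - eta)) / n
    g0 <- -mean(response - eta)
  } else {
    mu <- plogis(eta)
    g <- -as.numeric(crossprod(predictors, response - mu)) / n
    g0 <- -mean(response - mu)
  }
  b <- fit$coefficients
  viol <- ifelse(b == 0, pmax(abs(g) - fit$lambda, 0),
                 abs(g + sign(b) * fit$lambda))
  viol <- c(viol, abs(g0))
  list(ok = max(viol) <= tol, max_violation = max(viol), gradient = g)
}

#' Penalized objective value of an L1 fit
#'
#' @param intercept,coefficients candidate solution.
#' @param predictors,response data.
#' @param family `"gaussian"` or `"binomial"`.
#' @param lambda penalty.
#' @return The objective `loss + lambda * ||coefficients||_1`, with loss
#'   `(1/2n) RSS` (gaussian) or the mean logistic negative log-likelihood.
#' @export
lasso_objective <- function(intercept, coefficients, predictors, response,
                            family = c("gaussian", "binomial"), lambda) {
  family <- match.arg(family)
  n <- length(response)
  eta <- intercept + as.numeric(predictors %*% coefficients)
  loss <- if (family == "gaussian") {
    sum((response - eta)^2) / (2 * n)
  } else {
    s <- (2 * response - 1) * eta
    mean(ifelse(s > 0, log1p(exp(-s)), -s + log1p(exp(s))))
  }
  loss + lambda * sum(abs(coefficients))
}
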