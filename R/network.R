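#' Estimation configuration for mixed graphical models
#'
#' @param rule edge aggregation rule, `"AND"` (default, conservative) or
#'   `"OR"`.
#' @param folds cross-validation folds (default 10).
#' @param n_lambda penalty grid size (default 50).
#' @param min_ratio smallest/largest penalty ratio (default 1e-4).
#' @param lambda_policy `"min"` (CV-loss minimizer, default) or `"1se"`.
#' @param seed master seed; per-node fold seeds are derived from it.
#' @param reselect_lambda logical; under the bootstrap, re-select lambda by CV
#'   within each replicate (default `TRUE`) or freeze the full-sample values.
#' @return A `network_config` list.
#' @export
network_config <- function(rule = c("AND", "OR"), folds = 10L, n_lambda = 50L,
                           min_ratio = 1e-4, lambda_policy = c("min", "1se"),
                           seed = 1L, reselect_lambda = TRUE) {
  structure(list(rule = match.arg(rule), folds = as.integer(folds),
                 n_lambda = as.integer(n_lambda), min_ratio = min_ratio,
                 lambda_policy = match.arg(lambda_policy),
                 seed = as.integer(seed),
                 reselect_lambda = isTRUE(reselect_lambda)),
            class = "network_config")
}

#' Node specification table
#'
#' @param symptoms character vector of symptom node names.
#' @param treatment name of the binary treatment node (default `"arm"`).
#' @param covariates optional character vector of predictor-only covariate
#'   columns (binary dummies or continuous).
#' @param covariate_kinds kinds for the covariates (`"binary"`/`"continuous"`);
#'   inferred as binary when omitted and values are 0/1.
#' @return data.frame with columns `name`, `kind`, `role`.
#' @export
node_spec <- function(symptoms, treatment = "arm", covariates = character(),
                      covariate_kinds = NULL) {
  if (length(treatment) != 1L) stop_("exactly one treatment node is required")
  kinds <- covariate_kinds %||% rep("continuous", length(covariates))
  data.frame(
    name = c(treatment, symptoms, covariates),
    kind = c("binary", rep("continuous", length(symptoms)), kinds),
    role = c("treatment", rep("symptom", length(symptoms)),
             rep("covariate", length(covariates))),
    stringsAsFactors = FALSE
  )
}

#' Aggregate nodewise fits into an undirected network
#'
#' For each node pair (j, k), let `a` be k's coefficient in j's regression and
#' `b` be j's coefficient in k's regression. Under the AND rule the edge is
#' present iff both are nonzero; under OR iff at least one is. Present edges
#' carry magnitude `(|a| + |b|) / 2`. The sign is the shared sign (or, under
#' OR with one zero coefficient, the sign of the nonzero one); when the two
#' signs disagree the magnitude is kept, the sign is recorded as `NA`
#' (undefined) and a warning is issued. The `weights` matrix is signed where
#' the sign is defined and carries the positive magnitude otherwise.
#'
#' @param fits named list of `nodewise_fit` objects, one per reported node;
#'   coefficients must be aligned by name.
#' @param rule `"AND"` or `"OR"`.
#' @param n_samples sample size to record on the model.
#' @return A `network_model`.
#' @export
combine_nodewise <- function(fits, rule = c("AND", "OR"), n_samples = NA_integer_) {
  rule <- match.arg(rule)
  nodes <- names(fits)
  if (is.null(nodes) || any(!nzchar(nodes))) stop_("fits must be named by node")
  p <- length(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  S <- matrix(0, p, p, dimnames = list(nodes, nodes))
  disagreements <- character()
  for (j in seq_len(p - 1)) for (k in seq(j + 1, p)) {
    cj <- fits[[j]]$coefficients
    ck <- fits[[k]]$coefficients
    if (!(nodes[k] %in% names(cj)) || !(nodes[j] %in% names(ck)))
      stop_("misaligned fits: pair (%s, %s)", nodes[j], nodes[k])
    a <- unname(cj[nodes[k]])
    b <- unname(ck[nodes[j]])
    present <- if (rule == "AND") a != 0 && b != 0 else a != 0 || b != 0
    if (!present) next
    mag <- (abs(a) + abs(b)) / 2
    sgn <- if (a != 0 && b != 0) {
      if (sign(a) == sign(b)) sign(a) else NA_real_
    } else {
      sign(a + b)
    }
    if (is.na(sgn)) disagreements <- c(disagreements,
                                       paste(nodes[j], nodes[k], sep = "~"))
    W[j, k] <- W[k, j] <- if (is.na(sgn)) mag else sgn * mag
    S[j, k] <- S[k, j] <- sgn
  }
  if (length(disagreements))
    warning("sign disagreement on edge(s): ",
            paste(disagreements, collapse = ", "), call. = FALSE)
  structure(list(nodes = nodes, weights = W, signs = S, rule = rule,
                 fits = fits, n_samples = n_samples),
            class = "network_model")
}

#' Estimate a mixed graphical model over treatment and symptoms
#'
#' Nodewise neighborhood regression with L1 regularization: each symptom node
#' is regressed on all other nodes by penalized least squares, and the binary
#' treatment node by penalized logistic regression; each node's penalty is
#' selected by K-fold cross-validation; the full-data refits are aggregated
#' into an undirected weighted network by the configured rule. Continuous
#' columns are standardized once (unit SD), so symptom-symptom edges are on
#' the standardized-coefficient scale and treatment-symptom edges in per-SD
#' units of the symptom. Covariate nodes (role `"covariate"`) enter every
#' regression as penalized predictors but are not reported as network nodes.
#'
#' @param data complete-case numeric matrix (or data.frame), columns covering
#'   `nodes$name`.
#' @param nodes a [node_spec()] table.
#' @param config a [network_config()].
#' @param lambdas optional named vector of frozen per-node penalties (skips
#'   CV; used by the bootstrap's frozen-lambda mode).
#' @param only_nodes optional subset of reported node names whose nodewise
#'   regressions are fit (all nodes still enter every regression as
#'   predictors, so edge values among the subset are identical to the full
#'   estimation; used by the bootstrap to summarize selected edges cheaply).
#' @return A `network_model` with fields `nodes`, `weights` (symmetric, zero
#'   diagonal, signed), `signs`, `rule`, `fits` (per reported node, each with
#'   `lambda` and `cv_curve`), `n_samples`.
#' @export
estimate_network <- function(data, nodes, config = network_config(),
                             lambdas = NULL, only_nodes = NULL) {
  data <- as.matrix(as.data.frame(data)[, nodes$name, drop = FALSE])
  if (anyNA(data))
    stop_("data contains missing values; apply complete-case filtering first (see complete_case_week)")
  if (nrow(data) <= nrow(nodes))
    stop_("need more rows than nodes (n = %d, nodes = %d)",
          nrow(data), nrow(nodes))
  if (sum(nodes$role == "treatment") != 1L)
    stop_("exactly one treatment node is required")
  if (anyDuplicated(nodes$name)) stop_("duplicated column: %s",
                                       nodes$name[duplicated(nodes$name)][1])

  std <- standardize(data, nodes$kind)
  Z <- std$x
  reported <- nodes$name[nodes$role %in% c("treatment", "symptom")]
  if (!is.null(only_nodes)) {
    bad <- setdiff(only_nodes, reported)
    if (length(bad)) stop_("only_nodes not reported nodes: %s",
                           paste(bad, collapse = ", "))
    reported <- intersect(reported, only_nodes)
  }
  fits <- setNames(vector("list", length(reported)), reported)
  for (nm in reported) {
    fam <- if (nodes$kind[nodes$name == nm] == "binary") "binomial" else "gaussian"
    xj <- Z[, setdiff(nodes$name, nm), drop = FALSE]
    yj <- Z[, nm]
    if (!is.null(lambdas)) {
      lam <- unname(lambdas[nm])
      cvc <- NULL
    } else {
      grid <- lambda_grid(xj, yj, fam, config$n_lambda, config$min_ratio)
      sel <- select_lambda_cv(xj, yj, fam, grid, config$folds,
                              seed = derive_seed(config$seed, paste0("node_", nm)))
      lam <- if (config$lambda_policy == "1se") sel$lambda_1se else sel$lambda_star
      cvc <- sel$cv_curve
    }
    fit <- fit_nodewise(xj, yj, fam, lam)
    fit$cv_curve <- cvc
    fit$node <- nm
    fits[[nm]] <- fit
  }
  net <- combine_nodewise(fits, config$rule, n_samples = nrow(data))
  net$node_spec <- nodes
  net$config <- config
  net
}

#' Extract the tidy edge list of a network
#'
#' @param model a `network_model`.
#' @param nonzero_only drop zero-weight pairs (default `TRUE`).
#' @return data.frame `node_a`, `node_b`, `weight`, `sign`, `rule`.
#' @export
network_edges <- function(model, nonzero_only = TRUE) {
  W <- model$weights
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- data.frame(node_a = rownames(W)[idx[, 1]],
                    node_b = colnames(W)[idx[, 2]],
                    weight = W[idx],
                    sign = model$signs[idx],
                    rule = model$rule,
                    stringsAsFactors = FALSE)
  if (nonzero_only) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.network_model <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("Mixed graphical model: %d nodes, %d edges (%s rule), n = %s\n",
              length(x$nodes), ne, x$rule, x$n_samples))
  tr <- x$node_spec$name[x$node_spec$role == "treatment"][1] %||% x$nodes[1]
  if (tr %in% rownames(x$weights)) {
    trow <- x$weights[tr, ]
    trow <- trow[names(trow) != tr & trow != 0]
    if (length(trow)) {
      cat("Treatment edges:\n")
      for (nm in names(sort(abs(trow), decreasing = TRUE)))
        cat(sprintf("  %-18s %+.3f\n", nm, trow[nm]))
    } else cat("No treatment edges.\n")
  }
  invisible(x)
}
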