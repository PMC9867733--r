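#' Type-7 empirical quantile
#'
#' Linear-interpolation (type-7) order-statistic quantile, the convention used
#' for all bootstrap interval summaries in this package.
#'
#' @param values non-empty numeric vector.
#' @param q probability in \[0, 1\] (vectorized).
#' @return Numeric quantile(s).
#' @export
boot_quantile <- function(values, q) {
  if (!length(values)) stop_("empty values")
  stopifnot(all(q >= 0 & q <= 1))
  unname(quantile(values, q, type = 7))
}

#' Nonparametric bootstrap of the network estimation
#'
#' Resamples patient rows with replacement at the original n and re-runs the
#' entire estimation procedure per replicate (standardization, per-node
#' cross-validated penalty selection with replicate-derived fold seeds, refit,
#' aggregation), then summarizes the replicate edge-weight distributions.
#' With `config$reselect_lambda = FALSE` the per-node penalties are frozen at
#' their full-sample values (faster, less conservative).
#'
#' @param data complete-case week matrix (as from [complete_case_week()]).
#' @param nodes a [node_spec()] table.
#' @param config a [network_config()].
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed for the resampling stream.
#' @param edges_of_interest optional data.frame with columns `node_a`,
#'   `node_b`; defaults to all treatment-symptom pairs.
#' @return A `bootstrap_summary` data.frame: `node_a`, `node_b`, `B`
#'   (effective replicate count), `point_estimate`, `q05`, `q95`,
#'   `prop_nonzero`, `includes_zero`; replicate weights in
#'   `attr(, "estimates")`.
#' @export
bootstrap_network <- function(data, nodes, config = network_config(), B = 100L,
                              seed = 1L, edges_of_interest = NULL) {
  if (B < 1) stop_("B must be >= 1")
  data <- as.data.frame(data)
  tr <- nodes$name[nodes$role == "treatment"][1]
  if (is.null(edges_of_interest)) {
    symptoms <- nodes$name[nodes$role == "symptom"]
    edges_of_interest <- data.frame(node_a = tr, node_b = symptoms,
                                    stringsAsFactors = FALSE)
  }
  # only nodes incident to the requested edges need their own regressions;
  # edge values are identical to the full estimation (see estimate_network)
  incident <- unique(c(edges_of_interest$node_a, edges_of_interest$node_b))
  full <- estimate_network(data, nodes, config, only_nodes = incident)
  ne <- nrow(edges_of_interest)
  est <- matrix(NA_real_, B, ne)
  frozen <- if (config$reselect_lambda) NULL else
    vapply(full$fits, function(f) f$lambda, numeric(1))

  n <- nrow(data)
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, paste0("bootdraw", b)))
    idx <- sample.int(n, n, replace = TRUE)
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("bootfit", b))
    net <- tryCatch(
      estimate_network(data[idx, , drop = FALSE], nodes, cfg,
                       lambdas = frozen, only_nodes = incident),
      error = function(e) NULL)
    if (is.null(net)) { failed <- failed + 1L; next }
    for (e in seq_len(ne))
      est[b, e] <- net$weights[edges_of_interest$node_a[e],
                               edges_of_interest$node_b[e]]
  }
  if (failed > 0.2 * B)
    stop_("%d of %d bootstrap replicates failed", failed, B)
  if (failed > 0)
    warning(sprintf("%d of %d bootstrap replicates failed and were skipped",
                    failed, B), call. = FALSE)

  out <- edges_of_interest
  out$B <- colSums(!is.na(est))
  out$point_estimate <- mapply(function(a, b) full$weights[a, b],
                               edges_of_interest$node_a,
                               edges_of_interest$node_b)
  out$q05 <- apply(est, 2, function(v) boot_quantile(v[!is.na(v)], 0.05))
  out$q95 <- apply(est, 2, function(v) boot_quantile(v[!is.na(v)], 0.95))
  out$prop_nonzero <- apply(est, 2, function(v) mean(v[!is.na(v)] != 0))
  out$includes_zero <- out$q05 <= 0 & 0 <= out$q95
  rownames(out) <- NULL
  attr(out, "estimates") <- est
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}
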