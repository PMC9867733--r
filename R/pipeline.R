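#' Per-week complete-case filter
#'
#' Retains, for one assessment week, exactly the patients with all 17 items
#' present at that week, and returns the analysis matrix (treatment + item
#' columns, plus any requested covariate columns).
#'
#' @param data a `trial_data` data.frame.
#' @param week assessment week present in `data`.
#' @param covariates optional covariate column names to carry along.
#' @return `list(matrix, patients, n)`: the complete-case data.frame, the
#'   retained patient ids, and the retained count.
#' @export
complete_case_week <- function(data, week, covariates = character()) {
  if (!week %in% data$week) stop_("week %s absent from data", week)
  items <- item_columns(data)
  wk <- data[data$week == week, , drop = FALSE]
  keep <- stats::complete.cases(wk[, items, drop = FALSE])
  cols <- c("arm", items, covariates)
  missing_cov <- setdiff(covariates, names(wk))
  if (length(missing_cov))
    stop_("covariate(s) not in data: %s", paste(missing_cov, collapse = ", "))
  list(matrix = wk[keep, cols, drop = FALSE],
       patients = wk$patient_id[keep],
       n = sum(keep))
}

#' Estimate one network per assessment week
#'
#' Independently estimates a mixed graphical model at each requested follow-up
#' week on that week's complete cases (no parameter sharing across weeks).
#' Per-week CV seeds are derived deterministically from the config's master
#' seed and the week tag.
#'
#' @param data a `trial_data` data.frame.
#' @param weeks follow-up weeks to fit (default all follow-up weeks present).
#' @param config a [network_config()].
#' @param covariates optional covariate columns to adjust for (predictor-only
#'   blocks; see [adjusted_networks()]).
#' @return Named list (by week) of `network_model`s.
#' @export
fit_weekly_networks <- function(data, weeks = NULL, config = network_config(),
                                covariates = character()) {
  weeks <- weeks %||% setdiff(sort(unique(data$week)), 0)
  items <- item_columns(data)
  out <- setNames(vector("list", length(weeks)), as.character(weeks))
  for (w in weeks) {
    cc <- complete_case_week(data, w, covariates)
    cov_cols <- expand_covariates(cc$matrix, covariates)
    nodes <- node_spec(items, treatment = "arm",
                       covariates = cov_cols$names,
                       covariate_kinds = cov_cols$kinds)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("week", w))
    out[[as.character(w)]] <- estimate_network(cov_cols$data, nodes, cfg)
  }
  out
}

# One-hot expand categorical covariates (e.g. trial_id); continuous pass
# through standardization downstream. Duplicated symptom columns are refused.
expand_covariates <- function(mat, covariates) {
  items <- setdiff(names(mat), c("arm", covariates))
  df <- mat[, c("arm", items), drop = FALSE]
  covnames <- character(); covkinds <- character()
  for (cv in covariates) {
    v <- mat[[cv]]
    if (cv %in% items) stop_("duplicated column: %s", cv)
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      for (l in lev[-1]) {            # reference level dropped
        nm <- paste0(cv, "_", l)
        df[[nm]] <- as.numeric(v == l)
        covnames <- c(covnames, nm); covkinds <- c(covkinds, "binary")
      }
    } else if (all(v %in% c(0, 1))) {
      df[[cv]] <- v
      covnames <- c(covnames, cv); covkinds <- c(covkinds, "binary")
    } else {
      df[[cv]] <- v
      covnames <- c(covnames, cv); covkinds <- c(covkinds, "continuous")
    }
  }
  list(data = df, names = covnames, kinds = covkinds)
}

#' Direct treatment-effect trajectories
#'
#' Extracts the signed treatment-edge row of each weekly network: the direct
#' (conditional) effect of treatment on each symptom. Negative values mean a
#' lower symptom score under active treatment (beneficial).
#'
#' @param models named list of weekly `network_model`s (names are weeks).
#' @return A `direct_effect_trajectory`: list with `weeks`, `symptoms` and the
#'   weeks x symptoms `values` matrix.
#' @export
direct_effects <- function(models) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  symptoms <- setdiff(models[[1]]$nodes, treatment_node(models[[1]]))
  vals <- matrix(NA_real_, length(models), length(symptoms),
                 dimnames = list(names(models), symptoms))
  for (w in names(models)) {
    m <- models[[w]]
    tr <- treatment_node(m)
    if (!setequal(setdiff(m$nodes, tr), symptoms))
      stop_("inconsistent symptom sets across weekly models")
    vals[w, symptoms] <- m$weights[tr, symptoms]
  }
  structure(list(weeks = as.numeric(names(models)), symptoms = symptoms,
                 values = vals),
            class = "direct_effect_trajectory")
}

treatment_node <- function(model) {
  ns <- model$node_spec
  if (!is.null(ns)) ns$name[ns$role == "treatment"][1] else model$nodes[1]
}

#' @export
print.direct_effect_trajectory <- function(x, ...) {
  cat("Direct treatment effects:", length(x$weeks), "weeks x",
      length(x$symptoms), "symptoms\n")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
as.data.frame.direct_effect_trajectory <- function(x, ...) {
  data.frame(week = rep(x$weeks, times = length(x$symptoms)),
             symptom = rep(x$symptoms, each = length(x$weeks)),
             direct_effect = as.vector(x$values),
             stringsAsFactors = FALSE)
}

#' Indirect treatment-effect table (two-path products)
#'
#' Enumerates treatment -> mediator -> target two-paths with both edges
#' nonzero and scores each by the product of the two edge weights. This is a
#' descriptive surrogate for effects transmitted through directly affected
#' symptoms, not a formal mediation test.
#'
#' @param model a `network_model` containing a treatment node.
#' @param max_path_len currently only 2 is supported.
#' @return data.frame (`mediator`, `target`, `treatment_edge`,
#'   `mediator_target_edge`, `product`), sorted by decreasing `|product|`.
#' @export
indirect_effects <- function(model, max_path_len = 2) {
  stopifnot(max_path_len == 2)
  tr <- treatment_node(model)
  symptoms <- setdiff(model$nodes, tr)
  rows <- list()
  for (m in symptoms) {
    te <- model$weights[tr, m]
    if (te == 0) next
    for (s in setdiff(symptoms, m)) {
      me <- model$weights[m, s]
      if (me == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        mediator = m, target = s, treatment_edge = te,
        mediator_target_edge = me, product = te * me,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mediator = character(), target = character(),
                      treatment_edge = numeric(),
                      mediator_target_edge = numeric(), product = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$product), out$mediator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-week stability of the direct-effect profile
#'
#' Pearson correlation between the symptom-wise direct-effect vectors of
#' consecutive weeks (zeros included). A zero-variance vector yields `NA`
#' (undefined) for its pairs rather than an error.
#'
#' @param traj a `direct_effect_trajectory` with at least 2 weeks and 3
#'   symptoms.
#' @return Named numeric vector, names like `"1-2"`.
#' @export
stability_correlation <- function(traj) {
  stopifnot(length(traj$weeks) >= 2, length(traj$symptoms) >= 3)
  w <- traj$weeks
  out <- numeric(length(w) - 1)
  names(out) <- paste(w[-length(w)], w[-1], sep = "-")
  for (i in seq_len(length(w) - 1)) {
    a <- traj$values[i, ]; b <- traj$values[i + 1, ]
    out[i] <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }
  out
}

#' Covariate-adjusted sensitivity networks
#'
#' Re-estimates the weekly networks with covariate predictor blocks
#' (categorical covariates one-hot encoded, reference level dropped) and
#' reports the adjusted and unadjusted treatment rows side by side.
#'
#' @param data a `trial_data` data.frame.
#' @param weeks follow-up weeks.
#' @param covariates covariate column names (e.g. `"trial_id"`, `"age"`).
#' @param config a [network_config()].
#' @return Named list per week: `list(adjusted, unadjusted, comparison)` where
#'   `comparison` is a data.frame of the two treatment rows and their
#'   difference.
#' @export
adjusted_networks <- function(data, weeks, covariates,
                              config = network_config()) {
  adj <- fit_weekly_networks(data, weeks, config, covariates = covariates)
  raw <- fit_weekly_networks(data, weeks, config)
  out <- setNames(vector("list", length(weeks)), as.character(weeks))
  for (w in as.character(weeks)) {
    tr <- treatment_node(raw[[w]])
    symptoms <- setdiff(raw[[w]]$nodes, tr)
    cmp <- data.frame(
      symptom = symptoms,
      unadjusted = raw[[w]]$weights[tr, symptoms],
      adjusted = adj[[w]]$weights[tr, symptoms],
      stringsAsFactors = FALSE)
    cmp$change <- cmp$adjusted - cmp$unadjusted
    rownames(cmp) <- NULL
    out[[w]] <- list(adjusted = adj[[w]], unadjusted = raw[[w]],
                     comparison = cmp)
  }
  out
}
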