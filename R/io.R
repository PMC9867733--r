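#' Write a trial dataset to long-format CSV
#'
#' Header: `patient_id, trial_id, arm, age, sex, week`, then one column per
#' item; absent scores are written as empty fields.
#'
#' @param data a `trial_data` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a long-format trial CSV
#'
#' @param path CSV written in the [write_trial_csv()] schema.
#' @param items item battery the columns must match (default [hdrs_items()]).
#' @param latent treat item columns as continuous latent scores (skips the
#'   integer/range validation).
#' @return A validated `trial_data` data.frame.
#' @export
read_trial_csv <- function(path, items = hdrs_items(), latent = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- c("patient_id", "trial_id", "arm", "age", "sex", "week")
  expected <- c(meta, items$name)
  if (!identical(names(df), expected))
    stop_("schema mismatch: expected columns [%s], got [%s]",
          paste(expected, collapse = ", "), paste(names(df), collapse = ", "))
  dup <- duplicated(df[c("patient_id", "week")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_("duplicated (patient, week) pair: (%s, %s)",
          df$patient_id[i], df$week[i])
  }
  if (!all(df$arm %in% c(0, 1))) stop_("arm must be 0/1")
  if (!all(df$week %in% c(0, 1, 2, 3, 4, 6))) stop_("invalid week value")
  if (!latent) {
    for (i in seq_len(nrow(items))) {
      v <- df[[items$name[i]]]
      ok <- is.na(v) | (v >= 0 & v <= items$scale_max[i] & v == round(v))
      if (!all(ok))
        stop_("row %d: item %s score %s outside 0..%d or non-integer",
              which(!ok)[1], items$name[i], v[which(!ok)[1]],
              items$scale_max[i])
    }
  }
  # whole-assessment missingness: any NA item row must be all-NA? not enforced;
  # partially missing rows are simply dropped by the complete-case filter.
  attr(df, "items") <- items
  attr(df, "latent") <- latent
  class(df) <- c("trial_data", "data.frame")
  df
}

#' Serialize a ground-truth scenario to JSON
#'
#' @param gt a `ground_truth` object.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  x <- unclass(gt)
  x$Sigma <- NULL        # derived from Omega on read
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a ground-truth scenario from JSON
#'
#' @param path JSON file written by [write_ground_truth()].
#' @return A validated `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as.data.frame(x$items, stringsAsFactors = FALSE)
  omega <- as.matrix(x$Omega)
  dimnames(omega) <- list(items$name, items$name)
  tg <- as.matrix(x$direct_targets)
  dimnames(tg) <- list(setdiff(names(x$delta), "0"), items$name)
  gt <- structure(list(
    scenario = x$scenario, items = items, Omega = omega,
    Sigma = solve(omega),
    mu = setNames(as.numeric(x$mu), items$name),
    delta = lapply(x$delta, as.numeric),
    direct_targets = tg,
    cutpoints = lapply(x$cutpoints, as.numeric),
    p_treat = x$p_treat,
    missing_rate = unlist(x$missing_rate),
    missing_mode = x$missing_mode,
    n_trials = as.integer(x$n_trials),
    trial_shift_sd = x$trial_shift_sd
  ), class = "ground_truth")
  validate_ground_truth(gt)
}

#' Export a network as an edge-list CSV
#'
#' @param model a `network_model`.
#' @param path output CSV (`node_a, node_b, weight, sign, rule`).
#' @param nonzero_only drop zero edges (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_edge_csv <- function(model, path, nonzero_only = TRUE) {
  write.csv(network_edges(model, nonzero_only), path, row.names = FALSE,
            na = "")
  invisible(path)
}

#' Export a network to GraphML
#'
#' @param model a `network_model`.
#' @param path output `.graphml` file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(model, path) {
  ed <- network_edges(model, nonzero_only = TRUE)
  g <- igraph::graph_from_data_frame(
    ed[, c("node_a", "node_b", "weight", "sign")],
    directed = FALSE,
    vertices = data.frame(name = model$nodes, stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network (weights, penalties, CV curves) as a JSON bundle
#'
#' @param model a `network_model`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
network_to_json <- function(model, path = NULL) {
  bundle <- list(
    nodes = model$nodes,
    rule = model$rule,
    n_samples = model$n_samples,
    weights = model$weights,
    signs = model$signs,
    lambdas = lapply(model$fits, function(f) f$lambda),
    cv_curves = lapply(model$fits, function(f) f$cv_curve)
  )
  if (is.null(path))
    return(jsonlite::toJSON(bundle, digits = NA, auto_unbox = TRUE,
                            matrix = "rowmajor"))
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param scenario generator scenario name, or `NULL` when `input` is given.
#' @param input path to an existing trial CSV (overrides `scenario`).
#' @param n_patients generator size (default 2000).
#' @param weeks follow-up weeks to analyze.
#' @param seed master seed; all stage seeds derive from it.
#' @param latent_only generate continuous latent scores.
#' @param estimation a [network_config()] (its seed is overridden by `seed`).
#' @param bootstrap_B bootstrap replicates (0 disables the bootstrap stage).
#' @param covariates covariates for the sensitivity stage (empty disables).
#' @param out_dir output directory.
#' @return A `run_config` list; serializes losslessly to JSON.
#' @export
run_config <- function(scenario = "paper_like", input = NULL,
                       n_patients = 2000L, weeks = c(1, 2, 3, 4, 6),
                       seed = 1L, latent_only = FALSE,
                       estimation = network_config(),
                       bootstrap_B = 0L, covariates = character(),
                       out_dir = tempfile("ssrinet_run_")) {
  if (!length(weeks)) stop_("weeks must be non-empty")
  structure(list(scenario = scenario, input = input,
                 n_patients = as.integer(n_patients), weeks = weeks,
                 seed = as.integer(seed), latent_only = isTRUE(latent_only),
                 estimation = unclass(estimation),
                 bootstrap_B = as.integer(bootstrap_B),
                 covariates = covariates, out_dir = out_dir),
            class = "run_config")
}

#' Run the full per-week analysis pipeline
#'
#' Executes, in order: simulate (or load) -> baseline table -> weekly networks
#' -> direct/indirect effects -> cross-week stability -> overall effects ->
#' direct-vs-overall comparison -> optional bootstrap -> optional
#' covariate-adjusted sensitivity networks. All outputs are written as
#' CSV/JSON/GraphML under `config$out_dir` together with a manifest recording
#' the resolved config, stage seeds, per-stage sample sizes and timing. Every
#' artifact is a pure function of (input data or scenario, config).
#'
#' @param config a [run_config()].
#' @return The output directory path, invisibly; the manifest is
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!length(config$weeks)) stop_("weeks must be non-empty")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    log[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  data <- stage("data", {
    if (!is.null(config$input)) {
      read_trial_csv(config$input, latent = config$latent_only)
    } else {
      gt <- make_ground_truth(config$scenario)
      d <- simulate_trial(gt, config$n_patients,
                          weeks = sort(unique(c(0, config$weeks))),
                          seed = derive_seed(config$seed, "simulate"),
                          latent_only = config$latent_only)
      write_ground_truth(gt, file.path(config$out_dir, "ground_truth.json"))
      write_trial_csv(d, file.path(config$out_dir, "trial_data.csv"))
      d
    }
  })

  baseline <- stage("baseline", baseline_table(data))
  write.csv(baseline, file.path(config$out_dir, "baseline_table.csv"),
            row.names = FALSE)

  cfg <- do.call(network_config, config$estimation[
    setdiff(names(config$estimation), "seed")])
  cfg$seed <- derive_seed(config$seed, "networks")
  models <- stage("networks", fit_weekly_networks(data, config$weeks, cfg))
  for (w in names(models)) {
    write_edge_csv(models[[w]], file.path(config$out_dir,
                                          sprintf("network_week%s.csv", w)))
    write_graphml(models[[w]], file.path(config$out_dir,
                                         sprintf("network_week%s.graphml", w)))
    network_to_json(models[[w]], file.path(config$out_dir,
                                           sprintf("network_week%s.json", w)))
    log[[paste0("network_week", w)]] <- list(n = models[[w]]$n_samples)
  }

  traj <- stage("direct_effects", direct_effects(models))
  write.csv(as.data.frame(traj),
            file.path(config$out_dir, "direct_effects.csv"), row.names = FALSE)

  indirect <- stage("indirect_effects", {
    do.call(rbind, lapply(names(models), function(w) {
      tab <- indirect_effects(models[[w]])
      if (nrow(tab)) cbind(week = as.numeric(w), tab) else NULL
    }))
  })
  if (!is.null(indirect))
    write.csv(indirect, file.path(config$out_dir, "indirect_effects.csv"),
              row.names = FALSE)

  stab <- stage("stability", {
    if (length(config$weeks) >= 2) stability_correlation(traj) else NULL
  })
  if (!is.null(stab))
    write.csv(data.frame(pair = names(stab), r = unname(stab)),
              file.path(config$out_dir, "stability_correlations.csv"),
              row.names = FALSE)

  eff <- stage("overall_effects", overall_effects(data, config$weeks))
  write.csv(eff, file.path(config$out_dir, "overall_effects.csv"),
            row.names = FALSE)

  cmp <- stage("direct_vs_overall", direct_vs_overall(traj, eff))
  write.csv(cmp, file.path(config$out_dir, "direct_vs_overall.csv"),
            row.names = FALSE)

  if (config$bootstrap_B > 0) {
    boot <- stage("bootstrap", {
      w <- max(config$weeks)
      cc <- complete_case_week(data, w)
      nodes <- node_spec(item_columns(data))
      bcfg <- cfg
      bcfg$seed <- derive_seed(config$seed, "bootstrap")
      bootstrap_network(cc$matrix, nodes, bcfg, B = config$bootstrap_B,
                        seed = bcfg$seed)
    })
    write.csv(as.data.frame(boot),
              file.path(config$out_dir, "bootstrap_summary.csv"),
              row.names = FALSE)
  }

  if (length(config$covariates)) {
    sens <- stage("sensitivity", {
      w <- max(config$weeks)
      scfg <- cfg
      scfg$seed <- derive_seed(config$seed, "sensitivity")
      adjusted_networks(data, w, config$covariates, scfg)
    })
    write.csv(sens[[1]]$comparison,
              file.path(config$out_dir, "sensitivity_comparison.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ssrinet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    n_networks = length(models),
    stages = log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}
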