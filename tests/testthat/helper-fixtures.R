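# Shared fixtures: small configs and datasets built in code at test time.

quick_cfg <- function(seed = 1L, ...) {
  network_config(folds = 5L, n_lambda = 25L, seed = seed, ...)
}

# latent paper_like data without missingness (model-matched recovery setting)
recovery_data <- function(n = 2000, weeks = c(0, 6), seed = 1,
                          scenario = "paper_like") {
  gt <- make_ground_truth(scenario, overrides = list(
    missing_rate = setNames(rep(0, 6), c("0", "1", "2", "3", "4", "6")),
    trial_shift_sd = 0))
  simulate_trial(gt, n, weeks = weeks, seed = seed, latent_only = TRUE)
}

battery <- hdrs_items()

# hand-built network model for extraction tests
toy_model <- function(weights, treatment = "arm") {
  nodes <- colnames(weights)
  structure(list(
    nodes = nodes, weights = weights, signs = sign(weights),
    rule = "AND", fits = NULL, n_samples = 100L,
    node_spec = data.frame(
      name = nodes, kind = c("binary", rep("continuous", length(nodes) - 1)),
      role = c("treatment", rep("symptom", length(nodes) - 1)),
      stringsAsFactors = FALSE)
  ), class = "network_model")
}

toy_weights <- function(symptoms, treatment = "arm") {
  nm <- c(treatment, symptoms)
  matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
}

# random solvable lasso instance
random_instance <- function(seed, n = 120, p = 6, family = "gaussian") {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  beta <- c(1, -0.5, rep(0, p - 2))
  eta <- x %*% beta
  y <- if (family == "gaussian") as.numeric(eta + rnorm(n)) else
    rbinom(n, 1, plogis(as.numeric(eta)))
  list(x = x, y = y)
}
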