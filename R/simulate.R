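#' Simulate a randomized antidepressant trial
#'
#' Draws a long-format trial dataset (one row per patient x assessment week)
#' from a [make_ground_truth()] scenario. Per patient: arm ~
#' Bernoulli(`p_treat`); a trial stratum with a Normal(0, `trial_shift_sd`^2)
#' severity intercept; age ~ truncated Normal(44, 14.5^2) on \[18, 90\]; sex ~
#' Bernoulli(0.595). Per retained week `w` the latent 17-vector is
#' `mu + arm * delta[w] + trial_shift + z`, `z ~ MVN(0, solve(Omega))`. With
#' `latent_only = TRUE` the latent values are emitted as continuous scores
#' (so estimation-model assumptions hold exactly, for recovery tests);
#' otherwise each is discretized through the item's cutpoints onto its 0-2 or
#' 0-4 ordinal scale. Each week's assessment is independently absent with
#' probability `missing_rate[w]` (all 17 items `NA` for that visit).
#'
#' @param gt a `ground_truth` object.
#' @param n_patients number of patients (>= 1).
#' @param weeks assessment weeks, a subset of `c(0,1,2,3,4,6)` containing 0.
#' @param seed integer seed; output is fully reproducible given the seed.
#' @param latent_only emit continuous latent scores instead of ordinal ones.
#' @return A `trial_data` data.frame with columns `patient_id`, `trial_id`,
#'   `arm` (0 = placebo, 1 = active), `age`, `sex`, `week`, then one column
#'   per item. Missing assessments carry `NA` in all item columns.
#' @export
#' @examples
#' gt <- make_ground_truth("null")
#' d <- simulate_trial(gt, n_patients = 50, seed = 1)
#' head(d)
simulate_trial <- function(gt, n_patients, weeks = c(0, 1, 2, 3, 4, 6),
                           seed = 1L, latent_only = FALSE) {
  validate_ground_truth(gt)
  if (n_patients < 1) stop_("n_patients must be >= 1")
  if (!all(weeks %in% c(0, 1, 2, 3, 4, 6)))
    stop_("weeks must be a subset of {0,1,2,3,4,6}")
  if (!0 %in% weeks) stop_("weeks must contain the baseline week 0")
  weeks <- sort(unique(weeks))
  items <- gt$items
  p <- nrow(items)
  n <- as.integer(n_patients)

  set.seed(as.integer(seed))
  arm <- rbinom(n, 1L, gt$p_treat)
  trial <- sample.int(gt$n_trials, n, replace = TRUE)
  trial_shift <- rnorm(gt$n_trials, 0, gt$trial_shift_sd)
  plo <- pnorm(18, 44, 14.5); phi <- pnorm(90, 44, 14.5)
  age <- round(qnorm(runif(n, plo, phi), 44, 14.5), 1)
  sex <- rbinom(n, 1L, 0.595)
  R <- chol(gt$Sigma)

  rows <- vector("list", length(weeks))
  for (k in seq_along(weeks)) {
    w <- weeks[k]
    wk <- as.character(w)
    z <- matrix(rnorm(n * p), n, p) %*% R
    y <- z + rep(gt$mu, each = n) + outer(arm, gt$delta[[wk]]) +
      trial_shift[trial]
    rate <- unname(gt$missing_rate[wk])
    if (is.na(rate)) rate <- 0
    if (identical(gt$missing_mode, "MNAR") && w > 0) {
      # absence probability tilted by the patient's latent mood that week
      lp <- qlogis(min(max(rate, 1e-6), 1 - 1e-6)) +
        0.5 * (y[, "depressed_mood"] - mean(gt$mu))
      absent <- runif(n) < plogis(lp)
    } else {
      absent <- runif(n) < rate
    }
    if (latent_only) {
      scores <- y
    } else {
      scores <- vapply(seq_len(p), function(i)
        findInterval(y[, i], gt$cutpoints[[items$name[i]]]),
        integer(n))
    }
    scores[absent, ] <- NA
    df <- data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      trial_id = sprintf("T%02d", trial),
      arm = arm, age = age, sex = sex, week = w,
      stringsAsFactors = FALSE
    )
    df[items$name] <- as.data.frame(scores)
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$week), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "items") <- items
  attr(out, "latent") <- latent_only
  class(out) <- c("trial_data", "data.frame")
  out
}

item_columns <- function(data) {
  items <- attr(data, "items") %||% hdrs_items()
  intersect(items$name, names(data))
}
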