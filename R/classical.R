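#' Pooled-variance two-sample t-test
#'
#' Classical Student's t (equal-variance) comparison of two groups, two-sided.
#' `groupA` is the active arm and `groupB` placebo under the package's sign
#' convention (negative t = lower scores under active treatment).
#'
#' @param groupA,groupB numeric vectors, each with >= 2 finite values.
#' @param welch use the Welch (unequal-variance) variant instead.
#' @return `list(t, df, p)`.
#' @export
students_t <- function(groupA, groupB, welch = FALSE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop_("each group needs at least 2 values")
  if (sd(groupA) == 0 && sd(groupB) == 0 && mean(groupA) == mean(groupB)) {
    n <- length(groupA) + length(groupB)
    return(list(t = 0, df = if (welch) NA_real_ else n - 2, p = 1))
  }
  ht <- stats::t.test(groupA, groupB, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Cohen's d (pooled standard deviation)
#'
#' Standardized mean difference `(mean(groupA) - mean(groupB)) / s_pooled`
#' with `s_pooled^2 = ((n1-1)s1^2 + (n0-1)s0^2) / (n1+n0-2)`. Negative values
#' mean lower scores in `groupA` (the active arm convention).
#'
#' @param groupA,groupB numeric vectors, each with >= 2 values.
#' @return The effect size; `NA` (undefined) if the pooled SD is zero.
#' @export
cohens_d <- function(groupA, groupB) {
  n1 <- length(groupA); n0 <- length(groupB)
  if (n1 < 2 || n0 < 2) stop_("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * var(groupA) + (n0 - 1) * var(groupB)) / (n1 + n0 - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(groupA) - mean(groupB)) / sqrt(sp2)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction (sample sizes in scope are large), df = 1.
#'
#' @param table 2x2 matrix of counts.
#' @return `list(statistic, p)`.
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_("zero marginal in 2x2 table")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Bonferroni-corrected per-test threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param fwer familywise error rate in (0, 1), default 0.05.
#' @return `fwer / n_tests` (unrounded; reporting layers round to 3 decimals).
#' @export
#' @examples
#' round(bonferroni_alpha(17), 3)  # 0.003
bonferroni_alpha <- function(n_tests, fwer = 0.05) {
  if (n_tests < 1) stop_("n_tests must be >= 1")
  if (fwer <= 0 || fwer >= 1) stop_("fwer must be in (0,1)")
  fwer / n_tests
}

#' Baseline comparison table
#'
#' Per-arm summaries and tests at the pretreatment assessment: chi-square for
#' sex, pooled t for age, and pooled t per symptom with the Bonferroni
#' threshold `fwer/17` applied to the 17 symptom tests only (sex and age are
#' tested at `fwer`).
#'
#' @param data a `trial_data` data.frame with week-0 records.
#' @param fwer familywise error rate for the symptom block (default 0.05).
#' @return data.frame with per-variable arm summaries, statistic, `p`,
#'   `threshold` and `significant` flag.
#' @export
baseline_table <- function(data, fwer = 0.05) {
  if (!0 %in% data$week) stop_("no week-0 records")
  items <- item_columns(data)
  b <- data[data$week == 0, , drop = FALSE]
  b <- b[stats::complete.cases(b[, items, drop = FALSE]), , drop = FALSE]
  if (length(unique(b$arm)) < 2) stop_("single-arm data: arm column is constant")
  act <- b[b$arm == 1, , drop = FALSE]
  plc <- b[b$arm == 0, , drop = FALSE]
  thr <- bonferroni_alpha(length(items), fwer)

  rows <- list()
  if ("sex" %in% names(b)) {
    tab <- matrix(c(sum(plc$sex == 1), sum(plc$sex == 0),
                    sum(act$sex == 1), sum(act$sex == 0)), 2, 2)
    cs <- chi_square_2x2(tab)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "sex", type = "categorical",
      placebo = sprintf("%d (%.1f%%)", sum(plc$sex == 1), 100 * mean(plc$sex)),
      active = sprintf("%d (%.1f%%)", sum(act$sex == 1), 100 * mean(act$sex)),
      statistic = cs$statistic, p = cs$p, threshold = fwer,
      significant = cs$p < fwer, stringsAsFactors = FALSE)
  }
  if ("age" %in% names(b)) {
    tt <- students_t(act$age, plc$age)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "age", type = "continuous",
      placebo = sprintf("%.1f (%.1f)", mean(plc$age), sd(plc$age)),
      active = sprintf("%.1f (%.1f)", mean(act$age), sd(act$age)),
      statistic = tt$t, p = tt$p, threshold = fwer,
      significant = tt$p < fwer, stringsAsFactors = FALSE)
  }
  for (it in items) {
    tt <- students_t(act[[it]], plc[[it]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = it, type = "symptom",
      placebo = sprintf("%.2f (%.2f)", mean(plc[[it]]), sd(plc[[it]])),
      active = sprintf("%.2f (%.2f)", mean(act[[it]]), sd(act[[it]])),
      statistic = tt$t, p = tt$p, threshold = thr,
      significant = tt$p < thr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_placebo") <- nrow(plc)
  attr(out, "n_active") <- nrow(act)
  out
}

#' Overall (unconditional) treatment effects per week
#'
#' Per week x symptom, on that week's complete cases (the same patients as the
#' corresponding network run): pooled-variance t-test and Cohen's d of active
#' vs placebo scores.
#'
#' @param data a `trial_data` data.frame.
#' @param weeks follow-up weeks (default all present follow-up weeks).
#' @return An `effect_size_table` data.frame with columns `week`, `symptom`,
#'   `n_active`, `n_placebo`, `mean_active`, `mean_placebo`, `sd_active`,
#'   `sd_placebo`, `t`, `df`, `p`, `cohens_d`.
#' @export
overall_effects <- function(data, weeks = NULL) {
  weeks <- weeks %||% setdiff(sort(unique(data$week)), 0)
  items <- item_columns(data)
  rows <- list()
  for (w in weeks) {
    cc <- complete_case_week(data, w)
    m <- cc$matrix
    act <- m[m$arm == 1, , drop = FALSE]
    plc <- m[m$arm == 0, , drop = FALSE]
    for (it in items) {
      tt <- students_t(act[[it]], plc[[it]])
      rows[[length(rows) + 1L]] <- data.frame(
        week = w, symptom = it,
        n_active = nrow(act), n_placebo = nrow(plc),
        mean_active = mean(act[[it]]), mean_placebo = mean(plc[[it]]),
        sd_active = sd(act[[it]]), sd_placebo = sd(plc[[it]]),
        t = tt$t, df = tt$df, p = tt$p,
        cohens_d = cohens_d(act[[it]], plc[[it]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_size_table", "data.frame")
  out
}

#' Compare direct (network) and overall (unconditional) effects
#'
#' Side-by-side table of the treatment-edge weight and Cohen's d per week x
#' symptom, with a discordance flag: `"indirect_dominant"` when `|d| >=
#' d_threshold` but the direct edge is zero (the symptom changes only through
#' its connections), `"direct_only"` for the converse.
#'
#' @param traj a `direct_effect_trajectory`.
#' @param table an `effect_size_table` over matching weeks and symptoms.
#' @param d_threshold discordance threshold on `|d|` (default 0.15).
#' @return data.frame `week`, `symptom`, `direct`, `overall_d`, `flag`.
#' @export
direct_vs_overall <- function(traj, table, d_threshold = 0.15) {
  tw <- sort(unique(table$week))
  if (!setequal(traj$weeks, tw) || !setequal(traj$symptoms, unique(table$symptom)))
    stop_("mismatched weeks or symptom labels between trajectory and table")
  rows <- list()
  for (w in traj$weeks) for (s in traj$symptoms) {
    direct <- traj$values[as.character(w), s]
    d <- table$cohens_d[table$week == w & table$symptom == s]
    flag <- if (abs(d) >= d_threshold && direct == 0) {
      "indirect_dominant"
    } else if (abs(direct) >= d_threshold && abs(d) < d_threshold) {
      "direct_only"
    } else ""
    rows[[length(rows) + 1L]] <- data.frame(
      week = w, symptom = s, direct = direct, overall_d = d, flag = flag,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
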