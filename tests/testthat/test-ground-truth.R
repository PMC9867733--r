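test_that("item battery has the documented composition", {
  it <- hdrs_items()
  expect_equal(nrow(it), 17L)
  expect_equal(as.integer(table(it$category)[c("affective", "cognitive",
                                               "arousal_somatic", "sleep",
                                               "insight")]),
               c(2L, 4L, 7L, 3L, 1L))
  # 0-4 items: all affective/cognitive plus somatic anxiety, hypochondriasis
  four <- it$name[it$scale_max == 4]
  expect_setequal(four, c(it$name[it$category %in% c("affective", "cognitive")],
                          "somatic_anxiety", "hypochondriasis"))
  expect_true(all(it$scale_max[!it$name %in% four] == 2))
})

test_that("paper_like scenario stores the printed calibration exactly", {
  gt <- make_ground_truth("paper_like")
  pc <- partial_correlations(gt$Omega)
  expect_equal(pc["depressed_mood", "psychic_anxiety"], 0.20, tolerance = 1e-10)
  expect_equal(pc["psychic_anxiety", "agitation"], 0.19, tolerance = 1e-10)
  expect_equal(pc["psychic_anxiety", "somatic_anxiety"], 0.19, tolerance = 1e-10)
  expect_equal(pc["psychic_anxiety", "guilt"], 0.12, tolerance = 1e-10)
  expect_equal(pc["psychic_anxiety", "work_activities"], 0.10, tolerance = 1e-10)
  # mood-cognitive block spans the printed 0.20-0.31 range
  cog <- gt$items$name[gt$items$category == "cognitive"]
  expect_equal(min(pc["depressed_mood", cog]), 0.20, tolerance = 1e-10)
  expect_equal(max(pc["depressed_mood", cog]), 0.31, tolerance = 1e-10)
  # direct (conditional) treatment-effect anchors
  expect_equal(gt$direct_targets["1", "depressed_mood"], -0.09)
  expect_equal(gt$direct_targets["6", "depressed_mood"], -0.17)
  expect_equal(gt$direct_targets["2", "psychic_anxiety"], -0.09)
  expect_equal(gt$direct_targets["6", "psychic_anxiety"], -0.11)
  expect_equal(gt$direct_targets["1", "genital"], 0.02)
  expect_equal(gt$direct_targets["6", "genital"], 0.11)
  expect_equal(gt$direct_targets["1", "weight_loss"], 0.16)
  expect_equal(gt$direct_targets["6", "weight_loss"], 0.03)
})

test_that("marginal shifts are consistent with the conditional targets", {
  gt <- make_ground_truth("paper_like")
  # Omega delta = diag(Omega) * target => conditional effect of every
  # non-target symptom is exactly zero and of targets exactly the anchor
  for (w in c("1", "6")) {
    cond <- as.numeric(gt$Omega %*% gt$delta[[w]]) / unname(diag(gt$Omega))
    expect_equal(unname(cond), unname(gt$direct_targets[w, ]),
                 tolerance = 1e-10)
  }
  # the implied marginal shift on mood lands near the printed overall d -0.40
  expect_lt(gt$delta[["6"]][1], -0.3)
  expect_gt(gt$delta[["6"]][1], -0.45)
})

test_that("ground-truth invariants hold across scenarios", {
  for (sc in c("paper_like", "null", "dense_random")) {
    gt <- make_ground_truth(sc)
    ev <- eigen(gt$Omega, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(gt$Omega, t(gt$Omega), tolerance = 1e-12)
    expect_equal(gt$delta[["0"]], numeric(17))
    for (i in seq_len(17)) {
      cp <- gt$cutpoints[[gt$items$name[i]]]
      expect_length(cp, gt$items$scale_max[i])
      expect_true(all(diff(cp) > 0))
    }
  }
})

test_that("null scenario has zero shifts and identity precision", {
  gt <- make_ground_truth("null")
  expect_true(all(vapply(gt$delta, function(d) all(d == 0), logical(1))))
  expect_equal(unname(gt$Omega), diag(17))
})

test_that("dense_random is reproducible from its seed and varies with it", {
  g1 <- make_ground_truth("dense_random")
  g2 <- make_ground_truth("dense_random")
  g3 <- make_ground_truth("dense_random", overrides = list(seed = 7L))
  expect_identical(g1$Omega, g2$Omega)
  expect_false(identical(g1$Omega, g3$Omega))
})

test_that("scenario and override validation errors fire", {
  expect_error(make_ground_truth("unknown"))
  expect_error(make_ground_truth("paper_like", overrides = list(bogus = 1)),
               "unknown override")
  bad <- diag(17); bad[1, 2] <- bad[2, 1] <- 2   # not PD
  dimnames(bad) <- list(hdrs_items()$name, hdrs_items()$name)
  expect_error(make_ground_truth("paper_like", overrides = list(Omega = bad)),
               "positive definite")
  expect_error(make_ground_truth("null", overrides = list(p_treat = 1.2)),
               "p_treat")
})

test_that("default missing schedule matches the printed completeness", {
  ms <- default_missing_schedule()
  expect_equal(unname(ms["6"]), 1 - 0.589)
  expect_equal(unname(ms["1"]), 1 - 0.913)
  expect_equal(unname(ms["2"]), 1 - 0.825)
  expect_equal(unname(ms["3"]), 1 - 0.691)
  expect_equal(unname(ms["4"]), 1 - 0.753)
  expect_true(all(ms >= 0 & ms < 1))
  # non-monotone by design: week 3 less complete than week 4
  expect_gt(ms["3"], ms["4"])
})
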