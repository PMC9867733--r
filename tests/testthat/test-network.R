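mk_fit <- function(node, coefs, lambda = 0.1, family = "gaussian") {
  structure(list(intercept = 0, coefficients = coefs, lambda = lambda,
                 family = family, node = node), class = "nodewise_fit")
}

test_that("AND/OR aggregation follows the stated rule", {
  fits <- list(
    A = mk_fit("A", c(B = -0.2)),
    B = mk_fit("B", c(A = -0.1))
  )
  net <- combine_nodewise(fits, "AND")
  expect_equal(net$weights["A", "B"], -0.15)
  expect_equal(net$signs["A", "B"], -1)

  fits2 <- list(A = mk_fit("A", c(B = 0.2)), B = mk_fit("B", c(A = 0)))
  expect_equal(combine_nodewise(fits2, "AND")$weights["A", "B"], 0)
  net_or <- combine_nodewise(fits2, "OR")
  expect_equal(net_or$weights["A", "B"], 0.1)
  expect_equal(net_or$signs["A", "B"], 1)

  fits3 <- list(A = mk_fit("A", c(B = 0.2)), B = mk_fit("B", c(A = -0.3)))
  expect_warning(net3 <- combine_nodewise(fits3, "AND"), "disagreement")
  expect_equal(net3$weights["A", "B"], 0.25)
  expect_true(is.na(net3$signs["A", "B"]))

  bad <- list(A = mk_fit("A", c(C = 1)), B = mk_fit("B", c(A = 1)))
  expect_error(combine_nodewise(bad, "AND"), "misaligned")
})

test_that("weights are symmetric with zero diagonal and signs track zeros", {
  d <- recovery_data(n = 700, weeks = c(0, 6), seed = 21)
  cc <- complete_case_week(d, 6)
  net <- estimate_network(cc$matrix, node_spec(battery$name), quick_cfg(3))
  expect_equal(net$weights, t(net$weights))
  expect_equal(unname(diag(net$weights)), rep(0, 18))
  expect_equal(net$weights == 0, net$signs == 0)
  expect_equal(net$n_samples, cc$n)
})

test_that("estimation preconditions are enforced", {
  d <- recovery_data(n = 100, weeks = c(0, 6), seed = 2)
  cc <- complete_case_week(d, 6)
  m <- cc$matrix
  m$depressed_mood[1] <- NA
  expect_error(estimate_network(m, node_spec(battery$name), quick_cfg()),
               "complete-case")
  expect_error(estimate_network(cc$matrix[1:10, ], node_spec(battery$name),
                                quick_cfg()),
               "more rows than nodes")
})

test_that("null-scenario latent data yields no substantial treatment edges", {
  d <- recovery_data(n = 2000, weeks = c(0, 6), seed = 31, scenario = "null")
  cc <- complete_case_week(d, 6)
  net <- estimate_network(cc$matrix, node_spec(battery$name),
                          network_config(seed = 13))
  expect_true(all(abs(net$weights["arm", ]) <= 0.05))
})

test_that("paper_like week-6 data recovers a negative treatment-mood edge", {
  d <- recovery_data(n = 2500, weeks = c(0, 6), seed = 41)
  cc <- complete_case_week(d, 6)
  net <- estimate_network(cc$matrix, node_spec(battery$name),
                          network_config(seed = 17))
  expect_lt(net$weights["arm", "depressed_mood"], 0)
})

test_that("node-subset estimation reproduces the full network's edge values", {
  d <- recovery_data(n = 900, weeks = c(0, 6), seed = 51)
  cc <- complete_case_week(d, 6)
  cfg <- quick_cfg(19)
  full <- estimate_network(cc$matrix, node_spec(battery$name), cfg)
  sub <- estimate_network(cc$matrix, node_spec(battery$name), cfg,
                          only_nodes = c("arm", "depressed_mood"))
  expect_equal(sub$weights["arm", "depressed_mood"],
               full$weights["arm", "depressed_mood"])
})

test_that("re-running on rowwise-duplicated data is deterministic", {
  d <- recovery_data(n = 1200, weeks = c(0, 6), seed = 61)
  cc <- complete_case_week(d, 6)
  dup <- rbind(cc$matrix, cc$matrix)
  cfg <- quick_cfg(23)
  n1 <- estimate_network(dup, node_spec(battery$name), cfg)
  n2 <- estimate_network(dup, node_spec(battery$name), cfg)
  expect_identical(n1$weights, n2$weights)
  # the dominant treatment edge survives duplication (fold noise aside)
  n0 <- estimate_network(cc$matrix, node_spec(battery$name), cfg)
  expect_lt(n1$weights["arm", "depressed_mood"], 0)
  expect_lt(n0$weights["arm", "depressed_mood"], 0)
})

test_that("edge extraction returns tidy rows", {
  W <- toy_weights(c("m", "g"))
  W["arm", "m"] <- W["m", "arm"] <- -0.2
  model <- toy_model(W)
  ed <- network_edges(model)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$weight, -0.2)
  expect_setequal(c(ed$node_a, ed$node_b), c("arm", "m"))
})
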