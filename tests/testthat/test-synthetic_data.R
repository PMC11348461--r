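test_that("generation is deterministic and honours the planted structure", {
  spec <- synthetic_spec(30, 12, n_degenerate = 3, n_collinear_pairs = 2,
                         response_kind = "linear",
                         true_support = c("d9", "d10"),
                         true_coefficients = c(1, -2), noise_sd = 0.1,
                         seed = 17)
  g1 <- generate_synthetic(spec)
  g2 <- generate_synthetic(spec)
  expect_identical(g1, g2)
  # degenerate block is exactly what drop_degenerate removes
  out <- drop_degenerate(g1$table)
  expect_setequal(out$dropped_degenerate, g1$truth$degenerate_labels)
  expect_length(g1$truth$degenerate_labels, 3L)
  # generated tables pass container validation by construction
  expect_s3_class(g1$table, "descriptor_table")
  expect_equal(dim(g1$table), c(30L, 12L))
})

test_that("collinear pairs land in the engineered correlation band", {
  spec <- synthetic_spec(1000, 6, n_collinear_pairs = 1, collinear_r = 0.99,
                         true_support = c("d5", "d6"), seed = 23)
  g <- generate_synthetic(spec)
  pair <- g$truth$collinear_pairs
  r <- cor(g$table$values[, pair$base], g$table$values[, pair$derived])
  expect_gt(abs(r), 0.985)
  expect_lt(abs(r), 0.995)
})

test_that("noiseless linear responses give machine-precision fits", {
  spec <- synthetic_spec(25, 8, response_kind = "linear",
                         true_support = c("d2", "d5"),
                         true_coefficients = c(3, -1.5), intercept = 0.7,
                         noise_sd = 0, seed = 31)
  g <- generate_synthetic(spec)
  fit <- fit_ols(g$table$values[, c("d2", "d5")], g$table$activity)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), c(3, -1.5), tolerance = 1e-10)
  expect_equal(fit$intercept, 0.7, tolerance = 1e-10)
})

test_that("expression responses evaluate the planted formula exactly", {
  spec <- synthetic_spec(50, 5, response_kind = "expression",
                         true_support = c("d1", "d2", "d3"),
                         true_expression = "d1 + d2 * d3", noise_sd = 0,
                         seed = 47)
  g <- generate_synthetic(spec)
  v <- g$table$values
  expect_equal(g$table$activity, unname(v[, "d1"] + v[, "d2"] * v[, "d3"]),
               tolerance = 1e-12)
  expect_equal(g$truth$noiseless_response, g$table$activity)
  # only arithmetic over the declared support is allowed
  expect_error(synthetic_spec(10, 5, response_kind = "expression",
                              true_support = "d1",
                              true_expression = "sin(d1)"), "may only use")
  expect_error(synthetic_spec(10, 5, response_kind = "expression",
                              true_support = "d1",
                              true_expression = "d1 + d4"), "outside")
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(10, 5, n_degenerate = 2, n_collinear_pairs = 2,
                              true_support = "d5"), "exceeds")
  expect_error(synthetic_spec(10, 5, noise_sd = -1), "noise_sd")
  expect_error(synthetic_spec(10, 5, true_support = "d9"), "must name")
  expect_error(synthetic_spec(10, 5, response_kind = "expression",
                              true_support = "d1"), "required")
})

test_that("recovery scoring distinguishes hits, misses and symbolic identity", {
  spec <- synthetic_spec(40, 10, response_kind = "linear",
                         true_support = c("d4", "d6"),
                         true_coefficients = c(2, 1), noise_sd = 0, seed = 53)
  g <- generate_synthetic(spec)
  hit <- score_recovery(g$truth, selected = c("d6", "d4"))
  expect_true(hit$support_recovered)
  miss <- score_recovery(g$truth, selected = c("d1", "d2"))
  expect_false(miss$support_recovered)
  fit <- fit_ols(g$table$values[, c("d4", "d6")], g$table$activity)
  sc <- score_recovery(g$truth, selected = fit$descriptors, model = fit)
  expect_equal(sc$coefficient_rmse, 0, tolerance = 1e-10)
  # evolved tree identical to the truth scores zero RMSE; invalid rows Inf
  sc2 <- score_recovery(g$truth, predictions = g$truth$noiseless_response)
  expect_equal(sc2$expression_rmse, 0)
  bad <- g$truth$noiseless_response; bad[3] <- NA
  expect_equal(score_recovery(g$truth, predictions = bad)$expression_rmse, Inf)
})

test_that("screening plus selection recovers well-separated planted supports", {
  # support correlations comfortably above the relevance floor survive the
  # screen; the screen-then-select path then recovers the support
  ok <- vapply(1:25, function(s) {
    spec <- synthetic_spec(40, 20, n_degenerate = 2, n_collinear_pairs = 1,
                           response_kind = "linear",
                           true_support = c("d10", "d15"),
                           true_coefficients = c(1, 2), noise_sd = 0.05,
                           seed = s)
    g <- generate_synthetic(spec)
    scr <- screen_descriptors(g$table)
    tr <- forward_select(scr$table, k_max = 3)
    score_recovery(g$truth,
                   selected = tr$models[[length(tr$models)]]$descriptors
    )$support_recovered
  }, logical(1))
  expect_true(all(ok))
})
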