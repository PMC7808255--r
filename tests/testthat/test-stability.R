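# The printed (ddG, unfolding) pairs of the published mutation tables,
# used to gate the two-state conversion.
published_pairs <- function() {
  rbind(
    data.frame(mutation = c("W39R", "R77G", "K142M", "S323R", "T325A",
                            "M370V", "V393D", "R402G"),
               ddg = c(1.2, 5.7, -1.7, 0.8, -0.3, 4.5, 4.8, 2.1),
               unfolding = c(0.88, 1, 0.06, 0.8, 0.39, 1, 1, 0.97)),
    data.frame(mutation = c("H180N", "H180R", "H202R", "H202Q", "H211R",
                            "H363T", "H363R", "H363Y", "H367Y", "H367R",
                            "H390D"),
               ddg = c(-0.95, 2.16, 2.81, 1.36, 9.24, -1.46, -0.80,
                       1.58, 0.93, -0.91, -0.17),
               unfolding = c(0.17, 0.97, 0.99, 0.91, 1.00, 0.08, 0.21,
                             0.93, 0.82, 0.18, 0.43)))
}

test_that("the two-state conversion reproduces the published unfolding values", {
  tab <- published_pairs()
  u <- round(unfolding_propensity(tab$ddg), 2)
  matches <- abs(u - tab$unfolding) <= 0.01 + 1e-12
  expect_gte(sum(matches), 15) # conversion-adoption gate
  # packaged fixtures carry the same ddg values
  expect_equal(oca1_mutations("oca1b")$ddg, tab$ddg[1:8])
  expect_equal(oca1_mutations("oca1a")$ddg, tab$ddg[9:19])
  # reference tables load with the expected shapes
  expect_equal(dim(oca1_reference("copper_distances")), c(12, 4))
  expect_equal(nrow(oca1_reference("interface_cavity")), 9)
})

test_that("unfolding propensity has the two-state symmetry properties", {
  expect_identical(unfolding_propensity(0), 0.5)
  expect_equal(unfolding_propensity(50), 1.0, tolerance = 1e-12)
  expect_equal(unfolding_propensity(-50), 0.0, tolerance = 1e-12)
  grid <- seq(-6, 6, by = 0.25)
  u <- unfolding_propensity(grid)
  expect_true(all(diff(u) > 0)) # strictly increasing in ddG
  expect_equal(unfolding_propensity(-grid), 1 - u, tolerance = 1e-12)
  expect_error(unfolding_propensity(NA), "finite")
  expect_error(unfolding_propensity(1, temperature = 0), "positive")
  # higher temperature flattens the curve toward 0.5
  expect_lt(unfolding_propensity(1, temperature = 400),
            unfolding_propensity(1, temperature = 298))
})

test_that("severity binning rounds to 2 decimals first", {
  expect_equal(classify_severity(0.80), "moderate")
  expect_equal(classify_severity(0.88), "severe")
  expect_equal(classify_severity(0.195), "moderate") # rounds to 0.20
  expect_equal(classify_severity(0.19), "weak")
  expect_equal(classify_severity(0.804), "moderate")
  expect_equal(classify_severity(0.806), "severe")
  expect_error(classify_severity(1.2), "0, 1")
  # class never inverts as ddG grows
  cls <- classify_severity(unfolding_propensity(seq(-8, 8, by = 0.05)))
  ranks <- match(cls, c("weak", "moderate", "severe"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("predicted effect labels stabilizing mutations Severe", {
  expect_equal(predicted_effect(-1.7), "Severe") # stable but non-native
  expect_equal(predicted_effect(0.8), "Moderate")
  expect_equal(predicted_effect(0), "Moderate") # u = 0.5 bins moderate
  tab <- stability_table(published_pairs()[1:8, c("mutation", "ddg")])
  expect_equal(tab$predicted_effect,
               c("Severe", "Severe", "Severe", "Moderate", "Severe",
                 "Severe", "Severe", "Severe"))
})

test_that("foldability is the severity-weighted propensity sum", {
  expect_equal(foldability(c(0.9, 0.85, 0.5),
                           classes = c("severe", "severe", "moderate")),
               0.9 + 0.85 + 0.25)
  expect_equal(foldability(rep(0, 19), classes = rep("weak", 19)), 0)
  expect_equal(foldability(c(0.2, 0.3),
                           weights = c(weak = 1, moderate = 1, severe = 1)),
               0.5)
  expect_error(foldability(rep(0.5, 21)), "20")
  expect_error(foldability(0.5, weights = c(weak = -1, moderate = 0.5,
                                            severe = 1)), "non-negative")
})

test_that("the internal control behaves on identity mutations", {
  ic <- internal_control(rep(0, 10))
  expect_equal(ic$mean, 0.5)
  expect_equal(ic$sd, 0)
  expect_equal(ic$p_value, 1)
  # antisymmetry: symmetric ddG values average to exactly 0.5
  eps <- c(0.3, -0.3, 0.7, -0.7, 1.1, -1.1)
  expect_equal(internal_control(eps)$mean, 0.5, tolerance = 1e-9)
  expect_error(internal_control(0), "at least 2")

  # near-ideal models rarely reject the 0.5 null
  set.seed(99)
  pvals <- replicate(200, {
    internal_control(rnorm(100, 0, 0.1))$p_value
  })
  expect_gte(mean(pvals > 0.05), 0.95)
})
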