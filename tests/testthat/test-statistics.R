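test_that("variance conventions behave as defined", {
  # single band: zero variance under the fitted-center convention
  single <- suppressWarnings(
    lk_variance(lk_distribution(0L, 1, normalize = FALSE)))
  expect_equal(single, 0)
  # equal weights at -1, +1 about center 0
  d <- as_lk_distribution(data.frame(delta_lk = c(-1L, 1L),
                                     fraction = c(0.5, 0.5)))
  expect_equal(suppressWarnings(lk_variance(d)), 1.0)
  # reference-topoisomer mode is the densitometry-literal moment sum
  eq <- equilibrium_distribution(en43)
  expect_equal(lk_variance(eq, "reference_topoisomer", reference = 0L),
               lk_variance(eq), tolerance = 1e-6) # center is 0 here
  expect_error(lk_variance(eq, "reference_topoisomer"), "explicit")
  expect_error(lk_variance(eq, "reference_topoisomer", reference = 99L),
               "outside")
  # an off-center integer reference overestimates the variance
  eqo <- equilibrium_distribution(en43, support = -12:13, lk0_offset = 0.5)
  for (ref in c(-1L, 0L, 1L, 2L))
    expect_gte(lk_variance(eqo, "reference_topoisomer", reference = ref),
               lk_variance(eqo) - 1e-9)
})

test_that("Monte Carlo draws recover the model variance at large n", {
  set.seed(90)
  eq <- equilibrium_distribution(en43)
  draws <- sample(eq$support, 1e5, TRUE, eq$fractions)
  d <- as_lk_distribution(data.frame(delta_lk = draws, count = 1))
  se <- en43$sigma2_eq * sqrt(2 / 1e5)
  expect_equal(lk_variance(d), en43$sigma2_eq, tolerance = 3 * se)
})

test_that("fitted center recovers fractional Gaussian means and translates", {
  d <- equilibrium_distribution(en43, support = -12:13, lk0_offset = 0.7)
  expect_equal(distribution_center(d), 0.7, tolerance = 1e-6)
  expect_equal(distribution_center(equilibrium_distribution(en43)), 0,
               tolerance = 1e-9)
  shifted <- lk_distribution(d$support + 3L, d$fractions, normalize = FALSE)
  expect_equal(distribution_center(shifted), 3.7, tolerance = 1e-6)
  # sparse input falls back to the weighted mean with a warning
  expect_warning(
    ctr <- distribution_center(as_lk_distribution(
      data.frame(delta_lk = c(0L, 2L), fraction = c(0.5, 0.5)))),
    "weighted mean")
  expect_equal(ctr, 1)
})

test_that("R_Lk compares variances the way lane plots do", {
  eq <- equilibrium_distribution(en79, support = -16:16)
  expect_equal(r_lk(eq, eq), 1.0)
  ss <- stationary_closed_form(en79, gate_model(p0 = 5e-4, alpha = 0.6,
                                                pi0 = 0.01),
                               support = -16:16)
  expect_equal(r_lk(eq, ss), 1.6, tolerance = 0.01)
  # invariant under rescaling of raw band weights
  bt <- data.frame(delta_lk = ss$support, intensity = ss$fractions * 5000)
  expect_equal(r_lk(eq, bt), r_lk(eq, ss), tolerance = 1e-9)
})

test_that("delta Lk^S measures center displacement", {
  eq <- equilibrium_distribution(en43, support = -14:14)
  expect_equal(delta_lk_s(eq, eq), 0)
  shift <- lk0_temperature_shift(pbr322, 40, en43)
  eq_shift <- equilibrium_distribution(en43, support = -14:14,
                                       lk0_offset = shift)
  expect_equal(delta_lk_s(eq_shift, eq), shift, tolerance = 1e-6)
})

test_that("topoisomer ratios and their guards", {
  eq <- equilibrium_distribution(en43)
  expect_equal(adjacent_topoisomer_ratio(eq, -2, 0), 0.36, tolerance = 0.01)
  expect_equal(adjacent_topoisomer_ratio(eq, 3, 3), 1)
  expect_error(adjacent_topoisomer_ratio(eq, -50, 0), "support")
  d0 <- as_lk_distribution(data.frame(delta_lk = 0:1, fraction = c(1, 0)))
  expect_error(adjacent_topoisomer_ratio(d0, 0, 1), "zero weight")
})

test_that("parity split yields independent renormalized sub-distributions", {
  eq <- equilibrium_distribution(en43, support = -12:12)
  ps <- parity_split(eq)
  expect_equal(sum(ps$odd$fractions), 1)
  expect_equal(sum(ps$even$fractions), 1)
  expect_equal(sum(ps$masses), 1, tolerance = 1e-12)
  # exact reconstruction from the parts
  recon <- ps$odd$fractions * ps$masses[["odd"]] +
    ps$even$fractions * ps$masses[["even"]]
  expect_equal(recon, eq$fractions, tolerance = 1e-12)
  # both parity classes carry the full model variance
  expect_equal(lk_variance(ps$odd), en43$sigma2_eq, tolerance = 0.02)
  expect_equal(lk_variance(ps$even), en43$sigma2_eq, tolerance = 0.02)
  # all-even input: even class is the input, odd class empty and flagged
  d <- as_lk_distribution(data.frame(delta_lk = c(-2L, 0L, 2L),
                                     fraction = c(0.25, 0.5, 0.25)))
  ps2 <- parity_split(d)
  expect_true(isTRUE(attr(ps2$odd, "empty")))
  expect_equal(ps2$masses[["even"]], 1)
})

test_that("summary bundle reports the headline statistics together", {
  eq <- equilibrium_distribution(en79)
  ss <- stationary_closed_form(en79, gate_cal)
  s <- lk_summary(ss, equilibrium = eq)
  expect_equal(s$r_lk, 1 + gate_cal$alpha, tolerance = 1e-3)
  expect_equal(s$delta_lk_s, 0, tolerance = 1e-6)
  expect_equal(s$ratios[[1]]$ratio,
               adjacent_topoisomer_ratio(ss, -2, 0))
})
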