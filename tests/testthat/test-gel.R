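gp0 <- gel_params(noise_sd = 0) # noise-free rendering for exact checks

test_that("migration map is monotone in writhe magnitude and saturates", {
  gp <- gel_params()
  expect_equal(migration_map(0L, gp), 0)
  expect_gt(migration_map(2L, gp), migration_map(1L, gp))
  expect_gt(migration_map(-2L, gp), migration_map(-1L, gp)) # |writhe|
  expect_lt(migration_map(11L, gp) - migration_map(10L, gp),
            migration_map(2L, gp) - migration_map(1L, gp))
  # chloroquine offset shifts the writhe of every topoisomer
  expect_equal(migration_map(-3L, gp, chloroquine_offset = 3),
               migration_map(0L, gp, chloroquine_offset = 0))
})

test_that("synthetic lanes integrate to unit area and reproduce bitwise", {
  d <- equilibrium_distribution(en43)
  lane <- synth_lane(d, gp0, chloroquine_offset = 15)
  dx <- diff(lane$position[1:2])
  area <- sum(lane$intensity - gp0$baseline) * dx
  expect_equal(area, 1, tolerance = 1e-3)
  # single topoisomer: one Gaussian band of unit area
  one <- lk_distribution(0L, 1, normalize = FALSE)
  lane1 <- synth_lane(one, gp0, chloroquine_offset = 5)
  expect_equal(sum(lane1$intensity - gp0$baseline) * dx, 1,
               tolerance = 1e-3)
  expect_equal(lane1$position[which.max(lane1$intensity)],
               migration_map(0L, gp0, 5), tolerance = 0.1)
  # same seed, same noise: bitwise-identical profiles
  gpn <- gel_params(noise_sd = 0.01)
  a <- synth_lane(d, gpn, seed = 5, chloroquine_offset = 15)
  b <- synth_lane(d, gpn, seed = 5, chloroquine_offset = 15)
  expect_identical(a$intensity, b$intensity)
  expect_error(synth_lane(d, gpn), "seed")
  # bands closer than half a width are recorded as unresolved
  tight <- gel_params(noise_sd = 0, migration_gain = 0.2)
  lane_t <- synth_lane(d, tight, chloroquine_offset = 15)
  expect_gt(nrow(attr(lane_t, "unresolved")), 0)
})

test_that("quantification inverts rendering for resolvable bands", {
  d <- equilibrium_distribution(en43)
  off <- 15
  lane <- synth_lane(d, gp0, chloroquine_offset = off)
  pos <- stats::setNames(migration_map(d$support, gp0, off), d$support)
  bt <- quantify_lane(lane, pos)
  f <- bt$intensity / sum(bt$intensity)
  expect_lt(max(abs(f - d$fractions)), 1e-2)
  # linearity: doubling the profile doubles every band integral
  lane2 <- lane
  lane2$intensity <- 2 * lane$intensity
  attr(lane2, "params") <- attr(lane, "params")
  bt2 <- quantify_lane(lane2, pos)
  keep <- bt$intensity > 1e-6
  expect_equal(bt2$intensity[keep] / bt$intensity[keep],
               rep(2, sum(keep)), tolerance = 1e-2)
  # flat zero profile: every band flagged at zero intensity
  flat <- lane
  flat$intensity <- rep(0, nrow(flat))
  attr(flat, "params") <- attr(lane, "params")
  bt0 <- quantify_lane(flat, pos)
  expect_true(all(bt0$intensity == 0))
  expect_true(all(bt0$flagged))
  expect_error(quantify_lane(lane, c(`0` = 1e6)), "outside")
})

test_that("quantifier ignores out-of-model contaminant bands", {
  d <- equilibrium_distribution(en43)
  off <- 15
  # nicked and linear species migrate outside the topoisomer ladder
  spikes <- data.frame(position = c(3, 95), area = c(0.3, 0.2))
  lane <- synth_lane(d, gp0, chloroquine_offset = off,
                     contaminants = spikes)
  pos <- stats::setNames(migration_map(d$support, gp0, off), d$support)
  bt <- quantify_lane(lane, pos)
  f <- bt$intensity / sum(bt$intensity)
  expect_lt(max(abs(f - d$fractions)), 1e-2)
})

test_that("round-trip densitometry preserves the variance statistics", {
  for (en in list(en43, en79)) {
    d <- equilibrium_distribution(en)
    off <- max(abs(d$support)) + 1
    gp <- gel_params(noise_sd = 0.01 * max(
      synth_lane(d, gp0, chloroquine_offset = off)$intensity))
    lane <- synth_lane(d, gp, seed = 3, chloroquine_offset = off)
    pos <- stats::setNames(migration_map(d$support, gp, off), d$support)
    bt <- quantify_lane(lane, pos)
    expect_equal(lk_variance(bt), lk_variance(d),
                 tolerance = 0.05 * lk_variance(d))
  }
})

test_that("R_Lk survives the full gel pipeline at default parameters", {
  eq <- equilibrium_distribution(en79)
  ss <- stationary_closed_form(en79, gate_cal)
  gp <- gel_params()
  pipeline <- function(d, seed) {
    lane <- synth_lane(d, gp, seed = seed)
    pos <- stats::setNames(migration_map(d$support, gp, 0), d$support)
    quantify_lane(lane, pos)
  }
  r_gel <- r_lk(pipeline(eq, 11), pipeline(ss, 12))
  expect_lt(abs(r_gel - r_lk(eq, ss)), 0.1)
})

test_that("lane and band-table files round trip", {
  d <- equilibrium_distribution(en43)
  lane <- synth_lane(d, gp0, chloroquine_offset = 15)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_lane_profile(lane, p1)
  back <- read_lane_profile(p1)
  expect_equal(back$intensity, lane$intensity, tolerance = 1e-6)
  pos <- stats::setNames(migration_map(d$support, gp0, 15), d$support)
  bt <- quantify_lane(lane, pos)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_band_table(bt, p2)
  bt2 <- read_band_table(p2)
  expect_equal(bt2$intensity, bt$intensity, tolerance = 1e-6)
  expect_equal(lk_variance(bt2), lk_variance(d), tolerance = 0.02)
})
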