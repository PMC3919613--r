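test_that("closed-form stationary law narrows by exactly 1 + alpha", {
  g <- gate_model(p0 = 5e-4, alpha = 0.66, pi0 = 0.01)
  ss <- stationary_closed_form(en43, g, support = -15:15)
  expect_distribution_ok(ss)
  expect_equal(adjacent_topoisomer_ratio(ss, -2, 0),
               exp(-1.023256)^(1 + 0.66), tolerance = 1e-4)
  expect_lt(abs(adjacent_topoisomer_ratio(ss, -2, 0) - 0.18), 0.005)
  eq <- equilibrium_distribution(en43, support = -15:15)
  expect_equal(lk_moment(eq, 2L, central = TRUE) /
                 lk_moment(ss, 2L, central = TRUE),
               1 + 0.66, tolerance = 1e-4)
  # alpha = 0 reduces to thermal equilibrium
  ss0 <- stationary_closed_form(en43, gate_model(p0 = 5e-4, alpha = 0,
                                                 pi0 = 0.01),
                                support = -15:15)
  expect_equal(ss0$fractions, eq$fractions, tolerance = 1e-12)
  expect_error(stationary_closed_form(en43, g, mode = enzyme_mode("AMPPNP")),
               "ATP, intact")
})

test_that("matrix-solved stationary distribution matches the closed form", {
  for (alpha in c(0, 0.66, 1.2)) {
    g <- gate_model(p0 = 5e-4, alpha = alpha, pi0 = 0.01)
    sn <- stationary_numeric(en43, g, support = -15:15)
    sc <- stationary_closed_form(en43, g, support = -15:15)
    expect_lt(max(abs(sn$fractions - sc$fractions)), 1e-8)
  }
  # deleted C-gate: no release challenge, stationary = equilibrium
  g <- gate_model(p0 = 5e-4, alpha = 0.9, pi0 = 0.01)
  sn <- stationary_numeric(en43, g, mode = enzyme_mode("ATP", "deleted"),
                           support = -15:15)
  eq <- equilibrium_distribution(en43, support = -15:15)
  expect_lt(max(abs(sn$fractions - eq$fractions)), 1e-8)
  # single-state support collapses to that state
  s1 <- stationary_numeric(en43, g, support = 3L)
  expect_equal(s1$support, 3L)
  expect_equal(s1$fractions, 1)
  # absorbing modes have no stationary law
  expect_error(stationary_numeric(en43, g, mode = enzyme_mode("AMPPNP")),
               "ergodic")
  expect_error(stationary_numeric(en43, g,
                                  mode = enzyme_mode("ATP", "locked")),
               "ergodic")
})

test_that("R_Lk of the stationary state grows monotonically in alpha from 1", {
  eq <- equilibrium_distribution(en43, support = -15:15)
  alphas <- c(0, 0.3, 0.7, 1.2, 2)
  rl <- vapply(alphas, function(a) {
    ss <- stationary_closed_form(en43, gate_model(p0 = 5e-4, alpha = a,
                                                  pi0 = 0.01),
                                 support = -15:15)
    r_lk(eq, ss)
  }, numeric(1))
  expect_equal(rl[1], 1, tolerance = 1e-6)
  expect_true(all(diff(rl) > 0))
  expect_equal(rl, 1 + alphas, tolerance = 1e-3)
})

test_that("population simulation conserves molecules and parity, reproducibly", {
  eq <- equilibrium_distribution(en43)
  tr <- simulate_population(eq, 2000, 60, enzyme_mode(), gate_cal, en43,
                            seed = 101)
  per_cycle <- tapply(tr$counts$count, tr$counts$cycle, sum)
  expect_true(all(per_cycle == 2000))
  odd_per_cycle <- tapply(tr$counts$count[tr$counts$delta_lk %% 2 != 0],
                          tr$counts$cycle[tr$counts$delta_lk %% 2 != 0], sum)
  expect_equal(length(unique(odd_per_cycle)), 1L)

  tr2 <- simulate_population(eq, 2000, 60, enzyme_mode(), gate_cal, en43,
                             seed = 101)
  expect_identical(tr$final_states, tr2$final_states)
  tr3 <- simulate_population(eq, 2000, 60, enzyme_mode(), gate_cal, en43,
                             seed = 102)
  expect_false(identical(tr$final_states, tr3$final_states))

  # zero cycles returns the initial ensemble unchanged
  tr0 <- simulate_population(eq, 500, 0, enzyme_mode(), gate_cal, en43,
                             seed = 7)
  set.seed(7)
  expect_identical(sort(tr0$final_states),
                   sort(sample(eq$support, 500, TRUE, eq$fractions)))
  expect_error(simulate_population(eq, 0, 10, enzyme_mode(), gate_cal, en43,
                                   seed = 1), "n_molecules")
  expect_error(simulate_population(eq, 10, 10, enzyme_mode(), gate_cal,
                                   en43), "seed")
})

test_that("simulated proofreading steady state reproduces the closed-form narrowing", {
  eq <- equilibrium_distribution(en79)
  tr <- simulate_population(eq, 5000, 300, enzyme_mode(), gate_cal, en79,
                            0.5, seed = 31, record = FALSE)
  expect_equal(r_lk(eq, tr$final), 1 + gate_cal$alpha, tolerance = 0.08)
  # C-gate deleted: relaxation but no simplification, R_Lk stays ~1
  trd <- simulate_population(eq, 5000, 300, enzyme_mode("ATP", "deleted"),
                             gate_cal, en79, 0.5, seed = 32, record = FALSE)
  expect_equal(r_lk(eq, trd$final), 1, tolerance = 0.06)
})

test_that("release exponent is recoverable from simulated stationary ratios", {
  eq <- equilibrium_distribution(en43)
  tr <- simulate_population(eq, 10000, 400, enzyme_mode(), gate_cal, en43,
                            0.5, seed = 55, record = FALSE)
  c_ss <- adjacent_topoisomer_ratio(tr$final, -2, 0)
  c_eq <- exp(-1.023256)
  alpha_hat <- log(c_ss) / log(c_eq) - 1
  expect_equal(alpha_hat, gate_cal$alpha, tolerance = 0.12)
})

test_that("one-passage assay fractions estimate capture probabilities", {
  p0 <- calibrate_p0(0.50, -2L, 0L, en43)
  g <- gate_model(p0 = p0)
  f_m2 <- one_step_capture_assay(-2L, 10000, g, en43, seed = 61)
  f_0 <- one_step_capture_assay(0L, 10000, g, en43, seed = 62)
  expect_equal(sum(f_m2), 1)
  expect_lt(abs(f_m2[["0"]] - 0.50), 0.02)
  expect_lt(abs(f_0[["-2"]] - 0.18), 0.02)
  expect_lt(abs(f_0[["-2"]] / f_m2[["0"]] - 0.36), 0.04)
})

test_that("blocked N-gate broadening is stoichiometric and sub-equilibrium", {
  eq <- equilibrium_distribution(en79)
  run_block <- function(ratio, seed) {
    apply_protocol(eq, 4000, 250, enzyme_mode(), gate_cal, en79,
                   plasmid = ycp50, enzyme_to_dna_ratio = 0.5,
                   events = list(
                     protocol_event(150L, "set_enzyme_ratio", ratio),
                     protocol_event(151L, "switch_n_gate_agent", "AMPPNP")),
                   seed = seed, record = FALSE)
  }
  r1 <- run_block(1, 71)
  r2 <- run_block(2, 71)
  v_eq <- lk_variance(eq)
  v_before <- r1$phases[[1]]$variance
  expect_lt(v_before, v_eq) # narrowed steady state
  v1 <- r1$phases[[length(r1$phases)]]$variance
  v2 <- r2$phases[[length(r2$phases)]]$variance
  expect_gt(v1, v_before)        # broadening on block
  expect_gt(v2, v1)              # more enzyme, more broadening
  expect_lt(v2, v_eq * 1.03)     # toward, not beyond, equilibrium
})

test_that("temperature inversion with a locked C-gate reverses trapped passages", {
  frac_at <- function(d, k) if (k %in% d$support)
    d$fractions[match(k, d$support)] else 0
  run_variant <- function(agent) {
    apply_protocol(0L, 4000, 60, enzyme_mode(agent, "locked"), gate_cal,
                   en43, plasmid = pbr322, enzyme_to_dna_ratio = 0.5,
                   temperature_C = 15,
                   events = list(protocol_event(31L, "shift_temperature", 40)),
                   seed = 81, record = FALSE)
  }
  atp <- run_variant("ATP")
  p1 <- atp$phases[[1]]$distribution
  p2 <- atp$phases[[2]]$distribution
  expect_gt(frac_at(p1, 2L), 0.05)            # +2 develops at 15 C
  expect_lt(frac_at(p2, 2L), frac_at(p1, 2L) / 2) # and collapses at 40 C
  expect_gt(frac_at(p2, -2L), 0.05)           # while -2 appears
  expect_gt(frac_at(p2, -2L), frac_at(p1, -2L))

  # AMPPNP control: both gates shut, phase 2 identical to phase 1
  pnp <- run_variant("AMPPNP")
  expect_identical(pnp$phases[[1]]$distribution$fractions,
                   pnp$phases[[2]]$distribution$fractions)
})

test_that("protocol event validation rejects malformed schedules", {
  eq <- equilibrium_distribution(en43)
  ev <- list(protocol_event(10L, "shift_temperature", 40),
             protocol_event(5L, "set_enzyme_ratio", 1))
  expect_error(apply_protocol(eq, 100, 20, enzyme_mode(), gate_cal, en43,
                              plasmid = pbr322, events = ev, seed = 1),
               "ordered")
  expect_error(apply_protocol(eq, 100, 20, enzyme_mode(), gate_cal, en43,
                              plasmid = pbr322,
                              events = list(protocol_event(30L,
                                                           "set_enzyme_ratio",
                                                           1)),
                              seed = 1),
               "outside")
})
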