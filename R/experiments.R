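#' Resolved run configuration
#'
#' Collects everything a scripted experiment needs: plasmid, energetics
#' overrides, gate parameters, enzyme mode, ensemble sizes and the seed
#' (mandatory — every run must be reproducible). Every report echoes the
#' resolved configuration.
#'
#' @param seed Integer seed (mandatory).
#' @param plasmid A [plasmid_spec()]; default the 7.9-kb plasmid.
#' @param nk_coefficient,helical_temp_coeff Energetics overrides.
#' @param p0,alpha,pi0,trap_backtrack Gate parameters (see [gate_model()]).
#' @param n_gate_agent,c_gate Enzyme mode (see [enzyme_mode()]).
#' @param n_molecules,n_cycles Ensemble size (defaults 5000 and 300).
#' @param enzyme_to_dna_ratio Enzyme/DNA molar ratio (default 0.5).
#' @param temperature_C Reaction temperature; default the reference.
#' @param support Optional explicit integer support.
#' @param gel A [gel_params()] for the synthetic densitometry pathway.
#' @param chloroquine_offset Writhe offset used when rendering lanes
#'   (default: one past the largest support magnitude, so every topoisomer
#'   gets its own band, as on a resolving chloroquine gel).
#' @param output_dir Optional directory for report files.
#' @return A list of class `run_config` with resolved `energetics`,
#'   `gate` and `mode` objects.
#' @export
run_config <- function(seed,
                       plasmid = plasmid_spec("YCp50", 7900),
                       nk_coefficient = 1100, helical_temp_coeff = 0.011,
                       p0 = NULL, alpha = NULL, pi0 = 0.5,
                       trap_backtrack = 1,
                       n_gate_agent = "ATP", c_gate = "intact",
                       n_molecules = 5000, n_cycles = 300,
                       enzyme_to_dna_ratio = 0.5,
                       temperature_C = NULL, support = NULL,
                       gel = gel_params(), chloroquine_offset = NULL,
                       output_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  energetics <- energetics_model(plasmid, nk_coefficient = nk_coefficient,
                                 helical_temp_coeff = helical_temp_coeff)
  gd <- gate_model() # package calibration defaults
  gate <- gate_model(p0 = if (is.null(p0)) gd$p0 else p0,
                     alpha = if (is.null(alpha)) gd$alpha else alpha,
                     pi0 = pi0, trap_backtrack = trap_backtrack)
  mode <- enzyme_mode(n_gate_agent, c_gate)
  if (is.null(temperature_C)) temperature_C <- energetics$reference_temperature_C
  if (is.null(support)) support <- default_support(energetics)
  if (is.null(chloroquine_offset)) chloroquine_offset <- max(abs(support)) + 1
  structure(list(seed = as.integer(seed), plasmid = plasmid,
                 energetics = energetics, gate = gate, mode = mode,
                 n_molecules = n_molecules, n_cycles = n_cycles,
                 enzyme_to_dna_ratio = enzyme_to_dna_ratio,
                 temperature_C = temperature_C, support = support,
                 gel = gel, chloroquine_offset = chloroquine_offset,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [run_config()]; `plasmid` is given as
#' `plasmid_name`/`plasmid_length_bp`/`reference_temperature_C`, gel
#' parameters under `gel_*`. Unknown keys are an error; `seed` is
#' mandatory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "plasmid_name", "plasmid_length_bp",
             "reference_temperature_C", "nk_coefficient",
             "helical_temp_coeff", "p0", "alpha", "pi0", "trap_backtrack",
             "n_gate_agent", "c_gate", "n_molecules", "n_cycles",
             "enzyme_to_dna_ratio", "temperature_C", "chloroquine_offset",
             "gel_lane_length", "gel_band_sigma", "gel_migration_gain",
             "gel_migration_saturation", "gel_noise_sd", "gel_baseline",
             "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(raw$seed)) stop("config must set `seed`", call. = FALSE)
  plasmid <- plasmid_spec(
    raw$plasmid_name %||% "plasmid",
    raw$plasmid_length_bp %||% 7900,
    raw$reference_temperature_C %||% 25)
  gel <- gel_params(
    lane_length = raw$gel_lane_length %||% 100,
    band_sigma = raw$gel_band_sigma %||% 0.6,
    migration_gain = raw$gel_migration_gain %||% 6,
    migration_saturation = raw$gel_migration_saturation %||% 30,
    noise_sd = raw$gel_noise_sd %||% 0.002,
    baseline = raw$gel_baseline %||% 0.01)
  args <- raw[intersect(names(raw),
                        c("seed", "nk_coefficient", "helical_temp_coeff",
                          "p0", "alpha", "pi0", "trap_backtrack",
                          "n_gate_agent", "c_gate", "n_molecules",
                          "n_cycles", "enzyme_to_dna_ratio",
                          "temperature_C", "chloroquine_offset",
                          "output_dir"))]
  do.call(run_config, c(args, list(plasmid = plasmid, gel = gel)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_echo <- function(config) {
  list(seed = config$seed,
       plasmid = list(name = config$plasmid$name,
                      length_bp = config$plasmid$length_bp),
       sigma2_eq = config$energetics$sigma2_eq,
       nk_coefficient = config$energetics$nk_coefficient,
       gate = config$gate[c("p0", "alpha", "pi0", "trap_backtrack")],
       mode = unclass(config$mode),
       n_molecules = config$n_molecules, n_cycles = config$n_cycles,
       enzyme_to_dna_ratio = config$enzyme_to_dna_ratio,
       temperature_C = config$temperature_C)
}

msg <- function(...) message("[topoproof] ", sprintf(...))

# gel-pathway R_Lk: render both lanes, quantify, compare band tables
gel_pathway_r_lk <- function(d_eq, d_test, config) {
  gp <- config$gel
  off <- config$chloroquine_offset
  quant <- function(d, seed_shift) {
    lane <- synth_lane(d, gp, seed = config$seed + seed_shift,
                       chloroquine_offset = off)
    pos <- stats::setNames(migration_map(d$support, gp, off), d$support)
    quantify_lane(lane, pos)
  }
  bt_eq <- quant(d_eq, 101L)
  bt_t <- quant(d_test, 202L)
  r_lk(bt_eq, bt_t)
}

#' Steady-state comparison of type-I and type-II products
#'
#' Reproduces the canonical relaxation comparison: a type-I enzyme leaves
#' the thermal-equilibrium Lk distribution, the type-II proofreading cycle
#' leaves a narrower stationary one. Reports the closed-form expectation
#' (R_Lk = 1 + alpha) next to Monte Carlo estimates through both the
#' direct-count and the synthetic-gel densitometry pathways, plus
#' Delta Lk^S.
#'
#' @param config A [run_config()].
#' @return A report list (class `topoproof_report`).
#' @export
expt_steady_state <- function(config) {
  stopifnot(inherits(config, "run_config"))
  msg("steady-state comparison: %s, alpha = %.3f, seed %d",
      config$plasmid$name, config$gate$alpha, config$seed)
  en <- config$energetics
  d_eq <- equilibrium_distribution(en, config$support)
  d_ss_cf <- stationary_closed_form(en, config$gate, config$support)
  tr <- simulate_population(d_eq, config$n_molecules, config$n_cycles,
                            config$mode, config$gate, en,
                            config$enzyme_to_dna_ratio, seed = config$seed)
  report <- list(
    experiment = "steady_state",
    config = config_echo(config),
    closed_form = list(r_lk = 1 + config$gate$alpha,
                       variance_eq = lk_variance(d_eq),
                       variance_ss = lk_variance(d_ss_cf),
                       delta_lk_s = 0),
    monte_carlo = list(
      r_lk_direct = r_lk(d_eq, tr$final),
      r_lk_gel = gel_pathway_r_lk(d_eq, tr$final, config),
      variance_ss = lk_variance(tr$final),
      delta_lk_s = delta_lk_s(tr$final, d_eq)),
    distributions = list(equilibrium = d_eq, stationary = tr$final))
  structure(report, class = "topoproof_report")
}

#' One-passage capture-probability assay
#'
#' Reproduces the AMPPNP single-passage experiment on purified adjacent
#' topoisomers: starting from pure `delta_lk = 0` and pure `delta_lk = -2`
#' populations, reports the conversion probabilities P(0 to -2) and
#' P(-2 to 0), their ratio (which the baseline capture efficiency cancels
#' out of), and the equilibrium and stationary concentration ratios for
#' comparison. `p0` is calibrated so P(-2 to 0) matches
#' `target_p_minus2_to_0`.
#'
#' @param config A [run_config()] (the plasmid should be the 4.3-kb one for
#'   the printed comparison).
#' @param target_p_minus2_to_0 Calibration target for P(-2 to 0); default
#'   0.50.
#' @return A report list.
#' @export
expt_capture_assay <- function(config, target_p_minus2_to_0 = 0.50) {
  stopifnot(inherits(config, "run_config"))
  en <- config$energetics
  p0 <- calibrate_p0(target_p_minus2_to_0, -2L, 0L, en)
  gate <- gate_model(p0 = p0, alpha = config$gate$alpha,
                     pi0 = config$gate$pi0)
  msg("capture assay: p0 calibrated to %.4f (target P(-2,0) = %.2f)",
      p0, target_p_minus2_to_0)
  f_from_m2 <- one_step_capture_assay(-2L, config$n_molecules, gate, en,
                                      seed = config$seed)
  f_from_0 <- one_step_capture_assay(0L, config$n_molecules, gate, en,
                                     seed = config$seed + 1L)
  p_m2_to_0 <- f_from_m2[["0"]]
  p_0_to_m2 <- f_from_0[["-2"]]
  d_eq <- equilibrium_distribution(en, config$support)
  d_ss <- stationary_closed_form(en, config$gate, config$support)
  structure(list(
    experiment = "capture_assay",
    config = config_echo(config),
    p0_calibrated = p0,
    closed_form = list(
      p_minus2_to_0 = as.numeric(capture_probabilities(-2L, en, gate)[["+2"]]),
      p_0_to_minus2 = as.numeric(capture_probabilities(0L, en, gate)[["-2"]]),
      c_ratio_eq = adjacent_topoisomer_ratio(d_eq, -2L, 0L),
      c_ratio_stationary = adjacent_topoisomer_ratio(d_ss, -2L, 0L)),
    monte_carlo = list(
      p_minus2_to_0 = p_m2_to_0,
      p_0_to_minus2 = p_0_to_m2,
      capture_ratio = p_0_to_m2 / p_m2_to_0,
      fractions_from_minus2 = f_from_m2,
      fractions_from_0 = f_from_0)),
    class = "topoproof_report")
}

#' Temperature-inversion backtracking protocol (locked C-gate)
#'
#' Starts a pure topoisomer with a C-gate-locked enzyme at a low
#' temperature, where the free-energy minimum sits above the start state:
#' captures trap a T-segment and shift molecules up by 2. The reaction is
#' then shifted to a high temperature, moving the minimum below the start
#' state. With ATP the trapped T-segments backtrack out of the reopened
#' N-gate (the up-shifted fraction collapses) and new captures appear two
#' below; with AMPPNP both gates stay shut and the phase-1 pattern is
#' frozen. Reports per-phase fractions at start-state -2 / start / +2.
#'
#' @param config A [run_config()] (4.3-kb plasmid for the printed design).
#' @param start_state Purified topoisomer state (default 0).
#' @param temp_low,temp_high Phase temperatures, degrees C (defaults 15 and
#'   40).
#' @param phase_cycles Cycles per phase (default 50).
#' @return A report list with both the ATP and the AMPPNP variants.
#' @export
expt_temperature_inversion <- function(config, start_state = 0L,
                                       temp_low = 15, temp_high = 40,
                                       phase_cycles = 50) {
  stopifnot(inherits(config, "run_config"))
  en <- config$energetics
  run_variant <- function(agent, seed) {
    res <- apply_protocol(
      initial = start_state, n_molecules = config$n_molecules,
      n_cycles = 2L * phase_cycles,
      mode = enzyme_mode(agent, "locked"),
      gate = config$gate, energetics = en, plasmid = config$plasmid,
      enzyme_to_dna_ratio = config$enzyme_to_dna_ratio,
      temperature_C = temp_low,
      events = list(protocol_event(phase_cycles + 1L, "shift_temperature",
                                   temp_high)),
      seed = seed)
    lapply(res$phases, function(ph) {
      d <- ph$distribution
      frac <- function(k) if (k %in% d$support)
        d$fractions[match(k, d$support)] else 0
      list(temperature_C = ph$temperature_C,
           fractions = c(minus2 = frac(start_state - 2L),
                         start = frac(start_state),
                         plus2 = frac(start_state + 2L)))
    })
  }
  msg("temperature inversion: %g -> %g C, locked C-gate", temp_low, temp_high)
  structure(list(
    experiment = "temperature_inversion",
    config = config_echo(config),
    start_state = start_state,
    atp = run_variant("ATP", config$seed),
    amppnp = run_variant("AMPPNP", config$seed + 1L)),
    class = "topoproof_report")
}

#' N-gate block broadening protocol
#'
#' Relaxes an ensemble to the proofreading steady state with ATP, then
#' blocks N-gate reopening (AMPPNP or ICRF-193) at given enzyme/DNA molar
#' ratios. Each blocked enzyme completes at most one non-backtrackable
#' passage, so the narrowed distribution broadens back toward (never
#' beyond) thermal equilibrium, and the broadening grows with the molar
#' ratio. Reports variance before and after the block per ratio.
#'
#' @param config A [run_config()].
#' @param block_agent `"AMPPNP"` or `"ICRF193"`.
#' @param ratios Enzyme/DNA molar ratios to test (default `c(1, 2)`).
#' @param block_cycles Cycles simulated after the block (default 100).
#' @return A report list.
#' @export
expt_ngate_block <- function(config, block_agent = "AMPPNP",
                             ratios = c(1, 2), block_cycles = 100) {
  stopifnot(inherits(config, "run_config"))
  en <- config$energetics
  d_eq <- equilibrium_distribution(en, config$support)
  runs <- lapply(seq_along(ratios), function(i) {
    res <- apply_protocol(
      initial = d_eq, n_molecules = config$n_molecules,
      n_cycles = config$n_cycles + block_cycles,
      mode = config$mode, gate = config$gate, energetics = en,
      plasmid = config$plasmid,
      enzyme_to_dna_ratio = config$enzyme_to_dna_ratio,
      events = list(
        protocol_event(config$n_cycles, "set_enzyme_ratio", ratios[i]),
        protocol_event(config$n_cycles + 1L, "switch_n_gate_agent",
                       block_agent)),
      seed = config$seed + i)
    nph <- length(res$phases)
    list(ratio = ratios[i],
         variance_before = res$phases[[1L]]$variance,
         variance_after = res$phases[[nph]]$variance,
         distribution_after = res$phases[[nph]]$distribution)
  })
  msg("N-gate block (%s): ratios %s", block_agent,
      paste(ratios, collapse = ", "))
  structure(list(
    experiment = "ngate_block",
    config = config_echo(config),
    block_agent = block_agent,
    variance_eq = lk_variance(d_eq),
    runs = runs),
    class = "topoproof_report")
}

#' Relaxation by a C-gate-deleted enzyme
#'
#' With the C-gate removed there is no release challenge: every passed
#' T-segment exits, transport follows capture alone, and the stationary
#' law is thermal equilibrium — supercoils are relaxed but the distribution
#' is never narrowed below equilibrium. Runs from a supercoiled start and
#' from a pre-simplified (proofreading steady-state) start and reports the
#' R_Lk trajectory toward 1.
#'
#' @param config A [run_config()].
#' @param supercoiled_delta_lk Starting state of the supercoiled substrate
#'   (default -7).
#' @param checkpoints Cycle counts at which R_Lk is reported.
#' @return A report list.
#' @export
expt_cgate_deleted <- function(config, supercoiled_delta_lk = -7L,
                               checkpoints = c(50L, 150L, 300L)) {
  stopifnot(inherits(config, "run_config"))
  en <- config$energetics
  mode <- enzyme_mode(config$mode$n_gate_agent, "deleted")
  d_eq <- equilibrium_distribution(en, config$support)
  d_ss <- stationary_closed_form(en, config$gate, config$support)
  run_from <- function(initial, seed) {
    tr <- simulate_population(initial, config$n_molecules, max(checkpoints),
                              mode, config$gate, en,
                              config$enzyme_to_dna_ratio, seed = seed)
    rl <- vapply(checkpoints, function(cy) {
      d <- as_lk_distribution(
        tr$counts[tr$counts$cycle == cy, c("delta_lk", "count")])
      r_lk(d_eq, d)
    }, numeric(1))
    list(r_lk_trajectory = stats::setNames(rl, checkpoints),
         final = tr$final)
  }
  msg("C-gate-deleted relaxation: %s", config$plasmid$name)
  structure(list(
    experiment = "cgate_deleted",
    config = config_echo(config),
    from_supercoiled = run_from(supercoiled_delta_lk, config$seed),
    from_presimplified = run_from(d_ss, config$seed + 1L)),
    class = "topoproof_report")
}

#' @export
print.topoproof_report <- function(x, ...) {
  cat(sprintf("<topoproof report: %s>\n", x$experiment))
  utils::str(x[setdiff(names(x), c("distributions", "config"))],
             max.level = 3, give.attr = FALSE)
  invisible(x)
}

#' Write a report to JSON (plus TSV tables for its distributions)
#'
#' @param report A report from one of the `expt_*` runners.
#' @param dir Output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ser <- rapply(report, function(x) {
    if (inherits(x, "lk_distribution")) as.data.frame(x) else x
  }, classes = "ANY", how = "replace")
  path <- file.path(dir, paste0(report$experiment, ".json"))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  if (!is.null(report$distributions)) {
    for (nm in names(report$distributions))
      write_lk_distribution(report$distributions[[nm]],
                            file.path(dir, paste0(report$experiment, "_",
                                                  nm, ".tsv")))
  }
  invisible(path)
}
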