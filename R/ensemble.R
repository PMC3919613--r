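#' Closed-form stationary topoisomer distribution under proofreading
#'
#' For the normal catalytic cycle (ATP, intact C-gate) the effective
#' transition probability between adjacent same-parity states is
#' capture x release \eqn{\propto \exp\{-(1+\alpha)\Delta G/2\}}, which
#' satisfies detailed balance with respect to the weight
#' \eqn{\exp\{-(1+\alpha) G(\Delta Lk)\}}. The stationary law is therefore a
#' Gaussian-weighted integer distribution with variance
#' \eqn{\sigma^2_{eq}/(1+\alpha)}: the steady state is narrower than thermal
#' equilibrium by exactly the factor R_Lk = 1 + alpha. Adjacent steady-state
#' concentration ratios obey \eqn{C_{-2}/C_0 = [C_{-2}/C_0]_{eq}^{1+\alpha}}.
#'
#' @param energetics An [energetics_model()].
#' @param gate A [gate_model()].
#' @param support Integer support; defaults to `lk0_offset` +/- 8 sigma.
#' @param lk0_offset Displacement of the free-energy minimum.
#' @param mode An [enzyme_mode()]; must be (ATP, intact), the only mode with
#'   a nontrivial proofreading steady state.
#' @return An [lk_distribution()].
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' st <- stationary_closed_form(m, gate_model())
#' @export
stationary_closed_form <- function(energetics, gate, support = NULL,
                                   lk0_offset = 0, mode = enzyme_mode()) {
  stopifnot(inherits(gate, "gate_model"))
  if (mode$n_gate_agent != "ATP" || mode$c_gate != "intact")
    stop("closed-form stationary distribution requires mode (ATP, intact)",
         call. = FALSE)
  if (is.null(support)) support <- default_support(energetics, lk0_offset)
  support <- sort(as.integer(round(support)))
  check_truncation(support, sqrt(energetics$sigma2_eq / (1 + gate$alpha)),
                   lk0_offset)
  w <- exp(-(1 + gate$alpha) * free_energy(support, energetics, lk0_offset))
  lk_distribution(support, w)
}

# per-cycle move probabilities used by both the matrix solver and the
# Monte Carlo engine: capture (both directions) and completion probability
# of the resulting transport, by mode
transport_probs <- function(support, mode, gate, energetics, lk0_offset,
                            clip = FALSE) {
  pu <- numeric(length(support))
  pd <- numeric(length(support))
  for (i in seq_along(support)) {
    p <- capture_probabilities(support[i], energetics, gate, lk0_offset,
                               clip = clip)
    pu[i] <- p[["+2"]]
    pd[i] <- p[["-2"]]
  }
  complete_u <- rep(1, length(support))
  complete_d <- rep(1, length(support))
  if (mode$c_gate == "intact" && mode$n_gate_agent == "ATP") {
    dgu <- free_energy(support + gate$step, energetics, lk0_offset) -
      free_energy(support, energetics, lk0_offset)
    dgd <- free_energy(support - gate$step, energetics, lk0_offset) -
      free_energy(support, energetics, lk0_offset)
    complete_u <- as.numeric(suppressWarnings(release_probability(dgu, gate)))
    complete_d <- as.numeric(suppressWarnings(release_probability(dgd, gate)))
  }
  list(up = pu * complete_u, down = pd * complete_d)
}

#' Numerically solved stationary distribution (independent oracle)
#'
#' Builds the per-cycle transition matrix from the gate cycle's outcome
#' probabilities (capture x release; backtracks and failed captures are
#' self-transitions) and solves the stationary vector by linear algebra.
#' Because type-II passage moves in steps of 2, odd and even states form
#' separate communicating classes: each class is solved on its own and the
#' classes are combined with `parity_weights` (default: the Boltzmann class
#' masses of the target stationary weight, so the result is comparable to
#' [stationary_closed_form()]).
#'
#' Supported modes are (ATP, intact) and (ATP, deleted) (the latter has no
#' release challenge, so its stationary law is thermal equilibrium);
#' AMPPNP/ICRF-193 chains are absorbing, not ergodic, and are rejected.
#'
#' @inheritParams stationary_closed_form
#' @param mode An [enzyme_mode()].
#' @param parity_weights Optional `c(even =, odd =)` masses for combining
#'   the two parity classes.
#' @return An [lk_distribution()].
#' @export
stationary_numeric <- function(energetics, gate, mode = enzyme_mode(),
                               support = NULL, lk0_offset = 0,
                               parity_weights = NULL) {
  if (n_gate_blocked(mode) || mode$c_gate == "locked")
    stop("stationary distribution undefined: mode (", mode$n_gate_agent,
         ", ", mode$c_gate, ") gives an absorbing, non-ergodic chain",
         call. = FALSE)
  if (is.null(support)) support <- default_support(energetics, lk0_offset)
  support <- sort(as.integer(round(support)))
  alpha_eff <- if (mode$c_gate == "deleted") 0 else gate$alpha
  tw <- exp(-(1 + alpha_eff) * free_energy(support, energetics, lk0_offset))
  if (is.null(parity_weights)) {
    parity_weights <- c(
      even = sum(tw[support %% 2L == 0L]),
      odd  = sum(tw[support %% 2L == 1L])
    ) / sum(tw)
  }
  mv <- transport_probs(support, mode, gate, energetics, lk0_offset,
                        clip = FALSE)
  pi_full <- numeric(length(support))
  for (par in c(0L, 1L)) {
    idx <- which(support %% 2L == abs(par))
    if (length(idx) == 0L) next
    wname <- if (par == 0L) "even" else "odd"
    pi_full[idx] <- solve_parity_class(support[idx], mv$up[idx], mv$down[idx]) *
      parity_weights[[wname]]
  }
  lk_distribution(support, pi_full)
}

# stationary vector of one parity class (states step 2, transitions to
# nearest same-parity neighbours); reflecting at the support edges
solve_parity_class <- function(states, p_up, p_down) {
  m <- length(states)
  if (m == 1L) return(1)
  P <- diag(m)
  for (i in seq_len(m)) {
    up <- if (i < m) p_up[i] else 0
    dn <- if (i > 1L) p_down[i] else 0
    if (i < m) P[i, i + 1L] <- up
    if (i > 1L) P[i, i - 1L] <- dn
    P[i, i] <- 1 - up - dn
  }
  off <- P[row(P) != col(P)]
  interior_up <- p_up[-m]
  interior_dn <- p_down[-1L]
  if (any(interior_up <= 0) || any(interior_dn <= 0)) {
    bad <- states[c(which(interior_up <= 0), which(interior_dn <= 0) + 1L)]
    stop("reducible chain: no flux through state(s) ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  A <- t(P) - diag(m)
  A[m, ] <- 1
  b <- c(rep(0, m - 1L), 1)
  v <- solve(A, b)
  # far-tail stationary masses (~exp(-50)) can come back as tiny negatives
  v[v < 0 & abs(v) < 1e-12] <- 0
  if (any(v < 0))
    stop("stationary solve produced negative probabilities", call. = FALSE)
  v / sum(v)
}

# ---- Monte Carlo population engine ------------------------------------

# internal mutable ensemble state carried across protocol phases
new_engine_state <- function(states, mode, gate, energetics, lk0_offset,
                             enzyme_to_dna_ratio) {
  st <- list(states = as.integer(states),
             trapped_from = rep(NA_integer_, length(states)),
             budget = NULL, # single-use enzymes per molecule (AMPPNP/ICRF)
             mode = mode, gate = gate, energetics = energetics,
             lk0_offset = lk0_offset, ratio = enzyme_to_dna_ratio)
  if (n_gate_blocked(mode)) st <- init_budget(st)
  st
}

# a non-hydrolysable agent makes each enzyme single-use: give every molecule
# floor(ratio) enzymes plus one more with probability frac(ratio)
init_budget <- function(st) {
  n <- length(st$states)
  fl <- floor(st$ratio)
  fr <- st$ratio - fl
  st$budget <- fl + stats::rbinom(n, 1L, fr)
  st
}

run_cycles <- function(st, n_cycles, record = TRUE) {
  n <- length(st$states)
  step <- st$gate$step
  atp <- st$mode$n_gate_agent == "ATP"
  recs <- vector("list", n_cycles)
  g <- function(k) free_energy(k, st$energetics, st$lk0_offset)
  for (cy in seq_len(n_cycles)) {
    # trapped T-segments (locked C-gate) resolve first
    tr <- !is.na(st$trapped_from)
    if (any(tr)) {
      if (atp && st$gate$trap_backtrack > 0) {
        back <- tr & (stats::runif(n) < st$gate$trap_backtrack)
        st$states[back] <- st$trapped_from[back]
        st$trapped_from[back] <- NA_integer_
      }
      # under AMPPNP/ICRF both gates are shut: trapped molecules stay frozen
    }
    free <- is.na(st$trapped_from)
    att <- free & (stats::runif(n) < min(1, st$ratio))
    if (!is.null(st$budget)) {
      att <- att & st$budget > 0L
      # a blocked enzyme closes its N-gate once: the attempt consumes it
      # whether or not a T-segment was juxtaposed for capture
      st$budget[att] <- st$budget[att] - 1L
    }
    if (any(att)) {
      k <- st$states[att]
      pu <- st$gate$p0 * exp(-(g(k + step) - g(k)) / 2)
      pd <- st$gate$p0 * exp(-(g(k - step) - g(k)) / 2)
      pu <- pmin(pu, 1); pd <- pmin(pd, 1)
      tot <- pu + pd
      over <- tot > 1
      pu[over] <- pu[over] / tot[over]
      pd[over] <- pd[over] / tot[over]
      u <- stats::runif(sum(att))
      dir <- integer(sum(att)) # 0 = no capture
      dir[u < pu] <- step
      dir[u >= pu & u < pu + pd] <- -step
      cap <- dir != 0L
      if (any(cap)) {
        idx <- which(att)[cap]
        newk <- st$states[idx] + dir[cap]
        if (st$mode$c_gate == "locked") {
          st$trapped_from[idx] <- st$states[idx]
          st$states[idx] <- newk
        } else if (st$mode$c_gate == "deleted" || !atp) {
          st$states[idx] <- newk
        } else { # intact + ATP: release-versus-backtrack competition
          dg <- g(newk) - g(st$states[idx])
          rel <- pmin(1, st$gate$pi0 * exp(-st$gate$alpha * dg / 2))
          win <- stats::runif(length(idx)) < rel
          st$states[idx[win]] <- newk[win]
        }
      }
    }
    if (record) recs[[cy]] <- tabulate_states(st$states, cy)
  }
  st$record <- if (record) do.call(rbind, recs) else NULL
  st
}

tabulate_states <- function(states, cycle) {
  tb <- table(states)
  data.frame(cycle = cycle,
             delta_lk = as.integer(names(tb)),
             count = as.integer(tb))
}

states_to_distribution <- function(states) {
  as_lk_distribution(data.frame(delta_lk = states, count = 1))
}

draw_initial_states <- function(initial, n_molecules) {
  if (inherits(initial, "lk_distribution"))
    return(sample(initial$support, n_molecules, replace = TRUE,
                  prob = initial$fractions))
  if (is.numeric(initial) && length(initial) == 1L)
    return(rep(as.integer(initial), n_molecules))
  if (is.numeric(initial) && !is.null(names(initial))) {
    counts <- round(initial)
    return(rep(as.integer(names(counts)), counts))
  }
  stop("`initial` must be an lk_distribution, a single state, or named counts",
       call. = FALSE)
}

#' Simulate an ensemble of plasmids under enzyme action
#'
#' Discrete-cycle Monte Carlo over `n_molecules` closed circles. Each cycle,
#' each molecule undergoes an enzyme encounter with probability
#' `min(1, enzyme_to_dna_ratio)`, whose outcome follows the gate cycle of
#' [cycle_step()] for the given mode. Under a non-hydrolysable N-gate agent
#' (AMPPNP/ICRF-193) enzymes are single-use: each molecule carries
#' approximately `enzyme_to_dna_ratio` of them, and each closes its N-gate
#' exactly once — one capture attempt, consumed whether or not a T-segment
#' was juxtaposed. The expected number of blocked (non-backtrackable)
#' transports per molecule is therefore the molar ratio times the capture
#' probability: broadening is stoichiometric in enzyme and approaches, but
#' cannot overshoot, thermal equilibrium.
#'
#' Molecule number and per-parity totals are conserved along the
#' trajectory; runs are reproducible given `seed`.
#'
#' @param initial An [lk_distribution()] to sample starting states from, a
#'   single integer state, or a named vector of per-state counts.
#' @param n_molecules Number of plasmid molecules (ignored when `initial`
#'   is a vector of counts).
#' @param n_cycles Number of encounter cycles.
#' @param mode An [enzyme_mode()].
#' @param gate A [gate_model()].
#' @param energetics An [energetics_model()].
#' @param enzyme_to_dna_ratio Enzyme/DNA molar ratio (default 0.5).
#' @param lk0_offset Displacement of the free-energy minimum.
#' @param seed Integer seed; mandatory.
#' @param record Record per-cycle state counts (default `TRUE`).
#' @return An object of class `lk_trajectory`: list with `counts` (data
#'   frame `cycle`, `delta_lk`, `count`), `final_states`, `final`
#'   (an `lk_distribution`), and the run parameters.
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' eq <- equilibrium_distribution(m)
#' tr <- simulate_population(eq, 500, 50, enzyme_mode(), gate_model(), m,
#'                           seed = 1)
#' @export
simulate_population <- function(initial, n_molecules, n_cycles, mode, gate,
                                energetics, enzyme_to_dna_ratio = 0.5,
                                lk0_offset = 0, seed, record = TRUE) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_molecules < 1 || n_cycles < 0)
    stop("need n_molecules >= 1 and n_cycles >= 0", call. = FALSE)
  set.seed(seed)
  states <- draw_initial_states(initial, n_molecules)
  st <- new_engine_state(states, mode, gate, energetics, lk0_offset,
                         enzyme_to_dna_ratio)
  st <- if (n_cycles > 0) run_cycles(st, n_cycles, record) else
    c(st, list(record = NULL))
  structure(list(counts = st$record,
                 final_states = st$states,
                 final = states_to_distribution(st$states),
                 n_molecules = length(states), n_cycles = n_cycles,
                 mode = mode, gate = gate, energetics = energetics,
                 enzyme_to_dna_ratio = enzyme_to_dna_ratio,
                 lk0_offset = lk0_offset, seed = seed),
            class = "lk_trajectory")
}

#' @export
print.lk_trajectory <- function(x, ...) {
  cat(sprintf("<lk_trajectory: %d molecules, %d cycles, mode (%s, %s)>\n",
              x$n_molecules, x$n_cycles, x$mode$n_gate_agent, x$mode$c_gate))
  print(x$final)
  invisible(x)
}

#' One-passage capture assay (irreversible N-gate closure)
#'
#' Emulates the AMPPNP single-passage experiment: enzyme is pre-bound to a
#' purified topoisomer population, the N-gate is closed irreversibly, and
#' each enzyme captures (and passes) at most one T-segment. The conversion
#' fraction to each neighbouring topoisomer is a direct Monte Carlo estimate
#' of the capture probability.
#'
#' @param delta_lk Starting topoisomer state (all molecules identical).
#' @param n_molecules Number of enzyme-bound molecules.
#' @param gate A [gate_model()].
#' @param energetics An [energetics_model()].
#' @param lk0_offset Displacement of the free-energy minimum.
#' @param seed Integer seed; mandatory.
#' @return Named numeric vector of fractions over the states
#'   `delta_lk - 2`, `delta_lk`, `delta_lk + 2`.
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' one_step_capture_assay(-2, 1000, gate_model(), m, seed = 7)
#' @export
one_step_capture_assay <- function(delta_lk, n_molecules, gate, energetics,
                                   lk0_offset = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  p <- capture_probabilities(delta_lk, energetics, gate, lk0_offset)
  u <- stats::runif(n_molecules)
  n_up <- sum(u < p[["+2"]])
  n_dn <- sum(u >= p[["+2"]] & u < p[["+2"]] + p[["-2"]])
  out <- c(n_dn, n_molecules - n_up - n_dn, n_up) / n_molecules
  names(out) <- as.character(delta_lk + c(-2L, 0L, 2L))
  out
}

#' Mid-run perturbation event
#'
#' @param at_cycle Cycle (1-based) at whose start the action applies.
#' @param action One of `"switch_n_gate_agent"`, `"shift_temperature"`,
#'   `"set_enzyme_ratio"`.
#' @param payload Agent name, temperature in degrees C, or new ratio.
#' @return An object of class `protocol_event`.
#' @export
protocol_event <- function(at_cycle,
                           action = c("switch_n_gate_agent",
                                      "shift_temperature",
                                      "set_enzyme_ratio"),
                           payload) {
  structure(list(at_cycle = as.integer(at_cycle),
                 action = match.arg(action), payload = payload),
            class = "protocol_event")
}

#' Run a simulation with mid-run perturbations
#'
#' Carries a Monte Carlo ensemble through an ordered list of
#' [protocol_event()]s, reproducing the blocked-reopening and
#' temperature-inversion experiment designs: switching the N-gate agent
#' (e.g. ATP to AMPPNP once steady state is reached), shifting the reaction
#' temperature (which moves the free-energy minimum via
#' [lk0_temperature_shift()]), or changing the enzyme/DNA ratio. Enzyme
#' budgets are (re)assigned when a switch enters a non-hydrolysable agent.
#'
#' @inheritParams simulate_population
#' @param plasmid A [plasmid_spec()]; required when any event shifts
#'   temperature.
#' @param temperature_C Starting reaction temperature (default: the
#'   energetics model's reference temperature).
#' @param events List of [protocol_event()]s, strictly ordered by
#'   `at_cycle`, all within `n_cycles`.
#' @return An object of class `lk_protocol_result`: per-phase list with the
#'   resolved conditions, end-of-phase `lk_distribution` and summary
#'   statistics, plus the combined per-cycle counts.
#' @export
apply_protocol <- function(initial, n_molecules, n_cycles, mode, gate,
                           energetics, plasmid = NULL,
                           enzyme_to_dna_ratio = 0.5,
                           temperature_C = NULL, events = list(), seed,
                           record = TRUE) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  at <- vapply(events, `[[`, integer(1), "at_cycle")
  if (length(at) > 1L && any(diff(at) <= 0))
    stop("events must be strictly ordered by `at_cycle`", call. = FALSE)
  if (any(at > n_cycles) || any(at < 1L))
    stop("event at_cycle outside [1, n_cycles]", call. = FALSE)
  if (is.null(temperature_C)) temperature_C <- energetics$reference_temperature_C

  offset_at <- function(temp) {
    if (temp == energetics$reference_temperature_C) return(0)
    if (is.null(plasmid))
      stop("temperature events need a `plasmid`", call. = FALSE)
    lk0_temperature_shift(plasmid, temp, energetics)
  }

  set.seed(seed)
  states <- draw_initial_states(initial, n_molecules)
  st <- new_engine_state(states, mode, gate, energetics,
                         offset_at(temperature_C), enzyme_to_dna_ratio)
  bounds <- c(1L, at, n_cycles + 1L)
  phases <- list()
  all_counts <- list()
  done <- 0L
  for (ph in seq_len(length(bounds) - 1L)) {
    len <- bounds[ph + 1L] - bounds[ph]
    if (ph > 1L) { # apply the event opening this phase
      ev <- events[[ph - 1L]]
      if (ev$action == "switch_n_gate_agent") {
        st$mode <- enzyme_mode(ev$payload, st$mode$c_gate)
        st$budget <- NULL
        if (n_gate_blocked(st$mode)) st <- init_budget(st)
      } else if (ev$action == "shift_temperature") {
        temperature_C <- ev$payload
        st$lk0_offset <- offset_at(temperature_C)
      } else {
        st$ratio <- ev$payload
        if (!is.null(st$budget)) st <- init_budget(st)
      }
    }
    if (len > 0L) {
      st <- run_cycles(st, len, record)
      if (record && !is.null(st$record)) {
        rec <- st$record
        rec$cycle <- rec$cycle + done
        all_counts[[ph]] <- rec
      }
      done <- done + len
    }
    d <- states_to_distribution(st$states)
    phases[[ph]] <- list(
      phase = ph,
      cycles = c(bounds[ph], bounds[ph + 1L] - 1L),
      mode = st$mode, temperature_C = temperature_C,
      enzyme_to_dna_ratio = st$ratio, lk0_offset = st$lk0_offset,
      distribution = d,
      variance = lk_variance(d),
      center = suppressWarnings(distribution_center(d)))
  }
  structure(list(phases = phases,
                 counts = if (record) do.call(rbind, all_counts) else NULL,
                 final_states = st$states,
                 final = states_to_distribution(st$states),
                 seed = seed),
            class = "lk_protocol_result")
}

#' @export
print.lk_protocol_result <- function(x, ...) {
  cat(sprintf("<lk_protocol_result: %d phase(s)>\n", length(x$phases)))
  for (p in x$phases)
    cat(sprintf(
      "  phase %d [cycles %d-%d] mode (%s, %s) T = %g C: var %.3f, center %.3f\n",
      p$phase, p$cycles[1], p$cycles[2], p$mode$n_gate_agent, p$mode$c_gate,
      p$temperature_C, p$variance, p$center))
  invisible(x)
}

#' Write a trajectory's per-cycle counts to TSV
#'
#' Columns `cycle`, `delta_lk`, `count`.
#'
#' @param trajectory An `lk_trajectory` or `lk_protocol_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  if (is.null(trajectory$counts))
    stop("trajectory was run with record = FALSE", call. = FALSE)
  utils::write.table(trajectory$counts, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
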