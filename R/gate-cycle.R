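#' Enzyme mode: N-gate agent and C-gate state
#'
#' A type-II topoisomerase encounter is controlled by two experimental
#' handles. The N-gate agent is ATP (normal cycling; the N-gate reopens
#' after hydrolysis), AMPPNP (non-hydrolysable analog, N-gate closes
#' irreversibly, at most one passage per enzyme) or ICRF-193 (bisdioxo-
#' piperazine that traps the N-gate closed; simulator-equivalent to AMPPNP,
#' kept as a distinct label for reporting). The C-gate is intact,
#' disulfide-locked (a passed T-segment stays trapped in the central
#' chamber) or deleted (no release challenge at all).
#'
#' @param n_gate_agent One of `"ATP"`, `"AMPPNP"`, `"ICRF193"`.
#' @param c_gate One of `"intact"`, `"locked"`, `"deleted"`.
#' @return An object of class `enzyme_mode`.
#' @examples
#' enzyme_mode()                  # ATP, intact: the normal catalytic cycle
#' enzyme_mode("AMPPNP", "locked")
#' @export
enzyme_mode <- function(n_gate_agent = c("ATP", "AMPPNP", "ICRF193"),
                        c_gate = c("intact", "locked", "deleted")) {
  structure(list(n_gate_agent = match.arg(n_gate_agent),
                 c_gate = match.arg(c_gate)),
            class = "enzyme_mode")
}

# AMPPNP and ICRF-193 share simulator semantics: the N-gate cannot reopen
n_gate_blocked <- function(mode) mode$n_gate_agent %in% c("AMPPNP", "ICRF193")

#' @export
print.enzyme_mode <- function(x, ...) {
  cat(sprintf("<enzyme_mode: N-gate %s, C-gate %s>\n", x$n_gate_agent, x$c_gate))
  invisible(x)
}

#' Proofreading gate model
#'
#' Parameters of the post-passage proofreading cycle:
#' * `p0` — baseline T-segment capture efficiency per N-gate closure; the
#'   topology-dependent part is the symmetric detailed-balance factor
#'   \eqn{\exp(-\Delta G/2)} (see [capture_probabilities()]).
#' * `alpha` — release exponent, the strength of the C-gate's selection on
#'   passed T-segments. `alpha = 0` means release is blind to topology (no
#'   proofreading); the stationary distribution narrows as
#'   \eqn{\sigma^2/(1+\alpha)}, so the variance ratio R_Lk equals
#'   `1 + alpha`.
#' * `pi0` — baseline release probability at \eqn{\Delta G = 0}.
#' * `trap_backtrack` — per-cycle probability that a T-segment trapped by a
#'   locked C-gate backtracks out of the reopened N-gate (ATP only);
#'   default 1.
#'
#' Every transport outcome changes Lk by exactly `step = 2`.
#'
#' The defaults are the package's calibration against one-step capture
#' assays: `p0` reproduces a conversion probability of 0.50 from
#' `delta_lk = -2` to 0 on a 4.3-kb plasmid, and `1 + alpha` is set from the
#' steady-state versus equilibrium adjacent-topoisomer ratio pair
#' (0.17, 0.35), i.e. `alpha = log(0.17)/log(0.35) - 1`.
#'
#' @param p0 Baseline capture efficiency in (0, 1].
#' @param alpha Non-negative release exponent.
#' @param pi0 Baseline release probability in (0, 1].
#' @param trap_backtrack Per-cycle backtrack probability of a trapped
#'   T-segment under ATP, in `[0, 1]`.
#' @return An object of class `gate_model` (with constant `step = 2`).
#' @examples
#' gate_model()
#' gate_model(p0 = 0.25, alpha = 0)
#' @export
gate_model <- function(p0 = 0.2998, alpha = log(0.17) / log(0.35) - 1,
                       pi0 = 0.5, trap_backtrack = 1) {
  if (!is.finite(p0) || p0 <= 0 || p0 > 1)
    stop("`p0` must lie in (0, 1]", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0)
    stop("`alpha` must be non-negative", call. = FALSE)
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1)
    stop("`pi0` must lie in (0, 1]", call. = FALSE)
  if (!is.finite(trap_backtrack) || trap_backtrack < 0 || trap_backtrack > 1)
    stop("`trap_backtrack` must lie in [0, 1]", call. = FALSE)
  structure(list(p0 = p0, alpha = alpha, pi0 = pi0,
                 trap_backtrack = trap_backtrack, step = 2L),
            class = "gate_model")
}

#' @export
print.gate_model <- function(x, ...) {
  cat(sprintf("<gate_model: p0 = %.4f, alpha = %.4f, pi0 = %.2f, step = %d>\n",
              x$p0, x$alpha, x$pi0, x$step))
  invisible(x)
}

#' T-segment capture probabilities at the N-gate
#'
#' Per N-gate closure, the probability of capturing (and, once the N-gate
#' closes, inevitably passing) a T-segment that would change the topoisomer
#' state from `delta_lk` to `delta_lk +/- 2` is
#' \deqn{p(k \to k \pm 2) = p_0 \exp\{-[G(k\pm2) - G(k)]/2\},}
#' the minimal symmetric split that satisfies detailed balance:
#' \eqn{p(k\to k')/p(k'\to k) = \exp\{-[G(k')-G(k)]\}} is exactly the
#' Boltzmann factor, so capture alone cannot narrow the distribution below
#' equilibrium. Remaining probability mass is "no capture".
#'
#' With `clip = FALSE` (the default) a raw probability above 1, or a pair
#' summing above 1, is an error naming the offending state: `p0` must be
#' chosen valid over the support a calculation touches. The Monte Carlo
#' engine evaluates with `clip = TRUE`, which clamps each probability to 1
#' and rescales the pair to sum at most 1; this only triggers at states far
#' outside the occupied region.
#'
#' @param delta_lk Integer topoisomer state.
#' @param energetics An [energetics_model()].
#' @param gate A [gate_model()].
#' @param lk0_offset Displacement of the free-energy minimum (Lk units).
#' @param clip Clamp instead of erroring on probability overflow.
#' @return Named numeric vector `c("+2" = ..., "-2" = ...)`; attribute
#'   `clipped` is `TRUE` when clamping occurred.
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' capture_probabilities(-2, m, gate_model()) # "+2" is the move toward 0
#' @export
capture_probabilities <- function(delta_lk, energetics, gate, lk0_offset = 0,
                                  clip = FALSE) {
  stopifnot(inherits(gate, "gate_model"))
  s <- gate$step
  dgu <- free_energy(delta_lk + s, energetics, lk0_offset) -
    free_energy(delta_lk, energetics, lk0_offset)
  dgd <- free_energy(delta_lk - s, energetics, lk0_offset) -
    free_energy(delta_lk, energetics, lk0_offset)
  pu <- gate$p0 * exp(-dgu / 2)
  pd <- gate$p0 * exp(-dgd / 2)
  clipped <- FALSE
  if (pu > 1 || pd > 1 || pu + pd > 1) {
    if (!clip)
      stop(sprintf(
        "capture probability overflow at delta_lk = %d (p+2 = %.3g, p-2 = %.3g); choose a smaller p0",
        delta_lk, pu, pd), call. = FALSE)
    clipped <- TRUE
    pu <- min(pu, 1)
    pd <- min(pd, 1)
    tot <- pu + pd
    if (tot > 1) {
      pu <- pu / tot
      pd <- pd / tot
    }
  }
  structure(c(`+2` = pu, `-2` = pd), clipped = clipped)
}

#' Release-versus-backtrack probability at the C-gate
#'
#' After passage, the T-segment sits in the central chamber and the C-gate
#' challenges it to dissociate before the N-gate reopens. The probability
#' that release wins (completing transport) is
#' \deqn{\pi(\Delta G) = \min\{1,\ \pi_0 \exp(-\alpha \Delta G / 2)\},}
#' where \eqn{\Delta G} is the free-energy change of the transport just
#' made. `1 - pi` is the backtrack probability. When no clipping occurs,
#' \eqn{\pi(\Delta G)/\pi(-\Delta G) = \exp(-\alpha \Delta G)}: transports
#' that drive topology uphill are preferentially cancelled, which is the
#' proofreading step. Vectorized over `delta_g_transport`.
#'
#' @param delta_g_transport Free-energy change of the transport (kT).
#' @param gate A [gate_model()].
#' @return Release probability in (0, 1]; attribute `clipped` marks values
#'   clamped at 1 (a warning is also issued).
#' @export
release_probability <- function(delta_g_transport, gate) {
  stopifnot(inherits(gate, "gate_model"))
  raw <- gate$pi0 * exp(-gate$alpha * delta_g_transport / 2)
  clipped <- raw > 1
  if (any(clipped))
    warning("release probability clipped at 1 for ",
            sum(clipped), " value(s); pi0/alpha reach saturation",
            call. = FALSE)
  structure(pmin(raw, 1), clipped = any(clipped))
}

#' Calibrate the baseline capture efficiency against a measured probability
#'
#' Solves for `p0` so that the capture probability from `from_state` to
#' `to_state` equals `target_probability`. Used to anchor the model to
#' one-passage (AMPPNP) assay readouts, where the conversion fraction of a
#' purified topoisomer is a direct measurement of capture probability.
#'
#' @param target_probability Measured conversion probability in (0, 1).
#' @param from_state,to_state Integer states with `|from - to| = 2`.
#' @param energetics An [energetics_model()].
#' @param lk0_offset Displacement of the free-energy minimum.
#' @return The calibrated `p0`.
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' calibrate_p0(0.50, -2, 0, m) # about 0.2998
#' @export
calibrate_p0 <- function(target_probability, from_state, to_state,
                         energetics, lk0_offset = 0) {
  if (abs(from_state - to_state) != 2L)
    stop("`from_state` and `to_state` must differ by exactly 2", call. = FALSE)
  if (!is.finite(target_probability) ||
      target_probability <= 0 || target_probability >= 1)
    stop("`target_probability` must lie in (0, 1)", call. = FALSE)
  dg <- free_energy(to_state, energetics, lk0_offset) -
    free_energy(from_state, energetics, lk0_offset)
  p0 <- target_probability / exp(-dg / 2)
  # validity of the full probability pair over a working support is checked
  # where capture_probabilities is used; here only the p0 bound applies
  if (p0 <= 0 || p0 > 1)
    stop(sprintf("calibrated p0 = %.4g falls outside (0, 1]", p0),
         call. = FALSE)
  p0
}

#' One enzyme encounter on a single DNA molecule
#'
#' Plays a single gate cycle: capture at the N-gate (probabilities from
#' [capture_probabilities()]), unidirectional passage across the DNA-gate,
#' then the mode-dependent fate at the C-gate:
#' * intact C-gate, ATP — released (transported) with probability
#'   \eqn{\pi(\Delta G)}, otherwise the N-gate reopens first and the
#'   T-segment backtracks (net zero within the same encounter);
#' * intact C-gate, AMPPNP/ICRF-193 — the N-gate cannot reopen so
#'   backtracking is impossible: transported;
#' * locked C-gate, ATP — the passed T-segment is trapped in the central
#'   chamber (`trapped_chamber`, state changed by 2); on a later call with
#'   `trapped_from` set, it backtracks with probability `trap_backtrack`
#'   (reverting the state) and the enzyme may then recapture;
#' * locked C-gate, AMPPNP/ICRF-193 — trapped permanently;
#' * deleted C-gate — no release challenge: transported on every capture.
#'
#' Draws from R's random number stream; seed it (`set.seed()`) for
#' reproducibility.
#'
#' @param delta_lk Current integer topoisomer state.
#' @param mode An [enzyme_mode()].
#' @param gate A [gate_model()].
#' @param energetics An [energetics_model()].
#' @param lk0_offset Displacement of the free-energy minimum.
#' @param trapped_from Integer: the pre-passage state of a molecule whose
#'   T-segment is currently trapped (locked C-gate), or `NULL`.
#' @return A list of class `cycle_outcome`: `kind` (one of `no_capture`,
#'   `transported`, `backtracked`, `trapped_chamber`), `direction` (+2, -2
#'   or `NA`), `new_delta_lk`.
#' @export
cycle_step <- function(delta_lk, mode, gate, energetics, lk0_offset = 0,
                       trapped_from = NULL) {
  stopifnot(inherits(mode, "enzyme_mode"))
  outcome <- function(kind, direction, new)
    structure(list(kind = kind, direction = direction, new_delta_lk = new),
              class = "cycle_outcome")

  if (!is.null(trapped_from)) {
    if (mode$c_gate != "locked")
      stop("`trapped_from` only applies to a locked C-gate", call. = FALSE)
    if (n_gate_blocked(mode)) # both gates shut: frozen forever
      return(outcome("trapped_chamber", NA_integer_, delta_lk))
    if (stats::runif(1) < gate$trap_backtrack)
      return(outcome("backtracked", NA_integer_, trapped_from))
    return(outcome("trapped_chamber", NA_integer_, delta_lk))
  }

  p <- capture_probabilities(delta_lk, energetics, gate, lk0_offset,
                             clip = TRUE)
  u <- stats::runif(1)
  if (u >= p[["+2"]] + p[["-2"]])
    return(outcome("no_capture", NA_integer_, delta_lk))
  dir <- if (u < p[["+2"]]) gate$step else -gate$step
  new <- delta_lk + dir
  # N-gate has closed: passage across the DNA-gate is now unidirectional
  if (mode$c_gate == "deleted")
    return(outcome("transported", dir, new))
  if (mode$c_gate == "locked")
    return(outcome("trapped_chamber", dir, new))
  if (n_gate_blocked(mode))
    return(outcome("transported", dir, new))
  dg <- free_energy(new, energetics, lk0_offset) -
    free_energy(delta_lk, energetics, lk0_offset)
  if (stats::runif(1) < suppressWarnings(release_probability(dg, gate)))
    outcome("transported", dir, new)
  else
    outcome("backtracked", dir, delta_lk)
}
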