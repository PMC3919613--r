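#' Plasmid specification
#'
#' Describes a covalently closed circular plasmid by its size in base pairs.
#' The quadratic supercoiling free-energy model used throughout the package
#' assumes the long-plasmid regime, so sizes below 1 kb are rejected.
#'
#' @param name Label for reports.
#' @param length_bp Plasmid size in base pairs (>= 1000).
#' @param reference_temperature_C Temperature (degrees C) at which the
#'   relaxed center Lk0 defines delta_lk = 0. Default 25.
#' @return An object of class `plasmid_spec`.
#' @examples
#' plasmid_spec("pBR322", 4300)
#' @export
plasmid_spec <- function(name, length_bp, reference_temperature_C = 25) {
  length_bp <- as.numeric(length_bp)
  if (!is.finite(length_bp) || length_bp < 1000)
    stop("`length_bp` must be >= 1000 bp (quadratic free-energy regime)",
         call. = FALSE)
  structure(list(name = as.character(name),
                 length_bp = length_bp,
                 reference_temperature_C = as.numeric(reference_temperature_C)),
            class = "plasmid_spec")
}

#' Equilibrium variance of the topoisomer distribution
#'
#' The thermal-equilibrium distribution of linking-number topoisomers of a
#' closed circle of N bp is, in the quadratic regime, a discretized Gaussian
#' with variance \eqn{\sigma^2 = N / (2 K)} where \eqn{K} is the quadratic
#' free-energy coefficient (free energy \eqn{G/kT = (K/N)\,\Delta Lk^2}).
#'
#' @param plasmid A [plasmid_spec()].
#' @param nk_coefficient Quadratic coefficient K (dimensionless, in kT bp);
#'   default 1100, the literature consensus for plasmids over ~2 kb.
#' @return The equilibrium variance in Lk^2 units.
#' @examples
#' equilibrium_variance(plasmid_spec("pBR322", 4300)) # 4300/2200
#' @export
equilibrium_variance <- function(plasmid, nk_coefficient = 1100) {
  if (!inherits(plasmid, "plasmid_spec")) stop("`plasmid` must be a plasmid_spec")
  if (!is.finite(nk_coefficient) || nk_coefficient <= 0)
    stop("`nk_coefficient` must be positive", call. = FALSE)
  plasmid$length_bp / (2 * nk_coefficient)
}

#' Equilibrium energetics model for Lk topoisomers
#'
#' Bundles everything the simulator needs about DNA supercoiling
#' thermodynamics: the equilibrium topoisomer variance, the quadratic
#' free-energy coefficient, and the linear thermal shift of the relaxed
#' center Lk0.
#'
#' Either give a `plasmid` (then `sigma2_eq = N / (2 * nk_coefficient)`) or
#' set `sigma2_eq` directly.
#'
#' @param plasmid Optional [plasmid_spec()].
#' @param sigma2_eq Equilibrium variance (Lk^2); derived from `plasmid` when
#'   omitted.
#' @param nk_coefficient Quadratic free-energy coefficient (default 1100).
#' @param helical_temp_coeff DNA unwinding coefficient in degrees of helical
#'   rotation per bp per degree C (default 0.011). Sets dLk0/dT.
#' @param reference_temperature_C Reference temperature; taken from
#'   `plasmid` when one is given.
#' @return An object of class `energetics_model`.
#' @examples
#' energetics_model(plasmid_spec("YCp50", 7900))
#' @export
energetics_model <- function(plasmid = NULL, sigma2_eq = NULL,
                             nk_coefficient = 1100,
                             helical_temp_coeff = 0.011,
                             reference_temperature_C = 25) {
  if (is.null(sigma2_eq)) {
    if (is.null(plasmid))
      stop("give either `plasmid` or `sigma2_eq`", call. = FALSE)
    sigma2_eq <- equilibrium_variance(plasmid, nk_coefficient)
    reference_temperature_C <- plasmid$reference_temperature_C
  }
  if (!is.finite(sigma2_eq) || sigma2_eq <= 0)
    stop("`sigma2_eq` must be positive", call. = FALSE)
  structure(list(sigma2_eq = sigma2_eq,
                 nk_coefficient = nk_coefficient,
                 helical_temp_coeff = helical_temp_coeff,
                 reference_temperature_C = reference_temperature_C,
                 plasmid = plasmid),
            class = "energetics_model")
}

#' @export
print.energetics_model <- function(x, ...) {
  cat(sprintf("<energetics_model: sigma2_eq = %.4f Lk^2, K = %g, Tref = %g C>\n",
              x$sigma2_eq, x$nk_coefficient, x$reference_temperature_C))
  invisible(x)
}

#' Supercoiling free energy of a topoisomer
#'
#' Quadratic free energy in kT units,
#' \eqn{G(\Delta Lk) = (\Delta Lk - Lk^0\ \mathrm{offset})^2 / (2\sigma^2)},
#' zero at the (possibly fractional) energy minimum. Vectorized over
#' `delta_lk`.
#'
#' @param delta_lk Integer topoisomer state(s).
#' @param model An [energetics_model()].
#' @param lk0_offset Real-valued displacement of the energy minimum from 0
#'   (e.g. a thermal shift of Lk0). Default 0.
#' @return Free energy in kT.
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' free_energy(-2, m) # ~1.023 kT
#' @export
free_energy <- function(delta_lk, model, lk0_offset = 0) {
  stopifnot(inherits(model, "energetics_model"))
  (delta_lk - lk0_offset)^2 / (2 * model$sigma2_eq)
}

# default contiguous support: |delta_lk - center| <= ceil(8*sigma)
default_support <- function(model, lk0_offset = 0, width_sigmas = 8) {
  hw <- ceiling(width_sigmas * sqrt(model$sigma2_eq))
  c0 <- round(lk0_offset)
  seq.int(c0 - hw, c0 + hw)
}

#' Thermal-equilibrium (Boltzmann) topoisomer distribution
#'
#' Boltzmann-normalized distribution \eqn{\propto \exp(-G(\Delta Lk))} over a
#' contiguous integer support. This is the distribution a type-I enzyme (or
#' nick-religation) produces: its variance equals `sigma2_eq` up to
#' truncation error.
#'
#' @inheritParams free_energy
#' @param support Integer support; default covers `lk0_offset` +/- 8 sigma.
#'   An error is raised if the truncated tail mass exceeds `1e-10`.
#' @return An [lk_distribution()].
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' eq <- equilibrium_distribution(m)
#' @export
equilibrium_distribution <- function(model, support = NULL, lk0_offset = 0) {
  stopifnot(inherits(model, "energetics_model"))
  if (is.null(support)) support <- default_support(model, lk0_offset)
  support <- sort(as.integer(round(support)))
  check_truncation(support, sqrt(model$sigma2_eq), lk0_offset)
  w <- exp(-free_energy(support, model, lk0_offset))
  lk_distribution(support, w)
}

# Gaussian tail bound on the mass excluded by a finite support
check_truncation <- function(support, sigma, center, tol = 1e-10) {
  lo <- stats::pnorm(min(support) - 0.5, mean = center, sd = sigma)
  hi <- stats::pnorm(max(support) + 0.5, mean = center, sd = sigma,
                     lower.tail = FALSE)
  if (lo + hi > tol)
    stop(sprintf(
      "support [%d, %d] too narrow: truncated tail mass %.3g exceeds %.1g",
      min(support), max(support), lo + hi, tol), call. = FALSE)
  invisible(TRUE)
}

#' Thermal shift of the relaxed center Lk0
#'
#' DNA unwinds on heating, so the relaxed linking number decreases with
#' temperature: \eqn{\Delta Lk^0 = -h \cdot N \cdot (T - T_{ref}) / 360}
#' with h the unwinding coefficient in degrees of helical rotation per bp
#' per degree C. The returned shift moves the free-energy minimum; topoisomer
#' states stay integer.
#'
#' @param plasmid A [plasmid_spec()].
#' @param temperature_C Reaction temperature in degrees C.
#' @param model An [energetics_model()] supplying the coefficient and the
#'   reference temperature.
#' @return Shift of Lk0 in Lk units (negative for heating).
#' @examples
#' p <- plasmid_spec("pBR322", 4300)
#' m <- energetics_model(p)
#' lk0_temperature_shift(p, 50, m) # about -3.28
#' @export
lk0_temperature_shift <- function(plasmid, temperature_C, model) {
  stopifnot(inherits(plasmid, "plasmid_spec"), inherits(model, "energetics_model"))
  -model$helical_temp_coeff * plasmid$length_bp *
    (temperature_C - model$reference_temperature_C) / 360
}
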