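#' Topoisomer variance of an Lk distribution
#'
#' Two conventions are offered:
#' * `"fitted_center"` (default): second central moment about the estimated
#'   distribution center ([distribution_center()]), which may be
#'   fractional.
#' * `"reference_topoisomer"`: the densitometry-literal formula
#'   \eqn{\sum_i p_i (\Delta Lk_i - Lk_{ref})^2 / \sum_i p_i} with an
#'   explicit integer reference topoisomer near the center. When the true
#'   center is fractional this convention overestimates the variance, which
#'   is why the fitted-center convention is the default; for the variance
#'   *ratio* R_Lk either convention works as long as it is applied
#'   consistently.
#'
#' @param x An [lk_distribution()], band table, or coercible data frame.
#' @param center_mode `"fitted_center"` or `"reference_topoisomer"`.
#' @param reference Integer reference topoisomer (required in
#'   `"reference_topoisomer"` mode; must lie in the support).
#' @return The variance in Lk^2 units.
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' lk_variance(equilibrium_distribution(m))
#' @export
lk_variance <- function(x, center_mode = c("fitted_center",
                                           "reference_topoisomer"),
                        reference = NULL) {
  center_mode <- match.arg(center_mode)
  d <- as_lk_distribution(x)
  if (length(d$support) == 0L || sum(d$fractions) <= 0)
    stop("empty distribution", call. = FALSE)
  if (center_mode == "fitted_center") {
    ctr <- suppressWarnings(distribution_center(d))
  } else {
    if (is.null(reference))
      stop("reference_topoisomer mode needs an explicit `reference`",
           call. = FALSE)
    if (!(reference %in% d$support))
      stop("`reference` lies outside the support", call. = FALSE)
    ctr <- reference
  }
  sum(d$fractions * (d$support - ctr)^2)
}

#' Center of an Lk distribution (Lk^S or Lk^0 estimate)
#'
#' Estimates the (generally fractional) center the way a Gaussian fit to a
#' lane plot would: a quadratic fit to the log-weights, whose apex is the
#' Gaussian mean. The fit is parity-aware — odd and even sub-distributions
#' are fitted jointly with a shared curvature and center but separate
#' intercepts, so a parity imbalance does not bias the center. Falls back
#' to the weighted mean (with a warning) when fewer than 3 states carry
#' weight or the fitted curvature is not concave.
#'
#' @param x An [lk_distribution()] or coercible object.
#' @return The center in Lk units.
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' distribution_center(equilibrium_distribution(m, lk0_offset = 0.7))
#' @export
distribution_center <- function(x) {
  d <- as_lk_distribution(x)
  keep <- d$fractions > 0
  k <- d$support[keep]
  w <- d$fractions[keep]
  wmean <- sum(w * k) / sum(w)
  if (length(k) < 3L) {
    warning("fewer than 3 informative states; using weighted mean",
            call. = FALSE)
    return(wmean)
  }
  parity <- factor(k %% 2L)
  df <- data.frame(logw = log(w), k = k, k2 = k^2, parity = parity)
  fit <- if (nlevels(droplevels(parity)) > 1L)
    stats::lm(logw ~ k + k2 + parity, data = df, weights = w)
  else
    stats::lm(logw ~ k + k2, data = df, weights = w)
  cf <- stats::coef(fit)
  if (!is.finite(cf[["k2"]]) || cf[["k2"]] >= 0) {
    warning("degenerate log-quadratic fit; using weighted mean",
            call. = FALSE)
    return(wmean)
  }
  -cf[["k"]] / (2 * cf[["k2"]])
}

#' Variance ratio R_Lk between equilibrium and a test distribution
#'
#' \eqn{R_{Lk} = \langle\Delta Lk^2\rangle_{eq} /
#' \langle\Delta Lk^2\rangle_{test}}: values above 1 mean the test
#' distribution is narrower than thermal equilibrium (topology
#' simplification). Under the proofreading model the stationary value is
#' `1 + alpha`.
#'
#' @param dist_equilibrium,dist_test Distributions (coercible via
#'   [as_lk_distribution()]).
#' @param center_mode,reference Passed to [lk_variance()] (for both
#'   distributions).
#' @return The dimensionless ratio.
#' @export
r_lk <- function(dist_equilibrium, dist_test,
                 center_mode = "fitted_center", reference = NULL) {
  v_eq <- lk_variance(dist_equilibrium, center_mode, reference)
  v_t <- lk_variance(dist_test, center_mode, reference)
  if (v_t <= 0) stop("test distribution has zero variance", call. = FALSE)
  v_eq / v_t
}

#' Center offset Delta Lk^S between a steady state and equilibrium
#'
#' \eqn{\Delta Lk^S = Lk^S - Lk^0}: the displacement of the type-II
#' steady-state center from the thermal-equilibrium center. Near the
#' reference temperature it is ~0; it grows positive (negative) when the
#' reaction runs above (below) the temperature at which the substrate's
#' Lk0 was set.
#'
#' @param dist_test Steady-state distribution.
#' @param dist_equilibrium Equilibrium distribution.
#' @return The offset in Lk units.
#' @export
delta_lk_s <- function(dist_test, dist_equilibrium) {
  distribution_center(dist_test) - distribution_center(dist_equilibrium)
}

#' Ratio of two topoisomer fractions
#'
#' Concentration ratio `C_a / C_b` of two resolvable topoisomer bands, e.g.
#' the adjacent pair two Lk units apart that diagnoses steady-state versus
#' equilibrium weighting.
#'
#' @param x A distribution or band table.
#' @param state_a,state_b Integer states in the support.
#' @return The ratio of fractions.
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' adjacent_topoisomer_ratio(equilibrium_distribution(m), -2, 0) # ~0.36
#' @export
adjacent_topoisomer_ratio <- function(x, state_a, state_b) {
  d <- as_lk_distribution(x)
  if (!(state_a %in% d$support) || !(state_b %in% d$support))
    stop("both states must lie in the support", call. = FALSE)
  fb <- d$fractions[match(state_b, d$support)]
  if (fb <= 0) stop("denominator state has zero weight", call. = FALSE)
  d$fractions[match(state_a, d$support)] / fb
}

#' Split a distribution into its odd and even parity classes
#'
#' Type-II enzymes change Lk in steps of two, so the odd and even
#' topoisomer populations evolve as two independent distributions. Returns
#' both sub-distributions renormalized to unit mass (on the full support,
#' with zeros at the opposite parity) together with their original masses,
#' so the input can be reconstructed exactly as
#' `mass_odd * odd + mass_even * even`.
#'
#' @param x A distribution or coercible object.
#' @return List with `odd`, `even` (each an [lk_distribution()], or an
#'   empty flagged one when the class carries no mass) and `masses`
#'   (`c(odd =, even =)`).
#' @export
parity_split <- function(x) {
  d <- as_lk_distribution(x)
  out <- list()
  masses <- c(odd = 0, even = 0)
  for (nm in c("odd", "even")) {
    par <- if (nm == "odd") 1L else 0L
    sel <- (d$support %% 2L) == par
    m <- sum(d$fractions[sel])
    masses[nm] <- m
    if (m <= 0) {
      out[[nm]] <- lk_distribution(integer(0), numeric(0))
    } else {
      f <- ifelse(sel, d$fractions, 0)
      out[[nm]] <- lk_distribution(d$support, f / m, normalize = FALSE)
    }
  }
  c(out, list(masses = masses))
}

#' Summary statistics of an Lk distribution
#'
#' Bundles the quantities used to characterize topology simplification:
#' variance, fitted center, R_Lk and Delta Lk^S against a supplied
#' equilibrium reference, selected adjacent-topoisomer ratios, and parity
#' masses.
#'
#' @param x Test distribution (or band table).
#' @param equilibrium Optional equilibrium reference distribution.
#' @param ratios Optional list of `c(state_a, state_b)` pairs.
#' @param center_mode,reference Passed to [lk_variance()].
#' @return A list of class `lk_summary`.
#' @export
lk_summary <- function(x, equilibrium = NULL, ratios = list(c(-2L, 0L)),
                       center_mode = "fitted_center", reference = NULL) {
  d <- as_lk_distribution(x)
  out <- list(variance = lk_variance(d, center_mode, reference),
              center = suppressWarnings(distribution_center(d)))
  if (!is.null(equilibrium)) {
    out$r_lk <- r_lk(equilibrium, d, center_mode, reference)
    out$delta_lk_s <- delta_lk_s(d, equilibrium)
  }
  out$ratios <- lapply(ratios, function(pr) {
    list(states = pr,
         ratio = tryCatch(adjacent_topoisomer_ratio(d, pr[1], pr[2]),
                          error = function(e) NA_real_))
  })
  out$parity_masses <- parity_split(d)$masses
  structure(out, class = "lk_summary")
}

#' @export
print.lk_summary <- function(x, ...) {
  cat(sprintf("<lk_summary: variance %.4f, center %.4f>\n",
              x$variance, x$center))
  if (!is.null(x$r_lk))
    cat(sprintf("  R_Lk %.4f, delta Lk^S %.4f\n", x$r_lk, x$delta_lk_s))
  for (r in x$ratios)
    cat(sprintf("  C(%d)/C(%d) = %.4f\n", r$states[1], r$states[2], r$ratio))
  invisible(x)
}
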