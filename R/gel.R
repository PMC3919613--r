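#' Synthetic agarose-gel parameters
#'
#' Controls the rendering of a topoisomer distribution as a one-dimensional
#' lane intensity profile. Migration is monotone in the magnitude of the
#' effective writhe and saturates at high supercoiling, as on a chloroquine
#' gel where relaxed topoisomers adopt positive writhe and run ahead of
#' nicked circles.
#'
#' @param lane_length Lane extent in arbitrary migration units (default
#'   100).
#' @param band_sigma Gaussian band width, migration units (default 0.6).
#' @param migration_gain Initial migration distance per writhe unit
#'   (default 6).
#' @param migration_saturation Writhe scale at which band spacing halves
#'   (default 30).
#' @param noise_sd Additive Gaussian noise SD on the profile (default
#'   0.002).
#' @param baseline Constant background intensity (default 0.01).
#' @return An object of class `gel_params`.
#' @export
gel_params <- function(lane_length = 100, band_sigma = 0.6,
                       migration_gain = 6, migration_saturation = 30,
                       noise_sd = 0.002, baseline = 0.01) {
  stopifnot(lane_length > 0, band_sigma > 0, migration_gain > 0,
            migration_saturation > 0, noise_sd >= 0, baseline >= 0)
  structure(list(lane_length = lane_length, band_sigma = band_sigma,
                 migration_gain = migration_gain,
                 migration_saturation = migration_saturation,
                 noise_sd = noise_sd, baseline = baseline),
            class = "gel_params")
}

#' Gel migration position of a topoisomer band
#'
#' Deterministic, monotone-then-saturating map from effective writhe
#' magnitude to migration distance:
#' \deqn{x = g \cdot s / (1 + s / s_{max}), \quad s = |\Delta Lk + c|,}
#' where `c` is the chloroquine offset (the intercalator shifts the writhe
#' of every topoisomer by the same amount, which is how a gel places all
#' relaxed bands on one side of the nicked-circle position). The band at
#' `s = 0` comigrates with the slowest (nicked-like) position, and band
#' spacing shrinks as supercoiling saturates the gel's resolving power.
#' Vectorized over `delta_lk`.
#'
#' @param delta_lk Integer topoisomer state(s).
#' @param params A [gel_params()].
#' @param chloroquine_offset Writhe shift added by the intercalator
#'   (default 0).
#' @return Migration position(s) in lane units.
#' @export
migration_map <- function(delta_lk, params, chloroquine_offset = 0) {
  stopifnot(inherits(params, "gel_params"))
  s <- abs(delta_lk + chloroquine_offset)
  params$migration_gain * s / (1 + s / params$migration_saturation)
}

#' Render a topoisomer distribution as a synthetic lane profile
#'
#' Sum of Gaussian bands (area proportional to topoisomer fraction, common
#' width `band_sigma`) at [migration_map()] positions, over a constant
#' baseline, with seeded additive Gaussian noise. Optional out-of-model
#' contaminant bands (nicked and linear species) can be spiked in to
#' exercise the quantifier's robustness.
#'
#' @param dist An [lk_distribution()].
#' @param params A [gel_params()].
#' @param seed Integer seed (mandatory when `noise_sd > 0`).
#' @param chloroquine_offset Passed to [migration_map()].
#' @param n_points Number of profile samples along the lane (default 2001).
#' @param contaminants Optional data frame with columns `position`, `area`
#'   (e.g. nicked/linear bands).
#' @return A `lane_profile`: data frame with columns `position`,
#'   `intensity`; attributes carry the parameters, band positions and a
#'   record of unresolvable band pairs (center spacing < `band_sigma / 2`).
#' @export
synth_lane <- function(dist, params, seed = NULL, chloroquine_offset = 0,
                       n_points = 2001, contaminants = NULL) {
  dist <- as_lk_distribution(dist)
  stopifnot(inherits(params, "gel_params"))
  if (params$noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is mandatory when noise_sd > 0",
                            call. = FALSE)
    set.seed(seed)
  }
  x <- seq(0, params$lane_length, length.out = n_points)
  centers <- migration_map(dist$support, params, chloroquine_offset)
  y <- rep(params$baseline, n_points)
  for (i in seq_along(centers))
    y <- y + dist$fractions[i] *
      stats::dnorm(x, mean = centers[i], sd = params$band_sigma)
  if (!is.null(contaminants))
    for (j in seq_len(nrow(contaminants)))
      y <- y + contaminants$area[j] *
        stats::dnorm(x, mean = contaminants$position[j],
                     sd = params$band_sigma)
  if (params$noise_sd > 0)
    y <- y + stats::rnorm(n_points, 0, params$noise_sd)
  # flag band pairs the gel cannot resolve (distinct states, overlapping
  # centers closer than half a band width)
  o <- order(centers)
  sp <- diff(centers[o])
  unres <- which(sp < params$band_sigma / 2 & sp > 0)
  warn <- if (length(unres))
    data.frame(state_a = dist$support[o][unres],
               state_b = dist$support[o][unres + 1L])
  else NULL
  structure(data.frame(position = x, intensity = y),
            class = c("lane_profile", "data.frame"),
            params = params, band_positions = centers,
            band_states = dist$support,
            unresolved = warn, seed = seed)
}

#' Quantify a lane profile into a band intensity table
#'
#' Densitometry emulation: estimates the baseline (low quantile of the
#' profile), verifies a local maximum near each expected band position, and
#' apportions the baseline-subtracted profile among Gaussian bands at the
#' expected positions by non-negative least squares — overlapping bands are
#' thereby split by the fitted Gaussian mixture rather than by hard
#' windows. States whose expected positions coincide (within
#' `band_sigma / 4`, e.g. +k and -k on an offset-free |writhe| gel) share
#' one fitted band whose intensity is apportioned equally among them. A
#' band with no detectable local maximum gets intensity 0 and is flagged.
#'
#' @param profile A `lane_profile` (or data frame with `position`,
#'   `intensity`).
#' @param expected_positions Named numeric vector: names are `delta_lk`
#'   states, values their expected migration positions (from
#'   [migration_map()]).
#' @param band_sigma Band width; defaults to the profile's rendering
#'   parameters when present.
#' @return A `band_table`: data frame with columns `delta_lk`, `position`,
#'   `intensity`, `flagged`.
#' @examples
#' m <- energetics_model(plasmid_spec("pBR322", 4300))
#' d <- equilibrium_distribution(m)
#' gp <- gel_params(noise_sd = 0)
#' lane <- synth_lane(d, gp, chloroquine_offset = 15)
#' pos <- stats::setNames(migration_map(d$support, gp, 15), d$support)
#' bt <- quantify_lane(lane, pos)
#' @export
quantify_lane <- function(profile, expected_positions, band_sigma = NULL) {
  if (is.null(band_sigma)) {
    pp <- attr(profile, "params")
    if (is.null(pp)) stop("give `band_sigma` (profile carries no parameters)",
                          call. = FALSE)
    band_sigma <- pp$band_sigma
  }
  x <- profile$position
  y <- profile$intensity
  if (any(expected_positions < min(x) | expected_positions > max(x)))
    stop("expected positions outside the profile range", call. = FALSE)
  states <- as.integer(names(expected_positions))
  if (length(states) == 0L || any(is.na(states)))
    stop("`expected_positions` must be named by delta_lk states", call. = FALSE)

  baseline <- stats::quantile(y, 0.1, names = FALSE)
  b <- pmax(y - baseline, 0)
  noise_level <- stats::mad(diff(y)) / sqrt(2)

  # collapse states whose bands comigrate into shared fitted positions
  grp <- integer(length(states))
  upos <- numeric(0)
  for (i in order(expected_positions)) {
    j <- which(abs(upos - expected_positions[i]) < band_sigma / 4)
    if (length(j)) grp[i] <- j[1L]
    else {
      upos <- c(upos, expected_positions[i])
      grp[i] <- length(upos)
    }
  }

  detected <- vapply(seq_along(upos), function(j) {
    win <- which(abs(x - upos[j]) <= 3 * band_sigma)
    if (length(win) < 3L) return(FALSE)
    pk <- win[which.max(y[win])]
    peak_height <- y[pk] - baseline
    peak_height > max(5 * noise_level, 1e-12)
  }, logical(1))

  A <- vapply(seq_along(upos),
              function(j) stats::dnorm(x, upos[j], band_sigma),
              numeric(length(x)))
  areas <- rep(0, length(upos))
  if (any(detected)) {
    fit <- pracma::lsqnonneg(A[, detected, drop = FALSE], b)
    areas[detected] <- fit$x
  }
  share <- tabulate(grp, nbins = length(upos))
  inten <- areas[grp] / share[grp]
  flagged <- !detected[grp]
  inten[flagged] <- 0
  structure(data.frame(delta_lk = states,
                       position = as.numeric(expected_positions),
                       intensity = inten,
                       flagged = flagged)[order(states), ],
            class = c("band_table", "data.frame"),
            baseline = baseline)
}

#' Write / read lane profiles and band tables
#'
#' `write_lane_profile()` stores a profile as two-column CSV
#' (`position,intensity`); `write_band_table()` stores a band table as TSV
#' (`delta_lk`, `position`, `intensity`). The readers invert them.
#'
#' @param profile,band_table Objects to write.
#' @param path File path.
#' @return `path` invisibly (writers); the object (readers).
#' @name gel_io
#' @export
write_lane_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("position", "intensity")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname gel_io
#' @export
read_lane_profile <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("lane_profile", "data.frame"))
}

#' @rdname gel_io
#' @export
write_band_table <- function(band_table, path) {
  utils::write.table(
    as.data.frame(band_table)[, c("delta_lk", "position", "intensity")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gel_io
#' @export
read_band_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(df, class = c("band_table", "data.frame"))
}
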