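#' Linking-number topoisomer distribution
#'
#' An `lk_distribution` holds a normalized probability distribution over
#' integer linking-number states \eqn{\Delta Lk}, expressed relative to the
#' relaxed center \eqn{Lk^0} at the reference temperature. It is the central
#' object of the package: equilibrium models, stationary solutions, Monte
#' Carlo ensembles and quantified gel lanes all produce or consume one.
#'
#' The support is a contiguous run of integers (step 1, so both parity
#' classes are representable) and the fractions sum to 1 within `1e-9`.
#'
#' @param support Integer vector of contiguous \eqn{\Delta Lk} states.
#' @param fractions Non-negative weights, one per state. Normalized to sum
#'   to 1 when `normalize = TRUE`.
#' @param normalize Divide `fractions` by their sum (default `TRUE`).
#'
#' @return An object of class `lk_distribution` with elements `support`
#'   (integer) and `fractions` (numeric).
#' @examples
#' d <- lk_distribution(-3:3, exp(-((-3:3)^2) / 4))
#' sum(d$fractions)
#' @export
lk_distribution <- function(support, fractions, normalize = TRUE) {
  if (length(support) == 0L) {
    d <- structure(list(support = integer(0), fractions = numeric(0)),
                   class = "lk_distribution")
    attr(d, "empty") <- TRUE
    return(d)
  }
  if (length(support) != length(fractions))
    stop("`support` and `fractions` must have equal length", call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions < 0))
    stop("`fractions` must be finite and non-negative", call. = FALSE)
  if (any(support != round(support)))
    stop("`support` must be integer-valued", call. = FALSE)
  support <- as.integer(round(support))
  o <- order(support)
  support <- support[o]
  fractions <- as.numeric(fractions[o])
  if (length(support) > 1L && any(diff(support) != 1L))
    stop("`support` must be contiguous in steps of 1", call. = FALSE)
  tot <- sum(fractions)
  if (tot <= 0) stop("total weight must be positive", call. = FALSE)
  if (normalize) {
    fractions <- fractions / tot
  } else if (abs(tot - 1) > 1e-9) {
    stop("fractions must sum to 1 within 1e-9 (got ", format(tot), ")",
         call. = FALSE)
  }
  structure(list(support = support, fractions = fractions),
            class = "lk_distribution")
}

#' Coerce topoisomer weights to an `lk_distribution`
#'
#' Accepts an existing `lk_distribution`, a band table or data frame with a
#' `delta_lk` column and a `fraction`/`intensity`/`count` column, or a table
#' of counts. Gaps in the support are filled with zero weight so the result
#' is contiguous.
#'
#' @param x Object to coerce.
#' @param ... Unused.
#' @return An `lk_distribution`.
#' @export
as_lk_distribution <- function(x, ...) UseMethod("as_lk_distribution")

#' @export
as_lk_distribution.lk_distribution <- function(x, ...) x

#' @export
as_lk_distribution.data.frame <- function(x, ...) {
  if (!"delta_lk" %in% names(x))
    stop("data frame needs a `delta_lk` column", call. = FALSE)
  wcol <- intersect(c("fraction", "intensity", "count"), names(x))
  if (length(wcol) == 0L)
    stop("data frame needs a `fraction`, `intensity` or `count` column",
         call. = FALSE)
  k <- as.integer(round(x$delta_lk))
  w <- as.numeric(x[[wcol[1L]]])
  w[!is.finite(w) | w < 0] <- 0
  full <- seq(min(k), max(k))
  agg <- rowsum(w, k) # duplicate states accumulate
  f <- numeric(length(full))
  f[match(as.integer(rownames(agg)), full)] <- agg[, 1L]
  lk_distribution(full, f)
}

#' @export
as_lk_distribution.numeric <- function(x, ...) {
  if (is.null(names(x)))
    stop("a bare numeric vector needs names giving the delta_lk states",
         call. = FALSE)
  as_lk_distribution(data.frame(delta_lk = as.integer(names(x)), fraction = x))
}

#' @export
as.data.frame.lk_distribution <- function(x, ...) {
  data.frame(delta_lk = x$support, fraction = x$fractions)
}

#' @export
print.lk_distribution <- function(x, ...) {
  if (isTRUE(attr(x, "empty"))) {
    cat("<lk_distribution: empty>\n")
    return(invisible(x))
  }
  cat(sprintf("<lk_distribution: %d states, delta_lk %d..%d>\n",
              length(x$support), min(x$support), max(x$support)))
  cat(sprintf("  mean %.4f  variance %.4f\n",
              lk_moment(x, 1L), lk_moment(x, 2L, central = TRUE)))
  invisible(x)
}

# raw/central moment about the weighted mean; internal workhorse
lk_moment <- function(dist, order = 1L, central = FALSE, about = NULL) {
  k <- dist$support
  p <- dist$fractions
  if (is.null(about)) about <- if (central) sum(p * k) else 0
  sum(p * (k - about)^order)
}

#' Write an `lk_distribution` to a two-column TSV file
#'
#' The on-disk format is `delta_lk<TAB>fraction` with a header line.
#'
#' @param dist An `lk_distribution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lk_distribution <- function(dist, path) {
  dist <- as_lk_distribution(dist)
  utils::write.table(as.data.frame(dist), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an `lk_distribution` from a two-column TSV file
#'
#' @param path File written by [write_lk_distribution()] (columns
#'   `delta_lk`, `fraction`).
#' @return An `lk_distribution`.
#' @export
read_lk_distribution <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  as_lk_distribution(df)
}
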