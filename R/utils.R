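## Internal helpers shared across modules.

## Boltzmann constant in kcal mol^-1 K^-1 (CODATA, 4 significant figures).
.kB <- 0.0019872

#' @noRd
.wrapCoords <- function(x, L) {
  ## Wrap values into [-L/2, L/2).
  x - L * floor(x / L + 0.5)
}

#' @noRd
.minImageDist2 <- function(dx, dy, dz, box) {
  dx <- .wrapCoords(dx, box[1])
  dy <- .wrapCoords(dy, box[2])
  dz <- .wrapCoords(dz, box[3])
  dx * dx + dy * dy + dz * dz
}

#' @noRd
.polar <- function(xy) {
  list(r = sqrt(xy[, 1]^2 + xy[, 2]^2),
       theta = atan2(xy[, 2], xy[, 1]) %% (2 * pi))
}

## Angular helpers: all angles reduced to [0, 2*pi).
#' @noRd
.wrapAngle <- function(a) a %% (2 * pi)

## TRUE if angle a lies in the arc from lo going counter-clockwise to hi.
#' @noRd
.inArc <- function(a, lo, hi) {
  a <- .wrapAngle(a - lo)
  w <- .wrapAngle(hi - lo)
  a < w
}

## Counter-clockwise arc width from lo to hi.
#' @noRd
.arcWidth <- function(lo, hi) .wrapAngle(hi - lo)

## Circular midpoint of the short arc between two angles.
#' @noRd
.arcMid <- function(a, b) .wrapAngle(a + .wrapAngle(b - a) / 2)

#' Standard error of a (possibly autocorrelated) per-frame series
#'
#' Uses the batch-means method: the series is split into contiguous batches
#' and the SEM of the batch means is reported, which is robust to the frame-
#' to-frame correlation produced by diffusive lipid motion.
#'
#' @param x numeric per-frame series.
#' @param nBatches number of contiguous batches (default 20, reduced when the
#'   series is short).
#' @return standard error of the mean of `x`.
#' @keywords internal
batchSEM <- function(x, nBatches = 20L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  nBatches <- max(2L, min(nBatches, n %/% 2L))
  idx <- cut(seq_len(n), breaks = nBatches, labels = FALSE)
  bm <- tapply(x, idx, mean)
  stats::sd(bm) / sqrt(length(bm))
}

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
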