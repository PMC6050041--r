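#' Canonical motion directions
#'
#' Equally spaced directions of motion in degrees, starting at 0 and tiling
#' direction space. The standard stimulus set uses 8 directions, 45 degrees
#' apart (0, 45, ..., 315).
#'
#' @param n Number of directions.
#' @return Numeric vector of directions in degrees.
#' @export
#' @examples
#' sc_directions()      # 0 45 ... 315
#' sc_directions(4)     # 0 90 180 270
sc_directions <- function(n = 8) {
  seq(0, 360 - 360 / n, by = 360 / n)
}

#' Folded center-surround direction difference
#'
#' Absolute angular difference between center and surround motion directions,
#' folded into [0, 180] so that clockwise and counterclockwise offsets of the
#' same magnitude map onto the same value (delta-theta).
#'
#' @param center,surround Directions in degrees (vectors recycle).
#' @return Folded difference in degrees, in [0, 180].
#' @export
#' @examples
#' fold_dtheta(0, 315)   # 45
#' fold_dtheta(90, 270)  # 180
fold_dtheta <- function(center, surround) {
  d <- abs(center - surround) %% 360
  pmin(d, 360 - d)
}

deg2rad <- function(x) x * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls do not disturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

check_count <- function(x, name = deparse(substitute(x)), min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < min || x != round(x)) {
    stop("invalid parameter: `", name, "` must be a single integer >= ",
         min, call. = FALSE)
  }
  invisible(as.integer(x))
}

# Row-wise sd of a numeric matrix (n-1 denominator), without apply().
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("row_sds() needs at least 2 columns", call. = FALSE)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

# Standard error of the mean, NA-safe.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
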