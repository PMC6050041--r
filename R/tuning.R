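# Direction-tuning and surround-modulation statistics: vector-sum gDSI,
# preferred direction (including the center-silent rule), the clipped
# modulation index and the pooled-resampling bootstrap classification.

#' Global direction selectivity index (gDSI)
#'
#' The magnitude of the response-weighted vector sum over directions divided
#' by the scalar response sum:
#' `gDSI = |sum(R_theta * exp(i * theta))| / sum(R_theta)`.
#' Negative responses are rectified to zero first (configurable), keeping
#' the index in [0, 1]; 0 means untuned, 1 a response to a single direction
#' only.
#'
#' @param tuning_curve Mean dF/F0 per direction.
#' @param directions Directions in degrees (default 8 directions, 45 degree
#'   steps).
#' @param rectify Rectify negative responses to zero before the sums
#'   (default `TRUE`).
#' @return gDSI in [0, 1], or `NA` if the rectified curve sums to zero
#'   (undefined; such cells are excluded from gDSI analyses).
#' @export
#' @examples
#' compute_gdsi(c(2, 1, 1, 1, 1, 1, 1, 1))  # 1/9
compute_gdsi <- function(tuning_curve, directions = sc_directions(8),
                         rectify = TRUE) {
  if (length(tuning_curve) != length(directions) || length(directions) < 2) {
    stop("tuning_curve and directions must match (length >= 2)",
         call. = FALSE)
  }
  r <- tuning_curve
  if (rectify) r <- pmax(r, 0)
  total <- sum(r)
  if (!is.finite(total) || total <= 0) return(NA_real_)
  Mod(sum(r * exp(1i * deg2rad(directions)))) / total
}

#' Preferred direction of a cell
#'
#' For center-responsive cells: the center direction eliciting the peak mean
#' dF/F0 in the center-alone conditions. For center-silent cells (no
#' response to center alone): the center direction of the center-surround
#' combination eliciting the peak mean dF/F0. Ties break toward the lowest
#' direction value.
#'
#' @param matrix An `sc_matrix` (unaligned) from [build_matrix()].
#' @param responsive_center Is the cell responsive to center-alone stimuli?
#' @return List with `direction` (degrees, or `NA` if every candidate
#'   response is non-positive) and `source` (`"center_alone"` or
#'   `"center_silent_CS"`).
#' @export
preferred_direction <- function(matrix, responsive_center = TRUE) {
  v <- matrix$values
  nd <- nrow(v) - 1
  dirs <- matrix$directions
  if (responsive_center) {
    curve <- v[seq_len(nd), nd + 1]
    if (all(curve <= 0)) {
      return(list(direction = NA_real_, source = "center_alone"))
    }
    list(direction = dirs[which.max(curve)], source = "center_alone")
  } else {
    cs <- v[seq_len(nd), seq_len(nd), drop = FALSE]
    if (all(cs <= 0)) {
      return(list(direction = NA_real_, source = "center_silent_CS"))
    }
    # column-major which.max with the center (row) index varying fastest
    # breaks ties toward the lowest center direction, then lowest surround
    k <- which.max(cs)
    list(direction = dirs[(k - 1) %% nd + 1], source = "center_silent_CS")
  }
}

#' Surround modulation index
#'
#' `MI = (R_CwS - R_C) / (R_CwS + R_C)` where `R_C` is the response to the
#' preferred-direction center alone and `R_CwS` the response to the same
#' center coupled with the surround under assessment. Values outside
#' [-1, 1], which arise from negative dF/F0, are clipped to the bounds.
#' Negative MI indicates suppression by the surround, positive MI
#' potentiation. If the denominator is exactly zero the index is the sign of
#' the numerator (0 when both responses are zero).
#'
#' @param r_cs Response to center-with-surround (vectorized).
#' @param r_c Response to center alone.
#' @return MI in [-1, 1].
#' @export
#' @examples
#' modulation_index(3, 1)     # 0.5
#' modulation_index(-0.5, 1)  # clipped to -1
modulation_index <- function(r_cs, r_c) {
  num <- r_cs - r_c
  den <- r_cs + r_c
  mi <- ifelse(den == 0, sign(num), num / den)
  pmin(pmax(mi, -1), 1)
}

#' Pooled-resampling bootstrap classification of surround modulation
#'
#' Tests whether two sets of per-trial dF/F0 values (e.g. preferred center
#' alone vs preferred center with opposite surround) differ significantly.
#' The `2n` values are pooled; `n_boot` times, `2n` values are drawn from
#' the pool with replacement and split at random into two groups of `n`
#' whose mean difference forms the null distribution. The observed
#' `mean(trials_b) - mean(trials_a)` is compared with the null's central
#' `1 - alpha` interval (empirical quantiles, linear interpolation):
#' above it, the response is potentiated; below, suppressed; inside,
#' non-modulated.
#'
#' @param trials_a Per-trial dF/F0 of the reference condition (typically 4
#'   values).
#' @param trials_b Per-trial dF/F0 of the compared condition (same length).
#' @param n_boot Number of resamples (default 10000).
#' @param alpha Two-sided significance level (default 0.05).
#' @param seed Optional integer seed; the result is deterministic given the
#'   seed.
#' @return List with `class` (`"potentiated"`, `"suppressed"` or
#'   `"non_modulated"`), `observed`, and `ci` (the null interval).
#' @export
#' @examples
#' bootstrap_classify(c(0, 0, 0, 0), c(10, 10, 10, 10), seed = 1)$class
bootstrap_classify <- function(trials_a, trials_b, n_boot = 10000,
                               alpha = 0.05, seed = NULL) {
  n <- length(trials_a)
  if (length(trials_b) != n || n < 2) {
    stop("invalid input: trial groups must have equal length >= 2",
         call. = FALSE)
  }
  check_count(n_boot, min = 1000)
  pool <- c(trials_a, trials_b)
  observed <- mean(trials_b) - mean(trials_a)
  d <- with_seed(seed, {
    idx <- sample.int(2 * n, 2 * n * n_boot, replace = TRUE)
    m <- matrix(pool[idx], nrow = 2 * n)
    # rows of m are exchangeable draws, so the first n vs last n rows is a
    # random split of each resampled set
    .colMeans(m[seq_len(n), , drop = FALSE], n, n_boot) -
      .colMeans(m[n + seq_len(n), , drop = FALSE], n, n_boot)
  })
  ci <- stats::quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  cls <- if (observed > ci[2]) "potentiated" else
    if (observed < ci[1]) "suppressed" else "non_modulated"
  list(class = cls, observed = observed, ci = ci)
}

#' Four-way response category of a cell
#'
#' The population taxonomy for the preferred-center + opposite-surround
#' condition: cells that respond to no stimulus condition, and cells that
#' respond to the surround alone but not to the center or any
#' center-surround combination, are `"non_responsive"`; all other cells
#' carry their bootstrap class (`"potentiated"`, `"suppressed"`,
#' `"non_modulated"`).
#'
#' @param bootstrap_class Class from [bootstrap_classify()] for the
#'   preferred-center/opposite-surround comparison (may be `NA` for
#'   non-responsive cells).
#' @param responsive Did any center-alone or center-surround condition pass
#'   the responsiveness criterion?
#' @param surround_alone_only Is the cell responsive only to surround-alone
#'   conditions?
#' @return Category string.
#' @export
categorize_cell <- function(bootstrap_class, responsive,
                            surround_alone_only = FALSE) {
  if (!isTRUE(responsive) || isTRUE(surround_alone_only)) {
    return("non_responsive")
  }
  if (is.na(bootstrap_class)) return("non_responsive")
  match.arg(bootstrap_class,
            c("potentiated", "suppressed", "non_modulated"))
}
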