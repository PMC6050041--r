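# Stimulus protocol constructors. A protocol is the ordered description of
# what was shown: a condition table plus a seeded pseudo-random presentation
# order of (condition, repeat) pairs. BLANK (gray) components are encoded as
# NA in the `center` / `surround` columns.

new_protocol <- function(kind, conditions, n_repeats, seed) {
  conditions$condition_id <- seq_len(nrow(conditions))
  conditions <- conditions[, c("condition_id",
                               setdiff(names(conditions), "condition_id"))]
  pairs <- expand.grid(condition_id = conditions$condition_id,
                       rep = seq_len(n_repeats))
  ord <- with_seed(seed, sample.int(nrow(pairs)))
  order <- pairs[ord, , drop = FALSE]
  order$trial <- seq_len(nrow(order))
  rownames(order) <- NULL
  structure(list(kind = kind,
                 conditions = conditions,
                 n_repeats = as.integer(n_repeats),
                 order = order[, c("trial", "condition_id", "rep")],
                 seed = as.integer(seed)),
            class = "sc_protocol")
}

#' Direction-contrast (center x surround) stimulus protocol
#'
#' Builds the full factorial design of center and surround drifting-grating
#' directions, each direction set augmented with a blank (gray) component:
#' `(n_directions + 1)^2` unique conditions. With the standard 8 directions
#' this is the 81-condition (9 x 9) set, including the center-alone row, the
#' surround-alone column and the all-gray condition. Each condition is
#' presented `n_repeats` times in a seeded pseudo-random order. Stimuli last
#' 2 s and are followed by a 5 s gray inter-trial interval.
#'
#' @param n_directions Number of motion directions (default 8, i.e. 45 degree
#'   steps).
#' @param n_repeats Repeats per condition (at least 4 in a typical session).
#' @param seed Integer seed for the presentation order; the condition table
#'   itself does not depend on the seed.
#' @return An object of class `sc_protocol` with elements `kind`,
#'   `conditions` (data frame: `condition_id`, `center`, `surround`,
#'   `surround_kind`, `surround_param`, `duration_s`, `iti_s`), `n_repeats`
#'   and `order` (one row per trial).
#' @export
#' @examples
#' p <- direction_contrast_protocol(n_repeats = 4, seed = 1)
#' nrow(p$conditions)  # 81
#' nrow(p$order)       # 324
direction_contrast_protocol <- function(n_directions = 8, n_repeats = 4,
                                        seed = 1L) {
  check_count(n_directions)
  check_count(n_repeats)
  dirs <- sc_directions(n_directions)
  grid <- expand.grid(center = c(dirs, NA_real_),
                      surround = c(dirs, NA_real_))
  cond <- data.frame(center = grid$center,
                     surround = grid$surround,
                     surround_kind = "drifting",
                     surround_param = NA_real_,
                     duration_s = 2,
                     iti_s = 5,
                     stringsAsFactors = FALSE)
  new_protocol("direction_contrast", cond, n_repeats, seed)
}

#' Feature-contrast stimulus protocols
#'
#' Builds the condition sets probing surround contrasts other than motion
#' direction, with the surround drifting in the same direction as the center
#' unless noted:
#' \describe{
#'   \item{`anti_phase`}{8 center directions, surround at a 180 degree phase
#'     offset: 8 unique conditions.}
#'   \item{`temporal_freq`}{8 center directions (center at 2 Hz) crossed with
#'     a surround at 1 Hz or 4 Hz: 16 unique conditions.}
#'   \item{`static_orientation`}{static gratings of 4 orientations (0, 45,
#'     90, 135 degrees) plus blank for both center and surround: 25 (5 x 5)
#'     unique conditions, including center-alone, surround-alone and
#'     all-gray. For this kind the `center` / `surround` columns hold
#'     orientations rather than motion directions.}
#' }
#'
#' @param kind One of `"anti_phase"`, `"temporal_freq"`,
#'   `"static_orientation"`.
#' @param n_repeats Repeats per condition.
#' @param seed Seed for the presentation order.
#' @return An `sc_protocol`; see [direction_contrast_protocol()].
#' @export
#' @examples
#' nrow(feature_contrast_protocol("temporal_freq")$conditions)  # 16
feature_contrast_protocol <- function(kind = c("anti_phase", "temporal_freq",
                                               "static_orientation"),
                                      n_repeats = 4, seed = 1L) {
  if (!is.character(kind) || length(kind) < 1 ||
      !(kind[1] %in% c("anti_phase", "temporal_freq", "static_orientation"))) {
    stop("invalid parameter: unknown feature-contrast kind", call. = FALSE)
  }
  kind <- kind[1]
  check_count(n_repeats)
  dirs <- sc_directions(8)
  cond <- switch(kind,
    anti_phase = data.frame(center = dirs,
                            surround = dirs,
                            surround_kind = "anti_phase",
                            surround_param = 180,
                            duration_s = 2, iti_s = 5),
    temporal_freq = {
      g <- expand.grid(center = dirs, tf = c(1, 4))
      data.frame(center = g$center,
                 surround = g$center,
                 surround_kind = "temporal_freq",
                 surround_param = g$tf,
                 duration_s = 2, iti_s = 5)
    },
    static_orientation = {
      ors <- c(0, 45, 90, 135)
      g <- expand.grid(center = c(ors, NA_real_),
                       surround = c(ors, NA_real_))
      data.frame(center = g$center,
                 surround = g$surround,
                 surround_kind = "static_orientation",
                 surround_param = NA_real_,
                 duration_s = 2, iti_s = 5)
    })
  new_protocol(kind, cond, n_repeats, seed)
}

#' Flashing-square receptive-field mapping protocol
#'
#' A black square flashed at each location of a square grid tiling the mapped
#' region of visual space without overlap (default: 6 x 6 grid of 5 degree
#' squares covering 30 x 30 degrees, centered on the grating-patch center).
#' Each square is on for 1 s and followed by 3 s of gray.
#'
#' @param n_repeats Repeats per grid location.
#' @param seed Seed for the presentation order.
#' @param grid_dim Squares per side.
#' @param square_size_deg Square side length, degrees of visual angle.
#' @param center Grid center (azimuth, elevation) in degrees.
#' @return An `sc_protocol` of kind `"rf_mapping"` whose condition table has
#'   `x`, `y` grid-center coordinates (degrees).
#' @export
flash_grid_protocol <- function(n_repeats = 4, seed = 1L, grid_dim = 6,
                                square_size_deg = 5, center = c(0, 0)) {
  check_count(n_repeats)
  check_count(grid_dim)
  half <- grid_dim * square_size_deg / 2
  pos <- seq(-half + square_size_deg / 2, half - square_size_deg / 2,
             by = square_size_deg)
  g <- expand.grid(x = pos + center[1], y = pos + center[2])
  cond <- data.frame(x = g$x, y = g$y,
                     square_size_deg = square_size_deg,
                     duration_s = 1, iti_s = 3)
  new_protocol("rf_mapping", cond, n_repeats, seed)
}

#' @export
print.sc_protocol <- function(x, ...) {
  cat("<sc_protocol> kind:", x$kind, "\n")
  cat(" ", nrow(x$conditions), "unique conditions x", x$n_repeats,
      "repeats =", nrow(x$order), "trials\n")
  cat("  stimulus", x$conditions$duration_s[1], "s, ITI",
      x$conditions$iti_s[1], "s\n")
  invisible(x)
}
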