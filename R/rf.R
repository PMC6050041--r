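# Receptive-field estimation from flashing-square grid responses.

#' Receptive-field center of mass
#'
#' The RF center is the response-weighted mean of the grid positions at
#' which the cell was responsive:
#' `RF_center = sum(R_i * r_i) / sum(R_i)` over responsive locations `i`.
#' Non-responsive locations are excluded from the sum.
#'
#' @param responses Mean dF/F0 per grid location.
#' @param positions Matrix or data frame with one (x, y) row per location,
#'   degrees of visual angle.
#' @param responsive Logical mask of responsive locations (default: positive
#'   responses). Responsive responses must be positive.
#' @return Named numeric vector `c(x, y)` in degrees.
#' @export
#' @examples
#' compute_rf_center(c(3, 1), rbind(c(0, 0), c(4, 0)))  # x = 1
compute_rf_center <- function(responses, positions,
                              responsive = responses > 0) {
  positions <- as.matrix(positions)
  if (length(responses) != nrow(positions)) {
    stop("responses and positions disagree in length", call. = FALSE)
  }
  if (!any(responsive)) {
    stop("no responsive grid location: RF unmappable", call. = FALSE)
  }
  r <- responses[responsive]
  if (any(r <= 0)) {
    stop("responsive grid responses must be positive", call. = FALSE)
  }
  p <- positions[responsive, , drop = FALSE]
  out <- colSums(r * p) / sum(r)
  names(out) <- c("x", "y")
  out
}

#' Is a receptive field covered by the center grating patch?
#'
#' @param centroid RF center `c(x, y)` in degrees.
#' @param patch_center Patch center in degrees (default the origin).
#' @param patch_radius_deg Patch radius (default 10 degrees). The boundary
#'   is inclusive: a centroid exactly at the radius counts as covered.
#' @return Logical.
#' @export
is_rf_covered <- function(centroid, patch_center = c(0, 0),
                          patch_radius_deg = 10) {
  sqrt(sum((centroid - patch_center)^2)) <= patch_radius_deg
}

#' Two-dimensional dispersion of RF centroids
#'
#' Root-mean-square Euclidean distance of the centroids from their mean --
#' a single rotation-invariant scalar per field of view.
#'
#' @param centroids Matrix or data frame, one (x, y) row per cell.
#' @return Dispersion in degrees.
#' @export
#' @examples
#' centroid_dispersion(rbind(c(0, 0), c(2, 0)))  # 1
centroid_dispersion <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2) {
    stop("insufficient data: need at least 2 centroids", call. = FALSE)
  }
  ctr <- colMeans(centroids)
  sqrt(mean(rowSums(sweep(centroids, 2, ctr)^2)))
}

#' Per-cell receptive-field maps from flashing-square trials
#'
#' Computes each cell's mean response per grid location, flags responsive
#' locations with the same 2-SD criterion used for whole-cell
#' responsiveness ([assess_responsiveness()]), and estimates the RF centroid
#' from the responsive locations. Cells with no responsive location are
#' flagged unmappable (`NA` centroid) rather than dropped.
#'
#' @param trials An `sc_trials` table from an `rf_mapping` recording.
#' @param n_sd Responsiveness threshold in baseline-SD units.
#' @param patch_center,patch_radius_deg Passed to [is_rf_covered()] for the
#'   coverage flag.
#' @return List with `cells` (data frame: `cell_id`, `x`, `y`,
#'   `n_responsive`, `rf_area_deg2`, `mappable`, `covered`), `responses`
#'   (matrix cells x locations of mean dF/F0) and `positions`. The RF area
#'   is `n_responsive` times the square area -- a reported convention, not a
#'   fitted size.
#' @export
rf_map <- function(trials, n_sd = 2, patch_center = c(0, 0),
                   patch_radius_deg = 10) {
  protocol <- attr(trials, "protocol")
  if (is.null(protocol) || protocol$kind != "rf_mapping") {
    stop("`trials` must come from an rf_mapping protocol", call. = FALSE)
  }
  pos <- as.matrix(protocol$conditions[, c("x", "y")])
  resp <- assess_responsiveness(trials, n_sd = n_sd)
  cond_levels <- protocol$conditions$condition_id
  m <- with(resp$conditions,
            tapply(mean_dff, list(cell_id, condition_id), mean))
  fl <- with(resp$conditions,
             tapply(responsive, list(cell_id, condition_id), any))
  m <- m[, as.character(cond_levels), drop = FALSE]
  fl <- fl[, as.character(cond_levels), drop = FALSE]
  area <- protocol$conditions$square_size_deg[1]^2
  cells <- data.frame(cell_id = rownames(m), x = NA_real_, y = NA_real_,
                      n_responsive = as.integer(rowSums(fl, na.rm = TRUE)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    mask <- !is.na(fl[i, ]) & fl[i, ] & m[i, ] > 0
    if (any(mask)) {
      ctr <- compute_rf_center(m[i, ], pos, mask)
      cells$x[i] <- ctr["x"]
      cells$y[i] <- ctr["y"]
    }
  }
  cells$rf_area_deg2 <- cells$n_responsive * area
  cells$mappable <- !is.na(cells$x)
  cells$covered <- ifelse(cells$mappable,
                          mapply(function(x, y) is_rf_covered(c(x, y),
                                   patch_center, patch_radius_deg),
                                 cells$x, cells$y),
                          NA)
  rownames(cells) <- NULL
  list(cells = cells, responses = m, positions = pos)
}
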