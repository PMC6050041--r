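# Center-surround response matrices and the divisive/multiplicative
# modulation analysis. A cell's responses to the 81-condition design are
# arranged as a 9 x 9 matrix (center direction incl. blank x surround
# direction incl. blank); matrices are circularly shifted to align every
# cell's preferred direction before population averaging.

#' Build a cell's center-surround response matrix
#'
#' @param trials An `sc_trials` table from a direction-contrast recording
#'   (all cells, or pass `cell_id` to select one).
#' @param cell_id Cell to build the matrix for; defaults to the only cell
#'   present.
#' @return An `sc_matrix`: list with `cell_id`, `values` (9 x 9 mean dF/F0,
#'   rows = center, cols = surround, last index = blank), `trials` (the
#'   per-trial rows retained for resampling tests), `directions`, `aligned`,
#'   `alignment_shift`.
#' @export
build_matrix <- function(trials, cell_id = NULL) {
  protocol <- attr(trials, "protocol")
  if (is.null(protocol) || protocol$kind != "direction_contrast") {
    stop("`trials` must come from a direction_contrast protocol",
         call. = FALSE)
  }
  if (is.null(cell_id)) {
    ids <- unique(trials$cell_id)
    if (length(ids) != 1) {
      stop("multiple cells present; supply `cell_id`", call. = FALSE)
    }
    cell_id <- ids
  }
  tr <- trials[trials$cell_id == cell_id, , drop = FALSE]
  cond <- protocol$conditions
  present <- unique(tr$condition_id)
  if (!all(cond$condition_id %in% present)) {
    stop("incomplete matrix: conditions without trials", call. = FALSE)
  }
  dirs <- sort(unique(cond$center[!is.na(cond$center)]))
  nd <- length(dirs)
  ridx <- ifelse(is.na(cond$center), nd + 1, match(cond$center, dirs))
  cidx <- ifelse(is.na(cond$surround), nd + 1, match(cond$surround, dirs))
  means <- tapply(tr$dff, factor(tr$condition_id,
                                 levels = cond$condition_id), mean)
  v <- matrix(NA_real_, nd + 1, nd + 1,
              dimnames = list(center = c(dirs, "blank"),
                              surround = c(dirs, "blank")))
  v[cbind(ridx, cidx)] <- means
  structure(list(cell_id = cell_id, values = v, trials = tr,
                 directions = dirs, aligned = FALSE,
                 alignment_shift = 0L),
            class = "sc_matrix")
}

#' Response matrices for every cell of a trial table
#'
#' Vectorized convenience wrapper around [build_matrix()].
#'
#' @param trials An `sc_trials` table.
#' @return Named list of `sc_matrix`, one per cell.
#' @export
response_matrices <- function(trials) {
  ids <- unique(trials$cell_id)
  out <- lapply(ids, function(id) build_matrix(trials, id))
  names(out) <- ids
  out
}

#' Align a response matrix to a preferred direction
#'
#' Circularly shifts the direction indices of both axes so the preferred
#' center direction lands at relative direction 0, keeping the blank row and
#' column fixed. The multiset of matrix entries is conserved, and aligning
#' an already-aligned matrix to 0 degrees is the identity.
#'
#' @param matrix An `sc_matrix`.
#' @param preferred_direction Preferred direction in degrees (multiple of
#'   the direction step).
#' @return The aligned `sc_matrix` (`aligned = TRUE`; row/column names
#'   become relative directions).
#' @export
align_matrix <- function(matrix, preferred_direction) {
  dirs <- matrix$directions
  nd <- length(dirs)
  step <- 360 / nd
  if (is.na(preferred_direction) ||
      preferred_direction %% step != 0) {
    stop("preferred_direction must be a multiple of ", step, " degrees",
         call. = FALSE)
  }
  k <- (preferred_direction %% 360) / step
  perm <- ((seq_len(nd) - 1 + k) %% nd) + 1
  v <- matrix$values
  out <- v
  out[seq_len(nd), seq_len(nd)] <- v[perm, perm]
  out[seq_len(nd), nd + 1] <- v[perm, nd + 1]
  out[nd + 1, seq_len(nd)] <- v[nd + 1, perm]
  dimnames(out) <- list(center = c(dirs, "blank"),
                        surround = c(dirs, "blank"))
  matrix$values <- out
  matrix$aligned <- TRUE
  matrix$alignment_shift <- as.integer(k)
  matrix
}

# Extract a cell's 8-point curve for one center-surround relationship from
# an aligned matrix. `relationship` is "center_alone" or a folded
# delta-theta in {0, 45, 90, 135, 180}; intermediate delta-thetas average
# the clockwise and counterclockwise off-diagonals.
relationship_curve <- function(matrix, relationship) {
  v <- matrix$values
  nd <- nrow(v) - 1
  if (identical(relationship, "center_alone")) {
    return(v[seq_len(nd), nd + 1])
  }
  k <- relationship / (360 / nd)
  i <- seq_len(nd)
  j1 <- ((i - 1 + k) %% nd) + 1
  j2 <- ((i - 1 - k) %% nd) + 1
  (v[cbind(i, j1)] + v[cbind(i, j2)]) / 2
}

#' Population tuning curves per center-surround relationship
#'
#' Averages aligned response matrices across cells to give mean +/- s.e.m.
#' tuning curves for the center-alone condition and for each folded
#' center-surround direction difference (0 = same-direction surround,
#' 180 = opposite surround).
#'
#' @param matrices List of aligned `sc_matrix` objects.
#' @param relationships Which curves to extract.
#' @return Data frame of class `sc_popcurves`: `relationship`, `rel_dir`
#'   (center direction relative to preferred), `mean`, `sem`, `n`.
#' @export
population_curves <- function(matrices,
                              relationships = c("center_alone",
                                                0, 45, 90, 135, 180)) {
  if (length(matrices) < 2) {
    stop("need at least 2 cells for population curves", call. = FALSE)
  }
  if (!all(vapply(matrices, function(m) isTRUE(m$aligned), logical(1)))) {
    stop("matrices must be aligned first", call. = FALSE)
  }
  nd <- length(matrices[[1]]$directions)
  rel_dir <- sc_directions(nd)
  out <- lapply(relationships, function(rel) {
    rel_num <- suppressWarnings(as.numeric(rel))
    rel_key <- if (is.na(rel_num)) "center_alone" else rel_num
    curves <- vapply(matrices, relationship_curve, numeric(nd),
                     relationship = rel_key)
    data.frame(relationship = as.character(rel), rel_dir = rel_dir,
               mean = rowMeans(curves),
               sem = apply(curves, 1, sem),
               n = length(matrices), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("sc_popcurves", "data.frame"))
}

#' Linear modulation fit of a center-with-surround curve
#'
#' Ordinary least squares of the center-with-surround tuning curve on the
#' center-alone curve (8 paired points, one per direction), with intercept.
#' A slope below 1 with near-zero intercept diagnoses divisive suppression;
#' a slope above 1, multiplicative potentiation. The slope's 95% confidence
#' interval uses the regression's t-based standard error.
#'
#' @param center_alone_curve,cs_curve Paired responses per direction.
#' @param conf_level Confidence level for the slope interval.
#' @return An `sc_modfit`: list with `slope`, `intercept`, `r_squared`,
#'   `slope_ci`, `slope_se`, `n_points` and the input curves.
#' @export
#' @examples
#' f <- fit_modulation(1:8, 0.5 * (1:8) + 1)
#' c(f$slope, f$intercept, f$r_squared)  # 0.5 1 1
fit_modulation <- function(center_alone_curve, cs_curve,
                           conf_level = 0.95) {
  x <- as.numeric(center_alone_curve)
  y <- as.numeric(cs_curve)
  if (length(x) != length(y) || length(x) < 3) {
    stop("curves must be paired with at least 3 points", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("degenerate fit: center-alone curve has zero variance",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  se <- sm$coefficients["x", "Std. Error"]
  slope <- unname(stats::coef(fit)["x"])
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = length(x) - 2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared,
                 slope_se = se,
                 slope_ci = c(slope - tcrit * se, slope + tcrit * se),
                 n_points = length(x),
                 center = x, cs = y),
            class = "sc_modfit")
}

#' @export
print.sc_modfit <- function(x, digits = 3, ...) {
  cat("<sc_modfit> slope =", signif(x$slope, digits),
      "[", signif(x$slope_ci[1], digits), ",",
      signif(x$slope_ci[2], digits), "], intercept =",
      signif(x$intercept, digits), ", R^2 =", signif(x$r_squared, digits),
      "(", x$n_points, "points )\n")
  invisible(x)
}

#' Modulation slope as a function of direction difference
#'
#' Fits the population center-with-surround curve on the population
#' center-alone curve at each folded delta-theta. With monotone surround
#' tuning the slope grades from below 1 (divisive suppression by the same
#' surround) to above 1 (multiplicative potentiation by the opposite
#' surround); monotonicity is reported, not enforced.
#'
#' @param matrices List of aligned `sc_matrix` objects.
#' @return Data frame: `delta_theta`, `slope`, `intercept`, `r_squared`,
#'   `slope_ci_lo`, `slope_ci_hi`, `n_points`.
#' @export
slopes_vs_delta_theta <- function(matrices) {
  pc <- population_curves(matrices)
  center <- pc$mean[pc$relationship == "center_alone"]
  out <- lapply(DTHETA_LEVELS, function(dt) {
    cs <- pc$mean[pc$relationship == as.character(dt)]
    f <- fit_modulation(center, cs)
    data.frame(delta_theta = dt, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, slope_ci_lo = f$slope_ci[1],
               slope_ci_hi = f$slope_ci[2], n_points = f$n_points)
  })
  do.call(rbind, out)
}

#' Per-cell modulation fits with a goodness-of-fit filter
#'
#' Fits each cell's own center-with-surround curve on its center-alone
#' curve at every folded delta-theta, and summarizes the mean slope per
#' delta-theta over cells passing the `r_squared >= r2_min` filter. Cells
#' whose center-alone curve has zero variance are flagged (`ok = FALSE`),
#' not dropped silently.
#'
#' @param matrices List of aligned `sc_matrix` objects.
#' @param r2_min Quality filter on the per-cell fit (default 0.5).
#' @return List with `fits` (one row per cell x delta-theta: `cell_id`,
#'   `delta_theta`, `slope`, `intercept`, `r_squared`, `ok`, `pass`) and
#'   `summary` (mean filtered slope per delta-theta with `n_pass`).
#' @export
per_cell_fits <- function(matrices, r2_min = 0.5) {
  rows <- lapply(matrices, function(m) {
    center <- relationship_curve(m, "center_alone")
    lapply(DTHETA_LEVELS, function(dt) {
      cs <- relationship_curve(m, dt)
      if (stats::var(center) == 0) {
        return(data.frame(cell_id = m$cell_id, delta_theta = dt,
                          slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, ok = FALSE, pass = FALSE))
      }
      f <- fit_modulation(center, cs)
      data.frame(cell_id = m$cell_id, delta_theta = dt, slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 ok = TRUE, pass = f$r_squared >= r2_min)
    })
  })
  fits <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(fits) <- NULL
  summ <- do.call(rbind, lapply(DTHETA_LEVELS, function(dt) {
    sel <- fits$delta_theta == dt & fits$pass
    data.frame(delta_theta = dt,
               mean_slope = mean(fits$slope[sel]),
               sem_slope = sem(fits$slope[sel]),
               n_pass = sum(sel))
  }))
  list(fits = fits, summary = summ)
}

#' Emergent response curve of center-silent cells
#'
#' Mean dF/F0 of center-silent cells' center-surround responses as a
#' function of the folded direction difference, with the (near-zero)
#' center-alone response as reference. Matrices need not be aligned: the
#' folded delta-theta of each matrix cell is alignment-invariant.
#'
#' @param matrices List of `sc_matrix` objects of center-silent cells.
#' @return Data frame: `delta_theta` (degrees, or `NA` for the center-alone
#'   reference), `mean`, `sem`, `n`.
#' @export
center_silent_curve <- function(matrices) {
  if (length(matrices) < 1) {
    stop("need at least one center-silent cell", call. = FALSE)
  }
  per_cell <- vapply(matrices, function(m) {
    v <- m$values
    nd <- nrow(v) - 1
    dirs <- m$directions
    dt <- outer(dirs, dirs, fold_dtheta)
    vals <- vapply(DTHETA_LEVELS, function(d) {
      mean(v[seq_len(nd), seq_len(nd)][dt == d])
    }, numeric(1))
    c(vals, mean(v[seq_len(nd), nd + 1]))
  }, numeric(length(DTHETA_LEVELS) + 1))
  data.frame(delta_theta = c(DTHETA_LEVELS, NA),
             mean = rowMeans(per_cell),
             sem = apply(per_cell, 1, sem),
             n = length(matrices))
}

#' Linearity-of-summation comparison
#'
#' Compares each center-surround response with the sum of the cell's
#' center-alone and surround-alone responses:
#' `R_CS - (R_C + R_S)` per condition. Negative differences indicate
#' sub-linear summation (suppression below the additive prediction).
#'
#' @param matrices List of `sc_matrix` objects (aligned or not).
#' @return List with `per_cell` (one row per cell x center x surround
#'   direction: `difference`, `delta_theta`) and `by_dtheta` (population
#'   mean +/- s.e.m. difference per folded delta-theta).
#' @export
summation_comparison <- function(matrices) {
  rows <- lapply(matrices, function(m) {
    v <- m$values
    nd <- nrow(v) - 1
    dirs <- m$directions
    g <- expand.grid(ci = seq_len(nd), si = seq_len(nd))
    data.frame(cell_id = m$cell_id,
               center = dirs[g$ci], surround = dirs[g$si],
               delta_theta = fold_dtheta(dirs[g$ci], dirs[g$si]),
               r_cs = v[cbind(g$ci, g$si)],
               r_c = v[g$ci, nd + 1],
               r_s = v[nd + 1, g$si],
               difference = v[cbind(g$ci, g$si)] -
                 (v[g$ci, nd + 1] + v[nd + 1, g$si]))
  })
  per_cell <- do.call(rbind, rows)
  rownames(per_cell) <- NULL
  by_dtheta <- do.call(rbind, lapply(DTHETA_LEVELS, function(dt) {
    d <- per_cell$difference[per_cell$delta_theta == dt]
    data.frame(delta_theta = dt, mean = mean(d), sem = sem(d),
               n = length(d))
  }))
  list(per_cell = per_cell, by_dtheta = by_dtheta)
}

#' Modulation indices under feature-contrast surrounds
#'
#' Computes per-cell modulation indices for the anti-phase, temporal-
#' frequency and static-orientation condition sets. The drifting feature
#' protocols (anti-phase, temporal frequency) have no center-alone
#' conditions, so the reference `R_pref_C` and preferred direction must be
#' supplied from the direction-contrast session of the same cells; the
#' static-orientation set is self-contained (its center-alone conditions
#' define a preferred orientation).
#'
#' @param trials An `sc_trials` table from a feature-contrast recording.
#' @param reference Data frame with `cell_id`, `preferred_direction`,
#'   `r_pref_c` (required for `anti_phase` and `temporal_freq`).
#' @return Data frame: `cell_id`, `tag` (one of `anti_phase`, `tf_1Hz`,
#'   `tf_4Hz`, `static_iso`, `static_cross`), `r_cs`, `r_c`, `mi`.
#' @export
feature_contrast_mi <- function(trials, reference = NULL) {
  protocol <- attr(trials, "protocol")
  if (is.null(protocol)) stop("`trials` lacks a protocol", call. = FALSE)
  cond <- protocol$conditions
  means <- with(trials, tapply(dff, list(cell_id, condition_id), mean))
  means <- means[, as.character(cond$condition_id), drop = FALSE]
  ids <- rownames(means)

  if (protocol$kind %in% c("anti_phase", "temporal_freq")) {
    if (is.null(reference)) {
      stop("`reference` (preferred direction and R_pref_C per cell) is ",
           "required for drifting feature-contrast protocols",
           call. = FALSE)
    }
    ref <- reference[match(ids, reference$cell_id), ]
    rows <- lapply(seq_along(ids), function(i) {
      pref <- ref$preferred_direction[i]
      r_c <- ref$r_pref_c[i]
      if (is.na(pref) || is.na(r_c)) return(NULL)
      sel <- which(cond$center == pref)
      tag <- if (protocol$kind == "anti_phase") rep("anti_phase",
                                                    length(sel)) else
        ifelse(cond$surround_param[sel] <= 2, "tf_1Hz", "tf_4Hz")
      data.frame(cell_id = ids[i], tag = tag,
                 r_cs = means[i, sel], r_c = r_c,
                 mi = modulation_index(means[i, sel], r_c))
    })
  } else if (protocol$kind == "static_orientation") {
    center_alone <- which(!is.na(cond$center) & is.na(cond$surround))
    rows <- lapply(seq_along(ids), function(i) {
      ca <- means[i, center_alone]
      if (all(ca <= 0)) return(NULL)
      pref_o <- cond$center[center_alone][which.max(ca)]
      r_c <- max(ca)
      iso <- which(cond$center == pref_o & !is.na(cond$surround) &
                     cond$surround == pref_o)
      cross <- which(cond$center == pref_o & !is.na(cond$surround) &
                       abs(cond$surround - pref_o) == 90)
      sel <- c(iso, cross)
      data.frame(cell_id = ids[i],
                 tag = c(rep("static_iso", length(iso)),
                         rep("static_cross", length(cross))),
                 r_cs = means[i, sel], r_c = r_c,
                 mi = modulation_index(means[i, sel], r_c))
    })
  } else {
    stop("`trials` must come from a feature-contrast protocol",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sc_matrix <- function(x, digits = 3, ...) {
  cat("<sc_matrix>", x$cell_id,
      if (x$aligned) "(aligned)" else "(unaligned)", "\n")
  print(round(x$values, digits))
  invisible(x)
}
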