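# End-to-end per-cell analysis of a direction-contrast recording: trial
# table -> responsiveness -> response matrix -> preferred direction, gDSI,
# modulation indices, bootstrap classes and the four-way category.

#' Per-cell tuning and modulation summary
#'
#' Runs the full single-cell pipeline on a direction-contrast recording:
#' per-trial dF/F0 extraction, the 2-SD responsiveness criterion, response
#' matrix assembly, preferred direction (center-alone rule, or the
#' center-silent rule for cells unresponsive to center alone), gDSI from
#' the rectified center-alone tuning curve, modulation indices for the
#' same-direction and opposite surrounds, the pooled-resampling bootstrap
#' classification of both, and the four-way response category.
#'
#' @param recording An `sc_recording` from a direction-contrast protocol.
#' @param window Optional `sc_window` override.
#' @param n_boot Bootstrap resamples per cell and surround (default 10000).
#' @param alpha Bootstrap significance level.
#' @param seed Integer seed for the bootstrap resampling (one derived seed
#'   per cell).
#' @return Data frame of class `sc_cell_summary`, one row per cell:
#'   responsiveness flags, `preferred_direction`, `preferred_source`,
#'   `gdsi`, `r_pref_c`, `r_same`, `r_opp`, `mi_same`, `mi_opp`,
#'   `boot_same`, `boot_opp`, `category`, plus the recording's cell
#'   metadata columns (`cell_class`, `depth_um`, `fov`, ground truth where
#'   present).
#' @export
#' @examples
#' \donttest{
#' p <- direction_contrast_protocol(n_repeats = 4, seed = 1)
#' cells <- sample_population(12, seed = 2)
#' rec <- simulate_recording(p, cells, seed = 3)
#' head(cell_summary(rec, n_boot = 1000, seed = 4))
#' }
cell_summary <- function(recording, window = NULL, n_boot = 10000,
                         alpha = 0.05, seed = 1L) {
  if (recording$protocol$kind != "direction_contrast") {
    stop("`recording` must use a direction_contrast protocol",
         call. = FALSE)
  }
  trials <- build_response_table(recording, window)
  resp <- assess_responsiveness(trials)
  mats <- response_matrices(trials)
  cond <- recording$protocol$conditions
  center_ids <- cond$condition_id[!is.na(cond$center) & is.na(cond$surround)]
  cs_ids <- cond$condition_id[!is.na(cond$center) & !is.na(cond$surround)]
  sur_ids <- cond$condition_id[is.na(cond$center) & !is.na(cond$surround)]

  ids <- resp$cells$cell_id
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    m <- mats[[id]]
    flags <- resp$conditions[resp$conditions$cell_id == id, ]
    flag_of <- function(cid) flags$responsive[match(cid, flags$condition_id)]
    responsive_center <- any(flag_of(center_ids), na.rm = TRUE)
    responsive_cs <- any(flag_of(cs_ids), na.rm = TRUE)
    responsive_sur <- any(flag_of(sur_ids), na.rm = TRUE)
    responsive_any <- responsive_center || responsive_cs
    surround_alone_only <- responsive_sur && !responsive_any
    center_silent_obs <- !responsive_center && responsive_cs

    pref <- preferred_direction(m, responsive_center = responsive_center ||
                                  !responsive_cs)
    dirs <- m$directions
    nd <- length(dirs)
    tuning <- m$values[seq_len(nd), nd + 1]
    gdsi <- compute_gdsi(tuning, dirs)

    if (is.na(pref$direction)) {
      rows[[i]] <- data.frame(
        cell_id = id, responsive = responsive_any,
        responsive_center = responsive_center,
        responsive_surround_alone = responsive_sur,
        center_silent_observed = center_silent_obs,
        preferred_direction = NA_real_, preferred_source = pref$source,
        gdsi = gdsi, r_pref_c = NA_real_, r_same = NA_real_,
        r_opp = NA_real_, mi_same = NA_real_, mi_opp = NA_real_,
        boot_same = NA_character_, boot_opp = NA_character_,
        category = "non_responsive", stringsAsFactors = FALSE)
      next
    }
    pi <- match(pref$direction, dirs)
    oi <- match((pref$direction + 180) %% 360, dirs)
    r_pref_c <- m$values[pi, nd + 1]
    r_same <- m$values[pi, pi]
    r_opp <- m$values[pi, oi]

    cid_at <- function(ci, si) cond$condition_id[
      (if (is.na(ci)) is.na(cond$center) else !is.na(cond$center) &
         cond$center == ci) &
      (if (is.na(si)) is.na(cond$surround) else !is.na(cond$surround) &
         cond$surround == si)]
    tr_of <- function(cid) m$trials$dff[m$trials$condition_id == cid]
    a_tr <- tr_of(cid_at(pref$direction, NA))
    boot <- function(b_tr, k) {
      if (length(b_tr) != length(a_tr) || length(a_tr) < 2)
        return(NA_character_)
      bootstrap_classify(a_tr, b_tr, n_boot = n_boot, alpha = alpha,
                         seed = seed + 13L * i + k)$class
    }
    boot_same <- boot(tr_of(cid_at(pref$direction, pref$direction)), 1L)
    boot_opp <- boot(tr_of(cid_at(pref$direction,
                                  (pref$direction + 180) %% 360)), 2L)
    rows[[i]] <- data.frame(
      cell_id = id, responsive = responsive_any,
      responsive_center = responsive_center,
      responsive_surround_alone = responsive_sur,
      center_silent_observed = center_silent_obs,
      preferred_direction = pref$direction,
      preferred_source = pref$source,
      gdsi = gdsi, r_pref_c = r_pref_c, r_same = r_same, r_opp = r_opp,
      mi_same = modulation_index(r_same, r_pref_c),
      mi_opp = modulation_index(r_opp, r_pref_c),
      boot_same = boot_same, boot_opp = boot_opp,
      category = categorize_cell(boot_opp, responsive_any,
                                 surround_alone_only),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  meta_cols <- intersect(c("cell_id", "cell_class", "depth_um", "fov",
                           "center_silent", "kappa", "peak_response"),
                         names(recording$cells))
  out <- merge(out, recording$cells[meta_cols], by = "cell_id",
               sort = FALSE)
  structure(out, class = c("sc_cell_summary", "data.frame"))
}
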