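# Trace processing: raw fluorescence -> per-trial dF/F0. F0 is the mean
# fluorescence over a fixed pre-onset baseline; F is the mean over an
# indicator- and stimulus-specific response window. A frame belongs to a
# window if its acquisition midpoint falls in the half-open interval
# [start, end), which is unambiguous when windows are not frame-aligned.

#' Construct an analysis window specification
#'
#' @param baseline_pre_s Baseline duration before stimulus onset (s).
#' @param response_start_offset_s Response-window start, seconds after onset.
#' @param response_end_offset_s Response-window end, seconds after offset.
#' @param stimulus_kind,indicator Optional labels carried for bookkeeping.
#' @return A list of class `sc_window`.
#' @export
window_spec <- function(baseline_pre_s, response_start_offset_s,
                        response_end_offset_s, stimulus_kind = NA_character_,
                        indicator = NA_character_) {
  if (baseline_pre_s <= 0) {
    stop("invalid parameter: baseline_pre_s must be > 0", call. = FALSE)
  }
  structure(list(baseline_pre_s = baseline_pre_s,
                 response_start_offset_s = response_start_offset_s,
                 response_end_offset_s = response_end_offset_s,
                 stimulus_kind = stimulus_kind,
                 indicator = indicator),
            class = "sc_window")
}

#' Default analysis windows per stimulus kind and indicator
#'
#' For drifting/static gratings with a fast indicator: 1.25 s baseline and a
#' response window from 250 ms after onset to 750 ms after offset (2.5 s for
#' a 2 s stimulus). The slow nuclear indicator uses the same window shifted
#' forward by 375 ms (625 ms after onset to 1125 ms after offset) to account
#' for its slower dynamics. Flashing squares: 0.75 s baseline, response from
#' 250 ms after onset to 350 ms after offset (1.1 s for a 1 s flash), again
#' shifted by 375 ms for the slow indicator.
#'
#' @param stimulus_kind `"grating"` or `"flash_square"`.
#' @param indicator `"fast"` or `"slow_nuclear"`.
#' @return An `sc_window`.
#' @export
#' @examples
#' default_windows("grating", "fast")
default_windows <- function(stimulus_kind = c("grating", "flash_square"),
                            indicator = c("fast", "slow_nuclear")) {
  if (!(stimulus_kind[1] %in% c("grating", "flash_square")) ||
      !(indicator[1] %in% c("fast", "slow_nuclear"))) {
    stop("invalid parameter: unknown stimulus_kind/indicator combination",
         call. = FALSE)
  }
  stimulus_kind <- stimulus_kind[1]
  indicator <- indicator[1]
  shift <- if (indicator == "slow_nuclear") 0.375 else 0
  if (stimulus_kind == "grating") {
    window_spec(1.25, 0.25 + shift, 0.75 + shift, stimulus_kind, indicator)
  } else {
    window_spec(0.75, 0.25 + shift, 0.35 + shift, stimulus_kind, indicator)
  }
}

window_frames <- function(tf, onset, offset, window) {
  list(baseline = which(tf >= onset - window$baseline_pre_s & tf < onset),
       response = which(tf >= onset + window$response_start_offset_s &
                          tf < offset + window$response_end_offset_s))
}

#' Per-trial dF/F0 from a raw trace
#'
#' Computes `dF/F0 = (F - F0) / F0` for one stimulus presentation, where
#' `F0` is the mean fluorescence over the pre-onset baseline window and `F`
#' the mean over the response window. Negative values are retained (they
#' arise with slow indicators whose decay outlasts the inter-trial
#' interval); clipping happens only in the modulation index.
#'
#' @param trace Numeric vector of raw fluorescence, one value per frame.
#' @param onset_time_s,offset_time_s Stimulus onset/offset in seconds from
#'   the start of the trace.
#' @param window An `sc_window`.
#' @param frame_rate_hz Acquisition rate; frame `f` is timestamped at its
#'   midpoint `(f - 0.5) / frame_rate_hz`.
#' @return List with `dff`, `f0`, `baseline_sd` (SD of the baseline frames,
#'   raw fluorescence units), `n_baseline`, `n_response`.
#' @export
#' @examples
#' tr <- c(10, 10, 12, 13)
#' compute_dff(tr, onset_time_s = 2, offset_time_s = 4,
#'             window = window_spec(2, 0, 0), frame_rate_hz = 1)$dff  # 0.25
compute_dff <- function(trace, onset_time_s, offset_time_s, window,
                        frame_rate_hz) {
  tf <- (seq_along(trace) - 0.5) / frame_rate_hz
  if (onset_time_s - window$baseline_pre_s < 0 ||
      offset_time_s + window$response_end_offset_s >
        length(trace) / frame_rate_hz) {
    stop("analysis window exceeds trace bounds", call. = FALSE)
  }
  idx <- window_frames(tf, onset_time_s, offset_time_s, window)
  if (length(idx$baseline) < 2) {
    stop("baseline window contains fewer than 2 frames", call. = FALSE)
  }
  if (length(idx$response) < 1) {
    stop("response window contains no frames", call. = FALSE)
  }
  f0 <- mean(trace[idx$baseline])
  if (f0 <= 0) {
    stop("degenerate baseline: F0 <= 0", call. = FALSE)
  }
  f <- mean(trace[idx$response])
  list(dff = (f - f0) / f0,
       f0 = f0,
       baseline_sd = stats::sd(trace[idx$baseline]),
       n_baseline = length(idx$baseline),
       n_response = length(idx$response))
}

#' Build the per-trial response table of a recording
#'
#' Applies [compute_dff()] to every (cell, trial) pair of a recording, using
#' each cell's indicator-specific default window (or a user-supplied one).
#' The result has one row per (cell, condition, repeat) and is the input to
#' all downstream analyses.
#'
#' @param recording An `sc_recording`.
#' @param window Optional `sc_window` overriding the defaults for all cells.
#' @return Data frame of class `sc_trials` with columns `cell_id`, `trial`,
#'   `condition_id`, `rep`, `dff`, `f0`, `baseline_sd`; the protocol and the
#'   recording's cell metadata are attached as attributes `"protocol"` and
#'   `"cells"`.
#' @export
build_response_table <- function(recording, window = NULL) {
  ev <- recording$events
  cond <- recording$protocol$conditions
  if (any(!(ev$condition_id %in% cond$condition_id))) {
    stop("event/protocol mismatch: unknown condition index", call. = FALSE)
  }
  n_frames <- ncol(recording$traces)
  tf <- (seq_len(n_frames) - 0.5) / recording$frame_rate_hz
  stim_kind <- if (recording$protocol$kind == "rf_mapping")
    "flash_square" else "grating"
  cells <- recording$cells
  indicators <- if (!is.null(cells$indicator)) cells$indicator else
    rep("fast", nrow(recording$traces))

  out <- vector("list", length(unique(indicators)))
  gi <- 0
  for (ind in unique(indicators)) {
    gi <- gi + 1
    rows <- which(indicators == ind)
    w <- window %||% default_windows(stim_kind, ind)
    tr <- recording$traces[rows, , drop = FALSE]
    blocks <- vector("list", nrow(ev))
    for (i in seq_len(nrow(ev))) {
      idx <- window_frames(tf, ev$onset_time_s[i], ev$offset_time_s[i], w)
      if (length(idx$baseline) < 2 || length(idx$response) < 1) {
        stop("analysis window exceeds trace bounds at trial ", ev$trial[i],
             call. = FALSE)
      }
      bl <- tr[, idx$baseline, drop = FALSE]
      f0 <- rowMeans(bl)
      if (any(f0 <= 0)) stop("degenerate baseline: F0 <= 0", call. = FALSE)
      f <- rowMeans(tr[, idx$response, drop = FALSE])
      blocks[[i]] <- data.frame(cell_id = rownames(tr) %||%
                                  as.character(rows),
                                trial = ev$trial[i],
                                condition_id = ev$condition_id[i],
                                rep = ev$rep[i],
                                dff = (f - f0) / f0,
                                f0 = f0,
                                baseline_sd = row_sds(bl),
                                stringsAsFactors = FALSE)
    }
    out[[gi]] <- do.call(rbind, blocks)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, protocol = recording$protocol, cells = cells,
            class = c("sc_trials", "data.frame"))
}

#' Responsiveness criterion
#'
#' A cell is responsive if, for at least one stimulus condition, its mean
#' dF/F0 across repeats exceeds `n_sd` times its baseline noise, where the
#' baseline noise is the cell's pooled baseline SD expressed in dF/F0 units
#' (root mean square of the per-trial `baseline_sd / f0`, pooled over all of
#' the cell's trials).
#'
#' @param trials An `sc_trials` table (or any data frame with `cell_id`,
#'   `condition_id`, `dff`, `f0`, `baseline_sd`).
#' @param n_sd Threshold in baseline-SD units (default 2).
#' @return List with `cells` (data frame: `cell_id`, `responsive`,
#'   `pooled_sd_dff`) and `conditions` (data frame: `cell_id`,
#'   `condition_id`, `mean_dff`, `responsive` flag per condition).
#' @export
assess_responsiveness <- function(trials, n_sd = 2) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("empty trial table", call. = FALSE)
  }
  cell <- factor(trials$cell_id, levels = unique(trials$cell_id))
  cond <- factor(trials$condition_id)
  mean_dff <- tapply(trials$dff, list(cell, cond), mean)
  pooled <- sqrt(tapply((trials$baseline_sd / trials$f0)^2, cell, mean))
  pooled <- stats::setNames(as.numeric(pooled), names(pooled))
  flags <- mean_dff > n_sd * as.numeric(pooled[rownames(mean_dff)])
  conditions <- data.frame(
    cell_id = rep(rownames(mean_dff), ncol(mean_dff)),
    condition_id = rep(as.integer(colnames(mean_dff)),
                       each = nrow(mean_dff)),
    mean_dff = as.vector(mean_dff),
    responsive = as.vector(flags),
    stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = rownames(mean_dff),
                      responsive = apply(flags, 1, any, na.rm = TRUE),
                      pooled_sd_dff = as.vector(pooled[rownames(mean_dff)]),
                      stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  list(cells = cells, conditions = conditions)
}
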