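# Fluorescence trace synthesis. Each trial's noiseless dF/F0 time course is
# the generative expected response scaled by an indicator response template:
# a boxcar of the stimulus duration convolved with a difference-of-
# exponentials calcium kernel (fast: 50 ms rise / 600 ms decay; slow nuclear:
# 400 ms / 3 s). The template is normalized so that its average over the
# indicator's default analysis window is 1, making the window-averaged dF/F0
# of a noiseless trial equal the generative expected response (up to window
# quadrature).

indicator_kinetics <- function(indicator) {
  switch(indicator,
         fast = c(rise = 0.05, decay = 0.6),
         slow_nuclear = c(rise = 0.4, decay = 3),
         stop("invalid parameter: unknown indicator `", indicator, "`",
              call. = FALSE))
}

# Boxcar (duration D) convolved with exp(-t/tau), closed form.
boxcar_exp <- function(t, tau, D) {
  out <- numeric(length(t))
  rising <- t > 0 & t < D
  after <- t >= D
  out[rising] <- tau * (1 - exp(-t[rising] / tau))
  out[after] <- tau * (exp(-(t[after] - D) / tau) - exp(-t[after] / tau))
  out
}

# Unnormalized response template: difference of the decay and rise terms.
response_template <- function(t, kin, D) {
  boxcar_exp(t, kin["decay"], D) - boxcar_exp(t, kin["rise"], D)
}

# Normalization constant: mean template value over the analysis window.
template_norm <- function(kin, D, window) {
  tt <- seq(window$response_start_offset_s,
            D + window$response_end_offset_s, by = 0.001)
  1 / mean(response_template(tt, kin, D))
}

#' Simulate a two-photon recording
#'
#' Synthesizes per-ROI fluorescence traces for a cell population presented
#' with a stimulus protocol. For each trial the noiseless dF/F0 equals the
#' generative law of [generative_response()] shaped in time by the
#' indicator's calcium kernel; the raw trace is
#' `baseline_f * (1 + dF/F0(t))` plus i.i.d. Gaussian noise of SD
#' `noise_sd * baseline_f` per frame. Trials follow each other at
#' `duration + iti` second intervals (stimulus onsets are not frame-aligned,
#' as in real acquisition).
#'
#' @param protocol An `sc_protocol`.
#' @param cells An `sc_population` (all cells imaged simultaneously, i.e.
#'   one field of view per call is the typical use).
#' @param frame_rate_hz Acquisition frame rate (default 8.079 Hz).
#' @param seed Integer seed for the trace noise.
#' @param noise If `FALSE`, traces are noiseless regardless of the cells'
#'   `noise_sd` (used by round-trip tests).
#' @return An object of class `sc_recording`: list with `traces` (matrix,
#'   cells x frames), `frame_rate_hz`, `events` (data frame: `trial`,
#'   `condition_id`, `rep`, `onset_frame`, `onset_time_s`,
#'   `offset_time_s`), `protocol`, `cells` and `seed`.
#' @export
#' @examples
#' p <- direction_contrast_protocol(n_repeats = 4, seed = 1)
#' cells <- sample_population(5, seed = 2)
#' rec <- simulate_recording(p, cells, seed = 3)
simulate_recording <- function(protocol, cells, frame_rate_hz = 8.079,
                               seed = 1L, noise = TRUE) {
  if (!inherits(protocol, "sc_protocol")) {
    stop("`protocol` must be an sc_protocol", call. = FALSE)
  }
  if (!is.data.frame(cells) || nrow(cells) == 0) {
    stop("`cells` must be a non-empty sc_population", call. = FALSE)
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    stop("invalid parameter: frame_rate_hz", call. = FALSE)
  }
  cond <- protocol$conditions
  dur <- cond$duration_s[1]
  iti <- cond$iti_s[1]
  stim_kind <- if (protocol$kind == "rf_mapping") "flash_square" else "grating"

  # frame rate must resolve the analysis windows of every indicator present
  for (ind in unique(cells$indicator)) {
    w <- default_windows(stim_kind, ind)
    if (floor(w$baseline_pre_s * frame_rate_hz) < 2 ||
        floor((dur + w$response_end_offset_s - w$response_start_offset_s) *
                frame_rate_hz) < 1) {
      stop("invalid parameter: frame rate too low to resolve the analysis ",
           "windows", call. = FALSE)
    }
  }

  ord <- protocol$order
  n_trials <- nrow(ord)
  period <- dur + iti
  onset <- iti + (seq_len(n_trials) - 1) * period
  offset <- onset + dur
  total <- iti + n_trials * period + 5
  n_frames <- ceiling(total * frame_rate_hz)
  tf <- (seq_len(n_frames) - 0.5) / frame_rate_hz

  E <- generative_response(cells, protocol)
  n_cells <- nrow(cells)
  resp <- matrix(0, n_cells, n_frames)

  for (ind in unique(cells$indicator)) {
    rows <- which(cells$indicator == ind)
    kin <- indicator_kinetics(ind)
    w <- default_windows(stim_kind, ind)
    K <- template_norm(kin, dur, w)
    horizon <- dur + 5 * kin["decay"]
    for (i in seq_len(n_trials)) {
      idx <- which(tf >= onset[i] & tf < onset[i] + horizon)
      if (length(idx) == 0) next
      gv <- K * response_template(tf[idx] - onset[i], kin, dur)
      amp <- E[rows, ord$condition_id[i]]
      resp[rows, idx] <- resp[rows, idx] + amp %o% gv
    }
  }

  traces <- cells$baseline_f * (1 + resp)
  if (noise) {
    traces <- traces + with_seed(seed,
      cells$noise_sd * cells$baseline_f *
        matrix(stats::rnorm(n_cells * n_frames), n_cells))
  }
  rownames(traces) <- cells$cell_id

  events <- data.frame(trial = ord$trial,
                       condition_id = ord$condition_id,
                       rep = ord$rep,
                       onset_frame = ceiling(onset * frame_rate_hz + 0.5),
                       onset_time_s = onset,
                       offset_time_s = offset)
  structure(list(traces = traces,
                 frame_rate_hz = frame_rate_hz,
                 events = events,
                 protocol = protocol,
                 cells = cells,
                 seed = as.integer(seed)),
            class = "sc_recording")
}

#' @export
print.sc_recording <- function(x, ...) {
  cat("<sc_recording>", nrow(x$traces), "ROIs x", ncol(x$traces),
      "frames @", x$frame_rate_hz, "Hz\n")
  cat("  protocol:", x$protocol$kind, "-", nrow(x$events), "trials\n")
  invisible(x)
}
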