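# Synthetic cell population generator. Each simulated neuron carries the
# generative parameters the analysis is meant to recover: a von Mises
# direction tuning curve, an affine surround-modulation law per folded
# center-surround direction difference (R_CS = a * R_C + b), feature-contrast
# gain factors, a 2D Gaussian receptive field, indicator kinetics and noise.

DTHETA_LEVELS <- c(0, 45, 90, 135, 180)

#' Default generator configuration
#'
#' Returns the configuration list used by [sample_population()]. The defaults
#' encode the study conditions the analysis assumes:
#' \itemize{
#'   \item Excitatory surround-modulation law at the superficial depth level:
#'     slope/intercept pairs (0.50, 0.0048) at delta-theta 0, (1.17, 0.0254)
#'     at 90 and (1.63, 0.0155) at 180 degrees (intercepts in fractional
#'     dF/F0, i.e. 0.48/2.54/1.55 in % units), with both slope and intercept
#'     linearly interpolated at 45 and 135 degrees. The slope profile is
#'     monotone in delta-theta: divisive suppression by an iso-directional
#'     surround grading into multiplicative potentiation by an
#'     opposite-direction surround.
#'   \item Inhibitory law: slopes below 1 at every delta-theta and smallest
#'     at 180 degrees (any surround suppresses; the opposite surround most),
#'     zero intercepts.
#'   \item Class mix 45% inhibitory; 23.6% of excitatory cells center-silent;
#'     surround-alone responsiveness 53.8% (inhibitory) vs 10% (excitatory).
#'   \item Four imaging depth levels (25, 60, 120, 180 um). Tuning
#'     concentration declines with depth, and the potentiating part of the
#'     excitatory law (slope - 1 where positive) declines from full strength
#'     superficially to net suppression at depth.
#'   \item Per-cell coupling between tuning strength and the modulation law
#'     (positive for excitatory potentiation, negative for the inhibitory
#'     opposite-surround slope) so that modulation-index vs gDSI correlations
#'     have class-specific signs.
#'   \item Indicator kinetics `"fast"` (rise 50 ms, decay 600 ms) or
#'     `"slow_nuclear"` (rise 400 ms, decay 3 s); additive Gaussian trace
#'     noise with SD 0.04 dF/F0 per frame.
#' }
#' Any element can be overridden by passing a modified copy to
#' [sample_population()].
#'
#' @return Named list of generator parameters.
#' @export
default_population_config <- function() {
  list(
    p_inhibitory = 0.45,
    p_center_silent_exc = 0.236,
    p_center_silent_inh = 0,
    p_surround_alone_exc = 0.10,
    p_surround_alone_inh = 0.538,
    surround_alone_gain = 0.4,
    depth_levels = c(25, 60, 120, 180),
    depth_probs = c(0.25, 0.25, 0.25, 0.25),
    # multiplies (slope - 1) of potentiating excitatory law entries per depth
    depth_mod_factor = c(1, 0.6, 0.1, -0.4),
    # multiplies tuning concentration kappa per depth level
    depth_kappa_factor = c(1, 0.8, 0.6, 0.4),
    kappa_shape = 2,
    kappa_rate = 1.3,
    peak_meanlog = log(0.12),
    peak_sdlog = 0.5,
    exc_law = list(a = c(`0` = 0.50, `90` = 1.17, `180` = 1.63),
                   b = c(`0` = 0.0048, `90` = 0.0254, `180` = 0.0155)),
    inh_law = list(a = c(`0` = 0.85, `90` = 0.70, `180` = 0.50),
                   b = c(`0` = 0, `90` = 0, `180` = 0)),
    # center-silent emergent response, as a fraction of peak_response
    silent_b = c(`0` = 0.05, `45` = 0.15, `90` = 0.30, `135` = 0.45,
                 `180` = 0.60),
    law_jitter_sd = 0.08,
    gdsi_coupling_exc = 0.6,
    inh_coupling_same = 0.5,
    inh_coupling_opp = -0.8,
    inh_profile_jitter_sd = 0.05,
    s_ref = 0.42,
    feature_factors_exc = c(anti_phase = 1.0, tf_low = 0.85, tf_high = 0.9,
                            static_iso = 0.7, static_cross = 1.2),
    feature_factors_inh = c(anti_phase = 0.75, tf_low = 0.7, tf_high = 0.8,
                            static_iso = 0.6, static_cross = 0.7),
    static_center_gain = 0.6,
    rf_scatter_exc = 2,
    rf_scatter_inh = 4,
    rf_sigma_deg = 4,
    rf_amp_gain = 0.8,
    p_rf_mappable_silent = 0.806,
    baseline_meanlog = log(500),
    baseline_sdlog = 0.3,
    noise_sd = 0.04,
    indicator = "fast",
    n_fov = 1
  )
}

validate_population_config <- function(config) {
  ref <- default_population_config()
  missing <- setdiff(names(ref), names(config))
  unknown <- setdiff(names(config), names(ref))
  bad <- character(0)
  if (length(missing) == 0) {
    prob <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
    if (!prob(config$p_inhibitory)) bad <- c(bad, "p_inhibitory")
    if (!prob(config$p_center_silent_exc)) bad <- c(bad, "p_center_silent_exc")
    if (!prob(config$p_center_silent_inh)) bad <- c(bad, "p_center_silent_inh")
    if (!prob(config$p_surround_alone_exc)) bad <- c(bad, "p_surround_alone_exc")
    if (!prob(config$p_surround_alone_inh)) bad <- c(bad, "p_surround_alone_inh")
    if (!prob(config$p_rf_mappable_silent)) bad <- c(bad, "p_rf_mappable_silent")
    nd <- length(config$depth_levels)
    if (nd < 1 || any(config$depth_levels < 0)) bad <- c(bad, "depth_levels")
    if (length(config$depth_probs) != nd ||
        abs(sum(config$depth_probs) - 1) > 1e-8) bad <- c(bad, "depth_probs")
    if (length(config$depth_mod_factor) != nd) bad <- c(bad, "depth_mod_factor")
    if (length(config$depth_kappa_factor) != nd ||
        any(config$depth_kappa_factor < 0)) bad <- c(bad, "depth_kappa_factor")
    for (law in c("exc_law", "inh_law")) {
      l <- config[[law]]
      if (!is.list(l) || !all(c("a", "b") %in% names(l)) ||
          !all(c("0", "90", "180") %in% names(l$a)) ||
          !all(c("0", "90", "180") %in% names(l$b))) bad <- c(bad, law)
    }
    if (!all(as.character(DTHETA_LEVELS) %in% names(config$silent_b)))
      bad <- c(bad, "silent_b")
    if (!is.numeric(config$noise_sd) || config$noise_sd < 0)
      bad <- c(bad, "noise_sd")
    if (!(config$indicator %in% c("fast", "slow_nuclear")))
      bad <- c(bad, "indicator")
    if (!is.numeric(config$kappa_shape) || config$kappa_shape <= 0)
      bad <- c(bad, "kappa_shape")
    if (!is.numeric(config$kappa_rate) || config$kappa_rate <= 0)
      bad <- c(bad, "kappa_rate")
  }
  if (length(missing) || length(unknown) || length(bad)) {
    stop("invalid generator config; offending keys: ",
         paste(unique(c(paste0("missing:", missing),
                        paste0("unknown:", unknown), bad)), collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

# Interpolate a modulation law given at delta-theta 0/90/180 onto all five
# folded levels (linear in delta-theta for both slope and intercept).
interp_law <- function(v) {
  v <- v[c("0", "90", "180")]
  out <- c(v[1], mean(v[1:2]), v[2], mean(v[2:3]), v[3])
  names(out) <- as.character(DTHETA_LEVELS)
  out
}

#' Sample a synthetic cell population
#'
#' Draws `n_cells` simulated neurons from the generative model described in
#' [default_population_config()]. The result is deterministic given
#' `(config, seed)`.
#'
#' @param n_cells Number of cells (>= 1).
#' @param config Generator configuration; see [default_population_config()].
#' @param seed Integer seed.
#' @return A data frame of class `sc_population`, one row per cell, holding
#'   the generative ground truth: class, depth, preferred direction, tuning
#'   concentration `kappa`, peak response, center-silent and surround-alone
#'   flags, the per-cell modulation law columns `a_0 ... a_180` and
#'   `b_0 ... b_180`, feature-contrast factors, receptive-field geometry,
#'   baseline fluorescence, noise SD and indicator. The configuration is
#'   attached as attribute `"config"`.
#' @export
#' @examples
#' cells <- sample_population(20, seed = 1)
#' table(cells$cell_class)
sample_population <- function(n_cells, config = default_population_config(),
                              seed = 1L) {
  check_count(n_cells)
  validate_population_config(config)
  with_seed(seed, {
    cls <- ifelse(stats::runif(n_cells) < config$p_inhibitory,
                  "inhibitory", "excitatory")
    depth_idx <- sample.int(length(config$depth_levels), n_cells,
                            replace = TRUE, prob = config$depth_probs)
    depth <- config$depth_levels[depth_idx]
    kappa <- stats::rgamma(n_cells, shape = config$kappa_shape,
                           rate = config$kappa_rate) *
      config$depth_kappa_factor[depth_idx]
    pref <- sample(sc_directions(8), n_cells, replace = TRUE)
    peak <- stats::rlnorm(n_cells, config$peak_meanlog, config$peak_sdlog)
    p_sil <- ifelse(cls == "excitatory", config$p_center_silent_exc,
                    config$p_center_silent_inh)
    silent <- stats::runif(n_cells) < p_sil
    p_sur <- ifelse(cls == "excitatory", config$p_surround_alone_exc,
                    config$p_surround_alone_inh)
    sur_resp <- stats::runif(n_cells) < p_sur
    sur_amp <- ifelse(sur_resp, config$surround_alone_gain * peak, 0)

    # tuning strength in [0, 1); its coupling to the modulation law drives
    # the class-specific MI-vs-gDSI correlation signs
    s <- kappa / (kappa + 2)
    jit <- exp(stats::rnorm(n_cells, 0, config$law_jitter_sd))

    a_exc <- interp_law(config$exc_law$a)
    b_exc <- interp_law(config$exc_law$b)
    a_inh <- interp_law(config$inh_law$a)
    b_inh <- interp_law(config$inh_law$b)
    # inhibitory tuning-strength coupling, linear in delta-theta between the
    # same-surround and opposite-surround coupling coefficients
    couple_inh <- config$inh_coupling_same +
      (config$inh_coupling_opp - config$inh_coupling_same) *
      DTHETA_LEVELS / 180
    inh_shift <- stats::rnorm(n_cells, 0, config$inh_profile_jitter_sd)

    A <- matrix(NA_real_, n_cells, 5,
                dimnames = list(NULL, paste0("a_", DTHETA_LEVELS)))
    B <- matrix(NA_real_, n_cells, 5,
                dimnames = list(NULL, paste0("b_", DTHETA_LEVELS)))
    for (k in seq_along(DTHETA_LEVELS)) {
      dt <- as.character(DTHETA_LEVELS[k])
      exc <- cls == "excitatory" & !silent
      inh <- cls == "inhibitory" & !silent
      # excitatory: scale the deviation from unity; potentiating entries
      # (a > 1) additionally decline with depth and couple to tuning strength
      a0 <- a_exc[dt]
      if (a0 > 1) {
        m <- (1 + config$gdsi_coupling_exc * (s - config$s_ref)) * jit
        dev <- (a0 - 1) * config$depth_mod_factor[depth_idx]
        A[exc, k] <- 1 + dev[exc] * m[exc]
        B[exc, k] <- b_exc[dt] *
          pmax(config$depth_mod_factor[depth_idx][exc], 0) * jit[exc]
      } else {
        A[exc, k] <- 1 - (1 - a0) * jit[exc]
        B[exc, k] <- b_exc[dt] * jit[exc]
      }
      A[inh, k] <- pmin(pmax(a_inh[dt] + couple_inh[k] *
                               (s[inh] - config$s_ref) + inh_shift[inh],
                             0.05), 0.98)
      B[inh, k] <- b_inh[dt] * jit[inh]
      # center-silent: intercept-only emergent response rising with
      # delta-theta, expressed as a fraction of the cell's peak response
      A[silent, k] <- 0
      B[silent, k] <- config$silent_b[dt] * peak[silent] * jit[silent]
    }
    # inhibitory profiles are monotone non-increasing in delta-theta by
    # construction of the mean law; enforce it per cell so the coupling
    # jitter cannot invert the order (opposite surround most suppressive)
    inh_rows <- which(cls == "inhibitory" & !silent)
    if (length(inh_rows)) {
      for (k in 2:length(DTHETA_LEVELS)) {
        A[inh_rows, k] <- pmin(A[inh_rows, k], A[inh_rows, k - 1] - 0.005)
      }
    }

    ff <- rbind(config$feature_factors_exc)[rep(1, n_cells), , drop = FALSE]
    inh_rows <- cls == "inhibitory"
    ff[inh_rows, ] <- rbind(config$feature_factors_inh)[
      rep(1, sum(inh_rows)), , drop = FALSE]
    ff <- ff * exp(stats::rnorm(n_cells * ncol(ff), 0,
                                config$law_jitter_sd / 2))
    colnames(ff) <- paste0("fc_", names(config$feature_factors_exc))

    scatter <- ifelse(cls == "excitatory", config$rf_scatter_exc,
                      config$rf_scatter_inh)
    rf_x <- stats::rnorm(n_cells, 0, scatter)
    rf_y <- stats::rnorm(n_cells, 0, scatter)
    mappable <- !silent | stats::runif(n_cells) < config$p_rf_mappable_silent

    cells <- data.frame(
      cell_id = sprintf("cell%04d", seq_len(n_cells)),
      cell_class = cls,
      depth_um = depth,
      fov = paste0("fov", sample.int(config$n_fov, n_cells, replace = TRUE)),
      preferred_direction = pref,
      kappa = kappa,
      peak_response = peak,
      center_silent = silent,
      surround_alone_responsive = sur_resp,
      surround_alone_amp = sur_amp,
      A, B, ff,
      static_amp = config$static_center_gain * peak,
      rf_x = rf_x, rf_y = rf_y,
      rf_sigma_deg = config$rf_sigma_deg,
      rf_amp = config$rf_amp_gain * peak,
      rf_mappable = mappable,
      baseline_f = stats::rlnorm(n_cells, config$baseline_meanlog,
                                 config$baseline_sdlog),
      noise_sd = config$noise_sd,
      indicator = config$indicator,
      stringsAsFactors = FALSE
    )
    structure(cells, config = config,
              class = c("sc_population", "data.frame"))
  })
}

# von Mises direction tuning, normalized to 1 at the preferred direction;
# kappa = 0 gives a flat (untuned) profile.
vm_tuning <- function(theta, pref, kappa) {
  exp(kappa * (cos(deg2rad(theta - pref)) - 1))
}

law_lookup <- function(cells, prefix, dtheta) {
  cols <- paste0(prefix, "_", dtheta)
  m <- as.matrix(cells[paste0(prefix, "_", DTHETA_LEVELS)])
  m[, match(cols, colnames(m))]
}

#' Noiseless expected responses of a population to a protocol
#'
#' Evaluates the generative response law for every (cell, condition) pair:
#' the trial-averaged dF/F0 each cell would show with zero noise. Used by the
#' simulator and by round-trip tests.
#'
#' @param cells An `sc_population`.
#' @param protocol An `sc_protocol`.
#' @return Numeric matrix, cells x conditions (fractional dF/F0).
#' @export
generative_response <- function(cells, protocol) {
  cond <- protocol$conditions
  n <- nrow(cells)
  E <- matrix(0, n, nrow(cond),
              dimnames = list(cells$cell_id, NULL))
  if (protocol$kind == "rf_mapping") {
    for (j in seq_len(nrow(cond))) {
      d2 <- (cond$x[j] - cells$rf_x)^2 + (cond$y[j] - cells$rf_y)^2
      E[, j] <- ifelse(cells$rf_mappable,
                       cells$rf_amp * exp(-d2 / (2 * cells$rf_sigma_deg^2)),
                       0)
    }
    return(E)
  }
  center_resp <- function(theta) {
    ifelse(cells$center_silent, 0,
           cells$peak_response *
             vm_tuning(theta, cells$preferred_direction, cells$kappa))
  }
  for (j in seq_len(nrow(cond))) {
    cc <- cond$center[j]
    ss <- cond$surround[j]
    kind <- cond$surround_kind[j]
    if (kind %in% c("drifting", "anti_phase", "temporal_freq")) {
      if (is.na(cc) && is.na(ss)) {
        E[, j] <- 0
      } else if (is.na(ss)) {                    # center alone
        E[, j] <- center_resp(cc)
      } else if (is.na(cc)) {                    # surround alone
        E[, j] <- cells$surround_alone_amp
      } else if (kind == "drifting") {
        dt <- fold_dtheta(cc, ss)
        a <- law_lookup(cells, "a", dt)
        b <- law_lookup(cells, "b", dt)
        shape <- vm_tuning(cc, cells$preferred_direction, cells$kappa)
        E[, j] <- ifelse(cells$center_silent,
                         b * shape,              # emergent C-S response
                         a * center_resp(cc) + b)
      } else if (kind == "anti_phase") {
        E[, j] <- cells$fc_anti_phase * center_resp(cc)
      } else {                                   # temporal_freq
        f <- if (cond$surround_param[j] <= 2) cells$fc_tf_low else
          cells$fc_tf_high
        E[, j] <- f * center_resp(cc)
      }
    } else if (kind == "static_orientation") {
      if (is.na(cc)) {
        E[, j] <- 0                              # gray or surround-alone
      } else if (is.na(ss)) {
        E[, j] <- ifelse(cells$center_silent, 0, cells$static_amp)
      } else {
        d <- fold_dtheta(cc, ss) %% 180
        d <- pmin(d, 180 - d)                    # orientation difference
        f <- if (d == 0) cells$fc_static_iso else if (d == 90)
          cells$fc_static_cross else
          (cells$fc_static_iso + cells$fc_static_cross) / 2
        E[, j] <- ifelse(cells$center_silent, 0, cells$static_amp * f)
      }
    }
  }
  E
}

#' @export
print.sc_population <- function(x, ...) {
  cat("<sc_population>", nrow(x), "cells:",
      sum(x$cell_class == "excitatory"), "excitatory /",
      sum(x$cell_class == "inhibitory"), "inhibitory;",
      sum(x$center_silent), "center-silent\n")
  cat("  depths:", paste(sort(unique(x$depth_um)), collapse = ", "),
      "um; indicator:", x$indicator[1], "\n")
  invisible(x)
}
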