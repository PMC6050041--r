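# Shared synthetic fixtures, built once per test run and memoized.

fx_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fx_env, inherits = FALSE)) {
    assign(name, builder(), envir = fx_env)
  }
  get(name, envir = fx_env, inherits = FALSE)
}

# Excitatory-only configuration at the superficial depth level, where the
# generator's modulation law equals its nominal slope/intercept values.
exc_config <- function() {
  cfg <- default_population_config()
  cfg$p_inhibitory <- 0
  cfg$depth_levels <- 25
  cfg$depth_probs <- 1
  cfg$depth_mod_factor <- 1
  cfg$depth_kappa_factor <- 1
  cfg
}

inh_config <- function() {
  cfg <- exc_config()
  cfg$p_inhibitory <- 1
  cfg
}

# Align the response matrices of every center-responsive, non-silent cell.
aligned_matrices <- function(trials, resp = assess_responsiveness(trials)) {
  protocol <- attr(trials, "protocol")
  cond <- protocol$conditions
  center_ids <- cond$condition_id[!is.na(cond$center) & is.na(cond$surround)]
  mats <- response_matrices(trials)
  out <- list()
  for (id in resp$cells$cell_id) {
    fl <- resp$conditions[resp$conditions$cell_id == id, ]
    rc <- any(fl$responsive[match(center_ids, fl$condition_id)], na.rm = TRUE)
    if (!rc) next
    pref <- preferred_direction(mats[[id]], TRUE)
    if (is.na(pref$direction)) next
    out[[id]] <- align_matrix(mats[[id]], pref$direction)
  }
  out
}

# Small noiseless excitatory recording with full derived products.
fx_exc_noiseless <- function() fixture("exc_noiseless", function() {
  cfg <- exc_config()
  cfg$p_center_silent_exc <- 0
  p <- direction_contrast_protocol(n_repeats = 4, seed = 101)
  cells <- sample_population(48, cfg, seed = 102)
  rec <- simulate_recording(p, cells, seed = 103, noise = FALSE)
  trials <- build_response_table(rec)
  list(cfg = cfg, protocol = p, cells = cells, rec = rec, trials = trials,
       aligned = aligned_matrices(trials))
})

fx_inh_noiseless <- function() fixture("inh_noiseless", function() {
  cfg <- inh_config()
  p <- direction_contrast_protocol(n_repeats = 4, seed = 111)
  cells <- sample_population(48, cfg, seed = 112)
  rec <- simulate_recording(p, cells, seed = 113, noise = FALSE)
  trials <- build_response_table(rec)
  list(cfg = cfg, protocol = p, cells = cells, rec = rec, trials = trials,
       aligned = aligned_matrices(trials),
       summary = cell_summary(rec, n_boot = 1000, seed = 114))
})

# Mixed-class, all-depth noiseless population run through the full
# per-cell pipeline (used by depth/correlation/class summaries).
fx_mixed_noiseless <- function() fixture("mixed_noiseless", function() {
  p <- direction_contrast_protocol(n_repeats = 4, seed = 121)
  cells <- sample_population(260, default_population_config(), seed = 122)
  rec <- simulate_recording(p, cells, seed = 123, noise = FALSE)
  list(cells = cells, rec = rec,
       summary = cell_summary(rec, n_boot = 1000, seed = 124))
})

# A bare response matrix object built from given 9x9 values (for alignment
# and index-arithmetic tests without a simulation round).
raw_matrix <- function(values, cell_id = "cellX") {
  dirs <- sc_directions(8)
  dimnames(values) <- list(center = c(dirs, "blank"),
                           surround = c(dirs, "blank"))
  structure(list(cell_id = cell_id, values = values, trials = NULL,
                 directions = dirs, aligned = FALSE, alignment_shift = 0L),
            class = "sc_matrix")
}
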