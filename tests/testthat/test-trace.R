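test_that("default analysis windows match the indicator and stimulus", {
  w <- default_windows("grating", "fast")
  expect_equal(c(w$baseline_pre_s, w$response_start_offset_s,
                 w$response_end_offset_s), c(1.25, 0.25, 0.75))
  # 2 s grating: response window [0.25, 2.75] s, 2.5 s long
  expect_equal(2 + w$response_end_offset_s - w$response_start_offset_s, 2.5)
  ws <- default_windows("grating", "slow_nuclear")
  expect_equal(c(ws$response_start_offset_s, ws$response_end_offset_s),
               c(0.625, 1.125))
  wf <- default_windows("flash_square", "fast")
  expect_equal(c(wf$baseline_pre_s, wf$response_start_offset_s,
                 wf$response_end_offset_s), c(0.75, 0.25, 0.35))
  # 1 s flash: response window 1.1 s long
  expect_equal(1 + wf$response_end_offset_s - wf$response_start_offset_s,
               1.1)
  expect_error(default_windows("movie", "fast"), "invalid")
})

test_that("dF/F0 follows (F - F0) / F0 on hand-computed traces", {
  w <- window_spec(2, 0, 0)
  expect_equal(compute_dff(rep(7, 8), 2, 4, w, 1)$dff, 0)
  out <- compute_dff(c(10, 10, 12, 13), 2, 4, w, 1)
  expect_equal(out$dff, 0.25)   # (12.5 - 10) / 10
  expect_equal(out$f0, 10)
  expect_equal(compute_dff(c(5, 5, 10, 10), 2, 4, w, 1)$dff, 1.0)
  # negative dF/F0 is retained, not clipped
  expect_equal(compute_dff(c(10, 10, 5, 5), 2, 4, w, 1)$dff, -0.5)
})

test_that("dF/F0 is invariant to rescaling the whole trace", {
  set.seed(61)
  tr <- 100 + cumsum(rnorm(50))
  w <- window_spec(1, 0.1, 0.2)
  a <- compute_dff(tr, 10, 12, w, 2)
  b <- compute_dff(3.7 * tr, 10, 12, w, 2)
  expect_equal(a$dff, b$dff, tolerance = 1e-12)
})

test_that("window errors are reported", {
  w <- window_spec(2, 0, 0)
  expect_error(compute_dff(c(10, 10, 12), 1, 2, w, 1), "bounds")
  expect_error(compute_dff(c(10, 10, 12, 13), 2, 5, w, 1), "bounds")
  expect_error(compute_dff(c(-10, -10, 1, 1), 2, 4, w, 1), "baseline")
  expect_error(window_spec(0, 0.25, 0.75), "invalid")
})

test_that("the trial table has one row per cell, condition and repeat", {
  p <- direction_contrast_protocol(n_repeats = 4, seed = 71)
  cells <- sample_population(10, seed = 72)
  rec <- simulate_recording(p, cells, seed = 73)
  tr <- build_response_table(rec)
  expect_equal(nrow(tr), 81 * 4 * 10)
  expect_true(all(table(tr$cell_id, tr$condition_id) == 4))
  expect_identical(tr, build_response_table(rec))  # deterministic
})

test_that("responsiveness uses the 2-SD pooled-baseline criterion", {
  mk <- function(mean_dff, sd_dff, n_cond = 5, n_rep = 4) {
    data.frame(cell_id = "c1",
               condition_id = rep(seq_len(n_cond), each = n_rep),
               rep = rep(seq_len(n_rep), n_cond),
               dff = rep(mean_dff, each = n_rep),
               f0 = 100, baseline_sd = 100 * sd_dff)
  }
  # all condition means at zero with positive noise: non-responsive
  r <- assess_responsiveness(mk(rep(0, 5), 0.1))
  expect_false(r$cells$responsive)
  # one condition at 10x the baseline SD: responsive
  r2 <- assess_responsiveness(mk(c(0, 0, 1, 0, 0), 0.1))
  expect_true(r2$cells$responsive)
  expect_equal(sum(r2$conditions$responsive), 1)
  expect_equal(r2$conditions$responsive[3], TRUE)
  # exactly at threshold: strict inequality, not responsive
  r3 <- assess_responsiveness(mk(c(0.2, 0, 0, 0, 0), 0.1))
  expect_false(r3$cells$responsive)
  expect_error(assess_responsiveness(mk(0, 0.1)[0, ]), "empty")
})

test_that("pipeline false-positive rate on null cells matches a direct
           Monte-Carlo oracle of the criterion", {
  # Route 1: full trace pipeline on cells with vanishing responses
  cfg <- exc_config()
  cfg$peak_meanlog <- log(1e-9)
  cfg$p_center_silent_exc <- 0
  cfg$p_surround_alone_exc <- 0
  p <- direction_contrast_protocol(n_repeats = 4, seed = 81)
  cells <- sample_population(400, cfg, seed = 82)
  rec <- simulate_recording(p, cells, seed = 83)
  frac_pipeline <- mean(assess_responsiveness(
    build_response_table(rec))$cells$responsive)

  # Route 2: Monte-Carlo oracle drawing the criterion's ingredients
  # directly: per-trial dff ~ N(0, sd * sqrt(1/nb + 1/nr)), baseline SD
  # estimates ~ sd * sqrt(chi2_{nb-1} / (nb - 1)), 81 conditions x 4 reps.
  set.seed(84)
  nb <- floor(1.25 * 8.079); nr <- floor(2.5 * 8.079); sdf <- cfg$noise_sd
  n_mc <- 2000
  hits <- vapply(seq_len(n_mc), function(i) {
    cond_means <- rowMeans(matrix(
      rnorm(81 * 4, 0, sdf * sqrt(1 / nb + 1 / nr)), 81))
    pooled <- sqrt(mean(sdf^2 * rchisq(81 * 4, nb - 1) / (nb - 1)))
    any(cond_means > 2 * pooled)
  }, logical(1))
  frac_oracle <- mean(hits)
  # the criterion is conservative: both routes sit near zero and agree
  # within Monte-Carlo error
  tol <- 3 * sqrt(max(frac_oracle, 0.005) * 0.995 / 400)
  expect_lt(abs(frac_pipeline - frac_oracle), tol + 0.01)
  expect_lt(frac_pipeline, 0.05)
})
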