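# Normal-equations OLS oracle, independent of stats::lm.
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) /
    (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  c(slope = slope, intercept = intercept, r2 = 1 - ss_res / ss_tot)
}

test_that("response matrices hold per-condition trial means", {
  fx <- fx_exc_noiseless()
  m <- build_matrix(fx$trials, fx$cells$cell_id[1])
  expect_equal(dim(m$values), c(9, 9))
  expect_false(any(is.na(m$values)))
  expect_equal(nrow(m$trials), 81 * 4)
  # all-gray response vanishes on noiseless data
  expect_equal(m$values["blank", "blank"], 0, tolerance = 1e-3)
  # matrix equals the generative law within window quadrature
  E <- generative_response(fx$cells[1, ], fx$protocol)
  cond <- fx$protocol$conditions
  dirs <- sc_directions(8)
  ridx <- ifelse(is.na(cond$center), 9, match(cond$center, dirs))
  cidx <- ifelse(is.na(cond$surround), 9, match(cond$surround, dirs))
  expect_equal(m$values[cbind(ridx, cidx)], unname(E[1, ]),
               tolerance = 0.02)
  # missing conditions are an error
  sub <- fx$trials[fx$trials$condition_id != 5, ]
  attr(sub, "protocol") <- fx$protocol
  expect_error(build_matrix(sub, fx$cells$cell_id[1]), "incomplete")
})

test_that("alignment shifts indices circularly and conserves entries", {
  set.seed(191)
  v <- matrix(rnorm(81), 9, 9)
  m <- raw_matrix(v)
  a0 <- align_matrix(m, 0)
  expect_equal(a0$values, m$values)  # preferred 0: identity
  a90 <- align_matrix(m, 90)
  # entry (center 90, surround 270) moves to relative (0, 180)
  expect_equal(a90$values["0", "180"], v[3, 7])
  expect_equal(a90$values["0", "blank"], v[3, 9])
  expect_equal(a90$values["blank", "0"], v[9, 3])
  expect_equal(a90$values["blank", "blank"], v[9, 9])
  # multiset of entries conserved, for every shift
  for (pref in sc_directions(8)) {
    expect_equal(sort(as.vector(align_matrix(m, pref)$values)),
                 sort(as.vector(v)))
  }
  # aligning an aligned matrix to 0 is idempotent
  expect_equal(align_matrix(a90, 0)$values, a90$values)
  expect_error(align_matrix(m, 30), "multiple")
})

test_that("population curves order by surround relationship", {
  fx <- fx_exc_noiseless()
  pc <- population_curves(fx$aligned)
  center <- pc$mean[pc$relationship == "center_alone"]
  same <- pc$mean[pc$relationship == "0"]
  opp <- pc$mean[pc$relationship == "180"]
  expect_true(all(opp >= center))   # potentiation at every direction
  expect_true(all(same <= center))  # suppression at every direction
  # identical cells give zero s.e.m.
  two <- fx$aligned[c(1, 1)]
  pc2 <- population_curves(two)
  expect_equal(max(pc2$sem, na.rm = TRUE), 0)
})

test_that("modulation fits agree with the normal-equations oracle", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  f <- fit_modulation(x, 2 * x)
  expect_equal(c(f$slope, f$intercept, f$r_squared), c(2, 0, 1),
               tolerance = 1e-12)
  f2 <- fit_modulation(x, 0.5 * x + 1)
  expect_equal(c(f2$slope, f2$intercept, f2$r_squared), c(0.5, 1, 1),
               tolerance = 1e-12)
  set.seed(201)
  for (i in 1:50) {
    xx <- rnorm(8); yy <- rnorm(8)
    f3 <- fit_modulation(xx, yy)
    o <- ols_oracle(xx, yy)
    expect_equal(f3$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f3$intercept, unname(o["intercept"]), tolerance = 1e-10)
    expect_equal(f3$r_squared, unname(o["r2"]), tolerance = 1e-10)
    expect_true(f3$slope_ci[1] < f3$slope && f3$slope < f3$slope_ci[2])
  }
  expect_error(fit_modulation(rep(1, 8), rnorm(8)), "degenerate")
})

test_that("population slopes rise monotonically with direction difference", {
  fx <- fx_exc_noiseless()
  s <- slopes_vs_delta_theta(fx$aligned)
  expect_equal(s$delta_theta, c(0, 45, 90, 135, 180))
  expect_true(all(diff(s$slope) > 0))
  expect_lt(s$slope[1], 1)
  expect_gt(s$slope[5], 1)
  expect_true(all(s$r_squared > 0.9))
})

test_that("an untuned-modulation population has unit slopes", {
  # control: a = 1, b = 0 at every delta-theta
  fx <- fx_exc_noiseless()
  mats <- lapply(fx$aligned[1:10], function(m) {
    v <- m$values
    center <- v[1:8, 9]
    for (i in 1:8) for (j in 1:8) v[i, j] <- center[i]
    m$values <- v
    m
  })
  s <- slopes_vs_delta_theta(mats)
  expect_equal(s$slope, rep(1, 5), tolerance = 1e-10)
  expect_equal(s$intercept, rep(0, 5), tolerance = 1e-10)
})

test_that("inhibitory populations show deeper suppression at 180 degrees", {
  fx <- fx_inh_noiseless()
  s <- slopes_vs_delta_theta(fx$aligned)
  expect_lt(s$slope[s$delta_theta == 180], s$slope[s$delta_theta == 0])
  expect_true(all(s$slope < 1))
})

test_that("per-cell fits recover the per-cell law and filter noise cells", {
  fx <- fx_exc_noiseless()
  pf <- per_cell_fits(fx$aligned)
  good <- pf$fits[pf$fits$ok, ]
  # noiseless: near-perfect fits for every cell with non-flat tuning
  kappa <- fx$cells$kappa[match(good$cell_id, fx$cells$cell_id)]
  expect_true(all(good$r_squared[kappa > 0.3] > 0.99))
  expect_true(all(diff(pf$summary$mean_slope) > 0))
  # a pure-noise cell fails the R^2 filter
  set.seed(211)
  noisy <- fx$aligned[[1]]
  noisy$values[1:8, 1:8] <- rnorm(64, 0.05, 0.2)
  pfn <- per_cell_fits(c(fx$aligned[2:4], list(noisy = noisy)))
  expect_false(all(pfn$fits$pass[pfn$fits$cell_id == noisy$cell_id]))
})

test_that("center-silent emergent responses rise with direction difference", {
  cfg <- exc_config()
  cfg$p_center_silent_exc <- 1
  p <- direction_contrast_protocol(n_repeats = 4, seed = 221)
  cells <- sample_population(12, cfg, seed = 222)
  rec <- simulate_recording(p, cells, seed = 223, noise = FALSE)
  mats <- response_matrices(build_response_table(rec))
  cs <- center_silent_curve(mats)
  emergent <- cs$mean[!is.na(cs$delta_theta)]
  expect_true(all(diff(emergent) > 0))
  # center-alone reference is (near) zero
  expect_equal(cs$mean[is.na(cs$delta_theta)], 0, tolerance = 1e-3)
  # curve is proportional to the generative intercept profile
  b <- colMeans(as.matrix(cells[paste0("b_", c(0, 45, 90, 135, 180))]))
  ratio <- emergent / unname(b)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.05)
})

test_that("summation comparison flags sub-linear center-surround responses", {
  fx <- fx_inh_noiseless()
  sc <- summation_comparison(fx$aligned)
  # suppressed class: C-S response falls below C + S at every dtheta
  expect_true(all(sc$by_dtheta$mean < 0))
  # additive control: R_CS := R_C + R_S gives zero differences
  m <- fx$aligned[[1]]
  v <- m$values
  for (i in 1:8) for (j in 1:8) v[i, j] <- v[i, 9] + v[9, j]
  m$values <- v
  expect_equal(max(abs(summation_comparison(list(m))$per_cell$difference)),
               0, tolerance = 1e-12)
  # a cell with no surround-alone response reduces to R_CS - R_C
  m2 <- fx$aligned[[2]]
  m2$values[9, 1:8] <- 0
  sc2 <- summation_comparison(list(m2))
  expect_equal(sc2$per_cell$difference,
               sc2$per_cell$r_cs - sc2$per_cell$r_c, tolerance = 1e-12)
})

test_that("feature-contrast modulation indices order by class", {
  fx <- fx_exc_noiseless()
  ref <- data.frame(cell_id = names(fx$aligned))
  ref$preferred_direction <- vapply(fx$aligned, function(m)
    fx$cells$preferred_direction[fx$cells$cell_id == m$cell_id],
    numeric(1))
  ref$r_pref_c <- vapply(fx$aligned, function(m) m$values["0", "blank"],
                         numeric(1))
  sim_mi <- function(cells, kind, seed) {
    pf <- feature_contrast_protocol(kind, n_repeats = 4, seed = seed)
    recf <- simulate_recording(pf, cells, seed = seed + 1, noise = FALSE)
    feature_contrast_mi(build_response_table(recf), ref)
  }
  anti <- sim_mi(fx$cells, "anti_phase", 231)
  stat <- sim_mi(fx$cells, "static_orientation", 233)
  pc <- population_curves(fx$aligned)
  mi_same <- median(modulation_index(pc$mean[pc$relationship == "0"],
                                     pc$mean[pc$relationship ==
                                               "center_alone"]))
  mi_opp <- median(modulation_index(pc$mean[pc$relationship == "180"],
                                    pc$mean[pc$relationship ==
                                              "center_alone"]))
  med_anti <- median(anti$mi)
  expect_gt(med_anti, mi_same)
  expect_lt(med_anti, mi_opp)
  # static orientation: iso-surround suppresses, cross-surround potentiates
  expect_lt(median(stat$mi[stat$tag == "static_iso"]), 0)
  expect_gt(median(stat$mi[stat$tag == "static_cross"]), 0)

  # inhibitory cells: opposite drifting surround suppresses more than the
  # anti-phase surround
  fxi <- fx_inh_noiseless()
  refi <- data.frame(cell_id = names(fxi$aligned))
  refi$preferred_direction <- vapply(fxi$aligned, function(m)
    fxi$cells$preferred_direction[fxi$cells$cell_id == m$cell_id],
    numeric(1))
  refi$r_pref_c <- vapply(fxi$aligned, function(m) m$values["0", "blank"],
                          numeric(1))
  pfi <- feature_contrast_protocol("anti_phase", n_repeats = 4, seed = 235)
  reci <- simulate_recording(pfi, fxi$cells, seed = 236, noise = FALSE)
  antii <- feature_contrast_mi(build_response_table(reci), refi)
  pci <- population_curves(fxi$aligned)
  mi_oppi <- median(modulation_index(pci$mean[pci$relationship == "180"],
                                     pci$mean[pci$relationship ==
                                                "center_alone"]))
  expect_lt(mi_oppi, median(antii$mi))
})
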