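# Brute-force vector-sum oracle for gDSI, kept independent of the
# implementation (explicit cos/sin accumulation).
gdsi_oracle <- function(r, dirs) {
  r <- pmax(r, 0)
  sx <- 0; sy <- 0; s <- 0
  for (k in seq_along(r)) {
    sx <- sx + r[k] * cos(dirs[k] * pi / 180)
    sy <- sy + r[k] * sin(dirs[k] * pi / 180)
    s <- s + r[k]
  }
  sqrt(sx^2 + sy^2) / s
}

test_that("gDSI matches its defining examples", {
  expect_equal(compute_gdsi(c(1, 0, 0, 0, 0, 0, 0, 0)), 1)
  expect_equal(compute_gdsi(rep(0.3, 8)), 0)
  expect_equal(compute_gdsi(c(2, 1, 1, 1, 1, 1, 1, 1)), 1 / 9)
  expect_true(is.na(compute_gdsi(rep(0, 8))))
  expect_true(is.na(compute_gdsi(rep(-1, 8))))  # fully rectified away
})

test_that("gDSI stays in [0, 1] and agrees with the brute-force oracle", {
  set.seed(151)
  dirs <- sc_directions(8)
  for (i in 1:200) {
    r <- rnorm(8, 0.1, 0.3)
    g <- compute_gdsi(r, dirs)
    if (is.na(g)) {
      expect_true(all(pmax(r, 0) == 0))
      next
    }
    expect_gte(g, 0)
    expect_lte(g, 1)
    expect_equal(g, gdsi_oracle(r, dirs), tolerance = 1e-10)
  }
  # gDSI = 1 iff exactly one nonzero rectified response
  one <- c(0, 0, 0.7, 0, 0, -2, 0, 0)
  expect_equal(compute_gdsi(one), 1)
  expect_lt(compute_gdsi(c(0.7, 0.1, 0, 0, 0, 0, 0, 0)), 1)
})

test_that("preferred direction follows the center-alone and silent rules", {
  v <- matrix(0, 9, 9)
  v[3, 9] <- 0.5            # center-alone peak at 90 degrees
  v[5, 9] <- 0.3
  m <- raw_matrix(v)
  p <- preferred_direction(m, responsive_center = TRUE)
  expect_equal(p$direction, 90)
  expect_equal(p$source, "center_alone")
  # center-silent: peak C-S combination at (center 45, surround 225)
  v2 <- matrix(0, 9, 9)
  v2[2, 6] <- 0.8
  p2 <- preferred_direction(raw_matrix(v2), responsive_center = FALSE)
  expect_equal(p2$direction, 45)
  expect_equal(p2$source, "center_silent_CS")
  # two-way tie at 0 and 180: lowest direction wins
  v3 <- matrix(0, 9, 9)
  v3[1, 9] <- 0.4; v3[5, 9] <- 0.4
  expect_equal(preferred_direction(raw_matrix(v3), TRUE)$direction, 0)
  # all-non-positive: no preference
  expect_true(is.na(preferred_direction(raw_matrix(matrix(-1, 9, 9)),
                                        TRUE)$direction))
})

test_that("modulation index matches its formula, clipping and conventions", {
  expect_equal(modulation_index(2, 2), 0)
  expect_equal(modulation_index(3, 1), 0.5)
  expect_equal(modulation_index(-0.5, 1), -1)   # raw -3, clipped
  expect_equal(modulation_index(1, -0.5), 1)
  expect_equal(modulation_index(0, 0), 0)       # both-zero convention
  expect_equal(modulation_index(1, -1), 1)      # zero denominator, sign
  expect_equal(modulation_index(-1, 1), -1)
  # antisymmetric under swapping arguments (before clipping binds)
  set.seed(161)
  a <- runif(100, 0.01, 2); b <- runif(100, 0.01, 2)
  expect_equal(modulation_index(a, b), -modulation_index(b, a),
               tolerance = 1e-12)
})

test_that("bootstrap classification handles degenerate and strong cases", {
  expect_equal(bootstrap_classify(c(1, 1, 1, 1), c(1, 1, 1, 1),
                                  seed = 1)$class, "non_modulated")
  expect_equal(bootstrap_classify(c(0, 0, 0, 0), c(10, 10, 10, 10),
                                  seed = 1)$class, "potentiated")
  expect_equal(bootstrap_classify(c(10, 10, 10, 10), c(0, 0, 0, 0),
                                  seed = 1)$class, "suppressed")
  expect_error(bootstrap_classify(c(1, 2, 3), c(1, 2, 3, 4)), "equal")
  expect_error(bootstrap_classify(1:4, 5:8, n_boot = 10), "invalid")
  # determinism given the seed
  a <- c(0.1, 0.5, 0.2, 0.4); b <- c(0.6, 0.9, 0.5, 0.7)
  expect_identical(bootstrap_classify(a, b, seed = 7),
                   bootstrap_classify(a, b, seed = 7))
})

test_that("bootstrap type-I rate is near alpha on exchangeable nulls", {
  set.seed(171)
  n <- 400
  cls <- character(n)
  for (i in seq_len(n)) {
    cls[i] <- bootstrap_classify(rnorm(4), rnorm(4), n_boot = 2000,
                                 seed = 1700 + i)$class
  }
  rate <- mean(cls != "non_modulated")
  # 5% nominal; allow Monte-Carlo spread at n = 400
  expect_lt(abs(rate - 0.05), 0.035)
})

test_that("strong synthetic effects are classified potentiated", {
  fx <- fx_exc_noiseless()
  # low-noise trials: preferred center alone vs with opposite surround
  set.seed(181)
  hits <- 0; total <- 0
  for (i in seq_len(20)) {
    r_c <- fx$cells$peak_response[i]
    r_cs <- fx$cells$a_180[i] * r_c + fx$cells$b_180[i]
    a <- r_c + rnorm(4, 0, 0.01)
    b <- r_cs + rnorm(4, 0, 0.01)
    total <- total + 1
    if (bootstrap_classify(a, b, n_boot = 2000,
                           seed = 180 + i)$class == "potentiated")
      hits <- hits + 1
  }
  expect_gte(hits / total, 0.9)
})

test_that("the four-way category applies the non-responsive footnote rule", {
  expect_equal(categorize_cell("potentiated", responsive = FALSE),
               "non_responsive")
  expect_equal(categorize_cell("potentiated", responsive = TRUE,
                               surround_alone_only = TRUE),
               "non_responsive")
  expect_equal(categorize_cell("potentiated", responsive = TRUE),
               "potentiated")
  expect_equal(categorize_cell(NA_character_, responsive = TRUE),
               "non_responsive")
})
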