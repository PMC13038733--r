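test_that("resultant handles concentration, symmetry and cancellation", {
  expect_equal(circ_resultant(rep(45, 7)),
               list(mean_direction = 45, r = 1))
  res <- circ_resultant(c(0, 90))
  expect_equal(res$mean_direction, 45)
  expect_equal(res$r, sqrt(2) / 2, tolerance = 1e-12)
  res0 <- circ_resultant(c(0, 90, 180, 270))
  expect_equal(res0$r, 0, tolerance = 1e-12)
  expect_true(is.na(res0$mean_direction))
  expect_error(circ_resultant(numeric(0)), class = "skytuner_undefined_statistic")
  expect_error(circ_resultant(c(0, 10), weights = c(0, 0)),
               class = "skytuner_undefined_statistic")
})

test_that("resultant matches the brute-force unit-vector oracle on random inputs", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    a <- runif(n, 0, 360)
    w <- if (i %% 3 == 0) runif(n, 0.1, 5) else NULL
    got <- circ_resultant(a, w)
    want <- oracle_resultant(a, w)
    expect_equal(got$r, want$r, tolerance = 1e-9)
    if (got$r > 1e-9) {
      expect_lt(axial_err(got$mean_direction, want$mean_direction, 360), 1e-9)
    }
  }
})

test_that("axial doubling and halving recover the 180-degree class", {
  expect_equal(axial_double(c(10, 190)), c(20, 20))
  expect_equal(axial_halve(240), 120)
  expect_equal(phi_max(c(80, 260), periodicity = 180)$phi_max, 80)
  set.seed(4)
  a <- runif(50, 0, 180)
  expect_equal(axial_halve(axial_double(a)), a %% 180, tolerance = 1e-10)
})

test_that("phi_max handles axial identity and degenerate cancellation", {
  expect_equal(phi_max(c(10, 190, 10, 190), 180)$phi_max, 10)
  expect_error(phi_max(c(0, 90), 180), class = "skytuner_no_preferred_angle")
  expect_error(phi_max(5, 360), class = "skytuner_undefined_statistic")
})

test_that("phi_max is rotation-equivariant and axially flip-invariant", {
  set.seed(21)
  for (i in 1:50) {
    a <- runif(sample(5:40, 1), 0, 120) # concentrated enough to not cancel
    for (per in c(360, 180)) {
      base <- phi_max(a, per)$phi_max
      cshift <- runif(1, 0, 360)
      shifted <- phi_max(a + cshift, per)$phi_max
      expect_lt(axial_err(shifted, (base + cshift) %% per, per), 1e-6)
    }
    # flipping any subset by 180 leaves the axial estimate unchanged
    flip <- sample(c(TRUE, FALSE), length(a), replace = TRUE)
    flipped <- a + 180 * flip
    expect_lt(axial_err(phi_max(flipped, 180)$phi_max,
                        phi_max(a, 180)$phi_max, 180), 1e-6)
  }
})

test_that("phi_max recovers the generator's axial preferred angle from dense samples", {
  set.seed(7)
  # draw spike angles from an axial cosine-modulated density, true angle 51.8
  n <- 1000
  ang <- numeric(0)
  while (length(ang) < n) {
    cand <- runif(2 * n, 0, 360)
    keep <- runif(2 * n) < (1 + 0.8 * cos(2 * (cand - 51.8) * pi / 180)) / 1.8
    ang <- c(ang, cand[keep])
  }
  est <- phi_max(ang[1:n], 180)$phi_max
  expect_lt(axial_err(est, 51.8, 180), 3)
})

test_that("circular SD follows the mean angular deviation closed form", {
  expect_equal(circ_sd_from_r(1), 0)
  expect_equal(circ_sd_from_r(0), (180 / pi) * sqrt(2), tolerance = 1e-10)
  expect_equal(circ_sd_from_r(0.5), (180 / pi) * sqrt(1), tolerance = 1e-10)
  expect_equal(round(circ_sd_from_r(0), 2), 81.03)
  expect_equal(round(circ_sd_from_r(0.5), 2), 57.3)
  # monotone decreasing in r
  r <- seq(0, 1, by = 0.05)
  expect_true(all(diff(circ_sd_from_r(r)) < 0))
  expect_error(circ_sd_from_r(1.2), class = "skytuner_domain_error")
  # alternative convention
  expect_equal(circ_sd_from_r(1, "circular_sd"), 0)
  expect_gt(circ_sd_from_r(0.5, "circular_sd"), circ_sd_from_r(0.9, "circular_sd"))
})

test_that("confidence arc shrinks with concentration and is undefined for dispersed samples", {
  expect_lt(ci95_mean_direction(20, 0.9999), 1)
  expect_lt(ci95_mean_direction(20, 0.9999), ci95_mean_direction(20, 0.99))
  expect_true(is.na(ci95_mean_direction(20, 0.2)))
  expect_error(ci95_mean_direction(1, 0.5), class = "skytuner_domain_error")
  # axial arc is half the doubled-space arc
  d360 <- ci95_mean_direction(100, 0.8, 360)
  d180 <- ci95_mean_direction(100, 0.8, 180)
  expect_equal(d180, d360 / 2)
  # larger n narrows the arc at fixed r
  expect_lt(ci95_mean_direction(200, 0.6), ci95_mean_direction(30, 0.6))
})

test_that("analytic confidence arc agrees with the bootstrap within 2 degrees", {
  set.seed(31)
  a <- (rnorm(100, mean = 120, sd = 38)) %% 360 # wrapped normal, r ~ 0.8
  r <- circ_resultant(a)$r
  expect_gt(r, 0.7)
  analytic <- ci95_mean_direction(100, r, 360)
  boot <- circ_ci_bootstrap(a, 360, B = 2000)
  expect_lt(abs(analytic - boot), 2)
})

test_that("linear-circular correlation is exact for a noiseless cosine and errors on degenerate input", {
  phi <- seq(7.5, 352.5, by = 15) # 24 equally spaced bin centers
  x <- 5 + 3 * cos((phi - 40) * pi / 180)
  res <- linear_circular_corr(x, phi, 360)
  expect_equal(res$R2, 1, tolerance = 1e-10)
  expect_equal(res$p, exp(-12), tolerance = 1e-6)
  # axial version: doubled-angle cosine
  x2 <- 5 + 3 * cos(2 * (phi - 40) * pi / 180)
  res2 <- linear_circular_corr(x2, phi, 180)
  expect_equal(res2$R2, 1, tolerance = 1e-10)
  expect_error(linear_circular_corr(rep(2, 24), phi, 360),
               class = "skytuner_undefined_statistic")
  expect_error(linear_circular_corr(1:3, c(0, 10, 20), 360),
               class = "skytuner_domain_error")
})

test_that("R2 decreases with added noise on a cosine tuning curve", {
  set.seed(5)
  phi <- seq(7.5, 352.5, by = 15)
  base <- 10 + 5 * cos((phi - 100) * pi / 180)
  r2 <- sapply(c(0.5, 2, 8), function(sdn) {
    mean(replicate(40, linear_circular_corr(base + rnorm(24, 0, sdn), phi, 360)$R2))
  })
  expect_true(all(diff(r2) < 0))
})

test_that("Rayleigh test flags concentration and respects its sample-size floor", {
  res <- rayleigh_test(rep(33, 20), 360)
  expect_equal(res$z, 20, tolerance = 1e-9)
  expect_lt(res$p, 1e-6)
  expect_error(rayleigh_test(runif(4, 0, 360)), class = "skytuner_domain_error")
  set.seed(13)
  p_uniform <- replicate(100, rayleigh_test(runif(50, 0, 360))$p)
  expect_gt(mean(p_uniform > 0.05), 0.85)
})

test_that("angular distance respects periodicity and wrapping", {
  expect_equal(angular_distance(107.8, 154.4, 180), 46.6)
  expect_equal(angular_distance(10, 10, 180), 0)
  expect_equal(angular_distance(5, 175, 180), 10)
  expect_equal(angular_distance(350, 10, 360), 20)
})
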