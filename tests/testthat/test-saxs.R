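test_that("profile construction validates its invariants", {
  expect_error(saxs_profile(c(1, 0.5), c(1, 1)), "increasing")
  expect_error(saxs_profile(c(0.5, 1), c(1, 1), sigma = c(-1, 1)),
               "negative")
  expect_error(saxs_profile(c(-0.1, 1), c(1, 1)), "increasing and positive")
})

test_that("profile files round-trip and the unit heuristic rescales inverse-Angstrom grids", {
  p <- gen_geometry_profile("sphere", 5, noise = noise_spec(seed = 1))
  path <- withr::local_tempfile(fileext = ".dat")
  write_profile(p, path)
  p2 <- read_profile(path)
  expect_equal(p2$q, p$q, tolerance = 1e-7)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-7)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-7)

  # a grid maxing at 0.5 is taken as A^-1 and converted to nm^-1
  ang <- saxs_profile(seq(0.01, 0.5, by = 0.01),
                      exp(-seq(0.01, 0.5, by = 0.01)))
  path2 <- withr::local_tempfile(fileext = ".dat")
  write_profile(ang, path2)
  back <- read_profile(path2)
  expect_equal(max(back$q), 5, tolerance = 1e-6)
  expect_true(attr(back, "synthetic_sigma"))
  back_nm <- read_profile(path2, units = "nm")
  expect_equal(max(back_nm$q), 0.5, tolerance = 1e-6)
})

test_that("the Debye sum reproduces the two-bead closed form and conserves I(0)", {
  q <- c(0.3, 0.9, 2.1)
  d_nm <- 2.4
  p <- debye_intensity(matrix(c(0, 0, 0, 0, 0, d_nm * 10), ncol = 3,
                              byrow = TRUE), q = q, form_factor = 1.7)
  expect_equal(p$intensity,
               1.7^2 * 2 * (1 + sin(q * d_nm) / (q * d_nm)),
               tolerance = 1e-12)
  # I(q -> 0) = (N f)^2 for an arbitrary model
  set.seed(3)
  X <- matrix(rnorm(60), ncol = 3) * 15
  p0 <- debye_intensity(X, q = c(1e-7, 0.5))
  expect_equal(p0$intensity[1], 20^2, tolerance = 1e-6)
  expect_true(all(p0$intensity > 0))
})

test_that("Guinier analysis of a uniform bead sphere recovers sqrt(3/5) R within 2%", {
  set.seed(11)
  n <- 800
  X <- matrix(rnorm(3 * n), ncol = 3)
  X <- X / sqrt(rowSums(X^2)) * stats::runif(n)^(1 / 3) * 50  # R = 5 nm
  g <- guinier_rg(debye_intensity(X, q = seq(0.05, 1.2, by = 0.01)))
  expect_equal(g$rg, sqrt(3 / 5) * 5, tolerance = 0.02)
  expect_lte(g$qmax_rg, 1.3)
})

test_that("Guinier recovery on noisy synthetic spheres is tight and nearly unbiased", {
  rgs <- vapply(1:20, function(k) {
    p <- gen_geometry_profile("sphere", 5, q = seq(0.05, 2, by = 0.01),
                              noise = noise_spec(0.02, seed = 400 + k))
    guinier_rg(p)$rg
  }, numeric(1))
  # a sphere fitted to qmax*Rg = 1.3 carries a small positive truncation
  # bias from the q^4 term of its form factor; the recovered mean stays
  # within 2.5% of sqrt(3/5) R
  expect_lt(abs(mean(rgs) / (sqrt(3 / 5) * 5) - 1), 0.025)
  expect_lt(stats::sd(rgs) / (sqrt(3 / 5) * 5), 0.05)
})

test_that("p(r) of a bead model matches direct geometry", {
  # two beads: single occupied bin at their separation
  two <- pr_from_model(matrix(c(0, 0, 0, 0, 0, 37), ncol = 3, byrow = TRUE),
                       bin_width = 0.1)
  expect_equal(two$dmax, 3.7)
  expect_equal(sum(two$p > 0), 1)
  expect_equal(two$r[which(two$p > 0)], 3.65, tolerance = 0.051)

  # a dense uniform bead filling of a 5 nm sphere
  set.seed(6)
  n <- 4000
  X <- matrix(rnorm(3 * n), ncol = 3)
  X <- X / sqrt(rowSums(X^2)) * stats::runif(n)^(1 / 3) * 50
  pr <- pr_from_model(X, bin_width = 0.2)
  # Rg from p(r) equals the coordinate Rg within bin-width error
  expect_equal(pr$rg, model_rg(X) / 10, tolerance = 0.02)
  # solid-sphere p(r) peaks near 0.525 * 2R = 5.25 nm
  expect_equal(pr$r[which.max(pr$p)], 5.25, tolerance = 0.05)
})

test_that("the indirect Fourier transform recovers sphere geometry under constraints", {
  noiseless <- ift(gen_geometry_profile("sphere", 5, noise = NULL))
  expect_equal(noiseless$dmax, 10, tolerance = 0.11)
  expect_equal(noiseless$rg, sqrt(3 / 5) * 5, tolerance = 0.02)
  noisy <- ift(gen_geometry_profile("sphere", 5,
                                    noise = noise_spec(0.02, seed = 21)))
  expect_equal(noisy$dmax, 10, tolerance = 0.1)
  expect_lte(noisy$chi, 1.5)
  for (pr in list(noiseless, noisy)) {
    expect_true(all(pr$p >= 0))
    expect_equal(pr$p[1], 0)
    expect_equal(pr$p[length(pr$p)], 0)
  }
  expect_error(ift(saxs_profile(1:3 / 2, c(3, 2, 1))), "sigma")
})

test_that("chi fitting has the closed-form scale and unit chi on matched noise", {
  p <- gen_geometry_profile("sphere", 5, noise = NULL)
  doubled <- saxs_profile(p$q, 2 * p$intensity, p$sigma)
  cf <- chi_fit(p, doubled)
  expect_equal(cf$scale, 2, tolerance = 1e-9)
  expect_equal(cf$chi, 0, tolerance = 1e-9)

  # I_e = I_m + N(0, sigma) at N = 500 gives chi ~ 1
  set.seed(8)
  q <- seq(0.05, 2.5, length.out = 500)
  Im <- exp(-q^2 * 3) + 0.05
  sig <- 0.05 * Im
  Ie <- Im + rnorm(500, 0, sig)
  cf2 <- chi_fit(saxs_profile(q, Im), saxs_profile(q, Ie, sig))
  expect_equal(cf2$chi, 1, tolerance = 0.1)

  # joint rescaling of I_e and sigma leaves chi unchanged
  cf3 <- chi_fit(saxs_profile(q, Im),
                 saxs_profile(q, 3.7 * Ie, 3.7 * sig))
  expect_equal(cf3$chi, cf2$chi, tolerance = 1e-9)
  expect_error(chi_fit(p, saxs_profile(c(9, 10, 11), c(1, 1, 1),
                                       c(0.1, 0.1, 0.1))), "overlapping")
})

test_that("chi and V_r are stable under refinement of the model grid", {
  # smooth decaying profile (no form-factor zeros) so the only difference
  # between the variants is the interpolation grid
  smooth_I <- function(q) 10 * exp(-3 * q^2) + 0.5 * exp(-0.4 * q) + 0.05
  qe <- seq(0.1, 2.5, by = 0.01)
  set.seed(31)
  p_exp <- saxs_profile(qe, smooth_I(qe) * exp(rnorm(length(qe), 0, 0.02)),
                        sigma = 0.02 * smooth_I(qe))
  qs1 <- seq(0.08, 2.6, by = 0.01)
  qs2 <- seq(0.08, 2.6, by = 0.0025)
  m1 <- saxs_profile(qs1, smooth_I(qs1))
  m2 <- saxs_profile(qs2, smooth_I(qs2))
  expect_equal(chi_fit(m1, p_exp)$chi, chi_fit(m2, p_exp)$chi,
               tolerance = 1e-3)
  expect_equal(volatility_ratio(p_exp, m1)$value,
               volatility_ratio(p_exp, m2)$value, tolerance = 1e-3)
})

test_that("V_r is zero on self and scaled profiles, symmetric, and positive otherwise", {
  p <- gen_geometry_profile("sphere", 5, noise = noise_spec(0.02, seed = 41))
  expect_equal(volatility_ratio(p, p)$value, 0, tolerance = 1e-9)
  scaled <- saxs_profile(p$q, 13.7 * p$intensity, p$sigma)
  expect_equal(volatility_ratio(p, scaled)$value, 0, tolerance = 1e-9)
  for (seed in 1:8) {
    pair <- random_positive_profiles(seed)
    v_ab <- volatility_ratio(pair$a, pair$b)$value
    v_ba <- volatility_ratio(pair$b, pair$a)$value
    expect_equal(v_ab, v_ba, tolerance = 1e-9)
    expect_gt(v_ab, 0)
    # scale invariance of either argument
    b_scaled <- saxs_profile(pair$b$q, 0.21 * pair$b$intensity,
                             pair$b$sigma)
    expect_equal(volatility_ratio(pair$a, b_scaled)$value, v_ab,
                 tolerance = 1e-9)
  }
  # the binning uses pi/d-wide bins anchored at 0.15 nm^-1
  v <- volatility_ratio(p, p)
  expect_equal(diff(v$bins)[1], pi / 40, tolerance = 1e-12)
  expect_equal(v$bins[1], 0.15)
})

test_that("the V_r matrix is symmetric with a zero diagonal and ranks dissimilarity", {
  base <- gen_geometry_profile("sphere", 5, noise = noise_spec(0.02, seed = 1))
  alike <- gen_geometry_profile("sphere", 5, noise = noise_spec(0.02, seed = 2))
  perturbed <- gen_geometry_profile("sphere", 5.5,
                                    noise = noise_spec(0.02, seed = 3))
  rod <- gen_geometry_profile("rod", 18, noise = noise_spec(0.02, seed = 4))
  more_perturbed <- gen_geometry_profile("sphere", 6,
                                         noise = noise_spec(0.02, seed = 5))
  M <- vr_matrix(list(base = base, alike = alike, perturbed = perturbed,
                      more = more_perturbed, rod = rod))
  expect_equal(M, t(M), tolerance = 1e-9)
  expect_true(all(diag(M) == 0))
  # dissimilarity grows monotonically with the size perturbation
  expect_lt(M["base", "alike"], M["base", "perturbed"])
  expect_lt(M["base", "perturbed"], M["base", "more"])
  identical3 <- vr_matrix(list(base, base, base))
  expect_true(all(identical3 < 1e-9))
})
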