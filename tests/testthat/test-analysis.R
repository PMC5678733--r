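test_that("difference maps subtract orthogonal responses", {
  m <- synthetic_bandpass_map(32, cycles = 4, seed = 3)
  dm <- difference_maps(m)
  expect_equal(dm$d0_90, m$responses[, , 1] - m$responses[, , 3])
  # swapping the pair negates the map
  m2 <- m
  m2$responses <- m$responses[, , c(3, 4, 1, 2)]
  dm2 <- difference_maps(m2)
  expect_equal(dm2$d0_90, -dm$d0_90)
  # identical responses at the pair orientations give a zero map
  m3 <- m
  m3$responses[, , 3] <- m3$responses[, , 1]
  expect_true(all(difference_maps(m3)$d0_90 == 0))
  m4 <- m
  m4$angles <- m4$angles[-1]
  m4$responses <- m4$responses[, , -1]
  expect_error(difference_maps(m4), "orientation")
})

test_that("a map with uniform 0-degree preference loads the cardinal pair only", {
  n <- 32
  pref <- matrix(0, n, n); sel <- matrix(1, n, n)
  angles <- (0:3) * pi / 4
  responses <- array(0, c(n, n, 4))
  for (k in 1:4) responses[, , k] <- 1 + cos(2 * (pref - angles[k]))
  dm <- difference_maps(list(responses = responses, angles = angles))
  expect_true(all(dm$d0_90 > 0))
  expect_lt(max(abs(dm$d45_135)), 1e-12)
})

test_that("the Fermi function is 1/2 at the cutoff and sharpens to a step", {
  S <- function(k, khp, beta) 1 / (1 + exp((k - khp) / beta))
  expect_equal(S(6, 6, 0.5), 0.5)
  b <- 1e-3
  expect_lt(abs(S(6 + 10 * b, 6, b) - exp(-10) / (1 + exp(-10))), 1e-4)
  expect_lt(abs(S(6 - 10 * b, 6, b) - 1 / (1 + exp(-10))), 1e-4)
})

test_that("Fermi filtering attenuates single frequencies per the transfer function", {
  n <- 64
  u <- (0:(n - 1)) / n
  for (k0 in c(2, 5, 8, 12)) {
    I <- outer(cos(2 * pi * k0 * u), rep(1, n))
    f <- fermi_highpass(I, k_hp = 6, beta_hp = 0.75, boundary = "periodic")
    S <- 1 / (1 + exp((k0 - 6) / 0.75))
    expect_lt(abs(max(abs(f$J)) / max(abs(I)) - S), 1e-6)
    expect_lt(abs(max(abs(f$filtered)) / max(abs(I)) - (1 - S)), 1e-6)
  }
  # the printed convention retains high frequencies in J instead
  I <- outer(cos(2 * pi * 12 * u), rep(1, n))
  fp <- fermi_highpass(I, k_hp = 6, beta_hp = 0.75, boundary = "periodic",
                       convention = "printed")
  expect_lt(abs(max(abs(fp$J)) / max(abs(I)) -
                  1 / (1 + exp((6 - 12) / 0.75))), 1e-6)
  expect_error(fermi_highpass(I, k_hp = -1), "k_hp")
})

test_that("radial power spectrum finds planted frequencies and conserves energy", {
  n <- 64
  u <- (0:(n - 1)) / n
  I <- outer(cos(2 * pi * 5 * u), rep(1, n))
  ps <- radial_power_spectrum(I, pad = FALSE)
  expect_equal(ps$k[which.max(ps$P)], 5)
  # Parseval: binned mean times counts recovers total spectral energy
  set.seed(4)
  J <- matrix(rnorm(n * n), n, n)
  ps2 <- radial_power_spectrum(J, pad = FALSE)
  expect_lt(abs(sum(ps2$P * ps2$count) - sum(Mod(fft(J))^2)) /
              sum(Mod(fft(J))^2), 1e-6)
  # rotating the map by 90 degrees leaves the radial average unchanged
  Jr <- t(J[, rev(seq_len(n))])
  ps3 <- radial_power_spectrum(Jr, pad = FALSE)
  expect_lt(max(abs(ps3$P - ps2$P)), 1e-8 * max(ps2$P))
})

test_that("spectrum peak fit recovers a planted Gaussian peak", {
  k <- 0:20
  P <- exp(-(k - 6)^2 / 2)
  f <- fit_spectrum_peak(k, P, extent_mm = 3)
  expect_lt(abs(f$zeta - 6), 1e-6)
  expect_equal(f$quality, "fit")
  expect_equal(f$lambda_mm, 3 / f$zeta)
  # a linear background does not bias the peak
  f2 <- fit_spectrum_peak(k, P + 0.01 * k, extent_mm = 3)
  expect_lt(abs(f2$zeta - 6), 1e-3)
  expect_error(fit_spectrum_peak(0:4, rep(1, 5)), "bins")
})

test_that("a map with three full periods across 3 mm has a 1 mm hypercolumn", {
  n <- 96
  u <- (0:(n - 1)) / n
  z <- matrix(complex(real = cos(2 * pi * 3 * u) %o% rep(1, n),
                      imaginary = rep(1, n) %o% cos(2 * pi * 3 * u)), n, n)
  m <- astromap:::synthetic_map_from_z(z)
  dm <- difference_maps(m)
  f <- fermi_highpass(dm$d0_90, k_hp = 1.5, beta_hp = 0.2)
  ps <- radial_power_spectrum(f$filtered)
  fit <- fit_spectrum_peak(ps$k, ps$P, extent_mm = 3)
  expect_lt(abs(fit$lambda_mm - 1), 3 / 3^2 * ps$bin_width + 0.15)
})

test_that("planted wavelengths are recovered within one bin across random draws", {
  for (s in 1:20) {
    m <- synthetic_bandpass_map(64, cycles = 6, bandwidth = 1, seed = s)
    an <- analyze_map(m)
    expect_lt(abs(an$zeta - 6), 1 + 1e-9)
  }
})

test_that("pinwheel detection matches the canonical single-pinwheel field", {
  m <- synthetic_pinwheel_map(64, charge = 1)
  pw <- find_pinwheels(m)
  expect_equal(pw$count, 1L)
  expect_lt(sqrt(sum((pw$centers[1, ] - 32.5)^2)), 0.5)
  expect_equal(pw$charges, 1L)
  mc <- synthetic_pinwheel_map(64, charge = -1)
  pwc <- find_pinwheels(mc)
  expect_equal(pwc$count, 1L)
  expect_lt(sqrt(sum((pwc$centers[1, ] - 32.5)^2)), 0.5)
  expect_equal(pwc$charges, -1L)
})

test_that("detector and plaquette-winding oracle agree on periodic synthetic maps", {
  m <- synthetic_crossing_map(64, fx = 1, fy = 2)
  pw <- find_pinwheels(m)
  oracle <- pinwheel_winding_oracle(m)
  expect_equal(pw$count, attr(m, "n_pinwheels"))
  expect_equal(pw$count, oracle$count)
  expect_equal(sum(pw$charges), 0L)
  expect_equal(sum(oracle$charges), 0L)
  expect_equal(sort(table(pw$charges)), sort(table(oracle$charges)),
               ignore_attr = TRUE)
  # every detected centre sits in a plaquette the oracle flags
  det_plaq <- cbind(floor(pw$centers[, 1]), floor(pw$centers[, 2]))
  ora_plaq <- oracle$plaquettes
  key <- function(x) paste(x[, 1], x[, 2])
  expect_setequal(key(det_plaq), key(ora_plaq))
  # an empty map yields an empty set
  empty <- list(preference = matrix(0, 8, 8), selectivity = matrix(0, 8, 8))
  expect_equal(find_pinwheels(empty)$count, 0L)
})

test_that("net topological charge of periodic synthetic maps is zero", {
  for (s in 1:5) {
    m <- synthetic_bandpass_map(48, cycles = 5, seed = s)
    expect_equal(sum(pinwheel_winding_oracle(m, periodic = TRUE)$charges), 0L)
  }
})

test_that("pinwheels per hypercolumn follows the defining arithmetic", {
  expect_equal(pinwheels_per_hypercolumn(9, 1, 3), 1)
  expect_equal(pinwheels_per_hypercolumn(9, 2, 3), 4)  # doubling Lambda x4
  expect_error(pinwheels_per_hypercolumn(9, NA, 3), "not estimable")
})

test_that("stability index closed forms", {
  set.seed(8)
  F <- matrix(runif(32 * 32, 0, pi), 32, 32)
  expect_identical(stability_index(F, F), 1)
  O <- (F + pi / 4) %% pi
  expect_equal(stability_index(F, O), 0, tolerance = 1e-12)
  expect_equal(stability_index(F, O), stability_index(O, F))
  expect_error(stability_index(F, matrix(0, 2, 2)), "shape")
})

test_that("independent uniform maps have stability index 1/2", {
  set.seed(10)
  sis <- replicate(100, {
    F <- matrix(runif(48 * 48, 0, pi), 48, 48)
    O <- matrix(runif(48 * 48, 0, pi), 48, 48)
    stability_index(F, O)
  })
  expect_lt(abs(mean(sis) - 0.5), 0.01)
  expect_true(all(abs(sis - 0.5) < 0.05))
})

test_that("local orientation similarity separates smooth from shuffled maps", {
  n <- 48
  const <- structure(list(preference = matrix(1, n, n),
                          selectivity = matrix(1, n, n),
                          density = n, mm_per_unit = 3, extent_mm = 3),
                     class = "orientation_map")
  expect_equal(local_orientation_similarity(const, 0.3), 0)
  set.seed(12)
  rnd <- synthetic_random_map(n, seed = 2)
  expect_lt(abs(local_orientation_similarity(rnd, 0.4) - 45), 1)
  smooth <- synthetic_bandpass_map(n, cycles = 4, seed = 3)
  shuf <- smooth
  shuf$preference <- matrix(sample(smooth$preference), n, n)
  r <- 3 / 4 / 4   # quarter wavelength in mm
  expect_lt(local_orientation_similarity(smooth, r),
            local_orientation_similarity(shuf, r))
  expect_error(local_orientation_similarity(rnd, 0.001), "spacing")
  crv <- similarity_curve(smooth, c(0.2, 0.4))
  expect_equal(dim(crv), c(2L, 2L))
})
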