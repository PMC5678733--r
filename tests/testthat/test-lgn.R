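test_that("DoG kernels sum to zero with exact ON/OFF negation", {
  on <- make_dog_kernel(0.0375, 0.15, density = 24)
  off <- make_dog_kernel(0.0375, 0.15, polarity = "OFF", density = 24)
  expect_lt(abs(sum(on$weights)), 1e-10)
  expect_identical(off$weights, -on$weights)
  h <- on$half + 1L
  expect_gt(on$weights[h, h], 0)
  expect_lt(off$weights[h, h], 0)
  # zero-sum kernel ignores uniform fields
  resp <- sum(on$weights * 1)
  expect_lt(abs(resp), 1e-8)
  expect_warning(make_dog_kernel(0.0375, 0.15, support_radius = 0.2,
                                 density = 24), "truncation")
  expect_error(make_dog_kernel(0.2, 0.1, density = 24), "sigma")
})

test_that("DoG spectral peak matches the analytic transfer argmax", {
  sc <- 0.0375; ss <- 0.15; density <- 48
  k <- make_dog_kernel(sc, ss, density = density)
  n <- nrow(k$weights)
  M <- 256
  pad <- matrix(0, M, M)
  pad[seq_len(n), seq_len(n)] <- k$weights
  amp <- Mod(fft(pad))
  freqs <- c(0:(M / 2), -((M / 2 - 1):1)) * density / M  # cycles per sheet unit
  # restrict to the kx axis (ky = 0)
  axis_amp <- amp[, 1][1:(M / 2)]
  k_emp <- freqs[1:(M / 2)][which.max(axis_amp)]
  k_ana <- dog_peak_frequency(sc, ss)
  expect_lt(abs(k_emp - k_ana), density / M + 1e-9)  # within one bin
})

test_that("LGN response to nothing is nothing", {
  g <- sheet_geometry(1, 24)
  lgn <- lgn_stage(g)
  x <- matrix(0, g$n, g$n)
  L <- lgn_settle(x, lgn)
  expect_true(all(L$on == 0) && all(L$off == 0))
  L1 <- lgn_step(x, list(on = x, off = x), lgn)
  expect_true(all(L1$on == 0) && all(L1$off == 0))
  expect_error(lgn_step(matrix(0, 3, 3), L, lgn), "geometry")
})

test_that("settled LGN response saturates with contrast", {
  g <- sheet_geometry(1.5, 24)
  lgn <- lgn_stage(g)
  st <- structure(list(center = c(0.75, 0.75), orientation = pi / 5,
                       sigma_major = 0.4, sigma_minor = 0.09, amplitude = 1),
                  class = "training_stimulus")
  x <- render_stimulus(st, g)
  hi <- lgn_settle(x, lgn)
  lo <- lgn_settle(0.5 * x, lgn)
  expect_lt(max(hi$on) / max(lo$on), 2)
  expect_gt(max(hi$on), max(lo$on))   # still monotone in contrast
  expect_true(all(hi$on >= 0) && all(hi$off >= 0))
})

test_that("ON response to a bright spot equals OFF response to a dark spot", {
  # narrow pool and short settling keep the truncated kernels' reach finite,
  # so an interior window is exactly free of zero-padding edge effects
  g <- sheet_geometry(2, 24)
  lgn <- lgn_stage(g, sigma_pool = 0.0375, settle_steps = 2)
  st <- structure(list(center = c(1, 1), orientation = 0,
                       sigma_major = 0.1, sigma_minor = 0.1, amplitude = 0.4),
                  class = "training_stimulus")
  spot <- render_stimulus(st, g)
  bright <- 0.5 + spot
  dark <- 0.5 - spot
  Lb <- lgn_settle(bright, lgn)
  Ld <- lgn_settle(dark, lgn)
  interior <- 20:29
  expect_lt(max(abs(Lb$on[interior, interior] - Ld$off[interior, interior])),
            1e-8)
  expect_lt(max(abs(Lb$off[interior, interior] - Ld$on[interior, interior])),
            1e-8)
})

test_that("lgn_settle is deterministic", {
  g <- sheet_geometry(1, 24)
  lgn <- lgn_stage(g)
  st <- structure(list(center = c(0.4, 0.6), orientation = 1,
                       sigma_major = 0.4, sigma_minor = 0.09, amplitude = 1),
                  class = "training_stimulus")
  x <- render_stimulus(st, g)
  expect_identical(lgn_settle(x, lgn), lgn_settle(x, lgn))
})
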