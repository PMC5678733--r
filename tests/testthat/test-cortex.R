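test_that("silent LGN input leaves V1 silent", {
  m <- astro_model(tiny_config())
  z <- matrix(0, m$retina$n, m$retina$n)
  st <- v1_settle(list(on = z, off = z), m)
  expect_true(all(st$y == 0))
  expect_true(all(st$gs == 0))
})

test_that("without recurrence the settled rate is the rectified afferent drive", {
  cfg <- tiny_config(q = 1e-12, r = 1e-12, v1_alpha = 1, y_gain = 1)
  m <- astro_model(cfg)
  x <- render_stimulus(centre_stimulus(m), m$retina)
  L <- lgn_settle(x, m$lgn)
  st1 <- v1_settle(L, m, steps = 1)
  stN <- v1_settle(L, m, steps = 8)
  aff_only <- pmin(pmax(st1$aff - as.vector(m$rho), 0), cfg$y_max)
  expect_equal(as.vector(st1$y), aff_only, tolerance = 1e-9)
  expect_equal(stN$y, st1$y, tolerance = 1e-9)
})

test_that("settled activity to an oriented stimulus is a sparse blob", {
  cfg <- small_config()
  m <- train(cfg, run_schedule(300, probe_iterations = integer(0)))$model
  stream <- rng_stream(5, "stimuli")
  active <- replicate(20, {
    st <- sample_training_stimulus(stream, m$retina, m$stim_params)
    L <- lgn_settle(render_stimulus(st, m$retina), m$lgn)
    y <- v1_settle(L, m)$y
    mean(y > 0.05 * max(1e-12, max(y)))
  })
  expect_true(any(active > 0))
  expect_lt(mean(active), 0.5)
})

test_that("synaptic drive variants and the shared settling path agree", {
  m <- astro_model(tiny_config())
  x <- render_stimulus(centre_stimulus(m), m$retina)
  L <- lgn_settle(x, m$lgn)
  st <- v1_settle(L, m)
  gs_full <- synaptic_drive(L, st$y_prev, m, "full")
  expect_identical(gs_full, st$gs)    # bitwise: same code path
  gs_ng <- synaptic_drive(L, st$y_prev, m, "no_gaba")
  expect_true(all(gs_ng >= gs_full))
  z <- matrix(0, m$nc, m$nc)
  zL <- list(on = matrix(0, m$retina$n, m$retina$n),
             off = matrix(0, m$retina$n, m$retina$n))
  expect_true(all(synaptic_drive(zL, z, m) == 0))
  expect_error(synaptic_drive(L, st$y, m, "bogus"), "variant")
})

test_that("astrocyte disc pooling equals the brute-force oracle bitwise", {
  set.seed(9)
  gs <- matrix(rnorm(16 * 16), 16, 16)
  g <- sheet_geometry(1, 16)
  for (r_mm in c(0.2, 0.4, 0.7)) {
    a <- astrocyte_activation(gs, r_mm, g, gfap_scale = 2)
    oracle <- pool_disc_oracle(gs, 2 * r_mm / 3 * 16)
    expect_identical(a$S_raw, oracle)
  }
})

test_that("astrocyte pooling is uniform on uniform drive and identity for tiny radii", {
  g <- sheet_geometry(1, 16)
  gs <- matrix(2.5, 16, 16)
  a <- astrocyte_activation(gs, 0.2, g)
  r_px <- ceiling(a$radius_px)
  interior <- a$S_raw[(1 + r_px):(16 - r_px), (1 + r_px):(16 - r_px)]
  expect_lt(diff(range(interior)), 1e-10)
  # disc below one node spacing pools only the node itself
  set.seed(2)
  gs2 <- matrix(runif(16 * 16), 16, 16)
  a2 <- astrocyte_activation(gs2, 0.015, g)
  expect_lt(a2$radius_px, 1)
  expect_equal(a2$S_raw, gs2, tolerance = 0)
  expect_error(astrocyte_activation(gs2, -1, g), "radius")
  # normalized S lands in [0, 1]
  expect_true(all(a2$S >= 0 & a2$S <= 1))
})

test_that("gap junction coupling is local, uniformity-preserving, and off at zero strength", {
  k0 <- make_gap_junction_kernel(rng_stream(1, "gap-junction"), strength = 0)
  S <- matrix(runif(100), 10, 10)
  expect_identical(gap_junction_update(S, k0), S)

  k <- make_gap_junction_kernel(rng_stream(1, "gap-junction"),
                                strength = 0.1)
  expect_equal(sum(k), 0.1)
  expect_identical(k[2, 2], 0)
  U <- matrix(0.5, 10, 10)
  out <- gap_junction_update(U, k)
  expect_lt(max(abs(out[2:9, 2:9] - 0.5)), 1e-12)
  # single-node impulse spreads exactly one ring
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  oi <- gap_junction_update(imp, k)
  expect_true(all(oi[abs(row(oi) - 6) > 1 | abs(col(oi) - 6) > 1] == 0))
  expect_true(all(oi[5:7, 5:7] > 0))
  expect_error(gap_junction_update(S, matrix(1, 3, 3)), "centre")
})

test_that("homeostatic updates smooth and slide the threshold as specified", {
  # fixed point of the printed rule: lambda * ybar = mu
  h <- homeostatic_update(y = 1, ybar = 1, rho = 0.3, beta = 0.5,
                          lambda = 0.2, mu = 0.2, form = "printed")
  expect_equal(h$rho, 0.3)
  # beta = 1 freezes the trace (boundary of the smoothing recursion)
  h2 <- homeostatic_update(y = 5, ybar = 2, rho = 0, beta = 1 - 1e-15,
                           lambda = 0.1, mu = 0.1)
  expect_equal(h2$ybar, 2, tolerance = 1e-10)
  # persistent activity above target raises the threshold monotonically
  ybar <- 0.024; rho <- 0
  rhos <- numeric(100)
  for (i in 1:100) {
    h3 <- homeostatic_update(0.5, ybar, rho, 0.9, 0.01, 0.024, "balanced")
    ybar <- h3$ybar; rho <- h3$rho
    rhos[i] <- rho
  }
  expect_true(all(diff(rhos) > 0))
})

test_that("full model runs are bitwise reproducible", {
  cfg <- tiny_config()
  sch <- run_schedule(30, probe_iterations = integer(0))
  r1 <- train(cfg, sch)
  r2 <- train(cfg, sch)
  expect_identical(r1$model$W, r2$model$W)
  expect_identical(r1$model$rho, r2$model$rho)
  expect_identical(r1$model$s_max, r2$model$s_max)
})
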