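test_that("flow schedules validate windows and expose a half-open indicator", {
  s <- flow_schedule(list(), duration = 300)
  expect_identical(flow_indicator(s), integer(300))

  s <- flow_schedule(list(c(60, 120)), duration = 300, dt = 1)
  ind <- flow_indicator(s)
  t <- 0:299
  expect_identical(which(ind == 1L) - 1L, 60:119)  # half-open [60, 120)

  expect_error(flow_schedule(list(c(10, 50), c(40, 80))), "overlap")
  expect_error(flow_schedule(list(c(50, 10))), "start must be <")
  expect_error(flow_schedule(list(c(-5, 10))), "within")
  expect_error(flow_schedule(list(c(0, 400)), duration = 300), "within")
  expect_error(flow_schedule(duration = -1), "positive")
  expect_error(flow_schedule(dt = 0), "dt")
})

test_that("regional cGMP follows first-order kinetics exactly", {
  kin <- cgmp_kinetics()
  # all-off schedule: constant baseline
  off <- simulate_region_cgmp(flow_schedule(list(), duration = 100), kin)
  expect_true(all(off$core == kin$c_base))
  expect_true(all(off$periphery == kin$c_base))

  # step response: c(t0 + tau_on) - c_base = (1 - 1/e) * step
  s <- flow_schedule(list(c(50, 300)), duration = 300)
  tr <- simulate_region_cgmp(s, kin)
  for (rg in c("core", "periphery")) {
    step <- (if (rg == "core") kin$c_on_core else kin$c_on_periphery) - kin$c_base
    got <- tr[[rg]][tr$t == 50 + kin$tau_on] - kin$c_base
    expect_equal(got, (1 - exp(-1)) * step, tolerance = 1e-12)
  }
  # bounded within [c_base, c_on]
  expect_true(all(tr$periphery >= kin$c_base - 1e-12 &
                    tr$periphery <= kin$c_on_periphery + 1e-12))
  # periphery >= core gradient throughout
  expect_true(all(tr$periphery >= tr$core - 1e-12))
})

test_that("cGMP returns to a 5% band of baseline within 3 tau_off of flow cessation", {
  kin <- cgmp_kinetics(tau_off = 5)
  s <- flow_schedule(list(c(50, 150)), duration = 300)
  tr <- simulate_region_cgmp(s, kin)
  # closed-form e-folding: deviation <= 5% of the step after 3 tau_off = 15 s
  for (rg in c("core", "periphery")) {
    step <- (if (rg == "core") kin$c_on_core else kin$c_on_periphery) - kin$c_base
    post <- tr[tr$t >= 150 + 3 * kin$tau_off, ]
    expect_true(all(abs(post[[rg]] - kin$c_base) <= 0.05 * step))
    expect_lte(3 * kin$tau_off, 20)  # recovery complete within ~20 s
  }
})

test_that("stiff frame grids trigger a discretization warning", {
  s <- flow_schedule(list(c(10, 20)), duration = 50, dt = 3)
  expect_warning(simulate_region_cgmp(s, cgmp_kinetics(tau_on = 4, tau_off = 5)),
                 "barely resolved")
})

test_that("area profiles pass through their knots and validate ordering", {
  # triangular: 0 -> 100 um2 over 0-60 s, linear decay to 40 um2 at 300 s
  p <- area_profile(A_max = 100, t_max = 60, A_end = 40, t_end = 300)
  expect_equal(p$A[p$t == 60], 100)
  expect_equal(p$A[p$t == 300], 40)
  expect_equal(p$A[p$t == 0], 0)
  expect_equal(p$A[p$t == 30], 50)

  # plateau when A_end = A_max
  p2 <- area_profile(A_max = 100, t_max = 60, A_end = 100, t_end = 300)
  expect_true(all(p2$A[p2$t > 60] == 100))

  # logistic shape hits the knots to well under 1% of A_max
  p3 <- area_profile(A_max = 100, t_max = 60, A_end = 40, t_end = 300,
                     shape = "logistic")
  expect_lt(abs(p3$A[p3$t == 60] - 100), 1)
  expect_lt(abs(p3$A[p3$t == 300] - 40), 1)
  expect_true(all(diff(p3$A[p3$t <= 60]) >= 0))   # unimodal
  expect_true(all(diff(p3$A[p3$t >= 60]) <= 0))

  expect_error(area_profile(A_max = 100, t_max = 100, A_end = 40, t_end = 60),
               "t_injury < t_max < t_end")
  expect_error(area_profile(A_max = 100, t_max = 60, A_end = 150, t_end = 300),
               "A_base <= A_end <= A_max")
})

test_that("noise-free rendering puts every thrombus pixel on the sensor curve", {
  # uniform concentration over the thrombus
  kin <- cgmp_kinetics(c_base = 0.1, c_on_core = 1.5, c_on_periphery = 1.5)
  s <- flow_schedule(list(c(0, 30)), duration = 30)
  cg <- simulate_region_cgmp(s, kin)
  g <- synth_geometry(width = 64, height = 64)
  p <- area_profile(A_max = 150, t_max = 10, A_end = 150, t_end = 29)
  nm <- noise_model(shot_noise = FALSE, read_noise_sd = 0)
  mv <- render_movie(g, p, cg, noise = nm)
  sens <- sensor_model()
  k <- 25L
  m <- mv$truth$masks$masks$whole[, , k]
  cfp <- mv$stack$data[, , 1, k][m] - nm$background_level
  yfp <- mv$stack$data[, , 2, k][m] - nm$background_level
  expected_R <- sensor_forward(cg$periphery[k], sens)
  # intensities are rounded to integer counts; allow the quantization
  expect_true(all(abs(cfp / yfp - expected_R) < 0.01))
})

test_that("rendering is seed-deterministic and seeds change the noise", {
  g <- synth_geometry(width = 48, height = 48)
  p <- area_profile(A_max = 80, t_max = 10, A_end = 40, t_end = 29)
  s <- flow_schedule(list(c(5, 20)), duration = 30)
  cg <- simulate_region_cgmp(s, cgmp_kinetics())
  a <- render_movie(g, p, cg, noise = noise_model(seed = 5))
  b <- render_movie(g, p, cg, noise = noise_model(seed = 5))
  c <- render_movie(g, p, cg, noise = noise_model(seed = 6))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$c_region, b$truth$c_region)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(123); x1 <- runif(3)
  set.seed(123)
  g <- synth_geometry(width = 48, height = 48)
  p <- area_profile(A_max = 80, t_max = 10, A_end = 40, t_end = 29)
  cg <- simulate_region_cgmp(flow_schedule(list(), duration = 30),
                             cgmp_kinetics())
  render_movie(g, p, cg, noise = noise_model(seed = 5))
  expect_identical(runif(3), x1)
})

test_that("background pixels average to the configured level", {
  mv <- demo_movie()
  nm <- noise_model()
  k <- 10L
  outside <- !mv$truth$masks$masks$whole[, , k]
  # stay clear of the dim skirt around the thrombus
  g <- demo_geometry()
  D <- sqrt(outer((seq_len(g$height) - g$center[1])^2,
                  (seq_len(g$width) - g$center[2])^2, "+"))
  far <- outside & D > g$width / 2.2
  vals <- mv$stack$data[, , 2, k][far]
  se <- sd(vals) / sqrt(length(vals))
  expect_gt(length(vals), 1e3)
  expect_lt(abs(mean(vals) - nm$background_level), 3 * se + 0.5)
})

test_that("CFP and YFP move in opposite directions on a cGMP step", {
  mv <- demo_movie(noise_free = TRUE)
  tr <- extract_traces(mv$stack, mv$truth$masks, noise_model()$background_level)
  w <- tr[tr$region == "whole", ]
  pre <- w$t >= 30 & w$t < 40   # before flow-on
  on <- w$t >= 70 & w$t < 90    # plateau
  d480 <- mean(w$F480[on]) - mean(w$F480[pre])
  d535 <- mean(w$F535[on]) - mean(w$F535[pre])
  expect_gt(d480, 0)
  expect_lt(d535, 0)
})

test_that("ground-truth whole mask conserves the area profile", {
  mv <- demo_movie(noise_free = TRUE)
  counts <- apply(mv$truth$masks$masks$whole, 3, sum)
  A_px <- mv$profile$A / mv$stack$pixel_size^2
  r <- sqrt(A_px / pi)
  # disc pixelation: within one pixel row (~2r pixels) of the ideal area
  expect_true(all(abs(counts - A_px) <= pmax(2 * r, 4)))
})

test_that("Ca2+ traces are lagged and anticorrelated with cGMP", {
  kin <- cgmp_kinetics()
  cm <- ca_model(lag = 2, coupling = -1)
  s <- flow_schedule(list(c(60, 120)), duration = 300)
  cg <- simulate_region_cgmp(s, kin)
  ca <- simulate_region_ca(cg, kin, cm)
  # anticorrelation
  expect_lt(cor(cg$periphery, ca$periphery), -0.9)
  # the Ca2+ drop starts `lag` seconds after the cGMP rise
  i_cg <- which(cg$periphery > kin$c_base + 0.01)[1]
  i_ca <- which(ca$periphery < cm$ca_high - 0.01)[1]
  expect_equal(cg$t[i_ca] - cg$t[i_cg], cm$lag, tolerance = 1)
  expect_error(ca_model(lag = -1), "lag")
  expect_error(ca_model(coupling = 0), "coupling")
})

test_that("oversized thrombi and invalid parameters are rejected", {
  g <- synth_geometry(width = 32, height = 32)
  p <- area_profile(A_max = 5000, t_max = 10, A_end = 100, t_end = 29)
  cg <- simulate_region_cgmp(flow_schedule(list(), duration = 30),
                             cgmp_kinetics())
  expect_error(render_movie(g, p, cg), "does not fit")
  expect_error(cgmp_kinetics(c_on_core = 5, c_on_periphery = 1), ">=")
  expect_error(cgmp_kinetics(tau_on = 0), "tau")
  expect_error(noise_model(background_level = -1), "background_level")
  expect_error(synth_geometry(center_gain = 1), "center_gain")
})
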