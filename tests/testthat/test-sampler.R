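test_that("simulated pulls are deterministic under a fixed seed", {
  pot <- well50()
  p <- fast_protocol()
  p$seed <- 99
  a <- simulate_pull(pot, p)
  b <- simulate_pull(pot, p)
  expect_identical(a$work, b$work)
  expect_identical(a$xi, b$xi)
  set1 <- make_bidirectional_set(pot, fast_protocol(), 2, 2, seed = 4)
  set2 <- make_bidirectional_set(pot, fast_protocol(), 2, 2, seed = 4)
  expect_identical(lapply(set1, as.data.frame), lapply(set2, as.data.frame))
})

test_that("dragging a free particle costs exactly the friction drag work", {
  # flat potential: the only mean force is the viscous lag, so the average
  # work over the pull distance L is gamma * v * L (0 in the slow limit)
  pot <- model_potential("flat")
  gamma <- 5; v <- 0.02; L <- 10
  finals <- vapply(1:10, function(s) {
    p <- pull_protocol(12, 2, velocity = v, friction = gamma)
    p$seed <- 800 + s
    w <- simulate_pull(pot, p)
    w$work[nrow(w)]
  }, double(1))
  drag <- gamma * v * L
  expect_lt(abs(mean(finals) - drag), 4 * sd(finals) / sqrt(10) + 0.05 * drag)
})

test_that("the compiled force matches a numerical derivative of U", {
  for (kind in c("adsorption_well", "hydration_oscillatory")) {
    pot <- model_potential(kind, well_depth = -30, osc_amplitude = 5)
    x <- seq(1.2, 12, length.out = 80)
    h <- 1e-5
    num <- (pot$U(x + h) - pot$U(x - h)) / (2 * h)
    expect_equal(pot$dU(x), num, tolerance = 1e-6)
  }
  ramp <- model_potential("extraction_plateau", plateau_height = 90)
  x <- seq(0.1, 10, length.out = 50)
  h <- 1e-6
  num <- (ramp$U(x + h) - ramp$U(x - h)) / (2 * h)
  expect_equal(ramp$dU(x), num, tolerance = 1e-4)
  # plateau landscape is nondecreasing from 0 to its plateau
  u <- ramp$U(seq(0, 30, length.out = 200))
  expect_true(all(diff(u) >= -1e-12))
  expect_equal(u[1], 0)
  expect_equal(u[200], 90)
})

test_that("a stationary trap samples the Boltzmann distribution", {
  # flat potential + harmonic trap: stationary law is Gaussian with
  # sd = sqrt(kB T / k)
  pot <- model_potential("flat")
  x <- sample_equilibrium(pot, at = 5, n_samples = 1500, thin = 60,
                          spring_k = 200, temperature = 310, friction = 20,
                          seed = 21)
  ks <- stats::ks.test(x, "pnorm", mean = 5, sd = sqrt(kB * 310 / 200))
  expect_gt(ks$p.value, 0.01)
})

test_that("work fluctuations grow with pulling speed", {
  pot <- well50()
  final_var <- sapply(c(0.01, 0.04, 0.16), function(v) {
    curves <- forward_set(pot, fast_protocol(velocity = v), 25, seed = 17)
    var(vapply(curves, function(c) c$work[nrow(c)], double(1)))
  })
  expect_true(all(diff(final_var) > 0))
})

test_that("the stability guard rejects an under-resolved time step", {
  expect_error(pull_protocol(12, 2, spring_k = 1000, friction = 50, dt = 0.1),
               class = "cin2d_stability_error")
  expect_error(pull_protocol(5, 5), class = "cin2d_parameter_error")
  expect_error(make_bidirectional_set(well50(), fast_protocol(), 1, 0),
               class = "cin2d_parameter_error")
})

test_that("extraction fixtures hit their plateaus exactly at zero noise", {
  profs <- make_extraction_fixture(
    data.frame(n = 1:3, per_lipid = c(93.3, 76.0, 74.8)))
  plateaus <- vapply(seq_along(profs), function(i) {
    extraction_barrier(profs[[i]], i)$g_n
  }, double(1))
  expect_equal(plateaus, c(93.3, 152.0, 224.4))
  expect_equal(extraction_barrier(profs$N1, 1)$g_n, 93.3)
  expect_error(make_extraction_fixture(data.frame(n = 1, per_lipid = -3)),
               class = "cin2d_parameter_error")
})

test_that("noisy extraction fixtures recover the plateau on average", {
  truth <- 90
  rec <- vapply(1:100, function(s) {
    p <- make_extraction_fixture(data.frame(n = 1, per_lipid = truth),
                                 noise_sd = 2, seed = s)$N1
    extraction_barrier(p, 1)$g_n
  }, double(1))
  # max-of-noisy-curve is biased high by design; mean within 3 noise sd
  expect_lt(abs(mean(rec) - truth), 3 * 2)
})
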