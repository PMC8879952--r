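test_that("unidirectional conversions reorder, negate and re-zero correctly", {
  # forward: reorder onto increasing grid, already zero at the bulk end
  pf <- pmf_forward(tiny_forward())
  expect_equal(pf$xi, c(2, 6, 10))
  expect_equal(pf$dG, c(-20, -5, 0))
  expect_equal(pf$sd, rep(0, 3))
  expect_equal(attr(pf, "n_replicates"), 1L)

  # reverse: dG = -(W_end - W), zero at the bulk end
  pr <- pmf_reverse(tiny_reverse())
  expect_equal(pr$xi, c(2, 6, 10))
  expect_equal(pr$dG, c(-20, -5, 0))

  # zero work gives a flat profile, both directions
  expect_equal(pmf_forward(flat_curve("adsorption"))$dG, rep(0, 11))
  expect_equal(pmf_reverse(flat_curve("desorption"))$dG, rep(0, 11))
})

test_that("bidirectional averaging is the pointwise mean/sd of the two branches", {
  # two flat curves, one per direction: flat profile, no dispersion
  pb <- pmf_bidirectional(list(flat_curve("adsorption"), flat_curve("desorption")))
  expect_equal(pb$dG, rep(0, length(pb$dG)))
  expect_equal(pb$sd, rep(0, length(pb$sd)))
  expect_equal(attr(pb, "n_replicates"), 2L)

  # forward branch f(xi), reverse branch g(xi): mean and sample sd pointwise
  fwd <- tiny_forward()                               # profile (-20, -5, 0)
  rev <- work_curve(c(2, 6, 10), c(0, 19, 30), "desorption")  # profile (-30, -11, 0)
  pb <- pmf_bidirectional(list(fwd, rev))
  f <- c(-20, -5, 0); g <- c(-30, -11, 0)
  expect_equal(approx(pb$xi, pb$dG, xout = c(2, 6, 10))$y, (f + g) / 2)
  expect_equal(approx(pb$xi, pb$sd, xout = c(2, 6, 10))$y,
               abs(f - g) / sqrt(2))
  expect_equal(pb$dG[length(pb$dG)], 0)
})

test_that("bidirectional estimation requires overlap and consistent temperature", {
  a <- work_curve(c(10, 6), c(0, -1), "adsorption")
  b <- work_curve(c(11, 12), c(0, 1), "desorption")
  expect_error(pmf_bidirectional(list(a, b)), class = "cin2d_estimation_error")
  warm <- work_curve(c(2, 6, 10), c(0, 1, 2), "desorption", temperature = 350)
  expect_error(pmf_bidirectional(list(tiny_forward(), warm)),
               class = "cin2d_estimation_error")
})

test_that("Jarzynski reduces to the re-zeroed work for identical curves", {
  w <- work_curve(seq(10, 2, by = -1), c(0, cumsum(rep(-2, 8))), "adsorption")
  pj <- pmf_jarzynski(list(w, w, w), n_boot = 20, seed = 1)
  pf <- pmf_forward(w)
  expect_equal(approx(pj$xi, pj$dG, xout = pf$xi)$y, pf$dG, tolerance = 1e-10)
  # exponential average of a constant has no spread
  expect_equal(max(pj$sd), 0, tolerance = 1e-10)
  expect_error(pmf_jarzynski(list(w)), class = "cin2d_insufficient_sample")
  expect_error(pmf_jarzynski(list(w, tiny_reverse())),
               class = "cin2d_estimation_error")
})

test_that("Jarzynski over a free particle recovers zero free energy", {
  pot <- model_potential("flat")
  # low friction keeps the dissipated work a few kB*T so 50 pulls converge
  proto <- pull_protocol(12, 2, velocity = 0.05, friction = 5)
  curves <- forward_set(pot, proto, 50, seed = 5)
  pj <- pmf_jarzynski(curves, n_boot = 100, seed = 2)
  final <- pj$dG[1]  # surface end, after re-zero in bulk
  expect_lt(abs(final), max(3 * pj$sd[1], 1))
})

test_that("log-sum-exp guard keeps strongly dissipative averages finite", {
  # work far exceeding kB*T would overflow exp(-W/kBT) without the guard
  w1 <- work_curve(c(10, 2), c(0, 5000), "adsorption")
  w2 <- work_curve(c(10, 2), c(0, 5200), "adsorption")
  pj <- pmf_jarzynski(list(w1, w2), n_boot = 10, seed = 1)
  expect_true(all(is.finite(pj$dG)))
})

test_that("re-zeroing is idempotent and profile invariants hold", {
  p <- pmf_forward(tiny_forward())
  expect_equal(rezero_profile(p), p)
  expect_equal(rezero_profile(rezero_profile(p)), rezero_profile(p))
  # adding a constant then re-zeroing leaves the profile unchanged
  shifted <- p
  shifted$dG <- shifted$dG + 7
  expect_equal(rezero_profile(shifted)$dG, p$dG)
  expect_error(free_energy_profile(c(1, 1, 2), c(0, 0, 0)),
               class = "cin2d_invalid_profile")
  expect_error(free_energy_profile(1:3, 1:3, sd = -1),
               class = "cin2d_invalid_profile")
})

test_that("halving the resample grid spacing barely moves the minimum", {
  pot <- well50()
  curves <- make_bidirectional_set(pot, fast_protocol(velocity = 0.05), 2, 2,
                                   seed = 3)
  coarse <- pmf_bidirectional(curves, dx = 0.2)
  fine <- pmf_bidirectional(curves, dx = 0.1)
  expect_lt(abs(min(coarse$dG) - min(fine$dG)), 0.5)
})
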