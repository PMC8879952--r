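test_that("adsorption_energy finds the well and honours the reference", {
  p <- free_energy_profile(xi = 1:5, dG = c(-14, -3, -1, -0.5, 0))
  ae <- adsorption_energy(p, "head")
  expect_equal(ae$value, -14)
  expect_equal(ae$xi_min, 1)

  # monotone profile without a well: minimum sits at the bulk reference, 0
  q <- free_energy_profile(xi = 1:5, dG = c(8, 5, 3, 1, 0), sd = 0.05)
  at <- adsorption_energy(q, "tail")
  expect_equal(at$value, 0)
  expect_equal(at$sd, 0.05)

  flat <- free_energy_profile(xi = 1:3, dG = c(0, 0, 0))
  expect_equal(adsorption_energy(flat)$value, 0)
  # ties break toward the surface (smaller xi)
  tie <- free_energy_profile(xi = 1:4, dG = c(-2, -2, -1, 0))
  expect_equal(adsorption_energy(tie)$xi_min, 1)

  bad <- free_energy_profile(xi = 1:3, dG = c(NA_real_, NA, NA))
  expect_error(adsorption_energy(bad), class = "cin2d_invalid_profile")

  # never positive, invariant under shift + re-zero
  set.seed(1)
  for (i in 1:20) {
    prof <- free_energy_profile(xi = 1:10, dG = c(rnorm(9), 0))
    v <- adsorption_energy(prof)$value
    expect_lte(v, 0)
    shifted <- prof
    shifted$dG <- shifted$dG + runif(1, -5, 5)
    expect_equal(adsorption_energy(rezero_profile(shifted))$value, v)
  }
})

test_that("extraction barriers and g0 follow the min-over-N rule", {
  profs <- make_extraction_fixture(
    data.frame(n = c(1, 3), per_lipid = c(93.3, 74.8)))
  expect_equal(extraction_barrier(profs$N3, 3)$g_n, 3 * 74.8)

  falling <- free_energy_profile(xi = 1:4, dG = c(0, -1, -2, -3))
  expect_error(extraction_barrier(falling, 1), class = "cin2d_stability_error")

  s <- g0_from_series(data.frame(n = 1:3, g_n = c(93.3, 152.0, 224.4)))
  expect_equal(attr(s, "g0"), 74.8)
  expect_equal(attr(s, "argmin_n"), 3)
  expect_equal(glance(s)$g0, 74.8)

  expect_equal(attr(g0_from_series(data.frame(n = 1, g_n = 10)), "g0"), 10)
  expect_equal(attr(g0_from_series(data.frame(n = c(1, 3), g_n = c(9, 9))), "g0"), 3)
  expect_error(g0_from_series(data.frame(n = 1, g_n = 0)),
               class = "cin2d_stability_error")
  expect_error(g0_from_series(data.frame(n = integer(0), g_n = double(0))),
               class = "cin2d_parameter_error")

  # brute force equivalence on random positive series
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:6, sample(2:5, 1))
    g <- runif(length(n), 1, 300)
    expect_equal(attr(g0_from_series(data.frame(n = n, g_n = g)), "g0"),
                 min(g / n))
  }
})

test_that("cin2d difference and summed-absolute-error propagation", {
  expect_equal(cin2d(-20, -115, 3, 12), tibble::tibble(cin = 95, cin_sd = 15))
  r <- cin2d(-3.5, 0.00, 1.4, 0.12)
  expect_equal(r$cin, -3.5)
  expect_equal(r$cin_sd, 1.52)
  expect_equal(cin2d(0, 0)$cin, 0)
  expect_equal(cin2d(0, 0)$cin_sd, 0)
  # accepts adsorption_energy rows
  ph <- free_energy_profile(xi = 1:3, dG = c(-14, -2, 0), sd = 2)
  pt <- free_energy_profile(xi = 1:3, dG = c(-103, -4, 0), sd = 11)
  r2 <- cin2d(adsorption_energy(ph, "head"), adsorption_energy(pt, "tail"))
  expect_equal(r2$cin, 89)
  expect_equal(r2$cin_sd, 13)
  expect_error(cin2d(NA_real_, 0), class = "cin2d_parameter_error")
})

test_that("classification matches the four-regime rules and flags confidence", {
  r <- classify_regime(
    data.frame(material = "GN", g_h = -14, g_h_sd = 2, g_t = -103, g_t_sd = 11))
  expect_equal(as.character(r$regime), "lipid_extraction")
  expect_true(r$confident)

  r <- classify_regime(
    data.frame(material = "GON", g_h = -19, g_h_sd = 4, g_t = -30, g_t_sd = 14))
  expect_equal(as.character(r$regime), "insertion")
  expect_false(r$confident)

  # both couplings below thermal energy at 310 K (kB*T ~ 2.577 kJ/mol)
  r <- classify_regime(data.frame(g_h = -1, g_t = -1))
  expect_equal(as.character(r$regime), "no_interaction")

  # boundary conventions
  r0 <- classify_regime(data.frame(g_h = -10, g_t = -10))
  expect_equal(as.character(r0$regime), "insertion")
  expect_match(r0$notes, "boundary")
  rg0 <- classify_regime(data.frame(g_h = -5, g_t = -80), g0 = 75)
  expect_equal(as.character(rg0$regime), "lipid_extraction")
  expect_match(rg0$notes, "boundary")

  expect_error(classify_regime(data.frame(g_h = -1, g_t = -1), g0 = -1),
               class = "cin2d_parameter_error")
  expect_error(classify_regime(data.frame(g_h = -1, g_t = -1), temperature = 0),
               class = "cin2d_parameter_error")
})

test_that("classifier is exhaustive/exclusive and extraction implies |g_t| > g0", {
  set.seed(7)
  pts <- tibble::tibble(g_h = -runif(400, 0, 60), g_t = -runif(400, 0, 160))
  r <- classify_regime(pts, g0 = 75, temperature = 310)
  expect_false(anyNA(r$regime))  # every point gets exactly one regime
  ext <- dplyr::filter(r, regime == "lipid_extraction")
  expect_true(all(abs(ext$g_t) > 75))
})

test_that("the six reference nanosheets reproduce the published regime calls", {
  r <- classify_regime(nanosheet_energies(), g0 = 75, temperature = 310)
  expect_equal(as.character(r$regime), r$reported_prediction)
  expect_equal(sum(r$regime == "lipid_extraction"), 3)
  expect_false(r$confident[r$material == "GON"])
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("material", "g_h", "g_h_sd", "g_t", "g_t_sd",
                     "cin", "cin_sd", "regime", "confident", "notes"))
  g <- glance(r)
  expect_equal(g$n_materials, 6)
  expect_equal(g$n_cytotoxic, 3)
})
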