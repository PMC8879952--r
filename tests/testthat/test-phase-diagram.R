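test_that("diagram places the reference materials in their regions", {
  reports <- classify_regime(nanosheet_energies(), g0 = 75)
  d <- phase_diagram(reports, g0 = 75, temperature = 310)
  reg <- setNames(d$materials$regime, d$materials$material)
  expect_equal(unname(reg[c("GN", "BNN (PAC +/- 1.05 e)", "BNN (PAC +/- 0.5 e)")]),
               rep("lipid_extraction", 3))
  expect_equal(unname(reg[c("Mg/Al-LDH", "Aloohene")]), rep("adsorption", 2))
  expect_equal(unname(reg["GON"]), "insertion")
  # ellipse semi-axes are the reported uncertainties
  expect_equal(d$materials$semi_g_h[d$materials$material == "GN"], 2)
  expect_equal(d$materials$semi_g_t[d$materials$material == "GN"], 11)
})

test_that("an empty diagram still carries the three boundary curves", {
  d <- phase_diagram(NULL, g0 = 75)
  expect_equal(nrow(d$materials), 0)
  expect_setequal(unique(d$boundaries$curve), c("cin_zero", "cin_g0", "thermal"))
  # the CIN = 0 boundary is the diagonal, the g0 line is offset by g0
  z <- dplyr::filter(d$boundaries, curve == "cin_zero")
  expect_equal(z$g_h, z$g_t)
  l <- dplyr::filter(d$boundaries, curve == "cin_g0")
  expect_equal(l$g_h - l$g_t, rep(75, nrow(l)))
  # thermal triangle vertices at kB*T on each axis
  th <- dplyr::filter(d$boundaries, curve == "thermal")
  expect_equal(sort(abs(c(th$g_t, th$g_h))), c(0, 0, kB * 310, kB * 310))
})

test_that("points on the diagonal go to the insertion side and get flagged", {
  d <- phase_diagram(data.frame(material = "edge", g_h = -30, g_t = -30))
  expect_equal(d$materials$regime, "insertion")
  r <- classify_regime(data.frame(g_h = -30, g_t = -30))
  expect_match(r$notes, "assigned insertion")
})

test_that("degenerate bounds are rejected and the plot builds", {
  expect_error(phase_diagram(NULL, bounds = c(0, -40)),
               class = "cin2d_parameter_error")
  expect_error(phase_diagram(NULL, g0 = 0), class = "cin2d_parameter_error")
  p <- autoplot(phase_diagram(classify_regime(nanosheet_energies())),
                grid_n = 31)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 2)
})
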