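#' Phase diagram of nanosheet-membrane interaction regimes
#'
#' Lays out the `(g_t, g_h)` quarter-plane diagram: the diagonal
#' `g_h = g_t` (CIN2D = 0) separating adsorption from insertion, the
#' parallel line `g_h - g_t = g0` beyond which lipid extraction becomes
#' favourable, and the thermal triangle `|g_h| + |g_t| < kB T` where no
#' significant interaction occurs. Each classified material is placed as a
#' point with an uncertainty ellipse whose semi-axes are the reported
#' uncertainties.
#'
#' @param reports A `regime_tbl` from [classify_regime()], a plain data
#'   frame with `g_h`/`g_t` columns (classified on the fly), or `NULL` for
#'   boundaries only.
#' @param g0 Specific lipid-extraction resistance, kJ/mol (> 0).
#' @param temperature Temperature in kelvin.
#' @param bounds Named vector `c(g_t_min, g_h_min)` (both < 0): the
#'   rectangle `[g_t_min, 0] x [g_h_min, 0]` the diagram covers.
#' @return An object of class `diagram_spec`: a list with `boundaries`
#'   (tibble of polyline vertices, one `curve` per boundary), `materials`
#'   (tibble of points with ellipse semi-axes and regimes), `g0`,
#'   `temperature`, `bounds`. Render with [autoplot()][autoplot.diagram_spec]
#'   or serialise with [write_diagram_json()].
#' @examples
#' d <- phase_diagram(classify_regime(nanosheet_energies()))
#' d$materials[, c("material", "regime")]
#' @export
phase_diagram <- function(reports = NULL, g0 = 75, temperature = 310,
                          bounds = c(g_t_min = -140, g_h_min = -40)) {
  if (length(bounds) != 2 || any(!is.finite(bounds)) || any(bounds >= 0)) {
    abort("`bounds` must give two negative extents (g_t_min, g_h_min).",
          class = "cin2d_parameter_error")
  }
  if (g0 <= 0) abort("`g0` must be positive.", class = "cin2d_parameter_error")
  gt_min <- as.double(bounds[[1]])
  gh_min <- as.double(bounds[[2]])
  th <- thermal_energy(temperature)

  # CIN2D = 0 diagonal, clipped to the rectangle
  lo <- max(gt_min, gh_min)
  b1 <- tibble(curve = "cin_zero", g_t = c(lo, 0), g_h = c(lo, 0))
  # CIN2D = g0 line: g_h = g_t + g0, needs g_h <= 0 hence g_t <= -g0
  b2 <- tibble(curve = "cin_g0",
               g_t = c(min(gt_min, -g0), -g0),
               g_h = c(min(gt_min, -g0) + g0, 0))
  # thermal triangle |g_h| + |g_t| = kB T
  b3 <- tibble(curve = "thermal", g_t = c(-th, 0), g_h = c(0, -th))

  materials <- tibble(material = character(0), g_t = double(0),
                      g_h = double(0), semi_g_t = double(0),
                      semi_g_h = double(0), regime = character(0),
                      confident = logical(0))
  if (!is.null(reports)) {
    if (!inherits(reports, "regime_tbl")) {
      reports <- classify_regime(reports, g0 = g0, temperature = temperature)
    }
    materials <- tibble(
      material = reports$material,
      g_t = reports$g_t, g_h = reports$g_h,
      semi_g_t = reports$g_t_sd, semi_g_h = reports$g_h_sd,
      regime = as.character(reports$regime),
      confident = reports$confident
    )
  }
  structure(
    list(boundaries = dplyr::bind_rows(b1, b2, b3), materials = materials,
         g0 = g0, temperature = temperature,
         bounds = c(g_t_min = gt_min, g_h_min = gh_min),
         schema_version = "1.0"),
    class = "diagram_spec"
  )
}

#' @export
print.diagram_spec <- function(x, ...) {
  cat(sprintf(
    "<diagram_spec> g0 = %g kJ/mol, T = %g K, %d material(s), bounds g_t >= %g, g_h >= %g\n",
    x$g0, x$temperature, nrow(x$materials), x$bounds[1], x$bounds[2]))
  invisible(x)
}

ellipse_path <- function(x0, y0, a, b, n = 90) {
  t <- seq(0, 2 * pi, length.out = n)
  tibble(g_t = x0 + a * cos(t), g_h = y0 + b * sin(t))
}

#' @rdname autoplot.diagram_spec
#' @param diagram A `diagram_spec`.
#' @export
plot_diagram <- function(diagram, ...) {
  ggplot2::autoplot(diagram, ...)
}

#' Render the regime phase diagram
#'
#' Shades the four regions (classified on a fine grid), draws the regime
#' boundaries, and overlays each material with its uncertainty ellipse.
#'
#' @param object A `diagram_spec` from [phase_diagram()].
#' @param grid_n Resolution of the background shading grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diagram_spec <- function(object, grid_n = 201, ...) {
  g <- tidyr::expand_grid(
    g_t = seq(object$bounds[["g_t_min"]], 0, length.out = grid_n),
    g_h = seq(object$bounds[["g_h_min"]], 0, length.out = grid_n)
  )
  g <- classify_regime(g, g0 = object$g0, temperature = object$temperature)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = g,
                         ggplot2::aes(x = .data$g_t, y = .data$g_h,
                                      fill = .data$regime),
                         alpha = 0.5) +
    ggplot2::geom_path(data = object$boundaries,
                       ggplot2::aes(x = .data$g_t, y = .data$g_h,
                                    group = .data$curve),
                       linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = c(
      no_interaction = "#9ecae1", adsorption = "#a1d99b",
      insertion = "#fee391", lipid_extraction = "#ffffff"
    ), drop = FALSE) +
    ggplot2::labs(x = expression(g[t] ~ (kJ/mol)),
                  y = expression(g[h] ~ (kJ/mol)), fill = "regime")
  if (nrow(object$materials) > 0) {
    ell <- dplyr::bind_rows(lapply(seq_len(nrow(object$materials)), function(i) {
      m <- object$materials[i, ]
      dplyr::mutate(ellipse_path(m$g_t, m$g_h, m$semi_g_t, m$semi_g_h),
                    material = m$material)
    }))
    p <- p +
      ggplot2::geom_path(data = ell,
                         ggplot2::aes(x = .data$g_t, y = .data$g_h,
                                      group = .data$material)) +
      ggplot2::geom_point(data = object$materials,
                          ggplot2::aes(x = .data$g_t, y = .data$g_h)) +
      ggplot2::geom_text(data = object$materials,
                         ggplot2::aes(x = .data$g_t, y = .data$g_h,
                                      label = .data$material),
                         vjust = -1, size = 3)
  }
  p
}
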