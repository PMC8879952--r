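#' Adsorption free energy of a lipid moiety from a profile
#'
#' The adsorption free energy `g_h` (head) or `g_t` (tail) is the global
#' minimum of the zero-referenced free-energy profile: the depth of the
#' well near the nanomaterial surface. Because the unbound reference point
#' is 0, the result is never positive; a profile with no well returns 0 at
#' the bulk reference. Ties are broken toward smaller `xi` (toward the
#' surface).
#'
#' @param profile A [free_energy_profile()], zero-referenced.
#' @param moiety `"head"` or `"tail"`, recorded in the result.
#' @return A one-row tibble of class `adsorption_energy` with columns
#'   `moiety`, `value` (kJ/mol, <= 0), `sd` (the dispersion at the
#'   minimum), `xi_min` (location of the minimum, angstrom).
#' @examples
#' p <- free_energy_profile(xi = 1:5, dG = c(-14, -3, -1, -0.5, 0))
#' adsorption_energy(p, "head")
#' @export
adsorption_energy <- function(profile, moiety = c("head", "tail")) {
  moiety <- match.arg(moiety)
  stopifnot(inherits(profile, "free_energy_profile"))
  if (all(is.na(profile$dG))) {
    abort("Profile has no finite values.", class = "cin2d_invalid_profile")
  }
  i <- which.min(profile$dG)  # first index = smallest xi on ties
  out <- tibble(
    moiety = moiety,
    value = profile$dG[i],
    sd = profile$sd[i],
    xi_min = profile$xi[i]
  )
  class(out) <- c("adsorption_energy", class(out))
  out
}

#' Lipid-extraction barrier from an extraction profile
#'
#' For a group of `n_lipids` concatenated lipids pulled out of the bilayer,
#' the extraction barrier `g_N` is the maximum of the free-energy change
#' over the pulled distance. A stable membrane gives `g_N > 0`; a
#' non-positive maximum signals an unstable membrane model and is an error.
#'
#' @param profile A [free_energy_profile()] from an extraction pull
#'   (rising from 0 at the embedded state).
#' @param n_lipids Number of lipids in the extracted group (>= 1).
#' @return A one-row tibble with columns `n`, `g_n` (kJ/mol).
#' @export
extraction_barrier <- function(profile, n_lipids) {
  stopifnot(inherits(profile, "free_energy_profile"),
            n_lipids >= 1)
  g_n <- max(profile$dG, na.rm = TRUE)
  if (g_n <= 0) {
    abort("Extraction profile has a non-positive maximum: unstable membrane.",
          class = "cin2d_stability_error")
  }
  tibble(n = as.integer(n_lipids), g_n = g_n)
}

#' Specific lipid-extraction resistance g0 from a barrier series
#'
#' The membrane's specific extraction resistance is
#' \eqn{g_0 = \min_N (g_N / N)}: collective extraction of adjacent lipids
#' can be cheaper per lipid than one-by-one extraction because the exposed
#' hydrophobic contact area grows sublinearly with the group size.
#'
#' @param entries A data frame with columns `n` (lipid count, >= 1) and
#'   `g_n` (barrier, kJ/mol, > 0), one row per group size.
#' @return A tibble of class `extraction_series` with an added `per_lipid`
#'   column and attributes `g0` (the minimum per-lipid barrier) and
#'   `argmin_n` (the group size achieving it). [glance()] extracts them.
#' @examples
#' g0_from_series(data.frame(n = 1:3, g_n = c(93.3, 152.0, 224.4)))
#' @export
g0_from_series <- function(entries) {
  entries <- as_tibble(entries)
  if (nrow(entries) == 0 || !all(c("n", "g_n") %in% names(entries))) {
    abort("`entries` must be a non-empty data frame with columns `n`, `g_n`.",
          class = "cin2d_parameter_error")
  }
  if (any(entries$g_n <= 0) || any(entries$n < 1)) {
    abort("All extraction barriers must be positive (stable membrane) and n >= 1.",
          class = "cin2d_stability_error")
  }
  out <- dplyr::mutate(entries, per_lipid = .data$g_n / .data$n)
  class(out) <- c("extraction_series", class(out))
  attr(out, "g0") <- min(out$per_lipid)
  attr(out, "argmin_n") <- out$n[which.min(out$per_lipid)]
  out
}

#' @rdname g0_from_series
#' @param x An `extraction_series`.
#' @param ... Unused.
#' @export
glance.extraction_series <- function(x, ...) {
  tibble(g0 = attr(x, "g0"), argmin_n = attr(x, "argmin_n"),
         n_sizes = nrow(x))
}

as_energy_pair <- function(x, x_sd) {
  if (inherits(x, "adsorption_energy")) {
    c(x$value, x$sd)
  } else {
    c(as.double(x), as.double(x_sd))
  }
}

#' The membrane-interaction indicator CIN2D
#'
#' `CIN2D = g_h - g_t`: the free-energy preference of the nanosheet surface
#' for the lipid tail over the lipid head. Uncertainties are propagated as
#' the sum of absolute errors.
#'
#' @param g_h,g_t Adsorption free energies of the head and tail moieties:
#'   either [adsorption_energy()] rows or plain numbers (kJ/mol).
#' @param g_h_sd,g_t_sd Uncertainties when `g_h`/`g_t` are plain numbers.
#' @return A one-row tibble with columns `cin`, `cin_sd` (kJ/mol).
#' @examples
#' cin2d(-20, -115, 3, 12)  # tail-loving sheet: strongly positive
#' @export
cin2d <- function(g_h, g_t, g_h_sd = 0, g_t_sd = 0) {
  h <- as_energy_pair(g_h, g_h_sd)
  t <- as_energy_pair(g_t, g_t_sd)
  if (!all(is.finite(c(h, t)))) {
    abort("Adsorption energies must be finite.", class = "cin2d_parameter_error")
  }
  tibble(cin = h[1] - t[1], cin_sd = h[2] + t[2])
}

#' Classify nanomaterials into membrane-interaction regimes
#'
#' Applies the four-regime decision rules to a table of head/tail
#' adsorption free energies:
#' \itemize{
#'   \item `no_interaction` when `|g_h| + |g_t| < kB * T` (both couplings
#'     below thermal energy);
#'   \item `adsorption` when `CIN2D < 0` (the sheet prefers the head group
#'     and sits on the membrane surface);
#'   \item `insertion` when `0 <= CIN2D < g0` (tail preference, but below
#'     the extraction resistance: the sheet embeds in the bilayer);
#'   \item `lipid_extraction` when `CIN2D >= g0` (tail preference strong
#'     enough to pull lipids out: membrane disruption, the cytotoxic
#'     regime).
#' }
#' Boundary convention: `CIN2D = 0` classifies as insertion and
#' `CIN2D = g0` as lipid_extraction; exact boundary hits are noted.
#' A classification is flagged not confident when the uncertainty interval
#' `[cin - u, cin + u]` straddles a decision boundary (0 or `g0`) or when
#' `u >= |cin|`.
#'
#' @param data A data frame with columns `g_h`, `g_t` (kJ/mol) and
#'   optionally `material`, `g_h_sd`, `g_t_sd` (defaulting to 0).
#' @param g0 Specific lipid-extraction resistance of the target membrane,
#'   kJ/mol (> 0). Default 75, the POPC bilayer at 310 K.
#' @param temperature Temperature in kelvin (> 0), default 310.
#' @return A tibble of class `regime_tbl`: the input plus `cin`, `cin_sd`,
#'   `g0_used`, `temperature`, `regime`, `confident`, `notes`.
#' @examples
#' classify_regime(data.frame(material = "GN", g_h = -14, g_t = -103,
#'                            g_h_sd = 2, g_t_sd = 11))
#' @export
classify_regime <- function(data, g0 = 75, temperature = 310) {
  if (!(is.numeric(g0) && length(g0) == 1 && g0 > 0)) {
    abort("`g0` must be a single positive number.", class = "cin2d_parameter_error")
  }
  if (!(is.numeric(temperature) && length(temperature) == 1 && temperature > 0)) {
    abort("`temperature` must be a single positive number.",
          class = "cin2d_parameter_error")
  }
  data <- as_tibble(data)
  if (!all(c("g_h", "g_t") %in% names(data))) {
    abort("`data` needs columns `g_h` and `g_t`.", class = "cin2d_parameter_error")
  }
  if (!("material" %in% names(data))) {
    data$material <- paste0("material_", seq_len(nrow(data)))
  }
  if (!("g_h_sd" %in% names(data))) data$g_h_sd <- 0
  if (!("g_t_sd" %in% names(data))) data$g_t_sd <- 0

  th <- thermal_energy(temperature)
  out <- dplyr::mutate(
    data,
    cin = .data$g_h - .data$g_t,
    cin_sd = .data$g_h_sd + .data$g_t_sd,
    g0_used = g0,
    temperature = temperature
  )
  decide <- function(g_h, g_t, cin) {
    if (abs(g_h) + abs(g_t) < th) "no_interaction"
    else if (cin < 0) "adsorption"
    else if (cin < g0) "insertion"
    else "lipid_extraction"
  }
  note_for <- function(cin, u) {
    notes <- character(0)
    if (cin == 0) notes <- c(notes, "on CIN2D = 0 boundary; assigned insertion")
    if (cin == g0) notes <- c(notes, "on CIN2D = g0 boundary; assigned lipid_extraction")
    if (u > 0 && cin - u < 0 && 0 < cin + u) {
      notes <- c(notes, "uncertainty straddles CIN2D = 0")
    }
    if (u > 0 && cin - u < g0 && g0 < cin + u) {
      notes <- c(notes, "uncertainty straddles CIN2D = g0")
    }
    if (u > 0 && u >= abs(cin)) {
      notes <- c(notes, "uncertainty exceeds |CIN2D|")
    }
    paste(notes, collapse = "; ")
  }
  out$regime <- factor(
    mapply(decide, out$g_h, out$g_t, out$cin),
    levels = c("no_interaction", "adsorption", "insertion", "lipid_extraction")
  )
  out$notes <- mapply(note_for, out$cin, out$cin_sd)
  boundary <- grepl("straddles|exceeds", out$notes)
  out$confident <- !boundary
  class(out) <- c("regime_tbl", class(out))
  out
}

#' @rdname classify_regime
#' @param x A `regime_tbl`.
#' @param ... Unused.
#' @export
tidy.regime_tbl <- function(x, ...) {
  as_tibble(x)[, c("material", "g_h", "g_h_sd", "g_t", "g_t_sd",
                   "cin", "cin_sd", "regime", "confident", "notes")]
}

#' @rdname classify_regime
#' @export
glance.regime_tbl <- function(x, ...) {
  tibble(
    n_materials = nrow(x),
    n_cytotoxic = sum(x$regime == "lipid_extraction"),
    n_not_confident = sum(!x$confident),
    g0 = x$g0_used[1],
    temperature = x$temperature[1]
  )
}

#' Reference head/tail adsorption free energies for five 2D nanomaterials
#'
#' Literature-reported adsorption free energies (kJ/mol) of the POPC lipid
#' head and tail moieties on six nanosheet models — graphene (GN), graphene
#' oxide (GON), Mg/Al layered double hydroxide, aloohene, and hexagonal
#' boron nitride with two partial-atomic-charge parameterisations — from
#' atomistic bidirectional steered-MD estimates at 310 K, together with the
#' published regime call for each. Useful as a worked example and as a
#' cross-check for [classify_regime()] with the POPC default `g0 = 75`.
#'
#' @return A tibble with columns `material`, `g_h`, `g_h_sd`, `g_t`,
#'   `g_t_sd`, `reported_prediction`.
#' @examples
#' classify_regime(nanosheet_energies())
#' @export
nanosheet_energies <- function() {
  tibble(
    material = c("GN", "GON", "Mg/Al-LDH", "Aloohene",
                 "BNN (PAC +/- 1.05 e)", "BNN (PAC +/- 0.5 e)"),
    g_h = c(-14, -19, -3.5, -5.2, -20, -16),
    g_h_sd = c(2, 4, 1.4, 1.3, 3, 7),
    g_t = c(-103, -30, 0.00, -0.03, -115, -118),
    g_t_sd = c(11, 14, 0.12, 0.05, 12, 4),
    reported_prediction = c("lipid_extraction", "insertion", "adsorption",
                            "adsorption", "lipid_extraction", "lipid_extraction")
  )
}

#' Reference lipid-extraction barrier series for the POPC membrane
#'
#' Extraction barriers `g_N` for groups of N = 1, 2, 3 concatenated POPC
#' lipids pulled out of a hydrated bilayer at 310 K, reconstructed from the
#' reported per-lipid values 93.3, 76.0 and 74.8 kJ/mol. Feeding the series
#' to [g0_from_series()] gives the default `g0` of about 75 kJ/mol.
#'
#' @return A tibble with columns `n`, `g_n`.
#' @examples
#' glance(g0_from_series(popc_extraction_series()))
#' @export
popc_extraction_series <- function() {
  tibble(n = 1:3, g_n = c(93.3, 2 * 76.0, 3 * 74.8))
}
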