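CURVE_SCHEMA <- "cin2d-work-curve/1"
PROFILE_SCHEMA <- "cin2d-profile/1"
REPORT_SCHEMA <- "cin2d-report/1"
DIAGRAM_SCHEMA <- "cin2d-diagram/1"

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a work curve to a columnar text file
#'
#' Work curves are stored as plain columnar text with a commented metadata
#' header (`# key: value` lines) followed by a column header naming
#' `time_ps`, `xi_angstrom` and either `work_kjmol` (work mode) or
#' `force_kjmolA` (spring-force mode; readers reconstruct the work by
#' trapezoidal integration). The `tsv`/`csv` dialects use a tab/comma
#' separated header row; the `lammps` dialect writes a whitespace table
#' with the column names on the last comment line.
#'
#' @param curve A [work_curve()].
#' @param path Output file.
#' @param dialect `"tsv"`, `"csv"` or `"lammps"`.
#' @param mode `"work"` to store accumulated work, `"force"` to store the
#'   instantaneous spring force (available for simulated curves).
#' @return `path`, invisibly.
#' @export
write_work_curve <- function(curve, path, dialect = c("tsv", "csv", "lammps"),
                             mode = c("work", "force")) {
  assert_work_curve(curve)
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (mode == "force" && is.null(attr(curve, "force"))) {
    abort("Curve carries no spring-force samples; write in work mode.",
          class = "cin2d_parse_error")
  }
  meta <- c(
    sprintf("# schema: %s", CURVE_SCHEMA),
    sprintf("# direction: %s", curve_direction(curve)),
    sprintf("# temperature_K: %s", fmt_num(attr(curve, "temperature"))),
    sprintf("# spring_k_kjmolA2: %s", fmt_num(attr(curve, "spring_k"))),
    sprintf("# velocity_Aps: %s", fmt_num(attr(curve, "velocity"))),
    sprintf("# label: %s", attr(curve, "label")),
    sprintf("# mode: %s", mode)
  )
  val_col <- if (mode == "work") "work_kjmol" else "force_kjmolA"
  vals <- if (mode == "work") curve$work else attr(curve, "force")
  cols <- c("time_ps", "xi_angstrom", val_col)
  sep <- switch(dialect, tsv = "\t", csv = ",", lammps = " ")
  header <- if (dialect == "lammps") {
    c(meta, paste("#", paste(cols, collapse = " ")))
  } else {
    c(meta, paste(cols, collapse = sep))
  }
  body <- paste(fmt_num(curve$time), fmt_num(curve$xi), fmt_num(vals),
                sep = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

parse_curve_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", meta_lines))
  kv <- kv[lengths(kv) == 3]
  setNames(vapply(kv, `[`, character(1), 3),
           vapply(kv, `[`, character(1), 2))
}

read_one_curve <- function(path, dialect) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cin2d_parse_error")
  }
  lines <- readLines(path)
  meta <- parse_curve_meta(lines)
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "csv") "csv" else if (ext == "tsv") "tsv" else "lammps"
  }
  n_comment <- sum(grepl("^#", lines))
  if (dialect == "lammps") {
    # column names live on the last comment line
    cols <- strsplit(sub("^#\\s*", "", lines[n_comment]), "\\s+")[[1]]
    dat <- utils::read.table(text = lines[-seq_len(n_comment)],
                             col.names = cols)
  } else {
    sep <- if (dialect == "csv") "," else "\t"
    dat <- utils::read.table(text = lines[-seq_len(n_comment)], sep = sep,
                             header = TRUE)
  }
  need_any <- c("work_kjmol", "force_kjmolA")
  if (!all(c("time_ps", "xi_angstrom") %in% names(dat)) ||
      !any(need_any %in% names(dat))) {
    abort(sprintf(
      "%s: expected columns time_ps, xi_angstrom and work_kjmol or force_kjmolA (got: %s).",
      path, paste(names(dat), collapse = ", ")), class = "cin2d_parse_error")
  }
  direction <- meta[["direction"]]
  if (is.null(direction) || !direction %in% c("adsorption", "desorption")) {
    abort(sprintf("%s: missing or invalid `# direction:` header.", path),
          class = "cin2d_parse_error")
  }
  xi <- dat$xi_angstrom
  bad <- which(sign(diff(xi)) != if (direction == "adsorption") -1 else 1)
  if (length(bad)) {
    abort(sprintf("%s: non-monotone xi_angstrom at data line %d.",
                  path, bad[1] + 1L), class = "cin2d_parse_error")
  }
  if ("work_kjmol" %in% names(dat)) {
    work <- dat$work_kjmol
  } else {
    # spring force recorded instead of work: W(xi) = integral of f d(xi)
    # along the trap path, trapezoidal rule
    work <- pracma::cumtrapz(xi, dat$force_kjmolA)[, 1]
  }
  num_meta <- function(key, default) {
    if (!is.null(meta[key]) && !is.na(meta[key])) as.double(meta[[key]]) else default
  }
  work_curve(
    xi = xi, work = work, direction = direction,
    temperature = num_meta("temperature_K", 310),
    spring_k = num_meta("spring_k_kjmolA2", 1000),
    velocity = num_meta("velocity_Aps", 1e-4),
    time = dat$time_ps,
    label = if (!is.na(meta["label"])) meta[["label"]] else basename(path)
  )
}

#' Read steered-pulling work curves from columnar text files
#'
#' Accepts the dialects written by [write_work_curve()]; files recording
#' the spring force instead of accumulated work are integrated by the
#' trapezoidal rule. Parse failures name the offending file (and line, for
#' monotonicity violations).
#'
#' @param paths Character vector of file paths (globs already expanded).
#' @param dialect `"tsv"`, `"csv"`, `"lammps"`, or `NULL` to infer from
#'   the file extension.
#' @return A list of [work_curve()] objects.
#' @export
read_work_curves <- function(paths, dialect = NULL) {
  if (length(paths) == 0) {
    abort("No input files.", class = "cin2d_parse_error")
  }
  lapply(paths, read_one_curve, dialect = dialect)
}

#' Write a free-energy profile as TSV plus a JSON metadata sidecar
#'
#' @param profile A [free_energy_profile()].
#' @param path Output TSV (`xi`, `dG`, `sd`); the sidecar is written next
#'   to it as `<path>.json` and records the estimator, replicate count and
#'   temperature.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  writeLines(c(
    "xi\tdG\tsd",
    paste(fmt_num(profile$xi), fmt_num(profile$dG), fmt_num(profile$sd),
          sep = "\t")
  ), path)
  jsonlite::write_json(
    list(schema = PROFILE_SCHEMA,
         estimator = attr(profile, "estimator"),
         n_replicates = attr(profile, "n_replicates"),
         temperature_K = attr(profile, "temperature")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a free-energy profile written by [write_profile()]
#' @param path Profile TSV path (sidecar `<path>.json` read when present).
#' @return A [free_energy_profile()].
#' @export
read_profile <- function(path) {
  dat <- utils::read.table(path, sep = "\t", header = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (!is.null(meta$schema) && !identical(meta$schema, PROFILE_SCHEMA)) {
    abort(sprintf("%s: unsupported profile schema `%s`.", sidecar, meta$schema),
          class = "cin2d_parse_error")
  }
  free_energy_profile(
    xi = dat$xi, dG = dat$dG, sd = dat$sd,
    n_replicates = meta$n_replicates %||% 1L,
    estimator = meta$estimator %||% "unknown",
    temperature = meta$temperature_K %||% 310
  )
}

#' Write / read a classification report as JSON
#'
#' The report mirrors the summary table: per material the head and tail
#' adsorption energies with uncertainties, the indicator value, the regime
#' call and the confidence flag. Reports re-validate on read: the regimes
#' are recomputed from the stored energies.
#'
#' @param reports A `regime_tbl` from [classify_regime()].
#' @param path JSON output path.
#' @return `path` invisibly; `read_report_json()` returns a `regime_tbl`.
#' @export
write_report_json <- function(reports, path) {
  stopifnot(inherits(reports, "regime_tbl"))
  materials <- lapply(seq_len(nrow(reports)), function(i) {
    r <- as_tibble(reports)[i, ]
    list(material = r$material,
         g_h = list(value = r$g_h, sd = r$g_h_sd),
         g_t = list(value = r$g_t, sd = r$g_t_sd),
         cin = r$cin, cin_sd = r$cin_sd,
         regime = as.character(r$regime), confident = r$confident,
         notes = r$notes)
  })
  jsonlite::write_json(
    list(schema = REPORT_SCHEMA, g0 = reports$g0_used[1],
         temperature_K = reports$temperature[1], materials = materials),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  j <- jsonlite::read_json(path)
  if (!identical(j$schema, REPORT_SCHEMA)) {
    abort(sprintf("%s: unsupported report schema `%s`.", path, j$schema),
          class = "cin2d_parse_error")
  }
  rows <- purrr::map_dfr(j$materials, function(m) {
    tibble(material = m$material, g_h = m$g_h$value, g_h_sd = m$g_h$sd,
           g_t = m$g_t$value, g_t_sd = m$g_t$sd)
  })
  classify_regime(rows, g0 = j$g0, temperature = j$temperature_K)
}

#' Serialise a phase diagram to JSON
#'
#' @param diagram A `diagram_spec` from [phase_diagram()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_diagram_json <- function(diagram, path) {
  stopifnot(inherits(diagram, "diagram_spec"))
  jsonlite::write_json(
    list(schema = DIAGRAM_SCHEMA, g0 = diagram$g0,
         temperature_K = diagram$temperature,
         bounds = as.list(diagram$bounds),
         boundaries = diagram$boundaries,
         materials = diagram$materials),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
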