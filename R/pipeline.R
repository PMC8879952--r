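#' Configuration for an end-to-end indicator run
#'
#' Bundles everything [run_indicator()] needs: where the head- and
#' tail-moiety work curves live, which profile estimator to use, and the
#' membrane parameters the classification is made against.
#'
#' @param head,tail Character vectors of file paths or globs for the
#'   adsorption/desorption work curves of the lipid head and tail
#'   moieties.
#' @param estimator `"bidirectional"` (default, suited to a handful of
#'   paired pulls) or `"jarzynski"` (needs several same-direction pulls).
#' @param g0 Specific lipid-extraction resistance of the target membrane,
#'   kJ/mol (> 0); default 75 (POPC bilayer, 310 K).
#' @param temperature Temperature, K (> 0).
#' @param outdir Output directory for the report, profiles and diagram.
#' @param dialect Input file dialect, see [read_work_curves()].
#' @param material Label used in the report.
#' @param seed Seed for the bootstrap dispersion of the Jarzynski
#'   estimator.
#' @param bootstrap_replicates Bootstrap replicate count.
#' @return A list of class `run_config`.
#' @export
run_config <- function(head, tail, estimator = c("bidirectional", "jarzynski"),
                       g0 = 75, temperature = 310, outdir = ".",
                       dialect = NULL, material = "material",
                       seed = 1L, bootstrap_replicates = 200L) {
  estimator <- match.arg(estimator)
  if (g0 <= 0 || temperature <= 0) {
    abort("`g0` and `temperature` must be positive.",
          class = "cin2d_config_error")
  }
  if (length(head) == 0 || length(tail) == 0) {
    abort("Both `head` and `tail` inputs are required.",
          class = "cin2d_config_error")
  }
  structure(
    list(head = head, tail = tail, estimator = estimator, g0 = g0,
         temperature = temperature, outdir = outdir, dialect = dialect,
         material = material, seed = as.integer(seed),
         bootstrap_replicates = as.integer(bootstrap_replicates)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of [run_config()] (`head` and
#'   `tail` may be scalars or lists of paths/globs; relative paths are
#'   resolved against the file's directory).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    p <- unlist(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  miss <- setdiff(c("head", "tail"), names(y))
  if (length(miss)) {
    abort(sprintf("Config %s is missing required field(s): %s.", path,
                  paste(miss, collapse = ", ")), class = "cin2d_config_error")
  }
  run_config(
    head = resolve(y$head), tail = resolve(y$tail),
    estimator = y$estimator %||% "bidirectional",
    g0 = y$g0 %||% 75, temperature = y$temperature %||% 310,
    outdir = if (!is.null(y$outdir)) resolve(y$outdir) else base,
    dialect = y$dialect, material = y$material %||% "material",
    seed = y$seed %||% 1L,
    bootstrap_replicates = y$bootstrap_replicates %||% 200L
  )
}

expand_inputs <- function(patterns, what) {
  paths <- unlist(lapply(patterns, function(p) {
    if (file.exists(p)) p else Sys.glob(p)
  }))
  if (length(paths) == 0) {
    abort(sprintf("No %s-moiety input files match: %s.", what,
                  paste(patterns, collapse = ", ")),
          class = "cin2d_config_error")
  }
  paths
}

estimate_profile <- function(curves, config) {
  switch(config$estimator,
         bidirectional = pmf_bidirectional(curves),
         jarzynski = pmf_jarzynski(curves, temperature = config$temperature,
                                   n_boot = config$bootstrap_replicates,
                                   seed = config$seed))
}

#' Run the full indicator pipeline
#'
#' Reads the head- and tail-moiety work-curve sets, estimates both
#' free-energy profiles, extracts the adsorption energies `g_h` and `g_t`,
#' computes the indicator `CIN2D = g_h - g_t`, classifies the material
#' against `g0`, and writes the outputs into `config$outdir`:
#' `report.json`, `profile_head.tsv`(+sidecar), `profile_tail.tsv`, and
#' `diagram.json`.
#'
#' @param config A [run_config()] (or the path of a YAML file for
#'   [read_run_config()]).
#' @return The one-row `regime_tbl` for the material, with the two
#'   profiles attached as attributes `profile_head` and `profile_tail`.
#' @export
run_indicator <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  head_paths <- expand_inputs(config$head, "head")
  tail_paths <- expand_inputs(config$tail, "tail")

  head_curves <- read_work_curves(head_paths, dialect = config$dialect)
  tail_curves <- read_work_curves(tail_paths, dialect = config$dialect)
  prof_h <- estimate_profile(head_curves, config)
  prof_t <- estimate_profile(tail_curves, config)
  g_h <- adsorption_energy(prof_h, "head")
  g_t <- adsorption_energy(prof_t, "tail")

  energies <- tibble(material = config$material)
  energies$g_h <- g_h$value
  energies$g_h_sd <- g_h$sd
  energies$g_t <- g_t$value
  energies$g_t_sd <- g_t$sd
  report <- classify_regime(
    energies,
    g0 = config$g0, temperature = config$temperature
  )

  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  write_profile(prof_h, file.path(config$outdir, "profile_head.tsv"))
  write_profile(prof_t, file.path(config$outdir, "profile_tail.tsv"))
  write_report_json(report, file.path(config$outdir, "report.json"))
  write_diagram_json(
    phase_diagram(report, g0 = config$g0, temperature = config$temperature),
    file.path(config$outdir, "diagram.json")
  )
  attr(report, "profile_head") <- prof_h
  attr(report, "profile_tail") <- prof_t
  report
}
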