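#' Write a line scan as TSV
#'
#' Columns `position_um, counts_ca, counts_f, counts_cu, charge`, tab
#' separated with a header; the lossless on-disk dialect of [linescan()].
#'
#' @param scan A [linescan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_linescan <- function(scan, path) {
  stopifnot(inherits(scan, "linescan"))
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

.linescan_cols <- c("position_um", "counts_ca", "counts_f", "counts_cu",
                    "charge")

#' Read a line scan from TSV
#'
#' Validates the header, cell types, and strict monotonicity of positions;
#' malformed rows are reported with their file line numbers.
#'
#' @param path TSV file with the [write_linescan()] layout.
#' @return A [linescan()].
#' @export
read_linescan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (nrow(raw) == 0) stop("empty input: no data rows in ", path)
  miss <- setdiff(.linescan_cols, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  num <- lapply(.linescan_cols, function(cl) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]))
    if (length(bad))
      stop(sprintf("non-numeric cell in column '%s' at line %d", cl,
                   bad[1] + 1L))  # +1 for the header line
    v
  })
  names(num) <- .linescan_cols
  nonmono <- which(diff(num$position_um) <= 0)
  if (length(nonmono))
    stop(sprintf("positions not strictly increasing at line %d",
                 nonmono[1] + 2L))  # offending row, 1 header + next row
  linescan(num$position_um, num$counts_ca, num$counts_f, num$counts_cu,
           num$charge)
}

#' Write / read a depth profile as TSV
#'
#' @param profile A [depth_profile()].
#' @param path File path.
#' @return `write_profile`: `path` invisibly; `read_profile`: a
#'   [depth_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param element,unit Labels restored on read.
#' @export
read_profile <- function(path, element = "", unit = "") {
  d <- utils::read.delim(path)
  if (!all(c("position_um", "value") %in% names(d)))
    stop("profile file needs columns position_um, value")
  depth_profile(d$position_um, d$value, element = element, unit = unit)
}

#' Write a registered pair as aligned-profile TSV plus a registration report
#'
#' The TSV has columns `position_um, ca_before, ca_after, f_before, f_after,
#' missing_after`; the optional JSON report records both fiducial fixes and
#' the applied shift.
#'
#' @param pair A [superimpose()] result.
#' @param path Output TSV path.
#' @param report_path Optional JSON path for the registration report.
#' @return `path`, invisibly.
#' @export
write_sequential_pair <- function(pair, path, report_path = NULL) {
  stopifnot(inherits(pair, "sequential_pair"))
  df <- data.frame(position_um = pair$grid,
                   ca_before = pair$ca_before, ca_after = pair$ca_after,
                   f_before = pair$f_before, f_after = pair$f_after,
                   missing_after = pair$missing_after)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report_path))
    .write_json(list(applied_shift = pair$applied_shift,
                     ref_pos = pair$ref_pos,
                     fiducial_before = unclass(pair$fiducial_before),
                     fiducial_after = unclass(pair$fiducial_after)),
                report_path)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' Serialize / restore a calibration curve as JSON
#' @param curve A [fit_calibration()] result.
#' @param path JSON file path.
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  .write_json(unclass(curve), path)
}

#' @rdname write_calibration_curve
#' @export
read_calibration_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$references_used <- as.data.frame(x$references_used)
  structure(x[c("kind", "slope", "intercept", "quad", "degree", "r_squared",
                "references_used")], class = "calibration_curve")
}

#' Serialize / restore a cohort report as JSON
#'
#' The report round-trips: `read_cohort_report(write_cohort_report(r, p))`
#' reproduces `r` up to numeric representation.
#'
#' @param report A [cohort_report()] result.
#' @param path JSON file path.
#' @export
write_cohort_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  x <- unclass(report)
  x$comparisons <- lapply(x$comparisons, unclass)
  x$correlations <- lapply(x$correlations, unclass)
  .write_json(x, path)
}

#' @rdname write_calibration_curve
#' @export
read_cohort_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  fix_na <- function(l) lapply(l, function(v) if (is.null(v)) NA else v)
  x$summaries <- as.data.frame(x$summaries)
  x$comparisons <- lapply(seq_len(nrow(x$comparisons)), function(i) {
    structure(fix_na(as.list(x$comparisons[i, ])), class = "group_comparison")
  })
  x$correlations <- lapply(seq_len(nrow(x$correlations)), function(i) {
    structure(fix_na(as.list(x$correlations[i, ])),
              class = "correlation_result")
  })
  structure(x, class = "cohort_report")
}

# match arguments of a constructor against a named list, rejecting unknowns
.apply_config <- function(fn, args, what) {
  if (is.null(args)) args <- list()
  unknown <- setdiff(names(args), names(formals(fn)))
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", what,
                 paste(unknown, collapse = ", ")))
  do.call(fn, args)
}

#' Assemble and validate a pipeline configuration
#'
#' Bundles the cohort design, beam model, analysis settings and the micro-CT
#' scanner model into one validated object.  Unknown keys in any section are
#' rejected with the offending names.
#'
#' @param cohort Named list of [cohort_spec()] arguments (or a `cohort_spec`).
#' @param beam Named list of [beam_config()] arguments (or a `beam_config`).
#' @param analysis Named list of [analysis_config()] arguments (or an
#'   `analysis_config`).
#' @param uct Named list of micro-CT scanner model settings (`gain`,
#'   `intercept`, `noise_sd`, `step`).
#' @param seed Master seed of the run.
#' @param quiet Suppress progress logging.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), beam = list(), analysis = list(),
                            uct = list(), seed = 1, quiet = FALSE) {
  cohort <- if (inherits(cohort, "cohort_spec")) cohort
            else .apply_config(cohort_spec, cohort, "cohort")
  beam <- if (inherits(beam, "beam_config")) beam
          else .apply_config(beam_config, beam, "beam")
  analysis <- if (inherits(analysis, "analysis_config")) analysis
              else .apply_config(analysis_config, analysis, "analysis")
  uct_defaults <- list(gain = 2, intercept = 100, noise_sd = 5, step = 8.1)
  unknown <- setdiff(names(uct), names(uct_defaults))
  if (length(unknown))
    stop("unknown uct key(s): ", paste(unknown, collapse = ", "))
  uct <- utils::modifyList(uct_defaults, uct)
  structure(list(cohort = cohort, beam = beam, analysis = analysis,
                 uct = uct, seed = seed, quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Top-level keys other than `cohort`, `beam`, `analysis`, `uct`, `seed`,
#' `quiet` are rejected, as are unknown keys within each section.
#'
#' @param path JSON file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("cohort", "beam", "analysis", "uct", "seed", "quiet")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  # c(mean, sd) pairs arrive as length-2 vectors already
  do.call(pipeline_config, x)
}

.log_stage <- function(quiet, fmt, ...) {
  if (!quiet)
    message(sprintf("[seqpixe %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

#' Run the end-to-end pipeline
#'
#' simulate -> calibrate -> register -> metrics -> cohort statistics, writing
#' every artifact under `out_dir`: per-specimen scan TSVs and ground-truth
#' JSON sidecars, the three fitted calibration curves, the per-specimen
#' metrics CSV, the cohort report JSON, and the full configuration (with
#' seed) for provenance.  The run is a pure function of `(config, seed)`:
#' repeating it reproduces every artifact byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; defaults to `config$seed`.
#' @return Invisibly, a list: `report` ([cohort_report()]), `metrics`
#'   (data.frame), `curves`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = config$seed) {
  stopifnot(inherits(config, "pipeline_config"))
  quiet <- config$quiet
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "scans"), showWarnings = FALSE)
  t0 <- Sys.time()

  .log_stage(quiet, "simulating cohort of %d tooth pairs (seed %s)",
             config$cohort$n_pairs, format(seed))
  beam <- config$beam
  cohort <- generate_cohort(config$cohort, beam, seed = seed,
                            uct_args = config$uct)

  .log_stage(quiet, "calibrating PIGE-F, PIXE-Ca and uCT density")
  # F: the fluoridated-apatite series spans 0 - 3.77 wt% F.  Ca: the same
  # series is nearly constant in Ca (39.7 - 39.9 wt%), an ill-conditioned
  # design, so the Ca channel uses a synthetic dilution series instead.
  xs <- c(0, 0.25, 0.5, 0.75, 1)
  ca_levels <- seq(0, 40, by = 10)
  ref_seeds <- with_local_seed(seed + 1L,
                               sample.int(.Machine$integer.max - 1L, 3L))
  refs_f <- simulate_reference_yields(reference_f_content(xs) * 1e4,
                                      yield = beam$yield_f,
                                      background = beam$background_f,
                                      charge = 1000, seed = ref_seeds[1])
  refs_ca <- simulate_reference_yields(ca_levels,
                                       yield = beam$yield_ca,
                                       background = beam$background_ca,
                                       charge = 1000, seed = ref_seeds[2])
  dens <- c(100, 200, 300, 400, 1550)
  phantoms <- with_local_seed(ref_seeds[3], data.frame(
    density = dens,
    grey = config$uct$gain * dens + config$uct$intercept +
      stats::rnorm(length(dens), 0, config$uct$noise_sd / sqrt(100))))
  curves <- list(f = fit_calibration(refs_f, "pige_f"),
                 ca = fit_calibration(refs_ca, "pixe_ca"),
                 uct = fit_calibration(phantoms, "uct_density"))
  for (nm in names(curves))
    write_calibration_curve(curves[[nm]],
                            file.path(out_dir, paste0("curve_", nm, ".json")))

  .log_stage(quiet, "writing scans and analyzing %d specimens",
             2L * config$cohort$n_pairs)
  for (tooth in cohort) {
    for (g in c("fcm", "control")) {
      sp <- tooth[[g]]
      base <- file.path(out_dir, "scans", paste0(tooth$tooth_id, "_", g))
      for (when in c("before", "after"))
        for (k in seq_along(sp$scans[[when]]))
          write_linescan(sp$scans[[when]][[k]],
                         sprintf("%s_%s_line%d.tsv", base, when, k))
      .write_json(unclass(sp$truth), paste0(base, "_truth.json"))
    }
  }
  metrics <- cohort_metrics(cohort, curves, config$analysis)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)

  .log_stage(quiet, "cohort statistics")
  report <- cohort_report(metrics)
  if (report$underpowered)
    .log_stage(quiet, "WARNING: a group has < 2 specimens; tests skipped")
  write_cohort_report(report, file.path(out_dir, "report.json"))
  prov <- list(seed = seed,
               cohort = unclass(config$cohort),
               beam = unclass(config$beam),
               analysis = unclass(config$analysis), uct = config$uct)
  .write_json(prov, file.path(out_dir, "config.json"))
  .log_stage(quiet, "done in %.1f s",
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(report = report, metrics = metrics, curves = curves,
                 out_dir = out_dir))
}
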