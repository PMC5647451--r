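# IUPAC 2021 standard atomic weights
.atomic_mass <- c(Ca = 40.078, P = 30.973761998, O = 15.999, H = 1.008,
                  F = 18.998403163)

# Formula mass of Ca10(PO4)6(OH)(2-2x)F(2x)
.apatite_mass <- function(x) {
  m <- .atomic_mass
  10 * m[["Ca"]] + 6 * (m[["P"]] + 4 * m[["O"]]) +
    (2 - 2 * x) * (m[["O"]] + m[["H"]]) + 2 * x * m[["F"]]
}

#' Stoichiometric fluorine content of fluoridated hydroxyapatite
#'
#' Mass fraction of fluorine in Ca10(PO4)6(OH)(2-2x)F(2x), the reference
#' series used to calibrate the PIGE gamma yield.  `x = 0` is hydroxyapatite
#' (0 wt\% F); `x = 1` is fluorapatite (about 3.77 wt\% F).
#'
#' @param x Fluoridation fraction(s) in `[0, 1]`.
#' @return Fluorine content in wt\%, strictly increasing in `x`.
#' @export
reference_f_content <- function(x) {
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
  100 * (2 * x * .atomic_mass[["F"]]) / .apatite_mass(x)
}

#' Stoichiometric calcium content of fluoridated hydroxyapatite
#'
#' Companion to [reference_f_content()]: the Ca mass fraction of the same
#' apatite series, used when the PIXE Ca channel is calibrated against the
#' identical reference disks.
#'
#' @inheritParams reference_f_content
#' @return Calcium content in wt\%.
#' @export
reference_ca_content <- function(x) {
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
  100 * (10 * .atomic_mass[["Ca"]]) / .apatite_mass(x)
}

#' Fit a linear calibration curve
#'
#' Least-squares fit of `yield = slope * concentration + intercept` (for the
#' micro-CT case: `grey = slope * density + intercept`).  Linearity is the
#' default because PIXE/PIGE yield is first-order proportional to
#' concentration; `degree = 2` adds a quadratic term for curvature checks.
#'
#' @param references A `data.frame` with a concentration column
#'   (`concentration` or `density`) and a response column (`measured_yield`
#'   or `grey`); at least 2 rows with distinct concentrations.
#' @param kind `"pige_f"`, `"pixe_ca"`, or `"uct_density"`.
#' @param degree 1 (linear, default) or 2 (quadratic).
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, the references used, and (for `degree = 2`) `quad`.
#' @export
fit_calibration <- function(references,
                            kind = c("pige_f", "pixe_ca", "uct_density"),
                            degree = 1) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(references), degree %in% c(1, 2))
  conc_col <- intersect(c("concentration", "density", "x"),
                        names(references))[1]
  resp_col <- intersect(c("measured_yield", "grey", "yield"),
                        names(references))[1]
  if (is.na(conc_col) || is.na(resp_col))
    stop("references need a concentration/density and a yield/grey column")
  conc <- references[[conc_col]]
  resp <- references[[resp_col]]
  if (length(conc) < 2L) stop("need at least 2 references")
  if (length(unique(conc)) < degree + 1L)
    stop("degenerate design: references must span at least ",
         degree + 1L, " distinct concentrations")
  fit <- if (degree == 1) stats::lm(resp ~ conc)
         else stats::lm(resp ~ conc + I(conc^2))
  cf <- stats::coef(fit)
  r2 <- {
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((resp - mean(resp))^2)
    if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  }
  slope <- unname(cf[2])
  if (slope <= 0)
    warning("fitted slope is not positive; curve is not usable for inversion")
  structure(list(
    kind = kind, slope = slope, intercept = unname(cf[1]),
    quad = if (degree == 2) unname(cf[3]) else 0,
    degree = degree, r_squared = r2,
    references_used = data.frame(concentration = conc, response = resp)
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve [%s]\n", x$kind))
  eq <- if (x$degree == 2)
    sprintf("yield = %.6g + %.6g*c + %.6g*c^2", x$intercept, x$slope, x$quad)
  else sprintf("yield = %.6g + %.6g * concentration", x$intercept, x$slope)
  cat("  ", eq, "\n", sep = "")
  cat(sprintf("  r-squared %.6f on %d references\n",
              x$r_squared, nrow(x$references_used)))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  if (object$degree == 2)
    c(intercept = object$intercept, slope = object$slope, quad = object$quad)
  else c(intercept = object$intercept, slope = object$slope)
}

#' Predicted yield at given concentrations
#' @param object A `calibration_curve`.
#' @param concentration Concentrations at which to predict the response.
#' @param ... Unused.
#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  object$intercept + object$slope * concentration +
    object$quad * concentration^2
}

# Invert the curve: response (per unit charge) -> concentration.
.invert_curve <- function(curve, y) {
  if (curve$degree == 1) return((y - curve$intercept) / curve$slope)
  a <- curve$quad; b <- curve$slope; cc <- curve$intercept - y
  disc <- pmax(b^2 - 4 * a * cc, 0)
  (-b + sqrt(disc)) / (2 * a)  # branch increasing at the origin for a small
}

#' Convert a raw line scan to a concentration-depth profile
#'
#' Applies the inverse of a fitted calibration curve to one channel of a line
#' scan: `concentration = ((counts / charge) - intercept) / slope`.  Negative
#' results are floored at 0 by default (counts below background cannot mean
#' negative concentration; the floor biases near-zero fluorine slightly
#' upward and can be disabled).
#'
#' @param scan A [linescan()] (or, for `channel = "grey"`, a grey-value
#'   [depth_profile()]).
#' @param curve A [fit_calibration()] result whose `kind` matches the
#'   channel (`pixe_ca`/`ca`, `pige_f`/`f`, `uct_density`/`grey`).
#' @param channel `"ca"`, `"f"`, or `"grey"`.
#' @param floor_zero Floor negative concentrations at 0 (default `TRUE`).
#' @return A [depth_profile()] in the channel's concentration unit.
#' @export
apply_calibration <- function(scan, curve, channel = c("ca", "f", "grey"),
                              floor_zero = TRUE) {
  channel <- match.arg(channel)
  stopifnot(inherits(curve, "calibration_curve"))
  expected <- c(ca = "pixe_ca", f = "pige_f", grey = "uct_density")[[channel]]
  if (curve$kind != expected)
    stop(sprintf("curve kind '%s' does not match channel '%s' (need '%s')",
                 curve$kind, channel, expected))
  if (channel == "grey") {
    stopifnot(inherits(scan, "depth_profile"))
    y <- scan$value
    pos <- scan$position_um
  } else {
    stopifnot(inherits(scan, "linescan"))
    bad <- which(scan$charge <= 0)
    if (length(bad))
      stop(sprintf("non-positive charge at position %.6g um",
                   scan$position_um[bad[1]]))
    y <- scan[[paste0("counts_", channel)]] / scan$charge
    pos <- scan$position_um
  }
  conc <- .invert_curve(curve, y)
  if (floor_zero) conc <- pmax(conc, 0)
  info <- switch(channel,
                 ca = c("Ca", "wt%"), f = c("F", "ppm"),
                 grey = c("density", "mg/cm3"))
  depth_profile(pos, conc, element = info[1], unit = info[2])
}

#' Detection limit implied by a fluorine calibration curve
#'
#' Concentration equivalent of `k` Poisson standard deviations of the
#' background above zero: `k * sqrt(background_counts) / (slope * charge)`,
#' with the background counts taken from the curve intercept (counts per unit
#' charge at zero concentration).
#'
#' @param curve A `pige_f` [fit_calibration()] result.
#' @param charge Accumulated charge per scan point.
#' @param k Number of standard deviations (default 3).
#' @return Detection limit in ppm F.
#' @export
derive_f_lod <- function(curve, charge, k = 3) {
  stopifnot(inherits(curve, "calibration_curve"), curve$kind == "pige_f")
  bg_counts <- max(curve$intercept, 0) * charge
  k * sqrt(bg_counts) / (curve$slope * charge)
}
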