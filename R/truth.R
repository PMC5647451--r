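#' Ground-truth description of one root-dentin specimen
#'
#' A `specimen_truth` object holds the noise-free state of a single exposed
#' root-dentin specimen: the calcium content of sound dentin, the shape of the
#' demineralized lesion produced by the acid challenge (surface erosion plus a
#' sigmoid ramp back to sound dentin), and the fluorine uptake profile left by
#' a fluoride-containing material (FCM), modelled as an exponential decay from
#' the exposed surface.  Depth `z` is measured in micrometres from the
#' original (pre-demineralization) outer edge of the dentin; the copper
#' fiducial foil sits at `fiducial_pos` micrometres from that edge.
#'
#' @param ca_sound Calcium content of intact dentin (wt\%).
#' @param ca_surface_after Calcium content at the lesion surface after
#'   demineralization (wt\%); must lie in `[0, ca_sound]`.
#' @param lesion_mid Sigmoid midpoint of the lesion ramp, measured from the
#'   receded surface (µm).
#' @param lesion_width Sigmoid width of the lesion ramp (µm), > 0.
#' @param erosion Surface recession caused by demineralization (µm); dentin
#'   at `z < erosion` is gone after the acid challenge.
#' @param f_amplitude Fluorine concentration at the surface (ppm F);
#'   effectively 0 for control specimens.
#' @param f_decay Exponential decay length of the fluorine profile before
#'   demineralization (µm), > 0.
#' @param f_depth_gain Multiplier (>= 1) applied to `f_decay` after
#'   demineralization; fluorine penetrates deeper through the porous lesion.
#' @param f_background Trace fluorine level of dentin itself (ppm), added to
#'   the uptake profile.
#' @param group `"FCM"` (treated) or `"control"`.
#' @param fiducial_pos Position of the Cu foil centre, µm from the outer edge.
#'
#' @return An object of class `specimen_truth` (a validated named list).
#' @seealso [true_ca_profile()], [true_f_profile()], [simulate_linescan()]
#' @export
specimen_truth <- function(ca_sound = 27,
                           ca_surface_after = 8,
                           lesion_mid = 45,
                           lesion_width = 15,
                           erosion = 10,
                           f_amplitude = 0,
                           f_decay = 40,
                           f_depth_gain = 1.8,
                           f_background = 0,
                           group = c("control", "FCM"),
                           fiducial_pos = 800) {
  group <- match.arg(group)
  stopifnot(is.numeric(ca_sound), length(ca_sound) == 1L, ca_sound > 0)
  if (!(ca_surface_after >= 0 && ca_surface_after <= ca_sound))
    stop("'ca_surface_after' must lie in [0, ca_sound]")
  if (lesion_width <= 0) stop("'lesion_width' must be > 0")
  if (f_amplitude < 0) stop("'f_amplitude' must be >= 0")
  if (f_decay <= 0) stop("'f_decay' must be > 0")
  if (f_depth_gain < 1) stop("'f_depth_gain' must be >= 1")
  if (erosion < 0) stop("'erosion' must be >= 0")
  if (f_background < 0) stop("'f_background' must be >= 0")
  if (fiducial_pos <= 0) stop("'fiducial_pos' must be > 0")
  structure(list(
    ca_sound = ca_sound, ca_surface_after = ca_surface_after,
    lesion_mid = lesion_mid, lesion_width = lesion_width,
    erosion = erosion, f_amplitude = f_amplitude, f_decay = f_decay,
    f_depth_gain = f_depth_gain, f_background = f_background,
    group = group, fiducial_pos = fiducial_pos
  ), class = "specimen_truth")
}

#' @export
print.specimen_truth <- function(x, ...) {
  cat(sprintf("Specimen truth (%s group)\n", x$group))
  cat(sprintf("  Ca sound %.1f wt%%, surface after DM %.1f wt%%\n",
              x$ca_sound, x$ca_surface_after))
  cat(sprintf("  lesion: erosion %.1f um, midpoint %.1f um, width %.1f um\n",
              x$erosion, x$lesion_mid, x$lesion_width))
  cat(sprintf("  fluorine: F0 %.0f ppm, decay %.1f um (x%.2f after DM)\n",
              x$f_amplitude, x$f_decay, x$f_depth_gain))
  cat(sprintf("  Cu fiducial at %.0f um from outer edge\n", x$fiducial_pos))
  invisible(x)
}

#' Noise-free calcium concentration at depth
#'
#' Before demineralization the profile is flat at `ca_sound`.  After
#' demineralization, material shallower than `erosion` is gone (0 wt\%) and
#' the remaining profile ramps sigmoidally from `ca_surface_after` at the
#' receded surface back to `ca_sound` in sound dentin:
#' `ca_surface_after + (ca_sound - ca_surface_after) *
#'  plogis((z - erosion - lesion_mid) / lesion_width)`.
#'
#' @param truth A [specimen_truth()] object.
#' @param when `"before"` or `"after"` demineralization.
#' @param z Depth(s) from the original outer edge (µm), `z >= 0`.
#' @return Numeric vector of Ca concentrations (wt\%), same length as `z`.
#' @export
true_ca_profile <- function(truth, when = c("before", "after"), z) {
  when <- match.arg(when)
  stopifnot(inherits(truth, "specimen_truth"), all(z >= 0))
  if (when == "before") return(rep_len(truth$ca_sound, length(z)))
  out <- truth$ca_surface_after + (truth$ca_sound - truth$ca_surface_after) *
    stats::plogis((z - truth$erosion - truth$lesion_mid) / truth$lesion_width)
  out[z < truth$erosion] <- 0
  out
}

#' Noise-free fluorine concentration at depth
#'
#' `f_amplitude * exp(-z / lambda) + f_background`, where `lambda = f_decay`
#' before demineralization and `f_decay * f_depth_gain` after.  After
#' demineralization the eroded region (`z < erosion`) carries no material and
#' returns 0.
#'
#' @inheritParams true_ca_profile
#' @return Numeric vector of F concentrations (ppm), same length as `z`.
#' @export
true_f_profile <- function(truth, when = c("before", "after"), z) {
  when <- match.arg(when)
  stopifnot(inherits(truth, "specimen_truth"), all(z >= 0))
  lambda <- truth$f_decay * if (when == "after") truth$f_depth_gain else 1
  out <- truth$f_amplitude * exp(-z / lambda) + truth$f_background
  if (when == "after") out[z < truth$erosion] <- 0
  out
}

# int_a^b (1 - plogis((z - m0)/w)) dz in closed form (softplus antiderivative)
.sigmoid_deficit <- function(a, b, m0, w) {
  sp <- function(u) ifelse(u > 30, u, log1p(exp(u)))  # softplus, overflow-safe
  w * (sp(-(a - m0) / w) - sp(-(b - m0) / w))
}

#' Analytic Ca loss implied by a specimen truth
#'
#' Closed-form depth integral of `before - after` calcium from the original
#' outer edge (`z = 0`) to the reference depth, in wt\%·µm.  Used as the
#' ground-truth value that the measured Ca loss estimates.
#'
#' @param truth A [specimen_truth()] object.
#' @param ref Upper integration limit (µm); defaults to the fiducial depth.
#' @return Ca loss in wt\%·µm.
#' @export
true_ca_loss <- function(truth, ref = truth$fiducial_pos) {
  stopifnot(inherits(truth, "specimen_truth"), ref > truth$erosion)
  with(truth, {
    eroded <- ca_sound * erosion
    ramp <- (ca_sound - ca_surface_after) *
      .sigmoid_deficit(erosion, ref, erosion + lesion_mid, lesion_width)
    eroded + ramp
  })
}

#' Analytic F uptake implied by a specimen truth
#'
#' Depth integral of the noise-free fluorine profile from the (possibly
#' receded) surface to the reference depth, in ppmF·µm.
#'
#' @inheritParams true_ca_loss
#' @param when `"before"` or `"after"` demineralization.
#' @return F uptake in ppmF·µm.
#' @export
true_f_uptake <- function(truth, when = c("before", "after"),
                          ref = truth$fiducial_pos) {
  when <- match.arg(when)
  stopifnot(inherits(truth, "specimen_truth"))
  lambda <- truth$f_decay * if (when == "after") truth$f_depth_gain else 1
  a <- if (when == "after") truth$erosion else 0
  truth$f_amplitude * lambda * (exp(-a / lambda) - exp(-ref / lambda)) +
    truth$f_background * (ref - a)
}

#' Proton-beam and detector configuration for the line-scan simulator
#'
#' Collects scan geometry and linear-yield detector response used by
#' [simulate_linescan()].  Counts in each channel are Poisson with mean
#' `yield * concentration * charge + background`; the Cu fiducial channel
#' responds through the overlap of a Gaussian beam spot with the 4 µm foil.
#'
#' @param step Distance between scan points (µm), > 0.
#' @param spot_fwhm Beam-spot full width at half maximum (µm), > 0.
#' @param charge_per_point Accumulated charge per scan point (arbitrary
#'   charge units).
#' @param yield_ca Ca K-alpha X-ray yield, counts per (wt\% · charge unit).
#' @param yield_f Fluorine gamma yield, counts per (ppm · charge unit).
#' @param yield_cu Cu channel yield, counts per charge unit with the beam
#'   fully on the foil.
#' @param background_ca,background_f,background_cu Mean background counts per
#'   scan point in each channel.
#' @param edge_pos Stage position of the dentin outer edge at zero offset
#'   (µm); scan points below it see air.
#' @param scan_length Length of the scanned line (µm).
#' @param foil_width Thickness of the Cu fiducial foil (µm).
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(step = 10, spot_fwhm = 10, charge_per_point = 1,
                        yield_ca = 50, yield_f = 0.2, yield_cu = 500,
                        background_ca = 5, background_f = 4,
                        background_cu = 2,
                        edge_pos = 100, scan_length = 1000, foil_width = 4) {
  if (step <= 0) stop("'step' must be > 0")
  if (spot_fwhm <= 0) stop("'spot_fwhm' must be > 0")
  if (charge_per_point <= 0) stop("'charge_per_point' must be > 0")
  yields <- c(yield_ca, yield_f, yield_cu)
  if (any(yields < 0)) stop("yields must be >= 0")
  if (any(c(background_ca, background_f, background_cu) < 0))
    stop("backgrounds must be >= 0")
  if (scan_length <= 0 || foil_width <= 0)
    stop("'scan_length' and 'foil_width' must be > 0")
  structure(list(
    step = step, spot_fwhm = spot_fwhm, charge_per_point = charge_per_point,
    yield_ca = yield_ca, yield_f = yield_f, yield_cu = yield_cu,
    background_ca = background_ca, background_f = background_f,
    background_cu = background_cu, edge_pos = edge_pos,
    scan_length = scan_length, foil_width = foil_width
  ), class = "beam_config")
}

#' @export
print.beam_config <- function(x, ...) {
  cat("Beam configuration\n")
  cat(sprintf("  step %.1f um, spot FWHM %.1f um, charge/point %.2f\n",
              x$step, x$spot_fwhm, x$charge_per_point))
  cat(sprintf("  yields (Ca/F/Cu): %.2f, %.3f, %.1f; backgrounds: %.1f, %.1f, %.1f\n",
              x$yield_ca, x$yield_f, x$yield_cu,
              x$background_ca, x$background_f, x$background_cu))
  cat(sprintf("  edge at %.0f um, scan length %.0f um, foil %.1f um\n",
              x$edge_pos, x$scan_length, x$foil_width))
  invisible(x)
}

# Run expr with a temporarily-seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
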