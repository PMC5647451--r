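#' Construct a line-scan record
#'
#' The instrument-facing record: per-position raw channel counts and the
#' accumulated charge.  Positions are stage coordinates in µm and must be
#' strictly increasing.
#'
#' @param position_um Strictly increasing scan positions (µm).
#' @param counts_ca,counts_f,counts_cu Non-negative channel counts.
#' @param charge Positive accumulated charge per point.
#' @return A `data.frame` of class `linescan`.
#' @export
linescan <- function(position_um, counts_ca, counts_f, counts_cu, charge) {
  n <- length(position_um)
  stopifnot(length(counts_ca) == n, length(counts_f) == n,
            length(counts_cu) == n, length(charge) == n, n > 0)
  if (any(diff(position_um) <= 0))
    stop("positions must be strictly increasing")
  if (any(c(counts_ca, counts_f, counts_cu) < 0))
    stop("counts must be >= 0")
  structure(
    data.frame(position_um = position_um, counts_ca = counts_ca,
               counts_f = counts_f, counts_cu = counts_cu, charge = charge),
    class = c("linescan", "data.frame"))
}

#' A calibrated concentration-depth profile
#'
#' @param position_um Positions (µm), increasing.
#' @param value Concentrations (or densities / grey values).
#' @param element Label, e.g. `"Ca"`, `"F"`, `"density"`.
#' @param unit Unit string, e.g. `"wt%"`, `"ppm"`, `"mg/cm3"`.
#' @return A `data.frame` of class `depth_profile` with `element` and `unit`
#'   attributes.
#' @export
depth_profile <- function(position_um, value, element = "", unit = "") {
  stopifnot(length(position_um) == length(value), length(value) > 0)
  structure(
    data.frame(position_um = position_um, value = value),
    element = element, unit = unit,
    class = c("depth_profile", "data.frame"))
}

# Fraction of a Gaussian beam spot (FWHM -> sd) overlapping the foil top-hat.
.foil_overlap <- function(pos, centre, foil_width, spot_fwhm) {
  sdev <- spot_fwhm / (2 * sqrt(2 * log(2)))
  stats::pnorm((pos - centre + foil_width / 2) / sdev) -
    stats::pnorm((pos - centre - foil_width / 2) / sdev)
}

#' Simulate one PIXE/PIGE line scan
#'
#' Realizes a line scan of a specimen at stage positions
#' `seq(0, scan_length, by = step)`.  Depth below the dentin surface is
#' `z = position - edge_pos - offset`; points with `z < 0` see air (background
#' only).  Channel counts are Poisson with mean
#' `yield * concentration * charge + background`; the Cu channel mean is
#' elevated by the Gaussian-spot / 4 µm-foil overlap at the fiducial.  With
#' `noise = "none"` the counts equal their means exactly (variance
#' suppressed), which makes the calibration round trip exact.
#'
#' @param truth A [specimen_truth()].
#' @param beam A [beam_config()].
#' @param when `"before"` or `"after"` demineralization.
#' @param offset Rigid stage offset of this scan (µm).
#' @param seed Optional integer; fixes the Poisson stream without disturbing
#'   the caller's RNG.
#' @param noise `"poisson"` (default) or `"none"` (noise-free mode).
#' @return A [linescan()].
#' @export
simulate_linescan <- function(truth, beam, when = c("before", "after"),
                              offset = 0, seed = NULL,
                              noise = c("poisson", "none")) {
  when <- match.arg(when)
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "specimen_truth"), inherits(beam, "beam_config"))
  if (beam$step <= 0) stop("'step' must be > 0")
  pos <- seq(0, beam$scan_length, by = beam$step)
  z <- pos - beam$edge_pos - offset
  in_tooth <- z >= 0
  zc <- pmax(z, 0)
  ca <- ifelse(in_tooth, true_ca_profile(truth, when, zc), 0)
  fl <- ifelse(in_tooth, true_f_profile(truth, when, zc), 0)
  q <- beam$charge_per_point
  fid_stage <- beam$edge_pos + offset + truth$fiducial_pos
  cu_frac <- .foil_overlap(pos, fid_stage, beam$foil_width, beam$spot_fwhm)
  mu_ca <- beam$yield_ca * ca * q + beam$background_ca
  mu_f <- beam$yield_f * fl * q + beam$background_f
  mu_cu <- beam$yield_cu * cu_frac * q + beam$background_cu
  draw <- function(mu) {
    if (noise == "none") mu else stats::rpois(length(mu), mu)
  }
  counts <- with_local_seed(seed, {
    list(ca = draw(mu_ca), f = draw(mu_f), cu = draw(mu_cu))
  })
  linescan(pos, counts$ca, counts$f, counts$cu, rep_len(q, length(pos)))
}

#' Simulate a micro-CT grey-value line profile
#'
#' Mineral density truth is the noise-free Ca profile rescaled so intact
#' dentin maps to `density_sound` mg/cm3; grey values follow the affine
#' detector model `grey = gain * density + intercept + N(0, noise_sd)`.
#'
#' @inheritParams simulate_linescan
#' @param gain Grey units per (mg/cm3), > 0.
#' @param intercept Grey value at zero density.
#' @param noise_sd Gaussian noise standard deviation (grey units).
#' @param step Sampling step (µm); the scanner voxel pitch.
#' @param density_sound Mineral density of intact dentin (mg/cm3).
#' @param edge_pos Stage position of the dentin edge at zero offset (µm).
#' @param scan_length Profile length (µm).
#' @return A [depth_profile()] of grey values (element `"grey"`).
#' @export
simulate_uct_profile <- function(truth, when = c("before", "after"),
                                 gain = 2, intercept = 100, noise_sd = 5,
                                 step = 8.1, density_sound = 1100,
                                 edge_pos = 100, scan_length = 1000,
                                 offset = 0, seed = NULL) {
  when <- match.arg(when)
  stopifnot(inherits(truth, "specimen_truth"))
  if (gain <= 0) stop("'gain' must be > 0")
  pos <- seq(0, scan_length, by = step)
  z <- pos - edge_pos - offset
  in_tooth <- z >= 0
  dens <- ifelse(in_tooth,
                 true_ca_profile(truth, when, pmax(z, 0)) / truth$ca_sound *
                   density_sound, 0)
  grey <- with_local_seed(seed, {
    gain * dens + intercept +
      if (noise_sd > 0) stats::rnorm(length(dens), 0, noise_sd) else 0
  })
  depth_profile(pos, grey, element = "grey", unit = "grey value")
}

#' Simulate calibration-reference yields
#'
#' Emulates measuring a series of reference materials of known concentration
#' under the beam: counts are Poisson with mean
#' `(yield * concentration + background) * charge`, reported as
#' charge-normalized yield, so the fitted intercept estimates the
#' per-unit-charge background of the scans.
#'
#' @param concentration Known concentrations of the references (same unit as
#'   the channel: ppm for F, wt\% for Ca).
#' @param yield Detector yield (counts per concentration-unit per charge).
#' @param background Mean background counts per unit charge.
#' @param charge Accumulated charge per reference measurement (large values
#'   emulate long reference acquisitions).
#' @param label Optional reference labels.
#' @param seed,noise As in [simulate_linescan()].
#' @return A `data.frame` with columns `label`, `concentration`,
#'   `measured_yield` (counts per unit charge).
#' @export
simulate_reference_yields <- function(concentration, yield, background = 0,
                                      charge = 100, label = NULL,
                                      seed = NULL,
                                      noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  mu <- (yield * concentration + background) * charge
  counts <- with_local_seed(seed, {
    if (noise == "none") mu else stats::rpois(length(mu), mu)
  })
  data.frame(
    label = if (is.null(label)) sprintf("ref%02d", seq_along(mu)) else label,
    concentration = concentration,
    measured_yield = counts / charge)
}

#' Study design for a synthetic cohort of tooth pairs
#'
#' Encodes the conditions the generator emulates: `n_pairs` teeth, each
#' contributing one FCM-treated and one control specimen (paired halves of the
#' same tooth sharing a tooth-level lesion-severity latent), independent rigid
#' stage offsets per scan, and a negative coupling between fluorine uptake and
#' lesion severity: for FCM specimens both `lesion_mid` and `erosion` are
#' scaled by `1 - coupling_kappa * min(f_amplitude / f_ref, 1)`.
#'
#' Parameter distributions are `c(mean, sd)` pairs; draws are Gaussian,
#' truncated to each parameter's valid range.
#'
#' @param n_pairs Number of tooth pairs (default 9).
#' @param seed Default master seed used by [generate_cohort()].
#' @param ca_sound,ca_surface_after,lesion_mid,lesion_width,erosion,f_decay
#'   `c(mean, sd)` for the corresponding [specimen_truth()] fields.
#' @param f_amplitude_fcm,f_amplitude_control `c(mean, sd)` of surface
#'   fluorine (ppm) per group.
#' @param coupling_kappa Attenuation (0-1) of lesion severity by F uptake.
#' @param f_ref Fluorine amplitude (ppm) at which the attenuation saturates.
#' @param severity_sd SD of the log-normal tooth-level severity latent.
#' @param offset_sd SD of the rigid per-scan stage offset (µm).
#' @param f_depth_gain Post-demineralization fluorine decay-length gain.
#' @param n_lines Analysis lines scanned per specimen per occasion.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 9, seed = 1,
                        ca_sound = c(27, 0.5),
                        ca_surface_after = c(8, 2),
                        lesion_mid = c(45, 8),
                        lesion_width = c(15, 2),
                        erosion = c(10, 3),
                        f_amplitude_fcm = c(3000, 800),
                        f_amplitude_control = c(0, 0),
                        f_decay = c(40, 8),
                        coupling_kappa = 0.6, f_ref = 3000,
                        severity_sd = 0.25, offset_sd = 20,
                        f_depth_gain = 1.8, n_lines = 2) {
  if (n_pairs < 1) stop("'n_pairs' must be >= 1")
  if (coupling_kappa < 0 || coupling_kappa > 1)
    stop("'coupling_kappa' must lie in [0, 1]")
  if (offset_sd < 0 || severity_sd < 0)
    stop("'offset_sd' and 'severity_sd' must be >= 0")
  dists <- list(ca_sound = ca_sound, ca_surface_after = ca_surface_after,
                lesion_mid = lesion_mid, lesion_width = lesion_width,
                erosion = erosion, f_amplitude_fcm = f_amplitude_fcm,
                f_amplitude_control = f_amplitude_control, f_decay = f_decay)
  for (nm in names(dists)) {
    d <- dists[[nm]]
    if (length(d) != 2L || !is.numeric(d) || d[2] < 0 || anyNA(d))
      stop(sprintf("'%s' must be a numeric c(mean, sd) with sd >= 0", nm))
  }
  structure(c(dists, list(
    n_pairs = as.integer(n_pairs), seed = seed,
    coupling_kappa = coupling_kappa, f_ref = f_ref,
    severity_sd = severity_sd, offset_sd = offset_sd,
    f_depth_gain = f_depth_gain, n_lines = as.integer(n_lines)
  )), class = "cohort_spec")
}

# Truncated-normal draw by clamping (simple, adequate for mild truncation).
.rtnorm <- function(n, mean_sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean_sd[1], mean_sd[2]), lo), hi)
}

#' Generate a synthetic cohort of paired specimens
#'
#' Draws `n_pairs` teeth.  Each tooth carries a log-normal severity latent
#' shared by its FCM and control halves (scaling `lesion_mid` and `erosion`),
#' and each specimen gets a before- and an after-demineralization line scan
#' (plus optionally micro-CT profiles), each with an independent rigid stage
#' offset `~ Normal(0, offset_sd)`.  The whole cohort is a pure function of
#' `(spec, beam, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param beam A [beam_config()] used for all scans.
#' @param seed Master seed (defaults to `spec$seed`); spawns independent
#'   per-scan seeds.
#' @param scans If `FALSE`, only the ground-truth specimens and offsets are
#'   generated (fast path for truth-level studies).
#' @param uct If `TRUE` (default), micro-CT before/after profiles are
#'   simulated for every specimen.
#' @param uct_args List of overrides passed to [simulate_uct_profile()]
#'   (e.g. `gain`, `noise_sd`, `offset` handling); the default µCT inter-scan
#'   offset is 0 (reproducible scanner-bed coordinates).
#' @param noise `"poisson"` or `"none"`, forwarded to the simulators.
#' @return An object of class `cohort`: a list with one element per tooth,
#'   each holding `fcm` and `control` specimens (`truth`, `offsets`,
#'   `scans$before`/`scans$after` lists of [linescan()]s, `uct` profiles).
#' @export
generate_cohort <- function(spec, beam = beam_config(), seed = spec$seed,
                            scans = TRUE, uct = TRUE, uct_args = list(),
                            noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "cohort_spec"), inherits(beam, "beam_config"))
  with_local_seed(seed, {
    n <- spec$n_pairs
    severity <- exp(stats::rnorm(n, 0, spec$severity_sd))
    teeth <- vector("list", n)
    for (i in seq_len(n)) {
      # tooth-level state shared by the two halves: chemistry and the
      # lesion-severity latent; lesion geometry varies per specimen
      tooth_base <- list(
        ca_sound = .rtnorm(1, spec$ca_sound, lo = 1),
        f_decay = .rtnorm(1, spec$f_decay, lo = 5))
      mk <- function(group) {
        amp_dist <- if (group == "FCM") spec$f_amplitude_fcm
                    else spec$f_amplitude_control
        f_amp <- .rtnorm(1, amp_dist, lo = 0)
        atten <- if (group == "FCM")
          1 - spec$coupling_kappa * min(f_amp / spec$f_ref, 1) else 1
        tr <- specimen_truth(
          ca_sound = tooth_base$ca_sound,
          ca_surface_after = min(.rtnorm(1, spec$ca_surface_after, lo = 0),
                                 tooth_base$ca_sound),
          lesion_mid = .rtnorm(1, spec$lesion_mid, lo = 1) * severity[i] *
            atten,
          lesion_width = .rtnorm(1, spec$lesion_width, lo = 1),
          erosion = .rtnorm(1, spec$erosion, lo = 0) * severity[i] * atten,
          f_amplitude = f_amp, f_decay = tooth_base$f_decay,
          f_depth_gain = spec$f_depth_gain, group = group)
        offs <- stats::rnorm(2, 0, spec$offset_sd)
        sp <- list(truth = tr,
                   offsets = c(before = offs[1], after = offs[2]))
        if (scans) {
          seeds <- sample.int(.Machine$integer.max - 1L, 2L * spec$n_lines + 2L)
          sim_lines <- function(when, off, s0) {
            lapply(seq_len(spec$n_lines), function(k)
              simulate_linescan(tr, beam, when, offset = off,
                                seed = seeds[s0 + k], noise = noise))
          }
          sp$scans <- list(before = sim_lines("before", offs[1], 0L),
                           after = sim_lines("after", offs[2], spec$n_lines))
          if (uct) {
            ua <- utils::modifyList(
              list(gain = 2, intercept = 100, noise_sd = 5, step = 8.1,
                   edge_pos = beam$edge_pos, scan_length = beam$scan_length,
                   offset = 0), uct_args)
            sim_uct <- function(when, s) do.call(simulate_uct_profile,
              c(list(truth = tr, when = when, seed = s), ua))
            sp$uct <- list(before = sim_uct("before", seeds[2L * spec$n_lines + 1L]),
                           after = sim_uct("after", seeds[2L * spec$n_lines + 2L]))
          }
        }
        sp
      }
      teeth[[i]] <- list(tooth_id = sprintf("tooth%02d", i),
                         fcm = mk("FCM"), control = mk("control"))
    }
    structure(teeth, class = "cohort", spec = spec, seed = seed)
  })
}

#' @export
print.cohort <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("Synthetic cohort: %d tooth pairs (seed %s)\n",
              length(x), format(attr(x, "seed"))))
  has_scans <- !is.null(x[[1]]$fcm$scans)
  cat(sprintf("  scans: %s; coupling kappa = %.2f, offset sd = %.0f um\n",
              if (has_scans) sprintf("%d line(s) per occasion", sp$n_lines)
              else "truths only", sp$coupling_kappa, sp$offset_sd))
  invisible(x)
}
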