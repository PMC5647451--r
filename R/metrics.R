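#' Analysis configuration for the lesion metrics
#'
#' @param bin_width Averaging interval (µm, default 10): profiles are reduced
#'   to bin means anchored at the Cu reference before integration.
#' @param outer_frac Fraction of intact-dentin Ca defining the outermost
#'   lesion surface (default 0.05).
#' @param inner_frac Fraction defining the innermost lesion surface
#'   (default 0.95).
#' @param f_lod Fluorine detection limit (ppm).  `NA` (default) means derive
#'   it from the fluorine calibration background via [derive_f_lod()] where a
#'   curve is available; direct metric calls then require an explicit value.
#' @param intact_window Width (µm) of the intact-dentin averaging window
#'   adjacent to the Cu reference (default 200).
#' @param clamp_nonnegative Clamp integral losses at 0 (default `FALSE`;
#'   negative bin differences are kept, which is unbiased under noise).
#' @param integration `"rectangle"` (bin mean times bin width, default,
#'   matching 10 µm interval averaging) or `"trapezoid"`.
#' @param uptake_surface Integrate F uptake from the `"before"` profile's
#'   outer surface for both occasions (default; one common region) or from
#'   each occasion's `"respective"` surface.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(bin_width = 10, outer_frac = 0.05,
                            inner_frac = 0.95, f_lod = NA_real_,
                            intact_window = 200, clamp_nonnegative = FALSE,
                            integration = c("rectangle", "trapezoid"),
                            uptake_surface = c("before", "respective")) {
  integration <- match.arg(integration)
  uptake_surface <- match.arg(uptake_surface)
  if (!(outer_frac > 0 && outer_frac < inner_frac && inner_frac < 1))
    stop("need 0 < outer_frac < inner_frac < 1")
  if (bin_width <= 0) stop("'bin_width' must be > 0")
  if (intact_window <= 0) stop("'intact_window' must be > 0")
  structure(list(bin_width = bin_width, outer_frac = outer_frac,
                 inner_frac = inner_frac, f_lod = f_lod,
                 intact_window = intact_window,
                 clamp_nonnegative = isTRUE(clamp_nonnegative),
                 integration = integration, uptake_surface = uptake_surface),
            class = "analysis_config")
}

#' Average a profile into bins anchored at the Cu reference
#'
#' Bin centres sit at `ref_pos - k * bin_width` (k = 0, 1, ...), extending
#' outward from the reference toward the surface; each bin covers the
#' half-open interval `[centre - w/2, centre + w/2)` and takes the mean of
#' the profile points it covers.  Bins containing no points (or only missing
#' points) are `NA` (flagged missing, not dropped).
#'
#' @param profile A [depth_profile()] (grid at least as fine as the bins).
#' @param ref_pos Cu reference position (µm) anchoring the bins.
#' @param cfg An [analysis_config()].
#' @return A [depth_profile()] whose positions are the bin centres
#'   (increasing).
#' @export
bin_profile <- function(profile, ref_pos, cfg = analysis_config()) {
  stopifnot(inherits(profile, "depth_profile"))
  pos <- profile$position_um
  val <- profile$value
  if (length(pos) == 0L) stop("empty profile")
  w <- cfg$bin_width
  u <- (ref_pos - pos) / w
  k <- ceiling(u - 0.5 - 1e-9)          # bin index; [centre - w/2, centre + w/2)
  keep <- k >= 0
  if (!any(keep)) stop("no profile points at or outside the reference")
  k <- k[keep]; val <- val[keep]
  kmax <- max(k)
  sums <- rep(NA_real_, kmax + 1L)
  for (kk in unique(k)) {
    v <- val[k == kk]
    sums[kk + 1L] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  centres <- ref_pos - (kmax:0) * w
  depth_profile(centres, rev(sums),
                element = attr(profile, "element"),
                unit = attr(profile, "unit"))
}

#' Mean Ca of intact dentin
#'
#' Average of the profile over the `intact_window` adjacent to (on the
#' shallow side of) the Cu reference — the sound region that anchors the
#' 5\%/95\% boundary thresholds.
#'
#' @param profile A calcium [depth_profile()] (raw or binned).
#' @param ref_pos Cu reference position (µm).
#' @param cfg An [analysis_config()].
#' @return Mean intact-dentin Ca (wt\%).
#' @export
intact_ca <- function(profile, ref_pos, cfg = analysis_config()) {
  stopifnot(inherits(profile, "depth_profile"))
  idx <- profile$position_um >= ref_pos - cfg$intact_window &
    profile$position_um <= ref_pos
  v <- profile$value[idx]
  if (!any(idx) || all(is.na(v)))
    stop("intact-dentin window is not covered by the profile")
  mean(v, na.rm = TRUE)
}

#' Locate the lesion boundaries on a Ca profile
#'
#' Scanning inward (increasing position), the outermost surface is the first
#' linearly-interpolated crossing of `outer_frac * intact` (5\% of intact
#' dentin by default); if the profile already starts above that threshold the
#' profile start is the surface.  The innermost surface is the first crossing
#' of `inner_frac * intact` (95\%) at or after the outer surface.  A profile
#' never dropping below the 95\% threshold has no lesion (both boundaries
#' `NA`, `lesion = FALSE`); a profile entirely below the 5\% threshold does
#' not reach the tooth and is an error.
#'
#' @param profile A calcium [depth_profile()] (typically binned).
#' @param intact Mean intact-dentin Ca (wt\%), > 0.
#' @param cfg An [analysis_config()].
#' @return A list: `outer`, `inner` (µm or `NA`), `lesion` (logical),
#'   `intact`.
#' @export
find_boundaries <- function(profile, intact, cfg = analysis_config()) {
  stopifnot(inherits(profile, "depth_profile"), intact > 0)
  ok <- !is.na(profile$value)
  p <- profile$position_um[ok]
  v <- profile$value[ok]
  if (length(v) < 2L) stop("profile has fewer than 2 non-missing points")
  lo <- cfg$outer_frac * intact
  hi <- cfg$inner_frac * intact
  if (all(v < lo)) stop("profile entirely below the outer threshold: ",
                        "scan does not reach the tooth")
  first_crossing <- function(threshold, from = 1L) {
    idx <- seq(from, length(v))
    i <- idx[which(v[idx] >= threshold)[1]]
    if (is.na(i)) return(NA_real_)
    if (i == from && v[i] >= threshold) {
      if (i == 1L) return(p[1L])
      # rose above threshold before 'from': boundary is at 'from' itself
      if (v[i - 1L] >= threshold) return(p[i])
    }
    if (i == 1L) return(p[1L])
    p[i - 1L] + (threshold - v[i - 1L]) / (v[i] - v[i - 1L]) *
      (p[i] - p[i - 1L])
  }
  if (all(v >= hi))
    return(list(outer = NA_real_, inner = NA_real_, lesion = FALSE,
                intact = intact))
  outer <- first_crossing(lo)
  i_outer <- which(p >= outer)[1]
  inner <- first_crossing(hi, from = max(i_outer, 1L))
  list(outer = outer, inner = inner, lesion = TRUE, intact = intact)
}

# Shared integral: sum over bins in [from, ref] of (before - after) * w.
.integrate_loss <- function(before_bin, after_bin, from, ref_pos, cfg) {
  stopifnot(identical(before_bin$position_um, after_bin$position_um))
  centres <- before_bin$position_um
  sel <- centres >= from - 1e-9 & centres <= ref_pos + 1e-9
  if (!any(sel)) stop("insufficient overlap: no bins in the analysis region")
  d <- before_bin$value[sel] - after_bin$value[sel]
  n_missing <- sum(is.na(d))
  if (n_missing == length(d))
    stop("insufficient overlap: all bins in the analysis region are missing")
  if (cfg$integration == "trapezoid" && sum(!is.na(d)) > 1L) {
    x <- centres[sel][!is.na(d)]
    y <- d[!is.na(d)]
    loss <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  } else {
    loss <- sum(d, na.rm = TRUE) * cfg$bin_width
  }
  if (cfg$clamp_nonnegative) loss <- max(loss, 0)
  structure(loss, n_missing_bins = n_missing)
}

#' Integrated Ca loss of a registered pair
#'
#' Sum, over `bin_width` bins from the before profile's outermost surface to
#' the Cu reference, of `(Ca_before - Ca_after) * bin_width` (wt\%·µm) — the
#' PIXE analogue of the transverse-microradiography mineral-loss integral
#' ΔZ.  The before surface is used so that eroded material counts as loss;
#' when the before profile shows no 5\% crossing (scan starts inside sound
#' dentin) the region starts at the first covered bin.  Missing bins are
#' excluded and reported via the `n_missing_bins` attribute.
#'
#' @param pair A [superimpose()] result.
#' @param cfg An [analysis_config()].
#' @return Ca loss (wt\%·µm) with attributes `outer_surface` and
#'   `n_missing_bins`.
#' @export
compute_ca_loss <- function(pair, cfg = analysis_config()) {
  stopifnot(inherits(pair, "sequential_pair"))
  ref <- pair$ref_pos
  bp <- bin_profile(depth_profile(pair$grid, pair$ca_before, "Ca", "wt%"),
                    ref, cfg)
  ap <- bin_profile(depth_profile(pair$grid, pair$ca_after, "Ca", "wt%"),
                    ref, cfg)
  intact <- intact_ca(bp, ref, cfg)
  bnd <- find_boundaries(bp, intact, cfg)
  from <- if (bnd$lesion && !is.na(bnd$outer)) bnd$outer
          else min(bp$position_um[!is.na(bp$value)])
  loss <- .integrate_loss(bp, ap, from, ref, cfg)
  structure(as.numeric(loss), outer_surface = from,
            n_missing_bins = attr(loss, "n_missing_bins"))
}

#' Integrated F uptake over the lesion region
#'
#' Cumulates the binned fluorine concentrations from the outermost surface to
#' the Cu reference: `sum(F_bin * bin_width)` in ppmF·µm.  Values are the
#' background-floored calibrated concentrations.
#'
#' @param profile A binned fluorine [depth_profile()] (see [bin_profile()]).
#' @param outer_surface Outermost lesion surface (µm).
#' @param ref_pos Cu reference position (µm).
#' @param cfg An [analysis_config()].
#' @return F uptake (ppmF·µm) with attribute `n_missing_bins`.
#' @export
compute_f_uptake <- function(profile, outer_surface, ref_pos,
                             cfg = analysis_config()) {
  stopifnot(inherits(profile, "depth_profile"))
  sel <- profile$position_um >= outer_surface - 1e-9 &
    profile$position_um <= ref_pos + 1e-9
  v <- profile$value[sel]
  if (!any(sel) || all(is.na(v)))
    stop("F-uptake region [outer_surface, ref_pos] is not covered")
  structure(sum(v, na.rm = TRUE) * cfg$bin_width,
            n_missing_bins = sum(is.na(v)))
}

#' Fluorine penetration depth
#'
#' Distance from the outermost lesion surface to the first bin, scanning
#' inward, whose fluorine concentration falls below the detection limit
#' `f_lod`.  If the first bin is already below the limit the penetration is
#' 0; if no bin falls below it before the profile ends, the full covered
#' distance is returned.
#'
#' @inheritParams compute_f_uptake
#' @return Penetration depth (µm).
#' @export
compute_f_penetration <- function(profile, outer_surface,
                                  cfg = analysis_config()) {
  stopifnot(inherits(profile, "depth_profile"))
  if (is.na(cfg$f_lod))
    stop("'f_lod' is NA: set it in analysis_config() or derive it from the ",
         "fluorine calibration (derive_f_lod)")
  sel <- which(profile$position_um >= outer_surface - 1e-9 &
                 !is.na(profile$value))
  if (!length(sel)) stop("F-penetration region is not covered")
  pos <- profile$position_um[sel]
  v <- profile$value[sel]
  below <- which(v < cfg$f_lod)
  if (!length(below)) return(max(pos) - outer_surface)
  if (below[1] == 1L) return(0)
  max(pos[below[1]] - outer_surface, 0)
}

#' Integrated micro-CT mineral loss
#'
#' Same integral contract as [compute_ca_loss()] applied to aligned
#' before/after mineral-density profiles, in mg/cm3·µm.  The micro-CT scans
#' carry no Cu fiducial: the analysis region runs from the before profile's
#' outermost surface (5\% rule on density) to `ref_depth` µm inside it, and
#' the pair is expected to be pre-aligned (see [align_uct_pair()]).
#'
#' @param before,after Calibrated mineral-density [depth_profile()]s on a
#'   common grid.
#' @param cfg An [analysis_config()].
#' @param ref_depth Depth of the reference point below the before surface
#'   (µm, default 800 to mirror the Cu foil placement).
#' @return Mineral loss (mg/cm3·µm) with attributes `outer_surface` and
#'   `n_missing_bins`.
#' @export
compute_mineral_loss <- function(before, after, cfg = analysis_config(),
                                 ref_depth = 800) {
  stopifnot(inherits(before, "depth_profile"), inherits(after, "depth_profile"))
  # provisional reference: sound plateau near the deep end of the before scan
  deep <- max(before$position_um)
  intact0 <- intact_ca(before, deep, cfg)
  bnd0 <- find_boundaries(before, intact0, cfg)
  surf <- if (bnd0$lesion && !is.na(bnd0$outer)) bnd0$outer
          else min(before$position_um)
  ref <- min(surf + ref_depth, deep)
  bb <- bin_profile(before, ref, cfg)
  ab <- bin_profile(after, ref, cfg)
  loss <- .integrate_loss(bb, ab, surf, ref, cfg)
  structure(as.numeric(loss), outer_surface = surf,
            n_missing_bins = attr(loss, "n_missing_bins"))
}

#' Full lesion analysis of one specimen
#'
#' Composes the pipeline for one specimen: fiducial registration and
#' calibration of each analysis line ([superimpose()]), binning at the Cu
#' reference, intact-dentin averaging, 5\%/95\% boundary detection on the
#' before and after Ca profiles, and the four integral metrics.  Metrics from
#' multiple analysis lines (the instrument protocol scans two lines per
#' specimen) are averaged into a single result.
#'
#' @param before_scans,after_scans A [linescan()] or list of them (one per
#'   analysis line, matched by position in the list).
#' @param curves Named list of calibration curves (`ca`, `f`).
#' @param cfg An [analysis_config()]; an `NA` `f_lod` is derived from the
#'   fluorine curve via [derive_f_lod()].
#' @param uct_before,uct_after Optional aligned mineral-density
#'   [depth_profile()]s (or raw grey profiles plus `curves$uct` to calibrate
#'   them here).
#' @return An object of class `lesion_metrics`.
#' @export
analyze_specimen <- function(before_scans, after_scans, curves,
                             cfg = analysis_config(),
                             uct_before = NULL, uct_after = NULL) {
  as_list <- function(x) if (inherits(x, "linescan")) list(x) else x
  before_scans <- as_list(before_scans)
  after_scans <- as_list(after_scans)
  stopifnot(length(before_scans) == length(after_scans),
            length(before_scans) >= 1L)
  per_line <- lapply(seq_along(before_scans), function(i) {
    stage <- "registration"
    res <- tryCatch({
      pair <- superimpose(before_scans[[i]], after_scans[[i]], curves)
      stage <- "metrics"
      cfg_i <- cfg
      if (is.na(cfg_i$f_lod))
        cfg_i$f_lod <- derive_f_lod(curves$f,
                                    stats::median(before_scans[[i]]$charge))
      ref <- pair$ref_pos
      bin_ca_b <- bin_profile(depth_profile(pair$grid, pair$ca_before), ref, cfg_i)
      bin_ca_a <- bin_profile(depth_profile(pair$grid, pair$ca_after), ref, cfg_i)
      bin_f_b <- bin_profile(depth_profile(pair$grid, pair$f_before), ref, cfg_i)
      bin_f_a <- bin_profile(depth_profile(pair$grid, pair$f_after), ref, cfg_i)
      intact <- intact_ca(bin_ca_b, ref, cfg_i)
      bnd_b <- find_boundaries(bin_ca_b, intact, cfg_i)
      bnd_a <- find_boundaries(bin_ca_a, intact, cfg_i)
      surf_b <- if (bnd_b$lesion && !is.na(bnd_b$outer)) bnd_b$outer
                else min(bin_ca_b$position_um[!is.na(bin_ca_b$value)])
      surf_a <- if (bnd_a$lesion && !is.na(bnd_a$outer)) bnd_a$outer else surf_b
      ca_loss <- .integrate_loss(bin_ca_b, bin_ca_a, surf_b, ref, cfg_i)
      up_surf_a <- if (cfg_i$uptake_surface == "before") surf_b else surf_a
      f_up_b <- compute_f_uptake(bin_f_b, surf_b, ref, cfg_i)
      f_up_a <- compute_f_uptake(bin_f_a, up_surf_a, ref, cfg_i)
      f_pen_b <- compute_f_penetration(bin_f_b, surf_b, cfg_i)
      f_pen_a <- compute_f_penetration(bin_f_a, surf_a, cfg_i)
      list(outer_before = surf_b, inner_before = bnd_b$inner,
           outer_after = surf_a, inner_after = bnd_a$inner,
           intact_ca_mean = intact,
           ca_loss = as.numeric(ca_loss),
           f_uptake_before = as.numeric(f_up_b),
           f_uptake_after = as.numeric(f_up_a),
           f_penetration_before = f_pen_b, f_penetration_after = f_pen_a,
           shift = pair$applied_shift, snr = pair$fiducial_before$snr,
           f_lod = cfg_i$f_lod)
    }, error = function(e) {
      stop(sprintf("line %d, stage %s: %s", i, stage, conditionMessage(e)),
           call. = FALSE)
    })
    res
  })
  avg <- function(field) mean(vapply(per_line, `[[`, numeric(1), field))
  mineral_loss <- NA_real_
  if (!is.null(uct_before) && !is.null(uct_after)) {
    if (!is.null(curves$uct)) {
      uct_before <- apply_calibration(uct_before, curves$uct, "grey")
      uct_after <- apply_calibration(uct_after, curves$uct, "grey")
    }
    aligned <- align_uct_pair(uct_before, uct_after)
    mineral_loss <- as.numeric(compute_mineral_loss(aligned$before,
                                                    aligned$after, cfg))
  }
  structure(list(
    outer_surface_before = avg("outer_before"),
    inner_surface_before = avg("inner_before"),
    outer_surface_after = avg("outer_after"),
    inner_surface_after = avg("inner_after"),
    intact_ca_mean = avg("intact_ca_mean"),
    ca_loss = avg("ca_loss"),
    f_uptake_before = avg("f_uptake_before"),
    f_uptake_after = avg("f_uptake_after"),
    f_penetration_before = avg("f_penetration_before"),
    f_penetration_after = avg("f_penetration_after"),
    mineral_loss = mineral_loss,
    n_lines = length(per_line),
    provenance = lapply(per_line, function(l)
      l[c("shift", "snr", "f_lod")])
  ), class = "lesion_metrics")
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat("Lesion metrics (mean of", x$n_lines, "analysis line(s))\n")
  cat(sprintf("  intact Ca %.2f wt%%; lesion %.1f-%.1f um (after DM)\n",
              x$intact_ca_mean, x$outer_surface_after, x$inner_surface_after))
  cat(sprintf("  Ca loss        %12.4g wt%%*um\n", x$ca_loss))
  cat(sprintf("  F uptake       %12.4g / %.4g ppmF*um (before/after DM)\n",
              x$f_uptake_before, x$f_uptake_after))
  cat(sprintf("  F penetration  %12.4g / %.4g um (before/after DM)\n",
              x$f_penetration_before, x$f_penetration_after))
  if (!is.na(x$mineral_loss))
    cat(sprintf("  mineral loss   %12.4g mg/cm3*um (uCT)\n", x$mineral_loss))
  invisible(x)
}

#' @export
as.data.frame.lesion_metrics <- function(x, ...) {
  data.frame(ca_loss = x$ca_loss,
             f_uptake_before = x$f_uptake_before,
             f_uptake_after = x$f_uptake_after,
             f_penetration_before = x$f_penetration_before,
             f_penetration_after = x$f_penetration_after,
             mineral_loss = x$mineral_loss,
             intact_ca_mean = x$intact_ca_mean)
}

#' Analyze every specimen of a synthetic cohort
#'
#' @param cohort A [generate_cohort()] result (with scans).
#' @param curves Named list of calibration curves (`ca`, `f`, optionally
#'   `uct`).
#' @param cfg An [analysis_config()].
#' @return A `data.frame`, one row per specimen: `tooth_id`, `group`, and the
#'   [analyze_specimen()] metrics.
#' @export
cohort_metrics <- function(cohort, curves, cfg = analysis_config()) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- list()
  for (tooth in cohort) {
    for (g in c("fcm", "control")) {
      sp <- tooth[[g]]
      if (is.null(sp$scans))
        stop("cohort was generated without scans (scans = FALSE)")
      m <- analyze_specimen(sp$scans$before, sp$scans$after, curves, cfg,
                            uct_before = sp$uct$before,
                            uct_after = sp$uct$after)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(tooth_id = tooth$tooth_id, group = sp$truth$group),
        as.data.frame(m))
    }
  }
  do.call(rbind, rows)
}
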