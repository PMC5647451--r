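#' Locate the Cu fiducial foil in a line scan
#'
#' The foil shows up as a narrow peak in the Cu channel.  The background is
#' estimated robustly (median of the Cu counts; the foil occupies a tiny
#' fraction of the scan), a Poisson-motivated threshold
#' `background + k * sqrt(background)` is applied, and the foil centre is the
#' background-subtracted, counts-weighted centroid of the contiguous
#' supra-threshold cluster containing the global Cu maximum — giving sub-step
#' precision.  A disjoint competing cluster of fiducial-like height (lone
#' Poisson excursions just over the detection threshold do not qualify)
#' triggers a warning; the cluster holding the global maximum wins.
#'
#' @param scan A [linescan()] with a Cu channel.
#' @param k Threshold multiplier on the background Poisson sd (default 3).
#' @param snr_min Minimum peak/background ratio for a valid fix (default 5).
#' @return An object of class `fiducial_fix`: `position` (µm),
#'   `peak_counts`, `snr`.
#' @export
detect_fiducial <- function(scan, k = 3, snr_min = 5) {
  stopifnot(inherits(scan, "linescan"))
  cu <- scan$counts_cu
  pos <- scan$position_um
  bg <- stats::median(cu)
  thr <- bg + k * sqrt(bg)
  above <- cu > thr
  if (!any(above))
    stop("no fiducial: no Cu point exceeds background + ", k,
         "*sqrt(background)")
  imax <- which.max(cu)
  if (!above[imax]) stop("no fiducial: Cu maximum does not exceed threshold")
  lo <- imax
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- imax
  while (hi < length(cu) && above[hi + 1L]) hi <- hi + 1L
  # warn only on a competing cluster of fiducial-like height, not on lone
  # Poisson excursions just over the detection threshold
  competitor <- max(bg + max(k, snr_min) * sqrt(bg), 0.25 * cu[imax])
  if (any(cu[-(lo:hi)] > competitor))
    warning("multiple supra-threshold Cu clusters; using the one containing ",
            "the global maximum")
  idx <- lo:hi
  w <- pmax(cu[idx] - bg, 0)
  centre <- sum(w * pos[idx]) / sum(w)
  snr <- if (bg > 0) cu[imax] / bg else Inf
  if (snr <= snr_min)
    stop(sprintf("no fiducial: Cu peak SNR %.2f below minimum %.2f",
                 snr, snr_min))
  structure(list(position = centre, peak_counts = cu[imax], snr = snr,
                 cluster = c(pos[lo], pos[hi]), background = bg),
            class = "fiducial_fix")
}

#' @export
print.fiducial_fix <- function(x, ...) {
  cat(sprintf("Cu fiducial at %.2f um (peak %d counts, SNR %.1f)\n",
              x$position, as.integer(x$peak_counts),
              if (is.finite(x$snr)) x$snr else Inf))
  invisible(x)
}

#' Superimpose before/after scans on the Cu reference point
#'
#' Detects the fiducial in both scans, applies the rigid shift
#' `fiducial_before - fiducial_after` to the after scan, calibrates the Ca
#' and F channels, and linearly interpolates the shifted after profiles onto
#' the before grid.  Grid ends not shared by both scans are flagged missing,
#' never extrapolated.  The common grid is anchored at the before-scan
#' fiducial position, so every downstream metric is invariant to a common
#' rigid translation of both scans.
#'
#' @param before_scan,after_scan [linescan()]s of the same specimen line.
#' @param curves Named list with `ca` (`pixe_ca`) and `f` (`pige_f`)
#'   [fit_calibration()] curves.
#' @param min_overlap Minimum required overlap between the two scans, as a
#'   fraction of the before-fiducial depth range (default 0.8); shorter
#'   overlap raises an insufficient-overlap error.
#' @param ... Passed to [detect_fiducial()].
#' @return An object of class `sequential_pair`: shared `grid`, calibrated
#'   `ca_before`, `ca_after`, `f_before`, `f_after`, a `missing_after` flag,
#'   `applied_shift`, both fiducial fixes, and `ref_pos` (the common Cu
#'   reference position on the grid).
#' @export
superimpose <- function(before_scan, after_scan, curves, min_overlap = 0.8,
                        ...) {
  stopifnot(inherits(before_scan, "linescan"), inherits(after_scan, "linescan"),
            is.list(curves), all(c("ca", "f") %in% names(curves)))
  fid_b <- detect_fiducial(before_scan, ...)
  fid_a <- detect_fiducial(after_scan, ...)
  shift <- fid_b$position - fid_a$position
  grid <- before_scan$position_um
  prof_b <- list(ca = apply_calibration(before_scan, curves$ca, "ca"),
                 f = apply_calibration(before_scan, curves$f, "f"))
  prof_a <- list(ca = apply_calibration(after_scan, curves$ca, "ca"),
                 f = apply_calibration(after_scan, curves$f, "f"))
  regrid <- function(p) {
    stats::approx(p$position_um + shift, p$value, xout = grid,
                  method = "linear", rule = 1)$y
  }
  ca_after <- regrid(prof_a$ca)
  f_after <- regrid(prof_a$f)
  missing_after <- is.na(ca_after)
  span_after <- range(after_scan$position_um + shift)
  overlap <- min(max(grid), span_after[2]) - max(min(grid), span_after[1])
  if (overlap < min_overlap * fid_b$position)
    stop(sprintf(paste0("insufficient overlap: %.0f um shared, need at ",
                        "least %.0f um"), overlap,
         min_overlap * fid_b$position))
  structure(list(
    grid = grid,
    ca_before = prof_b$ca$value, ca_after = ca_after,
    f_before = prof_b$f$value, f_after = f_after,
    missing_after = missing_after,
    applied_shift = shift, fiducial_before = fid_b, fiducial_after = fid_a,
    ref_pos = fid_b$position
  ), class = "sequential_pair")
}

#' @export
print.sequential_pair <- function(x, ...) {
  cat("Registered before/after pair\n")
  cat(sprintf("  grid: %d points, %.0f-%.0f um; Cu reference at %.2f um\n",
              length(x$grid), min(x$grid), max(x$grid), x$ref_pos))
  cat(sprintf("  applied shift %.2f um; %d grid point(s) missing after shift\n",
              x$applied_shift, sum(x$missing_after)))
  invisible(x)
}

#' @export
plot.sequential_pair <- function(x, which = c("ca", "f"), ...) {
  which <- match.arg(which)
  b <- x[[paste0(which, "_before")]]
  a <- x[[paste0(which, "_after")]]
  ylab <- if (which == "ca") "Ca (wt%)" else "F (ppm)"
  graphics::plot(x$grid, b, type = "l", xlab = "position (um)", ylab = ylab,
                 ylim = range(c(b, a), na.rm = TRUE), ...)
  graphics::lines(x$grid, a, col = 2)
  graphics::abline(v = x$ref_pos, lty = 3)
  graphics::legend("bottomright", c("before DM", "after DM", "Cu reference"),
                   col = c(1, 2, 1), lty = c(1, 1, 3), bty = "n")
  invisible(x)
}

#' Align a before/after pair of micro-CT density profiles
#'
#' The micro-CT scans carry no Cu fiducial, so alignment falls back to a
#' rigid shift chosen by grid search to minimize the mean squared difference
#' over the sound-dentin window (the deep plateau adjacent to the reference
#' depth).  A featureless plateau identifies translation only weakly, so this
#' is flagged approximate; with reproducible scanner-bed coordinates
#' (`max_shift = 0`, the default) it is the identity.
#'
#' @param before,after [depth_profile()]s of calibrated mineral density.
#' @param sound_region `c(lo, hi)` positions (µm) of the sound window on the
#'   before grid.
#' @param max_shift Half-width of the shift search window (µm); 0 skips the
#'   search.
#' @param shift_step Search resolution (µm).
#' @return A list: `before`, `after` (both on the before grid), `shift`,
#'   `approximate = TRUE`.
#' @export
align_uct_pair <- function(before, after, sound_region = c(700, 900),
                           max_shift = 0, shift_step = 1) {
  stopifnot(inherits(before, "depth_profile"), inherits(after, "depth_profile"))
  grid <- before$position_um
  in_win <- grid >= sound_region[1] & grid <= sound_region[2]
  if (!any(in_win)) stop("sound_region does not overlap the before grid")
  best <- 0
  if (max_shift > 0) {
    cand <- seq(-max_shift, max_shift, by = shift_step)
    sse <- vapply(cand, function(s) {
      av <- stats::approx(after$position_um + s, after$value, xout = grid[in_win],
                          rule = 1)$y
      if (all(is.na(av))) return(Inf)
      mean((av - before$value[in_win])^2, na.rm = TRUE)
    }, numeric(1))
    best <- cand[which.min(sse)]
  }
  after_on_grid <- stats::approx(after$position_um + best, after$value,
                                 xout = grid, rule = 1)$y
  list(before = before,
       after = depth_profile(grid, after_on_grid,
                             element = attr(after, "element"),
                             unit = attr(after, "unit")),
       shift = best, approximate = TRUE)
}
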