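# Independent brute-force oracles.  Each is written as directly as possible
# from the defining formula, on a different code path from the package
# implementation it checks.

# per-bin means by explicit looping over half-open intervals anchored at ref
oracle_bin_means <- function(pos, val, ref, w) {
  kmax <- max(ceiling((ref - pos) / w - 0.5 - 1e-9))
  centres <- ref - (kmax:0) * w
  means <- vapply(centres, function(ctr) {
    inside <- pos >= ctr - w / 2 - 1e-9 & pos < ctr + w / 2 - 1e-9
    v <- val[inside]
    if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  list(centres = centres, means = means)
}

# rectangle-rule loss integral: explicit loop over bins in [from, ref]
oracle_loss <- function(centres, before, after, from, ref, w) {
  total <- 0
  for (i in seq_along(centres)) {
    if (centres[i] >= from - 1e-9 && centres[i] <= ref + 1e-9) {
      d <- before[i] - after[i]
      if (!is.na(d)) total <- total + d * w
    }
  }
  total
}

oracle_uptake <- function(centres, fval, from, ref, w) {
  total <- 0
  for (i in seq_along(centres))
    if (centres[i] >= from - 1e-9 && centres[i] <= ref + 1e-9 &&
        !is.na(fval[i]))
      total <- total + fval[i] * w
  total
}

# first bin at/after 'from' whose F is below the limit, scanned point by point
oracle_penetration <- function(centres, fval, from, lod) {
  idx <- which(centres >= from - 1e-9 & !is.na(fval))
  first <- TRUE
  for (i in idx) {
    if (fval[i] < lod) {
      if (first) return(0)
      return(centres[i] - from)
    }
    first <- FALSE
  }
  max(centres[idx]) - from
}

# dense first-crossing scan for the 5%/95% boundary rule
oracle_crossings <- function(pos, val, lo, hi, step = 0.01) {
  dense_x <- seq(min(pos), max(pos), by = step)
  dense_y <- approx(pos, val, xout = dense_x)$y
  outer <- if (dense_y[1] >= lo) dense_x[1] else
    dense_x[which(dense_y >= lo)[1]]
  after <- dense_x >= outer
  inner_i <- which(dense_y >= hi & after)[1]
  list(outer = outer, inner = if (is.na(inner_i)) NA else dense_x[inner_i])
}

# exact two-sided Mann-Whitney p by enumerating labelings, with U computed
# from pairwise comparisons (not rank sums)
oracle_mwu <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_of <- function(xs, ys) {
    u <- 0
    for (x in xs) for (y in ys)
      u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  u_obs <- u_of(a, b)
  mu <- n1 * (n - n1) / 2
  combos <- combn(n, n1)
  devs <- apply(combos, 2, function(idx)
    abs(u_of(pooled[idx], pooled[-idx]) - mu))
  list(U = u_obs, p = mean(devs >= abs(u_obs - mu) - 1e-9))
}

# midranks and Spearman rho from first principles (sort-based midranks,
# explicit Pearson sums)
oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# a quick noise-free FCM-like specimen + matched scans for reuse
make_noise_free_pair <- function(truth = specimen_truth(f_amplitude = 3000,
                                                        group = "FCM"),
                                 beam = beam_config(background_ca = 0,
                                                    background_f = 0,
                                                    background_cu = 0),
                                 offset_before = 0, offset_after = 0) {
  list(truth = truth, beam = beam,
       before = simulate_linescan(truth, beam, "before",
                                  offset = offset_before, noise = "none"),
       after = simulate_linescan(truth, beam, "after",
                                 offset = offset_after, noise = "none"))
}

# exact calibration curves corresponding to a beam's linear yield model
true_curves <- function(beam) {
  mk <- function(slope, intercept, kind) {
    refs <- data.frame(concentration = c(0, 1), measured_yield = NA)
    structure(list(kind = kind, slope = slope, intercept = intercept,
                   quad = 0, degree = 1, r_squared = 1,
                   references_used = refs),
              class = "calibration_curve")
  }
  list(ca = mk(beam$yield_ca, beam$background_ca / beam$charge_per_point,
               "pixe_ca"),
       f = mk(beam$yield_f, beam$background_f / beam$charge_per_point,
              "pige_f"))
}
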