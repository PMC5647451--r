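test_that("noise-free truth profiles honour their closed forms", {
  tr <- specimen_truth(ca_sound = 27, ca_surface_after = 7, lesion_mid = 50,
                       lesion_width = 12, erosion = 8, f_amplitude = 2000,
                       f_decay = 35, group = "FCM")
  z <- c(0, 13, 57, 200, 799)
  expect_equal(true_ca_profile(tr, "before", z), rep(27, length(z)))
  # sigmoid midpoint and deep limit
  expect_equal(true_ca_profile(tr, "after", 8 + 50), (7 + 27) / 2)
  deep <- 8 + 50 + 10 * 12
  expect_lt(abs(true_ca_profile(tr, "after", deep) - 27) / 27, 0.001)
  expect_equal(true_ca_profile(tr, "after", 7.9), 0)  # eroded material
  # exponential fluorine forms
  expect_equal(true_f_profile(tr, "before", 0), 2000)
  expect_equal(true_f_profile(tr, "before", 35), 2000 / exp(1),
               tolerance = 1e-12)
  ctrl <- specimen_truth(f_amplitude = 0, f_background = 0)
  expect_equal(true_f_profile(ctrl, "before", c(0, 50, 300)), rep(0, 3))
  # after-DM decay length is stretched by the depth gain
  expect_equal(true_f_profile(tr, "after", 63), 2000 * exp(-1),
               tolerance = 1e-12)
})

test_that("analytic truth integrals agree with numerical quadrature", {
  tr <- specimen_truth(ca_sound = 26, ca_surface_after = 9, lesion_mid = 40,
                       lesion_width = 18, erosion = 12, f_amplitude = 2500,
                       f_decay = 45, group = "FCM")
  # midpoint rule with the erosion discontinuity on a cell edge
  z <- seq(0.025, 800 - 0.025, by = 0.05)
  num_loss <- sum(true_ca_profile(tr, "before", z) -
                    true_ca_profile(tr, "after", z)) * 0.05
  expect_equal(true_ca_loss(tr), num_loss, tolerance = 1e-6)
  for (when in c("before", "after")) {
    lo <- if (when == "after") tr$erosion else 0
    zq <- seq(lo + 0.025, 800 - 0.025, by = 0.05)
    num_up <- sum(true_f_profile(tr, when, zq)) * 0.05
    expect_equal(true_f_uptake(tr, when), num_up, tolerance = 1e-6)
  }
})

test_that("simulated scans are deterministic per seed and exact in noise-free mode", {
  tr <- specimen_truth(f_amplitude = 1500, group = "FCM")
  beam <- beam_config()
  s1 <- simulate_linescan(tr, beam, "after", offset = 12, seed = 42)
  s2 <- simulate_linescan(tr, beam, "after", offset = 12, seed = 42)
  expect_identical(s1, s2)
  s3 <- simulate_linescan(tr, beam, "after", offset = 12, seed = 43)
  expect_false(identical(s1, s3))

  clean <- beam_config(background_ca = 0, background_f = 0, background_cu = 0)
  nf <- simulate_linescan(tr, clean, "before", noise = "none")
  z <- nf$position_um - clean$edge_pos
  in_tooth <- z >= 0
  expect_equal(nf$counts_ca[in_tooth] / (clean$yield_ca * nf$charge[in_tooth]),
               true_ca_profile(tr, "before", z[in_tooth]))
  expect_equal(nf$counts_f[in_tooth] / (clean$yield_f * nf$charge[in_tooth]),
               true_f_profile(tr, "before", z[in_tooth]))
  expect_true(all(nf$counts_ca[!in_tooth] == 0))
})

test_that("counting noise is Poisson (index of dispersion near 1)", {
  # 1000 replicate points at a fixed mean via a flat sound specimen
  tr <- specimen_truth(f_amplitude = 0)
  beam <- beam_config(step = 1, scan_length = 1100, edge_pos = 0,
                      background_cu = 0)
  sc <- simulate_linescan(tr, beam, "before", seed = 11)
  counts <- sc$counts_ca[sc$position_um <= 999]  # 1000 points, equal mean
  mu <- beam$yield_ca * tr$ca_sound + beam$background_ca
  expect_gt(var(counts) / mu, 0.9)
  expect_lt(var(counts) / mu, 1.1)
  expect_lt(abs(mean(counts) - mu) / mu, 0.02)
})

test_that("Cu channel is at background except near the fiducial", {
  tr <- specimen_truth()
  beam <- beam_config(background_cu = 0)
  sc <- simulate_linescan(tr, beam, "before", offset = 15, noise = "none")
  fid <- beam$edge_pos + 15 + tr$fiducial_pos
  margin <- beam$spot_fwhm + beam$foil_width
  far <- abs(sc$position_um - fid) > margin
  expect_true(all(sc$counts_cu[far] < 0.01 * max(sc$counts_cu)))
  expect_gt(max(sc$counts_cu), 50)
})

test_that("micro-CT profiles invert exactly without noise and recover their noise level", {
  tr <- specimen_truth()
  p0 <- simulate_uct_profile(tr, "before", gain = 2.5, intercept = 80,
                             noise_sd = 0)
  dens <- (p0$value - 80) / 2.5
  in_tooth <- p0$position_um >= 100
  expect_equal(dens[in_tooth],
               true_ca_profile(tr, "before", p0$position_um[in_tooth] - 100) /
                 tr$ca_sound * 1100)
  expect_identical(simulate_uct_profile(tr, "after", seed = 5),
                   simulate_uct_profile(tr, "after", seed = 5))
  # Gaussian noise-level recovery about the affine model, n = 500
  p <- simulate_uct_profile(specimen_truth(), "before", gain = 2,
                            intercept = 100, noise_sd = 5, step = 1,
                            scan_length = 499, edge_pos = 0, seed = 21)
  resid_sd <- sd(p$value - (2 * 1100 + 100))
  expect_gt(resid_sd, 4)
  expect_lt(resid_sd, 6)
})

test_that("cohorts are reproducible, paired, and couple F uptake to lesion severity", {
  spec <- cohort_spec(n_pairs = 3, seed = 9, n_lines = 1)
  c1 <- generate_cohort(spec, uct = FALSE)
  c2 <- generate_cohort(spec, uct = FALSE)
  expect_identical(c1, c2)
  expect_identical(c1[[1]]$fcm$truth$group, "FCM")
  expect_identical(c1[[1]]$control$truth$group, "control")

  # no coupling: FCM and control true Ca loss have equal means (200 pairs)
  s0 <- cohort_spec(n_pairs = 200, seed = 4, coupling_kappa = 0)
  coh0 <- generate_cohort(s0, scans = FALSE)
  loss <- function(coh, g) vapply(coh, function(t) true_ca_loss(t[[g]]$truth),
                                  numeric(1))
  d <- loss(coh0, "fcm") - loss(coh0, "control")
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))

  # kappa = 0.6: FCM lesions are genuinely milder
  s1 <- cohort_spec(n_pairs = 50, seed = 4, coupling_kappa = 0.6)
  coh1 <- generate_cohort(s1, scans = FALSE)
  expect_lt(median(loss(coh1, "fcm")), median(loss(coh1, "control")))
})

test_that("invalid generator parameters are rejected", {
  expect_error(specimen_truth(ca_surface_after = 30), "ca_sound")
  expect_error(specimen_truth(lesion_width = 0), "lesion_width")
  expect_error(specimen_truth(f_decay = -1), "f_decay")
  expect_error(beam_config(step = 0), "step")
  expect_error(cohort_spec(n_pairs = 0), "n_pairs")
  expect_error(cohort_spec(coupling_kappa = 1.5), "coupling_kappa")
  expect_error(cohort_spec(lesion_mid = c(45, -1)), "lesion_mid")
})
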