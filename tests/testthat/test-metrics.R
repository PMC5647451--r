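cfg10 <- analysis_config(bin_width = 10)

test_that("binning reproduces constant and piecewise-constant profiles", {
  pos <- seq(0, 800, by = 10)
  flat <- depth_profile(pos, rep(23, length(pos)))
  bf <- bin_profile(flat, ref_pos = 800, cfg10)
  expect_true(all(bf$value == 23))
  expect_equal(max(bf$position_um), 800)

  step <- depth_profile(pos, ifelse(pos < 100, 20, 30))
  bs <- bin_profile(step, ref_pos = 800, cfg10)
  expect_true(all(bs$value[bs$position_um < 100] == 20))
  expect_true(all(bs$value[bs$position_um >= 100] == 30))
  expect_error(bin_profile(depth_profile(numeric(0), numeric(0)), 800),
               "length")
})

test_that("binning matches a brute-force per-bin mean oracle on random profiles", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(30:120, 1)
    pos <- sort(runif(n, 0, 900))
    val <- rnorm(n, 20, 5)
    ref <- runif(1, 600, 850)
    w <- sample(c(5, 10, 20), 1)
    got <- bin_profile(depth_profile(pos, val), ref,
                       analysis_config(bin_width = w))
    want <- oracle_bin_means(pos, val, ref, w)
    expect_equal(got$position_um, want$centres, tolerance = 1e-12)
    expect_equal(got$value, want$means, tolerance = 1e-12)
  }
})

test_that("intact-dentin averaging uses the window adjacent to the reference", {
  pos <- seq(0, 800, by = 10)
  flat <- depth_profile(pos, rep(27, length(pos)))
  expect_equal(intact_ca(flat, 800, cfg10), 27)
  # lesion confined to [0, 300]: the [600, 800] window sees only sound dentin
  lesion <- depth_profile(pos, ifelse(pos <= 300, 5, 27))
  expect_equal(intact_ca(lesion, 800, cfg10), 27)
  expect_error(intact_ca(depth_profile(c(0, 10), c(1, 2)), 800), "window")
})

test_that("5%/95% boundary rule interpolates the ramp example exactly", {
  pos <- seq(0, 800, by = 10)
  ramp <- depth_profile(pos, pmin(pos / 200, 1) * 27)
  bnd <- find_boundaries(ramp, intact = 27, cfg10)
  expect_true(bnd$lesion)
  expect_equal(bnd$outer, 10)   # 5% of 27 crossed at z = 10
  expect_equal(bnd$inner, 190)  # 95% of 27 crossed at z = 190

  flat <- depth_profile(pos, rep(27, length(pos)))
  bf <- find_boundaries(flat, 27, cfg10)
  expect_false(bf$lesion)
  expect_true(is.na(bf$outer) && is.na(bf$inner))

  low <- depth_profile(pos, rep(0.5, length(pos)))
  expect_error(find_boundaries(low, 27, cfg10), "does not reach")
})

test_that("boundaries on noisy sigmoid lesions match a dense first-crossing oracle", {
  set.seed(31)
  for (rep in 1:40) {
    tr <- specimen_truth(ca_surface_after = runif(1, 2, 12),
                         lesion_mid = runif(1, 25, 70),
                         lesion_width = runif(1, 8, 25),
                         erosion = runif(1, 0, 20))
    pos <- seq(0, 800, by = 10)
    val <- true_ca_profile(tr, "after", pos) + rnorm(length(pos), 0, 0.3)
    prof <- bin_profile(depth_profile(pos, val), 800, cfg10)
    bnd <- find_boundaries(prof, tr$ca_sound, cfg10)
    want <- oracle_crossings(prof$position_um, prof$value,
                             0.05 * tr$ca_sound, 0.95 * tr$ca_sound)
    expect_equal(bnd$outer, want$outer, tolerance = 0.02)
    expect_equal(bnd$inner, want$inner, tolerance = 0.02)
  }
})

test_that("rectangular-lesion integrals are exact", {
  pos <- seq(0, 800, by = 10)
  beam <- beam_config(background_ca = 0, background_f = 0, background_cu = 0)
  n <- length(pos)
  mk_scan <- function(ca_wt) {
    cu <- rep(0, n); cu[pos == 800] <- 500
    linescan(pos, ca_wt * beam$yield_ca, rep(0, n), cu, rep(1, n))
  }
  before <- mk_scan(rep(27, n))
  after <- mk_scan(ifelse(pos < 100, 7, 27))
  pair <- superimpose(before, after, true_curves(beam))
  expect_equal(as.numeric(compute_ca_loss(pair, cfg10)), 2000,
               tolerance = 1e-9)
  # identity: before = after gives zero loss
  pair0 <- superimpose(before, before, true_curves(beam))
  expect_equal(as.numeric(compute_ca_loss(pair0, cfg10)), 0)

  # mineral-loss analogue: 500 mg/cm3 drop over 100 um
  db <- depth_profile(pos, rep(1100, n), "density", "mg/cm3")
  da <- depth_profile(pos, ifelse(pos < 100, 600, 1100), "density", "mg/cm3")
  expect_equal(as.numeric(compute_mineral_loss(db, da, cfg10)), 5e4,
               tolerance = 1e-9)
  expect_equal(as.numeric(compute_mineral_loss(db, db, cfg10)), 0)
})

test_that("F uptake and penetration follow their rectangle/step closed forms", {
  pos <- seq(0, 800, by = 10)
  zero <- bin_profile(depth_profile(pos, rep(0, length(pos))), 800, cfg10)
  expect_equal(as.numeric(compute_f_uptake(zero, 0, 800, cfg10)), 0)

  fprof <- bin_profile(depth_profile(pos, ifelse(pos < 200, 1000, 0)),
                       800, cfg10)
  expect_equal(as.numeric(compute_f_uptake(fprof, 0, 800, cfg10)), 2e5)

  cfg_lod <- analysis_config(f_lod = 100)
  fstep <- bin_profile(depth_profile(pos, ifelse(pos < 150, 1000, 0)),
                       800, cfg_lod)
  expect_equal(compute_f_penetration(fstep, 0, cfg_lod), 150)
  # all-background control-like profile: penetration 0
  bg <- bin_profile(depth_profile(pos, rep(20, length(pos))), 800, cfg_lod)
  expect_equal(compute_f_penetration(bg, 0, cfg_lod), 0)
  expect_error(compute_f_penetration(fstep, 0, cfg10), "f_lod")
})

test_that("integral metrics match brute-force oracles on random registered pairs", {
  set.seed(55)
  for (rep in 1:50) {
    pos <- seq(0, 800, by = 10)
    n <- length(pos)
    bvals <- rnorm(n, 27, 1)
    avals <- rnorm(n, 18, 4)
    fvals <- pmax(rnorm(n, 300, 200), 0)
    ref <- 800
    from <- runif(1, 0, 150)
    bb <- bin_profile(depth_profile(pos, bvals), ref, cfg10)
    ab <- bin_profile(depth_profile(pos, avals), ref, cfg10)
    fb <- bin_profile(depth_profile(pos, fvals), ref, cfg10)
    want_loss <- oracle_loss(bb$position_um, bb$value, ab$value, from, ref, 10)
    got_loss <- seqpixe:::.integrate_loss(bb, ab, from, ref, cfg10)
    expect_equal(as.numeric(got_loss), want_loss, tolerance = 1e-9)
    expect_equal(as.numeric(compute_f_uptake(fb, from, ref, cfg10)),
                 oracle_uptake(fb$position_um, fb$value, from, ref, 10),
                 tolerance = 1e-9)
    lod <- runif(1, 50, 400)
    cfg_lod <- analysis_config(f_lod = lod)
    expect_equal(compute_f_penetration(fb, from, cfg_lod),
                 oracle_penetration(fb$position_um, fb$value, from, lod))
  }
})

test_that("Ca loss is additive over bin-aligned subregions", {
  pos <- seq(0, 800, by = 10)
  set.seed(8)
  bb <- bin_profile(depth_profile(pos, rnorm(length(pos), 27, 1)), 800, cfg10)
  ab <- bin_profile(depth_profile(pos, rnorm(length(pos), 15, 3)), 800, cfg10)
  total <- oracle_loss(bb$position_um, bb$value, ab$value, 0, 800, 10)
  left <- oracle_loss(bb$position_um, bb$value, ab$value, 0, 395, 10)
  right <- oracle_loss(bb$position_um, bb$value, ab$value, 395, 800, 10)
  expect_equal(left + right, total, tolerance = 1e-9)
})

test_that("noise-free specimen analysis recovers the analytic truth integral", {
  tr <- specimen_truth(f_amplitude = 2500, group = "FCM")
  # fine 1 um sampling so 10 um bin means approximate true interval averages
  beam <- beam_config(step = 1, background_ca = 0, background_f = 0)
  pr <- make_noise_free_pair(tr, beam)
  curves <- true_curves(beam)
  m <- analyze_specimen(pr$before, pr$after, curves,
                        analysis_config(f_lod = 20))
  expect_lt(abs(m$ca_loss - true_ca_loss(tr)) / true_ca_loss(tr), 0.01)
  expect_lt(abs(m$f_uptake_before - true_f_uptake(tr, "before")) /
              true_f_uptake(tr, "before"), 0.02)
  # monotonicity: deeper lesions and stronger F give larger metrics
  deeper <- specimen_truth(f_amplitude = 2500, lesion_mid = 70, group = "FCM")
  pr2 <- make_noise_free_pair(deeper, beam)
  m2 <- analyze_specimen(pr2$before, pr2$after, curves,
                         analysis_config(f_lod = 20))
  expect_gt(m2$ca_loss, m$ca_loss)
  weaker <- specimen_truth(f_amplitude = 800, group = "FCM")
  pr3 <- make_noise_free_pair(weaker, beam)
  m3 <- analyze_specimen(pr3$before, pr3$after, curves,
                         analysis_config(f_lod = 20))
  expect_lt(m3$f_uptake_before, m$f_uptake_before)
  expect_lt(m3$f_penetration_before, m$f_penetration_before)
})

test_that("control specimens yield near-zero F metrics; identical scans give zero losses", {
  ctrl <- specimen_truth(f_amplitude = 0)
  beam <- beam_config()
  b <- simulate_linescan(ctrl, beam, "before", seed = 4)
  a <- simulate_linescan(ctrl, beam, "after", seed = 5)
  curves <- true_curves(beam)
  m <- analyze_specimen(b, a, curves)
  lod <- derive_f_lod(curves$f, 1)
  expect_lt(m$f_uptake_before, lod * 800)  # bounded by background-level signal
  expect_equal(m$f_penetration_before, 0)

  m_same <- analyze_specimen(b, b, curves)
  expect_equal(m_same$ca_loss, 0)
  expect_equal(m_same$f_uptake_before, m_same$f_uptake_after)
})

test_that("estimated Ca loss tracks truth across a noisy cohort (slope near 1)", {
  spec <- cohort_spec(n_pairs = 25, seed = 12, n_lines = 1)
  coh <- generate_cohort(spec, uct = FALSE)
  beam <- beam_config()
  curves <- true_curves(beam)
  est <- tru <- numeric(0)
  for (tooth in coh) for (g in c("fcm", "control")) {
    sp <- tooth[[g]]
    m <- analyze_specimen(sp$scans$before, sp$scans$after, curves)
    est <- c(est, m$ca_loss)
    tru <- c(tru, true_ca_loss(sp$truth))
  }
  slope <- coef(lm(est ~ tru))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})
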