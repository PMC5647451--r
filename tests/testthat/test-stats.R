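test_that("Mann-Whitney exact test handles the canonical small cases", {
  # identical multisets: perfect overlap, p = 1, U at its null mean
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 9 / 2)
  expect_equal(r$p_value, 1)
  expect_identical(r$method, "exact")

  # complete separation of 3 vs 3: U = 0, two-sided p = 2/20
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  expect_equal(r2$p_value, 0.1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p-values match brute-force enumeration on random samples", {
  set.seed(19)
  for (rep in 1:200) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    # integer draws force ties regularly
    a <- sample(1:6, n1, replace = TRUE)
    b <- sample(1:6, n2, replace = TRUE)
    got <- mann_whitney_u(a, b, method = "exact")
    want <- oracle_mwu(a, b)
    expect_equal(got$U, want$U, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free data and is monotone-invariant", {
  set.seed(23)
  for (rep in 1:25) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    got <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    # invariance under a common monotone transform of the pooled data
    tf <- mann_whitney_u(exp(a), exp(b))
    expect_identical(tf$p_value, got$p_value)
    expect_identical(tf$U, got$U)
  }
})

test_that("large samples fall back to a tie-corrected normal approximation", {
  set.seed(2)
  a <- rnorm(30, 0.6); b <- rnorm(25)
  got <- mann_whitney_u(a, b)
  expect_identical(got$method, "normal_approx")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Spearman rho is exact on monotone data and matches the midrank oracle under ties", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, -2 * x + 1)$rho, -1)
  expect_error(spearman_rho(x, rep(2, 5)), "constant")
  expect_error(spearman_rho(1:2, 1:2), "3")

  set.seed(41)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y)$rho,
                 suppressWarnings(cor.test(x, y, method = "spearman")$estimate[[1]]),
                 tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under separate monotone transforms", {
  set.seed(6)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- spearman_rho(x, y)
  r1 <- spearman_rho(exp(x), atan(y))
  expect_equal(r1$rho, r0$rho, tolerance = 1e-12)
  expect_equal(r1$p_value, r0$p_value, tolerance = 1e-12)
})

test_that("exact permutation p-values for Spearman match a brute-force enumeration", {
  set.seed(9)
  for (rep in 1:10) {
    n <- 5
    x <- rnorm(n); y <- rnorm(n)
    got <- spearman_rho(x, y, method = "exact")
    # brute force over all 120 permutations using the rank-product statistic
    rx <- rank(x); ry <- rank(y)
    perms <- seqpixe:::.all_perms(n)
    s <- apply(perms, 1, function(p) sum(rx * ry[p]))
    e_s <- sum(rx) * mean(ry)
    want <- mean(abs(s - e_s) >= abs(sum(rx * ry) - e_s) - 1e-9)
    expect_equal(got$p_value, want, tolerance = 1e-12)
    # and agrees with cor.test's exact Spearman p on tie-free data
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("type-I error of the exact test at alpha 0.05 stays near nominal", {
  set.seed(71)
  rejections <- vapply(1:500, function(i) {
    a <- rnorm(9); b <- rnorm(9)
    mann_whitney_u(a, b)$significant
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.08)
})

make_metrics_df <- function(n = 6, seed = 1) {
  set.seed(seed)
  data.frame(
    tooth_id = rep(sprintf("t%02d", 1:n), 2),
    group = rep(c("FCM", "control"), each = n),
    ca_loss = c(rnorm(n, 400, 80), rnorm(n, 1200, 200)),
    mineral_loss = c(rnorm(n, 1.5e4, 3e3), rnorm(n, 4.5e4, 8e3)),
    f_uptake_before = c(rnorm(n, 1e5, 2e4), abs(rnorm(n, 1e3, 5e2))),
    f_uptake_after = c(rnorm(n, 2e5, 4e4), abs(rnorm(n, 2e3, 1e3))),
    f_penetration_before = c(rnorm(n, 250, 40), rep(0, n)),
    f_penetration_after = c(rnorm(n, 450, 60), rep(0, n)))
}

test_that("cohort_report summarizes groups, tests and correlations", {
  df <- make_metrics_df()
  rep_ <- cohort_report(df)
  expect_s3_class(rep_, "cohort_report")
  expect_false(rep_$underpowered)
  expect_equal(nrow(rep_$summaries), 12)  # 6 metrics x 2 groups
  expect_length(rep_$comparisons, 6)
  expect_length(rep_$correlations, 4)
  cl <- rep_$comparisons[[1]]
  expect_identical(cl$metric, "ca_loss")
  expect_lt(cl$p_value, 0.05)
  med <- rep_$summaries
  expect_lt(med$median[med$metric == "ca_loss" & med$group == "FCM"],
            med$median[med$metric == "ca_loss" & med$group == "control"])
  # constant penetration in controls must not break the FCM-only correlation
  expect_true(all(vapply(rep_$correlations, function(x)
    is.na(x$rho) || (x$rho >= -1 && x$rho <= 1), logical(1))))
  expect_error(cohort_report(df[, -3]), "ca_loss")
})

test_that("degenerate cohorts are flagged, not crashed", {
  # all-identical specimens: p = 1 everywhere, correlations undefined
  df <- make_metrics_df()
  df[3:8] <- lapply(df[3:8], function(x) rep(1, length(x)))
  rep_ <- cohort_report(df)
  for (cmp in rep_$comparisons) expect_equal(cmp$p_value, 1)
  for (co in rep_$correlations) {
    expect_true(is.na(co$rho))
    expect_match(co$method, "undefined")
  }
  # single pair: underpowered flag, no crash
  df1 <- make_metrics_df(n = 1)
  rep1 <- cohort_report(df1)
  expect_true(rep1$underpowered)
  expect_true(all(is.na(vapply(rep1$comparisons, `[[`, numeric(1),
                               "p_value"))))
})
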