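# Memoized permutation distributions of the rank-sum statistic.  The exact
# null distribution of U depends only on (n1, n2, multiset of pooled
# midranks), so for tie-free data one enumeration per sample-size pair
# serves every call.
.mwu_cache <- new.env(parent = emptyenv())

.mwu_exact_udist <- function(ranks, n1) {
  key <- paste(n1, length(ranks), paste(signif(sort(ranks), 12),
                                        collapse = ","), sep = "|")
  hit <- .mwu_cache[[key]]
  if (!is.null(hit)) return(hit)
  combos <- utils::combn(length(ranks), n1)
  udist <- colSums(matrix(ranks[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  if (length(.mwu_cache) > 32L) rm(list = ls(.mwu_cache), envir = .mwu_cache)
  .mwu_cache[[key]] <- udist
  udist
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Rank-sum test of two independent samples, with midranks for ties.  For
#' `n1, n2 <= 10` (covering the nine-pair study design) the two-sided p-value
#' is exact: every one of the `choose(n1 + n2, n1)` group labelings of the
#' pooled data is enumerated and the p-value is the probability of a U at
#' least as far from its null mean `n1 * n2 / 2` as observed.  Larger samples
#' use the normal approximation with tie and continuity corrections.
#'
#' @param a,b Non-empty numeric samples.
#' @param alpha Significance level (default 0.05, i.e. 95\% confidence).
#' @param method `"auto"` (exact when both n <= 10), `"exact"`, or
#'   `"normal"`.
#' @param metric Optional label of the compared quantity.
#' @return An object of class `group_comparison`: `U`, `p_value`, `method`,
#'   `n1`, `n2`, `significant`.
#' @export
mann_whitney_u <- function(a, b, alpha = 0.05,
                           method = c("auto", "exact", "normal"),
                           metric = NULL) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  use_exact <- switch(method,
                      auto = n1 <= 10 && n2 <= 10,
                      exact = TRUE, normal = FALSE)
  if (use_exact && n1 > 12) stop("exact enumeration limited to n <= 12")
  if (use_exact) {
    udist <- .mwu_exact_udist(r, n1)
    p <- mean(abs(udist - mu) >= abs(U - mu) - 1e-9)
    meth <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    meth <- "normal_approx"
  }
  structure(list(metric = metric, n1 = n1, n2 = n2, U = U, p_value = p,
                 method = meth, alpha = alpha, significant = p < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test%s\n",
              if (is.null(x$metric)) "" else paste0(" [", x$metric, "]")))
  cat(sprintf("  n1 = %d, n2 = %d, U = %.1f, p = %.4g (%s)%s\n",
              x$n1, x$n2, x$U, x$p_value, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

# All permutations of 1..n as a matrix (n! rows); used by the exact
# permutation p-value for small n.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with ties
#'
#' Pearson correlation of the midranks of `x` and `y`.  The p-value uses the
#' t-distribution approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom; for `n <= 9` an exact permutation p-value
#' (enumeration of all `n!` pairings) is available.
#'
#' @param x,y Equal-length numeric samples, `n >= 3`.
#' @param alpha Significance level (default 0.01, i.e. 99\% confidence).
#' @param method `"t"` (default) or `"exact"` (permutation, n <= 9).
#' @param pair Optional label of the variable pair.
#' @return An object of class `correlation_result`: `rho`, `p_value`, `n`,
#'   `significant`.
#' @export
spearman_rho <- function(x, y, alpha = 0.01, method = c("t", "exact"),
                         pair = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 9L) stop("exact permutation limited to n <= 9")
    perms <- .all_perms(n)
    sdist <- as.vector(matrix(ry[perms], nrow(perms), n) %*% rx)
    s_obs <- sum(rx * ry)
    e_s <- sum(rx) * mean(ry)
    p <- mean(abs(sdist - e_s) >= abs(s_obs - e_s) - 1e-9)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  structure(list(pair = pair, rho = rho, p_value = p, n = n,
                 method = if (method == "exact") "exact_permutation"
                          else "t_approx",
                 alpha = alpha, significant = p < alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation%s\n",
              if (is.null(x$pair)) "" else paste0(" [", x$pair, "]")))
  cat(sprintf("  n = %d, rho = %.3f, p = %.4g (%s)%s\n",
              x$n, x$rho, x$p_value, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

.report_metrics <- c("ca_loss", "mineral_loss", "f_uptake_before",
                     "f_uptake_after", "f_penetration_before",
                     "f_penetration_after")

#' Cohort-level report: group summaries, tests, correlations
#'
#' From a per-specimen metrics table (one row per specimen, as produced by
#' [cohort_metrics()]), computes per-group median and range (min~max) of each
#' lesion metric, Mann-Whitney U comparisons of FCM vs control for every
#' metric, and the Spearman correlations of the study design: (Ca loss,
#' mineral loss), (F uptake before, Ca loss), (F penetration before, Ca
#' loss), plus the FCM-only (F penetration before, Ca loss) correlation.
#' Undefined correlations (constant input) are flagged, not errors.  A group
#' with fewer than 2 specimens marks the report `underpowered` and skips the
#' tests rather than failing.
#'
#' @param metrics A `data.frame` with columns `group` (values `FCM`,
#'   `control`) and the six lesion metrics; missing columns are named in the
#'   error.
#' @param alpha_u Significance level of the group comparisons (default 0.05).
#' @param alpha_rho Significance level of the correlations (default 0.01).
#' @return An object of class `cohort_report`.
#' @export
cohort_report <- function(metrics, alpha_u = 0.05, alpha_rho = 0.01) {
  stopifnot(is.data.frame(metrics))
  need <- c("group", .report_metrics)
  miss <- setdiff(need, names(metrics))
  # mineral_loss is optional (no uCT supplied)
  miss <- setdiff(miss, "mineral_loss")
  if (length(miss))
    stop("missing metric column(s): ", paste(miss, collapse = ", "))
  if (!"mineral_loss" %in% names(metrics))
    metrics$mineral_loss <- NA_real_
  groups <- c("FCM", "control")
  if (!all(metrics$group %in% groups))
    stop("'group' must be 'FCM' or 'control'")
  n_by <- table(factor(metrics$group, groups))
  if (any(n_by == 0)) stop("both groups must be present")
  underpowered <- any(n_by < 2)
  have <- function(col) !all(is.na(metrics[[col]]))
  summaries <- do.call(rbind, lapply(.report_metrics, function(m) {
    if (!have(m)) return(NULL)
    do.call(rbind, lapply(groups, function(g) {
      v <- metrics[[m]][metrics$group == g]
      v <- v[!is.na(v)]
      data.frame(metric = m, group = g, n = length(v),
                 median = stats::median(v), min = min(v), max = max(v))
    }))
  }))
  comparisons <- lapply(.report_metrics, function(m) {
    if (!have(m)) return(NULL)
    if (underpowered)
      return(structure(list(metric = m, n1 = n_by[["FCM"]],
                            n2 = n_by[["control"]], U = NA_real_,
                            p_value = NA_real_, method = "underpowered",
                            alpha = alpha_u, significant = NA),
                       class = "group_comparison"))
    mann_whitney_u(metrics[[m]][metrics$group == "FCM"],
                   metrics[[m]][metrics$group == "control"],
                   alpha = alpha_u, metric = m)
  })
  comparisons <- Filter(Negate(is.null), comparisons)
  corr_spec <- list(
    c("ca_loss", "mineral_loss", "pooled"),
    c("f_uptake_before", "ca_loss", "pooled"),
    c("f_penetration_before", "ca_loss", "pooled"),
    c("f_penetration_before", "ca_loss", "FCM"))
  correlations <- lapply(corr_spec, function(cs) {
    sub <- if (cs[3] == "FCM") metrics[metrics$group == "FCM", ] else metrics
    label <- sprintf("%s vs %s (%s)", cs[1], cs[2], cs[3])
    x <- sub[[cs[1]]]; y <- sub[[cs[2]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L)
      return(structure(list(pair = label, rho = NA_real_, p_value = NA_real_,
                            n = sum(ok), method = "insufficient_data",
                            alpha = alpha_rho, significant = NA),
                       class = "correlation_result"))
    tryCatch(spearman_rho(x[ok], y[ok], alpha = alpha_rho, pair = label),
             error = function(e)
               structure(list(pair = label, rho = NA_real_,
                              p_value = NA_real_, n = sum(ok),
                              method = paste("undefined:",
                                             conditionMessage(e)),
                              alpha = alpha_rho, significant = NA),
                         class = "correlation_result"))
  })
  structure(list(n_fcm = as.integer(n_by[["FCM"]]),
                 n_control = as.integer(n_by[["control"]]),
                 underpowered = underpowered,
                 summaries = summaries,
                 comparisons = comparisons,
                 correlations = correlations,
                 alpha_u = alpha_u, alpha_rho = alpha_rho),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d FCM, %d control specimen(s)%s\n",
              x$n_fcm, x$n_control,
              if (x$underpowered) "  [UNDERPOWERED: tests skipped]" else ""))
  cat("\nGroup summaries (median [min ~ max]):\n")
  s <- x$summaries
  for (m in unique(s$metric)) {
    rows <- s[s$metric == m, ]
    cat(sprintf("  %-22s", m))
    cat(paste(sprintf("%s %.4g [%.4g ~ %.4g]", rows$group, rows$median,
                      rows$min, rows$max), collapse = "   "), "\n")
  }
  cat("\nFCM vs control (Mann-Whitney U):\n")
  for (cmp in x$comparisons)
    cat(sprintf("  %-22s U = %5.1f  p = %.4g%s\n", cmp$metric, cmp$U,
                cmp$p_value,
                if (isTRUE(cmp$significant)) " *" else ""))
  cat("\nSpearman correlations:\n")
  for (co in x$correlations)
    cat(sprintf("  %-42s rho = %6.3f  p = %.4g%s\n", co$pair, co$rho,
                co$p_value, if (isTRUE(co$significant)) " *" else ""))
  invisible(x)
}
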