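# Group-comparison and reliability statistics: one-way ANOVA (raw and
# summary-statistic forms), robust alternatives, effect size, Bonferroni
# post hocs, chi-square, and two-way mixed absolute-agreement single-measure
# ICC.

new_anova <- function(F, df1, df2, msw = NA_real_, posthoc = NULL) {
  structure(list(F = F, df_between = df1, df_within = df2,
                 p = stats::pf(F, df1, df2, lower.tail = FALSE),
                 eta2p = partial_eta_squared(F, df1, df2),
                 msw = msw, posthoc = posthoc),
            class = "start_anova")
}

#' @export
print.start_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$eta2p))
  if (!is.null(x$posthoc)) {
    cat("Bonferroni post hoc:\n")
    for (nm in names(x$posthoc)) cat(sprintf("  %s: p = %.4g\n", nm, x$posthoc[[nm]]))
  }
  invisible(x)
}

#' Partial eta-squared from an F statistic
#'
#' The one-way ANOVA effect size F*df1 / (F*df1 + df2).
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Effect size in \[0, 1).
#' @export
partial_eta_squared <- function(F, df1, df2) {
  F * df1 / (F * df1 + df2)
}

#' One-way ANOVA from printed group summaries
#'
#' Reconstructs the classical fixed-effects one-way ANOVA from per-group
#' (n, mean, sd): the between-group sum of squares is sum n_i (m_i - m.)^2
#' about the n-weighted grand mean and the within-group sum of squares is
#' sum (n_i - 1) sd_i^2. Identical to the raw-data ANOVA on any data with
#' those summaries.
#'
#' @param summary a `start_summary` (see [read_summary_table()]) or a data
#'   frame with columns `n`, `mean`, `sd`.
#' @return A `start_anova` with F, dfs, p and partial eta-squared.
#' @export
anova_from_summary <- function(summary) {
  g <- if (inherits(summary, "start_summary")) summary$groups else summary
  if (any(g$n <= 1)) stopf("every group must have n > 1")
  if (any(g$sd < 0)) stopf("group sd must be non-negative")
  N <- sum(g$n)
  k <- nrow(g)
  gm <- sum(g$n * g$mean) / N
  ssb <- sum(g$n * (g$mean - gm)^2)
  ssw <- sum((g$n - 1) * g$sd^2)
  if (ssw == 0 && ssb == 0) stopf("degenerate input: all observations identical")
  df1 <- k - 1
  df2 <- N - k
  new_anova((ssb / df1) / (ssw / df2), df1, df2, msw = ssw / df2)
}

split_groups <- function(values, group) {
  if (!is.null(dim(values))) stopf("values must be a vector")
  g <- split(as.numeric(values), group)
  g <- lapply(g, function(v) v[!is.na(v)])
  g <- g[vapply(g, length, integer(1)) > 0]
  if (length(g) < 2) stopf("need at least 2 non-empty groups")
  if (any(vapply(g, length, integer(1)) < 2)) stopf("every group must have n > 1")
  g
}

#' One-way ANOVA on raw data
#'
#' Classical fixed-effects one-way ANOVA computed from definitional sums of
#' squares, with Bonferroni-adjusted pairwise post hocs using the pooled
#' within-group mean square.
#'
#' @param values numeric vector of observations.
#' @param group grouping factor/vector, parallel to `values`.
#' @param posthoc compute Bonferroni pairwise comparisons?
#' @return A `start_anova`.
#' @export
anova_oneway <- function(values, group, posthoc = TRUE) {
  g <- split_groups(values, group)
  ns <- vapply(g, length, integer(1))
  ms <- vapply(g, mean, numeric(1))
  sds <- vapply(g, stats::sd, numeric(1))
  res <- anova_from_summary(data.frame(n = ns, mean = ms, sd = sds))
  if (posthoc) res$posthoc <- bonferroni_posthoc(values, group, res$msw, res$df_within)
  res
}

#' Bonferroni pairwise post hoc comparisons
#'
#' Pairwise t statistics using the pooled within-group mean square from the
#' omnibus ANOVA; two-sided p-values are multiplied by the number of pairs
#' and capped at 1.
#'
#' @param values,group as in [anova_oneway()].
#' @param msw pooled within-group mean square.
#' @param df_w within-group degrees of freedom.
#' @return Named numeric of adjusted p-values, one per group pair
#'   (`"A vs B"`).
#' @export
bonferroni_posthoc <- function(values, group, msw, df_w) {
  g <- split_groups(values, group)
  nm <- names(g)
  pairs <- utils::combn(length(g), 2)
  npairs <- ncol(pairs)
  out <- numeric(npairs)
  labs <- character(npairs)
  for (j in seq_len(npairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(msw * (1 / length(g[[a]]) + 1 / length(g[[b]])))
    tstat <- (mean(g[[a]]) - mean(g[[b]])) / se
    out[j] <- min(1, 2 * stats::pt(abs(tstat), df_w, lower.tail = FALSE) * npairs)
    labs[j] <- sprintf("%s vs %s", nm[a], nm[b])
  }
  stats::setNames(out, labs)
}

#' Robust and non-parametric alternatives
#'
#' `welch_anova()` is the Welch heteroscedasticity-robust one-way test,
#' `brown_forsythe()` the Brown-Forsythe robust F* (group deviations about a
#' variance-weighted denominator with Satterthwaite df), `kruskal_wallis()`
#' the rank-based test, `levene_test()` the Brown-Forsythe spread test
#' (one-way ANOVA on absolute deviations from group medians) and
#' `normality_check()` the per-sample Shapiro-Wilk test.
#'
#' @param values,group as in [anova_oneway()].
#' @return A list with the statistic, degrees of freedom and p-value.
#' @name robust-tests
NULL

#' @rdname robust-tests
#' @export
welch_anova <- function(values, group) {
  g <- split_groups(values, group)
  ht <- stats::oneway.test(v ~ gr,
                           data = data.frame(v = unlist(g),
                                             gr = rep(names(g), lengths(g))),
                           var.equal = FALSE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p = ht$p.value)
}

#' @rdname robust-tests
#' @export
brown_forsythe <- function(values, group) {
  g <- split_groups(values, group)
  ns <- lengths(g)
  N <- sum(ns)
  ms <- vapply(g, mean, numeric(1))
  vs <- vapply(g, stats::var, numeric(1))
  gm <- sum(ns * ms) / N
  num <- sum(ns * (ms - gm)^2)
  ci <- (1 - ns / N) * vs
  den <- sum(ci)
  Fstar <- num / den
  df1 <- length(g) - 1
  df2 <- den^2 / sum(ci^2 / (ns - 1))
  list(F = Fstar, df1 = df1, df2 = df2,
       p = stats::pf(Fstar, df1, df2, lower.tail = FALSE))
}

#' @rdname robust-tests
#' @export
kruskal_wallis <- function(values, group) {
  g <- split_groups(values, group)
  ht <- stats::kruskal.test(g)
  list(H = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' @rdname robust-tests
#' @export
levene_test <- function(values, group) {
  g <- split_groups(values, group)
  dev <- lapply(g, function(v) abs(v - stats::median(v)))
  res <- anova_oneway(unlist(dev), rep(names(g), lengths(g)), posthoc = FALSE)
  list(W = res$F, df1 = res$df_between, df2 = res$df_within, p = res$p)
}

#' @rdname robust-tests
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || stats::sd(values) == 0) {
    return(list(stat = NA_real_, p = NA_real_))
  }
  ht <- stats::shapiro.test(values)
  list(stat = unname(ht$statistic), p = ht$p.value)
}

#' Assumption-aware group comparison
#'
#' Runs the classical one-way ANOVA and, alongside it, the robust variants
#' triggered by failed assumption checks at `alpha`: Welch and
#' Brown-Forsythe when homogeneity of variance fails (Levene), and
#' Kruskal-Wallis when per-group normality fails (Shapiro-Wilk). Nothing is
#' silently substituted; all computed results are reported.
#'
#' @param values,group as in [anova_oneway()].
#' @param alpha assumption-check significance level.
#' @return A list: `anova`, `checks` (levene + per-group shapiro p),
#'   `welch`/`brown_forsythe` (when variance homogeneity fails),
#'   `kruskal_wallis` (when normality fails).
#' @export
compare_groups <- function(values, group, alpha = 0.05) {
  g <- split_groups(values, group)
  lev <- levene_test(values, group)
  shap <- vapply(g, function(v) normality_check(v)$p, numeric(1))
  out <- list(anova = anova_oneway(values, group),
              checks = list(levene_p = lev$p, shapiro_p = shap))
  if (is.finite(lev$p) && lev$p < alpha) {
    out$welch <- welch_anova(values, group)
    out$brown_forsythe <- brown_forsythe(values, group)
  }
  if (any(is.finite(shap) & shap < alpha)) {
    out$kruskal_wallis <- kruskal_wallis(values, group)
  }
  out
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic sum (O-E)^2/E without continuity correction,
#' df = (r-1)(c-1). Used for the sex-by-group contingency table.
#'
#' @param table an r x c matrix of counts.
#' @return list(chi2, df, p).
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("chi-square undefined: zero marginal")
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way mixed-effects model, absolute agreement, single measure:
#' ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)) with MSR,
#' MSC, MSE the subject, rater and error mean squares of the two-way layout.
#' The p-value tests ICC = 0 via F = MSR/MSE, and the confidence interval
#' follows the standard absolute-agreement F approximation (Satterthwaite
#' denominator df).
#'
#' @param ratings complete subjects x raters numeric matrix (>= 5 subjects,
#'   >= 2 raters).
#' @param conf_level confidence level for the interval.
#' @return A `start_icc`: `icc`, `p`, `ci95`, mean squares and dimensions.
#' @export
icc_a1 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stopf("ratings matrix must be complete")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5 || k < 2) stopf("need >= 5 subjects and >= 2 raters")
  gm <- mean(ratings)
  if (all(ratings == ratings[1])) stopf("zero total variance: ICC undefined")
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  SSR <- k * sum((row_m - gm)^2)
  SSC <- n * sum((col_m - gm)^2)
  SST <- sum((ratings - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  Fv <- MSR / MSE
  p <- stats::pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(icc = icc, p = p, ci95 = c(lower = lo, upper = hi),
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE), n = n, k = k),
            class = "start_icc")
}

#' @export
print.start_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f, p = %.4g, 95%% CI [%.3f, %.3f] (%d subjects, %d raters)\n",
              x$icc, x$p, x$ci95[1], x$ci95[2], x$n, x$k))
  invisible(x)
}

#' Group-comparison table for a feature table
#'
#' Per measure: per-group n/mean/SD, F, partial eta-squared, p and the
#' Bonferroni post hoc p-values, laid out one measure per row.
#'
#' @param features a `start_features` data frame.
#' @param measures feature slots to tabulate (default: the 14 measures with
#'   printed group-comparison rows).
#' @return A data frame of class `start_group_table`.
#' @export
group_table <- function(features,
                        measures = setdiff(FEATURE_SLOTS,
                                           c("wheel_dist_min", "wheel_dist_max"))) {
  rows <- lapply(measures, function(m) {
    v <- features[[m]]
    g <- factor(features$group, GROUP_LEVELS)
    keep <- !is.na(v)
    base <- data.frame(measure = m)
    for (lev in GROUP_LEVELS) {
      vv <- v[keep & g == lev]
      base[[paste0("n_", lev)]] <- length(vv)
      base[[paste0("mean_", lev)]] <- if (length(vv)) mean(vv) else NA_real_
      base[[paste0("sd_", lev)]] <- if (length(vv) > 1) stats::sd(vv) else NA_real_
    }
    res <- tryCatch(anova_oneway(v[keep], droplevels(g[keep])), error = function(e) NULL)
    base$F <- if (is.null(res)) NA_real_ else res$F
    base$eta2p <- if (is.null(res)) NA_real_ else res$eta2p
    base$p <- if (is.null(res)) NA_real_ else res$p
    ph <- if (is.null(res)) NULL else res$posthoc
    base$p_TD_AS <- ph[["TD vs AS"]] %||% NA_real_
    base$p_TD_ID <- ph[["TD vs ID"]] %||% NA_real_
    base$p_AS_ID <- ph[["AS vs ID"]] %||% NA_real_
    base
  })
  structure(do.call(rbind, rows), class = c("start_group_table", "data.frame"))
}

#' @export
print.start_group_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  numcols <- vapply(df, is.numeric, logical(1))
  df[numcols] <- lapply(df[numcols], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
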