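#' @importFrom stats aov TukeyHSD manova chisq.test ks.test p.adjust
#'   pf setNames
NULL

test_result <- function(test, statistic, df, p, detail = list(),
                        degenerate = FALSE) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 detail = detail, degenerate = degenerate),
            class = "stemtraj_test")
}

#' @export
print.stemtraj_test <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", df = ", paste(format(x$df, digits = 4), collapse = "/"),
      ", p = ", format.pval(x$p, digits = 3),
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic Kolmogorov p value; ties
#' are handled by evaluating both ECDFs on the pooled support.
#'
#' @param a,b Numeric samples.
#' @return A `stemtraj_test` with the D statistic and p value.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  # D evaluated on the pooled support (robust to ties)
  pooled <- sort(unique(c(a, b)))
  d_stat <- max(abs(stats::ecdf(a)(pooled) - stats::ecdf(b)(pooled)))
  p <- if (d_stat == 0) 1 else
    suppressWarnings(stats::ks.test(a, b, exact = FALSE)$p.value)
  test_result("ks_two_sample", statistic = d_stat, df = NA_real_,
              p = min(1, max(p, .Machine$double.xmin)),
              detail = list(n_a = length(a), n_b = length(b)))
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' F test with (k-1, N-k) degrees of freedom followed by Tukey's honestly
#' significant difference comparisons via the studentized range
#' distribution. If the data carry no variance at all the result is flagged
#' degenerate with `F = 0, p = 1`.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @param alpha Level used to report the Tukey confidence intervals.
#' @return A `stemtraj_test`; the pairwise Tukey table is
#'   `$detail$tukey` (columns diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (min(table(groups)) < 2) stop("every group needs at least 2 observations")
  if (stats::var(values) == 0) {
    k <- nlevels(groups); n <- length(values)
    return(test_result("anova_oneway", statistic = 0,
                       df = c(k - 1, n - k), p = 1, degenerate = TRUE))
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  fstat <- s$`F value`[1]
  p <- s$`Pr(>F)`[1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  test_result("anova_oneway", statistic = fstat,
              df = c(s$Df[1], s$Df[2]), p = p,
              detail = list(tukey = tukey,
                            group_means = tapply(values, groups, mean)))
}

#' Two-response MANOVA (Pillai trace)
#'
#' Compares bivariate group means with the Pillai trace statistic and its F
#' approximation; observational units (typically mice) are treated as
#' independent.
#'
#' @param Y n x 2 numeric response matrix.
#' @param groups Group labels (coerced to factor).
#' @return A `stemtraj_test` with the Pillai statistic, the approximate F
#'   and its df pair in `$detail`.
#' @export
manova_two_response <- function(Y, groups) {
  Y <- as.matrix(Y)
  groups <- factor(groups)
  if (ncol(Y) != 2) stop("Y must have exactly two response columns")
  k <- nlevels(groups)
  if (nrow(Y) <= k + 2) stop("need n > k + 2 observations")
  if (all(apply(Y, 2, function(col)
    max(abs(tapply(col, groups, mean) - mean(col))) < 1e-12))) {
    return(test_result("manova_pillai", statistic = 0, df = NA_real_, p = 1,
                       degenerate = TRUE))
  }
  resid <- Y - apply(Y, 2, function(col) stats::ave(col, groups))
  if (qr(resid)$rank < 2 || stats::var(resid[, 1]) == 0 ||
      stats::var(resid[, 2]) == 0)
    stop("singular within-group covariance (collinear or constant responses)")
  fit <- stats::manova(Y ~ groups)
  s <- summary(fit, test = "Pillai")$stats
  test_result("manova_pillai", statistic = s["groups", "Pillai"],
              df = c(s["groups", "num Df"], s["groups", "den Df"]),
              p = s["groups", "Pr(>F)"],
              detail = list(approx_F = s["groups", "approx F"]))
}

#' Pearson chi-squared test with Monte-Carlo p value
#'
#' Pearson statistic on an r x c contingency table with
#' `p = (1 + #{simulated >= observed}) / (n_sim + 1)`, simulating tables
#' with the observed margins fixed (Patefield sampling).
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param n_sim Number of simulated tables (default 2000).
#' @param seed Integer seed.
#' @return A `stemtraj_test`.
#' @export
chisq_mc <- function(table, n_sim = 2000, seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has a zero row or column margin")
  res <- with_seed(seed, suppressWarnings(
    stats::chisq.test(table, simulate.p.value = TRUE, B = n_sim)))
  stat <- unname(res$statistic)
  test_result("chisq_mc", statistic = stat, df = NA_real_,
              p = if (stat == 0) 1 else unname(res$p.value),
              detail = list(n_sim = n_sim, seed = seed))
}
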