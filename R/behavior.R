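#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test of observed genotype counts against the
#' Hardy-Weinberg expectations `N p^2, 2 N p q, N q^2`, where `p` is the
#' A-allele frequency estimated from the counts. 1 degree of freedom.
#'
#' @param n_AA,n_AG,n_GG Non-negative genotype counts.
#' @return List with `chi2`, `df` (1), `p`, `allele_freq_A`, `expected`.
#' @export
hwe_chi2 <- function(n_AA, n_AG, n_GG) {
  counts <- c(n_AA, n_AG, n_GG)
  if (any(counts < 0)) stop_field("counts", "must be non-negative")
  N <- sum(counts)
  if (N < 1) stop_field("counts", "total count is zero")
  p <- (2 * n_AA + n_AG) / (2 * N)
  q <- 1 - p
  expected <- N * c(p^2, 2 * p * q, q^2)
  if (any(expected == 0)) {
    chi2 <- sum((counts[expected > 0] - expected[expected > 0])^2 /
                  expected[expected > 0])
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
  }
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       allele_freq_A = p, expected = expected)
}

#' Pearson chi-square test of a contingency table
#'
#' Without continuity correction, as used for sex-by-genotype comparisons.
#'
#' @param table Integer matrix of counts (e.g. 2 x 3), no zero marginal.
#' @return List with `chi2`, `df`, `p`.
#' @export
contingency_chi2 <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop_field("table", "must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_field("table", "has a zero marginal")
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' One-way ANOVA from group summary moments
#'
#' Reconstructs the one-way ANOVA F statistic from per-group size, mean
#' and SD (as printed in demographic tables):
#' `SSB = sum n_i (m_i - grand)^2`, `SSW = sum (n_i - 1) sd_i^2`,
#' `F = (SSB / (k - 1)) / (SSW / (N - k))` - algebraically identical to
#' the raw-data ANOVA with those moments.
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param mean Numeric vector of group means.
#' @param sd Numeric vector of group SDs.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(n, mean, sd) {
  k <- length(n)
  if (k < 2L) stop_field("n", "need at least 2 groups")
  if (length(mean) != k || length(sd) != k)
    stop_field("mean", "n, mean, sd must have equal length")
  if (any(n < 2)) stop_field("n", "every group needs n >= 2")
  if (any(!is.finite(sd)) || any(sd < 0))
    stop_field("sd", "must be finite and non-negative")
  N <- sum(n)
  grand <- sum(n * mean) / N
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- k - 1L; df2 <- N - k
  Fv <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = as.integer(df2),
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' One-way ANOVA on raw values
#'
#' Standard between/within decomposition; agrees exactly with
#' [anova_from_summary()] applied to the sample's own group moments.
#'
#' @param values Numeric vector.
#' @param labels Group labels, each group with >= 2 observations.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
oneway_anova <- function(values, labels) {
  g <- factor(labels)
  ng <- table(g)
  if (nlevels(g) < 2L) stop_field("labels", "need at least 2 groups")
  if (any(ng < 2L)) stop_field("labels", "every group needs >= 2 values")
  anova_from_summary(as.integer(ng),
                     as.numeric(tapply(values, g, mean)),
                     as.numeric(tapply(values, g, stats::sd)))
}

#' Genotype-stratified Spearman brain-behavior correlations
#'
#' Spearman rank correlation (average ranks for ties) between a
#' per-subject brain measure and each behavioral score column, separately
#' within each genotype group, with two-tailed p from the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` and a Bonferroni-style
#' significance flag at `p < 0.05 / alpha_divisor`.
#'
#' @param brain_values Numeric per-subject vector (e.g. cluster FCS).
#' @param scores Data frame of per-subject score columns.
#' @param genotypes Group labels per subject.
#' @param alpha_divisor Bonferroni divisor applied to 0.05 (default 5).
#' @return Data frame with one row per (group, score): `group`, `score`,
#'   `n`, `rho`, `p`, `significant`. A constant vector within a group
#'   yields NA rho/p with a warning.
#' @export
spearman_by_group <- function(brain_values, scores, genotypes,
                              alpha_divisor = 5) {
  g <- factor(genotypes)
  scores <- as.data.frame(scores)
  if (length(brain_values) != nrow(scores) ||
      length(brain_values) != length(g))
    stop_field("scores", "inputs disagree on subject count")
  alpha <- 0.05 / alpha_divisor
  out <- list()
  for (lev in levels(g)) {
    idx <- which(g == lev)
    for (sc in names(scores)) {
      x <- brain_values[idx]; y <- scores[[sc]][idx]
      n <- length(idx)
      if (n < 4L || stats::sd(x) == 0 || stats::sd(y) == 0) {
        if (n >= 4L)
          warning(sprintf(
            "constant values in group %s, score %s: rho undefined",
            lev, sc), call. = FALSE)
        rho <- NA_real_; p <- NA_real_
      } else {
        rho <- stats::cor(rank(x), rank(y))
        tv <- rho * sqrt((n - 2) / (1 - min(rho^2, 1 - 1e-15)))
        p <- 2 * stats::pt(-abs(tv), n - 2)
      }
      out[[length(out) + 1L]] <- data.frame(
        group = lev, score = sc, n = n, rho = rho, p = p,
        significant = !is.na(p) & p < alpha, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  res
}
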