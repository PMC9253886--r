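# Effect sizes and non-parametric tests: Cohen's d on the root-mean-variance
# scale, two-tailed rank tests, Kruskal-Wallis gating of Dunn-Holland-Wolfe
# multiple comparisons, KS distribution tests, and fold ratios.

#' Cohen's d from group means and SDs
#'
#' d = |M1 - M2| / sqrt((SD1^2 + SD2^2) / 2), with the effect-size scale
#' anchored at small (d <= 0.2), medium (d = 0.5), large (d = 0.8) and very
#' large (d >= 1.2); label boundaries are the midpoints between anchors
#' (0.35, 0.65, 1.2).
#'
#' @param m1,sd1,m2,sd2 group means and standard deviations.
#' @return list of class "effect_size": d, label.
#' @export
#' @examples
#' cohens_d(0.589, 0.147, 0.365, 0.133)$d  # 1.60
cohens_d <- function(m1, sd1, m2, sd2) {
  if (sd1 == 0 && sd2 == 0) stop("both SDs are 0: d is undefined")
  d <- abs(m1 - m2) / sqrt((sd1^2 + sd2^2) / 2)
  structure(list(d = d, label = effect_label(d)), class = "effect_size")
}

effect_label <- function(d) {
  if (d < 0.35) "small"
  else if (d < 0.65) "medium"
  else if (d < 1.2) "large"
  else "very large"
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%s)\n", x$d, x$label)); invisible(x)
}

#' Fold ratio
#'
#' @param a,b numerator and denominator; b must be > 0.
#' @param digits rounding used in reports (default 2); the full-precision
#'   value is returned in \code{ratio}.
#' @return list(ratio, rounded).
#' @export
#' @examples
#' fold_ratio(17.57, 9.53)$rounded  # 1.84
fold_ratio <- function(a, b, digits = 2) {
  if (b <= 0) stop("denominator must be > 0")
  r <- a / b
  list(ratio = r, rounded = round(r, digits))
}

#' Two-tailed rank and distribution tests
#'
#' Thin dispatch over the standard non-parametric tests used throughout the
#' pipeline, with exact small-sample p-values where available:
#' \itemize{
#'   \item \code{mww}: Wilcoxon-Mann-Whitney rank-sum for unpaired samples
#'     (exact when combined n <= 25 and no ties);
#'   \item \code{wilcoxon_signed}: Wilcoxon signed-rank for paired samples;
#'   \item \code{kw}: Kruskal-Wallis across a list of groups;
#'   \item \code{ks}: two-sample Kolmogorov-Smirnov (significance 0.001).
#' }
#'
#' @param x first sample, or a list of groups for \code{kind = "kw"}.
#' @param y second sample (ignored for kw).
#' @param kind test kind.
#' @return list(statistic, p_value, kind, alpha, significant).
#' @export
rank_tests <- function(x, y = NULL, kind = c("mww", "wilcoxon_signed",
                                             "kw", "ks")) {
  kind <- match.arg(kind)
  alpha <- if (kind == "ks") 0.001 else 0.05
  res <- switch(kind,
    mww = {
      if (!length(x) || !length(y)) stop("empty sample")
      exact <- (length(x) + length(y)) <= 25
      suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                          correct = !exact))
    },
    wilcoxon_signed = {
      if (!length(x) || length(x) != length(y)) stop("need equal-length pairs")
      d <- x - y
      if (all(d == 0)) {
        return(list(statistic = NA_real_, p_value = NA_real_, kind = kind,
                    alpha = alpha, significant = NA,
                    flag = "all paired differences are zero: test undefined"))
      }
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                          exact = length(x) <= 25))
    },
    kw = {
      if (!is.list(x)) stop("kw expects a list of groups")
      if (any(!lengths(x))) stop("empty sample")
      stats::kruskal.test(x)
    },
    ks = {
      if (!length(x) || !length(y)) stop("empty sample")
      suppressWarnings(stats::ks.test(x, y))
    })
  list(statistic = unname(res$statistic), p_value = res$p.value, kind = kind,
       alpha = alpha, significant = res$p.value < alpha)
}

#' Dunn-Holland-Wolfe multiple comparisons after Kruskal-Wallis
#'
#' Pairwise mean-rank comparisons for unequal sample sizes, gated on a
#' significant Kruskal-Wallis test: z = (Rbar_i - Rbar_j) /
#' sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) with tie correction
#' T = sum(t^3 - t) / (12 (N - 1)); family-wise adjusted p-values multiply
#' the two-sided normal p by the number of comparisons.
#'
#' @param groups named list of numeric samples (>= 2 groups).
#' @param alpha Kruskal-Wallis gate (default 0.05).
#' @param force skip the gate (for diagnostics only).
#' @return data.frame(group1, group2, mean_rank_diff, z, p_unadjusted,
#'   p_adjusted, significant) with attribute \code{kw_p}.
#' @export
dunn_holland_wolfe <- function(groups, alpha = 0.05, force = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  if (!force && kw$p.value >= alpha) {
    stop(sprintf(paste0("Kruskal-Wallis p = %.4g is not significant at %.3g; ",
                        "multiple comparisons are not run"), kw$p.value, alpha))
  }
  all_v <- unlist(groups, use.names = FALSE)
  N <- length(all_v)
  rk <- rank(all_v)
  g <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(rk, g, mean)
  n_i <- lengths(groups)
  tie_tab <- table(all_v)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  k <- length(groups)
  combs <- utils::combn(k, 2)
  n_comp <- ncol(combs)
  out <- data.frame(
    group1 = names(groups)[combs[1, ]],
    group2 = names(groups)[combs[2, ]])
  out$mean_rank_diff <- rbar[combs[1, ]] - rbar[combs[2, ]]
  se <- sqrt(v0 * (1 / n_i[combs[1, ]] + 1 / n_i[combs[2, ]]))
  out$z <- out$mean_rank_diff / se
  out$p_unadjusted <- 2 * stats::pnorm(-abs(out$z))
  out$p_adjusted <- pmin(1, out$p_unadjusted * n_comp)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  attr(out, "kw_p") <- kw$p.value
  out
}

#' Group summary statistics
#'
#' @param x numeric sample.
#' @return list(mean, sd, sem, n, ci95) with a normal-approximation 95% CI.
#' @export
group_summary <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1L) stop("empty sample")
  m <- mean(x); s <- stats::sd(x)
  sem <- s / sqrt(n)
  list(mean = m, sd = s, sem = sem, n = n,
       ci95 = m + c(-1, 1) * stats::qnorm(0.975) * sem)
}

#' Reference group summaries distributed with the package
#'
#' Group means and SDs from the accelerated-ovarian-failure (VCD) mouse LFP
#' study that this pipeline replicates, one row per comparison, together
#' with the reported effect size. Rows whose reported d is inconsistent
#' with its own printed mean/SD pair (SEM/SD or sign issues in the source)
#' carry \code{consistent = FALSE} and are excluded from replication checks.
#'
#' @return data.frame(comparison, m1, sd1, m2, sd2, d_reported, consistent).
#' @export
reference_group_stats <- function() {
  path <- system.file("extdata", "reference_group_stats.csv",
                      package = "lfprhythms", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute every reference effect size
#'
#' Applies [cohens_d()] to the stored mean/SD pairs and compares with the
#' reported values.
#'
#' @param tol |recomputed - reported| above which a row is flagged.
#' @return the reference table with d_recomputed, delta and matched columns.
#' @export
replicate_effect_sizes <- function(tol = 0.02) {
  ref <- reference_group_stats()
  ref$d_recomputed <- mapply(function(m1, s1, m2, s2) cohens_d(m1, s1, m2, s2)$d,
                             ref$m1, ref$sd1, ref$m2, ref$sd2)
  ref$delta <- ref$d_recomputed - ref$d_reported
  ref$matched <- abs(ref$delta) <= tol
  ref
}
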