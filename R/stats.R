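#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return Tibble: `statistic` (W), `p.value`, `n`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("sample is constant; normality undefined")
  sw <- stats::shapiro.test(x)
  tibble::tibble(statistic = unname(sw$statistic), p.value = sw$p.value,
                 n = length(x))
}

#' Mann-Whitney U test (two-tailed)
#'
#' Exact p-value by enumeration of rank arrangements when the combined
#' sample size is at most 16 and there are no ties; otherwise the normal
#' approximation with mid-ranks, tie-corrected variance and continuity
#' correction.
#'
#' @param a,b Numeric samples (both nonempty).
#' @param exact Force exact (`TRUE`) / approximate (`FALSE`); default
#'   decides by the size rule above.
#' @return Tibble: `u` (U of the first sample), `p.value`, `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact)) exact <- (length(a) + length(b) <= 16L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  tibble::tibble(u = unname(wt$statistic), p.value = min(wt$p.value, 1),
                 method = if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis H test
#'
#' Rank-based k-group comparison with tie-corrected H and a chi-square
#' p-value.
#'
#' @param x Numeric observations.
#' @param g Group labels (same length as `x`).
#' @return Tibble: `statistic` (H), `df`, `p.value`, `n_groups`.
#' @export
kruskal_wallis <- function(x, g) {
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  if (nlevels(g) < 2L) stop("need at least 2 nonempty groups")
  kw <- stats::kruskal.test(x, g)
  tibble::tibble(statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p.value = kw$p.value, n_groups = nlevels(g))
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni correction
#'
#' Dunn's (1964) z statistics on mean ranks of the pooled sample, with
#' tie-corrected pooled variance; each two-sided p-value is multiplied by
#' the number of pairwise comparisons and capped at 1 (Bonferroni), and
#' adjusted p-values are reported.
#'
#' @param x Numeric observations.
#' @param g Group labels (>= 3 groups, each nonempty).
#' @return Tibble: `group1`, `group2`, `z`, `p.value` (raw),
#'   `p.adjusted`.
#' @export
dunn_bonferroni <- function(x, g) {
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  if (nlevels(g) < 3L) stop("Dunn's procedure needs at least 3 groups")
  if (any(table(g) == 0L)) stop("every group must be nonempty")
  N <- length(x)
  r <- rank(x)                       # mid-ranks
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  tie_tab <- table(x)
  Tcorr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - Tcorr
  lev <- levels(g)
  cmb <- utils::combn(seq_along(lev), 2L)
  k <- ncol(cmb)
  z <- p <- numeric(k)
  for (q in seq_len(k)) {
    i <- cmb[1, q]; j <- cmb[2, q]
    se <- sqrt(s2 * (1 / ni[i] + 1 / ni[j]))
    z[q] <- (rbar[i] - rbar[j]) / se
    p[q] <- 2 * stats::pnorm(-abs(z[q]))
  }
  tibble::tibble(group1 = lev[cmb[1, ]], group2 = lev[cmb[2, ]],
                 z = z, p.value = p, p.adjusted = pmin(1, p * k))
}

#' Two-tailed paired t-test
#'
#' @param a,b Paired numeric samples of equal length (n >= 3) with
#'   non-constant differences.
#' @return Tibble: `t`, `df`, `p.value`, `mean_diff`, `conf.low`,
#'   `conf.high` (95% CI of the mean difference).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (stats::sd(a - b) == 0) stop("zero variance of paired differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, mean_diff = unname(tt$estimate),
                 conf.low = tt$conf.int[1], conf.high = tt$conf.int[2])
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Tibble: `r`, `r.squared`, `p.value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), r.squared = unname(ct$estimate)^2,
                 p.value = ct$p.value, n = length(x))
}

#' Group summary and nonparametric comparison of a metric
#'
#' The reporting battery applied to structural metrics across point
#' categories: per-group median and interquartile range, Shapiro-Wilk
#' normality, then Mann-Whitney (2 groups) or Kruskal-Wallis with
#' Dunn-Bonferroni post-hoc comparisons (>= 3 groups).
#'
#' @param data Data frame of observations.
#' @param value Column (tidy-eval) holding the metric.
#' @param group Column (tidy-eval) holding the group labels.
#' @return List of tibbles: `summary` (n, median, IQR bounds, Shapiro p
#'   where computable), `test`, and `pairwise` (NULL unless >= 3
#'   groups).
#' @export
#' @examples
#' d <- data.frame(v = c(1:5, 6:10), g = rep(c("a", "b"), each = 5))
#' compare_groups(d, v, g)$test
compare_groups <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  summ <- dplyr::group_by(tibble::tibble(v = v, g = g), g) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(v),
      q25 = stats::quantile(v, 0.25),
      q75 = stats::quantile(v, 0.75),
      shapiro_p = if (dplyr::n() >= 3 && dplyr::n() <= 5000 &&
                      stats::sd(v) > 0)
        stats::shapiro.test(v)$p.value else NA_real_,
      .groups = "drop") |>
    dplyr::rename(group = g)
  if (nlevels(g) == 2L) {
    lv <- levels(g)
    test <- mann_whitney(v[g == lv[1]], v[g == lv[2]])
    test$method <- paste("Mann-Whitney U,", test$method)
    pairwise <- NULL
  } else {
    test <- kruskal_wallis(v, g)
    test$method <- "Kruskal-Wallis H"
    pairwise <- dunn_bonferroni(v, g)
  }
  list(summary = summ, test = test, pairwise = pairwise)
}
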