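# The nine per-specimen items summarized in the cohort reports, in
# printed order: crossing distances, segment lengths, crossing
# fractions, auxiliary distances and the distal angle.
COHORT_ITEMS <- c("ipa_ol", "aa_ol", "r_a", "ipb_leh", "aa_leh", "r_b",
                  "ipa_ipb", "ipb_bpc", "beta")

#' Descriptive moments of a measurement series
#'
#' Mean, SD (n-1 denominator), adjusted Fisher-Pearson skewness and
#' bias-corrected excess kurtosis — the same conventions major
#' statistics packages print, so values are directly comparable with
#' published tables.
#'
#' @param values numeric vector, n >= 2, non-constant. Kurtosis needs
#'   n >= 4 and is NA below that.
#' @return list with \code{n}, \code{mean}, \code{sd}, \code{skewness},
#'   \code{kurtosis} (excess).
#' @export
describe <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("sd requires at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("skewness undefined for a constant series", call. = FALSE)
  if (n < 3L) stop("skewness requires at least 3 values", call. = FALSE)
  list(
    n = n,
    mean = mean(values),
    sd = s,
    skewness = e1071::skewness(values, type = 2),
    kurtosis = if (n >= 4L) e1071::kurtosis(values, type = 2) else NA_real_
  )
}

#' Null distribution of the Lilliefors statistic
#'
#' Monte-Carlo sample of the Kolmogorov-Smirnov distance between the
#' empirical CDF of a standard-normal sample of size n and the normal
#' CDF refitted to that sample (mean and sd re-estimated). Used to
#' calibrate [lilliefors_normality()] p-values; computing it once and
#' reusing it across tests of the same n is valid and much cheaper.
#'
#' @param n sample size.
#' @param n_mc number of Monte-Carlo replicates (>= 1000).
#' @param seed integer seed.
#' @return sorted numeric vector of n_mc null D values.
#' @export
lilliefors_null <- function(n, n_mc = 10000L, seed = 1L) {
  if (n_mc < 1000L) stop("n_mc must be at least 1000", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n * n_mc), nrow = n)
  d <- apply(z, 2L, lilliefors_d)
  sort(d)
}

# sup-distance between the ECDF and the fitted normal CDF, evaluated at
# both sides of every jump point
lilliefors_d <- function(x) {
  n <- length(x)
  x <- sort(x)
  p <- stats::pnorm((x - mean(x)) / stats::sd(x))
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Lilliefors normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov test of composite normality: the reference normal
#' has its mean and SD estimated from the sample, so the plain K-S null
#' distribution does not apply. The p-value is the fraction of seeded
#' standard-normal Monte-carlo samples of the same size whose refitted
#' D statistic reaches the observed one.
#'
#' @param values numeric vector, n >= 5.
#' @param n_mc Monte-Carlo replicates for the p-value (>= 1000).
#' @param seed integer seed for the null sample.
#' @param null_d optional precomputed output of [lilliefors_null()] for
#'   this n, overriding \code{n_mc}/\code{seed}.
#' @return object of class \code{rn_normality} with \code{d_statistic},
#'   \code{p_value}, \code{n}, and \code{classification}
#'   (NA until [classify_normality()] is applied).
#' @export
lilliefors_normality <- function(values, n_mc = 10000L, seed = 1L,
                                 null_d = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 5L) stop("normality testing requires at least 5 values",
                   call. = FALSE)
  if (stats::sd(values) == 0) stop("constant series", call. = FALSE)
  d <- lilliefors_d(values)
  if (is.null(null_d)) null_d <- lilliefors_null(n, n_mc = n_mc, seed = seed)
  p <- mean(null_d >= d)
  structure(list(d_statistic = d, p_value = p, n = n,
                 classification = NA_character_),
            class = "rn_normality")
}

#' @export
print.rn_normality <- function(x, ...) {
  cat(sprintf("Lilliefors normality: D = %.4f, p = %.4f (n = %d)%s\n",
              x$d_statistic, x$p_value, x$n,
              if (is.na(x$classification)) ""
              else paste0(" -> ", x$classification)))
  invisible(x)
}

#' Classify a distribution as normal, approximately normal or neither
#'
#' A sample that passes the normality test (p > alpha) is \code{normal};
#' one that fails it but has |skewness| < 3 and |excess kurtosis| < 10
#' is retained as \code{approximately_normal} (the usual screening rule
#' for moment-based methods at moderate n); anything else is
#' \code{non_normal}.
#'
#' @param report \code{rn_normality} for the sample.
#' @param summary output of [describe()] for the same sample.
#' @param alpha significance level (default 0.05).
#' @return the report with \code{classification} filled in.
#' @export
classify_normality <- function(report, summary, alpha = 0.05) {
  stopifnot(inherits(report, "rn_normality"))
  report$classification <-
    if (report$p_value > alpha) {
      "normal"
    } else if (abs(summary$skewness) < 3 &&
               !is.na(summary$kurtosis) && abs(summary$kurtosis) < 10) {
      "approximately_normal"
    } else {
      "non_normal"
    }
  report
}

#' Two-sample comparison of one measurement item
#'
#' Pooled-variance Student's t-test (df = n1 + n2 - 2) by default, the
#' convention behind the published group tables; Welch's unequal
#' variance test is available via \code{var_equal = FALSE}.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param labels character pair naming the groups.
#' @param var_equal pooled-variance t (TRUE, default) or Welch.
#' @return object of class \code{rn_comparison}.
#' @export
compare_groups <- function(a, b, labels = c("a", "b"), var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("degenerate comparison: zero variance in both groups",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(
    list(group_labels = labels,
         summaries = list(
           list(n = length(a), mean = mean(a), sd = stats::sd(a)),
           list(n = length(b), mean = mean(b), sd = stats::sd(b))),
         t_statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         var_equal = var_equal),
    class = "rn_comparison"
  )
}

#' Two-sample pooled t-test from printed summaries
#'
#' Evaluates the same pooled-variance t statistic as [compare_groups()]
#' directly from group means, SDs and sizes, so published tables can be
#' checked without the raw data.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries; n >= 2 each, SDs
#'   not both zero.
#' @param labels group names.
#' @return \code{rn_comparison}.
#' @export
compare_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2,
                                   labels = c("a", "b")) {
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    stop("degenerate comparison: zero variance in both groups",
         call. = FALSE)
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(
    list(group_labels = labels,
         summaries = list(list(n = n1, mean = mean1, sd = sd1),
                          list(n = n2, mean = mean2, sd = sd2)),
         t_statistic = t_stat, df = df,
         p_value = 2 * stats::pt(-abs(t_stat), df),
         var_equal = TRUE),
    class = "rn_comparison"
  )
}

#' @export
print.rn_comparison <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("%s (%.3f +/- %.3f, n=%d) vs %s (%.3f +/- %.3f, n=%d): t = %.3f, df = %.1f, p = %.4g\n",
              x$group_labels[1], s[[1]]$mean, s[[1]]$sd, s[[1]]$n,
              x$group_labels[2], s[[2]]$mean, s[[2]]$sd, s[[2]]$n,
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Regression of one crossing fraction on the other
#'
#' Ordinary least squares of \code{r_b} (crossing fraction on the
#' AA-LEH edge) on \code{r_a} (AA-Ol edge). A significant positive
#' slope indicates that nerves crossing the AA-Ol line more proximally
#' also cross the AA-LEH line more proximally — the nerve course shifts
#' as a whole rather than pivoting.
#'
#' @param x an \code{rn_cohort} with at least 3 specimens.
#' @return object of class \code{rn_regression} with \code{slope},
#'   \code{intercept}, \code{slope_t}, \code{slope_p}, \code{pearson_r},
#'   \code{n}, and \code{perfect_fit} (TRUE when the residual variance
#'   is zero, in which case the t statistic is undefined and reported
#'   as Inf).
#' @export
fit_ratio_regression <- function(x) {
  stopifnot(inherits(x, "rn_cohort"))
  if (nrow(x) < 3L) stop("regression requires at least 3 specimens",
                         call. = FALSE)
  if (stats::sd(x$r_a) == 0) stop("zero variance in predictor r_a",
                                  call. = FALSE)
  fit <- stats::lm(r_b ~ r_a, data = as.data.frame(x))
  sm <- summary(fit)
  coefs <- sm$coefficients
  perfect <- sm$sigma < 1e-12
  structure(
    list(slope = unname(coefs["r_a", "Estimate"]),
         intercept = unname(coefs["(Intercept)", "Estimate"]),
         slope_t = if (perfect) Inf else unname(coefs["r_a", "t value"]),
         slope_p = if (perfect) 0 else unname(coefs["r_a", "Pr(>|t|)"]),
         pearson_r = stats::cor(x$r_a, x$r_b),
         n = nrow(x), perfect_fit = perfect),
    class = "rn_regression"
  )
}

#' @export
print.rn_regression <- function(x, ...) {
  cat(sprintf("r_b ~ r_a: slope %.3f (t = %.3f, p = %.4g), r = %.3f, n = %d%s\n",
              x$slope, x$slope_t, x$slope_p, x$pearson_r, x$n,
              if (x$perfect_fit) " [perfect fit]" else ""))
  invisible(x)
}

#' t statistic implied by a slope and the two marginal SDs
#'
#' For OLS of y on x, the Pearson correlation is
#' \code{r = slope * sd(x) / sd(y)} and the slope's t statistic equals
#' \code{r sqrt(n - 2) / sqrt(1 - r^2)}. This reconstructs the t value
#' a reported regression implies from its printed slope and the two
#' marginal SDs, a useful consistency check on published results.
#'
#' @param slope OLS slope of y on x.
#' @param sd_x,sd_y marginal SDs (> 0).
#' @param n sample size (>= 3).
#' @return the implied t statistic.
#' @export
implied_slope_t <- function(slope, sd_x, sd_y, n) {
  if (sd_x <= 0 || sd_y <= 0) stop("sds must be positive", call. = FALSE)
  if (n < 3L) stop("n must be at least 3", call. = FALSE)
  r <- slope * sd_x / sd_y
  if (abs(r) >= 1) stop("implied |correlation| >= 1: inconsistent inputs",
                        call. = FALSE)
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Normality report over the nine cohort items
#'
#' Runs [describe()], [lilliefors_normality()] and
#' [classify_normality()] per item; incomplete auxiliary items use the
#' rows where they are present.
#'
#' @param x an \code{rn_cohort}.
#' @param n_mc Monte-Carlo replicates per item.
#' @param seed integer seed.
#' @param alpha significance level for the classification.
#' @return data frame, one row per item.
#' @export
normality_table <- function(x, n_mc = 2000L, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(x, "rn_cohort"))
  rows <- lapply(seq_along(COHORT_ITEMS), function(i) {
    item <- COHORT_ITEMS[i]
    v <- x[[item]]
    v <- v[is.finite(v)]
    ds <- describe(v)
    rep_ <- lilliefors_normality(v, n_mc = n_mc, seed = seed + i)
    rep_ <- classify_normality(rep_, ds, alpha = alpha)
    data.frame(item = item, n = ds$n, mean = ds$mean, sd = ds$sd,
               skewness = ds$skewness, kurtosis = ds$kurtosis,
               d_statistic = rep_$d_statistic, p_value = rep_$p_value,
               classification = rep_$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

group_comparison_table <- function(x, group_col, levels_) {
  rows <- lapply(COHORT_ITEMS, function(item) {
    v <- x[[item]]; g <- x[[group_col]]
    keep <- is.finite(v)
    cmp <- compare_groups(v[keep & g == levels_[1]],
                          v[keep & g == levels_[2]], labels = levels_)
    s <- cmp$summaries
    data.frame(item = item,
               mean_1 = s[[1]]$mean, sd_1 = s[[1]]$sd, n_1 = s[[1]]$n,
               mean_2 = s[[2]]$mean, sd_2 = s[[2]]$sd, n_2 = s[[2]]$n,
               t_statistic = cmp$t_statistic, df = cmp$df,
               p_value = cmp$p_value,
               significant = cmp$p_value < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_1$", paste0("_", levels_[1]), names(out))
  names(out) <- sub("_2$", paste0("_", levels_[2]), names(out))
  rownames(out) <- NULL
  out
}

#' Male/female comparison of the nine cohort items
#' @param x an \code{rn_cohort} containing both sexes.
#' @return data frame, one pooled t-test per item.
#' @export
sex_comparison <- function(x) {
  stopifnot(inherits(x, "rn_cohort"))
  group_comparison_table(x, "sex", c("male", "female"))
}

#' Left/right comparison of the nine cohort items
#' @param x an \code{rn_cohort} containing both sides.
#' @return data frame, one pooled t-test per item.
#' @export
side_comparison <- function(x) {
  stopifnot(inherits(x, "rn_cohort"))
  group_comparison_table(x, "side", c("left", "right"))
}
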