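#' Technical error of measurement
#'
#' Intraobserver TEM for duplicate readings:
#' \code{sqrt(sum((x1 - x2)^2) / (2 n))} over the n pairs. This is the
#' typical magnitude of error attached to a single measurement by the
#' same observer.
#'
#' @param x an \code{rn_repeated} set with at least 2 pairs.
#' @return TEM in the measurement unit (cm).
#' @export
technical_error <- function(x) {
  stopifnot(inherits(x, "rn_repeated"))
  n <- nrow(x$pairs)
  if (n < 2L) stop("at least 2 duplicate pairs are required", call. = FALSE)
  d <- x$pairs$first - x$pairs$second
  sqrt(sum(d^2) / (2 * n))
}

#' Relative technical error of measurement
#'
#' TEM expressed as a percentage of the variable's grand mean.
#'
#' @param tem TEM (cm).
#' @param grand_mean mean of all readings (cm), > 0.
#' @return rTEM in percent.
#' @export
relative_tem <- function(tem, grand_mean) {
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    stop("grand mean must be positive", call. = FALSE)
  }
  100 * tem / grand_mean
}

#' Coefficient of reliability
#'
#' \code{R = 1 - TEM^2 / SD^2}, the proportion of between-subject
#' variance free of measurement error, where SD is the standard
#' deviation of all readings. Clamped to [0, 1] for pathological inputs
#' (TEM exceeding SD).
#'
#' @param tem TEM (cm).
#' @param sd_all standard deviation of all readings (cm), > 0.
#' @return reliability in [0, 1].
#' @export
reliability <- function(tem, sd_all) {
  if (!is.finite(sd_all) || sd_all <= 0) {
    stop("standard deviation of the readings must be positive (degenerate data)",
         call. = FALSE)
  }
  min(1, max(0, 1 - tem^2 / sd_all^2))
}

#' Precision estimates for one duplicated variable
#'
#' Bundles TEM, rTEM and R for a duplicate-measurement set. The grand
#' mean and SD use all 2n readings; the SD uses the n-1 denominator.
#'
#' @param x an \code{rn_repeated} set.
#' @return object of class \code{rn_precision} with fields \code{tem},
#'   \code{rtem_percent}, \code{r_coeff}, \code{n_pairs},
#'   \code{grand_mean}, \code{sd_all}.
#' @export
precision_report <- function(x) {
  tem <- technical_error(x)
  all_vals <- c(x$pairs$first, x$pairs$second)
  grand_mean <- mean(all_vals)
  sd_all <- stats::sd(all_vals)
  structure(
    list(variable = x$variable, side = x$side,
         tem = tem,
         rtem_percent = relative_tem(tem, grand_mean),
         r_coeff = reliability(tem, sd_all),
         n_pairs = nrow(x$pairs),
         grand_mean = grand_mean, sd_all = sd_all),
    class = "rn_precision"
  )
}

#' @export
print.rn_precision <- function(x, ...) {
  cat(sprintf("%s %s (n = %d): TEM %.4f cm, rTEM %.2f%%, R %.2f\n",
              x$side, x$variable, x$n_pairs,
              x$tem, x$rtem_percent, round(x$r_coeff, 2)))
  invisible(x)
}

#' Precision table for several duplicated variables
#'
#' Applies [precision_report()] to each set and collects the estimates
#' in one data frame shaped like a published precision table.
#'
#' @param sets list of \code{rn_repeated}, e.g. [table1_fixture()].
#' @return data frame with one row per set.
#' @export
precision_table <- function(sets = table1_fixture()) {
  rows <- lapply(sets, function(s) {
    p <- precision_report(s)
    data.frame(variable = p$variable, side = p$side, n = p$n_pairs,
               tem = p$tem, rtem_percent = p$rtem_percent,
               r_coeff = p$r_coeff,
               grand_mean = p$grand_mean, sd_all = p$sd_all,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
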