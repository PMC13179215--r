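#' Build the landmark triangle frame
#'
#' Places the three bony landmarks in 2D: Olecranon (Ol) at the origin,
#' Lateral Epicondyle (LEH) on the positive x axis at the base width,
#' and the Acromial Angle (AA) above the base at the circle-circle
#' intersection fixed by the two arm-segment lengths.
#'
#' Only the polygon coordinates depend on the base width; the
#' safe-zone boundary fractions are ratios along the edges and are
#' independent of all three lengths.
#'
#' @param l_ao AA-Ol length (cm).
#' @param l_aleh AA-LEH length (cm).
#' @param base_width Ol-LEH distance (cm); not measured in cadaveric
#'   protocols based on these landmarks, default 5.
#' @return object of class \code{rn_frame} with points \code{ol},
#'   \code{leh}, \code{aa} and the three lengths.
#' @export
build_frame <- function(l_ao = 28.852, l_aleh = 28.555, base_width = 5) {
  if (any(c(l_ao, l_aleh, base_width) <= 0)) {
    stop("all triangle lengths must be positive", call. = FALSE)
  }
  s <- sort(c(l_ao, l_aleh, base_width))
  if (s[1] + s[2] <= s[3]) {
    stop("triangle inequality violated: ", l_ao, ", ", l_aleh, ", ",
         base_width, call. = FALSE)
  }
  x <- (l_ao^2 - l_aleh^2 + base_width^2) / (2 * base_width)
  y <- sqrt(l_ao^2 - x^2)
  structure(
    list(ol = c(0, 0), leh = c(base_width, 0), aa = c(x, y),
         l_ao = l_ao, l_aleh = l_aleh, base_width = base_width),
    class = "rn_frame"
  )
}

#' @export
print.rn_frame <- function(x, ...) {
  cat(sprintf("Landmark triangle: Ol (0,0), LEH (%.3f,0), AA (%.3f,%.3f)\n",
              x$base_width, x$aa[1], x$aa[2]))
  cat(sprintf("  |AA-Ol| = %.3f cm, |AA-LEH| = %.3f cm\n", x$l_ao, x$l_aleh))
  invisible(x)
}

# point at fraction f along Ol -> AA
point_on_ao <- function(frame, f) frame$ol + f * (frame$aa - frame$ol)
# point at fraction f along LEH -> AA
point_on_aleh <- function(frame, f) frame$leh + f * (frame$aa - frame$leh)

#' Nerve chord across the triangle
#'
#' The straight segment joining the nerve's crossing points on the two
#' edges: the point at fraction \code{r_a} along Ol->AA and the point
#' at fraction \code{r_b} along LEH->AA (fractions measured from the
#' distal landmark toward the Acromial Angle).
#'
#' @param frame an \code{rn_frame}.
#' @param r_a,r_b crossing fractions, strictly in (0, 1).
#' @return list with \code{r_a}, \code{r_b}, \code{p_a}, \code{p_b}.
#' @export
chord <- function(frame, r_a, r_b) {
  stopifnot(inherits(frame, "rn_frame"))
  if (r_a <= 0 || r_a >= 1 || r_b <= 0 || r_b >= 1) {
    stop("crossing fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(r_a = r_a, r_b = r_b,
                 p_a = point_on_ao(frame, r_a),
                 p_b = point_on_aleh(frame, r_b)),
            class = "rn_chord")
}

zone_result <- function(kind, alpha, f_a, f_b, frame, n) {
  structure(
    list(kind = kind, alpha = alpha, f_a = f_a, f_b = f_b,
         polygon = rbind(ol = frame$ol,
                         p_a = point_on_ao(frame, f_a),
                         p_b = point_on_aleh(frame, f_b),
                         leh = frame$leh),
         n_specimens = n, frame = frame),
    class = "rn_zone"
  )
}

#' @export
print.rn_zone <- function(x, ...) {
  cat(sprintf("%s safe zone (n = %d%s):\n", x$kind, x$n_specimens,
              if (x$kind == "relative") sprintf(", alpha = %g", x$alpha)
              else ""))
  cat(sprintf("  boundary at %.2f%% of AA-Ol (from Ol) and %.2f%% of AA-LEH (from LEH)\n",
              100 * x$f_a, 100 * x$f_b))
  invisible(x)
}

#' Absolute safe zone: the region no observed nerve enters
#'
#' The quadrilateral bounded by Ol, LEH and the lowest observed
#' crossing point on each edge: \code{f_a = min(r_a)},
#' \code{f_b = min(r_b)}. By construction no specimen chord crosses
#' its open interior (chords touching the boundary do not count).
#'
#' @param x an \code{rn_cohort}, non-empty.
#' @param frame an \code{rn_frame}; defaults to the triangle built from
#'   the cohort's mean segment lengths.
#' @return \code{rn_zone} of kind \code{"absolute"}.
#' @export
absolute_zone <- function(x, frame = NULL) {
  stopifnot(inherits(x, "rn_cohort"))
  if (nrow(x) == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(frame)) frame <- build_frame(mean(x$aa_ol), mean(x$aa_leh))
  zone_result("absolute", 0, min(x$r_a), min(x$r_b), frame, nrow(x))
}

#' Relative safe zone: below the per-edge alpha-quantile crossings
#'
#' The quadrilateral below the empirical alpha-quantiles of the two
#' crossing fractions, so that on each edge fewer than
#' (alpha + 1/n) of the observed nerves cross below the boundary.
#' Quantiles use linear interpolation between order statistics at
#' position alpha*(n-1)+1 by default (\code{stats::quantile} type 7);
#' the convention is configurable because published boundaries rarely
#' state one.
#'
#' Note the per-edge construction: the probability that a nerve enters
#' the zone through either edge exceeds alpha unless the two fractions
#' are perfectly correlated — quantify it with
#' [violation_probability_model()].
#'
#' @param x an \code{rn_cohort}; n >= 1/alpha specimens so the quantile
#'   is interior.
#' @param frame an \code{rn_frame}; default as in [absolute_zone()].
#' @param alpha marginal crossing probability, in (0, 0.5).
#' @param type quantile convention passed to \code{stats::quantile}.
#' @return \code{rn_zone} of kind \code{"relative"}.
#' @export
relative_zone <- function(x, frame = NULL, alpha = 0.05, type = 7) {
  stopifnot(inherits(x, "rn_cohort"))
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)",
                                       call. = FALSE)
  if (nrow(x) < ceiling(1 / alpha)) {
    stop("cohort too small for alpha = ", alpha, ": need at least ",
         ceiling(1 / alpha), " specimens", call. = FALSE)
  }
  if (is.null(frame)) frame <- build_frame(mean(x$aa_ol), mean(x$aa_leh))
  f_a <- unname(stats::quantile(x$r_a, alpha, type = type))
  f_b <- unname(stats::quantile(x$r_b, alpha, type = type))
  zone_result("relative", alpha, f_a, f_b, frame, nrow(x))
}

#' Fraction of nerves entering a candidate zone
#'
#' A specimen violates the zone bounded by edge fractions (f_a, f_b)
#' when its chord crosses the zone's open interior, which for this
#' chord family is exactly \code{r_a < f_a || r_b < f_b}. Boundary
#' contact (equality) is not a violation.
#'
#' @param x an \code{rn_cohort}, non-empty.
#' @param f_a,f_b boundary fractions in (0, 1).
#' @return proportion of specimens in violation.
#' @export
zone_violation_rate <- function(x, f_a, f_b) {
  stopifnot(inherits(x, "rn_cohort"))
  if (nrow(x) == 0L) stop("empty cohort", call. = FALSE)
  if (f_a <= 0 || f_a >= 1 || f_b <= 0 || f_b >= 1) {
    stop("boundary fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  mean(x$r_a < f_a | x$r_b < f_b)
}

#' Joint probability of entering a per-edge quantile zone
#'
#' Monte-Carlo estimate of \code{P(r_a < f_a or r_b < f_b)} when the
#' two crossing fractions follow a bivariate normal distribution. With
#' f_a and f_b at the marginal 5% quantiles this exceeds 5% whenever
#' the correlation is below 1 (it is 1 - 0.95^2 ~ 9.75% under
#' independence), so a "less than 5% per edge" zone admits more than
#' 5% of nerves overall.
#'
#' @param ratio_mean_a,ratio_sd_a,ratio_mean_b,ratio_sd_b marginal
#'   moments of the two fractions.
#' @param ratio_correlation correlation in (-1, 1).
#' @param f_a,f_b boundary fractions.
#' @param n_mc Monte-Carlo draws (>= 10000).
#' @param seed integer seed.
#' @return estimated violation probability.
#' @export
violation_probability_model <- function(ratio_mean_a, ratio_sd_a,
                                        ratio_mean_b, ratio_sd_b,
                                        ratio_correlation, f_a, f_b,
                                        n_mc = 1e5, seed = 1L) {
  if (ratio_sd_a <= 0 || ratio_sd_b <= 0 ||
      abs(ratio_correlation) >= 1) {
    stop("invalid ratio distribution parameters", call. = FALSE)
  }
  if (n_mc < 10000) stop("n_mc must be at least 10000", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  z1 <- stats::rnorm(n_mc)
  z2 <- ratio_correlation * z1 +
    sqrt(1 - ratio_correlation^2) * stats::rnorm(n_mc)
  ra <- ratio_mean_a + ratio_sd_a * z1
  rb <- ratio_mean_b + ratio_sd_b * z2
  mean(ra < f_a | rb < f_b)
}

svg_num <- function(x) formatC(x, format = "f", digits = 3)

# fixed qualitative palette cycled over chords
CHORD_COLORS <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
                  "#a65628", "#f781bf", "#999999", "#66c2a5", "#fc8d62",
                  "#8da0cb", "#e78ac3")

#' Render the triangle, nerve chords and safe zones as SVG
#'
#' Writes a deterministic standalone SVG: the landmark triangle
#' outline, one colored line per specimen chord, the absolute zone
#' filled green and the relative zone filled purple (semi-transparent,
#' drawn under the chords). Identical inputs produce byte-identical
#' files.
#'
#' @param frame an \code{rn_frame}.
#' @param x an \code{rn_cohort} (may be empty for a zones-only sketch).
#' @param zones list of \code{rn_zone} objects (possibly empty).
#' @param path output file path (.svg).
#' @param width_px canvas width in pixels.
#' @return \code{path}, invisibly.
#' @export
render_figure <- function(frame, x, zones = list(), path,
                          width_px = 600) {
  stopifnot(inherits(frame, "rn_frame"))
  pts <- rbind(frame$ol, frame$leh, frame$aa)
  pad <- 0.05 * max(frame$l_ao, frame$l_aleh, frame$base_width)
  xr <- range(pts[, 1]) + c(-pad, pad)
  yr <- range(pts[, 2]) + c(-pad, pad)
  scale <- width_px / diff(xr)
  height_px <- diff(yr) * scale
  # SVG y axis points down; flip so AA is drawn at the top
  tx <- function(p) (p[1] - xr[1]) * scale
  ty <- function(p) (yr[2] - p[2]) * scale
  pt_str <- function(p) paste0(svg_num(tx(p)), ",", svg_num(ty(p)))
  poly_str <- function(m) paste(apply(m, 1, pt_str), collapse = " ")

  lines_out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            svg_num(width_px), svg_num(height_px),
            svg_num(width_px), svg_num(height_px)),
    '<rect width="100%" height="100%" fill="white"/>'
  )
  zone_fill <- c(absolute = "#2ca02c", relative = "#9467bd")
  # draw the relative zone first so the nested absolute zone stays visible
  ord <- order(match(vapply(zones, function(z) z$kind, character(1)),
                     c("relative", "absolute")))
  for (z in zones[ord]) {
    lines_out <- c(lines_out, sprintf(
      '<polygon class="zone-%s" points="%s" fill="%s" fill-opacity="0.45" stroke="%s" stroke-width="1"/>',
      z$kind, poly_str(z$polygon), zone_fill[[z$kind]], zone_fill[[z$kind]]))
  }
  if (nrow(x) > 0L) {
    for (i in seq_len(nrow(x))) {
      ch <- chord(frame, x$r_a[i], x$r_b[i])
      col <- CHORD_COLORS[(i - 1L) %% length(CHORD_COLORS) + 1L]
      lines_out <- c(lines_out, sprintf(
        '<line class="chord" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="0.8"/>',
        svg_num(tx(ch$p_a)), svg_num(ty(ch$p_a)),
        svg_num(tx(ch$p_b)), svg_num(ty(ch$p_b)), col))
    }
  }
  tri <- rbind(frame$ol, frame$leh, frame$aa)
  lines_out <- c(lines_out, sprintf(
    '<polygon class="triangle" points="%s" fill="none" stroke="black" stroke-width="1.5"/>',
    poly_str(tri)),
    "</svg>")
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open ", path, " for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con), add = TRUE)
  writeLines(lines_out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
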