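# Build a small valid cohort with prescribed crossing fractions.
# Segment lengths default to round numbers so ipa_ol = r_a * aa_ol stays
# exact in double precision.
make_cohort <- function(r_a, r_b, aa_ol = 30, aa_leh = 28,
                        sex = NULL, side = NULL, label = "test") {
  n <- length(r_a)
  stopifnot(length(r_b) == n)
  aa_ol <- rep_len(aa_ol, n)
  aa_leh <- rep_len(aa_leh, n)
  if (is.null(side)) side <- rep(c("left", "right"), length.out = n)
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  cad <- cumsum(side == "left")
  if (n > 0L && side[1] != "left") cad <- cad + 1L  # ids start at 1
  df <- data.frame(
    specimen_id = sprintf("T%03d", seq_len(n)),
    cadaver_id = sprintf("C%03d", cad),
    sex = sex, side = side,
    aa_ol = aa_ol, aa_leh = aa_leh,
    ipa_ol = r_a * aa_ol, ipb_leh = r_b * aa_leh,
    ipa_ipb = rep(4.8, n), ipb_bpc = rep(8.6, n),
    beta = rep(7.3, n),
    stringsAsFactors = FALSE
  )
  cohort(df, label = label)
}

# random valid cohort of n limbs for property-style tests
random_cohort <- function(n, seed) {
  set.seed(seed)
  make_cohort(r_a = runif(n, 0.2, 0.9), r_b = runif(n, 0.1, 0.8))
}

# Independent geometric oracle: does the open segment p_a--p_b meet the
# open interior of the convex polygon (rows = CCW or CW vertices)?
# Clips the segment against every edge half-plane (Liang-Barsky) and
# checks that the clipped piece has positive length with a strictly
# interior midpoint.
segment_hits_interior <- function(p_a, p_b, poly, eps = 1e-9) {
  m <- nrow(poly)
  # orient consistently: signed area
  area <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    area <- area + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  if (area < 0) poly <- poly[rev(seq_len(m)), , drop = FALSE]
  d <- p_b - p_a
  t0 <- 0; t1 <- 1
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    nrm <- c(-e[2], e[1])                # inward normal for CCW
    num <- sum(nrm * (poly[i, ] - p_a))  # nrm . (p(t) - v_i) >= 0
    den <- sum(nrm * d)
    if (abs(den) < eps) {
      if (num < -eps) return(FALSE)      # parallel and outside
    } else {
      t <- num / den
      if (den > 0) t0 <- max(t0, t) else t1 <- min(t1, t)
    }
    if (t0 > t1) return(FALSE)
  }
  if (t1 - t0 < eps) return(FALSE)
  mid <- p_a + (t0 + t1) / 2 * d
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    nrm <- c(-e[2], e[1])
    if (sum(nrm * (mid - poly[i, ])) <= eps) return(FALSE)
  }
  TRUE
}
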