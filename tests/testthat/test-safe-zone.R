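test_that("the landmark triangle is placed by its three lengths", {
  eq <- build_frame(1, 1, 1)
  expect_equal(eq$aa, c(0.5, sqrt(3) / 2), tolerance = 1e-12)

  fr <- build_frame(28.852, 28.555, 5)
  expect_equal(sqrt(sum((fr$aa - fr$ol)^2)), 28.852, tolerance = 1e-9)
  expect_equal(sqrt(sum((fr$aa - fr$leh)^2)), 28.555, tolerance = 1e-9)
  expect_gt(fr$aa[2], 0)

  expect_error(build_frame(1, 1, 3), "triangle inequality")
  expect_error(build_frame(-1, 1, 1), "positive")
})

test_that("chords interpolate along the edges from the distal landmarks", {
  fr <- build_frame(1, 1, 1)
  expect_error(chord(fr, 0, 0.5), "strictly")
  expect_error(chord(fr, 0.5, 1), "strictly")

  ch <- chord(fr, 0.5, 0.5)
  expect_equal(ch$p_a[2], ch$p_b[2])  # parallel to the base at mid height
  expect_equal(ch$p_a[2], sqrt(3) / 4)

  ch <- chord(fr, 0.599, 0.429)
  expect_equal(ch$p_a, 0.599 * c(0.5, sqrt(3) / 2), tolerance = 1e-12)
  expect_equal(ch$p_b, c(1, 0) + 0.429 * c(-0.5, sqrt(3) / 2),
               tolerance = 1e-12)

  # point at fraction f sits at distance f * edge length from the
  # distal landmark, for any frame shape
  for (fr2 in list(build_frame(28.852, 28.555, 5), build_frame(3, 4, 5))) {
    f <- 0.37
    ch2 <- chord(fr2, f, f)
    expect_equal(sqrt(sum((ch2$p_a - fr2$ol)^2)), f * fr2$l_ao,
                 tolerance = 1e-9)
    expect_equal(sqrt(sum((ch2$p_b - fr2$leh)^2)), f * fr2$l_aleh,
                 tolerance = 1e-9)
  }
})

test_that("the absolute zone is the elementwise minimum with zero violations", {
  one <- make_cohort(0.6, 0.4)
  z <- absolute_zone(one)
  expect_equal(z$f_a, 0.6)
  expect_equal(z$f_b, 0.4)

  three <- make_cohort(c(0.5, 0.45, 0.6), c(0.4, 0.45, 0.35))
  z <- absolute_zone(three)
  expect_equal(z$f_a, 0.45)
  expect_equal(z$f_b, 0.35)

  for (seed in 1:5) {
    co <- random_cohort(40, seed)
    z <- absolute_zone(co)
    expect_equal(z$f_a, min(co$r_a))
    expect_equal(z$f_b, min(co$r_b))
    expect_identical(zone_violation_rate(co, z$f_a, z$f_b), 0)
  }
  expect_error(absolute_zone(make_cohort(numeric(0), numeric(0))), "empty")
})

test_that("the relative zone uses interpolated order statistics", {
  # n = 60 known fractions: the 5% quantile interpolates between the
  # 3rd and 4th order statistics at position 0.05 * 59 + 1 = 3.95
  r_a <- seq(0.30, 0.889, length.out = 60)
  r_b <- seq(0.20, 0.789, length.out = 60)
  co <- make_cohort(r_a, r_b)
  z <- relative_zone(co, alpha = 0.05)
  s <- sort(r_a)
  expect_equal(z$f_a, s[3] + 0.95 * (s[4] - s[3]), tolerance = 1e-12)
  s <- sort(r_b)
  expect_equal(z$f_b, s[3] + 0.95 * (s[4] - s[3]), tolerance = 1e-12)

  # no more than alpha + 1/n of the defining cohort crosses below
  expect_lte(zone_violation_rate(co, z$f_a, z$f_b), 0.05 + 1 / 60)

  expect_error(relative_zone(make_cohort(0.5, 0.5), alpha = 0.05),
               "too small")
  expect_error(relative_zone(co, alpha = 0.7), "alpha")
})

test_that("zones nest and their fractions are scale invariant", {
  for (seed in 1:5) {
    co <- random_cohort(60, seed)
    za <- absolute_zone(co)
    zr <- relative_zone(co, alpha = 0.05)
    expect_lte(za$f_a, zr$f_a)
    expect_lte(za$f_b, zr$f_b)

    # uniform rescaling of every length (base width included)
    cc <- 2.5
    fr0 <- build_frame(30, 28, 5)
    frs <- build_frame(30 * cc, 28 * cc, 5 * cc)
    scaled <- make_cohort(co$r_a, co$r_b, aa_ol = co$aa_ol * cc,
                          aa_leh = co$aa_leh * cc)
    za0 <- absolute_zone(co, fr0)
    zas <- absolute_zone(scaled, frs)
    expect_equal(zas$f_a, za0$f_a, tolerance = 1e-12)
    expect_equal(relative_zone(scaled, frs, alpha = 0.05)$f_b,
                 relative_zone(co, fr0, alpha = 0.05)$f_b,
                 tolerance = 1e-12)
    # polygon scales with the frame but fractions do not
    expect_equal(zas$polygon, za0$polygon * cc, tolerance = 1e-9)
  }
})

test_that("violation flags agree with a segment-polygon oracle", {
  fr <- build_frame(28.852, 28.555, 5)
  f_a <- 0.45; f_b <- 0.30
  poly <- rbind(fr$ol, radsafe:::point_on_ao(fr, f_a),
                radsafe:::point_on_aleh(fr, f_b), fr$leh)
  set.seed(17)
  r_a <- runif(1000, 0.05, 0.95)
  r_b <- runif(1000, 0.05, 0.95)
  co <- make_cohort(r_a, r_b)
  flagged <- co$r_a < f_a | co$r_b < f_b
  oracle <- vapply(seq_len(1000), function(i) {
    ch <- chord(fr, r_a[i], r_b[i])
    segment_hits_interior(ch$p_a, ch$p_b, poly)
  }, logical(1))
  expect_identical(flagged, oracle)
  expect_equal(zone_violation_rate(co, f_a, f_b), mean(oracle))

  # boundary contact is not a violation, in both routes
  ch <- chord(fr, f_a, f_b)
  expect_false(segment_hits_interior(ch$p_a, ch$p_b, poly))
  expect_equal(zone_violation_rate(make_cohort(f_a, f_b), f_a, f_b), 0)
})

test_that("the joint crossing probability exceeds the per-edge level", {
  f_a <- qnorm(0.05, 0.599, 0.062)
  f_b <- qnorm(0.05, 0.429, 0.066)
  # independent fractions: closed form 1 - 0.95^2
  p0 <- violation_probability_model(0.599, 0.062, 0.429, 0.066, 0,
                                    f_a, f_b, n_mc = 2e5, seed = 6)
  expect_equal(p0, 1 - 0.95^2, tolerance = 0.002 / 0.0975)
  # correlated fractions: exact bivariate-normal value 0.08599
  p1 <- violation_probability_model(0.599, 0.062, 0.429, 0.066, 0.557,
                                    f_a, f_b, n_mc = 2e5, seed = 6)
  expect_equal(p1, 0.08599, tolerance = 0.003 / 0.08599)
  expect_gt(p1, 0.05)
  # vanishing zone admits nobody
  p2 <- violation_probability_model(0.599, 0.062, 0.429, 0.066, 0.557,
                                    0.01, 0.01, n_mc = 1e4, seed = 6)
  expect_lt(p2, 1e-4)
  expect_error(violation_probability_model(0.6, -1, 0.4, 0.1, 0, .1, .1),
               "invalid")
})

test_that("the SVG rendering is structured and byte-deterministic", {
  co <- simulate_cohort(seed = 12)
  fr <- build_frame(mean(co$aa_ol), mean(co$aa_leh))
  zones <- list(absolute_zone(co, fr), relative_zone(co, fr))
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  render_figure(fr, co, zones, p1)
  render_figure(fr, co, zones, p2)
  svg <- readLines(p1)
  expect_equal(sum(grepl('class="chord"', svg)), 60L)
  expect_equal(sum(grepl('class="zone-', svg)), 2L)
  expect_equal(sum(grepl('class="triangle"', svg)), 1L)
  expect_identical(readLines(p1), readLines(p2))

  # zones optional: triangle and chords only
  p3 <- withr::local_tempfile(fileext = ".svg")
  render_figure(fr, co, list(), p3)
  expect_equal(sum(grepl("polygon", readLines(p3))), 1L)
})
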