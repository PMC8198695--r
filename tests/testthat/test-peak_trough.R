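test_that("peak finder locates an analytic bump with the expected width", {
  expect_equal(nrow(find_wps_peaks(make_wps_track(rep(0, 2000)))), 0)

  # Gaussian bump, amplitude 1, sd chosen so the half-prominence width
  # (FWHM = 2*sqrt(2 log 2)*sd) is ~140 bp, inside the default [115,164]
  xs <- seq_len(2000)
  sd <- 140 / (2 * sqrt(2 * log(2)))
  tr <- make_wps_track(exp(-(xs - 1000)^2 / (2 * sd^2)))
  pk <- find_wps_peaks(tr)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$apex, 999, tolerance = 2)
  expect_equal(pk$width, 140, tolerance = 1)
  expect_equal(pk$height, 1, tolerance = 1e-6)

  # too narrow a bump fails the width filter
  tr2 <- make_wps_track(exp(-(xs - 1000)^2 / (2 * 20^2)))
  expect_equal(nrow(find_wps_peaks(tr2)), 0)
})

test_that("minimum-distance rule keeps the higher of two close apexes", {
  # two triangular bumps 20 bp apart; enumerating candidates by hand:
  # maxima at 500 (height 1.0) and 520 (height 0.9); distance 20 < 25
  # -> the higher survives
  v <- numeric(1200)
  tri <- function(center, h, half) {
    i <- (center - half):(center + half)
    v[i + 1] <<- pmax(v[i + 1], h * (1 - abs(i - center) / half))
  }
  tri(500, 1, 8)
  tri(520, 0.9, 8)
  pk <- find_wps_peaks(make_wps_track(v),
                       peak_params(min_height = 0.1, min_distance = 25,
                                   width_range = c(1, 1000)))
  expect_equal(pk$apex, 500)
})

test_that("peaks get alternating flanking troughs on periodic signal", {
  xs <- seq_len(3000)
  tr <- make_wps_track(0.8 * sin(2 * pi * xs / 187))
  pk <- find_wps_peaks(tr, peak_params(min_height = 0.2, min_distance = 25,
                                       width_range = c(10, 200)))
  expect_gt(nrow(pk), 10)
  inner <- pk[-c(1, nrow(pk)), ]
  # troughs strictly alternate with apexes
  expect_true(all(inner$left_trough < inner$apex))
  expect_true(all(inner$apex < inner$right_trough))
  expect_true(all(diff(pk$apex) >= 25))
  # spacing reflects the 187 bp period
  expect_equal(mean(diff(pk$apex)), 187, tolerance = 0.02)
})

test_that("trough scan proposes minima of dips and sinusoids", {
  xs <- seq_len(1000)
  expect_equal(nrow(find_troughs(make_wps_track(xs / 1000), w = 5)), 0)

  v <- abs(xs - 500) / 500  # V-dip centered at 500
  pr <- find_troughs(make_wps_track(v), w = 5)
  expect_equal(nrow(pr), 1)
  expect_lte(abs(pr$position - 499), 5)

  xs2 <- seq_len(2000)
  sine <- make_wps_track(sin(2 * pi * xs2 / 180))
  pr2 <- find_troughs(sine, w = 5)
  # analytic minima at x = 135 + 180k (0-based: 134, 314, ...)
  mins <- seq(134, 1950, by = 180)
  expect_equal(nrow(pr2), length(mins))
  expect_true(all(abs(pr2$position - mins[findInterval(pr2$position,
                                                       mins - 90)]) <= 5))
})

test_that("trough credibility equals the printed predicate on random triples", {
  expect_false(credible_trough_predicate(0.9, 60, 150))   # fails height
  expect_true(credible_trough_predicate(0.3, 60, 150))    # all conjuncts

  set.seed(17)
  for (i in 1:1000) {
    h <- runif(1, -0.5, 1.5); wd <- runif(1, 0, 250); pw <- runif(1, 0, 300)
    direct <- (h < 0.58) && (wd > 25 && wd < 100) && (pw > 50 && pw < 220)
    expect_identical(credible_trough_predicate(h, wd, pw), direct)
    # inverted switch flips only the height conjunct
    direct_inv <- (h > 0.58) && (wd > 25 && wd < 100) && (pw > 50 && pw < 220)
    expect_identical(credible_trough_predicate(h, wd, pw, inverted = TRUE),
                     direct_inv)
  }
})

test_that("is_credible_trough reads heights and distances off the track", {
  set.seed(19)
  for (i in 1:200) {
    wd <- sample(30:120, 1)
    pw <- wd + sample(10:150, 1)   # prev trough before prev peak
    h <- runif(1, 0, 1.2)
    v <- numeric(400)
    peak_pos <- 150; pend <- peak_pos + wd; ptr <- pend - pw
    v[peak_pos + 1] <- h          # 0-based coords -> index +1
    v[pend + 1] <- 0
    tr <- make_wps_track(v)
    got <- is_credible_trough(tr, peak_pos, ptr, pend)
    expect_identical(got, credible_trough_predicate(h, wd, pw))
  }
  # no previous peak -> boundary trough, rejected
  expect_false(is_credible_trough(make_wps_track(numeric(100)), NA, NA, 50))
})

test_that("calibration recovers mu - 3*sigma from sampled heights", {
  set.seed(23)
  p <- calibrate_params(heights = rnorm(2000, 0.7, 0.14))
  expect_equal(p$min_height, 0.28, tolerance = 0.02 / 0.28)

  expect_warning(pd <- calibrate_params(heights = rep(0.5, 100)),
                 "degenerate")
  expect_equal(pd$min_height, 0.5)

  # stability: recovered threshold varies < 5% across seeds
  mh <- vapply(1:10, function(s) {
    set.seed(100 + s)
    calibrate_params(heights = rnorm(2000, 0.7, 0.14))$min_height
  }, numeric(1))
  expect_lt(diff(range(mh)) / mean(mh), 0.1)
  expect_true(all(abs(mh - 0.28) < 0.02))
})

test_that("calibration from tracks reports normality and usable widths", {
  set.seed(29)
  xs <- seq_len(6000)
  tracks <- lapply(1:8, function(i) {
    make_wps_track(0.75 * sin(2 * pi * xs / 187) + rnorm(6000, 0, 0.05))
  })
  tracks <- lapply(tracks, function(tr) {
    tr$normalized <- tr$smoothed
    sg_smooth(tr)
  })
  p <- calibrate_params(tracks, n_regions = 200, seed = 3)
  expect_s3_class(p, "peak_params")
  expect_false(is.na(attr(p, "normality")["p.value"]))
  expect_gt(p$min_height, 0)
  expect_lt(p$min_height, 0.8)
  expect_lt(p$width_range[1], p$width_range[2])
})

test_that("trough proposals depend only on waveform shape", {
  set.seed(31)
  v <- cumsum(rnorm(800, 0, 0.1))
  a <- find_troughs(make_wps_track(v), w = 5)
  b <- find_troughs(make_wps_track(v + 3.7), w = 5)
  expect_equal(a$position, b$position)
})
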