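test_that("feature windows are centered, clamped and flagged", {
  expect_equal(as.integer(window_2000(5000)), c(4000, 6000))
  expect_false(attr(window_2000(5000), "clamped"))
  w <- window_2000(500)
  expect_equal(as.integer(w), c(0, 1500))
  expect_true(attr(w, "clamped"))
  expect_equal(diff(as.integer(window_2000(3000, contig_length = 10000))),
               2000)
})

test_that("peak geometry matches closed-form triangle values", {
  # symmetric triangle: apex (150, 1.0), troughs (100, 0) and (200, 0)
  v <- numeric(400)
  v[101:201] <- 1 - abs(101:201 - 151) / 50
  tr <- make_wps_track(v)
  g <- peak_geometry(150, 100, 200, tr)
  expect_equal(unname(g["width"]), 100)
  expect_equal(unname(g["height"]), 1)
  expect_equal(unname(g["area"]), 50)  # 1/2 * base * height
  # angle with x in 10 bp units: arms (-5,-1) and (5,-1)
  expected_angle <- acos(-24 / 26) * 180 / pi
  expect_equal(unname(g["angle"]), expected_angle)

  flat <- peak_geometry(150, 100, 200, make_wps_track(numeric(400)))
  expect_equal(unname(flat["area"]), 0)
  expect_equal(unname(flat["height"]), 0)

  expect_null(peak_geometry(150, NA, 200, tr))
})

test_that("coverage trends recover exact and noisy linear fits", {
  pos <- 0:1999
  tr <- coverage_trends(2 * pos + 1)
  expect_equal(unname(tr[c("slope_full", "slope_left", "slope_right")]),
               rep(2, 3))
  expect_equal(unname(tr[c("intercept_full", "intercept_left",
                           "intercept_right")]), rep(1, 3))

  expect_equal(unname(coverage_trends(rep(3.5, 2000))["slope_full"]), 0)

  set.seed(53)
  y <- 0.002 * pos - 1 + rnorm(2000, 0, 0.3)
  tr <- coverage_trends(y)
  # closed-form OLS normal equations on each sub-interval
  for (iv in list(c(0, 2000, "full"), c(0, 1200, "left"),
                  c(800, 2000, "right"))) {
    idx <- which(pos >= as.numeric(iv[1]) & pos < as.numeric(iv[2]))
    x <- pos[idx]; yy <- y[idx]
    beta <- sum((x - mean(x)) * (yy - mean(yy))) / sum((x - mean(x))^2)
    alpha <- mean(yy) - beta * mean(x)
    expect_equal(unname(tr[paste0("slope_", iv[3])]), beta, tolerance = 1e-9)
    expect_equal(unname(tr[paste0("intercept_", iv[3])]), alpha,
                 tolerance = 1e-9)
  }
})

# deterministic two-peak fixture shared by the tests below
two_peak_fixture <- function(shift = 0L) {
  v <- numeric(4000)
  tri <- function(center, h, half) {
    idx <- (center - half):(center + half)
    v[idx + 1] <<- pmax(v[idx + 1], h * (1 - abs(idx - center) / half))
  }
  tri(1800, 1.0, 100)
  tri(2150, 0.8, 80)
  depth <- rep(20, 4000)
  depth[1901:2100] <- 8
  list(wps = make_wps_track(v, start = shift),
       cov = make_cov_track(depth, start = shift),
       peaks = data.frame(apex = c(1800, 2150) + shift, height = c(1, 0.8),
                          prominence = c(1, 0.8), width = c(100, 80),
                          left_trough = c(1700, 2070) + shift,
                          right_trough = c(1900, 2230) + shift))
}

test_that("assembled features equal hand calculations on a two-peak fixture", {
  fx <- two_peak_fixture()
  f <- assemble_features(2000, fx$peaks, fx$wps, fx$cov)
  expect_named(f, feature_names())
  expect_true(all(is.finite(f)))

  # geometry: triangle 1 (h 1.0, half 100) and triangle 2 (h .8, half 80)
  # NB triangle 2's left trough (2070) sits on triangle 1's right slope
  expect_equal(unname(f["peak_height_mean"]),
               mean(c(1, 0.8 - mean(c(fx$wps$smoothed[2071], 0)))))
  expect_equal(unname(f["peak_width_mean"]), mean(c(200, 160)))
  expect_equal(unname(f["peak_spacing_mean"]), 350)
  expect_equal(unname(f["peak_spacing_var"]), 0)
  expect_equal(unname(f["geometry_missing"]), 0)
  # coverage features: hand-computed from the planted dip
  lm2000 <- (1800 * 20 + 200 * 8) / 2000
  expect_equal(unname(f["broad_interval_coverage"]), 1)  # window = hood
  # narrow window [1700,2300): 400 bases at depth 20, 200 at depth 8
  expect_equal(unname(f["narrow_interval_coverage"]),
               (400 * 20 + 200 * 8) / 600 / lm2000)

  # single complete peak -> zero variances
  single <- fx$peaks[1, , drop = FALSE]
  f1 <- assemble_features(1800, single, fx$wps, fx$cov)
  expect_equal(unname(f1["peak_height_var"]), 0)
  expect_equal(unname(f1["peak_area_var"]), 0)

  # uniform coverage -> narrow = broad = 1
  fu <- assemble_features(2000, fx$peaks, fx$wps,
                          make_cov_track(rep(7, 4000)))
  expect_equal(unname(fu["narrow_interval_coverage"]), 1)
  expect_equal(unname(fu["broad_interval_coverage"]), 1)
})

test_that("features are invariant under genomic translation", {
  a <- two_peak_fixture(0L)
  b <- two_peak_fixture(10000L)
  fa <- assemble_features(2000, a$peaks, a$wps, a$cov)
  fb <- assemble_features(12000, b$peaks, b$wps, b$cov)
  expect_equal(fa, fb)
})

test_that("windows without complete peaks are flagged, not dropped", {
  tr <- make_wps_track(numeric(4000))
  cov <- make_cov_track(rep(10, 4000))
  pk <- find_wps_peaks(make_wps_track(numeric(4000)))
  f <- assemble_features(2000, pk, tr, cov)
  expect_equal(unname(f["geometry_missing"]), 1)
  expect_equal(unname(f["peak_area_mean"]), 0)
  expect_true(all(is.finite(f)))
})

test_that("feature TSV export keeps the documented column order", {
  fx <- two_peak_fixture()
  f <- assemble_features(2000, fx$peaks, fx$wps, fx$cov)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_features_tsv(t(as.matrix(f)), tsv)
  got <- read.delim(tsv)
  expect_equal(names(got), feature_names())
})
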