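# peak scaffold: regular 170 bp arrays flanking a configurable gap
gap_scaffold <- function(gap_start = 1000, gap_end = 1400) {
  left <- seq(gap_start - 170 * 5, gap_start, by = 170)
  right <- seq(gap_end, gap_end + 170 * 5, by = 170)
  make_peaks(c(left, right))
}

test_that("a wide, low-coverage, regular gap becomes one 600 bp candidate", {
  pk <- gap_scaffold(1000, 1400)
  depth <- rep(40, 4000)
  depth[(1050 + 1):1350] <- 10  # central initial region at 0.25x
  cov <- make_cov_track(depth)
  cand <- call_candidates(pk, cov)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 900)
  expect_equal(cand$end, 1500)
  # hand computation: local mean over [200,2200) = (1700*40+300*10)/2000
  expect_equal(cand$mean_norm_coverage, 10 / ((1700 * 40 + 300 * 10) / 2000))
  expect_lt(cand$mean_norm_coverage, 0.6)
})

test_that("narrow gaps and high coverage are rejected", {
  depth <- rep(40, 4000)
  cov <- make_cov_track(depth)
  # gap of exactly 200 <= 250
  expect_equal(nrow(call_candidates(gap_scaffold(1000, 1200), cov)), 0)
  # wide gap but full coverage (normalized ~1 > 0.6)
  expect_equal(nrow(call_candidates(gap_scaffold(1000, 1400), cov)), 0)
})

test_that("flank regularity needs enough evenly spaced peaks per side", {
  expect_true(flank_regularity(gap_scaffold(1000, 1400), c(1000, 1400)))
  one_per_side <- make_peaks(c(1000, 1400))
  expect_false(flank_regularity(one_per_side, c(1000, 1400)))

  # random peak sets vs direct enumeration of the predicate
  set.seed(37)
  for (i in 1:200) {
    apex <- sort(sample(0:3000, sample(2:12, 1)))
    span <- c(1200, 1600)
    left <- apex[apex >= span[1] - 1000 & apex <= span[1]]
    right <- apex[apex >= span[2] & apex <= span[2] + 1000]
    ok_side <- function(s) {
      length(s) >= 3 && all(diff(s) >= 120 & diff(s) <= 220)
    }
    expect_identical(flank_regularity(make_peaks(apex), span),
                     ok_side(left) && ok_side(right))
  }
})

test_that("repeat subtraction drops overlapping calls only", {
  cand <- data.frame(contig = "chrT", gap_start = 1000, gap_end = 1400,
                     center = 1200, start = 900, end = 1500,
                     mean_norm_coverage = 0.3, flank_regular = TRUE)
  reps <- data.frame(contig = "chrT", start = 1400, end = 1600)
  expect_equal(nrow(subtract_repeats(cand, reps)), 0)
  expect_equal(subtract_repeats(cand, reps[0, , drop = FALSE]), cand)
  unsorted <- data.frame(contig = "chrT", start = c(5000, 100),
                         end = c(5100, 200))
  expect_warning(kept <- subtract_repeats(cand, unsorted), "sort")
  expect_equal(kept, cand)

  set.seed(41)
  for (i in 1:20) {
    ncand <- 50
    cs <- sample(0:50000, ncand) %/% 600 * 600
    cand <- data.frame(contig = "chrT", gap_start = cs, gap_end = cs + 400,
                       center = cs + 300, start = cs, end = cs + 600,
                       mean_norm_coverage = 0.3, flank_regular = TRUE)
    rs <- sort(sample(0:50000, 40))
    reps <- data.frame(contig = "chrT", start = rs,
                       end = rs + sample(50:800, 40, replace = TRUE))
    got <- subtract_repeats(cand, reps)
    # quadratic all-pairs oracle
    hit <- vapply(seq_len(ncand), function(k) {
      any(pmin(cand$end[k], reps$end) - pmax(cand$start[k], reps$start) > 0)
    }, logical(1))
    expect_equal(got$start, cand$start[!hit])
  }
})

test_that("tile-boundary duplicates merge into one fixed-size call", {
  cand <- data.frame(contig = "chrT", gap_start = c(1000, 1000),
                     gap_end = c(1400, 1400), center = c(1200, 1210),
                     start = c(900, 910), end = c(1500, 1510),
                     mean_norm_coverage = 0.3, flank_regular = TRUE)
  m <- merge_tile_calls(cand)
  expect_equal(nrow(m), 1)
  expect_equal(m$end - m$start, 600)

  disjoint <- data.frame(contig = "chrT", gap_start = c(1000, 9000),
                         gap_end = c(1400, 9400), center = c(1200, 9200),
                         start = c(900, 8900), end = c(1500, 9500),
                         mean_norm_coverage = 0.3, flank_regular = TRUE)
  expect_equal(merge_tile_calls(disjoint)[, c("start", "end")],
               disjoint[, c("start", "end")])

  # duplicated subset of well-separated base calls: count = number of bases
  set.seed(43)
  for (i in 1:10) {
    base <- sort(sample(seq(1000, 90000, by = 1500), 20))
    dup <- sample(base, 8)
    cs <- sort(c(base, dup + sample(c(-100, 100), 8, replace = TRUE)))
    cand <- data.frame(contig = "chrT", gap_start = cs, gap_end = cs + 400,
                       center = cs + 300, start = cs, end = cs + 600,
                       mean_norm_coverage = 0.3, flank_regular = TRUE)
    m <- merge_tile_calls(cand)
    expect_equal(nrow(m), 20)
    expect_true(all(m$end - m$start == 600))
  }
})

test_that("candidate counts are monotone in the weak-filter thresholds", {
  set.seed(47)
  ocrs <- plant_ocrs(4, 2e5, seed = 47)
  sim <- sample_fragments(sim_config(genome_length = 2e5,
                                     ocr_intervals = ocrs, depth = 30,
                                     seed = 47))
  tile <- simple_tile("sim", 0, 2e5, pad = 0)
  w <- sg_smooth(detrend_normalize(compute_wps(sim$fragments, tile)))
  cov <- compute_coverage(sim$fragments, tile)
  pk <- find_wps_peaks(w, peak_params(min_height = 0.3, min_distance = 25,
                                      width_range = c(10, 200)))
  n_base <- nrow(call_candidates(pk, cov))
  expect_gt(n_base, 0)
  expect_gte(nrow(call_candidates(pk, cov, max_cov = 0.9)), n_base)
  expect_gte(nrow(call_candidates(pk, cov, min_gap = 200)), n_base)
  expect_lte(nrow(call_candidates(pk, cov, max_cov = 0.3)), n_base)
  got <- call_candidates(pk, cov)
  expect_true(all(got$end - got$start == 600))
})
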