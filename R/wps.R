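#' Per-base signal tracks
#'
#' A `wps_track` covers a tile plus its padding: positions
#' `[start, end)` in 0-based genomic coordinates, one value per base.
#' Layers are filled in stages: `raw` by [compute_wps()], `normalized`
#' by [detrend_normalize()], `smoothed` by [sg_smooth()]. A
#' `coverage_track` carries `depth` and (locally) `normalized` layers.
#'
#' @name tracks
NULL

new_track <- function(tile, values, class, layer) {
  start <- max(0L, tile$start - tile$pad)
  end <- tile$end + tile$pad
  tr <- list(tile = tile, start = start, end = end)
  tr[[layer]] <- values
  structure(tr, class = class)
}

track_positions <- function(track) seq.int(track$start, track$end - 1L)

track_index <- function(track, coord) as.integer(coord - track$start + 1L)

#' Compute the raw window protection score track
#'
#' The WPS at coordinate x is the number of fragments completely
#' spanning the `window`-bp window centered at x, minus the number of
#' fragments with at least one endpoint (start base or last base) inside
#' that window. A fragment with both endpoints inside the window
#' contributes -1 once. The window is `[x - window/2, x + window/2)`.
#'
#' Implemented with difference arrays: a fragment `[s, e)` spans the
#' window exactly for `x` in `[s + h, e - h]` (h = window/2), and has an
#' endpoint `p` inside it for `x` in `[p - h + 1, p + h]`; the two
#' endpoint intervals are merged before subtraction so short fragments
#' are not double-counted.
#'
#' @param frags fragment data.frame (pre-filtered by length)
#' @param tile single tile row (see [tile_genome()])
#' @param window protection window in bp, even, default 120
#' @return a `wps_track` with the `raw` layer filled
#' @export
compute_wps <- function(frags, tile, window = 120L) {
  stopifnot(window >= 2, window %% 2 == 0)
  h <- window %/% 2L
  start <- max(0L, tile$start - tile$pad)
  end <- tile$end + tile$pad
  L <- end - start
  delta <- numeric(L + 1L)
  frags <- frags[frags$contig == tile$contig, , drop = FALSE]
  if (nrow(frags) > 0) {
    s <- frags$start
    e <- frags$end
    add_interval <- function(delta, lo, hi, sign) {
      # add `sign` over genomic coord range [lo, hi], clipped to track
      lo <- pmax(lo, start)
      hi <- pmin(hi, end - 1L)
      ok <- lo <= hi
      lo <- lo[ok] - start + 1L
      hi <- hi[ok] - start + 2L
      if (length(lo) > 0) {
        delta <- delta + sign * (tabulate(lo, nbins = L + 1L) -
                                 tabulate(hi, nbins = L + 1L))
      }
      delta
    }
    delta <- add_interval(delta, s + h, e - h, +1)
    # endpoint windows around s and e-1; merge when they touch/overlap
    lo1 <- s - h + 1L; hi1 <- s + h
    lo2 <- e - 1L - h + 1L; hi2 <- e - 1L + h
    merged <- lo2 <= hi1 + 1L
    delta <- add_interval(delta, lo1[merged], hi2[merged], -1)
    delta <- add_interval(delta, lo1[!merged], hi1[!merged], -1)
    delta <- add_interval(delta, lo2[!merged], hi2[!merged], -1)
  }
  raw <- cumsum(delta[seq_len(L)])
  tr <- new_track(tile, raw, "wps_track", "raw")
  tr$window <- as.integer(window)
  tr
}

#' Compute the per-base fragment coverage track
#'
#' `depth[x]` counts fragments with `start <= x < end`.
#'
#' @inheritParams compute_wps
#' @return a `coverage_track` with the `depth` layer filled
#' @export
compute_coverage <- function(frags, tile) {
  start <- max(0L, tile$start - tile$pad)
  end <- tile$end + tile$pad
  L <- end - start
  delta <- numeric(L + 1L)
  frags <- frags[frags$contig == tile$contig, , drop = FALSE]
  if (nrow(frags) > 0) {
    lo <- pmax(frags$start, start)
    hi <- pmin(frags$end, end)
    ok <- lo < hi
    lo <- lo[ok] - start + 1L
    hi <- hi[ok] - start + 1L
    if (length(lo) > 0) {
      delta <- tabulate(lo, nbins = L + 1L) - tabulate(hi, nbins = L + 1L)
    }
  }
  new_track(tile, cumsum(delta[seq_len(L)]), "coverage_track", "depth")
}

#' Running median with truncated windows at the edges
#'
#' Interior positions use the fast C implementation in [stats::runmed()];
#' within half a window of either edge the median is taken over the
#' available (truncated) window, so the baseline does not bend toward an
#' extrapolated end rule.
#'
#' @param x numeric vector
#' @param k odd window size
#' @return numeric vector, same length as x
#' @export
running_median <- function(x, k) {
  stopifnot(k %% 2 == 1, k >= 1)
  n <- length(x)
  if (k == 1 || n == 0) return(as.numeric(x))
  if (k >= n) k <- if (n %% 2 == 1) n else n - 1L
  h <- (k - 1L) %/% 2L
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  out[seq_len(h)] <- edge_medians(x, h)
  out[n - seq_len(h) + 1L] <- edge_medians(rev(x), h)
  out
}

# medians of the growing prefix windows x[1:(i+h)], i = 1..h, via
# incremental sorted insertion (the truncated windows at a track edge)
edge_medians <- function(x, h) {
  n <- length(x)
  out <- numeric(h)
  s <- sort(x[seq_len(min(n, h + 1L))])
  for (i in seq_len(h)) {
    m <- length(s)
    out[i] <- if (m %% 2L == 1L) s[(m + 1L) %/% 2L] else
      (s[m %/% 2L] + s[m %/% 2L + 1L]) / 2
    nxt <- i + h + 1L
    if (nxt <= n) s <- append(s, x[nxt], after = findInterval(x[nxt], s))
  }
  out
}

#' Detrend and normalize a raw WPS track
#'
#' Subtracts a running-median baseline (which removes the slow
#' coverage-driven drift of the waveform so it sits on a stable
#' horizontal line) and scales by the maximum absolute deviation over
#' the tile, mapping the waveform into [-1, 1]. Peak/trough thresholds
#' downstream (0.28, 0.58) are defined on this unit scale.
#'
#' @param track a `wps_track` with `raw` filled
#' @param baseline_window odd running-median window in bp (default 1001,
#'   several nucleosome repeats, so the baseline tracks drift but not
#'   the ~187 bp oscillation itself)
#' @return the track with `normalized` filled; attribute `low_signal` is
#'   TRUE when the detrended waveform is identically zero
#' @export
detrend_normalize <- function(track, baseline_window = 1001L) {
  stopifnot(baseline_window %% 2 == 1)
  n <- length(track$raw)
  if (baseline_window >= n) stop("baseline_window must be < track length")
  det <- track$raw - running_median(track$raw, baseline_window)
  m <- max(abs(det))
  if (m == 0) {
    track$normalized <- numeric(n)
    track$low_signal <- TRUE
  } else {
    track$normalized <- det / m
    track$low_signal <- FALSE
  }
  track
}

# Savitzky-Golay smoothing of a bare numeric vector. Interior points are
# the center of an order-`p` least-squares polynomial fit over `n`
# points (a fixed convolution); the first/last half-windows are filled
# by evaluating a polynomial fit to the first/last full window at the
# edge positions, so no artificial peaks are reflected into the tile.
savgol <- function(x, p = 2L, n = 31L) {
  stopifnot(n %% 2 == 1, p < n)
  L <- length(x)
  if (n > L) stop("SG window larger than signal")
  h <- (n - 1L) %/% 2L
  t <- seq(-h, h)
  A <- outer(t, 0:p, `^`)
  # convolution weights = first row of (A'A)^-1 A'
  w <- solve(crossprod(A), t(A))[1L, ]
  out <- stats::filter(x, rev(w), method = "convolution", sides = 2)
  out <- as.numeric(out)
  fit_edge <- function(idx) {
    tt <- seq_along(idx) - 1
    co <- stats::lm.fit(outer(tt, 0:p, `^`), x[idx])$coefficients
    co[is.na(co)] <- 0
    function(pos) drop(outer(pos, 0:p, `^`) %*% co)
  }
  fl <- fit_edge(1:n)
  out[1:h] <- fl(0:(h - 1))
  fr <- fit_edge((L - n + 1L):L)
  out[(L - h + 1L):L] <- fr((n - h):(n - 1))
  out
}

#' Savitzky-Golay smoothing of the normalized WPS layer
#'
#' Local least-squares polynomial smoothing preserves the shape and
#' width of nucleosome peaks while removing sampling noise; an order-2
#' filter reproduces any locally quadratic waveform exactly.
#'
#' @param track a `wps_track` with `normalized` filled
#' @param order polynomial order (default 2)
#' @param window odd filter window in bp (default 31)
#' @return the track with `smoothed` filled
#' @export
sg_smooth <- function(track, order = 2L, window = 31L) {
  if (is.null(track$normalized)) stop("normalize the track first")
  track$smoothed <- savgol(track$normalized, order, window)
  track
}

#' Normalize coverage against a local neighborhood
#'
#' Divides depth by its mean over a `neighborhood`-bp region centered on
#' `center`, so 1.0 means locally average coverage. The normalized layer
#' spans the whole track but its unit is defined by that neighborhood.
#'
#' @param cov a `coverage_track`
#' @param center genomic coordinate (midpoint of the region under test)
#' @param neighborhood size of the normalization region in bp (default 2000)
#' @return the track with `normalized` filled; attribute `uncallable` is
#'   TRUE when the neighborhood mean depth is zero
#' @export
normalize_coverage <- function(cov, center, neighborhood = 2000L) {
  m <- local_mean_depth(cov, center, neighborhood)
  if (m == 0) {
    cov$normalized <- rep(NA_real_, length(cov$depth))
    cov$uncallable <- TRUE
  } else {
    cov$normalized <- cov$depth / m
    cov$uncallable <- FALSE
  }
  cov
}

local_mean_depth <- function(cov, center, neighborhood = 2000L) {
  h <- neighborhood %/% 2L
  lo <- max(cov$start, as.integer(center) - h)
  hi <- min(cov$end, as.integer(center) + h)
  if (hi <= lo) return(0)
  mean(cov$depth[track_index(cov, lo):track_index(cov, hi - 1L)])
}

#' Export a track layer as bedGraph
#' @param track a `wps_track` or `coverage_track`
#' @param layer which layer to export
#' @param path output file
#' @export
write_bedgraph <- function(track, layer, path) {
  v <- track[[layer]]
  if (is.null(v)) stop("layer '", layer, "' not computed")
  runs <- rle(v)
  ends <- track$start + cumsum(runs$lengths)
  starts <- ends - runs$lengths
  data.table::fwrite(data.frame(track$tile$contig, starts, ends, runs$values),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Export a track layer as fixedStep wiggle
#' @inheritParams write_bedgraph
#' @export
write_wiggle <- function(track, layer, path) {
  v <- track[[layer]]
  if (is.null(v)) stop("layer '", layer, "' not computed")
  con <- file(path, "w")
  on.exit(close(con))
  # wiggle is 1-based
  writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                     track$tile$contig, track$start + 1L), con)
  writeLines(format(v, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}
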