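# build tracks directly from explicit per-base vectors (no fragments)

make_wps_track <- function(values, start = 0L, contig = "chrT",
                           layer = "smoothed") {
  tile <- data.frame(contig = contig, start = as.integer(start),
                     end = as.integer(start + length(values)), pad = 0L,
                     stringsAsFactors = FALSE)
  tr <- structure(list(tile = tile, start = as.integer(start),
                       end = as.integer(start + length(values)),
                       window = 120L),
                  class = "wps_track")
  tr[[layer]] <- as.numeric(values)
  tr
}

make_cov_track <- function(depth, start = 0L, contig = "chrT") {
  tile <- data.frame(contig = contig, start = as.integer(start),
                     end = as.integer(start + length(depth)), pad = 0L,
                     stringsAsFactors = FALSE)
  structure(list(tile = tile, start = as.integer(start),
                 end = as.integer(start + length(depth)),
                 depth = as.numeric(depth)),
            class = "coverage_track")
}

# peaks table from bare apex coordinates (heights optional)
make_peaks <- function(apex, height = NULL) {
  data.frame(apex = as.integer(apex),
             height = if (is.null(height)) rep(1, length(apex)) else height,
             prominence = 1, width = 60,
             left_trough = NA_integer_, right_trough = NA_integer_)
}

simple_tile <- function(contig, start, end, pad = 0L) {
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end), pad = as.integer(pad),
             stringsAsFactors = FALSE)
}

# brute-force WPS oracle: tests every window against every fragment
wps_oracle <- function(frags, tile, window = 120L) {
  h <- window %/% 2L
  start <- max(0L, tile$start - tile$pad)
  end <- tile$end + tile$pad
  s <- frags$start; e <- frags$end
  vapply(seq.int(start, end - 1L), function(x) {
    wlo <- x - h; whi <- x + h  # window [wlo, whi)
    span <- s <= wlo & e >= whi
    endpt <- (s >= wlo & s < whi) | ((e - 1L) >= wlo & (e - 1L) < whi)
    # two counts, as defined: a fragment sitting exactly on the window
    # edge can appear in both (net 0)
    sum(span) - sum(endpt)
  }, numeric(1))
}
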