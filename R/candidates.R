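#' Call candidate OCRs from the peak landscape and coverage
#'
#' A missing nucleosome opens a gap in the peak array: with a 167 bp
#' core, adjacent apexes more than ~250 bp apart mark a possible open
#' region. The initial OCR is the central `initial_size` (~300) bp of
#' the gap. Each gap is kept as a candidate iff (a) the
#' mean coverage of that initial region, normalized to the 2000 bp
#' neighborhood centered on the gap midpoint, is below `max_cov`, and
#' (b) the flanking nucleosome array is regular (see
#' [flank_regularity()]). The call interval is the gap midpoint extended
#' to exactly 600 bp: the ~300 bp open core plus one nucleosome (167 bp)
#' of positional tolerance on each side.
#'
#' @param peaks peak table from [find_wps_peaks()] (sorted by apex)
#' @param coverage a `coverage_track` with `depth` filled
#' @param min_gap minimum apex separation in bp (strict, default 250)
#' @param max_cov maximum mean normalized coverage over the initial
#'   region (default 0.6)
#' @param initial_size size of the initial OCR region tested for low
#'   coverage, centered on the gap midpoint (default 300). The flanks of
#'   the gap are partially covered by the fragments of the two bounding
#'   nucleosomes, so averaging over the whole apex-to-apex span would
#'   dilute the dip.
#' @param flank,min_peaks_per_side,spacing_range regularity parameters,
#'   see [flank_regularity()]
#' @param call_size final call size in bp (default 600)
#' @return data.frame of candidates: contig, gap_start, gap_end, center,
#'   start, end (the call interval), mean_norm_coverage, flank_regular
#' @export
call_candidates <- function(peaks, coverage, min_gap = 250L, max_cov = 0.6,
                            flank = 1000L, min_peaks_per_side = 3L,
                            spacing_range = c(120, 220), call_size = 600L,
                            initial_size = 300L) {
  empty <- data.frame(contig = character(), gap_start = integer(),
                      gap_end = integer(), center = integer(),
                      start = integer(), end = integer(),
                      mean_norm_coverage = numeric(),
                      flank_regular = logical())
  if (is.null(peaks) || nrow(peaks) < 2) return(empty)
  apex <- sort(peaks$apex)
  gaps <- which(diff(apex) > min_gap)
  if (length(gaps) == 0) return(empty)
  half <- call_size %/% 2L
  rows <- lapply(gaps, function(k) {
    g0 <- apex[k]; g1 <- apex[k + 1L]
    center <- (g0 + g1) %/% 2L
    m <- local_mean_depth(coverage, center, 2000L)
    if (m == 0) return(NULL)  # uncallable: no local signal at all
    ihalf <- initial_size %/% 2L
    i0 <- track_index(coverage, max(coverage$start, center - ihalf))
    i1 <- track_index(coverage, min(coverage$end - 1L, center + ihalf - 1L))
    mcov <- mean(coverage$depth[i0:i1]) / m
    reg <- flank_regularity(peaks, c(g0, g1), flank, min_peaks_per_side,
                            spacing_range)
    if (mcov < max_cov && reg) {
      data.frame(contig = coverage$tile$contig, gap_start = g0, gap_end = g1,
                 center = center, start = center - half, end = center + half,
                 mean_norm_coverage = mcov, flank_regular = reg)
    } else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test whether a gap is flanked by regular nucleosome arrays
#'
#' TRUE iff each side of `span` has at least `min_peaks_per_side` peak
#' apexes within `flank` bp and every consecutive spacing among those
#' side peaks lies inside `spacing_range` (by default 120-220 bp, the
#' band around the ~187 bp nucleosome repeat).
#'
#' @param peaks peak table (uses the `apex` column)
#' @param span numeric length-2: the gap (gap_start, gap_end)
#' @param flank search distance from the gap edge in bp
#' @param min_peaks_per_side minimum apexes per side
#' @param spacing_range allowed consecutive-spacing band in bp
#' @return logical
#' @export
flank_regularity <- function(peaks, span, flank = 1000L,
                             min_peaks_per_side = 3L,
                             spacing_range = c(120, 220)) {
  apex <- sort(peaks$apex)
  side_ok <- function(side) {
    if (length(side) < min_peaks_per_side) return(FALSE)
    if (length(side) == 1) return(TRUE)
    sp <- diff(sort(side))
    all(sp >= spacing_range[1] & sp <= spacing_range[2])
  }
  left <- apex[apex >= span[1] - flank & apex <= span[1]]
  right <- apex[apex >= span[2] & apex <= span[2] + flank]
  side_ok(left) && side_ok(right)
}

#' Remove candidates overlapping repeat regions
#'
#' Mapping artifacts inside interspersed and tandem repeats (SINE, LINE,
#' LTR, satellites) depress coverage and mimic open chromatin, so calls
#' touching annotated repeats are dropped wholesale (the 600 bp output
#' contract is preserved by dropping rather than truncating).
#'
#' @param candidates candidate data.frame (with start/end call intervals)
#' @param repeats repeat intervals: data.frame with contig/start/end
#'   (e.g. a RepeatMasker BED read via [read_bed_intervals()]) or a
#'   `GRanges`
#' @param min_overlap_frac drop a call when at least this fraction of it
#'   overlaps a repeat; 0 (default) drops on any overlap
#' @return the surviving candidates
#' @export
subtract_repeats <- function(candidates, repeats, min_overlap_frac = 0) {
  if (nrow(candidates) == 0) return(candidates)
  rg <- as_granges(repeats)
  key <- order(as.character(GenomicRanges::seqnames(rg)),
               GenomicRanges::start(rg))
  if (is.unsorted(key)) {
    warning("repeat regions not sorted; sorting internally")
    rg <- rg[key]
  }
  cg <- GenomicRanges::GRanges(candidates$contig,
                               IRanges::IRanges(candidates$start + 1L,
                                                candidates$end))
  hits <- GenomicRanges::findOverlaps(cg, rg)
  if (length(hits) == 0) return(candidates)
  ov <- GenomicRanges::pintersect(cg[S4Vectors::queryHits(hits)],
                                  rg[S4Vectors::subjectHits(hits)])
  frac <- GenomicRanges::width(ov) /
    GenomicRanges::width(cg[S4Vectors::queryHits(hits)])
  thresh <- if (min_overlap_frac <= 0) 0 else min_overlap_frac
  drop <- unique(S4Vectors::queryHits(hits)[
    if (min_overlap_frac <= 0) rep(TRUE, length(hits)) else frac >= thresh])
  if (length(drop) == 0) return(candidates)
  out <- candidates[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge duplicate calls across tile boundaries
#'
#' Tiles are padded, so a region near a core edge can be called from two
#' neighboring tiles. Calls on the same contig whose 600 bp intervals
#' overlap by at least `min_overlap` bp are merged: the merged call is
#' re-centered on the midpoint of their union and re-extended to the
#' fixed call size.
#'
#' @param candidates candidate data.frame pooled over tiles
#' @param min_overlap bp of overlap that triggers a merge (default 300)
#' @param call_size fixed output size (default 600)
#' @return deduplicated, coordinate-sorted candidates
#' @export
merge_tile_calls <- function(candidates, min_overlap = 300L,
                             call_size = 600L) {
  if (nrow(candidates) == 0) return(candidates)
  candidates <- candidates[order(candidates$contig, candidates$start), ,
                           drop = FALSE]
  half <- call_size %/% 2L
  out <- list()
  grp <- candidates[1, , drop = FALSE]
  u0 <- grp$start[1]; u1 <- grp$end[1]
  flush <- function(g, u0, u1) {
    center <- (u0 + u1) %/% 2L
    prob <- if ("prob" %in% names(g)) max(g$prob) else NULL
    g <- g[1, , drop = FALSE]
    g$center <- center; g$start <- center - half; g$end <- center + half
    g$mean_norm_coverage <- NA_real_
    if (!is.null(prob)) g$prob <- prob
    g
  }
  for (i in seq_len(nrow(candidates))[-1]) {
    row <- candidates[i, , drop = FALSE]
    if (row$contig == grp$contig[1] && (min(u1, row$end) - row$start) >= min_overlap) {
      u0 <- min(u0, row$start); u1 <- max(u1, row$end)
      grp <- rbind(grp, row)
    } else {
      out[[length(out) + 1L]] <- if (nrow(grp) > 1) flush(grp, u0, u1) else grp
      grp <- row; u0 <- row$start; u1 <- row$end
    }
  }
  out[[length(out) + 1L]] <- if (nrow(grp) > 1) flush(grp, u0, u1) else grp
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED file of plain intervals (e.g. RepeatMasker regions, truth sets)
#' @param path BED3+ file
#' @return data.frame with contig, start, end (0-based half-open)
#' @export
read_bed_intervals <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  data.frame(contig = as.character(dt[[1]]), start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]), stringsAsFactors = FALSE)
}

as_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  GenomicRanges::GRanges(x$contig, IRanges::IRanges(x$start + 1L, x$end))
}

#' Write calls as BED6
#'
#' Score column is `1000 * classifier probability` when a `prob` column
#' is present, else 0.
#'
#' @param calls candidate/call data.frame
#' @param path output file
#' @export
write_calls_bed <- function(calls, path) {
  score <- if ("prob" %in% names(calls) && nrow(calls) > 0) {
    as.integer(round(1000 * calls$prob))
  } else rep(0L, nrow(calls))
  df <- data.frame(calls$contig, calls$start, calls$end,
                   sprintf("ocr_%05d", seq_len(nrow(calls))), score, ".")
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
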