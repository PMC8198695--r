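#' Fragment and tile containers
#'
#' Fragments are plain `data.frame`s with columns `contig` (character),
#' `start` and `end` (0-based half-open, BED convention). `length` is
#' derived as `end - start`. All internal coordinates are 0-based
#' half-open; conversion from 1-based BAM records happens at the import
#' boundary only.
#'
#' @param contig character vector of contig names
#' @param start,end integer vectors, 0-based half-open
#' @return a validated fragment `data.frame` with a `length` column
#' @export
fragments <- function(contig = character(), start = integer(), end = integer()) {
  df <- data.frame(contig = as.character(contig),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  validate_fragments(df)
}

validate_fragments <- function(df) {
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  if (nrow(df) > 0) {
    if (any(df$start < 0)) stop("fragment start < 0")
    if (any(df$end <= df$start)) stop("fragment end <= start")
  }
  df$length <- df$end - df$start
  df[, c("contig", "start", "end", "length")]
}

#' Read cfDNA fragments from BED3 or coordinate-sorted indexed BAM
#'
#' For BAM input a fragment is the outer template span of a properly
#' paired read pair, taken once per pair from the leftmost mate
#' (`TLEN > 0`), subject to a mapping-quality filter. For BED input each
#' line is one fragment, already in 0-based half-open coordinates.
#'
#' @param path BED3 (`.bed`) or indexed BAM (`.bam`) file
#' @param region optional single tile (see [tile_genome()]); fragments
#'   overlapping `region` extended by its `pad` are returned. Required
#'   for BAM input.
#' @param length_bounds keep fragments with `length_bounds[1] <= length
#'   <= length_bounds[2]`. Default 120-180 bp selects mononucleosome-
#'   sized molecules, the size class that carries the nucleosome
#'   protection signal.
#' @param mapq minimum mapping quality for BAM records (default 30)
#' @return fragment data.frame (see [fragments()])
#' @export
read_fragments <- function(path, region = NULL, length_bounds = c(120L, 180L),
                           mapq = 30L) {
  stopifnot(length(length_bounds) == 2, length_bounds[1] <= length_bounds[2])
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    frags <- read_fragments_bam(path, region, mapq)
  } else {
    frags <- read_fragments_bed(path)
    if (!is.null(region)) {
      lo <- region$start - region$pad
      hi <- region$end + region$pad
      keep <- frags$contig == region$contig & frags$end > lo & frags$start < hi
      if (!any(frags$contig == region$contig)) {
        warning("contig '", region$contig, "' not present in ", path,
                "; returning empty fragment set")
      }
      frags <- frags[keep, , drop = FALSE]
    }
  }
  frags <- frags[frags$length >= length_bounds[1] &
                 frags$length <= length_bounds[2], , drop = FALSE]
  rownames(frags) <- NULL
  frags
}

read_fragments_bed <- function(path) {
  if (file.size(path) == 0) return(fragments())
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3) stop("BED file ", path, " has fewer than 3 columns")
  s <- suppressWarnings(as.integer(as.character(dt[[2]])))
  e <- suppressWarnings(as.integer(as.character(dt[[3]])))
  bad <- which(is.na(s) | is.na(e) | e <= s | s < 0)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path, ": '",
         paste(unlist(dt[bad[1], 1:3]), collapse = "\t"), "'")
  }
  fragments(dt[[1]], s, e)
}

read_fragments_bam <- function(path, region, mapq) {
  if (is.null(region)) stop("BAM input requires a `region` tile")
  bai <- paste0(path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("BAM index (.bai) not found for ", path,
         "; run `samtools index` first")
  }
  lo <- max(0L, region$start - region$pad)
  hi <- region$end + region$pad
  gr <- GenomicRanges::GRanges(region$contig,
                               IRanges::IRanges(lo + 1L, hi))
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, which = gr,
                                   what = c("rname", "pos", "isize", "mapq"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(res$isize) & res$isize > 0 &
    !is.na(res$mapq) & res$mapq >= mapq
  # leftmost mate: TLEN > 0; outer span = [pos-1, pos-1+TLEN) in 0-based
  start0 <- res$pos[keep] - 1L
  fragments(as.character(res$rname[keep]), start0, start0 + res$isize[keep])
}

#' Write fragments as BED3
#' @param frags fragment data.frame
#' @param path output path
#' @export
write_fragments_bed <- function(frags, path) {
  data.table::fwrite(frags[, c("contig", "start", "end")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read contig lengths from a FASTA index (.fai) style TSV
#'
#' Only the first two columns (contig, length) are used.
#' @param path two-or-more column TSV
#' @return named integer vector of contig lengths
#' @export
read_contig_lengths <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  len <- as.integer(dt[[2]])
  if (any(is.na(len) | len <= 0)) stop("invalid contig length in ", path)
  stats::setNames(len, as.character(dt[[1]]))
}

#' Tile a genome into fixed-size processing windows
#'
#' Each contig is partitioned into disjoint `tile`-bp cores (the last
#' core on a contig may be shorter). Each tile additionally carries `pad`
#' bp of context on both sides so that the WPS window, the running-median
#' baseline and the 2000 bp feature windows never touch a core edge.
#' Calls are later deduplicated on cores by [merge_tile_calls()].
#'
#' @param contig_lengths named integer vector (or .fai-style path)
#' @param tile core size in bp (default 20000)
#' @param pad context on each side in bp (default 2000)
#' @return data.frame with columns contig, start, end, pad (one row per tile)
#' @export
tile_genome <- function(contig_lengths, tile = 20000L, pad = 2000L) {
  if (is.character(contig_lengths) && length(contig_lengths) == 1) {
    contig_lengths <- read_contig_lengths(contig_lengths)
  }
  stopifnot(all(contig_lengths > 0))
  if (tile <= 2 * pad) stop("tile size must exceed 2*pad")
  out <- lapply(names(contig_lengths), function(ctg) {
    L <- contig_lengths[[ctg]]
    starts <- seq.int(0L, L - 1L, by = tile)
    data.frame(contig = ctg, start = as.integer(starts),
               end = as.integer(pmin(starts + tile, L)),
               pad = as.integer(pad), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# single-row tile helper used throughout tests and internals
genome_tile <- function(contig, start, end, pad = 2000L) {
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end), pad = as.integer(pad),
             stringsAsFactors = FALSE)
}
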