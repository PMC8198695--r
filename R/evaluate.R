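#' Overlap percentage of calls against a reference interval set
#'
#' A reference interval counts as detected iff it shares at least one
#' base with any call. Strand is ignored.
#'
#' @param calls data.frame with contig/start/end (0-based half-open) or
#'   GRanges
#' @param reference same formats
#' @return list: `n_reference`, `n_overlapped`, `percentage` (0-100),
#'   `hit` (logical per reference interval)
#' @export
overlap_percentage <- function(calls, reference) {
  cg <- as_granges(calls)
  rg <- as_granges(reference)
  miss <- setdiff(as.character(unique(GenomicRanges::seqnames(rg))),
                  as.character(unique(GenomicRanges::seqnames(cg))))
  if (length(miss) > 0 && length(cg) > 0) {
    warning("reference contigs absent from calls: ",
            paste(miss, collapse = ", "))
  }
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(rg, cg, minoverlap = 1L) > 0)
  list(n_reference = length(rg), n_overlapped = sum(hit),
       percentage = if (length(rg) == 0) NA_real_ else
         100 * sum(hit) / length(rg),
       hit = hit)
}

#' Signed distances from call centers to the nearest TSS
#'
#' @param calls call data.frame (contig/start/end)
#' @param tss data.frame with `contig` and `position` (point TSS), or
#'   contig/start/end intervals (their midpoints are used)
#' @return data.frame with per-call `distance` (call center - nearest
#'   TSS, bp; NA when the contig has no TSS) plus the call coordinates
#' @export
tss_distance_distribution <- function(calls, tss) {
  if (!"position" %in% names(tss)) {
    tss <- data.frame(contig = tss$contig,
                      position = (tss$start + tss$end) %/% 2L)
  }
  centers <- (calls$start + calls$end) %/% 2L
  dist <- rep(NA_real_, nrow(calls))
  for (ctg in unique(calls$contig)) {
    tp <- sort(tss$position[tss$contig == ctg])
    if (length(tp) == 0) next
    ci <- which(calls$contig == ctg)
    for (i in ci) {
      dist[i] <- centers[i] - tp[which.min(abs(tp - centers[i]))]
    }
  }
  data.frame(contig = calls$contig, center = centers, distance = dist)
}

#' Precision and recall against a simulated truth set
#'
#' A truth interval is recalled iff it intersects a call after extension
#' by `slack` bp on each side; a call is precise iff it intersects some
#' extended truth interval.
#'
#' @param calls call data.frame or GRanges
#' @param truth truth data.frame or GRanges
#' @param slack bp of positional tolerance (default 300)
#' @return list with `precision` (NA when there are no calls), `recall`,
#'   `n_calls`, `n_truth`
#' @export
pr_against_truth <- function(calls, truth, slack = 300L) {
  tg <- as_granges(truth)
  tg <- GenomicRanges::resize(tg, GenomicRanges::width(tg) + 2L * slack,
                              fix = "center")
  cg <- as_granges(calls)
  n_truth <- length(tg)
  n_calls <- length(cg)
  recall <- if (n_truth == 0) NA_real_ else
    sum(suppressWarnings(GenomicRanges::countOverlaps(tg, cg)) > 0) / n_truth
  precision <- if (n_calls == 0) NA_real_ else
    sum(suppressWarnings(GenomicRanges::countOverlaps(cg, tg)) > 0) / n_calls
  list(precision = precision, recall = recall,
       n_calls = n_calls, n_truth = n_truth)
}

#' Expand point TSS to evaluation windows
#'
#' Gene-detection overlap is conventionally evaluated on the ~2000 bp
#' promoter-bearing region around each TSS rather than the single base.
#'
#' @param tss data.frame with contig/position
#' @param half half-window (default 1000)
#' @return interval data.frame (contig/start/end)
#' @export
expand_tss <- function(tss, half = 1000L) {
  data.frame(contig = tss$contig,
             start = pmax(0L, as.integer(tss$position - half)),
             end = as.integer(tss$position + half))
}

#' Write an overlap report as TSV and JSON
#' @param report list from [overlap_percentage()]
#' @param tsv,json output paths (either may be NULL)
#' @export
write_overlap_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    data.table::fwrite(data.frame(index = seq_along(report$hit),
                                  hit = as.integer(report$hit)),
                       tsv, sep = "\t")
  }
  if (!is.null(json)) {
    jsonlite::write_json(report[c("n_reference", "n_overlapped",
                                  "percentage")],
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
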