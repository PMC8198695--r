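#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default.
#' Defaults follow the published operating point: 20 kb tiles, 120 bp
#' WPS window, order-2 / window-31 Savitzky-Golay smoothing, peak
#' height 0.28 / distance 25 / width 115-164 on the unit-normalized
#' waveform, >250 bp peak gaps with mean normalized coverage < 0.6, and
#' 600 bp output calls.
#'
#' @param tile,pad genome tiling (bp)
#' @param wps_window WPS protection window (bp)
#' @param baseline_window running-median detrend window (bp, odd)
#' @param sg_order,sg_window Savitzky-Golay parameters
#' @param peaks a [peak_params()] object, or the string `"calibrate"`
#'   (the default) to calibrate the peak thresholds from the data at run
#'   time by the mu +/- 3*sigma rule — the same procedure that produced
#'   the published operating point (height 0.28, width 115-164) on real
#'   plasma data; peak geometry depends on how well nucleosomes are
#'   positioned in the sample, so the thresholds are data-dependent by
#'   construction
#' @param min_gap,max_cov weak-filter thresholds
#' @param flank,min_peaks_per_side,spacing_range flank-regularity rule
#' @param call_size final call size (bp)
#' @param classifier_threshold keep a call iff its random-forest
#'   probability is at least this (default 0.5)
#' @param length_bounds fragment length filter (bp)
#' @param seed master seed for any stochastic step (calibration sampling)
#' @return an `ocr_config` list
#' @export
ocr_config <- function(tile = 20000L, pad = 2000L, wps_window = 120L,
                       baseline_window = 1001L, sg_order = 2L,
                       sg_window = 31L, peaks = "calibrate",
                       min_gap = 250L, max_cov = 0.6, flank = 1000L,
                       min_peaks_per_side = 3L, spacing_range = c(120, 220),
                       call_size = 600L, classifier_threshold = 0.5,
                       length_bounds = c(120L, 180L), seed = 1L) {
  structure(list(tile = as.integer(tile), pad = as.integer(pad),
                 wps_window = as.integer(wps_window),
                 baseline_window = as.integer(baseline_window),
                 sg_order = as.integer(sg_order),
                 sg_window = as.integer(sg_window), peaks = peaks,
                 min_gap = as.integer(min_gap), max_cov = max_cov,
                 flank = as.integer(flank),
                 min_peaks_per_side = as.integer(min_peaks_per_side),
                 spacing_range = spacing_range,
                 call_size = as.integer(call_size),
                 classifier_threshold = classifier_threshold,
                 length_bounds = as.integer(length_bounds),
                 seed = as.integer(seed)),
            class = "ocr_config")
}

# process one padded tile: tracks -> peaks -> candidates (+features/prob)
detect_tile <- function(frags, tile, config, model = NULL) {
  wps <- compute_wps(frags, tile, config$wps_window)
  wps <- detrend_normalize(wps, config$baseline_window)
  if (isTRUE(wps$low_signal)) return(NULL)
  wps <- sg_smooth(wps, config$sg_order, config$sg_window)
  cov <- compute_coverage(frags, tile)
  pk <- find_wps_peaks(wps, config$peaks)
  cand <- call_candidates(pk, cov, config$min_gap, config$max_cov,
                          config$flank, config$min_peaks_per_side,
                          config$spacing_range, config$call_size)
  if (nrow(cand) == 0) return(NULL)
  # only calls whose center falls in the tile core; padded neighbors see
  # the same region and would duplicate it
  cand <- cand[cand$center >= tile$start & cand$center < tile$end, ,
               drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  if (!is.null(model)) {
    feats <- t(vapply(cand$center, function(ctr) {
      assemble_features(ctr, pk, wps, cov)
    }, numeric(length(feature_names()))))
    cand$prob <- rf_predict_proba(model, feats)
  }
  cand
}

#' Run the end-to-end OCR detection pipeline
#'
#' Per padded 20 kb tile: read fragments, compute the WPS and coverage
#' tracks, detrend/normalize and smooth the waveform, locate peaks,
#' call candidate gaps, extract features and score them with the
#' classifier. Tile calls are then pooled, deduplicated across tile
#' boundaries, filtered by classifier probability, and cleared of
#' repeat-region overlaps. The manifest records the count after each
#' stage; counts are monotone nonincreasing.
#'
#' @param frags fragment data.frame, or a BED/BAM path
#' @param contig_lengths named integer vector or .fai-style path
#' @param config an [ocr_config()]
#' @param model an `rf_model`, or NULL to skip classifier filtering
#' @param repeats optional repeat intervals (data.frame or GRanges); see
#'   [subtract_repeats()]
#' @param out_dir optional output directory: writes `ocrs.bed` (BED6),
#'   `manifest.json` and the serialized configuration
#' @return list with `calls` (final 600 bp intervals) and `manifest`
#' @export
detect_ocrs <- function(frags, contig_lengths, config = ocr_config(),
                        model = NULL, repeats = NULL, out_dir = NULL) {
  if (is.character(contig_lengths)) {
    contig_lengths <- read_contig_lengths(contig_lengths)
  }
  tiles <- tile_genome(contig_lengths, config$tile, config$pad)
  from_path <- is.character(frags)
  if (!from_path) frags <- validate_fragments(frags)
  per_tile <- vector("list", nrow(tiles))
  failed <- 0L
  if (identical(config$peaks, "calibrate")) {
    config$peaks <- calibrate_pipeline_params(frags, tiles, config)
  }
  for (i in seq_len(nrow(tiles))) {
    tile <- tiles[i, , drop = FALSE]
    res <- tryCatch({
      tf <- if (from_path) {
        read_fragments(frags, tile, config$length_bounds)
      } else {
        lo <- tile$start - tile$pad; hi <- tile$end + tile$pad
        frags[frags$contig == tile$contig & frags$end > lo &
              frags$start < hi &
              frags$length >= config$length_bounds[1] &
              frags$length <= config$length_bounds[2], , drop = FALSE]
      }
      detect_tile(tf, tile, config, model)
    }, error = function(e) {
      message("tile ", tile$contig, ":", tile$start, "-", tile$end,
              " failed: ", conditionMessage(e))
      failed <<- failed + 1L
      NULL
    })
    per_tile[[i]] <- res
  }
  if (failed > 0.01 * nrow(tiles)) {
    stop(failed, " of ", nrow(tiles), " tiles failed (>1%)")
  }
  per_tile <- per_tile[!vapply(per_tile, is.null, logical(1))]
  cand <- if (length(per_tile) > 0) do.call(rbind, per_tile) else
    call_candidates(NULL, NULL)
  cand <- merge_tile_calls(cand, min_overlap = 300L, config$call_size)
  # keep calls inside their contig
  if (nrow(cand) > 0) {
    clen <- contig_lengths[cand$contig]
    cand <- cand[cand$start >= 0 & cand$end <= clen, , drop = FALSE]
  }
  n_initial <- nrow(cand)
  if (!is.null(model) && nrow(cand) > 0) {
    cand <- cand[cand$prob >= config$classifier_threshold, , drop = FALSE]
  }
  n_classified <- nrow(cand)
  if (!is.null(repeats)) cand <- subtract_repeats(cand, repeats)
  n_final <- nrow(cand)
  rownames(cand) <- NULL
  manifest <- list(n_tiles = nrow(tiles), n_tiles_failed = failed,
                   n_initial = n_initial, n_post_classifier = n_classified,
                   n_post_repeat = n_final,
                   classifier_used = !is.null(model),
                   repeats_used = !is.null(repeats),
                   seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls_bed(cand, file.path(out_dir, "ocrs.bed"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg <- config
    cfg$peaks <- unclass(cfg$peaks)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(calls = cand, manifest = manifest)
}

# run-time calibration: smooth a sample of tiles, then mu +/- 3 sigma
calibrate_pipeline_params <- function(frags, tiles, config,
                                      n_regions = 2000L) {
  set.seed(config$seed)
  take <- sample(seq_len(nrow(tiles)), min(nrow(tiles), 50L))
  tracks <- list()
  for (i in take) {
    tile <- tiles[i, , drop = FALSE]
    tf <- if (is.character(frags)) {
      read_fragments(frags, tile, config$length_bounds)
    } else {
      frags[frags$contig == tile$contig &
            frags$end > tile$start - tile$pad &
            frags$start < tile$end + tile$pad, , drop = FALSE]
    }
    tr <- detrend_normalize(compute_wps(tf, tile, config$wps_window),
                            config$baseline_window)
    if (!isTRUE(tr$low_signal)) {
      tracks[[length(tracks) + 1L]] <-
        sg_smooth(tr, config$sg_order, config$sg_window)
    }
  }
  if (length(tracks) == 0) stop("no signal-bearing tiles to calibrate on")
  calibrate_params(tracks, n_regions = n_regions, seed = config$seed)
}
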