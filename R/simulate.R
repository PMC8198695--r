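#' Synthetic cfDNA simulation configuration
#'
#' The simulator emulates the cfDNA signal model: outside open regions
#' the genome is covered by well-positioned nucleosome arrays (167 bp
#' cores separated by short linkers) and sequenced fragments are
#' mononucleosome-sized molecules centered on the protected cores;
#' inside a planted OCR nucleosomes are absent, fragment density drops
#' to `ocr_protection_factor` of normal, and the fragments that remain
#' have uniformly random endpoints (they contribute endpoint signal, not
#' spanning protection). A small global rate of uniformly placed
#' fragments models background endpoint noise.
#'
#' @param genome_length simulated contig length in bp
#' @param contig contig name (default "sim")
#' @param nucleosome_core protected core size in bp (default 167)
#' @param linker_mean mean linker length in bp (default 20, giving a
#'   ~187 bp repeat inside the 120-220 bp regularity band)
#' @param linker_jitter uniform jitter on each linker in bp (default 5)
#' @param ocr_intervals data.frame with `start`, `end` of planted OCRs
#'   (0-based half-open, disjoint, typically 300-600 bp wide)
#' @param depth target mean fold-coverage
#' @param frag_len_mean,frag_len_sd fragment length distribution
#'   (normal, clipped to 120-180 bp)
#' @param dyad_jitter positional sd of fragment centers around the dyad
#'   (default 5 bp)
#' @param ocr_protection_factor fragment density inside OCRs relative to
#'   array regions (default 0.2)
#' @param endpoint_noise_rate uniformly placed background fragments as a
#'   fraction of the signal fragments (default 0.02)
#' @param seed RNG seed; same seed, same fragments
#' @return a `sim_config` list
#' @export
sim_config <- function(genome_length = 2e6, contig = "sim",
                       nucleosome_core = 167L, linker_mean = 20L,
                       linker_jitter = 5L,
                       ocr_intervals = NULL, depth = 30,
                       frag_len_mean = 167, frag_len_sd = 10,
                       dyad_jitter = 5,
                       ocr_protection_factor = 0.2,
                       endpoint_noise_rate = 0.02, seed = 1L) {
  if (is.null(ocr_intervals)) {
    ocr_intervals <- data.frame(start = integer(), end = integer())
  }
  if (nrow(ocr_intervals) > 1) {
    o <- order(ocr_intervals$start)
    ocr_intervals <- ocr_intervals[o, , drop = FALSE]
    if (any(utils::head(ocr_intervals$end, -1) >
            utils::tail(ocr_intervals$start, -1))) {
      stop("ocr_intervals must be disjoint")
    }
  }
  if (nrow(ocr_intervals) > 0 &&
      (min(ocr_intervals$start) < 0 ||
       max(ocr_intervals$end) > genome_length)) {
    stop("ocr_intervals outside the genome")
  }
  stopifnot(depth >= 0, ocr_protection_factor >= 0,
            ocr_protection_factor <= 1)
  structure(list(genome_length = as.integer(genome_length), contig = contig,
                 nucleosome_core = as.integer(nucleosome_core),
                 linker_mean = as.integer(linker_mean),
                 linker_jitter = as.integer(linker_jitter),
                 ocr_intervals = ocr_intervals, depth = depth,
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 dyad_jitter = dyad_jitter,
                 ocr_protection_factor = ocr_protection_factor,
                 endpoint_noise_rate = endpoint_noise_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Place positioned nucleosome dyads along the simulated genome
#'
#' Arrays of cores spaced core + linker apart (linker jittered
#' uniformly) tile the genome; planted OCRs contain no dyads — an array
#' restarts just past each OCR end.
#'
#' @param config a [sim_config()]
#' @return integer vector of dyad positions
#' @export
place_nucleosomes <- function(config) {
  set.seed(config$seed)
  core <- config$nucleosome_core
  ocrs <- config$ocr_intervals
  dyads <- integer()
  pos <- 0L
  while (pos + core <= config$genome_length) {
    hit <- if (nrow(ocrs) > 0) {
      which(ocrs$start < pos + core & ocrs$end > pos)
    } else integer()
    if (length(hit) > 0) {
      pos <- as.integer(max(ocrs$end[hit]))
      next
    }
    dyads <- c(dyads, pos + core %/% 2L)
    linker <- config$linker_mean +
      sample.int(2L * config$linker_jitter + 1L, 1L) -
      config$linker_jitter - 1L
    pos <- pos + core + max(1L, linker)
  }
  dyads
}

rnorm_len <- function(n, config) {
  as.integer(pmin(180, pmax(120, round(stats::rnorm(n, config$frag_len_mean,
                                                    config$frag_len_sd)))))
}

#' Sample cfDNA fragments from the nucleosome landscape
#'
#' Per dyad the fragment count is Poisson with mean chosen so the
#' realized mean coverage matches `depth`; fragments are centered on the
#' dyad with normal positional jitter. Planted OCRs receive unprotected
#' fragments at `ocr_protection_factor` of normal density with uniform
#' random positions, and uniformly placed background fragments are added
#' genome-wide at `endpoint_noise_rate`.
#'
#' @param config a [sim_config()]
#' @param dyads dyad positions from [place_nucleosomes()]
#' @return list with `fragments` (sorted fragment data.frame) and
#'   `truth` (a `sim_truth` list: ocr_intervals, dyads, realized_depth,
#'   config)
#' @export
sample_fragments <- function(config, dyads = place_nucleosomes(config)) {
  set.seed(config$seed + 1L)
  G <- config$genome_length
  frags <- list()
  if (config$depth > 0 && length(dyads) > 0) {
    spacing <- G / length(dyads)
    lambda <- config$depth * spacing / config$frag_len_mean
    counts <- stats::rpois(length(dyads), lambda)
    centers <- rep(dyads, counts) +
      round(stats::rnorm(sum(counts), 0, config$dyad_jitter))
    lens <- rnorm_len(sum(counts), config)
    starts <- as.integer(centers - lens %/% 2L)
    frags$protected <- data.frame(start = starts, end = starts + lens)
  }
  ocrs <- config$ocr_intervals
  if (config$depth > 0 && nrow(ocrs) > 0 && config$ocr_protection_factor > 0) {
    w <- ocrs$end - ocrs$start
    n_ocr <- stats::rpois(nrow(ocrs),
                          config$ocr_protection_factor * config$depth * w /
                            config$frag_len_mean)
    centers <- unlist(lapply(seq_len(nrow(ocrs)), function(k) {
      if (n_ocr[k] == 0) return(integer())
      ocrs$start[k] + sample.int(w[k], n_ocr[k], replace = TRUE) - 1L
    }))
    if (length(centers) > 0) {
      lens <- rnorm_len(length(centers), config)
      starts <- as.integer(centers - lens %/% 2L)
      frags$ocr <- data.frame(start = starts, end = starts + lens)
    }
  }
  n_signal <- sum(vapply(frags, nrow, integer(1)))
  n_noise <- stats::rpois(1, config$endpoint_noise_rate * n_signal)
  if (n_noise > 0) {
    centers <- sample.int(G, n_noise, replace = TRUE) - 1L
    lens <- rnorm_len(n_noise, config)
    starts <- as.integer(centers - lens %/% 2L)
    frags$noise <- data.frame(start = starts, end = starts + lens)
  }
  df <- do.call(rbind, frags)
  if (is.null(df)) df <- data.frame(start = integer(), end = integer())
  keep <- df$start >= 0 & df$end <= G
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  out <- fragments(rep(config$contig, nrow(df)), df$start, df$end)
  realized <- if (G > 0) sum(as.numeric(out$length)) / G else 0
  truth <- structure(list(ocr_intervals = ocrs, dyads = dyads,
                          realized_depth = realized, config = config),
                     class = "sim_truth")
  list(fragments = out, truth = truth)
}

#' Bernoulli-thin a fragment set to emulate lower sequencing depth
#'
#' @param frags fragment data.frame
#' @param fraction keep probability in `[0, 1]`
#' @param seed RNG seed
#' @return thinned fragment data.frame
#' @export
downsample_fragments <- function(frags, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 1) return(frags)
  set.seed(seed)
  keep <- stats::runif(nrow(frags)) < fraction
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write simulation ground truth to plain-text files
#'
#' @param truth a `sim_truth`
#' @param ocr_bed path for the planted OCR BED3
#' @param config_json optional path for the configuration JSON
#' @export
write_truth <- function(truth, ocr_bed, config_json = NULL) {
  ocrs <- truth$ocr_intervals[order(truth$ocr_intervals$start), ,
                              drop = FALSE]
  df <- data.frame(truth$config$contig, ocrs$start, ocrs$end)
  data.table::fwrite(df, ocr_bed, sep = "\t", col.names = FALSE)
  if (!is.null(config_json)) {
    cfg <- truth$config
    cfg$ocr_intervals <- as.data.frame(cfg$ocr_intervals)
    jsonlite::write_json(unclass(cfg), config_json, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(ocr_bed)
}

#' Plant non-overlapping OCRs at random positions
#'
#' @param n number of OCRs
#' @param genome_length contig length
#' @param width_range OCR width range in bp (default 400-600)
#' @param min_gap minimum distance between planted OCRs and from the
#'   genome ends (default 5000, several feature windows, so planted
#'   regions do not interact)
#' @param seed RNG seed
#' @return data.frame with start/end
#' @export
plant_ocrs <- function(n, genome_length, width_range = c(400L, 600L),
                       min_gap = 5000L, seed = 1L) {
  set.seed(seed)
  slots <- floor((genome_length - 2 * min_gap) / (width_range[2] + min_gap))
  if (n > slots) stop("genome too small for ", n, " OCRs with min_gap ",
                      min_gap)
  anchor <- sort(sample.int(slots, n)) - 1L
  width <- sample.int(width_range[2] - width_range[1] + 1L, n,
                      replace = TRUE) + width_range[1] - 1L
  start <- min_gap + anchor * (width_range[2] + min_gap)
  data.frame(start = as.integer(start), end = as.integer(start + width))
}

#' Simulate labeled feature windows for classifier training
#'
#' Positives are 2000 bp windows centered on planted OCRs embedded in
#' regular nucleosome arrays — the synthetic analog of housekeeping-gene
#' TSS regions, which are reliably open. Negatives are windows with
#' abnormal waveform distortion but no true open region: nucleosome
#' positioning is strongly irregular (heavy dyad jitter), a shallow
#' random coverage dip is thinned into the center (mimicking mapping
#' artifacts), and extra background fragments are added. Each window is
#' processed by the standard track/peak/feature stack.
#'
#' @param n_pos,n_neg samples per class
#' @param depth simulated coverage
#' @param seed RNG seed
#' @return list with `features` (matrix, [feature_names()] columns),
#'   `labels` (1 = open region), `centers`
#' @export
simulate_labeled_windows <- function(n_pos = 400L, n_neg = 400L, depth = 30,
                                     seed = 1L) {
  slot <- 6000L
  make_side <- function(n, positive, side_seed) {
    G <- n * slot + 2L * slot
    centers <- slot + slot * (seq_len(n) - 1L) + slot %/% 2L
    set.seed(side_seed)
    widths <- sample(400:600, n, replace = TRUE)
    ocrs <- if (positive) {
      data.frame(start = as.integer(centers - widths %/% 2L),
                 end = as.integer(centers + widths - widths %/% 2L))
    } else data.frame(start = integer(), end = integer())
    cfg <- sim_config(genome_length = G, ocr_intervals = ocrs, depth = depth,
                      dyad_jitter = if (positive) 5 else 40,
                      endpoint_noise_rate = if (positive) 0.02 else 0.1,
                      seed = side_seed)
    sim <- sample_fragments(cfg)
    fr <- sim$fragments
    if (!positive) {
      # thin a shallow dip into each window center: distortion, not an OCR
      set.seed(side_seed + 2L)
      dip <- stats::runif(n, 0.5, 0.85)
      mid <- (fr$start + fr$end) / 2
      bin <- findInterval(mid, centers - 300L)
      inside <- bin >= 1 & bin <= n & mid < centers[pmin(pmax(bin, 1), n)] + 300L
      u <- stats::runif(nrow(fr))
      keep <- !inside | u < dip[pmin(pmax(bin, 1), n)]
      fr <- fr[keep, , drop = FALSE]
    }
    list(fragments = fr, centers = centers, G = G)
  }
  pos <- make_side(n_pos, TRUE, seed)
  neg <- make_side(n_neg, FALSE, seed + 1000L)
  feat_rows <- function(side) {
    t(vapply(side$centers, function(ctr) {
      tile <- genome_tile("sim", ctr - slot %/% 2L, ctr + slot %/% 2L,
                          pad = 2000L)
      tile$start <- max(0L, tile$start)
      fr <- side$fragments
      fr <- fr[fr$end > tile$start - tile$pad &
               fr$start < tile$end + tile$pad, , drop = FALSE]
      wps <- compute_wps(fr, tile)
      wps <- sg_smooth(detrend_normalize(wps))
      cov <- compute_coverage(fr, tile)
      pk <- find_wps_peaks(wps)
      assemble_features(ctr, pk, wps, cov)
    }, numeric(length(feature_names()))))
  }
  fpos <- feat_rows(pos)
  fneg <- feat_rows(neg)
  list(features = rbind(fpos, fneg),
       labels = c(rep(1L, nrow(fpos)), rep(0L, nrow(fneg))),
       centers = c(pos$centers, neg$centers))
}
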