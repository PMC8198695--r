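#' Feature window around a region center
#'
#' Promoters and most regulatory elements live within ~1000 bp of their
#' anchor point, so features are computed on a 2000 bp window centered
#' on the region (TSS or candidate center).
#'
#' @param center genomic coordinate
#' @param half half-window in bp (default 1000)
#' @param contig_length optional; the window is clamped to
#'   `[0, contig_length)` and flagged when clamping occurred
#' @return integer length-2 `(start, end)` with attribute `clamped`
#' @export
window_2000 <- function(center, half = 1000L, contig_length = NULL) {
  lo <- center - half
  hi <- center + half
  clamped <- FALSE
  if (lo < 0) { lo <- 0L; clamped <- TRUE }
  if (!is.null(contig_length) && hi > contig_length) {
    hi <- as.integer(contig_length); clamped <- TRUE
  }
  structure(c(as.integer(lo), as.integer(hi)), clamped = clamped)
}

# x axis scaling used for angle features: bp are divided by this before
# any trigonometry, so 10 bp of genomic distance weighs like 1 unit of
# normalized WPS. Angles are meaningless without a declared aspect ratio.
ANGLE_BP_UNIT <- 10

#' Geometry of one peak between its flanking troughs
#'
#' In (bp, normalized WPS) coordinates: `width` is the trough-to-trough
#' distance; `height` the apex WPS minus the mean trough WPS; `area` the
#' trapezoidal integral of the waveform above the chord joining the two
#' troughs; `angle` the apex angle (degrees) between the vectors
#' apex->left trough and apex->right trough after scaling the x axis by
#' 10 bp per unit.
#'
#' @param apex apex coordinate
#' @param left_trough,right_trough flanking trough coordinates
#' @param track a `wps_track` with `smoothed` filled
#' @return named numeric `(area, angle, height, width)` or NULL when a
#'   flanking trough is missing
#' @export
peak_geometry <- function(apex, left_trough, right_trough, track) {
  if (is.na(left_trough) || is.na(right_trough)) return(NULL)
  x <- track$smoothed
  il <- track_index(track, left_trough)
  ir <- track_index(track, right_trough)
  ia <- track_index(track, apex)
  seg <- x[il:ir]
  chord <- seq(x[il], x[ir], length.out = length(seg))
  area <- sum(diff(seq_along(seg)) * (utils::head(seg - chord, -1) +
                                      utils::tail(seg - chord, -1)) / 2)
  height <- x[ia] - mean(c(x[il], x[ir]))
  width <- right_trough - left_trough
  v1 <- c((left_trough - apex) / ANGLE_BP_UNIT, x[il] - x[ia])
  v2 <- c((right_trough - apex) / ANGLE_BP_UNIT, x[ir] - x[ia])
  angle <- vector_angle_deg(v1, v2)
  c(area = area, angle = angle, height = height, width = width)
}

vector_angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  ct <- sum(v1 * v2) / (n1 * n2)
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Linear coverage trends over the feature window
#'
#' Ordinary least-squares lines of normalized coverage against
#' window-relative position (bp, 0 at the window start) over the three
#' sub-intervals [0, 2000), [0, 1200) and [800, 2000). A real open
#' region shows a slow decline into the center and recovery after it;
#' the three slope/intercept pairs capture the full, left and right
#' trends, which separate OCR-shaped dips from step-like coverage drops.
#'
#' @param covw numeric vector of normalized coverage, one value per base
#'   of the window (length 2000 for an unclamped window)
#' @return named numeric: slope_full, intercept_full, slope_left,
#'   intercept_left, slope_right, intercept_right
#' @export
coverage_trends <- function(covw) {
  n <- length(covw)
  pos <- seq_len(n) - 1
  ols <- function(idx) {
    f <- stats::lm.fit(cbind(1, pos[idx]), covw[idx])$coefficients
    c(slope = unname(f[2]), intercept = unname(f[1]))
  }
  full <- ols(seq_len(n))
  left <- ols(which(pos < 1200))
  right <- ols(which(pos >= 800))
  out <- c(full["slope"], full["intercept"], left["slope"],
           left["intercept"], right["slope"], right["intercept"])
  stats::setNames(out, c("slope_full", "intercept_full", "slope_left",
                         "intercept_left", "slope_right", "intercept_right"))
}

#' Names and order of the feature columns
#' @return character vector, the stable column schema
#' @export
feature_names <- function() {
  c("peak_area_mean", "peak_area_var", "peak_angle_mean", "peak_angle_var",
    "peak_spacing_mean", "peak_spacing_var", "peak_height_mean",
    "peak_height_var", "peak_width_mean", "peak_width_var",
    "narrow_interval_coverage", "broad_interval_coverage",
    "slope_full", "intercept_full", "slope_left", "intercept_left",
    "slope_right", "intercept_right", "bisector_dx", "bisector_dy",
    "geometry_missing")
}

# population variance: a single observation has zero spread by definition
pvar <- function(v) if (length(v) == 0) 0 else mean((v - mean(v))^2)

#' Assemble the full feature vector for one region
#'
#' Waveform-geometry statistics (mean and variance of peak area, apex
#' angle, spacing, height, width over all peaks complete within the
#' window), coverage levels (mean normalized coverage of the central
#' 600 bp and of the full window), the three coverage-trend regressions,
#' and the unit bisector of the central gap: with vertex at the window
#' center (at its smoothed WPS value) and arms to the nearest peak apex
#' on each side, the bisector direction encodes the asymmetry of the
#' central dip. `geometry_missing` is 1 when no complete peak lies in
#' the window (all geometry features are then 0).
#'
#' @param center window center (genomic coordinate)
#' @param peaks peak table from [find_wps_peaks()]
#' @param wps a `wps_track` with `smoothed` filled
#' @param coverage a `coverage_track` with `depth` filled
#' @param half half-window (default 1000)
#' @return named numeric vector following [feature_names()]
#' @export
assemble_features <- function(center, peaks, wps, coverage, half = 1000L) {
  win <- c(center - half, center + half)
  win[1] <- max(win[1], wps$start)
  win[2] <- min(win[2], wps$end)
  inwin <- peaks[!is.na(peaks$left_trough) & !is.na(peaks$right_trough) &
                 peaks$left_trough >= win[1] & peaks$right_trough < win[2], ,
                 drop = FALSE]
  geom <- lapply(seq_len(nrow(inwin)), function(k) {
    peak_geometry(inwin$apex[k], inwin$left_trough[k], inwin$right_trough[k],
                  wps)
  })
  geom <- do.call(rbind, geom)
  spacing <- if (nrow(inwin) >= 2) diff(sort(inwin$apex)) else numeric()
  gmiss <- is.null(geom)
  gstat <- function(col) {
    if (gmiss) c(0, 0) else c(mean(geom[, col]), pvar(geom[, col]))
  }
  area <- gstat("area"); angle <- gstat("angle")
  height <- gstat("height"); width <- gstat("width")
  sp <- if (length(spacing) == 0) c(0, 0) else c(mean(spacing), pvar(spacing))

  m <- local_mean_depth(coverage, center, 2L * half)
  covw <- coverage$depth[track_index(coverage, win[1]):
                         track_index(coverage, win[2] - 1L)]
  covw <- if (m == 0) rep(0, length(covw)) else covw / m
  pos_w <- seq.int(win[1], win[2] - 1L)
  narrow_idx <- which(pos_w >= center - 300L & pos_w < center + 300L)
  narrow <- mean(covw[narrow_idx])
  broad <- mean(covw)
  tr <- coverage_trends(covw)

  bis <- central_gap_bisector(center, peaks, wps)

  out <- c(area[1], area[2], angle[1], angle[2], sp[1], sp[2],
           height[1], height[2], width[1], width[2],
           narrow, broad, tr, bis, as.numeric(gmiss))
  stats::setNames(out, feature_names())
}

central_gap_bisector <- function(center, peaks, wps) {
  left <- peaks$apex[peaks$apex < center]
  right <- peaks$apex[peaks$apex >= center]
  if (length(left) == 0 || length(right) == 0) return(c(0, 0))
  la <- max(left); ra <- min(right)
  x <- wps$smoothed
  vy <- x[track_index(wps, center)]
  v1 <- c((la - center) / ANGLE_BP_UNIT, x[track_index(wps, la)] - vy)
  v2 <- c((ra - center) / ANGLE_BP_UNIT, x[track_index(wps, ra)] - vy)
  unit <- function(v) { n <- sqrt(sum(v^2)); if (n == 0) c(0, 0) else v / n }
  b <- unit(unit(v1) + unit(v2))
  c(bisector_dx = b[1], bisector_dy = b[2])
}

#' Write a feature matrix as TSV with the stable column order
#' @param feats matrix or data.frame whose columns follow [feature_names()]
#' @param path output file
#' @export
write_features_tsv <- function(feats, path) {
  df <- as.data.frame(feats)[, feature_names(), drop = FALSE]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
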