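## Outcome measures: on-target ROI mean, whole-brain 99th-percentile mean,
## focality volume and peak-location offset.

#' Define a spherical region of interest
#'
#' @param center_mm ROI center (mm); must carry a tissue label in
#'   `tissue_mask`.
#' @param radius_mm Radius (default 10 mm).
#' @param tissue_mask Integer tissue labels included (default grey matter).
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(center_mm, radius_mm = 10, tissue_mask = 4L) {
  if (radius_mm <= 0) stop("invalid-spec: ROI radius must be > 0")
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 tissue_mask = as.integer(tissue_mask)), class = "roi_spec")
}

#' Place the motor ROI under an EEG position
#'
#' Casts a ray from the scalp point toward the head centroid and centers a
#' spherical grey-matter ROI on the first grey-matter voxel hit, emulating
#' "first grey-matter voxel directly underneath the electrode position". The
#' ROI is a deterministic function of phantom + EEG map, so it is identical
#' across montages within a subject.
#'
#' @param phantom A `head_phantom`.
#' @param eeg An `eeg_map`.
#' @param label EEG label (default `"C3"`).
#' @param radius_mm ROI radius (default 10).
#' @return A [roi_spec()].
#' @export
locate_roi <- function(phantom, eeg, label = "C3", radius_mm = 10) {
  if (!label %in% rownames(eeg)) stop("lookup error: EEG label ", label, " missing")
  if (radius_mm <= 0) stop("invalid-spec: ROI radius must be > 0")
  p0 <- eeg[label, ]
  ctr <- phantom$center_mm
  dir <- ctr - p0
  len <- sqrt(sum(dir^2))
  dir <- dir / len
  h <- phantom$voxel_size_mm
  steps <- seq(0, len, by = h / 4)
  pts <- rep(p0, each = length(steps)) + outer(steps, dir)
  lab <- label_at(phantom, pts)
  hit <- which(lab == 4L)[1]
  if (is.na(hit)) stop("anatomy error: ray reached the centroid without hitting grey matter")
  vox <- voxel_of(phantom, pts[hit, ])
  roi_spec(voxel_centers(phantom, vox), radius_mm)
}

## Tissue label at arbitrary points (0 outside grid).
label_at <- function(phantom, pts) {
  n <- dim(phantom$label)
  ij <- sweep(pts, 2, phantom$origin_mm) / phantom$voxel_size_mm
  ij <- floor(ij)
  ok <- ij[, 1] >= 0 & ij[, 1] < n[1] & ij[, 2] >= 0 & ij[, 2] < n[2] &
    ij[, 3] >= 0 & ij[, 3] < n[3]
  out <- integer(nrow(pts))
  lin <- 1 + ij[ok, 1] + ij[ok, 2] * n[1] + ij[ok, 3] * n[1] * n[2]
  out[ok] <- phantom$label[lin]
  out
}

## Linear voxel index containing a point.
voxel_of <- function(phantom, p) {
  n <- dim(phantom$label)
  ij <- floor((p - phantom$origin_mm) / phantom$voxel_size_mm)
  as.integer(1 + ij[1] + ij[2] * n[1] + ij[3] * n[1] * n[2])
}

## Linear indices of voxels whose label is in `labels`.
mask_voxels <- function(phantom, labels) which(phantom$label %in% labels)

#' Mean E-field magnitude in a region of interest
#'
#' Volume-weighted mean of |E| over the masked-tissue voxels whose centers
#' fall within the ROI radius.
#'
#' @param sol A `field_solution`.
#' @param roi A [roi_spec()].
#' @return V/m.
#' @export
roi_mean <- function(sol, roi) {
  ph <- sol$phantom
  vox <- mask_voxels(ph, roi$tissue_mask)
  ctrs <- voxel_centers(ph, vox)
  d2 <- rowSums((ctrs - rep(roi$center_mm, each = nrow(ctrs)))^2)
  sel <- vox[d2 <= roi$radius_mm^2]
  if (!length(sel)) stop("empty-mask error: no masked voxels inside the ROI")
  mean(sol$e_mag[sel])
}

## Volume-weighted quantile with linear interpolation between order
## statistics (ties included by the >= comparison downstream). With equal
## weights this matches the continuous sample quantile.
weighted_quantile <- function(x, p, w = NULL) {
  if (!length(x)) stop("empty-mask error")
  o <- order(x)
  x <- x[o]
  if (is.null(w)) w <- rep(1, length(x)) else w <- w[o]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = p, rule = 2, ties = "ordered")$y
}

#' Whole-brain 99th-percentile mean E-field
#'
#' Mean |E| over the top `top_frac` of the masked tissue by volume, with the
#' boundary element weighted fractionally.
#'
#' @param sol A `field_solution`.
#' @param mask Tissue labels (default grey + white matter).
#' @param top_frac Fraction of masked volume (default 0.01).
#' @return V/m.
#' @export
p99_mean <- function(sol, mask = c(4L, 5L), top_frac = 0.01) {
  vals <- sol$e_mag[mask_voxels(sol$phantom, mask)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("empty-mask error: mask selects no voxels")
  vals <- sort(vals, decreasing = TRUE)
  k <- top_frac * length(vals)
  kf <- floor(k)
  total <- if (kf >= 1) sum(vals[seq_len(kf)]) else 0
  frac <- k - kf
  if (frac > 0 && kf < length(vals)) total <- total + frac * vals[kf + 1]
  total / k
}

#' Focality volume
#'
#' Volume (mm^3) of masked tissue with |E| at or above `level_fraction` of
#' the robust peak (the `peak_percentile` volume-weighted percentile of |E|).
#' Smaller volume means more focal stimulation.
#'
#' @param sol A `field_solution`.
#' @param mask Tissue labels (default grey + white matter).
#' @param level_fraction Threshold as a fraction of the robust peak
#'   (default 0.5).
#' @param peak_percentile Percentile defining the robust peak (default 99.9;
#'   100 uses the maximum).
#' @return Volume in mm^3.
#' @export
focality_volume <- function(sol, mask = c(4L, 5L), level_fraction = 0.5,
                            peak_percentile = 99.9) {
  if (level_fraction <= 0 || level_fraction > 1) {
    stop("invalid-spec: level_fraction must be in (0, 1]")
  }
  vals <- sol$e_mag[mask_voxels(sol$phantom, mask)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("empty-mask error: mask selects no voxels")
  peak <- if (peak_percentile >= 100) max(vals) else
    weighted_quantile(vals, peak_percentile / 100)
  thr <- level_fraction * peak
  sum(vals >= thr) * sol$phantom$voxel_size_mm^3
}

#' Offset of the field peak from the montage midpoint
#'
#' Distance (mm) from the volume-weighted centroid of the voxels above the
#' robust-peak percentile to the scalp midpoint between the two electrode
#' centers projected onto the grey-matter surface. For multi-cathode (4x1)
#' montages the offset is measured to the central electrode's grey-matter
#' projection instead and the result carries attribute `reference =
#' "central_electrode"`.
#'
#' @param sol A `field_solution`.
#' @param m The `montage` that produced it.
#' @param mask Tissue labels (default grey + white matter).
#' @param peak_percentile Percentile defining the peak region (default 99.9).
#' @return Distance in mm.
#' @export
peak_offset <- function(sol, m, mask = c(4L, 5L), peak_percentile = 99.9) {
  ph <- sol$phantom
  vox <- mask_voxels(ph, mask)
  vals <- sol$e_mag[vox]
  ok <- !is.na(vals)
  vox <- vox[ok]; vals <- vals[ok]
  if (!length(vals)) stop("empty-mask error: mask selects no voxels")
  thr <- weighted_quantile(vals, peak_percentile / 100)
  sel <- vox[vals >= thr]
  centroid <- colMeans(voxel_centers(ph, sel))
  els <- m$electrodes
  reference <- "midpoint"
  if (length(els) == 2) {
    midpt <- arc_point_frac(ph, els[[1]]$center, els[[2]]$center, 0.5)
  } else {
    pol <- vapply(els, function(e) e$polarity, character(1))
    an <- which(pol == "anode")
    if (length(an) != 1) stop("geometry error: ambiguous peak reference")
    midpt <- els[[an]]$center
    reference <- "central_electrode"
  }
  gm_pt <- project_to_gm(ph, midpt)
  out <- sqrt(sum((centroid - gm_pt)^2))
  attr(out, "reference") <- reference
  out
}

## First grey-matter voxel center along the ray from a scalp point to the
## centroid.
project_to_gm <- function(phantom, p0) {
  ctr <- phantom$center_mm
  dir <- ctr - p0
  len <- sqrt(sum(dir^2))
  dir <- dir / len
  steps <- seq(0, len, by = phantom$voxel_size_mm / 4)
  pts <- rep(p0, each = length(steps)) + outer(steps, dir)
  lab <- label_at(phantom, pts)
  hit <- which(lab == 4L)[1]
  if (is.na(hit)) stop("anatomy error: no grey matter under the point")
  voxel_centers(phantom, voxel_of(phantom, pts[hit, ]))[1, ]
}

#' All outcome measures for one solve
#'
#' @param sol A `field_solution` (already scaled to the montage current).
#' @param m The `montage`.
#' @param roi The subject's [roi_spec()].
#' @param mask Tissue labels for the whole-brain measures.
#' @param level_fraction,peak_percentile Focality parameters.
#' @return Object of class `metric_set` (named list).
#' @export
compute_metrics <- function(sol, m, roi, mask = c(4L, 5L),
                            level_fraction = 0.5, peak_percentile = 99.9) {
  po <- peak_offset(sol, m, mask, peak_percentile)
  structure(list(
    roi_mean_Vpm = roi_mean(sol, roi),
    p99_mean_Vpm = p99_mean(sol, mask),
    focality_mm3 = focality_volume(sol, mask, level_fraction, peak_percentile),
    peak_offset_mm = as.numeric(po),
    peak_reference = attr(po, "reference")
  ), class = "metric_set")
}
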