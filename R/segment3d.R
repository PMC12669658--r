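#' Resample the z axis to isotropic voxels
#'
#' 3D stacks are acquired with a z step much larger than the lateral pixel
#' size; all 3D measurements here assume isotropic voxels, so the z axis is
#' resampled by the factor `f = z_spacing / xy_spacing` using linear
#' interpolation before segmentation. y and x are untouched. `f < 1` (z finer
#' than xy) is handled by the same formula.
#'
#' @param stack A [channel_stack()]; y and x spacing must be equal.
#' @return A [channel_stack()] with isotropic spacing equal to the xy pixel
#'   size. Already-isotropic input is returned unchanged.
#' @export
correct_anisotropy <- function(stack) {
  stopifnot(inherits(stack, "channel_stack"))
  sp <- stack$spacing
  if (!isTRUE(all.equal(sp[2], sp[3])))
    stop("y and x spacing must be equal for anisotropy correction",
         call. = FALSE)
  f <- sp[1] / sp[2]
  if (isTRUE(all.equal(f, 1))) return(stack)
  d <- dim(stack$channels[[1]])
  nz_out <- max(1L, as.integer(round(d[1] * f)))
  # output slice j (0-based) samples input coordinate j / f, clamped
  zi <- pmin((seq_len(nz_out) - 1) / f, d[1] - 1)
  k0 <- pmin(floor(zi), d[1] - 2); k0 <- pmax(k0, 0)
  w <- zi - k0
  channels <- lapply(stack$channels, function(vol) {
    out <- array(0, dim = c(nz_out, d[2], d[3]))
    for (j in seq_len(nz_out)) {
      lo <- vol[k0[j] + 1, , ]
      if (w[j] == 0) out[j, , ] <- lo
      else out[j, , ] <- (1 - w[j]) * lo + w[j] * vol[k0[j] + 2, , ]
    }
    out
  })
  channel_stack(channels, rep(sp[2], 3), source = stack$source)
}

#' Global Otsu threshold of a numeric array
#'
#' Classic histogram-based Otsu: the threshold maximising between-class
#' variance over `levels` equal-width bins spanning the data range. Returned
#' as an intensity value; foreground is `x > threshold`.
#'
#' @param x Numeric vector or array.
#' @param levels Number of histogram bins (default 256).
#' @return Threshold intensity, or `NA` for a constant input.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(NA_real_)
  breaks <- seq(r[1], r[2], length.out = levels + 1L)
  h <- as.double(tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                       all.inside = TRUE), nbins = levels))
  w <- cumsum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  m <- cumsum(h * mids)
  n <- w[levels]; mtot <- m[levels]
  w1 <- w[-levels]; m1 <- m[-levels]
  valid <- w1 > 0 & w1 < n
  bc <- rep(-Inf, levels - 1L)
  bc[valid] <- (mtot * w1[valid] - n * m1[valid])^2 /
    (w1[valid] * (n - w1[valid]))
  breaks[which.max(bc) + 1L]
}

#' Label volume
#'
#' @param labels Integer 3D array, 0 background, labels consecutive positive
#'   integers.
#' @param spacing Isotropic voxel spacing in micrometres (scalar).
#' @param channel Channel name.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, channel = NA_character_) {
  stopifnot(length(dim(labels)) == 3L, length(spacing) == 1L, spacing > 0)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 channel = channel), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> channel %s, %d labels, shape (%s), spacing %g um\n",
              x$channel, max(x$labels, 0L),
              paste(dim(x$labels), collapse = ", "), x$spacing))
  invisible(x)
}

#' Voronoi-Otsu segmentation of a 3D volume
#'
#' Segments blob-like foci with the Voronoi-Otsu labelling workflow:
#' Gaussian blur at `blur_sigma`, spot detection as 3D local maxima of the
#' volume blurred at `spot_sigma`, global Otsu thresholding of the blurred
#' volume, then seeded watershedding of the thresholded region from the
#' detected spots, so that touching foci are split along the Voronoi-like
#' watershed boundary between their seeds.
#'
#' @param volume 3D numeric array (z, y, x) with isotropic voxels.
#' @param spacing Isotropic voxel spacing in micrometres.
#' @param blur_sigma,spot_sigma Gaussian SDs in micrometres; `NULL` defaults
#'   to one voxel (`spacing`).
#' @param channel Channel name carried into the result.
#' @return A [label_volume()]. A constant volume yields zero labels.
#' @export
voronoi_otsu_segment <- function(volume, spacing, blur_sigma = NULL,
                                 spot_sigma = NULL, channel = NA_character_) {
  stopifnot(length(dim(volume)) == 3L, length(spacing) == 1L, spacing > 0)
  if (is.null(blur_sigma)) blur_sigma <- spacing
  if (is.null(spot_sigma)) spot_sigma <- spacing
  d <- dim(volume)
  empty <- function() label_volume(array(0L, d), spacing, channel)
  if (min(volume) == max(volume)) return(empty())
  sb <- rep(blur_sigma / spacing, 3)
  ss <- rep(spot_sigma / spacing, 3)
  blurred <- cpp_gaussian_blur3d(as.double(volume), d, sb)
  spotvol <- if (isTRUE(all.equal(blur_sigma, spot_sigma))) blurred
             else cpp_gaussian_blur3d(as.double(volume), d, ss)
  thr <- otsu_threshold(blurred)
  mask <- blurred > thr
  if (!any(mask)) return(empty())
  maxima <- cpp_local_maxima3d(spotvol, d) & mask
  if (!any(maxima)) return(empty())
  # merge plateau maxima into single seeds, then flood the mask
  seeds <- cpp_label3d(maxima, d)
  lab <- cpp_watershed_seeded(blurred, seeds, mask, d)
  lab <- compact_labels(lab)
  label_volume(lab, spacing, channel)
}

# renumber labels to consecutive 1..n, preserving order of first appearance
# by original label value
compact_labels <- function(lab) {
  d <- dim(lab)
  u <- sort(unique(lab[lab > 0L]))
  if (!length(u)) {
    out <- array(0L, d)
    return(out)
  }
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- lab
  pos <- lab > 0L
  out[pos] <- map[lab[pos]]
  dim(out) <- d
  out
}

#' Assign foci to nuclei and discard foci outside the nuclear mask
#'
#' A focus is kept if and only if the (y, x) position of its centroid falls on
#' a non-zero pixel of the 2D nuclear mask; it then inherits that pixel's
#' nucleus label. Removed foci are deleted and remaining labels compacted.
#'
#' @param labels A [label_volume()].
#' @param mask A [nuclear_mask()] whose shape matches the (y, x) shape of
#'   `labels`.
#' @return List with `labels` (filtered, compacted [label_volume()]) and
#'   `nucleus_id` (integer vector indexed by new focus label).
#' @export
apply_nuclear_mask <- function(labels, mask) {
  stopifnot(inherits(labels, "label_volume"), inherits(mask, "nuclear_mask"))
  d <- dim(labels$labels)
  if (!identical(dim(mask$labels), d[2:3]))
    stop("mask shape must match the (y, x) shape of the label volume",
         call. = FALSE)
  n <- max(labels$labels, 0L)
  if (n == 0L)
    return(list(labels = labels, nucleus_id = integer(0)))
  cen <- label_centroids_vox(labels$labels)      # 0-based voxel coords
  py <- pmin(pmax(round(cen[, 2]) + 1, 1), d[2])
  px <- pmin(pmax(round(cen[, 3]) + 1, 1), d[3])
  nuc <- mask$labels[cbind(py, px)]
  keep <- which(nuc > 0L)
  lab <- labels$labels
  lab[!(lab %in% keep)] <- 0L
  lab <- compact_labels(lab)
  list(labels = label_volume(lab, labels$spacing, labels$channel),
       nucleus_id = as.integer(nuc[keep]))
}

# per-label mean 0-based voxel coordinates, rows = label 1..n
label_centroids_vox <- function(lab) {
  idx <- which(lab > 0L)
  l <- lab[idx]
  co <- arrayInd(idx, dim(lab)) - 1L
  cnt <- tabulate(l, nbins = max(l))
  sums <- rowsum(co + 0.0, l)
  sums / cnt[sort(unique(l))]
}

#' Remove foci below the minimum voxel size
#'
#' Applies the size cutoff that excludes small objects: foci with strictly
#' fewer than `min_voxels` voxels are removed (a focus of exactly
#' `min_voxels` voxels is retained). Labels are recompacted.
#'
#' @param labels A [label_volume()].
#' @param min_voxels Minimum voxel count (default 50).
#' @return List with `labels` (filtered [label_volume()]), `kept` (old label
#'   ids retained, in order of their new ids) and `report` (counts before and
#'   after, retained fraction).
#' @export
filter_small <- function(labels, min_voxels = 50L) {
  stopifnot(inherits(labels, "label_volume"))
  n <- max(labels$labels, 0L)
  if (n == 0L)
    return(list(labels = labels, kept = integer(0),
                report = list(n_before = 0L, n_after = 0L,
                              retained_fraction = NA_real_)))
  cnt <- tabulate(labels$labels[labels$labels > 0L], nbins = n)
  kept <- which(cnt >= min_voxels)
  lab <- labels$labels
  if (length(kept) < n) {
    lab[!(lab %in% kept)] <- 0L
    lab <- compact_labels(lab)
  }
  list(labels = label_volume(lab, labels$spacing, labels$channel),
       kept = kept,
       report = list(n_before = n, n_after = length(kept),
                     retained_fraction = length(kept) / n))
}

#' Per-focus properties
#'
#' Centroid is the intensity-unweighted mean of member voxel coordinates,
#' converted to micrometres with the 0-based voxel-centre convention; volume
#' is `voxel_count * spacing^3`.
#'
#' @param labels A [label_volume()].
#' @param intensity 3D numeric array of the same shape (the channel volume the
#'   labels were segmented from).
#' @param nucleus_id Optional integer vector of nucleus assignments indexed by
#'   focus label (from [apply_nuclear_mask()]).
#' @return Data frame with one row per focus: `focus_id`, `channel`,
#'   `nucleus_id`, `voxel_count`, `volume_um3`, `centroid_z_um`,
#'   `centroid_y_um`, `centroid_x_um`, `integrated_intensity`,
#'   `mean_intensity`.
#' @export
compute_focus_props <- function(labels, intensity, nucleus_id = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (!identical(dim(intensity), dim(labels$labels)))
    stop("labels and intensity must share shape", call. = FALSE)
  n <- max(labels$labels, 0L)
  s <- labels$spacing
  if (n == 0L) {
    return(data.frame(focus_id = integer(0), channel = character(0),
                      nucleus_id = integer(0), voxel_count = integer(0),
                      volume_um3 = double(0), centroid_z_um = double(0),
                      centroid_y_um = double(0), centroid_x_um = double(0),
                      integrated_intensity = double(0),
                      mean_intensity = double(0)))
  }
  idx <- which(labels$labels > 0L)
  l <- labels$labels[idx]
  cnt <- tabulate(l, nbins = n)
  cen <- label_centroids_vox(labels$labels) * s
  tot <- rowsum(as.double(intensity[idx]), l)[, 1]
  if (is.null(nucleus_id)) nucleus_id <- rep(NA_integer_, n)
  data.frame(focus_id = seq_len(n),
             channel = rep(labels$channel, n),
             nucleus_id = as.integer(nucleus_id),
             voxel_count = cnt,
             volume_um3 = cnt * s^3,
             centroid_z_um = cen[, 1],
             centroid_y_um = cen[, 2],
             centroid_x_um = cen[, 3],
             integrated_intensity = tot,
             mean_intensity = tot / cnt)
}
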