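#' Illumination correction by polynomial surface fitting
#'
#' Fits a low-order 2D polynomial to the image (the smooth illumination
#' field) and divides the image by the fitted surface normalised to its mean,
#' so the output keeps the input's mean intensity; alternatively the surface
#' can be subtracted. Division is the default. A degenerate (constant-image)
#' fit returns the input unchanged.
#'
#' @param image Numeric matrix.
#' @param order Polynomial order (default 2, the usual fit-polynomial
#'   smoothing convention).
#' @param mode `"divide"` (default) or `"subtract"`.
#' @return Corrected matrix of the same shape.
#' @export
illumination_correct <- function(image, order = 2L, mode = c("divide",
                                                             "subtract")) {
  mode <- match.arg(mode)
  if (max(image) == min(image)) return(image)
  ny <- nrow(image); nx <- ncol(image)
  yy <- (row(image) - 1) / max(1, ny - 1)
  xx <- (col(image) - 1) / max(1, nx - 1)
  terms <- list()
  for (i in 0:order)
    for (j in 0:(order - i))
      terms[[length(terms) + 1L]] <- as.vector(yy^i * xx^j)
  X <- do.call(cbind, terms)
  fit <- stats::lm.fit(X, as.vector(image))
  surface <- matrix(X %*% fit$coefficients, ny, nx)
  if (mode == "divide") {
    surface <- pmax(surface, 1e-12)
    image / surface * mean(surface)
  } else {
    image - surface + mean(surface)
  }
}

#' Segment nuclei in a 2D DAPI image
#'
#' Adaptive (tiled) Otsu thresholding, connected-component labelling, hole
#' filling, and a size gate keeping objects whose equivalent diameter lies in
#' `diameter_range` pixels.
#'
#' Per-tile Otsu thresholds are interpolated bilinearly between tile centres
#' and clamped to 0.7-1.5 times the global Otsu threshold so that empty tiles
#' do not produce spurious foreground.
#'
#' @param image Corrected 2D DAPI matrix.
#' @param diameter_range Equivalent-diameter gate in pixels (default
#'   `c(6, 40)`).
#' @param tile_size Adaptive threshold tile edge in pixels; default 4 times
#'   the maximum object diameter.
#' @return Integer label matrix (y, x); 0 background.
#' @export
segment_nuclei_2d <- function(image, diameter_range = c(6, 40),
                              tile_size = 4 * max(diameter_range)) {
  if (max(image) == min(image))
    return(matrix(0L, nrow(image), ncol(image)))
  thr <- adaptive_otsu_surface(image, tile_size)
  bw <- image > thr
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  area <- tabulate(lab[lab > 0], nbins = max(lab))
  eqd <- 2 * sqrt(area / pi)
  keep <- which(eqd >= diameter_range[1] & eqd <= diameter_range[2])
  out <- array(0L, dim(lab))
  if (length(keep)) {
    m <- lab %in% keep
    out[m] <- match(lab[m], keep)
  }
  matrix(as.integer(out), nrow(image), ncol(image))
}

adaptive_otsu_surface <- function(image, tile_size) {
  ny <- nrow(image); nx <- ncol(image)
  global <- otsu_threshold(image)
  nty <- max(1L, floor(ny / tile_size))
  ntx <- max(1L, floor(nx / tile_size))
  if (nty == 1L && ntx == 1L) return(matrix(global, ny, nx))
  ty <- floor(seq(0, ny, length.out = nty + 1L))
  tx <- floor(seq(0, nx, length.out = ntx + 1L))
  thr <- matrix(global, nty, ntx)
  cy <- numeric(nty); cx <- numeric(ntx)
  for (a in seq_len(nty)) {
    cy[a] <- (ty[a] + ty[a + 1] + 1) / 2
    for (b in seq_len(ntx)) {
      cx[b] <- (tx[b] + tx[b + 1] + 1) / 2
      tile <- image[(ty[a] + 1):ty[a + 1], (tx[b] + 1):tx[b + 1]]
      t_loc <- otsu_threshold(tile)
      if (is.na(t_loc)) t_loc <- global
      thr[a, b] <- min(max(t_loc, 0.7 * global), 1.5 * global)
    }
  }
  # bilinear interpolation of the tile-centre thresholds over the image
  interp_axis <- function(pos, centres) {
    i1 <- findInterval(pos, centres, all.inside = TRUE)
    i2 <- i1 + 1L
    w <- (pos - centres[i1]) / (centres[i2] - centres[i1])
    w <- pmin(pmax(w, 0), 1)
    list(i1 = i1, i2 = i2, w = w)
  }
  ay <- interp_axis(seq_len(ny), cy)
  ax <- interp_axis(seq_len(nx), cx)
  wy <- matrix(ay$w, ny, nx); wx <- matrix(ax$w, ny, nx, byrow = TRUE)
  t11 <- thr[cbind(rep(ay$i1, nx), rep(ax$i1, each = ny))]
  t21 <- thr[cbind(rep(ay$i2, nx), rep(ax$i1, each = ny))]
  t12 <- thr[cbind(rep(ay$i1, nx), rep(ax$i2, each = ny))]
  t22 <- thr[cbind(rep(ay$i2, nx), rep(ax$i2, each = ny))]
  matrix((1 - wy) * (1 - wx) * t11 + wy * (1 - wx) * t21 +
           (1 - wy) * wx * t12 + wy * wx * t22, ny, nx)
}

#' Per-nucleus integrated intensities
#'
#' Sums pixel intensities of each channel over every labelled nucleus.
#'
#' @param labels Integer 2D label matrix from [segment_nuclei_2d()].
#' @param channels Named list of numeric matrices aligned with `labels`.
#' @return Data frame with `cell_id`, `area_px`, and one
#'   `<channel>_integrated` column per channel.
#' @export
integrate_intensities <- function(labels, channels) {
  if (!is.list(channels)) channels <- list(channel = channels)
  for (ch in channels)
    if (!identical(dim(ch), dim(labels)))
      stop("channel shape must match label shape", call. = FALSE)
  n <- max(labels, 0L)
  out <- data.frame(cell_id = seq_len(n),
                    area_px = tabulate(labels[labels > 0], nbins = n))
  idx <- which(labels > 0)
  l <- labels[idx]
  for (nm in names(channels)) {
    sums <- rep(0, n)
    if (length(idx)) {
      rs <- rowsum(as.double(channels[[nm]][idx]), l)
      sums[as.integer(rownames(rs))] <- rs[, 1]
    }
    out[[paste0(nm, "_integrated")]] <- sums
  }
  out
}

#' Gate cells by a fixed intensity threshold
#'
#' Stratifies cells into signal-negative and signal-positive (S-phase) by a
#' fixed threshold on an integrated-intensity column: positive means strictly
#' greater than the threshold.
#'
#' @param records Data frame from [integrate_intensities()].
#' @param column Name of the intensity column to gate on.
#' @param threshold Fixed threshold in intensity units.
#' @return List with `records` (input plus logical `positive`) and
#'   `percent_positive`.
#' @export
gate_positive <- function(records, column, threshold) {
  if (!column %in% names(records))
    stop("column not found: ", column, call. = FALSE)
  records$positive <- records[[column]] > threshold
  list(records = records,
       percent_positive = if (nrow(records)) 100 * mean(records$positive)
                          else NA_real_)
}

#' Robust signal span: p95 minus p5
#'
#' The robust dynamic range of a set of per-cell intensities, computed with
#' the linear-interpolation percentile convention (R quantile type 7). The
#' convention matters: other percentile definitions give different spans.
#'
#' @param values Numeric vector, length at least 2.
#' @return `p95 - p5`.
#' @export
robust_signal <- function(values) {
  if (length(values) < 2L)
    stop("robust_signal needs at least 2 values", call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.95), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Build a dose-time signal matrix
#'
#' Aggregates per-cell intensities into a matrix of robust signal spans
#' (p95 - p5) over a pulse-duration by concentration grid.
#'
#' @param cells Data frame with columns `duration`, `concentration` and the
#'   intensity column named by `column`.
#' @param column Intensity column to summarise.
#' @return List with `matrix` (rows = sorted durations, columns = sorted
#'   concentrations) and `n` (cell counts per condition).
#' @export
dose_time_matrix <- function(cells, column) {
  durs <- sort(unique(cells$duration))
  concs <- sort(unique(cells$concentration))
  m <- matrix(NA_real_, length(durs), length(concs),
              dimnames = list(duration = durs, concentration = concs))
  n <- m
  for (i in seq_along(durs))
    for (j in seq_along(concs)) {
      v <- cells[[column]][cells$duration == durs[i] &
                             cells$concentration == concs[j]]
      n[i, j] <- length(v)
      if (length(v) >= 2) m[i, j] <- robust_signal(v)
    }
  list(matrix = m, n = n)
}

#' Fold difference in labelling efficiency between two pulse conditions
#'
#' Two labelling conditions that give comparable signal differ in
#' incorporation efficiency by the product of their duration and
#' concentration ratios: `(t2 / t1) * (c2 / c1)`.
#'
#' @param t1_min,c1 Duration (minutes) and concentration of the efficient
#'   label.
#' @param t2_min,c2 Duration and concentration of the comparison label.
#' @return Fold efficiency (dimensionless).
#' @export
fold_efficiency <- function(t1_min, c1, t2_min, c2) {
  vals <- c(t1_min, c1, t2_min, c2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all durations and concentrations must be > 0", call. = FALSE)
  (t2_min / t1_min) * (c2 / c1)
}

#' Convert stretched-fibre track length to DNA length
#'
#' @param length_um Track length in micrometres (>= 0).
#' @param rate_kbp_per_um Fibre extension rate (default 2.59 kbp per
#'   micrometre).
#' @return DNA length in kilobases.
#' @export
tract_to_kb <- function(length_um, rate_kbp_per_um = 2.59) {
  if (any(length_um < 0))
    stop("track length must be >= 0", call. = FALSE)
  length_um * rate_kbp_per_um
}
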