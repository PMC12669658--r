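focus_centroid <- function(foci, channel, id) {
  row <- foci[foci$channel == channel & foci$focus_id == id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("focus ", channel, ":", id, " not found in foci table",
         call. = FALSE)
  c(row$centroid_z_um, row$centroid_y_um, row$centroid_x_um)
}

event_member_ids <- function(event) {
  list(edu = split_focus_ids(event$edu_focus_ids),
       dutp = split_focus_ids(event$dutp_focus_ids))
}

#' Centroid distance of an ongoing event
#'
#' Euclidean distance in micrometres between the centroids of the EdU and
#' dUTP focus of an ongoing event — the spatial offset the two sequential
#' pulses leave along a moving replication fork. Fork-slowing treatments
#' shrink it.
#'
#' @param event One row of the events table (as a data frame row or list).
#' @param foci Combined focus table.
#' @return Distance in micrometres.
#' @export
centroid_distance <- function(event, foci) {
  if (event$type != "ongoing")
    stop("centroid_distance is defined for ongoing events only",
         call. = FALSE)
  ids <- event_member_ids(event)
  a <- focus_centroid(foci, "EdU", ids$edu)
  b <- focus_centroid(foci, "dUTP", ids$dutp)
  sqrt(sum((a - b)^2))
}

#' Volume-overlap ratio of a dual-colour event
#'
#' Voxels shared between the event's EdU and dUTP foci divided by the voxels
#' of the union of all member foci (the total event volume). Lies in [0, 1];
#' fork-slowing treatments increase it.
#'
#' @param event One row of the events table.
#' @param labels_edu,labels_dutp [label_volume()]s the event was built from.
#' @return Fraction in [0, 1].
#' @export
overlap_ratio <- function(event, labels_edu, labels_dutp) {
  ids <- event_member_ids(event)
  if (!length(ids$edu) || !length(ids$dutp))
    stop("overlap_ratio is defined for dual-colour events only",
         call. = FALSE)
  in_e <- labels_edu$labels %in% ids$edu
  in_d <- labels_dutp$labels %in% ids$dutp
  sum(in_e & in_d) / sum(in_e | in_d)
}

#' Inter-fork angle of an initiation (or termination) event
#'
#' The angle between the two vectors from the centre-focus centroid (EdU for
#' initiations, dUTP for terminations) to the two flanking-focus centroids,
#' computed as the arccosine of the normalised dot product (cosine clamped to
#' [-1, 1]).
#'
#' @param event One row of the events table, type `initiation` or
#'   `termination`.
#' @param foci Combined focus table.
#' @return Angle in degrees, in [0, 180].
#' @export
initiation_angle <- function(event, foci) {
  ids <- event_member_ids(event)
  if (event$type == "initiation") {
    centre <- focus_centroid(foci, "EdU", ids$edu)
    flanks <- lapply(ids$dutp, function(i) focus_centroid(foci, "dUTP", i))
  } else if (event$type == "termination") {
    centre <- focus_centroid(foci, "dUTP", ids$dutp)
    flanks <- lapply(ids$edu, function(i) focus_centroid(foci, "EdU", i))
  } else {
    stop("initiation_angle is defined for initiation/termination events",
         call. = FALSE)
  }
  vector_angle(flanks[[1]] - centre, flanks[[2]] - centre)
}

#' Angle between two vectors in degrees
#'
#' @param v1,v2 Numeric length-3 vectors.
#' @return Angle in degrees; error on a zero-length vector.
#' @export
vector_angle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    stop("zero-length vector: coincident centroids have no angle",
         call. = FALSE)
  acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Per-event geometry metrics
#'
#' Computes, for every event: the total event volume (union of member-foci
#' voxels times voxel volume); for ongoing events the centroid distance; for
#' dual-colour events the volume-overlap ratio; for initiation and
#' termination events the inter-fork angle.
#'
#' @param events Events table from [classify_events()].
#' @param foci Combined focus table.
#' @param labels_edu,labels_dutp [label_volume()]s.
#' @return Data frame keyed by `event_id` with `type`, `nucleus_id`,
#'   `event_volume_um3`, `centroid_distance_um`, `overlap_ratio`,
#'   `angle_deg` (NA where not defined).
#' @export
event_metrics <- function(events, foci, labels_edu, labels_dutp) {
  n <- nrow(events)
  vox_vol <- labels_edu$spacing^3
  out <- data.frame(event_id = events$event_id, type = events$type,
                    nucleus_id = events$nucleus_id,
                    event_volume_um3 = rep(NA_real_, n),
                    centroid_distance_um = rep(NA_real_, n),
                    overlap_ratio = rep(NA_real_, n),
                    angle_deg = rep(NA_real_, n))
  if (n == 0L) return(out)
  cnt_e <- tabulate(labels_edu$labels, nbins = max(labels_edu$labels, 1L))
  cnt_d <- tabulate(labels_dutp$labels, nbins = max(labels_dutp$labels, 1L))
  # intersection voxel counts per (EdU, dUTP) label pair
  ov <- compute_overlaps(labels_edu, labels_dutp)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    ids <- event_member_ids(ev)
    pair_ov <- ov[ov$focus_a %in% ids$edu & ov$focus_b %in% ids$dutp, ,
                  drop = FALSE]
    inter <- sum(pair_ov$overlap_voxels)
    union <- sum(cnt_e[ids$edu]) + sum(cnt_d[ids$dutp]) - inter
    out$event_volume_um3[i] <- union * vox_vol
    if (ev$type == "ongoing")
      out$centroid_distance_um[i] <- centroid_distance(ev, foci)
    if (ev$type %in% .DUAL_TYPES)
      out$overlap_ratio[i] <- inter / union
    if (ev$type %in% c("initiation", "termination"))
      out$angle_deg[i] <- initiation_angle(ev, foci)
  }
  out
}

#' Nearest-neighbour centroid distances between focus sets
#'
#' For each source focus, the minimum centroid distance to the target set.
#' Both directions are reported separately (A to B and B to A); with
#' `foci_b = NULL` the within-set mode is used, excluding each focus itself
#' (at least two foci required).
#'
#' @param foci_a Focus table (or any data frame with `centroid_z_um`,
#'   `centroid_y_um`, `centroid_x_um`).
#' @param foci_b Target focus table, or `NULL` for within-set distances.
#' @return For two sets, a list with `a_to_b` and `b_to_a` numeric vectors;
#'   for the within-set mode a single numeric vector.
#' @export
nearest_neighbour_distances <- function(foci_a, foci_b = NULL) {
  pa <- as.matrix(foci_a[, c("centroid_z_um", "centroid_y_um",
                             "centroid_x_um")])
  if (is.null(foci_b)) {
    if (nrow(pa) < 2L)
      stop("within-set nearest neighbour needs at least 2 foci",
           call. = FALSE)
    d <- as.matrix(stats::dist(pa))
    diag(d) <- Inf
    return(apply(d, 1, min))
  }
  pb <- as.matrix(foci_b[, c("centroid_z_um", "centroid_y_um",
                             "centroid_x_um")])
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stop("both focus sets must be non-empty", call. = FALSE)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  list(a_to_b = sqrt(apply(d2, 1, min)), b_to_a = sqrt(apply(d2, 2, min)))
}

#' Distance of foci to the nuclear periphery
#'
#' In-plane (2D) Euclidean distance from each focus centroid to the boundary
#' of its own nucleus in the 2D mask, computed with a distance transform of
#' the nucleus interior and converted to micrometres. Masks are 2D by
#' construction, so the distance is measured in the (y, x) plane.
#'
#' @param foci Focus table with `nucleus_id` assigned.
#' @param mask A [nuclear_mask()].
#' @return Numeric vector of distances in micrometres, one per focus row.
#' @export
periphery_distances <- function(foci, mask) {
  stopifnot(inherits(mask, "nuclear_mask"))
  if (!isTRUE(all.equal(mask$spacing[1], mask$spacing[2])))
    stop("periphery distances need square mask pixels", call. = FALSE)
  px <- mask$spacing[1]
  out <- rep(NA_real_, nrow(foci))
  for (nid in unique(foci$nucleus_id)) {
    sel <- which(foci$nucleus_id == nid)
    dm <- EBImage::distmap(mask$labels == nid)
    iy <- pmin(pmax(round(foci$centroid_y_um[sel] / px) + 1, 1),
               nrow(mask$labels))
    ix <- pmin(pmax(round(foci$centroid_x_um[sel] / px) + 1, 1),
               ncol(mask$labels))
    vals <- dm[cbind(iy, ix)]
    if (any(vals == 0))
      stop("focus centroid outside its nucleus mask (nucleus ", nid, ")",
           call. = FALSE)
    out[sel] <- vals * px
  }
  out
}

#' Per-nucleus event summary
#'
#' Counts per event type, relative frequencies among the dual-colour types
#' (initiation, ongoing, termination), the focus retention fraction, and the
#' medians of the per-event geometry metrics.
#'
#' @param events Events table of one or more nuclei.
#' @param metrics Per-event metrics from [event_metrics()].
#' @param retention Retention report from [classify_events()] (optional).
#' @return Data frame with one row per nucleus (columns as in the summaries
#'   CSV). With no dual events the relative frequencies are `NA` and
#'   `n_dual` is 0.
#' @export
summarise_nucleus <- function(events, metrics, retention = NULL) {
  nuclei <- sort(unique(stats::na.omit(events$nucleus_id)))
  rows <- lapply(nuclei, function(nid) {
    ev <- events[!is.na(events$nucleus_id) & events$nucleus_id == nid, ]
    mt <- metrics[metrics$event_id %in% ev$event_id, ]
    cnt <- table(factor(ev$type, levels = c("single_colour", .DUAL_TYPES,
                                            "crowded")))
    n_dual <- sum(cnt[.DUAL_TYPES])
    rf <- if (n_dual > 0) as.numeric(cnt[.DUAL_TYPES]) / n_dual
          else rep(NA_real_, 3)
    ret <- if (!is.null(retention) && nid %in% retention$nucleus_id)
      retention$retention[retention$nucleus_id == nid] else NA_real_
    med <- function(x) if (all(is.na(x))) NA_real_ else
      stats::median(x, na.rm = TRUE)
    data.frame(nucleus_id = nid,
               n_single_colour = as.integer(cnt[["single_colour"]]),
               n_ongoing = as.integer(cnt[["ongoing"]]),
               n_initiation = as.integer(cnt[["initiation"]]),
               n_termination = as.integer(cnt[["termination"]]),
               n_crowded = as.integer(cnt[["crowded"]]),
               n_dual = as.integer(n_dual),
               rel_freq_initiation = rf[2],
               rel_freq_ongoing = rf[1],
               rel_freq_termination = rf[3],
               retention = ret,
               median_centroid_distance_um = med(mt$centroid_distance_um),
               median_overlap_ratio = med(mt$overlap_ratio),
               median_angle_deg = med(mt$angle_deg))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    as_cols(NULL, .SUMMARY_COLS)
  rownames(out) <- NULL
  out
}

#' Compare a per-nucleus metric between two groups
#'
#' Two-sided Mann-Whitney U test with tie handling (exact when both groups
#' have at most 8 untied values, normal approximation with tie correction
#' otherwise) and Bonferroni adjustment over the test family.
#'
#' @param x,y Numeric per-nucleus values of the two groups.
#' @param metric Name of the metric (carried into the output).
#' @param labels Character length-2 group labels.
#' @param n_tests Number of tests in the family for the Bonferroni cap.
#' @return Data frame with `metric`, `group1`, `group2`, `n1`, `n2`,
#'   `U`, `p_raw`, `p_adjusted` (`min(1, p_raw * n_tests)`).
#' @export
compare_groups <- function(x, y, metric = "metric",
                           labels = c("group1", "group2"), n_tests = 1L) {
  if (!length(x) || !length(y))
    stop("both groups must contain at least one value", call. = FALSE)
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  data.frame(metric = metric, group1 = labels[1], group2 = labels[2],
             n1 = length(x), n2 = length(y),
             U = unname(wt$statistic), p_raw = wt$p.value,
             p_adjusted = min(1, wt$p.value * n_tests))
}

#' Pearson colocalization of two 2D projections
#'
#' Pearson correlation coefficient of pixel intensities over the masked
#' region of two 2D images (typically maximum-intensity projections of the
#' two channels), with no intensity threshold applied.
#'
#' @param projection_a,projection_b Numeric matrices of equal shape.
#' @param mask Matrix of the same shape; pixels with `mask > 0` enter the
#'   correlation. `NULL` uses all pixels.
#' @return Pearson R.
#' @export
pearson_colocalization <- function(projection_a, projection_b, mask = NULL) {
  if (!identical(dim(projection_a), dim(projection_b)))
    stop("projections must share shape", call. = FALSE)
  if (is.null(mask)) mask <- array(1, dim(projection_a))
  if (!identical(dim(mask), dim(projection_a)))
    stop("mask must share the projection shape", call. = FALSE)
  a <- projection_a[mask > 0]
  b <- projection_b[mask > 0]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero-variance channel: Pearson R undefined", call. = FALSE)
  stats::cor(a, b)
}

#' Maximum-intensity projection of a channel volume
#'
#' @param volume 3D array (z, y, x).
#' @return Matrix (y, x) of per-pixel maxima over z.
#' @export
max_projection <- function(volume) {
  apply(volume, c(2, 3), max)
}
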