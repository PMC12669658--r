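#' Run the full nanofocus analysis chain on one field
#'
#' Executes anisotropy correction, per-channel Voronoi-Otsu segmentation,
#' nuclear masking, the size filter, overlap computation, event
#' classification, per-event geometry metrics and per-nucleus summaries.
#' Deterministic given inputs and configuration.
#'
#' @param stack A [channel_stack()] containing the EdU and dUTP channels
#'   named in `config`.
#' @param mask A [nuclear_mask()] over the stack's (y, x) plane.
#' @param config A [spark_config()].
#' @param out_dir Optional directory; when given, foci/events/summaries CSVs
#'   and the run manifest are written there.
#' @return List of class `spark_run`: `foci`, `events`, `records`,
#'   `metrics`, `summaries`, `retention`, `labels` (per-channel
#'   [label_volume()]s), `filter_reports` and `manifest`.
#' @export
run_spark <- function(stack, mask, config = spark_config(), out_dir = NULL) {
  stopifnot(inherits(stack, "channel_stack"), inherits(mask, "nuclear_mask"),
            inherits(config, "spark_config"))
  t0 <- Sys.time()
  for (ch in c(config$channel_edu, config$channel_dutp))
    if (!ch %in% names(stack$channels))
      stop("channel not present in stack: ", ch, call. = FALSE)

  iso <- correct_anisotropy(stack)
  spacing <- iso$spacing[2]

  segment_channel <- function(name, role) {
    lv <- voronoi_otsu_segment(iso$channels[[name]], spacing,
                               blur_sigma = config$blur_sigma,
                               spot_sigma = config$spot_sigma,
                               channel = role)
    masked <- apply_nuclear_mask(lv, mask)
    filt <- filter_small(masked$labels, config$min_voxels)
    nucleus_id <- masked$nucleus_id[filt$kept]
    props <- compute_focus_props(filt$labels, iso$channels[[name]],
                                 nucleus_id)
    list(labels = filt$labels, props = props, report = filt$report)
  }
  seg_e <- segment_channel(config$channel_edu, "EdU")
  seg_d <- segment_channel(config$channel_dutp, "dUTP")

  foci <- rbind(seg_e$props, seg_d$props)
  records <- compute_overlaps(seg_e$labels, seg_d$labels)
  cls <- classify_events(foci, records, config)
  metrics <- event_metrics(cls$events, foci, seg_e$labels, seg_d$labels)
  summaries <- summarise_nucleus(cls$events, metrics, cls$retention)

  manifest <- list(config = unclass(config),
                   source = stack$source,
                   version = as.character(utils::packageVersion("spark3d")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   n_foci = nrow(foci), n_events = nrow(cls$events),
                   outputs = character(0))
  res <- structure(list(foci = foci, events = cls$events,
                        records = cls$records, metrics = metrics,
                        summaries = summaries, retention = cls$retention,
                        labels = list(EdU = seg_e$labels, dUTP = seg_d$labels),
                        filter_reports = list(EdU = seg_e$report,
                                              dUTP = seg_d$report),
                        manifest = manifest),
                   class = "spark_run")
  if (!is.null(out_dir)) {
    paths <- write_tables(foci, cls$events, summaries, out_dir)
    mpath <- file.path(out_dir, "metrics.csv")
    write_table_csv(metrics, mpath)
    manifest$outputs <- c(paths, metrics = mpath)
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    res$manifest <- manifest
  }
  res
}

#' @export
print.spark_run <- function(x, ...) {
  cat(sprintf("<spark_run> %d foci, %d events (%s)\n",
              nrow(x$foci), nrow(x$events),
              paste(sprintf("%s: %d", names(table(x$events$type)),
                            table(x$events$type)), collapse = ", ")))
  invisible(x)
}

#' Match detected events to planted ground truth
#'
#' Greedy nearest matching of event positions (mean of member-foci centroids
#' against mean of planted blob centres) within `max_dist` micrometres.
#'
#' @param truth Ground truth from [simulate_nucleus()] (`$truth`).
#' @param run A `spark_run` from [run_spark()].
#' @param max_dist Maximum match distance in micrometres; default half the
#'   simulation's minimum event gap.
#' @return Data frame with one row per planted event: `event_id`,
#'   `true_type`, `true_separation`, `true_angle`, matched `detected_type`,
#'   `detected_event_id`, `centroid_distance_um`, `angle_deg` (NA when
#'   unmatched).
#' @export
match_events <- function(truth, run, max_dist = NULL) {
  cfg <- truth$config
  if (is.null(max_dist)) max_dist <- cfg$min_event_gap / 2
  evs <- truth$events
  n <- length(evs)
  out <- data.frame(event_id = integer(n), true_type = character(n),
                    true_separation = NA_real_, true_angle = NA_real_,
                    detected_event_id = NA_integer_,
                    detected_type = NA_character_,
                    centroid_distance_um = NA_real_, angle_deg = NA_real_)
  if (n == 0L) return(out[0, ])
  truth_pos <- t(vapply(evs, function(ev)
    colMeans(as.matrix(ev$blobs[, c("z_um", "y_um", "x_um")])), numeric(3)))
  det <- run$events
  det_pos <- matrix(NA_real_, nrow(det), 3)
  for (i in seq_len(nrow(det))) {
    ids <- event_member_ids(det[i, ])
    sel <- (run$foci$channel == "EdU" & run$foci$focus_id %in% ids$edu) |
      (run$foci$channel == "dUTP" & run$foci$focus_id %in% ids$dutp)
    det_pos[i, ] <- colMeans(as.matrix(
      run$foci[sel, c("centroid_z_um", "centroid_y_um", "centroid_x_um")]))
  }
  for (i in seq_len(n)) {
    out$event_id[i] <- evs[[i]]$event_id
    out$true_type[i] <- evs[[i]]$true_type
    out$true_separation[i] <- evs[[i]]$true_separation
    out$true_angle[i] <- evs[[i]]$true_angle
    if (!nrow(det)) next
    d2 <- colSums((t(det_pos) - truth_pos[i, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_dist) {
      out$detected_event_id[i] <- det$event_id[j]
      out$detected_type[i] <- det$type[j]
      out$centroid_distance_um[i] <- run$metrics$centroid_distance_um[j]
      out$angle_deg[i] <- run$metrics$angle_deg[j]
    }
  }
  out
}

#' Recovery benchmark over a grid of simulation configurations
#'
#' Simulates each configuration, runs the full analysis chain and reports
#' how well the planted ground truth is recovered: classification accuracy
#' over planted events, mean absolute error of the ongoing-event centroid
#' distance against the planted separation, mean absolute error of the
#' recovered initiation/termination angle, and the recovered dual-type
#' mixture with its 99% binomial confidence intervals.
#'
#' @param configs List of [sim_config()]s (may be empty).
#' @param analysis_config A [spark_config()].
#' @return Data frame with one row per configuration.
#' @export
run_benchmark <- function(configs, analysis_config = spark_config()) {
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    sim <- simulate_nucleus(cfg)
    run <- run_spark(sim$stack, sim$mask, analysis_config)
    matched <- match_events(sim$truth, run)
    acc <- mean(!is.na(matched$detected_type) &
                  matched$detected_type == matched$true_type)
    ong <- matched[matched$true_type == "ongoing" &
                     !is.na(matched$centroid_distance_um), ]
    ang <- matched[matched$true_type %in% c("initiation", "termination") &
                     !is.na(matched$angle_deg), ]
    dist_mae <- if (nrow(ong))
      mean(abs(ong$centroid_distance_um - ong$true_separation)) else NA_real_
    angle_mae <- if (nrow(ang))
      mean(abs(ang$angle_deg - ang$true_angle)) else NA_real_
    dual <- run$events$type[run$events$type %in% .DUAL_TYPES]
    freq <- as.numeric(table(factor(dual, levels = .DUAL_TYPES))) /
      max(1, length(dual))
    data.frame(config = i, seed = cfg$seed, n_events = cfg$n_events,
               amplitude = cfg$amplitude,
               separation_mean = cfg$separation_mean,
               n_detected_events = nrow(run$events),
               type_accuracy = acc,
               centroid_distance_mae_um = dist_mae,
               angle_mae_deg = angle_mae,
               freq_ongoing = freq[1], freq_initiation = freq[2],
               freq_termination = freq[3])
  })
  if (!length(rows)) {
    return(data.frame(config = integer(0), seed = integer(0),
                      n_events = integer(0), amplitude = double(0),
                      separation_mean = double(0),
                      n_detected_events = integer(0),
                      type_accuracy = double(0),
                      centroid_distance_mae_um = double(0),
                      angle_mae_deg = double(0), freq_ongoing = double(0),
                      freq_initiation = double(0),
                      freq_termination = double(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact binomial confidence interval
#'
#' Clopper-Pearson interval, used to check recovery of planted event-mixture
#' proportions.
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level (default 0.99).
#' @return Numeric length-2 `c(lower, upper)`.
#' @export
binomial_ci <- function(k, n, conf = 0.99) {
  as.numeric(stats::binom.test(k, n, conf.level = conf)$conf.int)
}
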