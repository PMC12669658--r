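#' Multi-channel 3D intensity stack
#'
#' Container for one field of view: one 3D volume per channel plus the
#' physical voxel spacing. Axis order is fixed as (z, y, x) and all physical
#' quantities are micrometres; voxel indices are 0-based in physical
#' conversions, i.e. the centre of voxel (i, j, k) sits at
#' `(i, j, k) * spacing` micrometres.
#'
#' @param channels Named list of 3D numeric arrays with dim (nz, ny, nx); all
#'   channels must share one shape.
#' @param spacing Numeric length-3, voxel spacing in micrometres (z, y, x).
#' @param source Optional path the stack was read from.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, spacing, source = NA_character_) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a named list of 3D arrays", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array (z, y, x)", call. = FALSE)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("channel shape mismatch: all channels must share one (z, y, x) shape",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive micrometre values (z, y, x)",
         call. = FALSE)
  structure(list(channels = channels, spacing = spacing, source = source),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack> %d channel(s) [%s], shape (%d, %d, %d), spacing (%g, %g, %g) um\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' 2D nuclear mask
#'
#' Label image over (y, x): 0 is background, k > 0 is nucleus k. Masks are 2D
#' by construction (drawn on, or simulated as, maximum-intensity projections)
#' and are applied to every z plane.
#'
#' @param labels Integer matrix (y, x) of nucleus labels.
#' @param spacing Numeric length-2 pixel spacing in micrometres (y, x).
#' @return An object of class `nuclear_mask`.
#' @export
nuclear_mask <- function(labels, spacing) {
  labels <- as.matrix(labels)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("mask labels must be non-negative integers", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("mask spacing must be 2 positive values (y, x)", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing), class = "nuclear_mask")
}

# uint16 storage scale used in TIFF containers
.TIFF_SCALE <- 65535

#' Write and read multi-channel 3D stacks as TIFF plus JSON sidecar
#'
#' The stack is stored as a multi-page 16-bit TIFF (pages ordered channel by
#' channel, z within channel) with a JSON sidecar carrying the voxel spacing,
#' channel names and shape. Intensities are quantised to integers in
#' `[0, 65535]` on write, the native range of microscopy camera data;
#' integer-valued stacks (such as simulated photon counts) round-trip exactly.
#'
#' @param stack A [channel_stack()].
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json` unless `sidecar` is given.
#' @param sidecar Path of the JSON metadata sidecar.
#' @return `write_stack()` returns the two paths invisibly; `read_stack()`
#'   returns a [channel_stack()].
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$channels[[1]])
  pages <- list()
  for (ch in names(stack$channels)) {
    vol <- stack$channels[[ch]]
    if (min(vol) < 0 || max(vol) > .TIFF_SCALE)
      stop("intensities must lie in [0, 65535] for 16-bit TIFF storage",
           call. = FALSE)
    for (z in seq_len(d[1]))
      pages[[length(pages) + 1L]] <- round(vol[z, , ]) / .TIFF_SCALE
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(spacing_um = stack$spacing, channels = names(stack$channels),
               shape = as.integer(d), scale = .TIFF_SCALE)
  jsonlite::write_json(meta, sidecar, auto_unbox = FALSE, digits = NA)
  invisible(c(tiff = path, sidecar = sidecar))
}

#' @rdname write_stack
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar))
    stop("missing spacing metadata: sidecar file not found: ", sidecar,
         call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$spacing_um) || length(meta$spacing_um) != 3L)
    stop("sidecar does not provide spacing_um (z, y, x)", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape)
  chans <- as.character(meta$channels)
  if (length(pages) != d[1] * length(chans))
    stop("TIFF page count does not match sidecar shape/channels", call. = FALSE)
  scale <- if (is.null(meta$scale)) .TIFF_SCALE else meta$scale
  channels <- list()
  p <- 0L
  for (ch in chans) {
    vol <- array(0, dim = d)
    for (z in seq_len(d[1])) {
      p <- p + 1L
      vol[z, , ] <- round(pages[[p]] * scale)
    }
    channels[[ch]] <- vol
  }
  channel_stack(channels, meta$spacing_um, source = path)
}

#' Write and read 2D nuclear masks as TIFF plus JSON sidecar
#'
#' Nucleus labels are stored verbatim as 16-bit pixel values.
#'
#' @param mask A [nuclear_mask()].
#' @param path TIFF path; JSON sidecar at `<path>.json`.
#' @param sidecar Sidecar path.
#' @return `write_mask()` returns the paths invisibly; `read_mask()` a
#'   [nuclear_mask()].
#' @export
write_mask <- function(mask, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(mask, "nuclear_mask"))
  tiff::writeTIFF(mask$labels / .TIFF_SCALE, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(spacing_um = mask$spacing,
                            shape = as.integer(dim(mask$labels))),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(c(tiff = path, sidecar = sidecar))
}

#' @rdname write_mask
#' @export
read_mask <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar))
    stop("missing spacing metadata: sidecar file not found: ", sidecar,
         call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  nuclear_mask(round(img * .TIFF_SCALE), meta$spacing_um)
}

# stable column orders for the three result tables
.FOCI_COLS <- c("focus_id", "channel", "nucleus_id", "voxel_count",
                "volume_um3", "centroid_z_um", "centroid_y_um",
                "centroid_x_um", "integrated_intensity", "mean_intensity")
.EVENT_COLS <- c("event_id", "nucleus_id", "type", "n_foci",
                 "edu_focus_ids", "dutp_focus_ids")
.SUMMARY_COLS <- c("nucleus_id", "n_single_colour", "n_ongoing",
                   "n_initiation", "n_termination", "n_crowded", "n_dual",
                   "rel_freq_initiation", "rel_freq_ongoing",
                   "rel_freq_termination", "retention",
                   "median_centroid_distance_um", "median_overlap_ratio",
                   "median_angle_deg")

#' Write foci, event and nucleus-summary tables as CSV
#'
#' Files have a stable column order and round-trip losslessly: integers
#' exactly, doubles to better than 1e-9 (15 significant digits are written).
#' Event member ids are checked against the foci table.
#'
#' @param foci Data frame of per-focus properties ([compute_focus_props()]).
#' @param events Data frame of classified events ([classify_events()]).
#' @param summaries Data frame of per-nucleus summaries
#'   ([summarise_nucleus()]).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the written paths.
#' @export
write_tables <- function(foci, events, summaries, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  check_event_ids(foci, events)
  paths <- c(foci = file.path(out_dir, "foci.csv"),
             events = file.path(out_dir, "events.csv"),
             summaries = file.path(out_dir, "summaries.csv"))
  write_table_csv(as_cols(foci, .FOCI_COLS), paths[["foci"]])
  write_table_csv(as_cols(events, .EVENT_COLS), paths[["events"]])
  write_table_csv(as_cols(summaries, .SUMMARY_COLS), paths[["summaries"]])
  paths
}

#' @rdname write_tables
#' @export
read_tables <- function(out_dir) {
  list(foci = utils::read.csv(file.path(out_dir, "foci.csv")),
       events = utils::read.csv(file.path(out_dir, "events.csv")),
       summaries = utils::read.csv(file.path(out_dir, "summaries.csv")))
}

as_cols <- function(df, cols) {
  if (is.null(df) || nrow(df) == 0L) {
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  missing <- setdiff(cols, names(df))
  for (m in missing) df[[m]] <- NA
  df[, cols, drop = FALSE]
}

write_table_csv <- function(df, path) {
  # 15 significant digits: enough for 1e-9 round-trips, stable across rewrites
  for (j in seq_along(df))
    if (is.double(df[[j]])) {
      v <- df[[j]]
      df[[j]] <- ifelse(is.na(v), "NA", sprintf("%.15g", v))
    }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

check_event_ids <- function(foci, events) {
  if (is.null(events) || nrow(events) == 0L) return(invisible(TRUE))
  have <- paste(foci$channel, foci$focus_id)
  split_ids <- function(s) {
    s <- as.character(s)
    s <- s[!is.na(s) & nzchar(s)]
    if (!length(s)) return(integer(0))
    as.integer(unlist(strsplit(s, ";", fixed = TRUE)))
  }
  want <- c(paste("EdU", split_ids(events$edu_focus_ids)),
            paste("dUTP", split_ids(events$dutp_focus_ids)))
  # channel names in tables are normalised to EdU/dUTP roles
  missing <- setdiff(want, have)
  if (length(missing))
    stop("event member foci absent from foci table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
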