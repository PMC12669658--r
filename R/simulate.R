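#' Simulation configuration for synthetic dual-channel nuclei
#'
#' Parameterises the synthetic early-S-phase nucleus: an elliptical 2D
#' nuclear mask, a slab of allowed z positions, and a mixture of planted
#' replication events (single-colour, ongoing, initiation, termination,
#' crowded) rendered as isotropic 3D Gaussian foci on an anisotropic voxel
#' grid with Poisson photon noise and Gaussian camera read noise.
#'
#' Defaults emulate a 3D-SIM-like acquisition: 50 nm lateral pixels with a
#' 125 nm z step, foci of 125 nm Gaussian SD, peak amplitude 200 photons over
#' a 20-photon background (peak SNR about 13), event separation 0.3 um and an
#' inter-event gap of at least 6 focus SDs so that planted events are
#' resolvable.
#'
#' @param grid_shape Integer (nz, ny, nx) voxel grid.
#' @param voxel_spacing Micrometres per voxel (z, y, x).
#' @param nucleus_semiaxes Micrometres, named or ordered (y, x, z): ellipse
#'   semiaxes in y and x for the 2D mask, and the half-thickness of the z slab
#'   (centred mid-stack) in which foci are planted.
#' @param n_events Number of planted events.
#' @param event_mixture Probabilities over the event types `single_A`
#'   (EdU-only), `single_B` (dUTP-only), `ongoing`, `initiation`,
#'   `termination`, `crowded`; must sum to 1.
#' @param separation_mean,separation_sd Centre-to-flank centroid offset
#'   between paired foci, micrometres (normal, truncated at
#'   `separation_mean / 3`).
#' @param angle_range Degrees, length 2: the inter-dUTP angle of initiation
#'   events (and inter-EdU angle of terminations) is drawn uniformly from
#'   this interval.
#' @param focus_sigma Gaussian SD of a rendered focus, micrometres
#'   (isotropic in physical space).
#' @param amplitude Peak signal of one focus, photons.
#' @param background Uniform background, photons.
#' @param gaussian_read_noise_sd Camera read noise SD, photons.
#' @param min_event_gap Minimum distance between blobs of different events,
#'   micrometres.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(32L, 448L, 448L),
                       voxel_spacing = c(0.125, 0.05, 0.05),
                       nucleus_semiaxes = c(y = 10.5, x = 10.5, z = 1.5),
                       n_events = 500L,
                       event_mixture = c(single_A = 0, single_B = 0,
                                         ongoing = 0.8, initiation = 0.1,
                                         termination = 0.1, crowded = 0),
                       separation_mean = 0.3,
                       separation_sd = 0.05,
                       angle_range = c(90, 180),
                       focus_sigma = 0.125,
                       amplitude = 200,
                       background = 20,
                       gaussian_read_noise_sd = 2,
                       min_event_gap = 0.75,
                       seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              nucleus_semiaxes = as.numeric(nucleus_semiaxes),
              n_events = as.integer(n_events),
              event_mixture = event_mixture,
              separation_mean = separation_mean,
              separation_sd = separation_sd,
              angle_range = as.numeric(angle_range),
              focus_sigma = focus_sigma,
              amplitude = amplitude,
              background = background,
              gaussian_read_noise_sd = gaussian_read_noise_sd,
              min_event_gap = min_event_gap,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.EVENT_TYPES <- c("single_A", "single_B", "ongoing", "initiation",
                  "termination", "crowded")

validate_sim_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    stop("grid_shape must be 3 positive integers (nz, ny, nx)", call. = FALSE)
  if (length(cfg$voxel_spacing) != 3L || any(cfg$voxel_spacing <= 0))
    stop("voxel_spacing must be 3 positive values (z, y, x)", call. = FALSE)
  if (length(cfg$nucleus_semiaxes) != 3L || any(cfg$nucleus_semiaxes <= 0))
    stop("nucleus_semiaxes must be 3 positive values (y, x, z)", call. = FALSE)
  mix <- cfg$event_mixture
  if (is.null(names(mix)) || !setequal(names(mix), .EVENT_TYPES))
    stop("event_mixture must be named with exactly the types ",
         paste(.EVENT_TYPES, collapse = ", "), call. = FALSE)
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("event_mixture probabilities must be non-negative and sum to 1",
         call. = FALSE)
  if (cfg$n_events < 0L) stop("n_events must be >= 0", call. = FALSE)
  for (p in c("separation_mean", "focus_sigma", "amplitude", "min_event_gap"))
    if (cfg[[p]] <= 0) stop(p, " must be > 0", call. = FALSE)
  for (p in c("separation_sd", "background", "gaussian_read_noise_sd"))
    if (cfg[[p]] < 0) stop(p, " must be >= 0", call. = FALSE)
  if (length(cfg$angle_range) != 2L || cfg$angle_range[1] <= 0 ||
      cfg$angle_range[2] > 180 || cfg$angle_range[1] > cfg$angle_range[2])
    stop("angle_range must lie within (0, 180] with min <= max", call. = FALSE)
  invisible(cfg)
}

# run code with a private RNG stream, restoring the caller's state
with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-9) return(v / n)
  }
}

orthogonal_unit <- function(v) {
  repeat {
    r <- stats::rnorm(3)
    w <- r - sum(r * v) * v
    n <- sqrt(sum(w^2))
    if (n > 1e-9) return(w / n)
  }
}

planted_event <- function(type, blobs, separation = NA_real_,
                          angle = NA_real_) {
  structure(list(event_id = NA_integer_, true_type = type, blobs = blobs,
                 true_separation = separation, true_angle = angle),
            class = "planted_event")
}

blob_df <- function(channel, pos) {
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = 3, byrow = TRUE)
  data.frame(channel = channel, z_um = pos[, 1], y_um = pos[, 2],
             x_um = pos[, 3])
}

#' Plant a single initiation event
#'
#' An initiation event is one EdU focus with two flanking dUTP foci: both
#' flanks sit at `separation` micrometres from the centre, with the given
#' angle between the two centre-to-flank vectors (bidirectional origin firing
#' within the pulse window).
#'
#' @param centre Numeric length-3 (z, y, x) in micrometres.
#' @param separation Centre-to-flank distance, micrometres (> 0).
#' @param angle Inter-flank angle in degrees, in (0, 180].
#' @param dir Optional unit vector (z, y, x): the bisector of the two flank
#'   directions. Random if `NULL`.
#' @param ortho Optional unit vector orthogonal to `dir` spanning the event
#'   plane. Random if `NULL`.
#' @return A `planted_event` with one EdU blob and two dUTP blobs.
#' @export
plant_initiation <- function(centre, separation, angle, dir = NULL,
                             ortho = NULL) {
  if (!is.numeric(separation) || separation <= 0)
    stop("separation must be > 0", call. = FALSE)
  if (!is.numeric(angle) || angle <= 0 || angle > 180)
    stop("angle must lie in (0, 180] degrees", call. = FALSE)
  if (is.null(dir)) dir <- unit_vector()
  if (is.null(ortho)) ortho <- orthogonal_unit(dir)
  half <- angle * pi / 360
  v1 <- cos(half) * dir + sin(half) * ortho
  v2 <- cos(half) * dir - sin(half) * ortho
  blobs <- rbind(blob_df("EdU", centre),
                 blob_df("dUTP", c(centre + separation * v1,
                                   centre + separation * v2)))
  planted_event("initiation", blobs, separation, angle)
}

#' @rdname plant_initiation
#' @details `plant_termination()` is the mirror image: one dUTP focus with
#'   two flanking EdU foci (converging forks).
#' @export
plant_termination <- function(centre, separation, angle, dir = NULL,
                              ortho = NULL) {
  ev <- plant_initiation(centre, separation, angle, dir, ortho)
  ev$blobs$channel <- c("dUTP", "EdU", "EdU")
  ev$true_type <- "termination"
  ev
}

plant_ongoing <- function(centre, separation, dir = NULL) {
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  if (is.null(dir)) dir <- unit_vector()
  blobs <- rbind(blob_df("EdU", centre - dir * separation / 2),
                 blob_df("dUTP", centre + dir * separation / 2))
  planted_event("ongoing", blobs, separation)
}

plant_single <- function(centre, channel) {
  planted_event(if (channel == "EdU") "single_A" else "single_B",
                blob_df(channel, centre))
}

# >= 4 mutually overlapping blobs: two same-channel pairs on orthogonal axes,
# so every cross-channel pair overlaps and the component has 4 foci
plant_crowded <- function(centre, separation, dir = NULL, ortho = NULL) {
  if (is.null(dir)) dir <- unit_vector()
  if (is.null(ortho)) ortho <- orthogonal_unit(dir)
  r <- 0.75 * separation
  blobs <- rbind(blob_df("EdU", c(centre - r * dir, centre + r * dir)),
                 blob_df("dUTP", c(centre - r * ortho, centre + r * ortho)))
  planted_event("crowded", blobs, separation)
}

draw_separation <- function(cfg) {
  s <- stats::rnorm(1, cfg$separation_mean, cfg$separation_sd)
  max(s, cfg$separation_mean / 3)
}

draw_angle <- function(cfg) {
  if (cfg$angle_range[1] == cfg$angle_range[2]) return(cfg$angle_range[1])
  stats::runif(1, cfg$angle_range[1], cfg$angle_range[2])
}

plant_event_of_type <- function(type, centre, cfg) {
  switch(type,
         single_A = plant_single(centre, "EdU"),
         single_B = plant_single(centre, "dUTP"),
         ongoing = plant_ongoing(centre, draw_separation(cfg)),
         initiation = plant_initiation(centre, draw_separation(cfg),
                                       draw_angle(cfg)),
         termination = plant_termination(centre, draw_separation(cfg),
                                         draw_angle(cfg)),
         crowded = plant_crowded(centre, draw_separation(cfg)),
         stop("unknown event type: ", type, call. = FALSE))
}

#' Simulate a synthetic dual-channel nucleus with planted events
#'
#' Generates an elliptical 2D nuclear mask, plants `n_events` ground-truth
#' replication events inside it by bounded rejection sampling (blobs of
#' different events at least `min_event_gap` apart; at most
#' `10 * n_events` placement attempts, exceeding them is an explicit error),
#' renders every blob as an isotropic 3D Gaussian of SD `focus_sigma`
#' sampled on the anisotropic voxel grid, and corrupts the photon signal with
#' Poisson noise plus additive Gaussian read noise, rounded to integer camera
#' counts.
#'
#' @param config A [sim_config()].
#' @param render If `FALSE`, skip rendering the intensity stack (ground truth
#'   and mask only); used for fast placement-level checks.
#' @return A list of class `spark_simulation`: `stack` (a [channel_stack()]
#'   with channels `EdU` and `dUTP`, or `NULL` when `render = FALSE`),
#'   `mask` (a [nuclear_mask()]), and `truth` (list with `events`, a
#'   `blobs` data frame of one row per planted blob, and the echoed
#'   `config`).
#' @export
simulate_nucleus <- function(config, render = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    d <- config$grid_shape
    sp <- config$voxel_spacing
    ax <- config$nucleus_semiaxes   # (y, x, z-half)
    centre_yx <- c((d[2] - 1) / 2 * sp[2], (d[3] - 1) / 2 * sp[3])
    centre_z <- (d[1] - 1) / 2 * sp[1]
    margin <- 3 * config$focus_sigma
    if (ax[1] - margin <= 0 || ax[2] - margin <= 0)
      stop("nucleus semiaxes too small for the focus size", call. = FALSE)
    if (centre_z - ax[3] < margin || centre_z + ax[3] > (d[1] - 1) * sp[1] - margin)
      stop("z slab does not fit inside the stack with a 3 sigma margin",
           call. = FALSE)

    mask <- nuclear_mask(ellipse_mask(d[2:3], sp[2:3], centre_yx, ax[1:2]),
                         sp[2:3])

    events <- list()
    placed <- matrix(numeric(0), ncol = 3)  # all blob positions so far
    if (config$n_events > 0L) {
      types <- sample(.EVENT_TYPES, config$n_events, replace = TRUE,
                      prob = config$event_mixture)
      max_attempts <- 10L * config$n_events
      attempts <- 0L
      for (i in seq_len(config$n_events)) {
        repeat {
          attempts <- attempts + 1L
          if (attempts > max_attempts)
            stop(sprintf(paste0("placement failure: could not place %d events",
                                " with min_event_gap %.3g um in %d attempts"),
                         config$n_events, config$min_event_gap, max_attempts),
                 call. = FALSE)
          anchor <- c(stats::runif(1, centre_z - ax[3], centre_z + ax[3]),
                      sample_in_ellipse(centre_yx, ax[1:2] - margin))
          ev <- plant_event_of_type(types[i], anchor, config)
          pos <- as.matrix(ev$blobs[, c("z_um", "y_um", "x_um")])
          if (!blobs_admissible(pos, centre_yx, ax, centre_z, margin,
                                placed, config$min_event_gap)) next
          ev$event_id <- i
          events[[i]] <- ev
          placed <- rbind(placed, pos)
          break
        }
      }
    }

    blobs <- truth_blob_table(events, config)
    stack <- if (render) render_stack(events, config) else NULL
    structure(list(stack = stack, mask = mask,
                   truth = list(events = events, blobs = blobs,
                                config = config)),
              class = "spark_simulation")
  })
}

ellipse_mask <- function(shape_yx, spacing_yx, centre_yx, semiaxes_yx) {
  y <- ((seq_len(shape_yx[1]) - 1) * spacing_yx[1] - centre_yx[1]) / semiaxes_yx[1]
  x <- ((seq_len(shape_yx[2]) - 1) * spacing_yx[2] - centre_yx[2]) / semiaxes_yx[2]
  m <- outer(y^2, x^2, `+`) <= 1
  matrix(as.integer(m), nrow = shape_yx[1])
}

sample_in_ellipse <- function(centre_yx, semiaxes_yx) {
  repeat {
    p <- stats::runif(2, -1, 1)
    if (sum(p^2) <= 1) return(centre_yx + p * semiaxes_yx)
  }
}

blobs_admissible <- function(pos, centre_yx, ax, centre_z, margin, placed,
                             gap) {
  inside <- ((pos[, 2] - centre_yx[1]) / (ax[1] - margin))^2 +
    ((pos[, 3] - centre_yx[2]) / (ax[2] - margin))^2 <= 1 &
    abs(pos[, 1] - centre_z) <= ax[3]
  if (!all(inside)) return(FALSE)
  if (nrow(placed) == 0L) return(TRUE)
  for (b in seq_len(nrow(pos))) {
    d2 <- (placed[, 1] - pos[b, 1])^2 + (placed[, 2] - pos[b, 2])^2 +
      (placed[, 3] - pos[b, 3])^2
    if (any(d2 < gap^2)) return(FALSE)
  }
  TRUE
}

truth_blob_table <- function(events, config) {
  if (!length(events)) {
    return(data.frame(event_id = integer(0), true_type = character(0),
                      channel = character(0), z_um = double(0),
                      y_um = double(0), x_um = double(0),
                      true_separation = double(0), true_angle = double(0),
                      true_halfmax_voxels = double(0)))
  }
  rows <- lapply(events, function(ev) {
    cbind(data.frame(event_id = ev$event_id, true_type = ev$true_type),
          ev$blobs,
          data.frame(true_separation = ev$true_separation,
                     true_angle = ev$true_angle))
  })
  out <- do.call(rbind, rows)
  # analytic count of voxels above half maximum for one isolated blob
  r <- config$focus_sigma * sqrt(2 * log(2))
  out$true_halfmax_voxels <- (4 / 3) * pi * r^3 / prod(config$voxel_spacing)
  rownames(out) <- NULL
  out
}

render_stack <- function(events, config) {
  d <- config$grid_shape
  sp <- config$voxel_spacing
  channels <- list()
  for (ch in c("EdU", "dUTP")) {
    sig <- array(0, dim = d)
    idx_parts <- list(); val_parts <- list()
    for (ev in events) {
      sel <- which(ev$blobs$channel == ch)
      for (b in sel) {
        gb <- gaussian_blob_values(
          d, sp, c(ev$blobs$z_um[b], ev$blobs$y_um[b], ev$blobs$x_um[b]),
          config$focus_sigma, config$amplitude)
        idx_parts[[length(idx_parts) + 1L]] <- gb$idx
        val_parts[[length(val_parts) + 1L]] <- gb$val
      }
    }
    if (length(idx_parts)) {
      idx <- unlist(idx_parts, use.names = FALSE)
      val <- unlist(val_parts, use.names = FALSE)
      # overlapping windows sum: aggregate values per voxel first
      sums <- rowsum(val, idx)
      sig[as.integer(rownames(sums))] <- sums[, 1]
    }
    lambda <- sig + config$background
    counts <- stats::rpois(length(lambda), lambda) +
      stats::rnorm(length(lambda), 0, config$gaussian_read_noise_sd)
    channels[[ch]] <- array(round(pmin(pmax(counts, 0), 65535)), dim = d)
  }
  channel_stack(channels, sp)
}

# amplitude * exp(-r^2 / (2 sigma^2)) within a 4 sigma window, as linear
# indices into the (nz, ny, nx) array plus values
gaussian_blob_values <- function(d, spacing, centre_um, sigma, amplitude) {
  ctr_vox <- centre_um / spacing                 # 0-based fractional index
  r_vox <- ceiling(4 * sigma / spacing)
  lo <- pmax(floor(ctr_vox) - r_vox, 0)
  hi <- pmin(ceiling(ctr_vox) + r_vox, d - 1)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  gz <- exp(-((iz * spacing[1] - centre_um[1])^2) / (2 * sigma^2))
  gy <- exp(-((iy * spacing[2] - centre_um[2])^2) / (2 * sigma^2))
  gx <- exp(-((ix * spacing[3] - centre_um[3])^2) / (2 * sigma^2))
  val <- amplitude * as.vector(gz %o% gy %o% gx)
  idx1 <- outer(iz, iy * d[1], `+`)
  idx <- as.vector(outer(as.vector(idx1), ix * (d[1] * d[2]), `+`)) + 1
  list(idx = idx, val = val)
}

#' Write a simulation to disk
#'
#' Writes the intensity stack as a multi-page TIFF with JSON sidecar, the
#' nuclear mask likewise, the planted blobs as `truth_blobs.csv` (one row per
#' blob), the planted events as `truth_events.csv` (one row per event) and
#' the configuration as `sim_config.yaml`.
#'
#' @param sim A `spark_simulation` from [simulate_nucleus()].
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of written paths.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "spark_simulation"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stack = file.path(out_dir, "stack.tif"),
             mask = file.path(out_dir, "mask.tif"),
             blobs = file.path(out_dir, "truth_blobs.csv"),
             events = file.path(out_dir, "truth_events.csv"),
             config = file.path(out_dir, "sim_config.yaml"))
  if (!is.null(sim$stack)) write_stack(sim$stack, paths[["stack"]])
  write_mask(sim$mask, paths[["mask"]])
  write_table_csv(sim$truth$blobs, paths[["blobs"]])
  evs <- sim$truth$events
  ev_df <- if (length(evs)) {
    data.frame(event_id = vapply(evs, `[[`, 1L, "event_id"),
               true_type = vapply(evs, `[[`, "", "true_type"),
               n_blobs = vapply(evs, function(e) nrow(e$blobs), 1L),
               true_separation = vapply(evs, `[[`, 1.0, "true_separation"),
               true_angle = vapply(evs, `[[`, 1.0, "true_angle"))
  } else {
    data.frame(event_id = integer(0), true_type = character(0),
               n_blobs = integer(0), true_separation = double(0),
               true_angle = double(0))
  }
  write_table_csv(ev_df, paths[["events"]])
  cfg <- unclass(sim$truth$config)
  cfg$event_mixture <- as.list(cfg$event_mixture)
  yaml::write_yaml(cfg, paths[["config"]])
  paths
}
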