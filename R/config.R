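#' Analysis configuration
#'
#' Bundles the constants of the nanofocus analysis workflow. The defaults are
#' the curation rules used throughout: foci smaller than 50 voxels are
#' discarded, inter-channel overlaps are kept only when they exceed 20% of the
#' largest overlap of each participating focus, and connected components with
#' more than 3 foci are classified as crowded.
#'
#' @param min_voxels Minimum focus size in voxels; smaller objects are
#'   discarded (strict less-than). Default 50.
#' @param overlap_rel_threshold Relative overlap cutoff: an overlap is retained
#'   when it is strictly greater than this fraction of the maximum overlap of a
#'   focus. Default 0.20.
#' @param max_foci_per_event Components with more foci than this are labelled
#'   crowded. Default 3.
#' @param blur_sigma Gaussian blur SD in micrometres used before thresholding.
#'   `NULL` means one isotropic voxel, resolved at segmentation time.
#' @param spot_sigma Gaussian SD in micrometres of the spot-detection scale
#'   (local maxima are found on the volume blurred at this scale). `NULL`
#'   means one isotropic voxel.
#' @param channel_edu,channel_dutp Names of the first-pulse (EdU) and
#'   second-pulse (dUTP) channels in the stack.
#' @param overlap_rule `"and"` (default) keeps an overlap only if it passes the
#'   relative cutoff from the perspective of both foci; `"or"` keeps it if it
#'   passes for either.
#' @param periphery_mode Distance-to-periphery mode; only `"2d"` (distance
#'   transform of the 2D nuclear mask) is implemented.
#' @param fibre_rate_kbp_per_um Fibre extension rate converting stretched-fibre
#'   track length to DNA length, in kbp per micrometre. Default 2.59.
#'
#' @return An object of class `spark_config` (a validated list).
#' @seealso [read_analysis_config()], [classify_events()], [filter_small()]
#' @export
spark_config <- function(min_voxels = 50L,
                         overlap_rel_threshold = 0.20,
                         max_foci_per_event = 3L,
                         blur_sigma = NULL,
                         spot_sigma = NULL,
                         channel_edu = "EdU",
                         channel_dutp = "dUTP",
                         overlap_rule = c("and", "or"),
                         periphery_mode = "2d",
                         fibre_rate_kbp_per_um = 2.59) {
  overlap_rule <- match.arg(overlap_rule)
  cfg <- list(
    min_voxels = as.integer(min_voxels),
    overlap_rel_threshold = overlap_rel_threshold,
    max_foci_per_event = as.integer(max_foci_per_event),
    blur_sigma = blur_sigma,
    spot_sigma = spot_sigma,
    channel_edu = channel_edu,
    channel_dutp = channel_dutp,
    overlap_rule = overlap_rule,
    periphery_mode = periphery_mode,
    fibre_rate_kbp_per_um = fibre_rate_kbp_per_um
  )
  validate_spark_config(cfg)
  class(cfg) <- "spark_config"
  cfg
}

validate_spark_config <- function(cfg) {
  if (cfg$min_voxels < 1L)
    stop("min_voxels must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$overlap_rel_threshold) ||
      cfg$overlap_rel_threshold <= 0 || cfg$overlap_rel_threshold >= 1)
    stop("overlap_rel_threshold must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$max_foci_per_event < 1L)
    stop("max_foci_per_event must be >= 1", call. = FALSE)
  for (s in c("blur_sigma", "spot_sigma")) {
    if (!is.null(cfg[[s]]) && (!is.numeric(cfg[[s]]) || cfg[[s]] <= 0))
      stop(s, " must be a positive number (micrometres) or NULL", call. = FALSE)
  }
  if (identical(cfg$channel_edu, cfg$channel_dutp))
    stop("channel_edu and channel_dutp must differ", call. = FALSE)
  if (!identical(cfg$periphery_mode, "2d"))
    stop("only periphery_mode = '2d' is supported", call. = FALSE)
  if (!is.numeric(cfg$fibre_rate_kbp_per_um) || cfg$fibre_rate_kbp_per_um <= 0)
    stop("fibre_rate_kbp_per_um must be positive", call. = FALSE)
  invisible(cfg)
}

#' Read or write an analysis configuration as YAML
#'
#' The file is a flat YAML mapping; missing keys fall back to the defaults of
#' [spark_config()], unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @param config A `spark_config` object.
#' @return `read_analysis_config()` returns a `spark_config`;
#'   `write_analysis_config()` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(spark_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(spark_config, vals)
}

#' @rdname read_analysis_config
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "spark_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.spark_config <- function(x, ...) {
  cat("<spark_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "(1 isotropic voxel)" else format(v)))
  }
  invisible(x)
}
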