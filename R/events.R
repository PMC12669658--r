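#' Exact voxel overlaps between two label volumes
#'
#' One record per pair of labels (one from each channel) sharing at least one
#' voxel, with the exact shared voxel count and, after scoring, the overlap
#' size relative to the largest overlap of each participating focus.
#'
#' @param labels_edu,labels_dutp [label_volume()]s of the EdU and dUTP
#'   channels; must share shape.
#' @return Data frame with columns `focus_a` (EdU label), `focus_b` (dUTP
#'   label) and `overlap_voxels`; zero rows when the label sets are disjoint.
#' @export
compute_overlaps <- function(labels_edu, labels_dutp) {
  stopifnot(inherits(labels_edu, "label_volume"),
            inherits(labels_dutp, "label_volume"))
  if (!identical(dim(labels_edu$labels), dim(labels_dutp$labels)))
    stop("label volumes must share shape", call. = FALSE)
  df <- cpp_pair_overlaps(labels_edu$labels, labels_dutp$labels)
  names(df) <- c("focus_a", "focus_b", "overlap_voxels")
  df
}

#' Select overlaps by the relative-size rule
#'
#' For each focus, its largest overlap is found; an overlap scores
#' `rel = overlap / max overlap` from that focus's perspective, and ties for
#' the maximum all score 1. An overlap is kept when its relative score is
#' strictly greater than `rel_threshold` (default 0.20), evaluated under
#' `rule = "and"` from the perspective of both participating foci, or under
#' `rule = "or"` from either. This prioritises the key overlaps of each focus
#' in crowded neighbourhoods; a focus's only overlap is always kept.
#'
#' @param records Data frame from [compute_overlaps()].
#' @param rel_threshold Relative cutoff in (0, 1); strict greater-than.
#' @param rule `"and"` (default, symmetric) or `"or"`.
#' @return `records` with added columns `rel_score_a`, `rel_score_b` and
#'   logical `kept`.
#' @export
select_overlaps <- function(records, rel_threshold = 0.20,
                            rule = c("and", "or")) {
  rule <- match.arg(rule)
  if (nrow(records) == 0L) {
    records$rel_score_a <- double(0)
    records$rel_score_b <- double(0)
    records$kept <- logical(0)
    return(records)
  }
  max_a <- tapply(records$overlap_voxels, records$focus_a, max)
  max_b <- tapply(records$overlap_voxels, records$focus_b, max)
  records$rel_score_a <- records$overlap_voxels /
    as.numeric(max_a[as.character(records$focus_a)])
  records$rel_score_b <- records$overlap_voxels /
    as.numeric(max_b[as.character(records$focus_b)])
  pass_a <- records$rel_score_a > rel_threshold
  pass_b <- records$rel_score_b > rel_threshold
  records$kept <- if (rule == "and") pass_a & pass_b else pass_a | pass_b
  records
}

#' Connected components of the bipartite focus-overlap graph
#'
#' Foci are nodes (both channels), kept overlaps are edges; isolated foci are
#' their own components.
#'
#' @param edu_ids,dutp_ids Integer focus ids present in each channel.
#' @param records Data frame with `focus_a`, `focus_b` and logical `kept`
#'   (from [select_overlaps()]); only kept rows become edges.
#' @return List of components; each component is a list with `edu_ids`,
#'   `dutp_ids` and `edges` (data frame `focus_a`, `focus_b`).
#' @export
build_components <- function(edu_ids, dutp_ids, records) {
  edges <- records[isTRUE_vec(records$kept), c("focus_a", "focus_b"),
                   drop = FALSE]
  if (nrow(edges)) {
    if (!all(edges$focus_a %in% edu_ids) || !all(edges$focus_b %in% dutp_ids))
      stop("overlap records reference foci absent from the id lists",
           call. = FALSE)
  }
  verts <- c(sprintf("E%d", edu_ids), sprintf("D%d", dutp_ids))
  if (!length(verts)) return(list())
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(verts)
  if (nrow(edges))
    g <- g + igraph::edges(rbind(sprintf("E%d", edges$focus_a),
                                 sprintf("D%d", edges$focus_b)))
  memb <- igraph::components(g)$membership
  out <- vector("list", max(memb))
  for (ci in seq_len(max(memb))) {
    vs <- names(memb)[memb == ci]
    e_ids <- as.integer(sub("^E", "", vs[startsWith(vs, "E")]))
    d_ids <- as.integer(sub("^D", "", vs[startsWith(vs, "D")]))
    comp_edges <- edges[edges$focus_a %in% e_ids & edges$focus_b %in% d_ids, ,
                        drop = FALSE]
    rownames(comp_edges) <- NULL
    out[[ci]] <- list(edu_ids = sort(e_ids), dutp_ids = sort(d_ids),
                      edges = comp_edges)
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Classify one overlap component into the replication-event taxonomy
#'
#' Exact mapping on the pruned overlap graph: an isolated focus is a
#' single-colour event; one EdU focus overlapping one dUTP focus is an
#' ongoing event (a single fork synthesising through both pulses); one EdU
#' focus overlapping two dUTP foci that overlap only that EdU focus is an
#' initiation event; two EdU foci overlapping one dUTP focus likewise is a
#' termination event; everything else, including any component of more than
#' `max_foci` foci, is crowded. Exclusivity is automatic on connected
#' components of the kept-edge graph.
#'
#' @param component One component from [build_components()].
#' @param max_foci Components with more foci than this are crowded
#'   (default 3).
#' @return One of `"single_colour"`, `"ongoing"`, `"initiation"`,
#'   `"termination"`, `"crowded"`.
#' @export
classify_component <- function(component, max_foci = 3L) {
  ne <- length(component$edu_ids)
  nd <- length(component$dutp_ids)
  nedge <- nrow(component$edges)
  if (ne + nd == 0L) stop("empty component", call. = FALSE)
  if (ne + nd > max_foci) return("crowded")
  if ((ne == 1L && nd == 0L) || (ne == 0L && nd == 1L))
    return("single_colour")
  if (ne == 1L && nd == 1L && nedge == 1L) return("ongoing")
  if (ne == 1L && nd == 2L && nedge == 2L) return("initiation")
  if (ne == 2L && nd == 1L && nedge == 2L) return("termination")
  "crowded"
}

#' Classify all foci of a field into replication events
#'
#' Runs the full event-building chain: relative-overlap selection
#' ([select_overlaps()]), bipartite connected components
#' ([build_components()]) and per-component classification
#' ([classify_component()]). Every retained focus lands in exactly one event.
#' The retention report gives, per nucleus, the fraction of detected foci
#' that end up in dual-colour (ongoing, initiation or termination) events —
#' the curated subset carried into kinetics inference.
#'
#' @param foci Combined focus table (both channels) as returned by
#'   [compute_focus_props()], with `channel` values `"EdU"` and `"dUTP"`.
#' @param records Overlap records from [compute_overlaps()].
#' @param config A [spark_config()] (relative threshold, rule, crowding
#'   cutoff).
#' @return List with `events` (data frame: `event_id`, `nucleus_id`, `type`,
#'   `n_foci`, `edu_focus_ids`, `dutp_focus_ids`, semicolon-separated),
#'   `records` (scored overlap records) and `retention` (data frame per
#'   nucleus: `nucleus_id`, `n_foci`, `n_retained`, `retention`).
#' @export
classify_events <- function(foci, records, config = spark_config()) {
  stopifnot(inherits(config, "spark_config"))
  edu_ids <- foci$focus_id[foci$channel == "EdU"]
  dutp_ids <- foci$focus_id[foci$channel == "dUTP"]
  records <- select_overlaps(records, config$overlap_rel_threshold,
                             config$overlap_rule)
  comps <- build_components(edu_ids, dutp_ids, records)
  nuc_of <- function(channel, ids) {
    foci$nucleus_id[match(paste(channel, ids), paste(foci$channel,
                                                     foci$focus_id))]
  }
  n <- length(comps)
  events <- data.frame(
    event_id = seq_len(n),
    nucleus_id = rep(NA_integer_, n),
    type = character(n),
    n_foci = integer(n),
    edu_focus_ids = character(n),
    dutp_focus_ids = character(n))
  for (i in seq_len(n)) {
    cp <- comps[[i]]
    events$type[i] <- classify_component(cp, config$max_foci_per_event)
    events$n_foci[i] <- length(cp$edu_ids) + length(cp$dutp_ids)
    events$edu_focus_ids[i] <- paste(cp$edu_ids, collapse = ";")
    events$dutp_focus_ids[i] <- paste(cp$dutp_ids, collapse = ";")
    nucs <- c(nuc_of("EdU", cp$edu_ids), nuc_of("dUTP", cp$dutp_ids))
    nucs <- nucs[!is.na(nucs)]
    if (length(nucs))
      events$nucleus_id[i] <- as.integer(names(which.max(table(nucs))))
  }
  retention <- retention_report(foci, events)
  list(events = events, records = records, retention = retention)
}

.DUAL_TYPES <- c("ongoing", "initiation", "termination")

retention_report <- function(foci, events) {
  nuclei <- sort(unique(foci$nucleus_id))
  if (!length(nuclei))
    return(data.frame(nucleus_id = integer(0), n_foci = integer(0),
                      n_retained = integer(0), retention = double(0)))
  n_ret <- setNames(integer(length(nuclei)), nuclei)
  dual <- events[events$type %in% .DUAL_TYPES, , drop = FALSE]
  for (i in seq_len(nrow(dual))) {
    nid <- as.character(dual$nucleus_id[i])
    if (nid %in% names(n_ret))
      n_ret[nid] <- n_ret[nid] + dual$n_foci[i]
  }
  n_foci <- as.integer(table(factor(foci$nucleus_id, levels = nuclei)))
  data.frame(nucleus_id = nuclei, n_foci = n_foci,
             n_retained = as.integer(n_ret),
             retention = as.integer(n_ret) / n_foci)
}

# parse "1;4;9" member-id strings back to integer vectors
split_focus_ids <- function(s) {
  s <- as.character(s)
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}
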