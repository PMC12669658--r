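# Fixtures are built in code; no binary test data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Gaussian-blob renderer (deliberately simple and loop-based, so
# it does not share code with the package's renderer)
render_blob_volume <- function(dim_zyx, spacing, centres_um, sigma,
                               amplitude = 100, background = 0) {
  vol <- array(background, dim = dim_zyx)
  z <- (seq_len(dim_zyx[1]) - 1) * spacing[1]
  y <- (seq_len(dim_zyx[2]) - 1) * spacing[2]
  x <- (seq_len(dim_zyx[3]) - 1) * spacing[3]
  if (!is.matrix(centres_um))
    centres_um <- matrix(centres_um, ncol = 3, byrow = TRUE)
  for (b in seq_len(nrow(centres_um))) {
    c0 <- centres_um[b, ]
    gz <- exp(-(z - c0[1])^2 / (2 * sigma^2))
    gy <- exp(-(y - c0[2])^2 / (2 * sigma^2))
    gx <- exp(-(x - c0[3])^2 / (2 * sigma^2))
    for (k in seq_len(dim_zyx[3]))
      vol[, , k] <- vol[, , k] + amplitude * gx[k] * (gz %o% gy)
  }
  vol
}

# label volume holding rectangular boxes of given voxel counts
box_label_volume <- function(dim_zyx, spacing, boxes, channel = "EdU") {
  lab <- array(0L, dim = dim_zyx)
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]  # list(z = a:b, y = a:b, x = a:b), 1-based
    lab[b$z, b$y, b$x] <- i
  }
  spark3d::label_volume(lab, spacing, channel)
}

# small scene used by several pipeline-level tests (about 3 s to analyse)
small_scene_config <- function(seed = 11, n_events = 40, ...) {
  spark3d::sim_config(grid_shape = c(20L, 192L, 192L),
                      nucleus_semiaxes = c(y = 4.2, x = 4.2, z = 0.8),
                      n_events = n_events, seed = seed, ...)
}

# brute-force union-find over an edge list (oracle for component building)
uf_components <- function(vertices, edges_from, edges_to) {
  parent <- setNames(vertices, vertices)
  find <- function(v) {
    while (parent[[v]] != v) v <- parent[[v]]
    v
  }
  for (i in seq_along(edges_from))
    parent[[find(edges_from[i])]] <- find(edges_to[i])
  vapply(vertices, find, "")
}

# literal rule checker for one bipartite overlap graph (oracle for
# classification): edges as a logical ne x nd adjacency matrix
classify_graph_oracle <- function(adj) {
  ne <- nrow(adj); nd <- ncol(adj)
  verts <- c(sprintf("E%d", seq_len(ne)), sprintf("D%d", seq_len(nd)))
  ef <- character(0); et <- character(0)
  for (i in seq_len(ne))
    for (j in seq_len(nd))
      if (adj[i, j]) {
        ef <- c(ef, sprintf("E%d", i))
        et <- c(et, sprintf("D%d", j))
      }
  comp <- uf_components(verts, ef, et)
  out <- character(0)
  for (root in unique(comp)) {
    vs <- names(comp)[comp == comp[[root]]]
    es <- grep("^E", vs, value = TRUE)
    ds <- grep("^D", vs, value = TRUE)
    n_edge <- 0
    for (i in seq_len(ne))
      for (j in seq_len(nd))
        if (adj[i, j] && sprintf("E%d", i) %in% es) n_edge <- n_edge + 1
    type <- if (length(es) + length(ds) == 1) "single_colour"
      else if (length(es) == 1 && length(ds) == 1 && n_edge == 1) "ongoing"
      else if (length(es) == 1 && length(ds) == 2 && n_edge == 2) "initiation"
      else if (length(es) == 2 && length(ds) == 1 && n_edge == 2) "termination"
      else "crowded"
    out[paste(sort(vs), collapse = ",")] <- type
  }
  out
}
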