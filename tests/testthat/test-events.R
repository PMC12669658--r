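make_lv <- function(arr, channel) label_volume(arr, 0.05, channel)

test_that("overlap records match brute-force per-voxel counting", {
  set.seed(7)
  for (rep in 1:5) {
    d <- c(6, 8, 8)
    a <- array(sample(0:3, prod(d), TRUE), d)
    b <- array(sample(0:3, prod(d), TRUE), d)
    rec <- compute_overlaps(make_lv(a, "EdU"), make_lv(b, "dUTP"))
    # oracle: exhaustive voxel loop
    oracle <- list()
    for (i in seq_len(prod(d))) {
      if (a[i] > 0 && b[i] > 0) {
        key <- paste(a[i], b[i])
        oracle[[key]] <- (oracle[[key]] %||% 0L) + 1L
      }
    }
    expect_identical(nrow(rec), length(oracle))
    for (r in seq_len(nrow(rec))) {
      key <- paste(rec$focus_a[r], rec$focus_b[r])
      expect_identical(rec$overlap_voxels[r], oracle[[key]])
    }
  }
})

test_that("disjoint and identical label sets give the expected records", {
  d <- c(4, 6, 6)
  a <- array(0L, d); a[1:2, 1:3, 1:3] <- 1L
  b <- array(0L, d); b[3:4, 4:6, 4:6] <- 1L
  expect_identical(nrow(compute_overlaps(make_lv(a, "EdU"),
                                         make_lv(b, "dUTP"))), 0L)
  ident <- array(0L, d); ident[1:4, 1:5, 1:5] <- 1L  # 100 voxels
  rec <- compute_overlaps(make_lv(ident, "EdU"), make_lv(ident, "dUTP"))
  expect_identical(rec$overlap_voxels, 100L)
})

test_that("relative-overlap selection keeps >20% of the per-focus maximum", {
  # one EdU focus with three partners of overlap 100, 25 and 10 voxels;
  # each partner has only this overlap, so its own relative score is 1
  rec <- data.frame(focus_a = c(1L, 1L, 1L), focus_b = c(1L, 2L, 3L),
                    overlap_voxels = c(100L, 25L, 10L))
  out <- select_overlaps(rec)
  expect_identical(out$kept, c(TRUE, TRUE, FALSE))
  expect_equal(out$rel_score_a, c(1, 0.25, 0.10))
  expect_equal(out$rel_score_b, c(1, 1, 1))
})

test_that("a focus's only overlap is always kept and exact 20% is dropped", {
  one <- select_overlaps(data.frame(focus_a = 1L, focus_b = 1L,
                                    overlap_voxels = 3L))
  expect_true(one$kept)
  expect_equal(one$rel_score_a, 1)
  # 20 is exactly 20% of 100: strict greater-than drops it
  rec <- data.frame(focus_a = c(1L, 1L), focus_b = c(1L, 2L),
                    overlap_voxels = c(100L, 20L))
  expect_identical(select_overlaps(rec)$kept, c(TRUE, FALSE))
})

test_that("ties for the maximum overlap both score 1 and are kept", {
  rec <- data.frame(focus_a = c(1L, 1L), focus_b = c(1L, 2L),
                    overlap_voxels = c(50L, 50L))
  out <- select_overlaps(rec)
  expect_equal(out$rel_score_a, c(1, 1))
  expect_identical(out$kept, c(TRUE, TRUE))
})

test_that("the OR rule keeps records the AND rule prunes", {
  # overlap 15 is 15% for focus_a (dropped from its view) but 100% for its
  # partner: OR keeps it, AND does not
  rec <- data.frame(focus_a = c(1L, 1L), focus_b = c(1L, 2L),
                    overlap_voxels = c(100L, 15L))
  expect_identical(select_overlaps(rec, rule = "and")$kept, c(TRUE, FALSE))
  expect_identical(select_overlaps(rec, rule = "or")$kept, c(TRUE, TRUE))
})

test_that("components match a union-find oracle on random bipartite graphs", {
  set.seed(11)
  for (rep in 1:20) {
    ne <- sample(0:5, 1); nd <- sample(0:5, 1)
    pairs <- expand.grid(a = seq_len(ne), b = seq_len(nd))
    take <- if (nrow(pairs)) pairs[runif(nrow(pairs)) < 0.3, ] else pairs
    rec <- data.frame(focus_a = as.integer(take$a),
                      focus_b = as.integer(take$b))
    rec$overlap_voxels <- rep(10L, nrow(rec))
    rec$kept <- rep(TRUE, nrow(rec))
    comps <- build_components(seq_len(ne), seq_len(nd), rec)
    verts <- c(sprintf("E%d", seq_len(ne)), sprintf("D%d", seq_len(nd)))
    if (!length(verts)) {
      expect_length(comps, 0L)
      next
    }
    oracle <- uf_components(verts, sprintf("E%d", rec$focus_a),
                            sprintf("D%d", rec$focus_b))
    expect_length(comps, length(unique(oracle)))
    # identical partitions: every component's vertex set appears in the oracle
    oracle_sets <- sort(vapply(split(names(oracle), oracle),
                               function(v) paste(sort(v), collapse = ","), ""))
    got_sets <- sort(vapply(comps, function(cp)
      paste(sort(c(sprintf("E%d", cp$edu_ids), sprintf("D%d", cp$dutp_ids))),
            collapse = ","), ""))
    expect_identical(unname(got_sets), unname(oracle_sets))
  }
})

test_that("isolated foci become singleton components", {
  comps <- build_components(1:3, 1:2,
                            data.frame(focus_a = integer(0),
                                       focus_b = integer(0),
                                       overlap_voxels = integer(0),
                                       kept = logical(0)))
  expect_length(comps, 5L)
  expect_true(all(vapply(comps, function(cp)
    length(cp$edu_ids) + length(cp$dutp_ids), 1L) == 1L))
})

test_that("component classification follows the event taxonomy exactly", {
  comp <- function(e, d, edges)
    list(edu_ids = e, dutp_ids = d,
         edges = data.frame(focus_a = edges[, 1], focus_b = edges[, 2]))
  no_edges <- matrix(integer(0), ncol = 2)
  expect_identical(classify_component(comp(1L, integer(0), no_edges)),
                   "single_colour")
  expect_identical(classify_component(comp(integer(0), 1L, no_edges)),
                   "single_colour")
  expect_identical(classify_component(comp(1L, 1L, cbind(1L, 1L))),
                   "ongoing")
  expect_identical(classify_component(comp(1L, 1:2, cbind(1L, 1:2))),
                   "initiation")
  expect_identical(classify_component(comp(1:2, 1L, cbind(1:2, 1L))),
                   "termination")
  # 4-focus chain E1-D1-E2-D2 is crowded (exceeds 3 foci)
  expect_identical(classify_component(
    comp(1:2, 1:2, rbind(c(1L, 1L), c(2L, 1L), c(2L, 2L)))), "crowded")
  expect_error(classify_component(comp(integer(0), integer(0), no_edges)),
               "empty")
})

test_that("all-isolated foci give zero retention", {
  foci <- data.frame(focus_id = c(1:2, 1:2),
                     channel = rep(c("EdU", "dUTP"), each = 2),
                     nucleus_id = 1L)
  cls <- classify_events(foci, data.frame(focus_a = integer(0),
                                          focus_b = integer(0),
                                          overlap_voxels = integer(0)))
  expect_true(all(cls$events$type == "single_colour"))
  expect_equal(cls$retention$retention, 0)
})

test_that("a scene of well-separated ongoing events retains every focus", {
  cfg <- small_scene_config(
    n_events = 30, seed = 17,
    event_mixture = c(single_A = 0, single_B = 0, ongoing = 1,
                      initiation = 0, termination = 0, crowded = 0))
  sim <- simulate_nucleus(cfg)
  run <- run_spark(sim$stack, sim$mask)
  expect_true(all(run$events$type == "ongoing"))
  expect_equal(run$retention$retention, 1.0)
})

test_that("swapping channels maps initiation to termination exactly", {
  cfg <- small_scene_config(n_events = 35, seed = 19,
                            event_mixture = c(single_A = 0.1, single_B = 0.1,
                                              ongoing = 0.4, initiation = 0.2,
                                              termination = 0.2, crowded = 0))
  sim <- simulate_nucleus(cfg)
  run <- run_spark(sim$stack, sim$mask)
  swapped <- channel_stack(list(EdU = sim$stack$channels$dUTP,
                                dUTP = sim$stack$channels$EdU),
                           sim$stack$spacing)
  run_sw <- run_spark(swapped, sim$mask)
  tab <- function(r) table(factor(r$events$type,
                                  levels = c("single_colour", "ongoing",
                                             "initiation", "termination",
                                             "crowded")))
  t1 <- tab(run); t2 <- tab(run_sw)
  expect_identical(t1[["initiation"]], t2[["termination"]])
  expect_identical(t1[["termination"]], t2[["initiation"]])
  expect_identical(t1[["ongoing"]], t2[["ongoing"]])
  expect_identical(t1[["single_colour"]], t2[["single_colour"]])
  expect_identical(t1[["crowded"]], t2[["crowded"]])
})

test_that("every retained focus lands in exactly one event", {
  sim <- simulate_nucleus(small_scene_config(n_events = 30, seed = 23))
  run <- run_spark(sim$stack, sim$mask)
  all_ids <- c()
  for (i in seq_len(nrow(run$events))) {
    ids <- c(paste("E", spark3d:::split_focus_ids(run$events$edu_focus_ids[i])),
             paste("D", spark3d:::split_focus_ids(run$events$dutp_focus_ids[i])))
    all_ids <- c(all_ids, ids)
  }
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_identical(length(all_ids), nrow(run$foci))
})
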