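fake_foci <- function(pos, channel, nucleus_id = 1L) {
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = 3, byrow = TRUE)
  data.frame(focus_id = seq_len(nrow(pos)), channel = channel,
             nucleus_id = nucleus_id, voxel_count = 60L,
             volume_um3 = 60 * 0.05^3, centroid_z_um = pos[, 1],
             centroid_y_um = pos[, 2], centroid_x_um = pos[, 3],
             integrated_intensity = 1, mean_intensity = 1)
}

ongoing_event <- data.frame(event_id = 1L, nucleus_id = 1L, type = "ongoing",
                            n_foci = 2L, edu_focus_ids = "1",
                            dutp_focus_ids = "1")

test_that("centroid distance is the physical Euclidean distance", {
  foci <- rbind(fake_foci(c(0, 0, 0), "EdU"), fake_foci(c(0, 3, 4), "dUTP"))
  expect_equal(centroid_distance(ongoing_event, foci), 5)
  coincident <- rbind(fake_foci(c(1, 1, 1), "EdU"),
                      fake_foci(c(1, 1, 1), "dUTP"))
  expect_equal(centroid_distance(ongoing_event, coincident), 0)
  bad <- ongoing_event; bad$type <- "initiation"
  expect_error(centroid_distance(bad, foci), "ongoing")
})

test_that("measured ongoing distances recover the planted separation", {
  cfg <- small_scene_config(
    n_events = 30, seed = 29, separation_mean = 0.3, separation_sd = 0,
    event_mixture = c(single_A = 0, single_B = 0, ongoing = 1,
                      initiation = 0, termination = 0, crowded = 0))
  sim <- simulate_nucleus(cfg)
  run <- run_spark(sim$stack, sim$mask)
  d <- run$metrics$centroid_distance_um[run$metrics$type == "ongoing"]
  expect_gt(length(d), 25)
  expect_true(all(abs(d - 0.3) < 0.05))  # within one voxel pitch
})

test_that("overlap ratio is intersection over union of member foci", {
  d <- c(5, 10, 10)
  a <- array(0L, d); a[1:2, 1:10, 1:5] <- 1L      # 100 voxels
  b <- array(0L, d); b[1:2, 1:10, 3:7] <- 1L      # 100 voxels, 60 shared
  lv_a <- label_volume(a, 0.05, "EdU"); lv_b <- label_volume(b, 0.05, "dUTP")
  expect_equal(overlap_ratio(ongoing_event, lv_a, lv_b), 60 / 140)
  expect_equal(overlap_ratio(ongoing_event, lv_a, lv_a), 1)
  single <- ongoing_event; single$type <- "single_colour"
  single$dutp_focus_ids <- ""
  expect_error(overlap_ratio(single, lv_a, lv_b), "dual-colour")
})

test_that("overlap ratio decreases and distance increases with separation", {
  # noise-free sweep of planted separation (fork-slowing signature mirrored)
  s <- 0.05; sigma <- 0.1
  seps <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  dist_m <- ratio_m <- numeric(length(seps))
  for (i in seq_along(seps)) {
    c1 <- c(0.5, 0.5, 0.5 - seps[i] / 2)
    c2 <- c(0.5, 0.5, 0.5 + seps[i] / 2)
    va <- render_blob_volume(c(21, 21, 25), rep(s, 3), c1, sigma)
    vb <- render_blob_volume(c(21, 21, 25), rep(s, 3), c2, sigma)
    la <- voronoi_otsu_segment(va, s, channel = "EdU")
    lb <- voronoi_otsu_segment(vb, s, channel = "dUTP")
    pa <- compute_focus_props(la, va); pa$channel <- "EdU"
    pb <- compute_focus_props(lb, vb); pb$channel <- "dUTP"
    dist_m[i] <- centroid_distance(ongoing_event, rbind(pa, pb))
    ratio_m[i] <- overlap_ratio(ongoing_event, la, lb)
  }
  expect_true(all(diff(dist_m) > 0))
  expect_true(all(diff(ratio_m) < 0))
})

test_that("initiation angles come from the clamped arccosine", {
  foci <- rbind(fake_foci(c(0, 0, 0), "EdU"),
                fake_foci(rbind(c(0, 1, 0), c(0, 0, 1)), "dUTP"))
  ev <- data.frame(event_id = 1L, nucleus_id = 1L, type = "initiation",
                   n_foci = 3L, edu_focus_ids = "1", dutp_focus_ids = "1;2")
  expect_equal(initiation_angle(ev, foci), 90)
  anti <- rbind(fake_foci(c(0, 0, 0), "EdU"),
                fake_foci(rbind(c(0, 1, 0), c(0, -1, 0)), "dUTP"))
  expect_equal(initiation_angle(ev, anti), 180)
  expect_equal(vector_angle(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_error(vector_angle(c(0, 0, 0), c(0, 1, 0)), "zero-length")
  # termination measures from the dUTP centre
  tfoci <- rbind(fake_foci(rbind(c(0, 1, 0), c(0, 0, 1)), "EdU"),
                 fake_foci(c(0, 0, 0), "dUTP"))
  tev <- data.frame(event_id = 1L, nucleus_id = 1L, type = "termination",
                    n_foci = 3L, edu_focus_ids = "1;2", dutp_focus_ids = "1")
  expect_equal(initiation_angle(tev, tfoci), 90)
})

test_that("nearest-neighbour distances match exhaustive search", {
  set.seed(31)
  pa <- matrix(runif(150), ncol = 3); pb <- matrix(runif(150), ncol = 3)
  fa <- fake_foci(pa, "EdU"); fb <- fake_foci(pb, "dUTP")
  nn <- nearest_neighbour_distances(fa, fb)
  # brute-force oracle
  for (i in seq_len(50)) {
    d <- sqrt(colSums((t(pb) - pa[i, ])^2))
    expect_equal(nn$a_to_b[i], min(d), tolerance = 1e-12)
  }
  for (j in seq_len(50)) {
    d <- sqrt(colSums((t(pa) - pb[j, ])^2))
    expect_equal(nn$b_to_a[j], min(d), tolerance = 1e-12)
  }
  # within-channel excludes self
  within <- nearest_neighbour_distances(fa)
  expect_true(all(within > 0))
  expect_error(nearest_neighbour_distances(fake_foci(c(0, 0, 0), "EdU")),
               "at least 2")
  one_a <- fake_foci(c(0, 0, 0), "EdU"); one_b <- fake_foci(c(0, 0, 2), "dUTP")
  both <- nearest_neighbour_distances(one_a, one_b)
  expect_equal(both$a_to_b, 2)
  expect_equal(both$b_to_a, 2)
})

test_that("periphery distance equals depth inside the nucleus mask", {
  px <- 0.05; R <- 40
  m <- matrix(0L, 101, 101)
  yy <- row(m) - 51; xx <- col(m) - 51
  m[yy^2 + xx^2 <= R^2] <- 1L
  mask <- nuclear_mask(m, c(px, px))
  centre <- fake_foci(c(0, 50 * px, 50 * px), "EdU")
  expect_equal(periphery_distances(centre, mask), R * px, tolerance = 2 * px)
  edge <- fake_foci(c(0, 50 * px, (50 + R) * px), "EdU")
  expect_lte(periphery_distances(edge, mask), px + 1e-9)
  outside <- fake_foci(c(0, 0, 0), "EdU")
  expect_error(periphery_distances(outside, mask), "outside")
})

test_that("periphery-distance density on uniform-disc foci is triangular", {
  set.seed(37)
  px <- 0.05; R <- 100; n <- 2000
  m <- matrix(0L, 221, 221)
  yy <- row(m) - 111; xx <- col(m) - 111
  m[yy^2 + xx^2 <= R^2] <- 1L
  mask <- nuclear_mask(m, c(px, px))
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  pos <- cbind(0, (110 + r * sin(th)) * px, (110 + r * cos(th)) * px)
  # drop the few boundary points whose pixel rounds just outside the disc
  inside <- m[cbind(round(pos[, 2] / px) + 1, round(pos[, 3] / px) + 1)] > 0
  foci <- fake_foci(pos[inside, ], "EdU")
  d <- periphery_distances(foci, mask)
  # for uniform points in a disc, depth d has CDF 1 - (1 - d/R)^2
  ks <- suppressWarnings(ks.test(d / (R * px), function(q) 1 - (1 - q)^2))
  expect_gt(ks$p.value, 0.01)
})

test_that("nucleus summaries report the 1:8:1 relative frequencies", {
  events <- data.frame(event_id = 1:10, nucleus_id = 1L,
                       type = c("initiation", rep("ongoing", 8),
                                "termination"),
                       n_foci = 2L, edu_focus_ids = "1", dutp_focus_ids = "1")
  metrics <- data.frame(event_id = 1:10, type = events$type, nucleus_id = 1L,
                        event_volume_um3 = 0.01,
                        centroid_distance_um = c(NA, seq(0.1, 0.8, 0.1), NA),
                        overlap_ratio = 0.5, angle_deg = NA_real_)
  s <- summarise_nucleus(events, metrics)
  expect_equal(s$rel_freq_initiation, 0.1)
  expect_equal(s$rel_freq_ongoing, 0.8)
  expect_equal(s$rel_freq_termination, 0.1)
  expect_equal(s$n_dual, 10L)
  expect_equal(s$median_centroid_distance_um, 0.45)
})

test_that("summaries handle nuclei without dual events", {
  events <- data.frame(event_id = 1:2, nucleus_id = 1L,
                       type = "single_colour", n_foci = 1L,
                       edu_focus_ids = c("1", "2"), dutp_focus_ids = "")
  metrics <- data.frame(event_id = 1:2, type = events$type, nucleus_id = 1L,
                        event_volume_um3 = 0.01,
                        centroid_distance_um = NA_real_,
                        overlap_ratio = NA_real_, angle_deg = NA_real_)
  s <- summarise_nucleus(events, metrics)
  expect_identical(s$n_dual, 0L)
  expect_true(is.na(s$rel_freq_ongoing))
})

test_that("group comparison matches exhaustive permutation for tiny samples", {
  x <- c(1, 2); y <- c(3, 4)
  res <- compare_groups(x, y, n_tests = 1)
  # oracle: enumerate all choose(4, 2) assignments of ranks to group 1
  vals <- c(x, y)
  combs <- combn(4, 2)
  u_obs <- sum(rank(vals)[1:2]) - 2 * 3 / 2
  u_all <- apply(combs, 2, function(ix) sum(rank(vals)[ix]) - 3)
  p_oracle <- mean(u_all <= u_obs) + mean(u_all >= (4 - u_obs))
  expect_equal(res$p_raw, p_oracle, tolerance = 1e-12)
  expect_equal(res$p_raw, 1 / 3, tolerance = 1e-12)
  expect_equal(res$U, 0)
})

test_that("Bonferroni adjustment caps at 1", {
  res <- compare_groups(c(1, 3, 2), c(2, 4, 1.5), n_tests = 3)
  expect_equal(res$p_adjusted, min(1, res$p_raw * 3))
  hi <- compare_groups(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2), n_tests = 5)
  expect_equal(hi$p_adjusted, 1)
  expect_error(compare_groups(numeric(0), c(1)), "at least one")
})

test_that("identical groups give a p value of 1", {
  res <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_gte(res$p_raw, 0.99)
})

test_that("Pearson colocalization matches the direct formula", {
  set.seed(41)
  a <- matrix(runif(400), 20, 20)
  b <- 0.4 * a + matrix(rnorm(400, sd = 0.1), 20, 20)
  mask <- matrix(1, 20, 20)
  r <- pearson_colocalization(a, b, mask)
  # direct summation oracle
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  expect_equal(r, num / den, tolerance = 1e-12)
  expect_equal(pearson_colocalization(a, a), 1)
  expect_equal(pearson_colocalization(a, -2 * a + 5), -1)
  expect_error(pearson_colocalization(a, matrix(1, 20, 20)), "zero-variance")
})

test_that("distances and volumes scale with voxel spacing", {
  s <- 0.05
  lab <- array(0L, c(8, 8, 8)); lab[2:3, 2:4, 2:4] <- 1L; lab[6:7, 6:8, 6:8] <- 2L
  for (mult in c(1, 2)) {
    lv <- label_volume(lab, s * mult, "EdU")
    p <- compute_focus_props(lv, array(1, dim(lab)))
    if (mult == 1) {
      v1 <- p$volume_um3
      d1 <- dist(as.matrix(p[, c("centroid_z_um", "centroid_y_um",
                                 "centroid_x_um")]))[1]
    } else {
      expect_equal(p$volume_um3, v1 * 8)
      d2 <- dist(as.matrix(p[, c("centroid_z_um", "centroid_y_um",
                                 "centroid_x_um")]))[1]
      expect_equal(as.numeric(d2), as.numeric(d1) * 2)
    }
  }
})
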