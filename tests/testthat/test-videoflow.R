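test_that("frame-pair selection follows the stride-3 span-3 rule", {
  expect_equal(select_frame_pairs(12),
               cbind(i = c(3L, 6L, 9L), j = c(6L, 9L, 12L)))
  expect_equal(nrow(select_frame_pairs(3)), 0L)
  p160 <- select_frame_pairs(160)
  expect_equal(nrow(p160), 52L)
  expect_equal(unname(p160[52L, ]), c(156L, 159L))
  expect_equal(frame_pair_interval(25, 3), 0.120)
})

test_that("optical flow vanishes without temporal change", {
  f <- matrix(runif(400), 20, 20)
  fl <- compute_optical_flow(f, f)
  expect_true(all(fl$u == 0) && all(fl$v == 0))
  g <- matrix(0.5, 20, 20)
  fl2 <- compute_optical_flow(g, g + 0)   # constant intensity
  expect_true(all(abs(fl2$u) < 1e-9) && all(abs(fl2$v) < 1e-9))
  expect_error(compute_optical_flow(f, matrix(0, 10, 10)), "size")
})

test_that("flow direction matches the known rightward shift", {
  fs <- render_silhouette_sequence(walk_script(0, speed = 50, duration = 0.6),
                                   small_scene(), seed = 2)
  pr <- select_frame_pairs(length(fs$frames))
  # 2 px/frame = 6 px per pair: use span 1 to stay in the linear range
  fl <- compute_optical_flow(fs$frames[[7]], fs$frames[[9]],
                             n_iter = 200, tol = 1e-6)
  gt <- attr(fs, "gt_masks")[[7]]
  ang <- atan2(-fl$v[gt], fl$u[gt])
  circ_mean <- atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
  expect_lt(abs(circ_mean), 10)
  expect_equal(nrow(pr), 4L)
})

test_that("iteration residual decreases monotonically", {
  fs <- render_silhouette_sequence(walk_script(), small_scene(), seed = 3)
  fl <- compute_optical_flow(fs$frames[[3]], fs$frames[[6]], n_iter = 120,
                             tol = 0)
  expect_true(all(diff(fl$residual) <= 1e-12))
})

test_that("binarized flow overlaps the true silhouette", {
  expect_error(binarize_flow(list(u = diag(2), v = diag(2)), 0), "threshold")
  zero <- compute_optical_flow(matrix(1, 8, 8), matrix(1, 8, 8))
  expect_false(any(binarize_flow(zero, 0.1)))
  fl <- list(u = matrix(0.6, 4, 4), v = matrix(0, 4, 4))
  expect_true(all(binarize_flow(fl, 0.3)))

  ious <- sapply(1:5, function(sd) {
    fs <- render_silhouette_sequence(walk_script(), small_scene(), seed = sd)
    pr <- select_frame_pairs(length(fs$frames))
    fl <- compute_optical_flow(fs$frames[[pr[2, 1]]], fs$frames[[pr[2, 2]]],
                               n_iter = 200, tol = 1e-6)
    m <- binarize_flow(fl, 0.3)
    gt <- attr(fs, "gt_masks")[[pr[2, 1]]]
    sum(m & gt) / sum(m | gt)
  })
  expect_true(all(ious >= 0.5))
})

test_that("silhouette intersection behaves as set arithmetic", {
  a <- matrix(FALSE, 10, 10); a[3:7, 2:6] <- TRUE
  expect_identical(unclass(silhouette_from_masks(a, a))[, ], a[, ])
  b <- matrix(FALSE, 10, 10); b[3:7, 8:10] <- TRUE
  expect_false(any(silhouette_from_masks(a, b)))
  # rectangles offset by 2 px horizontally: intersection width w - 2
  c1 <- matrix(FALSE, 12, 12); c1[4:9, 3:8] <- TRUE    # width 6
  c2 <- matrix(FALSE, 12, 12); c2[4:9, 5:10] <- TRUE
  expect_equal(sum(silhouette_from_masks(c1, c2)), 6 * 4)
  expect_error(silhouette_from_masks(a, matrix(TRUE, 2, 2)), "size")
})

test_that("edge band matches the brute-force morphology oracle", {
  empty <- matrix(FALSE, 8, 8)
  eb <- edge_band(empty, 4)
  expect_false(any(eb))
  expect_true(attr(eb, "empty"))

  sq <- matrix(FALSE, 20, 20); sq[5:14, 5:14] <- TRUE
  expect_identical(edge_band(sq, 4)[, ], oracle_edge_band(sq, 4))

  # band stays within the bounding box grown by band_px
  bb <- which(edge_band(sq, 4), arr.ind = TRUE)
  expect_true(all(bb[, 1] >= 5 - 4 & bb[, 1] <= 14 + 4))
  set.seed(11)
  for (trial in 1:10) {
    m <- matrix(runif(16 * 16) < 0.4, 16, 16)
    expect_identical(edge_band(m, 4)[, ], oracle_edge_band(m, 4))
  }
})

test_that("direction histograms bin canonical angles correctly", {
  mk <- function(u, v) list(u = matrix(u, 2, 2), v = matrix(v, 2, 2))
  band <- matrix(TRUE, 2, 2)
  h <- direction_histogram(mk(1, 0), band)       # rightward
  expect_equal(unname(h["B1"]), 1)
  expect_equal(sum(h), 1)
  h5 <- direction_histogram(mk(-1, 0), band)     # leftward
  expect_equal(unname(h5["B5"]), 1)
  h3 <- direction_histogram(mk(0, -1), band)     # v negative = upward
  expect_equal(unname(h3["B3"]), 1)
  h7 <- direction_histogram(mk(0, 1), band)      # downward
  expect_equal(unname(h7["B7"]), 1)

  # equal counts at the 8 centres -> uniform histogram
  angs <- (0:7) * 45 * pi / 180
  fl <- list(u = matrix(cos(angs), 2, 4), v = matrix(-sin(angs), 2, 4))
  h8 <- direction_histogram(fl, matrix(TRUE, 2, 4))
  expect_equal(as.numeric(h8), rep(0.125, 8))

  # empty band flags the histogram as undetermined
  hz <- direction_histogram(mk(0, 0), band)
  expect_true(all(hz == 0))
  expect_true(attr(hz, "undetermined"))
})

test_that("rotating a flow field by 90 degrees permutes the bins cyclically", {
  set.seed(21)
  for (trial in 1:25) {
    u <- matrix(rnorm(36), 6, 6); v <- matrix(rnorm(36), 6, 6)
    band <- matrix(TRUE, 6, 6)
    h1 <- direction_histogram(list(u = u, v = v), band)
    # vector rotation by +90 degrees in the image convention: (u,v)->(v,-u)
    h2 <- direction_histogram(list(u = v, v = -u), band)
    expect_equal(as.numeric(h2[c(3:8, 1:2)]), as.numeric(h1),
                 tolerance = 1e-12)
    expect_equal(sum(h1), 1, tolerance = 1e-9)
  }
})

test_that("time-angle representation reflects the scripted motion phases", {
  sc <- small_scene(width = 120, height = 70, actor_width = 18,
                    actor_height = 34)
  segs <- data.frame(label = c("6a", "static", "6b"),
                     start = c(0, 1.8, 3.6),
                     duration = c(1.8, 1.8, 1.8),
                     direction_deg = c(0, 0, 180),
                     speed = c(10, 0, 8))
  fs <- render_silhouette_sequence(activity_script("V1", segs), sc, seed = 6)
  tam <- time_angle_representation(fs, n_iter = 80)
  pairs <- attr(tam, "pairs")
  expect_equal(ncol(tam), nrow(select_frame_pairs(length(fs$frames))))
  expect_true(all(abs(colSums(tam) - 1) < 1e-9 | colSums(tam) == 0))

  times <- attr(tam, "times")
  right <- times < 1.5; still <- times > 2.0 & times < 3.4; left <- times > 3.9
  expect_true(all(apply(tam[, right, drop = FALSE], 2, which.max) == 1))
  expect_true(all(tam[, still] == 0))
  expect_true(all(apply(tam[, left, drop = FALSE], 2, which.max) == 5))
})

test_that("a fully static scene yields all-zero columns", {
  sc <- small_scene(width = 40, height = 40, actor_width = 10,
                    actor_height = 16)
  script <- activity_script("V1", data.frame(label = "static", start = 0,
                                             duration = 1.2, speed = 0))
  fs <- render_silhouette_sequence(script, sc, seed = 2)
  tam <- time_angle_representation(fs)
  expect_true(all(tam == 0))
})
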