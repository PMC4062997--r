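test_that("feature fusion concatenates blocks in the documented order", {
  h <- setNames(rep(0.125, 8), paste0("B", 1:8))
  a <- c(X = 0.5, Y = 0.6, Z = 0.4)
  expect_length(fuse(h, mode = "video"), 8L)
  expect_length(fuse(accel = a, mode = "acc"), 3L)
  f <- fuse(h, a, mode = "both")
  expect_length(f, 11L)
  expect_equal(names(f), c(paste0("B", 1:8), "X", "Y", "Z"))
  expect_equal(unname(f[1:8]), unname(h))
  expect_error(fuse(h, mode = "both"), "accelerometer")
  z <- fuse(setNames(numeric(8), paste0("B", 1:8)), a, mode = "both")
  expect_true(attr(z, "undetermined"))
})

test_that("1-NN returns the label of an exact training point", {
  ds <- synthetic_benchmark(counts = table1_counts()[1:2, ], seed = 1)
  i <- 40L
  q <- ds[i, ]
  expect_equal(knn_classify(ds, q, k = 1), ds$label[i])
})

test_that("k-NN separates well-spaced clusters and matches a scan oracle", {
  set.seed(5)
  centers <- rbind(A = c(rep(0, 8), 0.1, 0.1, 0.1),
                   B = c(rep(0.8, 8), 0.9, 0.9, 0.9))
  mk <- function(n, lab) {
    m <- centers[lab, ] + matrix(rnorm(11 * n, sd = 0.02), n, 11,
                                 byrow = FALSE)
    df <- as.data.frame(t(t(m)))
    names(df) <- c(paste0("B", 1:8), "X", "Y", "Z")
    df$label <- lab
    df
  }
  train <- rbind(mk(50, "A"), mk(50, "B"))
  queries <- rbind(mk(500, "A"), mk(500, "B"))
  pred <- knn_classify(train, queries, k = 1)
  # nearest-centroid oracle
  qm <- as.matrix(queries[, 1:11])
  oracle <- rownames(centers)[apply(qm, 1, function(r)
    which.min(c(sum((r - centers[1, ])^2), sum((r - centers[2, ])^2))))]
  expect_gte(mean(pred == queries$label), 0.99)
  expect_gte(mean(pred == oracle), 0.99)

  # brute-force all-pairs oracle equivalence on a modest dataset
  small <- synthetic_benchmark(counts = table1_counts()[1, , drop = FALSE],
                               seed = 2)
  qs <- small[seq(1, nrow(small), 7), ]
  tm <- as.matrix(small[, 1:11])
  brute <- apply(as.matrix(qs[, 1:11]), 1, function(r)
    small$label[which.min(colSums((t(tm) - r)^2))])
  expect_equal(unname(knn_classify(small, qs, k = 1)), unname(brute))
})

test_that("exact 1-NN distance ties resolve to the lowest record index", {
  train <- data.frame(X = c(0, 0, 1), Y = 0, Z = 0,
                      label = c("b", "a", "c"))
  # query equidistant from records 1 and 2: record 1 ("b") wins
  expect_equal(knn_classify(train, c(X = 0, Y = 0, Z = 0), k = 1,
                            mode = "acc"), "b")
})

test_that("training-order permutation leaves predictions unchanged off ties", {
  ds <- synthetic_benchmark(counts = table1_counts()[1:3, ], seed = 9)
  qs <- ds[seq(1, nrow(ds), 11), ]
  set.seed(1)
  perm <- ds[sample(nrow(ds)), ]
  expect_equal(knn_classify(ds, qs, k = 1), knn_classify(perm, qs, k = 1))
})

test_that("leave-one-out k selection maximizes accuracy, ties to smallest", {
  # constructed dataset where LOO accuracy strictly decreases in k:
  # tight pairs of same-label points, pairs of different labels adjacent
  df <- data.frame(X = c(0, 0.001, 0.2, 0.201, 0.4, 0.401, 0.6, 0.601),
                   Y = 0, Z = 0,
                   label = c("a", "a", "b", "b", "c", "c", "d", "d"))
  expect_equal(as.integer(loo_select_k(df, c(1L, 3L, 5L), mode = "acc")), 1L)
  acc <- attr(loo_select_k(df, c(1L, 3L, 5L), mode = "acc"), "loo_accuracy")
  # exact LOO accuracies are computable by hand for this geometry: k = 1
  # matches every point with its twin (1.0); larger k is outvoted (0.0)
  expect_equal(unname(acc), c(1, 0, 0))

  # duplicate-only dataset: every k ties, smallest returned
  dup <- data.frame(X = rep(0.5, 6), Y = 0.5, Z = 0.5, label = "a")
  expect_equal(as.integer(loo_select_k(dup, c(3L, 1L, 5L), mode = "acc")), 3L)
  single <- data.frame(X = runif(5), Y = 0, Z = 0, label = "a")
  ks <- loo_select_k(single, c(1L, 3L), mode = "acc")
  expect_equal(as.integer(ks), 1L)
  expect_true(all(attr(ks, "loo_accuracy") == 1))
  expect_error(loo_select_k(dup, integer(0), mode = "acc"), "empty")
})

test_that("the stratified split is exact, disjoint and exhaustive", {
  ds <- synthetic_benchmark(counts = table1_counts()[1:4, ], seed = 3)
  ds$.row <- seq_len(nrow(ds))
  sp <- split_protocol(ds, per_cell = 10, seed = 7)
  expect_equal(sort(c(sp$learning$.row, sp$testing$.row)), ds$.row)
  expect_length(intersect(sp$learning$.row, sp$testing$.row), 0L)
  counts <- table(sp$learning$label, sp$learning$subject)
  expect_true(all(counts == 10))

  sp0 <- split_protocol(ds, per_cell = 0, seed = 1)
  expect_equal(nrow(sp0$learning), 0L)
  expect_equal(nrow(sp0$testing), nrow(ds))

  low <- ds[ds$.row %in% setdiff(ds$.row, which(ds$label == "1a")[1:25]), ]
  expect_error(split_protocol(low, per_cell = 10), "1a")
})

test_that("evaluation reports are internally consistent", {
  ds <- synthetic_benchmark(counts = table1_counts()[1:3, ], seed = 4)
  sp <- split_protocol(ds, per_cell = 10, seed = 4)
  # duplicates of training records classify perfectly with k = 1
  ev0 <- evaluate(sp$learning, sp$learning, k = 1, mode = "both")
  expect_equal(ev0$overall, 100)
  expect_true(all(ev0$per_activity == 100))

  ev <- evaluate(sp$learning, sp$testing, k = 1, mode = "both")
  expect_true(all(ev$per_activity >= 0 & ev$per_activity <= 100))
  cm <- ev$confusion
  expect_equal(ev$overall, 100 * sum(diag(cm[, rownames(cm)])) / sum(cm),
               tolerance = 1e-9)
  recomputed <- 100 * vapply(rownames(cm), function(lb)
    cm[lb, lb] / sum(cm[lb, ]), 0)
  expect_equal(unname(ev$per_activity[rownames(cm)]), unname(recomputed),
               tolerance = 1e-9)
})

test_that("outdoor features separate running from standing", {
  # stationary subject: acceleration level near its gravity baseline, 0 speed
  quiet <- activity_script("V1", data.frame(label = "standing", start = 0,
                                            duration = 30, speed = 0))
  tr <- simulate_accelerometer(quiet, noise_sd = 0.01, seed = 1)
  sp0 <- data.frame(t = 0:29, speed = 0)
  f0 <- outdoor_feature(tr, sp0, window = 5)
  expect_true(all(f0$speed == 0))
  expect_true(all(f0$accel_level > 0.8))  # |a| ~ max throughout when quiet

  # windowed means are invariant to window doubling for constant signals
  f0b <- outdoor_feature(tr, sp0, window = 10)
  expect_equal(mean(f0b$accel_level), mean(f0$accel_level), tolerance = 1e-3)

  # running vs standing: >= 80% 1-NN accuracy over >= 100 windows
  mk_session <- function(label, speed_mps, sd) {
    scr <- activity_script("V1", data.frame(label = label, start = 0,
                                            duration = 120, speed = 0))
    tr <- simulate_accelerometer(scr, noise_sd = 0.05, seed = sd)
    gp <- gps_speed(simulate_gps(speed_mps, 120, noise_m = 0.5, seed = sd))
    cbind(outdoor_feature(tr, gp, window = 2), label = label)
  }
  feats <- do.call(rbind, lapply(1:2, function(s) rbind(
    mk_session("running", 3, s), mk_session("standing", 0.05, s + 50))))
  expect_gte(nrow(feats), 100)
  X <- scale(feats[, c("accel_level", "speed")])
  pred <- sapply(seq_len(nrow(X)), function(i) {
    d <- colSums((t(X) - X[i, ])^2); d[i] <- Inf
    feats$label[which.min(d)]
  })
  expect_gte(mean(pred == feats$label), 0.8)

  expect_error(outdoor_feature(tr, data.frame(t = 500:510, speed = 1)),
               "overlap")
})

test_that("windowed classification takes the majority label per window", {
  ds <- synthetic_benchmark(counts = table1_counts()[1:2, ], seed = 6)
  feats <- ds[ds$label %in% c("1a", "2a"), ]
  times <- seq(0, by = 0.04, length.out = nrow(feats))
  res <- classify_windows(ds, feats, times, window = max(times) + 1)
  expect_equal(nrow(res), 1L)
  expect_true(res$label %in% c("1a", "2a"))
  expect_equal(res$n, nrow(feats))
  res2 <- classify_windows(ds, feats, times, window = 2)
  expect_equal(sum(res2$n), nrow(feats))
  expect_error(classify_windows(ds, feats, times, window = 0), "window")
})
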