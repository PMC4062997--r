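# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own implementations: plain loops and recursion only.

# Exhaustive DTW: enumerate every monotone path from (1,1) to (l1,l2) with
# steps (1,0), (0,1), (1,1) over a precomputed distance matrix and return the
# minimal accumulated cost.
oracle_dtw_cost <- function(d) {
  l1 <- nrow(d); l2 <- ncol(d)
  rec <- function(i, j) {
    if (i == l1 && j == l2) return(d[i, j])
    best <- Inf
    if (i < l1) best <- min(best, rec(i + 1L, j))
    if (j < l2) best <- min(best, rec(i, j + 1L))
    if (i < l1 && j < l2) best <- min(best, rec(i + 1L, j + 1L))
    d[i, j] + best
  }
  rec(1L, 1L)
}

# Squared state distance computed by direct per-element summation.
oracle_distance_matrix <- function(m1, m2) {
  d <- matrix(0, nrow(m1), nrow(m2))
  for (i in seq_len(nrow(m1))) {
    for (j in seq_len(nrow(m2))) {
      s <- 0
      for (p in seq_len(ncol(m1))) s <- s + (m1[i, p] - m2[j, p])^2
      d[i, j] <- s
    }
  }
  d
}

# Brute-force contour-band morphology: contour = mask pixels with a 4-neighbour
# outside the mask (out of bounds counts as outside); band = all pixels within
# Euclidean distance band_px/2 of some contour pixel. Pure double loops.
oracle_edge_band <- function(mask, band_px = 4) {
  h <- nrow(mask); w <- ncol(mask)
  inside <- function(i, j) i >= 1 && i <= h && j >= 1 && j <= w && mask[i, j]
  contour <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      if (!inside(i - 1, j) || !inside(i + 1, j) ||
          !inside(i, j - 1) || !inside(i, j + 1)) contour[i, j] <- TRUE
    }
  }
  r2 <- (band_px / 2)^2 + 1e-9
  out <- matrix(FALSE, h, w)
  cpx <- which(contour, arr.ind = TRUE)
  if (nrow(cpx) == 0) return(out)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      for (k in seq_len(nrow(cpx))) {
        if ((i - cpx[k, 1])^2 + (j - cpx[k, 2])^2 <= r2) {
          out[i, j] <- TRUE
          break
        }
      }
    }
  }
  out
}

# Sort-based empirical quantile (rank ceiling(q*n) of the sorted sample).
oracle_quantile <- function(v, q) {
  s <- sort(v)
  s[max(1, ceiling(q * length(s)))]
}

# Two-pass mean/sd/min/max summary.
oracle_summary <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  c(MEAN = m, STD = s, MIN = min(v), MAX = max(v))
}

# Random pose-state sequence: rows are convex combinations over 7 classes.
random_state_seq <- function(len, concentrated = TRUE) {
  m <- matrix(stats::rexp(len * 7L), len, 7L)
  if (concentrated) m <- m^3   # push mass toward one class per row
  m / rowSums(m)
}

# --- shared scene fixtures -------------------------------------------------

# Walking actor scene: moderate speed, textured rigid actor on a constant
# background; small enough for fast flow computation.
walk_script <- function(direction_deg = 0, speed = 12.5, duration = 1.2,
                        label = "6a") {
  activity_script("V1", data.frame(label = label, start = 0,
                                   duration = duration,
                                   direction_deg = direction_deg,
                                   speed = speed))
}

small_scene <- function(width = 100, height = 80, actor_width = 24,
                        actor_height = 44) {
  scene_spec(width = width, height = height, fps = 25,
             actor_width = actor_width, actor_height = actor_height,
             background = "constant")
}

# Dual-stream synchronization fixture: a long quiet stand with a single
# scripted jump whose speed profile matches the accelerometer burst envelope.
jump_dual_stream <- function(seed, delay) {
  set.seed(seed)
  jt <- stats::runif(1, 25, 40)
  segs <- data.frame(
    label = c("static", "jump", "static"),
    start = c(0, jt, jt + 4),
    duration = c(jt, 4, 70 - jt - 4),
    direction_deg = c(0, 90, 0),
    speed = c(0, 5, 0))
  scene <- scene_spec(width = 64, height = 88, fps = 25, actor_width = 20,
                      actor_height = 36, background = "constant")
  make_dual_stream(activity_script("V1", segs), scene, delay = delay,
                   seed = seed)
}
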