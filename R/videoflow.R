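#' Frame pairs used for optical-flow steps
#'
#' Flow is computed over frames three apart, stepping three frames at a
#' time: step n uses the pair (3n, 3n + 3) in 1-based frame numbering. At
#' 25 fps this makes the effective flow interval 120 ms, long enough that
#' even slow movers produce a measurable shift.
#'
#' @param n_frames Number of frames available.
#' @param stride Frames between successive steps (default 3).
#' @param span Frame-number difference within one pair (default 3).
#' @return A two-column integer matrix (`i`, `j`), possibly with zero rows.
#' @export
select_frame_pairs <- function(n_frames, stride = 3L, span = 3L) {
  stopifnot(stride >= 1L, span >= 1L)
  n_max <- floor((n_frames - span) / stride)
  if (n_max < 1L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  n <- seq_len(n_max)
  cbind(i = as.integer(n * stride), j = as.integer(n * stride + span))
}

#' Time interval spanned by one flow pair
#'
#' @param fps Frame rate in Hz.
#' @param span Frame-number difference within a pair.
#' @return Interval in seconds (0.120 at 25 fps, span 3).
#' @export
frame_pair_interval <- function(fps, span = 3L) {
  stopifnot(fps > 0)
  span / fps
}

# 3x3 neighbourhood average with replicated borders; the weighted kernel of
# the classic global-smoothness flow scheme (1/6 edge, 1/12 corner)
.hs_average <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[c(1L, seq_len(h - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  lf <- m[, c(1L, seq_len(w - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  ul <- up[, c(1L, seq_len(w - 1L)), drop = FALSE]
  ur <- up[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  dl <- dn[, c(1L, seq_len(w - 1L)), drop = FALSE]
  dr <- dn[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  (up + dn + lf + rt) / 6 + (ul + ur + dl + dr) / 12
}

#' Horn-Schunck dense optical flow
#'
#' Global variational flow between two grayscale frames: first-order finite
#' differences estimate the spatio-temporal gradients, then Jacobi-style
#' iterations trade the brightness-constancy residual against smoothness of
#' the field. `u` is horizontal motion (+right), `v` vertical motion in
#' matrix row direction (+down), both in pixels per pair interval.
#'
#' @param frame_a,frame_b Intensity matrices of equal size.
#' @param alpha Smoothness weight (regularization strength).
#' @param n_iter Maximum iterations.
#' @param tol Stop when the mean absolute update falls below this.
#' @return A `flow_field`: list with `u`, `v`, `residual` (mean absolute
#'   update per iteration) and `iterations`.
#' @export
compute_optical_flow <- function(frame_a, frame_b, alpha = 1, n_iter = 100L,
                                 tol = 1e-4) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frames must have identical size")
  h <- nrow(frame_a); w <- ncol(frame_a)
  shift_dr <- function(m) m[c(seq_len(h - 1L) + 1L, h),
                            c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  shift_d <- function(m) m[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  shift_r <- function(m) m[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  # first-order differences averaged over the 2x2x2 cube around each pixel
  Ex <- ((shift_r(frame_a) - frame_a) + (shift_dr(frame_a) - shift_d(frame_a)) +
         (shift_r(frame_b) - frame_b) + (shift_dr(frame_b) - shift_d(frame_b))) / 4
  Ey <- ((shift_d(frame_a) - frame_a) + (shift_dr(frame_a) - shift_r(frame_a)) +
         (shift_d(frame_b) - frame_b) + (shift_dr(frame_b) - shift_r(frame_b))) / 4
  Et <- ((frame_b - frame_a) + (shift_r(frame_b) - shift_r(frame_a)) +
         (shift_d(frame_b) - shift_d(frame_a)) +
         (shift_dr(frame_b) - shift_dr(frame_a))) / 4

  u <- matrix(0, h, w); v <- matrix(0, h, w)
  denom <- alpha^2 + Ex^2 + Ey^2
  residual <- numeric(n_iter)
  it <- 0L
  for (k in seq_len(n_iter)) {
    ub <- .hs_average(u); vb <- .hs_average(v)
    common <- (Ex * ub + Ey * vb + Et) / denom
    u_new <- ub - Ex * common
    v_new <- vb - Ey * common
    it <- k
    residual[k] <- mean(abs(u_new - u)) + mean(abs(v_new - v))
    u <- u_new; v <- v_new
    if (residual[k] < tol) break
  }
  structure(list(u = u, v = v, residual = residual[seq_len(it)],
                 iterations = it),
            class = "flow_field")
}

#' Flow modulus |OF|
#' @param flow A `flow_field`.
#' @return Matrix of per-pixel flow magnitudes.
#' @export
flow_modulus <- function(flow) sqrt(flow$u^2 + flow$v^2)

#' Binarize a flow field by its modulus
#'
#' Moving-object detection: a pixel is marked as moving when its flow
#' magnitude reaches a constant threshold. The default of 0.3 px per pair
#' interval is deliberately permissive so slow movers are caught; it is the
#' main tunable of the silhouette stage.
#'
#' @param flow A `flow_field`.
#' @param threshold Modulus threshold (> 0), px per pair interval.
#' @return Logical matrix, `TRUE` where `|OF| >= threshold`.
#' @export
binarize_flow <- function(flow, threshold = 0.3) {
  if (threshold <= 0) stop("threshold must be > 0")
  flow_modulus(flow) >= threshold
}

#' Silhouette as the intersection of two consecutive binarized flows
#'
#' A single binarized flow overshoots the mover (it includes both the old
#' and new object positions); the common part of two consecutive flow masks
#' recovers the actual silhouette shape.
#'
#' @param mask_n,mask_n_plus_1 Logical matrices of equal size.
#' @return A `silhouette_mask` (logical matrix).
#' @export
silhouette_from_masks <- function(mask_n, mask_n_plus_1) {
  if (!identical(dim(mask_n), dim(mask_n_plus_1)))
    stop("masks must have identical size")
  structure(mask_n & mask_n_plus_1, class = c("silhouette_mask", "matrix"))
}

# pixels of the mask having at least one 4-neighbour outside it
.contour <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- function(di, dj) {
    out <- matrix(FALSE, h, w)
    ri <- seq_len(h) + di; cj <- seq_len(w) + dj
    ok_r <- ri >= 1L & ri <= h; ok_c <- cj >= 1L & cj <= w
    out[ok_r, ok_c] <- mask[ri[ok_r], cj[ok_c]]
    out
  }
  inner <- pad(1L, 0L) & pad(-1L, 0L) & pad(0L, 1L) & pad(0L, -1L)
  mask & !inner
}

#' Edge band of a silhouette
#'
#' Flow vectors inside a silhouette are chaotic; vectors at its edge follow
#' the object motion. The band is the silhouette contour dilated with a
#' grid-approximated disk so the band is about `band_px` pixels wide
#' (disk radius `band_px / 2`).
#'
#' @param silhouette Logical matrix (e.g. from [silhouette_from_masks()]).
#' @param band_px Approximate band width in pixels (>= 1).
#' @return Logical matrix; attribute `empty` is `TRUE` when the silhouette
#'   had no pixels.
#' @export
edge_band <- function(silhouette, band_px = 4L) {
  if (band_px < 1) stop("band_px must be >= 1")
  if (!any(silhouette)) {
    out <- silhouette & FALSE
    attr(out, "empty") <- TRUE
    return(out)
  }
  ctr <- .contour(silhouette)
  r <- band_px / 2
  ri <- floor(r)
  offs <- expand.grid(di = -ri:ri, dj = -ri:ri)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2 + 1e-9, , drop = FALSE]
  h <- nrow(silhouette); w <- ncol(silhouette)
  out <- matrix(FALSE, h, w)
  idx <- which(ctr, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    ii <- idx[, 1L] + offs$di[k]; jj <- idx[, 2L] + offs$dj[k]
    keep <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
    out[cbind(ii[keep], jj[keep])] <- TRUE
  }
  attr(out, "empty") <- FALSE
  out
}

#' Flow-direction histogram over eight aggregated directions
#'
#' Band pixels vote for one of eight 45-degree direction bins B1-B8 with
#' centers 0, 45, ..., 315 degrees (bin i covers center +/- 22.5, half-open
#' at the upper edge). Angle convention: 0 = motion toward image right,
#' 90 = toward image top (the vertical flow component points down in matrix
#' coordinates, hence `atan2(-v, u)`). Counts are L1-normalized; zero-motion
#' pixels carry no direction and are excluded.
#'
#' @param flow A `flow_field`.
#' @param band Logical matrix selecting contributing pixels.
#' @return Named numeric vector B1..B8 summing to 1, or all zeros with
#'   attribute `undetermined = TRUE` when no pixel contributes.
#' @export
direction_histogram <- function(flow, band) {
  if (!identical(dim(flow$u), dim(band)))
    stop("flow and band must have identical size")
  u <- flow$u[band]; v <- flow$v[band]
  mag <- sqrt(u^2 + v^2)
  sel <- mag > 0
  h <- stats::setNames(numeric(8L), paste0("B", 1:8))
  if (!any(sel)) {
    attr(h, "undetermined") <- TRUE
    return(h)
  }
  ang <- atan2(-v[sel], u[sel]) * 180 / pi        # degrees, (-180, 180]
  bin <- (floor((ang + 22.5) / 45) %% 8) + 1      # nearest 45-degree center
  counts <- tabulate(bin, nbins = 8L)
  h[] <- counts / sum(counts)
  attr(h, "undetermined") <- FALSE
  h
}

#' Time-angle representation of a frame sequence
#'
#' Runs the full silhouette feature chain over every flow step of a
#' sequence: flow on pairs (3n, 3n+3), binarization, silhouette by
#' intersection of consecutive masks, edge band, direction histogram. Column
#' n of the result is the B1..B8 histogram at step n; static scenes yield
#' all-zero columns.
#'
#' @param seq A `frame_sequence`.
#' @param threshold Binarization threshold (see [binarize_flow()]).
#' @param band_px Edge band width (see [edge_band()]).
#' @param stride,span Pair selection (see [select_frame_pairs()]).
#' @param alpha,n_iter,tol Flow parameters (see [compute_optical_flow()]).
#' @return A `time_angle_matrix`: 8 x n_steps matrix with rows B1..B8,
#'   attributes `pairs` (the frame pairs) and `times` (pair mid-times, s).
#' @export
time_angle_representation <- function(seq, threshold = 0.3, band_px = 4L,
                                      stride = 3L, span = 3L, alpha = 1,
                                      n_iter = 100L, tol = 1e-4) {
  pairs <- select_frame_pairs(length(seq$frames), stride, span)
  if (nrow(pairs) < 1L) stop("sequence too short for any flow pair")
  flows <- vector("list", nrow(pairs))
  masks <- vector("list", nrow(pairs))
  for (n in seq_len(nrow(pairs))) {
    flows[[n]] <- compute_optical_flow(seq$frames[[pairs[n, 1L]]],
                                       seq$frames[[pairs[n, 2L]]],
                                       alpha = alpha, n_iter = n_iter,
                                       tol = tol)
    masks[[n]] <- binarize_flow(flows[[n]], threshold)
  }
  out <- matrix(0, 8L, nrow(pairs),
                dimnames = list(paste0("B", 1:8), NULL))
  for (n in seq_len(nrow(pairs))) {
    m2 <- if (n < nrow(pairs)) masks[[n + 1L]] else
      if (nrow(pairs) > 1L) masks[[n - 1L]] else masks[[n]]
    sil <- silhouette_from_masks(masks[[n]], m2)
    band <- edge_band(sil, band_px)
    out[, n] <- direction_histogram(flows[[n]], band)
  }
  times <- (rowMeans(pairs) - 1) / seq$fps
  structure(out, class = c("time_angle_matrix", "matrix"),
            pairs = pairs, times = times)
}
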