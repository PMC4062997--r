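#' Synchronization state
#'
#' Holds the current delay estimate between a wearable and a premise stream,
#' the correlation that last justified it, and the trailing history horizon
#' used by the salient-section detector (15 min by default).
#'
#' @param delay Initial delay estimate, seconds.
#' @param corr Correlation attached to the estimate.
#' @param horizon History horizon in seconds (> 0).
#' @return An object of class `sync_state` with an empty decision log.
#' @export
sync_state <- function(delay = 0, corr = NA_real_, horizon = 900) {
  if (horizon <= 0) stop("horizon must be > 0")
  structure(list(delay = delay, corr = corr, horizon = horizon,
                 log = data.frame(delay = numeric(0), corr = numeric(0),
                                  accepted = logical(0))),
            class = "sync_state")
}

#' @export
print.sync_state <- function(x, ...) {
  cat(sprintf("<sync_state> delay=%.4f s corr=%s (%d decision(s) logged)\n",
              x$delay, format(x$corr), nrow(x$log)))
  invisible(x)
}

#' Motion envelope of a sensor stream
#'
#' Reduces either modality to a single nonnegative activity time series on
#' which streams can be compared: the wearable side uses the acceleration
#' magnitude; the premise side uses the mean flow modulus per optical-flow
#' step (a velocity envelope — cross-correlation alignment only needs the
#' two envelopes to peak together, not to share physical units).
#'
#' @param x An [accel_trace()] or a `frame_sequence`.
#' @param ... Flow parameters passed to [time_angle_representation()]'s
#'   constituents for the video side (`threshold`, `alpha`, `n_iter`, `tol`).
#' @return Data frame `t`, `v` with attribute `source` set to `"wearable"`
#'   or `"premise"`.
#' @export
motion_envelope <- function(x, ...) {
  UseMethod("motion_envelope")
}

#' @rdname motion_envelope
#' @export
motion_envelope.accel_trace <- function(x, ...) {
  structure(data.frame(t = x$t, v = sqrt(x$x^2 + x$y^2 + x$z^2)),
            source = "wearable", fs = attr(x, "fs"))
}

#' @param alpha,n_iter,tol Flow solver parameters.
#' @param stride,span Frame-pair selection; the envelope defaults to
#'   overlapping pairs at every frame (stride 1) so alignment is sampled at
#'   the full frame rate, unlike the stride-3 feature pipeline.
#' @rdname motion_envelope
#' @export
motion_envelope.frame_sequence <- function(x, alpha = 1, n_iter = 40L,
                                           tol = 1e-3, stride = 1L,
                                           span = 3L, ...) {
  pairs <- select_frame_pairs(length(x$frames), stride, span)
  if (nrow(pairs) < 1L) stop("sequence too short for any flow pair")
  v <- vapply(seq_len(nrow(pairs)), function(n) {
    fl <- compute_optical_flow(x$frames[[pairs[n, 1L]]],
                               x$frames[[pairs[n, 2L]]],
                               alpha = alpha, n_iter = n_iter, tol = tol)
    mean(flow_modulus(fl))
  }, 0)
  structure(data.frame(t = (rowMeans(pairs) - 1) / x$fps, v = v),
            source = "premise")
}

# empirical quantile by sorting: smallest value with rank >= q * n
.empirical_quantile <- function(v, q) {
  sort(v)[max(1L, ceiling(q * length(v)))]
}

#' Detect salient high-activity sections of an envelope
#'
#' Thresholds the envelope at the given quantile (top 5% by default) of the
#' trailing history horizon and returns maximal contiguous runs above it.
#' Only such sections carry enough structure for reliable delay estimation.
#'
#' @param env Envelope data frame `t`, `v` (at least one minute of samples).
#' @param state A [sync_state()] (provides the horizon).
#' @param quantile Threshold quantile.
#' @return Data frame `start`, `end` (seconds); attribute `flat = TRUE` and
#'   zero rows when the envelope has no spread.
#' @export
detect_salient_sections <- function(env, state = sync_state(),
                                    quantile = 0.95) {
  if (diff(range(env$t)) < 60)
    stop("need at least one minute of envelope history")
  recent <- env$v[env$t >= max(env$t) - state$horizon]
  empty <- data.frame(start = numeric(0), end = numeric(0))
  if (diff(range(recent)) == 0) {
    attr(empty, "flat") <- TRUE
    return(empty)
  }
  thr <- .empirical_quantile(recent, quantile)
  above <- env$v >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = env$t[starts[keep]], end = env$t[ends[keep]])
  attr(out, "threshold") <- thr
  out
}

#' Estimate inter-stream delay by normalized cross-correlation
#'
#' Resamples both envelopes onto a common uniform grid (linear
#' interpolation) and scans integer lags within `max_lag`, scoring each by
#' the Pearson correlation of the overlapping samples. The returned delay
#' `d` maximizes the correlation of `a(t)` with `b(t + d)`, i.e. a positive
#' delay means stream `b` lags stream `a`. The peak lag is refined by
#' parabolic interpolation of the correlation around the maximum.
#'
#' @param env_a,env_b Envelope data frames `t`, `v`.
#' @param max_lag Largest absolute delay scanned, seconds.
#' @param rate Common resampling rate, Hz (the wearable's 100 Hz by
#'   default, so delays resolve on the accelerometer sample grid).
#' @param section Optional `c(start, end)` restricting stream `a` to one
#'   salient section (context of `max_lag` is added on both sides).
#' @return List with `delay` (s) and `corr` (in \[-1, 1\]).
#' @export
estimate_delay <- function(env_a, env_b, max_lag = 3, rate = 100,
                           section = NULL) {
  if (!is.null(section)) {
    keep <- env_a$t >= section[1L] - max_lag & env_a$t <= section[2L] + max_lag
    env_a <- env_a[keep, , drop = FALSE]
  }
  lo <- min(env_a$t); hi <- max(env_a$t)
  tt <- seq(lo, hi, by = 1 / rate)
  a <- stats::approx(env_a$t, env_a$v, xout = tt)$y
  max_k <- round(max_lag * rate)
  # per-lag Pearson correlation over the samples both streams cover; lags
  # with less than half the section overlapping are not considered
  cors <- vapply(-max_k:max_k, function(k) {
    b <- stats::approx(env_b$t, env_b$v, xout = tt + k / rate)$y
    ok <- !is.na(b)
    if (sum(ok) < max(10L, length(tt) %/% 2)) return(-Inf)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(0)
    stats::cor(a[ok], b[ok])
  }, 0)
  if (all(!is.finite(cors)))
    stop("stream B does not cover the section within max_lag")
  ks <- -max_k:max_k
  best <- which.max(cors)
  # refine the peak by a least-squares quadratic fit over the connected run
  # of lags near the maximum; pointwise argmax alone is unstable when the
  # correlation peak is broad relative to the lag spacing
  fin <- is.finite(cors)
  thr <- cors[best] - 0.1 * (cors[best] - stats::median(cors[fin]))
  lo <- best; while (lo > 1L && fin[lo - 1L] && cors[lo - 1L] >= thr) lo <- lo - 1L
  hi <- best; while (hi < length(cors) && fin[hi + 1L] && cors[hi + 1L] >= thr)
    hi <- hi + 1L
  lag_k <- ks[best]
  if (hi - lo >= 4L) {
    kk <- ks[lo:hi]
    fit <- stats::lm.fit(cbind(1, kk, kk^2), cors[lo:hi])
    a2 <- fit$coefficients[3L]
    if (is.finite(a2) && a2 < 0) {
      vertex <- -fit$coefficients[2L] / (2 * a2)
      if (vertex >= ks[lo] && vertex <= ks[hi]) lag_k <- vertex
    }
  }
  list(delay = lag_k / rate, corr = cors[best])
}

#' Gated update of the delay estimate
#'
#' The stored delay is corrected only when the supporting cross-correlation
#' is significant (above 0.7 by default); weaker alignments leave the state
#' untouched. Every decision is appended to the state's log.
#'
#' @param state A [sync_state()].
#' @param delay Candidate delay, seconds.
#' @param corr Its correlation, in \[-1, 1\].
#' @param gate Acceptance gate on the correlation.
#' @return The updated `sync_state`.
#' @export
update_delay <- function(state, delay, corr, gate = 0.70) {
  if (is.na(corr) || corr < -1 || corr > 1)
    stop("corr must lie in [-1, 1]")
  accepted <- corr > gate
  if (accepted) {
    state$delay <- delay
    state$corr <- corr
  }
  state$log <- rbind(state$log,
                     data.frame(delay = delay, corr = corr,
                                accepted = accepted))
  state
}

#' Apply delay compensation to a timestamped series
#'
#' Shifts timestamps by minus the sum of the estimated transmission delay
#' and the series' nominal (design-known) processing delay, bringing the
#' stream back onto the common timeline. Sample order is preserved.
#'
#' @param series Data frame with a `t` column (envelope, trace, ...).
#' @param state A [sync_state()].
#' @param nominal Nominal processing delay of this source, seconds.
#' @return The series with compensated timestamps.
#' @export
apply_compensation <- function(series, state, nominal = 0) {
  if (!is.finite(state$delay)) stop("delay estimate is not finite")
  series$t <- series$t - (state$delay + nominal)
  series
}

#' One full synchronization cycle on a dual stream
#'
#' Convenience wrapper chaining the pieces: envelopes for both modalities,
#' salient-section detection on the wearable envelope, cross-correlation
#' delay estimation on the most salient section, gated state update, and
#' compensation of the wearable stream.
#'
#' @param dual A `dual_stream` from [make_dual_stream()].
#' @param state A [sync_state()].
#' @param max_lag Largest absolute delay scanned, seconds.
#' @param gate Correlation acceptance gate.
#' @param ... Passed to [motion_envelope()] for the video side.
#' @return List with `state`, `accel` (compensated trace), `delay`, `corr`.
#' @export
sync_cycle <- function(dual, state = sync_state(), max_lag = 3, gate = 0.70,
                       ...) {
  env_w <- motion_envelope(dual$accel)
  env_p <- motion_envelope(dual$frames, ...)
  secs <- detect_salient_sections(env_w, state)
  if (!nrow(secs)) stop("no salient section found in the wearable envelope")
  pick <- which.max(secs$end - secs$start)
  est <- estimate_delay(env_p, env_w, max_lag = max_lag,
                        section = c(secs$start[pick] - state$delay,
                                    secs$end[pick] - state$delay))
  state <- update_delay(state, est$delay, est$corr, gate)
  list(state = state, accel = apply_compensation(dual$accel, state),
       delay = est$delay, corr = est$corr)
}
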