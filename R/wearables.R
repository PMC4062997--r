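#' Construct a 3-axis accelerometer trace
#'
#' @param t Timestamps in seconds, strictly increasing.
#' @param x,y,z Accelerations in g.
#' @param fs Nominal sampling frequency in Hz.
#' @return Data frame of class `accel_trace` with attribute `fs`.
#' @export
accel_trace <- function(t, x, y, z, fs) {
  if (length(t) < 1L) stop("empty trace")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (length(x) != length(t) || length(y) != length(t) ||
      length(z) != length(t))
    stop("channel lengths must match timestamps")
  structure(data.frame(t = t, x = x, y = y, z = z),
            class = c("accel_trace", "data.frame"), fs = fs)
}

.trace_fs <- function(trace) {
  fs <- attr(trace, "fs")
  if (is.null(fs)) fs <- 1 / stats::median(diff(trace$t))
  fs
}

.rewrap <- function(trace, x, y, z, fs = .trace_fs(trace), t = trace$t) {
  out <- accel_trace(t, x, y, z, fs)
  attrs <- attributes(trace)
  for (nm in setdiff(names(attrs), c("names", "row.names", "class", "fs")))
    attr(out, nm) <- attrs[[nm]]
  out
}

#' Remove the per-axis local offset measured in a motionless stand pose
#'
#' Subtracts, separately for each axis, the mean over a baseline window of at
#' least 10 s recorded in a motionless stand pose. This removes the gravity
#' projection and sensor bias for the mounting of that subject.
#'
#' @param trace An [accel_trace()].
#' @param baseline `c(start, end)` of the baseline window in seconds
#'   (defaults to the first 10 s of the trace).
#' @param min_duration Minimum admissible baseline length, seconds.
#' @return The offset-corrected trace; attribute `offset` holds the
#'   subtracted per-axis means.
#' @export
subtract_offset <- function(trace, baseline = NULL, min_duration = 10) {
  if (is.null(baseline)) baseline <- c(trace$t[1L], trace$t[1L] + min_duration)
  if (diff(baseline) < min_duration - 1e-9 ||
      max(trace$t) < baseline[2L] - 1e-9)
    stop("baseline window must span at least ", min_duration,
         " s inside the trace")
  idx <- trace$t >= baseline[1L] - 1e-9 & trace$t <= baseline[2L] + 1e-9
  if (!any(idx)) stop("baseline window contains no samples")
  off <- c(x = mean(trace$x[idx]), y = mean(trace$y[idx]),
           z = mean(trace$z[idx]))
  out <- .rewrap(trace, trace$x - off["x"], trace$y - off["y"],
                 trace$z - off["z"])
  attr(out, "offset") <- off
  out
}

# centred moving average with edges handled by shrinking the window
.moving_average <- function(v, w) {
  zoo::rollapply(v, width = w, FUN = mean, align = "center", partial = TRUE)
}

#' Smooth a trace with a short centred moving average
#'
#' A 0.2 s averaging window suppresses sensor distortions while keeping the
#' main direction of the signal changes. Edges use a shrunken window so the
#' output length equals the input length.
#'
#' @param trace An [accel_trace()].
#' @param window Window length in seconds (must cover >= 2 samples).
#' @return Smoothed trace of the same length.
#' @export
smooth_trace <- function(trace, window = 0.2) {
  if (window <= 0) stop("window must be > 0")
  fs <- .trace_fs(trace)
  w <- round(window * fs)
  if (w < 2L) stop("window must span at least 2 samples at fs = ", fs)
  .rewrap(trace, .moving_average(trace$x, w), .moving_average(trace$y, w),
          .moving_average(trace$z, w))
}

#' Normalize all of one subject's traces by a common scale
#'
#' Divides every sample by the maximal absolute value found across all the
#' measurements of all the activities for that person, so amplitudes become
#' comparable between subjects while within-subject proportions are kept.
#'
#' @param traces A single [accel_trace()] or a list of them (one subject's
#'   whole corpus).
#' @return Object of the same shape, rescaled; attribute `scale` holds the
#'   divisor.
#' @export
normalize_subject <- function(traces) {
  single <- inherits(traces, "accel_trace")
  lst <- if (single) list(traces) else traces
  m <- max(vapply(lst, function(tr) max(abs(c(tr$x, tr$y, tr$z))), 0))
  if (m == 0) stop("all-zero corpus cannot be normalized")
  out <- lapply(lst, function(tr) {
    r <- .rewrap(tr, tr$x / m, tr$y / m, tr$z / m)
    attr(r, "scale") <- m
    r
  })
  if (single) out[[1L]] else out
}

#' Map a normalized trace affinely into the unit range
#'
#' After per-subject normalization values lie in \[-1, 1\]; the affine map
#' `v -> (v + 1) / 2` takes them into \[0, 1\], the amplitude range of the
#' classifier feature vector.
#'
#' @param trace An [accel_trace()] with values in \[-1, 1\].
#' @return Trace with values in \[0, 1\].
#' @export
to_unit_range <- function(trace) {
  vals <- c(trace$x, trace$y, trace$z)
  if (any(vals < -1 - 1e-9 | vals > 1 + 1e-9))
    stop("input must lie within [-1, 1]; run normalize_subject() first")
  .rewrap(trace, (trace$x + 1) / 2, (trace$y + 1) / 2, (trace$z + 1) / 2)
}

#' Decimate a trace by plain subsampling
#'
#' Keeps every `factor`-th sample starting with the first; the 0.2 s
#' averaging applied earlier in the chain already acts as the low-pass.
#' The nominal use is fourfold subsampling from 100 Hz to 25 Hz.
#'
#' @param trace An [accel_trace()].
#' @param factor Integer >= 1.
#' @return Trace of length `ceiling(n / factor)` with `fs / factor`.
#' @export
decimate_trace <- function(trace, factor = 4L) {
  if (factor < 1 || factor != round(factor)) stop("factor must be integer >= 1")
  idx <- seq(1L, nrow(trace), by = factor)
  .rewrap(trace, trace$x[idx], trace$y[idx], trace$z[idx],
          fs = .trace_fs(trace) / factor, t = trace$t[idx])
}

#' Full accelerometer preprocessing chain
#'
#' Applies, in order: offset subtraction, 0.2 s smoothing, per-subject
#' normalization, unit-range mapping and fourfold decimation, producing the
#' `[x y z]` classifier features at 25 Hz (for 100 Hz input).
#'
#' @param traces One [accel_trace()] or a list (a subject's corpus).
#' @param baseline Baseline window for [subtract_offset()], one per trace
#'   (recycled).
#' @param window Smoothing window, s.
#' @param factor Decimation factor.
#' @return A `processed_accel` trace (or list of them): values in \[0, 1\]
#'   at `fs / factor`.
#' @export
process_accel <- function(traces, baseline = NULL, window = 0.2, factor = 4L) {
  single <- inherits(traces, "accel_trace")
  lst <- if (single) list(traces) else traces
  lst <- lapply(lst, function(tr)
    smooth_trace(subtract_offset(tr, baseline), window))
  lst <- normalize_subject(lst)
  lst <- lapply(lst, function(tr) {
    out <- decimate_trace(to_unit_range(tr), factor)
    class(out) <- c("processed_accel", class(out))
    out
  })
  if (single) lst[[1L]] else lst
}

#' Detect fall events from total accelerometer magnitude
#'
#' A fall is flagged whenever the absolute sum of the three axis signals
#' exceeds the trigger level; hits closer together than the refractory
#' window are merged into one event.
#'
#' @param trace An [accel_trace()].
#' @param trigger Trigger level in g (> 0); the default of 2.5 g clears
#'   ordinary ambulation, which stays near 1 g.
#' @param refractory Merge window in seconds.
#' @return Numeric vector of event times (the peak of each merged
#'   excursion; possibly empty).
#' @export
detect_fall <- function(trace, trigger = 2.5, refractory = 1) {
  if (trigger <= 0) stop("trigger must be > 0")
  s <- abs(trace$x) + abs(trace$y) + abs(trace$z)
  hit <- which(s > trigger)
  if (!length(hit)) return(numeric(0))
  cluster <- cumsum(c(TRUE, diff(trace$t[hit]) > refractory))
  vapply(split(hit, cluster), function(ix) trace$t[ix[which.max(s[ix])]], 0)
}

#' Pan-Tompkins QRS detection and heart rate
#'
#' The classic time-domain QRS detector: a 5-15 Hz bandpass (zero-phase
#' Butterworth, the digital equivalent of the cascaded low/high-pass pair),
#' five-point differentiation, squaring, 150 ms moving-window integration,
#' and adaptive dual-threshold peak picking with a 200 ms refractory period
#' and search-back at half threshold.
#'
#' @param ecg A `signal_trace` (data frame `t`, `v`, attribute `fs`) as from
#'   [simulate_ecg()], with `fs >= 100` and duration >= 5 s.
#' @return List with `beat_idx`, `beat_times`, `heart_rate` (bpm,
#'   60 / median RR; `NA` with `undetermined = TRUE` when fewer than two
#'   beats are found) and `n_beats`.
#' @export
pan_tompkins_qrs <- function(ecg) {
  fs <- attr(ecg, "fs")
  if (is.null(fs)) fs <- 1 / stats::median(diff(ecg$t))
  if (fs < 100) stop("sampling frequency must be >= 100 Hz")
  v <- ecg$v
  n <- length(v)
  if (n / fs < 5) stop("trace must be at least 5 s long")
  if (stats::sd(v) == 0)
    return(list(beat_idx = integer(0), beat_times = numeric(0),
                heart_rate = NA_real_, n_beats = 0L, undetermined = TRUE))

  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bp, v)
  # five-point derivative, 1/8 * (-x[n-2] - 2 x[n-1] + 2 x[n+1] + x[n+2])
  der <- stats::filter(filt, c(2, 1, 0, -1, -2) / 8, sides = 2L)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  wi <- max(2L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / wi, wi), sides = 2L))
  integ[is.na(integ)] <- 0

  refr <- round(0.200 * fs)
  # local maxima of the integrated signal
  peaks <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(peaks))
    return(list(beat_idx = integer(0), beat_times = numeric(0),
                heart_rate = NA_real_, n_beats = 0L, undetermined = TRUE))
  spk <- max(integ[seq_len(min(n, round(2 * fs)))]) * 0.5
  npk <- mean(integ[seq_len(min(n, round(2 * fs)))]) * 0.5
  thr <- npk + 0.25 * (spk - npk)
  beats <- integer(0)
  for (p in peaks) {
    if (length(beats) && (p - beats[length(beats)]) < refr) {
      # within refractory period: keep the larger peak
      if (integ[p] > integ[beats[length(beats)]] &&
          integ[p] >= thr) beats[length(beats)] <- p
      next
    }
    if (integ[p] >= thr) {
      beats <- c(beats, p)
      spk <- 0.125 * integ[p] + 0.875 * spk
    } else {
      npk <- 0.125 * integ[p] + 0.875 * npk
    }
    thr <- npk + 0.25 * (spk - npk)
  }
  # search-back: if an expected beat is missing, accept peaks at half threshold
  if (length(beats) >= 2L) {
    rr <- stats::median(diff(beats))
    filled <- beats
    for (g in which(diff(beats) > 1.66 * rr)) {
      lo <- beats[g] + refr; hi <- beats[g + 1L] - refr
      cand <- peaks[peaks > lo & peaks < hi]
      cand <- cand[integ[cand] >= thr / 2]
      if (length(cand)) filled <- c(filled, cand[which.max(integ[cand])])
    }
    beats <- sort(filled)
  }
  # refine beat position to the bandpassed R peak near the integration peak
  half <- as.integer(round(0.075 * fs))
  beats <- vapply(beats, function(p) {
    lo <- max(1L, as.integer(p) - half); hi <- as.integer(min(n, as.integer(p) + half))
    lo + which.max(abs(filt[lo:hi])) - 1L
  }, integer(1))
  beats <- unique(beats)
  hr <- if (length(beats) >= 2L) 60 / (stats::median(diff(beats)) / fs)
        else NA_real_
  list(beat_idx = beats, beat_times = ecg$t[beats], heart_rate = hr,
       n_beats = length(beats), undetermined = length(beats) < 2L)
}

#' Ground speed from a GPS track
#'
#' Haversine distance between consecutive fixes divided by the time step.
#'
#' @param track Data frame with columns `t` (s), `lat`, `lon` (degrees).
#' @return Data frame `t` (time of the later fix) and `speed` (m/s).
#' @export
gps_speed <- function(track) {
  if (nrow(track) < 2L) stop("need at least two fixes")
  dt <- diff(track$t)
  if (any(dt == 0)) stop("duplicate timestamps in track")
  d <- geosphere::distHaversine(cbind(track$lon[-nrow(track)],
                                      track$lat[-nrow(track)]),
                                cbind(track$lon[-1L], track$lat[-1L]))
  data.frame(t = track$t[-1L], speed = d / dt)
}

#' Per-axis summary statistics of a trace
#'
#' The summary format used for outdoor sessions: mean, standard deviation
#' (sample, n - 1 denominator), minimum and maximum per axis, in g.
#'
#' @param trace An [accel_trace()].
#' @return Data frame with rows `x`, `y`, `z` and columns `MEAN`, `STD`,
#'   `MIN`, `MAX`.
#' @export
summarize_trace <- function(trace) {
  if (nrow(trace) < 1L) stop("empty trace")
  ax <- list(x = trace$x, y = trace$y, z = trace$z)
  out <- data.frame(
    MEAN = vapply(ax, mean, 0),
    STD = vapply(ax, function(v) if (length(v) > 1L) stats::sd(v) else 0, 0),
    MIN = vapply(ax, min, 0),
    MAX = vapply(ax, max, 0))
  rownames(out) <- names(ax)
  out
}
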