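#' Indoor activity vocabulary
#'
#' The twelve elementary indoor activities used throughout the package. Codes
#' pair into six movements: each movement has an "a" phase (going into the
#' pose) and a "b" phase (returning from it).
#'
#' @return Character vector of the twelve activity codes `"1a"` ... `"6b"`.
#' @export
activity_codes <- function() {
  paste0(rep(1:6, each = 2L), c("a", "b"))
}

#' Outdoor activity vocabulary
#'
#' @return Character vector of the outdoor action labels.
#' @export
outdoor_codes <- function() {
  c("standing", "walking", "running")
}

# labels accepted by the generators beyond the indoor/outdoor vocabulary
.extra_codes <- c("static", "jump", "fall")

.known_codes <- function() c(activity_codes(), outdoor_codes(), .extra_codes)

#' Build an activity script
#'
#' An activity script is the shared ground-truth timeline that drives every
#' synthetic generator: the same script renders to a silhouette movie and to
#' an accelerometer trace, so dual-stream experiments have a known alignment.
#'
#' @param subject_id Subject identifier, e.g. `"V1"`.
#' @param segments A data frame with columns `label` (activity code),
#'   `start` and `duration` (seconds), and optionally `direction_deg`
#'   (motion direction, 0 = image right, 90 = image up), `speed` (pixels per
#'   second) and `amp` (accelerometer burst amplitude in g; `NA` uses the
#'   template default).
#' @return An object of class `activity_script`.
#' @export
activity_script <- function(subject_id, segments) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L)
  required <- c("label", "start", "duration")
  missing <- setdiff(required, names(segments))
  if (length(missing))
    stop("segments lacks columns: ", paste(missing, collapse = ", "))
  if (!all(segments$label %in% .known_codes()))
    stop("unknown activity label(s): ",
         paste(setdiff(segments$label, .known_codes()), collapse = ", "))
  if (any(segments$duration <= 0)) stop("segment durations must be > 0")
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  ends <- segments$start + segments$duration
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] < ends[-nrow(segments)] - 1e-9))
    stop("segments overlap")
  if (is.null(segments$direction_deg)) segments$direction_deg <- 0
  if (is.null(segments$speed)) segments$speed <- 0
  if (is.null(segments$amp)) segments$amp <- NA_real_
  rownames(segments) <- NULL
  structure(list(subject_id = subject_id, segments = segments),
            class = "activity_script")
}

#' @export
print.activity_script <- function(x, ...) {
  cat("<activity_script> subject", x$subject_id, "-",
      nrow(x$segments), "segment(s),",
      sprintf("%.1f s total\n", script_duration(x)))
  print(x$segments)
  invisible(x)
}

#' Total scripted duration in seconds
#' @param script An `activity_script`.
#' @export
script_duration <- function(script) {
  with(script$segments, max(start + duration))
}

#' Describe the synthetic camera scene
#'
#' Defaults follow the DV-PAL indoor recording setup: 720 x 576 pixels at
#' 25 frames per second. The actor is a textured rigid shape; a non-uniform
#' fill is required because flow-based segmentation needs intensity gradients
#' on the moving object (clothes are assumed not to be perfectly uniform).
#'
#' @param width,height Frame size in pixels.
#' @param fps Frame rate in Hz.
#' @param actor_width,actor_height Actor bounding box in pixels.
#' @param actor_shape `"rectangle"` or `"ellipse"`.
#' @param background `"constant"` or `"textured"`.
#' @param texture_contrast Peak-to-peak amplitude of the actor texture
#'   (intensities in \[0, 1\]).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 720L, height = 576L, fps = 25,
                       actor_width = max(8L, round(width / 10)),
                       actor_height = max(12L, round(height / 3)),
                       actor_shape = c("rectangle", "ellipse"),
                       background = c("constant", "textured"),
                       texture_contrast = 0.8) {
  actor_shape <- match.arg(actor_shape)
  background <- match.arg(background)
  if (fps <= 0) stop("fps must be > 0")
  if (texture_contrast <= 0)
    stop("actor texture must be non-uniform (texture_contrast > 0)")
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, actor_width = as.integer(actor_width),
                 actor_height = as.integer(actor_height),
                 actor_shape = actor_shape, background = background,
                 texture_contrast = texture_contrast),
            class = "scene_spec")
}

# continuous actor centre position (px) at time t for a script; the actor
# starts at the scene centre and integrates segment velocities. Constant
# speed within a segment, except jump/fall events whose speed follows a
# Gaussian burst centred mid-segment — the same temporal envelope as their
# accelerometer templates, so the two modalities peak at the same instant.
.script_position <- function(script, scene, t) {
  segs <- script$segments
  x0 <- scene$width / 2
  y0 <- scene$height / 2
  pos <- matrix(0, nrow = length(t), ncol = 2L)
  for (s in seq_len(nrow(segs))) {
    a <- segs$start[s]; d <- segs$duration[s]
    ang <- segs$direction_deg[s] * pi / 180
    el <- pmin(pmax(t - a, 0), d)      # time elapsed inside the segment
    dist <- if (segs$label[s] %in% c("jump", "fall")) {
      # excursion with a Gaussian speed envelope (same temporal profile as
      # the accelerometer burst template) that reverses at mid-segment: the
      # actor rises and returns, like a real jump, so the position path is
      # time-symmetric about the burst centre
      sig <- 0.15
      G <- function(e) d * sig * sqrt(2 * pi) *
        (stats::pnorm((e / d - 0.5) / sig) - stats::pnorm(-0.5 / sig))
      ifelse(el <= d / 2, G(el), 2 * G(d / 2) - G(el))
    } else {
      el
    }
    pos[, 1L] <- pos[, 1L] + segs$speed[s] * cos(ang) * dist
    pos[, 2L] <- pos[, 2L] - segs$speed[s] * sin(ang) * dist  # image y down
  }
  cbind(x = x0 + pos[, 1L], y = y0 + pos[, 2L])
}

.actor_mask_template <- function(scene) {
  w <- scene$actor_width; h <- scene$actor_height
  if (scene$actor_shape == "rectangle") return(matrix(TRUE, h, w))
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  outer(seq_len(h), seq_len(w), function(r, c)
    ((r - cy) / (h / 2))^2 + ((c - cx) / (w / 2))^2 <= 1)
}

#' Render a silhouette image sequence from a script
#'
#' Draws a textured rigid actor moving over a static background according to
#' the script, emulating an indoor activity recording. Per-frame ground truth
#' (actor mask and continuous displacement) is kept as a side channel so
#' downstream flow features can be verified.
#'
#' @param script An [activity_script()].
#' @param scene A [scene_spec()].
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @return An object of class `frame_sequence`: a list with `frames` (list of
#'   intensity matrices in \[0, 1\]), `fps`, and ground-truth attributes
#'   `gt_masks` (logical matrices) and `gt_displacement` (per consecutive
#'   frame pair, columns `dx`, `dy` in pixels).
#' @export
render_silhouette_sequence <- function(script, scene, seed = 1L) {
  stopifnot(inherits(script, "activity_script"), inherits(scene, "scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n_frames <- round(scene$fps * script_duration(script))
  t <- (seq_len(n_frames) - 1) / scene$fps
  pos <- .script_position(script, scene, t)

  tmpl_mask <- .actor_mask_template(scene)
  h <- nrow(tmpl_mask); w <- ncol(tmpl_mask)
  tex <- .smooth_texture(h, w, scene$texture_contrast)
  bg <- if (scene$background == "textured")
    matrix(0.1 + 0.1 * stats::runif(scene$height * scene$width),
           scene$height, scene$width)
  else matrix(0.1, scene$height, scene$width)

  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    # sub-pixel placement: the actor patch is distributed bilinearly over
    # the four integer positions around the continuous centre, so frame
    # intensities vary smoothly with position and optical flow sees the
    # true motion profile rather than whole-pixel jumps
    top_c <- pos[i, 2L] - h / 2; left_c <- pos[i, 1L] - w / 2
    top <- floor(top_c); left <- floor(left_c)
    fy <- top_c - top; fx <- left_c - left
    if (top < 1L || left < 1L || top + h > scene$height ||
        left + w > scene$width) {
      seg <- findInterval(t[i], script$segments$start)
      stop(sprintf("actor leaves the frame at t=%.2f s (segment %d, '%s')",
                   t[i], seg, script$segments$label[max(seg, 1L)]))
    }
    patch <- matrix(0, h + 1L, w + 1L)
    alpha <- matrix(0, h + 1L, w + 1L)
    wts <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
    offs <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    for (q in 1:4) {
      if (wts[q] == 0) next
      rr <- offs[[q]][1L] + seq_len(h); cc <- offs[[q]][2L] + seq_len(w)
      patch[rr, cc] <- patch[rr, cc] + wts[q] * tex * tmpl_mask
      alpha[rr, cc] <- alpha[rr, cc] + wts[q] * tmpl_mask
    }
    fr <- bg
    rows <- top:(top + h); cols <- left:(left + w)
    fr[rows, cols] <- (1 - alpha) * fr[rows, cols] + patch
    mk <- matrix(FALSE, scene$height, scene$width)
    mk[rows, cols] <- alpha > 0.5
    frames[[i]] <- fr
    masks[[i]] <- mk
  }
  disp <- if (n_frames > 1L) {
    cbind(dx = diff(pos[, 1L]), dy = diff(pos[, 2L]))
  } else matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("dx", "dy")))
  structure(list(frames = frames, fps = scene$fps,
                 width = scene$width, height = scene$height),
            class = "frame_sequence",
            gt_masks = masks, gt_displacement = disp, gt_position = pos)
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.1f fps\n",
              length(x$frames), x$width, x$height, x$fps))
  invisible(x)
}

# ---- accelerometer templates ---------------------------------------------

#' Accelerometer burst templates per activity
#'
#' Hand-designed, deterministic 3-axis waveforms, one per activity code, used
#' by [simulate_accelerometer()]. Each class has a distinct amplitude, axis
#' mix and temporal shape so a classifier trained on simulated traces can
#' separate them; the "a"/"b" phases of a movement mirror each other in sign.
#' Axis convention (sternum placement): x = lateral, y = vertical (carries the
#' +1 g gravity offset added by the simulator), z = anteroposterior.
#'
#' @param label Activity code.
#' @param t_rel Time since segment start, seconds (vector).
#' @param duration Segment duration, seconds.
#' @param amp Optional amplitude override in g.
#' @return A `length(t_rel)` x 3 matrix of accelerations in g (no gravity).
#' @export
accel_template <- function(label, t_rel, duration, amp = NA_real_) {
  u <- t_rel / duration                 # 0..1 within the segment
  half <- sin(pi * u)                   # single in-out stroke
  n <- length(t_rel)
  zero <- numeric(n)
  burst <- function(ax, ay, az, shape) cbind(ax * shape, ay * shape, az * shape)
  # centred impulse used for jumps/falls
  gauss <- exp(-(u - 0.5)^2 / (2 * 0.15^2))
  a <- switch(label,
    "1a" = burst(0.05, -0.50, 0.10, half),
    "1b" = burst(0.05,  0.50, 0.10, half),
    "2a" = burst(0.00, -0.35, 0.20, half),
    "2b" = burst(0.00,  0.35, 0.20, half),
    "3a" = burst(0.15,  0.03, 0.08, half),
    "3b" = burst(-0.15, 0.03, 0.08, half),
    "4a" = burst(0.05,  0.20, -0.05, half),
    "4b" = burst(0.05, -0.20, -0.05, half),
    "5a" = burst(0.02, -0.25, 0.40, half),
    "5b" = burst(0.02,  0.25, -0.40, half),
    "6a" = cbind(0.30 * sin(2 * pi * 2 * t_rel), 0.15 * half,
                 0.10 * sin(2 * pi * 2 * t_rel + pi / 3)),
    "6b" = cbind(-0.30 * sin(2 * pi * 2 * t_rel), 0.15 * half,
                 -0.10 * sin(2 * pi * 2 * t_rel + pi / 3)),
    "standing" = cbind(zero, zero, zero),
    "static"   = cbind(zero, zero, zero),
    "walking"  = cbind(0.10 * sin(2 * pi * 2 * t_rel),
                       0.25 * abs(sin(2 * pi * 1 * t_rel)),
                       0.10 * sin(2 * pi * 2 * t_rel + pi / 4)),
    "running"  = cbind(0.25 * sin(2 * pi * 3 * t_rel),
                       0.80 * abs(sin(2 * pi * 1.5 * t_rel)),
                       0.30 * sin(2 * pi * 3 * t_rel + pi / 4)),
    "jump"     = burst(0.10, 3.00, 0.20, gauss),
    "fall"     = burst(1.50, -3.00, 1.50, gauss),
    stop("no accelerometer template for label '", label, "'")
  )
  if (!is.na(amp)) {
    base <- max(abs(a))
    if (base > 0) a <- a * (amp / base)
  }
  a
}

#' Simulate a 3-axis accelerometer trace from a script
#'
#' Produces the wearable-side view of a script: per-activity template bursts
#' plus a +1 g gravity offset on the vertical (y) axis and additive Gaussian
#' noise. Ground-truth per-sample labels and the noise-free template are
#' retained as attributes.
#'
#' @param script An [activity_script()].
#' @param fs Sampling frequency in Hz (nominal 100).
#' @param noise_sd Noise standard deviation in g (per axis).
#' @param seed Integer seed.
#' @return An `accel_trace` (see [accel_trace()]) with attributes `gt_labels`
#'   (per-sample activity code or `"none"`) and `gt_template` (noise-free
#'   trace including gravity).
#' @export
simulate_accelerometer <- function(script, fs = 100, noise_sd = 0.02,
                                   seed = 1L) {
  stopifnot(inherits(script, "activity_script"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (fs <= 0) stop("fs must be > 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- round(fs * script_duration(script))
  t <- (seq_len(n) - 1) / fs
  a <- matrix(0, n, 3L)
  labels <- rep("none", n)
  segs <- script$segments
  for (s in seq_len(nrow(segs))) {
    idx <- which(t >= segs$start[s] - 1e-9 &
                 t < segs$start[s] + segs$duration[s] - 1e-9)
    if (!length(idx)) next
    a[idx, ] <- a[idx, ] + accel_template(segs$label[s], t[idx] - segs$start[s],
                                          segs$duration[s], segs$amp[s])
    labels[idx] <- segs$label[s]
  }
  a[, 2L] <- a[, 2L] + 1            # gravity on the vertical axis
  template <- a
  if (noise_sd > 0) a <- a + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3L)
  tr <- accel_trace(t, a[, 1L], a[, 2L], a[, 3L], fs = fs)
  attr(tr, "gt_labels") <- labels
  attr(tr, "gt_template") <- template
  tr
}

#' Simulate a single-lead ECG trace
#'
#' A PQRST-like waveform built from Gaussian bumps placed at known beat
#' times; beat times are retained as ground truth for QRS-detector checks.
#'
#' @param heart_rate Beats per minute, in \[30, 220\].
#' @param fs Sampling frequency in Hz.
#' @param duration Trace duration in seconds (> 0).
#' @param noise_sd Additive Gaussian noise SD (signal units).
#' @param seed Integer seed.
#' @return A `signal_trace` (data frame `t`, `v` with attribute `fs`) plus
#'   attribute `gt_beats` (R-wave times in seconds).
#' @export
simulate_ecg <- function(heart_rate, fs = 200, duration = 30,
                         noise_sd = 0, seed = 1L) {
  if (heart_rate < 30 || heart_rate > 220)
    stop("heart_rate must be within [30, 220] bpm")
  if (duration <= 0) stop("duration must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  rr <- 60 / heart_rate
  beat_times <- seq(0.5, duration - 0.3, by = rr)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  v <- numeric(n)
  bump <- function(centre, amp, width) amp * exp(-(t - centre)^2 / (2 * width^2))
  for (b in beat_times) {
    v <- v + bump(b - 0.20, 0.25, 0.040) +  # P
         bump(b - 0.035, -0.10, 0.012) +    # Q
         bump(b, 1.00, 0.012) +             # R
         bump(b + 0.035, -0.20, 0.014) +    # S
         bump(b + 0.25, 0.35, 0.060)        # T
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n, sd = noise_sd)
  tr <- structure(data.frame(t = t, v = v), class = c("signal_trace",
                                                      "data.frame"),
                  fs = fs, gt_beats = beat_times)
  tr
}

#' Simulate a GPS track at constant speed and heading
#'
#' Straight-line track on the sphere, for outdoor feature experiments.
#'
#' @param speed Ground speed in m/s (may be a per-fix vector).
#' @param duration Seconds.
#' @param fix_rate Fixes per second (GPS receivers are typically 1 Hz).
#' @param heading Degrees clockwise from north.
#' @param origin `c(lon, lat)` of the first fix.
#' @param noise_m Per-fix position jitter SD in metres.
#' @param seed Integer seed.
#' @return Data frame `t`, `lat`, `lon`.
#' @export
simulate_gps <- function(speed, duration, fix_rate = 1, heading = 90,
                         origin = c(19.9, 50.06), noise_m = 0, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- floor(duration * fix_rate) + 1L
  t <- (seq_len(n) - 1) / fix_rate
  sp <- rep_len(speed, n)
  dist <- c(0, cumsum(sp[-n] / fix_rate))
  pts <- geosphere::destPoint(origin, heading, dist)
  if (noise_m > 0) {
    jitter <- matrix(stats::rnorm(2L * n, sd = noise_m), n, 2L)
    pts <- geosphere::destPoint(pts, stats::runif(n, 0, 360),
                                sqrt(rowSums(jitter^2)))
  }
  data.frame(t = t, lat = pts[, "lat"], lon = pts[, "lon"])
}

#' Generate a synchronized dual sensor stream with a known delay
#'
#' Renders the script to frames and simulates the matching accelerometer
#' trace, then shifts the accelerometer timestamps by exactly `delay`
#' seconds, emulating processing/transmission lag between the wearable and
#' premise-embedded paths. The injected delay is kept as ground truth for
#' synchronization experiments.
#'
#' @param script An [activity_script()].
#' @param scene A [scene_spec()].
#' @param fs Accelerometer rate, Hz.
#' @param delay Seconds the accelerometer stream lags the video stream.
#'   Must satisfy `abs(delay) < script_duration(script) / 4`.
#' @param noise_sd Accelerometer noise SD in g.
#' @param seed Integer seed (drives both modalities).
#' @return List with `frames` (a `frame_sequence`), `accel` (an
#'   `accel_trace` with shifted timestamps) and attribute `gt_delay`.
#' @export
make_dual_stream <- function(script, scene, fs = 100, delay = 0,
                             noise_sd = 0.02, seed = 1L) {
  if (abs(delay) >= script_duration(script) / 4)
    stop("abs(delay) must be < total duration / 4")
  frames <- render_silhouette_sequence(script, scene, seed = seed)
  accel <- simulate_accelerometer(script, fs = fs, noise_sd = noise_sd,
                                  seed = seed + 10007L)
  accel$t <- accel$t + delay
  structure(list(frames = frames, accel = accel), gt_delay = delay,
            class = "dual_stream")
}

# random texture with a correlation length of a few pixels: white noise
# blurred by a separable moving average, rescaled to the requested contrast.
# Gradient-based flow needs structure wider than one pixel to latch onto.
.smooth_texture <- function(h, w, contrast, k = 5L) {
  m <- matrix(stats::runif(h * w), h, w)
  m <- stats::filter(m, rep(1 / k, k), circular = TRUE)
  m <- t(stats::filter(t(m), rep(1 / k, k), circular = TRUE))
  m <- (m - mean(m)) / max(abs(range(m - mean(m))))
  matrix(pmin(pmax(0.5 + contrast * m / 2, 0), 1), h, w)
}

# save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
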