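#' Names of the seven elementary pose classes
#'
#' The twelve indoor activity codes collapse into six movements (the a/b
#' phases of one movement belong to the same class); "undetermined"
#' completes the basis, so any subject state is a convex combination of
#' P = 7 elementary poses.
#'
#' @return Character vector of length 7.
#' @export
pose_classes <- function() {
  c(paste0("class", 1:6), "undetermined")
}

#' Build a pose-contribution state vector
#'
#' @param w Numeric vector of 7 nonnegative contribution coefficients
#'   (classes 1..6 then "undetermined"); normalized to sum to 1.
#' @param timestamp Optional time in seconds.
#' @return Named numeric vector of class `state_vector`.
#' @export
state_vector <- function(w, timestamp = NA_real_) {
  if (length(w) != 7L) stop("a state has exactly 7 contributions")
  if (any(w < -1e-12)) stop("contributions must be nonnegative")
  s <- sum(w)
  if (s <= 0) stop("contributions must not be all zero")
  structure(stats::setNames(as.numeric(w) / s, pose_classes()),
            timestamp = timestamp, class = "state_vector")
}

#' State vector from classifier votes
#'
#' Collapses k-NN neighbor labels into pose-contribution coefficients:
#' activity codes `1a`/`1b` map to class 1 and so on, and each class
#' receives its fraction of the k votes. When the nearest neighbor is
#' farther than `undetermined_threshold` the full mass goes to the
#' "undetermined" pose.
#'
#' @param labels Neighbor labels (activity codes or `"undetermined"`).
#' @param distances Optional neighbor distances (same length).
#' @param undetermined_threshold Distance above which the state is declared
#'   undetermined.
#' @param timestamp Optional time in seconds.
#' @return A [state_vector()].
#' @export
state_from_classification <- function(labels, distances = NULL,
                                      undetermined_threshold = Inf,
                                      timestamp = NA_real_) {
  w <- numeric(7L)
  if (!is.null(distances) && length(distances) &&
      min(distances) > undetermined_threshold) {
    w[7L] <- 1
    return(state_vector(w, timestamp))
  }
  for (lb in labels) {
    cls <- if (lb == "undetermined") 7L else {
      k <- suppressWarnings(as.integer(substr(lb, 1L, 1L)))
      if (is.na(k) || k < 1L || k > 6L)
        stop("label '", lb, "' is not an activity code")
      k
    }
    w[cls] <- w[cls] + 1
  }
  state_vector(w / length(labels), timestamp)
}

.as_state_matrix <- function(x) {
  if (inherits(x, "state_vector")) x <- matrix(x, nrow = 1L)
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (ncol(x) != 7L) stop("state sequences must have 7 pose contributions")
  x
}

#' Pairwise squared state distances between two sequences
#'
#' Entry (i, j) is the squared difference between the i-th state of the
#' first sequence and the j-th state of the second: the sum over the seven
#' pose classes of the squared coefficient differences.
#'
#' @param x1,x2 State sequences: matrices (rows = states, 7 columns), lists
#'   of [state_vector()]s, or single state vectors.
#' @return An l1 x l2 matrix of nonnegative distances.
#' @export
distance_matrix <- function(x1, x2) {
  m1 <- .as_state_matrix(x1); m2 <- .as_state_matrix(x2)
  if (nrow(m1) < 1L || nrow(m2) < 1L) stop("sequences must be nonempty")
  d <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * tcrossprod(m1, m2)
  d[d < 0] <- 0
  d
}

#' Dynamic time warping between two state sequences
#'
#' Aligns two behavioral sequences by a monotone path through their distance
#' matrix, from (1, 1) to (l1, l2) with steps right, down or diagonal, and
#' returns the alignment minimizing the accumulated squared state distance.
#' The cost depends on both amplitude differences and the local timing
#' differences the warping absorbs.
#'
#' @param x1,x2 State sequences (see [distance_matrix()]).
#' @param root_distance Use the square-rooted (Euclidean) local distance
#'   instead of the squared one.
#' @return A `dtw_result`: list with `cost`, `path` (K x 2 matrix of
#'   indices), `step_costs` and the distance matrix `d`.
#' @export
dtw_align <- function(x1, x2, root_distance = FALSE) {
  d <- distance_matrix(x1, x2)
  if (root_distance) d <- sqrt(d)
  l1 <- nrow(d); l2 <- ncol(d)
  acc <- matrix(Inf, l1, l2)
  acc[1L, ] <- cumsum(d[1L, ])
  if (l1 > 1L) acc[, 1L] <- cumsum(d[, 1L])
  if (l1 > 1L && l2 > 1L) {
    for (i in 2:l1) {
      for (j in 2:l2) {
        acc[i, j] <- d[i, j] + min(acc[i - 1L, j], acc[i, j - 1L],
                                   acc[i - 1L, j - 1L])
      }
    }
  }
  # backtracking; diagonal preferred on ties
  path <- matrix(c(l1, l2), 1L, 2L)
  i <- l1; j <- l2
  while (i > 1L || j > 1L) {
    if (i == 1L) { j <- j - 1L }
    else if (j == 1L) { i <- i - 1L }
    else {
      prev <- c(acc[i - 1L, j - 1L], acc[i - 1L, j], acc[i, j - 1L])
      pick <- which.min(prev)
      if (pick == 1L) { i <- i - 1L; j <- j - 1L }
      else if (pick == 2L) { i <- i - 1L }
      else { j <- j - 1L }
    }
    path <- rbind(c(i, j), path)
  }
  colnames(path) <- c("phi1", "phi2")
  step_costs <- d[path]
  structure(list(cost = acc[l1, l2], path = path, step_costs = step_costs,
                 d = d), class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> cost=%.4f, path length K=%d (%dx%d)\n",
              x$cost, nrow(x$path), nrow(x$d), ncol(x$d)))
  invisible(x)
}

#' Behavioral-pattern statistics from labeled status segments
#'
#' Summarizes a behavioral record into one pattern per status label: mean
#' and standard deviation of segment duration, plus the successor labels
#' ordered by observed transition probability.
#'
#' @param segments Data frame with columns `label` and `duration` (s), in
#'   chronological order.
#' @return Named list of `behavioral_pattern`s, each a list with `label`,
#'   `mean_duration`, `sd_duration`, `n` and `successors` (data frame
#'   `label`, `prob`, descending).
#' @export
pattern_statistics <- function(segments) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L,
            all(c("label", "duration") %in% names(segments)))
  labs <- as.character(segments$label)
  out <- lapply(unique(labs), function(lb) {
    dur <- segments$duration[labs == lb]
    nexts <- labs[which(labs == lb & seq_along(labs) < length(labs)) + 1L]
    succ <- if (length(nexts)) {
      tb <- sort(table(nexts), decreasing = TRUE)
      data.frame(label = names(tb), prob = as.numeric(tb) / sum(tb))
    } else data.frame(label = character(0), prob = numeric(0))
    structure(list(label = lb, mean_duration = mean(dur),
                   sd_duration = if (length(dur) > 1L) stats::sd(dur) else 0,
                   n = length(dur), successors = succ),
              class = "behavioral_pattern")
  })
  stats::setNames(out, unique(labs))
}

#' Cluster behavioral sequences by pairwise warping cost
#'
#' Agglomerative (average-linkage) grouping of sequences on their pairwise
#' DTW costs, cut at a cost threshold; each group receives a fresh symbol.
#' Groups isolate pattern families — e.g. ones carrying danger information —
#' under one label.
#'
#' @param sequences List of state sequences (>= 2).
#' @param linkage_threshold Cost at which the dendrogram is cut.
#' @param root_distance Passed to [dtw_align()].
#' @return Integer-free grouping: list with `groups` (character vector of
#'   symbols, one per sequence) and `cost_matrix`.
#' @export
cluster_patterns <- function(sequences, linkage_threshold,
                             root_distance = FALSE) {
  n <- length(sequences)
  if (n < 2L) stop("need at least two sequences")
  cm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cm[i, j] <- cm[j, i] <- dtw_align(sequences[[i]], sequences[[j]],
                                        root_distance)$cost
    }
  }
  hc <- stats::hclust(stats::as.dist(cm), method = "average")
  grp <- stats::cutree(hc, h = linkage_threshold)
  list(groups = paste0("G", grp), cost_matrix = cm)
}

#' Create an empty two-level behavioral record
#'
#' The record is a two-level graph: outer nodes localize the subject in a
#' premise zone; inner nodes describe the status while there, each holding
#' a probability-ordered list of status hypotheses.
#'
#' @param zones Character vector of valid zone identifiers.
#' @return An object of class `behavioral_record`.
#' @export
behavioral_record <- function(zones) {
  structure(list(zones = zones, outer = list()), class = "behavioral_record")
}

#' Append an observation to a behavioral record
#'
#' A new inner node (state plus candidate status list, stored sorted by
#' descending probability) is added under the current outer node; a new
#' outer node is opened only when the zone changes. Earlier nodes are never
#' modified.
#'
#' @param record A [behavioral_record()].
#' @param zone Zone identifier (must be known to the record).
#' @param state A [state_vector()].
#' @param candidates Data frame `label`, `prob` of status hypotheses.
#' @param timestamp Observation time, seconds.
#' @param raw_ref Optional pointer to a raw-data strip.
#' @return The extended record.
#' @export
record_append <- function(record, zone, state, candidates,
                          timestamp = NA_real_, raw_ref = NULL) {
  if (!zone %in% record$zones) stop("unknown zone '", zone, "'")
  candidates <- candidates[order(-candidates$prob), , drop = FALSE]
  rownames(candidates) <- NULL
  inner <- list(state = state, candidates = candidates,
                timestamp = timestamp, raw_ref = raw_ref)
  k <- length(record$outer)
  if (k == 0L || record$outer[[k]]$zone != zone) {
    record$outer[[k + 1L]] <- list(zone = zone, entered = timestamp,
                                   inner = list(inner))
  } else {
    record$outer[[k]]$inner[[length(record$outer[[k]]$inner) + 1L]] <- inner
  }
  record
}

#' @export
print.behavioral_record <- function(x, ...) {
  cat(sprintf("<behavioral_record> %d outer node(s): %s\n", length(x$outer),
              paste(vapply(x$outer, function(o)
                sprintf("%s[%d]", o$zone, length(o$inner)), ""),
                collapse = " -> ")))
  invisible(x)
}
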