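#' Premise database
#'
#' Describes the subject's premise: the purpose of each zone, the poses
#' forbidden there (e.g. no lying in the kitchen), operating limits of
#' sensorized appliances (e.g. a kettle off its base for at most 90 s), and
#' the probabilities of displacement between zones.
#'
#' @param zones Data frame with columns `id`, `purpose` and a list-column
#'   `forbidden` of forbidden pose classes (or a plain character column of
#'   comma-separated classes).
#' @param appliances Data frame `id`, `max_duration` (seconds, > 0).
#' @param transitions Optional square matrix of zone-transition
#'   probabilities (rows sum to 1), dimnames = zone ids.
#' @return An object of class `premise_db`.
#' @export
premise_db <- function(zones, appliances = NULL, transitions = NULL) {
  stopifnot(is.data.frame(zones), "id" %in% names(zones))
  if (is.null(zones$forbidden)) zones$forbidden <- replicate(nrow(zones),
                                                             character(0),
                                                             simplify = FALSE)
  if (is.character(zones$forbidden))
    zones$forbidden <- lapply(strsplit(zones$forbidden, ","), trimws)
  if (!is.null(appliances)) {
    stopifnot(all(c("id", "max_duration") %in% names(appliances)))
    if (any(appliances$max_duration <= 0))
      stop("appliance max_duration must be > 0")
  }
  if (!is.null(transitions)) {
    if (!all(rownames(transitions) %in% zones$id))
      stop("transition matrix rows must be known zones")
    if (any(abs(rowSums(transitions) - 1) > 1e-9))
      stop("zone-transition probabilities must sum to 1 per zone")
  }
  structure(list(zones = zones, appliances = appliances,
                 transitions = transitions), class = "premise_db")
}

#' Subject database
#'
#' Per-subject knowledge learned by the system: the library of safe
#' behavioral patterns (state sequences recorded during everyday life and
#' vetted by the operator) and the warping-cost thresholds separating the
#' behavior categories normal < suspicious < dangerous < critical.
#'
#' The default cut points follow the scale of the squared-distance DTW cost
#' on pose-contribution states: two one-hot states of different class are
#' 2 apart, so 0.5 tolerates coefficient noise around a known pattern (N),
#' 4 corresponds to roughly two mismatched states (S), and beyond 12 the
#' sequence shares little with any safe pattern (C).
#'
#' @param subject_id Identifier.
#' @param safe_patterns List of state sequences (may be empty before
#'   learning).
#' @param thresholds Named numeric `c(suspicious=, dangerous=, critical=)`,
#'   strictly increasing.
#' @return An object of class `subject_db`.
#' @export
subject_db <- function(subject_id, safe_patterns = list(),
                       thresholds = c(suspicious = 0.5, dangerous = 4,
                                      critical = 12)) {
  need <- c("suspicious", "dangerous", "critical")
  if (!all(need %in% names(thresholds)))
    stop("thresholds must name suspicious, dangerous and critical")
  th <- thresholds[need]
  if (any(diff(th) <= 0))
    stop("thresholds must be ordered: suspicious < dangerous < critical")
  structure(list(subject_id = subject_id, safe_patterns = safe_patterns,
                 thresholds = th), class = "subject_db")
}

#' Behavior category order
#' @return Factor levels in increasing severity: N, S, D, C.
#' @export
category_levels <- function() c("N", "S", "D", "C")

.escalate <- function(cat, by = 1L) {
  lv <- category_levels()
  lv[min(length(lv), match(cat, lv) + by)]
}

#' Check pose and appliance permissions
#'
#' A violation is raised when the dominant pose of the state (the class with
#' the largest contribution; "undetermined" never violates) is on the
#' zone's forbidden list, and for every appliance event exceeding its
#' maximum allowed duration. Events for appliances unknown to the database
#' produce a warning, not a violation.
#'
#' @param state A [state_vector()].
#' @param zone Zone id (must exist in `db`).
#' @param db A [premise_db()].
#' @param appliance_events Optional data frame `id`, `elapsed` (seconds the
#'   appliance has been in its flagged state).
#' @return Data frame `type` (`"pose"`/`"appliance"`), `what`, `detail` —
#'   zero rows when nothing is violated.
#' @export
check_permissions <- function(state, zone, db, appliance_events = NULL) {
  zi <- match(zone, db$zones$id)
  if (is.na(zi)) stop("unknown zone '", zone, "'")
  out <- data.frame(type = character(0), what = character(0),
                    detail = character(0))
  dominant <- pose_classes()[which.max(state)]
  forbidden <- db$zones$forbidden[[zi]]
  if (dominant != "undetermined" && dominant %in% forbidden)
    out <- rbind(out, data.frame(type = "pose", what = dominant,
                                 detail = sprintf("'%s' forbidden in zone %s",
                                                  dominant, zone)))
  if (!is.null(appliance_events) && nrow(appliance_events)) {
    for (r in seq_len(nrow(appliance_events))) {
      id <- appliance_events$id[r]
      ai <- if (is.null(db$appliances)) NA else match(id, db$appliances$id)
      if (is.na(ai)) {
        warning("unknown appliance '", id, "'")
        next
      }
      lim <- db$appliances$max_duration[ai]
      if (appliance_events$elapsed[r] > lim)
        out <- rbind(out, data.frame(type = "appliance", what = id,
                                     detail = sprintf(
                                       "%s active %.0f s (limit %.0f s)",
                                       id, appliance_events$elapsed[r], lim)))
    }
  }
  out
}

#' Categorize a behavioral sequence against the safe-pattern library
#'
#' Computes the minimum DTW cost between the sequence and every stored safe
#' pattern and maps it to a category band: normal up to the suspicious
#' threshold, then suspicious, dangerous, critical. Any permission
#' violation escalates the category by one band.
#'
#' @param sequence A state sequence.
#' @param db A [subject_db()] with a nonempty safe-pattern library.
#' @param violations Number of permission violations accompanying the
#'   sequence (or the data frame from [check_permissions()]).
#' @return A one-letter category (`"N"`, `"S"`, `"D"`, `"C"`) with
#'   attribute `cost` (the minimal warping cost).
#' @export
categorize <- function(sequence, db, violations = 0L) {
  if (!length(db$safe_patterns))
    stop("safe-pattern library is empty; run the learning mode first")
  if (is.data.frame(violations)) violations <- nrow(violations)
  cost <- min(vapply(db$safe_patterns, function(p)
    dtw_align(sequence, p)$cost, 0))
  th <- db$thresholds
  cat <- if (cost <= th["suspicious"]) "N"
         else if (cost <= th["dangerous"]) "S"
         else if (cost <= th["critical"]) "D"
         else "C"
  if (violations > 0L) cat <- .escalate(cat)
  structure(cat, cost = cost)
}

#' Run one pass of the danger-detection life cycle
#'
#' The mechanism runs in one of three modes. In setup, the operator's
#' configuration events populate the permission lists and alerting rules.
#' In learning, observed sequences are appended to the safe-pattern library
#' and detailed sensor data are recorded when a limit is exceeded or the
#' subject presses the button — but no alerts are raised. In supervision,
#' every sequence is categorized: dangerous and critical behavior raises an
#' alert, and everything from suspicious upward triggers a detail recording
#' for later human review.
#'
#' @param mode `"setup"`, `"learning"` or `"supervision"` (the text also
#'   calls supervision the discrimination mode).
#' @param events List of event lists. Recognized types: `sequence`
#'   (`seq`, `zone`, optional `id`, `time`, `appliance_events`), `button`
#'   (`time`), `config` (setup only: `zones`, `appliances`).
#' @param premise A [premise_db()].
#' @param subject A [subject_db()].
#' @return List with updated `premise`, `subject` and `actions` (list of
#'   `record_detail` / `alert` / `learned_pattern` / `configured` entries).
#' @export
run_mode <- function(mode = c("setup", "learning", "supervision"),
                     events, premise, subject) {
  mode <- match.arg(mode)
  if (mode == "supervision" && !length(subject$safe_patterns))
    stop("supervision requires learned patterns; run the learning mode first")
  actions <- list()
  emit <- function(a) actions[[length(actions) + 1L]] <<- a
  for (ev in events) {
    type <- ev$type %||% "sequence"
    if (mode == "setup") {
      if (type == "config") {
        if (!is.null(ev$zones)) premise$zones <- ev$zones
        if (!is.null(ev$appliances)) premise$appliances <- ev$appliances
        emit(list(action = "configured", time = ev$time %||% NA_real_))
      }
      next
    }
    if (type == "button") {
      if (mode == "learning")
        emit(list(action = "record_detail", reason = "button",
                  id = ev$id %||% NA_character_, time = ev$time %||% NA_real_,
                  severity = "S"))
      next
    }
    if (type != "sequence") next
    viol <- check_permissions(.sequence_last_state(ev$seq), ev$zone, premise,
                              ev$appliance_events)
    if (mode == "learning") {
      subject$safe_patterns <- c(subject$safe_patterns, list(ev$seq))
      emit(list(action = "learned_pattern", id = ev$id %||% NA_character_,
                time = ev$time %||% NA_real_))
      if (nrow(viol))
        emit(list(action = "record_detail", reason = "limit_exceeded",
                  id = ev$id %||% NA_character_, time = ev$time %||% NA_real_,
                  severity = "S"))
    } else {  # supervision
      cat <- categorize(ev$seq, subject, viol)
      if (cat %in% c("D", "C"))
        emit(list(action = "alert", category = as.character(cat),
                  id = ev$id %||% NA_character_, time = ev$time %||% NA_real_))
      if (cat %in% c("S", "D", "C"))
        emit(list(action = "record_detail", reason = "category",
                  severity = as.character(cat), id = ev$id %||% NA_character_,
                  time = ev$time %||% NA_real_,
                  cost = attr(cat, "cost"), raw_ref = ev$raw_ref))
    }
  }
  list(premise = premise, subject = subject, actions = actions)
}

.sequence_last_state <- function(s) {
  m <- .as_state_matrix(s)
  state_vector(m[nrow(m), ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordered review queue of suspicious events
#'
#' Collects the detail-recording actions of severity S and above and orders
#' them for human inspection: most severe first, then earliest first;
#' duplicate event ids are dropped (first occurrence kept).
#'
#' @param actions Action list as returned by [run_mode()].
#' @return Data frame `id`, `severity`, `time`, `reason`.
#' @export
review_queue <- function(actions) {
  recs <- Filter(function(a) identical(a$action, "record_detail") &&
                   (a$severity %||% "N") %in% c("S", "D", "C"), actions)
  if (!length(recs))
    return(data.frame(id = character(0), severity = character(0),
                      time = numeric(0), reason = character(0)))
  df <- do.call(rbind, lapply(recs, function(a)
    data.frame(id = a$id %||% NA_character_, severity = a$severity,
               time = a$time %||% NA_real_,
               reason = a$reason %||% NA_character_)))
  df <- df[order(-match(df$severity, category_levels()), df$time), ,
           drop = FALSE]
  df <- df[!duplicated(df$id) | is.na(df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
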