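onehot_seq <- function(cls, len) {
  m <- matrix(0, len, 7L); m[, cls] <- 1; m
}

demo_premise <- function() {
  premise_db(
    zones = data.frame(id = c("kitchen", "bedroom"),
                       purpose = c("cooking", "sleeping"),
                       forbidden = I(list("class5", character(0)))),
    appliances = data.frame(id = "kettle", max_duration = 90))
}

demo_subject <- function(patterns = list(onehot_seq(1, 4))) {
  subject_db("V1", safe_patterns = patterns)
}

test_that("database constructors validate their invariants", {
  expect_error(premise_db(data.frame(id = "a"),
                          appliances = data.frame(id = "k",
                                                  max_duration = -5)),
               "max_duration")
  tm <- matrix(c(0.5, 0.4, 0.5, 0.6), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))  # rows 0.9 / 1.1
  expect_error(premise_db(data.frame(id = c("a", "b")), transitions = tm),
               "sum to 1")
  tm2 <- matrix(c(0.5, 0.5, 0.4, 0.6), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_s3_class(premise_db(data.frame(id = c("a", "b")),
                             transitions = tm2), "premise_db")
  expect_error(subject_db("V1", thresholds = c(suspicious = 3, dangerous = 2,
                                               critical = 9)),
               "ordered")
})

test_that("pose and appliance permissions are enforced", {
  db <- demo_premise()
  lying <- state_vector(c(0, 0, 0, 0, 1, 0, 0))   # class5 dominant
  v <- check_permissions(lying, "kitchen", db)
  expect_equal(nrow(v), 1L)
  expect_equal(v$type, "pose")
  expect_equal(nrow(check_permissions(lying, "bedroom", db)), 0L)

  standing <- state_vector(c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(nrow(check_permissions(standing, "kitchen", db)), 0L)
  # undetermined never violates pose permissions
  und <- state_vector(c(0, 0, 0, 0, 0, 0, 1))
  expect_equal(nrow(check_permissions(und, "kitchen", db)), 0L)

  ok <- check_permissions(standing, "kitchen", db,
                          data.frame(id = "kettle", elapsed = 89))
  expect_equal(nrow(ok), 0L)
  bad <- check_permissions(standing, "kitchen", db,
                           data.frame(id = "kettle", elapsed = 91))
  expect_equal(bad$type, "appliance")
  expect_warning(check_permissions(standing, "kitchen", db,
                                   data.frame(id = "toaster", elapsed = 10)),
                 "unknown appliance")
  expect_error(check_permissions(standing, "garage", db), "unknown zone")
})

test_that("sequences are categorized by distance to the safe library", {
  db <- demo_subject()
  same <- categorize(onehot_seq(1, 4), db)
  expect_equal(as.character(same), "N")
  expect_equal(attr(same, "cost"), 0)

  # disjoint one-hot classes: cost 2 * max(l1, l2) = 12 > dangerous (4)
  far <- categorize(onehot_seq(3, 6), db)
  expect_equal(as.character(far), "D")
  expect_equal(attr(far, "cost"), 12)

  # a permission violation escalates one band
  expect_equal(as.character(categorize(onehot_seq(1, 4), db,
                                       violations = 1L)), "S")
  expect_equal(as.character(categorize(onehot_seq(3, 6), db,
                                       violations = 2L)), "C")

  expect_error(categorize(onehot_seq(1, 4), demo_subject(list())),
               "learning")
})

test_that("raising thresholds never increases any sequence's severity", {
  set.seed(12)
  lib <- list(random_state_seq(4), random_state_seq(5))
  seqs <- replicate(30, random_state_seq(sample(2:6, 1)), simplify = FALSE)
  sev <- function(th_mult) {
    db <- subject_db("V1", lib,
                     thresholds = c(suspicious = 0.5, dangerous = 4,
                                    critical = 12) * th_mult)
    vapply(seqs, function(s)
      match(as.character(categorize(s, db)), category_levels()), 0L)
  }
  s1 <- sev(1); s2 <- sev(1.5); s3 <- sev(3)
  expect_true(all(s2 <= s1))
  expect_true(all(s3 <= s2))
})

test_that("the learning mode records patterns but never alerts", {
  prem <- demo_premise()
  subj <- demo_subject(list())
  events <- list(
    list(type = "sequence", seq = onehot_seq(1, 4), zone = "bedroom",
         id = "e1", time = 10),
    list(type = "button", id = "e2", time = 20),
    list(type = "sequence", seq = onehot_seq(5, 4), zone = "kitchen",
         id = "e3", time = 30))  # lying in kitchen: limit exceeded
  out <- run_mode("learning", events, prem, subj)
  kinds <- vapply(out$actions, `[[`, "", "action")
  expect_false(any(kinds == "alert"))
  expect_equal(sum(kinds == "learned_pattern"), 2L)
  expect_equal(sum(kinds == "record_detail"), 2L)  # button + violation
  expect_length(out$subject$safe_patterns, 2L)
})

test_that("the supervision mode alerts on danger and records suspicion", {
  prem <- demo_premise()
  subj <- demo_subject()
  expect_error(run_mode("supervision", list(), prem, demo_subject(list())),
               "learning mode")

  events <- list(
    list(type = "sequence", seq = onehot_seq(1, 4), zone = "bedroom",
         id = "n1", time = 1),                     # normal
    list(type = "sequence", seq = onehot_seq(3, 6), zone = "bedroom",
         id = "d1", time = 2),                     # dangerous
    list(type = "sequence", seq = onehot_seq(3, 12), zone = "bedroom",
         id = "c1", time = 3))                     # critical (cost 24)
  out <- run_mode("supervision", events, prem, subj)
  kinds <- vapply(out$actions, `[[`, "", "action")
  expect_equal(sum(kinds == "alert"), 2L)
  details <- Filter(function(a) a$action == "record_detail", out$actions)
  # every S/D/C categorization produces exactly one detail recording
  expect_equal(vapply(details, `[[`, "", "id"), c("d1", "c1"))
  # supervision never mutates the safe-pattern library
  expect_identical(out$subject$safe_patterns, subj$safe_patterns)
})

test_that("the setup mode only rewrites configuration", {
  prem <- demo_premise()
  newz <- data.frame(id = "studio", purpose = "all",
                     forbidden = I(list(character(0))))
  out <- run_mode("setup", list(list(type = "config", zones = newz)),
                  prem, demo_subject())
  expect_equal(out$premise$zones$id, "studio")
  expect_equal(vapply(out$actions, `[[`, "", "action"), "configured")
})

test_that("the review queue orders by severity then time and deduplicates", {
  expect_equal(nrow(review_queue(list())), 0L)
  acts <- list(
    list(action = "record_detail", severity = "S", id = "a", time = 1,
         reason = "category"),
    list(action = "record_detail", severity = "D", id = "b", time = 5,
         reason = "category"),
    list(action = "record_detail", severity = "S", id = "a", time = 9,
         reason = "category"),
    list(action = "alert", category = "D", id = "b", time = 5))
  q <- review_queue(acts)
  expect_equal(q$id, c("b", "a"))
  expect_equal(q$severity, c("D", "S"))
})
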