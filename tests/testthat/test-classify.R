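test_that("a template matches itself with zero distance and wins the
           vote", {
  cycles <- toy_corpus(subjects = "S01", n_per = 3)
  ts <- build_template_set(cycles)
  query <- make_cycle(ts$templates$LW$values, mode = NA,
                      channels = ts$channels, subject = "S01")
  p <- predict_single_set(query, ts, prefix_fraction = 1.0)
  expect_identical(p$mode, "LW")
  expect_equal(p$distances[["LW"]], 0)
  expect_gt(p$distances[["LW_SC"]], 0)
  expect_gt(p$distances[["LW_SD"]], 0)
})

test_that("another subject's cycles from the same prototypes are
           recognized", {
  cycles <- toy_corpus(subjects = c("S01", "S02"), n_per = 3,
                       noise_sd = 0.01, seed = 42)
  subj <- vapply(cycles, function(cy) cy$subject_id, "")
  ts <- build_template_set(cycles[subj == "S01"])
  for (cy in cycles[subj == "S02"]) {
    p <- predict_single_set(cy, ts, prefix_fraction = 1.0)
    expect_identical(p$mode, cy$mode)
  }
})

test_that("too-short prefixes are rejected", {
  cycles <- toy_corpus(subjects = "S01")
  ts <- build_template_set(cycles)
  query <- cycles[[1]]
  expect_error(predict_single_set(query, ts, prefix_fraction = 0.01),
               "minimum of 4")
})

test_that("missing channels raise parameter errors", {
  cycles <- toy_corpus(subjects = "S01")
  ts <- build_template_set(cycles)
  narrow <- gait_cycle("S01", "LW", "instr_hip.joint_angle",
                       cycles[[1]]$data[1, , drop = FALSE], fs = 100)
  expect_error(predict_single_set(narrow, ts), "lacks channel")
  expect_error(predict_single_set(cycles[[1]], ts,
                                  channels = "chest.accel.z"),
               "lacks channel")
})

test_that("plurality voting and the average-distance tie-break", {
  # hand-built voters: two say LW cheaply, two say LW_SC expensively
  mk_voter <- function(subject, lw_d, sc_d, sd_d, len = 40) {
    phi <- (0:(len - 1)) / len
    base <- sin(2 * pi * phi)
    cycles <- list(
      gait_cycle(subject, "LW", "chest.accel.y",
                 matrix(base + lw_d, 1), fs = 100),
      gait_cycle(subject, "LW_SC", "chest.accel.y",
                 matrix(base + sc_d, 1), fs = 100),
      gait_cycle(subject, "LW_SD", "chest.accel.y",
                 matrix(base + sd_d, 1), fs = 100))
    build_template_set(cycles)
  }
  query <- gait_cycle("QX", NA, "chest.accel.y",
                      matrix(sin(2 * pi * (0:39) / 40), 1), fs = 100)
  # voters 1-2 vote LW (offset 0), voters 3-4 vote LW_SC; LW distances are
  # smaller on average
  sets <- list(mk_voter("A", 0.0, 1.0, 2.0),
               mk_voter("B", 0.0, 1.1, 2.0),
               mk_voter("C", 0.9, 0.1, 2.0),
               mk_voter("D", 0.9, 0.2, 2.0))
  p <- predict_voted(query, sets)
  expect_true(p$tie_broken)
  expect_identical(p$final, "LW")

  # strict majority: no tie-break
  p2 <- predict_voted(query, sets[c(1, 2, 3)])
  expect_false(p2$tie_broken)
  expect_identical(p2$final, "LW")

  # single voter
  p3 <- predict_voted(query, sets[4])
  expect_identical(p3$final, "LW_SC")

  expect_error(predict_voted(query, list()), "at least one")
})

test_that("voting is invariant to voter order and never overturns
           unanimity", {
  b <- make_benchmark(generator_spec(n_subjects = 4, n_cycles = 12,
                                     seed = 17))
  subj <- vapply(b$cycles, function(cy) cy$subject_id, "")
  sets <- lapply(unique(subj)[1:3], function(s) {
    build_template_set(b$cycles[subj == s])
  })
  queries <- b$cycles[subj == unique(subj)[4]][1:6]
  for (q in queries) {
    p <- predict_voted(q, sets, prefix_fraction = 0.5)
    p_rev <- predict_voted(q, rev(sets), prefix_fraction = 0.5)
    expect_identical(p$final, p_rev$final)
    if (length(unique(p$per_voter$vote)) == 1L) {
      expect_identical(p$final, p$per_voter$vote[1])
    }
  }
})

test_that("the fitted classifier object predicts and prints", {
  b <- make_benchmark(generator_spec(n_subjects = 3, n_cycles = 12,
                                     seed = 19))
  chans <- b$manifest$spec$channels[1:8]
  fit <- mdtw_classifier(b$cycles, channels = chans)
  expect_s3_class(fit, "mdtw_classifier")
  expect_length(fit$template_sets, 3L)

  labels <- predict(fit, b$cycles[1:5], prefix_fraction = 0.5)
  expect_length(labels, 5L)
  expect_true(all(labels %in% gait_modes()))

  det <- predict(fit, b$cycles[[1]], prefix_fraction = 0.5, details = TRUE)
  expect_s3_class(det[[1]], "gait_prediction")

  # excluding a subject removes its voter
  det2 <- predict(fit, b$cycles[[1]], exclude_subject = "S01",
                  details = TRUE)
  expect_false("S01" %in% det2[[1]]$per_voter$subject)

  expect_output(print(fit), "voters")
  expect_output(print(summary(fit)), "Per-subject")
})

test_that("open-end matching agrees with truncation on full cycles", {
  cycles <- toy_corpus(subjects = "S01", n_per = 3)
  ts <- build_template_set(cycles)
  q <- cycles[[1]]
  p1 <- predict_single_set(q, ts, prefix_fraction = 1.0)
  p2 <- predict_single_set(q, ts, prefix_fraction = 1.0, open_end = TRUE)
  expect_identical(p1$mode, p2$mode)
  # open-end distances can only be <= the truncated ones at the same prefix
  p3 <- predict_single_set(q, ts, prefix_fraction = 0.5)
  p4 <- predict_single_set(q, ts, prefix_fraction = 0.5, open_end = TRUE)
  expect_true(all(p4$distances <= p3$distances + 1e-12))
})
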