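test_that("confusion-matrix metrics match hand arithmetic", {
  cm <- rbind(c(8, 2, 0), c(1, 9, 0), c(0, 0, 10))
  dimnames(cm) <- list(gait_modes(), gait_modes())
  expect_equal(pooled_accuracy(cm), 100 * 27 / 30)

  # per-class F1 by definition: precision_k = cm[k,k]/colsum,
  # recall_k = cm[k,k]/rowsum
  f1 <- numeric(3)
  for (k in 1:3) {
    p <- cm[k, k] / sum(cm[, k])
    r <- cm[k, k] / sum(cm[k, ])
    f1[k] <- 2 * p * r / (p + r)
  }
  expect_equal(macro_f1(cm), mean(f1))

  # degenerate: empty class contributes zero F1
  cm0 <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 0))
  expect_equal(macro_f1(cm0), 2 / 3)
})

test_that("confusion_matrix tabulates in fixed mode order", {
  cm <- confusion_matrix(c("LW", "LW_SC", "LW_SD", "LW"),
                         c("LW", "LW_SD", "LW_SD", "LW_SC"))
  expect_equal(as.numeric(diag(cm)), c(1, 0, 1))
  expect_equal(sum(cm), 4)
})

test_that("separable noiseless subjects give perfect LOSO accuracy", {
  spec <- generator_spec(n_subjects = 3, n_cycles = 12,
                         noise_snr_db = Inf, seed = 23)
  b <- make_benchmark(spec)
  r <- loso_evaluate(b$cycles, channels = spec$channels[1:8],
                     prefix_fraction = 0.3)
  expect_equal(r$accuracy, 100)
  expect_equal(r$macro_f1, 1)
  # report invariants: rows of the pooled confusion sum to evaluated counts
  expect_equal(sum(r$confusion), sum(r$per_subject$n))
  expect_equal(r$accuracy,
               100 * sum(diag(r$confusion)) / sum(r$confusion))
})

test_that("LOSO excludes the held-out subject from every voting pool", {
  spec <- generator_spec(n_subjects = 3, n_cycles = 12, seed = 29)
  b <- make_benchmark(spec)
  aug <- augment_transitions(b$cycles, augmentation_spec(seed = 29))
  r <- loso_evaluate(aug, channels = spec$channels[1:8],
                     prefix_fraction = 0.5)
  expect_true(isTRUE(audit_loso(r, aug)))

  # the audit itself catches a poisoned record
  poisoned <- r
  poisoned$audit[[1]]$template_cycles[[1]]$LW <-
    c(poisoned$audit[[1]]$template_cycles[[1]]$LW,
      aug[[which(vapply(aug, function(cy) cy$subject_id, "") ==
                   poisoned$audit[[1]]$held_out)[1]]]$id)
  expect_false(isTRUE(audit_loso(poisoned, aug)))
})

test_that("prefix sweep reduces to plain LOSO at a single full fraction", {
  spec <- generator_spec(n_subjects = 3, n_cycles = 12, seed = 31)
  b <- make_benchmark(spec)
  chans <- spec$channels[1:8]
  sw <- prefix_sweep(b$cycles, fractions = 1.0, channels = chans)
  r <- loso_evaluate(b$cycles, channels = chans, prefix_fraction = 1.0)
  expect_equal(sw$summary$accuracy, r$accuracy)
  expect_equal(sw$summary$macro_f1, r$macro_f1)
  expect_identical(nrow(prefix_sweep(b$cycles, fractions = numeric(0),
                                     channels = chans)$summary), 0L)
})

test_that("forward selection recovers the informative channel pair and
           stops", {
  chans <- default_synth_channels()
  w <- matrix(0, length(chans), 2, dimnames = list(chans, c("sc", "sd")))
  w["instr_hip.joint_angle", ] <- c(1.2, 0)    # separates LW_SC only
  w["chest.accel.y", ] <- c(0, 1.2)            # separates LW_SD only
  spec <- generator_spec(n_subjects = 4, n_cycles = 18, noise_snr_db = 30,
                         transition_rate = c(0.15, 0.15),
                         mode_weights = w, seed = 21)
  b <- make_benchmark(spec)
  tr <- forward_select(b$cycles, candidates = chans[1:8],
                       prefix_fraction = 0.3)
  expect_setequal(tr$selected,
                  c("instr_hip.joint_angle", "chest.accel.y"))
  expect_identical(tr$stopped_because, "no_improvement")
  expect_equal(tr$steps$accuracy[2], 100)
  expect_gt(tr$steps$accuracy[2], tr$steps$accuracy[1])
})

test_that("selection on a single candidate is a one-step trace", {
  b <- make_benchmark(generator_spec(n_subjects = 3, n_cycles = 12,
                                     seed = 37))
  tr <- forward_select(b$cycles, candidates = "instr_hip.joint_angle",
                       prefix_fraction = 0.5)
  expect_identical(nrow(tr$steps), 1L)
  expect_identical(tr$selected, "instr_hip.joint_angle")
})

test_that("pure-noise channels stop selection at one chance-level step", {
  chans <- default_synth_channels()
  w <- matrix(0, length(chans), 2, dimnames = list(chans, c("sc", "sd")))
  spec <- generator_spec(n_subjects = 4, n_cycles = 18, noise_snr_db = 10,
                         transition_rate = c(0.15, 0.15),
                         mode_weights = w, seed = 41)
  b <- make_benchmark(spec)
  tr <- forward_select(b$cycles, candidates = chans[1:6],
                       prefix_fraction = 0.5, max_channels = 3)
  # with no mode information every step hovers near the majority-class
  # rate (12/18); chance jitter may admit a step or two but never real
  # separation
  expect_lte(nrow(tr$steps), 3L)
  expect_lt(max(tr$steps$accuracy), 90)
})

test_that("a deviant subject benefits from personalized templates", {
  spec <- generator_spec(n_subjects = 5, n_cycles = 24, noise_snr_db = 30,
                         transition_rate = c(0.15, 0.15),
                         deviant_subjects = 3L, seed = 31)
  b <- make_benchmark(spec)
  subj <- vapply(b$cycles, function(cy) cy$subject_id, "")
  sets <- lapply(unique(subj), function(s) {
    build_template_set(b$cycles[subj == s])
  })
  names(sets) <- unique(subj)
  chans <- spec$channels[1:8]
  cp <- compare_personalized(b$cycles[subj == "S03"],
                             sets[setdiff(names(sets), "S03")],
                             fractions = c(0.3, 0.5, 1.0),
                             channels = chans)
  expect_gt(mean(cp$summary$personalized_accuracy),
            mean(cp$summary$independent_accuracy))

  # a typical subject drawn from the shared prototypes gains little
  cp2 <- compare_personalized(b$cycles[subj == "S02"],
                              sets[c("S01", "S04", "S05")],
                              fractions = c(0.3, 0.5, 1.0),
                              channels = chans)
  expect_lte(mean(cp2$summary$personalized_accuracy) -
               mean(cp2$summary$independent_accuracy), 10)

  one_per_mode <- b$cycles[subj == "S03"][1:3]
  expect_error(compare_personalized(one_per_mode,
                                    sets[setdiff(names(sets), "S03")]),
               ">= 2 cycles")
})
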