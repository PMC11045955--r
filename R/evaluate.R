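#' Confusion matrix and derived metrics
#'
#' `confusion_matrix()` tabulates true vs. predicted modes in the fixed
#' mode order; `pooled_accuracy()` is the trace over the total count
#' (micro accuracy, in percent); `macro_f1()` averages the per-class F1
#' scores (harmonic mean of precision and recall, 0 where undefined) over
#' the three classes, which keeps the heavily outnumbered transition
#' classes visible.
#'
#' @param truth,pred Character vectors of mode labels.
#' @param cm A 3x3 confusion matrix (rows = truth, cols = predicted).
#' @return `confusion_matrix()`: 3x3 integer matrix; `pooled_accuracy()`:
#'   percent in `[0, 100]`; `macro_f1()`: value in `[0, 1]`.
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  table(factor(truth, levels = gait_modes()),
        factor(pred, levels = gait_modes()))
}

#' @rdname confusion_matrix
#' @export
pooled_accuracy <- function(cm) {
  100 * sum(diag(cm)) / sum(cm)
}

#' @rdname confusion_matrix
#' @export
macro_f1 <- function(cm) {
  f1 <- vapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    prec_den <- sum(cm[, k])
    rec_den <- sum(cm[k, ])
    if (prec_den == 0 || rec_den == 0) return(0)
    p <- tp / prec_den
    r <- tp / rec_den
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, 0.0)
  mean(f1)
}

#' Leave-one-subject-out evaluation
#'
#' For each subject in turn, template sets are built from all OTHER
#' subjects' cycles (original cycles only, so augmented copies never enter
#' a voting pool) and every cycle of the held-out subject — augmented
#' copies included by default — is classified by [predict_voted()] at the
#' given prefix fraction. A subject lacking a mode is excluded from voting
#' pools with a warning but still evaluated.
#'
#' @param cycles Labeled cycles across >= 2 subjects.
#' @param channels Channel subset for classification (default: all).
#' @param prefix_fraction Fraction of the cycle available.
#' @param strategy,open_end,window See [predict_single_set()].
#' @param include_augmented Evaluate augmented (derived) held-out cycles
#'   too; `FALSE` restricts scoring to original cycles.
#' @return Object of class `"loso_report"`: `confusion` (pooled 3x3),
#'   `accuracy` (pooled %), `macro_f1`, `per_subject` data frame, `audit`
#'   (per-fold record of held-out subject, voter subjects and every
#'   template's contributing cycle ids), plus the settings used.
#' @export
loso_evaluate <- function(cycles, channels = NULL, prefix_fraction = 1.0,
                          strategy = c("dependent", "independent"),
                          open_end = FALSE, window = NULL,
                          include_augmented = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(is.list(cycles), length(cycles) >= 2L)
  all_channels <- assert_shared_channels(cycles)
  if (is.null(channels)) channels <- all_channels
  labeled <- Filter(function(cy) !is.na(cy$mode), cycles)
  subj <- vapply(labeled, function(cy) cy$subject_id, "")
  subjects <- unique(subj)
  if (length(subjects) < 2L) {
    stop("leave-one-subject-out needs >= 2 subjects", call. = FALSE)
  }

  # build each subject's template set once; drop subjects missing a mode
  sets <- list()
  for (s in subjects) {
    ts <- tryCatch(
      build_template_set(labeled[subj == s], subject_id = s),
      error = function(e) {
        warning("subject ", s, " excluded from voting pools: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(ts)) sets[[s]] <- ts
  }
  if (length(sets) < 2L) {
    stop("fewer than 2 subjects have complete template sets",
         call. = FALSE)
  }

  per_subject <- list()
  audit <- list()
  cm_total <- confusion_matrix(character(0), character(0))
  for (s in subjects) {
    pool <- sets[setdiff(names(sets), s)]
    if (!length(pool)) next
    eval_cycles <- labeled[subj == s]
    if (!include_augmented) eval_cycles <- Filter(is_original, eval_cycles)
    truth <- vapply(eval_cycles, function(cy) cy$mode, "")
    pred <- vapply(eval_cycles, function(cy) {
      predict_voted(cy, pool, channels = channels,
                    prefix_fraction = prefix_fraction,
                    strategy = strategy, open_end = open_end,
                    window = window)$final
    }, "")
    cm <- confusion_matrix(truth, pred)
    cm_total <- cm_total + cm
    per_subject[[s]] <- data.frame(subject = s,
                                   n = length(truth),
                                   accuracy = pooled_accuracy(cm),
                                   macro_f1 = macro_f1(cm))
    audit[[s]] <- list(
      held_out = s,
      voters = names(pool),
      template_cycles = lapply(pool, function(ts) {
        lapply(ts$templates, function(tp) tp$cycle_ids)
      }))
  }
  structure(list(confusion = cm_total,
                 accuracy = pooled_accuracy(cm_total),
                 macro_f1 = macro_f1(cm_total),
                 per_subject = do.call(rbind, per_subject),
                 audit = audit,
                 prefix_fraction = prefix_fraction,
                 channels = channels, strategy = strategy),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat(sprintf(
    "LOSO evaluation @ %.0f%% of gait cycle: accuracy %.2f%%, macro F1 %.4f\n",
    100 * x$prefix_fraction, x$accuracy, x$macro_f1))
  cat("Pooled confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Audit fold hygiene of a LOSO report
#'
#' Verifies, from the report's provenance record, that no held-out
#' subject's cycles (original or augmented) contributed to any template in
#' that subject's voting pool.
#'
#' @param report A [loso_evaluate()] result.
#' @param cycles The cycle corpus the report was computed from.
#' @return `TRUE` if clean; otherwise a character vector describing every
#'   violation.
#' @export
audit_loso <- function(report, cycles) {
  stopifnot(inherits(report, "loso_report"))
  owner <- vapply(cycles, function(cy) cy$subject_id, "")
  names(owner) <- vapply(cycles, function(cy) cy$id, "")
  violations <- character(0)
  for (fold in report$audit) {
    held <- fold$held_out
    if (held %in% fold$voters) {
      violations <- c(violations,
                      sprintf("fold %s: own template set in pool", held))
    }
    for (v in names(fold$template_cycles)) {
      for (m in names(fold$template_cycles[[v]])) {
        ids <- unlist(fold$template_cycles[[v]][[m]])
        from_held <- ids[!is.na(owner[ids]) & owner[ids] == held]
        if (length(from_held)) {
          violations <- c(violations,
                          sprintf("fold %s: voter %s/%s uses cycle(s) %s",
                                  held, v, m,
                                  paste(from_held, collapse = ",")))
        }
      }
    }
  }
  if (length(violations)) violations else TRUE
}

#' Accuracy and F1 across prefix fractions
#'
#' Runs [loso_evaluate()] at each requested fraction of the gait cycle,
#' emulating early-recognition operation where only the first part of the
#' cycle (counted from toe-off) is available.
#'
#' @param cycles,channels,strategy,open_end,window,include_augmented As in
#'   [loso_evaluate()].
#' @param fractions Vector of prefix fractions in `(0, 1]`.
#' @return Object of class `"prefix_sweep"`: list of reports plus a tidy
#'   `summary` data frame (`fraction`, `accuracy`, `macro_f1`).
#' @export
prefix_sweep <- function(cycles, fractions = seq(0.1, 1.0, by = 0.1),
                         channels = NULL,
                         strategy = c("dependent", "independent"),
                         open_end = FALSE, window = NULL,
                         include_augmented = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(all(fractions > 0), all(fractions <= 1))
  reports <- lapply(fractions, function(f) {
    loso_evaluate(cycles, channels = channels, prefix_fraction = f,
                  strategy = strategy, open_end = open_end,
                  window = window, include_augmented = include_augmented)
  })
  summary <- data.frame(
    fraction = fractions,
    accuracy = vapply(reports, function(r) r$accuracy, 0.0),
    macro_f1 = vapply(reports, function(r) r$macro_f1, 0.0))
  structure(list(reports = reports, summary = summary),
            class = "prefix_sweep")
}

#' @export
print.prefix_sweep <- function(x, ...) {
  cat("Prefix-fraction sweep (LOSO):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.prefix_sweep <- function(x, ...) {
  s <- x$summary
  graphics::plot(100 * s$fraction, s$accuracy, type = "b", pch = 19,
                 xlab = "gait cycle available (%)", ylab = "accuracy (%)",
                 ylim = c(min(s$accuracy) - 2, 100), ...)
  graphics::grid()
  invisible(x)
}

#' Greedy forward channel selection
#'
#' Starts from the single channel with the best pooled LOSO accuracy and,
#' at each step, adds the channel that most improves it. Selection stops
#' when no candidate strictly improves the accuracy (`rule =
#' "strict"`), when accuracy would degrade (`rule = "degradation"`, which
#' admits accuracy-neutral additions), or at `max_channels`.
#'
#' @param cycles Labeled cycles across subjects.
#' @param candidates Candidate channel strings (default: all channels).
#' @param prefix_fraction Prefix at which accuracy is measured.
#' @param max_channels Cap on the subset size.
#' @param rule `"strict"` or `"degradation"` stopping rule.
#' @param strategy,include_augmented As in [loso_evaluate()].
#' @return Object of class `"selection_trace"`: data frame `steps`
#'   (`channel`, `accuracy`, `macro_f1` for the nested subsets), `selected`
#'   channels, and `stopped_because` (`"no_improvement"` or
#'   `"max_channels"`).
#' @export
forward_select <- function(cycles, candidates = NULL, prefix_fraction = 0.3,
                           max_channels = NULL, rule = c("strict",
                                                         "degradation"),
                           strategy = "dependent",
                           include_augmented = TRUE) {
  rule <- match.arg(rule)
  all_channels <- assert_shared_channels(cycles)
  if (is.null(candidates)) candidates <- all_channels
  stopifnot(all(candidates %in% all_channels), length(candidates) >= 1L)
  if (is.null(max_channels)) max_channels <- length(candidates)

  selected <- character(0)
  steps <- list()
  best_acc <- -Inf
  stopped <- "max_channels"
  while (length(selected) < max_channels) {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) { stopped <- "max_channels"; break }
    trial <- lapply(remaining, function(ch) {
      r <- loso_evaluate(cycles, channels = c(selected, ch),
                         prefix_fraction = prefix_fraction,
                         strategy = strategy,
                         include_augmented = include_augmented)
      list(channel = ch, accuracy = r$accuracy, macro_f1 = r$macro_f1)
    })
    accs <- vapply(trial, function(t) t$accuracy, 0.0)
    best <- trial[[which.max(accs)]]
    improved <- if (rule == "strict") best$accuracy > best_acc
                else best$accuracy >= best_acc
    if (length(selected) && !improved) {
      stopped <- "no_improvement"
      break
    }
    selected <- c(selected, best$channel)
    best_acc <- best$accuracy
    steps[[length(steps) + 1L]] <- data.frame(
      channel = best$channel, accuracy = best$accuracy,
      macro_f1 = best$macro_f1)
  }
  structure(list(steps = do.call(rbind, steps), selected = selected,
                 stopped_because = stopped,
                 prefix_fraction = prefix_fraction, rule = rule),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Forward channel selection (LOSO accuracy @",
      sprintf("%.0f%%", 100 * x$prefix_fraction), "prefix):\n")
  print(x$steps, row.names = FALSE)
  cat("stopped because:", x$stopped_because, "\n")
  invisible(x)
}

#' Personalized vs. user-independent comparison
#'
#' Splits one subject's cycles in half per mode: the first halves build a
#' personalized template set, the second halves are evaluated (a) against
#' that personalized set alone and (b) against the other subjects'
#' template sets with voting (user-independent), at every prefix fraction.
#'
#' @param subject_cycles Labeled cycles of the subject (>= 2 originals per
#'   mode).
#' @param other_sets Template sets of the other subjects.
#' @param fractions Prefix fractions to sweep.
#' @param channels,strategy As in [predict_single_set()].
#' @return Object of class `"personalization_report"`: data frame with
#'   `fraction`, `personalized_accuracy`, `independent_accuracy`.
#' @export
compare_personalized <- function(subject_cycles, other_sets,
                                 fractions = seq(0.1, 1.0, by = 0.1),
                                 channels = NULL, strategy = "dependent") {
  stopifnot(is.list(subject_cycles), length(subject_cycles) >= 2L,
            is.list(other_sets), length(other_sets) >= 1L)
  originals <- Filter(function(cy) is_original(cy) && !is.na(cy$mode),
                      subject_cycles)
  modes <- vapply(originals, function(cy) cy$mode, "")
  train <- list()
  test <- list()
  for (m in gait_modes()) {
    mc <- originals[modes == m]
    if (length(mc) < 2L) {
      stop("subject needs >= 2 cycles of mode ", m,
           " to split for personalization", call. = FALSE)
    }
    half <- floor(length(mc) / 2)
    train <- c(train, mc[seq_len(half)])
    test <- c(test, mc[(half + 1L):length(mc)])
  }
  own_set <- build_template_set(train)
  truth <- vapply(test, function(cy) cy$mode, "")
  rows <- lapply(fractions, function(f) {
    pred_p <- vapply(test, function(cy) {
      predict_voted(cy, list(own_set), channels = channels,
                    prefix_fraction = f, strategy = strategy)$final
    }, "")
    pred_i <- vapply(test, function(cy) {
      predict_voted(cy, other_sets, channels = channels,
                    prefix_fraction = f, strategy = strategy)$final
    }, "")
    data.frame(fraction = f,
               personalized_accuracy =
                 pooled_accuracy(confusion_matrix(truth, pred_p)),
               independent_accuracy =
                 pooled_accuracy(confusion_matrix(truth, pred_i)))
  })
  structure(list(summary = do.call(rbind, rows),
                 n_test = length(test)),
            class = "personalization_report")
}

#' @export
print.personalization_report <- function(x, ...) {
  cat("Personalized vs. user-independent accuracy (%):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
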