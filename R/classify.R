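#' Prefix of a sequence by gait-cycle fraction
#'
#' The early-recognition unit: the first `round(fraction * length)` samples
#' of a channels-x-samples matrix, counted from toe-off. A prefix shorter
#' than 4 samples is an error (too short to warp meaningfully).
#'
#' @param data Channels-x-samples matrix.
#' @param fraction Fraction of the cycle in `(0, 1]`.
#' @return The truncated matrix.
#' @keywords internal
prefix_matrix <- function(data, fraction) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1)
  k <- as.integer(round(fraction * ncol(data)))
  if (k < 4L) {
    stop("prefix of ", k, " samples is below the minimum of 4",
         call. = FALSE)
  }
  data[, seq_len(k), drop = FALSE]
}

#' Classify a (partial) cycle against one subject's template set
#'
#' Computes the mDTW distance between the query's prefix and each mode
#' template's prefix of the same fraction, restricted to the requested
#' channels, and votes for the mode with the smallest distance. Both the
#' query and the template are truncated to the prefix fraction so a partial
#' cycle is never forced to absorb the warping cost of a full template;
#' `open_end = TRUE` instead matches the full-length query prefix against
#' every template prefix length and keeps the cheapest (free template
#' endpoint).
#'
#' @param query A [gait_cycle()] whose channels include `channels`.
#' @param set A [build_template_set()] voter.
#' @param channels Channel subset to compare on (default: the set's).
#' @param prefix_fraction Fraction of the gait cycle available, `(0, 1]`.
#' @param strategy `"dependent"` or `"independent"` mDTW.
#' @param open_end Free-endpoint matching instead of template truncation.
#' @param window Optional Sakoe-Chiba half-width (samples).
#' @return List with `mode` (the vote) and `distances` (named per-mode
#'   mDTW distances). Argmin ties are broken by the fixed mode order
#'   LW, LW_SC, LW_SD.
#' @export
predict_single_set <- function(query, set, channels = NULL,
                               prefix_fraction = 1.0,
                               strategy = c("dependent", "independent"),
                               open_end = FALSE, window = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(query, "gait_cycle"), inherits(set, "template_set"))
  if (is.null(channels)) channels <- set$channels
  missing <- setdiff(channels, query$channels)
  if (length(missing)) {
    stop("query lacks channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(channels, set$channels)
  if (length(missing)) {
    stop("template set lacks channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  q <- prefix_matrix(query$data[channels, , drop = FALSE], prefix_fraction)
  distances <- vapply(gait_modes(), function(m) {
    tpl <- set$templates[[m]]$values[channels, , drop = FALSE]
    if (open_end) {
      lens <- max(4L, as.integer(round(prefix_fraction * ncol(tpl)))):ncol(tpl)
      min(vapply(lens, function(L) {
        mdtw_distance(q, tpl[, seq_len(L), drop = FALSE],
                      strategy = strategy, window = window)
      }, 0.0))
    } else {
      tp <- prefix_matrix(tpl, prefix_fraction)
      mdtw_distance(q, tp, strategy = strategy, window = window)
    }
  }, 0.0)
  list(mode = gait_modes()[which.min(distances)], distances = distances)
}

#' Voted prediction across multiple template sets
#'
#' Every subject's template set casts one vote via [predict_single_set()];
#' the final label is the plurality winner. When the top vote count is
#' tied, the tied mode with the smallest mean distance across all voters
#' wins and the prediction is flagged `tie_broken`.
#'
#' @param query A [gait_cycle()].
#' @param sets Nonempty list of template sets (the voting pool).
#' @inheritParams predict_single_set
#' @return An object of class `"gait_prediction"`: `final`, `per_voter`
#'   data frame (subject, vote, per-mode distances), `tie_broken`,
#'   `prefix_fraction`.
#' @export
predict_voted <- function(query, sets, channels = NULL,
                          prefix_fraction = 1.0,
                          strategy = c("dependent", "independent"),
                          open_end = FALSE, window = NULL) {
  strategy <- match.arg(strategy)
  if (!is.list(sets) || !length(sets)) {
    stop("need at least one template set to vote", call. = FALSE)
  }
  votes <- character(length(sets))
  dist_mat <- matrix(0, nrow = length(sets), ncol = 3L,
                     dimnames = list(NULL, gait_modes()))
  for (k in seq_along(sets)) {
    p <- predict_single_set(query, sets[[k]], channels = channels,
                            prefix_fraction = prefix_fraction,
                            strategy = strategy, open_end = open_end,
                            window = window)
    votes[k] <- p$mode
    dist_mat[k, ] <- p$distances
  }
  tally <- table(factor(votes, levels = gait_modes()))
  top <- names(tally)[tally == max(tally)]
  tie_broken <- length(top) > 1L
  final <- if (tie_broken) {
    mean_dist <- colMeans(dist_mat)[top]
    top[which.min(mean_dist)]
  } else {
    top
  }
  per_voter <- data.frame(
    subject = vapply(sets, function(s) s$subject_id, ""),
    vote = votes)
  per_voter <- cbind(per_voter, as.data.frame(dist_mat))
  structure(list(final = final, per_voter = per_voter,
                 tie_broken = tie_broken,
                 prefix_fraction = prefix_fraction),
            class = "gait_prediction")
}

#' @export
print.gait_prediction <- function(x, ...) {
  cat("<gait_prediction>", x$final,
      sprintf("(prefix %.0f%%,", 100 * x$prefix_fraction),
      nrow(x$per_voter), "voters",
      if (x$tie_broken) "- tie broken by mean distance" else "", ")\n")
  invisible(x)
}

#' Fit a voting mDTW locomotion-mode classifier
#'
#' The model-fitting entry point: builds one template set per subject from
#' labeled gait cycles and packages them, with the channel subset and mDTW
#' strategy, as a reusable classifier. Prediction compares an unknown
#' (optionally partial) cycle against every stored template set and votes.
#'
#' @param cycles Labeled [gait_cycle()] list covering >= 1 subject, each
#'   subject with all three modes.
#' @param channels Channel subset used at prediction time (default: all
#'   channels of the cycles).
#' @param strategy `"dependent"` (shared warping path over vector samples)
#'   or `"independent"` (per-channel DTW, summed).
#' @param include_derived Use augmented cycles for template building
#'   (default `FALSE`: templates come from original cycles only).
#' @param open_end,window Passed to [predict_single_set()].
#' @return An object of class `"mdtw_classifier"` with `print`, `summary`,
#'   `predict` and `plot` methods.
#' @examples
#' corpus <- make_benchmark(generator_spec(n_subjects = 3, n_cycles = 10,
#'                                         seed = 7))
#' fit <- mdtw_classifier(corpus$cycles)
#' predict(fit, corpus$cycles[[1]], prefix_fraction = 0.3)
#' @export
mdtw_classifier <- function(cycles, channels = NULL,
                            strategy = c("dependent", "independent"),
                            include_derived = FALSE, open_end = FALSE,
                            window = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(is.list(cycles), length(cycles) >= 1L)
  all_channels <- assert_shared_channels(cycles)
  if (is.null(channels)) channels <- all_channels
  stopifnot(all(channels %in% all_channels))
  subjects <- unique(vapply(cycles, function(cy) cy$subject_id, ""))
  sets <- lapply(subjects, function(s) {
    build_template_set(Filter(function(cy) cy$subject_id == s, cycles),
                       subject_id = s, include_derived = include_derived)
  })
  structure(list(template_sets = sets, channels = channels,
                 strategy = strategy, open_end = open_end, window = window,
                 subjects = subjects,
                 n_training_cycles = length(cycles)),
            class = "mdtw_classifier")
}

#' @export
print.mdtw_classifier <- function(x, ...) {
  cat("Voting mDTW locomotion-mode classifier\n")
  cat("  voters (template sets):", length(x$template_sets), "\n")
  cat("  channels:", length(x$channels), "-",
      paste(utils::head(x$channels, 3), collapse = ", "),
      if (length(x$channels) > 3) "..." else "", "\n")
  cat("  strategy:", x$strategy,
      if (x$open_end) "(open-end prefix matching)" else "", "\n")
  invisible(x)
}

#' @export
summary.mdtw_classifier <- function(object, ...) {
  ls <- t(vapply(object$template_sets,
                 function(s) vapply(s$templates, function(tp) tp$L, 0L),
                 integer(3)))
  ns <- t(vapply(object$template_sets,
                 function(s) vapply(s$templates, function(tp) tp$n_cycles, 0L),
                 integer(3)))
  out <- data.frame(subject = object$subjects, ls, ns,
                    check.names = FALSE)
  names(out) <- c("subject", paste0("L_", gait_modes()),
                  paste0("n_", gait_modes()))
  structure(list(classifier = object, per_subject = out),
            class = "summary.mdtw_classifier")
}

#' @export
print.summary.mdtw_classifier <- function(x, ...) {
  print(x$classifier)
  cat("\nPer-subject template lengths and contributing cycle counts:\n")
  print(x$per_subject, row.names = FALSE)
  invisible(x)
}

#' Predict locomotion mode for new cycles
#'
#' @param object An [mdtw_classifier()].
#' @param newdata A single [gait_cycle()] or a list of them.
#' @param prefix_fraction Fraction of the gait cycle available, `(0, 1]`.
#' @param exclude_subject Optional subject id whose template set is removed
#'   from the voting pool (user-independent operation on that subject).
#' @param details Return the full `"gait_prediction"` objects instead of a
#'   character vector of labels.
#' @param ... Unused.
#' @return Character vector of predicted modes (one per cycle), or a list
#'   of predictions when `details = TRUE`.
#' @export
predict.mdtw_classifier <- function(object, newdata,
                                    prefix_fraction = 1.0,
                                    exclude_subject = NULL,
                                    details = FALSE, ...) {
  if (inherits(newdata, "gait_cycle")) newdata <- list(newdata)
  sets <- object$template_sets
  if (!is.null(exclude_subject)) {
    sets <- Filter(function(s) !(s$subject_id %in% exclude_subject), sets)
  }
  if (!length(sets)) stop("voting pool is empty", call. = FALSE)
  preds <- lapply(newdata, function(cy) {
    predict_voted(cy, sets, channels = object$channels,
                  prefix_fraction = prefix_fraction,
                  strategy = object$strategy, open_end = object$open_end,
                  window = object$window)
  })
  if (details) return(preds)
  vapply(preds, function(p) p$final, "")
}

#' Plot the per-mode templates of a fitted classifier
#'
#' One panel per channel (up to `max_channels`), overlaying the three mode
#' templates of the chosen voter on a 0-100% gait-cycle axis.
#'
#' @param x An [mdtw_classifier()].
#' @param subject Voter to plot (default: first).
#' @param channels Channels to show.
#' @param max_channels Panel cap.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mdtw_classifier <- function(x, subject = NULL, channels = NULL,
                                 max_channels = 4L, ...) {
  sets <- x$template_sets
  if (is.null(subject)) subject <- sets[[1]]$subject_id
  set <- Filter(function(s) s$subject_id == subject, sets)[[1]]
  if (is.null(channels)) channels <- utils::head(x$channels, max_channels)
  old <- graphics::par(mfrow = c(length(channels), 1L),
                       mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    series <- lapply(gait_modes(), function(m) {
      v <- set$templates[[m]]$values[ch, ]
      list(x = seq(0, 100, length.out = length(v)), y = v)
    })
    rng <- range(unlist(lapply(series, `[[`, "y")))
    graphics::plot(NULL, xlim = c(0, 100), ylim = rng,
                   xlab = "gait cycle (%)", ylab = "normalized",
                   main = ch, ...)
    for (k in seq_along(series)) {
      graphics::lines(series[[k]]$x, series[[k]]$y, col = k, lwd = 2,
                      lty = k)
    }
    graphics::legend("topright", legend = gait_modes(), col = 1:3,
                     lty = 1:3, lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(x)
}
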