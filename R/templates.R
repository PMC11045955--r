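#' Build a reference template from gait cycles
#'
#' A template is the sample-by-sample average of all contributing cycles
#' after each cycle is resampled (linear interpolation, as in
#' [resample_cycle()]) to the average cycle length
#' `L = round(mean(lengths))`. All cycles must share the subject, mode and
#' channel ordering.
#'
#' @param cycles Nonempty list of [gait_cycle()] objects.
#' @param subject_id,mode Expected subject and mode; defaults are taken
#'   from the first cycle and every cycle is checked against them.
#' @param average `"mean"` (default) or `"median"` for a robust variant.
#' @return An object of class `"gait_template"` with fields `values`
#'   (channels x L), `L`, `n_cycles` and the contributing `cycle_ids`.
#' @export
build_template <- function(cycles, subject_id = NULL, mode = NULL,
                           average = c("mean", "median")) {
  average <- match.arg(average)
  if (!is.list(cycles) || !length(cycles)) {
    stop("need at least one cycle to build a template", call. = FALSE)
  }
  channels <- assert_shared_channels(cycles)
  if (is.null(subject_id)) subject_id <- cycles[[1]]$subject_id
  if (is.null(mode)) mode <- cycles[[1]]$mode
  for (cy in cycles) {
    if (!identical(cy$subject_id, subject_id)) {
      stop("cycle ", cy$id, " belongs to subject ", cy$subject_id,
           ", expected ", subject_id, call. = FALSE)
    }
    if (!identical(cy$mode, mode)) {
      stop("cycle ", cy$id, " has mode ", cy$mode, ", expected ", mode,
           call. = FALSE)
    }
  }
  lens <- vapply(cycles, cycle_length, 0L)
  L <- as.integer(round(mean(lens)))
  stack <- array(0, dim = c(length(channels), L, length(cycles)))
  for (k in seq_along(cycles)) {
    stack[, , k] <- resample_matrix(cycles[[k]]$data, L)
  }
  values <- if (average == "mean") {
    apply(stack, c(1L, 2L), mean)
  } else {
    apply(stack, c(1L, 2L), stats::median)
  }
  rownames(values) <- channels
  structure(list(subject_id = subject_id, mode = mode, channels = channels,
                 values = values, L = L, n_cycles = length(cycles),
                 cycle_ids = vapply(cycles, function(cy) cy$id, "")),
            class = "gait_template")
}

#' @export
print.gait_template <- function(x, ...) {
  cat("<gait_template>", x$subject_id, x$mode, "-", length(x$channels),
      "ch x", x$L, "samples (from", x$n_cycles, "cycles)\n")
  invisible(x)
}

#' Build a subject's full template set
#'
#' One template per locomotion mode for one subject, with identical channel
#' ordering across modes; the full set acts as one voter in
#' [predict_voted()]. With the 37-signal configuration of a fully
#' instrumented study, the three per-mode templates expand to 111
#' per-channel template series per subject. Templates are built from
#' original cycles only unless `include_derived = TRUE`, so augmented
#' copies never smuggle a subject's data into their own reference shapes.
#'
#' @param cycles Cycles of one subject covering all three modes.
#' @param subject_id Subject token; default from the first cycle.
#' @param include_derived Also use augmented (derived) cycles.
#' @param average Passed to [build_template()].
#' @return An object of class `"template_set"`: per-mode templates plus
#'   per-channel mean/sd statistics of the contributing cycles (metadata
#'   for placing external queries in the training space).
#' @export
build_template_set <- function(cycles, subject_id = NULL,
                               include_derived = FALSE,
                               average = "mean") {
  stopifnot(is.list(cycles), length(cycles) >= 1L)
  if (is.null(subject_id)) subject_id <- cycles[[1]]$subject_id
  keep <- vapply(cycles, function(cy) {
    identical(cy$subject_id, subject_id) && !is.na(cy$mode) &&
      (include_derived || is_original(cy))
  }, TRUE)
  cycles <- cycles[keep]
  if (!length(cycles)) {
    stop("no usable labeled cycles for subject ", subject_id, call. = FALSE)
  }
  channels <- assert_shared_channels(cycles)
  modes <- vapply(cycles, function(cy) cy$mode, "")
  missing <- setdiff(gait_modes(), unique(modes))
  if (length(missing)) {
    stop("subject ", subject_id, " has no cycles for mode(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  templates <- lapply(gait_modes(), function(m) {
    build_template(cycles[modes == m], subject_id = subject_id, mode = m,
                   average = average)
  })
  names(templates) <- gait_modes()
  flat <- do.call(cbind, lapply(cycles, function(cy) cy$data))
  stats <- list(mean = rowMeans(flat),
                sd = apply(flat, 1L, stats::sd))
  structure(list(subject_id = subject_id, channels = channels,
                 templates = templates, stats = stats),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  ls <- vapply(x$templates, function(tp) tp$L, 0L)
  cat("<template_set>", x$subject_id, "-", length(x$channels),
      "channels; L =", paste(names(ls), ls, sep = ":", collapse = " "), "\n")
  invisible(x)
}
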