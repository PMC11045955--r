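#' Continuous multichannel gait recording
#'
#' Container for a continuous recording from one subject: a channels-by-
#' samples matrix, the sampling rate, gait-event annotations (toe-off,
#' heel-strike) as 0-based sample indices, and mode-label intervals as
#' half-open 0-based `[start, end)` spans.
#'
#' @param subject_id Subject token.
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Character vector of channel strings (see [channel_id()]).
#' @param data Numeric matrix, `length(channels)` rows.
#' @param events Data frame with columns `sample` (0-based integer index)
#'   and `type` (`"toe_off"` or `"heel_strike"`); may be empty.
#' @param labels Data frame with columns `start`, `end` (0-based, half-open)
#'   and `mode` (one of [gait_modes()]); intervals must not overlap.
#' @return An object of class `"gait_recording"`.
#' @export
gait_recording <- function(subject_id, fs, channels, data,
                           events = empty_events(), labels = empty_labels()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.numeric(fs), fs > 0, is.matrix(data))
  channels <- validate_channels(channels)
  if (nrow(data) != length(channels)) {
    stop("data must have one row per channel", call. = FALSE)
  }
  rownames(data) <- channels
  n <- ncol(data)
  events <- as.data.frame(events)
  labels <- as.data.frame(labels)
  if (nrow(events)) {
    stopifnot(all(events$sample >= 0 & events$sample < n),
              all(events$type %in% c("toe_off", "heel_strike")))
    events <- events[order(events$sample), , drop = FALSE]
    rownames(events) <- NULL
  }
  if (nrow(labels)) {
    stopifnot(all(labels$start >= 0), all(labels$end <= n),
              all(labels$start < labels$end),
              all(labels$mode %in% gait_modes()))
    labels <- labels[order(labels$start), , drop = FALSE]
    if (nrow(labels) > 1L &&
        any(labels$start[-1L] < labels$end[-nrow(labels)])) {
      stop("label intervals overlap", call. = FALSE)
    }
    rownames(labels) <- NULL
  }
  structure(list(subject_id = subject_id, fs = fs, channels = channels,
                 data = data, events = events, labels = labels),
            class = "gait_recording")
}

empty_events <- function() {
  data.frame(sample = integer(0), type = character(0))
}
empty_labels <- function() {
  data.frame(start = integer(0), end = integer(0), mode = character(0))
}

#' @export
print.gait_recording <- function(x, ...) {
  cat("<gait_recording> subject", x$subject_id, "-",
      length(x$channels), "channels x", ncol(x$data), "samples @",
      x$fs, "Hz\n")
  cat("  events:", nrow(x$events), " label intervals:", nrow(x$labels), "\n")
  invisible(x)
}

#' One segmented gait cycle
#'
#' A toe-off-to-toe-off segment of a recording: a channels-by-samples
#' matrix with its mode label (or `NA` if unlabeled), subject id, source
#' span in the parent recording and sampling rate. `id` is a unique token
#' and `provenance` records how derived (augmented) cycles were produced.
#'
#' @param subject_id Subject token.
#' @param mode One of [gait_modes()] or `NA` for unlabeled.
#' @param channels Channel strings.
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate (Hz).
#' @param source_span Optional integer pair `(start, end)`, 0-based
#'   half-open, locating the cycle in its parent recording.
#' @param id Unique cycle token; autogenerated when `NULL`.
#' @param provenance `NULL` for an original cycle, else a list with
#'   `derived_from` (parent cycle id), `op` and the op's parameter.
#' @return An object of class `"gait_cycle"`.
#' @export
gait_cycle <- function(subject_id, mode, channels, data, fs,
                       source_span = NULL, id = NULL, provenance = NULL) {
  stopifnot(is.matrix(data), is.numeric(fs), fs > 0)
  channels <- validate_channels(channels)
  if (nrow(data) != length(channels)) {
    stop("data must have one row per channel", call. = FALSE)
  }
  if (!is.na(mode)) mode <- match.arg(mode, gait_modes())
  rownames(data) <- channels
  if (is.null(id)) {
    id <- sprintf("%s-%s", subject_id,
                  paste(sample(c(letters, 0:9), 8, replace = TRUE),
                        collapse = ""))
  }
  structure(list(id = id, subject_id = subject_id, mode = mode,
                 channels = channels, data = data, fs = fs,
                 source_span = source_span, provenance = provenance),
            class = "gait_cycle")
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat("<gait_cycle>", x$id, "subject", x$subject_id, "mode",
      ifelse(is.na(x$mode), "<unlabeled>", x$mode), "-",
      length(x$channels), "ch x", ncol(x$data), "samples\n")
  invisible(x)
}

cycle_length <- function(cycle) ncol(cycle$data)

is_original <- function(cycle) is.null(cycle$provenance)

# the subject a cycle's data ultimately came from (augmented cycles inherit)
source_subject <- function(cycle) cycle$subject_id

assert_shared_channels <- function(cycles) {
  chans <- cycles[[1]]$channels
  for (cy in cycles) {
    if (!identical(cy$channels, chans)) {
      stop("cycles do not share channel ordering", call. = FALSE)
    }
  }
  chans
}

#' Read and write gait recordings
#'
#' Recordings are stored as a long-form CSV (`time`, `channel`, `value`)
#' plus a JSON sidecar (same path with extension `.json`) carrying the
#' subject id, sampling rate, channel order, events and label intervals.
#' The pair is inspectable and diff-able; `read_recording()` validates the
#' result against the sidecar's declared channels.
#'
#' @param recording A [gait_recording()].
#' @param path CSV file path; the sidecar is `paste0(path, ".json")`.
#' @param max_nan_run Longest tolerated run of non-finite values per
#'   channel before `read_recording()` raises a data error.
#' @return `read_recording()` returns a `"gait_recording"`;
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "gait_recording"))
  n <- ncol(recording$data)
  tm <- rep((seq_len(n) - 1L) / recording$fs, each = nrow(recording$data))
  df <- data.frame(time = tm,
                   channel = rep(recording$channels, times = n),
                   value = as.vector(recording$data))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(subject_id = recording$subject_id, fs = recording$fs,
               channels = recording$channels,
               events = recording$events, labels = recording$labels)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, max_nan_run = 0L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  if (!all(c("time", "channel", "value") %in% names(df))) {
    stop("recording CSV must have columns time, channel, value",
         call. = FALSE)
  }
  missing <- setdiff(side$channels, unique(df$channel))
  if (length(missing)) {
    stop("declared channel(s) missing from CSV: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  times <- sort(unique(df$time))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("non-monotonic time column", call. = FALSE)
  }
  n <- length(times)
  data <- matrix(NA_real_, nrow = length(side$channels), ncol = n,
                 dimnames = list(side$channels, NULL))
  for (ch in side$channels) {
    sub <- df[df$channel == ch, , drop = FALSE]
    if (nrow(sub) != n) stop("channel '", ch, "' has ", nrow(sub),
                             " samples, expected ", n, call. = FALSE)
    data[ch, ] <- sub$value[order(sub$time)]
  }
  bad <- apply(data, 1L, function(r) max_run(!is.finite(r)))
  if (any(bad > max_nan_run)) {
    stop("NaN run of length ", max(bad), " exceeds allowed gap of ",
         max_nan_run, call. = FALSE)
  }
  events <- if (length(side$events)) as.data.frame(side$events)
            else empty_events()
  labels <- if (length(side$labels)) as.data.frame(side$labels)
            else empty_labels()
  gait_recording(side$subject_id, side$fs, side$channels, data,
                 events, labels)
}

max_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Read and write cycle collections
#'
#' Cycles are stored as a single JSON document. Values round-trip exactly
#' (full floating-point precision); all cycles in one file must share the
#' same channel ordering.
#'
#' @param cycles List of [gait_cycle()] objects (may be empty).
#' @param path JSON file path.
#' @return `read_cycles()` returns a list of `"gait_cycle"` objects;
#'   `write_cycles()` returns `path` invisibly.
#' @export
write_cycles <- function(cycles, path) {
  stopifnot(is.list(cycles))
  if (length(cycles)) assert_shared_channels(cycles)
  payload <- list(
    format = "gaitdtw-cycles-v1",
    cycles = lapply(cycles, function(cy) {
      list(id = cy$id, subject_id = cy$subject_id,
           mode = if (is.na(cy$mode)) NULL else cy$mode,
           channels = cy$channels, fs = cy$fs,
           source_span = cy$source_span,
           provenance = cy$provenance,
           data = lapply(asplit(cy$data, 1L), as.numeric))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_cycles
#' @export
read_cycles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e) {
                        stop("cannot parse cycle file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
  if (!identical(payload$format, "gaitdtw-cycles-v1")) {
    stop("not a gaitdtw cycle file: ", path, call. = FALSE)
  }
  lapply(payload$cycles, function(rec) {
    channels <- as.character(unlist(rec$channels))
    data <- do.call(rbind, lapply(rec$data, function(v) as.numeric(unlist(v))))
    gait_cycle(subject_id = rec$subject_id,
               mode = if (is.null(rec$mode)) NA_character_ else rec$mode,
               channels = channels, data = data, fs = rec$fs,
               source_span = if (is.null(rec$source_span)) NULL
                             else as.integer(unlist(rec$source_span)),
               id = rec$id,
               provenance = rec$provenance)
  })
}

#' Read and write template sets
#'
#' Template sets (see [build_template_set()]) serialize to JSON, carrying
#' subject id, per-mode template matrices, template lengths, contributing
#' cycle counts/ids and the training cycles' per-channel statistics.
#'
#' @param sets List of `"template_set"` objects.
#' @param path JSON file path.
#' @return `read_template_sets()` returns a list of `"template_set"`
#'   objects; the writer returns `path` invisibly.
#' @export
write_template_sets <- function(sets, path) {
  payload <- list(
    format = "gaitdtw-templates-v1",
    sets = lapply(sets, function(ts) {
      list(subject_id = ts$subject_id, channels = ts$channels,
           stats = ts$stats,
           templates = lapply(ts$templates, function(tp) {
             list(mode = tp$mode, L = tp$L, n_cycles = tp$n_cycles,
                  cycle_ids = tp$cycle_ids,
                  values = lapply(asplit(tp$values, 1L), as.numeric))
           }))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_template_sets
#' @export
read_template_sets <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "gaitdtw-templates-v1")) {
    stop("not a gaitdtw template file: ", path, call. = FALSE)
  }
  lapply(payload$sets, function(rec) {
    channels <- as.character(unlist(rec$channels))
    templates <- lapply(rec$templates, function(tp) {
      values <- do.call(rbind, lapply(tp$values,
                                      function(v) as.numeric(unlist(v))))
      rownames(values) <- channels
      structure(list(subject_id = rec$subject_id, mode = tp$mode,
                     channels = channels, values = values,
                     L = as.integer(tp$L), n_cycles = as.integer(tp$n_cycles),
                     cycle_ids = as.character(unlist(tp$cycle_ids))),
                class = "gait_template")
    })
    names(templates) <- vapply(templates, function(tp) tp$mode, "")
    structure(list(subject_id = rec$subject_id, channels = channels,
                   templates = templates, stats = rec$stats),
              class = "template_set")
  })
}
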