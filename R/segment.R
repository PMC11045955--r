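#' Toe-off detector settings
#'
#' Toe-off is detected from the in-shoe pressure sensors: after a stance
#' interval (both heel and ball FSR loaded), the first sample where both
#' fall below `fsr_low_threshold` marks foot lift-off. The candidate is
#' then refined to the nearest local extremum of the instrumented shank
#' accelerometer z axis within +/- `refine_window_s`, and candidates closer
#' than `min_cycle_duration` to the previous accepted toe-off are rejected.
#'
#' @param fsr_low_threshold Normalized pressure below which the foot is
#'   considered unloaded (0 < threshold < 1).
#' @param hysteresis Pressure margin above the threshold that must be
#'   exceeded before a new stance is recognized.
#' @param min_cycle_duration,max_cycle_duration Admissible cycle durations
#'   in seconds (`min < max`); used as a refractory period here and as a
#'   drop rule in [segment_cycles()].
#' @param refine_window_s Half-width (s) of the accelerometer refinement
#'   window.
#' @param refine Use the shank accel-z refinement (requires the channel).
#' @param heel_channel,ball_channel,accel_channel Channel strings.
#' @return A list of class `"toe_off_spec"`.
#' @export
toe_off_spec <- function(fsr_low_threshold = 0.05, hysteresis = 0.02,
                         min_cycle_duration = 0.6, max_cycle_duration = 2.5,
                         refine_window_s = 0.05, refine = TRUE,
                         heel_channel = "instr_heel.fsr",
                         ball_channel = "instr_ball.fsr",
                         accel_channel = "instr_shank.accel.z") {
  stopifnot(fsr_low_threshold > 0, fsr_low_threshold < 1,
            hysteresis >= 0, min_cycle_duration < max_cycle_duration)
  structure(list(fsr_low_threshold = fsr_low_threshold,
                 hysteresis = hysteresis,
                 min_cycle_duration = min_cycle_duration,
                 max_cycle_duration = max_cycle_duration,
                 refine_window_s = refine_window_s, refine = refine,
                 heel_channel = heel_channel, ball_channel = ball_channel,
                 accel_channel = accel_channel),
            class = "toe_off_spec")
}

#' Detect toe-off events in a recording
#'
#' @param recording A [gait_recording()] containing the heel FSR, ball FSR
#'   and (if `spec$refine`) the shank accel-z channels.
#' @param spec A [toe_off_spec()].
#' @return Integer vector of strictly increasing 0-based sample indices,
#'   one per detected toe-off. Standing (FSR never unloading) yields an
#'   empty vector; if the recording carries mode labels but no event is
#'   found, a detection-failure warning is raised.
#' @export
detect_toe_off <- function(recording, spec = toe_off_spec()) {
  stopifnot(inherits(recording, "gait_recording"))
  need <- c(spec$heel_channel, spec$ball_channel,
            if (spec$refine) spec$accel_channel)
  missing <- setdiff(need, recording$channels)
  if (length(missing)) {
    stop("recording lacks required channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  heel <- recording$data[spec$heel_channel, ]
  ball <- recording$data[spec$ball_channel, ]
  lo <- spec$fsr_low_threshold
  hi <- spec$fsr_low_threshold + spec$hysteresis
  n <- length(heel)
  min_gap <- round(spec$min_cycle_duration * recording$fs)
  win <- round(spec$refine_window_s * recording$fs)

  events <- integer(0)
  in_stance <- heel[1] > hi && ball[1] > hi
  last <- -Inf
  for (t in seq_len(n)) {
    if (!in_stance) {
      if (heel[t] > hi && ball[t] > hi) in_stance <- TRUE
    } else if (heel[t] < lo && ball[t] < lo) {
      in_stance <- FALSE
      cand <- t
      if (spec$refine) {
        idx <- max(1L, cand - win):min(n, cand + win)
        z <- recording$data[spec$accel_channel, idx]
        dz <- diff(z)
        ext <- which(dz[-length(dz)] * dz[-1L] < 0) + 1L  # local extrema
        if (length(ext)) {
          cand <- idx[ext[which.min(abs(idx[ext] - cand))]]
        }
      }
      if (cand - last >= min_gap) {
        events <- c(events, cand)
        last <- cand
      }
    }
  }
  if (!length(events) && nrow(recording$labels)) {
    warning("no toe-off detected on a recording with labeled cycles",
            call. = FALSE)
  }
  as.integer(events - 1L)  # 0-based
}

#' Slice a recording into toe-off-anchored gait cycles
#'
#' Cycle `k` spans `[toe_offs[k], toe_offs[k+1])` (0-based, half-open), so
#' every cycle starts at toe-off and the swing phase comes first. Channel
#' data are copied unmodified. The mode label is taken from the label
#' interval containing the cycle's midpoint (or the majority-overlap
#' interval when `labeling = "overlap"`); cycles with no covering interval
#' are unlabeled. Cycles whose duration falls outside
#' `[min_cycle_duration, max_cycle_duration]` are dropped (`durations =
#' NULL` disables the rule).
#'
#' @param recording A [gait_recording()].
#' @param toe_offs Integer vector of 0-based toe-off sample indices
#'   (e.g. from [detect_toe_off()]); fewer than 2 yields an empty list.
#' @param durations Optional [toe_off_spec()] (or any list with
#'   `min_cycle_duration` / `max_cycle_duration`) giving the drop rule.
#' @param labeling `"midpoint"` or `"overlap"`.
#' @return List of [gait_cycle()] objects.
#' @export
segment_cycles <- function(recording, toe_offs, durations = NULL,
                           labeling = c("midpoint", "overlap")) {
  stopifnot(inherits(recording, "gait_recording"))
  labeling <- match.arg(labeling)
  toe_offs <- sort(unique(as.integer(toe_offs)))
  if (length(toe_offs) < 2L) return(list())
  out <- list()
  for (k in seq_len(length(toe_offs) - 1L)) {
    start <- toe_offs[k]
    end <- toe_offs[k + 1L]
    len <- end - start
    if (!is.null(durations)) {
      dur <- len / recording$fs
      if (dur < durations$min_cycle_duration ||
          dur > durations$max_cycle_duration) next
    }
    mode <- cycle_mode_label(recording$labels, start, end, labeling)
    out[[length(out) + 1L]] <- gait_cycle(
      subject_id = recording$subject_id, mode = mode,
      channels = recording$channels,
      data = recording$data[, (start + 1L):end, drop = FALSE],
      fs = recording$fs, source_span = c(start, end),
      id = sprintf("%s-c%03d", recording$subject_id, k))
  }
  out
}

cycle_mode_label <- function(labels, start, end, labeling) {
  if (!nrow(labels)) return(NA_character_)
  if (labeling == "midpoint") {
    mid <- start + (end - start) %/% 2L
    hit <- labels$start <= mid & mid < labels$end
    if (any(hit)) labels$mode[which(hit)[1L]] else NA_character_
  } else {
    ov <- pmin(labels$end, end) - pmax(labels$start, start)
    ov[ov < 0] <- 0
    if (all(ov == 0)) return(NA_character_)
    best <- which.max(ov)
    if (ov[best] * 2 < (end - start)) NA_character_ else labels$mode[best]
  }
}
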