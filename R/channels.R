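#' Sensor channel identifiers
#'
#' A channel is identified by a body location, a sensing modality, and (for
#' triaxial IMU signals) an axis. The string form is
#' \code{"location.modality.axis"}, with the axis omitted for scalar
#' modalities (joint angles, segment angles, and in-shoe force-sensing
#' resistors). String forms are unique and round-trip through
#' [parse_channel()] / [format_channel()].
#'
#' Locations follow the instrumented (exoskeleton / prosthesis) vs.
#' uninstrumented (contralateral) side convention used for unilateral
#' lower-limb sensing; `instr_heel` / `instr_ball` are the two in-shoe FSRs
#' under the heel and the first metatarsal head.
#'
#' @param location One of `channel_locations()`.
#' @param modality One of `channel_modalities()`.
#' @param axis `"x"`, `"y"`, `"z"`, or `"none"` (required to be `"none"`
#'   for scalar modalities).
#' @return `channel_id()` and `parse_channel()` return a `"channel_id"`
#'   object; `format_channel()` returns its string form.
#' @examples
#' ch <- channel_id("instr_thigh", "gyro", "z")
#' format_channel(ch)
#' parse_channel("chest.accel.y")
#' @export
channel_id <- function(location, modality, axis = "none") {
  location <- match.arg(location, channel_locations())
  modality <- match.arg(modality, channel_modalities())
  axis <- match.arg(axis, c("x", "y", "z", "none"))
  if (modality %in% c("joint_angle", "segment_angle", "fsr") && axis != "none") {
    stop("scalar modality '", modality, "' must have axis 'none'", call. = FALSE)
  }
  if (modality %in% c("accel", "gyro") && axis == "none") {
    stop("triaxial modality '", modality, "' requires an axis", call. = FALSE)
  }
  structure(list(location = location, modality = modality, axis = axis),
            class = "channel_id")
}

#' @rdname channel_id
#' @export
channel_locations <- function() {
  c("instr_thigh", "instr_shank", "uninstr_thigh", "uninstr_shank", "chest",
    "instr_foot", "uninstr_foot", "instr_knee", "instr_ankle", "instr_hip",
    "uninstr_hip", "instr_heel", "instr_ball", "uninstr_heel", "uninstr_ball")
}

#' @rdname channel_id
#' @export
channel_modalities <- function() {
  c("accel", "gyro", "joint_angle", "segment_angle", "fsr")
}

#' @rdname channel_id
#' @param x For `format_channel()` a `channel_id`; for `parse_channel()` a
#'   string such as `"instr_shank.accel.z"`.
#' @export
format_channel <- function(x) {
  stopifnot(inherits(x, "channel_id"))
  if (x$axis == "none") paste(x$location, x$modality, sep = ".")
  else paste(x$location, x$modality, x$axis, sep = ".")
}

#' @rdname channel_id
#' @export
parse_channel <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    channel_id(parts[1], parts[2], "none")
  } else if (length(parts) == 3L) {
    channel_id(parts[1], parts[2], parts[3])
  } else {
    stop("malformed channel string: '", x, "'", call. = FALSE)
  }
}

#' @export
print.channel_id <- function(x, ...) {
  cat("<channel>", format_channel(x), "\n")
  invisible(x)
}

# validate a character vector of channel strings, returning it unchanged
validate_channels <- function(channels) {
  stopifnot(is.character(channels), length(channels) >= 1L)
  for (ch in channels) parse_channel(ch)
  if (anyDuplicated(channels)) stop("duplicate channel ids", call. = FALSE)
  channels
}

#' Locomotion modes
#'
#' The three locomotive states recognized by the classifier: steady level
#' walking (`LW`) and the two swing-phase transitions, level walking to
#' stair climbing (`LW_SC`) and level walking to stair descending
#' (`LW_SD`).
#'
#' @return Character vector of the three mode labels, in the fixed order
#'   used for deterministic tie-breaking.
#' @export
gait_modes <- function() c("LW", "LW_SC", "LW_SD")
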