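#' Synthetic gait generator settings
#'
#' Generates quasi-periodic multichannel gait recordings with analytic
#' ground truth for three locomotive states (LW, LW_SC, LW_SD). Each
#' channel's per-mode prototype is a sum of at most six harmonics of the
#' gait cycle: a channel-specific base shape shared by all modes plus
#' mode-specific transition shapes weighted per channel, so the modes
#' differ from the very start of the swing phase. Subjects perturb the
#' prototypes by a per-channel lognormal amplitude factor and a common
#' phase shift; cycle lengths jitter around the mean duration; white
#' Gaussian noise is added at a fixed SNR. In-shoe FSR channels follow a
#' stance-plateau/swing-zero pressure pattern tied to the true toe-off
#' instants, and the instrumented shank accelerometer z axis carries a
#' sharp harmonic burst at toe-off, so event detection is testable against
#' truth.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_cycles Gait cycles per subject.
#' @param channels Channel strings; FSR channels and the shank accel-z are
#'   event channels, all others carry mode prototypes.
#' @param fs Sampling rate in Hz.
#' @param cycle_duration_mean,cycle_duration_sd Cycle duration (s).
#' @param transition_rate Length-2 vector: fraction of cycles that are
#'   LW_SC and LW_SD. Counts are deterministic (`round`, at least 1 each);
#'   the cycle order is shuffled by the seed.
#' @param noise_snr_db Additive-noise SNR in dB (`Inf` = noiseless).
#' @param subject_amp_sdlog Lognormal sd of the per-(subject, channel)
#'   amplitude factor.
#' @param subject_phase_sd Sd (in samples) of the per-subject phase shift
#'   applied to prototype channels.
#' @param swing_fraction Fraction of the cycle before heel strike (stance
#'   onset); the toe-off-anchored cycle is swing-first.
#' @param mode_weights Channels x 2 matrix of per-channel weights of the
#'   two transition shapes (columns `sc`, `sd`); rows for event channels
#'   are ignored. `NULL` uses spread defaults making every prototype
#'   channel informative.
#' @param deviant_subjects Integer indices of subjects whose gait deviates
#'   from the shared prototypes (attenuated transition shapes, rotated base
#'   shape) — used to study personalization.
#' @param seed Integer master seed; every random draw derives from it.
#' @return A list of class `"generator_spec"`.
#' @export
generator_spec <- function(n_subjects = 9L, n_cycles = 30L,
                           channels = default_synth_channels(),
                           fs = 100, cycle_duration_mean = 1.1,
                           cycle_duration_sd = 0.05,
                           transition_rate = c(0.1, 0.1),
                           noise_snr_db = 35,
                           subject_amp_sdlog = 0.1,
                           subject_phase_sd = 2,
                           swing_fraction = 0.4,
                           mode_weights = NULL,
                           deviant_subjects = integer(0),
                           seed = 1L) {
  stopifnot(n_subjects >= 1L, n_cycles >= 3L, fs > 0,
            cycle_duration_mean > 0, cycle_duration_sd >= 0,
            length(transition_rate) == 2L, all(transition_rate >= 0),
            sum(transition_rate) < 1, swing_fraction > 0,
            swing_fraction < 1, subject_amp_sdlog >= 0,
            subject_phase_sd >= 0)
  channels <- validate_channels(channels)
  if (round(fs * cycle_duration_mean) < 20) {
    stop("cycles would be degenerately short", call. = FALSE)
  }
  proto_idx <- which(!is_event_channel(channels))
  if (is.null(mode_weights)) {
    mode_weights <- default_mode_weights(channels)
  }
  stopifnot(is.matrix(mode_weights), nrow(mode_weights) == length(channels),
            ncol(mode_weights) == 2L)
  colnames(mode_weights) <- c("sc", "sd")
  rownames(mode_weights) <- channels
  structure(list(n_subjects = as.integer(n_subjects),
                 n_cycles = as.integer(n_cycles), channels = channels,
                 fs = fs, cycle_duration_mean = cycle_duration_mean,
                 cycle_duration_sd = cycle_duration_sd,
                 transition_rate = transition_rate,
                 noise_snr_db = noise_snr_db,
                 subject_amp_sdlog = subject_amp_sdlog,
                 subject_phase_sd = subject_phase_sd,
                 swing_fraction = swing_fraction,
                 mode_weights = mode_weights,
                 proto_idx = proto_idx,
                 deviant_subjects = as.integer(deviant_subjects),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @export
default_synth_channels <- function() {
  c("instr_hip.joint_angle", "uninstr_hip.joint_angle",
    "uninstr_shank.accel.y", "instr_thigh.gyro.z",
    "chest.accel.y", "chest.accel.z", "instr_thigh.accel.x",
    "instr_thigh.segment_angle",
    "instr_shank.accel.z", "instr_heel.fsr", "instr_ball.fsr")
}

is_event_channel <- function(channels) {
  vapply(channels, function(ch) {
    p <- parse_channel(ch)
    p$modality == "fsr" || ch == "instr_shank.accel.z"
  }, TRUE)
}

default_mode_weights <- function(channels) {
  n <- length(channels)
  w <- matrix(0, nrow = n, ncol = 2L,
              dimnames = list(channels, c("sc", "sd")))
  proto <- which(!is_event_channel(channels))
  # spread, nonzero weights so every prototype channel is informative;
  # alternating emphasis between the two transitions
  for (k in seq_along(proto)) {
    w[proto[k], 1L] <- 0.5 + 0.5 * abs(cos(k))
    w[proto[k], 2L] <- 0.5 + 0.5 * abs(sin(k + 1))
  }
  w
}

# channel base shape (shared by all modes) and the two transition shapes;
# each a sum of <= 6 harmonics of the cycle phase (phi in [0, 1))
synth_base_shape <- function(phi, psi) {
  cos(2 * pi * phi + psi) + 0.5 * sin(4 * pi * phi + 0.7 * psi) +
    0.25 * cos(6 * pi * phi + 1.3 * psi)
}
synth_shape_sc <- function(phi) {
  0.8 * cos(2 * pi * phi) + 0.5 * cos(4 * pi * phi) +
    0.3 * sin(2 * pi * phi) - 0.2 * sin(4 * pi * phi)
}
synth_shape_sd <- function(phi) {
  0.7 * cos(2 * pi * phi) - 0.5 * cos(6 * pi * phi) -
    0.4 * sin(2 * pi * phi) + 0.25 * sin(4 * pi * phi)
}
# toe-off signature on the shank accel z: in-phase harmonic burst, sharply
# peaked at phi = 0 so event refinement is well conditioned
synth_shape_burst <- function(phi) {
  v <- 0
  for (k in 1:6) v <- v + cos(2 * pi * k * phi) / sqrt(k)
  v
}

synth_proto_value <- function(mode, phi, psi, w_sc, w_sd, deviant) {
  base_psi <- if (deviant) psi + 0.6 else psi
  scale <- if (deviant) 0.4 else 1.0
  v <- synth_base_shape(phi, base_psi)
  if (mode == "LW_SC") v <- v + scale * w_sc * synth_shape_sc(phi)
  if (mode == "LW_SD") v <- v + scale * w_sd * synth_shape_sd(phi)
  v
}

#' Generate one subject's synthetic recording
#'
#' Concatenates `spec$n_cycles` gait cycles for the given subject into a
#' continuous [gait_recording()] with truth annotations: toe-off events at
#' every cycle start, heel-strike events at stance onset, and mode label
#' intervals covering each cycle. Fully reproducible from `spec$seed` and
#' the subject index.
#'
#' @param spec A [generator_spec()].
#' @param subject Subject index in `1:spec$n_subjects`.
#' @return List with `recording` (a `"gait_recording"`) and `truth`
#'   (data frame `start`, `end`, `mode` per cycle, 0-based half-open; the
#'   `start` column is the true toe-off index list).
#' @export
generate_recording <- function(spec, subject) {
  stopifnot(inherits(spec, "generator_spec"),
            subject >= 1L, subject <= spec$n_subjects)
  subject_id <- sprintf("S%02d", subject)
  nch <- length(spec$channels)
  with_seed(spec$seed * 131L + subject * 7919L, {
    # deterministic mode counts, shuffled order
    n_sc <- max(1L, as.integer(round(spec$transition_rate[1] * spec$n_cycles)))
    n_sd <- max(1L, as.integer(round(spec$transition_rate[2] * spec$n_cycles)))
    n_lw <- spec$n_cycles - n_sc - n_sd
    stopifnot(n_lw >= 1L)
    modes <- sample(c(rep("LW", n_lw), rep("LW_SC", n_sc),
                      rep("LW_SD", n_sd)))
    lens <- pmax(20L, as.integer(round(
      stats::rnorm(spec$n_cycles, spec$cycle_duration_mean,
                   spec$cycle_duration_sd) * spec$fs)))

    amp <- stats::rlnorm(nch, 0, spec$subject_amp_sdlog)
    shift <- stats::rnorm(1, 0, spec$subject_phase_sd)   # samples
    deviant <- subject %in% spec$deviant_subjects
    psi <- 2 * pi * (seq_len(nch) - 1L) / nch

    total <- sum(lens)
    data <- matrix(0, nrow = nch, ncol = total,
                   dimnames = list(spec$channels, NULL))
    starts <- cumsum(c(0L, lens[-length(lens)]))   # 0-based
    hs <- integer(spec$n_cycles)
    event_ch <- is_event_channel(spec$channels)
    for (k in seq_len(spec$n_cycles)) {
      L <- lens[k]
      cols <- (starts[k] + 1L):(starts[k] + L)
      phi <- (0:(L - 1L)) / L
      i_hs <- as.integer(round(spec$swing_fraction * L))
      hs[k] <- starts[k] + i_hs
      for (c in seq_len(nch)) {
        ch <- spec$channels[c]
        if (!event_ch[c]) {
          data[c, cols] <- amp[c] *
            synth_proto_value(modes[k], (phi + shift / L) %% 1, psi[c],
                              spec$mode_weights[c, 1L],
                              spec$mode_weights[c, 2L], deviant)
        } else if (ch == "instr_shank.accel.z") {
          data[c, cols] <- synth_shape_burst(phi)
        } else {
          # FSR: zero through swing, rise at heel strike (heel) or shortly
          # after (ball), plateau at 1, linear fall reaching 0 at the next
          # toe-off
          rise <- if (grepl("ball", ch)) {
            min(L - 6L, i_hs + as.integer(round(0.05 * L)))
          } else {
            i_hs
          }
          v <- numeric(L)
          ramp_up <- rise + (1:3)
          ramp_up <- ramp_up[ramp_up <= L]
          v[ramp_up] <- (seq_along(ramp_up)) / 3
          if (rise + 4L <= L - 4L) v[(rise + 4L):(L - 4L)] <- 1
          v[(L - 3L):L] <- c(0.8, 0.6, 0.4, 0.2)
          data[c, cols] <- v
        }
      }
    }
    if (is.finite(spec$noise_snr_db)) {
      power <- rowMeans(data^2)
      noise_sd <- sqrt(power / 10^(spec$noise_snr_db / 10))
      data <- data + matrix(stats::rnorm(length(data)),
                            nrow = nch) * noise_sd
    }
    truth <- data.frame(start = starts, end = starts + lens, mode = modes)
    events <- rbind(
      data.frame(sample = starts, type = "toe_off"),
      data.frame(sample = hs, type = "heel_strike"))
    rec <- gait_recording(subject_id, spec$fs, spec$channels, data,
                          events = events,
                          labels = data.frame(start = starts,
                                              end = starts + lens,
                                              mode = modes))
    list(recording = rec, truth = truth)
  })
}

#' Generate a labeled multi-subject cycle corpus
#'
#' Runs [generate_recording()] for every subject, preprocesses each
#' recording (low-pass filtering and per-recording z-score normalization;
#' FSR channels keep their pressure scale), and segments it into labeled
#' cycles. By default the true toe-off events are used for segmentation so
#' downstream tests isolate classification behaviour; `use_detector = TRUE`
#' exercises [detect_toe_off()] instead.
#'
#' @param spec A [generator_spec()] with `n_subjects >= 1`.
#' @param preprocess Apply [preprocess_recording()] before segmentation.
#' @param use_detector Segment from detected rather than true toe-offs.
#' @param keep_recordings Also return the (preprocessed) recordings.
#' @return Object of class `"gait_benchmark"`: `cycles` (labeled
#'   [gait_cycle()] list across subjects), `manifest` (the spec plus
#'   per-subject truth tables), and optionally `recordings`.
#' @export
make_benchmark <- function(spec = generator_spec(), preprocess = TRUE,
                           use_detector = FALSE, keep_recordings = FALSE) {
  stopifnot(inherits(spec, "generator_spec"))
  cycles <- list()
  truths <- list()
  recordings <- list()
  for (s in seq_len(spec$n_subjects)) {
    g <- generate_recording(spec, s)
    rec <- if (preprocess) preprocess_recording(g$recording) else g$recording
    toe_offs <- if (use_detector) detect_toe_off(rec) else g$truth$start
    cyc <- segment_cycles(rec, c(toe_offs, ncol(rec$data)))
    cycles <- c(cycles, cyc)
    truths[[rec$subject_id]] <- g$truth
    if (keep_recordings) recordings[[rec$subject_id]] <- rec
  }
  out <- list(cycles = cycles,
              manifest = list(spec = spec, truth = truths))
  if (keep_recordings) out$recordings <- recordings
  structure(out, class = "gait_benchmark")
}

#' @export
print.gait_benchmark <- function(x, ...) {
  modes <- vapply(x$cycles, function(cy) cy$mode, "")
  cat("<gait_benchmark>", length(x$cycles), "cycles,",
      length(unique(vapply(x$cycles, function(cy) cy$subject_id, ""))),
      "subjects; modes:",
      paste(names(table(modes)), table(modes), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
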