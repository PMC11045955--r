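# quick single- or multi-channel cycle around a plain matrix
make_cycle <- function(data, mode = "LW", subject = "S01", fs = 100,
                       channels = NULL, id = NULL) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  if (is.null(channels)) {
    channels <- c("instr_hip.joint_angle", "uninstr_hip.joint_angle",
                  "uninstr_shank.accel.y", "instr_thigh.gyro.z",
                  "chest.accel.y", "chest.accel.z")[seq_len(nrow(data))]
  }
  gait_cycle(subject_id = subject, mode = mode, channels = channels,
             data = data, fs = fs, id = id)
}

# a smooth multi-channel prototype curve for template tests
proto_curve <- function(n_channels = 2L, len = 100L) {
  phi <- (0:(len - 1L)) / len
  t(vapply(seq_len(n_channels), function(c) {
    sin(2 * pi * phi + c) + 0.4 * cos(4 * pi * phi + 0.5 * c)
  }, numeric(len)))
}

# small labeled corpus: n_per mode cycles per subject, prototype + noise
toy_corpus <- function(subjects = c("S01", "S02", "S03"), n_per = 2L,
                       len = 60L, noise_sd = 0.02, seed = 99L) {
  set.seed(seed)
  phi <- (0:(len - 1L)) / len
  shapes <- list(LW = sin(2 * pi * phi),
                 LW_SC = sin(2 * pi * phi) + 0.8 * cos(2 * pi * phi),
                 LW_SD = sin(2 * pi * phi) - 0.8 * cos(2 * pi * phi))
  out <- list()
  for (s in subjects) {
    for (m in names(shapes)) {
      for (k in seq_len(n_per)) {
        data <- rbind(shapes[[m]] + rnorm(len, sd = noise_sd),
                      0.5 * shapes[[m]] + rnorm(len, sd = noise_sd))
        out[[length(out) + 1L]] <- gait_cycle(
          subject_id = s, mode = m,
          channels = c("instr_hip.joint_angle", "chest.accel.y"),
          data = data, fs = 100,
          id = sprintf("%s-%s-%d", s, m, k))
      }
    }
  }
  out
}
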