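#' Augmentation settings
#'
#' Minority (transitional) gait-cycle classes are expanded by three
#' families of perturbations: amplitude scaling to 96, 98, 102 and 104
#' percent of the original, time resampling by the same small factors, and
#' additive white Gaussian noise at signal-to-noise ratios of 30, 35, 40
#' and 45 dB. Each original cycle therefore yields
#' `1 + |amplitude_factors| + |resample_factors| + |snr_levels|` cycles
#' (13 under the defaults).
#'
#' @param amplitude_factors Multiplicative amplitude ratios (> 0).
#' @param resample_factors Length ratios (> 0) for time resampling.
#' @param snr_levels SNR targets in dB for the noise copies.
#' @param seed Integer seed recorded in output provenance and used to
#'   derive per-cycle noise seeds.
#' @return A list of class `"augmentation_spec"`.
#' @export
augmentation_spec <- function(amplitude_factors = c(0.96, 0.98, 1.02, 1.04),
                              resample_factors = c(0.96, 0.98, 1.02, 1.04),
                              snr_levels = c(30, 35, 40, 45),
                              seed = 1L) {
  stopifnot(all(amplitude_factors > 0), all(resample_factors > 0),
            all(is.finite(snr_levels)))
  structure(list(amplitude_factors = amplitude_factors,
                 resample_factors = resample_factors,
                 snr_levels = snr_levels, seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Amplitude-scale a cycle
#'
#' @param cycle A [gait_cycle()].
#' @param factor Positive ratio; every sample is multiplied by it.
#' @return A new cycle with provenance linking it to `cycle`.
#' @export
scale_amplitude <- function(cycle, factor) {
  stopifnot(inherits(cycle, "gait_cycle"))
  if (!is.numeric(factor) || factor <= 0) {
    stop("amplitude factor must be positive", call. = FALSE)
  }
  derived_cycle(cycle, cycle$data * factor,
                op = "scale", param = factor)
}

#' Resample a cycle to a new length
#'
#' Linear interpolation of every channel onto a uniform grid of
#' `round(old_length * factor)` samples; endpoints are preserved and affine
#' signals remain affine.
#'
#' @param cycle A [gait_cycle()].
#' @param factor Positive length ratio; the new length must be >= 4.
#' @return A new cycle with provenance linking it to `cycle`.
#' @export
resample_cycle <- function(cycle, factor) {
  stopifnot(inherits(cycle, "gait_cycle"), is.numeric(factor), factor > 0)
  old_len <- cycle_length(cycle)
  new_len <- as.integer(round(old_len * factor))
  if (new_len < 4L) {
    stop("resampled length ", new_len, " is below the minimum of 4",
         call. = FALSE)
  }
  derived_cycle(cycle, resample_matrix(cycle$data, new_len),
                op = "resample", param = factor)
}

# linear interpolation of each row onto a uniform grid of n_out samples
resample_matrix <- function(data, n_out) {
  n_in <- ncol(data)
  if (n_out == n_in) return(data)
  xin <- seq(0, 1, length.out = n_in)
  xout <- seq(0, 1, length.out = n_out)
  out <- matrix(0, nrow = nrow(data), ncol = n_out,
                dimnames = list(rownames(data), NULL))
  for (i in seq_len(nrow(data))) {
    out[i, ] <- stats::approx(xin, data[i, ], xout = xout)$y
  }
  out
}

#' Add white Gaussian noise at a target SNR
#'
#' Per channel, the noise variance is `signal power / 10^(snr_db / 10)`
#' where signal power is the mean square of the channel. `snr_db = Inf`
#' returns the cycle unchanged. Noise is i.i.d. Gaussian and fully
#' determined by `rng_seed`.
#'
#' @param cycle A [gait_cycle()].
#' @param snr_db Target signal-to-noise ratio in dB (may be `Inf`).
#' @param rng_seed Integer seed.
#' @return A new cycle with provenance linking it to `cycle`.
#' @export
add_awgn <- function(cycle, snr_db, rng_seed) {
  stopifnot(inherits(cycle, "gait_cycle"), is.numeric(snr_db))
  if (is.infinite(snr_db) && snr_db > 0) {
    return(derived_cycle(cycle, cycle$data, op = "awgn", param = snr_db))
  }
  power <- rowMeans(cycle$data^2)
  if (any(power == 0)) {
    stop("cycle has a zero-power channel; SNR is undefined", call. = FALSE)
  }
  noise_sd <- sqrt(power / 10^(snr_db / 10))
  data <- with_seed(as.integer(rng_seed), {
    cycle$data + matrix(stats::rnorm(length(cycle$data)),
                        nrow = nrow(cycle$data)) * noise_sd
  })
  derived_cycle(cycle, data, op = "awgn", param = snr_db)
}

derived_cycle <- function(cycle, data, op, param) {
  gait_cycle(subject_id = cycle$subject_id, mode = cycle$mode,
             channels = cycle$channels, data = data, fs = cycle$fs,
             source_span = cycle$source_span,
             id = sprintf("%s-%s%g", cycle$id, substr(op, 1, 1), param),
             provenance = list(derived_from = cycle$id, op = op,
                               param = param))
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Augment a set of cycles
#'
#' Applies every perturbation in `spec` to every input cycle and returns
#' originals plus derived cycles: `N * (1 + |amplitude_factors| +
#' |resample_factors| + |snr_levels|)` in total. Each derived cycle's
#' provenance names its original, so fold hygiene can be audited
#' downstream.
#'
#' @param cycles Nonempty list of [gait_cycle()] objects.
#' @param spec An [augmentation_spec()].
#' @return List of cycles (originals first, then scaled, resampled and
#'   noise copies per original).
#' @seealso [augment_transitions()] to augment only the transitional
#'   classes of a mixed corpus.
#' @export
augment_class <- function(cycles, spec = augmentation_spec()) {
  stopifnot(is.list(cycles), length(cycles) >= 1L,
            inherits(spec, "augmentation_spec"))
  out <- vector("list",
                length(cycles) * (1L + length(spec$amplitude_factors) +
                                    length(spec$resample_factors) +
                                    length(spec$snr_levels)))
  k <- 0L
  for (i in seq_along(cycles)) {
    cy <- cycles[[i]]
    out[[k <- k + 1L]] <- cy
    for (f in spec$amplitude_factors) {
      out[[k <- k + 1L]] <- scale_amplitude(cy, f)
    }
    for (f in spec$resample_factors) {
      out[[k <- k + 1L]] <- resample_cycle(cy, f)
    }
    for (j in seq_along(spec$snr_levels)) {
      out[[k <- k + 1L]] <- add_awgn(cy, spec$snr_levels[j],
                                     rng_seed = spec$seed + 131L * i + j)
    }
  }
  out
}

#' @rdname augment_class
#' @param classes Mode labels to augment (default: the two transitions);
#'   cycles of other modes pass through untouched.
#' @export
augment_transitions <- function(cycles, spec = augmentation_spec(),
                                classes = c("LW_SC", "LW_SD")) {
  take <- vapply(cycles, function(cy) !is.na(cy$mode) && cy$mode %in% classes,
                 TRUE)
  if (!any(take)) return(cycles)
  c(cycles[!take], augment_class(cycles[take], spec))
}
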