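#' Specification of a synthetic IMU movement dataset
#'
#' The generator emulates the statistical structure the analysis relies
#' on: two participant groups (non-disabled and stroke, the latter with a
#' hemiparesis side), class-specific oscillatory channel patterns, highly
#' variable segment durations, and movement-type-dependent left/right
#' energy asymmetry (unimanual movements far more one-sided than bimanual
#' asymmetric ones, bimanual symmetric movements balanced). Task presets
#' carry the observed segment-length statistics: ROM 1016 +/- 492 time
#' points, ADL 4229 +/- 3072, both floored at 240.
#'
#' @param task `"ROM"` or `"ADL"` (sets class count and length defaults)
#'   or `"custom"`.
#' @param n_nd,n_stroke Participant counts per group.
#' @param n_classes Number of movement classes (ROM default 14, ADL 56).
#' @param class_type_map Character vector of length `n_classes` mapping
#'   each movement id to `"UNI"`, `"BIA"` or `"BIS"`. Defaults: all UNI
#'   for ROM; cycling UNI/BIA/BIS for ADL and custom tasks.
#' @param length_mean,length_sd,length_floor Segment-length distribution
#'   (time points); lengths are drawn from a truncated normal whose
#'   location is adjusted so the post-truncation mean equals
#'   `length_mean`.
#' @param base_freq_range Oscillation band (Hz) the class templates draw
#'   their component frequencies from.
#' @param asym_energy_ratio Named numeric: target active/inactive side
#'   energy ratio of the deterministic template per movement type.
#'   Defaults (UNI 110, BIA 1.65, BIS 1) put the log-ratio asymmetry
#'   score near 4.7, 0.5 and 0 respectively, reproducing the observed
#'   UNI > BIA > BIS ordering.
#' @param stroke_distortion Named numeric `c(amp_sd, phase_sd,
#'   duration_factor)`: log-normal amplitude jitter and phase jitter
#'   applied per channel/harmonic to the affected side of stroke
#'   participants, and a multiplicative inflation of their segment
#'   durations.
#' @param noise_sd Additive white-noise standard deviation on every
#'   channel (template amplitudes are order 1).
#' @param trunk_amp Amplitude of the trunk-sensor channels.
#' @param sampling_rate Nominal sampling rate (Hz) for template time.
#' @param seed Integer seed making [generate_dataset()] reproducible.
#' @return Object of class `har_synthetic_spec`.
#' @export
synthetic_spec <- function(task = c("ROM", "ADL", "custom"),
                           n_nd = 3, n_stroke = 2, n_classes = NULL,
                           class_type_map = NULL,
                           length_mean = NULL, length_sd = NULL,
                           length_floor = 240,
                           base_freq_range = c(0.3, 3),
                           asym_energy_ratio = c(UNI = 110, BIA = 1.65, BIS = 1),
                           stroke_distortion = c(amp_sd = 0.3, phase_sd = 0.4,
                                                 duration_factor = 1.25),
                           noise_sd = 0.05, trunk_amp = 0.3,
                           sampling_rate = 80, seed = 1L) {
  task <- match.arg(task)
  n_classes <- n_classes %||% switch(task, ROM = 14L, ADL = 56L, custom = 6L)
  length_mean <- length_mean %||% switch(task, ROM = 1016, ADL = 4229, custom = 400)
  length_sd <- length_sd %||% switch(task, ROM = 492, ADL = 3072, custom = 100)
  if (is.null(class_type_map)) {
    class_type_map <- if (task == "ROM") rep("UNI", n_classes)
                      else c("UNI", "BIA", "BIS")[(seq_len(n_classes) - 1L) %% 3L + 1L]
  }
  stopifnot(n_nd >= 1 || n_stroke >= 1, n_classes >= 1,
            length(class_type_map) == n_classes,
            all(class_type_map %in% c("UNI", "BIA", "BIS")),
            length_sd < length_mean, length_floor < length_mean,
            all(asym_energy_ratio >= 1), noise_sd >= 0)
  structure(
    list(task = task, n_nd = as.integer(n_nd), n_stroke = as.integer(n_stroke),
         n_classes = as.integer(n_classes), class_type_map = class_type_map,
         length_mean = length_mean, length_sd = length_sd,
         length_floor = length_floor, base_freq_range = base_freq_range,
         asym_energy_ratio = asym_energy_ratio,
         stroke_distortion = stroke_distortion, noise_sd = noise_sd,
         trunk_amp = trunk_amp, sampling_rate = sampling_rate,
         seed = as.integer(seed)),
    class = "har_synthetic_spec"
  )
}

# Deterministic template parameters: low-discrepancy fractions of
# irrational multiples decorrelate frequencies/phases across
# (movement, channel, harmonic) without consuming RNG state.
template_params <- function(movement_id, channel_rank, freq_range) {
  H <- 2L + (movement_id %% 3L)          # 2..4 harmonics per class
  h <- seq_len(H)
  frac <- function(z) z - floor(z)
  freq <- freq_range[1] + frac(movement_id * 0.6180339887 +
                               channel_rank * 0.3247179572 +
                               h * 0.5698402910) * diff(freq_range)
  phase <- 2 * pi * frac(movement_id * 0.7548776662 +
                         channel_rank * 0.5698402910 + h * 0.1931851653)
  list(freq = freq, phase = phase, amp = 1 / h)
}

# Truncated-normal sampler whose post-truncation mean equals `mean`.
rlength_trunc <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(round(mean), n))
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                       c(mean - 6 * sd, mean))$root
  out <- stats::rnorm(n, mu, sd)
  while (any(bad <- out < lower)) out[bad] <- stats::rnorm(sum(bad), mu, sd)
  round(out)
}

#' Generate one synthetic movement segment
#'
#' Produces a full 45-channel segment. Each accelerometer/gyroscope
#' channel carries a deterministic class template (a sum of 2-4 sinusoids
#' whose frequencies and phases are fixed functions of the movement id
#' and channel), scaled per body side so the active-to-inactive energy
#' ratio matches the movement type's `asym_energy_ratio`. The active side
#' is the right for non-disabled and right-hemiparesis participants and
#' the left for left-hemiparesis participants. Stroke participants
#' receive amplitude and phase jitter on their affected side and longer
#' durations. Magnetometer channels carry a slowly varying offset plus
#' noise (they are excluded downstream).
#'
#' @param spec A [synthetic_spec()].
#' @param participant List with `participant_id`, `group`,
#'   `hemiparesis_side`, and optionally `amp_scale`, `phase_offset`
#'   (participant-level variability; default 1 and 0).
#' @param movement_id Movement class in `1..spec$n_classes`.
#' @param seed Optional seed; if `NULL` the current RNG stream is used
#'   (as when called from [generate_dataset()]).
#' @param layout Channel layout.
#' @return A [har_segment]; attribute `truth` (`$truth`) records the
#'   realized generative parameters (length, active side, per-side
#'   amplitude scales).
#' @export
generate_segment <- function(spec, participant, movement_id, seed = NULL,
                             layout = channel_layout()) {
  if (!movement_id %in% seq_len(spec$n_classes))
    stop("movement_id not in class_type_map")
  if (!is.null(seed)) set.seed(seed)
  type <- spec$class_type_map[movement_id]
  amp_scale <- participant$amp_scale %||% 1
  phase_off <- participant$phase_offset %||% 0
  affected <- if (participant$group == "Stroke") participant$hemiparesis_side else "none"
  active <- if (participant$group == "Stroke" && participant$hemiparesis_side == "left")
    "left" else "right"

  len <- rlength_trunc(1, spec$length_mean, spec$length_sd, spec$length_floor)
  if (participant$group == "Stroke")
    len <- round(len * spec$stroke_distortion[["duration_factor"]])
  tt <- (seq_len(len) - 1) / spec$sampling_rate

  ratio <- spec$asym_energy_ratio[[type]]
  side_amp <- c(right = 1, left = 1, trunk = spec$trunk_amp)
  if (type %in% c("UNI", "BIA")) {
    inactive <- if (active == "right") "left" else "right"
    side_amp[inactive] <- 1 / sqrt(ratio)
  }

  ch <- layout$channels
  v <- matrix(0, len, layout$n_channels, dimnames = list(NULL, ch$name))
  rank <- 0L
  for (i in seq_len(nrow(ch))) {
    if (ch$modality[i] == "mag") {
      v[, i] <- 30 + 5 * sin(2 * pi * 0.05 * tt + i) +
        stats::rnorm(len, 0, spec$noise_sd)
      next
    }
    rank <- rank + 1L
    tp <- template_params(movement_id, rank, spec$base_freq_range)
    amp <- tp$amp * side_amp[[ch$side[i]]] * amp_scale
    phase <- tp$phase + phase_off
    if (affected != "none" && ch$side[i] == affected) {
      amp <- amp * exp(stats::rnorm(length(amp), 0, spec$stroke_distortion[["amp_sd"]]))
      phase <- phase + stats::rnorm(length(phase), 0, spec$stroke_distortion[["phase_sd"]])
    }
    sig <- 0
    for (h in seq_along(tp$freq))
      sig <- sig + amp[h] * sin(2 * pi * tp$freq[h] * tt + phase[h])
    v[, i] <- sig + stats::rnorm(len, 0, spec$noise_sd)
  }
  seg <- har_segment(v, participant_id = participant$participant_id,
                     group = participant$group,
                     hemiparesis_side = participant$hemiparesis_side,
                     task = spec$task, movement_id = movement_id,
                     movement_type = type)
  seg$truth <- list(length = len, active_side = active,
                    side_amp = side_amp, movement_type = type)
  seg
}

#' Generate a complete synthetic dataset
#'
#' Creates `n_nd + n_stroke` participants, each performing every movement
#' class once. Stroke participants are assigned hemiparesis sides
#' alternately right/left unless `stroke_sides` is given. Participant
#' variability enters through a log-normal amplitude scale and a phase
#' offset drawn per participant. Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param stroke_sides Optional character vector of length `n_stroke`.
#' @return A [har_dataset()] with an extra element `truth`: a data.frame
#'   of per-segment generative parameters.
#' @export
generate_dataset <- function(spec, stroke_sides = NULL) {
  set.seed(spec$seed)
  sides <- stroke_sides %||% rep(c("right", "left"), length.out = spec$n_stroke)
  parts <- c(
    lapply(seq_len(spec$n_nd), function(i)
      list(participant_id = sprintf("ND%02d", i), group = "ND",
           hemiparesis_side = "none")),
    lapply(seq_len(spec$n_stroke), function(i)
      list(participant_id = sprintf("ST%02d", i), group = "Stroke",
           hemiparesis_side = sides[i]))
  )
  parts <- lapply(parts, function(p) {
    p$amp_scale <- exp(stats::rnorm(1, 0, 0.1))
    p$phase_offset <- stats::rnorm(1, 0, 0.2)
    p
  })
  segs <- list()
  truth <- list()
  for (p in parts) {
    for (m in seq_len(spec$n_classes)) {
      seg <- generate_segment(spec, p, m)
      segs[[length(segs) + 1L]] <- seg
      truth[[length(truth) + 1L]] <- data.frame(
        segment_id = seg$segment_id, participant_id = p$participant_id,
        movement_id = m, movement_type = seg$movement_type,
        active_side = seg$truth$active_side, length = seg$truth$length,
        stringsAsFactors = FALSE)
    }
  }
  ds <- har_dataset(segs, task = spec$task)
  ds$truth <- do.call(rbind, truth)
  ds
}
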