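#' Left/right channel sets for the energy asymmetry score
#'
#' The lateralized sensors are the wrists (1 right, 2 left) and upper arms
#' (4 right, 5 left); with the default accelerometer + gyroscope
#' selection each side contributes 12 channels. The trunk sensor belongs
#' to neither side and magnetometer channels are excluded.
#'
#' @param layout A [channel_layout()].
#' @param modalities Modalities entering the energy computation.
#' @return Object of class `har_side_sets`: list with character vectors
#'   `RC`, `LC` and counts `NR`, `NL`.
#' @export
side_channel_sets <- function(layout = channel_layout(),
                              modalities = c("acc", "gyro")) {
  ch <- layout$channels
  rc <- ch$name[ch$side == "right" & ch$modality %in% modalities]
  lc <- ch$name[ch$side == "left" & ch$modality %in% modalities]
  structure(list(RC = rc, LC = lc, NR = length(rc), NL = length(lc)),
            class = "har_side_sets")
}

#' Mean per-channel mean-square energy of each body side
#'
#' For a zero-centered segment with values `x[c, t]`, the right-side
#' energy is `ER = (1/NR) * sum_{c in RC} (1/T) * sum_t x[c, t]^2`, and
#' `EL` analogously over the left-side channels. `T` is the segment
#' length; comparisons across segments assume a common (interpolated)
#' length.
#'
#' @param segment A zero-centered [har_segment] containing the side
#'   channels.
#' @param sides A [side_channel_sets()].
#' @return Named numeric vector `c(ER = ..., EL = ...)`.
#' @export
side_energies <- function(segment, sides = side_channel_sets()) {
  if (!length(sides$RC) || !length(sides$LC)) stop("empty side channel set")
  v <- segment$values
  miss <- setdiff(c(sides$RC, sides$LC), colnames(v))
  if (length(miss)) stop("segment lacks side channels: ", miss[1], " ...")
  er <- mean(colMeans(v[, sides$RC, drop = FALSE]^2))
  el <- mean(colMeans(v[, sides$LC, drop = FALSE]^2))
  c(ER = er, EL = el)
}

#' Energy asymmetry score
#'
#' `Sasym = log((ER + eps) / (EL + eps))` with natural log and stabilizer
#' `eps = 0.001`. Positive when right-side energy dominates, negative when
#' the left side dominates, zero when both sides carry equal energy. Its
#' absolute value (AAS) quantifies how one-sided a movement is regardless
#' of side.
#'
#' @param ER,EL Nonnegative side energies (or a single vector as returned
#'   by [side_energies()] passed as `ER`).
#' @param epsilon Stabilizer; 0.001.
#' @return The asymmetry score (dimensionless).
#' @examples
#' asymmetry_score(1, 0)        # log(1.001/0.001) ~ 6.91
#' asymmetry_score(0.5, 0.5)    # 0
#' @export
asymmetry_score <- function(ER, EL = NULL, epsilon = 0.001) {
  if (is.null(EL)) { EL <- ER[["EL"]]; ER <- ER[["ER"]] }
  if (ER < 0 || EL < 0) stop("energies must be nonnegative")
  log((ER + epsilon) / (EL + epsilon))
}

#' Per-segment asymmetry table for a dataset
#'
#' Zero-centers each segment (scores are defined on zero-averaged
#' signals), optionally interpolates to a common length first, and
#' computes `ER`, `EL`, `Sasym` and `|Sasym|`.
#'
#' @param dataset A [har_dataset()].
#' @param sides A [side_channel_sets()].
#' @param interpolate_to If non-`NULL` (default: the nominal mean length of
#'   the dataset's segments, rounded), segments are linearly interpolated
#'   to this common length before scoring so `T` is constant across
#'   segments; pass `NULL` to score raw-length segments.
#' @return data.frame with segment metadata plus `ER`, `EL`, `Sasym`,
#'   `abs_Sasym`.
#' @export
segment_asymmetry <- function(dataset, sides = side_channel_sets(),
                              interpolate_to = round(mean(dataset_meta(dataset)$length))) {
  meta <- dataset_meta(dataset)
  res <- t(vapply(dataset$segments, function(seg) {
    seg <- zero_center(seg)
    if (!is.null(interpolate_to)) seg <- interpolate_segment(seg, interpolate_to)
    e <- side_energies(seg, sides)
    s <- asymmetry_score(e)
    c(e, Sasym = s, abs_Sasym = abs(s))
  }, numeric(4)))
  cbind(meta, as.data.frame(res))
}

#' Absolute asymmetry score summarized by movement type
#'
#' Mirrors the reporting convention of per-movement mean AAS across
#' participants: `|Sasym|` is first averaged per movement class across
#' participants, then mean and standard deviation are taken over the
#' movement classes of each type. `aggregation = "pooled"` instead pools
#' all segments of a type directly.
#'
#' @param dataset A [har_dataset()].
#' @param sides A [side_channel_sets()].
#' @param aggregation `"by_movement"` (default) or `"pooled"`.
#' @param ... Passed to [segment_asymmetry()].
#' @return data.frame with columns `movement_type`, `mean_aas`, `sd_aas`,
#'   `n` (movements or segments, per aggregation). Types with no segments
#'   are omitted with a warning. A single-member group reports `sd_aas` 0.
#' @export
aas_by_movement_type <- function(dataset, sides = side_channel_sets(),
                                 aggregation = c("by_movement", "pooled"), ...) {
  aggregation <- match.arg(aggregation)
  tab <- segment_asymmetry(dataset, sides, ...)
  types <- intersect(c("UNI", "BIA", "BIS"), unique(tab$movement_type))
  if (length(setdiff(c("UNI", "BIA", "BIS"), types)))
    warning("movement types absent from dataset: ",
            paste(setdiff(c("UNI", "BIA", "BIS"), types), collapse = ", "))
  rows <- lapply(types, function(tp) {
    sub <- tab[tab$movement_type == tp, ]
    vals <- if (aggregation == "by_movement")
      tapply(sub$abs_Sasym, sub$movement_id, mean)
    else sub$abs_Sasym
    data.frame(movement_type = tp, mean_aas = mean(vals),
               sd_aas = if (length(vals) > 1L) stats::sd(vals) else 0,
               n = length(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
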