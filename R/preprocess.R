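#' Preprocessing configuration
#'
#' Holds the parameters of the raw-segment-to-window pipeline. The task
#' presets carry the values used throughout: ROM segments are interpolated
#' to 1000 time points and cut with a 200-point window and stride 42; ADL
#' segments to 3700 points with window 740 and stride 150. Both choices
#' yield exactly 20 windows per segment, so every (participant, class)
#' pair contributes the same number of training examples regardless of how
#' long the movement took.
#'
#' @param task `"rom"`, `"adl"`, or `"custom"`.
#' @param target_length Interpolated segment length `T` (time points).
#' @param window_size Sliding-window length (time points).
#' @param stride Sliding-window step (time points).
#' @param channels Character vector of channel names to keep, ordered;
#'   default: accelerometer + gyroscope of all five sensors (30 channels).
#' @param swap_sides_for_left_hemiparesis If `TRUE` (default), left-right
#'   sensor blocks of left-hemiparesis participants are exchanged before
#'   windowing so the dominant-activity side is aligned across
#'   participants.
#' @param layout Channel layout of the raw segments.
#' @return An object of class `har_preprocess_config`.
#' @examples
#' cfg <- preprocess_config("rom")
#' windows_per_segment(cfg)  # 20
#' @export
preprocess_config <- function(task = c("rom", "adl", "custom"),
                              target_length = NULL, window_size = NULL,
                              stride = NULL,
                              channels = channel_subset(layout),
                              swap_sides_for_left_hemiparesis = TRUE,
                              layout = channel_layout()) {
  task <- match.arg(task)
  preset <- switch(task,
    rom = list(target_length = 1000L, window_size = 200L, stride = 42L),
    adl = list(target_length = 3700L, window_size = 740L, stride = 150L),
    custom = list(target_length = NULL, window_size = NULL, stride = NULL))
  target_length <- as.integer(target_length %||% preset$target_length)
  window_size <- as.integer(window_size %||% preset$window_size)
  stride <- as.integer(stride %||% preset$stride)
  if (anyNA(c(target_length, window_size, stride)))
    stop("custom task requires target_length, window_size and stride")
  if (window_size > target_length) stop("window_size must not exceed target_length")
  if (stride < 1L) stop("stride must be positive")
  if (!length(channels)) stop("channel subset must be nonempty")
  structure(
    list(task = task, target_length = target_length,
         window_size = window_size, stride = stride, channels = channels,
         swap_sides_for_left_hemiparesis = swap_sides_for_left_hemiparesis,
         layout = layout),
    class = "har_preprocess_config"
  )
}

#' Number of sliding windows a configuration produces per segment
#'
#' `floor((T - window_size) / stride) + 1`; 20 for both task presets.
#'
#' @param config A `har_preprocess_config`.
#' @return Integer window count.
#' @export
windows_per_segment <- function(config) {
  (config$target_length - config$window_size) %/% config$stride + 1L
}

#' Zero-center every channel of a segment
#'
#' Subtracts each channel's mean over the segment so all channel means are
#' exactly zero. This removes static offsets (gravity on accelerometers,
#' sensor bias) before energies and windows are computed.
#'
#' @param segment A [har_segment].
#' @return The segment with centered values.
#' @export
zero_center <- function(segment) {
  segment$values <- sweep(segment$values, 2L, colMeans(segment$values))
  segment
}

#' Keep a subset of channels
#'
#' @param segment A [har_segment].
#' @param channels Channel names to keep (see [channel_subset()]); order of
#'   the returned columns follows `channels`.
#' @return The segment restricted to `channels`.
#' @export
select_channels <- function(segment, channels) {
  miss <- setdiff(channels, colnames(segment$values))
  if (length(miss))
    stop("unknown channels: ", paste(utils::head(miss, 5), collapse = ", "))
  segment$values <- segment$values[, channels, drop = FALSE]
  segment
}

#' Exchange left- and right-side sensor blocks
#'
#' Swaps the wrist sensors (1 <-> 2) and the upper-arm sensors (4 <-> 5)
#' by renaming channel blocks; the trunk sensor (3) and all axis values
#' are untouched. Applied to left-hemiparesis participants so that the
#' side carrying the dominant (affected-limb) activity occupies the same
#' channel positions for every participant. Applying the swap twice
#' restores the original segment.
#'
#' @param segment A [har_segment] whose channels follow the standard
#'   naming (works on the 45-channel raw layout and any subset of it).
#' @return The segment with side blocks exchanged.
#' @export
swap_sides <- function(segment) {
  cn <- colnames(segment$values)
  sensor <- as.integer(sub("^S(\\d)_.*$", "\\1", cn))
  if (anyNA(sensor)) stop("channel names carry no sensor/side information")
  partner <- c(2L, 1L, 3L, 5L, 4L)[sensor]
  swapped_names <- sub("^S\\d", "", cn)
  swapped_names <- paste0("S", partner, swapped_names)
  take <- match(cn, swapped_names)
  if (anyNA(take))
    stop("channel subset is not side-symmetric; cannot swap sides")
  segment$values <- segment$values[, take, drop = FALSE]
  colnames(segment$values) <- cn
  segment
}

#' Linearly interpolate a segment to a fixed length
#'
#' Each channel is resampled by piecewise-linear interpolation at `T`
#' equally spaced query positions spanning the first to the last sample
#' (endpoints reproduced exactly). The abscissa is the sample index, not
#' the timestamp, so the operation is deterministic under irregular
#' sampling.
#'
#' @param segment A [har_segment] with at least 2 rows.
#' @param target_length Output length `T`.
#' @return The segment with exactly `target_length` rows.
#' @export
interpolate_segment <- function(segment, target_length) {
  n <- nrow(segment$values)
  if (n < 2L) stop("cannot interpolate a segment shorter than 2 samples")
  xq <- seq(1, n, length.out = target_length)
  lo <- pmin(floor(xq), n - 1L)
  w <- xq - lo
  v <- segment$values
  out <- v[lo, , drop = FALSE] * (1 - w) + v[lo + 1L, , drop = FALSE] * w
  colnames(out) <- colnames(v)
  segment$values <- out
  segment
}

#' Cut a fixed-length segment into sliding windows
#'
#' Window `i` (0-based) covers rows `[i * stride, i * stride + window_size)`
#' of the interpolated segment; windows are emitted until the remaining
#' length is shorter than the window, i.e.
#' `floor((T - window_size) / stride) + 1` windows. Trailing rows not
#' covered by the last window are discarded.
#'
#' @param segment A [har_segment] of length `config$target_length`.
#' @param config A `har_preprocess_config`.
#' @return 3-d array `[n_windows x window_size x n_channels]` with the
#'   segment's metadata in attributes `participant_id`, `movement_id`, ...
#' @export
slide_windows <- function(segment, config) {
  v <- segment$values
  Tlen <- nrow(v)
  w <- config$window_size; s <- config$stride
  if (w > Tlen) stop("window_size exceeds segment length")
  nw <- (Tlen - w) %/% s + 1L
  out <- array(0, dim = c(nw, w, ncol(v)),
               dimnames = list(NULL, NULL, colnames(v)))
  for (i in seq_len(nw)) out[i, , ] <- v[((i - 1L) * s + 1L):((i - 1L) * s + w), ]
  out
}

#' Run the full preprocessing pipeline on a dataset
#'
#' Applies, in order: zero-centering, channel selection, left/right sensor
#' swapping (left-hemiparesis participants only, when enabled), linear
#' interpolation to the configured length, and sliding-window slicing.
#' Every segment contributes the same number of windows, which is what
#' makes the class distribution balanced downstream.
#'
#' @param dataset A [har_dataset()].
#' @param config A [preprocess_config()].
#' @return List with `x`, a `[n_windows x window_size x n_channels]`
#'   array, and `meta`, a data.frame with one row per window (participant,
#'   group, side, movement id/type, segment id, window index).
#' @export
preprocess_dataset <- function(dataset, config) {
  nw <- windows_per_segment(config)
  segs <- dataset$segments
  n <- length(segs)
  x <- array(0, dim = c(n * nw, config$window_size, length(config$channels)),
             dimnames = list(NULL, NULL, config$channels))
  meta <- vector("list", n)
  for (j in seq_len(n)) {
    seg <- preprocess_segment(segs[[j]], config)
    win <- slide_windows(seg, config)
    stopifnot(dim(win)[1] == nw)
    x[((j - 1L) * nw + 1L):(j * nw), , ] <- win
    meta[[j]] <- data.frame(
      participant_id = seg$participant_id, group = seg$group,
      hemiparesis_side = seg$hemiparesis_side,
      movement_id = seg$movement_id, movement_type = seg$movement_type,
      segment_id = seg$segment_id, window_index = seq_len(nw) - 1L,
      stringsAsFactors = FALSE)
  }
  list(x = x, meta = do.call(rbind, meta), config = config)
}

#' @rdname preprocess_dataset
#' @param segment One [har_segment]; returns the interpolated (not yet
#'   windowed) segment.
#' @export
preprocess_segment <- function(segment, config) {
  seg <- zero_center(segment)
  seg <- select_channels(seg, config$channels)
  if (config$swap_sides_for_left_hemiparesis && seg$hemiparesis_side == "left")
    seg <- swap_sides(seg)
  interpolate_segment(seg, config$target_length)
}
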