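#' Channel layout of a five-sensor IMU recording
#'
#' The recording dialect carries 45 raw channels ordered sensor-major:
#' five sensors (1 = right wrist, 2 = left wrist, 3 = trunk, 4 = right
#' upper arm, 5 = left upper arm), each contributing nine channels in the
#' fixed order accelerometer, gyroscope, magnetometer, each with x, y, z
#' axes. The layout object makes the channel-index <-> (sensor, modality,
#' axis) mapping explicit so that channel selection, side swapping and
#' rotation can be expressed against names rather than magic indices.
#'
#' @param sensor_ids Integer sensor labels in storage order.
#' @return An object of class `har_layout` with components `sensor_ids`,
#'   `modalities`, `axes`, a `channels` data.frame (one row per channel,
#'   columns `index`, `sensor`, `modality`, `axis`, `name`, `side`) and
#'   `n_channels`.
#' @examples
#' lay <- channel_layout()
#' lay$n_channels                       # 45
#' channel_name(lay, 1)                 # "S1_acc_x"
#' channel_index(lay, 2, "gyro", "z")
#' @export
channel_layout <- function(sensor_ids = 1:5) {
  stopifnot(length(sensor_ids) == 5L)
  modalities <- c("acc", "gyro", "mag")
  axes <- c("x", "y", "z")
  grid <- expand.grid(axis = axes, modality = modalities, sensor = sensor_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder to sensor-major
  grid <- grid[, c("sensor", "modality", "axis")]
  side <- c("right", "left", "trunk", "right", "left")[match(grid$sensor, sensor_ids)]
  channels <- data.frame(
    index = seq_len(nrow(grid)),
    sensor = grid$sensor,
    modality = grid$modality,
    axis = grid$axis,
    name = sprintf("S%d_%s_%s", grid$sensor, grid$modality, grid$axis),
    side = side,
    stringsAsFactors = FALSE
  )
  structure(
    list(sensor_ids = sensor_ids, modalities = modalities, axes = axes,
         channels = channels, n_channels = nrow(channels)),
    class = "har_layout"
  )
}

#' Map (sensor, modality, axis) to a channel index
#'
#' @param layout A `har_layout`.
#' @param sensor Sensor id (1..5).
#' @param modality One of "acc", "gyro", "mag".
#' @param axis One of "x", "y", "z".
#' @return Integer channel index in 1..45.
#' @export
channel_index <- function(layout, sensor, modality, axis) {
  ch <- layout$channels
  i <- which(ch$sensor == sensor & ch$modality == modality & ch$axis == axis)
  if (length(i) != 1L)
    stop("unknown (sensor, modality, axis): (", sensor, ", ", modality, ", ", axis, ")")
  ch$index[i]
}

#' Inverse mapping: channel index to its (sensor, modality, axis) triple
#'
#' @param layout A `har_layout`.
#' @param index Channel index in 1..n_channels.
#' @return One-row data.frame with sensor, modality, axis, name, side.
#' @export
channel_info <- function(layout, index) {
  if (any(index < 1L | index > layout$n_channels))
    stop("channel index out of range")
  layout$channels[index, c("sensor", "modality", "axis", "name", "side")]
}

#' @rdname channel_index
#' @export
channel_name <- function(layout, index) layout$channels$name[index]

#' Resolve a (sensor, modality) channel subset to channel names
#'
#' Channel subsets are how the model-input selection and the single-sensor
#' ablations are expressed: the default keeps accelerometer and gyroscope
#' channels of all five sensors (30 channels); `sensors = 1` with
#' `modalities = c("acc", "gyro")` gives the 6-channel single-wrist subset,
#' `modalities = "acc"` the 3-channel accelerometer-only subset.
#'
#' @param layout A `har_layout`.
#' @param sensors Sensor ids to keep.
#' @param modalities Modalities to keep.
#' @return Character vector of channel names, in sensor-major layout order.
#' @export
channel_subset <- function(layout, sensors = layout$sensor_ids,
                           modalities = c("acc", "gyro")) {
  if (!all(sensors %in% layout$sensor_ids)) stop("unknown sensor id")
  if (!all(modalities %in% layout$modalities)) stop("unknown modality")
  ch <- layout$channels
  ch$name[ch$sensor %in% sensors & ch$modality %in% modalities]
}
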