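#' Construct a movement segment
#'
#' A segment is one annotated movement instance: a `[time x channel]` slice
#' of a recording together with the metadata the downstream stages need
#' (who performed it, which group and hemiparesis side, which task, which
#' movement class and movement type).
#'
#' @param values Numeric matrix, rows are time points, columns channels;
#'   column names must be layout channel names (see [channel_layout()]).
#' @param participant_id Character scalar.
#' @param group `"ND"` or `"Stroke"`.
#' @param hemiparesis_side `"none"`, `"left"` or `"right"`.
#' @param task `"ROM"` or `"ADL"` (or any task label).
#' @param movement_id Integer movement class label.
#' @param movement_type `"UNI"`, `"BIA"` or `"BIS"`.
#' @param segment_id Optional identifier; defaults to
#'   `"<participant>_<task>_<movement>"`.
#' @return An object of class `har_segment`.
#' @export
har_segment <- function(values, participant_id, group = "ND",
                        hemiparesis_side = "none", task = "ROM",
                        movement_id = 1L, movement_type = "UNI",
                        segment_id = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 1L)
  if (is.null(colnames(values)))
    stop("segment values must carry channel names as column names")
  if (!group %in% c("ND", "Stroke")) stop("group must be 'ND' or 'Stroke'")
  if (!hemiparesis_side %in% c("none", "left", "right"))
    stop("hemiparesis_side must be 'none', 'left' or 'right'")
  if (is.null(segment_id))
    segment_id <- sprintf("%s_%s_%02d", participant_id, task, as.integer(movement_id))
  structure(
    list(values = values, participant_id = as.character(participant_id),
         group = group, hemiparesis_side = hemiparesis_side, task = task,
         movement_id = as.integer(movement_id), movement_type = movement_type,
         segment_id = segment_id),
    class = "har_segment"
  )
}

#' @export
print.har_segment <- function(x, ...) {
  cat(sprintf("<har_segment %s: %s/%s %s movement %d (%s), %d x %d>\n",
              x$segment_id, x$participant_id, x$group, x$task,
              x$movement_id, x$movement_type, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.har_segment <- function(x) dim(x$values)

#' Bundle segments into a dataset
#'
#' @param segments List of [har_segment] objects.
#' @param exclusion_log data.frame with columns `participant_id`, `reason`
#'   recording participants or annotations dropped during loading.
#' @param task Task label the dataset belongs to.
#' @return An object of class `har_dataset`.
#' @export
har_dataset <- function(segments, exclusion_log = empty_exclusion_log(),
                        task = if (length(segments)) segments[[1]]$task else NA_character_) {
  stopifnot(is.list(segments))
  structure(list(segments = segments, exclusion_log = exclusion_log, task = task),
            class = "har_dataset")
}

empty_exclusion_log <- function() {
  data.frame(participant_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.har_dataset <- function(x, ...) {
  meta <- dataset_meta(x)
  cat(sprintf("<har_dataset: %d segments, %d participants (%d ND / %d Stroke), task %s>\n",
              nrow(meta), length(unique(meta$participant_id)),
              length(unique(meta$participant_id[meta$group == "ND"])),
              length(unique(meta$participant_id[meta$group == "Stroke"])),
              x$task))
  if (nrow(x$exclusion_log))
    cat(sprintf("  exclusions: %d (see $exclusion_log)\n", nrow(x$exclusion_log)))
  invisible(x)
}

#' Per-segment metadata table of a dataset
#'
#' @param dataset A `har_dataset`.
#' @return data.frame with one row per segment: participant_id, group,
#'   hemiparesis_side, task, movement_id, movement_type, segment_id, length.
#' @export
dataset_meta <- function(dataset) {
  segs <- dataset$segments
  data.frame(
    participant_id = vapply(segs, `[[`, "", "participant_id"),
    group = vapply(segs, `[[`, "", "group"),
    hemiparesis_side = vapply(segs, `[[`, "", "hemiparesis_side"),
    task = vapply(segs, `[[`, "", "task"),
    movement_id = vapply(segs, `[[`, 0L, "movement_id"),
    movement_type = vapply(segs, `[[`, "", "movement_type"),
    segment_id = vapply(segs, `[[`, "", "segment_id"),
    length = vapply(segs, function(s) nrow(s$values), 0L),
    stringsAsFactors = FALSE
  )
}
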