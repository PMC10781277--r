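#' Read a multichannel IMU recording from CSV
#'
#' The on-disk dialect is one CSV per participant-task recording: a header
#' row, a first `timestamp` column in seconds, then 45 numeric channel
#' columns ordered sensor-major as in [channel_layout()]. Rows containing
#' cells that do not parse as numbers are dropped; the number of dropped
#' rows is reported in the returned object.
#'
#' @param path Path to the CSV file.
#' @param layout Channel layout the file must match; defaults to the
#'   standard 45-channel layout.
#' @param header_map Optional named character vector mapping file column
#'   names to layout channel names, for files whose header spells channels
#'   differently. Names are file columns, values layout names.
#' @param participant_id,group,hemiparesis_side,task Metadata attached to
#'   the recording; `read_recording` also honours metadata stored in
#'   comment lines written by [write_recording()].
#' @return An object of class `har_recording`: list with `participant_id`,
#'   `group`, `hemiparesis_side`, `task`, `timestamps`, `values`
#'   (`[time x 45]`, named columns) and `n_dropped`.
#' @seealso [write_recording()], [load_dataset()]
#' @export
read_recording <- function(path, layout = channel_layout(), header_map = NULL,
                           participant_id = NULL, group = NULL,
                           hemiparesis_side = NULL, task = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- read_meta_comments(path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  cn <- colnames(raw)
  if (!is.null(header_map)) {
    hit <- match(cn, names(header_map))
    cn[!is.na(hit)] <- header_map[hit[!is.na(hit)]]
    colnames(raw) <- cn
  }
  if (!tolower(cn[1]) %in% c("timestamp", "time", "t"))
    stop("malformed header: first column must be the timestamp, got '", cn[1], "'")
  want <- layout$channels$name
  if (!all(want %in% cn))
    stop("malformed header: missing channel columns: ",
         paste(utils::head(setdiff(want, cn), 5), collapse = ", "))
  num <- suppressWarnings(
    vapply(c(cn[1], want), function(j) as.numeric(raw[[j]]), numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, c(cn[1], want)))
  bad <- apply(num, 1L, anyNA)
  num <- num[!bad, , drop = FALSE]
  values <- num[, want, drop = FALSE]
  structure(
    list(participant_id = participant_id %||% meta$participant_id %||% NA_character_,
         group = group %||% meta$group %||% "ND",
         hemiparesis_side = hemiparesis_side %||% meta$hemiparesis_side %||% "none",
         task = task %||% meta$task %||% NA_character_,
         timestamps = num[, 1L], values = values, n_dropped = sum(bad)),
    class = "har_recording"
  )
}

#' Write a recording in the CSV dialect
#'
#' Metadata travels in `#`-prefixed comment lines before the header so a
#' directory of recordings is self-describing.
#'
#' @param recording A `har_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# participant_id=%s", recording$participant_id), con)
  writeLines(sprintf("# group=%s", recording$group), con)
  writeLines(sprintf("# hemiparesis_side=%s", recording$hemiparesis_side), con)
  writeLines(sprintf("# task=%s", recording$task), con)
  df <- data.frame(timestamp = recording$timestamps,
                   recording$values, check.names = FALSE)
  utils::write.csv(format(df, digits = 9, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_meta_comments <- function(path) {
  out <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) out[[substr(kv, 1, eq - 1)]] <- substring(kv, eq + 1)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a segment annotation table
#'
#' Annotations are one CSV per task with columns `participant_id`, `group`,
#' `hemiparesis_side`, `task`, `movement_id`, `movement_type`,
#' `start_index`, `end_index`. Indices are 0-based, half-open
#' `[start, end)` sample positions into the participant's recording.
#' `column_map` renames columns of files using a different schema
#' (names = file columns, values = canonical names).
#'
#' @param path CSV path.
#' @param column_map Optional named character vector.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- match(colnames(df), names(column_map))
    colnames(df)[!is.na(hit)] <- column_map[hit[!is.na(hit)]]
  }
  need <- c("participant_id", "group", "hemiparesis_side", "task",
            "movement_id", "movement_type", "start_index", "end_index")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_annotations
#' @param annotations data.frame in the canonical schema.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Materialize a dataset from recordings and annotations
#'
#' Slices each annotated `[start, end)` range out of its recording and
#' applies the participant-level exclusion rule: a participant whose data
#' miss more than one movement segment for the task is dropped entirely
#' (one missing segment is tolerated). Annotations whose index range falls
#' outside the recording are rejected and logged, and count as missing for
#' the participant they belong to.
#'
#' @param recordings List of `har_recording` objects.
#' @param annotations Annotation data.frame (see [read_annotations()]).
#' @param task Task to load (`"ROM"` or `"ADL"`); only matching annotations
#'   and recordings are considered.
#' @param expected_classes Integer vector of movement classes that
#'   constitute a complete set for the task; defaults to the union of
#'   movement ids present in `annotations` for the task.
#' @return A [har_dataset()] whose `exclusion_log` records rejected
#'   annotations and excluded participants.
#' @export
load_dataset <- function(recordings, annotations, task,
                         expected_classes = NULL) {
  ann <- annotations[annotations$task == task, , drop = FALSE]
  if (is.null(expected_classes))
    expected_classes <- sort(unique(ann$movement_id))
  rec_key <- vapply(recordings, function(r) paste(r$participant_id, r$task), "")
  log <- empty_exclusion_log()
  ok <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    m <- match(paste(ann$participant_id[i], task), rec_key)
    if (is.na(m)) {
      log <- rbind(log, data.frame(participant_id = ann$participant_id[i],
                                   reason = sprintf("no recording for movement %d", ann$movement_id[i])))
      next
    }
    r <- recordings[[m]]
    s <- ann$start_index[i]; e <- ann$end_index[i]
    if (s < 0 || e <= s || e > nrow(r$values)) {
      log <- rbind(log, data.frame(participant_id = ann$participant_id[i],
                                   reason = sprintf("annotation out of bounds for movement %d", ann$movement_id[i])))
      next
    }
    ok[i] <- TRUE
  }
  # participant-level exclusion: > 1 expected class with no usable segment
  segs <- list()
  for (p in unique(ann$participant_id)) {
    rows <- which(ann$participant_id == p & ok)
    n_missing <- length(setdiff(expected_classes, ann$movement_id[rows]))
    if (n_missing > 1L) {
      log <- rbind(log, data.frame(participant_id = p,
                                   reason = sprintf("missing %d movement segments", n_missing)))
      next
    }
    for (i in rows) {
      r <- recordings[[match(paste(p, task), rec_key)]]
      vals <- r$values[(ann$start_index[i] + 1L):ann$end_index[i], , drop = FALSE]
      segs[[length(segs) + 1L]] <- har_segment(
        vals, participant_id = p, group = ann$group[i],
        hemiparesis_side = ann$hemiparesis_side[i], task = task,
        movement_id = ann$movement_id[i], movement_type = ann$movement_type[i])
    }
  }
  har_dataset(segs, exclusion_log = log, task = task)
}

#' Write a dataset as recordings plus an annotation table
#'
#' Segments of each participant are concatenated into one recording (with
#' nominal 80 Hz timestamps) and an annotation CSV locating every segment,
#' so a generated dataset round-trips through [read_recording()] and
#' [load_dataset()].
#'
#' @param dataset A `har_dataset` whose segments carry 45-channel values.
#' @param dir Output directory (created if needed).
#' @param sampling_rate Nominal sampling rate for synthesized timestamps.
#' @return Invisibly, a list with `recording_paths` and `annotation_path`.
#' @export
write_dataset <- function(dataset, dir, sampling_rate = 80) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- dataset_meta(dataset)
  ann <- NULL
  paths <- character()
  for (p in unique(meta$participant_id)) {
    idx <- which(meta$participant_id == p)
    vals <- do.call(rbind, lapply(dataset$segments[idx], `[[`, "values"))
    starts <- cumsum(c(0L, meta$length[idx]))[seq_along(idx)]
    rec <- structure(list(
      participant_id = p, group = meta$group[idx[1]],
      hemiparesis_side = meta$hemiparesis_side[idx[1]], task = dataset$task,
      timestamps = (seq_len(nrow(vals)) - 1) / sampling_rate,
      values = vals, n_dropped = 0L), class = "har_recording")
    path <- file.path(dir, sprintf("%s_%s.csv", p, dataset$task))
    write_recording(rec, path)
    paths <- c(paths, path)
    ann <- rbind(ann, data.frame(
      participant_id = p, group = meta$group[idx[1]],
      hemiparesis_side = meta$hemiparesis_side[idx[1]], task = dataset$task,
      movement_id = meta$movement_id[idx],
      movement_type = meta$movement_type[idx],
      start_index = starts, end_index = starts + meta$length[idx],
      stringsAsFactors = FALSE))
  }
  ann_path <- file.path(dir, sprintf("annotations_%s.csv", dataset$task))
  write_annotations(ann, ann_path)
  invisible(list(recording_paths = paths, annotation_path = ann_path))
}
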