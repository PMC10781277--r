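#' Training-condition specification
#'
#' Three training conditions are compared, all evaluated on the Stroke
#' group by default: `"ND"` trains once on all non-disabled participants
#' and evaluates every Stroke participant (plain split, no
#' cross-validation); `"Stroke"` runs leave-one-subject-out
#' cross-validation over Stroke participants; `"ND+Stroke"` runs LOSO
#' over Stroke participants with all ND participants always in the
#' training pool. Setting `evaluation_group = "ND"` instead runs LOSO
#' over ND participants (the cross-group report).
#'
#' @param name `"ND"`, `"Stroke"` or `"ND+Stroke"`.
#' @param evaluation_group Group whose participants are evaluated.
#' @return Object of class `har_condition`.
#' @export
condition_spec <- function(name = c("ND+Stroke", "Stroke", "ND"),
                           evaluation_group = "Stroke") {
  name <- match.arg(name)
  protocol <- if (name == "ND" && evaluation_group == "Stroke") "split" else "loso"
  structure(list(name = name, evaluation_group = evaluation_group,
                 protocol = protocol),
            class = "har_condition")
}

#' Leave-one-subject-out splits for a condition
#'
#' @param dataset A [har_dataset()].
#' @param condition A [condition_spec()].
#' @return List of splits, each `list(train, test)` of participant ids;
#'   the held-out participant(s) never appear in their split's training
#'   pool.
#' @export
loso_splits <- function(dataset, condition) {
  meta <- dataset_meta(dataset)
  by_group <- split(unique(meta[c("participant_id", "group")])$participant_id,
                    unique(meta[c("participant_id", "group")])$group)
  eval_ids <- sort(by_group[[condition$evaluation_group]])
  if (!length(eval_ids)) stop("no participants in evaluation group")
  pool <- switch(condition$name,
                 "ND" = by_group[["ND"]],
                 "Stroke" = by_group[["Stroke"]],
                 "ND+Stroke" = unlist(by_group, use.names = FALSE))
  if (!length(pool)) stop("empty training pool")
  if (condition$protocol == "split") {
    return(list(list(train = sort(pool), test = eval_ids)))
  }
  if (length(intersect(pool, eval_ids)) < 2L)
    stop("LOSO needs at least 2 evaluation-group participants in the pool")
  lapply(eval_ids, function(p)
    list(train = sort(setdiff(pool, p)), test = p))
}

#' One-vs-rest F1-scores per class
#'
#' For each class, precision and recall are computed over the supplied
#' (true, predicted) label pairs — typically all windows of one held-out
#' participant — and `F1 = 2PR / (P + R)`, with the convention `F1 = 0`
#' when `P + R = 0` (class never predicted and never present, or
#' degenerate).
#'
#' @param true,predicted Label vectors of equal length.
#' @param classes Class universe; defaults to the union of both vectors.
#' @return Named numeric vector of F1 values in `[0, 1]`.
#' @export
f1_by_class <- function(true, predicted, classes = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  stopifnot(length(true) == length(predicted))
  if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
  classes <- as.character(classes)
  vapply(stats::setNames(classes, classes), function(k) {
    tp <- sum(true == k & predicted == k)
    fp <- sum(true != k & predicted == k)
    fn <- sum(true == k & predicted != k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
}

#' Row-normalized confusion matrix
#'
#' @param true,predicted Label vectors.
#' @param classes Class universe (row/column order).
#' @param normalize Divide each row by its count (rows with no samples
#'   are left as zeros).
#' @return `n_classes x n_classes` matrix, rows = true class, columns =
#'   inferred class.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL, normalize = TRUE) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
  classes <- as.character(classes)
  m <- table(factor(true, classes), factor(predicted, classes))
  m <- unclass(m)
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, 1)
  }
  m
}

#' Most-confused class pairs
#'
#' @param confusion Row-normalized confusion matrix.
#' @param n Number of pairs to return.
#' @return data.frame `true`, `inferred`, `proportion`, sorted
#'   decreasingly, excluding the diagonal.
#' @export
top_confusion_pairs <- function(confusion, n = 10L) {
  off <- which(row(confusion) != col(confusion) & confusion > 0, arr.ind = TRUE)
  if (!nrow(off))
    return(data.frame(true = character(), inferred = character(),
                      proportion = numeric()))
  out <- data.frame(true = rownames(confusion)[off[, 1]],
                    inferred = colnames(confusion)[off[, 2]],
                    proportion = confusion[off], stringsAsFactors = FALSE)
  out <- out[order(-out$proportion), ]
  utils::head(out, n)
}

#' Run one training condition end to end
#'
#' Preprocesses the dataset, builds the condition's LOSO (or split)
#' folds, trains one classifier per fold on the training participants'
#' windows — optionally doubling the training set with one axis-rotated
#' copy of each training segment — predicts the held-out participants'
#' windows, and aggregates per-(participant, class) F1-scores, group and
#' movement-type summaries and confusion matrices.
#'
#' Rotated training copies are drawn once per run (seeded from
#' `augment$seed`) and shared across folds; a fold uses only the copies
#' of its own training participants. Evaluation windows are never
#' augmented. `test_rotation` injects orientation nuisance into the
#' held-out segments before windowing, for robustness experiments.
#'
#' @param dataset A [har_dataset()].
#' @param condition A [condition_spec()].
#' @param preprocess A [preprocess_config()].
#' @param model A [model_config()] sized for the preprocess window, or
#'   `NULL` to derive one.
#' @param training A [train_config()].
#' @param augment `NULL`/`FALSE` for original data, or a
#'   [rotation_spec()] to train on original + rotated copies.
#' @param test_rotation Optional [rotation_spec()] applied once to every
#'   evaluation segment (orientation nuisance at test time).
#' @param f1_unit `"window"` (each window is one prediction; default) or
#'   `"segment"` (majority vote over a segment's windows first).
#' @return Object of class `har_eval_report`; see [print.har_eval_report()].
#' @export
run_condition <- function(dataset, condition, preprocess, model = NULL,
                          training = train_config(), augment = NULL,
                          test_rotation = NULL,
                          f1_unit = c("window", "segment")) {
  f1_unit <- match.arg(f1_unit)
  if (isFALSE(augment)) augment <- NULL
  classes <- sort(unique(dataset_meta(dataset)$movement_id))
  if (is.null(model))
    model <- model_config(preprocess$window_size, length(classes),
                          input_channels = length(preprocess$channels))

  eval_ds <- dataset
  if (!is.null(test_rotation)) {
    if (!is.null(test_rotation$seed)) set.seed(test_rotation$seed)
    eval_ds$segments <- lapply(eval_ds$segments, rotate_segment,
                               spec = test_rotation)
  }
  train_pp <- preprocess_dataset(dataset, preprocess)
  eval_pp <- if (is.null(test_rotation)) train_pp
             else preprocess_dataset(eval_ds, preprocess)
  aug_pp <- NULL
  if (!is.null(augment)) {
    stopifnot(inherits(augment, "har_rotation_spec"))
    rot_ds <- dataset
    rot_ds$segments <- augment_dataset(dataset$segments, augment)[
      length(dataset$segments) + seq_along(dataset$segments)]
    aug_pp <- preprocess_dataset(rot_ds, preprocess)
  }

  ds_meta <- dataset_meta(dataset)
  type_of_class <- ds_meta$movement_type[match(classes, ds_meta$movement_id)]
  names(type_of_class) <- classes
  splits <- loso_splits(dataset, condition)
  f1_rows <- list()
  pooled_true <- character(); pooled_pred <- character()
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    stopifnot(length(intersect(sp$train, sp$test)) == 0L)
    tr <- train_pp$meta$participant_id %in% sp$train
    Xtr <- train_pp$x[tr, , , drop = FALSE]
    ytr <- train_pp$meta$movement_id[tr]
    if (!is.null(aug_pp)) {
      tra <- aug_pp$meta$participant_id %in% sp$train
      Xtr <- abind3(Xtr, aug_pp$x[tra, , , drop = FALSE])
      ytr <- c(ytr, aug_pp$meta$movement_id[tra])
    }
    fold_training <- training
    fold_training$seed <- (training$seed + 7919L * si) %% .Machine$integer.max
    fit <- har_cnn(Xtr, factor(ytr, classes), config = model,
                   training = fold_training,
                   condition = sprintf("%s fold %d", condition$name, si))
    for (p in sp$test) {
      te <- eval_pp$meta$participant_id == p
      pred <- predict.har_cnn(fit, eval_pp$x[te, , , drop = FALSE], type = "class")
      true <- as.character(eval_pp$meta$movement_id[te])
      pred <- as.character(pred)
      if (f1_unit == "segment") {
        seg_ids <- eval_pp$meta$segment_id[te]
        vote <- vapply(split(pred, seg_ids), function(v)
          names(sort(table(v), decreasing = TRUE))[1], "")
        true <- vapply(split(true, seg_ids), `[`, "", 1L)
        pred <- vote[names(true)]
      }
      f1 <- f1_by_class(true, pred, classes)
      f1_rows[[length(f1_rows) + 1L]] <- data.frame(
        participant_id = p,
        group = eval_pp$meta$group[te][1L],
        class = as.integer(names(f1)),
        movement_type = unname(type_of_class[names(f1)]),
        f1 = unname(f1), stringsAsFactors = FALSE)
      pooled_true <- c(pooled_true, true)
      pooled_pred <- c(pooled_pred, pred)
    }
  }
  f1_tab <- do.call(rbind, f1_rows)
  per_participant <- stats::aggregate(f1 ~ participant_id + group, f1_tab, mean)
  group_summary <- do.call(rbind, lapply(split(per_participant, per_participant$group),
    function(g) data.frame(
      group = g$group[1], mean_f1 = mean(g$f1),
      sd_f1 = if (nrow(g) > 1) stats::sd(g$f1) else 0,
      min_f1 = min(g$f1), min_participant = g$participant_id[which.min(g$f1)],
      max_f1 = max(g$f1), max_participant = g$participant_id[which.max(g$f1)],
      n = nrow(g), stringsAsFactors = FALSE)))
  conf <- confusion_matrix(pooled_true, pooled_pred, classes)
  structure(
    list(condition = condition, f1 = f1_tab,
         per_participant = per_participant, group_summary = group_summary,
         confusion = conf, top_confusions = top_confusion_pairs(conf),
         f1_unit = f1_unit, n_splits = length(splits),
         augmented = !is.null(augment), classes = classes),
    class = "har_eval_report"
  )
}

abind3 <- function(a, b) {
  stopifnot(all(dim(a)[-1] == dim(b)[-1]))
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]),
               dimnames = list(NULL, NULL, dimnames(a)[[3]]))
  if (dim(a)[1]) out[seq_len(dim(a)[1]), , ] <- a
  if (dim(b)[1]) out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' @export
print.har_eval_report <- function(x, ...) {
  cat(sprintf("<har_eval_report: condition %s (%s, %d split%s)%s, F1 unit = %s>\n",
              x$condition$name, x$condition$protocol, x$n_splits,
              if (x$n_splits > 1) "s" else "",
              if (x$augmented) ", augmented" else "", x$f1_unit))
  print(x$group_summary, row.names = FALSE)
  invisible(x)
}

#' Mean F1 by movement type and group
#'
#' @param report A `har_eval_report` (or its `$f1` table).
#' @param class_type_map Optional vector mapping movement id to type;
#'   defaults to the types recorded in the report.
#' @return data.frame with `group`, `movement_type`, `mean_f1`, `sd_f1`,
#'   `n`.
#' @export
movement_type_summary <- function(report, class_type_map = NULL) {
  tab <- if (inherits(report, "har_eval_report")) report$f1 else report
  if (!is.null(class_type_map)) {
    tab$movement_type <- class_type_map[tab$class]
  }
  if (anyNA(tab$movement_type)) stop("unmapped movement class")
  out <- do.call(rbind, lapply(
    split(tab, list(tab$group, tab$movement_type), drop = TRUE),
    function(g) data.frame(group = g$group[1], movement_type = g$movement_type[1],
                           mean_f1 = mean(g$f1),
                           sd_f1 = if (nrow(g) > 1) stats::sd(g$f1) else 0,
                           n = nrow(g), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$group, match(out$movement_type, c("UNI", "BIA", "BIS"))), ]
}
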