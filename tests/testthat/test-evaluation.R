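test_that("LOSO splits cover each evaluation participant once without leakage", {
  ds <- generate_dataset(synthetic_spec("custom", n_nd = 3, n_stroke = 4,
                                        n_classes = 2, length_mean = 260,
                                        length_sd = 30, length_floor = 150,
                                        seed = 2))
  st <- loso_splits(ds, condition_spec("Stroke"))
  expect_length(st, 4L)
  expect_setequal(vapply(st, `[[`, "", "test"), paste0("ST0", 1:4))
  for (s in st) {
    expect_length(intersect(s$train, s$test), 0L)
    expect_false(any(grepl("^ND", s$train)))
    expect_length(s$train, 3L)
  }

  joint <- loso_splits(ds, condition_spec("ND+Stroke"))
  expect_length(joint, 4L)
  for (s in joint) {
    expect_length(s$train, 6L)
    expect_true(all(paste0("ND0", 1:3) %in% s$train))
    expect_false(s$test %in% s$train)
  }

  nd <- loso_splits(ds, condition_spec("ND"))
  expect_length(nd, 1L)
  expect_setequal(nd[[1]]$train, paste0("ND0", 1:3))
  expect_setequal(nd[[1]]$test, paste0("ST0", 1:4))

  nd_eval <- loso_splits(ds, condition_spec("ND+Stroke", evaluation_group = "ND"))
  expect_length(nd_eval, 3L)
})

test_that("per-class F1 matches closed forms", {
  # perfect classifier: F1 = 1 for every class
  true <- rep(1:14, each = 20)
  expect_equal(unname(f1_by_class(true, true, 1:14)), rep(1, 14))

  # constant predictor over 14 balanced classes:
  # precision 1/14, recall 1 -> F1 = 2*(1/14)/(1/14 + 1)
  pred <- rep(1, length(true))
  f1 <- f1_by_class(true, pred, 1:14)
  expect_equal(unname(f1[1]), 2 * (1 / 14) / (1 / 14 + 1), tolerance = 1e-12)
  expect_equal(unname(f1[1]), 0.133, tolerance = 1e-2)
  expect_equal(unname(f1[-1]), rep(0, 13))

  # never-present, never-predicted class: F1 = 0 by convention
  expect_equal(unname(f1_by_class(c(1, 1), c(1, 1), 1:2)[2]), 0)
})

test_that("F1 and confusion agree with a brute-force counting oracle", {
  set.seed(31)
  classes <- 1:5
  true <- sample(classes, 400, replace = TRUE)
  pred <- ifelse(runif(400) < 0.6, true, sample(classes, 400, replace = TRUE))
  f1 <- f1_by_class(true, pred, classes)
  cm <- confusion_matrix(true, pred, classes, normalize = FALSE)
  for (k in classes) {
    tp <- cm[k, k]; fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    expected <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(unname(f1[as.character(k)]), expected, tolerance = 1e-12)
  }
  cmn <- confusion_matrix(true, pred, classes)
  expect_equal(unname(rowSums(cmn)), rep(1, 5), tolerance = 1e-6)
  # perfect classifier's normalized confusion is the identity
  expect_equal(unname(confusion_matrix(true, true, classes)), diag(5))
})

test_that("top confusion pairs rank off-diagonal proportions", {
  cm <- matrix(c(0.7, 0.3, 0.1, 0.9), 2, 2, byrow = TRUE,
               dimnames = list(c("1", "2"), c("1", "2")))
  top <- top_confusion_pairs(cm)
  expect_equal(top$true[1], "1")
  expect_equal(top$inferred[1], "2")
  expect_equal(top$proportion, c(0.3, 0.1))
})

test_that("run_condition produces a coherent report on a small dataset", {
  ds <- generate_dataset(synthetic_spec("custom", n_nd = 2, n_stroke = 2,
                                        n_classes = 3, length_mean = 260,
                                        length_sd = 40, length_floor = 150,
                                        seed = 9))
  rep <- run_condition(ds, condition_spec("ND+Stroke"), tiny_preprocess(),
                       model = tiny_model(3),
                       training = train_config(epochs = 2, batch_size = 64,
                                               seed = 1))
  expect_s3_class(rep, "har_eval_report")
  expect_equal(rep$n_splits, 2L)
  # one F1 per (participant, class)
  expect_equal(nrow(rep$f1), 2L * 3L)
  expect_true(all(rep$f1$f1 >= 0 & rep$f1$f1 <= 1))
  expect_equal(sort(unique(rep$f1$participant_id)), c("ST01", "ST02"))
  expect_equal(unname(rowSums(rep$confusion)), rep(1, 3), tolerance = 1e-6)
  # aggregate equals brute-force recomputation from the per-class table
  agg <- tapply(rep$f1$f1, rep$f1$participant_id, mean)
  expect_equal(unname(rep$per_participant$f1[order(rep$per_participant$participant_id)]),
               as.numeric(agg[sort(names(agg))]))
  expect_output(print(rep), "ND\\+Stroke")
})

test_that("segment-level F1 aggregates windows by majority vote", {
  ds <- generate_dataset(synthetic_spec("custom", n_nd = 2, n_stroke = 2,
                                        n_classes = 2, length_mean = 260,
                                        length_sd = 40, length_floor = 150,
                                        seed = 10))
  rep <- run_condition(ds, condition_spec("Stroke"), tiny_preprocess(),
                       model = tiny_model(2),
                       training = train_config(epochs = 2, batch_size = 64,
                                               seed = 1),
                       f1_unit = "segment")
  expect_equal(rep$f1_unit, "segment")
  expect_true(all(rep$f1$f1 %in% c(0, 1) | (rep$f1$f1 > 0 & rep$f1$f1 < 1)))
  expect_equal(nrow(rep$f1), 2L * 2L)
})

test_that("movement-type summary matches a brute-force recomputation", {
  f1_tab <- data.frame(
    participant_id = rep(c("A", "B"), each = 6),
    group = "Stroke",
    class = rep(1:6, 2),
    movement_type = rep(c("UNI", "BIA", "BIS"), 4),
    f1 = c(0.2, 0.4, 0.9, 0.3, 0.5, 0.8, 0.25, 0.45, 0.95, 0.35, 0.55, 0.85))
  fake <- structure(list(f1 = f1_tab), class = "har_eval_report")
  out <- movement_type_summary(fake)
  for (i in seq_len(nrow(out))) {
    sub <- f1_tab$f1[f1_tab$movement_type == out$movement_type[i]]
    expect_equal(out$mean_f1[i], mean(sub))
    expect_equal(out$sd_f1[i], sd(sub))
  }
  # identical F1 everywhere gives identical type means
  f1_tab$f1 <- 0.5
  fake2 <- structure(list(f1 = f1_tab), class = "har_eval_report")
  expect_true(all(movement_type_summary(fake2)$mean_f1 == 0.5))
  # explicit class-type map overrides and unmapped classes error
  expect_error(movement_type_summary(fake, class_type_map = c("UNI", "BIA")),
               "unmapped")
})
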