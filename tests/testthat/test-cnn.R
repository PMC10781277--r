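test_that("convolution length arithmetic reproduces the architecture chains", {
  expect_equal(conv_output_length(200), 98L)
  chain <- Reduce(function(L, i) conv_output_length(L), 1:4, accumulate = TRUE, 200L)
  expect_equal(chain, c(200L, 98L, 47L, 22L, 9L))
  chain_adl <- Reduce(function(L, i) conv_output_length(L), 1:4, accumulate = TRUE, 740L)
  expect_equal(chain_adl, c(740L, 368L, 182L, 89L, 43L))
  expect_equal(conv_output_length(5), 1L)
  expect_error(conv_output_length(4), "shorter than the kernel")
})

test_that("model configs expose the flattened feature sizes", {
  rom <- model_config(200, 14)
  expect_equal(rom$conv_lengths, c(98L, 47L, 22L, 9L))
  expect_equal(rom$flat_size, 2304L)
  adl <- model_config(740, 56)
  expect_equal(adl$conv_lengths, c(368L, 182L, 89L, 43L))
  expect_equal(adl$flat_size, 11008L)
  expect_error(model_config(30, 4), "configuration error")
})

test_that("an untrained forward pass returns valid probabilities", {
  cfg <- model_config(200, 14)
  set.seed(1)
  params <- strokehar:::init_params(cfg)
  X <- array(0, c(3, 200, 30))
  fw <- strokehar:::cnn_forward(params, X, cfg, training = FALSE)
  expect_equal(dim(fw$probs), c(3L, 14L))
  expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  for (fr in c(TRUE, FALSE)) {
    cfg <- model_config(30, 3, input_channels = 2, conv_features = c(3L, 4L),
                        dense_sizes = c(7L, 5L), dropout_p = 0, final_relu = fr)
    params <- strokehar:::init_params(cfg)
    X <- array(rnorm(4 * 30 * 2), c(4, 30, 2))
    y <- c(1L, 2L, 3L, 1L)
    loss_fn <- function(p) {
      fw <- strokehar:::cnn_forward(p, X, cfg, FALSE)
      -mean(log(fw$probs[cbind(1:4, y)]))
    }
    fw <- strokehar:::cnn_forward(params, X, cfg, FALSE)
    gr <- strokehar:::cnn_backward(params, cfg, fw, y)
    for (nm in names(params)) {
      for (j in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
        e <- 1e-6
        p2 <- params; p2[[nm]][j] <- p2[[nm]][j] + e; up <- loss_fn(p2)
        p2[[nm]][j] <- p2[[nm]][j] - 2 * e; dn <- loss_fn(p2)
        expect_equal(gr[[nm]][j], (up - dn) / (2 * e), tolerance = 1e-5)
      }
    }
  }
})

test_that("training on separable synthetic windows reaches high accuracy", {
  ds <- generate_dataset(synthetic_spec("custom", n_nd = 4, n_stroke = 0,
                                        n_classes = 4, length_mean = 300,
                                        length_sd = 60, length_floor = 100,
                                        seed = 3))
  w <- preprocess_dataset(ds, tiny_preprocess())
  fit <- har_cnn(w$x, factor(w$meta$movement_id), config = tiny_model(4),
                 training = train_config(epochs = 30, batch_size = 32, seed = 1))
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
  pred <- predict(fit, w$x, type = "class")
  expect_gt(mean(as.character(pred) == as.character(w$meta$movement_id)), 0.9)
})

test_that("a single-class training set predicts that class everywhere", {
  ds <- generate_dataset(synthetic_spec("custom", n_nd = 2, n_stroke = 0,
                                        n_classes = 2, length_mean = 280,
                                        length_sd = 40, length_floor = 120,
                                        seed = 5))
  w <- preprocess_dataset(ds, tiny_preprocess())
  keep <- w$meta$movement_id == 1
  fit <- har_cnn(w$x[keep, , , drop = FALSE],
                 factor(w$meta$movement_id[keep], levels = 1:2),
                 config = tiny_model(2),
                 training = train_config(epochs = 4, batch_size = 64, seed = 1))
  pred <- predict(fit, w$x, type = "class")
  expect_true(all(pred == "1"))
})

test_that("training is deterministic for a fixed seed", {
  ds <- generate_dataset(tiny_spec())
  w <- preprocess_dataset(ds, tiny_preprocess())
  tc <- train_config(epochs = 2, batch_size = 64, seed = 123)
  f1 <- har_cnn(w$x, factor(w$meta$movement_id), config = tiny_model(3), training = tc)
  f2 <- har_cnn(w$x, factor(w$meta$movement_id), config = tiny_model(3), training = tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params, f2$params)
})

test_that("prediction is batch-equivariant and rows sum to one", {
  ds <- generate_dataset(tiny_spec())
  w <- preprocess_dataset(ds, tiny_preprocess())
  fit <- har_cnn(w$x, factor(w$meta$movement_id), config = tiny_model(3),
                 training = train_config(epochs = 1, batch_size = 64, seed = 1))
  probs <- predict(fit, w$x)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  perm <- sample(dim(w$x)[1])
  probs_perm <- predict(fit, w$x[perm, , , drop = FALSE])
  expect_equal(probs_perm, probs[perm, ], tolerance = 1e-12)
  expect_error(predict(fit, w$x[, 1:10, , drop = FALSE]), "shape")
})

test_that("S3 methods summarize the fit", {
  ds <- generate_dataset(tiny_spec())
  w <- preprocess_dataset(ds, tiny_preprocess())
  fit <- har_cnn(w$x, factor(w$meta$movement_id), config = tiny_model(3),
                 training = train_config(epochs = 1, batch_size = 64, seed = 1))
  expect_output(print(fit), "1-D CNN")
  s <- summary(fit)
  expect_s3_class(s, "summary.har_cnn")
  expect_equal(s$n_parameters, sum(vapply(coef(fit), length, 0L)))
  expect_output(print(s), "total parameters")
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})
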