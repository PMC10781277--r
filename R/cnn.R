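#' Output length of a valid (no-padding) 1-D convolution
#'
#' `floor((L_in - kernel) / stride) + 1`. With kernel 5 and stride 2 the
#' feature lengths through the four convolutional layers are
#' 200 -> 98 -> 47 -> 22 -> 9 for the ROM window and
#' 740 -> 368 -> 182 -> 89 -> 43 for the ADL window.
#'
#' @param L_in Input length (>= kernel).
#' @param kernel,stride Convolution kernel size and stride.
#' @return Integer output length.
#' @export
conv_output_length <- function(L_in, kernel = 5L, stride = 2L) {
  if (any(L_in < kernel)) stop("input length shorter than the kernel")
  (L_in - kernel) %/% stride + 1L
}

#' Architecture of the 1-D convolutional movement classifier
#'
#' Four convolutional layers (kernel 5, stride 2, no padding; 32, 64,
#' 128 and 256 output features) followed by three dense layers (800, 200
#' and `n_classes` units). Every layer is ReLU-activated — by default
#' including the final dense layer, whose rectified logits are then
#' passed through a softmax; `final_relu = FALSE` gives the conventional
#' plain-logit softmax head. Dropout (p = 0.7) is applied to the first
#' two dense layers during training only.
#'
#' @param input_length Window length in time points (200 ROM / 740 ADL).
#' @param n_classes Number of movement classes.
#' @param input_channels Input channels (default 30).
#' @param kernel,stride Convolution parameters.
#' @param conv_features Output feature counts of the four conv layers.
#' @param dense_sizes Sizes of the two hidden dense layers.
#' @param dropout_p Dropout probability on the hidden dense layers.
#' @param final_relu Apply ReLU to the output-layer logits before the
#'   softmax (the literal layer description); see Details.
#' @return Object of class `har_model_config`, with the per-layer feature
#'   lengths in `$conv_lengths` and the flattened feature size in
#'   `$flat_size`.
#' @examples
#' cfg <- model_config(200, 14)
#' cfg$conv_lengths   # 98 47 22 9
#' cfg$flat_size      # 2304
#' @export
model_config <- function(input_length, n_classes, input_channels = 30L,
                         kernel = 5L, stride = 2L,
                         conv_features = c(32L, 64L, 128L, 256L),
                         dense_sizes = c(800L, 200L),
                         dropout_p = 0.7, final_relu = TRUE) {
  lens <- integer(length(conv_features))
  L <- input_length
  for (i in seq_along(conv_features)) {
    if (L < kernel)
      stop("configuration error: feature length ", L,
           " before conv layer ", i, " is shorter than the kernel")
    L <- conv_output_length(L, kernel, stride)
    lens[i] <- L
  }
  structure(
    list(input_length = as.integer(input_length),
         input_channels = as.integer(input_channels),
         n_classes = as.integer(n_classes), kernel = as.integer(kernel),
         stride = as.integer(stride), conv_features = as.integer(conv_features),
         dense_sizes = as.integer(dense_sizes), dropout_p = dropout_p,
         final_relu = final_relu, conv_lengths = lens,
         flat_size = lens[length(lens)] * conv_features[length(conv_features)]),
    class = "har_model_config"
  )
}

#' Optimization settings for the classifier
#'
#' AdamW with decoupled weight decay, cross-entropy loss, and fixed-epoch
#' training (no schedule, no early stopping; final-epoch weights are
#' kept). Defaults are learning rate 0.001, betas (0.9, 0.999),
#' eps 1e-8, weight decay 0.01, batch size 256 windows, 40 epochs.
#'
#' @param learning_rate,betas,eps,weight_decay AdamW parameters.
#' @param batch_size Windows per minibatch.
#' @param epochs Training epochs.
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @param verbose Print per-epoch loss.
#' @return Object of class `har_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, betas = c(0.9, 0.999),
                         eps = 1e-8, weight_decay = 0.01,
                         batch_size = 256L, epochs = 40L, seed = 1L,
                         verbose = FALSE) {
  stopifnot(learning_rate > 0, eps > 0, batch_size >= 1, epochs >= 1,
            length(betas) == 2L, all(betas > 0 & betas < 1))
  structure(list(learning_rate = learning_rate, betas = betas, eps = eps,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 verbose = verbose),
            class = "har_train_config")
}

# --- internal numerics ------------------------------------------------------

# He-normal initialization; biases zero.
init_params <- function(cfg) {
  p <- list()
  C <- cfg$input_channels
  for (i in seq_along(cfg$conv_features)) {
    fan_in <- cfg$kernel * C
    p[[paste0("Wc", i)]] <- matrix(stats::rnorm(fan_in * cfg$conv_features[i],
                                                0, sqrt(2 / fan_in)),
                                   fan_in, cfg$conv_features[i])
    p[[paste0("bc", i)]] <- numeric(cfg$conv_features[i])
    C <- cfg$conv_features[i]
  }
  sizes <- c(cfg$flat_size, cfg$dense_sizes, cfg$n_classes)
  for (i in seq_len(length(sizes) - 1L)) {
    p[[paste0("Wd", i)]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                                0, sqrt(2 / sizes[i])),
                                   sizes[i], sizes[i + 1L])
    p[[paste0("bd", i)]] <- numeric(sizes[i + 1L])
  }
  p
}

conv_fwd <- function(X, W, b, k, stride) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  Lout <- (L - k) %/% stride + 1L
  idx <- as.vector(outer(seq_len(k), (seq_len(Lout) - 1L) * stride, `+`))
  Xs <- X[, idx, , drop = FALSE]
  dim(Xs) <- c(N, k, Lout, C)
  Xcol <- aperm(Xs, c(1L, 3L, 2L, 4L))
  dim(Xcol) <- c(N * Lout, k * C)
  Z <- Xcol %*% W
  Z <- Z + rep(b, each = nrow(Z))
  mask <- Z > 0
  A <- Z * mask
  out <- A
  dim(out) <- c(N, Lout, ncol(W))
  list(out = out, Xcol = Xcol, mask = mask, Lout = Lout, dimX = d)
}

conv_bwd <- function(dOut, cache, W, k, stride) {
  d <- cache$dimX; N <- d[1]; L <- d[2]; C <- d[3]
  Lout <- cache$Lout
  dA <- dOut
  dim(dA) <- c(N * Lout, ncol(W))
  dZ <- dA * cache$mask
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- tcrossprod(dZ, W)
  dim(dXcol) <- c(N, Lout, k, C)
  dXs <- aperm(dXcol, c(1L, 3L, 2L, 4L))
  dX <- array(0, c(N, L, C))
  for (kk in seq_len(k)) {
    pos <- (seq_len(Lout) - 1L) * stride + kk
    tmp <- dXs[, kk, , , drop = FALSE]
    dim(tmp) <- c(N, Lout, C)
    dX[, pos, ] <- dX[, pos, , drop = FALSE] + tmp
  }
  list(dX = dX, dW = dW, db = db)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass; when training, dropout masks are drawn and kept for the
# backward pass.
cnn_forward <- function(params, X, cfg, training = FALSE) {
  caches <- list()
  A <- X
  for (i in seq_along(cfg$conv_features)) {
    cc <- conv_fwd(A, params[[paste0("Wc", i)]], params[[paste0("bc", i)]],
                   cfg$kernel, cfg$stride)
    caches[[paste0("conv", i)]] <- cc
    A <- cc$out
  }
  N <- dim(A)[1]
  H <- A
  dim(H) <- c(N, cfg$flat_size)
  caches$flat_in_dim <- dim(A)
  hidden <- list()
  keep <- 1 - cfg$dropout_p
  for (i in seq_along(cfg$dense_sizes)) {
    Z <- H %*% params[[paste0("Wd", i)]]
    Z <- Z + rep(params[[paste0("bd", i)]], each = N)
    mask <- Z > 0
    A2 <- Z * mask
    drop_mask <- NULL
    if (training && cfg$dropout_p > 0) {
      drop_mask <- matrix(stats::runif(length(A2)) < keep, nrow(A2)) / keep
      A2 <- A2 * drop_mask
    }
    hidden[[i]] <- list(input = H, mask = mask, drop_mask = drop_mask)
    H <- A2
  }
  i_out <- length(cfg$dense_sizes) + 1L
  Z <- H %*% params[[paste0("Wd", i_out)]]
  Z <- Z + rep(params[[paste0("bd", i_out)]], each = N)
  out_mask <- Z > 0
  logits <- if (cfg$final_relu) Z * out_mask else Z
  probs <- softmax_rows(logits)
  caches$hidden <- hidden
  caches$out <- list(input = H, mask = out_mask)
  list(probs = probs, caches = caches)
}

cnn_backward <- function(params, cfg, fw, y_idx) {
  N <- nrow(fw$probs)
  G <- fw$probs
  G[cbind(seq_len(N), y_idx)] <- G[cbind(seq_len(N), y_idx)] - 1
  G <- G / N
  if (cfg$final_relu) G <- G * fw$caches$out$mask
  grads <- list()
  i_out <- length(cfg$dense_sizes) + 1L
  grads[[paste0("Wd", i_out)]] <- crossprod(fw$caches$out$input, G)
  grads[[paste0("bd", i_out)]] <- colSums(G)
  dH <- tcrossprod(G, params[[paste0("Wd", i_out)]])
  for (i in rev(seq_along(cfg$dense_sizes))) {
    hc <- fw$caches$hidden[[i]]
    if (!is.null(hc$drop_mask)) dH <- dH * hc$drop_mask
    dZ <- dH * hc$mask
    grads[[paste0("Wd", i)]] <- crossprod(hc$input, dZ)
    grads[[paste0("bd", i)]] <- colSums(dZ)
    dH <- tcrossprod(dZ, params[[paste0("Wd", i)]])
  }
  dA <- dH
  dim(dA) <- fw$caches$flat_in_dim
  for (i in rev(seq_along(cfg$conv_features))) {
    cb <- conv_bwd(dA, fw$caches[[paste0("conv", i)]],
                   params[[paste0("Wc", i)]], cfg$kernel, cfg$stride)
    grads[[paste0("Wc", i)]] <- cb$dW
    grads[[paste0("bc", i)]] <- cb$db
    dA <- cb$dX
  }
  grads
}

adamw_step <- function(params, grads, state, tc) {
  b1 <- tc$betas[1]; b2 <- tc$betas[2]
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    step <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + tc$eps)
    params[[nm]] <- params[[nm]] - tc$learning_rate * step -
      tc$learning_rate * tc$weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

# --- fitting ----------------------------------------------------------------

#' Fit the 1-D convolutional movement classifier
#'
#' Trains the network of [model_config()] with minibatch AdamW and
#' cross-entropy loss on labeled windows. Training is deterministic for a
#' given `train_config$seed` (initialization, shuffling and dropout all
#' draw from R's RNG); residual floating-point differences can arise only
#' from a different BLAS.
#'
#' @param x Numeric array `[n_windows x time x channels]` (as produced by
#'   [preprocess_dataset()]).
#' @param y Window labels: factor or vector coercible to one; its levels
#'   define the class order of predictions.
#' @param config A [model_config()]; defaults to the standard
#'   architecture sized from `x` and `y`.
#' @param training A [train_config()].
#' @param condition Optional free-text provenance label (e.g. the
#'   training condition).
#' @return Object of class `har_cnn`: the learned parameters, configs,
#'   class levels, per-epoch loss/accuracy history and provenance.
#' @seealso [predict.har_cnn()]
#' @export
har_cnn <- function(x, y, config = NULL, training = train_config(),
                    condition = NULL) {
  stopifnot(length(dim(x)) == 3L)
  y <- as.factor(y)
  if (dim(x)[1] != length(y)) stop("x and y sizes differ")
  if (dim(x)[1] == 0L) stop("empty training set")
  if (is.null(config))
    config <- model_config(dim(x)[2], nlevels(y), input_channels = dim(x)[3])
  if (config$input_length != dim(x)[2] || config$input_channels != dim(x)[3])
    stop("window shape does not match model config")
  set.seed(training$seed)
  params <- init_params(config)
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  y_idx <- as.integer(y)
  N <- dim(x)[1]
  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  for (ep in seq_len(training$epochs)) {
    ord <- sample.int(N)
    losses <- numeric(); hits <- 0L
    for (start in seq(1L, N, by = training$batch_size)) {
      take <- ord[start:min(start + training$batch_size - 1L, N)]
      Xb <- x[take, , , drop = FALSE]
      yb <- y_idx[take]
      fw <- cnn_forward(params, Xb, config, training = TRUE)
      pb <- fw$probs[cbind(seq_along(take), yb)]
      losses <- c(losses, -mean(log(pmax(pb, 1e-12))))
      hits <- hits + sum(max.col(fw$probs, ties.method = "first") == yb)
      grads <- cnn_backward(params, config, fw, yb)
      upd <- adamw_step(params, grads, state, training)
      params <- upd$params; state <- upd$state
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         accuracy = hits / N))
    if (training$verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f", ep, mean(losses), hits / N))
  }
  structure(
    list(params = params, config = config, training = training,
         levels = levels(y), history = history,
         provenance = list(n_windows = N, seed = training$seed,
                           condition = condition,
                           data_checksum = signif(sum(x) + sum(y_idx), 10),
                           fitted_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "har_cnn"
  )
}

#' Predict movement classes for windows
#'
#' Inference is deterministic (dropout off). Class probabilities of each
#' window sum to 1; the hard label is the argmax, with ties broken toward
#' the lowest class index.
#'
#' @param object A fitted [har_cnn()].
#' @param x Array `[n x time x channels]` matching the model input shape.
#' @param type `"prob"` for the probability matrix, `"class"` for hard
#'   labels (factor with the training levels).
#' @param batch_size Windows per forward-pass chunk.
#' @param ... Unused.
#' @return Matrix `[n x n_classes]` of probabilities, or a factor.
#' @export
predict.har_cnn <- function(object, x, type = c("prob", "class"),
                            batch_size = 512L, ...) {
  type <- match.arg(type)
  stopifnot(length(dim(x)) == 3L)
  cfg <- object$config
  if (dim(x)[2] != cfg$input_length || dim(x)[3] != cfg$input_channels)
    stop("window shape does not match model input")
  n <- dim(x)[1]
  probs <- matrix(0, n, cfg$n_classes, dimnames = list(NULL, object$levels))
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    probs[take, ] <- cnn_forward(object$params, x[take, , , drop = FALSE],
                                 cfg, training = FALSE)$probs
  }
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.har_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("1-D CNN movement classifier (%d classes)\n", cfg$n_classes))
  cat(sprintf("  input [%d x %d]; conv lengths %s; flatten %d\n",
              cfg$input_length, cfg$input_channels,
              paste(cfg$conv_lengths, collapse = " -> "), cfg$flat_size))
  cat(sprintf("  trained %d epochs on %d windows; final loss %.4f, accuracy %.3f\n",
              nrow(x$history), x$provenance$n_windows,
              utils::tail(x$history$loss, 1), utils::tail(x$history$accuracy, 1)))
  invisible(x)
}

#' @export
summary.har_cnn <- function(object, ...) {
  cfg <- object$config
  shapes <- vapply(object$params, function(p)
    paste(if (is.matrix(p)) dim(p) else length(p), collapse = "x"), "")
  counts <- vapply(object$params, length, 0L)
  out <- list(config = cfg,
              layers = data.frame(parameter = names(shapes), shape = shapes,
                                  n = counts, row.names = NULL),
              n_parameters = sum(counts), history = object$history,
              provenance = object$provenance)
  class(out) <- "summary.har_cnn"
  out
}

#' @export
print.summary.har_cnn <- function(x, ...) {
  cat(sprintf("1-D CNN, %s total parameters\n",
              format(x$n_parameters, big.mark = ",")))
  print(x$layers)
  invisible(x)
}

#' @export
coef.har_cnn <- function(object, ...) object$params

#' @export
plot.har_cnn <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "b",
                 xlab = "epoch", ylab = "training loss",
                 main = "1-D CNN training loss", ...)
  invisible(x)
}
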