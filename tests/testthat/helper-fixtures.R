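# Small builders shared across test files.

# A segment with fully controlled values on the standard 45-channel layout.
make_segment <- function(values_fn = function(n, ch) rep(0, n), n = 20,
                         layout = channel_layout(), ...) {
  v <- sapply(seq_len(layout$n_channels),
              function(i) rep_len(values_fn(n, layout$channels[i, ]), n))
  v <- matrix(v, nrow = n, dimnames = list(NULL, layout$channels$name))
  har_segment(v, participant_id = "P1", ...)
}

# Segment with given constant per side: right-side acc/gyro channels get
# `right`, left-side get `left`, everything else 0; values alternate sign
# so channels are zero-mean.
make_sided_segment <- function(right = 1, left = 0, n = 20, ...) {
  make_segment(function(nn, ch) {
    amp <- if (ch$modality == "mag") 0
           else switch(ch$side, right = right, left = left, trunk = 0)
    amp * rep_len(c(1, -1), nn)
  }, n = n, ...)
}

tiny_spec <- function(...) {
  synthetic_spec("custom", n_nd = 2, n_stroke = 2, n_classes = 3,
                 length_mean = 300, length_sd = 60, length_floor = 100,
                 seed = 42, ...)
}

# Small-but-learnable preprocess/model pair used by training tests.
tiny_preprocess <- function() {
  preprocess_config("custom", target_length = 240, window_size = 64, stride = 16)
}
tiny_model <- function(n_classes, ...) {
  model_config(64, n_classes, input_channels = 30,
               conv_features = c(8L, 16L, 32L, 64L), dense_sizes = c(64L, 32L),
               dropout_p = 0.3, final_relu = FALSE, ...)
}
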