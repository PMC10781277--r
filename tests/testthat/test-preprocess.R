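test_that("zero_center removes channel means and is idempotent", {
  seg <- make_segment(function(n, ch) rep(5, n), n = 100)
  z <- zero_center(seg)
  expect_true(all(abs(z$values) < 1e-12))

  seg2 <- make_segment(function(n, ch) seq_len(n), n = 3)
  z2 <- zero_center(seg2)
  expect_equal(unname(z2$values[, 1]), c(-1, 0, 1))
  expect_equal(zero_center(z2)$values, z2$values)

  set.seed(1)
  seg3 <- make_segment(function(n, ch) rnorm(n), n = 57)
  z3 <- zero_center(seg3)
  expect_lt(max(abs(colMeans(z3$values))), 1e-9)
})

test_that("channel selection yields the documented subset sizes", {
  seg <- make_segment(function(n, ch) rnorm(n), n = 10)
  lay <- channel_layout()
  expect_equal(ncol(select_channels(seg, channel_subset(lay))$values), 30L)
  expect_equal(ncol(select_channels(seg, channel_subset(lay, 1))$values), 6L)
  expect_equal(ncol(select_channels(seg, channel_subset(lay, 1, "acc"))$values), 3L)
  expect_false(any(grepl("mag", colnames(
    select_channels(seg, channel_subset(lay))$values))))
  expect_error(select_channels(seg, "S9_acc_x"), "unknown channels")
})

test_that("swap_sides exchanges wrist and upper-arm blocks, fixes trunk, and is an involution", {
  set.seed(2)
  seg <- make_segment(function(n, ch) rnorm(n), n = 30)
  sw <- swap_sides(seg)
  expect_equal(unname(sw$values[, "S1_acc_x"]), unname(seg$values[, "S2_acc_x"]))
  expect_equal(unname(sw$values[, "S5_gyro_z"]), unname(seg$values[, "S4_gyro_z"]))
  expect_equal(sw$values[, grepl("^S3", colnames(sw$values))],
               seg$values[, grepl("^S3", colnames(seg$values))])
  expect_equal(swap_sides(sw)$values, seg$values)
})

test_that("swap_sides flips the sign of the asymmetry score exactly", {
  seg <- make_sided_segment(right = 2, left = 0.5, n = 40)
  s1 <- asymmetry_score(side_energies(seg))
  s2 <- asymmetry_score(side_energies(swap_sides(seg)))
  expect_identical(s1, -s2)
})

test_that("interpolation hits the target length, preserves endpoints, and is exact on ramps", {
  set.seed(3)
  seg <- make_segment(function(n, ch) rnorm(n), n = 500)
  out <- interpolate_segment(seg, 1000)
  expect_equal(nrow(out$values), 1000L)
  expect_equal(out$values[1, ], seg$values[1, ])
  expect_equal(out$values[1000, ], seg$values[500, ])

  # identity when query positions hit every sample
  out2 <- interpolate_segment(seg, 500)
  expect_equal(out2$values, seg$values)

  # affine signals are reproduced exactly at the query positions
  ramp <- make_segment(function(n, ch) seq(0, 1, length.out = n), n = 313)
  ri <- interpolate_segment(ramp, 1000)
  expect_lt(max(abs(ri$values[, 1] - seq(0, 1, length.out = 1000))), 1e-12)

  one <- make_segment(function(n, ch) 1, n = 1)
  expect_error(interpolate_segment(one, 10), "shorter than 2")
})

test_that("sliding windows follow the stated count and offsets", {
  cfg_rom <- preprocess_config("rom")
  cfg_adl <- preprocess_config("adl")
  expect_equal(windows_per_segment(cfg_rom), 20L)
  expect_equal(windows_per_segment(cfg_adl), 20L)

  seg <- make_segment(function(n, ch) seq_len(n), n = 1000)
  seg <- select_channels(seg, cfg_rom$channels)
  win <- slide_windows(seg, cfg_rom)
  expect_equal(dim(win), c(20L, 200L, 30L))
  for (i in c(1L, 7L, 20L)) {
    off <- (i - 1L) * 42L
    expect_equal(win[i, , 1], as.numeric((off + 1):(off + 200)))
  }

  cfg1 <- preprocess_config("custom", target_length = 200, window_size = 200,
                            stride = 42)
  seg200 <- make_segment(function(n, ch) rnorm(n), n = 200)
  seg200 <- select_channels(seg200, cfg1$channels)
  win1 <- slide_windows(seg200, cfg1)
  expect_equal(dim(win1)[1], 1L)
  expect_equal(win1[1, , ], seg200$values)

  expect_error(preprocess_config("custom", target_length = 100,
                                 window_size = 200, stride = 42),
               "window_size")
})

test_that("the full pipeline yields the same window count and shape per segment", {
  ds <- generate_dataset(tiny_spec())
  cfg <- tiny_preprocess()
  pp <- preprocess_dataset(ds, cfg)
  nw <- windows_per_segment(cfg)
  expect_equal(dim(pp$x), c(length(ds$segments) * nw, 64L, 30L))
  counts <- table(pp$meta$segment_id)
  expect_true(all(counts == nw))
  # every (participant, class) pair contributes exactly nw windows
  pc <- table(paste(pp$meta$participant_id, pp$meta$movement_id))
  expect_true(all(pc == nw))
})

test_that("disabling side swap changes only left-hemiparesis participants", {
  ds <- generate_dataset(tiny_spec())
  cfg_on <- tiny_preprocess()
  cfg_off <- tiny_preprocess(); cfg_off$swap_sides_for_left_hemiparesis <- FALSE
  on <- preprocess_dataset(ds, cfg_on)
  off <- preprocess_dataset(ds, cfg_off)
  left <- dataset_meta(ds)$hemiparesis_side == "left"
  nw <- windows_per_segment(cfg_on)
  for (j in seq_along(ds$segments)) {
    rows <- ((j - 1) * nw + 1):(j * nw)
    same <- isTRUE(all.equal(on$x[rows, , ], off$x[rows, , ]))
    expect_equal(same, !left[j])
  }
})
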