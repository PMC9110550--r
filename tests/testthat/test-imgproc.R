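# Stabilization, the filtering recipe, kymographs and track-width
# measurement.

test_that("stabilization recovers injected integer and sub-pixel drift", {
  # integer drift (3, -2) px/frame
  sc <- quiet_scene(drift = c(3, -2), n_frames = 4)
  g <- generate_stack(sc)
  st <- stabilize(g$stack)
  inj <- outer(0:3, c(3, -2))
  expect_lt(max(abs(st$shifts - inj)), 0.1)
  # zero drift -> identity
  st0 <- stabilize(generate_stack(quiet_scene(n_frames = 3))$stack)
  expect_lt(max(abs(st0$shifts)), 0.1)
  # sub-pixel drift 0.5 px/frame recovered within 0.1 px/frame
  sc5 <- quiet_scene(drift = c(0.5, 0.5), n_frames = 5, seed = 6)
  st5 <- stabilize(generate_stack(sc5)$stack)
  inj5 <- outer(0:4, c(0.5, 0.5))
  expect_lt(max(abs(st5$shifts - inj5)), 0.1)
})

test_that("stabilize then shift is the identity within a tenth of a pixel", {
  g <- generate_stack(quiet_scene(n_frames = 2, seed = 8))
  ref <- get_frame(g$stack, 1, "reflection")
  for (shift in list(c(2, 7), c(-10, 4), c(0.6, -3.4))) {
    moved <- translate_image(ref, shift[1], shift[2])
    est <- phase_correlation_shift(ref, moved)
    expect_lt(max(abs(est - shift)), 0.1)
  }
})

test_that("flat frames get zero shift and a warning", {
  arr <- array(0.5, dim = c(3, 3, 32, 32))
  stk <- timelapse_stack(arr, 0.32, 4)
  expect_warning(st <- stabilize(stk), "flat")
  expect_true(all(st$shifts == 0))
  expect_true(any(st$flat))
})

test_that("filtering preserves constants, rejects impulses, and never changes shape", {
  arr <- array(0.4, dim = c(5, 3, 24, 24))
  stk <- timelapse_stack(arr, 0.32, 4)
  out <- preprocess(stk)
  expect_identical(dim(out$data), dim(stk$data))
  expect_equal(out$data, stk$data, tolerance = 1e-12)
  # single-pixel impulse in a fluorescence channel is removed by the median
  arr2 <- arr
  arr2[3, 2, 12, 12] <- 5
  out2 <- preprocess(timelapse_stack(arr2, 0.32, 4))
  expect_equal(out2$data[3, 2, 12, 12], 0.4, tolerance = 1e-6)
})

test_that("temporal flicker on the reflection channel matches a brute-force window oracle", {
  nt <- 9
  amp <- 0.2
  flick <- 0.5 + amp * rep_len(c(1, -1), nt)
  arr <- array(0, dim = c(nt, 3, 16, 16))
  for (t in seq_len(nt)) {
    arr[t, 1, , ] <- flick[t]
    arr[t, 2, , ] <- 0.3
    arr[t, 3, , ] <- 0.3
  }
  out <- preprocess(timelapse_stack(arr, 0.32, 4))
  # oracle: truncated +/-2-frame sliding mean of the scalar time series
  # (the spatial mean of a constant frame is itself)
  oracle <- vapply(seq_len(nt), function(t)
    mean(flick[max(1, t - 2):min(nt, t + 2)]), numeric(1))
  expect_equal(out$data[, 1, 8, 8], oracle, tolerance = 1e-9)
})

test_that("kymographs of a static scene are constant along time", {
  sc <- quiet_scene(noise_sd = 0, n_frames = 4)
  g <- generate_stack(sc)
  extent <- sc$image_shape * sc$pixel_size
  line <- cbind(x_um = c(extent[2] / 2, extent[2] / 2),
                y_um = c(2, extent[1] - 2))
  kg <- kymograph(g$stack, line, "reflection")
  expect_identical(ncol(kg$data), sc$n_frames)
  expect_lt(max(apply(kg$data, 1, stats::sd)), 1e-9)
})

test_that("a moving edge appears in the kymograph with the right slope", {
  sc <- pull_scene(seed = 25)
  g <- generate_stack(sc)
  extent <- sc$image_shape * sc$pixel_size
  line <- cbind(x_um = c(1, extent[2] - 1),
                y_um = rep(sc$track_axis_y, 2))
  kg <- kymograph(g$stack, line, "cytoplasm", prefilter_radius = 0)
  # locus of the leading edge: last position above half-maximum per frame
  locus <- apply(kg$data, 2, function(col) {
    i <- which(col > 0.5)
    if (length(i)) kg$positions_um[max(i)] else NA_real_
  })
  tmin <- (seq_len(sc$n_frames) - 1) * sc$frame_interval
  fit <- stats::lm(locus ~ tmin)
  expect_lt(abs(stats::coef(fit)[2] - sc$cell_speed),
            0.1 * sc$cell_speed)
})

test_that("degenerate and out-of-bounds kymograph lines are handled", {
  g <- generate_stack(quiet_scene(n_frames = 2))
  extent <- dim(g$stack$data)[3:4] * g$stack$pixel_size
  kg1 <- kymograph(g$stack, cbind(20, 20), "reflection")
  expect_identical(dim(kg1$data), c(1L, 2L))
  expect_error(kymograph(g$stack, cbind(c(0, extent[2] + 5), c(10, 10))),
               "bounds")
})

test_that("track width is measured to sub-pixel accuracy on a known gap", {
  sc <- scene(track_width0 = 10, wall_force_peak = 0, seed = 3)
  g <- generate_stack(sc)
  w <- measure_track_width(g$stack, sc$x_ref, 1)
  expect_true(w$found)
  expect_lt(abs(w$width_um - 10), 0.5)
  # invariant to global intensity scaling
  g2 <- g$stack
  g2$data <- g2$data * 7.3
  w2 <- measure_track_width(g2, sc$x_ref, 1)
  expect_equal(w2$width_um, w$width_um, tolerance = 1e-9)
})

test_that("uniform collagen yields a no-track result distinct from width zero", {
  set.seed(1)
  frames <- replicate(2, matrix(0.5 + rnorm(64 * 64, 0, 0.05), 64, 64),
                      simplify = FALSE)
  stk <- stack_from_frames(frames)
  w <- measure_track_width(stk, 10, 1)
  expect_false(w$found)
  expect_true(is.na(w$width_um))
})

test_that("a cell widening a narrow track four-fold is measured as such", {
  # 2.6 um track pushed out to 4x its width: d_peak = (4 - 1) * 2.6 / 2
  d <- 3 * 2.6 / 2
  f_nn <- 340 * (d / 40) * 400 * 1e-3
  sc <- scene(track_width0 = 2.6, deformation_sign = "push",
              wall_force_peak = f_nn, cell_length = 30,
              nucleus_axes = c(10, 5), seed = 29)
  g <- generate_stack(sc)
  m <- which.max(g$truth$mechanics$d_um)
  wb <- measure_track_width(g$stack, sc$x_ref, 1)
  wd <- measure_track_width(g$stack, sc$x_ref, m)
  expect_true(wb$found && wd$found)
  ratio <- wd$width_um / wb$width_um
  expect_lt(abs(ratio - 4), 0.4)
})

test_that("width measurements are labelled by cell-passage phase", {
  # short cell and a longer movie so the reference position sees full
  # before / during / after phases
  sc <- scene(cell_length = 20, n_frames = 20L, seed = 31)
  g <- generate_stack(sc)
  frames <- seq_len(sc$n_frames)
  widths <- do.call(rbind, lapply(frames, function(f) {
    w <- measure_track_width(g$stack, sc$x_ref, f)
    data.frame(frame = f, position_um = sc$x_ref, width_um = w$width_um)
  }))
  cells <- g$truth$trajectories[g$truth$trajectories$role %in%
                                c("leading", "rear"), ]
  res <- width_phase_summary(widths, cells)
  s <- res$summary
  expect_true(all(c("before", "during_single", "after") %in% s$phase))
  # pull scenario 22 -> 11 um at peak: during/before ratio 0.50
  during <- res$labels$width_um[res$labels$phase == "during_single"]
  ratio <- min(during) / s$mean[s$phase == "before"]
  expect_lt(abs(ratio - 0.5), 0.06)
  # no plasticity: widths recover after passage
  expect_lt(abs(s$mean[s$phase == "after"] - s$mean[s$phase == "before"]),
            0.5)
  # a position the cell never reaches stays "before"
  far_pos <- widths
  far_pos$position_um <- 1
  res2 <- width_phase_summary(far_pos, cells)
  expect_true(all(res2$labels$phase == "before"))
})
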