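# Migration speed, persistence, cell length and nuclear position.

test_that("mean speed is path length over elapsed time, stop phases included", {
  # 15 um in 30 min -> 0.5 um/min
  tr <- trajectory(seq(0, 15, length.out = 11), rep(0, 11),
                   frame_interval = 3)
  expect_equal(compute_speed(tr), 0.5, tolerance = 1e-12)
  # stationary cell
  expect_equal(compute_speed(trajectory(rep(2, 5), rep(3, 5))), 0)
  # stop phases dilute the mean: same path, pause appended
  tr_pause <- trajectory(c(seq(0, 15, length.out = 11), rep(15, 5)),
                         rep(0, 16), frame_interval = 3)
  expect_equal(compute_speed(tr_pause), 15 / 45, tolerance = 1e-12)
  # single frame is undefined
  expect_error(compute_speed(trajectory(1, 1)), "single-frame")
})

test_that("zigzag speed counts direction changes at full path length", {
  # 10 steps of 2 um alternating up/down at 4-min intervals
  y <- c(0, rep_len(c(2, 0), 10))
  tr <- trajectory(rep(0, 11), y, frame_interval = 4)
  expect_equal(compute_speed(tr), 20 / 40, tolerance = 1e-12)
})

test_that("persistence is path over beeline with the returned-cell guard", {
  straight <- trajectory(seq(0, 30, 5), rep(0, 7))
  expect_equal(compute_persistence(straight)$value, 1, tolerance = 1e-12)
  # two orthogonal 10 um legs: 20 / sqrt(200)
  legs <- trajectory(c(0, 10, 10), c(0, 0, 10))
  expect_equal(compute_persistence(legs)$value, 20 / sqrt(200),
               tolerance = 1e-12)
  # out-and-back: zero beeline -> undefined, no number
  back <- compute_persistence(trajectory(c(0, 8, 0), c(0, 0, 0)))
  expect_false(back$defined)
  expect_true(is.na(back$value))
})

test_that("speed and persistence are invariant under rotation and translation", {
  set.seed(61)
  for (i in 1:20) {
    x <- cumsum(rnorm(10)); y <- cumsum(rnorm(10))
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    xr <- x * cos(th) - y * sin(th) + dx
    yr <- x * sin(th) + y * cos(th) + dy
    expect_equal(compute_speed(trajectory(x, y)),
                 compute_speed(trajectory(xr, yr)), tolerance = 1e-9)
    p1 <- compute_persistence(trajectory(x, y))
    p2 <- compute_persistence(trajectory(xr, yr))
    expect_identical(p1$defined, p2$defined)
    if (p1$defined) expect_equal(p1$value, p2$value, tolerance = 1e-9)
  }
})

test_that("persistence never drops below one on random walks", {
  set.seed(63)
  for (i in 1:200) {
    tr <- trajectory(cumsum(rnorm(8)), cumsum(rnorm(8)))
    p <- compute_persistence(tr)
    if (p$defined) expect_gte(p$value, 1 - 1e-12)
  }
})

test_that("concatenated-path speed equals the time-weighted segment combination", {
  set.seed(65)
  x1 <- cumsum(runif(6)); y1 <- cumsum(runif(6))
  x2 <- x1[6] + cumsum(runif(5)); y2 <- y1[6] + cumsum(runif(5))
  sp_cat <- compute_speed(trajectory(c(x1, x2), c(y1, y2)))
  s1 <- compute_speed(trajectory(x1, y1))
  s2 <- compute_speed(trajectory(c(x1[6], x2), c(y1[6], y2)))
  t1 <- 5 * 4; t2 <- 5 * 4
  expect_equal(sp_cat, (s1 * t1 + s2 * t2) / (t1 + t2), tolerance = 1e-9)
})

test_that("cell length series matches construction and generator truth", {
  lead <- trajectory(rep(60, 4), rep(0, 4), role = "leading")
  rear <- trajectory(rep(10, 4), rep(0, 4), role = "rear")
  cl <- cell_length_series(lead, rear)
  expect_true(all(cl$length_um == 50))
  expect_equal(cl$mean_um, 50)
  # oscillating 40 <-> 60 with equal dwell averages to 50
  lead2 <- trajectory(c(40, 60, 40, 60), rep(0, 4), role = "leading")
  rear2 <- trajectory(rep(0, 4), rep(0, 4), role = "rear")
  expect_equal(cell_length_series(lead2, rear2)$mean_um, 50)
  # role mismatch rejected
  expect_error(cell_length_series(rear, lead), "roles")
  # generator's prescribed length is recovered from its truth table
  g <- generate_stack(quiet_scene(seed = 67, n_frames = 4))
  trs <- trajectories_from_table(g$truth$trajectories, "cell_1")
  cl2 <- cell_length_series(trs$leading, trs$rear)
  expect_lt(max(abs(cl2$length_um - g$truth$scene$cell_length)), 0.32)
})

test_that("nuclear position is a clipped axis projection with a rear flag", {
  lead <- trajectory(rep(100, 3), rep(0, 3), role = "leading")
  rear <- trajectory(rep(0, 3), rep(0, 3), role = "rear")
  mid <- trajectory(rep(50, 3), rep(5, 3), role = "nucleus")
  np <- nuclear_position_series(lead, mid, rear)
  expect_true(all(np$position_pct == 50))
  expect_false(np$rear_nucleus_flag)
  # nucleus at the rear: 0 % and flagged
  at_rear <- trajectory(rep(0, 3), rep(0, 3), role = "nucleus")
  np0 <- nuclear_position_series(lead, at_rear, rear)
  expect_true(all(np0$position_pct == 0))
  expect_true(np0$rear_nucleus_flag)
  # 40 % with a 30 % threshold is not rear-nucleated
  at40 <- trajectory(rep(40, 3), rep(0, 3), role = "nucleus")
  np40 <- nuclear_position_series(lead, at40, rear, rear_threshold_pct = 30)
  expect_false(np40$rear_nucleus_flag)
  expect_true(nuclear_position_series(lead, at40, rear,
                                      rear_threshold_pct = 45)$rear_nucleus_flag)
  # off-axis excursions cannot push the projection outside [0, 100]
  off <- trajectory(c(120, -10, 50), c(30, -20, 0), role = "nucleus")
  npo <- nuclear_position_series(lead, off, rear)
  expect_true(all(npo$position_pct >= 0 & npo$position_pct <= 100))
})

test_that("zero-length frames are skipped and counted", {
  lead <- trajectory(c(10, 0, 10), rep(0, 3), role = "leading")
  rear <- trajectory(rep(0, 3), rep(0, 3), role = "rear")
  nuc <- trajectory(c(5, 0, 5), rep(0, 3), role = "nucleus")
  np <- nuclear_position_series(lead, nuc, rear)
  expect_identical(np$skipped_frames, 1L)
  expect_true(is.na(np$position_pct[2]))
  expect_equal(np$mean_pct, 50)
})

test_that("per-cell metrics summarize the generator's cell faithfully", {
  g <- generate_stack(quiet_scene(seed = 69, n_frames = 6))
  sc <- g$truth$scene
  trs <- trajectories_from_table(g$truth$trajectories, "cell_1",
                                 frame_interval = sc$frame_interval)
  met <- cell_metrics(trs$leading, trs$nucleus, trs$rear)
  expect_equal(met$mean_speed_um_min, sc$cell_speed, tolerance = 1e-9)
  expect_equal(met$persistence, 1, tolerance = 1e-9)
  expect_equal(met$mean_cell_length_um, sc$cell_length, tolerance = 1e-9)
  expect_equal(met$mean_nuclear_position_pct, 100 * sc$nucleus_frac,
               tolerance = 1e-9)
})
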