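# Generator: determinism, closed-form displacement, speckle sampling,
# conservation and sign conventions.

test_that("scene validation rejects impossible parameter combinations", {
  expect_error(scene(n_frames = 1), "n_frames")
  expect_error(scene(track_width0 = -1), "positive")
  # displacement beyond the clamped boundary
  expect_error(scene(wall_force_peak = 200, clamp_distance = 10,
                     track_width0 = 60, deformation_sign = "push"),
               "fold-over")
  # pulled walls crossing the centreline
  expect_error(scene(wall_force_peak = 40), "fold-over")
  expect_error(scene(plasticity = 1.5), "plasticity")
})

test_that("peak displacement follows the linear elastic closed form", {
  sc <- force_scenario(40, seed = 1)
  # hand arithmetic: 40e-9 N / (340 Pa * 400e-12 m^2) * 40 um
  expect_equal(scene_d_peak(sc), 40e-9 / (340 * 400e-12) * 40,
               tolerance = 1e-12)
  expect_equal(scene_d_peak(sc), 11.7647, tolerance = 1e-4)
  # d_peak is exactly linear in the prescribed force
  d <- vapply(c(10, 20, 40),
              function(f) scene_d_peak(force_scenario(f)), numeric(1))
  expect_equal(d[2] / d[1], 2, tolerance = 1e-12)
  expect_equal(d[3] / d[1], 4, tolerance = 1e-12)
})

test_that("ground-truth mechanics are unit-consistent with the elastic model", {
  g <- generate_stack(pull_scene())
  m <- g$truth$mechanics
  expect_equal(m$strain, m$d_um / 40, tolerance = 1e-12)
  expect_equal(m$force_nN, 340 * m$strain * 400 * 1e-3, tolerance = 1e-12)
  expect_equal(m$d_um[1], 0)
  expect_equal(max(m$d_um), scene_d_peak(g$truth$scene), tolerance = 1e-9)
})

test_that("zero prescribed force gives a static scene and zero-force truth", {
  sc <- quiet_scene(noise_sd = 0, cell_speed = 0)
  g <- generate_stack(sc)
  expect_true(all(g$truth$mechanics$force_nN == 0))
  dev <- max(vapply(2:sc$n_frames, function(t)
    max(abs(g$stack$data[t, , , ] - g$stack$data[1, , , ])), numeric(1)))
  expect_lt(dev, 1e-12)
})

test_that("identical scene and seed give byte-identical stacks", {
  g1 <- generate_stack(pull_scene(seed = 11))
  g2 <- generate_stack(pull_scene(seed = 11))
  expect_identical(g1$stack$data, g2$stack$data)
  expect_identical(g1$truth$trajectories, g2$truth$trajectories)
  g3 <- generate_stack(pull_scene(seed = 12))
  expect_false(identical(g1$stack$data, g3$stack$data))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(3)
  set.seed(123)
  invisible(generate_stack(quiet_scene(n_frames = 2)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("speckle sampling is Poisson in the collagen area and detectable", {
  # collagen band area ~10,000 um^2 at density 5 per 100 um^2 -> ~500
  sc <- scene(image_shape = c(456L, 256L), n_frames = 2L,
              wall_force_peak = 0, speckle_density = 5, seed = 13)
  g <- generate_stack(sc)
  extent <- sc$image_shape * sc$pixel_size
  area <- (extent[1] - (sc$track_width0 + 4 * sc$speckle_sigma)) * extent[2]
  expected <- 5 * area / 100
  n_true <- nrow(g$truth$speckles0)
  expect_lt(abs(n_true - expected), 3 * sqrt(expected))
  # detection resolves most speckles but merges sub-resolution neighbours
  n_det <- realized_speckle_count(g$stack, 1)
  expect_gt(n_det / n_true, 0.8)
  expect_lt(n_det / n_true, 1.05)

  # density 0 -> nothing to detect
  g0 <- generate_stack(scene(n_frames = 2L, wall_force_peak = 0,
                             speckle_density = 0, seed = 13))
  expect_identical(nrow(g0$truth$speckles0), 0L)
  expect_identical(realized_speckle_count(g0$stack, 1), 0L)

  # doubling density doubles the expected count
  g2 <- generate_stack(scene(image_shape = c(456L, 256L), n_frames = 2L,
                             wall_force_peak = 0, speckle_density = 10,
                             seed = 14))
  n2 <- nrow(g2$truth$speckles0)
  expect_lt(abs(n2 - 2 * expected), 3 * sqrt(2 * expected))
})

test_that("speckles are conserved and trajectories span all frames", {
  sc <- pull_scene(seed = 3)
  g <- generate_stack(sc)
  tt <- g$truth$trajectories
  counts <- table(paste(tt$object_id, tt$role))
  expect_true(all(counts == sc$n_frames))
  spk <- tt[tt$role == "speckle", ]
  expect_identical(length(unique(spk$object_id)), nrow(g$truth$speckles0))
})

test_that("pull narrows and push widens the track by twice the wall displacement", {
  for (sign in c("pull", "push")) {
    # x_ref on the width-truth grid so the analytic width applies exactly
    sc <- scene(deformation_sign = sign, seed = 17, x_ref = 40)
    g <- generate_stack(sc)
    m <- which.max(g$truth$mechanics$d_um)
    d <- g$truth$mechanics$d_um[m]
    w_truth <- g$truth$track_width
    w_ref <- w_truth$width_um[w_truth$frame == m &
                              abs(w_truth$position_um - sc$x_ref) < 1]
    expected <- sc$track_width0 + (if (sign == "push") 2 else -2) * d
    expect_equal(w_ref, expected, tolerance = 1e-9)
    # and the rendered image agrees within a pixel
    w_meas <- measure_track_width(g$stack, sc$x_ref, m)
    expect_true(w_meas$found)
    expect_lt(abs(w_meas$width_um - expected), 2 * sc$pixel_size)
  }
})

test_that("residual deformation persists according to the plasticity fraction", {
  sc <- scene(plasticity = 0.5, seed = 19, n_frames = 15L)
  g <- generate_stack(sc)
  m <- g$truth$mechanics
  peak <- max(m$d_um)
  expect_equal(m$d_um[nrow(m)], 0.5 * peak, tolerance = 1e-9)
  sc0 <- scene(plasticity = 0, seed = 19, n_frames = 15L)
  g0 <- generate_stack(sc0)
  expect_equal(g0$truth$mechanics$d_um[15], 0, tolerance = 1e-9)
})

test_that("stack TIFF round trip preserves data and calibration", {
  g <- generate_stack(quiet_scene(n_frames = 2, image_shape = c(96L, 64L),
                                  clamp_distance = 5, track_width0 = 8))
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(g$stack, path)
  rt <- read_stack_tiff(path)
  expect_equal(rt$data, pmin(pmax(g$stack$data, 0), 1), tolerance = 1e-6)
  expect_identical(rt$channel_roles, g$stack$channel_roles)
  expect_equal(rt$pixel_size, g$stack$pixel_size)
  file.remove(path, paste0(path, ".yaml"))
})

test_that("scene YAML round trip reproduces the scene and its stack", {
  sc <- quiet_scene(n_frames = 2, image_shape = c(96L, 64L),
                    clamp_distance = 5, track_width0 = 8, seed = 23)
  path <- tempfile(fileext = ".yaml")
  write_scene_yaml(sc, path)
  sc2 <- read_scene_yaml(path)
  expect_identical(generate_stack(sc)$stack$data,
                   generate_stack(sc2)$stack$data)
  file.remove(path)
})
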