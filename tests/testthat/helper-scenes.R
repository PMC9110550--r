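# Small scenes shared across test files. Kept deliberately compact so the
# whole suite renders in seconds; the acceptance tests use full-size
# benchmark scenes.

# default-geometry pull scenario (22 um track, 18.7 nN -> 11 um at peak)
pull_scene <- function(seed = 7, ...) {
  scene(seed = seed, ...)
}

# quiescent scene: no force, optional drift; used for registration and
# static-tracking tests
quiet_scene <- function(seed = 5, drift = c(0, 0), noise_sd = 0.05, ...) {
  scene(wall_force_peak = 0, drift_per_frame = drift, noise_sd = noise_sd,
        seed = seed, ...)
}

# hand-built three-channel stack from a single reflection matrix repeated
# over frames (other channels constant)
stack_from_frames <- function(frames, pixel_size = 0.32, frame_interval = 4) {
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  arr <- array(0, dim = c(length(frames), 3, ny, nx))
  for (t in seq_along(frames)) {
    arr[t, 1, , ] <- frames[[t]]
    arr[t, 2, , ] <- 0.2
    arr[t, 3, , ] <- 0.2
  }
  timelapse_stack(arr, pixel_size, frame_interval)
}

# conspicuous, well-isolated speckles an analyst would pick for tracking:
# bright, compact, clear of the track wall and the image border
pick_bright_seeds <- function(truth, n = 6) {
  sp <- truth$speckles0
  ext <- truth$scene$image_shape * truth$scene$pixel_size
  sp <- sp[sp$nn_um > 3 & sp$amp >= 0.5 &
           sp$sigma_major_um / sp$sigma_minor_um <= 2 &
           sp$dist_wall_um > 3 &
           sp$x_um > 5 & sp$x_um < ext[2] - 5 &
           sp$y_um > 5 & sp$y_um < ext[1] - 5, ]
  sp[order(-sp$amp), ][seq_len(min(n, nrow(sp))), ]
}

# speckle_trajectory stub from explicit coordinates
traj_stub <- function(x, y, id = "s1", frame_interval = 4) {
  structure(list(object_id = id, x_um = x, y_um = y,
                 quality = rep(1, length(x)), lost_from = NA_integer_,
                 frame_interval = frame_interval),
            class = "speckle_trajectory")
}

# speckle_trajectory objects straight from the generator's ground truth
truth_trajs <- function(truth, ids) {
  tt <- truth$trajectories
  lapply(ids, function(id) {
    s <- tt[tt$object_id == id, ]
    s <- s[order(s$frame), ]
    traj_stub(s$x_um, s$y_um, id = id,
              frame_interval = truth$scene$frame_interval)
  })
}
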