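# Raised-cosine contact envelope with compact support L:
# env(0) = 1, env(u) = 0 for |u| >= L/2.
contact_envelope <- function(u, L) {
  e <- numeric(length(u))
  i <- abs(u) < L / 2
  e[i] <- cos(pi * u[i] / L)^2
  e
}

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so generation never perturbs user RNG.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Soft ellipse membership rendered as a logistic of the normalized quadratic
# form; `soft` controls edge width in units of the form.
soft_ellipse <- function(xg, yg, cx, cy, a, b, soft = 0.08) {
  m <- outer((yg - cy)^2 / b^2, (xg - cx)^2 / a^2, "+")
  1 / (1 + exp((m - 1) / soft))
}

# anisotropic Gaussian spot: collagen reflection speckles are short
# fibril-like features, so each one has its own size, elongation and
# orientation, which is also what makes individual speckles recognizable
# to a tracker
add_gaussian_spot <- function(img, px, py, sigma_a_px, sigma_b_px, theta,
                              amp) {
  r <- ceiling(3 * max(sigma_a_px, sigma_b_px))
  i0 <- max(1L, floor(py) - r); i1 <- min(nrow(img), ceiling(py) + r)
  j0 <- max(1L, floor(px) - r); j1 <- min(ncol(img), ceiling(px) + r)
  if (i0 > i1 || j0 > j1) return(img)
  ys <- i0:i1; xs <- j0:j1
  dy <- matrix(ys - py, length(ys), length(xs))
  dx <- matrix(xs - px, length(ys), length(xs), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  g <- exp(-(u^2 / (2 * sigma_a_px^2) + v^2 / (2 * sigma_b_px^2)))
  img[ys, xs] <- img[ys, xs] + amp * g
  img
}

#' Render a synthetic microtrack time-lapse with ground truth
#'
#' Generates a deterministic, seeded three-channel stack (collagen
#' reflection speckle, cytoplasm, nucleus) of a single cell migrating along
#' a deformable microtrack, together with the ground-truth tables every
#' downstream stage can be validated against.
#'
#' The wall displacement at axial position `x` and time `t` is
#' `d_peak * envelope(x - x_cell(t))`, a raised-cosine envelope of support
#' `contact_length`; collagen speckles displace perpendicular to the wall
#' with a magnitude decaying linearly to zero at `clamp_distance`, so the
#' true strain between the wall and the clamped boundary is exactly
#' `d(t) / clamp_distance` and the true force `E * strain * A` (in nN).
#' With `plasticity > 0` a fraction of the largest displacement seen at a
#' position persists after the cell has passed.
#'
#' @param sc a [scene()].
#' @return A list with elements `stack` (a [timelapse_stack()]) and `truth`
#'   (class `ground_truth`): `mechanics` (frame, time_min, d_um, strain,
#'   force_nN), `trajectories` (frame, time_min, object_id, role, x_um,
#'   y_um for leading/nucleus/rear, both walls at `x_ref`, and every
#'   speckle), `track_width` (frame, position_um, width_um), and
#'   `speckles0` (initial speckle positions).
#' @export
generate_stack <- function(sc) {
  validate_scene(sc)
  with_local_seed(sc$seed, render_scene(sc))
}

render_scene <- function(sc) {
  ny <- sc$image_shape[1]; nx <- sc$image_shape[2]
  psz <- sc$pixel_size
  xg <- (seq_len(nx) - 0.5) * psz   # pixel-center x in um
  yg <- (seq_len(ny) - 0.5) * psz
  yc <- sc$track_axis_y
  hw0 <- sc$track_width0 / 2
  d_peak <- scene_d_peak(sc)
  s_dir <- if (sc$deformation_sign == "push") 1 else -1
  L <- sc$clamp_distance
  soft_um <- 0.35                     # wall edge half-transition, um
  track_floor <- 0.05
  base_int <- 0.5
  spot_amp <- 0.5

  ## --- sample speckles in the collagen (outside the undeformed track) ---
  extent_y <- ny * psz; extent_x <- nx * psz
  margin <- 2 * sc$speckle_sigma
  band_top <- c(0, yc - hw0 - margin)           # y range above ... (low y)
  band_bot <- c(yc + hw0 + margin, extent_y)
  h_top <- max(0, diff(band_top)); h_bot <- max(0, diff(band_bot))
  collagen_area <- (h_top + h_bot) * extent_x
  n_spk <- stats::rpois(1, sc$speckle_density * collagen_area / 100)
  if (n_spk > 0) {
    pick_top <- stats::runif(n_spk) < h_top / (h_top + h_bot)
    sy <- ifelse(pick_top,
                 stats::runif(n_spk, band_top[1], band_top[2]),
                 stats::runif(n_spk, band_bot[1], band_bot[2]))
    sx <- stats::runif(n_spk, 0, extent_x)
    # reflection speckle is heterogeneous: vary brightness, size,
    # elongation and orientation so individual speckles are identifiable,
    # as in real fibrillar collagen texture
    s_amp <- stats::runif(n_spk, 0.3, 0.9) * spot_amp / 0.6
    s_siga <- sc$speckle_sigma * stats::runif(n_spk, 1.0, 1.8)
    s_sigb <- sc$speckle_sigma * stats::runif(n_spk, 0.5, 0.9)
    s_theta <- stats::runif(n_spk, 0, pi)
  } else {
    sx <- sy <- s_amp <- s_siga <- s_sigb <- s_theta <- numeric(0)
  }
  side <- sign(sy - yc)
  dist0 <- abs(sy - yc) - hw0         # distance from the undeformed wall
  decay <- pmax(0, 1 - dist0 / L)

  ## --- per-frame geometry and rendering ---
  arr <- array(0, dim = c(sc$n_frames, 3L, ny, nx))
  env_max_col <- numeric(nx)          # running max envelope per column
  env_max_spk <- numeric(length(sx))
  wpos <- seq(2, extent_x - 2, by = 2)  # axial grid for width truth
  env_max_w <- numeric(length(wpos))
  env_max_ref <- 0

  mech <- data.frame(frame = seq_len(sc$n_frames),
                     time_min = (seq_len(sc$n_frames) - 1) * sc$frame_interval,
                     d_um = 0, strain = 0, force_nN = 0)
  traj <- vector("list", sc$n_frames)
  width_truth <- vector("list", sc$n_frames)

  for (t in seq_len(sc$n_frames)) {
    time_min <- (t - 1) * sc$frame_interval
    drift <- sc$drift_per_frame * psz * (t - 1)   # c(dy, dx) in um
    x_cell <- sc$x_start + sc$cell_speed * time_min

    eff_env <- function(cur, prev_max) pmax(cur, sc$plasticity * prev_max)

    e_col <- contact_envelope(xg - drift[2] - x_cell, sc$contact_length)
    env_max_col <- pmax(env_max_col, e_col)
    hw_col <- hw0 + s_dir * d_peak * eff_env(e_col, env_max_col)

    e_spk <- contact_envelope(sx - x_cell, sc$contact_length)
    env_max_spk <- pmax(env_max_spk, e_spk)
    disp_spk <- s_dir * side * d_peak * eff_env(e_spk, env_max_spk) * decay
    sy_t <- sy + disp_spk

    e_ref <- contact_envelope(sc$x_ref - x_cell, sc$contact_length)
    env_max_ref <- max(env_max_ref, e_ref)
    d_ref <- d_peak * eff_env(e_ref, env_max_ref)

    e_w <- contact_envelope(wpos - x_cell, sc$contact_length)
    env_max_w <- pmax(env_max_w, e_w)
    w_t <- sc$track_width0 + 2 * s_dir * d_peak * eff_env(e_w, env_max_w)

    ## reflection: base + speckles, attenuated inside the (deformed) track
    refl <- matrix(base_int, ny, nx)
    for (k in seq_along(sx)) {
      refl <- add_gaussian_spot(refl,
                                px = (sx[k] + drift[2]) / psz + 0.5,
                                py = (sy_t[k] + drift[1]) / psz + 0.5,
                                sigma_a_px = s_siga[k] / psz,
                                sigma_b_px = s_sigb[k] / psz,
                                theta = s_theta[k],
                                amp = s_amp[k])
    }
    dy_abs <- abs(yg - drift[1] - yc)
    frac <- pmin(pmax(outer(dy_abs, hw_col,
                            function(d, h) (d - h) / (2 * soft_um) + 0.5),
                      0), 1)
    refl <- track_floor + (refl - track_floor) * frac

    ## cytoplasm and nucleus
    b_cell <- hw0 + s_dir * d_peak     # cell fills the deformed track
    cyto <- soft_ellipse(xg, yg, x_cell + drift[2], yc + drift[1],
                         a = sc$cell_length / 2, b = b_cell)
    x_rear <- x_cell - sc$cell_length / 2
    x_lead <- x_cell + sc$cell_length / 2
    x_nuc <- x_rear + sc$nucleus_frac * sc$cell_length
    nb <- min(sc$nucleus_axes[2] / 2, b_cell)    # confinement clamps minor axis
    nuc <- soft_ellipse(xg, yg, x_nuc + drift[2], yc + drift[1],
                        a = sc$nucleus_axes[1] / 2, b = nb)

    if (sc$noise_sd > 0) {
      refl <- refl + stats::rnorm(length(refl), 0, sc$noise_sd)
      cyto <- cyto + stats::rnorm(length(cyto), 0, sc$noise_sd)
      nuc <- nuc + stats::rnorm(length(nuc), 0, sc$noise_sd)
    }
    arr[t, 1, , ] <- pmax(refl, 0)
    arr[t, 2, , ] <- pmax(cyto, 0)
    arr[t, 3, , ] <- pmax(nuc, 0)

    mech$d_um[t] <- d_ref
    mech$strain[t] <- d_ref / L
    mech$force_nN[t] <- sc$youngs_modulus * (d_ref / L) * sc$contact_area * 1e-3

    hw_ref <- hw0 + s_dir * d_ref
    cell_rows <- data.frame(
      frame = t, time_min = time_min,
      object_id = c("cell_1", "cell_1", "cell_1", "wall_top", "wall_bottom"),
      role = c("leading", "nucleus", "rear", "wall", "wall"),
      x_um = c(x_lead, x_nuc, x_rear, sc$x_ref, sc$x_ref),
      y_um = c(yc, yc, yc, yc - hw_ref, yc + hw_ref))
    if (length(sx)) {
      spk_rows <- data.frame(
        frame = t, time_min = time_min,
        object_id = sprintf("speckle_%04d", seq_along(sx)),
        role = "speckle", x_um = sx, y_um = sy_t)
      traj[[t]] <- rbind(cell_rows, spk_rows)
    } else traj[[t]] <- cell_rows

    width_truth[[t]] <- data.frame(frame = t, position_um = wpos,
                                   width_um = w_t)
  }

  stack <- timelapse_stack(arr, psz, sc$frame_interval,
                           c("reflection", "cytoplasm", "nucleus"))
  truth <- structure(list(
    mechanics = mech,
    trajectories = do.call(rbind, traj),
    track_width = do.call(rbind, width_truth),
    speckles0 = if (length(sx)) {
      nn <- vapply(seq_along(sx), function(k) {
        d2 <- (sx - sx[k])^2 + (sy - sy[k])^2
        sqrt(min(d2[-k], Inf))
      }, numeric(1))
      data.frame(object_id = sprintf("speckle_%04d", seq_along(sx)),
                 x_um = sx, y_um = sy, dist_wall_um = dist0, side = side,
                 amp = s_amp, sigma_major_um = s_siga,
                 sigma_minor_um = s_sigb, theta = s_theta, nn_um = nn)
    } else data.frame(object_id = character(0), x_um = numeric(0),
                      y_um = numeric(0), dist_wall_um = numeric(0),
                      side = numeric(0), amp = numeric(0),
                      sigma_major_um = numeric(0), sigma_minor_um = numeric(0),
                      theta = numeric(0), nn_um = numeric(0)),
    d_peak_um = d_peak, scene = sc), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d frames, %d speckles, d_peak %.2f um, peak force %.2f nN\n",
              max(x$mechanics$frame), nrow(x$speckles0), x$d_peak_um,
              max(x$mechanics$force_nN)))
  invisible(x)
}

#' Count rendered speckles in one frame
#'
#' Detects local intensity maxima in the (lightly smoothed) reflection
#' channel above a prominence threshold; maxima inside the dark track do not
#' reach the threshold, so the count covers the collagen region only.
#' Speckles closer than about the optical spot size merge into one maximum,
#' so at realistic densities the count runs 10-20% below the number of
#' generated speckles — an inherent resolution limit, not a detector bug.
#'
#' @param stack a [timelapse_stack()].
#' @param frame frame index.
#' @param threshold absolute intensity a maximum must exceed.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels.
#' @return Integer count of detected speckles.
#' @export
realized_speckle_count <- function(stack, frame, threshold = 0.56,
                                   smooth_sigma = 1) {
  img <- get_frame(stack, frame, "reflection")
  if (smooth_sigma > 0) img <- EBImage::gblur(img, sigma = smooth_sigma)
  sum(local_maxima(img) & img > threshold)
}

# strict 8-neighbour local maxima (interior pixels only)
local_maxima <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  res <- matrix(FALSE, ny, nx)
  ci <- 2:(ny - 1); cj <- 2:(nx - 1)
  m <- img[ci, cj]
  ok <- m > img[ci - 1, cj] & m > img[ci + 1, cj] &
        m > img[ci, cj - 1] & m > img[ci, cj + 1] &
        m > img[ci - 1, cj - 1] & m > img[ci - 1, cj + 1] &
        m > img[ci + 1, cj - 1] & m > img[ci + 1, cj + 1]
  res[ci, cj] <- ok
  res
}

#' Write ground-truth tables as CSV
#'
#' @param truth a `ground_truth` object from [generate_stack()].
#' @param traj_path trajectory CSV path (frame, time_min, object_id, role,
#'   x_um, y_um).
#' @param mech_path mechanics CSV path (frame, time_min, d_um, strain,
#'   force_nN); omitted when `NULL`.
#' @return `traj_path`, invisibly.
#' @export
write_truth_csv <- function(truth, traj_path, mech_path = NULL) {
  utils::write.csv(truth$trajectories, traj_path, row.names = FALSE)
  if (!is.null(mech_path))
    utils::write.csv(truth$mechanics, mech_path, row.names = FALSE)
  invisible(traj_path)
}
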