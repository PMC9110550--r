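#' Parametric description of a synthetic microtrack scene
#'
#' A `scene` describes a speckled collagen lattice containing one linear
#' low-intensity microtrack and a single elliptical cell (with labelled
#' nucleus) migrating along it. The cell exerts a prescribed peak force on
#' the track walls; the surrounding collagen deforms elastically,
#' perpendicular to the wall, with a displacement that decays linearly to
#' zero at `clamp_distance` from the wall. True strain at the wall is
#' therefore `d / clamp_distance` by construction, and the peak wall
#' displacement follows the linear-elastic closed form
#' `d_peak = F / (E * A) * clamp_distance` (force in nN, `E` in Pa, `A` in
#' square micrometres, displacement in micrometres).
#'
#' @param image_shape integer c(y, x) image size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames (>= 2).
#' @param track_axis_y track centreline, micrometres from the image top;
#'   default image centre.
#' @param track_width0 initial track width (diameter), micrometres.
#' @param speckle_density collagen speckles per 100 square micrometres.
#' @param speckle_sigma Gaussian speckle spot sigma, micrometres.
#' @param cell_speed migration speed along the track axis, micrometres/min.
#' @param cell_length cell length (leading edge to rear), micrometres.
#' @param nucleus_axes c(major, minor) nuclear ellipse axes, micrometres.
#' @param nucleus_frac nucleus centre position as a fraction of cell length
#'   from the rear (0 = rear, 1 = leading edge).
#' @param wall_force_peak prescribed peak traction force on the wall, nN.
#' @param contact_length axial support of the cell-wall contact envelope,
#'   micrometres (raised-cosine window).
#' @param clamp_distance distance from the wall at which the collagen is held
#'   fixed, micrometres.
#' @param youngs_modulus collagen Young's modulus, Pa.
#' @param contact_area cell-collagen contact area, square micrometres.
#' @param deformation_sign `"pull"` (walls move toward the centreline,
#'   narrowing) or `"push"` (walls move apart, widening).
#' @param plasticity fraction (0-1) of the peak local wall displacement that
#'   persists after the cell has passed; 0 gives fully elastic recovery.
#' @param noise_sd additive Gaussian intensity noise (dynamic range is 0-1).
#' @param drift_per_frame c(dy, dx) global stage drift in pixels per frame.
#' @param x_start cell centroid x at frame 1, micrometres; by default chosen
#'   so the centroid crosses the reference position mid-sequence.
#' @param x_ref reference axial position (micrometres) at which ground-truth
#'   wall displacement, strain and force are reported; default image centre.
#' @param seed integer seed making the rendered stack reproducible.
#' @return An object of class `scene`.
#' @seealso [generate_stack()]
#' @export
scene <- function(image_shape = c(352L, 256L),
                  pixel_size = 0.32,
                  frame_interval = 4,
                  n_frames = 15L,
                  track_axis_y = NULL,
                  track_width0 = 22,
                  speckle_density = 4,
                  speckle_sigma = 0.5,
                  cell_speed = 0.7,
                  cell_length = 40,
                  nucleus_axes = c(16, 8),
                  nucleus_frac = 0.4,
                  wall_force_peak = 18.7,
                  contact_length = 20,
                  clamp_distance = 40,
                  youngs_modulus = 340,
                  contact_area = 400,
                  deformation_sign = c("pull", "push"),
                  plasticity = 0,
                  noise_sd = 0.05,
                  drift_per_frame = c(0, 0),
                  x_start = NULL,
                  x_ref = NULL,
                  seed = 1L) {
  deformation_sign <- match.arg(deformation_sign)
  sc <- list(image_shape = as.integer(image_shape),
             pixel_size = pixel_size, frame_interval = frame_interval,
             n_frames = as.integer(n_frames),
             track_axis_y = track_axis_y, track_width0 = track_width0,
             speckle_density = speckle_density, speckle_sigma = speckle_sigma,
             cell_speed = cell_speed, cell_length = cell_length,
             nucleus_axes = nucleus_axes, nucleus_frac = nucleus_frac,
             wall_force_peak = wall_force_peak,
             contact_length = contact_length,
             clamp_distance = clamp_distance,
             youngs_modulus = youngs_modulus, contact_area = contact_area,
             deformation_sign = deformation_sign, plasticity = plasticity,
             noise_sd = noise_sd, drift_per_frame = drift_per_frame,
             x_start = x_start, x_ref = x_ref, seed = as.integer(seed))
  extent <- sc$image_shape * pixel_size  # c(y, x) in um
  if (is.null(sc$track_axis_y)) sc$track_axis_y <- extent[1] / 2
  if (is.null(sc$x_ref)) sc$x_ref <- extent[2] / 2
  if (is.null(sc$x_start)) {
    # centroid crosses x_ref exactly at the middle frame
    mid <- floor((sc$n_frames - 1) / 2)
    sc$x_start <- sc$x_ref - cell_speed * frame_interval * mid
  }
  class(sc) <- "scene"
  validate_scene(sc)
  sc
}

#' Canonical traction-force benchmark scene
#'
#' A wide-track pull scenario with a prescribed peak wall force, used for
#' end-to-end force recovery. The cell crawls slowly (default
#' 0.2 um/min), reflecting that strong wall pulling coincides with slow
#' translocation / stop phases and that measured traction builds up over
#' one to two hours; with the traveling contact envelope this yields
#' wall-deformation rates of order 1 um per 4-min frame, the regime
#' speckle tracking (manual or automated) can actually follow.
#'
#' The track is wide (32 um) so that even the strongest benchmark pull
#' (40 nN, peak wall displacement ~11.8 um) narrows the track without the
#' walls ever meeting, as in the wide-track pulling experiments.
#'
#' @param wall_force_peak prescribed peak force, nN.
#' @param seed integer seed.
#' @param cell_speed migration speed, um/min.
#' @param n_frames frames at 4-min intervals.
#' @param track_width0 initial track width, um.
#' @param image_shape image size c(y, x) in px.
#' @param ... further arguments to [scene()].
#' @return A [scene()].
#' @export
force_scenario <- function(wall_force_peak, seed = 1L, cell_speed = 0.2,
                           n_frames = 40L, track_width0 = 32,
                           image_shape = c(384L, 256L), ...) {
  scene(wall_force_peak = wall_force_peak, cell_speed = cell_speed,
        n_frames = n_frames, track_width0 = track_width0,
        image_shape = image_shape, seed = seed, ...)
}

#' Peak wall displacement implied by a scene's elastic parameters
#'
#' `d_peak = F / (E * A) * clamp_distance`, with the force in newtons and the
#' area in square metres so the ratio is a dimensionless strain.
#'
#' @param sc a [scene()].
#' @return Peak wall displacement in micrometres.
#' @export
scene_d_peak <- function(sc) {
  strain <- (sc$wall_force_peak * 1e-9) /
    (sc$youngs_modulus * sc$contact_area * 1e-12)
  strain * sc$clamp_distance
}

validate_scene <- function(sc) {
  pos <- c(image_shape = all(sc$image_shape > 0), pixel_size = sc$pixel_size > 0,
           frame_interval = sc$frame_interval > 0,
           track_width0 = sc$track_width0 > 0,
           speckle_density = sc$speckle_density >= 0,
           speckle_sigma = sc$speckle_sigma > 0,
           cell_length = sc$cell_length > 0,
           contact_length = sc$contact_length > 0,
           clamp_distance = sc$clamp_distance > 0,
           youngs_modulus = sc$youngs_modulus > 0,
           contact_area = sc$contact_area > 0)
  if (!all(pos))
    stop("scene parameters must be positive: ",
         paste(names(pos)[!pos], collapse = ", "))
  if (sc$n_frames < 2L) stop("n_frames must be >= 2")
  if (sc$wall_force_peak < 0) stop("wall_force_peak must be >= 0")
  if (sc$plasticity < 0 || sc$plasticity > 1) stop("plasticity must be in [0,1]")
  d_peak <- scene_d_peak(sc)
  if (d_peak >= sc$clamp_distance)
    stop(sprintf(paste0("fold-over: peak wall displacement %.2f um is not ",
                        "smaller than clamp_distance %.2f um; reduce ",
                        "wall_force_peak or stiffen the scene"),
                 d_peak, sc$clamp_distance))
  if (sc$deformation_sign == "pull" && d_peak >= sc$track_width0 / 2)
    stop(sprintf(paste0("fold-over: pulled walls would cross the ",
                        "centreline (d_peak %.2f um >= half-width %.2f um); ",
                        "use a wider track or a smaller wall_force_peak"),
                 d_peak, sc$track_width0 / 2))
  invisible(sc)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %dx%d px (%.2f um/px), %d frames @ %g min\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size, x$n_frames,
              x$frame_interval))
  cat(sprintf("  track width %g um, %s, peak force %g nN (d_peak %.2f um)\n",
              x$track_width0, x$deformation_sign, x$wall_force_peak,
              scene_d_peak(x)))
  invisible(x)
}

#' Write / read a scene as a YAML config
#'
#' @param sc a [scene()].
#' @param path YAML file path.
#' @return `path` (write) or a [scene()] (read).
#' @export
write_scene_yaml <- function(sc, path) {
  yaml::write_yaml(unclass(sc), path)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(scene, cfg[setdiff(names(cfg), character(0))])
}
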