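#' Linear elastic model of the cell-collagen interface
#'
#' The traction-force estimate rests on the simplified linear relation
#' between cell-induced stress and strain in the collagen,
#' `E = stress / strain`, so `F = E * strain * A`. The defaults are a
#' Young's modulus of 340 Pa (6 mg/ml fibrillar collagen) and a cell-wall
#' contact patch of 20 x 20 um, i.e. 400 square micrometres.
#'
#' @param youngs_modulus Young's modulus in Pa.
#' @param contact_area contact area in square micrometres; alternatively
#'   derived from `contact_side_um` when that is given.
#' @param contact_side_um optional side of a square contact patch in
#'   micrometres; overrides `contact_area` with `contact_side_um^2`.
#' @return Object of class `elastic_model`.
#' @export
elastic_model <- function(youngs_modulus = 340, contact_area = 400,
                          contact_side_um = NULL) {
  if (!is.null(contact_side_um)) {
    if (contact_side_um <= 0) stop("contact_side_um must be > 0")
    contact_area <- contact_side_um^2
  }
  if (youngs_modulus <= 0) stop("youngs_modulus must be > 0")
  if (contact_area <= 0) stop("contact_area must be > 0")
  structure(list(youngs_modulus = youngs_modulus, contact_area = contact_area),
            class = "elastic_model")
}

#' @export
print.elastic_model <- function(x, ...) {
  cat(sprintf("<elastic_model> E = %g Pa, A = %g um^2\n",
              x$youngs_modulus, x$contact_area))
  invisible(x)
}

#' Pairwise speckle-distance strain over time
#'
#' Strain is the relative deformation of the collagen with respect to time
#' point 0: `s(t) = (||p_a(t) - p_b(t)|| - L0) / L0`, with `L0` the frame-1
#' separation of the two tracked speckles. Positive strain means the
#' separation increased. If either trajectory is flagged lost, the series
#' is truncated at the loss frame. The operation is symmetric in its two
#' arguments.
#'
#' @param traj_a,traj_b `speckle_trajectory` objects spanning the same
#'   frames.
#' @param min_separation_um minimum admissible frame-1 separation.
#' @return Object of class `strain_series`: `strain` (per frame, `s[1] =
#'   0`), `time_min`, `L0_um`, `truncated_at`.
#' @export
compute_strain <- function(traj_a, traj_b, min_separation_um = 2) {
  if (length(traj_a$x_um) != length(traj_b$x_um))
    stop("trajectories must span the same frames")
  L0 <- sqrt((traj_a$x_um[1] - traj_b$x_um[1])^2 +
             (traj_a$y_um[1] - traj_b$y_um[1])^2)
  if (L0 <= min_separation_um)
    stop(sprintf("initial separation %.2f um is below the %.2f um minimum",
                 L0, min_separation_um))
  lost <- c(traj_a$lost_from, traj_b$lost_from)
  cutoff <- if (all(is.na(lost))) length(traj_a$x_um) else min(lost, na.rm = TRUE) - 1L
  idx <- seq_len(cutoff)
  d <- sqrt((traj_a$x_um[idx] - traj_b$x_um[idx])^2 +
            (traj_a$y_um[idx] - traj_b$y_um[idx])^2)
  structure(list(strain = (d - L0) / L0,
                 time_min = (idx - 1) * traj_a$frame_interval,
                 L0_um = L0,
                 truncated_at = if (cutoff < length(traj_a$x_um)) cutoff + 1L
                                else NA_integer_,
                 reference = "frame 1 separation"),
            class = "strain_series")
}

#' @export
print.strain_series <- function(x, ...) {
  cat(sprintf("<strain_series> %d frames, L0 = %.2f um, peak |s| = %.4f\n",
              length(x$strain), x$L0_um, max(abs(x$strain))))
  invisible(x)
}

#' Traction force from strain under the linear elastic model
#'
#' `F(t) = E * |s(t)| * A`, converted to nanonewtons
#' (1 Pa x 1 um^2 = 1e-3 nN). The direction flag records the sign of the
#' strain: `"pull"` when the tracked separation decreased (negative
#' strain), `"push"` when it increased.
#'
#' @param strain a [compute_strain()] result.
#' @param model an [elastic_model()].
#' @return Object of class `force_series`: `force_nN`, `stress_Pa`,
#'   `direction` (per frame), `time_min`, `model`.
#' @export
compute_force <- function(strain, model = elastic_model()) {
  stopifnot(inherits(strain, "strain_series"), inherits(model, "elastic_model"))
  s <- strain$strain
  stress <- model$youngs_modulus * abs(s)
  structure(list(force_nN = stress * model$contact_area * 1e-3,
                 stress_Pa = stress,
                 direction = ifelse(s < 0, "pull", ifelse(s > 0, "push", "none")),
                 time_min = strain$time_min,
                 strain = s,
                 model = model),
            class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf("<force_series> %d frames, peak force %.2f nN (E = %g Pa, A = %g um^2)\n",
              length(x$force_nN), max(x$force_nN),
              x$model$youngs_modulus, x$model$contact_area))
  invisible(x)
}

#' Peak force of a force series
#'
#' @param force a [compute_force()] result.
#' @return Maximum force in nN.
#' @export
peak_force <- function(force) max(force$force_nN)

#' Force series as a tidy data frame
#'
#' @param force a [compute_force()] result.
#' @return Data frame (frame, time_min, strain, stress_Pa, force_nN,
#'   direction).
#' @export
force_table <- function(force) {
  data.frame(frame = seq_along(force$force_nN),
             time_min = force$time_min,
             strain = force$strain,
             stress_Pa = force$stress_Pa,
             force_nN = force$force_nN,
             direction = force$direction)
}

#' Choose a wall-adjacent / far speckle pair for strain analysis
#'
#' The pairwise-distance strain needs one speckle next to the deforming
#' wall and one near the clamped boundary, both close to the same axial
#' position so they experience the same contact envelope. Returns the two
#' row indices of `speckles0` (the generator's initial speckle table) best
#' matching that geometry on one side of the track.
#'
#' @param truth a `ground_truth` object from [generate_stack()].
#' @param x_ref axial position of interest (defaults to the scene's
#'   reference position).
#' @param axial_tol maximum |x - x_ref| in micrometres.
#' @param near_range admissible wall distance of the near speckle (um).
#'   The lower bound keeps the tracking template clear of the moving track
#'   edge; the upper bound keeps the speckle in the strongly displaced
#'   zone.
#' @param far_range admissible wall distance of the far speckle as a
#'   fraction of the clamp distance.
#' @param iso_min minimum nearest-neighbour distance (um); isolated
#'   speckles are less likely to be confused with a neighbour during
#'   template tracking.
#' @return List with `near` and `far` rows of `speckles0`.
#' @export
select_strain_pair <- function(truth, x_ref = truth$scene$x_ref,
                               axial_tol = 3, near_range = c(3, 6),
                               far_range = c(0.85, 1.0), iso_min = 2) {
  sp <- truth$speckles0
  if (!is.null(sp$nn_um) && any(sp$nn_um >= iso_min))
    sp <- sp[sp$nn_um >= iso_min, , drop = FALSE]
  L <- truth$scene$clamp_distance
  best <- NULL
  for (sd_side in c(1, -1)) {
    cand <- sp[sp$side == sd_side & abs(sp$x_um - x_ref) <= axial_tol, ,
               drop = FALSE]
    near <- cand[cand$dist_wall_um >= near_range[1] &
                 cand$dist_wall_um <= near_range[2], , drop = FALSE]
    far <- cand[cand$dist_wall_um >= far_range[1] * L &
                cand$dist_wall_um <= far_range[2] * L, , drop = FALSE]
    if (nrow(near) && nrow(far)) {
      # the near speckle dominates the measured strain: keep it as close to
      # x_ref as possible so it sees the full contact envelope; the far
      # speckle barely moves, so push it toward the clamp
      ni <- which.min(abs(near$x_um - x_ref))
      fi <- which.max(far$dist_wall_um)
      score <- abs(near$x_um[ni] - x_ref)
      if (is.null(best) || score < best$score)
        best <- list(near = near[ni, ], far = far[fi, ], score = score)
    }
  }
  if (is.null(best))
    stop("no admissible speckle pair near x_ref; increase speckle_density ",
         "or axial_tol")
  best[c("near", "far")]
}

#' Select several wall-adjacent / far speckle pairs
#'
#' Like [select_strain_pair()] but returns up to `max_pairs` pairs (near
#' speckles ordered by axial distance from `x_ref`, each paired with the
#' most clamp-ward far speckle on its side), enabling a robust median over
#' per-pair force estimates.
#'
#' @inheritParams select_strain_pair
#' @param max_pairs maximum number of pairs returned.
#' @return List of `list(near =, far =)` pairs (possibly empty).
#' @export
select_strain_pairs <- function(truth, x_ref = truth$scene$x_ref,
                                axial_tol = 10, near_range = c(3, 12),
                                far_range = c(0.85, 1.0), iso_min = 2,
                                max_pairs = 7) {
  sp <- truth$speckles0
  if (!is.null(sp$nn_um) && any(sp$nn_um >= iso_min))
    sp <- sp[sp$nn_um >= iso_min, , drop = FALSE]
  L <- truth$scene$clamp_distance
  pairs <- list()
  for (sd_side in c(1, -1)) {
    cand <- sp[sp$side == sd_side & abs(sp$x_um - x_ref) <= axial_tol, ,
               drop = FALSE]
    near <- cand[cand$dist_wall_um >= near_range[1] &
                 cand$dist_wall_um <= near_range[2], , drop = FALSE]
    far <- cand[cand$dist_wall_um >= far_range[1] * L &
                cand$dist_wall_um <= far_range[2] * L, , drop = FALSE]
    if (!nrow(near) || !nrow(far)) next
    near <- near[order(abs(near$x_um - x_ref)), , drop = FALSE]
    for (i in seq_len(nrow(near))) {
      # each near speckle gets its own axially closest clamp-ward anchor,
      # so one mistracked far speckle cannot corrupt every pair
      fi <- which.min(abs(far$x_um - near$x_um[i]) - far$dist_wall_um / L)
      pairs[[length(pairs) + 1]] <- list(near = near[i, ], far = far[fi, ])
    }
  }
  if (length(pairs) > max_pairs) {
    ord <- order(vapply(pairs, function(p) abs(p$near$x_um - x_ref),
                        numeric(1)))
    pairs <- pairs[ord[seq_len(max_pairs)]]
  }
  pairs
}

#' Recover the peak wall force of a rendered scene end to end
#'
#' Validation harness running the full pipeline on a generated scene:
#' stabilization, filtering (spatial-only on the reflection channel, since
#' temporal averaging smears fast wall motion and would bias tracked
#' displacements low), NCC speckle tracking of several wall-adjacent / far
#' pairs, pairwise-distance strain, and the linear elastic force
#' conversion. The per-pair peak forces are combined by their median,
#' which is robust to an occasional speckle mismatch in dense fields.
#'
#' @param generated a `list(stack, truth)` from [generate_stack()].
#' @param template_px template size passed to [track_speckles()].
#' @param max_pairs maximum number of speckle pairs used.
#' @return List: `peak_force_nN` (median over pairs), `pair_peaks_nN`,
#'   `n_pairs`, `forces` (per-pair `force_series`).
#' @export
recover_wall_force <- function(generated, template_px = 11, max_pairs = 5) {
  sc <- generated$truth$scene
  st <- stabilize(generated$stack)
  pp <- preprocess(st$stack, refl_t = 0)
  pairs <- select_strain_pairs(generated$truth)
  if (!length(pairs))
    stop("no admissible speckle pair; increase speckle_density")
  ids <- unique(unlist(lapply(pairs, function(p) c(p$near$object_id,
                                                   p$far$object_id))))
  seeds <- seed_positions(generated$truth, ids)
  # no ensemble refinement here: averaging matched windows into the
  # template assumes a locally rigid neighbourhood, which the strongly
  # compressed near-wall collagen violates; the sub-pixel noise this
  # forgoes is negligible against the ~10 um displacement baseline
  trs <- track_speckles(pp, seeds, template_px = template_px,
                        search_px = suggested_search_px(sc), refine = FALSE)
  names(trs) <- ids
  model <- elastic_model(sc$youngs_modulus, sc$contact_area)
  forces <- lapply(pairs, function(p) {
    compute_force(compute_strain(trs[[p$near$object_id]],
                                 trs[[p$far$object_id]]), model)
  })
  peaks <- vapply(forces, peak_force, numeric(1))
  list(peak_force_nN = stats::median(peaks), pair_peaks_nN = peaks,
       n_pairs = length(peaks), forces = forces)
}

#' Frame-1 seed positions for a set of speckles
#'
#' Tracking seeds must be where the speckles appear in the first frame. A
#' cell already in wall contact at the start of the movie has displaced
#' the collagen around its initial position, so the generator's sampling
#' positions (`speckles0`) are not valid seeds there; the ground-truth
#' trajectories at frame 1 are.
#'
#' @param truth a `ground_truth` object from [generate_stack()].
#' @param object_ids speckle identifiers.
#' @return Data frame (object_id, x_um, y_um) in the requested order.
#' @export
seed_positions <- function(truth, object_ids) {
  t1 <- truth$trajectories[truth$trajectories$frame == 1 &
                           truth$trajectories$object_id %in% object_ids,
                           c("object_id", "x_um", "y_um")]
  t1[match(object_ids, t1$object_id), ]
}

#' Search radius covering the fastest per-frame speckle motion of a scene
#'
#' The largest frame-to-frame wall displacement increment is bounded by
#' `d_peak * (pi / contact_length) * cell_speed * frame_interval` (the peak
#' slope of the raised-cosine envelope times the axial advance per frame).
#'
#' @param sc a [scene()].
#' @param margin extra pixels on top of the bound.
#' @return Integer search radius in pixels (at least 10).
#' @export
suggested_search_px <- function(sc, margin = 3) {
  dmax <- scene_d_peak(sc) * pi / sc$contact_length *
    sc$cell_speed * sc$frame_interval
  max(10L, as.integer(ceiling(dmax / sc$pixel_size)) + margin)
}
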