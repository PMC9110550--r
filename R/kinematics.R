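#' Point trajectory of a tracked object
#'
#' @param x_um,y_um per-frame coordinates in micrometres.
#' @param frame_interval minutes between frames.
#' @param role one of `"leading"`, `"nucleus"`, `"rear"`, `"centroid"`.
#' @param object_id identifier.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(x_um, y_um, frame_interval = 4,
                       role = c("centroid", "leading", "nucleus", "rear"),
                       object_id = "cell_1") {
  role <- match.arg(role)
  if (length(x_um) != length(y_um)) stop("x_um and y_um differ in length")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(list(x_um = x_um, y_um = y_um,
                 frame_interval = frame_interval,
                 role = role, object_id = object_id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (%s), %d frames @ %g min\n",
              x$object_id, x$role, length(x$x_um), x$frame_interval))
  invisible(x)
}

step_lengths <- function(traj) {
  sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)
}

#' Mean migration speed including stop phases
#'
#' Total path length divided by total elapsed time; stationary frames
#' contribute zero path but full time, so pauses lower the mean speed
#' rather than being excluded.
#'
#' @param traj a [trajectory()] with at least two frames.
#' @return Speed in micrometres per minute.
#' @export
compute_speed <- function(traj) {
  n <- length(traj$x_um)
  if (n < 2) stop("speed is undefined for a single-frame trajectory")
  sum(step_lengths(traj)) / ((n - 1) * traj$frame_interval)
}

#' Directional persistence as path length over beeline
#'
#' Total path length divided by the start-to-end straight-line distance
#' (beeline). Equals 1 for perfectly straight motion and grows with
#' backtracking. When the beeline is at or below `epsilon_um` (a returned
#' cell), the ratio diverges and the result is flagged undefined instead
#' of reporting a number.
#'
#' @param traj a [trajectory()].
#' @param epsilon_um smallest beeline for which the ratio is reported.
#' @return List with `value` (NA when undefined), `defined`, `path_um`,
#'   `beeline_um`.
#' @export
compute_persistence <- function(traj, epsilon_um = 1) {
  n <- length(traj$x_um)
  if (n < 2) stop("persistence is undefined for a single-frame trajectory")
  path <- sum(step_lengths(traj))
  bee <- sqrt((traj$x_um[n] - traj$x_um[1])^2 +
              (traj$y_um[n] - traj$y_um[1])^2)
  if (bee <= epsilon_um)
    return(list(value = NA_real_, defined = FALSE,
                path_um = path, beeline_um = bee,
                reason = "returned cell (beeline below threshold)"))
  list(value = path / bee, defined = TRUE, path_um = path, beeline_um = bee)
}

check_shared_base <- function(...) {
  trs <- list(...)
  n <- unique(vapply(trs, function(t) length(t$x_um), integer(1)))
  dt <- unique(vapply(trs, function(t) t$frame_interval, numeric(1)))
  if (length(n) != 1 || length(dt) != 1)
    stop("trajectories must share frame count and frame interval")
  invisible(n)
}

#' Cell length over time from leading-edge and rear trajectories
#'
#' @param leading,rear [trajectory()] objects with roles `"leading"` and
#'   `"rear"` on a shared time base.
#' @return List with `length_um` (per frame), `time_min`, `mean_um`.
#' @export
cell_length_series <- function(leading, rear) {
  if (leading$role != "leading" || rear$role != "rear")
    stop("roles must be 'leading' and 'rear'")
  n <- check_shared_base(leading, rear)
  len <- sqrt((leading$x_um - rear$x_um)^2 + (leading$y_um - rear$y_um)^2)
  list(length_um = len, time_min = (seq_len(n) - 1) * leading$frame_interval,
       mean_um = mean(len))
}

#' Relative nuclear position along the cell axis
#'
#' Projects the nucleus centre onto the rear-to-leading axis and expresses
#' it as a percentage of cell length (0 = rear, 100 = leading edge),
#' clipped to that range so off-axis excursions cannot leave it. Frames
#' with zero cell length are skipped and counted. The cell is flagged as
#' rear-nucleated when the mean position falls below `rear_threshold_pct`.
#'
#' @param leading,nucleus,rear [trajectory()] objects on a shared time
#'   base with matching roles.
#' @param rear_threshold_pct rear-nucleus classification threshold (% of
#'   cell length).
#' @return List with `position_pct` (per frame, NA for skipped frames),
#'   `mean_pct`, `rear_nucleus_flag`, `skipped_frames`.
#' @export
nuclear_position_series <- function(leading, nucleus, rear,
                                    rear_threshold_pct = 30) {
  if (leading$role != "leading" || nucleus$role != "nucleus" ||
      rear$role != "rear")
    stop("roles must be 'leading', 'nucleus', 'rear'")
  n <- check_shared_base(leading, nucleus, rear)
  ux <- leading$x_um - rear$x_um
  uy <- leading$y_um - rear$y_um
  len <- sqrt(ux^2 + uy^2)
  pos <- rep(NA_real_, n)
  ok <- len > 0
  proj <- ((nucleus$x_um - rear$x_um) * ux +
           (nucleus$y_um - rear$y_um) * uy)[ok] / len[ok]
  pos[ok] <- pmin(pmax(100 * proj / len[ok], 0), 100)
  mp <- mean(pos, na.rm = TRUE)
  list(position_pct = pos, mean_pct = mp,
       rear_nucleus_flag = mp < rear_threshold_pct,
       skipped_frames = sum(!ok))
}

#' Per-cell migration metrics in one table
#'
#' @param leading,nucleus,rear [trajectory()] objects on a shared time
#'   base.
#' @param rear_threshold_pct see [nuclear_position_series()].
#' @return One-row data frame: mean_speed_um_min (of the nucleus track),
#'   persistence, mean_cell_length_um, mean_nuclear_position_pct,
#'   rear_nucleus_flag.
#' @export
cell_metrics <- function(leading, nucleus, rear, rear_threshold_pct = 30) {
  pers <- compute_persistence(nucleus)
  npos <- nuclear_position_series(leading, nucleus, rear, rear_threshold_pct)
  data.frame(object_id = nucleus$object_id,
             mean_speed_um_min = compute_speed(nucleus),
             persistence = pers$value,
             persistence_defined = pers$defined,
             mean_cell_length_um = cell_length_series(leading, rear)$mean_um,
             mean_nuclear_position_pct = npos$mean_pct,
             rear_nucleus_flag = npos$rear_nucleus_flag)
}

#' Build role trajectories from a tidy trajectory table
#'
#' @param df data frame with columns `frame`, `object_id`, `role`, `x_um`,
#'   `y_um` (the generator's ground-truth format).
#' @param id object to extract.
#' @param frame_interval minutes between frames.
#' @return Named list of [trajectory()] objects, one per role present.
#' @export
trajectories_from_table <- function(df, id, frame_interval = 4) {
  sub <- df[df$object_id == id, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for object '", id, "'")
  out <- list()
  for (r in intersect(c("leading", "nucleus", "rear", "centroid"),
                      unique(sub$role))) {
    s <- sub[sub$role == r, , drop = FALSE]
    s <- s[order(s$frame), ]
    out[[r]] <- trajectory(s$x_um, s$y_um, frame_interval, role = r,
                           object_id = id)
  }
  out
}
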