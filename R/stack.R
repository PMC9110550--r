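#' Time-lapse image stack container
#'
#' Wraps a `T x C x Y x X` intensity array together with its physical
#' calibration (pixel size in micrometres per pixel, frame interval in
#' minutes) and the biological role of each channel.
#'
#' @param data numeric array with dimensions time, channel, y, x.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param frame_interval frame interval in minutes (> 0).
#' @param channel_roles character vector, one role per channel, values in
#'   `"reflection"`, `"cytoplasm"`, `"nucleus"`.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(data, pixel_size, frame_interval,
                            channel_roles = c("reflection", "cytoplasm", "nucleus")) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (dim(data)[1] < 1L) stop("stack must contain at least one frame")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  if (length(channel_roles) != dim(data)[2])
    stop("channel_roles must name every channel")
  bad <- setdiff(channel_roles, c("reflection", "cytoplasm", "nucleus"))
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  structure(list(data = data,
                 pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_roles = channel_roles),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<timelapse_stack> %d frames, %d channels (%s), %d x %d px\n",
              d[1], d[2], paste(x$channel_roles, collapse = ", "), d[3], d[4]))
  cat(sprintf("  pixel size %.3g um/px, frame interval %.3g min\n",
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.timelapse_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1]

#' Index of the channel carrying a given role
#'
#' @param stack a [timelapse_stack()].
#' @param role one of `"reflection"`, `"cytoplasm"`, `"nucleus"`.
#' @return Integer channel index.
#' @export
channel_index <- function(stack, role) {
  i <- match(role, stack$channel_roles)
  if (is.na(i)) stop("stack has no channel with role '", role, "'")
  i
}

#' Extract one channel of one frame as a Y x X matrix
#'
#' @inheritParams channel_index
#' @param frame frame index (1-based).
#' @return Numeric matrix (rows = y, columns = x).
#' @export
get_frame <- function(stack, frame, role = "reflection") {
  if (frame < 1 || frame > n_frames(stack)) stop("frame index out of range")
  stack$data[frame, channel_index(stack, role), , ]
}

#' Write a stack as a multi-page TIFF plus a config echo
#'
#' Pages are ordered frame-major (frame 1 channels, then frame 2, ...). The
#' calibration and channel roles are echoed to a YAML side-car so the stack
#' can be re-read without guessing.
#'
#' @param stack a [timelapse_stack()].
#' @param path output TIFF path.
#' @param config_path YAML side-car path; default `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, config_path = paste0(path, ".yaml")) {
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) {
    m <- stack$data[t, c, , ]
    pages[[k]] <- pmin(pmax(m, 0), 1)
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(n_frames = d[1], n_channels = d[2],
                        ny = d[3], nx = d[4],
                        pixel_size_um = stack$pixel_size,
                        frame_interval_min = stack$frame_interval,
                        channel_roles = as.list(stack$channel_roles)),
                   config_path)
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#'
#' @param path TIFF path.
#' @param config_path YAML side-car path; default `<path>.yaml`.
#' @return A [timelapse_stack()].
#' @export
read_stack_tiff <- function(path, config_path = paste0(path, ".yaml")) {
  cfg <- yaml::read_yaml(config_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(cfg$n_frames, cfg$n_channels, cfg$ny, cfg$nx))
  k <- 1L
  for (t in seq_len(cfg$n_frames)) for (c in seq_len(cfg$n_channels)) {
    arr[t, c, , ] <- pages[[k]]
    k <- k + 1L
  }
  timelapse_stack(arr, cfg$pixel_size_um, cfg$frame_interval_min,
                  unlist(cfg$channel_roles))
}
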