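#' Phase-correlation shift between two images
#'
#' Translation-only registration in the Fourier domain: the whitened
#' cross-power spectrum of the mean-subtracted images, attenuated by a
#' Gaussian low-pass weight, is inverted to a correlation surface; the
#' integer peak is refined on an upsampled local DFT grid (default
#' 1/20 px) and a final parabolic fit gives the sub-pixel optimum.
#'
#' Whitening makes the estimate track the globally consistent translation
#' of the static speckle field rather than the highest-energy structure —
#' essential when part of the scene (the track and its walls) deforms
#' while only stage drift should be measured. The low-pass weight
#' suppresses the noise-dominated high frequencies that whitening would
#' otherwise amplify. `spectrum = "cross"` gives plain cross-correlation
#' (marginally more precise on strictly rigid scenes, but badly misled by
#' local deformations).
#'
#' Returns `c(dy, dx)` such that `img` equals `ref` translated by
#' `(dy, dx)` pixels; translating `img` by `-(dy, dx)` aligns it to `ref`.
#'
#' @param ref,img numeric matrices of identical size.
#' @param upsample sub-pixel refinement factor.
#' @param spectrum `"phase"` (whitened cross-power spectrum, default) or
#'   `"cross"` (plain cross-correlation).
#' @param lowpass_sigma Gaussian low-pass width in cycles per pixel
#'   applied to the whitened spectrum; 0 disables.
#' @return Numeric `c(dy, dx)` in pixels.
#' @export
phase_correlation_shift <- function(ref, img, upsample = 20,
                                    spectrum = c("phase", "cross"),
                                    lowpass_sigma = 0.15) {
  stopifnot(all(dim(ref) == dim(img)))
  spectrum <- match.arg(spectrum)
  if (stats::sd(ref) == 0 || stats::sd(img) == 0) {
    res <- c(0, 0)
    attr(res, "flat") <- TRUE
    return(res)
  }
  n <- nrow(ref); m <- ncol(ref)
  R <- stats::fft(ref - mean(ref)) * Conj(stats::fft(img - mean(img)))
  if (spectrum == "phase") {
    R <- R / pmax(Mod(R), 1e-12)
    if (lowpass_sigma > 0) {
      fy <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1)) / n
      fx <- c(0:(ceiling(m / 2) - 1), -(floor(m / 2):1)) / m
      R <- R * exp(-outer(fy^2, fx^2, "+") / (2 * lowpass_sigma^2))
    }
  }
  cc <- Re(stats::fft(R, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  dy <- pk[1] - 1; dx <- pk[2] - 1
  if (dy > n / 2) dy <- dy - n
  if (dx > m / 2) dx <- dx - m
  # local upsampled inverse DFT around the integer peak
  ky <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  kx <- c(0:(ceiling(m / 2) - 1), -(floor(m / 2):1))
  step <- 1 / upsample
  ys <- seq(dy - 1, dy + 1, by = step)
  xs <- seq(dx - 1, dx + 1, by = step)
  Ky <- exp(2i * pi * outer(ky, ys) / n)
  Kx <- exp(2i * pi * outer(kx, xs) / m)
  ccu <- Re(t(Ky) %*% R %*% Kx)
  pu <- arrayInd(which.max(ccu), dim(ccu))
  dyu <- ys[pu[1]]; dxu <- xs[pu[2]]
  # parabolic polish on the fine grid (interior peaks only)
  if (pu[1] > 1 && pu[1] < length(ys)) {
    v <- ccu[(pu[1] - 1):(pu[1] + 1), pu[2]]
    den <- v[1] - 2 * v[2] + v[3]
    if (den < 0) dyu <- dyu + step * 0.5 * (v[1] - v[3]) / den
  }
  if (pu[2] > 1 && pu[2] < length(xs)) {
    v <- ccu[pu[1], (pu[2] - 1):(pu[2] + 1)]
    den <- v[1] - 2 * v[2] + v[3]
    if (den < 0) dxu <- dxu + step * 0.5 * (v[1] - v[3]) / den
  }
  # fft peak at +s means img displaced by -s relative to ref; flip to the
  # "img = ref translated by (dy,dx)" convention
  -c(dyu, dxu)
}

#' Translate an image by a (sub-pixel) offset
#'
#' Content moves by `(dy, dx)` pixels; bilinear interpolation, replicated
#' edges.
#'
#' @param img numeric matrix.
#' @param dy,dx translation in pixels (row, column).
#' @return Translated matrix of the same size.
#' @export
translate_image <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  bilinear_sample(img,
                  py = outer(seq_len(ny) - dy, rep(1, nx)),
                  px = outer(rep(1, ny), seq_len(nx) - dx))
}

# bilinear interpolation at (possibly matrix-valued) pixel coordinates,
# clamped to the image domain
bilinear_sample <- function(img, py, px) {
  ny <- nrow(img); nx <- ncol(img)
  py <- pmin(pmax(py, 1), ny); px <- pmin(pmax(px, 1), nx)
  y0 <- pmin(floor(py), ny - 1); x0 <- pmin(floor(px), nx - 1)
  fy <- as.vector(py - y0); fx <- as.vector(px - x0)
  y0v <- as.vector(y0); x0v <- as.vector(x0)
  v <- (1 - fy) * (1 - fx) * img[cbind(y0v, x0v)] +
       fy * (1 - fx) * img[cbind(y0v + 1, x0v)] +
       (1 - fy) * fx * img[cbind(y0v, x0v + 1)] +
       fy * fx * img[cbind(y0v + 1, x0v + 1)]
  if (is.matrix(py)) matrix(v, nrow(py), ncol(py)) else v
}

#' Stabilize a stack against translational drift
#'
#' Registers every frame's reflection channel to a reference frame by phase
#' correlation and applies the (single, shared) per-frame translation to all
#' channels. Flat (zero-variance) frames get a zero shift and a warning
#' flag.
#'
#' @param stack a [timelapse_stack()].
#' @param reference_frame frame all others are registered to.
#' @return List with `stack` (stabilized), `shifts` (T x 2 matrix of
#'   `(dy, dx)` pixel shifts of each frame relative to the reference) and
#'   `flat` (logical flags).
#' @export
stabilize <- function(stack, reference_frame = 1L) {
  nt <- n_frames(stack)
  if (reference_frame < 1 || reference_frame > nt)
    stop("reference_frame out of range")
  ref <- get_frame(stack, reference_frame, "reflection")
  shifts <- matrix(0, nt, 2, dimnames = list(NULL, c("dy", "dx")))
  flat <- logical(nt)
  out <- stack$data
  for (t in seq_len(nt)) {
    if (t != reference_frame) {
      s <- phase_correlation_shift(ref, get_frame(stack, t, "reflection"))
      flat[t] <- isTRUE(attr(s, "flat"))
      shifts[t, ] <- s
      if (any(s != 0))
        for (c in seq_len(dim(stack$data)[2]))
          out[t, c, , ] <- translate_image(stack$data[t, c, , ], -s[1], -s[2])
    }
  }
  if (any(flat)) warning("flat frame(s) encountered; zero shift applied")
  res <- stack
  res$data <- out
  list(stack = res, shifts = shifts, flat = flat)
}

# median filter one frame via EBImage, tolerating intensities outside [0,1]
median_filter_frame <- function(m, size) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) return(m)
  f <- EBImage::medianFilter((m - lo) / (hi - lo), size = size)
  as.matrix(f) * (hi - lo) + lo
}

#' Apply the standard channel filtering recipe
#'
#' Fluorescence channels (cytoplasm, nucleus) are spatially median-filtered
#' (radius `fluor_radius` px); the reflection channel is spatiotemporally
#' mean-filtered over a window of +/- `refl_xy` px in x,y and +/- `refl_t`
#' frames in time, with truncated windows at the first/last frames.
#'
#' @param stack a [timelapse_stack()].
#' @param fluor_radius median filter radius for fluorescence channels (px).
#' @param refl_xy spatial mean half-window for the reflection channel (px).
#' @param refl_t temporal mean half-window for the reflection channel
#'   (frames).
#' @return Filtered [timelapse_stack()] of identical shape.
#' @export
preprocess <- function(stack, fluor_radius = 2, refl_xy = 1, refl_t = 2) {
  nt <- n_frames(stack)
  out <- stack$data
  for (c in seq_along(stack$channel_roles)) {
    if (stack$channel_roles[c] == "reflection") {
      k <- 2 * refl_xy + 1
      kern <- matrix(1 / k^2, k, k)
      sp <- array(0, dim = dim(stack$data)[c(1, 3, 4)])
      for (t in seq_len(nt))
        sp[t, , ] <- as.matrix(EBImage::filter2(stack$data[t, c, , ], kern,
                                                boundary = "replicate"))
      for (t in seq_len(nt)) {
        win <- max(1, t - refl_t):min(nt, t + refl_t)
        out[t, c, , ] <- apply(sp[win, , , drop = FALSE], c(2, 3), mean)
      }
    } else {
      for (t in seq_len(nt))
        out[t, c, , ] <- median_filter_frame(stack$data[t, c, , ],
                                             size = fluor_radius)
    }
  }
  res <- stack
  res$data <- out
  res
}

#' Position-versus-time kymograph along a polyline
#'
#' Samples intensity along a polyline (bilinear interpolation) in every
#' frame. The reflection channel is median-prefiltered (radius
#' `prefilter_radius` px) before sampling, matching the usual workflow for
#' speckled reflection data.
#'
#' @param stack a [timelapse_stack()].
#' @param line numeric matrix with columns `x_um`, `y_um`: polyline
#'   vertices in micrometres (a single row gives a one-sample kymograph).
#' @param channel channel role to sample.
#' @param prefilter_radius median prefilter radius in px (reflection only;
#'   0 disables).
#' @param spacing sample spacing along the line in micrometres; defaults to
#'   the pixel size.
#' @return Object of class `kymograph`: `data` (position x time matrix),
#'   `positions_um` (arc length of each sample), `line`, `channel`.
#' @export
kymograph <- function(stack, line, channel = "reflection",
                      prefilter_radius = 4, spacing = stack$pixel_size) {
  line <- as.matrix(line)
  if (ncol(line) != 2) stop("line must have two columns (x_um, y_um)")
  psz <- stack$pixel_size
  ny <- dim(stack$data)[3]; nx <- dim(stack$data)[4]
  if (any(line[, 1] < 0) || any(line[, 1] > nx * psz) ||
      any(line[, 2] < 0) || any(line[, 2] > ny * psz))
    stop("polyline outside image bounds")
  pts <- sample_polyline(line, spacing)
  px <- pts[, 1] / psz + 0.5
  py <- pts[, 2] / psz + 0.5
  nt <- n_frames(stack)
  kg <- matrix(0, nrow(pts), nt)
  ci <- channel_index(stack, channel)
  for (t in seq_len(nt)) {
    fr <- stack$data[t, ci, , ]
    if (channel == "reflection" && prefilter_radius > 0)
      fr <- median_filter_frame(fr, size = prefilter_radius)
    kg[, t] <- bilinear_sample(fr, py, px)
  }
  structure(list(data = kg, positions_um = attr(pts, "arclen"),
                 line = line, channel = channel,
                 frame_interval = stack$frame_interval),
            class = "kymograph")
}

sample_polyline <- function(line, spacing) {
  if (nrow(line) == 1) {
    out <- line
    attr(out, "arclen") <- 0
    return(out)
  }
  seg <- diff(line)
  seglen <- sqrt(rowSums(seg^2))
  total <- sum(seglen)
  s <- seq(0, total, by = spacing)
  cum <- c(0, cumsum(seglen))
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(line) - 1)
  f <- (s - cum[idx]) / pmax(seglen[idx], 1e-12)
  out <- line[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * f
  attr(out, "arclen") <- s
  out
}

#' Measure track width from a transverse reflection profile
#'
#' Averages the reflection intensity over a small axial window, locates the
#' track as the longest contiguous run below the 50% level between the
#' robust track floor (mean of the lowest profile values) and collagen
#' plateau (95th percentile), and interpolates both edges to sub-pixel
#' positions. The
#' criterion is relative, so the result is invariant to global intensity
#' scaling.
#'
#' @param stack a [timelapse_stack()].
#' @param axial_position axial (x) position in micrometres.
#' @param frame frame index.
#' @param axial_window axial averaging window in micrometres.
#' @param contrast_min minimum relative floor-to-plateau contrast below
#'   which the profile is declared trackless.
#' @return Object of class `track_width`: `width_um` (NA when no track was
#'   found), `found`, `edges_um`, `threshold`, `floor`, `plateau`.
#' @export
measure_track_width <- function(stack, axial_position, frame,
                                axial_window = 2, contrast_min = 0.3) {
  psz <- stack$pixel_size
  img <- get_frame(stack, frame, "reflection")
  x_um <- (seq_len(ncol(img)) - 0.5) * psz
  cols <- which(abs(x_um - axial_position) <= axial_window / 2)
  if (!length(cols)) cols <- which.min(abs(x_um - axial_position))
  profile <- rowMeans(img[, cols, drop = FALSE])
  y_um <- (seq_len(length(profile)) - 0.5) * psz
  # floor: mean of the lowest profile values (a narrow track can occupy
  # well under 5% of the transverse profile, which would defeat a
  # percentile floor); plateau: robust 95th percentile of the collagen
  flo <- mean(sort(profile)[1:3])
  pla <- stats::quantile(profile, 0.95, names = FALSE)
  no_track <- function() structure(list(width_um = NA_real_, found = FALSE,
                                        edges_um = c(NA_real_, NA_real_),
                                        threshold = NA_real_, floor = flo,
                                        plateau = pla), class = "track_width")
  if ((pla - flo) < contrast_min * max(abs(pla), 1e-12)) return(no_track())
  thr <- (flo + pla) / 2
  below <- profile < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= 2)
  if (!length(runs)) return(no_track())
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  left <- if (i0 > 1) {
    f <- (profile[i0 - 1] - thr) / (profile[i0 - 1] - profile[i0])
    y_um[i0 - 1] + f * psz
  } else y_um[i0]
  right <- if (i1 < length(profile)) {
    f <- (thr - profile[i1]) / (profile[i1 + 1] - profile[i1])
    y_um[i1] + f * psz
  } else y_um[i1]
  structure(list(width_um = right - left, found = TRUE,
                 edges_um = c(left, right), threshold = thr,
                 floor = flo, plateau = pla), class = "track_width")
}

#' @export
print.track_width <- function(x, ...) {
  if (x$found) cat(sprintf("<track_width> %.2f um (edges %.2f-%.2f um)\n",
                           x$width_um, x$edges_um[1], x$edges_um[2]))
  else cat("<track_width> no track found\n")
  invisible(x)
}

#' Label width measurements by cell-passage phase and summarize
#'
#' Each (frame, axial position) width measurement is labelled `before`,
#' `during_single`, `during_collective`, or `after` depending on whether a
#' cell body (rear to leading edge) overlaps the position at that frame,
#' and on how many cells overlap simultaneously.
#'
#' @param widths data frame with columns `frame`, `position_um`,
#'   `width_um`.
#' @param cell_traj data frame with columns `frame`, `object_id`, `role`,
#'   `x_um` containing `leading` and `rear` rows per cell per frame (the
#'   format of the generator's ground-truth trajectories).
#' @return List with `labels` (input plus `phase`) and `summary`
#'   (mean, sd, n per phase).
#' @export
width_phase_summary <- function(widths, cell_traj) {
  need <- c("frame", "position_um", "width_um")
  if (!all(need %in% names(widths))) stop("widths lacks required columns")
  lead <- cell_traj[cell_traj$role == "leading", c("frame", "object_id", "x_um")]
  rear <- cell_traj[cell_traj$role == "rear", c("frame", "object_id", "x_um")]
  names(lead)[3] <- "lead_x"; names(rear)[3] <- "rear_x"
  span <- merge(lead, rear, by = c("frame", "object_id"))
  if (!nrow(span)) stop("cell_traj lacks leading/rear rows")
  phase <- character(nrow(widths))
  for (i in seq_len(nrow(widths))) {
    p <- widths$position_um[i]; f <- widths$frame[i]
    sp <- span[span$frame == f, , drop = FALSE]
    n_over <- sum(pmin(sp$rear_x, sp$lead_x) <= p &
                  p <= pmax(sp$rear_x, sp$lead_x))
    if (n_over >= 2) phase[i] <- "during_collective"
    else if (n_over == 1) phase[i] <- "during_single"
    else {
      # before first passage at this position, after the last
      sp_all <- span[pmin(span$rear_x, span$lead_x) <= p &
                     p <= pmax(span$rear_x, span$lead_x), , drop = FALSE]
      if (!nrow(sp_all)) phase[i] <- "before"
      else if (f < min(sp_all$frame)) phase[i] <- "before"
      else if (f > max(sp_all$frame)) phase[i] <- "after"
      else phase[i] <- "before"   # between passes: not yet transmigrated here
    }
  }
  out <- widths
  out$phase <- phase
  agg <- do.call(rbind, lapply(split(out$width_um, out$phase), function(v) {
    data.frame(mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v), n = sum(!is.na(v)))
  }))
  agg <- data.frame(phase = rownames(agg), agg, row.names = NULL)
  list(labels = out, summary = agg)
}
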