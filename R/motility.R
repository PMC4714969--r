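# Motility quantification: kymograph reslicing and peak-count ciliary beat
# frequency, Ca2+ front velocity from line scans, and bead-tracking
# velocimetry of cilia-driven flow.

#' Image stack
#'
#' A time series of intensity frames with physical scales.
#'
#' @param frames 3-D array (y, x, t) or list of matrices.
#' @param frame_interval_s Frame interval, s (> 0).
#' @param pixel_size_um Pixel size, um.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval_s, pixel_size_um) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2) {
    stop("`frames` must be a (y, x, t) array with >= 2 frames", call. = FALSE)
  }
  stopifnot_positive(frame_interval_s = frame_interval_s,
                     pixel_size_um = pixel_size_um)
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' Kymograph
#'
#' Position-along-line x time intensity matrix with physical scales.
#'
#' @param data Matrix, rows = positions along the line, cols = frames.
#' @param pixel_size_um Spacing of line samples, um.
#' @param frame_interval_s Frame interval, s.
#' @param line Optional polyline (n x 2 matrix of x, y in pixels) recorded
#'   for provenance.
#' @return Object of class `kymograph`.
#' @export
kymograph <- function(data, pixel_size_um, frame_interval_s, line = NULL) {
  if (!is.matrix(data) || nrow(data) < 2) {
    stop("kymograph needs a matrix with >= 2 line samples", call. = FALSE)
  }
  stopifnot_positive(pixel_size_um = pixel_size_um,
                     frame_interval_s = frame_interval_s)
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, line = line),
            class = "kymograph")
}

# sample points every ~1 px along a polyline given as n x 2 (x, y)
polyline_samples <- function(line) {
  seglen <- sqrt(rowSums(diff(line)^2))
  total <- sum(seglen)
  n <- max(2L, ceiling(total) + 1L)
  s <- seq(0, total, length.out = n)
  cum <- c(0, cumsum(seglen))
  xy <- t(vapply(s, function(si) {
    k <- max(1L, findInterval(si, cum, rightmost.closed = TRUE))
    k <- min(k, nrow(line) - 1L)
    f <- if (seglen[k] > 0) (si - cum[k]) / seglen[k] else 0
    line[k, ] + f * (line[k + 1L, ] - line[k, ])
  }, numeric(2)))
  list(xy = xy, spacing = total / (n - 1L))
}

#' Reslice an image stack along a line
#'
#' Samples intensity along a polyline (bilinear interpolation, ~1 px sample
#' spacing) in every frame, optionally averaging across `width_px` parallel
#' offsets perpendicular to the line, and stacks the profiles over time.
#' Mirrors the ImageJ "reslice" operation used to build beating-cilium
#' kymographs.
#'
#' @param stack An [image_stack()].
#' @param line n x 2 matrix of (x, y) pixel coordinates (1-based, pixel
#'   centres); a 2-point line is the common case.
#' @param width_px Odd number of parallel lines averaged (1 = plain sampling).
#' @return A [kymograph()]; its `pixel_size_um` reflects the line sample
#'   spacing.
#' @export
reslice_kymograph <- function(stack, line, width_px = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  line <- matrix(as.numeric(line), ncol = 2)
  d <- dim(stack$frames)
  if (any(line[, 1] < 1 | line[, 1] > d[2] | line[, 2] < 1 | line[, 2] > d[1])) {
    stop("line extends outside the image bounds", call. = FALSE)
  }
  ps <- polyline_samples(line)
  xy <- ps$xy
  # unit normal per sample (from overall line direction; adequate for the
  # near-straight lines used in practice)
  dirv <- colMeans(diff(line))
  dirv <- dirv / sqrt(sum(dirv^2))
  nrm <- c(-dirv[2], dirv[1])
  offsets <- seq_len(width_px) - (width_px + 1) / 2
  nt <- d[3]
  out <- matrix(0, nrow(xy), nt)
  for (f in seq_len(nt)) {
    img <- stack$frames[, , f]
    acc <- 0
    for (o in offsets) {
      xs <- pmin(pmax(xy[, 1] + o * nrm[1], 1), d[2])
      ys <- pmin(pmax(xy[, 2] + o * nrm[2], 1), d[1])
      acc <- acc + bilinear_sample(img, ys, xs)
    }
    out[, f] <- acc / width_px
  }
  kymograph(out, pixel_size_um = ps$spacing * stack$pixel_size_um,
            frame_interval_s = stack$frame_interval_s, line = line)
}

#' Ciliary beat frequency from a kymograph
#'
#' Integrates the kymograph along the position axis to a single intensity
#' trace, detects peaks (prominence at least `prominence_fraction` of the
#' window's amplitude, minimum spacing set by `max_frequency_Hz`), and
#' reports peaks per second in each requested window. A flat trace gives
#' 0 Hz with a `low_signal` flag.
#'
#' @param kymo A [kymograph()].
#' @param windows List of `(start_s, end_s)` pairs (default: the whole record).
#' @param prominence_fraction Peak prominence threshold as a fraction of the
#'   window's intensity amplitude.
#' @param max_frequency_Hz Frequency ceiling used to set the minimum peak
#'   spacing.
#' @return data.frame: `start_s`, `end_s`, `n_peaks`, `frequency_Hz`,
#'   `low_signal`.
#' @export
beat_frequency <- function(kymo, windows = NULL, prominence_fraction = 0.25,
                           max_frequency_Hz = 25) {
  stopifnot(inherits(kymo, "kymograph"))
  nt <- ncol(kymo$data)
  t <- (seq_len(nt) - 1L) * kymo$frame_interval_s
  if (is.null(windows)) windows <- list(c(0, nt * kymo$frame_interval_s))
  trace_full <- colSums(kymo$data)
  min_sep <- max(1L, floor(1 / (max_frequency_Hz * kymo$frame_interval_s)))
  rows <- lapply(windows, function(w) {
    if (w[1] < 0 || w[2] > nt * kymo$frame_interval_s + 1e-9 || w[2] <= w[1]) {
      stop("analysis window outside the record", call. = FALSE)
    }
    idx <- which(t >= w[1] & t < w[2])
    tr <- trace_full[idx]
    amp <- diff(range(tr))
    # frame-to-frame differences give a robust noise scale; a trace whose
    # total amplitude is within a few noise SDs of that carries no beat signal
    noise_sd <- stats::mad(diff(tr)) / sqrt(2)
    low <- amp <= max(8 * noise_sd, .Machine$double.eps^0.5 * max(1, abs(mean(tr))))
    npk <- if (low) 0L else {
      length(find_peaks(tr, min_prominence = prominence_fraction * amp,
                        min_separation = min_sep))
    }
    data.frame(start_s = w[1], end_s = w[2], n_peaks = npk,
               frequency_Hz = npk / (w[2] - w[1]), low_signal = low)
  })
  do.call(rbind, rows)
}

#' Ca2+ front velocity from a line-scan kymograph
#'
#' For a line scan running from the ciliary base toward the tip, finds per
#' position the first time the fluorescence change exceeds
#' `threshold_fraction` of that position's plateau change, then fits
#' position against crossing time by least squares over the distal analysis
#' span (default: the distal half). The slope is the apparent front
#' velocity; the crossing time at the tip minus the stimulus time is the
#' time-to-tip.
#'
#' @param linescan A [kymograph()] whose rows run base (row 1) to tip.
#' @param base_pos_um,tip_pos_um Physical positions bounding the cilium along
#'   the line; default the full row range.
#' @param threshold_fraction Fraction of the per-position plateau change.
#' @param distal_fraction Fraction of the base-tip span, measured from the
#'   tip, used for the velocity fit.
#' @param stimulus_time_s Uncaging time; if `NULL`, taken as the time of the
#'   maximum temporal derivative at the base row.
#' @return List of class `front_trace`: `positions_um`, `crossing_times_s`,
#'   `velocity_um_s`, `time_to_tip_s`, `unresolved` flag.
#' @export
front_velocity <- function(linescan, base_pos_um = NULL, tip_pos_um = NULL,
                           threshold_fraction = 0.5, distal_fraction = 0.5,
                           stimulus_time_s = NULL) {
  stopifnot(inherits(linescan, "kymograph"))
  k <- linescan$data
  np <- nrow(k); nt <- ncol(k)
  pos <- (seq_len(np) - 1L) * linescan$pixel_size_um
  t <- (seq_len(nt) - 1L) * linescan$frame_interval_s
  if (is.null(base_pos_um)) base_pos_um <- pos[1]
  if (is.null(tip_pos_um)) tip_pos_um <- pos[np]
  in_span <- pos >= base_pos_um & pos <= tip_pos_um
  base_row <- which.min(abs(pos - base_pos_um))
  if (is.null(stimulus_time_s)) {
    stimulus_time_s <- t[which.max(diff(k[base_row, ]))]
  }
  # per-position baseline (pre-stimulus) and plateau (final 20%)
  pre <- t < stimulus_time_s
  if (!any(pre)) pre <- seq_len(max(1L, floor(nt / 10)))
  plateau_idx <- seq.int(max(1L, ceiling(0.8 * nt)), nt)
  cross <- rep(NA_real_, np)
  reached <- logical(np)
  for (i in which(in_span)) {
    b <- mean(k[i, pre])
    plateau_dF <- mean(k[i, plateau_idx]) - b
    if (plateau_dF <= 0) next
    hit <- which(k[i, ] - b >= threshold_fraction * plateau_dF & t >= stimulus_time_s)
    if (length(hit)) {
      cross[i] <- t[hit[1]]
      reached[i] <- TRUE
    }
  }
  if (sum(reached) < 0.5 * sum(in_span)) {
    stop("plateau not reached at >= 50% of positions: insufficient signal",
         call. = FALSE)
  }
  distal <- in_span & reached &
    pos >= tip_pos_um - distal_fraction * (tip_pos_um - base_pos_um)
  spread <- diff(range(cross[distal]))
  # crossings confined to a single frame interval are quantization-limited
  unresolved <- spread <= linescan$frame_interval_s * (1 + 1e-9)
  velocity <- if (unresolved) {
    # all distal positions rise within one frame: only a lower bound exists
    (tip_pos_um - base_pos_um) / linescan$frame_interval_s
  } else {
    unname(stats::coef(stats::lm(pos[distal] ~ cross[distal]))[2])
  }
  tip_row <- which.min(abs(pos - tip_pos_um))
  structure(list(positions_um = pos[in_span & reached],
                 crossing_times_s = cross[in_span & reached],
                 velocity_um_s = velocity,
                 time_to_tip_s = cross[tip_row] - stimulus_time_s,
                 unresolved = unresolved,
                 stimulus_time_s = stimulus_time_s),
            class = "front_trace")
}

#' Link per-frame detections into bead tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking with a gate distance.
#' Tracks shorter than `min_length` frames (default 4) are discarded; the
#' number discarded is returned as an attribute.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (pixels), or a
#'   list of per-frame n x 2 matrices.
#' @param max_link_distance_px Gate: a detection farther than this from every
#'   open track ends those tracks and seeds a new one.
#' @param pixel_size_um,frame_interval_s Physical scales stored on each track.
#' @param min_length Minimum track length in frames.
#' @return List of `bead_track` objects (each: `frame_indices`, `x_px`,
#'   `y_px`, `pixel_size_um`, `frame_interval_s`); attribute `n_discarded`.
#' @export
track_beads <- function(detections, max_link_distance_px,
                        pixel_size_um = 1, frame_interval_s = 1,
                        min_length = 4L) {
  if (is.data.frame(detections)) {
    frames <- sort(unique(detections$frame))
    det <- lapply(frames, function(f) {
      as.matrix(detections[detections$frame == f, c("x", "y"), drop = FALSE])
    })
  } else {
    det <- lapply(detections, function(m) matrix(as.numeric(m), ncol = 2))
    frames <- seq_along(det)
  }
  active <- list()   # each: list(frames=, xy= matrix)
  done <- list()
  for (fi in seq_along(det)) {
    pts <- det[[fi]]
    n_pts <- if (is.null(pts)) 0L else nrow(pts)
    assigned_track <- rep(NA_integer_, n_pts)
    if (length(active) && n_pts) {
      last_xy <- t(vapply(active, function(tr) tr$xy[nrow(tr$xy), ], numeric(2)))
      # greedy: repeatedly take the globally closest (track, point) pair
      dmat <- outer(seq_len(nrow(last_xy)), seq_len(n_pts),
                    Vectorize(function(a, b) sqrt(sum((last_xy[a, ] - pts[b, ])^2))))
      dmat <- matrix(dmat, nrow = nrow(last_xy))
      free_tr <- rep(TRUE, nrow(dmat)); free_pt <- rep(TRUE, n_pts)
      repeat {
        dmat2 <- dmat
        dmat2[!free_tr, ] <- Inf; dmat2[, !free_pt] <- Inf
        m <- which.min(dmat2)
        if (!length(m) || !is.finite(dmat2[m])) break
        ij <- arrayInd(m, dim(dmat2))
        if (dmat2[m] > max_link_distance_px) break
        assigned_track[ij[2]] <- ij[1]
        free_tr[ij[1]] <- FALSE; free_pt[ij[2]] <- FALSE
      }
    }
    new_active <- list()
    # extend matched tracks
    if (length(active)) {
      for (ti in seq_along(active)) {
        pt <- which(assigned_track == ti)
        if (length(pt) == 1L) {
          tr <- active[[ti]]
          tr$frames <- c(tr$frames, frames[fi])
          tr$xy <- rbind(tr$xy, pts[pt, ])
          new_active[[length(new_active) + 1L]] <- tr
        } else {
          done[[length(done) + 1L]] <- active[[ti]]
        }
      }
    }
    # unmatched detections seed new tracks
    for (pi in seq_len(n_pts)) {
      if (is.na(assigned_track[pi])) {
        new_active[[length(new_active) + 1L]] <-
          list(frames = frames[fi], xy = matrix(pts[pi, ], ncol = 2))
      }
    }
    active <- new_active
  }
  done <- c(done, active)
  keep <- vapply(done, function(tr) length(tr$frames) >= min_length, logical(1))
  tracks <- lapply(done[keep], function(tr) {
    structure(list(frame_indices = tr$frames, x_px = tr$xy[, 1],
                   y_px = tr$xy[, 2], pixel_size_um = pixel_size_um,
                   frame_interval_s = frame_interval_s),
              class = "bead_track")
  })
  attr(tracks, "n_discarded") <- sum(!keep)
  tracks
}

#' Bead velocity from a track
#'
#' Pathwise speed: total path length divided by elapsed time (matching how
#' manual frame-by-frame tracking reports speeds). The end-to-end
#' displacement speed is also returned; for a stationary bead with
#' localisation jitter the pathwise estimate is biased upward by the expected
#' step length of the jitter, so the displacement speed is the robust choice
#' in that regime.
#'
#' @param track A `bead_track` from [track_beads()].
#' @return List: `velocity_um_s` (pathwise), `displacement_velocity_um_s`,
#'   `path_length_um`, `elapsed_s`.
#' @export
bead_velocity <- function(track) {
  stopifnot(inherits(track, "bead_track"))
  if (length(track$frame_indices) < 2) stop("track too short", call. = FALSE)
  dt <- diff(track$frame_indices) * track$frame_interval_s
  elapsed <- sum(dt)
  if (elapsed <= 0) stop("zero elapsed time in track", call. = FALSE)
  steps <- sqrt(diff(track$x_px)^2 + diff(track$y_px)^2) * track$pixel_size_um
  path <- sum(steps)
  disp <- sqrt((track$x_px[length(track$x_px)] - track$x_px[1])^2 +
               (track$y_px[length(track$y_px)] - track$y_px[1])^2) *
    track$pixel_size_um
  list(velocity_um_s = path / elapsed,
       displacement_velocity_um_s = disp / elapsed,
       path_length_um = path, elapsed_s = elapsed)
}

#' Summarise bead velocities per condition
#'
#' @param tracks List of `bead_track` objects.
#' @return data.frame: `n_beads`, `mean_velocity_um_s`, `sem_um_s`.
#' @export
summarize_bead_velocities <- function(tracks) {
  v <- vapply(tracks, function(tr) bead_velocity(tr)$velocity_um_s, numeric(1))
  data.frame(n_beads = length(v), mean_velocity_um_s = mean(v),
             sem_um_s = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
}
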