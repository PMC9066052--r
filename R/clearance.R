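# ER clearance: the ER volume inside the cell over time, detection of the
# clearance time as the largest decrease of that trace, a random-occurrence
# null for comparison with controls, and misaligned-chromosome distance
# traces with the rescue classification.

#' ER volume trace within the cell
#'
#' volume(t) = count(ER mask AND cell mask) x voxel volume (µm³).
#'
#' @param er_masks_t list of ER `mask3d` objects (or logical arrays), one
#'   per frame.
#' @param cell_mask `mask3d` (or logical array) defining the cell.
#' @param voxel_size µm voxel size (taken from the masks when present).
#' @param frame_interval minutes between frames.
#' @return class `volume_trace`: numeric volumes with frame metadata.
#' @export
er_volume_trace <- function(er_masks_t, cell_mask, voxel_size = NULL,
                            frame_interval = 1) {
  get_m <- function(m) if (inherits(m, "mask3d")) m$mask else m
  cm <- get_m(cell_mask)
  if (is.null(voxel_size))
    voxel_size <- if (inherits(cell_mask, "mask3d")) cell_mask$voxel_size
                  else if (inherits(er_masks_t[[1]], "mask3d")) er_masks_t[[1]]$voxel_size
                  else stopf("supply voxel_size")
  if (length(er_masks_t) < 3) stopf("need >= 3 frames")
  v <- vapply(er_masks_t, function(m) {
    mm <- get_m(m)
    if (!identical(dim(mm), dim(cm))) stopf("ER and cell mask shapes differ")
    sum(mm & cm) * prod(voxel_size)
  }, numeric(1))
  structure(list(volume_um3 = v, frame_interval = frame_interval),
            class = "volume_trace")
}

#' @export
print.volume_trace <- function(x, ...) {
  cat(sprintf("volume_trace: %d frames, %.1f -> %.1f µm³ (min %.1f)\n",
              length(x$volume_um3), x$volume_um3[1], tail(x$volume_um3, 1),
              min(x$volume_um3)))
  invisible(x)
}

# Frames at which the smoothed central-difference derivative is fully
# defined (median window and difference stencil both complete).
eligible_frames <- function(n, window = 3) {
  h <- (window - 1) / 2
  seq.int(2 + h, n - 1 - h)
}

#' Detect ER clearance as the largest decrease of the volume trace
#'
#' The trace is median-filtered (default window 3), differentiated by
#' central differences, and the clearance frame is the minimum (most
#' negative) derivative over the frames where the full stencil exists; ties
#' break to the earliest frame. The call is flagged significant when the
#' drop magnitude exceeds 3x the MAD of the derivative excluding the
#' neighbourhood of the minimum; the argmin is always reported so control
#' cells can be compared against the random-occurrence null.
#'
#' @param trace a [er_volume_trace()] result or numeric vector.
#' @param smoothing_window odd median-filter window (frames).
#' @param frame_interval minutes per frame (taken from the trace if present).
#' @return class `clearance_call`: list(frame, time_min, derivative,
#'   eligible, significant, drop, threshold).
#' @export
detect_clearance <- function(trace, smoothing_window = 3, frame_interval = NULL) {
  v <- if (inherits(trace, "volume_trace")) trace$volume_um3 else as.numeric(trace)
  if (is.null(frame_interval))
    frame_interval <- if (inherits(trace, "volume_trace")) trace$frame_interval else 1
  n <- length(v)
  if (n < 5) stopf("need >= 5 frames, got %d", n)
  sm <- if (smoothing_window > 1) stats::runmed(v, smoothing_window, endrule = "median") else v
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / 2
  elig <- eligible_frames(n, smoothing_window)
  k <- elig[which.min(d[elig])]
  rest <- setdiff(elig, (k - 1):(k + 1))
  drop <- -d[k]
  # noise scale from the raw (unsmoothed) derivative: the median filter
  # flattens the derivative away from real steps, which would deflate a
  # MAD taken on the smoothed derivative and inflate false positives
  d_raw <- (v[3:n] - v[1:(n - 2)]) / 2
  thr <- 3 * stats::mad(d_raw[rest - 1], center = 0)
  structure(list(frame = k, time_min = (k - 1) * frame_interval,
                 derivative = d, eligible = elig,
                 significant = length(rest) > 0 && drop > thr,
                 drop = drop, threshold = thr),
            class = "clearance_call")
}

#' @export
print.clearance_call <- function(x, ...) {
  cat(sprintf("clearance at frame %d (%g min); drop %.3g vs threshold %.3g -> %ssignificant\n",
              x$frame, x$time_min, x$drop, x$threshold,
              if (x$significant) "" else "NOT "))
  invisible(x)
}

#' Random-occurrence null for clearance detection times
#'
#' Simulates constant-volume traces with iid Gaussian noise, applies
#' [detect_clearance()], and returns the empirical distribution of detected
#' frames. On such no-event traces the detected minimum occurs at a random
#' frame; the analytic expectation is the uniform distribution over the
#' eligible frames, which is what the control-group comparison uses.
#'
#' @param n_frames frames per trace (>= 5).
#' @param n_cells number of simulated traces.
#' @param seed RNG seed.
#' @param sd Gaussian noise SD (e.g. estimated from the first differences of
#'   control traces).
#' @param baseline constant volume level.
#' @param smoothing_window passed to [detect_clearance()].
#' @return class `clearance_null`: list(times = detected frames,
#'   ecdf, eligible).
#' @export
null_clearance_distribution <- function(n_frames, n_cells, seed = 1L, sd = 1,
                                        baseline = 100, smoothing_window = 3) {
  if (n_frames < 5) stopf("n_frames must be >= 5")
  times <- with_seed(seed, vapply(seq_len(n_cells), function(i) {
    tr <- baseline + rnorm(n_frames, 0, sd)
    detect_clearance(tr, smoothing_window)$frame
  }, numeric(1)))
  structure(list(times = times, ecdf = stats::ecdf(times),
                 eligible = eligible_frames(n_frames, smoothing_window)),
            class = "clearance_null")
}

#' Kolmogorov distance of detection times from the discrete uniform null
#'
#' @param times detected frames.
#' @param eligible the eligible frame set.
#' @return sup-norm distance between the empirical CDF of `times` and the
#'   uniform CDF over `eligible`.
#' @export
ks_distance_uniform <- function(times, eligible) {
  Fhat <- stats::ecdf(times)
  Funi <- cumsum(rep(1 / length(eligible), length(eligible)))
  max(abs(Fhat(eligible) - Funi))
}

#' Misaligned-chromosome distance trace
#'
#' Per frame, the shortest Euclidean distance (µm) from the chromosome
#' centroid to the edge (6-connectivity surface voxels) of the main
#' chromosome mass, normalized to the starting distance. The trace
#' terminates when the chromosome merges with the plate or at the time
#' window (90 min).
#'
#' @param track chromosome data.frame from [link_objects()] (columns frame,
#'   x, y, z).
#' @param plate_masks_t list of plate masks (logical arrays or `mask3d`),
#'   one per frame.
#' @param voxel_size µm voxel size.
#' @param frame_interval minutes per frame.
#' @param congression_frame merge frame (NA if never), e.g. from
#'   [detect_congression()].
#' @param window_min track termination window in minutes.
#' @return class `misalignment_trace`: data.frame (frame, minutes,
#'   distance_um, normalized) plus termination frame and reason
#'   ("merged" or "window_end").
#' @export
misalignment_trace <- function(track, plate_masks_t, voxel_size, frame_interval,
                               congression_frame = NA, window_min = 90) {
  get_m <- function(m) if (inherits(m, "mask3d")) m$mask else m
  surface_dist <- function(mask, pt) {
    er <- erode3d(mask, rbind(diag(3), -diag(3)))
    idx <- which(mask & !er, arr.ind = TRUE)
    if (!nrow(idx)) idx <- which(mask, arr.ind = TRUE)
    um <- sweep(sweep(idx - 1, 2, voxel_size, `*`), 2, pt)
    sqrt(min(rowSums(um^2)))
  }
  inside_mask <- function(mask, pt) {
    idx <- round(pt / voxel_size) + 1
    all(idx >= 1) && all(idx <= dim(mask)) && mask[idx[1], idx[2], idx[3]]
  }
  p1 <- as.numeric(track[1, c("x", "y", "z")])
  if (inside_mask(get_m(plate_masks_t[[track$frame[1]]]), p1))
    stopf("zero starting distance: chromosome already merged with the plate")
  rows <- list()
  for (r in seq_len(nrow(track))) {
    t <- track$frame[r]
    minutes <- (t - 1) * frame_interval
    if (minutes > window_min) break
    if (!is.na(congression_frame) && t >= congression_frame) break
    d <- surface_dist(get_m(plate_masks_t[[t]]), as.numeric(track[r, c("x", "y", "z")]))
    rows[[length(rows) + 1]] <- data.frame(frame = t, minutes = minutes, distance_um = d)
  }
  if (!length(rows)) stopf("zero starting distance: chromosome already merged with the plate")
  df <- do.call(rbind, rows)
  if (df$distance_um[1] <= 0) stopf("zero starting distance: chromosome already merged with the plate")
  df$normalized <- df$distance_um / df$distance_um[1]
  merged <- !is.na(congression_frame) &&
    (congression_frame - 1) * frame_interval <= window_min
  term_frame <- if (merged) congression_frame else df$frame[nrow(df)]
  structure(list(trace = df,
                 termination_frame = term_frame,
                 termination_min = (term_frame - 1) * frame_interval,
                 reason = if (merged) "merged" else "window_end"),
            class = "misalignment_trace")
}

#' Classify chromosome rescue after ER clearance
#'
#' A cell is rescued when its misaligned-chromosome trace terminates by
#' merging with the plate within the rescue window.
#'
#' @param traces list of [misalignment_trace()] results, or a data.frame
#'   with columns `reason` and `termination_min`.
#' @param rescue_window_min rescue window (minutes).
#' @return list: `table` (per-cell rescued flag), `n`, `rescued`, `percent`
#'   (1 decimal).
#' @export
classify_rescue <- function(traces, rescue_window_min = 80) {
  df <- if (is.data.frame(traces)) traces else {
    if (!length(traces)) stopf("empty input")
    do.call(rbind, lapply(traces, function(tr)
      data.frame(reason = tr$reason, termination_min = tr$termination_min)))
  }
  if (!nrow(df)) stopf("empty input")
  rescued <- df$reason == "merged" & df$termination_min <= rescue_window_min
  list(table = data.frame(cell = seq_len(nrow(df)), rescued = rescued,
                          reason = df$reason, termination_min = df$termination_min),
       n = nrow(df), rescued = sum(rescued),
       percent = round(100 * sum(rescued) / nrow(df), 1))
}
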