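# 4D tracking of DNA objects: frame-to-frame linking, congression detection
# (merge of a chromosome object with the metaphase plate), anaphase-onset
# detection (plate splitting into two persistent, separating children), and
# per-object fluorescence quantification as chromosome/plate ratios.

centroids_of <- function(lo) as.matrix(lo$table[, c("centroid_x_um", "centroid_y_um", "centroid_z_um")])

# Minimum µm distance from a point to the foreground voxels of a label.
min_dist_to_label <- function(lo, label, pt) {
  idx <- which(lo$labels == label, arr.ind = TRUE)
  if (!nrow(idx)) return(Inf)
  um <- sweep(sweep(idx - 1, 2, lo$voxel_size, `*`), 2, pt)
  sqrt(min(rowSums(um^2)))
}

#' Link labeled 3D objects across frames into tracks
#'
#' The plate (largest object) is linked by its plate flag; all other objects
#' are linked by greedy nearest-centroid assignment with a maximum
#' displacement gate. Unmatched objects start or end tracks; a jump beyond
#' the gate splits the track.
#'
#' @param labeled_frames list of [label_dna_objects()] results, one per frame.
#' @param gate_um maximum centroid displacement per frame (µm).
#' @return class `track_set`: `plate` data.frame (frame, label, x, y, z,
#'   volume) and `tracks`, a list of such data.frames for each chromosome,
#'   each with a `dist_to_plate` column (centroid-to-centroid, µm).
#' @export
link_objects <- function(labeled_frames, gate_um = 2) {
  if (!length(labeled_frames)) stopf("empty frame sequence")
  nT <- length(labeled_frames)
  row_of <- function(lo, id, frame) {
    r <- lo$table[lo$table$id == id, ]
    data.frame(frame = frame, label = id, x = r$centroid_x_um, y = r$centroid_y_um,
               z = r$centroid_z_um, volume = r$volume_um3)
  }
  plate <- do.call(rbind, lapply(seq_len(nT), function(t)
    row_of(labeled_frames[[t]], labeled_frames[[t]]$plate_id, t)))

  tracks <- list()     # finished + live; live ones flagged by attr "open"
  live <- list()       # index into tracks of tracks open at previous frame
  for (t in seq_len(nT)) {
    lo <- labeled_frames[[t]]
    ids <- setdiff(lo$table$id, lo$plate_id)
    cent <- centroids_of(lo)
    unmatched <- ids
    if (length(live) && length(ids)) {
      prev <- t(vapply(live, function(i) {
        tr <- tracks[[i]]
        as.numeric(tr[nrow(tr), c("x", "y", "z")])
      }, numeric(3)))
      dm <- outer(seq_len(nrow(prev)), seq_along(ids),
                  Vectorize(function(i, j) vnorm(prev[i, ] - cent[lo$table$id == ids[j], ])))
      dm <- matrix(dm, nrow(prev), length(ids))
      taken_tr <- rep(FALSE, nrow(prev)); taken_ob <- rep(FALSE, length(ids))
      repeat {
        dm2 <- dm; dm2[taken_tr, ] <- Inf; dm2[, taken_ob] <- Inf
        if (all(!is.finite(dm2)) || min(dm2) > gate_um) break
        k <- arrayInd(which.min(dm2), dim(dm2))
        i <- k[1]; j <- k[2]
        tracks[[live[[i]]]] <- rbind(tracks[[live[[i]]]], row_of(lo, ids[j], t))
        taken_tr[i] <- TRUE; taken_ob[j] <- TRUE
      }
      unmatched <- ids[!taken_ob]
    }
    for (id in unmatched) tracks[[length(tracks) + 1]] <- row_of(lo, id, t)
    live <- as.list(which(vapply(tracks, function(tr) tr$frame[nrow(tr)] == t, logical(1))))
  }
  tracks <- lapply(tracks, function(tr) {
    pl <- plate[match(tr$frame, plate$frame), ]
    tr$dist_to_plate <- sqrt((tr$x - pl$x)^2 + (tr$y - pl$y)^2 + (tr$z - pl$z)^2)
    tr
  })
  structure(list(plate = plate, tracks = tracks, gate_um = gate_um,
                 n_frames = nT), class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: plate + %d chromosome track(s) over %d frame(s)\n",
              length(x$tracks), x$n_frames))
  invisible(x)
}

#' Detect congression of a chromosome track
#'
#' Congression is the merging of the chromosome object with the plate
#' object: either the track's linked label is the plate's connected
#' component, or the track terminates and the plate component at the next
#' frame reaches the chromosome's last position (within the object's
#' equivalent radius plus two voxels).
#'
#' @param track one chromosome data.frame from [link_objects()].
#' @param plate_track the plate data.frame from [link_objects()].
#' @param labeled_frames the list of [label_dna_objects()] results.
#' @return the congression frame, or NA if the object never merges.
#' @export
detect_congression <- function(track, plate_track, labeled_frames) {
  for (r in seq_len(nrow(track))) {
    t <- track$frame[r]
    if (track$label[r] == plate_track$label[plate_track$frame == t]) return(t)
  }
  t_end <- track$frame[nrow(track)]
  if (t_end >= length(labeled_frames)) return(NA_integer_)
  t_next <- t_end + 1
  lo <- labeled_frames[[t_next]]
  r_eq <- (3 * track$volume[nrow(track)] / (4 * pi))^(1 / 3)
  last <- as.numeric(track[nrow(track), c("x", "y", "z")])
  merge_dist <- r_eq + 2 * max(lo$voxel_size)
  if (min_dist_to_label(lo, lo$plate_id, last) <= merge_dist) return(t_next)
  NA_integer_
}

#' Detect anaphase onset from the plate track
#'
#' Anaphase is the first frame at which the plate splits into exactly two
#' children, each at least `min_child_frac` of the prior plate volume, whose
#' centroid separation then increases for at least `persist` consecutive
#' frames. A transient single-frame split is not called.
#'
#' @param plate_track plate data.frame from [link_objects()].
#' @param labeled_frames list of [label_dna_objects()] results.
#' @param min_child_frac minimum child/parent volume fraction.
#' @param persist frames of increasing separation required.
#' @return class `anaphase_event`: list(frame, child_volumes, separation).
#' @export
detect_anaphase <- function(plate_track, labeled_frames, min_child_frac = 0.25,
                            persist = 2) {
  nT <- length(labeled_frames)
  children_at <- function(t, vref) {
    lo <- labeled_frames[[t]]
    big <- lo$table[lo$table$volume_um3 >= min_child_frac * vref, , drop = FALSE]
    big[order(-big$volume_um3), , drop = FALSE]
  }
  sep_of <- function(ch) vnorm(as.numeric(ch[1, c("centroid_x_um", "centroid_y_um", "centroid_z_um")]) -
                               as.numeric(ch[2, c("centroid_x_um", "centroid_y_um", "centroid_z_um")]))
  for (t in 2:nT) {
    vref <- plate_track$volume[plate_track$frame == t - 1]
    ch <- children_at(t, vref)
    if (nrow(ch) != 2) next
    seps <- numeric(0)
    ok <- TRUE
    for (k in 0:persist) {
      if (t + k > nT) { ok <- FALSE; break }
      chk <- children_at(t + k, vref)
      if (nrow(chk) != 2) { ok <- FALSE; break }
      seps <- c(seps, sep_of(chk))
    }
    if (ok && all(diff(seps) > 0))
      return(structure(list(frame = t, child_volumes = ch$volume_um3,
                            separation = seps), class = "anaphase_event"))
  }
  stopf("anaphase not detected: no qualifying plate split")
}

#' @export
print.anaphase_event <- function(x, ...) {
  cat(sprintf("anaphase at frame %d; children %.2f / %.2f µm³; separation %s µm\n",
              x$frame, x$child_volumes[1], x$child_volumes[2],
              paste(round(x$separation, 2), collapse = " -> ")))
  invisible(x)
}

# Statistic over an expanded ROI: mean voxel intensity, or the per-z-slice
# maximum averaged over the slices the ROI intersects.
roi_stat <- function(channel, roi, mode) {
  if (!any(roi)) return(NA_real_)
  if (mode == "mean_voxel") return(mean(channel[roi]))
  zs <- which(apply(roi, 3, any))
  mean(vapply(zs, function(z) max(channel[, , z][roi[, , z]]), numeric(1)))
}

#' Quantify a fluorescence signal along a track as a chromosome/plate ratio
#'
#' The object mask is expanded by `dilate_px` pixels in xy within each
#' z-slice (planar ROI semantics; set `dilate_3d = TRUE` for an isotropic
#' voxel dilation instead). `mean_voxel` takes the mean intensity over the
#' expanded region (used for ER); `max_per_z` takes the per-slice maximum
#' averaged over slices (used for Mad2, robust to the small spot size). The
#' plate statistic is computed identically, and the trace is their ratio.
#' Frames where the object has vanished yield NA (a recorded gap).
#'
#' @param track chromosome data.frame from [link_objects()].
#' @param stack the [hyperstack()] with the signal channel.
#' @param labeled_frames list of [label_dna_objects()] results.
#' @param role signal channel role (e.g. "SAC").
#' @param mode "mean_voxel" or "max_per_z".
#' @param dilate_px ROI expansion in pixels.
#' @param dilate_3d use a 3D ball (µm radius `dilate_px` xy-pixels) instead
#'   of planar expansion.
#' @param presmooth_px Gaussian sigma (xy pixels) applied before the
#'   `max_per_z` statistic; an unsmoothed per-slice maximum over a large ROI
#'   is biased upward by uncorrelated noise, and the bias is strongest for
#'   the dim plate signal in the denominator. Ignored for `mean_voxel`.
#' @return data.frame: frame, chromosome, plate, ratio.
#' @export
quantify_signal <- function(track, stack, labeled_frames, role,
                            mode = c("mean_voxel", "max_per_z"),
                            dilate_px = 3, dilate_3d = FALSE, presmooth_px = 1.5) {
  mode <- match.arg(mode)
  offs <- if (dilate_3d) ball_offsets_um(stack$voxel_size, dilate_px * stack$voxel_size[1])
          else disc_offsets_px(dilate_px)
  out <- lapply(seq_len(length(labeled_frames)), function(t) {
    lo <- labeled_frames[[t]]
    ch <- get_channel(stack, role, t)
    if (mode == "max_per_z" && presmooth_px > 0)
      ch <- gauss3d(ch, c(presmooth_px, presmooth_px, 0))
    r <- track[track$frame == t, ]
    if (!nrow(r)) return(data.frame(frame = t, chromosome = NA_real_, plate = NA_real_, ratio = NA_real_))
    roi_c <- dilate3d(lo$labels == r$label, offs)
    roi_p <- dilate3d(lo$labels == lo$plate_id, offs)
    a <- roi_stat(ch, roi_c, mode)
    b <- roi_stat(ch, roi_p, mode)
    data.frame(frame = t, chromosome = a, plate = b, ratio = a / b)
  })
  do.call(rbind, out)
}

#' Pooled linear regression of Mad2 ratios against time to anaphase
#'
#' Ordinary least squares of the chromosome/plate ratio on time relative to
#' anaphase onset (minutes), pooling chromosomes across cells; with
#' `congressed_only_last` only the last chromosome to congress (or fail to)
#' per cell enters, matching the one-chromosome-per-cell sampling rule.
#'
#' @param traces data.frame with columns cell, t_rel_min (t - t_anaphase),
#'   ratio, and is_last (logical).
#' @param congressed_only_last filter to the last chromosome per cell.
#' @return list: slope, intercept, ci (2x2 95% bounds), n_points, n_cells,
#'   fit (the lm object).
#' @export
mad2_regression <- function(traces, congressed_only_last = TRUE) {
  stopifnot(all(c("cell", "t_rel_min", "ratio") %in% names(traces)))
  if (congressed_only_last && "is_last" %in% names(traces))
    traces <- traces[traces$is_last, , drop = FALSE]
  traces <- traces[is.finite(traces$ratio) & is.finite(traces$t_rel_min), , drop = FALSE]
  if (length(unique(traces$cell)) < 2)
    warning("Mad2 regression pooled from a single cell", call. = FALSE)
  if (nrow(traces) < 3) stopf("fewer than 3 pooled points")
  fit <- stats::lm(ratio ~ t_rel_min, data = traces)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       ci = ci, n_points = nrow(traces), n_cells = length(unique(traces$cell)),
       fit = fit)
}
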