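# 3D segmentation: channel binarization, cell mask, exclusion-zone
# delineation, and labeling of DNA objects with plate identification.
# Masks carry their provenance (channel, frame, method, parameters); all
# centroids and volumes are µm, never voxels.

new_mask3d <- function(mask, voxel_size, provenance) {
  structure(list(mask = mask, voxel_size = voxel_size, provenance = provenance),
            class = "mask3d")
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("mask3d: %s voxels, %d foreground (%.1f µm³), method %s\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              sum(x$mask) * prod(x$voxel_size), x$provenance$method %||% "?"))
  invisible(x)
}

#' Binarize one channel of a hyperstack
#'
#' Gaussian smoothing (sigma in xy voxels, scaled by the voxel anisotropy in
#' z) followed by global 3D Otsu thresholding, or a fixed threshold. The
#' smoothing sigma and threshold are recorded in the mask provenance.
#'
#' @param stack a [hyperstack()].
#' @param role channel role to binarize.
#' @param frame frame index.
#' @param method "otsu3d" or "fixed_threshold".
#' @param params list: `sigma` (xy voxels, default 1) and, for
#'   "fixed_threshold", `threshold`.
#' @return a `mask3d` (true where smoothed intensity >= threshold).
#' @export
binarize_channel <- function(stack, role, frame = 1, method = c("otsu3d", "fixed_threshold"),
                             params = list()) {
  method <- match.arg(method)
  v <- get_channel(stack, role, frame)
  sigma <- params$sigma %||% 1
  sig_vox <- c(sigma, sigma, sigma * stack$voxel_size[1] / stack$voxel_size[3])
  if (sigma > 0) v <- gauss3d(v, sig_vox)
  thr <- if (method == "otsu3d") otsu_threshold(v) else {
    if (is.null(params$threshold)) stopf("fixed_threshold method requires params$threshold")
    params$threshold
  }
  new_mask3d(v >= thr, stack$voxel_size,
             list(channel = role, frame = frame, method = method,
                  sigma = sigma, threshold = thr))
}

# Slice-wise filled convex hull of a mask (chull per z-plane), used as the
# cell-mask fallback when no plasma-membrane channel was acquired.
convex_hull_slicewise <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  gx <- matrix(seq_len(d[1]), d[1], d[2])
  gy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  for (z in seq_len(d[3])) {
    sl <- mask[, , z]
    idx <- which(sl, arr.ind = TRUE)
    if (nrow(idx) < 3) { out[, , z] <- sl; next }
    h <- grDevices::chull(idx)
    out[, , z] <- matrix(pracma::inpolygon(as.vector(gx), as.vector(gy),
                                           idx[h, 1], idx[h, 2], boundary = TRUE),
                         d[1], d[2])
  }
  out
}

#' Segment the cell volume
#'
#' With a plasma-membrane (PM) channel: binarize the membrane shell, close
#' it, fill the enclosed volume and keep the largest connected component.
#' Without one, the fallback is the filled (slice-wise) convex hull of the
#' ER mask, which always contains the ER voxels used downstream.
#'
#' @param stack a [hyperstack()].
#' @param frame frame index.
#' @param er_mask optional `mask3d` for the fallback path.
#' @param fallback allow the ER-hull fallback when no PM channel is present.
#' @return a `mask3d`: one connected, hole-filled region.
#' @export
segment_cell <- function(stack, frame = 1, er_mask = NULL, fallback = TRUE,
                         membrane_halfwidth_um = 0.35) {
  if ("PM" %in% stack$channels) {
    pm <- binarize_channel(stack, "PM", frame)
    if (!any(pm$mask)) stopf("empty plasma-membrane segmentation; consider the ER-hull fallback")
    vs <- stack$voxel_size
    # close across the z gap left where the membrane is tangent to a slice,
    # seal each slice in-plane, then fill and trim back to the membrane
    # midline so the enclosed volume is unbiased
    closed <- close3d(pm$mask, ball_offsets_um(vs, max(3 * vs[1], vs[3])))
    sealed <- fill_holes_slicewise(closed)
    lab <- label3d(sealed, 26)
    keep <- which.max(tabulate(lab[lab > 0]))
    filled <- fill_holes3d(lab == keep)
    cell <- erode3d(filled, ball_offsets_um(vs, membrane_halfwidth_um))
    lab2 <- label3d(cell, 26)
    cell <- lab2 == which.max(tabulate(lab2[lab2 > 0]))
    return(new_mask3d(cell, vs,
                      list(channel = "PM", frame = frame, method = "pm_shell_fill",
                           membrane_halfwidth_um = membrane_halfwidth_um)))
  }
  if (!fallback) stopf("no PM channel and fallback disabled")
  if (is.null(er_mask)) er_mask <- binarize_channel(stack, "ER", frame)
  hull <- convex_hull_slicewise(er_mask$mask)
  new_mask3d(fill_holes3d(hull), stack$voxel_size,
             list(channel = "ER", frame = frame, method = "er_convex_hull"))
}

#' Delineate the exclusion zone
#'
#' The exclusion zone is the largest interior cavity of the ER: the largest
#' 6-connected component of `cell AND NOT closed(ER)` that does not touch
#' the cell-mask boundary. The ER mask is morphologically closed first
#' (disc radius 3 xy-voxels) so gaps between membrane layers do not leak the
#' cavity.
#'
#' @param er_mask,cell_mask `mask3d` objects on the same grid.
#' @return a `mask3d` for the exclusion zone (disjoint from the ER mask).
#' @export
delineate_exclusion_zone <- function(er_mask, cell_mask) {
  if (!identical(dim(er_mask$mask), dim(cell_mask$mask))) stopf("mask shapes differ")
  closed <- close3d(er_mask$mask, disc_offsets_px(3))
  cavity <- cell_mask$mask & !closed
  lab <- label3d(cavity, 6)
  if (!any(lab > 0)) stopf("no interior cavity found: cell is not mitotic or ER segmentation failed")
  # components touching the cell-mask boundary (adjacent to outside-cell) are
  # peripheral cytoplasm, not the exclusion zone
  outside <- !cell_mask$mask
  grown <- dilate3d(outside, rbind(diag(3), -diag(3)))
  grown[1, , ] <- TRUE; grown[dim(grown)[1], , ] <- TRUE
  grown[, 1, ] <- TRUE; grown[, dim(grown)[2], ] <- TRUE
  grown[, , 1] <- TRUE; grown[, , dim(grown)[3]] <- TRUE
  touching <- unique(lab[lab > 0 & grown])
  sizes <- tabulate(lab[lab > 0])
  sizes[touching] <- 0
  if (all(sizes == 0)) stopf("no interior cavity found: cell is not mitotic or ER segmentation failed")
  ez <- (lab == which.max(sizes)) & !er_mask$mask
  new_mask3d(ez, er_mask$voxel_size,
             list(channel = er_mask$provenance$channel, frame = er_mask$provenance$frame,
                  method = "largest_interior_cavity", closing_radius_px = 3))
}

#' Label DNA objects and identify the metaphase plate
#'
#' 26-connected components of the DNA mask; objects below `min_volume` µm³
#' are removed. The plate is the largest-volume object; equal-volume ties
#' break to the smallest (z, y, x) lexicographic centroid.
#'
#' @param dna_mask a `mask3d`.
#' @param min_volume minimum object volume in µm³.
#' @return class `labeled_objects`: `labels` array (relabeled contiguously
#'   from 1), `table` (id, centroid µm, volume µm³, bounding box), `plate_id`.
#' @export
label_dna_objects <- function(dna_mask, min_volume = 0.05) {
  if (!any(dna_mask$mask)) stopf("empty DNA mask")
  vs <- dna_mask$voxel_size
  lab <- label3d(dna_mask$mask, 26)
  vox_vol <- prod(vs)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts * vox_vol >= min_volume)
  if (!length(keep)) stopf("all %d objects below min_volume = %g µm³", length(counts), min_volume)
  newlab <- integer(length(counts))
  newlab[keep] <- seq_along(keep)
  lab2 <- array(0L, dim(lab))
  lab2[lab > 0] <- newlab[lab[lab > 0]]
  tab <- do.call(rbind, lapply(seq_along(keep), function(i) {
    idx <- which(lab2 == i, arr.ind = TRUE)
    data.frame(id = i,
               centroid_x_um = mean(idx[, 1] - 1) * vs[1],
               centroid_y_um = mean(idx[, 2] - 1) * vs[2],
               centroid_z_um = mean(idx[, 3] - 1) * vs[3],
               volume_um3 = nrow(idx) * vox_vol,
               xmin = min(idx[, 1]), xmax = max(idx[, 1]),
               ymin = min(idx[, 2]), ymax = max(idx[, 2]),
               zmin = min(idx[, 3]), zmax = max(idx[, 3]))
  }))
  vmax <- max(tab$volume_um3)
  cand <- which(abs(tab$volume_um3 - vmax) < 1e-12)
  if (length(cand) > 1) {
    key <- order(tab$centroid_z_um[cand], tab$centroid_y_um[cand], tab$centroid_x_um[cand])
    cand <- cand[key[1]]
  }
  tab$is_plate <- seq_len(nrow(tab)) == cand[1]
  structure(list(labels = lab2, table = tab, plate_id = tab$id[cand[1]],
                 voxel_size = vs, n_removed = length(counts) - length(keep)),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("labeled_objects: %d object(s), plate id %d (%.2f µm³), %d removed by size filter\n",
              nrow(x$table), x$plate_id, x$table$volume_um3[x$table$id == x$plate_id],
              x$n_removed))
  invisible(x)
}
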