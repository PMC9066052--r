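# Puncta detection and kinetochore-kinastrin nearest-neighbour analysis.
# Kinastrin marks stable end-on kinetochore-microtubule attachment; a
# kinetochore is scored as attached when its nearest punctum lies closer
# than the cutoff (600 nm).

#' Detect 3D puncta in a channel
#'
#' Connected components (26-connectivity) of the thresholded channel, with
#' an optional single-voxel closing to bridge sampling gaps; components
#' below `min_volume` µm³ are discarded. Centroids are intensity weighted.
#'
#' @param stack a [hyperstack()].
#' @param role channel role (e.g. "KIN" or "KT").
#' @param frame frame index.
#' @param threshold absolute intensity threshold.
#' @param min_volume minimum component volume (µm³).
#' @param closing_px radius (pixels) of the closing applied before labeling;
#'   0 disables it.
#' @return class `puncta_set`: data.frame (x_um, y_um, z_um, volume_um3,
#'   peak) plus the detection parameters. May be empty.
#' @export
detect_puncta <- function(stack, role, frame = 1, threshold, min_volume = 0,
                          closing_px = 1) {
  v <- get_channel(stack, role, frame)
  vs <- stack$voxel_size
  m <- v >= threshold
  if (closing_px > 0 && any(m)) m <- close3d(m, disc_offsets_px(closing_px))
  empty <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      volume_um3 = numeric(), peak = numeric())
  if (!any(m))
    return(structure(list(points = empty,
                          params = list(threshold = threshold, min_volume = min_volume,
                                        closing_px = closing_px)),
                     class = "puncta_set"))
  lab <- label3d(m, 26)
  rows <- lapply(seq_len(max(lab)), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    vol <- nrow(idx) * prod(vs)
    if (vol < min_volume) return(NULL)
    w <- v[lab == i]
    w <- pmax(w, 0); if (sum(w) <= 0) w <- rep(1, length(w))
    data.frame(x_um = sum((idx[, 1] - 1) * w) / sum(w) * vs[1],
               y_um = sum((idx[, 2] - 1) * w) / sum(w) * vs[2],
               z_um = sum((idx[, 3] - 1) * w) / sum(w) * vs[3],
               volume_um3 = vol, peak = max(w))
  })
  pts <- do.call(rbind, rows)
  structure(list(points = if (is.null(pts)) empty else pts,
                 params = list(threshold = threshold, min_volume = min_volume,
                               closing_px = closing_px)),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set: %d puncta (threshold %g, min volume %g µm³)\n",
              nrow(x$points), x$params$threshold, x$params$min_volume))
  invisible(x)
}

#' Nearest-punctum distance for each kinetochore
#'
#' Exact nearest-neighbour Euclidean distances in µm (full distance
#' computation, no approximate index).
#'
#' @param kinetochores a [kinetochore_set()] or data.frame with x, y, z (µm).
#' @param puncta a [detect_puncta()] result or data.frame with
#'   x_um, y_um, z_um.
#' @return data.frame: id, class (when available), nearest_um.
#' @export
nearest_distance <- function(kinetochores, puncta) {
  kt <- if (inherits(kinetochores, "kinetochore_set")) kinetochores$kt else kinetochores
  pp <- if (inherits(puncta, "puncta_set")) puncta$points else puncta
  if (!nrow(pp)) stopf("no puncta detected")
  km <- as.matrix(kt[, c("x", "y", "z")])
  pm <- as.matrix(pp[, c("x_um", "y_um", "z_um")])
  d2 <- outer(rowSums(km^2), rep(1, nrow(pm))) +
        outer(rep(1, nrow(km)), rowSums(pm^2)) - 2 * km %*% t(pm)
  data.frame(id = if ("id" %in% names(kt)) kt$id else seq_len(nrow(kt)),
             class = if ("class" %in% names(kt)) kt$class else NA_character_,
             nearest_um = sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Fraction of kinetochores with a punctum within the attachment cutoff
#'
#' Strict inequality at the cutoff (attachment is scored as "< 600 nm").
#'
#' @param distances data.frame from [nearest_distance()] (columns class,
#'   nearest_um), or a numeric vector with `groups`.
#' @param cutoff attachment cutoff in µm.
#' @param groups optional grouping vector when `distances` is numeric.
#' @param all_groups optional group universe; groups with no kinetochores
#'   are reported with n = 0 and fraction NA (undefined).
#' @param breaks histogram breaks (µm) for the per-group frequency
#'   distribution.
#' @return list: `summary` (group, n, n_below, fraction; empty groups NA)
#'   and `histograms` (per-group counts).
#' @export
fraction_within <- function(distances, cutoff = 0.6, groups = NULL,
                            all_groups = NULL, breaks = seq(0, 5, by = 0.1)) {
  if (is.numeric(distances)) {
    distances <- data.frame(class = if (is.null(groups)) "all" else groups,
                            nearest_um = distances)
  }
  gs <- union(unique(distances$class), all_groups)
  summ <- do.call(rbind, lapply(gs, function(g) {
    d <- distances$nearest_um[distances$class == g]
    data.frame(group = g, n = length(d),
               n_below = if (length(d)) sum(d < cutoff) else NA_integer_,
               fraction = if (length(d)) sum(d < cutoff) / length(d) else NA_real_)
  }))
  hists <- lapply(stats::setNames(gs, gs), function(g) {
    d <- distances$nearest_um[distances$class == g]
    graphics::hist(pmin(d, max(breaks)), breaks = breaks, plot = FALSE)$counts
  })
  list(summary = summ, histograms = hists, cutoff = cutoff)
}
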