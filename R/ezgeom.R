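# Exclusion-zone geometry: the position of each kinetochore relative to the
# EZ/ER boundary as a log2 distance ratio. For kinetochore P and aligned
# centroid C, Q is the point where the ray from C through P first leaves the
# exclusion zone; the statistic is log2(|CP| / |CQ|): 0 on the boundary,
# negative inside, +1 as far outside the zone as the boundary is from the
# centroid.

#' Centroid of the aligned kinetochores
#'
#' @param kset a [kinetochore_set()].
#' @param ez_mask optional `mask3d`; if given, warn when the centroid falls
#'   outside the exclusion zone (a sign of mis-annotation).
#' @return length-3 µm point C.
#' @export
aligned_centroid <- function(kset, ez_mask = NULL) {
  al <- kset$kt[kset$kt$class == "aligned", , drop = FALSE]
  if (nrow(al) < 3) stopf("need >= 3 aligned kinetochores to define the centroid, got %d", nrow(al))
  C <- c(mean(al$x), mean(al$y), mean(al$z))
  if (!is.null(ez_mask) && !point_in_mask(C, ez_mask))
    warning("aligned centroid lies outside the exclusion-zone mask", call. = FALSE)
  C
}

# Nearest-voxel membership of a µm point in a mask3d.
point_in_mask <- function(pt, m) {
  idx <- round(pt / m$voxel_size) + 1
  d <- dim(m$mask)
  if (any(idx < 1) || any(idx > d)) return(FALSE)
  m$mask[idx[1], idx[2], idx[3]]
}

# Trilinear interpolation of a (binary or numeric) 3D array at a µm point;
# outside the grid the value is 0.
trilinear <- function(vol, voxel_size, pt) {
  g <- pt / voxel_size + 1
  d <- dim(vol)
  i0 <- floor(g); f <- g - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- i0[1] + dx; iy <- i0[2] + dy; iz <- i0[3] + dz
    if (ix < 1 || ix > d[1] || iy < 1 || iy > d[2] || iz < 1 || iz > d[3]) next
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) * (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * vol[ix, iy, iz]
  }
  acc
}

#' Boundary intersection Q along the ray from C through P
#'
#' Marches from C in the direction of P in steps of half the smallest voxel
#' dimension, continuing past P if P is still inside the zone, and returns
#' the first inside-to-outside transition. The crossing is refined to
#' sub-voxel precision by linear interpolation of the trilinearly sampled
#' mask between the last inside and first outside sample.
#'
#' @param C,P µm points; C must lie inside the exclusion-zone mask.
#' @param ez_mask a `mask3d` of the exclusion zone.
#' @param max_dist_um maximum march distance before concluding the ray never
#'   leaves the zone (defaults to the grid diagonal).
#' @return µm point Q on the boundary.
#' @export
boundary_intersection <- function(C, P, ez_mask, max_dist_um = NULL) {
  if (!point_in_mask(C, ez_mask)) stopf("C is not inside the exclusion-zone mask")
  u <- P - C
  if (vnorm(u) < 1e-9) stopf("P coincides with C: direction undefined")
  u <- u / vnorm(u)
  step <- 0.5 * min(ez_mask$voxel_size)
  if (is.null(max_dist_um))
    max_dist_um <- vnorm(dim(ez_mask$mask) * ez_mask$voxel_size)
  ts <- seq(0, max_dist_um, by = step)
  num <- array(as.numeric(ez_mask$mask), dim(ez_mask$mask))
  hi <- (dim(ez_mask$mask) - 1) * ez_mask$voxel_size
  inside_prev <- TRUE
  f_prev <- 1
  for (k in seq_along(ts)[-1]) {
    pt <- C + ts[k] * u
    if (any(pt < 0) || any(pt > hi))
      stopf("no boundary crossing: ray leaves the grid without exiting the exclusion zone")
    f <- trilinear(num, ez_mask$voxel_size, pt)
    inside <- f >= 0.5
    if (inside_prev && !inside) {
      # linear sub-voxel refinement of the 0.5-crossing
      t_star <- ts[k - 1] + step * if (abs(f_prev - f) > 1e-12) (f_prev - 0.5) / (f_prev - f) else 0.5
      return(C + t_star * u)
    }
    inside_prev <- inside
    f_prev <- f
  }
  stopf("no boundary crossing: ray leaves the grid without exiting the exclusion zone")
}

#' Exclusion-zone distance ratio for one kinetochore
#'
#' @param C aligned-kinetochore centroid (µm).
#' @param P kinetochore position (µm).
#' @param Q boundary intersection from [boundary_intersection()].
#' @return list: `dist_CP`, `dist_CQ` (µm) and `log2_ratio` =
#'   log2(|CP|/|CQ|).
#' @export
ez_ratio <- function(C, P, Q) {
  cq <- vnorm(Q - C)
  if (cq < 1e-9) stopf("degenerate geometry: |CQ| = 0")
  cp <- vnorm(P - C)
  list(dist_CP = cp, dist_CQ = cq, log2_ratio = log2(cp / cq))
}

#' Exclusion-zone ratios for a whole kinetochore set
#'
#' @param kset a [kinetochore_set()].
#' @param ez_mask a `mask3d` exclusion zone.
#' @return data.frame: cell, id, class, CP_um, CQ_um, log2_ratio.
#' @export
ez_ratios <- function(kset, ez_mask) {
  C <- aligned_centroid(kset, ez_mask)
  out <- lapply(seq_len(nrow(kset$kt)), function(i) {
    P <- as.numeric(kset$kt[i, c("x", "y", "z")])
    r <- tryCatch({
      Q <- boundary_intersection(C, P, ez_mask)
      ez_ratio(C, P, Q)
    }, error = function(e) list(dist_CP = vnorm(P - C), dist_CQ = NA_real_,
                                log2_ratio = NA_real_))
    data.frame(cell = kset$cell_id, id = kset$kt$id[i], class = kset$kt$class[i],
               CP_um = r$dist_CP, CQ_um = r$dist_CQ, log2_ratio = r$log2_ratio)
  })
  do.call(rbind, out)
}

#' Classify a misaligned chromosome as ensheathed or free
#'
#' Auto mode scores ensheathment as the fraction of a 0.5 µm shell around
#' the object that is occupied by the ER mask; the object is called
#' ensheathed when the score reaches `threshold`. Manual mode copies the
#' class from point annotations.
#'
#' @param object_mask logical 3D array (the chromosome object).
#' @param er_mask a `mask3d`.
#' @param mode "auto" or "manual".
#' @param annotation for manual mode, the class recorded for this object.
#' @param shell_um shell thickness in µm.
#' @param threshold shell-occupancy threshold for the ensheathed call.
#' @return list: `class` ("ensheathed"/"free") and `score` (shell occupancy).
#' @export
classify_misaligned <- function(object_mask, er_mask, mode = c("auto", "manual"),
                                annotation = NULL, shell_um = 0.5, threshold = 0.75) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(annotation)) stopf("manual mode: no annotation supplied for this object")
    if (!annotation %in% c("free", "ensheathed")) stopf("unknown annotation class '%s'", annotation)
    return(list(class = annotation, score = NA_real_))
  }
  shell <- dilate3d(object_mask, ball_offsets_um(er_mask$voxel_size, shell_um)) & !object_mask
  s <- if (!any(shell) || !any(er_mask$mask)) 0 else mean(er_mask$mask[shell])
  list(class = if (s >= threshold) "ensheathed" else "free", score = s)
}

# Rotation matrix taking unit vector a onto unit vector b (Rodrigues).
rotation_onto <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any axis orthogonal to a
    w <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- w - sum(w * a) * a; v <- v / vnorm(v)
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Register kinetochore sets into a canonical frame and pool them
#'
#' Per cell: translate so the aligned centroid C is at the origin, rotate so
#' the pole-pole axis lies along x, fix the residual rotation about x from
#' the principal yz-axis of the aligned kinetochores, and reflect so the
#' misaligned side is +x. The pooled normalized points retain class labels
#' (spindle poles are included with class "pole") for spatially averaged
#' views.
#'
#' @param ksets list of [kinetochore_set()] objects.
#' @return data.frame: cell, id, class, x, y, z (µm, canonical frame).
#' @export
register_canonical <- function(ksets) {
  out <- lapply(ksets, function(ks) {
    if (vnorm(ks$poles[1, ] - ks$poles[2, ]) < 1e-9) stopf("cell %s: coincident spindle poles", ks$cell_id)
    C <- aligned_centroid(ks)
    pts <- rbind(as.matrix(ks$kt[, c("x", "y", "z")]), ks$poles)
    cls <- c(ks$kt$class, "pole", "pole")
    ids <- c(as.character(ks$kt$id), "pole1", "pole2")
    pts <- sweep(pts, 2, C)
    ax <- ks$poles[1, ] - ks$poles[2, ]
    R1 <- rotation_onto(ax / vnorm(ax), c(1, 0, 0))
    pts <- pts %*% t(R1)
    # residual rotation about x: principal axis of aligned kinetochores in yz
    al <- pts[cls == "aligned", 2:3, drop = FALSE]
    al <- sweep(al, 2, colMeans(al))
    sv <- svd(al)
    v1 <- sv$v[, 1]
    proj <- al %*% v1
    if (proj[which.max(abs(proj))] < 0) v1 <- -v1
    th <- -atan2(v1[2], v1[1])   # rotate the principal yz-axis onto +y
    R2 <- matrix(c(1, 0, 0,
                   0, cos(th), -sin(th),
                   0, sin(th), cos(th)), 3, 3, byrow = TRUE)
    pts <- pts %*% t(R2)
    # reflect so the misaligned side is +x (proper frame kept by flipping z too)
    mis <- pts[cls %in% c("free", "ensheathed"), 1]
    if (length(mis) && mean(mis) < 0) pts <- pts %*% diag(c(-1, 1, -1))
    data.frame(cell = ks$cell_id, id = ids, class = cls,
               x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
  do.call(rbind, out)
}
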