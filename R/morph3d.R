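# Low-level 3D grid operations used throughout the pipeline. All masks are
# logical arrays indexed [x, y, z]; physical voxel sizes are in micrometres
# and every distance-aware operation works in µm so that anisotropic stacks
# (z spacing typically 5x the xy pixel size) are handled correctly.

#' Fill holes independently within each z-slice
#'
#' 2D (4-connectivity) hole filling per plane; used to seal membrane shells
#' whose caps are tangent to the slices.
#' @param mask logical 3D array.
#' @export
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (z in seq_len(d[3])) {
    sl <- mask[, , z]
    bg <- label3d(array(!sl, c(d[1], d[2], 1)), 6)[, , 1]
    border <- setdiff(unique(c(bg[1, ], bg[d[1], ], bg[, 1], bg[, d[2]])), 0L)
    out[, , z] <- sl | (bg != 0 & !(bg %in% border))
  }
  out
}

#' Label connected components in a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (face neighbours) or 26 (face, edge and corner
#'   neighbours). Objects are labeled with 26-connectivity by convention;
#'   cavity detection uses 6.
#' @return integer array of the same shape; background 0, components labeled
#'   contiguously from 1 in deterministic raster-scan order.
#' @export
label3d <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  lab <- label3d_cpp(as.logical(mask), as.integer(dim(mask)), as.integer(connectivity))
  array(lab, dim(mask))
}

# Integer voxel offsets within a µm-radius ball, given anisotropic voxel
# sizes. Used for dilation/erosion with a physically meaningful radius.
ball_offsets_um <- function(voxel_size, r_um) {
  nmax <- floor(r_um / voxel_size)
  g <- expand.grid(dx = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2], dz = -nmax[3]:nmax[3])
  d2 <- (g$dx * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 + (g$dz * voxel_size[3])^2
  as.matrix(g[d2 <= r_um^2 + 1e-12, , drop = FALSE])
}

# Offsets for a 2D disc of `r_px` pixels applied within each z-slice
# (ImageJ-style planar ROI expansion).
disc_offsets_px <- function(r_px) {
  g <- expand.grid(dx = -r_px:r_px, dy = -r_px:r_px, dz = 0L)
  as.matrix(g[g$dx^2 + g$dy^2 <= r_px^2 + 1e-12, , drop = FALSE])
}

shift_mask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  sx <- max(1, 1 + off[1]):min(d[1], d[1] + off[1])
  sy <- max(1, 1 + off[2]):min(d[2], d[2] + off[2])
  sz <- max(1, 1 + off[3]):min(d[3], d[3] + off[3])
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx, sy, sz] <- m[sx - off[1], sy - off[2], sz - off[3]]
  out
}

#' Binary dilation of a 3D mask by a set of voxel offsets
#' @param mask logical 3D array.
#' @param offsets integer matrix of (dx, dy, dz) rows, e.g. from
#'   [ball_offsets_um()] or [disc_offsets_px()].
#' @export
dilate3d <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offsets))) out <- out | shift_mask(mask, offsets[i, ])
  out
}

#' @rdname dilate3d
#' @export
erode3d <- function(mask, offsets) !dilate3d(!mask, -offsets)

#' @rdname dilate3d
#' @export
close3d <- function(mask, offsets) erode3d(dilate3d(mask, offsets), offsets)

#' Fill interior cavities of a 3D mask
#'
#' Background components (6-connected) that do not touch the grid border are
#' considered holes and are filled.
#' @param mask logical 3D array.
#' @export
fill_holes3d <- function(mask) {
  bg <- label3d(!mask, connectivity = 6)
  border_labels <- unique(c(bg[1, , ], bg[dim(bg)[1], , ],
                            bg[, 1, ], bg[, dim(bg)[2], ],
                            bg[, , 1], bg[, , dim(bg)[3]]))
  border_labels <- setdiff(border_labels, 0L)
  mask | (bg != 0 & !(bg %in% border_labels))
}

# Separable Gaussian smoothing with per-axis sigma in voxels. Kernel rows are
# renormalised at the array edges (replicate-free truncation).
gauss3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  conv_axis <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    n <- dim(a)[axis]
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    K[abs(row(K) - col(K)) > ceiling(4 * sigma)] <- 0
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- K %*% matrix(ap, nrow = n)
    aperm(array(m, dim(a)[perm]), order(perm))
  }
  v <- conv_axis(vol, 1, sigma_vox[1])
  v <- conv_axis(v, 2, sigma_vox[2])
  conv_axis(v, 3, sigma_vox[3])
}

# Global Otsu threshold on a numeric array (256-bin histogram). Errors on a
# degenerate (constant) input, where no between-class variance exists.
otsu_threshold <- function(v, nbins = 256) {
  rng <- range(v)
  if (diff(rng) <= 1e-9 * max(abs(rng), 1))
    stopf("otsu threshold undefined: channel is constant (value %g)", rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

# µm coordinates of voxel centres along each axis (origin at voxel (1,1,1)).
axis_um <- function(dims, voxel_size) {
  list(x = (seq_len(dims[1]) - 1) * voxel_size[1],
       y = (seq_len(dims[2]) - 1) * voxel_size[2],
       z = (seq_len(dims[3]) - 1) * voxel_size[3])
}

# Quadratic-form value of an axis-aligned ellipsoid, vectorised on a grid:
# <= 1 inside. Returns a 3D array.
ellipsoid_form_grid <- function(dims, voxel_size, center, semi) {
  ax <- axis_um(dims, voxel_size)
  fx <- ((ax$x - center[1]) / semi[1])^2
  fy <- ((ax$y - center[2]) / semi[2])^2
  fz <- ((ax$z - center[3]) / semi[3])^2
  outer(outer(fx, fy, `+`), fz, `+`)
}

# Nearest point on an origin-centred axis-aligned ellipsoid surface to an
# exterior point, by dense surface sampling followed by local Newton
# refinement of the foot-point parameter.
ellipsoid_nearest_point <- function(semi, p) {
  th <- seq(0, pi, length.out = 25)
  ph <- seq(0, 2 * pi, length.out = 49)[-49]
  g <- expand.grid(th = th, ph = ph)
  S <- cbind(semi[1] * cos(g$th),
             semi[2] * sin(g$th) * cos(g$ph),
             semi[3] * sin(g$th) * sin(g$ph))
  i <- which.min(colSums((t(S) - p)^2))
  best <- c(g$th[i], g$ph[i])
  obj <- function(a) sum((c(semi[1] * cos(a[1]),
                            semi[2] * sin(a[1]) * cos(a[2]),
                            semi[3] * sin(a[1]) * sin(a[2])) - p)^2)
  o <- stats::optim(best, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-10, maxit = 200))
  a <- o$par
  c(semi[1] * cos(a[1]), semi[2] * sin(a[1]) * cos(a[2]),
    semi[3] * sin(a[1]) * sin(a[2]))
}

# Squared µm distance from each voxel centre to a point.
dist2_grid <- function(dims, voxel_size, pt) {
  ax <- axis_um(dims, voxel_size)
  outer(outer((ax$x - pt[1])^2, (ax$y - pt[2])^2, `+`), (ax$z - pt[3])^2, `+`)
}
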