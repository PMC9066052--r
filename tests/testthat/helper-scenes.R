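# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (loops, enumeration, closed forms) and never reuse the
# code paths they check.

# Compact scene/acquisition pair that renders quickly in unit tests.
small_params <- function(...) {
  args <- utils::modifyList(
    list(cell_semi = c(3, 3, 2.2), ez_semi = c(1.6, 1.6, 1.4),
         plate_semi = c(0.4, 1.1, 1.0), pole_offset = c(1.2, 0, 0),
         n_aligned_kt = 20),
    list(...))
  do.call(scene_params, args)
}

small_acq <- function(...) {
  acq_params(dims = c(64, 64, 12), voxel_size = c(0.11, 0.11, 0.55), ...)
}

# Acquisition used for the full-size default scene in recovery suites.
fast_acq <- function(...) {
  acq_params(dims = c(68, 68, 16), voxel_size = c(0.15, 0.15, 0.65), ...)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Closed-form distance from C along unit direction u to the surface of an
# axis-aligned ellipsoid (center ctr, semi-axes semi), C inside.
ray_ellipsoid_dist <- function(C, u, ctr, semi) {
  p <- (C - ctr) / semi
  q <- u / semi
  a <- sum(q^2); b <- 2 * sum(p * q); cc <- sum(p^2) - 1
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# Brute-force nearest neighbour: plain double loop.
oracle_nn <- function(kt, pp) {
  vapply(seq_len(nrow(kt)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(pp))) {
      d <- sqrt(sum((as.numeric(kt[i, ]) - as.numeric(pp[j, ]))^2))
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

# Full hypergeometric enumeration of the two-sided Fisher p for a 2x2 table.
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumeration over all group assignments.
oracle_wilcox <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Analytic mask on a voxel grid.
ellipsoid_mask3d <- function(dims, voxel, ctr, semi) {
  mitoez:::new_mask3d(mitoez:::ellipsoid_form_grid(dims, voxel, ctr, semi) < 1,
                      voxel, list(method = "analytic"))
}

# Default-geometry tracking scene: one congressing free chromosome, one
# ensheathed that never congresses, anaphase at frame 12.
tracking_scene <- function(seed, sd = 0, acq = acq_params(channels = "DNA")) {
  p <- scene_params(n_free = 1, n_ensheathed = 1,
                    congression_frames = c(7L, NA), anaphase_frame = 12L,
                    n_frames = 16L)
  s <- make_scene(p, seed = seed)
  acq$gaussian_sd <- sd
  acq$seed <- seed
  ts <- render_timeseries(s, acq)
  frames <- lapply(seq_len(s$n_frames), function(t)
    label_dna_objects(binarize_channel(ts$stack, "DNA", t)))
  list(scene = s, stack = ts$stack, frames = frames, tracks = link_objects(frames))
}

# Cell Counter XML written from a data.frame(type, x, y, z).
write_cellcounter_xml <- function(df, path) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             "<CellCounter_Marker_File>", " <Marker_Data>")
  for (ty in unique(df$type)) {
    lines <- c(lines, "  <Marker_Type>", sprintf("   <Type>%d</Type>", ty))
    sub <- df[df$type == ty, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      lines <- c(lines, "   <Marker>",
                 sprintf("    <MarkerX>%g</MarkerX>", sub$x[i]),
                 sprintf("    <MarkerY>%g</MarkerY>", sub$y[i]),
                 sprintf("    <MarkerZ>%g</MarkerZ>", sub$z[i]),
                 "   </Marker>")
    lines <- c(lines, "  </Marker_Type>")
  }
  writeLines(c(lines, " </Marker_Data>", "</CellCounter_Marker_File>"), path)
  path
}
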