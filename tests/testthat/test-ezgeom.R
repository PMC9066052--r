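# Exclusion-zone geometry: centroid, ray-boundary intersection against the
# closed-form ellipsoid solution, the log2 distance-ratio statistic,
# ensheathment classification and canonical registration.

test_that("aligned centroid is the arithmetic mean and needs >= 3 points", {
  mk <- function(pts, classes) {
    df <- data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3], label = classes)
    df <- rbind(df, data.frame(x_um = c(5, -5), y_um = 0, z_um = 0, label = "pole"))
    kinetochore_set(df)
  }
  ks <- mk(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0)), rep("aligned", 3))
  expect_equal(aligned_centroid(ks), c(1, 1, 0))
  same <- mk(rbind(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)), rep("aligned", 3))
  expect_equal(aligned_centroid(same), c(2, 2, 2))
  few <- mk(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), c("aligned", "aligned", "free"))
  expect_error(aligned_centroid(few), ">= 3 aligned")
})

test_that("centroid of rendered aligned kinetochores sits at the plate centre", {
  s <- make_scene(scene_params(n_aligned_kt = 46), seed = 31)
  acq <- acq_params()
  gt <- scene_ground_truth(s, 1, acq, channels = "ER")
  kt <- gt$kinetochores_um
  ks <- kinetochore_set(rbind(
    data.frame(x_um = kt$x, y_um = kt$y, z_um = kt$z, label = kt$class),
    data.frame(x_um = scene_offset(acq)[1] + c(1.6, -1.6),
               y_um = scene_offset(acq)[2], z_um = scene_offset(acq)[3],
               label = "pole")))
  C <- aligned_centroid(ks)
  expect_lt(vnorm <- sqrt(sum((C - (s$plate$center + scene_offset(acq)))^2)),
            max(acq$voxel_size) / 2)
})

test_that("boundary intersection matches the closed-form sphere and ellipsoid solutions", {
  dims <- c(96, 96, 40)
  voxel <- c(0.15, 0.15, 0.3)
  ctr <- (dims - 1) * voxel / 2
  sph <- ellipsoid_mask3d(dims, voxel, ctr, c(5, 5, 5))
  set.seed(4)
  for (i in 1:20) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    Q <- boundary_intersection(ctr, ctr + 8 * u, sph)
    expect_lt(abs(sqrt(sum((Q - ctr)^2)) - 5), 0.16)
  }
  ell <- ellipsoid_mask3d(dims, voxel, ctr, c(6, 4, 3))
  u <- c(1, 1, 1) / sqrt(3)
  t_true <- ray_ellipsoid_dist(ctr, u, ctr, c(6, 4, 3))
  Q <- boundary_intersection(ctr, ctr + 7 * u, ell)
  expect_lt(abs(sqrt(sum((Q - ctr)^2)) - t_true), 0.16)
})

test_that("marching continues past P when P is inside, and errors are explicit", {
  dims <- c(64, 64, 24); voxel <- c(0.15, 0.15, 0.3)
  ctr <- (dims - 1) * voxel / 2
  sph <- ellipsoid_mask3d(dims, voxel, ctr, c(3, 3, 3))
  P_in <- ctr + c(1, 0, 0)
  Q <- boundary_intersection(ctr, P_in, sph)
  expect_equal(sqrt(sum((Q - ctr)^2)), 3, tolerance = 0.05)
  P_on <- ctr + c(3, 0, 0)
  Q2 <- boundary_intersection(ctr, P_on, sph)
  expect_equal(sqrt(sum((Q2 - ctr)^2)), sqrt(sum((P_on - ctr)^2)), tolerance = 0.05)
  expect_error(boundary_intersection(ctr + c(5, 0, 0), ctr + c(6, 0, 0), sph),
               "not inside")
  expect_error(boundary_intersection(ctr, ctr, sph), "coincides")
  whole <- mitoez:::new_mask3d(array(TRUE, dims), voxel, list())
  expect_error(boundary_intersection(ctr, ctr + c(1, 0, 0), whole), "no boundary crossing")
})

test_that("log2 ratio calibration: boundary 0, double distance 1, half distance -1", {
  C <- c(0, 0, 0)
  expect_equal(ez_ratio(C, c(10, 0, 0), c(5, 0, 0))$log2_ratio, 1)
  expect_equal(ez_ratio(C, c(5, 0, 0), c(5, 0, 0))$log2_ratio, 0)
  expect_equal(ez_ratio(C, c(2.5, 0, 0), c(5, 0, 0))$log2_ratio, -1)
  expect_error(ez_ratio(C, c(1, 0, 0), C), "CQ")
})

test_that("log2 ratio is strictly increasing along a fixed ray", {
  dims <- c(64, 64, 24); voxel <- c(0.15, 0.15, 0.3)
  ctr <- (dims - 1) * voxel / 2
  m <- ellipsoid_mask3d(dims, voxel, ctr, c(3.5, 2.5, 2))
  u <- c(0.8, 0.6, 0) / 1
  rr <- vapply(seq(0.5, 4, by = 0.5), function(d) {
    P <- ctr + d * u
    Q <- boundary_intersection(ctr, P, m)
    ez_ratio(ctr, P, Q)$log2_ratio
  }, numeric(1))
  expect_true(all(diff(rr) > 0))
})

test_that("ratio sign agrees with exclusion-zone membership outside a one-voxel band", {
  s <- make_scene(scene_params(), seed = 17)
  acq <- acq_params()
  gt <- scene_ground_truth(s, 1, acq, channels = "ER")
  ez <- mitoez:::new_mask3d(gt$ez_mask, acq$voxel_size, list())
  ks <- kinetochore_set(rbind(
    data.frame(x_um = gt$kinetochores_um$x, y_um = gt$kinetochores_um$y,
               z_um = gt$kinetochores_um$z, label = gt$kinetochores_um$class),
    data.frame(x_um = scene_offset(acq)[1] + c(1.6, -1.6),
               y_um = scene_offset(acq)[2], z_um = scene_offset(acq)[3], label = "pole")))
  rr <- ez_ratios(ks, ez)
  expect_true(all(is.finite(rr$log2_ratio)))
  for (i in seq_len(nrow(rr))) {
    P <- as.numeric(ks$kt[i, c("x", "y", "z")])
    inside <- mitoez:::point_in_mask(P, ez)
    band <- abs(rr$CP_um[i] - rr$CQ_um[i]) <= max(acq$voxel_size)
    if (!band) {
      if (inside) expect_lt(rr$log2_ratio[i], 0) else expect_gt(rr$log2_ratio[i], 0)
    }
  }
})

test_that("log2 ratio is invariant under rigid motion of the whole grid", {
  dims <- c(72, 72, 28); voxel <- c(0.15, 0.15, 0.3)
  ctr <- (dims - 1) * voxel / 2
  semi <- c(3, 2.4, 1.8)
  m1 <- ellipsoid_mask3d(dims, voxel, ctr, semi)
  # rotate the scene 90 degrees about z: the ellipsoid swaps x/y semi-axes
  m2 <- ellipsoid_mask3d(dims, voxel, ctr, semi[c(2, 1, 3)])
  P1 <- ctr + c(2.0, 1.2, 0.8)
  P2 <- ctr + c(-1.2, 2.0, 0.8)
  r1 <- ez_ratio(ctr, P1, boundary_intersection(ctr, P1, m1))$log2_ratio
  r2 <- ez_ratio(ctr, P2, boundary_intersection(ctr, P2, m2))$log2_ratio
  expect_equal(r1, r2, tolerance = 0.05)
})

test_that("ensheathment score separates rendered ensheathed from free objects", {
  s <- make_scene(scene_params(n_free = 1, n_ensheathed = 1), seed = 42)
  acq <- acq_params(channels = "ER")
  erm <- binarize_channel(render_stack(s, 1, acq), "ER")
  gt <- scene_ground_truth(s, 1, acq, channels = c("ER", "DNA"))
  for (i in seq_len(nrow(s$objects))) {
    r <- classify_misaligned(gt$object_masks[[s$objects$id[i]]], erm)
    expect_equal(r$class, s$objects$class[i])
    if (s$objects$class[i] == "ensheathed") expect_gte(r$score, 0.95)
  }
  # deep inside the EZ there is no ER at all within the shell; a small
  # chromosome and relaxed plate clearance let it sit well inside
  deep <- make_scene(scene_params(n_free = 1, n_ensheathed = 0, chrom_radius = 0.3,
                                  free_scale_range = c(0.5, 0.55),
                                  plate_clearance = 0.2), seed = 3)
  gtd <- scene_ground_truth(deep, 1, acq, channels = c("ER", "DNA"))
  ermd <- binarize_channel(render_stack(deep, 1, acq), "ER")
  rd <- classify_misaligned(gtd$object_masks[["obj1"]], ermd)
  expect_lte(rd$score, 0.05)
  expect_equal(rd$class, "free")
})

test_that("empty ER mask yields score 0 and class free; manual mode needs annotation", {
  obj <- array(FALSE, c(16, 16, 6)); obj[7:9, 7:9, 3] <- TRUE
  empty_er <- mitoez:::new_mask3d(array(FALSE, c(16, 16, 6)), c(0.1, 0.1, 0.5), list())
  r <- classify_misaligned(obj, empty_er)
  expect_equal(r$class, "free")
  expect_equal(r$score, 0)
  expect_equal(classify_misaligned(obj, empty_er, mode = "manual",
                                   annotation = "ensheathed")$class, "ensheathed")
  expect_error(classify_misaligned(obj, empty_er, mode = "manual"), "no annotation")
})

test_that("canonical registration is identity-like in canonical pose and rigid invariant", {
  mk_kset <- function(R = diag(3), tr = c(0, 0, 0), cell = "c1") {
    set.seed(10)
    al <- cbind(runif(10, -0.3, 0.3), runif(10, -1.2, 1.2), runif(10, -1.1, 1.1))
    al <- sweep(al, 2, colMeans(al))   # aligned centroid exactly at the origin
    pts <- rbind(al, c(2.5, 0.4, 0.2), c(1.6, 0, 0), c(-1.6, 0, 0))
    pts <- t(R %*% t(pts)) + matrix(tr, nrow(pts), 3, byrow = TRUE)
    kinetochore_set(data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                               label = c(rep("aligned", 10), "ensheathed",
                                         "pole", "pole")), cell)
  }
  base <- register_canonical(list(mk_kset()))
  poles <- base[base$class == "pole", c("x", "y", "z")]
  expect_equal(sort(poles$x), c(-1.6, 1.6), tolerance = 1e-9)
  expect_equal(unlist(poles[, c("y", "z")], use.names = FALSE), rep(0, 4), tolerance = 1e-9)
  expect_gt(base$x[base$class == "ensheathed"], 0)
  set.seed(99)
  for (i in 1:5) {
    th <- runif(2, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])),
                 3, 3, byrow = TRUE)
    Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2]), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    moved <- register_canonical(list(mk_kset(Rz %*% Rx, runif(3, -5, 5))))
    expect_equal(as.matrix(moved[, c("x", "y", "z")]),
                 as.matrix(base[, c("x", "y", "z")]), tolerance = 1e-6)
  }
  degenerate <- mk_kset()
  degenerate$poles[2, ] <- degenerate$poles[1, ]
  expect_error(register_canonical(list(degenerate)), "coincident")
})
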