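# 4D tracking: linking, congression and anaphase detection, fluorescence
# ratio quantification and the pooled Mad2 regression.

# Labeled frames built directly from spheres placed in code (no rendering).
frames_from_centers <- function(centers_by_frame, voxel = c(0.15, 0.15, 0.5),
                                dims = c(48, 48, 12), radii = NULL) {
  lapply(centers_by_frame, function(cs) {
    m <- array(FALSE, dims)
    for (i in seq_len(nrow(cs))) {
      r <- if (is.null(radii)) 0.4 else radii[i]
      m <- m | (mitoez:::dist2_grid(dims, voxel, cs[i, ]) <= r^2)
    }
    label_dna_objects(mitoez:::new_mask3d(m, voxel, list()), min_volume = 0.01)
  })
}

test_that("two stationary objects stay two tracks with no identity swaps", {
  a <- c(1.5, 1.5, 2.5); b <- c(5.5, 5.5, 2.5); plate <- c(3.5, 3.5, 2.5)
  frames <- frames_from_centers(replicate(5, rbind(plate, a, b), simplify = FALSE),
                                radii = c(0.8, 0.4, 0.4))
  trk <- link_objects(frames)
  expect_equal(length(trk$tracks), 2)
  for (tr in trk$tracks) {
    expect_equal(nrow(tr), 5)
    expect_equal(length(unique(round(tr$x, 6))), 1)
  }
  expect_equal(nrow(trk$plate), 5)
})

test_that("a slow-moving object yields one unbroken track; a gate jump splits it", {
  plate <- c(3.5, 3.5, 2.5)
  moving <- lapply(0:4, function(t) rbind(plate, c(1.0 + 0.5 * t, 1.2, 2.5)))
  trk <- link_objects(frames_from_centers(moving, radii = c(0.8, 0.4)))
  expect_equal(length(trk$tracks), 1)
  expect_equal(nrow(trk$tracks[[1]]), 5)
  jumping <- lapply(0:4, function(t) rbind(plate, c(1.0 + if (t >= 3) 3 else 0.2 * t, 1.2, 2.5)))
  trk2 <- link_objects(frames_from_centers(jumping, radii = c(0.8, 0.4)))
  expect_equal(length(trk2$tracks), 2)   # jump beyond the 2 µm gate starts a new track
  expect_error(link_objects(list()), "empty")
})

test_that("congression is the first frame of shared chromosome/plate labels", {
  sc <- tracking_scene(seed = 5)
  cong <- vapply(seq_along(sc$tracks$tracks), function(i)
    detect_congression(sc$tracks$tracks[[i]], sc$tracks$plate, sc$frames), numeric(1))
  first <- vapply(sc$tracks$tracks, function(tr) tr$frame[1], numeric(1))
  expect_equal(sort(cong[first == 1], na.last = TRUE), c(7, NA))
  # never-merging stationary object
  frames <- frames_from_centers(replicate(4, rbind(c(3.5, 3.5, 2.5), c(1.0, 1.0, 2.5)),
                                          simplify = FALSE), radii = c(0.8, 0.4))
  trk <- link_objects(frames)
  expect_true(is.na(detect_congression(trk$tracks[[1]], trk$plate, frames)))
  # merged from the very first frame: the track label is the plate label
  pl <- trk$plate
  expect_equal(detect_congression(pl, pl, frames), 1)
})

test_that("distance to plate decreases to congression in synthetic scenes", {
  sc <- tracking_scene(seed = 8)
  first <- vapply(sc$tracks$tracks, function(tr) tr$frame[1], numeric(1))
  cong <- vapply(seq_along(sc$tracks$tracks), function(i)
    detect_congression(sc$tracks$tracks[[i]], sc$tracks$plate, sc$frames), numeric(1))
  tr <- sc$tracks$tracks[[which(first == 1 & !is.na(cong))[1]]]
  expect_lt(tr$dist_to_plate[nrow(tr)], tr$dist_to_plate[1])
})

test_that("anaphase detection requires two persistent separating children", {
  sc <- tracking_scene(seed = 3)
  ev <- detect_anaphase(sc$tracks$plate, sc$frames)
  expect_equal(ev$frame, 12)
  expect_true(all(diff(ev$separation) > 0))
  expect_true(all(ev$child_volumes >= 0.25 * sc$tracks$plate$volume[11]))
  # a plate that never splits
  frames <- frames_from_centers(replicate(6, matrix(c(3.5, 3.5, 2.5), 1), simplify = FALSE),
                                radii = 0.8)
  trk <- link_objects(frames)
  expect_error(detect_anaphase(trk$plate, frames), "anaphase not detected")
})

test_that("a transient one-frame split is not called as anaphase", {
  plate <- c(3.5, 3.5, 2.5)
  centers <- list(matrix(plate, 1), matrix(plate, 1),
                  rbind(plate - c(0.9, 0, 0), plate + c(0.9, 0, 0)),  # 1-frame flicker
                  matrix(plate, 1), matrix(plate, 1), matrix(plate, 1))
  frames <- frames_from_centers(centers, radii = c(0.7, 0.7))
  trk <- link_objects(frames)
  expect_error(detect_anaphase(trk$plate, frames), "anaphase not detected")
})

test_that("signal ratios: uniform channel gives 1 and doubling leaves ratios unchanged", {
  sc <- tracking_scene(seed = 2, acq = acq_params(channels = c("DNA", "SAC")))
  stack <- sc$stack
  stack$values[, , , 2, ] <- 11   # uniform SAC channel
  first <- vapply(sc$tracks$tracks, function(tr) tr$frame[1], numeric(1))
  tr <- sc$tracks$tracks[[which(first == 1)[1]]]
  for (mode in c("mean_voxel", "max_per_z")) {
    q <- quantify_signal(tr, stack, sc$frames, "SAC", mode = mode)
    expect_equal(q$ratio[!is.na(q$ratio)],
                 rep(1, sum(!is.na(q$ratio))), tolerance = 1e-9)
  }
  stack2 <- sc$stack
  q1 <- quantify_signal(tr, sc$stack, sc$frames, "SAC", mode = "max_per_z")
  stack2$values <- stack2$values * 2
  q2 <- quantify_signal(tr, stack2, sc$frames, "SAC", mode = "max_per_z")
  expect_equal(q2$ratio, q1$ratio, tolerance = 1e-9)
})

test_that("Mad2 max-per-z ratio at SNR 10 matches the zero-noise quantification within 10%", {
  p <- scene_params(n_free = 1, n_ensheathed = 0, congression_frames = NA_integer_,
                    n_frames = 3L, mad2_initial_ratio = 4)
  s <- make_scene(p, seed = 3)
  ratios <- lapply(c(0, 2), function(sd) {   # sd = plate Mad2 signal / 10
    acq <- acq_params(channels = c("DNA", "SAC"), gaussian_sd = sd, seed = 9)
    ts <- render_timeseries(s, acq)
    frames <- lapply(1:3, function(t) label_dna_objects(binarize_channel(ts$stack, "DNA", t)))
    trk <- link_objects(frames)
    quantify_signal(trk$tracks[[1]], ts$stack, frames, "SAC", mode = "max_per_z")$ratio
  })
  expect_true(all(abs(ratios[[2]] / ratios[[1]] - 1) < 0.10))
  # the rendered ratio tracks the linear ground-truth decay
  expect_true(all(diff(ratios[[1]]) < 0))
})

test_that("trace gaps are recorded as NA, not errors, when the object vanishes", {
  sc <- tracking_scene(seed = 2, acq = acq_params(channels = c("DNA", "SAC")))
  first <- vapply(sc$tracks$tracks, function(tr) tr$frame[1], numeric(1))
  cong <- vapply(seq_along(sc$tracks$tracks), function(i)
    detect_congression(sc$tracks$tracks[[i]], sc$tracks$plate, sc$frames), numeric(1))
  tr <- sc$tracks$tracks[[which(first == 1 & !is.na(cong))[1]]]
  q <- quantify_signal(tr, sc$stack, sc$frames, "SAC", mode = "max_per_z")
  expect_equal(nrow(q), length(sc$frames))
  expect_true(all(is.na(q$ratio[q$frame >= cong[which(first == 1 & !is.na(cong))[1]]])))
})

test_that("noiseless linear Mad2 traces give exact slope; flat trace gives slope 0", {
  tt <- seq(-30, 0, by = 3)
  tr <- do.call(rbind, lapply(1:3, function(cell)
    data.frame(cell = cell, t_rel_min = tt, ratio = 4 + -0.05 * tt, is_last = TRUE)))
  fit <- mad2_regression(tr)
  expect_equal(fit$slope, -0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, 4, tolerance = 1e-12)
  flat <- data.frame(cell = 1, t_rel_min = tt, ratio = 4, is_last = TRUE)
  fitf <- suppressWarnings(mad2_regression(flat))
  expect_equal(fitf$slope, 0, tolerance = 1e-12)
  expect_equal(fitf$intercept, 4, tolerance = 1e-12)
  expect_error(suppressWarnings(mad2_regression(data.frame(cell = 1, t_rel_min = 0,
                                                           ratio = 1, is_last = TRUE))),
               "fewer than 3")
})

test_that("last-chromosome filter keeps one chromosome per cell", {
  tt <- seq(-9, 0, by = 3)
  tr <- rbind(data.frame(cell = 1, chrom = "a", t_rel_min = tt, ratio = 1, is_last = FALSE),
              data.frame(cell = 1, chrom = "b", t_rel_min = tt, ratio = 2 - 0.01 * tt,
                         is_last = TRUE),
              data.frame(cell = 2, chrom = "c", t_rel_min = tt, ratio = 2 - 0.01 * tt,
                         is_last = TRUE))
  fit <- mad2_regression(tr, congressed_only_last = TRUE)
  expect_equal(fit$n_points, 8)
  expect_equal(fit$slope, -0.01, tolerance = 1e-10)
})

test_that("95% CI covers a true slope of -0.05/min in >= 90% of simulated cohorts", {
  hits <- vapply(1:120, function(rep) {
    set.seed(4000 + rep)
    tt <- seq(-30, 0, by = 3)
    rows <- do.call(rbind, lapply(1:8, function(cell)
      data.frame(cell = cell, t_rel_min = tt,
                 ratio = 4 + (-0.05) * tt + rnorm(length(tt), 0, 0.5), is_last = TRUE)))
    fit <- mad2_regression(rows)
    fit$ci[2, 1] <= -0.05 && -0.05 <= fit$ci[2, 2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
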