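# Synthetic mitotic scenes with exhaustive ground truth. A scene models one
# mitotic cell: a convex cell ellipsoid, an ER-free exclusion zone (EZ)
# ellipsoid around the spindle, a metaphase plate (oblate ellipsoid, normal
# along x, the pole-pole axis), misaligned chromosome objects that are
# either "free" (at/inside the EZ boundary, no surrounding ER) or
# "ensheathed" (beyond the EZ, wrapped in 3-4 concentric endomembrane
# layers), kinetochores, spindle poles, kinastrin puncta, and time-lapse
# events: congression (object merges with the plate), anaphase (plate
# splits), and ER clearance (ER relocates to a thin layer under the plasma
# membrane). Scene coordinates are µm with the cell centre at the origin;
# rendering maps the origin to the grid centre (see [scene_offset()]).

#' Scene parameters for the synthetic generator
#'
#' Defaults describe a flattened mitotic cell with a clear exclusion zone and
#' one misaligned chromosome of each class. All lengths are µm, times are
#' frames (1-based) or minutes where stated.
#'
#' @param cell_semi,ez_semi,plate_semi ellipsoid semi-axes (x, y, z). The
#'   plate is oblate with its normal along x (the spindle axis).
#' @param pole_offset poles sit at +/- this vector from the centre.
#' @param n_aligned_kt number of aligned kinetochores scattered in the plate.
#' @param kt_min_spacing minimum pairwise distance (µm) between aligned
#'   kinetochores (0 = unconstrained); useful when per-kinetochore
#'   attachment fractions must be recoverable without neighbour crosstalk.
#' @param n_free,n_ensheathed numbers of misaligned chromosome objects.
#' @param chrom_radius misaligned chromosome radius.
#' @param n_layers_range inclusive range for the number of ensheathing
#'   membrane layers (3-4 by default).
#' @param layer_thickness,layer_spacing radial thickness of each ensheathing
#'   layer and centre-to-centre spacing between consecutive layers.
#' @param free_scale_range,ensheathed_scale_range placement of object centres
#'   as a multiple of the EZ ellipsoid (free: inside/on; ensheathed: outside).
#' @param congression_frames integer vector (NA = never), one per misaligned
#'   object (free objects first), giving the frame at which the object merges
#'   with the plate.
#' @param anaphase_frame,clearance_frame frame of plate splitting / ER
#'   clearance (NA = never).
#' @param clearance_fraction fraction of the ER signal outside the EZ that is
#'   lost at clearance (the rest is retained in a thin subcortical layer).
#' @param n_frames,frame_interval movie length and frame spacing (minutes).
#' @param mad2_initial_ratio,mad2_slope_per_min linear Mad2 kinetics: the
#'   chromosome/plate ratio at the reference time (anaphase, or movie end)
#'   and its slope per minute.
#' @param p_attach named per-class probabilities that a kinetochore carries a
#'   kinastrin punctum at `attach_dist`; defaults use the observed attachment
#'   fractions for aligned/free/ensheathed kinetochores.
#' @param attach_dist distance (µm) of an attached punctum from its
#'   kinetochore.
#' @param n_bg_puncta,bg_min_dist background puncta count and their minimum
#'   distance from any kinetochore.
#' @param congression_speed chromosome speed during congression (µm/frame).
#' @param plate_clearance extra clearance (µm, beyond the chromosome radius)
#'   required between a placed object and the plate surface; the default
#'   keeps pre-congression objects separable from the plate after PSF
#'   blurring.
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(cell_semi = c(4.5, 4.5, 3.4),
                         ez_semi = c(2.0, 2.0, 1.9),
                         plate_semi = c(0.5, 1.4, 1.3),
                         pole_offset = c(1.6, 0, 0),
                         n_aligned_kt = 40, kt_min_spacing = 0,
                         n_free = 1, n_ensheathed = 1,
                         chrom_radius = 0.5,
                         n_layers_range = c(3L, 4L),
                         layer_thickness = 0.2, layer_spacing = 0.3,
                         free_scale_range = c(0.55, 0.95),
                         ensheathed_scale_range = c(1.10, 1.35),
                         congression_frames = NULL,
                         anaphase_frame = NA_integer_,
                         clearance_frame = NA_integer_,
                         clearance_fraction = 0.8,
                         n_frames = 1L, frame_interval = 3,
                         mad2_initial_ratio = 4, mad2_slope_per_min = -0.05,
                         p_attach = c(aligned = 0.268, free = 0.041, ensheathed = 0.062),
                         attach_dist = 0.3,
                         n_bg_puncta = 30L, bg_min_dist = 1.0,
                         congression_speed = 0.7,
                         plate_clearance = 0.55) {
  p <- as.list(environment())
  if (any(p$cell_semi <= 0) || any(p$ez_semi <= 0) || any(p$plate_semi <= 0))
    stopf("ellipsoid semi-axes must be positive")
  if (p$chrom_radius <= 0) stopf("chrom_radius must be positive")
  if (p$n_frames < 1) stopf("n_frames must be >= 1")
  if (any(p$ez_semi >= p$cell_semi)) stopf("EZ ellipsoid must be strictly inside the cell")
  if (any(p$plate_semi >= p$ez_semi)) stopf("plate must be strictly inside the EZ")
  n_mis <- p$n_free + p$n_ensheathed
  if (is.null(p$congression_frames)) p$congression_frames <- rep(NA_integer_, n_mis)
  if (length(p$congression_frames) != n_mis)
    stopf("congression_frames must have one entry per misaligned object (%d)", n_mis)
  if (!is.na(p$anaphase_frame)) {
    cf <- p$congression_frames[!is.na(p$congression_frames)]
    if (any(cf >= p$anaphase_frame)) stopf("congression frames must precede anaphase_frame")
  }
  class(p) <- "scene_params"
  p
}

# Radial extent of an ensheathed object including its membrane layers.
shell_extent <- function(p, n_layers) (n_layers - 1) * p$layer_spacing + p$layer_thickness

#' Generate a synthetic scene
#'
#' All stochastic placement (object directions, kinetochore scatter, puncta)
#' is drawn from an RNG seeded with `seed`; the same parameters and seed give
#' an identical scene. Errors if a requested misaligned object cannot fit
#' between the EZ and the cell boundary.
#'
#' @param params a [scene_params()] list.
#' @param seed integer seed.
#' @return an object of class `scene_truth`.
#' @export
make_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  with_seed(seed, {
    n_mis <- p$n_free + p$n_ensheathed
    classes <- c(rep("free", p$n_free), rep("ensheathed", p$n_ensheathed))
    plate_clear <- function(pos)
      vnorm(pos - ellipsoid_nearest_point(p$plate_semi, pos))
    objs <- vector("list", n_mis)
    for (i in seq_len(n_mis)) {
      cls <- classes[i]
      n_layers <- if (cls == "ensheathed")
        sample(seq(p$n_layers_range[1], p$n_layers_range[2]), 1) else 0L
      margin <- p$chrom_radius + (if (cls == "ensheathed") shell_extent(p, n_layers) else 0) + 0.15
      placed <- FALSE
      for (try in 1:200) {
        # ensheathed objects go in the equatorial band, off the spindle axis
        # (clear of the anaphase corridor and poles) and away from the
        # flattened z faces; free objects sit anywhere in/at the EZ with
        # enough clearance from the plate, which favours the polar regions
        repeat {
          u <- runit3(max_abs_z = if (cls == "ensheathed") 0.3 else 0.5)
          if (cls == "free" || abs(u[1]) <= 0.5) break
        }
        s <- if (cls == "ensheathed") runif(1, p$ensheathed_scale_range[1], p$ensheathed_scale_range[2])
             else runif(1, p$free_scale_range[1], p$free_scale_range[2])
        pos <- s * p$ez_semi * u
        # must fit inside the cell with room for the shells
        probes <- rbind(pos + c(margin, 0, 0), pos - c(margin, 0, 0),
                        pos + c(0, margin, 0), pos - c(0, margin, 0),
                        pos + c(0, 0, margin), pos - c(0, 0, margin))
        if (any(colSums((t(probes) / p$cell_semi)^2) > 1)) next
        # keep clear of the plate (true surface distance, not axis
        # inflation); the gap must survive PSF blurring so objects stay
        # separate connected components until they actually congress
        if (sum((pos / p$plate_semi)^2) <= 1 ||
            plate_clear(pos) < p$chrom_radius + p$plate_clearance) next
        # keep clear of previously placed objects
        if (i > 1 && any(vapply(objs[seq_len(i - 1)], function(o)
          vnorm(pos - c(o$x, o$y, o$z)) < 2 * p$chrom_radius + 0.3, logical(1)))) next
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("infeasible geometry: %s object %d cannot fit between EZ and cell boundary", cls, i)
      objs[[i]] <- data.frame(id = sprintf("obj%d", i), x = pos[1], y = pos[2], z = pos[3],
                              radius = p$chrom_radius, class = cls, n_layers = n_layers,
                              congression_frame = p$congression_frames[i])
    }
    objects <- if (n_mis) do.call(rbind, objs) else
      data.frame(id = character(), x = numeric(), y = numeric(), z = numeric(),
                 radius = numeric(), class = character(), n_layers = integer(),
                 congression_frame = integer())

    # aligned kinetochores scattered through the plate volume
    akt <- matrix(0, p$n_aligned_kt, 3)
    for (k in seq_len(p$n_aligned_kt)) {
      ok <- FALSE
      for (try in 1:400) {
        yz <- runif(2, -0.85, 0.85) * p$plate_semi[2:3]
        if ((yz[1] / p$plate_semi[2])^2 + (yz[2] / p$plate_semi[3])^2 > 0.85^2) next
        cand <- c(runif(1, -0.3, 0.3) * p$plate_semi[1], yz)
        if (p$kt_min_spacing > 0 && k > 1 &&
            min(sqrt(colSums((t(akt[seq_len(k - 1), , drop = FALSE]) - cand)^2))) <
              p$kt_min_spacing) next
        ok <- TRUE
        break
      }
      if (!ok) stopf("infeasible geometry: cannot place %d aligned kinetochores at spacing %g µm",
                     p$n_aligned_kt, p$kt_min_spacing)
      akt[k, ] <- cand
    }
    kts <- data.frame(id = sprintf("kt%d", seq_len(p$n_aligned_kt)),
                      x = akt[, 1], y = akt[, 2], z = akt[, 3],
                      class = "aligned", parent = "plate")
    # one sister-kinetochore pair per misaligned object
    if (n_mis) for (i in seq_len(n_mis)) {
      u <- runit3()
      for (sgn in c(-1, 1)) {
        pos <- as.numeric(objects[i, c("x", "y", "z")]) + sgn * 0.1 * u
        kts <- rbind(kts, data.frame(id = sprintf("kt%s_%d", objects$id[i], (sgn + 3) / 2),
                                     x = pos[1], y = pos[2], z = pos[3],
                                     class = objects$class[i], parent = objects$id[i]))
      }
    }

    # kinastrin puncta: per-kinetochore attachment by class probability, plus
    # background puncta kept >= bg_min_dist from every kinetochore
    pn <- list()
    for (k in seq_len(nrow(kts))) {
      if (runif(1) < p$p_attach[[kts$class[k]]]) {
        u <- runit3()
        pn[[length(pn) + 1]] <- data.frame(x = kts$x[k] + p$attach_dist * u[1],
                                           y = kts$y[k] + p$attach_dist * u[2],
                                           z = kts$z[k] + p$attach_dist * u[3],
                                           attached = TRUE, parent = kts$id[k])
      }
    }
    ktm <- as.matrix(kts[, c("x", "y", "z")])
    n_bg <- 0
    for (try in seq_len(50 * p$n_bg_puncta)) {
      if (n_bg >= p$n_bg_puncta) break
      u <- runit3()
      s <- runif(1)^(1 / 3) * 0.92
      pos <- s * p$cell_semi * u
      dmin <- sqrt(min(colSums((t(ktm) - pos)^2)))
      if (dmin < p$bg_min_dist) next
      n_bg <- n_bg + 1
      pn[[length(pn) + 1]] <- data.frame(x = pos[1], y = pos[2], z = pos[3],
                                         attached = FALSE, parent = NA_character_)
    }
    puncta <- if (length(pn)) do.call(rbind, pn) else
      data.frame(x = numeric(), y = numeric(), z = numeric(),
                 attached = logical(), parent = character())

    scene <- structure(list(
      cell = list(center = c(0, 0, 0), semi = p$cell_semi),
      ez = list(center = c(0, 0, 0), semi = p$ez_semi),
      plate = list(center = c(0, 0, 0), semi = p$plate_semi),
      objects = objects,
      kinetochores = kts,
      poles = rbind(p$pole_offset, -p$pole_offset),
      puncta = puncta,
      clearance_frame = p$clearance_frame,
      clearance_fraction = p$clearance_fraction,
      anaphase_frame = p$anaphase_frame,
      n_frames = p$n_frames,
      frame_interval = p$frame_interval,
      mad2 = list(initial_ratio = p$mad2_initial_ratio, slope_per_min = p$mad2_slope_per_min),
      params = p, seed = seed), class = "scene_truth")
    scene
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("scene_truth (seed %d): cell semi (%s) µm, EZ semi (%s) µm\n", x$seed,
              paste(x$cell$semi, collapse = ", "), paste(x$ez$semi, collapse = ", ")))
  cat(sprintf("  %d misaligned object(s) [%s], %d kinetochores, %d puncta, %d frame(s)\n",
              nrow(x$objects), paste(x$objects$class, collapse = ", "),
              nrow(x$kinetochores), nrow(x$puncta), x$n_frames))
  cat(sprintf("  events: congression (%s), anaphase %s, clearance %s\n",
              paste(x$objects$congression_frame, collapse = ", "),
              x$anaphase_frame, x$clearance_frame))
  invisible(x)
}

#' Audit a scene against its geometric invariants
#'
#' Checks (by the ellipsoid point-membership equation) that the EZ lies
#' strictly inside the cell and the plate inside the EZ, that every
#' ensheathed object centre is outside the EZ and every free centre inside or
#' on its boundary, and that the layer count and event ordering are valid.
#' @param scene a `scene_truth`.
#' @return TRUE invisibly; errors describing the first violated invariant.
#' @export
audit_scene <- function(scene) {
  ez_in_cell <- all(scene$ez$semi < scene$cell$semi)
  if (!ez_in_cell) stopf("invariant violated: EZ not strictly inside cell")
  if (!all(scene$plate$semi < scene$ez$semi)) stopf("invariant violated: plate not strictly inside EZ")
  if (nrow(scene$objects)) {
    form <- colSums((t(as.matrix(scene$objects[, c("x", "y", "z")])) / scene$ez$semi)^2)
    ens <- scene$objects$class == "ensheathed"
    if (any(form[ens] <= 1)) stopf("invariant violated: ensheathed object centre inside EZ")
    if (any(form[!ens] > 1 + 1e-9)) stopf("invariant violated: free object centre outside EZ")
    nl <- scene$objects$n_layers[ens]
    if (length(nl) && (any(nl < scene$params$n_layers_range[1]) || any(nl > scene$params$n_layers_range[2])))
      stopf("invariant violated: ensheathing layer count outside allowed range")
  }
  cf <- scene$objects$congression_frame
  if (!is.na(scene$anaphase_frame) && any(!is.na(cf) & cf >= scene$anaphase_frame))
    stopf("invariant violated: congression at/after anaphase")
  invisible(TRUE)
}

#' Acquisition parameters for rendering
#'
#' @param dims grid size (x, y, z) in voxels.
#' @param voxel_size µm per voxel along (x, y, z); z spacing may exceed xy.
#' @param channels channel roles to render, a subset of
#'   ER, DNA, PM, KT, SAC, KIN.
#' @param gaussian_sd additive Gaussian read-noise SD (intensity units; the
#'   structural plateau is 100, so `gaussian_sd = 10` is SNR 10).
#' @param poisson_scale photon scale for Poisson shot noise (0 = off);
#'   intensities are scaled by this, Poisson sampled, and scaled back.
#' @param psf_sigma isotropic PSF Gaussian sigma in µm applied to every
#'   channel before noise.
#' @param seed integer seed for the noise RNG (placement noise lives in
#'   [make_scene()]); identical seed means identical output.
#' @export
acq_params <- function(dims = c(96, 96, 20), voxel_size = c(0.1, 0.1, 0.5),
                       channels = c("ER", "DNA"), gaussian_sd = 0,
                       poisson_scale = 0, psf_sigma = 0.1, seed = 1L) {
  if (any(voxel_size <= 0)) stopf("voxel sizes must be positive")
  if (any(dims < 1)) stopf("grid dimensions must be >= 1")
  bad <- setdiff(channels, CHANNEL_ROLES)
  if (length(bad)) stopf("unknown channel role(s): %s", paste(bad, collapse = ", "))
  structure(list(dims = as.integer(dims), voxel_size = as.numeric(voxel_size),
                 channels = channels, gaussian_sd = gaussian_sd,
                 poisson_scale = poisson_scale, psf_sigma = psf_sigma,
                 seed = as.integer(seed)), class = "acq_params")
}

#' Translation from scene coordinates (cell centre at origin) to grid µm
#' @param acq an [acq_params()].
#' @return length-3 µm offset: grid position = scene position + offset.
#' @export
scene_offset <- function(acq) (acq$dims - 1) * acq$voxel_size / 2

# Centre of a misaligned object at frame t (scene frame, µm). Congressing
# objects move in a straight line at constant speed towards the nearest
# plate-boundary contact point, arriving (overlapping the plate) at
# congression_frame and staying merged afterwards.
object_center_at <- function(scene, i, t) {
  ob <- scene$objects[i, ]
  p0 <- c(ob$x, ob$y, ob$z)
  cf <- ob$congression_frame
  if (is.na(cf)) return(p0)
  # approach along the surface normal: from p0 to just past the nearest
  # plate-boundary point, so the Euclidean gap shrinks linearly with time
  q <- ellipsoid_nearest_point(scene$plate$semi, p0 - scene$plate$center) +
    scene$plate$center
  u_out <- (p0 - q) / vnorm(p0 - q)
  pf <- q + 0.6 * ob$radius * u_out   # overlaps the plate by 0.4 r: merged
  if (t >= cf || cf <= 1) return(pf)
  # constant speed, anchored at the merge: the object sits at p0, then walks
  # the last v*(cf - t) µm of the approach, so the final pre-merge step is
  # always a full step and the pre-merge gap is resolvable
  v <- scene$params$congression_speed
  d0 <- vnorm(p0 - pf)
  pf + min(v * (cf - t), d0) * (p0 - pf) / d0
}

# Mad2 chromosome/plate ratio ground truth at frame t (linear decay towards
# the reference time: anaphase onset, or the end of the movie).
mad2_ratio_at <- function(scene, t) {
  t_ref <- if (!is.na(scene$anaphase_frame)) scene$anaphase_frame else scene$n_frames
  r <- scene$mad2$initial_ratio +
    scene$mad2$slope_per_min * (t - t_ref) * scene$frame_interval
  max(r, 0.5)
}

# Kinetochore and puncta positions at frame t: points attached to a
# congressing object translate with it.
points_at <- function(scene, pts, t) {
  if (!nrow(pts) || !nrow(scene$objects)) return(pts)
  for (i in seq_len(nrow(scene$objects))) {
    id <- scene$objects$id[i]
    shift <- object_center_at(scene, i, t) -
      as.numeric(scene$objects[i, c("x", "y", "z")])
    sel <- !is.na(pts$parent) & (pts$parent == id | grepl(paste0("^kt", id, "_"), pts$parent))
    if (any(sel) && any(shift != 0)) {
      pts$x[sel] <- pts$x[sel] + shift[1]
      pts$y[sel] <- pts$y[sel] + shift[2]
      pts$z[sel] <- pts$z[sel] + shift[3]
    }
  }
  pts
}

# Clean (pre-PSF, pre-noise) intensity fields and ground-truth masks for one
# frame. Everything is computed analytically on the voxel grid in µm.
build_scene_fields <- function(scene, frame, acq, channels = acq$channels) {
  p <- scene$params
  d <- acq$dims; vs <- acq$voxel_size
  off <- scene_offset(acq)
  span <- (d - 1) * vs
  if (any(2 * scene$cell$semi > span))
    stopf("grid too small to contain cell: needs %s µm, have %s µm",
          paste(round(2 * scene$cell$semi, 2), collapse = "x"),
          paste(round(span, 2), collapse = "x"))
  if (frame < 1 || frame > scene$n_frames)
    stopf("frame %d outside scene duration 1..%d", frame, scene$n_frames)

  form_cell <- ellipsoid_form_grid(d, vs, scene$cell$center + off, scene$cell$semi)
  form_ez <- ellipsoid_form_grid(d, vs, scene$ez$center + off, scene$ez$semi)
  cell_mask <- form_cell <= 1
  ez_mask <- form_ez < 1

  cleared <- !is.na(scene$clearance_frame) && frame >= scene$clearance_frame
  anaphase <- !is.na(scene$anaphase_frame) && frame >= scene$anaphase_frame

  n_obj <- nrow(scene$objects)
  obj_centers <- if (n_obj) t(vapply(seq_len(n_obj), function(i)
    object_center_at(scene, i, frame) + off, numeric(3))) else matrix(0, 0, 3)
  obj_d2 <- if (n_obj) lapply(seq_len(n_obj), function(i)
    dist2_grid(d, vs, obj_centers[i, ])) else list()

  fields <- list()
  truth <- list(cell_mask = cell_mask, ez_mask = ez_mask,
                obj_centers_um = obj_centers, offset = off)

  if ("ER" %in% channels) {
    base <- (form_cell <= 0.96) & (form_ez >= 1)
    for (i in seq_len(n_obj)) {
      clear_r <- scene$objects$radius[i] + 0.15 +
        (if (scene$objects$class[i] == "ensheathed" && !cleared)
          shell_extent(p, scene$objects$n_layers[i]) else 0)
      base <- base & (obj_d2[[i]] > clear_r^2)
    }
    truth$er_base_region <- base
    if (cleared) {
      qthr <- quantile(form_cell[base], scene$clearance_fraction)
      base <- base & (form_cell >= qthr)
    }
    er <- ifelse(base, 100, 0)
    if (!cleared) for (i in seq_len(n_obj)) {
      if (scene$objects$class[i] != "ensheathed") next
      r0 <- scene$objects$radius[i]
      dd <- sqrt(obj_d2[[i]])
      for (l in seq_len(scene$objects$n_layers[i])) {
        lo <- r0 + (l - 1) * p$layer_spacing
        ring <- dd >= lo & dd <= lo + p$layer_thickness & cell_mask
        er[ring] <- 130
      }
    }
    fields$ER <- er
    truth$er_support <- er > 0
  }

  if ("DNA" %in% channels || "SAC" %in% channels) {
    if (!anaphase) {
      plate_mask <- ellipsoid_form_grid(d, vs, scene$plate$center + off, scene$plate$semi) <= 1
    } else {
      sep <- 0.7 + 0.4 * (frame - scene$anaphase_frame)
      child_semi <- c(0.35, 0.85 * scene$plate$semi[2:3])
      plate_mask <- (ellipsoid_form_grid(d, vs, scene$plate$center + off + c(sep, 0, 0), child_semi) <= 1) |
                    (ellipsoid_form_grid(d, vs, scene$plate$center + off - c(sep, 0, 0), child_semi) <= 1)
    }
    truth$plate_mask <- plate_mask
  }
  if ("DNA" %in% channels) {
    dna <- ifelse(truth$plate_mask, 100, 0)
    obj_masks <- list()
    for (i in seq_len(n_obj)) {
      cf <- scene$objects$congression_frame[i]
      merged <- !is.na(cf) && frame >= cf
      # once congressed the chromosome is part of the plate mass; after
      # anaphase it segregates with the children and is no longer distinct
      if (merged && anaphase) next
      m <- obj_d2[[i]] <= scene$objects$radius[i]^2
      obj_masks[[scene$objects$id[i]]] <- m
      dna[m] <- 100
    }
    fields$DNA <- dna
    truth$object_masks <- obj_masks
    truth$dna_support <- dna > 0
  }

  if ("PM" %in% channels) {
    s <- sqrt(form_cell)
    fields$PM <- ifelse(s >= 0.96 & s <= 1.04, 100, 0)
  }

  spot_field <- function(pts, amp, sigma = c(0.12, 0.12, 0.3)) {
    f <- array(0, d)
    ax <- axis_um(d, vs)
    for (k in seq_len(nrow(pts))) {
      ctr <- c(pts$x[k], pts$y[k], pts$z[k]) + off
      ix <- which(abs(ax$x - ctr[1]) <= 4 * sigma[1])
      iy <- which(abs(ax$y - ctr[2]) <= 4 * sigma[2])
      iz <- which(abs(ax$z - ctr[3]) <= 4 * sigma[3])
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- exp(-(ax$x[ix] - ctr[1])^2 / (2 * sigma[1]^2))
      gy <- exp(-(ax$y[iy] - ctr[2])^2 / (2 * sigma[2]^2))
      gz <- exp(-(ax$z[iz] - ctr[3])^2 / (2 * sigma[3]^2))
      add <- amp[min(k, length(amp))] * outer(outer(gx, gy), gz)
      f[ix, iy, iz] <- f[ix, iy, iz] + add
    }
    f
  }

  kts_t <- points_at(scene, scene$kinetochores, frame)
  truth$kinetochores_um <- transform(kts_t, x = x + off[1], y = y + off[2], z = z + off[3])
  if ("KT" %in% channels) fields$KT <- spot_field(kts_t, 200)

  if ("SAC" %in% channels) {
    sac <- ifelse(truth$plate_mask, 20, 0)
    truth$mad2_ratio <- mad2_ratio_at(scene, frame)
    mis <- kts_t[kts_t$class != "aligned", , drop = FALSE]
    if (nrow(mis)) sac <- sac + spot_field(mis, rep(20 * truth$mad2_ratio, nrow(mis)),
                                           sigma = c(0.15, 0.15, 0.45))
    fields$SAC <- sac
  }

  if ("KIN" %in% channels) {
    pts_t <- points_at(scene, scene$puncta, frame)
    truth$puncta_um <- if (nrow(pts_t))
      transform(pts_t, x = x + off[1], y = y + off[2], z = z + off[3]) else pts_t
    fields$KIN <- spot_field(pts_t, 150)
  }

  list(fields = fields, truth = truth)
}

#' Ground-truth masks and positions for one frame
#'
#' Exposes the analytic (pre-PSF, pre-noise) supports used by the renderer:
#' cell/EZ masks, ER support (including ensheathing layers), DNA supports per
#' object, plate mask, and kinetochore/puncta positions in grid µm.
#' @param scene a `scene_truth`.
#' @param frame frame index.
#' @param acq an [acq_params()].
#' @param channels channels whose truth to build.
#' @export
scene_ground_truth <- function(scene, frame, acq, channels = c("ER", "DNA", "KT", "KIN")) {
  build_scene_fields(scene, frame, acq, channels)$truth
}

#' Render one frame of a scene to a hyperstack
#'
#' Builds each channel analytically, applies the Gaussian PSF, then Poisson
#' shot noise and additive Gaussian noise (in that order). ER intensity is
#' ~0 inside the exclusion zone and high in the surrounding shell; from
#' `clearance_frame` on, the retained ER sits in a thin layer under the cell
#' boundary.
#' @inheritParams scene_ground_truth
#' @param acq an [acq_params()]; `acq$channels` selects the channels.
#' @export
render_stack <- function(scene, frame, acq) {
  bf <- build_scene_fields(scene, frame, acq)
  sig_vox <- acq$psf_sigma / acq$voxel_size
  vals <- array(0, c(acq$dims, length(acq$channels), 1))
  for (ci in seq_along(acq$channels)) {
    v <- gauss3d(bf$fields[[acq$channels[ci]]], sig_vox)
    vals[, , , ci, 1] <- v
  }
  vals <- with_seed(acq$seed * 7919 + frame, {
    if (acq$poisson_scale > 0)
      vals <- array(rpois(length(vals), pmax(vals, 0) * acq$poisson_scale) / acq$poisson_scale, dim(vals))
    if (acq$gaussian_sd > 0)
      vals <- vals + array(rnorm(length(vals), 0, acq$gaussian_sd), dim(vals))
    vals
  })
  hyperstack(vals, acq$voxel_size, acq$channels, scene$frame_interval)
}

#' Render a full time series plus ground-truth tables
#'
#' Concatenates [render_stack()] over all frames. Congressing objects move
#' linearly to the plate and merge at their congression frame; the plate
#' splits in two at the anaphase frame; ER relocates at the clearance frame.
#'
#' @inheritParams render_stack
#' @return list with `stack` (a [hyperstack()] with T frames),
#'   `object_frames` (data.frame: frame, id, class, grid-µm centre, merged
#'   flag, mad2_ratio truth) and `events` (per-object congression frame plus
#'   scene-level anaphase/clearance frames).
#' @export
render_timeseries <- function(scene, acq) {
  frames <- seq_len(scene$n_frames)
  vals <- array(0, c(acq$dims, length(acq$channels), scene$n_frames))
  for (t in frames) {
    fr <- render_stack(scene, t, acq)
    vals[, , , , t] <- fr$values
  }
  off <- scene_offset(acq)
  rows <- list()
  for (t in frames) for (i in seq_len(nrow(scene$objects))) {
    ctr <- object_center_at(scene, i, t) + off
    cf <- scene$objects$congression_frame[i]
    rows[[length(rows) + 1]] <- data.frame(
      frame = t, id = scene$objects$id[i], class = scene$objects$class[i],
      x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
      merged = !is.na(cf) && t >= cf,
      mad2_ratio = mad2_ratio_at(scene, t))
  }
  object_frames <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), id = character(), class = character(),
               x_um = numeric(), y_um = numeric(), z_um = numeric(),
               merged = logical(), mad2_ratio = numeric())
  events <- list(congression = stats::setNames(scene$objects$congression_frame,
                                               scene$objects$id),
                 anaphase_frame = scene$anaphase_frame,
                 clearance_frame = scene$clearance_frame)
  list(stack = hyperstack(vals, acq$voxel_size, acq$channels, scene$frame_interval),
       object_frames = object_frames, events = events)
}
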