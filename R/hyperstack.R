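# The hyperstack container and file I/O. Multi-channel 3D(+T) stacks are
# held as 5D arrays indexed [x, y, z, channel, t] with physical calibration
# in µm and named channel roles. On disk a stack is a multi-page TIFF whose
# pages nest as T (outer), Z, C (inner) — i.e. "TZCYX" — together with a
# JSON sidecar carrying calibration, channel roles and the intensity scale.

CHANNEL_ROLES <- c("ER", "DNA", "PM", "KT", "SAC", "KIN")

#' Construct an image hyperstack
#'
#' @param values numeric array: 3D (z-stack, one channel/frame), 4D
#'   (x,y,z,channel) or 5D (x,y,z,channel,t). Lower-dimensional input is
#'   promoted.
#' @param voxel_size numeric length-3, voxel size in µm along (x, y, z).
#' @param channels character vector of channel roles, one per channel plane
#'   (e.g. `c("ER", "DNA")`). Roles must be unique.
#' @param frame_interval time between frames in minutes.
#' @return an object of class `hyperstack`.
#' @export
hyperstack <- function(values, voxel_size, channels, frame_interval = 1) {
  nd <- length(dim(values))
  if (nd == 3) dim(values) <- c(dim(values), 1L, 1L)
  if (nd == 4) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 5) stopf("values must be a 3D, 4D or 5D array")
  if (any(dim(values) < 1)) stopf("all dimensions must be >= 1")
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) stopf("voxel_size must be 3 positive values (µm)")
  channels <- as.character(channels)
  if (length(channels) != dim(values)[4]) stopf("channels length (%d) != number of channel planes (%d)", length(channels), dim(values)[4])
  if (anyDuplicated(channels)) stopf("duplicate channel role: %s", channels[duplicated(channels)][1])
  structure(list(values = values,
                 voxel_size = as.numeric(voxel_size),
                 channels = channels,
                 frame_interval = frame_interval),
            class = "hyperstack")
}

#' @export
print.hyperstack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("hyperstack: %d x %d x %d voxels, %d channel(s) [%s], %d frame(s)\n",
              d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", "), d[5]))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g µm, frame interval %g min\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$frame_interval))
  invisible(x)
}

#' Extract one 3D channel volume from a hyperstack
#' @param hs a [hyperstack()].
#' @param role channel role name.
#' @param frame frame index (1-based).
#' @export
get_channel <- function(hs, role, frame = 1) {
  ci <- match(role, hs$channels)
  if (is.na(ci)) stopf("channel role '%s' not present (have: %s)", role, paste(hs$channels, collapse = ", "))
  if (frame < 1 || frame > dim(hs$values)[5]) stopf("frame %d out of range 1..%d", frame, dim(hs$values)[5])
  hs$values[, , , ci, frame, drop = TRUE] -> v
  if (length(dim(v)) != 3) dim(v) <- dim(hs$values)[1:3]
  v
}

#' Write a hyperstack to a multi-page TIFF plus JSON sidecar
#'
#' Pages are written in T, Z, C nesting order ("TZCYX"); intensities are
#' affinely mapped to [0, 1] 32-bit float with offset and scale recorded in
#' the sidecar, so round trips are value identical to float32 storage
#' precision.
#' @param hs a [hyperstack()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(hs, path) {
  d <- dim(hs$values)
  # affine map to [0, 1] float32; reuse the calibration a read stack came
  # with so read-write-read round trips are bit identical
  offset <- attr(hs$values, "intensity_offset")
  scale <- attr(hs$values, "intensity_scale")
  rng <- range(hs$values)
  if (is.null(offset) || is.null(scale) ||
      rng[1] < offset - 1e-9 || rng[2] > offset + scale + 1e-9) {
    offset <- rng[1]
    scale <- max(diff(rng), 1e-12)
  }
  # quantize to float32 here (round to nearest) so the TIFF conversion is
  # exact and read-write-read round trips are bit identical
  as_f32 <- function(m) {
    q <- readBin(writeBin(as.vector(m), raw(), size = 4L), "numeric",
                 n = length(m), size = 4L)
    matrix(pmin(pmax(q, 0), 1), nrow(m), ncol(m))
  }
  pages <- vector("list", d[5] * d[3] * d[4])
  k <- 0
  for (t in seq_len(d[5])) for (z in seq_len(d[3])) for (c in seq_len(d[4])) {
    k <- k + 1
    pages[[k]] <- as_f32((t(hs$values[, , z, c, t]) - offset) / scale)  # [y, x]
  }
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE))
  meta <- list(schema_version = 1L,
               axis_order = "TZCYX",
               shape = list(t = d[5], z = d[3], c = d[4], y = d[2], x = d[1]),
               voxel_size_um = as.list(stats::setNames(hs$voxel_size, c("x", "y", "z"))),
               channels = as.list(hs$channels),
               frame_interval_min = hs$frame_interval,
               intensity_scale = scale,
               intensity_offset = offset)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hyperstack from TIFF (+ sidecar) or with explicit metadata
#'
#' @param path TIFF path. If `<path>.json` exists it supplies axis order,
#'   shape, calibration and channel roles; otherwise `axis_order_hint`,
#'   `shape`, `voxel_size` and `channels` must resolve them.
#' @param axis_order_hint currently only "TZCYX" (page nesting T, Z, C) is
#'   supported; anything else errors naming the ambiguous axes.
#' @param shape integer named list/vector with t, z, c counts when no sidecar.
#' @param voxel_size,channels,frame_interval calibration when no sidecar.
#' @export
read_stack <- function(path, axis_order_hint = NULL, shape = NULL,
                       voxel_size = NULL, channels = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  scale <- 1
  offset <- 0
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    axis_order_hint <- meta$axis_order
    shape <- meta$shape
    voxel_size <- unlist(meta$voxel_size_um)[c("x", "y", "z")]
    channels <- unlist(meta$channels)
    frame_interval <- meta$frame_interval_min
    scale <- meta$intensity_scale
    offset <- meta$intensity_offset %||% 0
  }
  if (is.null(axis_order_hint)) stopf("axis order unresolvable (no sidecar): pass axis_order_hint; ambiguous axes: t, z, c")
  if (!identical(axis_order_hint, "TZCYX")) stopf("unsupported axis order '%s' (ambiguous axes: %s); only TZCYX is supported", axis_order_hint, axis_order_hint)
  if (is.null(shape)) stopf("page partition unresolvable: supply shape (t, z, c)")
  if (is.null(voxel_size)) stopf("missing µm calibration: supply voxel_size or a sidecar")
  nt <- as.integer(shape[["t"]]); nz <- as.integer(shape[["z"]]); nc <- as.integer(shape[["c"]])
  if (nt * nz * nc != length(pages)) stopf("shape t*z*c = %d does not match %d TIFF pages", nt * nz * nc, length(pages))
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vals <- array(0, c(nx, ny, nz, nc, nt))
  k <- 0
  for (t in seq_len(nt)) for (z in seq_len(nz)) for (c in seq_len(nc)) {
    k <- k + 1
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    vals[, , z, c, t] <- t(pg) * scale + offset
  }
  attr(vals, "intensity_scale") <- scale
  attr(vals, "intensity_offset") <- offset
  hyperstack(vals, voxel_size, channels %||% paste0("ch", seq_len(nc)),
             frame_interval %||% 1)
}

#' Read Cell Counter marker XML point annotations
#'
#' Targets the Fiji Cell Counter layout
#' `<CellCounter_Marker_File><Marker_Data><Marker_Type><Type>..<Marker>` and
#' rejects other schemas. Marker voxel indices are taken as 0-based on all
#' axes; µm positions are voxel index times voxel size.
#'
#' @param path XML file path.
#' @param stack optional [hyperstack()] supplying bounds and calibration.
#' @param dims,voxel_size grid dimensions and µm voxel size when no stack is
#'   given.
#' @param marker_map optional named character vector mapping marker type
#'   integers (as names) to labels, e.g. `c("1" = "aligned", "4" = "pole")`.
#' @return data.frame with columns type, label, x_vox, y_vox, z_vox,
#'   x_um, y_um, z_um; class `point_annotations`.
#' @export
read_points_xml <- function(path, stack = NULL, dims = NULL, voxel_size = NULL,
                            marker_map = NULL) {
  if (!is.null(stack)) {
    dims <- dim(stack$values)[1:3]
    voxel_size <- stack$voxel_size
  }
  if (is.null(dims) || is.null(voxel_size)) stopf("supply a stack or dims + voxel_size")
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "CellCounter_Marker_File") stopf("unknown XML schema: root element <%s>, expected <CellCounter_Marker_File>", xml2::xml_name(doc))
  md <- xml2::xml_find_first(doc, ".//Marker_Data")
  if (inherits(md, "xml_missing")) stopf("unknown XML schema: no <Marker_Data> element")
  types <- xml2::xml_find_all(md, ".//Marker_Type")
  rows <- list()
  marker_id <- 0
  for (tn in types) {
    ty <- as.integer(xml2::xml_text(xml2::xml_find_first(tn, "./Type")))
    for (mk in xml2::xml_find_all(tn, "./Marker")) {
      marker_id <- marker_id + 1
      x <- as.numeric(xml2::xml_text(xml2::xml_find_first(mk, "./MarkerX")))
      y <- as.numeric(xml2::xml_text(xml2::xml_find_first(mk, "./MarkerY")))
      z <- as.numeric(xml2::xml_text(xml2::xml_find_first(mk, "./MarkerZ")))
      if (anyNA(c(x, y, z))) stopf("marker %d: missing MarkerX/Y/Z", marker_id)
      if (x < 0 || x >= dims[1] || y < 0 || y >= dims[2] || z < 0 || z >= dims[3])
        stopf("marker %d (type %d) at voxel (%g, %g, %g) outside stack bounds %d x %d x %d",
              marker_id, ty, x, y, z, dims[1], dims[2], dims[3])
      rows[[marker_id]] <- data.frame(type = ty, x_vox = x, y_vox = y, z_vox = z)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = integer(), x_vox = numeric(), y_vox = numeric(), z_vox = numeric())
  out$x_um <- out$x_vox * voxel_size[1]
  out$y_um <- out$y_vox * voxel_size[2]
  out$z_um <- out$z_vox * voxel_size[3]
  out$label <- if (is.null(marker_map)) as.character(out$type) else {
    lb <- marker_map[as.character(out$type)]
    if (anyNA(lb)) stopf("marker type %s not present in marker_map", out$type[which(is.na(lb))[1]])
    unname(lb)
  }
  class(out) <- c("point_annotations", "data.frame")
  out
}

#' Build a kinetochore set from annotations or coordinates
#'
#' @param points data.frame with columns x_um, y_um, z_um and label
#'   (values among aligned, free, ensheathed, pole), e.g. from
#'   [read_points_xml()] with a marker map, or built in code.
#' @param cell_id identifier carried through outputs.
#' @return class `kinetochore_set`: list with `kt` (data.frame id, x, y, z,
#'   class, parent) and `poles` (2 x 3 matrix, µm).
#' @export
kinetochore_set <- function(points, cell_id = "cell1") {
  stopifnot(all(c("x_um", "y_um", "z_um", "label") %in% names(points)))
  bad <- setdiff(unique(points$label), c("aligned", "free", "ensheathed", "pole"))
  if (length(bad)) stopf("unknown point label(s): %s", paste(bad, collapse = ", "))
  poles <- as.matrix(points[points$label == "pole", c("x_um", "y_um", "z_um")])
  if (nrow(poles) != 2) stopf("exactly 2 pole points required, got %d", nrow(poles))
  kt <- points[points$label != "pole", , drop = FALSE]
  out <- list(kt = data.frame(id = seq_len(nrow(kt)),
                              x = kt$x_um, y = kt$y_um, z = kt$z_um,
                              class = kt$label,
                              parent = if ("parent" %in% names(kt)) kt$parent else NA_character_),
              poles = unname(poles), cell_id = cell_id)
  class(out) <- "kinetochore_set"
  out
}

#' @export
print.kinetochore_set <- function(x, ...) {
  cat(sprintf("kinetochore_set '%s': %d kinetochores (%s), 2 poles\n", x$cell_id,
              nrow(x$kt), paste(sprintf("%s=%d", names(table(x$kt$class)), table(x$kt$class)), collapse = ", ")))
  invisible(x)
}
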