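#' Phase label codes
#'
#' Integer codes used in [phasemap] label grids.
#'
#' @return Named integer vector `c(void = 0, bone = 1, bag = 2, interface = 3,
#'   morsel = 4)`.
#' @export
phase_levels <- function() {
  c(void = 0L, bone = 1L, bag = 2L, interface = 3L, morsel = 4L)
}

#' Per-voxel phase label volume
#'
#' @param labels 3-D integer array of codes from [phase_levels()].
#' @param voxel_size Voxel edge length in micrometres.
#' @return A `phasemap` object.
#' @export
phasemap <- function(labels, voxel_size) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array", call. = FALSE)
  if (!all(labels %in% phase_levels()))
    stop("labels must be drawn from phase_levels()", call. = FALSE)
  structure(list(labels = labels, voxel_size = voxel_size), class = "phasemap")
}

#' @export
print.phasemap <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phasemap> %d x %d x %d voxels @ %.4g um\n", d[1], d[2], d[3],
              x$voxel_size))
  lv <- phase_levels()
  n <- vapply(lv, function(code) sum(x$labels == code), numeric(1))
  for (i in seq_along(lv))
    if (n[i] > 0) cat(sprintf("  %-9s %d\n", names(lv)[i], n[i]))
  invisible(x)
}

#' @export
dim.phasemap <- function(x) dim(x$labels)

#' Phase counts of a phase map
#'
#' @param pm A [phasemap].
#' @return A tibble with one row per phase: `phase`, `voxels`, `fraction` (of
#'   non-void voxels).
#' @export
phase_counts <- function(pm) {
  stopifnot(inherits(pm, "phasemap"))
  lv <- phase_levels()
  n <- vapply(lv, function(code) sum(pm$labels == code), numeric(1))
  solid <- sum(n[names(lv) != "void"])
  tibble::tibble(
    phase = names(lv), voxels = as.integer(n),
    fraction = ifelse(names(lv) == "void", NA_real_,
                      if (solid > 0) n / solid else NA_real_)
  )
}

#' Segmentation thresholds
#'
#' Fixed-threshold segmentation settings. Single-lower mode labels everything
#' at or above `lower` as bone; band mode labels `lower <= I < upper` as bone
#' and `I >= upper` as BAG. Intervals are half-open: a voxel exactly at a
#' threshold belongs to the upper phase.
#'
#' @param lower Lower threshold (mgHA/cm^3).
#' @param upper Optional upper threshold separating bone from BAG.
#' @return A `seg_thresholds` object.
#' @export
seg_thresholds <- function(lower, upper = NULL) {
  stopifnot(is.numeric(lower), length(lower) == 1L)
  if (!is.null(upper)) {
    stopifnot(is.numeric(upper), length(upper) == 1L)
    if (lower >= upper) stop("lower threshold must be below upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper,
                 mode = if (is.null(upper)) "single-lower" else "band+upper-phase"),
            class = "seg_thresholds")
}

#' Threshold segmentation of a calibrated volume
#'
#' @param img An [image3d].
#' @param thr A [seg_thresholds].
#' @return A [phasemap] with voxels labeled void/bone/bag.
#' @export
segment_phases <- function(img, thr) {
  stopifnot(inherits(img, "image3d"), inherits(thr, "seg_thresholds"))
  lv <- phase_levels()
  lab <- array(lv[["void"]], dim = dim(img$voxels))
  if (is.null(thr$upper)) {
    lab[img$voxels >= thr$lower] <- lv[["bone"]]
  } else {
    lab[img$voxels >= thr$lower & img$voxels < thr$upper] <- lv[["bone"]]
    lab[img$voxels >= thr$upper] <- lv[["bag"]]
  }
  phasemap(lab, img$voxel_size)
}

# shift a 3-D array by (dx,dy,dz), filling vacated space with `fill`
shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

offsets27 <- function() {
  expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
}

# 3x3x3-cube (26-connectivity) binary erosion; outside the grid counts as
# background, so border voxels erode
erode_mask <- function(m) {
  off <- offsets27()
  out <- m
  for (i in seq_len(nrow(off))) {
    if (off$dx[i] == 0 && off$dy[i] == 0 && off$dz[i] == 0) next
    out <- out & shift3(m, off$dx[i], off$dy[i], off$dz[i], fill = FALSE)
  }
  out
}

# 3x3x3-cube binary dilation
dilate_mask <- function(m) {
  off <- offsets27()
  out <- m
  for (i in seq_len(nrow(off))) {
    if (off$dx[i] == 0 && off$dy[i] == 0 && off$dz[i] == 0) next
    out <- out | shift3(m, off$dx[i], off$dy[i], off$dz[i], fill = FALSE)
  }
  out
}

#' Build the granule interface layer
#'
#' Wraps segmented BAG granules in a soft continuum interface phase that
#' stands in for the contact and sliding compliance the continuum model would
#' otherwise miss. The BAG mask is eroded by one voxel and dilated by two
#' (3x3x3 cube structuring element); the shell between the dilated and eroded
#' masks relabels bone or BAG voxels as interface, overruling them, while void
#' voxels stay void. Granules too thin to survive the erosion are preserved as
#' BAG, with a warning.
#'
#' @param pm A [phasemap] containing a bag phase.
#' @return The relabeled [phasemap].
#' @export
build_interface_layer <- function(pm) {
  stopifnot(inherits(pm, "phasemap"))
  lv <- phase_levels()
  bag <- pm$labels == lv[["bag"]]
  if (!any(bag)) return(pm)
  er <- erode_mask(bag)
  shell <- dilate_mask(dilate_mask(er)) & !er
  lab <- pm$labels
  relabel <- shell & (lab == lv[["bone"]] | lab == lv[["bag"]])
  lab[relabel] <- lv[["interface"]]
  lost <- sum(bag & !er & !shell)
  if (lost > 0)
    warning(sprintf(
      "%d bag voxel(s) belong to granules thinner than the erosion and were kept as bag",
      lost), call. = FALSE)
  out <- phasemap(lab, pm$voxel_size)
  attributes(out) <- utils::modifyList(attributes(pm), attributes(out))
  out
}

#' Radial beam-hardening correction
#'
#' Fits the intensity of a reference phase (voxels believed to be a single
#' material, e.g. provisionally segmented BAG) against in-plane radius by
#' linear regression, then rescales every voxel by
#' `I_c / (I_c + (I_b - I_c) * r / r_max)` so the reference phase has the same
#' intensity throughout the image. `I_c` and `I_b` are the fitted reference
#' intensities at the axis and at the largest in-plane radius. Multiplicative
#' gain anchored at the axis preserves the zero background and the
#' center intensity.
#'
#' @param img An [image3d].
#' @param reference_phase_mask Logical 3-D array marking reference voxels.
#' @return The corrected [image3d].
#' @export
correct_beam_hardening <- function(img, reference_phase_mask) {
  stopifnot(inherits(img, "image3d"))
  if (!is.logical(reference_phase_mask) ||
      !identical(dim(reference_phase_mask), dim(img$voxels)))
    stop("`reference_phase_mask` must be a logical array matching the image",
         call. = FALSE)
  if (!any(reference_phase_mask))
    stop("reference phase mask is empty", call. = FALSE)
  rr <- inplane_radius(dim(img$voxels), img$voxel_size)
  rref <- rr$r[reference_phase_mask]
  if (stats::sd(rref) == 0)
    stop("degenerate fit: all reference voxels lie at one radius", call. = FALSE)
  iref <- img$voxels[reference_phase_mask]
  fit <- stats::lm.fit(cbind(1, rref), iref)
  ic <- fit$coefficients[1]
  slope <- fit$coefficients[2]
  if (ic <= 0)
    stop("degenerate fit: non-positive axis intensity for the reference phase",
         call. = FALSE)
  gain <- ic / (ic + slope * rr$r)
  image3d(img$voxels * gain, img$voxel_size, img$origin)
}

#' Write or read a phase map
#'
#' The label grid is stored as an unsigned-integer NIfTI volume with a JSON
#' sidecar (`<path>.labels.json`) naming the label-to-phase mapping.
#'
#' @param pm A [phasemap].
#' @param path Volume path ending in `.nii` or `.nii.gz`.
#' @return `write_phasemap()` returns `path` invisibly; `read_phasemap()` the
#'   restored [phasemap].
#' @export
write_phasemap <- function(pm, path) {
  stopifnot(inherits(pm, "phasemap"))
  img <- image3d(pm$labels + 0, pm$voxel_size)
  write_volume(img, path)
  jsonlite::write_json(as.list(phase_levels()),
                       paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phasemap
#' @export
read_phasemap <- function(path) {
  img <- read_volume(path)
  side <- paste0(path, ".labels.json")
  if (file.exists(side)) {
    mapping <- unlist(jsonlite::read_json(side))
    if (!identical(sort(unname(mapping)), sort(unname(phase_levels()))))
      stop("label sidecar does not match phase_levels()", call. = FALSE)
  }
  phasemap(array(as.integer(round(img$voxels)), dim = dim(img$voxels)),
           img$voxel_size)
}
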