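side_axis <- function(side) {
  switch(side,
         "+x" = list(axis = 1L, dir = 1), "-x" = list(axis = 1L, dir = -1),
         "+y" = list(axis = 2L, dir = 1), "-y" = list(axis = 2L, dir = -1),
         stop("side must be one of '+x', '-x', '+y', '-y'", call. = FALSE))
}

#' Projected width of the bone silhouette
#'
#' Width of the bone silhouette projected along the viewing direction onto the
#' transverse axis, averaged over the slice range. Viewing along y measures
#' the x-extent, and vice versa.
#'
#' @param pm A [phasemap].
#' @param z_range Longitudinal slice range in mm (`c(lo, hi)`); defaults to the
#'   full volume.
#' @param view_axis `"y"` (default) or `"x"`: the anatomical viewing direction.
#' @return Width in mm.
#' @export
projected_width <- function(pm, z_range = NULL, view_axis = c("y", "x")) {
  stopifnot(inherits(pm, "phasemap"))
  view_axis <- match.arg(view_axis)
  h <- pm$voxel_size / 1000
  d <- dim(pm$labels)
  kz <- seq_len(d[3])
  if (!is.null(z_range)) {
    zc <- axis_centers(d[3], pm$voxel_size)
    kz <- which(zc >= z_range[1] & zc <= z_range[2])
    if (!length(kz)) stop("slice range does not intersect the volume", call. = FALSE)
  }
  width_axis <- if (view_axis == "y") 1L else 2L
  occ <- pm$labels[, , kz, drop = FALSE] != phase_levels()[["void"]]
  # silhouette: collapse over the viewing axis, then extent along width axis per slice
  widths <- vapply(seq_along(kz), function(s) {
    sl <- occ[, , s]
    pres <- if (width_axis == 1L) apply(sl, 1, any) else apply(sl, 2, any)
    if (!any(pres)) return(NA_real_)
    (max(which(pres)) - min(which(pres)) + 1) * h
  }, numeric(1))
  if (all(is.na(widths))) stop("empty silhouette in the requested range", call. = FALSE)
  mean(widths, na.rm = TRUE)
}

#' Cortical-window defect specification
#'
#' A rectangular window of a given fraction of the projected diaphysis width
#' and a given longitudinal length, cut inward from one side. The depth
#' follows the published rule: narrow windows reach through the local cortical
#' thickness, wide windows down to the short-axis radius (the centerline).
#'
#' @param width_fraction Window width as % of the projected diaphysis width.
#' @param length Longitudinal window length in mm.
#' @param center Window center along the long axis in mm; `NULL` centers it on
#'   the volume (the middle of the diaphysis).
#' @param side Entry side: `"+y"`, `"-y"`, `"+x"` or `"-x"`.
#' @param depth_rule `"auto"` (cortical thickness up to `width_threshold`%,
#'   short-axis radius above), `"cortical-thickness"`, `"short-axis-radius"`,
#'   or an explicit depth in mm.
#' @param width_threshold Width fraction (%) separating the two automatic
#'   depth rules.
#' @return A `defect_spec` object.
#' @export
defect_spec <- function(width_fraction, length, center = NULL, side = "+y",
                        depth_rule = "auto", width_threshold = 50) {
  stopifnot(width_fraction > 0, width_fraction <= 100, length > 0)
  side_axis(side)  # validates
  if (is.character(depth_rule))
    depth_rule <- match.arg(depth_rule,
                            c("auto", "cortical-thickness", "short-axis-radius"))
  else stopifnot(is.numeric(depth_rule), depth_rule > 0)
  structure(list(width_fraction = width_fraction, length = length,
                 center = center, side = side, depth_rule = depth_rule,
                 width_threshold = width_threshold),
            class = "defect_spec")
}

# median cortical run length (mm) entering from `side` over the window footprint
local_cortical_thickness <- function(pm, kz, wsel, side) {
  sa <- side_axis(side)
  lv <- phase_levels()
  runs <- c()
  kk <- kz[round(length(kz) / 2)]
  sl <- pm$labels[, , kk]
  lines <- if (sa$axis == 1L) wsel else wsel  # selection along the width axis
  for (w in lines) {
    prof <- if (sa$axis == 1L) sl[, w] else sl[w, ]
    if (sa$dir > 0) prof <- rev(prof)
    first <- which(prof != lv[["void"]])[1]
    if (is.na(first)) next
    run <- which(prof[first:length(prof)] == lv[["void"]])[1]
    runs <- c(runs, if (is.na(run)) length(prof) - first + 1 else run - 1)
  }
  if (!length(runs)) stop("no cortical bone under the window footprint", call. = FALSE)
  stats::median(runs) * pm$voxel_size / 1000
}

#' Cut a cortical window
#'
#' Voids all voxels inside a box of the realized width, the requested length,
#' and the rule-determined depth, measured inward from the chosen side. The
#' box is centered on the silhouette center along the width axis. A defect
#' report and the box extents (for later grafting) are attached as attributes.
#'
#' @param pm A [phasemap].
#' @param d A [defect_spec].
#' @return The windowed [phasemap] with attributes `"defect_report"` (tibble)
#'   and `"defect_box"` (index ranges of the removed region).
#' @export
create_cortical_window <- function(pm, d) {
  stopifnot(inherits(pm, "phasemap"), inherits(d, "defect_spec"))
  h <- pm$voxel_size / 1000
  dims <- dim(pm$labels)
  lv <- phase_levels()
  zc <- axis_centers(dims[3], pm$voxel_size)
  zlen <- dims[3] * h
  center <- if (is.null(d$center)) zlen / 2 else d$center
  zlo <- center - d$length / 2
  zhi <- center + d$length / 2
  if (zlo < 0 || zhi > zlen)
    stop("window exceeds the scanned length", call. = FALSE)
  kz <- which(zc >= zlo & zc < zhi)

  sa <- side_axis(d$side)
  view <- if (sa$axis == 2L) "y" else "x"
  W <- projected_width(pm, c(zlo, zhi), view_axis = view)
  w <- d$width_fraction / 100 * W
  if (w < h / 2) {  # degenerate zero-width window: no voxels removed
    attr(pm, "defect_report") <- tibble::tibble(
      width_fraction = d$width_fraction, projected_width = W,
      realized_width = 0, length = length(kz) * h, depth = 0, area = 0,
      removed_voxels = 0L)
    attr(pm, "defect_box") <- list(i = integer(), j = integer(), k = integer())
    return(pm)
  }

  # silhouette occupancy within the window slices
  occ <- pm$labels[, , kz, drop = FALSE] != lv[["void"]]
  waxis <- if (sa$axis == 1L) 2L else 1L  # width axis is perpendicular to side
  pres_w <- apply(occ, waxis, any)
  wc_axis <- axis_centers(dims[waxis], pm$voxel_size)
  wcen <- mean(wc_axis[range(which(pres_w))])
  wsel <- which(abs(wc_axis - wcen) <= w / 2)

  pres_s <- apply(occ, sa$axis, any)
  sc_axis <- axis_centers(dims[sa$axis], pm$voxel_size)
  sext <- range(which(pres_s))
  short_radius <- (sext[2] - sext[1] + 1) * h / 2
  surface <- if (sa$dir > 0) sc_axis[sext[2]] + h / 2 else sc_axis[sext[1]] - h / 2

  depth <- if (is.numeric(d$depth_rule)) d$depth_rule
  else {
    rule <- d$depth_rule
    if (rule == "auto")
      rule <- if (d$width_fraction <= d$width_threshold) "cortical-thickness"
      else "short-axis-radius"
    if (rule == "cortical-thickness")
      local_cortical_thickness(pm, kz, wsel, d$side)
    else short_radius
  }
  if (sa$dir > 0) {
    ssel <- which(sc_axis > surface - depth & sc_axis <= surface)
  } else {
    ssel <- which(sc_axis < surface + depth & sc_axis >= surface)
  }

  lab <- pm$labels
  box <- if (sa$axis == 1L) list(i = ssel, j = wsel, k = kz)
  else list(i = wsel, j = ssel, k = kz)
  removed_lab <- lab[box$i, box$j, box$k]
  lab[box$i, box$j, box$k] <- lv[["void"]]
  removed <- sum(removed_lab != lv[["void"]])

  out <- phasemap(lab, pm$voxel_size)
  attr(out, "defect_report") <- tibble::tibble(
    width_fraction = d$width_fraction,
    projected_width = W,
    realized_width = length(wsel) * h,
    length = length(kz) * h,
    depth = length(ssel) * h,
    area = length(wsel) * h * length(kz) * h,
    removed_voxels = removed
  )
  attr(out, "defect_box") <- box
  out
}

#' Resample a phase map to a new voxel size
#'
#' Nearest-neighbor label resampling over the same physical extent; per-phase
#' volume fractions are preserved to within discretization error.
#'
#' @param pm A [phasemap].
#' @param new_voxel_size Target voxel edge length in micrometres.
#' @return The resampled [phasemap].
#' @export
rescale_phasemap <- function(pm, new_voxel_size) {
  stopifnot(inherits(pm, "phasemap"), new_voxel_size > 0)
  if (new_voxel_size == pm$voxel_size) return(pm)
  d <- dim(pm$labels)
  ext <- d * pm$voxel_size
  nd <- pmax(1L, round(ext / new_voxel_size))
  pick <- function(n_new, n_old) {
    src <- floor(((seq_len(n_new) - 0.5) * new_voxel_size) / pm$voxel_size) + 1
    pmin(pmax(as.integer(src), 1L), n_old)
  }
  lab <- pm$labels[pick(nd[1], d[1]), pick(nd[2], d[2]), pick(nd[3], d[3]),
                   drop = FALSE]
  phasemap(lab, new_voxel_size)
}

# reflective (mirrored-continuation) index mapping of 1..n onto 1..m
reflect_index <- function(i, m) {
  if (m == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * m)
  ifelse(p < m, p + 1L, 2L * m - p)
}

#' Implant a graft mixture into a cortical-window defect
#'
#' Copies the non-void labels of a (rescaled) mixture phase map into the
#' defect void recorded by [create_cortical_window()], clipped to the defect
#' box. If the source is smaller than the defect it is tiled with mirrored
#' continuation, with a warning.
#'
#' @param bone A [phasemap] carrying a `"defect_box"` attribute.
#' @param graft A [phasemap] of the mixture; resampled to the bone's voxel
#'   size if needed.
#' @return The grafted [phasemap]; attribute `"graft_report"` holds per-phase
#'   voxel counts inside the graft region.
#' @export
implant_graft <- function(bone, graft) {
  stopifnot(inherits(bone, "phasemap"), inherits(graft, "phasemap"))
  box <- attr(bone, "defect_box")
  if (is.null(box))
    stop("no defect recorded: run create_cortical_window() first", call. = FALSE)
  nb <- lengths(box)
  if (any(nb == 0L)) return(bone)  # zero-size defect: nothing to fill
  if (graft$voxel_size != bone$voxel_size)
    graft <- rescale_phasemap(graft, bone$voxel_size)
  lv <- phase_levels()
  # crop the source to its occupied bounding box first
  nz <- which(graft$labels != lv[["void"]], arr.ind = TRUE)
  if (!nrow(nz)) stop("graft source is empty", call. = FALSE)
  rng <- apply(nz, 2, range)
  src <- graft$labels[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                      rng[1, 3]:rng[2, 3], drop = FALSE]
  sd_ <- dim(src)
  if (any(sd_ < nb))
    warning("graft source smaller than the defect; tiling with mirrored continuation",
            call. = FALSE)
  fill <- src[reflect_index(seq_len(nb[1]), sd_[1]),
              reflect_index(seq_len(nb[2]), sd_[2]),
              reflect_index(seq_len(nb[3]), sd_[3]), drop = FALSE]
  lab <- bone$labels
  region <- lab[box$i, box$j, box$k, drop = FALSE]
  put <- region == lv[["void"]] & fill != lv[["void"]]
  region[put] <- fill[put]
  lab[box$i, box$j, box$k] <- region
  out <- phasemap(lab, bone$voxel_size)
  counts <- table(factor(names(lv)[match(region, lv)], levels = names(lv)))
  attr(out, "graft_report") <- tibble::tibble(
    phase = names(counts), voxels = as.integer(counts)
  )
  attr(out, "defect_box") <- box
  out
}

#' Published cortical-window presets
#'
#' The seven window geometries used in the defect-geometry study: widths of
#' 40-100% of the projected diaphysis width at 11.1 mm length, and 50% width
#' at 11.1, 18.5 and 37.0 mm lengths.
#'
#' @return A tibble with columns `preset`, `width_fraction`, `length`.
#' @export
defect_presets <- function() {
  tibble::tibble(
    preset = c("W40L11", "W60L11", "W80L11", "W100L11",
               "W50L11", "W50L18", "W50L37"),
    width_fraction = c(40, 60, 80, 100, 50, 50, 50),
    length = c(11.1, 11.1, 11.1, 11.1, 11.1, 18.5, 37.0)
  )
}
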