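#' Bone phantom specification
#'
#' Parameter record for the synthetic long-bone and distal-tibia phantoms that
#' stand in for calibrated CT scans. A `tube` is a circular cortical shell, an
#' `elliptical-tube` an elliptical shell, and a `distal-tibia` an elliptical
#' shell whose core carries a trabecular lattice at a requested volume
#' fraction.
#'
#' @param shape One of `"tube"`, `"elliptical-tube"`, `"distal-tibia"`.
#' @param outer_radii Outer semi-axes in mm; a single value for circular
#'   sections or a length-2 vector `(a_x, b_y)` for elliptical ones.
#' @param cortical_thickness Cortical shell thickness in mm.
#' @param length Longitudinal extent in mm.
#' @param trabecular_fill Volume fraction of the core occupied by the
#'   trabecular lattice (0 for hollow tubes).
#' @param trabecular_scale Correlation length (mm) of the Gaussian level-set
#'   field that shapes the lattice; roughly the trabecular spacing.
#' @param intensity_bone Intensity assigned to bone voxels (mgHA/cm^3).
#' @param seed Integer seed controlling the trabecular lattice.
#' @return A `bone_phantom_spec` object.
#' @export
bone_phantom_spec <- function(shape = c("tube", "elliptical-tube", "distal-tibia"),
                              outer_radii = 9, cortical_thickness = 3,
                              length = 60, trabecular_fill = 0,
                              trabecular_scale = 0.8,
                              intensity_bone = 800, seed = 1L) {
  shape <- match.arg(shape)
  if (length(outer_radii) == 1L) outer_radii <- rep(outer_radii, 2L)
  stopifnot(length(outer_radii) == 2L, all(outer_radii > 0),
            cortical_thickness > 0, length > 0,
            trabecular_fill >= 0, trabecular_fill <= 1,
            trabecular_scale > 0, intensity_bone > 0)
  if (cortical_thickness >= min(outer_radii))
    stop("cortical_thickness must be smaller than the smallest outer radius",
         call. = FALSE)
  structure(
    list(shape = shape, outer_radii = outer_radii,
         cortical_thickness = cortical_thickness, length = length,
         trabecular_fill = trabecular_fill, trabecular_scale = trabecular_scale,
         intensity_bone = intensity_bone, seed = as.integer(seed)),
    class = "bone_phantom_spec"
  )
}

#' Generate a bone phantom volume
#'
#' Rasterizes the cortical shell (and, for distal-tibia shapes, a trabecular
#' core lattice) of a [bone_phantom_spec] onto a voxel grid. The lattice is a
#' smoothed Gaussian random field thresholded at the quantile that realizes the
#' requested core fill fraction, giving one-parameter control of a BV/TV-like
#' density.
#'
#' @param spec A [bone_phantom_spec].
#' @param voxel_size Voxel edge length in micrometres; must resolve the
#'   cortical thickness with at least 3 voxels.
#' @return An [image3d] with bone voxels at `intensity_bone` and background 0.
#' @export
make_bone_phantom <- function(spec, voxel_size) {
  stopifnot(inherits(spec, "bone_phantom_spec"))
  h <- voxel_size / 1000
  if (spec$cortical_thickness / h < 3)
    stop("voxel size too coarse: cortical thickness spans fewer than 3 voxels",
         call. = FALSE)
  a <- spec$outer_radii[1]; b <- spec$outer_radii[2]
  nx <- ceiling(2 * a / h) + 2L
  ny <- ceiling(2 * b / h) + 2L
  nz <- max(1L, round(spec$length / h))
  xc <- axis_centers(nx, voxel_size) - nx * h / 2
  yc <- axis_centers(ny, voxel_size) - ny * h / 2
  r2_out <- outer((xc / a)^2, (yc / b)^2, `+`)
  ai <- a - spec$cortical_thickness; bi <- b - spec$cortical_thickness
  r2_in <- outer((xc / ai)^2, (yc / bi)^2, `+`)
  shell2d <- r2_out <= 1 & r2_in > 1
  core2d <- r2_in <= 1

  vox <- array(0, dim = c(nx, ny, nz))
  vox[rep(shell2d, nz)] <- spec$intensity_bone

  if (spec$shape == "distal-tibia" && spec$trabecular_fill > 0) {
    core <- array(rep(core2d, nz), dim = c(nx, ny, nz))
    field <- with_seed(spec$seed, {
      gaussian_field(c(nx, ny, nz), sigma_vox = spec$trabecular_scale / h)
    })
    thr <- stats::quantile(field[core], 1 - spec$trabecular_fill, names = FALSE)
    vox[core & field > thr] <- spec$intensity_bone
  }
  image3d(vox, voxel_size)
}

# periodic Gaussian-smoothed white noise via FFT, normalized to unit sd
gaussian_field <- function(dims, sigma_vox) {
  noise <- array(stats::rnorm(prod(dims)), dim = dims)
  k1 <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    if (n == 1) d <- 0
    d
  }
  g <- function(n) exp(-0.5 * (k1(n) * 2 * pi * sigma_vox / n)^2)
  gk <- outer(outer(g(dims[1]), g(dims[2])), g(dims[3]))
  sm <- Re(stats::fft(stats::fft(noise) * gk, inverse = TRUE)) / prod(dims)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Granule/morsel mixture specification
#'
#' Parameters of a confined bed of bioactive-glass (BAG) granules mixed with
#' bone morsels inside a cylindrical container, mimicking impacted graft
#' samples. Spheres are placed by random sequential adsorption; a small
#' overlap allowance acts as a proxy for impaction so that packing reaches the
#' 0.4-0.55 solid fractions typical of impacted granular beds.
#'
#' @param bag_fraction Target BAG share of the solid volume, in vol% (0-100).
#' @param granule_diameter_range BAG granule diameters, mm (uniform).
#' @param morsel_diameter_range Bone-morsel diameters, mm (uniform).
#' @param container Cylinder `c(radius, height)` in mm.
#' @param target_solid_fraction Solid volume / container volume to aim for.
#' @param overlap_tolerance Fraction of the contact distance by which spheres
#'   may interpenetrate (impaction proxy).
#' @param intensity_bag,intensity_morsel Voxel intensities (mgHA/cm^3);
#'   defaults straddle the 838 mgHA/cm^3 BAG/bone threshold.
#' @param seed Integer seed.
#' @return A `mixture_spec` object.
#' @export
mixture_spec <- function(bag_fraction = 50,
                         granule_diameter_range = c(2, 3.15),
                         morsel_diameter_range = c(3, 5),
                         container = c(6, 12),
                         target_solid_fraction = 0.45,
                         overlap_tolerance = 0.2,
                         intensity_bag = 1100, intensity_morsel = 650,
                         seed = 1L) {
  stopifnot(bag_fraction >= 0, bag_fraction <= 100,
            length(granule_diameter_range) == 2L,
            length(morsel_diameter_range) == 2L,
            all(granule_diameter_range > 0), all(morsel_diameter_range > 0),
            diff(granule_diameter_range) >= 0, diff(morsel_diameter_range) >= 0,
            length(container) == 2L, all(container > 0),
            target_solid_fraction > 0, target_solid_fraction < 1,
            overlap_tolerance >= 0, overlap_tolerance < 1,
            intensity_bag > 0, intensity_morsel > 0)
  structure(
    list(bag_fraction = bag_fraction,
         granule_diameter_range = granule_diameter_range,
         morsel_diameter_range = morsel_diameter_range,
         container = container, target_solid_fraction = target_solid_fraction,
         overlap_tolerance = overlap_tolerance,
         intensity_bag = intensity_bag, intensity_morsel = intensity_morsel,
         seed = as.integer(seed)),
    class = "mixture_spec"
  )
}

#' Generate a granule/morsel mixture phantom
#'
#' Packs non-overlapping (up to the impaction allowance) spheres into the
#' container by random sequential adsorption, alternating phases to track the
#' requested BAG share of solid volume, then voxelizes. Earlier-placed spheres
#' keep their voxels where allowances let spheres interpenetrate.
#'
#' @param spec A [mixture_spec].
#' @param voxel_size Voxel edge length in micrometres; must resolve the
#'   smallest granule with at least 4 voxels across.
#' @return An [image3d] with attribute `"packing"`: a list with the achieved
#'   solid fraction, BAG share of solid (voxel-counted), and a tibble of the
#'   placed spheres.
#' @export
make_mixture_phantom <- function(spec, voxel_size) {
  stopifnot(inherits(spec, "mixture_spec"))
  h <- voxel_size / 1000
  dmin <- if (spec$bag_fraction > 0) spec$granule_diameter_range[1] else
    spec$morsel_diameter_range[1]
  if (dmin / h < 4)
    stop("voxel size too coarse: smallest granule spans fewer than 4 voxels",
         call. = FALSE)
  R <- spec$container[1]; H <- spec$container[2]
  vol_container <- pi * R^2 * H
  target_vol <- spec$target_solid_fraction * vol_container

  sph <- with_seed(spec$seed, {
    pack_spheres_rsa(spec, R, H, target_vol)
  })

  nx <- ceiling(2 * R / h) + 2L
  ny <- nx
  nz <- ceiling(H / h) + 2L
  vox <- array(0, dim = c(nx, ny, nz))
  cx <- nx * h / 2; cy <- ny * h / 2; z0 <- h  # container sits 1 voxel in
  xc <- axis_centers(nx, voxel_size)
  yc <- axis_centers(ny, voxel_size)
  zc <- axis_centers(nz, voxel_size)
  if (nrow(sph)) {
    for (s in seq_len(nrow(sph))) {
      r <- sph$d[s] / 2
      px <- sph$x[s] + cx; py <- sph$y[s] + cy; pz <- sph$z[s] + z0
      ix <- which(abs(xc - px) <= r)
      iy <- which(abs(yc - py) <= r)
      iz <- which(abs(zc - pz) <= r)
      if (!length(ix) || !length(iy) || !length(iz)) next
      d2 <- outer(outer((xc[ix] - px)^2, (yc[iy] - py)^2, `+`), (zc[iz] - pz)^2, `+`)
      inside <- d2 <= r^2
      sub <- vox[ix, iy, iz, drop = FALSE]
      val <- if (sph$phase[s] == "bag") spec$intensity_bag else spec$intensity_morsel
      sub[inside & sub == 0] <- val
      vox[ix, iy, iz] <- sub
    }
  }
  img <- image3d(vox, voxel_size)
  in_container <- outer(outer((xc - cx)^2, (yc - cy)^2, `+`) <= R^2,
                        zc >= z0 & zc <= z0 + H)
  n_solid <- sum(vox > 0)
  n_bag <- sum(vox == spec$intensity_bag)
  attr(img, "packing") <- list(
    achieved_solid_fraction = n_solid / sum(in_container),
    bag_share_of_solid = if (n_solid > 0) n_bag / n_solid else NA_real_,
    spheres = sph
  )
  img
}

# Random sequential adsorption with a settling bias: each sphere samples a
# batch of candidate positions and keeps the feasible one with the lowest z,
# mimicking deposition under gravity. Together with the small overlap
# allowance this reaches the 0.4-0.55 solid fractions of impacted beds that
# plain RSA (saturation ~0.38) cannot.
pack_spheres_rsa <- function(spec, R, H, target_vol, candidates = 60L) {
  want_bag <- spec$bag_fraction / 100
  ovl <- 1 - spec$overlap_tolerance
  xs <- ys <- zs <- rs <- numeric(0)
  ph <- character(0)
  vol_bag <- 0; vol_mor <- 0
  fails <- 0L
  full <- 0L  # draws rejected only because they would overshoot the target
  max_fails <- 400L
  repeat {
    tot <- vol_bag + vol_mor
    if (tot >= target_vol) break
    if (fails >= max_fails) {
      warning(sprintf(
        "sphere packing stalled at solid fraction %.3f (target %.3f)",
        tot / (pi * R^2 * H), spec$target_solid_fraction), call. = FALSE)
      break
    }
    phase <- if (want_bag >= 1) "bag"
    else if (want_bag <= 0) "morsel"
    else if (tot == 0) (if (stats::runif(1) < want_bag) "bag" else "morsel")
    else if (vol_bag / tot < want_bag) "bag" else "morsel"
    rng <- if (phase == "bag") spec$granule_diameter_range else
      spec$morsel_diameter_range
    d <- stats::runif(1, rng[1], rng[2])
    r <- d / 2
    if (2 * r > min(2 * R, H)) { fails <- fails + 1L; next }
    vol <- 4 / 3 * pi * r^3
    if (tot + vol > target_vol + vol / 2) {
      full <- full + 1L
      if (full > 50L) break  # within half a sphere of the target: done
      next
    }
    rad <- (R - r) * sqrt(stats::runif(candidates))
    th <- stats::runif(candidates, 0, 2 * pi)
    cx <- rad * cos(th); cy <- rad * sin(th)
    cz <- stats::runif(candidates, r, H - r)
    ok <- rep(TRUE, candidates)
    if (length(xs)) {
      for (cc in seq_len(candidates)) {
        d2 <- (xs - cx[cc])^2 + (ys - cy[cc])^2 + (zs - cz[cc])^2
        ok[cc] <- !any(d2 < (ovl * (rs + r))^2)
      }
    }
    if (!any(ok)) { fails <- fails + 1L; next }
    pick <- which(ok)[which.min(cz[ok])]
    xs <- c(xs, cx[pick]); ys <- c(ys, cy[pick]); zs <- c(zs, cz[pick])
    rs <- c(rs, r)
    ph <- c(ph, phase)
    if (phase == "bag") vol_bag <- vol_bag + vol else vol_mor <- vol_mor + vol
    fails <- 0L
  }
  tibble::tibble(phase = ph, x = xs, y = ys, z = zs, d = 2 * rs)
}

#' Beam-hardening artifact specification
#'
#' Linear radial intensity droop plus optional Gaussian noise, the forward
#' model against which the radial intensity correction is tested.
#'
#' @param droop_fraction Relative intensity loss from the volume axis to the
#'   largest in-plane radius (0 <= droop < 1).
#' @param noise_sd Standard deviation of additive zero-mean Gaussian noise
#'   (mgHA/cm^3).
#' @param seed Integer seed for the noise.
#' @return An `artifact_spec` object.
#' @export
artifact_spec <- function(droop_fraction = 0.1, noise_sd = 0, seed = 1L) {
  stopifnot(droop_fraction >= 0, droop_fraction < 1, noise_sd >= 0)
  structure(list(droop_fraction = droop_fraction, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "artifact_spec")
}

#' Apply a beam-hardening artifact to a volume
#'
#' Multiplies every voxel by `1 - droop * r / r_max`, with `r` the in-plane
#' distance from the volume axis, then adds Gaussian noise if requested.
#'
#' @param img An [image3d].
#' @param art An [artifact_spec].
#' @return The degraded [image3d].
#' @export
apply_beam_hardening <- function(img, art) {
  stopifnot(inherits(img, "image3d"), inherits(art, "artifact_spec"))
  d <- dim(img$voxels)
  out <- img$voxels
  if (art$droop_fraction > 0) {
    rr <- inplane_radius(d, img$voxel_size)
    out <- out * (1 - art$droop_fraction * rr$r / rr$rmax)
  }
  if (art$noise_sd > 0) {
    out <- out + with_seed(art$seed,
                           array(stats::rnorm(prod(d), 0, art$noise_sd), dim = d))
  }
  image3d(out, img$voxel_size, img$origin)
}

#' Interior core block of a mixture phantom
#'
#' Crops a mixture volume or phase map to the dense interior of the packed
#' bed: the inscribed square prism of the container, inset from the walls and
#' plates where spheres only touch tangentially. This mimics a scan region
#' cut through the interior of an impacted sample and is the natural graft
#' source for [implant_graft()].
#'
#' @param pm A [phasemap] (or [image3d]) produced from a mixture phantom.
#' @param container The mixture's `c(radius, height)` in mm.
#' @param inset Margin stripped from the walls and plates, mm.
#' @return The cropped object of the same class.
#' @export
mixture_core_region <- function(pm, container = c(6, 12), inset = 1.5) {
  stopifnot(inherits(pm, "phasemap") || inherits(pm, "image3d"))
  arr <- if (inherits(pm, "phasemap")) pm$labels else pm$voxels
  d <- dim(arr)
  h <- pm$voxel_size / 1000
  xc <- axis_centers(d[1], pm$voxel_size) - d[1] * h / 2
  yc <- axis_centers(d[2], pm$voxel_size) - d[2] * h / 2
  zc <- axis_centers(d[3], pm$voxel_size)
  half <- container[1] / sqrt(2) - inset
  if (half <= h) stop("inset leaves no core region", call. = FALSE)
  xi <- which(abs(xc) <= half)
  yi <- which(abs(yc) <= half)
  zi <- which(zc >= h + inset & zc <= h + container[2] - inset)
  sub <- arr[xi, yi, zi, drop = FALSE]
  if (inherits(pm, "phasemap")) phasemap(sub, pm$voxel_size)
  else image3d(sub, pm$voxel_size)
}
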