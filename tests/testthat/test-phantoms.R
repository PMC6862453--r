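test_that("tube phantom shell volume matches the analytic annulus", {
  ro <- 9; thick <- 3; L <- 60; h <- 0.5
  spec <- bone_phantom_spec("tube", outer_radii = ro, cortical_thickness = thick,
                            length = L)
  img <- make_bone_phantom(spec, h * 1000)
  n_shell <- sum(img$voxels > 0)
  analytic <- pi * (ro^2 - (ro - thick)^2) * L / h^3
  expect_lt(abs(n_shell / analytic - 1), 0.03)
})

test_that("phantom generation is deterministic and validates its inputs", {
  spec <- bone_phantom_spec("distal-tibia", outer_radii = c(8, 6),
                            cortical_thickness = 1.5, length = 8,
                            trabecular_fill = 0.2, seed = 42)
  a <- make_bone_phantom(spec, 500)
  b <- make_bone_phantom(spec, 500)
  expect_identical(a$voxels, b$voxels)
  # under-resolved cortex
  expect_error(make_bone_phantom(spec, 800), "too coarse")
  expect_error(bone_phantom_spec("tube", outer_radii = 5,
                                 cortical_thickness = 6),
               "cortical_thickness")
})

test_that("trabecular core hits the requested fill fraction and empty core stays empty", {
  spec <- bone_phantom_spec("distal-tibia", outer_radii = c(10, 8),
                            cortical_thickness = 1.6, length = 10,
                            trabecular_fill = 0.15, seed = 7)
  img <- make_bone_phantom(spec, 500)
  h <- 0.5
  d <- dim(img$voxels)
  xc <- (seq_len(d[1]) - 0.5) * h - d[1] * h / 2
  yc <- (seq_len(d[2]) - 0.5) * h - d[2] * h / 2
  core2d <- outer((xc / (10 - 1.6))^2, (yc / (8 - 1.6))^2, `+`) <= 1
  core <- array(rep(core2d, d[3]), dim = d)
  fill <- mean(img$voxels[core] > 0)
  expect_lt(abs(fill - 0.15), 0.02)

  spec0 <- bone_phantom_spec("distal-tibia", outer_radii = c(10, 8),
                             cortical_thickness = 1.6, length = 10,
                             trabecular_fill = 0)
  img0 <- make_bone_phantom(spec0, 500)
  expect_true(all(img0$voxels[core] == 0))
})

mix50 <- suppressWarnings(
  make_mixture_phantom(mixture_spec(bag_fraction = 50,
                                    target_solid_fraction = 0.45, seed = 11),
                       300))

test_that("mixture packing realizes the requested composition", {
  pk <- attr(mix50, "packing")
  expect_gte(pk$achieved_solid_fraction, 0.40)
  expect_lte(pk$achieved_solid_fraction, 0.45)
  expect_lt(abs(pk$bag_share_of_solid - 0.5), 0.05)
  gr <- pk$spheres$d[pk$spheres$phase == "bag"]
  expect_true(all(gr >= 2 & gr <= 3.15))
  mo <- pk$spheres$d[pk$spheres$phase == "morsel"]
  expect_true(all(mo >= 3 & mo <= 5))
})

test_that("single-phase mixtures contain only their phase and repeat under a seed", {
  spec <- mixture_spec(bag_fraction = 100, target_solid_fraction = 0.35,
                       seed = 5)
  a <- make_mixture_phantom(spec, 300)
  expect_equal(sum(a$voxels == spec$intensity_morsel), 0)
  b <- make_mixture_phantom(spec, 300)
  expect_identical(a$voxels, b$voxels)
  # intensity ordering: bag > morsel > background
  expect_gt(spec$intensity_bag, mixture_spec()$intensity_morsel)
  expect_gt(min(mix50$voxels[mix50$voxels > 0]), 0)
})

test_that("voxelized sphere volumes converge to the analytic volume under refinement", {
  spec <- mixture_spec(bag_fraction = 100, granule_diameter_range = c(3, 3.15),
                       target_solid_fraction = 0.02, container = c(6, 12),
                       seed = 3)
  hs <- c(600, 300, 150)
  errs <- vapply(hs, function(vs) {
    img <- suppressWarnings(make_mixture_phantom(spec, vs))
    pk <- attr(img, "packing")
    analytic <- sum(4 / 3 * pi * (pk$spheres$d / 2)^3)
    vox <- sum(img$voxels > 0) * (vs / 1000)^3
    abs(vox / analytic - 1)
  }, numeric(1))
  # surface-term envelope: the relative error of a voxelized sphere of
  # diameter d is O(h/d); the realized error sits well inside 3h/d
  expect_true(all(errs < 3 * hs / 1000 / 3))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("beam hardening droop follows the radial forward model", {
  img <- image3d(array(1000, dim = c(21, 21, 5)), 1000)
  expect_equal(apply_beam_hardening(img, artifact_spec(0, 0))$voxels,
               img$voxels)
  out <- apply_beam_hardening(img, artifact_spec(0.1, 0))
  # center voxel sits on the axis: unchanged
  expect_equal(out$voxels[11, 11, 3], 1000)
  # the corner voxel sits at r_max: scaled by 1 - droop
  expect_equal(out$voxels[1, 1, 1], 900)
  # noise is reproducible and zero-mean-ish
  n1 <- apply_beam_hardening(img, artifact_spec(0, 5, seed = 2))
  n2 <- apply_beam_hardening(img, artifact_spec(0, 5, seed = 2))
  expect_identical(n1$voxels, n2$voxels)
  expect_lt(abs(mean(n1$voxels - img$voxels)), 0.5)
})

test_that("volumes and spec records round-trip through disk formats", {
  img <- image3d(array(stats::runif(4 * 5 * 6, 0, 100), dim = c(4, 5, 6)), 250)
  tmp <- tempfile(fileext = ".nii.gz")
  write_volume(img, tmp)
  back <- read_volume(tmp)
  expect_equal(back$voxels, img$voxels, tolerance = 1e-6)
  expect_equal(back$voxel_size, 250, tolerance = 1e-6)
  tmp2 <- tempfile(fileext = ".mha")
  write_volume(img, tmp2)
  back2 <- read_volume(tmp2)
  expect_equal(back2$voxels, img$voxels)

  sp <- mixture_spec(bag_fraction = 75, seed = 9)
  ty <- tempfile(fileext = ".yaml")
  write_spec_yaml(sp, ty)
  expect_equal(read_spec_yaml(ty), sp)
})
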