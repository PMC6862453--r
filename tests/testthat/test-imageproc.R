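test_that("threshold segmentation follows the half-open band convention", {
  img <- image3d(array(c(0, 300, 515, 600, 837.9, 838, 2000, 100),
                       dim = c(2, 2, 2)), 100)
  lv <- phase_levels()
  pm <- segment_phases(img, seg_thresholds(515, 838))
  expect_equal(as.vector(pm$labels),
               unname(lv[c("void", "void", "bone", "bone", "bone", "bag",
                           "bag", "void")]))
  pm1 <- segment_phases(img, seg_thresholds(485))
  expect_equal(sum(pm1$labels == lv[["bone"]]), 5)
  expect_true(all(segment_phases(image3d(array(0, dim = c(3, 3, 3)), 100),
                                 seg_thresholds(485))$labels == lv[["void"]]))
})

test_that("phase volumes are monotone non-increasing in the lower threshold", {
  set.seed(1)
  img <- image3d(array(stats::runif(1000, 0, 1200), dim = c(10, 10, 10)), 100)
  vols <- vapply(c(200, 400, 600, 800), function(thr)
    sum(segment_phases(img, seg_thresholds(thr))$labels > 0), numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("beam-hardening correction recovers a flat radial profile", {
  # no gradient: correction is the identity within floating tolerance
  flat <- image3d(array(1000, dim = c(15, 15, 5)), 1000)
  mask <- array(TRUE, dim = dim(flat$voxels))
  out <- correct_beam_hardening(flat, mask)
  expect_equal(out$voxels, flat$voxels, tolerance = 1e-10)

  # droop 0.1 on a BAG bed: corrected mean within 1%, radial slope ~ 0
  spec <- mixture_spec(bag_fraction = 100, target_solid_fraction = 0.35,
                       intensity_bag = 1000, seed = 4)
  bed <- make_mixture_phantom(spec, 300)
  degraded <- apply_beam_hardening(bed, artifact_spec(0.1, 0))
  ref <- bed$voxels > 0  # provisional reference phase
  corr <- correct_beam_hardening(degraded, ref)
  expect_lt(abs(mean(corr$voxels[ref]) / 1000 - 1), 0.01)
  rr <- osteofe:::inplane_radius(dim(bed$voxels), bed$voxel_size)
  beta <- stats::coef(stats::lm(corr$voxels[ref] ~ rr$r[ref]))[2]
  expect_lt(abs(beta), 1)

  expect_error(correct_beam_hardening(flat, mask & FALSE), "empty")
  one_r <- array(FALSE, dim = dim(flat$voxels))
  one_r[8, 8, ] <- TRUE
  expect_error(correct_beam_hardening(flat, one_r), "degenerate")
})

test_that("interface layer of an isolated bag cube matches the erode/dilate contract", {
  lv <- phase_levels()
  lab <- array(lv[["void"]], dim = c(11, 11, 11))
  lab[4:8, 4:8, 4:8] <- lv[["bag"]]
  out <- build_interface_layer(phasemap(lab, 100))
  expect_equal(sum(out$labels == lv[["bag"]]), 27)
  expect_equal(sum(out$labels == lv[["interface"]]), 98)
  # nothing appears in void space
  expect_true(all(out$labels[lab == lv[["void"]]] == lv[["void"]]))
})

test_that("granules destroyed by the erosion are preserved as bag, with a warning", {
  lv <- phase_levels()
  lab <- array(lv[["void"]], dim = c(7, 7, 7))
  lab[4, 4, 4] <- lv[["bag"]]
  expect_warning(out <- build_interface_layer(phasemap(lab, 100)), "thinner")
  expect_identical(out$labels, lab)
  # empty bag phase: unchanged, silently
  empty <- phasemap(array(lv[["bone"]], dim = c(4, 4, 4)), 100)
  expect_identical(build_interface_layer(empty)$labels, empty$labels)
})

test_that("bone near a granule is overruled by interface but void is not", {
  lv <- phase_levels()
  lab <- array(lv[["void"]], dim = c(12, 12, 12))
  lab[3:7, 3:7, 3:7] <- lv[["bag"]]     # granule
  lab[8:12, , ] <- lv[["bone"]]         # slab within 2 voxels of the eroded core
  out <- build_interface_layer(phasemap(lab, 100))
  expect_identical(out$labels, bf_interface(lab))
  expect_gt(sum(out$labels == lv[["interface"]] & lab == lv[["bone"]]), 0)
})

test_that("morphology matches the brute-force voxel-loop oracle on random grids", {
  set.seed(99)
  for (rep in 1:8) {
    lab <- random_label_grid()
    got <- suppressWarnings(build_interface_layer(phasemap(lab, 100))$labels)
    expect_identical(got, suppressWarnings(bf_interface(lab)))
    # set relations: cores kept, nothing created in void
    lv <- phase_levels()
    er <- bf_erode(lab == lv[["bag"]])
    expect_true(all(got[er] == lv[["bag"]]))
    expect_true(all(got[lab == lv[["void"]]] == lv[["void"]]))
  }
})

test_that("phase maps round-trip with their label sidecar", {
  lv <- phase_levels()
  lab <- array(sample(lv, 60, replace = TRUE), dim = c(3, 4, 5))
  pm <- phasemap(lab, 200)
  tmp <- tempfile(fileext = ".nii.gz")
  write_phasemap(pm, tmp)
  expect_true(file.exists(paste0(tmp, ".labels.json")))
  back <- read_phasemap(tmp)
  expect_identical(back$labels, pm$labels)
})
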