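tube1 <- tube_phasemap(500)

test_that("projected width measures the silhouette", {
  expect_lt(abs(projected_width(tube1) - 18), 0.5 + 1e-9)
  # ellipse 18 x 12 mm viewed along its short axis shows the full 18 mm
  ell <- segment_phases(make_bone_phantom(
    bone_phantom_spec("elliptical-tube", outer_radii = c(9, 6),
                      cortical_thickness = 2, length = 10), 500),
    seg_thresholds(485))
  expect_lt(abs(projected_width(ell, view_axis = "y") - 18), 0.5 + 1e-9)
  expect_lt(abs(projected_width(ell, view_axis = "x") - 12), 0.5 + 1e-9)
  expect_error(projected_width(tube1, z_range = c(100, 200)), "range")
})

test_that("cortical windows realize the requested geometry", {
  cut <- create_cortical_window(tube1, defect_spec(50, 18.5))
  rep_ <- attr(cut, "defect_report")
  expect_lt(abs(rep_$realized_width / (0.5 * rep_$projected_width) - 1), 0.1)
  expect_lt(abs(rep_$length - 18.5), 0.5 + 1e-9)
  expect_equal(rep_$area, rep_$realized_width * rep_$length, tolerance = 0.01)
  expect_gt(rep_$removed_voxels, 0)
  # windows removed voxels only inside the recorded box
  box <- attr(cut, "defect_box")
  outside <- tube1$labels
  outside[box$i, box$j, box$k] <- -1L
  expect_identical(cut$labels[outside != -1L], tube1$labels[outside != -1L])
})

test_that("full-width windows reach the centerline and tiny windows vanish", {
  cut <- create_cortical_window(tube1, defect_spec(100, 11.1))
  rep_ <- attr(cut, "defect_report")
  expect_equal(rep_$depth, 9, tolerance = 0.6)   # short-axis radius rule
  # over the window length, no bone remains above the centerline on +y
  box <- attr(cut, "defect_box")
  d <- dim(cut$labels)
  ymid <- ceiling(d[2] / 2)
  sl <- cut$labels[, (ymid + 1):d[2], box$k]
  expect_true(all(sl[box$i, , ] == 0))

  tiny <- create_cortical_window(tube1, defect_spec(1e-6, 11.1))
  expect_identical(tiny$labels, tube1$labels)
  expect_equal(attr(tiny, "defect_report")$removed_voxels, 0L)

  expect_error(create_cortical_window(tube1, defect_spec(50, 100)), "length")
})

test_that("window removal is monotone in width fraction", {
  removed <- lapply(c(40, 60, 80, 100), function(w)
    which(create_cortical_window(tube1, defect_spec(w, 11.1))$labels !=
            tube1$labels))
  for (i in 1:3)
    expect_true(all(removed[[i]] %in% removed[[i + 1]]))
})

test_that("nearest-neighbor rescaling preserves labels and fractions", {
  expect_identical(rescale_phasemap(tube1, 500), tube1)
  # integer-factor downsampling picks one parent per output voxel
  lv <- phase_levels()
  set.seed(3)
  lab <- random_label_grid(c(8, 8, 8))
  pm <- phasemap(lab, 360)
  half <- rescale_phasemap(pm, 720)
  expect_equal(dim(half$labels), c(4L, 4L, 4L))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_true(half$labels[i, j, k] %in%
                  lab[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                      (2 * k - 1):(2 * k)])
  # mixture fractions preserved within 2 points under 36 -> 60.7 style scaling
  mix <- suppressWarnings(make_mixture_phantom(mixture_spec(seed = 21), 300))
  pm3 <- suppressWarnings(build_interface_layer(local({
    p <- segment_phases(mix, seg_thresholds(515, 838))
    p$labels[p$labels == lv[["bone"]]] <- lv[["morsel"]]
    p
  })))
  re <- rescale_phasemap(pm3, 505.8)
  f0 <- phase_counts(pm3)$fraction
  f1 <- phase_counts(re)$fraction
  expect_true(all(abs(f1 - f0) < 0.02, na.rm = TRUE))
})

test_that("graft implantation fills the defect void and only the defect void", {
  lv <- phase_levels()
  cut <- create_cortical_window(tube1, defect_spec(60, 11.1))
  box <- attr(cut, "defect_box")
  mix <- suppressWarnings(make_mixture_phantom(
    mixture_spec(bag_fraction = 100, seed = 13), 300))
  src <- suppressWarnings(build_interface_layer(
    segment_phases(mix, seg_thresholds(515, 838))))
  src <- mixture_core_region(src)
  grafted <- suppressWarnings(implant_graft(cut, src))
  # outside the box nothing changed
  keep <- array(TRUE, dim = dim(cut$labels))
  keep[box$i, box$j, box$k] <- FALSE
  expect_identical(grafted$labels[keep], cut$labels[keep])
  # a 100% BAG source contributes only bag and interface labels
  inbox <- table(grafted$labels[box$i, box$j, box$k])
  got <- as.integer(names(inbox))
  expect_true(all(got %in% c(lv[["void"]], lv[["bag"]], lv[["interface"]])))
  rep_ <- attr(grafted, "graft_report")
  expect_equal(sum(rep_$voxels), length(box$i) * length(box$j) * length(box$k))
  expect_gt(rep_$voxels[rep_$phase == "bag"], 0)
})

test_that("implanting without a recorded defect fails; a zero-size defect is a no-op", {
  mixpm <- block_phasemap(3, 3, 3, phase = "bag", voxel_um = 500)
  expect_error(implant_graft(tube1, mixpm), "defect")
  tiny <- create_cortical_window(tube1, defect_spec(1e-6, 11.1))
  expect_identical(implant_graft(tiny, mixpm)$labels, tiny$labels)
})
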