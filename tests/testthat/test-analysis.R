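bar_bent <- local({
  # slender rectangular bar in pure bending: the energy-equivalent strain is
  # linear through the depth, giving closed-form quantiles
  pm <- block_phasemap(4, 10, 40, phase = "bone", voxel_um = 1000)
  m <- phasemap_to_model(pm, material_table(bone = 6829))
  m <- apply_bending_bc(m, bending_protocol(0.005, axis = c(1, 0)))
  solve_fe(m, x0 = beam_bending_guess(m))
})

test_that("bending and axial stiffness are load-level invariants", {
  k1 <- bending_stiffness(bar_bent)
  expect_equal(bending_stiffness(bar_bent,
                                 theta_total = bar_bent$model$protocol$theta_total),
               k1)
  # doubling the rotation doubles the moment, leaving the stiffness unchanged
  m2 <- apply_bending_bc(phasemap_to_model(
    block_phasemap(4, 10, 40, phase = "bone", voxel_um = 1000),
    material_table(bone = 6829)), bending_protocol(0.01, axis = c(1, 0)))
  r2 <- solve_fe(m2, x0 = beam_bending_guess(m2))
  expect_equal(bending_stiffness(r2), k1, tolerance = 1e-6)

  pmc <- block_phasemap(4, 4, 12, phase = "bone", voxel_um = 1000)
  rc1 <- solve_fe(apply_compression_bc(phasemap_to_model(pmc),
                                       compression_protocol("high-friction")))
  rc2 <- solve_fe(apply_compression_bc(phasemap_to_model(pmc),
                                       compression_protocol("high-friction",
                                                            displacement = 0.24)))
  expect_equal(axial_stiffness(rc1), axial_stiffness(rc2), tolerance = 1e-6)
})

test_that("high-friction column stiffness sits between the uniaxial bounds", {
  # friction at the platens stiffens the column above the uniaxial-stress
  # E*A/L but, with free lateral surfaces, Saint-Venant decay keeps it far
  # below the fully confined bound 1.3462*E*A/L; the end effect shrinks as
  # the column gets more slender
  E <- 6826
  k <- vapply(c(10, 20), function(nz) {
    pm <- block_phasemap(5, 5, nz, phase = "bone", voxel_um = 1000)
    res <- solve_fe(apply_compression_bc(phasemap_to_model(
      pm, material_table(bone = E)), compression_protocol("high-friction")))
    axial_stiffness(res) * nz / (E * 25) * 1000  # normalized by E*A/L
  }, numeric(1))
  expect_true(all(k > 1 & k < 1.3462))
  expect_lt(k[2], k[1])
  expect_lt(abs(k[2] - 1), 0.1)
})

test_that("the Pistoia scaling matches the ramp oracle and the linear-field closed form", {
  ees <- bar_bent$fields[, "ees"]
  mf <- pistoia_failure_moment(bar_bent, rescale_to_criterion_modulus = FALSE)
  r <- bar_bent$reactions
  m_applied <- mean(abs(c(r$mx[r$plane == "proximal"], r$mx[r$plane == "distal"])))
  # independent load-ramp bisection oracle
  expect_equal(mf, m_applied * bf_failure_scale(ees), tolerance = 1e-3)
  # closed form for a strain field linear through the depth
  expect_equal(mf, m_applied * 0.007 / (0.98 * max(ees)), tolerance = 0.02)
  # linear scaling in the criterion strain
  crit2 <- failure_criterion(critical_strain = 0.014)
  expect_equal(pistoia_failure_moment(bar_bent, crit2,
                                      rescale_to_criterion_modulus = FALSE),
               2 * mf, tolerance = 1e-12)
  # criterion-modulus rescaling for a displacement-controlled single-phase solve
  expect_equal(pistoia_failure_moment(bar_bent,
                                      failure_criterion(modulus = 2 * 6829)),
               2 * mf, tolerance = 1e-12)
  expect_error(pistoia_failure_moment(bar_bent,
                                      failure_criterion(phases = "bag")),
               "counted")
})

test_that("reduction arithmetic is pairwise and complements the maintained fraction", {
  expect_equal(reduction(1, 0.85), 0.15)
  expect_equal(reduction(10, 10), 0)
  expect_equal(maintained_fraction(10, 8) + reduction(10, 8), 1)
  expect_error(reduction(0, 1), "zero")
  a <- outcome_record("sheep-1", "intact", failure_moment = 100)
  b <- outcome_record("sheep-1", "W50L18", failure_moment = 73)
  expect_equal(reduction(a, b, "failure_moment"), 0.27)
  c_ <- outcome_record("sheep-2", "W50L18", failure_moment = 73)
  expect_error(reduction(a, c_, "failure_moment"), "pairwise")
  tab <- reduction_table(dplyr::bind_rows(a, b))
  expect_equal(tab$failure_moment_reduction, 0.27)
})

test_that("load sharing splits parallel columns by their axial rigidity", {
  lv <- phase_levels()
  lab <- array(lv[["void"]], dim = c(5, 2, 8))
  lab[1:2, , ] <- lv[["bag"]]     # E = 35 GPa
  lab[4:5, , ] <- lv[["morsel"]]  # E = 2.5 GPa
  m <- phasemap_to_model(phasemap(lab, 1000), material_table(), clean = FALSE)
  m <- apply_compression_bc(m, compression_protocol("high-friction"))
  res <- solve_fe(m)
  ls <- load_sharing(res, "distal")
  expect_equal(sum(ls$share), 1, tolerance = 1e-9)
  expect_equal(ls$share[ls$phase == "bag"], 35 / 37.5, tolerance = 0.001)
  expect_equal(ls$share[ls$phase == "morsel"], 2.5 / 37.5, tolerance = 0.001)
  # a single-phase model carries everything in that phase
  res1 <- solve_fe(apply_compression_bc(
    phasemap_to_model(block_phasemap(3, 3, 6, phase = "bone")),
    compression_protocol("high-friction")))
  ls1 <- load_sharing(res1, "proximal")
  expect_equal(ls1$share[ls1$phase == "bone"], 1)
})

test_that("single-phase modulus fitting is one-step linear scaling", {
  pm <- block_phasemap(3, 3, 6, phase = "morsel")
  m <- apply_compression_bc(phasemap_to_model(pm, material_table(morsel = 2500)),
                            compression_protocol("confined"))
  truth <- aggregate_modulus(solve_fe(m), 9)
  fit <- fit_phase_modulus(list(m), targets = 2 * truth, free_phase = "morsel",
                           areas = 9)
  expect_equal(fit$estimate, 5000, tolerance = 1e-6)
  expect_equal(fit$convergence$method, "linear-scaling")
  g <- glance(fit)
  expect_lt(g$mean_rel_error, 1e-6)
  expect_equal(nrow(tidy(fit)), 1)
})
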