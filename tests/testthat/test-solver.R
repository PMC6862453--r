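test_that("the brick element stiffness has the expected structure", {
  K <- hex_stiffness(20e3, 0.3, 0.5)
  expect_lt(max(abs(K - t(K))), 1e-9 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6)  # rigid-body nullspace
  expect_equal(hex_stiffness(40e3, 0.3, 0.5), 2 * K, tolerance = 1e-12)
  expect_equal(hex_stiffness(20e3, 0.3, 1.0), 2 * K, tolerance = 1e-12)
})

test_that("a prescribed uniaxial-strain field reproduces the C11 stress", {
  # single element, all dofs prescribed to u_z = eps * z
  eps <- 1e-3
  m <- phasemap_to_model(block_phasemap(1, 1, 1),
                         diaphysis_materials(E = 20e3))
  m$constraints <- tibble::tibble(
    node = rep(1:8, each = 3), dof = rep(1:3, 8),
    value = as.vector(t(cbind(0, 0, eps * m$coords[, 3]))))
  res <- solve_fe(m)
  c11 <- 20e3 * (1 - 0.3) / ((1 + 0.3) * (1 - 2 * 0.3))
  expect_equal(unname(res$fields[1, "szz"]), c11 * eps, tolerance = 1e-10)
  expect_equal(unname(res$fields[1, "ezz"]), eps, tolerance = 1e-12)
  # energy-equivalent strain of the uniaxial-strain state: eps * sqrt(C11/E)
  expect_equal(unname(res$fields[1, "ees"]), eps * sqrt(c11 / 20e3),
               tolerance = 1e-10)
})

tube_bent <- local({
  pm <- tube_phasemap(1000)
  m <- apply_bending_bc(phasemap_to_model(pm, diaphysis_materials(E = 20e3)),
                        bending_protocol(0.01))
  solve_fe(m, x0 = beam_bending_guess(m))
})

test_that("pure bending of a voxel tube balances, conserves energy and tracks beam theory", {
  r <- tube_bent$reactions
  mp <- sqrt(sum(unlist(r[r$plane == "proximal", c("mx", "my", "mz")])^2))
  md <- sqrt(sum(unlist(r[r$plane == "distal", c("mx", "my", "mz")])^2))
  expect_lt(abs(mp - md) / md, 0.001)          # end moments balance
  expect_lt(abs(tube_bent$strain_energy / tube_bent$external_work - 1), 0.005)
  kb <- 20e3 * pi * (9^4 - 6^4) / 4 / 60
  expect_lt(abs(bending_stiffness(tube_bent) / kb - 1), 0.05)
  expect_lt(tube_bent$solver$relres, 1e-6)
})

test_that("the solution is invariant under node renumbering", {
  pm <- block_phasemap(3, 3, 6)
  m <- apply_compression_bc(phasemap_to_model(pm),
                            compression_protocol("high-friction"))
  res <- solve_fe(m)
  nn <- nrow(m$coords)
  set.seed(12)
  perm <- sample(nn)           # new index -> old index
  inv <- integer(nn); inv[perm] <- seq_len(nn)
  m2 <- m
  m2$coords <- m$coords[perm, ]
  m2$conn <- matrix(inv[m$conn + 1L], nrow(m$conn), 8) - 1L
  m2$constraints$node <- inv[m$constraints$node]
  m2$planes$proximal$nodes <- inv[m$planes$proximal$nodes]
  m2$planes$distal$nodes <- inv[m$planes$distal$nodes]
  res2 <- solve_fe(m2)
  expect_lt(max(abs(res2$u[inv, ] - res$u)) / max(abs(res$u)), 1e-8)
})

test_that("the solution is invariant under in-plane axis permutation", {
  lv <- phase_levels()
  lab <- array(lv[["void"]], dim = c(5, 7, 8))
  lab[1:4, 2:4, ] <- lv[["bone"]]
  k1 <- axial_stiffness(solve_fe(apply_compression_bc(
    phasemap_to_model(phasemap(lab, 1000)), compression_protocol("high-friction"))))
  lab2 <- aperm(lab, c(2, 1, 3))
  k2 <- axial_stiffness(solve_fe(apply_compression_bc(
    phasemap_to_model(phasemap(lab2, 1000)), compression_protocol("high-friction"))))
  expect_equal(k1, k2, tolerance = 1e-8)
})

test_that("a rigid-body translation produces no strain and no reactions", {
  m <- phasemap_to_model(block_phasemap(3, 3, 6))
  t0 <- c(0.01, 0.02, 0.03)
  nd <- c(m$planes$proximal$nodes, m$planes$distal$nodes)
  m$constraints <- tibble::tibble(node = rep(nd, each = 3),
                                  dof = rep(1:3, length(nd)),
                                  value = rep(t0, length(nd)))
  res <- solve_fe(m, tol = 1e-12)
  # reference load: the same mesh under 1% compression
  ref <- solve_fe(apply_compression_bc(phasemap_to_model(block_phasemap(3, 3, 6)),
                                       compression_protocol("high-friction")))
  fref <- max(abs(ref$reactions$fz))
  expect_lt(max(abs(res$reactions$fz)) / fref, 1e-8)
  expect_lt(max(abs(res$fields[, "ees"])), 1e-10)
})

test_that("solving requires constraints and reports convergence", {
  m <- phasemap_to_model(block_phasemap(2, 2, 2))
  expect_error(solve_fe(m), "constraint")
  mc <- apply_compression_bc(m, compression_protocol("high-friction"))
  expect_error(solve_fe(mc, maxit = 1L), "converge")
  res <- solve_fe(mc)
  expect_true(res$solver$converged)
  g <- glance(res)
  expect_equal(g$n_elements, 8)
  td <- tidy(res)
  expect_equal(nrow(td), 8)
  expect_true(all(td$ees >= 0))
  pr <- plane_reaction(res, "distal")
  expect_equal(pr$force[3], res$reactions$fz[res$reactions$plane == "distal"])
})
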