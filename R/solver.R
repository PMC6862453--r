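#' Element stiffness matrix of a voxel brick element
#'
#' Standard 8-node trilinear hexahedron with 2x2x2 Gauss quadrature, isotropic
#' linear elasticity. The matrix is symmetric positive-semidefinite with a
#' 6-dimensional rigid-body nullspace and scales linearly in both `E` and `h`.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @param h Element edge length (mm).
#' @return A 24x24 numeric matrix (dof order: node-major x, y, z).
#' @export
hex_stiffness <- function(E, nu, h) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, h > 0)
  E * hex_khat_cpp(nu, h)
}

#' Solve the linear-elastic voxel FE system
#'
#' Matrix-free element-by-element conjugate gradients with a Jacobi
#' preconditioner. Dirichlet constraints are imposed exactly; the free
#' degrees of freedom are solved to the requested relative residual.
#'
#' @param model An `femodel` with a non-empty constraint set.
#' @param tol Relative residual tolerance.
#' @param maxit Iteration cap.
#' @param x0 Optional initial guess for the nodal displacements, an
#'   `nnodes x 3` matrix (e.g. a beam-theory field); defaults to zero.
#' @param on_nonconvergence `"error"` or `"warn"`.
#' @return An `feresult`: nodal displacements (mm), per-element centroid
#'   strain/stress summaries (von Mises stress in MPa, strain energy density
#'   in MPa, energy-equivalent strain), reaction force (N) and moment (N mm)
#'   about each constrained end plane's section centroid, and a solver report.
#' @export
solve_fe <- function(model, tol = 1e-6, maxit = 50000L, x0 = NULL,
                     on_nonconvergence = c("error", "warn")) {
  stopifnot(inherits(model, "femodel"))
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (!nrow(model$constraints))
    stop("constraint set is empty; apply boundary conditions first", call. = FALSE)
  nn <- nrow(model$coords)
  ndof <- 3L * nn

  grp_info <- nu_groups(model)
  khats <- lapply(grp_info$nus, hex_khat_cpp, h = model$h)

  fixed <- logical(ndof)
  fixedval <- numeric(ndof)
  di <- 3L * (model$constraints$node - 1L) + model$constraints$dof
  fixed[di] <- TRUE
  fixedval[di] <- model$constraints$value

  x0v <- NULL
  if (!is.null(x0)) {
    stopifnot(is.matrix(x0), nrow(x0) == nn, ncol(x0) == 3L)
    x0v <- as.vector(t(x0))
  }
  sol <- fe_cg_solve_cpp(model$conn, grp_info$grp, model$E_elem, khats, nn,
                         fixed, fixedval, x0v, tol, as.integer(maxit))
  if (!sol$converged) {
    msg <- sprintf("CG did not converge in %d iterations (relres %.3g)",
                   sol$iterations, sol$relres)
    if (on_nonconvergence == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  u <- sol$u
  fields <- element_fields_cpp(model$conn, grp_info$grp, model$E_elem,
                               grp_info$nus, khats, model$h, u)
  colnames(fields) <- c("exx", "eyy", "ezz", "gxy", "gyz", "gxz",
                        "sxx", "syy", "szz", "sxy", "syz", "sxz",
                        "von_mises", "sed", "ees", "energy")
  f <- fe_apply_k_cpp(model$conn, grp_info$grp, model$E_elem, khats, nn, u)
  fmat <- matrix(f, ncol = 3, byrow = TRUE)
  umat <- matrix(u, ncol = 3, byrow = TRUE)

  reactions <- purrr::map_dfr(c("proximal", "distal"), function(p) {
    nd <- model$planes[[p]]$nodes
    cen <- model$planes[[p]]$centroid
    fp <- fmat[nd, , drop = FALSE]
    d <- sweep(model$coords[nd, , drop = FALSE], 2, cen)
    M <- c(sum(d[, 2] * fp[, 3] - d[, 3] * fp[, 2]),
           sum(d[, 3] * fp[, 1] - d[, 1] * fp[, 3]),
           sum(d[, 1] * fp[, 2] - d[, 2] * fp[, 1]))
    tibble::tibble(plane = p, fx = sum(fp[, 1]), fy = sum(fp[, 2]),
                   fz = sum(fp[, 3]), mx = M[1], my = M[2], mz = M[3])
  })

  energy <- sum(fields[, "energy"])
  work <- 0.5 * sum(f[fixed] * u[fixed])

  structure(
    list(u = umat, fields = fields, reactions = reactions,
         internal_forces = fmat,
         solver = list(iterations = sol$iterations, relres = sol$relres,
                       converged = sol$converged, tol = tol),
         strain_energy = energy, external_work = work,
         model = model),
    class = "feresult"
  )
}

# group elements by Poisson ratio (unit-E stiffness matrices are shared)
nu_groups <- function(model) {
  nus <- sort(unique(model$nu_elem))
  grp <- match(model$nu_elem, nus) - 1L
  list(nus = nus, grp = grp)
}

#' @export
print.feresult <- function(x, ...) {
  cat(sprintf("<feresult> %d elements, %d nodes\n", nrow(x$fields), nrow(x$u)))
  cat(sprintf("  CG: %d iterations, relative residual %.3g\n",
              x$solver$iterations, x$solver$relres))
  cat(sprintf("  strain energy %.6g MPa mm^3 (external work %.6g)\n",
              x$strain_energy, x$external_work))
  print(x$reactions)
  invisible(x)
}

#' Reaction force and moment at a constrained plane
#'
#' The moment is taken about the plane's section centroid.
#'
#' @param result An `feresult`.
#' @param plane `"proximal"` or `"distal"`.
#' @return A list with `force` (N, length 3) and `moment` (N mm, length 3).
#' @export
plane_reaction <- function(result, plane = c("distal", "proximal")) {
  stopifnot(inherits(result, "feresult"))
  plane <- match.arg(plane)
  nd <- result$model$planes[[plane]]$nodes
  cons <- result$model$constraints
  if (!any(cons$node %in% nd))
    stop(plane, " plane is not constrained", call. = FALSE)
  r <- result$reactions[result$reactions$plane == plane, ]
  list(force = c(r$fx, r$fy, r$fz), moment = c(r$mx, r$my, r$mz))
}

#' Tidy per-element results
#'
#' @param x An `feresult`.
#' @param ... Unused.
#' @return A tibble with one row per element: voxel indices, phase, centroid
#'   strain and stress components, von Mises stress, strain energy density and
#'   energy-equivalent strain.
#' @export
tidy.feresult <- function(x, ...) {
  idx <- x$model$voxel_index
  dplyr::bind_cols(
    tibble::tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                   phase = x$model$elem_phase),
    tibble::as_tibble(x$fields)
  )
}

#' One-row summary of a solved model
#'
#' @param x An `feresult`.
#' @param ... Unused.
#' @return A tibble with element/node counts, solver diagnostics, strain
#'   energy, external work and the axial force and bending moments at the two
#'   end planes.
#' @export
glance.feresult <- function(x, ...) {
  r <- x$reactions
  tibble::tibble(
    n_elements = nrow(x$fields), n_nodes = nrow(x$u),
    iterations = x$solver$iterations, relres = x$solver$relres,
    converged = x$solver$converged,
    strain_energy = x$strain_energy, external_work = x$external_work,
    fz_proximal = r$fz[r$plane == "proximal"],
    fz_distal = r$fz[r$plane == "distal"],
    m_proximal = sqrt(sum(unlist(r[r$plane == "proximal", c("mx", "my", "mz")])^2)),
    m_distal = sqrt(sum(unlist(r[r$plane == "distal", c("mx", "my", "mz")])^2))
  )
}

#' Turn an object into a tidy tibble
#'
#' Broom-style generics: `tidy()` returns one row per estimated or evaluated
#' unit, `glance()` a one-row summary.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Beam-theory displacement guess for pure bending
#'
#' Euler-Bernoulli pure-bending displacement field evaluated at the model's
#' nodes, used to warm-start the conjugate-gradient solver.
#'
#' @param model An `femodel` with a bending protocol applied.
#' @return An `nnodes x 3` matrix of displacements (mm).
#' @export
beam_bending_guess <- function(model) {
  stopifnot(inherits(model, "femodel"),
            inherits(model$protocol, "bending_protocol"))
  prot <- model$protocol
  L <- model$planes$distal$z - model$planes$proximal$z
  kappa <- prot$theta_total / L
  cen <- (model$planes$proximal$centroid + model$planes$distal$centroid) / 2
  co <- sweep(model$coords, 2, cen)
  # rotate in-plane coords so the bending axis is local x
  a <- prot$axis
  xb <- a[1] * co[, 1] + a[2] * co[, 2]   # along bending axis
  yb <- -a[2] * co[, 1] + a[1] * co[, 2]  # transverse (bending plane)
  z <- co[, 3]
  s <- c(prot$compress_side, 0)
  sb <- -a[2] * s[1] + a[1] * s[2]
  sgn <- if (sb >= 0) -1 else 1  # compress the marked side: ezz = sgn*kappa*yb
  nu <- stats::median(model$nu_elem)
  uz <- sgn * kappa * yb * z
  uy <- -sgn * kappa / 2 * (z^2 - L^2 / 4 + nu * (yb^2 - xb^2))
  ux <- -sgn * kappa * nu * xb * yb
  # back to global in-plane axes
  gx <- a[1] * ux - a[2] * uy
  gy <- a[2] * ux + a[1] * uy
  cbind(gx, gy, uz)
}
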