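#' Material table
#'
#' Per-phase isotropic linear-elastic properties. The defaults follow the
#' grafted-tibia model: bone morsels 2.5 GPa, BAG 35 GPa, interface 25 MPa,
#' tibia bone 6826 MPa, all with Poisson ratio 0.3; the long-bone diaphysis
#' models instead use 20 GPa cortical bone (see [diaphysis_materials()]).
#'
#' @param bone,bag,interface,morsel Young's moduli in MPa.
#' @param nu Poisson ratio, shared by all phases unless a length-4 vector
#'   (bone, bag, interface, morsel) is given.
#' @return A tibble with columns `phase`, `young_modulus` (MPa), `poisson`.
#' @export
material_table <- function(bone = 6826, bag = 35e3, interface = 25,
                           morsel = 2.5e3, nu = 0.3) {
  E <- c(bone = bone, bag = bag, interface = interface, morsel = morsel)
  nu <- rep(nu, length.out = 4)
  if (any(E <= 0)) stop("Young's moduli must be positive", call. = FALSE)
  if (any(nu < 0 | nu >= 0.5)) stop("Poisson ratios must lie in [0, 0.5)",
                                    call. = FALSE)
  tibble::tibble(phase = names(E), young_modulus = unname(E), poisson = nu)
}

#' @rdname material_table
#' @param E Cortical bone modulus in MPa (default 20 GPa).
#' @export
diaphysis_materials <- function(E = 20e3, nu = 0.3) {
  material_table(bone = E, nu = nu)
}

#' Convert a phase map to a hexahedral FE model
#'
#' One 8-node brick element per non-void voxel, with shared nodes merged.
#' Elements outside the largest face-connected (6-neighborhood) component are
#' removed and counted in a cleaning report; corner- or edge-connected
#' elements would otherwise create near-singular systems.
#'
#' @param pm A [phasemap].
#' @param materials A [material_table()] tibble.
#' @param clean Remove elements outside the largest face-connected component.
#' @return An `femodel`: element connectivity, node coordinates (mm), element
#'   size (mm), per-element phase and material, empty constraint set, and end
#'   plane (proximal/distal) node sets with section centroids.
#' @export
phasemap_to_model <- function(pm, materials = material_table(), clean = TRUE) {
  stopifnot(inherits(pm, "phasemap"))
  lv <- phase_levels()
  d <- dim(pm$labels)
  nonvoid <- pm$labels != lv[["void"]]
  if (!any(nonvoid)) stop("phase map has no non-void voxels", call. = FALSE)

  removed <- tibble::tibble(phase = character(), elements = integer())
  keep <- nonvoid
  if (clean) {
    comp <- label_components6_cpp(as.vector(nonvoid), d[1], d[2], d[3])
    comp <- array(comp, dim = d)
    sizes <- tabulate(comp[nonvoid])
    main <- which.max(sizes)
    keep <- comp == main
    drop <- nonvoid & !keep
    if (any(drop)) {
      codes <- pm$labels[drop]
      tab <- table(factor(names(lv)[match(codes, lv)], levels = names(lv)))
      tab <- tab[tab > 0]
      removed <- tibble::tibble(phase = names(tab), elements = as.integer(tab))
    }
  }
  if (!any(keep)) stop("mesh is empty after cleaning", call. = FALSE)

  idx <- which(keep, arr.ind = TRUE)
  nx <- d[1]; ny <- d[2]
  npx <- nx + 1L; npy <- ny + 1L
  node_id <- function(i, j, k) i + npx * (j - 1L) + npx * npy * (k - 1L)
  # local order: (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)
  loc <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  conn_raw <- matrix(0L, nrow(idx), 8)
  for (l in 1:8)
    conn_raw[, l] <- node_id(idx[, 1] + loc[l, 1], idx[, 2] + loc[l, 2],
                             idx[, 3] + loc[l, 3])
  used <- sort(unique(as.vector(conn_raw)))
  conn <- matrix(match(conn_raw, used), nrow(idx), 8) - 1L  # 0-based

  h <- pm$voxel_size / 1000
  gi <- (used - 1L) %% npx + 1L
  gj <- ((used - 1L) %/% npx) %% npy + 1L
  gk <- (used - 1L) %/% (npx * npy) + 1L
  coords <- cbind(x = (gi - 1) * h, y = (gj - 1) * h, z = (gk - 1) * h)

  elem_code <- pm$labels[keep]
  elem_phase <- names(lv)[match(elem_code, lv)]
  mrow <- match(elem_phase, materials$phase)
  if (anyNA(mrow))
    stop("materials table lacks phase(s): ",
         paste(unique(elem_phase[is.na(mrow)]), collapse = ", "), call. = FALSE)
  E_elem <- materials$young_modulus[mrow]
  nu_elem <- materials$poisson[mrow]

  zmin <- min(coords[, "z"]); zmax <- max(coords[, "z"])
  prox <- which(abs(coords[, "z"] - zmin) < h / 4)
  dist <- which(abs(coords[, "z"] - zmax) < h / 4)
  planes <- list(
    proximal = list(nodes = prox, z = zmin,
                    centroid = colMeans(coords[prox, , drop = FALSE])),
    distal = list(nodes = dist, z = zmax,
                  centroid = colMeans(coords[dist, , drop = FALSE]))
  )

  structure(
    list(conn = conn, coords = coords, h = h, voxel_index = idx, dims = d,
         elem_phase = elem_phase, E_elem = E_elem, nu_elem = nu_elem,
         materials = materials,
         constraints = tibble::tibble(node = integer(), dof = integer(),
                                      value = numeric()),
         planes = planes, protocol = NULL,
         cleaning = removed),
    class = "femodel"
  )
}

#' @export
print.femodel <- function(x, ...) {
  cat(sprintf("<femodel> %d elements, %d nodes, h = %.4g mm\n",
              nrow(x$conn), nrow(x$coords), x$h))
  cat(sprintf("  phases: %s\n",
              paste(sprintf("%s (%d)", names(table(x$elem_phase)),
                            table(x$elem_phase)), collapse = ", ")))
  cat(sprintf("  constraints: %d; protocol: %s\n", nrow(x$constraints),
              if (is.null(x$protocol)) "none" else x$protocol$kind))
  if (nrow(x$cleaning))
    cat(sprintf("  cleaning removed %d element(s)\n", sum(x$cleaning$elements)))
  invisible(x)
}

#' Pure-bending protocol
#'
#' End planes receive opposite rigid rotations of half the total angle each
#' about the bending axis through the plane's section centroid, producing pure
#' bending under displacement control. The rotation sense is chosen so that
#' the marked side of the section is compressed.
#'
#' @param rotation_per_end Rotation magnitude applied at each end (rad); the
#'   total relative end rotation is twice this.
#' @param axis In-plane bending axis direction, length-2 unit vector (x, y).
#' @param compress_side In-plane direction of the region that must end up in
#'   compression.
#' @return A `bending_protocol` object.
#' @export
bending_protocol <- function(rotation_per_end = 0.01, axis = c(1, 0),
                             compress_side = c(0, 1)) {
  stopifnot(abs(rotation_per_end) > 0, length(axis) == 2L,
            length(compress_side) == 2L)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = "bending", rotation_per_end = rotation_per_end,
                 theta_total = 2 * rotation_per_end, axis = axis,
                 compress_side = compress_side),
            class = "bending_protocol")
}

#' Compression protocol
#'
#' High-friction mode fully fixes the bottom plane and prescribes an axial
#' displacement on the laterally fixed top plane; confined mode additionally
#' suppresses the wall-normal displacement of every lateral surface node.
#'
#' @param mode `"high-friction"` or `"confined"`.
#' @param displacement Applied axial shortening in mm; defaults to 1% of the
#'   specimen height.
#' @return A `compression_protocol` object.
#' @export
compression_protocol <- function(mode = c("high-friction", "confined"),
                                 displacement = NULL) {
  mode <- match.arg(mode)
  if (!is.null(displacement) && displacement == 0)
    stop("displacement must be non-zero", call. = FALSE)
  structure(list(kind = "compression", mode = mode, displacement = displacement),
            class = "compression_protocol")
}

check_end_planes <- function(model) {
  for (p in c("proximal", "distal")) {
    nd <- model$planes[[p]]$nodes
    if (length(nd) < 3) stop(p, " end plane has fewer than 3 nodes", call. = FALSE)
    xy <- model$coords[nd, 1:2, drop = FALSE]
    if (qr(sweep(xy, 2, colMeans(xy)))$rank < 1)
      stop(p, " end plane nodes are degenerate", call. = FALSE)
  }
}

#' Apply pure-bending boundary conditions
#'
#' @param model An `femodel`.
#' @param prot A [bending_protocol()].
#' @return The model with all three displacement components prescribed on
#'   every end-plane node and the protocol recorded.
#' @export
apply_bending_bc <- function(model, prot = bending_protocol()) {
  stopifnot(inherits(model, "femodel"), inherits(prot, "bending_protocol"))
  check_end_planes(model)
  n3 <- c(prot$axis, 0)
  rot_disp <- function(plane, sgn) {
    nd <- model$planes[[plane]]$nodes
    cen <- model$planes[[plane]]$centroid
    d <- sweep(model$coords[nd, , drop = FALSE], 2, cen)
    phi <- sgn * (prot$theta_total / 2) * n3
    u <- cbind(phi[2] * d[, 3] - phi[3] * d[, 2],
               phi[3] * d[, 1] - phi[1] * d[, 3],
               phi[1] * d[, 2] - phi[2] * d[, 1])
    list(nodes = nd, u = u)
  }
  # provisional sense: distal +, proximal -; flip if the marked side is in tension
  s <- c(prot$compress_side, 0)
  probe <- function(sgn) {
    phi_d <- sgn * (prot$theta_total / 2) * n3
    # axial displacement at centroid + s on distal minus proximal plane
    uz <- function(phi) phi[1] * s[2] - phi[2] * s[1]
    uz(phi_d) - uz(-phi_d)
  }
  sgn <- if (probe(1) <= 0) 1 else -1
  dd <- rot_disp("distal", sgn)
  pp <- rot_disp("proximal", -sgn)
  add <- tibble::tibble(
    node = rep(c(dd$nodes, pp$nodes), each = 3),
    dof = rep(1:3, length(dd$nodes) + length(pp$nodes)),
    value = as.vector(t(rbind(dd$u, pp$u)))
  )
  model$constraints <- merge_constraints(model$constraints, add)
  model$protocol <- prot
  model
}

#' Apply compression boundary conditions
#'
#' @param model An `femodel`.
#' @param prot A [compression_protocol()].
#' @return The model with constraints and protocol recorded.
#' @export
apply_compression_bc <- function(model, prot = compression_protocol()) {
  stopifnot(inherits(model, "femodel"), inherits(prot, "compression_protocol"))
  check_end_planes(model)
  height <- model$planes$distal$z - model$planes$proximal$z
  delta <- if (is.null(prot$displacement)) 0.01 * height else prot$displacement
  bot <- model$planes$proximal$nodes
  top <- model$planes$distal$nodes
  add <- tibble::tibble(
    node = c(rep(bot, each = 3), rep(top, each = 3)),
    dof = rep(1:3, length(bot) + length(top)),
    value = c(rep(0, 3 * length(bot)),
              as.vector(t(cbind(0, 0, rep(-delta, length(top))))))
  )
  if (prot$mode == "confined") {
    lat <- lateral_normal_constraints(model)
    already <- unique(add$node)
    lat <- lat[!(lat$node %in% already), , drop = FALSE]
    add <- dplyr::bind_rows(add, lat)
  }
  model$constraints <- merge_constraints(model$constraints, add)
  prot$displacement <- delta
  prot$height <- height
  model$protocol <- prot
  model
}

# wall-normal zero-displacement constraints for every lateral boundary face:
# a face between an occupied voxel and a missing +-x neighbour fixes x on its
# four nodes, likewise for y
lateral_normal_constraints <- function(model) {
  d <- model$dims
  occ <- array(FALSE, dim = d)
  occ[model$voxel_index] <- TRUE
  npx <- d[1] + 1L; npy <- d[2] + 1L
  node_id <- function(i, j, k) i + npx * (j - 1L) + npx * npy * (k - 1L)
  face_nodes <- function(idx, axis, side) {
    if (!nrow(idx)) return(integer())
    i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
    if (axis == 1L) {
      ii <- i + side
      c(node_id(ii, j, k), node_id(ii, j + 1L, k),
        node_id(ii, j, k + 1L), node_id(ii, j + 1L, k + 1L))
    } else {
      jj <- j + side
      c(node_id(i, jj, k), node_id(i + 1L, jj, k),
        node_id(i, jj, k + 1L), node_id(i + 1L, jj, k + 1L))
    }
  }
  grid_to_local <- local_node_lookup(model)
  out <- list()
  for (axis in 1:2) {
    for (side in 0:1) {
      sh <- c(0L, 0L, 0L)
      sh[axis] <- if (side == 1L) 1L else -1L
      nb <- shift3(occ, -sh[1], -sh[2], -sh[3], fill = FALSE)
      faces <- which(occ & !nb, arr.ind = TRUE)
      ids <- unique(face_nodes(faces, axis, side))
      loc <- grid_to_local(ids)
      loc <- loc[!is.na(loc)]
      if (length(loc))
        out[[length(out) + 1L]] <- tibble::tibble(node = loc, dof = axis, value = 0)
    }
  }
  res <- dplyr::distinct(dplyr::bind_rows(out))
  res
}

# map node-grid linear ids to local (compressed) node numbers
local_node_lookup <- function(model) {
  d <- model$dims
  npx <- d[1] + 1L; npy <- d[2] + 1L
  h <- model$h
  gi <- round(model$coords[, 1] / h) + 1L
  gj <- round(model$coords[, 2] / h) + 1L
  gk <- round(model$coords[, 3] / h) + 1L
  grid_ids <- gi + npx * (gj - 1L) + npx * npy * (gk - 1L)
  function(ids) match(ids, grid_ids)
}

# additive, idempotent merge: a (node, dof) pair already constrained keeps its
# existing value; conflicting duplicates within `add` are an error
merge_constraints <- function(existing, add) {
  add <- dplyr::distinct(add)
  dup <- duplicated(add[c("node", "dof")])
  if (any(dup)) stop("conflicting constraint values for a (node, dof) pair",
                     call. = FALSE)
  key_e <- paste(existing$node, existing$dof)
  key_a <- paste(add$node, add$dof)
  dplyr::bind_rows(existing, add[!(key_a %in% key_e), , drop = FALSE])
}
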