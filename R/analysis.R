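bending_moment_about_axis <- function(result, plane) {
  prot <- result$model$protocol
  r <- result$reactions[result$reactions$plane == plane, ]
  abs(r$mx * prot$axis[1] + r$my * prot$axis[2])
}

#' Bending stiffness
#'
#' Reaction moment about the bending axis over the applied total relative end
#' rotation, averaged over the two end planes (which differ only by the solver
#' residual).
#'
#' @param result An `feresult` from a model with bending boundary conditions.
#' @param theta_total Total relative end rotation in rad; defaults to the
#'   protocol's value.
#' @return Bending stiffness in N mm/rad.
#' @export
bending_stiffness <- function(result, theta_total = NULL) {
  stopifnot(inherits(result, "feresult"))
  if (!inherits(result$model$protocol, "bending_protocol"))
    stop("result does not come from a bending protocol", call. = FALSE)
  if (is.null(theta_total)) theta_total <- result$model$protocol$theta_total
  m <- mean(c(bending_moment_about_axis(result, "proximal"),
              bending_moment_about_axis(result, "distal")))
  m / theta_total
}

#' Axial stiffness
#'
#' Axial reaction force over the applied axial displacement, averaged over the
#' two end planes.
#'
#' @param result An `feresult` from a model with compression boundary
#'   conditions.
#' @param delta Applied axial displacement in mm; defaults to the protocol's.
#' @return Axial stiffness in kN/mm.
#' @export
axial_stiffness <- function(result, delta = NULL) {
  stopifnot(inherits(result, "feresult"))
  if (!inherits(result$model$protocol, "compression_protocol"))
    stop("result does not come from a compression protocol", call. = FALSE)
  if (is.null(delta)) delta <- result$model$protocol$displacement
  r <- result$reactions
  f <- mean(abs(r$fz))
  f / abs(delta) / 1000
}

#' Apparent (aggregate) modulus of a compressed sample
#'
#' Axial stress over axial strain: `(F / A) / (delta / H)`. For granular
#' samples `A` is the container (plunger) cross-section, not the solid area.
#'
#' @param result An `feresult` from a compression solve.
#' @param area Reference cross-sectional area in mm^2.
#' @return Apparent modulus in MPa.
#' @export
aggregate_modulus <- function(result, area) {
  stopifnot(inherits(result, "feresult"), area > 0)
  prot <- result$model$protocol
  if (!inherits(prot, "compression_protocol"))
    stop("result does not come from a compression protocol", call. = FALSE)
  f <- mean(abs(result$reactions$fz))
  (f / area) / (abs(prot$displacement) / prot$height)
}

#' Pistoia failure criterion
#'
#' Bone is considered failed when more than a critical fraction of the counted
#' phase's elements carry an energy-equivalent strain above a critical value.
#' The linear solution is scaled to the failure load.
#'
#' @param volume_fraction Critical element fraction (default 0.02).
#' @param critical_strain Critical energy-equivalent strain (default 0.007).
#' @param modulus Bone modulus (MPa) prescribed for failure estimation
#'   (default 6829).
#' @param phases Phases whose elements are counted (default `"bone"`).
#' @return A `failure_criterion` object.
#' @export
failure_criterion <- function(volume_fraction = 0.02, critical_strain = 0.007,
                              modulus = 6829, phases = "bone") {
  stopifnot(volume_fraction > 0, volume_fraction < 1, critical_strain > 0,
            modulus > 0)
  structure(list(volume_fraction = volume_fraction,
                 critical_strain = critical_strain,
                 modulus = modulus, phases = phases),
            class = "failure_criterion")
}

#' Estimated failure moment (Pistoia criterion)
#'
#' Exploits linearity: with `e98` the (1 - fraction) linear-interpolated
#' quantile of the energy-equivalent strain over counted elements at the
#' applied load, the failure moment is the applied reaction moment scaled by
#' `critical_strain / e98`. Element volumes are identical, so element-count
#' and volume fractions coincide.
#'
#' Displacement-controlled bending of a homogeneous model yields strains that
#' do not depend on the assigned modulus while moments scale with it, so when
#' the solve used a different (single) bone modulus the applied moment is
#' rescaled to the criterion modulus (`rescale_to_criterion_modulus`).
#'
#' @param result An `feresult` from a bending solve.
#' @param crit A [failure_criterion()].
#' @param rescale_to_criterion_modulus Rescale the applied moment from the
#'   model's (single-phase) modulus to the criterion modulus.
#' @return Failure moment in N mm.
#' @export
pistoia_failure_moment <- function(result, crit = failure_criterion(),
                                   rescale_to_criterion_modulus = TRUE) {
  stopifnot(inherits(result, "feresult"), inherits(crit, "failure_criterion"))
  counted <- result$model$elem_phase %in% crit$phases
  if (!any(counted)) stop("no elements in the counted phase(s)", call. = FALSE)
  ees <- result$fields[counted, "ees"]
  e98 <- stats::quantile(ees, 1 - crit$volume_fraction, type = 7, names = FALSE)
  if (e98 <= 0) stop("counted phase is unstrained", call. = FALSE)
  m <- mean(c(bending_moment_about_axis(result, "proximal"),
              bending_moment_about_axis(result, "distal")))
  if (rescale_to_criterion_modulus) {
    E <- unique(result$model$E_elem)
    if (length(E) == 1L && E != crit$modulus) m <- m * crit$modulus / E
  }
  m * crit$critical_strain / e98
}

#' Paired outcome record
#'
#' One row per subject and condition, mirroring the study's within-subject
#' (pairwise) design.
#'
#' @param subject Subject identifier.
#' @param condition Condition label (e.g. `"intact"`, a window preset, or a
#'   graft name).
#' @param ... Named outcome values (e.g. `bending_stiffness`,
#'   `failure_moment`, `axial_stiffness`).
#' @return A one-row tibble of class `outcome_record`.
#' @export
outcome_record <- function(subject, condition, ...) {
  out <- tibble::tibble(subject = subject, condition = condition, ...)
  class(out) <- c("outcome_record", class(out))
  out
}

#' Maintained fraction and reduction of a paired outcome
#'
#' `reduction = 1 - defect / intact`, computed strictly within-subject; the
#' maintained fraction is the complementary ratio. Cross-subject pairs are
#' refused.
#'
#' @param intact,defect Numeric outcome values, or `outcome_record` rows from
#'   the same subject.
#' @param outcome For records: the name of the outcome column to compare.
#' @return The reduction (unitless). For records the result carries the
#'   subject and both conditions as attributes-free tibble columns via
#'   [reduction_table()].
#' @export
reduction <- function(intact, defect, outcome = NULL) {
  if (inherits(intact, "outcome_record") || inherits(defect, "outcome_record")) {
    stopifnot(inherits(intact, "outcome_record"), inherits(defect, "outcome_record"))
    if (!identical(intact$subject, defect$subject))
      stop("pairwise design: intact and defect records must share the subject",
           call. = FALSE)
    if (is.null(outcome))
      stop("`outcome` must name the outcome column for record input", call. = FALSE)
    intact <- intact[[outcome]]
    defect <- defect[[outcome]]
  }
  if (any(intact == 0)) stop("intact outcome is zero", call. = FALSE)
  1 - defect / intact
}

#' @rdname reduction
#' @export
maintained_fraction <- function(intact, defect, outcome = NULL) {
  1 - reduction(intact, defect, outcome)
}

#' Per-subject reduction table
#'
#' Joins intact rows to every non-intact condition of the same subject and
#' computes maintained fractions and reductions for each numeric outcome.
#'
#' @param records A tibble of [outcome_record()] rows.
#' @param intact_label Condition label of the reference rows.
#' @return A tibble with one row per subject x condition and, per outcome,
#'   `<outcome>_maintained` and `<outcome>_reduction` columns.
#' @export
reduction_table <- function(records, intact_label = "intact") {
  stopifnot(all(c("subject", "condition") %in% names(records)))
  outcomes <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                      c("subject", "condition"))
  ref <- dplyr::filter(records, .data$condition == intact_label)
  cmp <- dplyr::filter(records, .data$condition != intact_label)
  joined <- dplyr::inner_join(cmp, ref, by = "subject",
                              suffix = c("", "_intact"))
  for (oc in outcomes) {
    joined[[paste0(oc, "_maintained")]] <- joined[[oc]] / joined[[paste0(oc, "_intact")]]
    joined[[paste0(oc, "_reduction")]] <- 1 - joined[[paste0(oc, "_maintained")]]
  }
  dplyr::select(joined, -dplyr::ends_with("_intact"))
}

#' Per-phase load sharing at a constrained plane
#'
#' For each material phase, sums the axial internal-force contributions of
#' that phase's elements to the plane's nodes and divides by the plane's total
#' axial force. Shares over the present phases sum to one by construction.
#'
#' @param result An `feresult` from a compression solve.
#' @param plane `"distal"` or `"proximal"`.
#' @return A tibble with `plane`, `phase`, `force` (N) and `share`.
#' @export
load_sharing <- function(result, plane = c("distal", "proximal")) {
  stopifnot(inherits(result, "feresult"))
  plane <- match.arg(plane)
  model <- result$model
  nd <- model$planes[[plane]]$nodes
  if (!any(model$constraints$node %in% nd))
    stop(plane, " plane is not constrained", call. = FALSE)
  lv <- phase_levels()
  phase_idx <- match(model$elem_phase, names(lv)) - 1L  # 0-based incl. void slot
  grp_info <- nu_groups(model)
  khats <- lapply(grp_info$nus, hex_khat_cpp, h = model$h)
  inplane <- logical(nrow(model$coords))
  inplane[nd] <- TRUE
  u <- as.vector(t(result$u))
  fz <- plane_phase_axial_cpp(model$conn, grp_info$grp, model$E_elem, khats,
                              nrow(model$coords), u, phase_idx, length(lv),
                              inplane)
  names(fz) <- names(lv)
  present <- names(lv)[names(lv) %in% unique(model$elem_phase)]
  fz <- fz[present]
  tibble::tibble(plane = plane, phase = present, force = unname(fz),
                 share = unname(fz) / sum(fz))
}

#' Fit a phase modulus to measured aggregate moduli
#'
#' Tunes the Young's modulus of one phase so that simulated confined- or
#' high-friction-compression aggregate moduli best match the targets. A model
#' made entirely of the free phase responds linearly in its modulus and is
#' solved in one step; otherwise a bracketed scalar search on the log-modulus
#' drives the mean (or median) signed relative error across all samples to
#' zero -- the least-mean-relative-error fit under the monotone shared-slope
#' response -- with warm-started inner solves.
#'
#' @param models List of `femodel`s with compression constraints applied.
#' @param targets Measured aggregate moduli (MPa), one per model.
#' @param free_phase Phase whose modulus is fitted.
#' @param areas Reference cross-section area(s) in mm^2 (recycled).
#' @param E_init Initial modulus (MPa); defaults to the phase's table value of
#'   the first model.
#' @param objective `"mean"` or `"median"` relative error.
#' @param bracket_factor Search interval `[E_init / f, E_init * f]`.
#' @param rel_tol Relative convergence tolerance on the fitted modulus.
#' @param solver_tol CG tolerance for the inner solves.
#' @return A `phase_modulus_fit`: fitted modulus, per-sample predictions and a
#'   convergence report; supports [tidy()] and [glance()].
#' @export
fit_phase_modulus <- function(models, targets, free_phase, areas,
                              E_init = NULL, objective = c("mean", "median"),
                              bracket_factor = 100, rel_tol = 1e-3,
                              solver_tol = 1e-6) {
  objective <- match.arg(objective)
  stopifnot(is.list(models), length(models) == length(targets),
            all(targets > 0))
  areas <- rep(areas, length.out = length(models))
  if (is.null(E_init)) {
    mt <- models[[1]]$materials
    E_init <- mt$young_modulus[mt$phase == free_phase]
  }
  stopifnot(length(E_init) == 1L, E_init > 0)

  warm <- new.env(parent = emptyenv())
  evals <- 0L
  predict_all <- function(E) {
    evals <<- evals + 1L
    vapply(seq_along(models), function(i) {
      m <- models[[i]]
      sel <- m$elem_phase == free_phase
      if (!any(sel))
        stop("model ", i, " has no '", free_phase, "' elements", call. = FALSE)
      m$E_elem[sel] <- E
      key <- paste0("m", i)
      x0 <- if (!is.null(warm[[key]])) warm[[key]] else NULL
      res <- solve_fe(m, tol = solver_tol, x0 = x0)
      warm[[key]] <- res$u
      aggregate_modulus(res, areas[i])
    }, numeric(1))
  }
  single <- all(vapply(models, function(m) all(m$elem_phase == free_phase),
                       logical(1)))
  if (single) {
    pred0 <- predict_all(E_init)
    ratio <- targets / pred0
    E_fit <- E_init * (if (objective == "mean") mean(ratio) else
      stats::median(ratio))
    pred <- pred0 * E_fit / E_init
    conv <- list(method = "linear-scaling", evaluations = evals,
                 rel_step = 0)
  } else {
    # the aggregate modulus is monotone increasing in the free-phase modulus,
    # so the least-mean-relative-error fit is found at the zero crossing of
    # the (signed) mean or median relative error; a safeguarded secant search
    # on log-modulus stays near E_init and expands the bracket geometrically
    # only when needed (extreme moduli make the inner solves expensive)
    err_at <- function(lE) {
      p <- predict_all(10^lE)
      e <- (p - targets) / targets
      if (objective == "mean") mean(e) else stats::median(e)
    }
    l0 <- log10(E_init)
    lmax <- log10(E_init * bracket_factor)
    lmin <- log10(E_init / bracket_factor)
    f0 <- err_at(l0)
    step <- log10(4)
    la <- lb <- l0; fa <- fb <- f0
    while (sign(fa) == sign(fb)) {
      if (fb < 0) {  # predictions too soft: raise the modulus
        la <- lb; fa <- fb
        lb <- lb + step
        if (lb > lmax)
          stop("initial interval does not bracket the targets; widen bracket_factor",
               call. = FALSE)
        fb <- err_at(lb)
        if (fb < fa - 1e-12)
          stop("aggregate modulus is not monotone in the free phase modulus; aborting",
               call. = FALSE)
      } else {
        lb <- la; fb <- fa
        la <- la - step
        if (la < lmin)
          stop("initial interval does not bracket the targets; widen bracket_factor",
               call. = FALSE)
        fa <- err_at(la)
        if (fa > fb + 1e-12)
          stop("aggregate modulus is not monotone in the free phase modulus; aborting",
           call. = FALSE)
      }
      if (fa == 0) { lb <- la; fb <- fa; break }
      if (fb == 0) { la <- lb; fa <- fb; break }
    }
    ltol <- log10(1 + rel_tol)
    while (lb - la > ltol && fb != fa) {
      lm <- la + (lb - la) * (-fa) / (fb - fa)  # secant within the bracket
      lm <- min(max(lm, la + 0.1 * (lb - la)), lb - 0.1 * (lb - la))
      fm <- err_at(lm)
      if (sign(fm) == sign(fa)) { la <- lm; fa <- fm } else { lb <- lm; fb <- fm }
      if (fm == 0) { la <- lb <- lm; break }
    }
    E_fit <- 10^((la + lb) / 2)
    pred <- predict_all(E_fit)
    conv <- list(method = "secant-log-bracket", evaluations = evals,
                 rel_step = rel_tol)
  }
  structure(
    list(estimate = E_fit, free_phase = free_phase, objective = objective,
         samples = tibble::tibble(sample = seq_along(models), target = targets,
                                  predicted = pred,
                                  rel_error = (pred - targets) / targets),
         convergence = conv),
    class = "phase_modulus_fit"
  )
}

#' @export
print.phase_modulus_fit <- function(x, ...) {
  cat(sprintf("<phase_modulus_fit> %s modulus = %.6g MPa (%s, %d solves/sample)\n",
              x$free_phase, x$estimate, x$convergence$method,
              x$convergence$evaluations))
  print(x$samples)
  invisible(x)
}

#' @export
tidy.phase_modulus_fit <- function(x, ...) x$samples

#' @export
glance.phase_modulus_fit <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, free_phase = x$free_phase,
    objective = x$objective,
    mean_rel_error = mean(abs(x$samples$rel_error)),
    evaluations = x$convergence$evaluations,
    method = x$convergence$method
  )
}
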