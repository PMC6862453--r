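# Independent brute-force oracles and tiny fixture builders. The oracles use
# explicit voxel loops on purpose: they share no code with the implementation.

# 3x3x3-cube erosion, outside the grid counting as background
bf_erode <- function(m) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    keep <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) {
        keep <- FALSE
      } else if (!m[ii, jj, kk]) keep <- FALSE
    }
    out[i, j, k] <- keep
  }
  out
}

bf_dilate <- function(m) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (out[i, j, k]) next
    hit <- FALSE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && kk >= 1 &&
          kk <= d[3] && m[ii, jj, kk]) hit <- TRUE
    }
    out[i, j, k] <- hit
  }
  out
}

# full interface-layer oracle on a label array
bf_interface <- function(lab) {
  lv <- phase_levels()
  bag <- lab == lv[["bag"]]
  if (!any(bag)) return(lab)
  er <- bf_erode(bag)
  shell <- bf_dilate(bf_dilate(er)) & !er
  out <- lab
  for (s in which(shell)) {
    if (out[s] == lv[["bone"]] || out[s] == lv[["bag"]])
      out[s] <- lv[["interface"]]
  }
  out
}

# load-ramp failure scale: smallest load multiplier at which more than
# `fraction` of the counted elements exceed the critical strain (bisection)
bf_failure_scale <- function(ees, fraction = 0.02, critical = 0.007) {
  exceeds <- function(lam) mean(ees * lam > critical) > fraction
  lo <- 0; hi <- 1
  while (!exceeds(hi)) hi <- hi * 2
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (exceeds(mid)) hi <- mid else lo <- mid
  }
  hi
}

# uniform-label phase map fixtures
block_phasemap <- function(nx, ny, nz, phase = "bone", voxel_um = 1000) {
  lv <- phase_levels()
  phasemap(array(lv[[phase]], dim = c(nx, ny, nz)), voxel_um)
}

# circular tube phantom segmented to a phase map
tube_phasemap <- function(voxel_um = 1000, ro = 9, thick = 3, L = 60) {
  ph <- make_bone_phantom(
    bone_phantom_spec("tube", outer_radii = ro, cortical_thickness = thick,
                      length = L, intensity_bone = 800), voxel_um)
  segment_phases(ph, seg_thresholds(485))
}

# random three-phase label grid for morphology property tests
random_label_grid <- function(dims = c(10, 10, 10), p = c(0.6, 0.2, 0.2)) {
  lv <- phase_levels()
  codes <- sample(c(lv[["void"]], lv[["bone"]], lv[["bag"]]), prod(dims),
                  replace = TRUE, prob = p)
  array(codes, dim = dims)
}
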