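#' Calibrated 3-D scalar volume
#'
#' The common currency of the pipeline: a dense 3-D grid of calibrated
#' intensities (mgHA/cm^3) with an isotropic voxel size. Axis order is
#' right-handed (x, y, z) with z the longitudinal/loading axis; voxel centers
#' sit at `(i - 0.5) * h` along each axis (1-based indices).
#'
#' @param voxels 3-D numeric array of intensities (mgHA/cm^3).
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param origin Physical position (mm) of the grid corner, length-3 numeric.
#' @return An `image3d` object.
#' @export
image3d <- function(voxels, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)", call. = FALSE)
  if (any(dim(voxels) < 1L)) stop("grid dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(voxels))) stop("intensities must be finite", call. = FALSE)
  structure(
    list(voxels = voxels, voxel_size = voxel_size, origin = as.numeric(origin)),
    class = "image3d"
  )
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image3d> %d x %d x %d voxels @ %.4g um (%.3g x %.3g x %.3g mm)\n",
    d[1], d[2], d[3], x$voxel_size,
    d[1] * x$voxel_size / 1000, d[2] * x$voxel_size / 1000, d[3] * x$voxel_size / 1000
  ))
  cat(sprintf("  intensity range [%.4g, %.4g] mgHA/cm^3\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image3d <- function(x) dim(x$voxels)

# voxel-center coordinates (mm) along one axis
axis_centers <- function(n, voxel_size_um) {
  (seq_len(n) - 0.5) * voxel_size_um / 1000
}

# in-plane radius (mm) of every voxel from the volume's central axis, plus the
# largest such radius; shared by the beam-hardening forward and inverse models
inplane_radius <- function(dims, voxel_size_um) {
  xc <- axis_centers(dims[1], voxel_size_um)
  yc <- axis_centers(dims[2], voxel_size_um)
  cx <- dims[1] * voxel_size_um / 2000
  cy <- dims[2] * voxel_size_um / 2000
  r2d <- sqrt(outer((xc - cx)^2, (yc - cy)^2, `+`))
  list(r = array(rep(r2d, dims[3]), dim = dims), rmax = max(r2d))
}

#' Read or write a volume
#'
#' NIfTI (`.nii`, `.nii.gz`) is handled through RNifti; uncompressed MetaImage
#' (`.mha`) through a built-in reader/writer for the plain
#' `MET_FLOAT`/`MET_DOUBLE`/`MET_SHORT`/`MET_UCHAR` local-data layout.
#'
#' @param img An [image3d] (for writing).
#' @param path File path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `read_volume()` returns an [image3d]; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "image3d"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    ni <- RNifti::asNifti(img$voxels)
    ni <- RNifti::`pixdim<-`(ni, rep(img$voxel_size / 1000, 3))
    RNifti::writeNifti(ni, path)
  } else if (grepl("\\.mha$", path)) {
    write_mha(img, path)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    ni <- RNifti::readNifti(path)
    vs <- RNifti::pixdim(ni)[1] * 1000
    image3d(array(as.numeric(ni), dim = dim(ni)), voxel_size = vs)
  } else if (grepl("\\.mha$", path)) {
    read_mha(path)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
}

write_mha <- function(img, path) {
  d <- dim(img$voxels)
  h <- img$voxel_size / 1000
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g\n", h, h, h),
    sprintf("Offset = %.9g %.9g %.9g\n", img$origin[1], img$origin[2], img$origin[3]),
    "ElementType = MET_DOUBLE\n",
    "ElementDataFile = LOCAL\n"
  )
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(img$voxels), con, size = 8, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1)
    hdr <- c(hdr, ln)
    if (grepl("^ElementDataFile", ln)) break
  }
  get_field <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  if (!identical(get_field("ElementDataFile"), "LOCAL"))
    stop("only LOCAL-data MetaImage files are supported", call. = FALSE)
  dims <- as.integer(strsplit(get_field("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(get_field("ElementSpacing"), " +")[[1]])
  off <- get_field("Offset")
  origin <- if (is.null(off)) c(0, 0, 0) else as.numeric(strsplit(off, " +")[[1]])
  type <- get_field("ElementType")
  n <- prod(dims)
  vals <- switch(type,
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "numeric", n, size = 4, endian = "little"),
    MET_SHORT = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    MET_UCHAR = readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little"),
    stop("unsupported MetaImage element type: ", type, call. = FALSE)
  )
  image3d(array(as.numeric(vals), dim = dims), voxel_size = sp[1] * 1000,
          origin = origin)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Serialize or restore a specification record as YAML
#'
#' Phantom, artifact and defect specification records round-trip through
#' plain YAML with a `spec_class` field naming the constructor.
#'
#' @param spec A `bone_phantom_spec`, `mixture_spec`, `artifact_spec` or
#'   `defect_spec`.
#' @param path YAML file path.
#' @return `write_spec_yaml()` returns `path` invisibly; `read_spec_yaml()`
#'   the restored record.
#' @export
write_spec_yaml <- function(spec, path) {
  cls <- class(spec)[1]
  if (!cls %in% c("bone_phantom_spec", "mixture_spec", "artifact_spec",
                  "defect_spec"))
    stop("not a serializable specification record: ", cls, call. = FALSE)
  yaml::write_yaml(c(list(spec_class = cls), unclass(spec)), path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  cls <- x$spec_class
  x$spec_class <- NULL
  x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  do.call(cls, x)
}
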