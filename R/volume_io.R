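#' @useDynLib spinemask, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd wilcox.test
#' @importFrom utils head
NULL

# Direction vectors (RAS world) for the six anatomical axis letters.
.axis_letters <- list(
  R = c(1, 0, 0), L = c(-1, 0, 0),
  A = c(0, 1, 0), P = c(0, -1, 0),
  S = c(0, 0, 1), I = c(0, 0, -1)
)

.opposite_letter <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")

#' Anatomical volume container
#'
#' A lightweight carrier for 3D images and label maps: a voxel array plus
#' the geometry needed to place it in scanner (RAS world) space. The affine
#' maps 0-based voxel indices to world millimetre coordinates; per-axis
#' voxel spacing and the 3-letter orientation code (the anatomical
#' direction each array axis points toward, e.g. `"PIR"`) are derived
#' from it.
#'
#' @param data 3D numeric or integer array.
#' @param spacing Positive length-3 numeric, voxel size in mm per axis.
#'   Ignored when `affine` is supplied (then derived from it).
#' @param orientation 3-letter orientation code used to build a default
#'   affine when none is given. Default `"PIR"`.
#' @param affine Optional 4x4 voxel-to-world matrix (0-based voxel
#'   indices, RAS world).
#' @return An object of class `anat_volume`: a list with elements `data`,
#'   `spacing` and `affine`.
#' @export
anat_volume <- function(data, spacing = c(1, 1, 1), orientation = "PIR",
                        affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("anat_volume requires 3D data, got ", length(dim(data)), "D",
         call. = FALSE)
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("spacing must be three strictly positive numbers", call. = FALSE)
    letters3 <- .check_orientation_code(orientation)
    affine <- diag(4)
    for (j in 1:3) affine[1:3, j] <- .axis_letters[[letters3[j]]] * spacing[j]
  } else {
    affine <- unclass(affine)
    attributes(affine) <- list(dim = c(4L, 4L))
    .check_affine(affine)
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  vol <- structure(list(data = data, spacing = as.numeric(spacing),
                        affine = affine),
                   class = "anat_volume")
  .check_orientation_code(vol_orientation(vol))
  vol
}

.check_orientation_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
    stop("orientation must be a 3-letter code such as \"PIR\"", call. = FALSE)
  letters3 <- strsplit(toupper(code), "")[[1]]
  if (!all(letters3 %in% names(.axis_letters)))
    stop("invalid orientation letters in \"", code, "\"", call. = FALSE)
  axes <- vapply(letters3, function(l) which.max(abs(.axis_letters[[l]])),
                 integer(1))
  if (length(unique(axes)) != 3L)
    stop("orientation \"", code, "\" does not name three distinct axes",
         call. = FALSE)
  letters3
}

.check_affine <- function(affine, tol = 1e-4) {
  if (!is.numeric(affine) || !all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 numeric matrix", call. = FALSE)
  m <- affine[1:3, 1:3]
  norms <- sqrt(colSums(m^2))
  if (any(norms <= 0)) stop("degenerate affine", call. = FALSE)
  u <- sweep(m, 2, norms, "/")
  g <- crossprod(u)
  if (max(abs(g[upper.tri(g)])) > tol)
    stop("unsupported geometry: affine is sheared/oblique beyond tolerance",
         call. = FALSE)
  invisible(affine)
}

#' @rdname anat_volume
#' @param vol An `anat_volume`.
#' @export
vol_orientation <- function(vol) {
  m <- vol$affine[1:3, 1:3]
  paste(vapply(1:3, function(j) {
    v <- m[, j]
    k <- which.max(abs(v))
    pos <- c("R", "A", "S")[k]
    if (v[k] >= 0) pos else .opposite_letter[[pos]]
  }, character(1)), collapse = "")
}

#' @rdname anat_volume
#' @export
vol_dim <- function(vol) dim(vol$data)

#' @rdname anat_volume
#' @export
is_anat_volume <- function(vol) inherits(vol, "anat_volume")

#' @export
print.anat_volume <- function(x, ...) {
  cat("<anat_volume> ", paste(vol_dim(x), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, orientation ", vol_orientation(x), "\n", sep = "")
  vals <- x$data
  if (is.integer(vals))
    cat("  integer labels: ", length(unique(as.vector(vals))),
        " distinct values\n", sep = "")
  invisible(x)
}

#' Convert voxel indices to world coordinates
#'
#' @param vol An `anat_volume`.
#' @param ijk Matrix (n x 3) or length-3 vector of 0-based voxel indices.
#' @return n x 3 matrix of RAS world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

.stop_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(what, " have mismatched grids: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file and decodes spacing and orientation from its
#' affine. Integer-typed data are preserved losslessly. Only strictly 3D
#' images with (near-)orthogonal affines are accepted; anything else is
#' rejected as unsupported geometry.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [anat_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("unsupported geometry: expected a 3D image, got ",
         length(d), "D in ", path, call. = FALSE)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  dat <- as.array(img)
  attributes(dat) <- list(dim = d)
  anat_volume(dat, affine = affine)
}

#' Write a NIfTI volume
#'
#' Integer label maps are stored as unsigned 8- or 16-bit (or signed
#' 32-bit) as their value range requires; floating point data as float32.
#'
#' @param vol An [anat_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_anat_volume(vol))
  dat <- vol$data
  if (is.logical(dat)) { storage.mode(dat) <- "integer" }
  if (is.integer(dat)) {
    rng <- range(dat, na.rm = TRUE)
    dtype <- if (rng[1] >= 0 && rng[2] <= 255) "uint8"
             else if (rng[1] >= 0 && rng[2] <= 65535) "uint16"
             else "int32"
  } else dtype <- "float"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Reorient a volume to a target axis code
#'
#' Permutes and flips the voxel array so that its axes point toward the
#' requested anatomical directions, updating the affine consistently.
#' Reorienting back restores the original data and affine exactly; the
#' multiset of voxel values is unchanged.
#'
#' @param vol An [anat_volume].
#' @param target 3-letter orientation code, e.g. `"PIR"` or `"RAS"`.
#' @return The reoriented [anat_volume].
#' @export
reorient <- function(vol, target = "PIR") {
  stopifnot(is_anat_volume(vol))
  tgt <- .check_orientation_code(target)
  cur <- strsplit(vol_orientation(vol), "")[[1]]
  if (identical(cur, tgt)) return(vol)

  perm <- integer(3)
  flip <- logical(3)
  for (t in 1:3) {
    s <- which(cur == tgt[t])
    if (length(s) == 1L) { perm[t] <- s; flip[t] <- FALSE }
    else {
      s <- which(cur == .opposite_letter[[tgt[t]]])
      if (length(s) != 1L)
        stop("cannot map orientation ", paste(cur, collapse = ""),
             " to ", target, call. = FALSE)
      perm[t] <- s; flip[t] <- TRUE
    }
  }
  dat <- aperm(vol$data, perm)
  dm <- dim(dat)
  idx <- lapply(1:3, function(t) if (flip[t]) rev(seq_len(dm[t])) else
                  seq_len(dm[t]))
  dat <- dat[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]

  # old_index = T %*% new_index (homogeneous, 0-based)
  tr <- matrix(0, 4, 4)
  tr[4, 4] <- 1
  olddim <- dim(vol$data)
  for (t in 1:3) {
    s <- perm[t]
    tr[s, t] <- if (flip[t]) -1 else 1
    if (flip[t]) tr[s, 4] <- olddim[s] - 1
  }
  anat_volume(dat, affine = vol$affine %*% tr)
}

#' Resample a volume to a target spacing
#'
#' Nearest-neighbour interpolation keeps label maps categorical (it can
#' never invent label values); trilinear interpolation is available for
#' images. Output voxel 0 is center-aligned with input voxel 0.
#'
#' @param vol An [anat_volume].
#' @param target_spacing Positive length-3 numeric, mm.
#' @param mode `"nearest"` (required for label maps) or `"linear"`.
#' @return The resampled [anat_volume].
#' @export
resample <- function(vol, target_spacing, mode = c("nearest", "linear")) {
  stopifnot(is_anat_volume(vol))
  mode <- match.arg(mode)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("target spacing must be three strictly positive numbers",
         call. = FALSE)
  if (isTRUE(all.equal(target_spacing, vol$spacing, tolerance = 1e-12)))
    return(vol)
  indim <- vol_dim(vol)
  ratio <- target_spacing / vol$spacing            # input voxels per output voxel
  outdim <- pmax(1L, as.integer(round(indim / ratio)))

  if (mode == "nearest") {
    idx <- lapply(1:3, function(a) {
      src <- round((seq_len(outdim[a]) - 1) * ratio[a]) + 1
      pmin(pmax(src, 1), indim[a])
    })
    dat <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    dat <- array(0, outdim)
    u <- lapply(1:3, function(a) {
      x <- (seq_len(outdim[a]) - 1) * ratio[a]
      pmin(pmax(x, 0), indim[a] - 1)
    })
    lo <- lapply(u, floor)
    fr <- Map(`-`, u, lo)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- pmin(lo[[1]] + cx, indim[1] - 1) + 1
      iy <- pmin(lo[[2]] + cy, indim[2] - 1) + 1
      iz <- pmin(lo[[3]] + cz, indim[3] - 1) + 1
      wx <- if (cx == 1) fr[[1]] else 1 - fr[[1]]
      wy <- if (cy == 1) fr[[2]] else 1 - fr[[2]]
      wz <- if (cz == 1) fr[[3]] else 1 - fr[[3]]
      w <- outer(outer(wx, wy), wz)
      dat <- dat + w * vol$data[ix, iy, iz, drop = FALSE]
    }
  }
  affine <- vol$affine
  affine[, 1:3] <- affine[, 1:3] %*% diag(ratio)
  anat_volume(dat, affine = affine)
}
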