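#' Phase 1: semantic segmentation behind a pluggable backend
#'
#' The semantic stage is a contract, not a model: a backend is any
#' function taking an image [anat_volume] and returning a semantic mask
#' on the same grid whose voxels hold one of the 14 structure codes or
#' background. In production this is where a trained patch-wise network
#' plugs in; for testing, phantom-backed oracle and noisy backends are
#' provided. `segment_semantic` runs the backend and validates its
#' output (grid congruence, scheme codes) before it is handed to the
#' instance stage.
#'
#' @param image An [anat_volume] image.
#' @param backend A function `image -> semantic anat_volume`.
#' @return The validated semantic mask ([anat_volume] of integer codes).
#' @export
segment_semantic <- function(image, backend) {
  stopifnot(is_anat_volume(image), is.function(backend))
  out <- backend(image)
  if (!is_anat_volume(out))
    stop("semantic backend contract violation: did not return an ",
         "anat_volume", call. = FALSE)
  if (!identical(vol_dim(out), vol_dim(image)))
    stop("semantic backend contract violation: output grid ",
         paste(vol_dim(out), collapse = "x"), " does not match input ",
         paste(vol_dim(image), collapse = "x"), call. = FALSE)
  if (!is.integer(out$data)) {
    if (any(out$data != round(out$data)))
      stop("semantic backend contract violation: non-integer voxel values",
           call. = FALSE)
    storage.mode(out$data) <- "integer"
  }
  .validate_semantic_codes(out$data)
  out
}

#' Phantom-backed semantic backends
#'
#' `oracle_semantic_backend` returns the phantom's ground-truth semantic
#' mask regardless of the image content; `noisy_semantic_backend` first
#' corrupts it with [corrupt_mask] to emulate model errors (e.g. missed
#' outermost voxels, ragged boundaries). An `external` backend would be
#' any user function satisfying the same contract.
#'
#' @param phantom A `spine_phantom` from [generate_phantom].
#' @param flip_rate,boundary_jitter,drop_components,seed Passed to
#'   [corrupt_mask].
#' @return A backend function for [segment_semantic].
#' @export
oracle_semantic_backend <- function(phantom) {
  stopifnot(inherits(phantom, "spine_phantom"))
  force(phantom)
  function(image) phantom$semantic
}

#' @rdname oracle_semantic_backend
#' @export
noisy_semantic_backend <- function(phantom, flip_rate = 0.02,
                                   boundary_jitter = 0.1,
                                   drop_components = NULL, seed = 1) {
  stopifnot(inherits(phantom, "spine_phantom"))
  force(phantom)
  function(image) corrupt_mask(phantom$semantic, flip_rate = flip_rate,
                               boundary_jitter = boundary_jitter,
                               drop_components = drop_components,
                               seed = seed)
}
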