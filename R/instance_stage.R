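#' Cutout geometry for the instance stage
#'
#' The instance model never sees the whole scan: it sees fixed-size,
#' fixed-spacing subvolumes ("cutouts") centered on each vertebral-body
#' center. Defaults follow the published convention: 248 x 304 x 64
#' voxels at 0.75 x 0.75 x 1.65 mm in P-I-R orientation, large enough to
#' contain the center vertebra and both neighbours. For phantom-scale
#' work [phantom_cutout_config] derives a geometry matched to the
#' phantom's native grid.
#'
#' @param size Cutout extent in voxels (P, I, R).
#' @param spacing Cutout voxel spacing in mm.
#' @param orientation Axis code; only `"PIR"` is supported.
#' @return A `cutout_config` list.
#' @export
cutout_config <- function(size = c(248, 304, 64),
                          spacing = c(0.75, 0.75, 1.65),
                          orientation = "PIR") {
  size <- as.integer(size)
  if (length(size) != 3 || any(is.na(size)) || any(size < 1))
    stop("cutout size must be three positive integers", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("cutout spacing must be three positive numbers", call. = FALSE)
  if (!identical(toupper(orientation), "PIR"))
    stop("cutout orientation must be PIR", call. = FALSE)
  structure(list(size = size, spacing = spacing, orientation = "PIR"),
            class = "cutout_config")
}

#' @rdname cutout_config
#' @param phantom A `spine_phantom`; the returned config uses the
#'   phantom's native spacing (so cutout extraction is an exact crop) and
#'   a window spanning roughly 3.5 vertebral pitches.
#' @export
phantom_cutout_config <- function(phantom) {
  stopifnot(inherits(phantom, "spine_phantom"))
  L <- .phantom_layout(phantom$spec)
  d <- vol_dim(phantom$semantic)
  # P and R windows span twice the volume extent so the whole slab is
  # covered from any center position; I spans ~3.5 vertebral pitches,
  # enough to contain the center vertebra and both neighbours in full
  cutout_config(size = c(2L * d[1] + 1L,
                         min(d[2], as.integer(ceiling(3.5 * L$pitch))),
                         2L * d[3] + 1L),
                spacing = phantom$spec$spacing)
}

#' Locate vertebral-body centers
#'
#' Runs 26-connected component analysis on the corpus label of a
#' semantic mask (canonical P-I-R orientation) and returns one center of
#' mass per component, sorted top to bottom (ascending inferior-axis
#' coordinate). Fused vertebral bodies form a single component and hence
#' a single center.
#'
#' @param semantic Semantic mask ([anat_volume]).
#' @return A data.frame with one row per center: `rank`, rounded voxel
#'   coordinates `p`, `i`, `r` (1-based), exact centroid columns
#'   `com_p/com_i/com_r`, `component` and `n_voxels`. Zero rows when the
#'   mask holds no corpus voxels.
#' @export
find_corpus_centers <- function(semantic) {
  stopifnot(is_anat_volume(semantic))
  if (vol_orientation(semantic) != "PIR")
    stop("semantic mask must be in canonical PIR orientation", call. = FALSE)
  fg <- semantic$data == scheme_code("corpus")
  empty <- data.frame(rank = integer(), p = integer(), i = integer(),
                      r = integer(), com_p = numeric(), com_i = numeric(),
                      com_r = numeric(), component = integer(),
                      n_voxels = integer())
  if (!any(fg)) return(empty)
  lab <- .components(fg)
  ncomp <- attr(lab, "n_components")
  ids <- seq_len(ncomp)
  com <- .label_centroids(lab, ids)
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  ord <- order(com[, 2], com[, 1], com[, 3])
  data.frame(rank = seq_len(ncomp),
             p = as.integer(round(com[ord, 1])),
             i = as.integer(round(com[ord, 2])),
             r = as.integer(round(com[ord, 3])),
             com_p = com[ord, 1], com_i = com[ord, 2], com_r = com[ord, 3],
             component = ids[ord], n_voxels = sizes[ord])
}

# Index vectors mapping each cutout axis position to a source canonical
# voxel (NA outside the volume): the shared kernel of extraction,
# oracle sampling and back-projection.
.cutout_axis_index <- function(placement, a) {
  j <- seq_len(placement$size[a])
  u <- placement$center[a] + (j - placement$c0[a]) * placement$ratio[a]
  src <- as.integer(round(u))
  src[src < 1L | src > placement$dim[a]] <- NA_integer_
  src
}

# Sample a canonical-grid array onto the cutout grid (nearest
# neighbour; background 0 outside the volume).
.sample_canonical <- function(arr, placement) {
  sx <- .cutout_axis_index(placement, 1)
  sy <- .cutout_axis_index(placement, 2)
  sz <- .cutout_axis_index(placement, 3)
  cx <- ifelse(is.na(sx), 1L, sx)
  cy <- ifelse(is.na(sy), 1L, sy)
  cz <- ifelse(is.na(sz), 1L, sz)
  out <- arr[cx, cy, cz, drop = FALSE]
  if (anyNA(sx)) out[is.na(sx), , ] <- 0L
  if (anyNA(sy)) out[, is.na(sy), ] <- 0L
  if (anyNA(sz)) out[, , is.na(sz)] <- 0L
  out
}

#' Extract a fixed-geometry cutout around a corpus center
#'
#' Resamples the semantic mask (nearest neighbour) onto the cutout grid
#' centered on the given vertebral-body center. The output shape equals
#' `config$size` regardless of proximity to the volume border; regions
#' outside the volume are background-padded. The placement transform
#' recorded with the cutout maps cutout voxels back to canonical voxels.
#'
#' @param semantic Semantic mask ([anat_volume], PIR).
#' @param center One row of [find_corpus_centers] output (or a list with
#'   `p`, `i`, `r`, `rank`).
#' @param config A [cutout_config].
#' @return A `spine_cutout`: list with `data` (integer array of
#'   `config$size`), `placement` and `rank`.
#' @export
extract_cutout <- function(semantic, center, config = cutout_config()) {
  stopifnot(is_anat_volume(semantic), inherits(config, "cutout_config"))
  ctr <- c(center$p, center$i, center$r)
  d <- vol_dim(semantic)
  if (any(ctr < 1) || any(ctr > d))
    stop("cutout center lies outside the volume", call. = FALSE)
  placement <- list(center = as.numeric(ctr),
                    ratio = config$spacing / semantic$spacing,
                    c0 = floor(config$size / 2) + 1L,
                    size = config$size, dim = d)
  dat <- .sample_canonical(semantic$data, placement)
  storage.mode(dat) <- "integer"
  structure(list(data = dat, placement = placement,
                 rank = if (!is.null(center$rank)) center$rank else NA_integer_),
            class = "spine_cutout")
}

# Back-project the voxels of one relative-label class onto the canonical
# grid (nearest neighbour), returning sorted 1-based linear indices.
.backproject_role <- function(rel, placement, role) {
  axes <- lapply(1:3, function(a) {
    lo <- placement$center[a] + (1 - placement$c0[a]) * placement$ratio[a]
    hi <- placement$center[a] +
      (placement$size[a] - placement$c0[a]) * placement$ratio[a]
    v <- seq.int(max(1L, ceiling(lo - 0.5)), min(placement$dim[a],
                                                 floor(hi + 0.5)))
    j <- as.integer(round((v - placement$center[a]) / placement$ratio[a])) +
      placement$c0[a]
    ok <- j >= 1L & j <= placement$size[a]
    list(v = v[ok], j = j[ok])
  })
  if (any(vapply(axes, function(x) length(x$v) == 0L, logical(1))))
    return(integer())
  sub <- rel[axes[[1]]$j, axes[[2]]$j, axes[[3]]$j, drop = FALSE] == role
  hit <- which(sub)
  if (!length(hit)) return(integer())
  ai <- arrayInd(hit, vapply(axes, function(x) length(x$v), integer(1)))
  d <- placement$dim
  sort(axes[[1]]$v[ai[, 1]] +
         (axes[[2]]$v[ai[, 2]] - 1L) * d[1] +
         (axes[[3]]$v[ai[, 3]] - 1L) * d[1] * d[2])
}

# Relative-label codes used inside cutout predictions.
.rel_above <- 1L
.rel_center <- 2L
.rel_below <- 3L

#' Phantom-backed cutout predictors
#'
#' A cutout predictor is a function mapping a `spine_cutout` (semantic
#' labels only -- the image is never consulted at this stage) to a
#' relative-label array of the same shape with values 0 (background),
#' 1 (vertebra above), 2 (center vertebra), 3 (vertebra below). The
#' oracle predictor reads the phantom's ground-truth instances through
#' the cutout's placement transform; the noisy variant corrupts the
#' oracle output per cutout with [corrupt_mask].
#'
#' @param phantom A `spine_phantom`.
#' @param flip_rate,boundary_jitter Noise rates for the noisy variant.
#' @param seed Base seed; each cutout uses `seed + rank`.
#' @return A predictor function for [predict_cutout].
#' @export
oracle_cutout_predictor <- function(phantom) {
  stopifnot(inherits(phantom, "spine_phantom"))
  gt <- phantom$instances$data
  function(cutout) {
    inst <- .sample_canonical(gt, cutout$placement)
    cid <- inst[cutout$placement$c0[1], cutout$placement$c0[2],
                cutout$placement$c0[3]]
    rel <- array(0L, dim(inst))
    if (cid >= 1L && cid < 100L) {
      rel[inst == cid] <- .rel_center
      if (cid > 1L) rel[inst == cid - 1L] <- .rel_above
      rel[inst == cid + 1L & inst < 100L] <- .rel_below
    }
    rel
  }
}

#' @rdname oracle_cutout_predictor
#' @export
noisy_cutout_predictor <- function(phantom, flip_rate = 0.02,
                                   boundary_jitter = 0.1, seed = 1) {
  oracle <- oracle_cutout_predictor(phantom)
  function(cutout) {
    rel <- oracle(cutout)
    corrupt_mask(rel, flip_rate = flip_rate,
                 boundary_jitter = boundary_jitter,
                 seed = seed + 7919 * (cutout$rank %||% 0))
  }
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Predict relative vertebra labels for one cutout
#'
#' Runs the predictor on the semantic cutout and validates its output
#' against the relative-label contract: same shape as the cutout, values
#' restricted to background/above/center/below. The predictor consumes
#' only the semantic cutout; passing image-valued data is rejected.
#'
#' @param cutout A `spine_cutout` from [extract_cutout].
#' @param predictor A predictor function (see
#'   [oracle_cutout_predictor]).
#' @return A `cutout_prediction`: list with `rel`, `placement`, `rank`.
#' @export
predict_cutout <- function(cutout, predictor) {
  stopifnot(inherits(cutout, "spine_cutout"), is.function(predictor))
  if (!is.integer(cutout$data))
    stop("cutout predictor contract violation: cutouts must carry ",
         "integer semantic labels, not image intensities", call. = FALSE)
  .validate_semantic_codes(cutout$data)
  rel <- predictor(cutout)
  if (!identical(dim(rel), dim(cutout$data)))
    stop("cutout predictor contract violation: output shape mismatch",
         call. = FALSE)
  vals <- unique(as.integer(rel))
  if (length(setdiff(vals, c(0L, .rel_above, .rel_center, .rel_below))))
    stop("cutout predictor contract violation: labels outside ",
         "{background, above, center, below}", call. = FALSE)
  storage.mode(rel) <- "integer"
  c0 <- cutout$placement$c0
  if (cutout$data[c0[1], c0[2], c0[3]] == scheme_code("corpus") &&
      !any(rel == .rel_center))
    warning("cutout ", cutout$rank, ": corpus at center but empty center ",
            "class; vertebra will be skipped", call. = FALSE)
  structure(list(rel = rel, placement = cutout$placement,
                 rank = cutout$rank),
            class = "cutout_prediction")
}

#' Gather per-vertebra appearances across cutout predictions
#'
#' Vertebra `k` appears in up to three cutouts: as the "below" class of
#' cutout `k-1`, the "center" class of cutout `k`, and the "above" class
#' of cutout `k+1`. Each non-empty appearance is back-projected onto the
#' canonical grid; inner vertebrae therefore collect three appearances
#' and the outer ones two (absent prediction failures). Each appearance
#' set carries its consistency score, the mean pairwise Dice across
#' appearances (0 for a single uncorroborated appearance).
#'
#' @param predictions List of `cutout_prediction`, one per center, in
#'   rank order.
#' @param centers Output of [find_corpus_centers].
#' @return List of appearance sets: `vertebra`, `roles`, `idx` (list of
#'   canonical linear-index vectors), `score`.
#' @export
collect_appearances <- function(predictions, centers) {
  k_n <- nrow(centers)
  stopifnot(length(predictions) == k_n)
  lapply(seq_len(k_n), function(k) {
    roles <- character()
    idx <- list()
    add <- function(pred, role, role_name) {
      v <- .backproject_role(pred$rel, pred$placement, role)
      if (length(v)) { idx[[length(idx) + 1L]] <<- v
                       roles[length(roles) + 1L] <<- role_name }
    }
    if (k > 1L) add(predictions[[k - 1L]], .rel_below, "below")
    add(predictions[[k]], .rel_center, "center")
    if (k < k_n) add(predictions[[k + 1L]], .rel_above, "above")
    set <- list(vertebra = k, roles = roles, idx = idx, score = NA_real_)
    set$score <- if (length(idx)) consistency_score(set) else NA_real_
    set
  })
}

#' Consistency score of an appearance set
#'
#' Mean pairwise Dice over all unordered pairs of a vertebra's
#' appearances. A single uncorroborated appearance scores 0 so that it
#' is integrated last during fusion and cannot claim contested voxels
#' from corroborated neighbours.
#'
#' @param appearances One appearance set from [collect_appearances].
#' @return Score in `[0, 1]`.
#' @export
consistency_score <- function(appearances) {
  idx <- appearances$idx
  m <- length(idx)
  if (m == 0L) stop("empty appearance set", call. = FALSE)
  if (m == 1L) return(0)
  pairs <- utils::combn(m, 2)
  mean(vapply(seq_len(ncol(pairs)), function(q) {
    a <- idx[[pairs[1, q]]]
    b <- idx[[pairs[2, q]]]
    2 * length(intersect(a, b)) / (length(a) + length(b))
  }, numeric(1)))
}

#' Fuse appearances into a vertebra instance mask
#'
#' Vertebrae are written into the instance mask from the highest to the
#' lowest consistency score (ties broken top-to-bottom), and a voxel
#' once assigned is never overwritten: the least consistent predictions
#' are addressed last and cannot disturb their neighbours. Each
#' vertebra's voxel set is the per-voxel majority across its
#' appearances, with exact ties resolved in favour of the center-role
#' appearance. Surviving instances are renumbered 1..N top to bottom.
#'
#' @param appearance_sets Output of [collect_appearances].
#' @param semantic The semantic mask (supplies grid geometry).
#' @return Instance mask ([anat_volume] of integer ids).
#' @export
fuse_instances <- function(appearance_sets, semantic) {
  stopifnot(is_anat_volume(semantic))
  d <- vol_dim(semantic)
  out <- array(0L, d)
  usable <- Filter(function(s) length(s$idx) > 0L, appearance_sets)
  if (length(usable) != length(appearance_sets)) {
    skipped <- setdiff(vapply(appearance_sets, `[[`, integer(1), "vertebra"),
                       vapply(usable, `[[`, integer(1), "vertebra"))
    warning("vertebra(e) ", paste(skipped, collapse = ", "),
            " had no usable appearances and were skipped", call. = FALSE)
  }
  ord <- order(-vapply(usable, `[[`, numeric(1), "score"),
               vapply(usable, `[[`, integer(1), "vertebra"))
  for (s in usable[ord]) {
    m <- length(s$idx)
    all_idx <- sort(unlist(s$idx, use.names = FALSE))
    r <- rle(all_idx)
    keep <- r$lengths > m / 2
    if (any(r$lengths == m / 2)) {
      ctr <- which(s$roles == "center")
      tied <- r$values[r$lengths == m / 2]
      if (length(ctr) == 1L)
        keep[r$lengths == m / 2] <- tied %in% s$idx[[ctr]]
    }
    vox <- r$values[keep]
    vox <- vox[out[vox] == 0L]
    if (!length(vox)) {
      warning("vertebra ", s$vertebra, " lost all voxels during fusion",
              call. = FALSE)
      next
    }
    out[vox] <- s$vertebra
  }
  present <- sort(unique(out[out > 0L]))
  if (length(present) && !identical(present, seq_along(present))) {
    remap <- integer(max(present))
    remap[present] <- seq_along(present)
    pos <- out > 0L
    out[pos] <- remap[out[pos]]
  }
  anat_volume(out, affine = semantic$affine)
}

#' Assign instance ids to discs and endplates
#'
#' Every 26-connected component of the semantic IVD and endplate labels
#' receives the id derived from the nearest vertebra instance *above*:
#' among vertebrae whose body center of mass lies strictly superior to
#' the component's center of mass, the closest one (Euclidean, mm)
#' donates its id, offset into the disc (`100 + v`) or endplate
#' (`200 + v`) block. A component with no vertebra above falls back to
#' the globally nearest vertebra, with a warning.
#'
#' @param semantic Semantic mask ([anat_volume], PIR).
#' @param instances Vertebra instance mask from [fuse_instances].
#' @return The instance mask with disc/endplate ids added.
#' @export
assign_disc_endplate_instances <- function(semantic, instances) {
  stopifnot(is_anat_volume(semantic), is_anat_volume(instances))
  .stop_geometry(semantic, instances, "semantic/instance masks")
  inst <- instances$data
  sem <- semantic$data
  sp <- semantic$spacing
  vids <- sort(unique(inst[inst > 0L & inst < 100L]))
  if (!length(vids)) return(instances)
  corpus <- scheme_code("corpus")
  vcom <- t(vapply(vids, function(v) {
    sel <- inst == v & sem == corpus
    if (!any(sel)) sel <- inst == v    # degraded mask: fall back to whole id
    colMeans(arrayInd(which(sel), dim(inst)))
  }, numeric(3)))

  for (kind in list(list(code = scheme_code("ivd"), fun = ivd_instance_id),
                    list(code = scheme_code("endplate"),
                         fun = endplate_instance_id))) {
    fg <- sem == kind$code
    if (!any(fg)) next
    lab <- .components(fg)
    for (vox in split(which(fg), lab[fg])) {
      com <- colMeans(arrayInd(vox, dim(inst)))
      dmm <- sqrt(colSums(((t(vcom) - com) * sp)^2))
      above <- vcom[, 2] < com[2]
      if (any(above)) {
        v <- vids[above][which.min(dmm[above])]
      } else {
        v <- vids[which.min(dmm)]
        warning("disc/endplate component with no vertebra above; ",
                "assigned to nearest vertebra ", v, call. = FALSE)
      }
      inst[vox] <- kind$fun(v)
    }
  }
  instances$data <- inst
  instances
}

#' Phase 2: semantic-to-instance conversion
#'
#' Runs the full instance stage on a validated semantic mask: locate
#' vertebral-body centers, extract one fixed-geometry cutout per center,
#' predict relative above/center/below labels, gather and score each
#' vertebra's appearances, fuse them in consistency order, and finally
#' give discs and endplates the id of the nearest vertebra above.
#'
#' @param semantic Semantic mask ([anat_volume], PIR).
#' @param predictor Cutout predictor (see [oracle_cutout_predictor]).
#' @param config A [cutout_config].
#' @return List with `instances` ([anat_volume]), `centers`,
#'   `appearance_sets` and `predictions`.
#' @export
segment_instances <- function(semantic, predictor,
                              config = cutout_config()) {
  centers <- find_corpus_centers(semantic)
  if (nrow(centers) == 0L) {
    return(list(instances = anat_volume(array(0L, vol_dim(semantic)),
                                        affine = semantic$affine),
                centers = centers, appearance_sets = list(),
                predictions = list()))
  }
  predictions <- lapply(seq_len(nrow(centers)), function(k) {
    predict_cutout(extract_cutout(semantic, centers[k, ], config), predictor)
  })
  sets <- collect_appearances(predictions, centers)
  fused <- fuse_instances(sets, semantic)
  list(instances = assign_disc_endplate_instances(semantic, fused),
       centers = centers, appearance_sets = sets,
       predictions = predictions)
}
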