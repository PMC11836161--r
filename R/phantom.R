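#' Specification of a synthetic whole-spine phantom
#'
#' Describes a sagittal whole-spine label map built from axis-aligned
#' blocks in the canonical P-I-R orientation: a column of vertebra-like
#' bodies with their nine posterior/peripheral substructures, junction
#' endplates and interleaved discs, a continuous spinal canal with an
#' embedded cord, and a sacrum block below the last vertebra. Geometry is
#' deliberately schematic (boxes, not anatomical meshes): it is designed
#' to exercise connectivity, top-to-bottom ordering, cutout fusion and
#' post-processing logic deterministically at desk scale.
#'
#' Default spacing (0.8, 0.8, 3.3) mm mimics thick-slice sagittal
#' acquisitions: high in-plane resolution, few left-right slices.
#'
#' @param n_vertebrae Number of vertebrae (1..99).
#' @param spacing Voxel spacing in mm (P, I, R axes).
#' @param corpus_depth_mm,corpus_height_mm Vertebral body extent in mm
#'   along the posterior and inferior axes.
#' @param disc_thickness_mm Disc height in mm (must be > 0).
#' @param slice_count Left-right extent in slices. Lateral substructures
#'   (articular and costal processes) need at least 13 slices and are
#'   suppressed on narrower phantoms.
#' @param fused_pairs List of adjacent index pairs `c(v, v+1)` whose
#'   junction (endplates and disc) is replaced by continuous vertebral
#'   body, so the two corpora form one connected component.
#' @param drop_outer_slices Number of outermost slices per side cleared
#'   to background, emulating a truncated left-right field of view.
#' @param seed RNG seed for the pseudo-image noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_vertebrae = 12, spacing = c(0.8, 0.8, 3.3),
                         corpus_depth_mm = 28, corpus_height_mm = 20,
                         disc_thickness_mm = 4, slice_count = 15,
                         fused_pairs = list(), drop_outer_slices = 0,
                         seed = 1) {
  n_vertebrae <- as.integer(n_vertebrae)
  if (is.na(n_vertebrae) || n_vertebrae < 1 || n_vertebrae > 99)
    stop("n_vertebrae must be in 1..99", call. = FALSE)
  if (disc_thickness_mm <= 0) stop("disc thickness must be > 0", call. = FALSE)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive numbers", call. = FALSE)
  if (slice_count < 5) stop("slice_count must be at least 5", call. = FALSE)
  if (length(fused_pairs) && !is.list(fused_pairs))
    fused_pairs <- list(fused_pairs)
  for (fp in fused_pairs) {
    if (length(fp) != 2 || fp[2] != fp[1] + 1 ||
        fp[1] < 1 || fp[2] > n_vertebrae)
      stop("fused pairs must be adjacent vertebra indices within 1..n",
           call. = FALSE)
  }
  structure(list(n_vertebrae = n_vertebrae, spacing = as.numeric(spacing),
                 corpus_depth_mm = corpus_depth_mm,
                 corpus_height_mm = corpus_height_mm,
                 disc_thickness_mm = disc_thickness_mm,
                 slice_count = as.integer(slice_count),
                 fused_pairs = lapply(fused_pairs, as.integer),
                 drop_outer_slices = as.integer(drop_outer_slices),
                 seed = seed),
            class = "phantom_spec")
}

# Integer layout (1-based voxel ranges) derived from a spec.
.phantom_layout <- function(spec) {
  sp <- spec$spacing
  dP <- max(6L, as.integer(round(spec$corpus_depth_mm / sp[1])))
  hC <- max(6L, as.integer(round(spec$corpus_height_mm / sp[2])))
  dD <- max(1L, as.integer(round(spec$disc_thickness_mm / sp[2])))
  S <- spec$slice_count
  rc <- as.integer(ceiling(S / 2))
  n <- spec$n_vertebrae

  p_corpus <- c(5L, 4L + dP)
  p_canal <- c(p_corpus[2] + 2L, p_corpus[2] + 8L)
  p_cord <- p_canal + c(2L, -2L)
  p_arcus <- c(p_canal[1], p_canal[2] + 3L)
  p_spin <- c(p_arcus[2] + 1L, p_arcus[2] + 16L)
  p_costal <- c(p_corpus[2] - 7L, p_corpus[2] + 1L)
  nP <- p_spin[2] + 4L

  pitch <- hC + dD + 2L               # corpus + two endplates + disc
  y1 <- 6L
  y_top <- y1 + (seq_len(n) - 1L) * pitch
  y_sac <- y_top[n] + hC + 2L
  nI <- y_sac + hC + 6L

  lateral_ok <- S >= 13L
  list(dP = dP, hC = hC, dD = dD, S = S, rc = rc, pitch = pitch,
       nP = nP, nI = nI, y_top = y_top, y_sac = y_sac,
       p_corpus = p_corpus, p_canal = p_canal, p_cord = p_cord,
       p_arcus = p_arcus, p_spin = p_spin, p_costal = p_costal,
       r_corpus = c(max(1L, rc - 4L), min(S, rc + 4L)),
       r_canal = c(rc - 2L, rc + 2L), r_cord = c(rc - 1L, rc + 1L),
       r_arcus = c(rc - 3L, rc + 3L), r_spin = c(rc - 1L, rc + 1L),
       r_art_l = c(rc - 5L, rc - 4L), r_art_r = c(rc + 4L, rc + 5L),
       r_cost_l = c(rc - 7L, rc - 6L), r_cost_r = c(rc + 6L, rc + 7L),
       lateral_ok = lateral_ok)
}

#' Generate a synthetic spine phantom
#'
#' Builds a pseudo-image, a 14-structure semantic mask and the matching
#' ground-truth instance mask, all as [anat_volume]s in the canonical
#' P-I-R orientation. The two masks are mutually consistent: every
#' vertebra-group semantic voxel carries exactly one vertebra instance id
#' (1..n, counted top to bottom), every disc voxel the disc id of the
#' vertebra above (`100 + v`), every endplate voxel the corresponding
#' `200 + v` id. Deterministic given the spec (including its seed).
#'
#' @param spec A [phantom_spec].
#' @return A list of class `spine_phantom` with elements `image`,
#'   `semantic`, `instances` and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- .phantom_layout(spec)
  n <- spec$n_vertebrae
  dims <- c(L$nP, L$nI, L$S)
  sem <- array(0L, dims)
  inst <- array(0L, dims)

  paint <- function(arr, p, y, r, value) {
    arr[p[1]:p[2], y[1]:y[2], max(1L, r[1]):min(L$S, r[2])] <- value
    arr
  }
  code <- scheme_code

  fused_junction <- vapply(seq_len(max(n - 1L, 1L)), function(v)
    any(vapply(spec$fused_pairs, function(fp) fp[1] == v, logical(1))),
    logical(1))

  for (v in seq_len(n)) {
    y0 <- L$y_top[v]
    yc <- c(y0, y0 + L$hC - 1L)
    # vertebral body
    sem <- paint(sem, L$p_corpus, yc, L$r_corpus, code("corpus"))
    inst <- paint(inst, L$p_corpus, yc, L$r_corpus, v)
    # junction below (endplate | disc | endplate), unless last or fused
    if (v < n) {
      if (fused_junction[v]) {
        yj <- c(yc[2] + 1L, yc[2] + L$dD + 2L)
        sem <- paint(sem, L$p_corpus, yj, L$r_corpus, code("corpus"))
        mid <- yc[2] + as.integer(ceiling((L$dD + 2L) / 2))
        inst <- paint(inst, L$p_corpus, c(yj[1], mid), L$r_corpus, v)
        inst <- paint(inst, L$p_corpus, c(mid + 1L, yj[2]), L$r_corpus,
                      v + 1L)
      } else {
        yep1 <- yc[2] + 1L
        ydisc <- c(yep1 + 1L, yep1 + L$dD)
        yep2 <- ydisc[2] + 1L
        sem <- paint(sem, L$p_corpus, c(yep1, yep1), L$r_corpus,
                     code("endplate"))
        inst <- paint(inst, L$p_corpus, c(yep1, yep1), L$r_corpus,
                      endplate_instance_id(v))
        sem <- paint(sem, L$p_corpus, ydisc, L$r_corpus, code("ivd"))
        inst <- paint(inst, L$p_corpus, ydisc, L$r_corpus, ivd_instance_id(v))
        sem <- paint(sem, L$p_corpus, c(yep2, yep2), L$r_corpus,
                     code("endplate"))
        inst <- paint(inst, L$p_corpus, c(yep2, yep2), L$r_corpus,
                      endplate_instance_id(v))
      }
    }
    # posterior arch bracket (canal carves its interior later)
    ya <- c(y0 + 3L, yc[2] - 3L)
    sem <- paint(sem, L$p_arcus, ya, L$r_arcus, code("arcus"))
    inst <- paint(inst, L$p_arcus, ya, L$r_arcus, v)
    # spinous process
    ys <- c(y0 + 8L, yc[2] - 7L)
    sem <- paint(sem, L$p_spin, ys, L$r_spin, code("spinous_process"))
    inst <- paint(inst, L$p_spin, ys, L$r_spin, v)
    if (L$lateral_ok) {
      # articular processes: superior upper third, inferior reaching below
      ysup <- c(y0, y0 + 7L)
      yinf <- c(yc[2] - 7L, yc[2] + 3L)
      for (side in list(list(r = L$r_art_l,
                             su = "articular_superior_left",
                             inf = "articular_inferior_left"),
                        list(r = L$r_art_r,
                             su = "articular_superior_right",
                             inf = "articular_inferior_right"))) {
        sem <- paint(sem, L$p_canal, ysup, side$r, code(side$su))
        inst <- paint(inst, L$p_canal, ysup, side$r, v)
        sem <- paint(sem, L$p_canal, yinf, side$r, code(side$inf))
        inst <- paint(inst, L$p_canal, yinf, side$r, v)
      }
      # costal/transverse processes
      yco <- c(y0 + 8L, yc[2] - 8L)
      sem <- paint(sem, L$p_costal, yco, L$r_cost_l,
                   code("costal_process_left"))
      inst <- paint(inst, L$p_costal, yco, L$r_cost_l, v)
      sem <- paint(sem, L$p_costal, yco, L$r_cost_r,
                   code("costal_process_right"))
      inst <- paint(inst, L$p_costal, yco, L$r_cost_r, v)
    }
  }
  # canal and cord: continuous column, carving the arch interiors
  ycanal <- c(max(1L, L$y_top[1] - 3L), min(L$nI, L$y_sac + L$hC))
  sem <- paint(sem, L$p_canal, ycanal, L$r_canal, code("spinal_canal"))
  inst <- paint(inst, L$p_canal, ycanal, L$r_canal, 0L)
  sem <- paint(sem, L$p_cord, ycanal, L$r_cord, code("spinal_cord"))
  # sacrum block
  ysac <- c(L$y_sac, L$y_sac + L$hC - 1L)
  sem <- paint(sem, c(L$p_corpus[1], L$p_canal[1] - 1L), ysac,
               L$r_corpus, code("sacrum"))

  if (spec$drop_outer_slices > 0) {
    k <- spec$drop_outer_slices
    drop <- c(seq_len(min(k, L$S)), seq.int(max(1L, L$S - k + 1L), L$S))
    sem[, , drop] <- 0L
    inst[, , drop] <- 0L
  }

  img <- .with_seed(spec$seed, {
    base <- c(0.6, 0.55, 0.5, 0.5, 0.5, 0.5, 0.5, 0.45, 0.45,
              0.8, 0.9, 0.3, 0.7, 0.55)
    intens <- array(0.1, dims)
    fg <- sem > 0
    intens[fg] <- base[sem[fg]]
    intens + array(rnorm(prod(dims), sd = 0.03), dims)
  })

  structure(list(
    image = anat_volume(img, spacing = spec$spacing, orientation = "PIR"),
    semantic = anat_volume(sem, spacing = spec$spacing, orientation = "PIR"),
    instances = anat_volume(inst, spacing = spec$spacing, orientation = "PIR"),
    spec = spec), class = "spine_phantom")
}

#' @export
print.spine_phantom <- function(x, ...) {
  cat("<spine_phantom> ", x$spec$n_vertebrae, " vertebrae, grid ",
      paste(vol_dim(x$semantic), collapse = " x "), ", spacing ",
      paste(x$spec$spacing, collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Corrupt a label map with reproducible noise
#'
#' Emulates model errors on a semantic, instance or relative label map:
#' random flips of foreground voxels to background and of near-boundary
#' background voxels to a neighbouring label (`flip_rate`), the same
#' perturbation restricted to the one-voxel surface shell
#' (`boundary_jitter`), and wholesale removal of selected label values
#' (`drop_components`). With all rates zero and nothing dropped the input
#' is returned unchanged. Deterministic given `seed`.
#'
#' @param mask An [anat_volume] with integer labels, or a plain 3D
#'   integer array.
#' @param flip_rate,boundary_jitter Probabilities in `[0, 1]`.
#' @param drop_components Integer label values to delete outright.
#' @param seed RNG seed.
#' @return Same type as `mask`.
#' @export
corrupt_mask <- function(mask, flip_rate = 0, boundary_jitter = 0,
                         drop_components = NULL, seed = NULL) {
  if (flip_rate < 0 || flip_rate > 1 || boundary_jitter < 0 ||
      boundary_jitter > 1)
    stop("noise rates must lie in [0, 1]", call. = FALSE)
  is_vol <- is_anat_volume(mask)
  lab <- if (is_vol) mask$data else mask
  stopifnot(length(dim(lab)) == 3L)
  storage.mode(lab) <- "integer"

  if (length(drop_components)) lab[lab %in% drop_components] <- 0L

  out <- .with_seed(seed, {
    arr <- lab
    if (flip_rate > 0 || boundary_jitter > 0) {
      fg <- arr > 0
      surf <- .surface_voxels(fg)
      nb <- .max_neighbor_label(arr)
      grow_cand <- !fg & nb > 0
      u <- array(runif(length(arr)), dim(arr))
      if (flip_rate > 0) {
        kill <- fg & u < flip_rate
        grow <- grow_cand & u < flip_rate
        arr[kill] <- 0L
        arr[grow] <- nb[grow]
      }
      if (boundary_jitter > 0) {
        u2 <- array(runif(length(arr)), dim(arr))
        kill <- surf & u2 < boundary_jitter
        grow <- grow_cand & u2 < boundary_jitter
        arr[kill] <- 0L
        arr[grow] <- nb[grow]
      }
    }
    arr
  })
  if (is_vol) { mask$data <- out; mask } else out
}
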