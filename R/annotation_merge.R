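#' Merge multi-source reference annotations
#'
#' Builds a combined semantic reference mask from three automated
#' sources, in strict priority order: the base annotation (vertebral
#' body, IVD, spinal canal, sacrum) comes first; translation-derived
#' substructure labels are added only onto voxels still background in
#' the accumulating mask; spinal-cord voxels are incorporated last under
#' the same no-overwrite rule. A voxel labelled by a higher-priority
#' source is never altered by a lower-priority one.
#'
#' @param base,translated Semantic masks ([anat_volume]) on congruent
#'   grids (resample first if needed).
#' @param cord A mask whose non-zero voxels mark the spinal cord.
#' @return The merged semantic mask.
#' @export
merge_annotations <- function(base, translated, cord) {
  stopifnot(is_anat_volume(base), is_anat_volume(translated),
            is_anat_volume(cord))
  .stop_geometry(base, translated, "annotation sources")
  .stop_geometry(base, cord, "annotation sources")
  .validate_semantic_codes(base$data)
  .validate_semantic_codes(translated$data)
  out <- base$data
  storage.mode(out) <- "integer"
  free <- out == 0L & translated$data != 0L
  out[free] <- as.integer(translated$data[free])
  free <- out == 0L & cord$data != 0L
  out[free] <- scheme_code("spinal_cord")
  base$data <- out
  base
}

#' Fill corpus-IVD gaps as endplates
#'
#' Reference annotations from heterogeneous sources leave thin
#' background seams between a vertebral body and the adjacent disc.
#' Along the inferior axis, background runs of at most `max_gap` voxels
#' sandwiched directly between a corpus voxel and an IVD voxel (in
#' either order) are filled with the endplate label; wider gaps are left
#' untouched, since unbounded filling would bridge unrelated structures.
#' Where corpus and IVD touch with no gap, the corpus-side transition
#' voxel is relabelled endplate.
#'
#' @param mask A semantic mask ([anat_volume], PIR).
#' @param max_gap Maximum fillable gap in voxels along the inferior
#'   axis (default 2).
#' @return The mask with endplates inserted.
#' @export
fill_corpus_ivd_gaps <- function(mask, max_gap = 2L) {
  stopifnot(is_anat_volume(mask))
  sem <- mask$data
  corpus <- scheme_code("corpus")
  ivd <- scheme_code("ivd")
  ep <- scheme_code("endplate")
  d <- dim(sem)
  ni <- d[2]
  for (g in seq_len(max_gap)) {
    # background run of exactly g voxels: corpus at i-1, ivd at i+g (or
    # the reverse), all of i..i+g-1 background
    if (ni < g + 2L) break
    run_bg <- array(TRUE, c(d[1], ni - g - 1L, d[3]))
    for (s in seq_len(g))
      run_bg <- run_bg & (sem[, (1L + s):(ni - g - 1L + s), , drop = FALSE] == 0L)
    upper <- sem[, 1:(ni - g - 1L), , drop = FALSE]
    lower <- sem[, (g + 2L):ni, , drop = FALSE]
    hit <- run_bg & ((upper == corpus & lower == ivd) |
                       (upper == ivd & lower == corpus))
    if (any(hit)) {
      pos <- which(hit)
      ai <- arrayInd(pos, dim(hit))
      for (s in seq_len(g)) {
        lin <- ai[, 1] + (ai[, 2] + s - 1L) * d[1] +
          (ai[, 3] - 1L) * d[1] * d[2]
        sem[lin] <- ep
      }
    }
  }
  # direct corpus-IVD contact: relabel the corpus-side voxel
  if (ni >= 2L) {
    a <- sem[, 1:(ni - 1L), , drop = FALSE]
    b <- sem[, 2:ni, , drop = FALSE]
    top_contact <- which(a == corpus & b == ivd)     # corpus above disc
    bot_contact <- which(a == ivd & b == corpus)     # disc above corpus
    if (length(top_contact)) {
      ai <- arrayInd(top_contact, dim(a))
      sem[ai[, 1] + (ai[, 2] - 1L) * d[1] + (ai[, 3] - 1L) * d[1] * d[2]] <- ep
    }
    if (length(bot_contact)) {
      ai <- arrayInd(bot_contact, dim(a))
      sem[ai[, 1] + ai[, 2] * d[1] + (ai[, 3] - 1L) * d[1] * d[2]] <- ep
    }
  }
  mask$data <- sem
  mask
}
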