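#' Mask pair container
#'
#' Bundles a semantic mask and an instance mask living on the same grid;
#' all post-processing rules operate on such pairs so that the two masks
#' stay mutually consistent.
#'
#' @param semantic,instances [anat_volume]s on congruent grids.
#' @return A `mask_pair` list.
#' @export
mask_pair <- function(semantic, instances) {
  stopifnot(is_anat_volume(semantic), is_anat_volume(instances))
  .stop_geometry(semantic, instances, "mask pair")
  structure(list(semantic = semantic, instances = instances),
            class = "mask_pair")
}

# Expected semantic group under each instance-id kind.
.kind_group <- c(vertebra = "vertebra", ivd = "ivd", endplate = "endplate")

#' Remove instance voxels unsupported by the semantic mask
#'
#' Voxels in the instance mask that are background in the semantic mask
#' are removed. The rule is applied group-aware: a vertebra-range id
#' additionally needs a vertebra-group semantic voxel underneath (and
#' disc/endplate ids an IVD/endplate voxel), so the two masks agree not
#' only on foreground but on the anatomic group. The semantic mask is
#' never modified.
#'
#' @param pair A [mask_pair].
#' @return The cleaned [mask_pair].
#' @export
remove_unsupported_instance_voxels <- function(pair) {
  stopifnot(inherits(pair, "mask_pair"))
  inst <- pair$instances$data
  sem <- pair$semantic$data
  groups <- c("background", unique(semantic_scheme()$group))
  gcode <- match(anatomic_group(0:14), groups)
  pos <- which(inst > 0L)
  if (length(pos)) {
    v <- inst[pos]
    if (any(v >= 300L))
      stop("instance id(s) outside known ranges", call. = FALSE)
    need <- ifelse(v < 100L, match("vertebra", groups),
                   ifelse(v < 200L, match("ivd", groups),
                          match("endplate", groups)))
    inst[pos[gcode[sem[pos] + 1L] != need]] <- 0L
    pair$instances$data <- inst
  }
  pair
}

#' Rescue semantic components missing from the instance mask
#'
#' Vertebra-group voxels present in the semantic mask but absent from
#' the instance mask (a whole dropped spinous process, or a hole left by
#' an inconsistent prediction) are rescued: each 26-connected component
#' of the uncovered region is assigned to the instance holding the
#' plurality of its 26-neighbourhood shell, ties going to the more
#' superior (smaller) id. Passes repeat until stable, so large uncovered
#' regions are filled inward from their instance-adjacent shell. A
#' component with no instance neighbours at all is left unassigned with
#' a warning.
#'
#' @param pair A [mask_pair] (apply
#'   [remove_unsupported_instance_voxels] first).
#' @return The completed [mask_pair].
#' @export
rescue_missing_components <- function(pair) {
  stopifnot(inherits(pair, "mask_pair"))
  inst <- pair$instances$data
  sem <- pair$semantic$data
  vert_sem <- array(sem %in% codes_in_group("vertebra"), dim(sem))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(offsets != 0) > 0, , drop = FALSE]
  repeat {
    uncovered <- vert_sem & inst == 0L
    if (!any(uncovered)) break
    lab <- .components(uncovered)
    ncomp <- attr(lab, "n_components")
    vert_inst <- array(0L, dim(inst))
    vv <- inst > 0L & inst < 100L
    vert_inst[vv] <- inst[vv]
    # one sweep over the 26 offsets counts, for every uncovered
    # component, how many of its shell voxels each instance id occupies
    comp_v <- integer(0)
    id_v <- integer(0)
    for (q in seq_len(nrow(offsets))) {
      nb <- .shift_offset(vert_inst, offsets[q, ])
      sel <- which(uncovered & nb > 0L)
      if (length(sel)) {
        comp_v <- c(comp_v, lab[sel])
        id_v <- c(id_v, nb[sel])
      }
    }
    if (!length(comp_v)) {
      warning("semantic component(s) with no neighbouring instance left ",
              "unassigned", call. = FALSE)
      break
    }
    cnt <- table(factor(comp_v, levels = seq_len(ncomp)),
                 factor(id_v, levels = sort(unique(id_v))))
    ids <- as.integer(colnames(cnt))
    win_map <- integer(ncomp)
    hit <- which(rowSums(cnt) > 0)
    # which.max returns the first maximum; columns are in ascending id
    # order, so ties go to the more superior id
    win_map[hit] <- ids[apply(cnt[hit, , drop = FALSE], 1, which.max)]
    sel_unc <- which(uncovered)
    w <- win_map[lab[sel_unc]]
    inst[sel_unc[w > 0L]] <- w[w > 0L]
    if (length(hit) == ncomp) {
      if (!any(vert_sem & inst == 0L)) break
    }
  }
  pair$instances$data <- inst
  pair
}

#' Remove elements isolated from the main spine column
#'
#' Bounding-box analysis: the largest 26-connected foreground component
#' is taken as the target spine; any component whose bounding box does
#' not intersect the spine's bounding box dilated by a 5-voxel margin is
#' deleted. The largest component itself always survives.
#'
#' @param mask An [anat_volume] label map (semantic or instance).
#' @param margin Dilation margin in voxels for the intersection test.
#' @return The cleaned [anat_volume].
#' @export
remove_isolated_elements <- function(mask, margin = 5L) {
  stopifnot(is_anat_volume(mask))
  keep <- .isolated_keep_voxels(mask$data, margin)
  if (is.null(keep)) return(mask)
  dat <- mask$data
  dat[!keep] <- 0L
  mask$data <- dat
  mask
}

# Logical array of voxels to keep, or NULL when the mask is empty.
.isolated_keep_voxels <- function(dat, margin = 5L) {
  fg <- dat > 0L
  if (!any(fg)) {
    warning("empty mask: nothing to isolate", call. = FALSE)
    return(NULL)
  }
  lab <- .components(fg)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 1L) return(fg | !fg)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  main <- which.max(sizes)
  coords <- arrayInd(which(fg), dim(dat))
  ids <- lab[fg]
  box <- function(sel) c(apply(coords[sel, , drop = FALSE], 2, range))
  main_box <- box(ids == main)
  lo <- main_box[c(1, 3, 5)] - margin
  hi <- main_box[c(2, 4, 6)] + margin
  keep_comp <- vapply(seq_len(ncomp), function(cmp) {
    if (cmp == main) return(TRUE)
    b <- box(ids == cmp)
    all(b[c(1, 3, 5)] <= hi) && all(b[c(2, 4, 6)] >= lo)
  }, logical(1))
  keep <- array(TRUE, dim(dat))
  keep[fg] <- keep_comp[ids]
  keep
}

#' Relabel articular-process components by majority vote
#'
#' The instance stage mostly mixes neighbouring vertebra ids at the
#' articular processes by just a few voxels. For each 26-connected
#' component of each articular (inferior/superior, left/right) semantic
#' label, all its instance voxels are set to the component's majority
#' instance id, ties going to the more superior id.
#'
#' @param pair A [mask_pair] with fused instances.
#' @return The relabelled [mask_pair].
#' @export
relabel_articular_processes <- function(pair) {
  stopifnot(inherits(pair, "mask_pair"))
  inst <- pair$instances$data
  sem <- pair$semantic$data
  art <- scheme_code(c("articular_inferior_left", "articular_inferior_right",
                       "articular_superior_left",
                       "articular_superior_right"))
  for (code in art) {
    fg <- sem == code
    if (!any(fg)) next
    lab <- .components(fg)
    for (vox in split(which(fg), lab[fg])) {
      ids <- inst[vox]
      sel <- ids > 0L & ids < 100L
      if (!any(sel)) next
      tab <- tabulate(ids[sel])
      winner <- which(tab == max(tab))[1]   # ties: more superior id
      inst[vox[sel]] <- winner
    }
  }
  pair$instances$data <- inst
  pair
}

#' Full post-processing chain
#'
#' Applies the four reconciliation rules in their canonical order:
#' unsupported-voxel removal, missing-component rescue, isolated-element
#' removal, and articular-process relabelling. Each rule is individually
#' toggleable via `skip` (they are optional refinements, not part of the
#' core conversion). Isolation removal is applied to the pair jointly:
#' the bounding-box analysis runs on the semantic foreground and the
#' same voxels are removed from both masks, preserving the foreground
#' consistency the first two rules establish.
#'
#' @param pair A [mask_pair].
#' @param skip Character vector among `"remove_unsupported"`,
#'   `"rescue_missing"`, `"remove_isolated"`, `"relabel_articular"`.
#' @return The post-processed [mask_pair].
#' @export
postprocess_pair <- function(pair, skip = character()) {
  stopifnot(inherits(pair, "mask_pair"))
  rules <- c("remove_unsupported", "rescue_missing", "remove_isolated",
             "relabel_articular")
  bad <- setdiff(skip, rules)
  if (length(bad)) stop("unknown rule(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!"remove_unsupported" %in% skip)
    pair <- remove_unsupported_instance_voxels(pair)
  if (!"rescue_missing" %in% skip)
    pair <- rescue_missing_components(pair)
  if (!"remove_isolated" %in% skip) {
    keep <- .isolated_keep_voxels(pair$semantic$data)
    if (!is.null(keep)) {
      pair$semantic$data[!keep] <- 0L
      pair$instances$data[!keep] <- 0L
    }
  }
  if (!"relabel_articular" %in% skip)
    pair <- relabel_articular_processes(pair)
  pair
}
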