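#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks on congruent
#' grids. Two empty masks score 1 (evaluation convention); exactly one
#' empty mask scores 0.
#'
#' @param a,b Logical arrays (or coercible) of identical dimension.
#' @return Score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks have mismatched grids", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' @rdname dice
#' @export
iou <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks have mismatched grids", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Average symmetric surface distance
#'
#' Surface voxels are foreground voxels with at least one 6-connected
#' background (or out-of-volume) neighbour. The ASSD pools, over both
#' surface voxel sets, each surface voxel's Euclidean distance in mm
#' (spacing-aware, via an exact distance transform) to the other
#' surface, and averages:
#' `(sum_a d(a, S_b) + sum_b d(b, S_a)) / (|S_a| + |S_b|)`.
#' Identical masks score 0. Undefined (returns `NA`) when either mask
#' is empty.
#'
#' @param a,b Logical arrays of identical dimension.
#' @param spacing Voxel spacing in mm.
#' @return Distance in mm, or `NA` if either mask is empty.
#' @export
assd <- function(a, b, spacing = c(1, 1, 1)) {
  a <- array(as.logical(a), dim(a)); b <- array(as.logical(b), dim(b))
  if (!identical(dim(a), dim(b)))
    stop("masks have mismatched grids", call. = FALSE)
  if (!any(a) || !any(b)) return(NA_real_)
  # crop to the joint bounding box (plus one voxel) for speed; distances
  # to seeds inside the box are unaffected
  idx <- which(a | b)
  ai <- arrayInd(idx, dim(a))
  lo <- pmax(apply(ai, 2, min) - 1L, 1L)
  hi <- pmin(apply(ai, 2, max) + 1L, dim(a))
  a <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  b <- b[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sa <- .surface_voxels(a)
  sb <- .surface_voxels(b)
  da <- sqrt(.edt_sq_3d(as.vector(sb), dim(b), as.numeric(spacing)))[sa]
  db <- sqrt(.edt_sq_3d(as.vector(sa), dim(a), as.numeric(spacing)))[sb]
  (sum(da) + sum(db)) / (length(da) + length(db))
}

#' Match predicted and reference instances
#'
#' Computes the IoU of every co-occurring (pred id, ref id) pair and
#' greedily matches pairs one-to-one in descending IoU order among those
#' meeting the threshold; at the default threshold of 0.5 matches are
#' provably unique, so the greedy strategy cannot change the result. A
#' pair with IoU exactly at the threshold counts as a true positive.
#' Unmatched predicted ids are false positives, unmatched reference ids
#' false negatives.
#'
#' @param pred,ref Instance masks ([anat_volume] or integer arrays) on
#'   congruent grids; 0 is background.
#' @param iou_threshold Minimum IoU for a true positive (default 0.5).
#' @return A `match_table`: list with `matches` (data.frame `pred`,
#'   `ref`, `iou`), `fp`, `fn`, `iou_threshold`.
#' @export
match_instances <- function(pred, ref, iou_threshold = 0.5) {
  p <- if (is_anat_volume(pred)) pred$data else pred
  r <- if (is_anat_volume(ref)) ref$data else ref
  if (!identical(dim(p), dim(r)))
    stop("masks have mismatched grids", call. = FALSE)
  fg <- p > 0L | r > 0L
  pv <- p[fg]; rv <- r[fg]
  p_ids <- sort(unique(pv[pv > 0L])); r_ids <- sort(unique(rv[rv > 0L]))
  p_sz <- table(factor(pv[pv > 0L], levels = p_ids))
  r_sz <- table(factor(rv[rv > 0L], levels = r_ids))
  both <- pv > 0L & rv > 0L
  cand <- data.frame(pred = integer(), ref = integer(), iou = numeric())
  if (any(both)) {
    inter <- table(factor(pv[both], levels = p_ids),
                   factor(rv[both], levels = r_ids))
    nz <- which(inter > 0, arr.ind = TRUE)
    iou_v <- vapply(seq_len(nrow(nz)), function(q) {
      i <- nz[q, 1]; j <- nz[q, 2]
      inter[i, j] / (p_sz[i] + r_sz[j] - inter[i, j])
    }, numeric(1))
    cand <- data.frame(pred = p_ids[nz[, 1]], ref = r_ids[nz[, 2]],
                       iou = as.numeric(iou_v))
  }
  cand <- cand[cand$iou >= iou_threshold, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$pred, cand$ref), , drop = FALSE]
  used_p <- integer(); used_r <- integer()
  keep <- logical(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    if (!(cand$pred[q] %in% used_p) && !(cand$ref[q] %in% used_r)) {
      keep[q] <- TRUE
      used_p <- c(used_p, cand$pred[q])
      used_r <- c(used_r, cand$ref[q])
    }
  }
  matches <- cand[keep, , drop = FALSE]
  rownames(matches) <- NULL
  structure(list(matches = matches,
                 fp = setdiff(p_ids, matches$pred),
                 fn = setdiff(r_ids, matches$ref),
                 iou_threshold = iou_threshold),
            class = "match_table")
}

#' Panoptic quality scores
#'
#' From a [match_instances] table: recognition quality
#' `RQ = TP / (TP + FP/2 + FN/2)`, segmentation quality `SQ` = mean IoU
#' over matched pairs (0 when nothing matched but instances exist), and
#' panoptic quality `PQ = RQ * SQ`. When neither mask contains any
#' instance all three are reported missing.
#'
#' @param table A `match_table`.
#' @return Named numeric vector `c(rq, sq, pq)`.
#' @export
panoptic_scores <- function(table) {
  stopifnot(inherits(table, "match_table"))
  tp <- nrow(table$matches)
  fp <- length(table$fp)
  fn <- length(table$fn)
  if (tp + fp + fn == 0)
    return(c(rq = NA_real_, sq = NA_real_, pq = NA_real_))
  rq <- tp / (tp + fp / 2 + fn / 2)
  sq <- if (tp > 0) mean(table$matches$iou) else 0
  c(rq = rq, sq = sq, pq = rq * sq)
}

# Numeric codes for anatomic-group masks derived from instances.
.group_codes <- c(vertebra = 1L, ivd = 2L, endplate = 3L)

#' Derive an anatomic-group mask from an instance mask
#'
#' Collapses instance identity: every vertebra-range id maps to one
#' vertebra group code (1), disc-range ids to the IVD code (2) and
#' endplate-range ids to the endplate code (3). Used to evaluate a
#' semantic-level comparison when only instance references exist.
#'
#' @param instances Instance mask ([anat_volume] or integer array).
#' @return Group-coded mask of the same type.
#' @export
derive_semantic_from_instances <- function(instances) {
  is_vol <- is_anat_volume(instances)
  inst <- if (is_vol) instances$data else instances
  kindmap <- c(.group_codes, background = 0L)
  out <- array(kindmap[instance_kind(inst)], dim(inst))
  storage.mode(out) <- "integer"
  if (is_vol) { instances$data <- out; instances } else out
}

#' Evaluate one subject against a reference
#'
#' Produces the per-structure and per-instance metric report for a
#' predicted mask pair against a reference pair on the same grid:
#' structure-wise Dice and ASSD for each of the 14 semantic structures
#' and each anatomic group, then instance-wise metrics (mean Dice and
#' ASSD over matched pairs, RQ/SQ/PQ) per instance kind. Structures
#' empty in both masks are excluded; structures empty in exactly one
#' yield Dice 0 and a missing ASSD.
#'
#' @param pred,ref [mask_pair]s on congruent grids.
#' @param iou_threshold Matching threshold for instance metrics.
#' @return A list of class `evaluation_report` with data.frames
#'   `structures`, `groups`, `instances` and `averages`.
#' @export
evaluate_subject <- function(pred, ref, iou_threshold = 0.5) {
  stopifnot(inherits(pred, "mask_pair"), inherits(ref, "mask_pair"))
  .stop_geometry(pred$semantic, ref$semantic, "pred/ref masks")
  sp <- ref$semantic$spacing
  ps <- pred$semantic$data
  rs <- ref$semantic$data

  row_for <- function(scope, name, pa, ra) {
    if (!any(pa) && !any(ra)) return(NULL)
    data.frame(scope = scope, name = name, dsc = dice(pa, ra),
               assd = if (any(pa) && any(ra)) assd(pa, ra, sp) else NA_real_,
               stringsAsFactors = FALSE)
  }
  sch <- semantic_scheme()
  structures <- do.call(rbind, lapply(seq_len(nrow(sch)), function(k)
    row_for("structure", sch$name[k], ps == sch$code[k], rs == sch$code[k])))
  groups <- do.call(rbind, lapply(unique(sch$group), function(g) {
    codes <- codes_in_group(g)
    row_for("group", g, array(ps %in% codes, dim(ps)),
            array(rs %in% codes, dim(rs)))
  }))

  pi_ <- pred$instances$data
  ri <- ref$instances$data
  inst_rows <- do.call(rbind, lapply(names(.group_codes), function(kind) {
    lohi <- switch(kind, vertebra = c(1L, 99L), ivd = c(100L, 199L),
                   endplate = c(200L, 299L))
    pk <- array(0L, dim(pi_)); sel <- pi_ >= lohi[1] & pi_ <= lohi[2]
    pk[sel] <- pi_[sel]
    rk <- array(0L, dim(ri)); sel <- ri >= lohi[1] & ri <= lohi[2]
    rk[sel] <- ri[sel]
    if (!any(pk > 0) && !any(rk > 0)) return(NULL)
    mt <- match_instances(pk, rk, iou_threshold)
    pq <- panoptic_scores(mt)
    if (nrow(mt$matches)) {
      per <- vapply(seq_len(nrow(mt$matches)), function(q) {
        a <- pk == mt$matches$pred[q]
        b <- rk == mt$matches$ref[q]
        c(dice(a, b), assd(a, b, sp))
      }, numeric(2))
      dsc <- mean(per[1, ]); as_ <- mean(per[2, ])
    } else { dsc <- 0; as_ <- NA_real_ }
    data.frame(scope = "instance", name = kind, dsc = dsc, assd = as_,
               rq = pq["rq"], sq = pq["sq"], pq = pq["pq"],
               tp = nrow(mt$matches), fp = length(mt$fp),
               fn = length(mt$fn), stringsAsFactors = FALSE,
               row.names = NULL)
  }))

  avg <- function(df, label) {
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(level = label,
               dsc_mean = mean(df$dsc, na.rm = TRUE),
               dsc_sd = sd(df$dsc, na.rm = TRUE),
               assd_mean = mean(df$assd, na.rm = TRUE),
               assd_sd = sd(df$assd, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  averages <- rbind(avg(structures, "structure"), avg(groups, "group"),
                    avg(inst_rows, "instance"))
  structure(list(structures = structures, groups = groups,
                 instances = inst_rows, averages = averages),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  if (!is.null(x$groups)) { cat("Groups:\n"); print(x$groups) }
  if (!is.null(x$instances)) { cat("Instances:\n"); print(x$instances) }
  if (!is.null(x$averages)) { cat("Averages:\n"); print(x$averages) }
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired per-subject scores (e.g. Dice
#' or RQ across a cohort under two methods). All-zero differences are
#' degenerate and reported as p = 1.
#'
#' @param scores_a,scores_b Equal-length numeric vectors of paired
#'   per-subject values, `n >= 5`.
#' @param alpha Significance threshold to report against (default 0.05).
#' @return List with `p_value`, `significant`, `alpha`, `n`.
#' @export
paired_signed_rank <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) != length(scores_b))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(scores_a)
  if (n < 5) stop("need at least 5 paired observations", call. = FALSE)
  d <- scores_a - scores_b
  p <- if (all(d == 0)) 1
  else suppressWarnings(
    wilcox.test(scores_a, scores_b, paired = TRUE,
                alternative = "two.sided")$p.value)
  list(p_value = p, significant = p < alpha, alpha = alpha, n = n)
}
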