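# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Shift a 3D array by one voxel along `axis` in direction `dir` (+1/-1),
# filling the vacated plane with `fill`.
.shift3 <- function(arr, axis, dir, fill = 0L) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (dir > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Shift a 3D array by an arbitrary integer offset, filling with `fill`.
.shift_offset <- function(arr, off, fill = 0L) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) { dst[[a]] <- (1 + o):d[a]; src[[a]] <- 1:(d[a] - o) }
    else { dst[[a]] <- 1:(d[a] + o); src[[a]] <- (1 - o):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Logical mask of foreground voxels with at least one 6-connected
# background (or out-of-volume) neighbour.
.surface_voxels <- function(fg) {
  stopifnot(is.logical(fg))
  interior <- fg
  for (axis in 1:3) for (dir in c(-1L, 1L))
    interior <- interior & .shift3(fg, axis, dir, fill = FALSE)
  fg & !interior
}

# For each voxel, the maximum label among its 6 neighbours (0 outside).
.max_neighbor_label <- function(lab) {
  out <- array(0L, dim(lab))
  for (axis in 1:3) for (dir in c(-1L, 1L))
    out <- pmax(out, .shift3(lab, axis, dir, fill = 0L))
  out
}

# 26-connected component labelling (compiled kernel).
.components <- function(fg) {
  stopifnot(is.logical(fg))
  .cc_label_3d(as.vector(fg), dim(fg))
}

# Center of mass (1-based voxel coordinates) of each positive label in a
# labelled array; returns a matrix with one row per label id in `ids`.
.label_centroids <- function(lab, ids) {
  idx <- which(lab > 0 & lab %in% ids)
  coords <- arrayInd(idx, dim(lab))
  g <- factor(lab[idx], levels = ids)
  cbind(rowsum(coords[, 1], g) / as.vector(table(g)),
        rowsum(coords[, 2], g) / as.vector(table(g)),
        rowsum(coords[, 3], g) / as.vector(table(g)))
}
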