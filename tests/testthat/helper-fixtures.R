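# Fixtures are generated in code; nothing is read from disk.

small_phantom <- function(n = 5, seed = 7, ...) {
  generate_phantom(phantom_spec(n_vertebrae = n, seed = seed, ...))
}

# Vertebra-range ids only (discs/endplates zeroed).
vertebra_ids_only <- function(inst) {
  out <- inst
  out[out >= 100L] <- 0L
  out
}

# An arbitrary small label volume with isotropic spacing.
toy_volume <- function(dims = c(8, 10, 6), spacing = c(1, 1, 1)) {
  anat_volume(array(0L, dims), spacing = spacing, orientation = "PIR")
}

# ---- independent brute-force metric oracles (small masks only) ----

brute_surface <- function(m) {
  d <- dim(m)
  s <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    nb <- c(if (i > 1) m[i - 1, j, k] else FALSE,
            if (i < d[1]) m[i + 1, j, k] else FALSE,
            if (j > 1) m[i, j - 1, k] else FALSE,
            if (j < d[2]) m[i, j + 1, k] else FALSE,
            if (k > 1) m[i, j, k - 1] else FALSE,
            if (k < d[3]) m[i, j, k + 1] else FALSE)
    if (i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 || k == d[3] ||
        !all(nb))
      s[i, j, k] <- TRUE
  }
  s
}

brute_assd <- function(a, b, spacing = c(1, 1, 1)) {
  pa <- arrayInd(which(brute_surface(a)), dim(a))
  pb <- arrayInd(which(brute_surface(b)), dim(b))
  pa <- sweep(pa, 2, spacing, "*")
  pb <- sweep(pb, 2, spacing, "*")
  da <- apply(pa, 1, function(p) min(sqrt(colSums((t(pb) - p)^2))))
  db <- apply(pb, 1, function(p) min(sqrt(colSums((t(pa) - p)^2))))
  (sum(da) + sum(db)) / (length(da) + length(db))
}

brute_dice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

brute_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

random_blob_mask <- function(dims, p = 0.25) {
  array(runif(prod(dims)) < p, dims)
}

# Oracle-driven pipeline run on a phantom, with full post-processing.
oracle_pipeline <- function(ph, skip = character()) {
  cfg <- phantom_cutout_config(ph)
  res <- segment_instances(ph$semantic, oracle_cutout_predictor(ph), cfg)
  postprocess_pair(mask_pair(ph$semantic, res$instances), skip = skip)
}

noisy_pipeline <- function(ph, seed = 1, flip_rate = 0.01,
                           boundary_jitter = 0.05) {
  cfg <- phantom_cutout_config(ph)
  pr <- noisy_cutout_predictor(ph, flip_rate = flip_rate,
                               boundary_jitter = boundary_jitter, seed = seed)
  res <- suppressWarnings(segment_instances(ph$semantic, pr, cfg))
  suppressWarnings(postprocess_pair(mask_pair(ph$semantic, res$instances)))
}
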