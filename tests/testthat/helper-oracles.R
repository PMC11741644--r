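# Independent brute-force oracles and small fixtures used across tests.
# These deliberately avoid the package's own code paths.

# Dice by explicit voxel-by-voxel counting
dice_bruteforce <- function(pred, truth, label) {
  inter <- 0L; ns <- 0L; nt <- 0L
  pv <- as.vector(pred); tv <- as.vector(truth)
  for (i in seq_along(pv)) {
    s <- pv[i] == label
    t <- tv[i] == label
    if (s) ns <- ns + 1L
    if (t) nt <- nt + 1L
    if (s && t) inter <- inter + 1L
  }
  if (ns + nt == 0L) 1 else 2 * inter / (ns + nt)
}

# surface voxels by explicit neighbour checking
surface_bruteforce <- function(mask) {
  d <- dim(mask)
  rank <- length(d)
  out <- NULL
  coords <- which(mask, arr.ind = TRUE)
  if (is.vector(coords)) coords <- matrix(coords, ncol = rank)
  for (r in seq_len(nrow(coords))) {
    v <- coords[r, ]
    exposed <- FALSE
    for (ax in seq_len(rank)) {
      for (dlt in c(-1L, 1L)) {
        nb <- v
        nb[ax] <- nb[ax] + dlt
        if (nb[ax] < 1L || nb[ax] > d[ax]) {
          exposed <- TRUE
        } else {
          if (!mask[matrix(nb, 1L)]) exposed <- TRUE
        }
      }
    }
    if (exposed) out <- rbind(out, v)
  }
  out
}

# symmetric average surface distance: double loop over surface points
asd_bruteforce <- function(pred, truth, label, spacing = NULL) {
  rank <- length(dim(pred))
  if (is.null(spacing)) spacing <- rep(1, rank)
  sa <- surface_bruteforce(pred == label)
  sb <- surface_bruteforce(truth == label)
  A <- sweep(sa, 2L, spacing, `*`)
  B <- sweep(sb, 2L, spacing, `*`)
  d_ab <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    d_ab[i] <- sqrt(min(colSums((t(B) - A[i, ])^2)))
  }
  d_ba <- numeric(nrow(B))
  for (j in seq_len(nrow(B))) {
    d_ba[j] <- sqrt(min(colSums((t(A) - B[j, ])^2)))
  }
  0.5 * (mean(d_ab) + mean(d_ba))
}

# random connected-ish blob mask for metric fuzzing
random_mask <- function(d, p = 0.4) {
  arr <- array(stats::runif(prod(d)) < p, d)
  if (!any(arr)) arr[ceiling(prod(d) / 2)] <- TRUE
  arr
}

# tiny planar dataset for fast network tests
tiny_dataset_2d <- function(n = 2, shape = c(16L, 16L), seed = 3) {
  generate_dataset(n, phantom_spec(shape = shape), seed = seed)
}

minimal_config <- function() assemble_configuration(rep(1L, 19L), c(0L, 0L))
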