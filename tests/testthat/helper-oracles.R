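# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# solid cuboid of nx x ny x nz foreground voxels inside a zero margin
solid_cuboid_mask <- function(nx, ny, nz, spacing = c(1, 1, 1)) {
  g <- array(0L, c(nx + 4L, ny + 4L, nz + 4L))
  g[2 + seq_len(nx), 2 + seq_len(ny), 2 + seq_len(nz)] <- 1L
  voxel_mask(g, spacing = spacing)
}

single_voxel_mask <- function(spacing = c(1, 1, 1)) {
  g <- array(0L, c(3, 3, 3))
  g[2, 2, 2] <- 1L
  voxel_mask(g, spacing = spacing)
}

# random valid box dims (l >= b >= t > 0)
random_box_dims <- function(n, min = 0.1, max = 50) {
  t(replicate(n, sort(runif(3, min, max), decreasing = TRUE)))
}

# two-sided Mann-Whitney p by full enumeration of group labelings
brute_mwu <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  mu <- nx * length(y) / 2
  labelings <- utils::combn(length(pooled), nx)
  u_all <- apply(labelings, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  list(u = u_obs,
       p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Benjamini-Hochberg step-up straight from the definition
brute_bh <- function(p, fdr) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * fdr / m)
  flags <- rep(FALSE, m)
  if (length(k) > 0) flags[ord[seq_len(max(k))]] <- TRUE
  flags
}

# best achievable threshold-rule accuracy by scanning all n+1 split
# positions of the sorted values (no thresholds involved)
brute_cutoff_accuracy <- function(values, labels, direction) {
  ord <- order(values)
  mal <- (labels == "malignant")[ord]
  n <- length(values)
  best <- 0
  for (k in 0:n) {  # rule: the top n-k values are called malignant
    pred <- c(rep(FALSE, k), rep(TRUE, n - k))
    if (direction == "less") pred <- !pred
    # collapse ties: a threshold cannot split equal values; emulate by
    # only allowing k at boundaries between distinct values
    if (k > 0 && k < n && values[ord][k] == values[ord][k + 1]) next
    best <- max(best, mean(pred == mal))
  }
  best
}

# toy linearly separable cohort in the canonical feature schema
separable_cohort <- function(n_per_class = 5, dataset = "toy") {
  n <- 2 * n_per_class
  base <- tibble::tibble(
    lesion_id = sprintf("t%02d", seq_len(n)),
    dataset = dataset,
    label = rep(c("benign", "malignant"), each = n_per_class))
  for (f in feature_names()) base[[f]] <- 0.5
  base$max3ddiam <- rep(c(10, 30), each = n_per_class) + seq_len(n) * 0.1
  base$surfarea <- rep(c(300, 1500), each = n_per_class) + seq_len(n)
  base$volume <- rep(c(500, 4000), each = n_per_class) + seq_len(n)
  base$afl <- rep(c(0.3, 0.05), each = n_per_class) + seq_len(n) * 1e-3
  base$aco <- rep(c(0.55, 0.9), each = n_per_class) - seq_len(n) * 1e-3
  base$kfl <- rep(c(0.4, 0.1), each = n_per_class) + seq_len(n) * 1e-3
  base$mps <- rep(c(0.6, 0.9), each = n_per_class) - seq_len(n) * 1e-3
  base
}
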