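# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Box count by direct occupancy scan: loop over every grid-aligned box of
# edge s anchored at the occupied bounding-box corner.
oracle_box_count <- function(occ, s) {
  idx <- which(occ, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  n_boxes <- 0L
  for (bx in seq(lo[1], hi[1], by = s)) {
    for (by in seq(lo[2], hi[2], by = s)) {
      for (bz in seq(lo[3], hi[3], by = s)) {
        sub <- occ[bx:min(bx + s - 1, hi[1]),
                   by:min(by + s - 1, hi[2]),
                   bz:min(bz + s - 1, hi[3])]
        if (any(sub)) n_boxes <- n_boxes + 1L
      }
    }
  }
  n_boxes
}

# Menger sponge voxel set by direct coordinate recursion (0-based corners).
oracle_menger_coords <- function(level) {
  corners <- matrix(0, nrow = 1, ncol = 3)
  size <- 3^level
  for (l in seq_len(level)) {
    size <- size / 3
    keep <- list()
    for (i in 0:2) for (j in 0:2) for (k in 0:2) {
      if (sum(c(i, j, k) == 1) >= 2) next
      keep[[length(keep) + 1]] <- cbind(corners[, 1] + i * size,
                                        corners[, 2] + j * size,
                                        corners[, 3] + k * size)
    }
    corners <- do.call(rbind, keep)
  }
  corners  # one row per unit voxel (size has reached 1)
}

# Gliding-box lacunarity by exhaustive window enumeration.
oracle_lacunarity <- function(occ, r) {
  d <- dim(occ)
  masses <- c()
  for (i in 1:(d[1] - r + 1)) for (j in 1:(d[2] - r + 1)) for (k in 1:(d[3] - r + 1)) {
    masses <- c(masses, sum(occ[i:(i + r - 1), j:(j + r - 1), k:(k + r - 1)]))
  }
  mu <- mean(masses)
  mean((masses - mu)^2) / mu^2
}

# MST total length: naive Prim on the full distance matrix.
oracle_mst_length <- function(pts) {
  n <- nrow(pts)
  dm <- as.matrix(dist(pts))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  total <- 0
  for (step in seq_len(n - 1)) {
    dsub <- dm[in_tree, !in_tree, drop = FALSE]
    total <- total + min(dsub)
    j <- which(!in_tree)[which(dsub == min(dsub), arr.ind = TRUE)[1, 2]]
    in_tree[j] <- TRUE
  }
  total
}

# Wilcoxon signed-rank two-sided p by full 2^n sign enumeration.
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# AUROC by exhaustive pairwise comparison (ties count 1/2).
oracle_auroc <- function(label, score) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# One-sided exact binomial tail P(X >= k) by direct summation.
oracle_binom_tail <- function(k, n, p) {
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

random_mask <- function(dim3, p = 0.3, seed = 1) {
  set.seed(seed)
  occ <- array(runif(prod(dim3)) < p, dim = dim3)
  if (!any(occ)) occ[1] <- TRUE
  binary_mask(occ)
}
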