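# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package internals they check.

brute_mw_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

brute_matching_coefficient <- function(dvals, mask) {
  s <- 0
  d <- dim(dvals)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    s <- s + dvals[i, j, k] * mask[i, j, k]
  s
}

brute_tissue_volume <- function(p, voxel_size) {
  cnt <- 0
  for (v in as.vector(p)) if (v > 0.5) cnt <- cnt + 1
  cnt * prod(voxel_size)
}

brute_bmu <- function(weights, x) {
  best <- 1L
  bestd <- Inf
  for (i in seq_len(nrow(weights))) {
    d <- sqrt(sum((weights[i, ] - x)^2))
    if (d < bestd) { bestd <- d; best <- i }
  }
  best
}

# Exhaustive pairwise coordinate ascent on the SVM dual: sweeps every (i, j)
# pair, taking the exact constrained maximizing step along the direction
# that preserves sum(alpha * y), until no pair improves the objective.
brute_svm_dual <- function(K, y, C, tol = 1e-12, max_sweeps = 5000) {
  n <- length(y)
  Q <- (y %o% y) * K
  a <- numeric(n)
  obj <- function(a) sum(a) - 0.5 * drop(a %*% Q %*% a)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      d <- numeric(n)
      d[i] <- y[i]; d[j] <- -y[j]
      g <- sum(d) - drop(d %*% Q %*% a)
      h <- drop(d %*% Q %*% d)
      ti <- sort(c((0 - a[i]) / y[i], (C - a[i]) / y[i]))
      tj <- sort(c((a[j] - 0) / y[j], (a[j] - C) / y[j]))
      lo <- max(ti[1], tj[1]); hi <- min(ti[2], tj[2])
      t_star <- if (h > 1e-14) g / h else if (g > 0) hi else lo
      t_star <- min(max(t_star, lo), hi)
      gain <- g * t_star - 0.5 * h * t_star^2
      if (gain > tol) {
        a <- a + t_star * d
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(alpha = a, objective = obj(a))
}

# deterministic small phantom pair for segmentation tests
test_phantom <- function(seed = 1, noise_sd = 8, ...) {
  generate_phantom(phantom_spec(seed = seed, noise_sd = noise_sd, ...))
}

truth_ventricle_mask <- function(ph) {
  vm_mask(ph$truth$label_volume == 4L, ph$image$voxel_size)
}

# separable 3-class toy feature table for classifier/evaluation tests
toy_feature_table <- function(n_per_class = 6, shift = 6, sd = 1, seed = 42,
                              n_features = 5) {
  set.seed(seed)
  groups <- rep(c("NC", "MCI", "AD"), each = n_per_class)
  centers <- c(NC = 0, MCI = shift, AD = 2 * shift)
  X <- sapply(seq_len(n_features), function(j)
    rnorm(length(groups), centers[groups], sd) + j)
  colnames(X) <- paste0("V_F", seq_len(n_features))
  cbind(data.frame(group = groups, stringsAsFactors = FALSE),
        as.data.frame(X))
}
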