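#' Fit a Gaussian mixture to brain intensities
#'
#' A three-class intensity Gaussian mixture fitted by expectation
#' maximization over the in-brain voxels (intensity != 0; the phantom
#' background is exactly zero). Classes are initialized by a k-quantile
#' split of the intensities and relabelled after convergence by ascending
#' mean to CSF, GM, WM (T1-like ordering). A small variance floor keeps the
#' noise-free, perfectly separable case well defined, in which the
#' posteriors collapse to 0/1 indicators.
#'
#' @param image a [vm_volume].
#' @param k number of classes (3: CSF, GM, WM).
#' @param seed seed (kept for interface stability; the quantile
#'   initialization itself is deterministic).
#' @param init_means optional numeric length-`k` initial means, overriding
#'   the quantile split (any order; final labels are mean-sorted).
#' @param tol convergence tolerance on the mean log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return An object of class `vm_tissue_maps`: posterior arrays `p_csf`,
#'   `p_gm`, `p_wm` (zero outside the brain mask), per-class `means`,
#'   `variances`, `weights`, the brain `mask`, the `loglik` trace and
#'   `voxel_size`.
#' @export
fit_tissue_gmm <- function(image, k = 3L, seed = 1L, init_means = NULL,
                           tol = 1e-6, max_iter = 500L) {
  if (!inherits(image, "vm_volume"))
    vm_stop("parameter", "image must be a vm_volume")
  mask <- image$data != 0
  x <- image$data[mask]
  if (length(unique(x)) < k)
    vm_stop("segmentation",
            "degenerate input: fewer than %d distinct in-brain intensities", k)
  n <- length(x)
  if (is.null(init_means)) {
    qs <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    mu <- as.numeric(qs)
  } else {
    if (length(init_means) != k) vm_stop("parameter", "need %d init_means", k)
    mu <- as.numeric(init_means)
  }
  var_floor <- (1e-4 * diff(range(x)))^2
  s2 <- rep(max(var(x) / k^2, var_floor), k)
  w <- rep(1 / k, k)
  loglik <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E step in log space for numerical safety
    lp <- vapply(seq_len(k), function(j)
      log(w[j]) - 0.5 * log(2 * pi * s2[j]) - (x - mu[j])^2 / (2 * s2[j]),
      numeric(n))
    m <- do.call(pmax, as.data.frame(lp))
    lse <- m + log(rowSums(exp(lp - m)))
    r <- exp(lp - lse)
    ll <- mean(lse)
    loglik <- c(loglik, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    # M step
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    s2 <- pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, var_floor)
  }
  ord <- order(mu)  # ascending mean: CSF < GM < WM
  r <- r[, ord, drop = FALSE]
  mk <- function(j) {
    a <- array(0, dim(image$data)); a[mask] <- r[, j]; a
  }
  structure(list(p_csf = mk(1L), p_gm = mk(2L), p_wm = mk(3L),
                 means = stats::setNames(mu[ord], c("CSF", "GM", "WM")),
                 variances = stats::setNames(s2[ord], c("CSF", "GM", "WM")),
                 weights = stats::setNames(w[ord], c("CSF", "GM", "WM")),
                 mask = mask, loglik = loglik,
                 voxel_size = image$voxel_size),
            class = "vm_tissue_maps")
}

#' @export
print.vm_tissue_maps <- function(x, ...) {
  cat("<vm_tissue_maps> class means:",
      paste(sprintf("%s=%.1f", names(x$means), x$means), collapse = ", "),
      sprintf("\n  EM iterations: %d\n", length(x$loglik)))
  invisible(x)
}

#' Tissue volume from posterior maps
#'
#' Counts the voxels whose class posterior exceeds 0.5 and multiplies by
#' the voxel volume. The whole-brain variant thresholds the combined
#' gray-or-white posterior `p_gm + p_wm`.
#'
#' @param maps a [fit_tissue_gmm] result.
#' @param tissue one of `"GM"`, `"WM"`, `"CSF"`, `"whole"`.
#' @return Volume in mm^3.
#' @export
tissue_volume <- function(maps, tissue) {
  if (!inherits(maps, "vm_tissue_maps"))
    vm_stop("parameter", "maps must come from fit_tissue_gmm()")
  p <- switch(as.character(tissue),
              GM = maps$p_gm, WM = maps$p_wm, CSF = maps$p_csf,
              whole = maps$p_gm + maps$p_wm,
              vm_stop("parameter", "unknown tissue label: %s", tissue))
  sum(p > 0.5) * prod(maps$voxel_size)
}
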