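#' Mann-Whitney U test with the normal approximation
#'
#' Rank-sum test of two independent samples using combined midranks. U
#' statistics are derived from the rank sums; `u_obt` is the smaller of U1
#' and U2 and the standard-normal deviate is
#' `Z = (U_obt - n1*n2/2) / sqrt(n1*n2*(n1+n2+1)/12)`, with no tie
#' correction and no continuity correction (the plain large-sample form).
#' The two-sided p-value is `2 * pnorm(-|Z|)`.
#'
#' @param sample_a,sample_b numeric vectors (each of length >= 2).
#' @return An object of class `vm_mw` with `u1`, `u2`, `u_obt`, `z`, `p`,
#'   `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$z  # -1.964
#' @export
mann_whitney <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L)
    vm_stop("parameter", "both samples need at least 2 observations")
  if (anyNA(a) || anyNA(b)) vm_stop("parameter", "samples contain NA")
  r <- rank(c(a, b))  # midranks for ties
  r1 <- sum(r[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u_obt <- min(u1, u2)
  z <- (u_obt - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  p <- min(1, 2 * pnorm(-abs(z)))
  structure(list(u1 = u1, u2 = u2, u_obt = u_obt, z = z, p = p,
                 n1 = n1, n2 = n2),
            class = "vm_mw")
}

#' @export
print.vm_mw <- function(x, ...) {
  cat(sprintf("<vm_mw> U1=%.1f U2=%.1f U_obt=%.1f Z=%.3f p=%.4g (n=%d, %d)\n",
              x$u1, x$u2, x$u_obt, x$z, x$p, x$n1, x$n2))
  invisible(x)
}

feature_columns <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  setdiff(names(table)[num], c("subject_id", "seed"))
}

#' Screen features by Mann-Whitney significance
#'
#' Keeps exactly the features whose two-sided Mann-Whitney p-value for the
#' given group contrast is below `alpha`, preserving column order.
#'
#' @param table data frame with a `group` column and numeric feature
#'   columns.
#' @param contrast character length-2: the two groups to compare.
#' @param alpha significance level (default 0.05).
#' @return The table restricted to the surviving features (non-feature
#'   columns retained), with the per-feature p-values in attribute
#'   `"p_values"`.
#' @export
filter_features <- function(table, contrast = c("NC", "AD"), alpha = 0.05) {
  if (!"group" %in% names(table)) vm_stop("parameter", "table needs a group column")
  check_number(alpha, "alpha", min = 0)
  feats <- feature_columns(table)
  ga <- table$group == contrast[1]
  gb <- table$group == contrast[2]
  if (sum(ga) < 2L || sum(gb) < 2L)
    vm_stop("parameter", "both contrast groups need >= 2 subjects")
  p <- vapply(feats, function(f)
    mann_whitney(table[[f]][ga], table[[f]][gb])$p, numeric(1))
  keep <- feats[p < alpha]
  if (length(keep) == 0L)
    vm_stop("empty_selection",
            "no feature passes the Mann-Whitney filter at alpha = %g", alpha)
  out <- table[, c(setdiff(names(table), feats), keep), drop = FALSE]
  # restore original column order
  out <- out[, names(table)[names(table) %in% names(out)], drop = FALSE]
  attr(out, "p_values") <- p
  out
}

#' Number of principal components needed for a variance target
#'
#' The smallest k whose cumulative explained proportion reaches the
#' target. Accepts fractions or percentages (as printed in component
#' tables).
#'
#' @param proportions per-component explained proportions, nonincreasing.
#' @param variance_target cumulative fraction to retain (default 0.95).
#' @return Integer count of retained components.
#' @export
retained_components <- function(proportions, variance_target = 0.95) {
  pr <- as.numeric(proportions)
  if (any(pr < 0)) vm_stop("parameter", "proportions must be nonnegative")
  if (sum(pr) > 1.5) pr <- pr / 100  # printed as percentages
  cum <- cumsum(pr)
  k <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(k))
    vm_stop("parameter",
            "listed proportions never reach the %g variance target",
            variance_target)
  as.integer(k)
}

#' Principal component reduction on the correlation matrix
#'
#' Standardizes every feature (zero mean, unit variance), eigendecomposes
#' the correlation matrix and retains the smallest number of leading
#' components whose cumulative explained proportion reaches
#' `variance_target`. Eigenvector signs are fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param table data frame (feature columns are used) or numeric matrix.
#' @param variance_target cumulative variance fraction to retain.
#' @return A list of class `vm_pca`: `scores` (subjects x retained
#'   components), `loadings` (all components), `explained_proportion`,
#'   `n_retained`, `feature_means`, `feature_sds`.
#' @export
pca_reduce <- function(table, variance_target = 0.95) {
  X <- if (is.data.frame(table))
    as.matrix(table[, feature_columns(table), drop = FALSE]) else as.matrix(table)
  if (ncol(X) < 2L) vm_stop("parameter", "need at least 2 features")
  if (nrow(X) < 3L) vm_stop("parameter", "need at least 3 subjects")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    vm_stop("parameter", "zero-variance feature: %s",
            paste(colnames(X)[sds == 0], collapse = ", "))
  mus <- colMeans(X)
  Z <- sweep(sweep(X, 2, mus), 2, sds, "/")
  e <- eigen(cor(X), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  prop <- ev / sum(ev)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)
  k <- retained_components(prop, variance_target)
  scores <- Z %*% V[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = V, eigenvalues = ev,
                 explained_proportion = prop, n_retained = k,
                 feature_means = mus, feature_sds = sds,
                 variance_target = variance_target),
            class = "vm_pca")
}

#' @export
print.vm_pca <- function(x, ...) {
  cat(sprintf("<vm_pca> %d of %d components retained (%.2f%% variance)\n",
              x$n_retained, length(x$explained_proportion),
              100 * sum(x$explained_proportion[seq_len(x$n_retained)])))
  invisible(x)
}

#' @export
predict.vm_pca <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata))
    as.matrix(newdata[, names(object$feature_means), drop = FALSE])
  else matrix(newdata, ncol = length(object$feature_means),
              dimnames = list(NULL, names(object$feature_means)))
  Z <- sweep(sweep(X, 2, object$feature_means), 2, object$feature_sds, "/")
  Z %*% object$loadings[, seq_len(object$n_retained), drop = FALSE]
}

#' Per-feature group statistics table
#'
#' Group means and standard deviations plus Mann-Whitney p-values for the
#' NC-vs-MCI and NC-vs-AD contrasts, in the layout of a feature
#' statistics report.
#'
#' @param table data frame with `group` and feature columns.
#' @return Data frame with one row per feature.
#' @export
feature_stats <- function(table) {
  feats <- feature_columns(table)
  g <- table$group
  row <- function(f) {
    x <- table[[f]]
    data.frame(
      feature = f,
      mean_NC = mean(x[g == "NC"]), sd_NC = sd(x[g == "NC"]),
      mean_MCI = mean(x[g == "MCI"]), sd_MCI = sd(x[g == "MCI"]),
      mean_AD = mean(x[g == "AD"]), sd_AD = sd(x[g == "AD"]),
      p_NC_MCI = mann_whitney(x[g == "NC"], x[g == "MCI"])$p,
      p_NC_AD = mann_whitney(x[g == "NC"], x[g == "AD"])$p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(feats, row))
}
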