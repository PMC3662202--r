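# Published worked-example fixtures: the 3x3 confusion matrices and
# per-component variance proportions reported for the 52-subject clinical
# cohort, shipped as plain CSV under inst/extdata. They are inputs for
# metric-arithmetic checks, not outputs of this package.

extdata <- function(f) {
  p <- system.file("extdata", f, package = "ventmorph")
  if (p == "") vm_stop("io", "missing installed fixture %s", f)
  p
}

#' Published confusion matrices (volume + shape features)
#'
#' The reported 3x3 confusion matrices for the SOM, SVM and PSO-SVM
#' classifiers on the clinical cohort, each in a plain ("raw") and a
#' "pca" variant.
#'
#' @return Named list (`som_raw`, `som_pca`, ..., `psosvm_pca`) of 3x3
#'   `vm_confusion` matrices in NC/MCI/AD order.
#' @export
published_confusions <- function() {
  d <- read.csv(extdata("confusion_matrices.csv"), stringsAsFactors = FALSE)
  out <- list()
  for (clf in unique(d$classifier)) for (vr in unique(d$variant)) {
    sub <- d[d$classifier == clf & d$variant == vr, ]
    m <- as.matrix(sub[, c("NC", "MCI", "AD")])
    rownames(m) <- sub$true
    out[[paste(clf, vr, sep = "_")]] <- as_confusion(m[c("NC", "MCI", "AD"), ])
  }
  out
}

#' Published per-component variance proportions
#'
#' The percentage of total variance explained by each principal component
#' for the three reported feature sets (volume, shape, volume + shape),
#' used to exercise the 95%-variance retention rule.
#'
#' @return Named list of numeric vectors (percentages).
#' @export
published_pca_proportions <- function() {
  d <- read.csv(extdata("pca_proportions.csv"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i) {
    v <- as.numeric(d[i, -1]); v[!is.na(v)]
  })
  names(out) <- d$feature_set
  out
}

#' Cohort group sizes of the published study
#'
#' Not every printed confusion-matrix row sums to its group size, so the
#' published per-task accuracies are the diagonal counts over these
#' totals.
#'
#' @return Named integer vector (NC, MCI, AD).
#' @export
published_group_sizes <- function() c(NC = 17L, MCI = 18L, AD = 17L)

#' Published headline accuracies
#'
#' The reported per-task accuracies (AD vs NC and MCI vs NC, volume +
#' shape features, with and without PCA) for the three classifiers, in
#' percent.
#'
#' @return Data frame with columns classifier, variant, task, accuracy.
#' @export
published_accuracies <- function() {
  read.csv(extdata("headline_accuracies.csv"), stringsAsFactors = FALSE)
}
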