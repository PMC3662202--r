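#' Confusion matrix in fixed class order
#'
#' @param truth,pred class labels of equal length.
#' @param classes class order (default NC, MCI, AD).
#' @return A matrix of class `vm_confusion` (true classes in rows,
#'   predictions in columns).
#' @export
confusion_matrix <- function(truth, pred, classes = c("NC", "MCI", "AD")) {
  present <- unique(c(as.character(truth), as.character(pred)))
  keep_cls <- classes[classes %in% present]
  cm <- table(factor(as.character(truth), levels = keep_cls),
              factor(as.character(pred), levels = keep_cls))
  structure(unclass(as.matrix(cm)), class = "vm_confusion")
}

#' @export
print.vm_confusion <- function(x, ...) {
  cat("<vm_confusion> true x predicted\n")
  print(unclass(x))
  invisible(x)
}

# wrap an already-counted matrix (e.g. a published table)
as_confusion <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) vm_stop("parameter", "confusion matrix must be square")
  structure(m, class = "vm_confusion")
}

#' Per-class accuracy: the diagonal over the row total
#'
#' The share of a class's subjects that were classified into that class,
#' the quantity the published per-task accuracy tables report.
#'
#' @param cm a [confusion_matrix].
#' @param class row class name.
#' @param total denominator: the class's subject count. Defaults to the
#'   row sum; pass the cohort group size explicitly when working with
#'   published matrices whose printed rows do not all sum to the group
#'   sizes.
#' @return Proportion in `[0, 1]`.
#' @export
class_accuracy <- function(cm, class, total = NULL) {
  if (!class %in% rownames(cm)) vm_stop("parameter", "class %s missing", class)
  cm[class, class] / (total %||% sum(cm[class, ]))
}

#' Binary metrics for one task from a confusion matrix
#'
#' Restricts the matrix to the two named classes' rows. A positive-class
#' subject predicted positive is a true positive; predicted anything else
#' (including a third class) a false negative, and mirrored for the
#' negatives. Reports the standard definitions
#' `accuracy = (TP+TN)/(P+N)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(FP+TN)`, and additionally the per-class accuracy of
#' the positive class ([class_accuracy]), which is what published
#' per-task accuracy rows correspond to.
#'
#' @param cm a [confusion_matrix].
#' @param positive,negative the two class names.
#' @return An object of class `vm_metrics`.
#' @export
binary_metrics <- function(cm, positive, negative) {
  for (cl in c(positive, negative))
    if (!cl %in% rownames(cm)) vm_stop("parameter", "class %s missing", cl)
  tp <- cm[positive, positive]
  fn <- sum(cm[positive, ]) - tp
  tn <- cm[negative, negative]
  fp <- sum(cm[negative, ]) - tn
  structure(list(task = c(positive = positive, negative = negative),
                 tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (fp + tn),
                 class_accuracy = class_accuracy(cm, positive)),
            class = "vm_metrics")
}

#' @export
print.vm_metrics <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", round_half_up(100 * v, 2))
  cat(sprintf("<vm_metrics> %s vs %s\n", x$task[1], x$task[2]))
  cat(sprintf("  accuracy    %s  (per-class %s)\n",
              pct(x$accuracy), pct(x$class_accuracy)))
  cat(sprintf("  sensitivity %s\n  specificity %s\n",
              pct(x$sensitivity), pct(x$specificity)))
  invisible(x)
}

feature_set_columns <- function(feature_sets) {
  cols <- character(0)
  if ("volume" %in% feature_sets) cols <- c(cols, volume_feature_names())
  if ("shape2d" %in% feature_sets) cols <- c(cols, shape_feature_names())
  if ("mc" %in% feature_sets) cols <- c(cols, c("MC_AD", "MC_MCI"))
  cols
}

# per-fold feature screening: keep features significant in any of the
# task's patient-vs-control contrasts. A contrast whose training fold has
# fewer than 2 subjects in a group is undefined and is skipped; if no
# contrast is defined at all (minimal cohorts), screening passes every
# feature through.
screen_features <- function(train, contrasts, alpha) {
  feats <- feature_columns(train)
  keep <- rep(FALSE, length(feats))
  applied <- FALSE
  for (ct in contrasts) {
    ga <- train$group == ct[1]
    gb <- train$group == ct[2]
    if (sum(ga) < 2L || sum(gb) < 2L) next
    applied <- TRUE
    p <- vapply(feats, function(f)
      mann_whitney(train[[f]][ga], train[[f]][gb])$p, numeric(1))
    keep <- keep | (p < alpha)
  }
  if (!applied) return(feats)
  if (!any(keep))
    vm_stop("empty_selection",
            "no feature passes the Mann-Whitney filter at alpha = %g", alpha)
  feats[keep]
}

train_classifier <- function(classifier, X, y, args, seed) {
  switch(classifier,
         som = do.call(som_train, c(list(X = X, y = y, seed = seed), args)),
         svm = do.call(svm_train, c(list(X = X, y = y), args)),
         pso_svm = do.call(pso_svm_train,
                           c(list(X = X, y = y, seed = seed), args)),
         vm_stop("parameter", "unknown classifier: %s", classifier))
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' For every subject, all data-dependent steps - unit-variance scaling,
#' Mann-Whitney screening, PCA (Route II), and optional probability /
#' discriminate maps for the matching-coefficient features - are refit on
#' the remaining subjects only; the held-out subject is transformed with
#' the fitted parameters and predicted once. Nothing from the held-out
#' subject leaks into any fitted statistic.
#'
#' @param table data frame with `group` plus feature columns (see
#'   [cohort_features]).
#' @param classifier `"som"`, `"svm"` or `"pso_svm"`.
#' @param route `"I"` (Mann-Whitney screen only) or `"II"` (screen then
#'   PCA on the correlation matrix).
#' @param task `"3class"`, or a length-2 character vector naming a binary
#'   task such as `c("AD", "NC")` (the table is then restricted to those
#'   groups).
#' @param feature_sets subset of `"volume"`, `"shape2d"`, `"mc"`, or
#'   `"all"` to use every numeric feature column of the table.
#' @param alpha Mann-Whitney significance level.
#' @param variance_target PCA cumulative-variance target.
#' @param classifier_args list of extra arguments for the classifier
#'   trainer (e.g. `n_particles`, `max_iter` for `pso_svm`).
#' @param masks list of [vm_mask] per subject, required when `"mc"` is in
#'   `feature_sets`.
#' @param seed master seed; per-fold seeds are derived from it.
#' @return An object of class `vm_loocv`: the `confusion` matrix, the
#'   per-subject `predictions` data frame, the overall `accuracy` and the
#'   configuration.
#' @export
loocv <- function(table, classifier = c("pso_svm", "svm", "som"),
                  route = c("II", "I"), task = "3class",
                  feature_sets = c("volume", "shape2d"),
                  alpha = 0.05, variance_target = 0.95,
                  classifier_args = list(), masks = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  route <- match.arg(route)
  use_mc <- "mc" %in% feature_sets
  if (use_mc && is.null(masks))
    vm_stop("parameter", "matching-coefficient features need per-subject masks")
  if (identical(task, "3class")) {
    contrasts <- list(c("NC", "MCI"), c("NC", "AD"))
  } else {
    if (length(task) != 2L) vm_stop("parameter", "task must be 3class or 2 groups")
    sel <- table$group %in% task
    masks <- if (!is.null(masks)) masks[sel]
    table <- table[sel, , drop = FALSE]
    contrasts <- list(task)
  }
  cols <- if (identical(feature_sets, "all")) feature_columns(table)
  else intersect(feature_set_columns(setdiff(feature_sets, "mc")),
                 names(table))
  if (length(cols) == 0L) vm_stop("parameter", "no feature columns selected")
  groups <- unique(table$group)
  if (any(table(table$group) < 2L))
    vm_stop("parameter", "every class needs at least 2 subjects for LOOCV")
  n <- nrow(table)
  fold_seeds <- derive_seeds(seed, n)
  preds <- character(n)
  base <- table[, c("group", cols), drop = FALSE]

  mask_arrays <- if (use_mc)
    lapply(masks, function(m) if (inherits(m, "vm_mask")) m$mask else m)

  for (i in seq_len(n)) {
    tr <- base[-i, , drop = FALSE]
    te <- base[i, , drop = FALSE]
    if (use_mc) {
      mc <- fold_mc_features(mask_arrays, base$group, holdout = i)
      tr <- cbind(tr, mc$train)
      te <- cbind(te, mc$test)
    }
    sc <- scale_unit_variance(tr)
    tr_s <- sc$scaled
    te_s <- apply_scaler(sc$scaler, te)
    keep <- screen_features(tr_s, contrasts, alpha)
    Xtr <- as.matrix(tr_s[, keep, drop = FALSE])
    Xte <- as.matrix(te_s[, keep, drop = FALSE])
    if (route == "II") {
      pca <- pca_reduce(Xtr, variance_target)
      Xte <- predict(pca, Xte)
      Xtr <- pca$scores
    }
    fit <- train_classifier(classifier, Xtr, factor(tr$group),
                            classifier_args, fold_seeds[i])
    preds[i] <- as.character(predict(fit, Xte))
  }
  cm <- confusion_matrix(table$group, preds)
  structure(list(confusion = cm,
                 predictions = data.frame(
                   subject = seq_len(n),
                   subject_id = table$subject_id %||% sprintf("S%03d", seq_len(n)),
                   truth = table$group, prediction = preds,
                   stringsAsFactors = FALSE),
                 accuracy = mean(preds == table$group),
                 config = list(classifier = classifier, route = route,
                               task = task, feature_sets = feature_sets,
                               alpha = alpha,
                               variance_target = variance_target,
                               classifier_args = classifier_args,
                               seed = seed)),
            class = "vm_loocv")
}

# Leave-one-out matching-coefficient features for one LOOCV fold. Training
# subjects get maps built without themselves (and without the held-out
# subject); the held-out subject is scored against maps from the full
# training set. Sums per group are precomputed so each exclusion is O(1)
# array work.
fold_mc_features <- function(mask_arrays, group, holdout) {
  idx_tr <- setdiff(seq_along(mask_arrays), holdout)
  sums <- list(); counts <- list()
  for (g in unique(group)) {
    ii <- intersect(idx_tr, which(group == g))
    counts[[g]] <- length(ii)
    sums[[g]] <- Reduce(`+`, mask_arrays[ii])
  }
  pmap <- function(g, excl = NULL) {
    s <- sums[[g]]; k <- counts[[g]]
    if (!is.null(excl) && group[excl] == g) { s <- s - mask_arrays[[excl]]; k <- k - 1L }
    s / max(k, 1L)
  }
  score <- function(i, excl) {
    d_ad <- pmap("AD", excl) - pmap("NC", excl)
    d_mci <- if ("MCI" %in% names(sums)) pmap("MCI", excl) - pmap("NC", excl)
    c(MC_AD = sum(d_ad * mask_arrays[[i]]),
      MC_MCI = if (!is.null(d_mci)) sum(d_mci * mask_arrays[[i]]) else 0)
  }
  train <- t(vapply(idx_tr, function(i) score(i, excl = i), numeric(2)))
  test <- matrix(score(holdout, excl = NULL), 1,
                 dimnames = list(NULL, c("MC_AD", "MC_MCI")))
  list(train = as.data.frame(train), test = as.data.frame(test))
}

#' @export
print.vm_loocv <- function(x, ...) {
  cat(sprintf("<vm_loocv> %s, route %s, features: %s\n",
              x$config$classifier, x$config$route,
              paste(x$config$feature_sets, collapse = "+")))
  cat(sprintf("  overall accuracy %.2f%%\n",
              round_half_up(100 * x$accuracy, 2)))
  print(x$confusion)
  invisible(x)
}

#' @export
summary.vm_loocv <- function(object, ...) {
  cm <- object$confusion
  per_class <- vapply(rownames(cm), function(cl) class_accuracy(cm, cl),
                      numeric(1))
  out <- list(accuracy = object$accuracy, per_class_accuracy = per_class,
              confusion = cm)
  class(out) <- "summary.vm_loocv"
  out
}

#' @export
print.summary.vm_loocv <- function(x, ...) {
  cat(sprintf("Overall LOOCV accuracy: %.2f%%\n",
              round_half_up(100 * x$accuracy, 2)))
  for (cl in names(x$per_class_accuracy))
    cat(sprintf("  %s: %.2f%%\n", cl,
                round_half_up(100 * x$per_class_accuracy[[cl]], 2)))
  print(x$confusion)
  invisible(x)
}
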