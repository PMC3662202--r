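#' Unit-variance scaling of a feature table
#'
#' Linearly scales every feature so its training-set variance is one
#' (division by the training standard deviation, no centering), and
#' returns the scaler so held-out subjects can be transformed with the
#' training parameters.
#'
#' @param table data frame with numeric feature columns (non-feature
#'   columns pass through) or a numeric matrix.
#' @return A list with `scaled` (same shape as the input) and `scaler`
#'   (named vector of training s.d.s, usable with [apply_scaler]).
#' @export
scale_unit_variance <- function(table) {
  feats <- if (is.data.frame(table)) feature_columns(table) else colnames(table)
  X <- if (is.data.frame(table)) table[, feats, drop = FALSE] else table
  sds <- apply(as.matrix(X), 2, sd)
  if (any(sds == 0))
    vm_stop("parameter", "zero-variance feature: %s",
            paste(feats[sds == 0], collapse = ", "))
  scaled <- table
  if (is.data.frame(table)) {
    for (f in feats) scaled[[f]] <- table[[f]] / sds[[f]]
  } else {
    scaled <- sweep(table, 2, sds, "/")
  }
  list(scaled = scaled, scaler = sds)
}

#' @rdname scale_unit_variance
#' @param scaler the `scaler` element of a [scale_unit_variance] result.
#' @export
apply_scaler <- function(scaler, table) {
  if (is.data.frame(table)) {
    for (f in names(scaler)) table[[f]] <- table[[f]] / scaler[[f]]
    table
  } else {
    sweep(table, 2, scaler[colnames(table)], "/")
  }
}

#' Two-stage training schedule for the self-organizing map
#'
#' Stage 1 (ordering) uses a high learning rate and a wide neighborhood
#' for fast global organization; stage 2 (tuning) refines slowly with the
#' fixed small neighborhood. Learning rates decay linearly within each
#' stage (strictly decreasing per update step); the stage-2 neighborhood
#' radius is held at its stated value.
#'
#' @param ordering_epochs,ordering_alpha epochs and initial learning rate
#'   of the ordering stage (defaults 100 and 0.9).
#' @param tuning_epochs,tuning_alpha epochs and initial learning rate of
#'   the tuning stage (defaults 1000 and 0.5).
#' @param tuning_sigma tuning-stage neighborhood radius (default 0.5).
#' @param ordering_sigma initial ordering-stage radius; defaults to half
#'   the larger lattice dimension at training time.
#' @return A list of class `vm_som_schedule`.
#' @export
som_schedule <- function(ordering_epochs = 100L, ordering_alpha = 0.9,
                         tuning_epochs = 1000L, tuning_alpha = 0.5,
                         tuning_sigma = 0.5, ordering_sigma = NULL) {
  structure(list(ordering_epochs = as.integer(ordering_epochs),
                 ordering_alpha = ordering_alpha,
                 tuning_epochs = as.integer(tuning_epochs),
                 tuning_alpha = tuning_alpha,
                 tuning_sigma = tuning_sigma,
                 ordering_sigma = ordering_sigma),
            class = "vm_som_schedule")
}

#' Train a self-organizing map classifier
#'
#' Kohonen map on a rectangular lattice with the Gaussian neighborhood
#' `h_ci(t) = exp(-||r_i - r_c||^2 / (2 sigma(t)^2))` and the update
#' `m_i(t+1) = m_i(t) + alpha(t) h_ci(t) (x(t) - m_i(t))`, trained with the
#' two-stage schedule of [som_schedule]. After training each node is
#' labelled by the majority class of the training samples whose best
#' matching unit it is (ties to the earliest class level); unlabelled
#' nodes defer to the nearest labelled node in lattice distance at
#' prediction time.
#'
#' @param X numeric matrix of scaled features (subjects x features).
#' @param y class labels (factor or character).
#' @param grid_shape lattice rows x columns (default 6 x 6).
#' @param schedule a [som_schedule].
#' @param seed integer seed for weight initialization and presentation
#'   order.
#' @return An object of class `vm_som`.
#' @export
som_train <- function(X, y, grid_shape = c(6L, 6L),
                      schedule = som_schedule(), seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) vm_stop("parameter", "empty training set")
  y <- factor(y)
  if (nrow(X) != length(y)) vm_stop("parameter", "X rows and y lengths differ")
  d <- ncol(X)
  nodes <- prod(grid_shape)
  pos <- as.matrix(expand.grid(row = seq_len(grid_shape[1]),
                               col = seq_len(grid_shape[2])))
  sched <- schedule
  sigma0 <- sched$ordering_sigma %||% (max(grid_shape) / 2)

  rng_lo <- apply(X, 2, min); rng_hi <- apply(X, 2, max)
  state <- with_seed(seed, {
    W <- matrix(runif(nodes * d, rep(rng_lo, each = nodes),
                      rep(rng_hi, each = nodes)), nodes, d)
    stages <- list(
      list(epochs = sched$ordering_epochs, alpha0 = sched$ordering_alpha,
           sig0 = sigma0, sig1 = sched$tuning_sigma),
      list(epochs = sched$tuning_epochs, alpha0 = sched$tuning_alpha,
           sig0 = sched$tuning_sigma, sig1 = sched$tuning_sigma))
    alpha_trace <- list()
    n <- nrow(X)
    lat2 <- as.matrix(stats::dist(pos))^2
    for (si in seq_along(stages)) {
      st <- stages[[si]]
      S <- st$epochs * n
      step <- 0L
      atr <- numeric(S)
      for (ep in seq_len(st$epochs)) {
        ord <- sample.int(n)
        for (i in ord) {
          frac <- step / S
          alpha <- st$alpha0 * (1 - frac) + 0.001 * st$alpha0 * frac
          sigma <- st$sig0 * (1 - frac) + st$sig1 * frac
          xi <- X[i, ]
          dif <- W - matrix(xi, nodes, d, byrow = TRUE)
          bmu <- which.min(rowSums(dif^2))
          h <- exp(-lat2[, bmu] / (2 * sigma^2))
          W <- W - (alpha * h) * dif
          step <- step + 1L
          atr[step] <- alpha
        }
      }
      alpha_trace[[si]] <- atr
    }
    list(W = W, alpha_trace = alpha_trace)
  })
  model <- structure(list(weights = state$W, positions = pos,
                          grid_shape = as.integer(grid_shape),
                          classes = levels(y), schedule = sched,
                          alpha_trace = state$alpha_trace, seed = seed,
                          node_labels = rep(NA_character_, nodes)),
                     class = "vm_som")
  hits <- vapply(seq_len(nrow(X)), function(i) som_bmu(model, X[i, ]),
                 integer(1))
  for (nd in unique(hits)) {
    tab <- table(factor(y[hits == nd], levels = levels(y)))
    model$node_labels[nd] <- names(tab)[which.max(tab)]
  }
  if (all(is.na(model$node_labels)))
    vm_stop("parameter", "no node received a training label")
  model
}

#' @export
print.vm_som <- function(x, ...) {
  cat(sprintf("<vm_som> %d x %d lattice, %d features, classes: %s\n",
              x$grid_shape[1], x$grid_shape[2], ncol(x$weights),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @export
plot.vm_som <- function(x, ...) {
  lab <- factor(x$node_labels, levels = x$classes)
  graphics::image(seq_len(x$grid_shape[1]), seq_len(x$grid_shape[2]),
                  matrix(as.integer(lab), x$grid_shape[1], x$grid_shape[2]),
                  col = grDevices::hcl.colors(length(x$classes), "Set 2"),
                  xlab = "row", ylab = "col", main = "SOM node labels", ...)
  invisible(x)
}

#' Best matching unit of an input vector
#'
#' @param model a [som_train] result.
#' @param x numeric vector (same dimension as the training features).
#' @return 1-based node index of the weight vector with minimum Euclidean
#'   distance; ties resolve to the lowest index.
#' @export
som_bmu <- function(model, x) {
  if (length(x) != ncol(model$weights))
    vm_stop("parameter", "input dimension %d does not match the map (%d)",
            length(x), ncol(model$weights))
  d2 <- rowSums((model$weights - matrix(x, nrow(model$weights),
                                        ncol(model$weights), byrow = TRUE))^2)
  which.min(d2)
}

#' @export
predict.vm_som <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  labelled <- which(!is.na(object$node_labels))
  if (length(labelled) == 0L) vm_stop("parameter", "no labelled nodes")
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    bmu <- som_bmu(object, X[i, ])
    lab <- object$node_labels[bmu]
    if (is.na(lab)) {
      lat <- rowSums((object$positions[labelled, , drop = FALSE] -
                        matrix(object$positions[bmu, ], length(labelled), 2,
                               byrow = TRUE))^2)
      lab <- object$node_labels[labelled[which.min(lat)]]
    }
    out[i] <- lab
  }
  factor(out, levels = object$classes)
}

#' Quantization error of a map on a data set
#'
#' Mean Euclidean distance from each sample to its best matching unit.
#'
#' @param model a [som_train] result.
#' @param X feature matrix.
#' @return Mean BMU distance.
#' @export
som_quant_error <- function(model, X) {
  X <- as.matrix(X)
  mean(vapply(seq_len(nrow(X)), function(i) {
    bmu <- som_bmu(model, X[i, ])
    sqrt(sum((X[i, ] - model$weights[bmu, ])^2))
  }, numeric(1)))
}
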