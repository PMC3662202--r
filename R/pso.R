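#' Particle swarm optimization
#'
#' Maximizes a fitness function over a box by the inertia-weight particle
#' swarm update
#' `v <- w*v + c1*rand1*(pbest - x) + c2*rand2*(gbest - x); x <- x + v`,
#' with fresh uniform `rand1`, `rand2` drawn per particle, per dimension,
#' per iteration. Velocities are clamped to a fraction of each
#' dimension's range and positions to the bounds. The best-ever position
#' (gbest) is monotone nondecreasing in fitness; the search stops at
#' `max_iter` iterations or when gbest has not improved for `patience`
#' consecutive iterations.
#'
#' @param fitness function mapping a position vector to a scalar fitness
#'   (maximized; must be deterministic).
#' @param lower,upper finite bounds per dimension.
#' @param n_particles swarm size P (default 30; 20-40 is the effective
#'   range).
#' @param max_iter iteration cap (default 200).
#' @param c1,c2 personal and social learning factors (defaults 2 and 2).
#' @param w inertia weight (default 0.8).
#' @param patience iterations without gbest improvement before stopping
#'   (default 200).
#' @param vmax_frac velocity clamp as a fraction of each range (default
#'   0.2).
#' @param init optional matrix of positions to seed into the initial
#'   swarm (rows; e.g. a known default configuration).
#' @param seed integer seed.
#' @return A list of class `vm_pso`: `par` (best position), `value` (best
#'   fitness), `trace` (gbest fitness per iteration), `n_iter`.
#' @export
pso_optimize <- function(fitness, lower, upper, n_particles = 30L,
                         max_iter = 200L, c1 = 2, c2 = 2, w = 0.8,
                         patience = 200L, vmax_frac = 0.2, init = NULL,
                         seed = 1L) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper))) ||
      any(upper <= lower))
    vm_stop("parameter", "bounds must be finite with upper > lower")
  ndim <- length(lower)
  P <- as.integer(n_particles)
  rng <- upper - lower
  vmax <- vmax_frac * rng
  with_seed(seed, {
    X <- matrix(runif(P * ndim, rep(lower, each = P), rep(upper, each = P)),
                P, ndim)
    if (!is.null(init)) {
      init <- matrix(init, ncol = ndim)
      ni <- min(nrow(init), P)
      X[seq_len(ni), ] <- pmin(pmax(init[seq_len(ni), , drop = FALSE],
                                    rep(lower, each = ni)),
                               rep(upper, each = ni))
    }
    V <- matrix(0, P, ndim)
    f <- apply(X, 1, fitness)
    pbest <- X; pbest_f <- f
    gi <- which.max(pbest_f)
    gbest <- pbest[gi, ]; gbest_f <- pbest_f[gi]
    trace <- numeric(max_iter)
    stall <- 0L
    t <- 0L
    while (t < max_iter && stall < patience) {
      t <- t + 1L
      r1 <- matrix(runif(P * ndim), P, ndim)
      r2 <- matrix(runif(P * ndim), P, ndim)
      V <- w * V + c1 * r1 * (pbest - X) +
        c2 * r2 * (matrix(gbest, P, ndim, byrow = TRUE) - X)
      V <- pmin(pmax(V, matrix(-vmax, P, ndim, byrow = TRUE)),
                matrix(vmax, P, ndim, byrow = TRUE))
      X <- X + V
      X <- pmin(pmax(X, matrix(lower, P, ndim, byrow = TRUE)),
                matrix(upper, P, ndim, byrow = TRUE))
      f <- apply(X, 1, fitness)
      imp <- f > pbest_f
      pbest[imp, ] <- X[imp, , drop = FALSE]
      pbest_f[imp] <- f[imp]
      gi <- which.max(pbest_f)
      if (pbest_f[gi] > gbest_f) {
        gbest <- pbest[gi, ]; gbest_f <- pbest_f[gi]; stall <- 0L
      } else stall <- stall + 1L
      trace[t] <- gbest_f
    }
    structure(list(par = gbest, value = gbest_f, trace = trace[seq_len(t)],
                   n_iter = t),
              class = "vm_pso")
  })
}

#' @export
print.vm_pso <- function(x, ...) {
  cat(sprintf("<vm_pso> best fitness %.4g at (%s) after %d iterations\n",
              x$value, paste(sprintf("%.3f", x$par), collapse = ", "),
              x$n_iter))
  invisible(x)
}

# Stratified k-fold assignment, seeded; every fold keeps every class when
# class counts allow it.
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' PSO-tuned support vector machine
#'
#' Searches `(log2 C, log2 gamma)` with [pso_optimize]; the fitness of a
#' particle is the internal cross-validated accuracy (correct/total) of an
#' SVM trained at that particle's `(C, gamma)` on the training data only,
#' over a stratified fold split fixed once per search (so the fitness is
#' deterministic and no held-out subject ever enters it). The swarm is
#' seeded to include the conventional default `C = 1`,
#' `gamma = 1/n_features`, and the final model is retrained on all
#' training data at the best position found.
#'
#' @param X feature matrix.
#' @param y class labels.
#' @param n_folds internal cross-validation folds for the fitness
#'   (default 5).
#' @param log2C_range,log2gamma_range search bounds (defaults
#'   `c(-5, 15)` and `c(-15, 3)`).
#' @param n_particles,max_iter,c1,c2,w,patience passed to [pso_optimize]
#'   (study-setting defaults 30, 200, 2, 2, 0.8, 200).
#' @param seed integer seed.
#' @param svm_tol solver tolerance used inside the fitness (the final
#'   model is refit at 1e-6).
#' @return An object of class `vm_pso_svm`: the final `vm_svm` model, the
#'   selected `C` and `gamma`, the search result and the fold assignment.
#' @export
pso_svm_train <- function(X, y, n_folds = 5L,
                          log2C_range = c(-5, 15),
                          log2gamma_range = c(-15, 3),
                          n_particles = 30L, max_iter = 200L,
                          c1 = 2, c2 = 2, w = 0.8, patience = 200L,
                          seed = 1L, svm_tol = 1e-3) {
  X <- as.matrix(X)
  y <- factor(y)
  n_folds <- min(n_folds, min(table(y)))
  folds <- stratified_folds(y, n_folds, seed)
  fitness <- function(pos) {
    C <- 2^pos[1]; gamma <- 2^pos[2]
    correct <- 0L
    for (fd in seq_len(n_folds)) {
      tr <- folds != fd
      mod <- svm_train(X[tr, , drop = FALSE], droplevels(y[tr]), C = C,
                       gamma = gamma, tol = svm_tol)
      pred <- predict(mod, X[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    correct / length(y)
  }
  search <- pso_optimize(fitness,
                         lower = c(log2C_range[1], log2gamma_range[1]),
                         upper = c(log2C_range[2], log2gamma_range[2]),
                         n_particles = n_particles, max_iter = max_iter,
                         c1 = c1, c2 = c2, w = w, patience = patience,
                         init = matrix(c(0, log2(1 / ncol(X))), 1),
                         seed = seed)
  model <- svm_train(X, y, C = 2^search$par[1], gamma = 2^search$par[2],
                     tol = 1e-6)
  structure(list(model = model, C = 2^search$par[1],
                 gamma = 2^search$par[2], search = search,
                 folds = folds, seed = seed),
            class = "vm_pso_svm")
}

#' @export
print.vm_pso_svm <- function(x, ...) {
  cat(sprintf(
    "<vm_pso_svm> C=%.4g gamma=%.4g (internal CV accuracy %.3f, %d PSO iterations)\n",
    x$C, x$gamma, x$search$value, x$search$n_iter))
  invisible(x)
}

#' @export
predict.vm_pso_svm <- function(object, newdata, ...)
  predict(object$model, newdata, ...)
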