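test_that("identical samples give U1 = U2 = n^2/2, Z = 0, p = 1", {
  a <- c(3, 1, 4, 1, 5)
  r <- mann_whitney(a, a)
  expect_equal(r$u1, length(a)^2 / 2)
  expect_equal(r$u2, length(a)^2 / 2)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
})

test_that("fully separated samples reproduce the hand-ranked statistic", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_obt, 0)
  expect_equal(r$z, -4.5 / sqrt(9 * 7 / 12))
  expect_equal(r$z, -1.96396, tolerance = 1e-5)
  expect_equal(r$p, 2 * pnorm(r$z))
})

test_that("U agrees with the exhaustive pair count and the rank-sum identity
          holds, with and without ties", {
  set.seed(101)
  for (rep in 1:50) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    a <- sample(0:8, n1, replace = TRUE) + rnorm(n1, 0, 0.01 * (rep %% 2))
    b <- sample(0:8, n2, replace = TRUE)
    r <- mann_whitney(a, b)
    expect_equal(r$u1, brute_mw_u(a, b))
    expect_equal(r$u1 + r$u2, n1 * n2)
    expect_equal(r$u_obt, min(r$u1, r$u2))
    # symmetric in its arguments up to U1/U2 swap; p unchanged
    rs <- mann_whitney(b, a)
    expect_equal(rs$u1, r$u2)
    expect_equal(rs$p, r$p)
  }
})

test_that("the U statistic matches the reference implementation on
          tie-free data", {
  set.seed(7)
  a <- rnorm(15); b <- rnorm(12, 0.5)
  r <- mann_whitney(a, b)
  w <- suppressWarnings(stats::wilcox.test(a, b))
  expect_equal(r$u1, unname(w$statistic))
})

test_that("screening keeps a strongly shifted feature and culls noise near
          the nominal rate", {
  set.seed(202)
  reps <- 400
  kept_noise <- 0
  for (i in seq_len(reps %/% 20)) {
    tab <- data.frame(group = rep(c("NC", "AD"), each = 20))
    tab$signal <- rnorm(40) + ifelse(tab$group == "AD", 8, 0)
    for (j in 1:9) tab[[paste0("noise", j)]] <- rnorm(40)
    out <- filter_features(tab, c("NC", "AD"), alpha = 0.05)
    expect_true("signal" %in% names(out))
    kept_noise <- kept_noise + sum(grepl("noise", names(out)))
  }
  # E[kept noise per run] ~ 0.05 * 9 = 0.45; loose band over 20 runs
  expect_lt(kept_noise / (reps %/% 20), 2)
  # alpha = 1 keeps everything; identical groups keep nothing
  tab2 <- data.frame(group = rep(c("NC", "AD"), each = 5),
                     f1 = rep(1:5, 2), f2 = rep(2:6, 2))
  expect_equal(names(filter_features(tab2, c("NC", "AD"), alpha = 1.01)),
               names(tab2))
  expect_error(filter_features(tab2, c("NC", "AD"), alpha = 0.05),
               class = "vm_empty_selection_error")
})

test_that("the 95% retention rule reproduces the published component counts", {
  pr <- published_pca_proportions()
  expect_equal(retained_components(pr$volume), 2L)
  expect_equal(retained_components(pr$shape), 8L)
  expect_equal(retained_components(pr$volume_shape), 6L)
})

test_that("two perfectly correlated features collapse to one component", {
  set.seed(5)
  x <- rnorm(20)
  tab <- data.frame(group = "NC", a = x, b = 2 * x + 3)
  p <- pca_reduce(tab)
  expect_equal(p$n_retained, 1L)
  expect_equal(p$explained_proportion[1], 1, tolerance = 1e-12)
})

test_that("retained scores are centred with diagonal covariance equal to the
          eigenvalues", {
  set.seed(8)
  X <- matrix(rnorm(30 * 6), 30, 6) %*% matrix(rnorm(36), 6, 6)
  colnames(X) <- paste0("f", 1:6)
  p <- pca_reduce(X, variance_target = 0.95)
  expect_true(all(abs(colMeans(p$scores)) < 1e-10))
  cv <- cov(p$scores)
  expect_equal(cv, diag(p$eigenvalues[seq_len(p$n_retained)],
                        p$n_retained), tolerance = 1e-8,
               ignore_attr = TRUE)
  # held-out projection with stored standardization equals in-sample scores
  expect_equal(unname(predict(p, X[3, , drop = FALSE])),
               unname(p$scores[3, , drop = FALSE]), tolerance = 1e-10)
})

test_that("zero-variance features are rejected by name", {
  X <- cbind(f1 = rnorm(10), flat = rep(2, 10), f3 = rnorm(10))
  expect_error(pca_reduce(X), "flat", class = "vm_parameter_error")
  tab <- data.frame(group = "NC", f1 = rnorm(10), dead = 1)
  expect_error(scale_unit_variance(tab), "dead", class = "vm_parameter_error")
})

test_that("unit-variance scaling is reusable on held-out subjects", {
  set.seed(11)
  tab <- data.frame(group = rep("NC", 10), a = rnorm(10, sd = 2),
                    b = rnorm(10, sd = 7))
  sc <- scale_unit_variance(tab)
  expect_equal(apply(as.matrix(sc$scaled[, c("a", "b")]), 2, sd),
               c(a = 1, b = 1), tolerance = 1e-9)
  held <- data.frame(group = "NC", a = 3, b = -1)
  out <- apply_scaler(sc$scaler, held)
  expect_equal(out$a, 3 / sd(tab$a))
  expect_equal(out$b, -1 / sd(tab$b))
})
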