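test_that("normalization and centering follow the hand-worked example", {
  raw <- rbind(c(1, 2), c(3, 0))
  sm <- normalize_and_center(raw)
  expect_equal(sm$sup_norms, c(2, 3))
  expect_equal(sm$a_bar, c(0.75, 0.5))
  expect_equal(sm$A, rbind(c(-0.25, 0.5), c(0.25, -0.5)))
  # identical rows center to zero
  sm2 <- normalize_and_center(matrix(rep(c(1, -2, 3), 4), 4, byrow = TRUE))
  expect_equal(max(abs(sm2$A)), 0)
  # column sums of the output vanish for random input
  set.seed(1)
  sm3 <- normalize_and_center(matrix(rnorm(60), 6))
  expect_lt(max(abs(colSums(sm3$A))), 1e-12)
  expect_error(normalize_and_center(rbind(c(1, 1), c(0, 0))),
               "all-zero signal")
})

test_that("SMOTE interpolates within the minority class", {
  set.seed(4)
  X <- matrix(rnorm(7 * 50), 7)
  # balancing 7 healthy against 22 stenotic needs 15 synthetic rows -> M = 44
  syn <- smote_augment(X, 15, k_neighbors = 5, seed = 3)
  expect_equal(dim(syn), c(15, 50))
  expect_equal(nrow(X) + 15 + 22, 44)
  # deterministic given the seed
  expect_identical(syn, smote_augment(X, 15, k_neighbors = 5, seed = 3))
  expect_equal(nrow(smote_augment(X, 0)), 0)
  # two points, k = 1: every synthetic sample lies on the segment [p, q]
  p <- c(0, 0)
  q <- c(2, 1)
  syn2 <- smote_augment(rbind(p, q), 25, k_neighbors = 1, seed = 8)
  lam <- syn2[, 1] / 2
  expect_true(all(lam >= 0 & lam <= 1))
  expect_equal(syn2[, 2], lam * 1, tolerance = 1e-12)
  expect_error(smote_augment(X, -1), "n_new")
  expect_error(smote_augment(X, 5, k_neighbors = 10), "k_neighbors")
})

test_that("SVD basis reconstructs and satisfies Eckart-Young", {
  d3 <- svd_basis(diag(c(3, 2, 1)))
  expect_equal(d3$d, c(3, 2, 1))
  set.seed(6)
  A <- matrix(rnorm(8 * 20), 8)
  b <- svd_basis(A)
  # full-rank reconstruction
  A_full <- b$u %*% diag(b$d) %*% t(b$v)
  expect_lt(max(abs(A - A_full)), 1e-10 * max(abs(A)))
  # Eckart-Young: squared P-mode reconstruction error equals the tail sum
  # of squared singular values; oracle from eigendecomposition of A A^T
  ev <- sort(eigen(A %*% t(A), symmetric = TRUE)$values, decreasing = TRUE)
  for (P in c(1, 3, 5, 7)) {
    AP <- b$u[, 1:P] %*% diag(b$d[1:P], P) %*% t(b$v[, 1:P])
    expect_equal(sum((A - AP)^2), sum(ev[(P + 1):8]), tolerance = 1e-8)
  }
  # projection features
  W <- project_signals(A, b, 3)
  expect_equal(W, A %*% b$v[, 1:3])
  expect_error(project_signals(A, b, 99), "P exceeds")
})

test_that("cross-validation finds the informative mode count", {
  # classes separated along a single direction buried in noise dimensions
  set.seed(10)
  n <- 12
  u <- c(rep(-6, n), rep(6, n)) + rnorm(2 * n, sd = 0.3)
  dir1 <- rep(1 / sqrt(40), 40)
  raw <- outer(u, dir1) + matrix(rnorm(2 * n * 40, sd = 0.2), 2 * n)
  labels <- rep(c("healthy", "stenotic"), each = n)
  sm <- normalize_and_center(raw + 10) # positive offset so sup-norms differ
  sel <- select_num_modes_cv(sm, labels, P_grid = 1:6, folds = 4, seed = 1)
  expect_equal(sel$P_cv, 1)
  expect_equal(sel$P_train, sel$P_cv + 1L)
  # fold assignment and selection are deterministic given the seed
  sel2 <- select_num_modes_cv(sm, labels, P_grid = 1:6, folds = 4, seed = 1)
  expect_identical(sel, sel2)
  expect_error(select_num_modes_cv(sm, c("a", rep("b", 23)), folds = 4),
               "stratification")
})

test_that("LDA threshold rule reproduces the hand-worked 1-D examples", {
  # healthy {0,1}, stenotic {3,4}: threshold (1+3)/2 = 2
  f <- matrix(c(0, 1, 3, 4), 4)
  lab <- c("healthy", "healthy", "stenotic", "stenotic")
  m <- train_classifier(f, lab)
  expect_equal(abs(m$w), 1)
  expect_equal(m$threshold, 2)
  expect_equal(m$excluded, 0L)
  # healthy {0,1,3.5}, stenotic {3,4}: the overlapping pair (3.5, 3) is
  # excluded, threshold (1+4)/2 = 2.5
  f2 <- matrix(c(0, 1, 3.5, 3, 4), 5)
  lab2 <- c("healthy", "healthy", "healthy", "stenotic", "stenotic")
  m2 <- train_classifier(f2, lab2)
  expect_equal(m2$threshold, 2.5)
  expect_equal(m2$excluded, 2L)
})

test_that("LDA direction matches a brute-force Fisher criterion search", {
  set.seed(12)
  n <- 40
  mu0 <- c(0, 0)
  mu1 <- c(3, 1.5)
  S <- matrix(c(1, 0.6, 0.6, 1.2), 2)
  L <- chol(S)
  X0 <- matrix(rnorm(2 * n), n) %*% L
  X1 <- sweep(matrix(rnorm(2 * n), n) %*% L, 2, mu1, "+")
  X <- rbind(X0, X1)
  lab <- rep(c("healthy", "stenotic"), each = n)
  m <- train_classifier(X, lab)
  # oracle: maximize (w.(mu1-mu0))^2 / (w' Sw w) over a fine angular grid
  Sw <- crossprod(sweep(X0, 2, colMeans(X0))) +
    crossprod(sweep(X1, 2, colMeans(X1)))
  dm <- colMeans(X1) - colMeans(X0)
  th <- seq(0, pi, length.out = 360 * 20) # 0.05 degree grid
  J <- sapply(th, function(a) {
    w <- c(cos(a), sin(a))
    (sum(w * dm))^2 / drop(t(w) %*% Sw %*% w)
  })
  w_star <- c(cos(th[which.max(J)]), sin(th[which.max(J)]))
  ang <- acos(min(1, abs(sum(m$w * w_star)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("classification is consistent, scale invariant and guarded", {
  set.seed(13)
  raw <- rbind(matrix(rnorm(5 * 30, mean = 0), 5),
               matrix(rnorm(5 * 30, mean = 1.5), 5))
  # make rows strictly nonzero signals with distinct structure
  raw <- raw + outer(rep(c(0, 3), each = 5), sin(seq_len(30)))
  lab <- rep(c("healthy", "stenotic"), each = 5)
  pipe <- train_pipeline(raw, lab, P_train = 4)
  # training cases reproduce their stored projections and labels
  res <- classify_signal(raw, pipe)
  expect_equal(res$projection, unname(pipe$lda$projections))
  expect_true(all(res$label == ifelse(
    pipe$lda$projections > pipe$lda$threshold, "stenotic", "healthy")))
  # positive rescaling leaves the projection unchanged (sup-norm)
  r1 <- classify_signal(raw[1, ], pipe)
  r2 <- classify_signal(37.5 * raw[1, ], pipe)
  expect_equal(r1$projection, r2$projection, tolerance = 1e-12)
  expect_error(classify_signal(rep(0, 30), pipe), "all-zero")
  expect_error(classify_signal(rep(1, 10), pipe), "length")
})

test_that("energy ratio matches the explicit reconstruction oracle", {
  set.seed(14)
  A <- matrix(rnorm(10 * 40), 10)
  lab <- rep(c("healthy", "stenotic"), each = 5)
  b <- svd_basis(A)
  for (j in c(1, 3, 6)) {
    # oracle: reconstruct each case from mode j and take squared norms
    er_oracle <- {
      recon <- b$d[j] * outer(b$u[, j], b$v[, j])
      e <- rowSums(recon^2)
      mean(e[lab == "stenotic"]) / mean(e[lab == "healthy"])
    }
    expect_equal(energy_ratio(b, lab, j), er_oracle, tolerance = 1e-12)
  }
  # stenotic reconstructions with twice the healthy norm give ER = 4
  b2 <- list(d = c(2), u = matrix(c(1, 1, 2, 2) / sqrt(10), 4),
             v = matrix(1, 1))
  class(b2) <- "svd_basis"
  expect_equal(energy_ratio(b2, c("healthy", "healthy", "stenotic",
                                  "stenotic"), 1), 4)
  expect_error(energy_ratio(b, lab, 99), "exceeds")
})

test_that("mode importance ranks by absolute LDA weight", {
  m <- structure(list(w = c(0.1, -0.9, 0.3)), class = "lda_model")
  imp <- mode_importance(m)
  expect_equal(imp$mode, c(2, 3, 1))
  expect_equal(imp$weight, c(0.9, 0.3, 0.1))
  m2 <- structure(list(w = -c(0.1, -0.9, 0.3)), class = "lda_model")
  expect_equal(mode_importance(m2)$mode, imp$mode)
  # ties broken by ascending mode index
  m3 <- structure(list(w = c(0.5, -0.5, 0.2)), class = "lda_model")
  expect_equal(mode_importance(m3)$mode, c(1, 2, 3))
})
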