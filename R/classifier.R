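#' Normalize and center a matrix of raw signals
#'
#' Each row (one recorded signal) is divided by its sup-norm, then the
#' ensemble mean of the normalized rows is subtracted from every row. The
#' stored mean vector is reused to center new signals prospectively.
#'
#' @param raw M x N matrix of raw signals (rows = cases).
#' @return object of class `signal_matrix`: centered matrix `A`, ensemble
#'   mean `a_bar`, per-row sup-norms `sup_norms`.
#' @export
normalize_and_center <- function(raw) {
  raw <- as.matrix(raw)
  sn <- apply(abs(raw), 1, max)
  if (any(sn == 0)) {
    stop("normalization error: all-zero signal in row(s) ",
         paste(which(sn == 0), collapse = ", "))
  }
  Astar <- raw / sn
  a_bar <- colMeans(Astar)
  structure(list(A = sweep(Astar, 2, a_bar), a_bar = a_bar,
                 sup_norms = sn), class = "signal_matrix")
}

#' SMOTE augmentation of a minority class
#'
#' Synthesizes `n_new` minority-class signals by convex interpolation: each
#' synthetic sample is `x + lambda * (x_nn - x)` with `x` a uniformly drawn
#' minority sample, `x_nn` one of its `k` nearest neighbors (Euclidean) and
#' `lambda ~ Uniform(0, 1)`. Operates on raw (pre-normalization) signals.
#'
#' @param minority m x N matrix of minority-class raw signals (m >= 2).
#' @param n_new number of synthetic signals (>= 0).
#' @param k_neighbors neighborhood size (< m); default `min(5, m - 1)`.
#' @param seed RNG seed.
#' @return n_new x N matrix of synthetic signals.
#' @export
smote_augment <- function(minority, n_new, k_neighbors = NULL, seed = 0L) {
  minority <- as.matrix(minority)
  m <- nrow(minority)
  if (n_new < 0) stop("input error: n_new must be >= 0")
  if (n_new == 0) return(minority[0, , drop = FALSE])
  if (m < 2) stop("need at least 2 minority samples")
  k <- k_neighbors %||% min(5L, m - 1L)
  if (k >= m) stop("k_neighbors must be smaller than the minority count")
  D <- as.matrix(stats::dist(minority))
  diag(D) <- Inf
  nn <- matrix(apply(D, 1, function(d) order(d)[seq_len(k)]),
               nrow = m, ncol = k, byrow = TRUE)
  with_seed(seed, {
    out <- matrix(0, n_new, ncol(minority))
    for (j in seq_len(n_new)) {
      i <- sample.int(m, 1)
      q <- nn[i, sample.int(k, 1)]
      lam <- stats::runif(1)
      out[j, ] <- minority[i, ] + lam * (minority[q, ] - minority[i, ])
    }
    out
  })
}

#' Singular value decomposition basis of a signal matrix
#'
#' Thin SVD `A = U diag(d) V'` of the centered signal matrix, with
#' explained-variance ratios from the squared singular values.
#'
#' @param sm a [normalize_and_center()] result (or a plain centered matrix).
#' @return object of class `svd_basis`: `u`, `d`, `v`, `var_ratio`,
#'   `cum_var_ratio`.
#' @export
svd_basis <- function(sm) {
  A <- if (inherits(sm, "signal_matrix")) sm$A else as.matrix(sm)
  if (nrow(A) < 2) stop("need at least 2 rows")
  s <- svd(A)
  vr <- s$d^2 / sum(s$d^2)
  structure(list(u = s$u, d = s$d, v = s$v, var_ratio = vr,
                 cum_var_ratio = cumsum(vr)), class = "svd_basis")
}

#' Project signals onto the leading right singular vectors
#'
#' Feature extraction: `Omega = A V_P`, the coordinates of each (centered)
#' signal along the first `P` principal directions.
#'
#' @param sm a `signal_matrix` or centered matrix (rows = cases).
#' @param basis a [svd_basis()].
#' @param P retained mode count (`<= min(M, N)`).
#' @return M x P feature matrix.
#' @export
project_signals <- function(sm, basis, P) {
  A <- if (inherits(sm, "signal_matrix")) sm$A else as.matrix(sm)
  if (P > length(basis$d)) stop("input error: P exceeds available modes")
  A %*% basis$v[, seq_len(P), drop = FALSE]
}

# stratified fold assignment: each class is spread across folds
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < folds) {
        stop("stratification error: class '", cl,
             "' has fewer cases than folds")
      }
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

#' Select the PCA mode count by stratified cross-validation
#'
#' For each candidate `P`, estimates the validation accuracy of the
#' downstream Fisher LDA classifier by stratified k-fold cross-validation
#' (the SVD basis is recomputed on each training fold). Returns the smallest
#' `P` maximizing mean validation accuracy (`P_cv`), and the training mode
#' count `P_train = P_cv + 1`, one extra mode to absorb the variance the
#' validation folds add when they rejoin the development set.
#'
#' @param sm a `signal_matrix` (centered development set).
#' @param labels per-row class labels (two classes).
#' @param P_grid candidate mode counts; default `1:25`.
#' @param folds fold count; default 5.
#' @param seed RNG seed for fold assignment.
#' @return list with `P_cv`, `P_train`, `accuracy` (mean validation accuracy
#'   per grid point) and `P_grid`.
#' @export
select_num_modes_cv <- function(sm, labels, P_grid = 1:25, folds = 5,
                                seed = 0L) {
  A <- if (inherits(sm, "signal_matrix")) sm$A else as.matrix(sm)
  labels <- as.character(labels)
  fold_id <- stratified_folds(labels, folds, seed)
  P_grid <- P_grid[P_grid <= min(dim(A)) - ceiling(nrow(A) / folds)]
  acc <- matrix(NA_real_, folds, length(P_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    basis <- svd_basis(A[tr, , drop = FALSE])
    for (p in seq_along(P_grid)) {
      P <- P_grid[p]
      if (P > length(basis$d)) next
      ftr <- A[tr, , drop = FALSE] %*% basis$v[, 1:P, drop = FALSE]
      fva <- A[!tr, , drop = FALSE] %*% basis$v[, 1:P, drop = FALSE]
      model <- train_classifier(ftr, labels[tr])
      pred <- apply_lda(model, fva)
      acc[f, p] <- mean(pred$label == labels[!tr])
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  P_cv <- P_grid[which.max(mean_acc)] # which.max takes the smallest argmax
  list(P_cv = P_cv, P_train = P_cv + 1L, accuracy = mean_acc,
       P_grid = P_grid)
}

#' Train the Fisher linear discriminant with midpoint threshold
#'
#' Two-class Fisher LDA: `w` proportional to `S_W^{-1} (mu_sten - mu_heal)`
#' with a small ridge term `eps * tr(S_W) / P * I` on the within-class
#' scatter (the feature count can exceed what the scatter supports), `w`
#' normalized to unit length and oriented so the stenotic class projects
#' higher. The discrimination threshold is the mean of the largest healthy
#' projection and the smallest stenotic projection after iteratively
#' excluding overlapping extremes (while `max(healthy) >= min(stenotic)`,
#' drop that healthy maximum and that stenotic minimum).
#'
#' @param features M x P feature matrix.
#' @param labels per-row labels; the class lexically equal to `"stenotic"`
#'   (or the second factor level) is the positive class.
#' @param ridge ridge coefficient `eps`; default 1e-6.
#' @return object of class `lda_model`: `w`, `threshold`, `classes`,
#'   `projections` (training), `labels`, `excluded` (indices dropped by the
#'   overlap rule).
#' @export
train_classifier <- function(features, labels, ridge = 1e-6) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("need exactly two classes")
  # positive class: "stenotic" if present, else the second sorted class
  pos <- if ("stenotic" %in% cls) "stenotic" else cls[2]
  neg <- setdiff(cls, pos)
  if (sum(labels == pos) < 2 || sum(labels == neg) < 2) {
    stop("need at least 2 cases per class")
  }
  X1 <- X[labels == pos, , drop = FALSE]
  X0 <- X[labels == neg, , drop = FALSE]
  mu1 <- colMeans(X1)
  mu0 <- colMeans(X0)
  S <- crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X0, 2, mu0))
  P <- ncol(X)
  Sr <- S + diag(ridge * sum(diag(S)) / P + 1e-300, P)
  w <- solve(Sr, mu1 - mu0)
  w <- w / sqrt(sum(w^2))
  proj <- drop(X %*% w)
  if (mean(proj[labels == pos]) < mean(proj[labels == neg])) {
    w <- -w
    proj <- -proj
  }
  # overlap-excluding midpoint threshold: while the classes overlap, drop
  # the overlapping pair of extremes (healthy maximum and stenotic minimum)
  heal <- sort(proj[labels == neg])
  sten <- sort(proj[labels == pos])
  excluded <- 0L
  while (length(heal) > 0 && length(sten) > 0 &&
         max(heal) >= min(sten)) {
    heal <- heal[-length(heal)]
    sten <- sten[-1]
    excluded <- excluded + 2L
  }
  if (length(heal) == 0 || length(sten) == 0) {
    warning("overlap exclusion emptied a class; threshold falls back to ",
            "the midpoint of the class means")
    threshold <- (mean(proj[labels == pos]) + mean(proj[labels == neg])) / 2
  } else {
    threshold <- (max(heal) + min(sten)) / 2
  }
  structure(list(w = w, threshold = threshold,
                 classes = c(negative = neg, positive = pos),
                 projections = proj, labels = labels,
                 excluded = excluded),
            class = "lda_model")
}

# project features through a trained LDA and label them
apply_lda <- function(model, features) {
  proj <- drop(as.matrix(features) %*% model$w)
  label <- ifelse(proj > model$threshold,
                  model$classes[["positive"]], model$classes[["negative"]])
  list(projection = proj, label = label)
}

#' Train the full classification pipeline on raw signals
#'
#' Normalization/centering, SVD, cross-validated mode-count selection and
#' Fisher LDA in one object that can classify new raw signals.
#'
#' @param raw M x N matrix of raw (balanced) development signals.
#' @param labels per-row labels.
#' @param P_grid,folds,seed passed to [select_num_modes_cv()].
#' @param P_train optional fixed mode count (skips cross-validation).
#' @return object of class `murmur_pipeline`: `a_bar`, `basis`, `P_cv`,
#'   `P_train`, `lda`, `features`, `labels`.
#' @export
train_pipeline <- function(raw, labels, P_grid = 1:25, folds = 5,
                           seed = 0L, P_train = NULL) {
  sm <- normalize_and_center(raw)
  basis <- svd_basis(sm)
  if (is.null(P_train)) {
    sel <- select_num_modes_cv(sm, labels, P_grid, folds, seed)
    P_cv <- sel$P_cv
    P_train <- sel$P_train
  } else {
    P_cv <- NA_integer_
  }
  features <- project_signals(sm, basis, P_train)
  lda <- train_classifier(features, labels)
  structure(list(a_bar = sm$a_bar, basis = basis, P_cv = P_cv,
                 P_train = P_train, lda = lda, features = features,
                 labels = labels, sm = sm),
            class = "murmur_pipeline")
}

#' Classify a raw signal with a trained pipeline
#'
#' The signal is sup-norm normalized, centered with the stored development
#' ensemble mean, projected on the retained right singular vectors and then
#' on the LDA direction, and compared to the threshold.
#'
#' @param raw_signal numeric vector (length N) or M x N matrix of raw
#'   signals.
#' @param pipeline a [train_pipeline()] object.
#' @return data.frame with columns `projection` and `label`.
#' @export
classify_signal <- function(raw_signal, pipeline) {
  X <- if (is.null(dim(raw_signal))) matrix(raw_signal, 1) else
    as.matrix(raw_signal)
  if (ncol(X) != length(pipeline$a_bar)) {
    stop("input error: signal length does not match the pipeline")
  }
  sn <- apply(abs(X), 1, max)
  if (any(sn == 0)) {
    stop("normalization error: all-zero signal")
  }
  Xc <- sweep(X / sn, 2, pipeline$a_bar)
  feats <- Xc %*% pipeline$basis$v[, seq_len(pipeline$P_train), drop = FALSE]
  res <- apply_lda(pipeline$lda, feats)
  data.frame(projection = res$projection, label = res$label)
}

#' Single-mode class energy ratio
#'
#' Diagnostic for which PCA modes carry stenotic information: the ratio of
#' the mean squared vector-norm of the mode-`j` reconstruction
#' (`a'_i = d_j U_ij v_j`) over the stenotic class to that over the healthy
#' class. `ER_j > 1` means mode `j` is on average more energetic in stenotic
#' signals.
#'
#' @param basis a [svd_basis()] of the development signal matrix.
#' @param labels per-row labels ("healthy"/"stenotic" or two classes, the
#'   positive one as in [train_classifier()]).
#' @param j mode index.
#' @return scalar energy ratio (`Inf` with a warning if the healthy-class
#'   mode energy is exactly zero).
#' @export
energy_ratio <- function(basis, labels, j) {
  if (j > length(basis$d)) stop("j exceeds the retained modes")
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  pos <- if ("stenotic" %in% cls) "stenotic" else cls[2]
  # ||a'_{i,j}||^2 = (d_j U_ij)^2 since v_j is a unit vector
  e <- (basis$d[j] * basis$u[, j])^2
  num <- mean(e[labels == pos])
  den <- mean(e[labels != pos])
  if (den == 0) {
    warning("healthy-class mode energy is zero; returning Inf")
    return(Inf)
  }
  num / den
}

#' Rank PCA modes by LDA projection weight
#'
#' @param model an [train_classifier()] `lda_model`.
#' @return data.frame with `mode` and `weight` (`|w_p|`), sorted descending
#'   (ties broken by ascending mode index).
#' @export
mode_importance <- function(model) {
  w <- abs(model$w)
  ord <- order(-w, seq_along(w))
  data.frame(mode = ord, weight = w[ord])
}
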