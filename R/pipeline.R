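#' Default run configuration
#'
#' Nested configuration for the full pipeline. Every stochastic stage draws
#' its child seeds from the single `seed` via [child_seed()].
#'
#' @param seed master seed.
#' @param ... overrides of the default fields (partial nested lists are
#'   merged).
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 0L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    valve = list(alpha = 40, kappa = 10600, annulus_diameter = 0.023,
                 leaflet_length = 0.015, nodes_per_leaflet = 64,
                 mapping = list(kind = "linear", beta = 2)),
    medium = list(rho_s = 1000, lambda = 9e5 - 2 * 2500 / 3, mu = 2500,
                  eta = 1),
    sampling = list(fs = 10000, duration = 0.5, f_max = 1000),
    monitor = c(0, 0.08, 0.04),
    dataset = list(n_healthy = 7, n_stenotic = 22, n_panels = 180),
    smote = list(k_neighbors = 5),
    classifier = list(k_folds = 5, P_grid = 1:25),
    test_set = list(n_stenotic = 5, n_healthy = 5,
                    mult_range = c(1.8, 6))
  )
  over <- list(...)
  modifyList(cfg, over)
}

config_components <- function(cfg) {
  list(
    geometry = build_valve_geometry(cfg$valve$annulus_diameter,
                                    cfg$valve$leaflet_length,
                                    cfg$valve$nodes_per_leaflet),
    mapping = valve_mapping(cfg$valve$mapping$kind, cfg$valve$mapping$beta),
    params = valve_params(cfg$valve$alpha, cfg$valve$kappa),
    panels = build_canonical_aorta(n_panels = cfg$dataset$n_panels),
    medium = make_medium(cfg$medium$rho_s, cfg$medium$lambda,
                         cfg$medium$mu, cfg$medium$eta),
    monitor = monitor_point(cfg$monitor)
  )
}

#' Generate a prospective test set
#'
#' Mirrors the prospective evaluation protocol: `n_stenotic` new mildly
#' stenotic simulations (multipliers drawn uniformly from `mult_range`,
#' which avoids the development grid values) plus `n_healthy` additional
#' SMOTE-synthesized healthy signals interpolated from the development
#' healthy cases.
#'
#' @param dev a [generate_dataset()] result (development set).
#' @param cfg a [default_config()].
#' @param seed seed for this test set.
#' @return list with `signals`, `labels`, `manifest` (stenotic rows only).
#' @export
generate_test_set <- function(dev, cfg = default_config(), seed = 1L) {
  comp <- config_components(cfg)
  ns <- cfg$test_set$n_stenotic
  nh <- cfg$test_set$n_healthy
  mr <- cfg$test_set$mult_range
  fs <- cfg$sampling$fs
  N <- round(fs * cfg$sampling$duration)

  sig_s <- matrix(0, 0, N)
  manifest <- data.frame()
  if (ns > 0) {
    freqs <- (seq_len(N) - 1) * fs / N
    nbin <- max(which(freqs <= cfg$sampling$f_max &
                        seq_len(N) <= floor(N / 2) + 1))
    transfer <- acoustic_transfer(comp$panels, comp$monitor, comp$medium,
                                  2 * pi * freqs[2:nbin], 2L)
    for (s in seq_len(ns)) {
      cs <- child_seed(seed, 3L, s)
      mult <- with_seed(cs, stats::runif(1, mr[1], mr[2]))
      lab <- if (s %% 2 == 0) "rlm2" else "rlm1"
      scn <- hemodynamic_scenario(lab, multiplier = mult,
                                  sv_ml = c(60, 72)[1 + s %% 2], seed = cs)
      traj <- simulate_valve_cycle(scn, comp$geometry, comp$mapping,
                                   comp$params, fs = fs,
                                   duration = cfg$sampling$duration)
      src <- synthesize_panel_pressures(scn, traj, comp$panels, fs = fs)
      rec <- propagate(src, comp$monitor, comp$medium,
                       f_max = cfg$sampling$f_max, transfer = transfer)
      sig_s <- rbind(sig_s, rec$a)
      manifest <- rbind(manifest, data.frame(
        case = s, label = lab, multiplier = mult, sv_ml = scn$sv_ml,
        seed = cs))
    }
  }
  sig_h <- if (nh > 0) {
    smote_augment(dev$signals[dev$labels == "healthy", , drop = FALSE],
                  nh, k_neighbors = cfg$smote$k_neighbors,
                  seed = child_seed(seed, 4L))
  } else {
    matrix(0, 0, N)
  }
  list(signals = rbind(sig_s, sig_h),
       labels = c(rep("stenotic", ns), rep("healthy", nh)),
       manifest = manifest)
}

#' Run the full pipeline end to end
#'
#' Generates the development dataset, balances it with SMOTE, trains the
#' PCA + LDA classifier (with cross-validated mode-count selection), then
#' evaluates it prospectively on a freshly generated test set of mildly
#' stenotic simulations and synthesized healthy signals.
#'
#' @param cfg a [default_config()].
#' @return list of class `pipeline_report`: the `pipeline`, `dev`
#'   (development set with `signals`, `labels`, `manifest`), `test`
#'   (test set plus predicted labels/projections), `training_accuracy` and
#'   `test_accuracy` (percent), `confusion` (test-set table), `P_cv`,
#'   `P_train`, `top_modes` (top-5 LDA modes with energy ratios).
#' @export
run_end_to_end <- function(cfg = default_config()) {
  if (cfg$dataset$n_stenotic <= 0 || cfg$dataset$n_healthy <= 0) {
    stop("orchestration error: both classes must be represented ",
         "before training")
  }
  comp <- config_components(cfg)
  dev <- generate_dataset(
    n_healthy = cfg$dataset$n_healthy, n_stenotic = cfg$dataset$n_stenotic,
    fs = cfg$sampling$fs, duration = cfg$sampling$duration, seed = cfg$seed,
    geometry = comp$geometry, mapping = comp$mapping, params = comp$params,
    panels = comp$panels, medium = comp$medium, monitor = comp$monitor,
    f_max = cfg$sampling$f_max)

  # balance the development set
  n_h <- sum(dev$labels == "healthy")
  n_s <- sum(dev$labels == "stenotic")
  n_new <- max(0, n_s - n_h)
  synth <- smote_augment(dev$signals[dev$labels == "healthy", , drop = FALSE],
                         n_new, k_neighbors = cfg$smote$k_neighbors,
                         seed = child_seed(cfg$seed, 5L))
  bal_signals <- rbind(dev$signals, synth)
  bal_labels <- c(dev$labels, rep("healthy", n_new))

  pipeline <- train_pipeline(bal_signals, bal_labels,
                             P_grid = cfg$classifier$P_grid,
                             folds = cfg$classifier$k_folds,
                             seed = child_seed(cfg$seed, 6L))
  train_pred <- classify_signal(bal_signals, pipeline)
  training_accuracy <- 100 * mean(train_pred$label == bal_labels)

  test <- generate_test_set(dev, cfg, seed = child_seed(cfg$seed, 7L))
  test_pred <- classify_signal(test$signals, pipeline)
  test_accuracy <- 100 * mean(test_pred$label == test$labels)
  test$predicted <- test_pred$label
  test$projection <- test_pred$projection

  imp <- mode_importance(pipeline$lda)
  top <- utils::head(imp, 5)
  top$energy_ratio <- vapply(top$mode, function(j) {
    energy_ratio(pipeline$basis, bal_labels, j)
  }, 1)

  structure(list(
    pipeline = pipeline,
    dev = list(signals = bal_signals, labels = bal_labels,
               manifest = dev$manifest, M = nrow(bal_signals)),
    test = test,
    training_accuracy = training_accuracy,
    test_accuracy = test_accuracy,
    confusion = table(truth = test$labels, predicted = test_pred$label),
    P_cv = pipeline$P_cv, P_train = pipeline$P_train,
    top_modes = top
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Murmur classification pipeline report\n")
  cat(sprintf("  development cases: %d (balanced)\n", x$dev$M))
  cat(sprintf("  PCA modes: P_cv = %s, P_train = %d\n",
              x$P_cv, x$P_train))
  cat(sprintf("  training (retrospective) accuracy: %.1f%%\n",
              x$training_accuracy))
  cat(sprintf("  test (prospective) accuracy: %.1f%%\n", x$test_accuracy))
  cat("  top LDA modes (|w|, energy ratio):\n")
  for (i in seq_len(nrow(x$top_modes))) {
    cat(sprintf("    mode %2d  |w| = %.3f  ER = %.3f\n",
                x$top_modes$mode[i], x$top_modes$weight[i],
                x$top_modes$energy_ratio[i]))
  }
  invisible(x)
}
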