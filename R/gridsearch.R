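#' Two-stage grid search for gradient-boosting hyperparameters
#'
#' Replays the tuning protocol used to fix the gradient-boosting
#' defaults: stage 1 scans tree depth with the other hyperparameters at
#' their inherited values (500 estimators, learning rate 0.1, `sqrt`
#' features, 4 samples per leaf); stage 2 scans the full estimators x
#' learning-rate grid at the chosen depth.  Each grid point is scored by
#' the mean stratified k-fold cross-validation AUC on one balanced
#' dataset (the positives paired with a random unlabelled sample of size
#' `rho * |P|`).  Ties are broken toward fewer estimators, the
#' "performance plateaus" rule.
#'
#' @param x A preprocessed [feature_table()].
#' @param positives A [label_set()].
#' @param depth_grid Depths scanned in stage 1 (default `c(1, 2, 3, 5)`).
#' @param estimator_grid Estimator counts scanned in stage 2
#'   (default `c(10, 50, 100, 200, 300, 400, 500)`).
#' @param lr_grid Learning rates scanned in stage 2
#'   (default `c(0.001, 0.01, 0.1, 1)`).
#' @param config A [run_config()] providing k, rho and the seed.
#' @return A list of class `"gb_grid_search"`: `best` (a
#'   [classifier_spec()]), `stage1` and `stage2` AUC tables.
#' @export
grid_search_gb <- function(x, positives,
                           depth_grid = c(1L, 2L, 3L, 5L),
                           estimator_grid = c(10L, 50L, 100L, 200L, 300L,
                                              400L, 500L),
                           lr_grid = c(0.001, 0.01, 0.1, 1),
                           config = run_config()) {
  stopifnot(inherits(x, "feature_table"), inherits(positives, "label_set"),
            length(depth_grid) >= 1L, length(estimator_grid) >= 1L,
            length(lr_grid) >= 1L)
  set.seed(substream_seed(config$seed, "grid_search"))
  all_genes <- genes(x)
  P <- intersect(positives$genes, all_genes)
  U <- setdiff(all_genes, P)
  n_u <- min(length(U), max(config$k, round(config$rho * length(P))))
  part <- c(P, sample(U, n_u))
  y <- as.integer(part %in% P)
  V <- x$values[part, , drop = FALSE]
  fold <- .stratified_folds(y, config$k)
  fold_seeds <- sample.int(2147483646L, config$k)

  cv_auc <- function(spec) {
    fac <- classifier_factory(spec)
    aucs <- vapply(seq_len(config$k), function(f) {
      test <- fold == f
      model <- fac$fit(V[!test, , drop = FALSE], y[!test],
                       seed = fold_seeds[f])
      auc_score(fac$predict_probability(model, V[test, , drop = FALSE]),
                y[test])
    }, numeric(1))
    mean(aucs)
  }

  inherited <- list(n_estimators = 500L, learning_rate = 0.1)
  stage1 <- data.frame(max_depth = depth_grid, auc = NA_real_)
  for (i in seq_along(depth_grid)) {
    stage1$auc[i] <- cv_auc(classifier_spec(
      "gradient_boosting", max_depth = depth_grid[i],
      n_estimators = inherited$n_estimators,
      learning_rate = inherited$learning_rate))
  }
  best_depth <- depth_grid[which.max(stage1$auc)]

  stage2 <- expand.grid(n_estimators = sort(estimator_grid),
                        learning_rate = lr_grid)
  stage2$auc <- NA_real_
  for (i in seq_len(nrow(stage2))) {
    stage2$auc[i] <- cv_auc(classifier_spec(
      "gradient_boosting", max_depth = best_depth,
      n_estimators = stage2$n_estimators[i],
      learning_rate = stage2$learning_rate[i]))
  }
  # highest AUC; on ties prefer fewer estimators (rows already sorted by
  # n_estimators ascending within each learning rate)
  ord <- order(-stage2$auc, stage2$n_estimators)
  pick <- stage2[ord[1L], ]

  best <- classifier_spec("gradient_boosting",
                          max_depth = best_depth,
                          n_estimators = as.integer(pick$n_estimators),
                          learning_rate = pick$learning_rate)
  structure(list(best = best, best_depth = best_depth,
                 stage1 = stage1, stage2 = stage2),
            class = "gb_grid_search")
}

#' @export
print.gb_grid_search <- function(x, ...) {
  cat("gb_grid_search: stage 1 over", nrow(x$stage1), "depths, stage 2 over",
      nrow(x$stage2), "points\n")
  cat(sprintf("  chosen depth %d; best: %d estimators, learning rate %g (CV AUC %.4f)\n",
              x$best_depth, x$best$hyperparameters$n_estimators,
              x$best$hyperparameters$learning_rate, max(x$stage2$auc)))
  invisible(x)
}
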