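#' Fit the stochastic positive-unlabelled ensemble
#'
#' The core learner.  For each of `L` stochastic iterations, the
#' unlabelled genes U are shuffled and cut into balanced chunks of about
#' `rho * |P|` genes; every chunk is paired with the full positive set P
#' to form a balanced partition.  On each partition a stratified k-fold
#' cross-validation is run: the classifier is trained on the k-1 training
#' folds and predicts probabilities for the held-out fold, so every gene
#' in the partition receives exactly one out-of-bag (OOB) prediction per
#' partition.  The final druggability score of a gene is the plain mean
#' of all its logged OOB probabilities; unlabelled genes accrue exactly
#' `L` predictions, positives one per partition per iteration.
#'
#' @param x A preprocessed [feature_table()] (no missing cells).
#' @param positives A [label_set()]; must be a subset of the genes of
#'   `x` with at least `k` members.
#' @param config A [run_config()] carrying L, k, rho, seed and the
#'   classifier specification.
#' @return An object of class `"pu_ensemble"` with components
#'   \describe{
#'     \item{scores}{data.frame gene, score (mean OOB probability),
#'       n_oob, percentile, is_positive.}
#'     \item{oob_log}{data.frame of every OOB prediction: iteration,
#'       partition, fold, gene, prob, label.}
#'     \item{config, positives, n_partitions, call}{run metadata.}
#'   }
#' @examples
#' \donttest{
#' spec <- synth_spec(n_genes = 120, n_pos = 20, seed = 7)
#' labs <- gen_labels(spec)
#' ft <- preprocess_features(gen_feature_matrix(spec, labs))$table
#' fit <- pu_ensemble(ft, labs,
#'                    run_config(L = 2, k = 5, seed = 7,
#'                               classifier = classifier_spec("naive_bayes")))
#' summary(fit)
#' }
#' @export
pu_ensemble <- function(x, positives, config = run_config()) {
  stopifnot(inherits(x, "feature_table"), inherits(positives, "label_set"),
            inherits(config, "run_config"))
  if (anyNA(x$values))
    stop("feature table has missing cells; run preprocess_features() first")
  all_genes <- genes(x)
  P <- intersect(positives$genes, all_genes)
  if (length(P) < length(positives$genes))
    warning(length(positives$genes) - length(P),
            " positive gene(s) absent from the feature table; ignored")
  if (length(P) < config$k)
    stop("need at least k = ", config$k, " positive genes")
  U <- setdiff(all_genes, P)
  if (!length(U)) stop("no unlabelled genes")
  if (config$rho * length(P) < config$k)
    stop("rho * |P| < k: unlabelled folds would be degenerate")

  fac <- classifier_factory(config$classifier)
  V <- x$values
  set.seed(substream_seed(config$seed, "pu_engine"))

  log_rows <- vector("list", 0L)
  n_partitions <- 0L
  for (l in seq_len(config$L)) {
    chunks <- make_balanced_partitions(P, U, config$rho)
    for (ci in seq_along(chunks)) {
      n_partitions <- n_partitions + (l == 1L)
      part_genes <- c(P, chunks[[ci]])
      y <- as.integer(part_genes %in% P)
      fold <- .stratified_folds(y, config$k)
      for (f in seq_len(config$k)) {
        test <- fold == f
        ytr <- y[!test]
        if (length(unique(ytr)) < 2L)   # defensive; stratification prevents it
          stop("training fold with a single class")
        model <- fac$fit(V[part_genes[!test], , drop = FALSE], ytr,
                         seed = sample.int(2147483646L, 1L))
        prob <- fac$predict_probability(
          model, V[part_genes[test], , drop = FALSE])
        if (any(prob < 0 | prob > 1))
          stop("classifier emitted probabilities outside [0, 1]")
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          iteration = l, partition = ci, fold = f,
          gene = part_genes[test], prob = prob, label = y[test],
          stringsAsFactors = FALSE)
      }
    }
  }
  oob_log <- do.call(rbind, log_rows)
  rownames(oob_log) <- NULL

  mean_by_gene <- tapply(oob_log$prob, oob_log$gene, mean)
  n_by_gene <- tapply(oob_log$prob, oob_log$gene, length)
  scores <- data.frame(gene = all_genes,
                       score = as.numeric(mean_by_gene[all_genes]),
                       n_oob = as.integer(n_by_gene[all_genes]),
                       stringsAsFactors = FALSE)
  scores <- percentile_rank(scores)
  scores$is_positive <- scores$gene %in% P

  structure(list(scores = scores, oob_log = oob_log, config = config,
                 positives = label_set(P, positives$name),
                 n_partitions = n_partitions, call = match.call()),
            class = "pu_ensemble")
}

#' Cut the unlabelled set into balanced chunks
#'
#' Shuffles U (using the current RNG state) and cuts it into consecutive
#' chunks of about `rho * |P|` genes.  A final chunk smaller than half
#' the nominal size is merged into the previous one, so every chunk
#' supports non-degenerate folds while the chunks remain pairwise
#' disjoint and cover U.
#'
#' @param P Character vector of positive genes (paired with every chunk).
#' @param U Character vector of unlabelled genes.
#' @param rho Balancing ratio (chunk size ~ rho * |P|).
#' @return List of character vectors (the unlabelled chunks).
#' @export
make_balanced_partitions <- function(P, U, rho) {
  stopifnot(length(P) >= 1L, length(U) >= 1L, rho > 0)
  target <- max(1L, as.integer(round(rho * length(P))))
  shuffled <- sample(U)
  id <- ceiling(seq_along(shuffled) / target)
  chunks <- split(shuffled, id)
  names(chunks) <- NULL
  n <- length(chunks)
  if (n > 1L && length(chunks[[n]]) < target / 2) {
    chunks[[n - 1L]] <- c(chunks[[n - 1L]], chunks[[n]])
    chunks[[n]] <- NULL
  }
  chunks
}

# Stratified fold assignment: within each class, fold labels 1..k are
# dealt out evenly and shuffled, so every fold holds both classes
# whenever each class has >= k members is not required -- only >= 1 per
# fold for the majority class and near-even positives.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Percentile-rank scores
#'
#' Adds a `percentile` column: `100 * rank / n` with average ranks for
#' ties (ascending, so the top-scoring gene gets 100 and equal scores
#' share a percentile).
#'
#' @param scores data.frame with a `score` column.
#' @return The data.frame with `percentile` added; monotone in score.
#' @export
percentile_rank <- function(scores) {
  stopifnot(is.data.frame(scores), "score" %in% colnames(scores),
            !anyNA(scores$score))
  scores$percentile <- 100 * rank(scores$score, ties.method = "average") /
    nrow(scores)
  scores
}

#' @export
print.pu_ensemble <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "pu_ensemble: %d genes (%d positive '%s'), %s classifier\n",
    nrow(x$scores), length(x$positives), x$positives$name,
    cfg$classifier$name))
  cat(sprintf("  L=%d iterations, k=%d folds, rho=%g, %d partitions/iter, seed=%d\n",
              cfg$L, cfg$k, cfg$rho, x$n_partitions, cfg$seed))
  top <- utils::head(x$scores[order(-x$scores$score), c("gene", "score")], 5)
  cat("  top genes:",
      paste(sprintf("%s (%.3f)", top$gene, top$score), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.pu_ensemble <- function(object, ...) {
  s <- object$scores
  pos <- s$score[s$is_positive]
  unl <- s$score[!s$is_positive]
  out <- list(
    n_genes = nrow(s), n_positive = length(pos),
    classifier = object$config$classifier$name,
    auc_pos_vs_unlabelled = auc_score(s$score, s$is_positive),
    score_quantiles = rbind(
      positive = stats::quantile(pos, c(.05, .25, .5, .75, .95)),
      unlabelled = stats::quantile(unl, c(.05, .25, .5, .75, .95))),
    oob_predictions = sum(s$n_oob))
  class(out) <- "summary.pu_ensemble"
  out
}

#' @export
print.summary.pu_ensemble <- function(x, ...) {
  cat(sprintf("pu_ensemble fit: %d genes, %d positives, classifier %s\n",
              x$n_genes, x$n_positive, x$classifier))
  cat(sprintf("  OOB AUC (positives vs unlabelled): %.4f\n",
              x$auc_pos_vs_unlabelled))
  cat(sprintf("  total OOB predictions: %d\n", x$oob_predictions))
  cat("  score quantiles:\n")
  print(round(x$score_quantiles, 4))
  invisible(x)
}

#' @export
as.data.frame.pu_ensemble <- function(x, ...) x$scores

#' Plot the fitted score distributions
#'
#' Overlaid densities of the druggability scores of positive and
#' unlabelled genes -- the visual counterpart of the OOB AUC.
#'
#' @param x A `pu_ensemble` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pu_ensemble <- function(x, ...) {
  s <- x$scores
  d_pos <- stats::density(s$score[s$is_positive], from = 0, to = 1)
  d_unl <- stats::density(s$score[!s$is_positive], from = 0, to = 1)
  ylim <- range(0, d_pos$y, d_unl$y)
  graphics::plot(d_unl, col = "grey40", lwd = 2, ylim = ylim,
                 xlab = "druggability score", main = "OOB score densities",
                 ...)
  graphics::lines(d_pos, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("positive", "unlabelled"),
                   col = c("firebrick", "grey40"), lwd = 2, bty = "n")
  invisible(x)
}
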