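#' Automated feature pre-processing
#'
#' The fixed pre-processing pipeline applied to a raw feature table
#' before learning: sparsity filtering, correlation pruning, class-aware
#' imputation and standardisation, in that order.  The gene set is never
#' altered; only columns change, and the returned report accounts for
#' every column added or removed.
#'
#' @param x A [feature_table()].
#' @param correlation_threshold Pairwise Pearson |r| above which one of a
#'   feature pair is dropped (strict `>`; default 0.8).
#' @param missing_data_thres Maximum missing fraction per feature
#'   (default 0.99, i.e. a feature is kept as long as at least 1% of its
#'   cells are observed).
#' @return A list with components `table` (the processed
#'   [feature_table()]) and `report` (a `preprocess_report`).
#' @seealso [drop_sparse()], [prune_correlated()], [impute_missing()],
#'   [standardize_features()]
#' @export
preprocess_features <- function(x, correlation_threshold = 0.8,
                                missing_data_thres = 0.99) {
  s1 <- drop_sparse(x, missing_data_thres)
  s2 <- prune_correlated(s1$table, correlation_threshold)
  s3 <- impute_missing(s2$table)
  s4 <- standardize_features(s3$table)
  report <- structure(list(
    dropped_sparse = s1$report$dropped_sparse,
    dropped_correlated = s2$report$dropped_correlated,
    imputed = s3$report$imputed,
    standardized = s4$report$standardized
  ), class = "preprocess_report")
  list(table = s4$table, report = report)
}

.empty_report <- function() {
  structure(list(
    dropped_sparse = data.frame(feature = character(),
                                missing_fraction = numeric()),
    dropped_correlated = data.frame(kept = character(),
                                    dropped = character(), r = numeric()),
    imputed = data.frame(feature = character(), policy = character(),
                         fill_value = numeric()),
    standardized = data.frame(feature = character(), mean = numeric(),
                              sd = numeric())
  ), class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess_report:\n")
  cat("  dropped (sparse):    ", nrow(x$dropped_sparse), "\n")
  cat("  dropped (correlated):", nrow(x$dropped_correlated), "\n")
  cat("  imputed features:    ", nrow(x$imputed), "\n")
  cat("  standardized:        ", nrow(x$standardized), "\n")
  invisible(x)
}

#' Drop features with too much missing data
#'
#' A feature survives when its missing fraction does not exceed
#' `missing_data_thres`; at the default 0.99 even very sparse features
#' with at least 1% observed cells are retained.
#'
#' @inheritParams preprocess_features
#' @return list(table, report).
#' @export
drop_sparse <- function(x, missing_data_thres = 0.99) {
  stopifnot(inherits(x, "feature_table"),
            missing_data_thres > 0, missing_data_thres <= 1)
  frac <- colMeans(is.na(x$values))
  drop <- frac > missing_data_thres
  report <- .empty_report()
  report$dropped_sparse <- data.frame(
    feature = features(x)[drop],
    missing_fraction = unname(frac[drop]))
  keep <- features(x)[!drop]
  tab <- if (length(keep)) select_features(x, keep) else
    feature_table(x$values[, 0, drop = FALSE], NULL)
  list(table = tab, report = report)
}

#' Prune highly correlated feature pairs
#'
#' Pairwise Pearson correlations are computed on cells where both
#' features are observed.  For every pair with |r| strictly above the
#' threshold exactly one member is dropped; features are visited in
#' column order and the earlier column is kept, so the result is
#' deterministic.  Pairs with fewer than 3 jointly observed cells are
#' not tested (both features retained).
#'
#' @inheritParams preprocess_features
#' @return list(table, report).
#' @export
prune_correlated <- function(x, correlation_threshold = 0.8) {
  stopifnot(inherits(x, "feature_table"),
            correlation_threshold > 0, correlation_threshold <= 1)
  v <- x$values
  p <- ncol(v)
  report <- .empty_report()
  if (p < 2L) return(list(table = x, report = report))

  obs <- !is.na(v)
  n_joint <- crossprod(obs)                       # jointly observed counts
  cc <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  cc[n_joint < 3L] <- NA                          # untestable pairs
  diag(cc) <- NA

  dropped <- logical(p)
  rec <- list()
  for (j in seq_len(p - 1L)) {
    if (dropped[j]) next
    for (k in seq.int(j + 1L, p)) {
      if (dropped[k]) next
      r <- cc[j, k]
      if (!is.na(r) && abs(r) > correlation_threshold) {
        dropped[k] <- TRUE
        rec[[length(rec) + 1L]] <- data.frame(
          kept = features(x)[j], dropped = features(x)[k], r = r)
      }
    }
  }
  if (length(rec)) report$dropped_correlated <- do.call(rbind, rec)
  keep <- features(x)[!dropped]
  list(table = select_features(x, keep), report = report)
}

#' Impute missing cells by feature class
#'
#' `binary_flag`, `subset_signal` and `network` features are filled with
#' zero (absence of evidence); `continuous_global` features are filled
#' with the feature's median over observed cells.
#'
#' @inheritParams preprocess_features
#' @return list(table, report).
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  v <- x$values
  report <- .empty_report()
  rec <- list()
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    cls <- x$feature_class[[colnames(v)[j]]]
    if (cls == "continuous_global") {
      obs <- v[!miss, j]
      if (!length(obs))
        stop("continuous feature '", colnames(v)[j],
             "' has no observed cells; drop_sparse should have removed it")
      fill <- stats::median(obs)
      policy <- "median"
    } else {
      fill <- 0
      policy <- "zero"
    }
    v[miss, j] <- fill
    rec[[length(rec) + 1L]] <- data.frame(
      feature = colnames(v)[j], policy = policy, fill_value = fill)
  }
  if (length(rec)) report$imputed <- do.call(rbind, rec)
  list(table = feature_table(v, x$feature_class), report = report)
}

#' Standardise features to zero mean and unit variance
#'
#' Uses the sample standard deviation (n - 1 denominator).  Constant
#' features are mapped to all-zeros rather than dropped, so downstream
#' column bookkeeping stays aligned; classifiers treat them as
#' uninformative.
#'
#' @inheritParams preprocess_features
#' @return list(table, report).
#' @export
standardize_features <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  v <- x$values
  if (anyNA(v)) stop("standardize_features requires a fully imputed table")
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  report <- .empty_report()
  report$standardized <- data.frame(feature = colnames(v),
                                    mean = unname(mu), sd = unname(sdv))
  for (j in seq_len(ncol(v))) {
    v[, j] <- if (sdv[j] > 0) (v[, j] - mu[j]) / sdv[j] else 0
  }
  list(table = feature_table(v, x$feature_class), report = report)
}
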