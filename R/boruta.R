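#' Boruta shadow-feature selection
#'
#' Iterative all-relevant feature selection against a permutation null.
#' Each of the `R` iterations: (1) shadow features -- independent
#' per-column permutations of the originals -- are appended to the
#' design; (2) a random forest is fit on the combined matrix and
#' impurity importances are computed; (3) the most important shadow
#' feature sets the bar s'; (4) every original feature whose importance
#' strictly exceeds s' scores a hit.  After `R` iterations the hit count
#' of each feature is compared with Binomial(R, 1/2) quantiles:
#' Confirmed above the 95th-percentile bound, Rejected below the
#' 5th-percentile bound, Tentative in between.
#'
#' All features stay in play for all `R` iterations and are classified
#' once at the end (no mid-run elimination); the terminal binomial rule
#' is the quantitative decision criterion.
#'
#' @param x A preprocessed [feature_table()] or numeric matrix.
#' @param y Binary labels (0/1 or logical), one per gene/row.
#' @param R Number of iterations (>= 10).
#' @param num_trees Trees per random forest (default 100).
#' @param seed RNG seed.
#' @return An object of class `"boruta_result"`: data.frame `decision`
#'   (feature, hits, status, mean_importance, z), the per-iteration
#'   `importance` matrix (features x R), `shadow_max` and `shadow_mean`
#'   per iteration, and `R`.
#' @export
boruta_select <- function(x, y, R = 40L, num_trees = 100L, seed = 1L) {
  X <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (!ncol(X)) stop("zero features")
  if (anyNA(X)) stop("missing cells; preprocess first")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L)
    stop("`y` must be binary with both classes present")
  stopifnot(length(y) == nrow(X))
  R <- as.integer(R)
  if (R < 10L) stop("R must be at least 10")

  p <- ncol(X)
  feat <- colnames(X)
  if (is.null(feat)) feat <- paste0("f", seq_len(p))
  set.seed(substream_seed(seed, "boruta"))

  hits <- integer(p)
  imp_mat <- matrix(NA_real_, p, R, dimnames = list(feat, NULL))
  shadow_max <- shadow_mean <- numeric(R)
  for (t in seq_len(R)) {
    shadows <- apply(X, 2L, sample)
    colnames(shadows) <- paste0(".shadow_", seq_len(p))
    design <- cbind(X, shadows)
    colnames(design) <- c(feat, colnames(shadows))
    rf <- ranger::ranger(x = design, y = factor(y, levels = c(0, 1)),
                         num.trees = num_trees, importance = "impurity",
                         seed = sample.int(2147483646L, 1L),
                         num.threads = 1)
    imp <- rf$variable.importance
    orig <- imp[seq_len(p)]
    shad <- imp[p + seq_len(p)]
    shadow_max[t] <- max(shad)
    shadow_mean[t] <- mean(shad)
    hits <- hits + (orig > shadow_max[t])
    imp_mat[, t] <- orig
  }

  status <- boruta_status(hits, R)
  mean_imp <- rowMeans(imp_mat)
  sd_imp <- apply(imp_mat, 1L, stats::sd)
  z <- ifelse(sd_imp > 0, (mean_imp - mean(shadow_mean)) / sd_imp, Inf)
  decision <- data.frame(feature = feat, hits = hits, status = status,
                         mean_importance = unname(mean_imp),
                         z = unname(z), stringsAsFactors = FALSE)
  structure(list(decision = decision, importance = imp_mat,
                 shadow_max = shadow_max, shadow_mean = shadow_mean,
                 R = R),
            class = "boruta_result")
}

#' Classify hit counts against Binomial(R, 1/2) bounds
#'
#' Pure function of (hits, R): Confirmed iff hits exceed the smallest q
#' with `pbinom(q, R, 0.5) >= 0.95`; Rejected iff hits fall below the
#' largest q with `pbinom(q, R, 0.5) <= 0.05`; Tentative otherwise.
#'
#' @param hits Integer vector of hit counts in [0, R].
#' @param R Total iterations.
#' @return Character vector in {"Confirmed", "Tentative", "Rejected"}.
#' @export
boruta_status <- function(hits, R) {
  stopifnot(all(hits >= 0), all(hits <= R))
  qs <- 0:R
  cdf <- stats::pbinom(qs, R, 0.5)
  upper <- qs[which(cdf >= 0.95)[1L]]
  low_ok <- qs[cdf <= 0.05]
  lower <- if (length(low_ok)) max(low_ok) else -1L
  ifelse(hits > upper, "Confirmed",
         ifelse(hits < lower, "Rejected", "Tentative"))
}

#' Rank features by importance Z-score
#'
#' For each feature, `z = (mean importance - mean shadow importance) /
#' sd(importance across iterations)`; features with zero importance
#' variance get `+Inf` and rank first.  Ranking is descending in z.
#'
#' @param result A [boruta_select()] result.
#' @return data.frame feature, z, status, ordered by decreasing z.
#' @export
importance_zscores <- function(result) {
  stopifnot(inherits(result, "boruta_result"))
  d <- result$decision
  d[order(-d$z, d$feature), c("feature", "z", "status")]
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$decision$status,
                      levels = c("Confirmed", "Tentative", "Rejected")))
  cat(sprintf("boruta_result: %d features over %d iterations\n",
              nrow(x$decision), x$R))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  conf <- x$decision[x$decision$status == "Confirmed", ]
  if (nrow(conf)) {
    conf <- conf[order(-conf$z), ]
    cat("  top confirmed:",
        paste(utils::head(conf$feature, 5), collapse = ", "), "\n")
  }
  invisible(x)
}
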