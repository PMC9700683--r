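#' Run configuration for the stochastic ensemble
#'
#' Collects every knob of the positive-unlabelled ensemble in one object
#' so a run is fully described by (config, inputs).  All randomness flows
#' from `seed` through named substreams per module, so any run is
#' bit-reproducible.
#'
#' @param L Number of stochastic iterations (positive integer).
#' @param k Number of cross-validation folds (>= 2).
#' @param rho Balancing ratio: size of each unlabelled chunk relative to
#'   the positive set (positive real).
#' @param seed Integer RNG seed for the whole run.
#' @param correlation_threshold Pearson |r| above which one of a feature
#'   pair is pruned (in (0, 1]).
#' @param missing_data_thres Maximum tolerated missing fraction per
#'   feature (in (0, 1]); features above it are dropped.
#' @param classifier A [classifier_spec()].
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(L = 10L, k = 10L, rho = 1.5, seed = 1L,
                       correlation_threshold = 0.8,
                       missing_data_thres = 0.99,
                       classifier = classifier_spec("gradient_boosting")) {
  L <- as.integer(L); k <- as.integer(k); seed <- as.integer(seed)
  stopifnot(L >= 1L, k >= 2L, rho > 0,
            correlation_threshold > 0, correlation_threshold <= 1,
            missing_data_thres > 0, missing_data_thres <= 1,
            inherits(classifier, "classifier_spec"))
  structure(list(L = L, k = k, rho = rho, seed = seed,
                 correlation_threshold = correlation_threshold,
                 missing_data_thres = missing_data_thres,
                 classifier = classifier),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run_config: L=%d, k=%d, rho=%g, seed=%d, cor>%g pruned, miss<=%g kept\n",
    x$L, x$k, x$rho, x$seed, x$correlation_threshold,
    x$missing_data_thres))
  cat("  classifier:", x$classifier$name, "\n")
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments; the classifier is
#' given as `classifier: <name>` plus an optional `hyperparameters:` map.
#' Unknown keys are an error so typos do not silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("L", "k", "rho", "seed", "correlation_threshold",
             "missing_data_thres", "classifier", "hyperparameters")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults <- formals(run_config)
  args <- raw[intersect(names(raw), names(defaults))]
  if (!is.null(raw$classifier)) {
    hp <- raw$hyperparameters
    args$classifier <- do.call(classifier_spec,
                               c(list(name = raw$classifier), hp))
  }
  do.call(run_config, args)
}

# Deterministic per-module seed derived from the run seed and a stream
# name; keeps every value below 2^31 so it is a valid R integer seed.
substream_seed <- function(seed, name) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer(((as.numeric(seed) %% m) * 48271 + h) %% m)
}
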