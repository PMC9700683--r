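#' Classifier specification
#'
#' Names one of the registered base classifiers and its hyperparameters.
#' The gradient-boosting defaults are the tuned values found by
#' two-stage grid search (depth first, then estimators x learning rate):
#' 200 estimators, learning rate 0.1, maximum depth 5, `sqrt`
#' column subsampling, minimum of 4 samples per leaf and 5 per split.
#'
#' @param name One of `"gradient_boosting"`, `"random_forest"`,
#'   `"extra_trees"`, `"svc"`, `"naive_bayes"`.
#' @param ... Hyperparameter overrides (name = value); unknown names are
#'   an error.
#' @return An object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(name = "gradient_boosting", ...) {
  reg <- .classifier_registry()
  if (!name %in% names(reg))
    stop("unknown classifier '", name, "'; registered: ",
         paste(names(reg), collapse = ", "))
  defaults <- reg[[name]]$defaults
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(bad, collapse = ", "))
  hp <- utils::modifyList(defaults, over)
  structure(list(name = name, hyperparameters = hp),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- vapply(x$hyperparameters, function(v) paste(format(v), collapse = ","),
               character(1))
  cat("classifier_spec:", x$name, "\n  ",
      paste(sprintf("%s=%s", names(hp), hp), collapse = ", "), "\n")
  invisible(x)
}

#' Registered classifier names
#' @return Character vector of names accepted by [classifier_spec()].
#' @export
registered_classifiers <- function() names(.classifier_registry())

# Registry: per classifier, hyperparameter defaults and a factory
# returning fit/predict_probability closures.  Every fit takes a seed so
# stochastic learners are reproducible from the run's RNG substreams;
# every predict_probability returns P(positive) in [0, 1].
.classifier_registry <- function() {
  list(
    gradient_boosting = list(
      defaults = list(n_estimators = 200L, learning_rate = 0.1,
                      max_depth = 5L, max_features = "sqrt",
                      min_samples_leaf = 4L, min_samples_split = 5L),
      factory = function(hp) {
        list(
          fit = function(X, y, seed = 1L) {
            p <- ncol(X)
            colsample <- if (identical(hp$max_features, "sqrt"))
              max(1, floor(sqrt(p))) / p else 1
            dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y),
                                           nthread = 1)
            params <- list(objective = "binary:logistic",
                           eta = hp$learning_rate,
                           max_depth = hp$max_depth,
                           colsample_bynode = colsample,
                           min_child_weight = hp$min_samples_leaf,
                           nthread = 1, seed = seed)
            xgboost::xgb.train(params = params, data = dtrain,
                               nrounds = hp$n_estimators, verbose = 0)
          },
          predict_probability = function(model, X) {
            as.numeric(stats::predict(
              model, xgboost::xgb.DMatrix(X, nthread = 1)))
          })
      }),
    random_forest = list(
      defaults = list(n_estimators = 100L, max_features = "sqrt",
                      min_samples_leaf = 4L),
      factory = function(hp) .ranger_factory(hp, splitrule = "gini")),
    extra_trees = list(
      defaults = list(n_estimators = 100L, max_features = "sqrt",
                      min_samples_leaf = 4L),
      factory = function(hp) .ranger_factory(hp, splitrule = "extratrees")),
    svc = list(
      defaults = list(cost = 1, gamma = "scale", kernel = "radial"),
      factory = function(hp) {
        list(
          fit = function(X, y, seed = 1L) {
            gamma <- if (identical(hp$gamma, "scale"))
              1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
            else hp$gamma
            set.seed(seed)   # probability calibration shuffles internally
            e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                       kernel = hp$kernel, cost = hp$cost, gamma = gamma,
                       probability = TRUE)
          },
          predict_probability = function(model, X) {
            pr <- attr(stats::predict(model, X, probability = TRUE),
                       "probabilities")
            as.numeric(pr[, "1"])
          })
      }),
    naive_bayes = list(
      defaults = list(laplace = 0),
      factory = function(hp) {
        list(
          fit = function(X, y, seed = 1L) {
            e1071::naiveBayes(as.data.frame(X),
                              factor(y, levels = c(0, 1)),
                              laplace = hp$laplace)
          },
          predict_probability = function(model, X) {
            pr <- stats::predict(model, as.data.frame(X), type = "raw")
            as.numeric(pr[, "1"])
          })
      })
  )
}

#' Build a trained-model factory from a specification
#'
#' @param spec A [classifier_spec()].
#' @return A list with closures `fit(X, y, seed)` (numeric matrix X,
#'   0/1 vector y) and `predict_probability(model, X)` returning
#'   P(positive) per row.
#' @export
classifier_factory <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  reg <- .classifier_registry()
  reg[[spec$name]]$factory(spec$hyperparameters)
}

.ranger_factory <- function(hp, splitrule) {
  list(
    fit = function(X, y, seed = 1L) {
      mtry <- if (identical(hp$max_features, "sqrt"))
        max(1L, floor(sqrt(ncol(X)))) else as.integer(hp$max_features)
      ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = hp$n_estimators,
                     mtry = mtry, min.node.size = hp$min_samples_leaf,
                     splitrule = splitrule, seed = seed, num.threads = 1)
    },
    predict_probability = function(model, X) {
      as.numeric(stats::predict(model, X,
                                num.threads = 1)$predictions[, "1"])
    })
}
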