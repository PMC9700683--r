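test_that("perfectly correlated pairs lose exactly one member", {
  set.seed(4)
  f1 <- rnorm(50)
  m <- cbind(f1 = f1, f2 = 2 * f1, f3 = rnorm(50))
  rownames(m) <- sprintf("g%02d", 1:50)
  out <- prune_correlated(feature_table(m), 0.8)
  expect_setequal(features(out$table), c("f1", "f3"))  # earlier column kept
  rep <- out$report$dropped_correlated
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$kept, "f1")
  expect_equal(rep$dropped, "f2")
  expect_equal(rep$r, 1.0, tolerance = 1e-12)
})

test_that("pruning matches a hand-rolled Pearson oracle", {
  # oracle: r = sum((x-mx)(y-my)) / sqrt(sum((x-mx)^2) sum((y-my)^2))
  pearson <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok] - mean(x[ok]); y <- y[ok] - mean(y[ok])
    sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  set.seed(11)
  n <- 200
  m <- cbind(u1 = runif(n), u2 = runif(n))
  rownames(m) <- sprintf("g%03d", 1:n)
  r <- pearson(m[, 1], m[, 2])
  expect_lt(abs(r), 0.8)
  out <- prune_correlated(feature_table(m), 0.8)
  expect_equal(ncol(out$table$values), 2L)  # both retained

  base <- rnorm(n)
  m2 <- cbind(a = base, b = base, c = rnorm(n))
  rownames(m2) <- rownames(m)
  expect_equal(pearson(m2[, "a"], m2[, "b"]), 1)
  out2 <- prune_correlated(feature_table(m2), 0.8)
  expect_equal(ncol(out2$table$values), 2L)
})

test_that("pairs with under 3 jointly observed cells are not tested", {
  m <- cbind(a = c(1, 2, NA, NA, NA), b = c(NA, NA, 1, 2, 3),
             c = c(1, 2, 3, 4, 5))
  rownames(m) <- paste0("g", 1:5)
  # a and b never jointly observed; a vs c has only 2 joint cells
  out <- prune_correlated(feature_table(m), 0.8)
  expect_true("a" %in% features(out$table))
  expect_true("b" %in% features(out$table))
})

test_that("sparsity filter keeps features with at least 1% observed", {
  n <- 200
  m <- cbind(all_missing = rep(NA_real_, n),
             one_pct = c(rnorm(2), rep(NA, n - 2)),   # exactly 1% observed
             half = c(rnorm(n / 2), rep(NA, n / 2)))
  rownames(m) <- sprintf("g%03d", 1:n)
  out <- drop_sparse(feature_table(m), 0.99)
  expect_setequal(features(out$table), c("one_pct", "half"))
  expect_equal(out$report$dropped_sparse$feature, "all_missing")
  expect_equal(out$report$dropped_sparse$missing_fraction, 1)
})

test_that("imputation follows the feature-class policy", {
  m <- cbind(cont = c(1, 2, NA, 4),
             flag = c(1, NA, 0, 1),
             net = c(NA, 0.5, NA, 0.25),
             sub = c(NA, 3, NA, 7))
  rownames(m) <- paste0("g", 1:4)
  ft <- feature_table(m, c(cont = "continuous_global", flag = "binary_flag",
                           net = "network", sub = "subset_signal"))
  out <- impute_missing(ft)
  v <- out$table$values
  expect_equal(v["g3", "cont"], 2)           # median of {1,2,4}
  expect_equal(v["g2", "flag"], 0)
  expect_equal(unname(v[c("g1", "g3"), "net"]), c(0, 0))
  expect_equal(unname(v[c("g1", "g3"), "sub"]), c(0, 0))
  expect_false(anyNA(v))
  imp <- out$report$imputed
  expect_equal(imp$policy[imp$feature == "cont"], "median")
  expect_equal(imp$fill_value[imp$feature == "cont"], 2)
  expect_equal(imp$policy[imp$feature == "flag"], "zero")
})

test_that("continuous feature with no observed cells is an error", {
  m <- cbind(gone = rep(NA_real_, 4), ok = 1:4)
  rownames(m) <- paste0("g", 1:4)
  expect_error(impute_missing(feature_table(m)), "no observed cells")
})

test_that("standardisation yields zero mean, unit sd; constants go to zero", {
  m <- cbind(bin = c(0, 0, 1, 1), const = rep(3, 4))
  rownames(m) <- paste0("g", 1:4)
  out <- standardize_features(feature_table(m))
  v <- out$table$values
  expect_equal(mean(v[, "bin"]), 0, tolerance = 1e-9)
  expect_equal(sd(v[, "bin"]), 1, tolerance = 1e-9)
  expect_equal(unname(v[, "const"]), rep(0, 4))

  set.seed(2)
  big <- toy_table(n = 1000, p = 1, seed = 2)
  out2 <- standardize_features(big)
  expect_equal(mean(out2$table$values), 0, tolerance = 1e-9)
  expect_equal(sd(out2$table$values), 1, tolerance = 1e-9)
  expect_equal(out2$report$standardized$mean, mean(big$values),
               tolerance = 1e-12)
  expect_equal(out2$report$standardized$sd, sd(big$values),
               tolerance = 1e-12)
})

test_that("the composed pipeline is idempotent and conserves genes/columns", {
  spec <- synth_spec(n_genes = 150, n_pos = 25, seed = 8, missing_frac = 0.2)
  labs <- gen_labels(spec)
  raw <- gen_feature_matrix(spec, labs)
  # plant a redundant and an all-missing column
  v <- cbind(raw$values, dup = 3 * raw$values[, 1] ,
             void = rep(NA_real_, nrow(raw$values)))
  v[is.na(raw$values[, 1]), "dup"] <- NA
  cls <- c(raw$feature_class, dup = "continuous_global",
           void = "continuous_global")
  ft <- feature_table(v, cls)

  out <- preprocess_features(ft)
  expect_identical(genes(out$table), genes(ft))         # gene set untouched
  expect_false(anyNA(out$table$values))

  # report accounts exactly for the column difference
  n_dropped <- nrow(out$report$dropped_sparse) +
    nrow(out$report$dropped_correlated)
  expect_equal(ncol(ft$values) - n_dropped, ncol(out$table$values))
  expect_true("void" %in% out$report$dropped_sparse$feature)
  expect_true("dup" %in% out$report$dropped_correlated$dropped ||
                "informative_01" %in% out$report$dropped_correlated$dropped)

  # idempotence on its own output
  again <- preprocess_features(out$table)
  expect_equal(again$table$values, out$table$values, tolerance = 1e-12)
  expect_equal(nrow(again$report$dropped_sparse), 0L)
  expect_equal(nrow(again$report$dropped_correlated), 0L)
  expect_equal(nrow(again$report$imputed), 0L)
})
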