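test_that("AUC equals the Mann-Whitney rank statistic", {
  expect_equal(auc_score(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_error(auc_score(1:4, rep(1, 4)), "both classes")
  set.seed(14)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    s <- rnorm(n)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) %in% c(0, n)) next
    u <- suppressWarnings(wilcox.test(s[y == 1], s[y == 0]))$statistic
    expect_equal(auc_score(s, y), unname(u) / (sum(y) * sum(!y)),
                 tolerance = 1e-12)
  }
  # independence -> AUC near 1/2
  set.seed(15)
  s <- rnorm(2000); y <- rbinom(2000, 1, 0.5)
  expect_lt(abs(auc_score(s, y) - 0.5), 0.03)
})

test_that("DeLong test: degenerate, symmetric, and consistent with AUC", {
  set.seed(16)
  y <- rbinom(120, 1, 0.4)
  a <- rnorm(120) + y
  expect_equal(delong_test(a, a, y)$p, 1.0)
  b <- rnorm(120) + 0.3 * y
  ab <- delong_test(a, b, y)
  ba <- delong_test(b, a, y)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$auc_a, ba$auc_b)
  expect_equal(ab$auc_a, auc_score(a, y), tolerance = 1e-12)
  expect_equal(ab$auc_b, auc_score(b, y), tolerance = 1e-12)
})

test_that("DeLong p agrees with the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:5) {
    n <- 150
    y <- rbinom(n, 1, 0.5)
    if (sum(y) %in% c(0, n)) next
    a <- rnorm(n) + 0.8 * y
    b <- rnorm(n) + 0.5 * y
    ours <- delong_test(a, b, y)
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                          pROC::roc(y, b, quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher 2x2 reproduces trivial and enumerated cases", {
  even <- fisher_2x2(1, 1, 1, 1)
  expect_equal(even$odds_ratio, 1.0)
  expect_equal(even$p, 1.0)
  expect_error(fisher_2x2(0, 0, 3, 4), "margin")
  # Haldane correction only when a zero cell is present
  z <- fisher_2x2(0, 10, 5, 5)
  expect_equal(z$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  # all tables with margins (5,5,5,5) against exhaustive enumeration
  for (a in 0:5) {
    got <- fisher_2x2(a, 5 - a, 5 - a, a)$p
    expect_equal(got, enum_fisher_p(a, 5 - a, 5 - a, a),
                 tolerance = 1e-12, label = paste("a =", a))
  }
  # and against stats::fisher.test on random tables
  set.seed(18)
  for (i in 1:10) {
    tb <- matrix(rpois(4, 8), 2)
    got <- fisher_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])$p
    expect_equal(got, fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher p is swap-invariant and the OR inverts on one swap", {
  f0 <- fisher_2x2(7, 2, 3, 9)
  both <- fisher_2x2(9, 3, 2, 7)    # rows and columns swapped
  expect_equal(both$p, f0$p, tolerance = 1e-12)
  expect_equal(both$odds_ratio, f0$odds_ratio, tolerance = 1e-12)
  one <- fisher_2x2(2, 7, 9, 3)     # columns swapped
  expect_equal(one$odds_ratio, 1 / f0$odds_ratio, tolerance = 1e-12)
})

test_that("rank intervals partition the universe and conserve evidence", {
  set.seed(19)
  universe <- sprintf("g%04d", 1:503)
  evidence <- sample(universe, 40)
  tab <- rank_interval_enrichment(universe, evidence, B = 20)
  expect_equal(nrow(tab), 20L)
  expect_equal(sum(tab$n_genes), 503L)
  expect_true(all(tab$n_genes %in% c(25L, 26L)))
  expect_equal(sum(tab$n_with_evidence), 40L)       # conservation
  expect_true(all(tab$odds_ratio >= 0))
  expect_error(rank_interval_enrichment(universe[1:10], evidence, 20),
               "more intervals|outside")
  expect_error(rank_interval_enrichment(universe, c("zzz"), 20), "outside")
})

test_that("evidence concentrated in the top interval maximises interval 1", {
  universe <- sprintf("g%03d", 1:200)
  evidence <- universe[1:10]        # exactly the first interval (B = 20)
  tab <- rank_interval_enrichment(universe, evidence, B = 20)
  expect_equal(tab$n_with_evidence[1], tab$n_genes[1])
  expect_true(all(tab$n_with_evidence[-1] == 0))
  expect_equal(which.max(tab$odds_ratio), 1L)
  cdf <- evidence_cdf(universe, evidence, B = 20)
  expect_equal(cdf, rep(1, 20))
})

test_that("uniform evidence gives near-null interval ORs and a linear CDF", {
  set.seed(20)
  universe <- sprintf("g%04d", 1:2000)
  med_or <- vapply(1:10, function(i) {
    ev <- sample(universe, 200)
    stats::median(rank_interval_enrichment(universe, ev, 20)$odds_ratio)
  }, numeric(1))
  expect_true(stats::median(med_or) > 0.7 && stats::median(med_or) < 1.4)
  ev <- sample(universe, 200)
  cdf <- evidence_cdf(universe, ev, 20)
  expect_true(all(diff(cdf) >= 0))
  expect_equal(cdf[20], 1)
  expect_lt(max(abs(cdf - (1:20) / 20)), 0.12)
  expect_error(evidence_cdf(universe, character(0)), "empty")
})

test_that("stepwise hypergeometric p matches brute-force tail sums", {
  # oracle: sum the hypergeometric pmf over the upper tail directly
  tail_sum <- function(x, K, N, k) {
    xs <- x:min(k, K)
    sum(choose(K, xs) * choose(N - K, k - xs) / choose(N, k))
  }
  set.seed(21)
  for (i in 1:10) {
    N <- sample(20:50, 1)
    universe <- paste0("g", 1:N)
    ref <- sample(universe, sample(3:10, 1))
    sw <- stepwise_hypergeom(universe, ref, step = 5)
    for (j in seq_len(nrow(sw$curve))) {
      k <- sw$curve$cutoff[j]
      x <- sw$curve$overlap[j]
      expect_equal(sw$curve$p[j], tail_sum(x, length(ref), N, k),
                   tolerance = 1e-10)
    }
    expect_true(all(sw$curve$p > 0 & sw$curve$p <= 1))
  }
})

test_that("a reference equal to the top-k genes minimises p at cutoff k", {
  universe <- paste0("g", 1:200)
  ref <- universe[1:30]
  sw <- stepwise_hypergeom(universe, ref, step = 10)
  expect_equal(sw$curve$cutoff[which.min(sw$curve$p)], 30L)
  expect_gt(sw$auc, 0)
})

test_that("stepwise AUC grows as the reference concentrates at the top", {
  universe <- paste0("g", 1:400)
  spread <- universe[seq(1, 400, by = 10)]          # 40 genes, uniform
  mid <- universe[1:80][seq(1, 80, by = 2)]         # 40 genes, top 20%
  top <- universe[1:40]                             # 40 genes, top 10%
  aucs <- vapply(list(spread, mid, top), function(r)
    stepwise_hypergeom(universe, r, step = 20)$auc, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("random references rarely produce an enriched region", {
  set.seed(22)
  null_auc <- vapply(1:20, function(i) {
    universe <- paste0("g", 1:1000)
    ref <- sample(universe, 50)
    stepwise_hypergeom(universe, ref, step = 50)$auc
  }, numeric(1))
  expect_gte(mean(null_auc == 0), 0.8)
})
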