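test_that("seed-overlap ratios match direct counts on small graphs", {
  # star: centre c with neighbours a,b,s1,s2; seeds = {s1, s2}
  g <- interaction_graph(rep("c", 4), c("a", "b", "s1", "s2"))
  seeds <- label_set(c("s1", "s2"))
  r1 <- seed_overlap_ratio(g, seeds, 1L)
  expect_equal(unname(r1["c"]), 0.5)
  expect_equal(unname(r1["a"]), 0)       # a's only neighbour is c

  # isolated gene scores 0 at both hops
  r1_iso <- seed_overlap_ratio(g, seeds, 1L, genes = c("c", "lonely"))
  expect_equal(unname(r1_iso["lonely"]), 0)
  r2_iso <- seed_overlap_ratio(g, seeds, 2L, genes = c("lonely"))
  expect_equal(unname(r2_iso["lonely"]), 0)

  # path a-b-c with seeds={c}: a has r1=0, r2=1
  path <- interaction_graph(c("a", "b"), c("b", "c"))
  sc <- label_set("c")
  expect_equal(unname(seed_overlap_ratio(path, sc, 1L)["a"]), 0)
  expect_equal(unname(seed_overlap_ratio(path, sc, 2L)["a"]), 1)
  # b is adjacent to the seed; distance-2 set of b is empty
  expect_equal(unname(seed_overlap_ratio(path, sc, 1L)["b"]), 0.5)
  expect_equal(unname(seed_overlap_ratio(path, sc, 2L)["b"]), 0)
})

test_that("a seed gene's own label does not leak into its ratio", {
  # s-a edge only; s is a seed with one non-seed neighbour
  g <- interaction_graph("s", "a")
  r1 <- seed_overlap_ratio(g, label_set("s"), 1L)
  expect_equal(unname(r1["s"]), 0)   # own membership not counted
  expect_equal(unname(r1["a"]), 1)
})

test_that("disjoint seed sets warn and give all-zero ratios", {
  g <- interaction_graph(c("a", "b"), c("b", "c"))
  expect_warning(r <- seed_overlap_ratio(g, label_set("zz"), 1L),
                 "disjoint")
  expect_true(all(r == 0))
})

test_that("harmonic mean combines hop ratios with zero-annihilation", {
  expect_equal(hmean_overlap(0.5, 0.5), 0.5)
  expect_equal(hmean_overlap(0, 0.9), 0)
  expect_equal(hmean_overlap(0.2, 0.8), 0.32)
  expect_equal(hmean_overlap(0, 0), 0)
  expect_error(hmean_overlap(1.2, 0.5))
})

test_that("ratios are invariant under gene relabelling", {
  fx <- random_graph_fixture(12, 0.3, seed = 21)
  seeds <- label_set(fx$nodes[1:3])
  r <- seed_overlap_ratio(fx$graph, seeds, 2L, genes = fx$nodes)

  perm <- setNames(sprintf("renamed_%02d", sample(12)), fx$nodes)
  g2 <- interaction_graph(perm[fx$graph$edges$from],
                          perm[fx$graph$edges$to])
  r2 <- seed_overlap_ratio(g2, label_set(perm[fx$nodes[1:3]]), 2L,
                           genes = unname(perm[fx$nodes]))
  expect_equal(unname(r2[perm[names(r)]]), unname(r))
})

test_that("adding a seed neighbour never decreases the 1-hop ratio", {
  set.seed(31)
  for (i in 1:20) {
    fx <- random_graph_fixture(10, 0.25, seed = 100 + i)
    seeds <- label_set(fx$nodes[sample(10, 3)])
    gene <- sample(setdiff(fx$nodes, seeds$genes), 1)
    r_before <- seed_overlap_ratio(fx$graph, seeds, 1L,
                                   genes = fx$nodes)[gene]
    g2 <- interaction_graph(c(fx$graph$edges$from, gene),
                            c(fx$graph$edges$to, "new_seed"))
    seeds2 <- label_set(c(seeds$genes, "new_seed"))
    r_after <- seed_overlap_ratio(g2, seeds2, 1L, genes = fx$nodes)[gene]
    expect_gte(r_after, r_before)
  }
})

test_that("overlap_features covers the universe per channel, no missing", {
  spec <- synth_spec(n_genes = 80, n_pos = 15, seed = 5)
  labs <- gen_labels(spec)
  g <- gen_ppi_graph(spec, labs)
  universe <- sprintf("G%05d", 1:80)
  ft <- overlap_features(g, labs, genes = universe)
  expect_identical(genes(ft), universe)
  expect_false(anyNA(ft$values))
  expect_true(all(ft$values >= 0 & ft$values <= 1))
  expect_equal(unname(ft$feature_class), rep("network", ncol(ft$values)))
  # one r1/r2/hmean triple per channel
  expect_equal(ncol(ft$values), 3L * length(graph_channels(g)))
  # hmean column equals the harmonic mean of its r1/r2 columns
  ch <- graph_channels(g)[1]
  expect_equal(
    unname(ft$values[, paste0(ch, "_seed_overlap_hmean")]),
    unname(hmean_overlap(ft$values[, paste0(ch, "_seed_overlap_1hop")],
                         ft$values[, paste0(ch, "_seed_overlap_2hop")])))
})

test_that("interaction-type featurisation keeps types above the percentile", {
  genes <- paste0("g", 1:6)
  counts <- cbind(t_a = c(2, 1, 1, 1, 0, 0),   # freq 5
                  t_b = c(1, 1, 1, 0, 0, 0),   # freq 3
                  t_c = c(1, 1, 0, 0, 0, 0),   # freq 2
                  t_d = c(1, 0, 0, 0, 0, 0))   # freq 1
  rownames(counts) <- genes
  ft <- featurize_interaction_types(counts, percentile = 50)
  # median of {5,3,2,1} = 2.5 -> t_a, t_b kept; plus other + unique
  expect_setequal(features(ft),
                  c("t_a", "t_b", "other_types", "unique_interactions"))
  expect_equal(unname(ft$values["g1", "other_types"]), 2)  # t_c + t_d
  expect_equal(unname(ft$values["g1", "unique_interactions"]), 4)
  expect_equal(unname(ft$values["g5", ]), rep(0, 4))  # all-zero gene

  single <- counts[, "t_a", drop = FALSE]
  ft1 <- featurize_interaction_types(single, 50)
  expect_true("t_a" %in% features(ft1))
  expect_true(all(ft1$values[, "other_types"] == 0))

  expect_error(featurize_interaction_types(counts[, 0, drop = FALSE]))
})

test_that("pathway featurisation flags large pathways, counts the rest", {
  genes <- paste0("g", 1:10)
  mem <- sapply(1:10, function(size) c(rep(1, size), rep(0, 10 - size)))
  dimnames(mem) <- list(genes, paste0("pw", 1:10))
  ft <- featurize_pathways(mem, percentile = 90)
  # 90th percentile of sizes 1..10 = 9.1 -> only the size-10 pathway
  expect_setequal(features(ft), c("pw10", "other_pathways"))
  expect_equal(unname(ft$feature_class["pw10"]), "binary_flag")
  expect_equal(unname(ft$values["g1", "other_pathways"]), 9)
  # a gene in no pathway: add one
  mem2 <- rbind(mem, g_none = 0)
  ft2 <- featurize_pathways(mem2, 90)
  expect_equal(unname(ft2$values["g_none", ]), c(0, 0))

  same <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4),
                                          paste0("pw", 1:3)))
  ft3 <- featurize_pathways(same, 90)
  expect_setequal(features(ft3), c("pw1", "pw2", "pw3", "other_pathways"))
  expect_true(all(ft3$values[, "other_pathways"] == 0))
})

test_that("domain featurisation is unfiltered flags with conserved sums", {
  set.seed(6)
  mem <- matrix(rbinom(40, 1, 0.3), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("d", 1:5)))
  ft <- featurize_domains(mem)
  expect_identical(features(ft), colnames(mem))
  expect_equal(colSums(ft$values), colSums(mem))
  expect_true(all(ft$values %in% c(0, 1)))
  mem["g1", ] <- 0
  expect_equal(unname(featurize_domains(mem)$values["g1", ]), rep(0, 5))
})
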