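#' Specification for the synthetic druggability benchmark
#'
#' Describes a seeded synthetic study: a gene universe with a planted
#' positive (druggable) set, informative features whose means are
#' shifted for positives, pure-noise features, a handful of
#' label-tilted binary flags, MCAR missingness, and an interaction graph
#' whose positive-positive edges are boosted so the druggable
#' neighbourhood signal of real interactomes is emulated.
#'
#' @param n_genes Universe size (default 1000).
#' @param n_pos Number of positive genes (default 100).
#' @param n_informative Continuous features with a mean shift of
#'   `effect` (in SD units) for positives (default 10).
#' @param n_noise Continuous pure-noise features (default 40).
#' @param n_binary Binary-flag features with label-tilted odds
#'   (default 5).
#' @param effect Mean shift on informative features, SD units
#'   (default 3).
#' @param missing_frac Completely-at-random missing fraction applied to
#'   the continuous features (default 0.1).
#' @param mean_degree Mean degree of the interaction graph (default 8).
#' @param boost Multiplier on the positive-positive edge probability
#'   (default 5; 1 = no assortativity).
#' @param seed RNG seed.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_genes = 1000L, n_pos = 100L, n_informative = 10L,
                       n_noise = 40L, n_binary = 5L, effect = 3,
                       missing_frac = 0.1, mean_degree = 8, boost = 5,
                       seed = 1L) {
  stopifnot(n_pos < n_genes, n_pos >= 1L, effect >= 0,
            missing_frac >= 0, missing_frac < 1, mean_degree >= 1,
            boost > 0)
  structure(list(n_genes = as.integer(n_genes), n_pos = as.integer(n_pos),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 n_binary = as.integer(n_binary),
                 effect = effect, missing_frac = missing_frac,
                 mean_degree = mean_degree, boost = boost,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

.synth_genes <- function(spec) sprintf("G%05d", seq_len(spec$n_genes))

#' Sample the planted positive gene set
#'
#' @param spec A [synth_spec()].
#' @return A [label_set()] of `n_pos` genes drawn uniformly without
#'   replacement; reproducible per seed.
#' @export
gen_labels <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(substream_seed(spec$seed, "labels"))
  label_set(sample(.synth_genes(spec), spec$n_pos), name = "synthetic")
}

#' Generate the synthetic feature matrix
#'
#' Informative features are Normal(effect, 1) for positives and
#' Normal(0, 1) otherwise; noise features are Normal(0, 1) throughout;
#' binary flags are Bernoulli(0.2) for unlabelled genes with the odds
#' tilted up for positives by `exp(effect / 2)`.  Missingness is applied
#' completely at random at `missing_frac` to the continuous columns
#' (flags stay observed).
#'
#' @param spec A [synth_spec()].
#' @param labels The [label_set()] from [gen_labels()].
#' @return A [feature_table()] with classes assigned (informative and
#'   noise columns `continuous_global`, flags `binary_flag`).
#' @export
gen_feature_matrix <- function(spec, labels) {
  stopifnot(inherits(spec, "synth_spec"), inherits(labels, "label_set"))
  gene_ids <- .synth_genes(spec)
  stopifnot(all(labels$genes %in% gene_ids))
  set.seed(substream_seed(spec$seed, "features"))
  n <- spec$n_genes
  pos <- gene_ids %in% labels$genes

  inf <- matrix(stats::rnorm(n * spec$n_informative), n)
  inf[pos, ] <- inf[pos, ] + spec$effect
  noise <- matrix(stats::rnorm(n * spec$n_noise), n)

  base_p <- 0.2
  tilt <- stats::plogis(stats::qlogis(base_p) + spec$effect / 2)
  flags <- matrix(stats::rbinom(n * spec$n_binary, 1L,
                                ifelse(rep(pos, spec$n_binary), tilt,
                                       base_p)), n)

  m <- cbind(inf, noise, flags)
  colnames(m) <- c(sprintf("informative_%02d", seq_len(spec$n_informative)),
                   sprintf("noise_%02d", seq_len(spec$n_noise)),
                   sprintf("flag_%02d", seq_len(spec$n_binary)))
  rownames(m) <- gene_ids
  if (spec$missing_frac > 0) {
    cont <- seq_len(spec$n_informative + spec$n_noise)
    mask <- matrix(stats::runif(n * length(cont)) < spec$missing_frac,
                   n)
    m[, cont][mask] <- NA_real_
  }
  cls <- c(rep("continuous_global", spec$n_informative + spec$n_noise),
           rep("binary_flag", spec$n_binary))
  names(cls) <- colnames(m)
  feature_table(m, cls)
}

#' Generate a synthetic interaction graph
#'
#' Erdős–Rényi-style random graph with edge probability
#' `mean_degree / (n_genes - 1)`, where the probability of
#' positive-positive edges is multiplied by `boost` (capped at 1) to
#' plant the assortative druggable neighbourhoods seen in real
#' interactomes.  Each edge gets a random evidence channel among
#' experimental / inferred / physical / protein.
#'
#' @param spec A [synth_spec()].
#' @param labels The [label_set()] from [gen_labels()].
#' @return An [interaction_graph()].
#' @export
gen_ppi_graph <- function(spec, labels) {
  stopifnot(inherits(spec, "synth_spec"), inherits(labels, "label_set"))
  gene_ids <- .synth_genes(spec)
  set.seed(substream_seed(spec$seed, "graph"))
  n <- spec$n_genes
  p_base <- spec$mean_degree / (n - 1)
  pos <- gene_ids %in% labels$genes

  # sample pairs in blocks to avoid materialising all n*(n-1)/2 pairs
  from <- to <- character(0)
  block <- 200000L
  pair_id <- 0
  total_pairs <- n * (n - 1) / 2
  # enumerate pairs lazily: pair t -> (i, j)
  starts <- seq(1, total_pairs, by = block)
  for (s in starts) {
    t_ids <- s:min(s + block - 1, total_pairs)
    # invert the triangular index
    i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * (t_ids - 1))) / 2) + 1
    off <- t_ids - (i - 1) * (2 * n - i) / 2
    j <- i + off
    pp <- ifelse(pos[i] & pos[j], pmin(1, p_base * spec$boost), p_base)
    keep <- stats::runif(length(t_ids)) < pp
    from <- c(from, gene_ids[i[keep]])
    to <- c(to, gene_ids[j[keep]])
  }
  channels <- sample(c("experimental", "inferred", "physical", "protein"),
                     length(from), replace = TRUE)
  interaction_graph(from, to, channel = channels,
                    confidence = stats::runif(length(from)))
}

#' Generate synthetic annotation tables
#'
#' Produces the three categorical inputs with heavy-tailed (Zipf-like)
#' marginals so the percentile-based featurisation rules are
#' non-trivial: a gene x interaction-type count table, a gene x pathway
#' membership table whose pathway sizes span more than an order of
#' magnitude, and a gene x domain membership table.
#'
#' @param spec A [synth_spec()].
#' @param n_types,n_pathways,n_domains Table widths.
#' @return list(interaction_types, pathways, domains) of matrices with
#'   gene rownames.
#' @export
gen_annotation_tables <- function(spec, n_types = 12L, n_pathways = 30L,
                                  n_domains = 20L) {
  stopifnot(inherits(spec, "synth_spec"))
  gene_ids <- .synth_genes(spec)
  set.seed(substream_seed(spec$seed, "annotations"))
  n <- spec$n_genes

  type_rate <- 2 / seq_len(n_types)          # Zipf-decaying type frequency
  counts <- sapply(type_rate, function(r) stats::rpois(n, r))
  dimnames(counts) <- list(gene_ids, sprintf("type_%02d", seq_len(n_types)))

  path_p <- pmin(0.5, 0.6 / seq_len(n_pathways))   # sizes span >= 10x
  pathways <- sapply(path_p, function(p) stats::rbinom(n, 1L, p))
  dimnames(pathways) <- list(gene_ids,
                             sprintf("pathway_%02d", seq_len(n_pathways)))

  dom_p <- pmin(0.3, 0.4 / sqrt(seq_len(n_domains)))
  domains <- sapply(dom_p, function(p) stats::rbinom(n, 1L, p))
  dimnames(domains) <- list(gene_ids,
                            sprintf("domain_%02d", seq_len(n_domains)))

  list(interaction_types = counts, pathways = pathways, domains = domains)
}

#' Write a full synthetic input bundle to disk
#'
#' Emits the four input kinds as plain-text files: feature table (TSV),
#' positive gene list, edge list (TSV), and the three annotation tables
#' (TSV).
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synth_inputs <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- gen_labels(spec)
  ft <- gen_feature_matrix(spec, labels)
  graph <- gen_ppi_graph(spec, labels)
  ann <- gen_annotation_tables(spec)

  paths <- c(features = file.path(dir, "features.tsv"),
             labels = file.path(dir, "positives.txt"),
             edges = file.path(dir, "edges.tsv"),
             types = file.path(dir, "interaction_types.tsv"),
             pathways = file.path(dir, "pathways.tsv"),
             domains = file.path(dir, "domains.tsv"))
  write_feature_table(ft, paths[["features"]])
  writeLines(labels$genes, paths[["labels"]])
  e <- graph$edges
  utils::write.table(e, paths[["edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (nm in c("types", "pathways", "domains")) {
    tab <- switch(nm, types = ann$interaction_types,
                  pathways = ann$pathways, domains = ann$domains)
    df <- data.frame(Gene_Name = rownames(tab), tab, check.names = FALSE)
    utils::write.table(df, paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
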