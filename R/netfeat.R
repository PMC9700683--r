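#' Seed-overlap ratio of network neighbours
#'
#' For each gene g, the fraction of its exact distance-`hops` neighbours
#' that belong to the positive (seed) set:
#' \deqn{r_d(g) = |\{v : dist(g, v) = d\} \cap S| / |\{v : dist(g, v) = d\}|}
#' Genes with no neighbours at that distance (including genes absent
#' from the graph) get 0.  The gene itself never counts towards its own
#' ratio, so a seed gene's label does not leak into its feature.  The
#' distance-2 shell is exactly distance 2: it excludes the gene and its
#' direct neighbours.
#'
#' @param graph An [interaction_graph()].
#' @param seeds A [label_set()] of positive genes.
#' @param hops 1 (direct) or 2 (indirect) neighbours.
#' @param genes Gene universe to score; defaults to the graph's vertices.
#' @param channel Optional evidence channel; edges of other channels are
#'   ignored.
#' @return Named numeric vector of ratios in [0, 1] over `genes`.
#' @export
seed_overlap_ratio <- function(graph, seeds, hops = 1L, genes = NULL,
                               channel = NULL) {
  stopifnot(inherits(graph, "interaction_graph"),
            inherits(seeds, "label_set"), hops %in% c(1L, 2L))
  g <- .as_igraph(graph, channel = channel, vertices = genes)
  verts <- igraph::V(g)$name
  if (is.null(genes)) genes <- verts
  if (!length(intersect(seeds$genes, verts)))
    warning("seed set is disjoint from the graph; all ratios are 0")

  shells <- .distance_shells(g, hops)
  out <- stats::setNames(numeric(length(genes)), genes)
  for (gene in genes) {
    nbrs <- shells[[gene]]
    if (is.null(nbrs) || !length(nbrs)) next
    out[[gene]] <- sum(nbrs %in% seeds$genes) / length(nbrs)
  }
  out
}

# Exact distance-d vertex shells for every vertex, via nested ego sets.
.distance_shells <- function(g, hops) {
  nm <- igraph::V(g)$name
  ego_d <- igraph::ego(g, order = hops, nodes = igraph::V(g))
  if (hops == 1L) {
    shells <- lapply(seq_along(nm), function(i)
      setdiff(ego_d[[i]]$name, nm[i]))
  } else {
    ego_prev <- igraph::ego(g, order = hops - 1L, nodes = igraph::V(g))
    shells <- lapply(seq_along(nm), function(i)
      setdiff(ego_d[[i]]$name, ego_prev[[i]]$name))
  }
  stats::setNames(shells, nm)
}

#' Harmonic mean of the two hop-overlap ratios
#'
#' Combines the direct (1-hop) and indirect (2-hop) seed-overlap ratios
#' into one score: `2 * r1 * r2 / (r1 + r2)`, defined as 0 when both are
#' 0 and annihilated to 0 whenever either ratio is 0.
#'
#' @param r1,r2 Numeric vectors of ratios in [0, 1].
#' @return Numeric vector of harmonic means in [0, 1].
#' @export
hmean_overlap <- function(r1, r2) {
  stopifnot(length(r1) == length(r2),
            all(r1 >= 0 & r1 <= 1), all(r2 >= 0 & r2 <= 1))
  s <- r1 + r2
  out <- numeric(length(r1))
  pos <- s > 0
  out[pos] <- 2 * r1[pos] * r2[pos] / s[pos]
  names(out) <- names(r1)
  out
}

#' Engineer seed-overlap features from an interaction graph
#'
#' Builds, per evidence channel (or once over all edges when the graph
#' has no channel tags), three network features: the 1-hop ratio, the
#' 2-hop ratio and their harmonic mean.  All outputs are tagged with
#' feature class `"network"` so imputation assigns 0 where a gene has no
#' interactions.
#'
#' @inheritParams seed_overlap_ratio
#' @param channels Channels to featurise; defaults to all channels in
#'   the graph, or a single untagged pass when there are none.
#' @return A [feature_table()] over `genes`.
#' @export
overlap_features <- function(graph, seeds, genes = NULL, channels = NULL) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (is.null(genes))
    genes <- unique(c(graph$edges$from, graph$edges$to))
  if (is.null(channels)) {
    channels <- graph_channels(graph)
    if (!length(channels)) channels <- NA_character_
  }
  cols <- list()
  for (ch in channels) {
    chan <- if (is.na(ch)) NULL else ch
    tag <- if (is.na(ch)) "all" else ch
    r1 <- seed_overlap_ratio(graph, seeds, 1L, genes, chan)
    r2 <- seed_overlap_ratio(graph, seeds, 2L, genes, chan)
    cols[[paste0(tag, "_seed_overlap_1hop")]] <- r1
    cols[[paste0(tag, "_seed_overlap_2hop")]] <- r2
    cols[[paste0(tag, "_seed_overlap_hmean")]] <- hmean_overlap(r1, r2)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- genes
  feature_table(m, "network")
}

#' Featurise interaction-type counts
#'
#' Given a gene-by-type count table (e.g. chemical-gene interaction
#' types), keeps as individual count features only the types whose total
#' frequency across genes is at or above the given percentile of the
#' type-frequency distribution; the remaining types are aggregated into
#' one `other_types` count.  A `unique_interactions` feature counts, per
#' gene, the number of distinct types it has at least one interaction
#' with.
#'
#' @param counts Non-negative integer matrix, genes x types, with
#'   dimnames.
#' @param percentile Frequency percentile cut (default 50); percentiles
#'   use linear interpolation and "at or above" is `>=`.
#' @return A [feature_table()] with class `"subset_signal"` features.
#' @export
featurize_interaction_types <- function(counts, percentile = 50) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !nrow(counts) || !ncol(counts))
    stop("`counts` must be a non-empty gene x type matrix")
  stopifnot(all(counts >= 0), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  freq <- colSums(counts)
  cut <- stats::quantile(freq, percentile / 100, names = FALSE)
  kept <- freq >= cut
  m <- cbind(counts[, kept, drop = FALSE],
             other_types = rowSums(counts[, !kept, drop = FALSE]),
             unique_interactions = rowSums(counts > 0))
  feature_table(m, "subset_signal")
}

#' Featurise pathway memberships
#'
#' Pathways whose size (number of member genes) is at or above the given
#' percentile of the pathway-size distribution become individual boolean
#' flags; memberships in the remaining pathways are summed into one
#' `other_pathways` count.
#'
#' @param membership Logical/0-1 matrix, genes x pathways, with dimnames.
#' @param percentile Size percentile cut (default 90).
#' @return A [feature_table()]; flags are `binary_flag`, the residual
#'   count is `subset_signal`.
#' @export
featurize_pathways <- function(membership, percentile = 90) {
  if (is.data.frame(membership)) membership <- as.matrix(membership)
  stopifnot(is.matrix(membership), !is.null(rownames(membership)),
            !is.null(colnames(membership)))
  mem <- (membership != 0) + 0
  sizes <- colSums(mem)
  cut <- stats::quantile(sizes, percentile / 100, names = FALSE)
  kept <- sizes >= cut
  m <- cbind(mem[, kept, drop = FALSE],
             other_pathways = rowSums(mem[, !kept, drop = FALSE]))
  cls <- c(rep("binary_flag", sum(kept)), "subset_signal")
  names(cls) <- colnames(m)
  feature_table(m, cls)
}

#' Featurise protein domain/family memberships
#'
#' One unfiltered 0/1 flag per domain, family or superfamily.
#'
#' @param membership Logical/0-1 matrix, genes x domains, with dimnames.
#' @return A [feature_table()] of `binary_flag` features.
#' @export
featurize_domains <- function(membership) {
  if (is.data.frame(membership)) membership <- as.matrix(membership)
  stopifnot(is.matrix(membership), !is.null(rownames(membership)),
            !is.null(colnames(membership)))
  feature_table((membership != 0) + 0, "binary_flag")
}
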