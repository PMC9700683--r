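#' Gene-by-feature table
#'
#' The central data container: a numeric matrix of genes (rows) by named
#' features (columns), with `NA` marking missing cells and a per-feature
#' class tag that drives the imputation policy downstream.
#'
#' Feature classes:
#' \describe{
#'   \item{`binary_flag`}{0/1 membership flags (e.g. protein-domain
#'     membership); missing means absent, imputed with 0.}
#'   \item{`subset_signal`}{signals measured only on a subset of genes
#'     (e.g. counts from a resource that covers part of the exome);
#'     missing means "not covered", imputed with 0.}
#'   \item{`continuous_global`}{continuous attributes defined over the
#'     whole gene universe; missing cells imputed with the feature
#'     median.}
#'   \item{`network`}{features engineered from interaction graphs; a gene
#'     with no interactions gets 0.}
#' }
#'
#' @param values Numeric matrix with unique gene identifiers as rownames
#'   and unique feature names as colnames.  `NA` marks missing cells;
#'   logical input columns are stored as 0/1.
#' @param feature_class Character vector naming the class of each feature
#'   (recycled scalar allowed), or a named vector covering a subset of
#'   features; unmapped features default to `"continuous_global"`.
#' @return An object of class `"feature_table"`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("G", 1:4), paste0("f", 1:3)))
#' ft <- feature_table(m)
#' ft
#' @export
feature_table <- function(values, feature_class = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.logical(values)) storage.mode(values) <- "double"
  if (!is.numeric(values)) stop("`values` must be numeric")
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene rownames and feature colnames")

  classes <- .resolve_feature_classes(colnames(values), feature_class)
  x <- structure(list(values = values, feature_class = classes),
                 class = "feature_table")
  validate_feature_table(x)
}

.feature_classes <- c("binary_flag", "subset_signal", "continuous_global",
                      "network")

.resolve_feature_classes <- function(feature_names, feature_class) {
  out <- rep("continuous_global", length(feature_names))
  names(out) <- feature_names
  if (is.null(feature_class)) return(out)
  bad <- setdiff(unique(feature_class), .feature_classes)
  if (length(bad))
    stop("unknown feature class: ", paste(bad, collapse = ", "))
  if (is.null(names(feature_class))) {
    if (length(feature_class) == 1L)
      feature_class <- rep(feature_class, length(feature_names))
    if (length(feature_class) != length(feature_names))
      stop("unnamed `feature_class` must have one entry per feature")
    names(out) <- feature_names
    out[] <- feature_class
  } else {
    extra <- setdiff(names(feature_class), feature_names)
    if (length(extra))
      stop("feature_class names not in table: ",
           paste(extra, collapse = ", "))
    out[names(feature_class)] <- feature_class
  }
  out
}

#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  g <- rownames(x$values)
  f <- colnames(x$values)
  if (anyDuplicated(g))
    stop("duplicate gene identifier: ", g[duplicated(g)][1L])
  if (anyDuplicated(f))
    stop("duplicate feature name: ", f[duplicated(f)][1L])
  if (!identical(sort(names(x$feature_class)), sort(f)) ||
      length(x$feature_class) != length(f))
    stop("feature_class must tag every feature exactly once")
  x$feature_class <- x$feature_class[f]
  x
}

#' @rdname feature_table
#' @param x A `feature_table`.
#' @export
genes <- function(x) UseMethod("genes")

#' @export
genes.feature_table <- function(x) rownames(x$values)

#' @rdname feature_table
#' @export
features <- function(x) UseMethod("features")

#' @export
features.feature_table <- function(x) colnames(x$values)

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

#' Subset the feature columns of a table
#'
#' @param x A `feature_table`.
#' @param keep Character vector of feature names to retain (order kept).
#' @return A `feature_table` with the same genes and the selected columns.
#' @export
select_features <- function(x, keep) {
  stopifnot(inherits(x, "feature_table"))
  missing <- setdiff(keep, features(x))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  feature_table(x$values[, keep, drop = FALSE], x$feature_class[keep])
}

#' Bind two feature tables over the same gene universe
#'
#' @param x,y `feature_table` objects on identical gene sets (any order).
#' @return A `feature_table` with the columns of both.
#' @export
cbind_features <- function(x, y) {
  stopifnot(inherits(x, "feature_table"), inherits(y, "feature_table"))
  if (!setequal(genes(x), genes(y)))
    stop("gene universes differ")
  vy <- y$values[genes(x), , drop = FALSE]
  feature_table(cbind(x$values, vy), c(x$feature_class, y$feature_class))
}

#' @export
print.feature_table <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf("feature_table: %d genes x %d features (%d missing cells)\n",
              nrow(x$values), ncol(x$values), n_miss))
  tab <- table(factor(x$feature_class, levels = .feature_classes))
  cat("  feature classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Named positive (seed) gene set
#'
#' @param genes Character vector of gene identifiers; duplicates are
#'   removed.  Identifiers are opaque, case-sensitive strings.
#' @param name Label for the set (e.g. the resource it came from).
#' @return An object of class `"label_set"`.
#' @export
label_set <- function(genes, name = "positives") {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("label set is empty")
  structure(list(name = name, genes = genes), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.label_set <- function(x) length(x$genes)

#' Undirected gene interaction graph
#'
#' Stores an undirected simple graph over genes, with an optional
#' evidence-channel tag and confidence per edge.  Edges are normalised so
#' that A-B and B-A are the same edge; self-loops are dropped with a
#' warning; duplicate edges within a channel are collapsed (first
#' occurrence kept).
#'
#' @param from,to Character vectors of endpoint gene identifiers.
#' @param channel Optional character vector of per-edge evidence channels
#'   (e.g. "experimental", "inferred", "physical", "protein").
#' @param confidence Optional numeric per-edge confidence.
#' @return An object of class `"interaction_graph"` wrapping an edge
#'   data.frame with columns from, to, channel, confidence.
#' @export
interaction_graph <- function(from, to, channel = NULL, confidence = NULL) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  n <- length(from)
  if (is.null(channel)) channel <- rep(NA_character_, n)
  if (is.null(confidence)) confidence <- rep(NA_real_, n)
  stopifnot(length(channel) == n, length(confidence) == n)

  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped")
    from <- from[!loops]; to <- to[!loops]
    channel <- channel[!loops]; confidence <- confidence[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, channel, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(from = a[keep], to = b[keep],
                      channel = as.character(channel)[keep],
                      confidence = as.numeric(confidence)[keep],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  ch <- unique(x$edges$channel)
  ch <- ch[!is.na(ch)]
  cat(sprintf("interaction_graph: %d edges, %d genes",
              nrow(x$edges),
              length(unique(c(x$edges$from, x$edges$to)))))
  if (length(ch)) cat(", channels:", paste(ch, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
graph_channels <- function(x) {
  stopifnot(inherits(x, "interaction_graph"))
  ch <- unique(x$edges$channel)
  ch[!is.na(ch)]
}

# igraph view of the edge list, optionally filtered to one channel and
# padded with isolated vertices for genes absent from the edge list.
.as_igraph <- function(x, channel = NULL, vertices = NULL) {
  e <- x$edges
  if (!is.null(channel)) e <- e[!is.na(e$channel) & e$channel == channel, ]
  verts <- unique(c(e$from, e$to, vertices))
  igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = verts))
}
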