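#' Read a gene-by-feature table from delimited text
#'
#' Expects a header row of feature names and a first column of gene
#' identifiers (conventionally named `Gene_Name`).  The delimiter is
#' taken from the file extension (`.csv` = comma, anything else = tab)
#' unless `sep` is given.  Empty cells and the token `NA` (any case) are
#' read as missing; any other non-numeric cell is a hard error naming the
#' offending row and column.  Logical `TRUE`/`FALSE` cells are stored as
#' 1/0.
#'
#' @param path Path to a TSV/CSV file.
#' @param class_map Optional named character vector feature -> class (see
#'   [feature_table()]); unmapped features default to
#'   `"continuous_global"`.
#' @param sep Field delimiter; `NULL` to infer from the extension.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, class_map = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          na.strings = character(0),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table needs a gene column plus features")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier: ", gene_ids[duplicated(gene_ids)][1L])
  feat_names <- colnames(df)[-1L]
  if (anyDuplicated(feat_names))
    stop("duplicate feature name: ", feat_names[duplicated(feat_names)][1L])

  vals <- matrix(NA_real_, nrow(df), length(feat_names),
                 dimnames = list(gene_ids, feat_names))
  for (j in seq_along(feat_names)) {
    cell <- trimws(df[[j + 1L]])
    miss <- cell == "" | toupper(cell) == "NA"
    cell[toupper(cell) == "TRUE"] <- "1"
    cell[toupper(cell) == "FALSE"] <- "0"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric cell '%s' at gene '%s', feature '%s'",
                   cell[i], gene_ids[i], feat_names[j]))
    }
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  feature_table(vals, class_map)
}

#' Write a feature table as delimited text
#'
#' Inverse of [read_feature_table()]: header row of feature names, first
#' column `Gene_Name`, missing cells written as empty strings.  Values
#' are written with full (17 significant digit) precision so a
#' write/read round-trip is bit-exact.
#'
#' @param x A [feature_table()].
#' @param path Output path; `.csv` selects comma, else tab.
#' @param sep Field delimiter; `NULL` to infer from the extension.
#' @export
write_feature_table <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  chr <- format(x$values, digits = 17, trim = TRUE, scientific = FALSE)
  chr[is.na(x$values)] <- ""
  df <- data.frame(Gene_Name = genes(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("Gene_Name", features(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a positive-label gene list
#'
#' One gene symbol per line; blank lines are skipped and repeated symbols
#' collapse to one.
#'
#' @param path Path to a plain-text file.
#' @param name Name for the set; defaults to the file stem.
#' @return A [label_set()].
#' @export
read_gene_list <- function(path, name = NULL) {
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty gene list: ", path)
  label_set(lines, name = name)
}

#' Read an interaction edge list
#'
#' Tab-separated with two mandatory columns (the endpoint genes) and two
#' optional columns (evidence channel, numeric confidence), without a
#' header.  Self-loops are dropped with a warning; A-B and B-A collapse
#' to one edge.
#'
#' @param path Path to a TSV file.
#' @return An [interaction_graph()].
#' @export
read_edge_list <- function(path) {
  if (!length(readLines(path, n = 1L, warn = FALSE)))
    stop("empty edge list: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty edge list: ", path)
  if (ncol(df) < 2L) stop("edge list needs at least two columns")
  channel <- if (ncol(df) >= 3L) df[[3L]] else NULL
  confidence <- if (ncol(df) >= 4L) suppressWarnings(as.numeric(df[[4L]])) else NULL
  interaction_graph(df[[1L]], df[[2L]], channel = channel,
                    confidence = confidence)
}

#' Write / read per-gene druggability scores
#'
#' Scores travel as CSV with columns `Gene_Name`, `druggability_score`
#' (mean out-of-bag probability, 6 decimals), `n_oob` and `percentile`.
#'
#' @param scores A score data.frame as produced by [pu_ensemble()]
#'   (columns gene, score, n_oob, percentile).
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  stopifnot(all(c("gene", "score", "n_oob", "percentile") %in%
                colnames(scores)))
  out <- data.frame(Gene_Name = scores$gene,
                    druggability_score = round(scores$score, 6),
                    n_oob = scores$n_oob,
                    percentile = round(scores$percentile, 6))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @return `read_scores` returns the score data.frame with the internal
#'   column names (gene, score, n_oob, percentile), in file order.
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("Gene_Name", "druggability_score", "n_oob",
                  "percentile") %in% colnames(df)))
  data.frame(gene = as.character(df$Gene_Name),
             score = df$druggability_score,
             n_oob = as.integer(df$n_oob),
             percentile = df$percentile,
             stringsAsFactors = FALSE)
}
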