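#' Run the full scoring pipeline from a configuration
#'
#' Orchestrates the end-to-end workflow: read inputs, engineer network
#' features, pre-process, fit the stochastic positive-unlabelled
#' ensemble, rank, and (optionally) compute rank-interval enrichment
#' against evidence gene lists.  Every artifact plus a run manifest
#' (config snapshot, input digests, package version, per-stage timings,
#' seed) is written to `out_dir`, which is sufficient to reproduce the
#' run bit-exactly.
#'
#' @param features Path to the feature table (TSV/CSV) or a
#'   [feature_table()].
#' @param labels Path to a positive gene list or a [label_set()].
#' @param out_dir Output directory (created if needed).
#' @param graph Optional path to an edge list or an
#'   [interaction_graph()]; when given, seed-overlap features are
#'   engineered and appended before pre-processing.
#' @param evidence Optional named list of evidence gene vectors (or
#'   paths); each is evaluated with [rank_interval_enrichment()].
#' @param config A [run_config()].
#' @param class_map Optional feature -> class map for
#'   [read_feature_table()].
#' @param skip_preprocess Skip pre-processing for pre-cleaned inputs.
#' @return Invisibly, the fitted [pu_ensemble()] object.
#' @export
run_pipeline <- function(features, labels, out_dir, graph = NULL,
                         evidence = NULL, config = run_config(),
                         class_map = NULL, skip_preprocess = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  digests <- list()
  note_input <- function(x, label) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
      digests[[label]] <<- unname(tools::md5sum(x))
    x
  }

  ft <- tick("read_features", {
    x <- note_input(features, "features")
    if (is.character(x)) read_feature_table(x, class_map = class_map) else x
  })
  labs <- tick("read_labels", {
    x <- note_input(labels, "labels")
    if (is.character(x)) read_gene_list(x) else x
  })
  if (!is.null(graph)) {
    g <- note_input(graph, "graph")
    if (is.character(g)) g <- read_edge_list(g)
    net <- tick("netfeat", overlap_features(g, labs, genes = genes(ft)))
    ft <- cbind_features(ft, net)
  }
  if (!skip_preprocess) {
    pp <- tick("preprocess",
               preprocess_features(ft, config$correlation_threshold,
                                   config$missing_data_thres))
    ft <- pp$table
    utils::write.csv(
      data.frame(stage = c(rep("sparse", nrow(pp$report$dropped_sparse)),
                           rep("correlated",
                               nrow(pp$report$dropped_correlated))),
                 feature = c(pp$report$dropped_sparse$feature,
                             pp$report$dropped_correlated$dropped)),
      file.path(out_dir, "dropped_features.csv"), row.names = FALSE)
  }

  fit <- tick("train", pu_ensemble(ft, labs, config))
  write_scores(fit$scores, file.path(out_dir, "scores.csv"))
  utils::write.csv(fit$oob_log, file.path(out_dir, "oob_log.csv"),
                   row.names = FALSE)

  if (!is.null(evidence)) {
    ranked <- fit$scores$gene[order(-fit$scores$score)]
    for (nm in names(evidence)) {
      ev <- evidence[[nm]]
      if (is.character(ev) && length(ev) == 1L && file.exists(ev))
        ev <- read_gene_list(ev)$genes
      ev <- intersect(ev, ranked)
      tab <- tick(paste0("evaluate_", nm),
                  rank_interval_enrichment(ranked, ev))
      tab$cdf <- evidence_cdf(ranked, ev)
      utils::write.csv(tab, file.path(out_dir,
                                      paste0("enrichment_", nm, ".csv")),
                       row.names = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("drugrankr")),
    seed = config$seed,
    config = list(L = config$L, k = config$k, rho = config$rho,
                  correlation_threshold = config$correlation_threshold,
                  missing_data_thres = config$missing_data_thres,
                  classifier = config$classifier$name,
                  hyperparameters = config$classifier$hyperparameters),
    input_md5 = digests,
    timings_sec = as.list(timings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(fit)
}
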