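# End-to-end pipeline: filter -> similarity graph -> score -> combine ->
# evaluate -> networks -> complexes -> DDIs, with a manifest that makes a
# run byte-reproducible. A thin command-line wrapper around these
# functions ships in inst/cli/preynet.R.

#' Pipeline run configuration
#'
#' @param methods base scoring methods to compute.
#' @param combine base methods to combine with the Sorensen coefficient.
#' @param min_cooccurrence minimum shared experiments for a pair to enter
#'   the universe.
#' @param e3_denominator rank-proximity averaging mode (see [e3()]).
#' @param network_fraction top fraction (per method, intersected) for the
#'   global interaction network (default 0.10).
#' @param complex_fraction stricter top fraction for complex extraction
#'   (default 0.01).
#' @param jaccard_threshold keep-edge cutoff for the experiment-similarity
#'   graph (default 0.7).
#' @param window sliding-recall window in ranks (default 2000).
#' @param n_shuffles permutations for the shuffled-rank null (default 1000).
#' @param ddi_score_col pair-score column propagated onto domain pairs.
#' @param seed integer seed controlling all randomness in the run.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(methods = c("sor", "pr", "e3", "ab"),
                       combine = c("e3", "ab", "pr"),
                       min_cooccurrence = 1,
                       e3_denominator = "all",
                       network_fraction = 0.10,
                       complex_fraction = 0.01,
                       jaccard_threshold = 0.7,
                       window = 2000,
                       n_shuffles = 1000,
                       ddi_score_col = NULL,
                       seed = 1L) {
  combine <- intersect(combine, methods)
  if (length(combine) && !"sor" %in% methods)
    stop_usage("combining requires the 'sor' method")
  for (f in c(network_fraction, complex_fraction))
    if (!(f > 0 && f <= 1)) stop_usage("fractions must be in (0, 1]")
  structure(list(methods = methods, combine = combine,
                 min_cooccurrence = min_cooccurrence,
                 e3_denominator = e3_denominator,
                 network_fraction = network_fraction,
                 complex_fraction = complex_fraction,
                 jaccard_threshold = jaccard_threshold,
                 window = window, n_shuffles = n_shuffles,
                 ddi_score_col = ddi_score_col,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full prediction pipeline and write all artifacts
#'
#' Stages: (1) sticky filtering; (2) experiment-similarity graph;
#' (3) pair scoring with every requested method; (4) combination with the
#' Sorensen coefficient; (5) evaluation against the reference set (ROC,
#' running sum, shuffled null, sliding recall) when one is supplied;
#' (6) top-fraction intersection network with edge classification;
#' (7) stricter-threshold triangle-filtered complex extraction; (8) DDI
#' scoring from the complex-level pair set. All outputs are plain text
#' under `out_dir`; `manifest.json` records parameters, input hashes and
#' per-stage outputs so a rerun reproduces byte-identical files.
#'
#' @param matrix an [spc_matrix].
#' @param experiments an [experiment_table] (defaults to one derived from
#'   `matrix` with unknown metadata).
#' @param sticky character vector of non-specific proteins (optional).
#' @param annotation optional `domain_annotation` for DDI scoring.
#' @param known_ppis optional reference PPI set for evaluation and edge
#'   classification.
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`scores`,
#'   `network`, `complexes`, `ddis`, `evaluation`, `manifest`).
#' @export
run_pipeline <- function(matrix, experiments = NULL, sticky = NULL,
                         annotation = NULL, known_ppis = NULL,
                         config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  t0 <- Sys.time()
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(paste0(...), "\n", sep = "", file = logf, append = TRUE)
  }
  cat("", file = logf)  # truncate

  # 1. sticky filter
  if (!is.null(sticky) && length(sticky)) {
    n_before <- nrow(matrix$spc)
    matrix <- suppressMessages(apply_sticky_filter(matrix, sticky))
    log_line("sticky_filter removed ", n_before - nrow(matrix$spc),
             " proteins")
  } else log_line("sticky_filter skipped (no list)")
  stages <- c(stages, "sticky_filter")
  if (is.null(experiments)) experiments <- experiment_table(matrix)
  else experiments <- experiment_table(matrix,
                                       bait = experiments$info$bait,
                                       antibody = experiments$info$antibody,
                                       cell_line = experiments$info$cell_line,
                                       condition = experiments$info$condition)

  # 2. similarity graph
  simg <- build_similarity_graph(experiments, config$jaccard_threshold)
  write_network(simg$nodes, simg$edges,
                file.path(out_dir, "similarity_graph.tsv"), format = "tsv")
  stages <- c(stages, "similarity_graph")
  log_line("similarity_graph: ", nrow(simg$nodes), " nodes, ",
           nrow(simg$edges), " edges")

  # 3-4. scoring + combination
  scores <- score_all_pairs(matrix, methods = config$methods,
                            min_cooccurrence = config$min_cooccurrence,
                            e3_denominator = config$e3_denominator)
  for (bm in config$combine) scores <- combine_with_sorensen(scores, bm)
  utils::write.table(scores, file.path(out_dir, "pair_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "score_pairs", "combine_sorensen")
  log_line("score_pairs: ", nrow(scores), " pairs")
  methods_final <- if (length(config$combine))
    paste0(config$combine, "_sor") else config$methods

  # 5. evaluation
  evaluation <- NULL
  if (!is.null(known_ppis)) {
    evaluation <- evaluate_ranking(scores, known_ppis,
                                   methods = c(config$methods, methods_final),
                                   window = config$window,
                                   n_shuffles = config$n_shuffles,
                                   seed = config$seed)
    jsonlite::write_json(evaluation$summary,
                         file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("evaluation: AUC ",
             paste(names(evaluation$summary$auc), "=",
                   vapply(evaluation$summary$auc,
                          function(a) sprintf("%.3f", a), ""),
                   collapse = ", "))
  } else log_line("evaluation skipped (no reference)")
  stages <- c(stages, "evaluation")

  # 6. global network at the looser threshold
  net_pairs <- top_fraction_intersection(scores, methods = methods_final,
                                         fraction = config$network_fraction)
  network <- build_network(net_pairs, experiments, known = known_ppis)
  write_network(network$nodes, network$edges,
                file.path(out_dir, "network_top.sif"), format = "sif")
  write_network(network$nodes, network$edges,
                file.path(out_dir, "network_top.graphml"),
                format = "graphml")
  stages <- c(stages, "network")
  log_line("network: ", nrow(network$nodes), " nodes, ",
           nrow(network$edges), " edges")

  # 7. complexes at the stricter threshold
  cx_pairs <- top_fraction_intersection(scores, methods = methods_final,
                                        fraction = config$complex_fraction)
  cx_net <- triangle_filter(build_network(cx_pairs, experiments,
                                          known = known_ppis))
  complexes <- extract_complexes(cx_net)
  write_gmt(complexes, file.path(out_dir, "complexes.gmt"))
  write_network(cx_net$nodes, cx_net$edges,
                file.path(out_dir, "complex_network.sif"), format = "sif")
  stages <- c(stages, "complexes")
  log_line("complexes: ", length(complexes$complexes))

  # 8. DDIs
  ddis <- NULL
  if (!is.null(annotation)) {
    score_col <- config$ddi_score_col %||% methods_final[1]
    ddis <- suppressMessages(
      score_ddis(cx_pairs, annotation, score_col = score_col))
    utils::write.table(ddis[setdiff(names(ddis), "support")],
                       file.path(out_dir, "ddi_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("ddi: ", nrow(ddis), " domain pairs from column ", score_col)
  } else log_line("ddi skipped (no annotation)")
  stages <- c(stages, "ddi")

  outputs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          c("manifest.json", "run.log")))
  manifest <- list(
    package = "preynet",
    version = as.character(utils::packageVersion("preynet")),
    config = unclass(config),
    seed = config$seed,
    n_proteins = nrow(matrix$spc),
    n_experiments = ncol(matrix$spc),
    input_hash = unname(matrix_hash(matrix)),
    stages = stages,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest[setdiff(names(manifest), "elapsed_sec")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scores = scores, network = network, complexes = complexes,
                 ddis = ddis, evaluation = evaluation, manifest = manifest))
}

# content hash of a matrix: serialize deterministically to text and md5
matrix_hash <- function(matrix) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_spc_matrix(matrix, tmp, paste0(tmp, ".mw"))
  on.exit(unlink(paste0(tmp, ".mw")), add = TRUE)
  unname(tools::md5sum(tmp))
}

#' Evaluate a scored pair table against a reference set
#'
#' Convenience wrapper running [roc_auc()], [running_sum()],
#' [shuffled_null()] and [sliding_recall()] for each requested method
#' column of a `scored_pairs` table.
#'
#' @param scores a `scored_pairs` table.
#' @param known reference interactions.
#' @param methods score columns to evaluate.
#' @param window sliding-recall window.
#' @param n_shuffles shuffled-null permutations (0 disables the null).
#' @param seed seed for the null.
#' @return List with `summary` (u, t and AUC/peak per method) and
#'   `curves` (per-method running-sum and recall curves).
#' @export
evaluate_ranking <- function(scores, known, methods, window = 2000,
                             n_shuffles = 0, seed = 1L) {
  methods <- intersect(methods, names(scores))
  auc <- list(); peak <- list(); curves <- list()
  u <- NULL; t <- NULL
  for (meth in methods) {
    rk <- scores[[paste0("rank_", meth)]]
    if (is.null(rk)) rk <- rank_desc(scores[[meth]], scores$protein_a,
                                     scores$protein_b)
    ok <- !is.na(rk)
    ranked <- scores[ok, , drop = FALSE][order(rk[ok]), , drop = FALSE]
    roc <- tryCatch(roc_auc(ranked, known, scores = ranked[[meth]]),
                    error = function(e) NULL)
    rs <- tryCatch(running_sum(ranked, known), error = function(e) NULL)
    if (is.null(roc) || is.null(rs)) next
    auc[[meth]] <- roc$auc
    peak[[meth]] <- rs$peak
    w <- min(window, rs$u)
    curves[[meth]] <- list(running_sum = rs,
                           recall = sliding_recall(ranked, known, w))
    u <- rs$u; t <- rs$t
  }
  null_summary <- NULL
  if (n_shuffles > 0 && length(methods)) {
    meth <- methods[1]
    rk <- scores[[paste0("rank_", meth)]]
    ok <- !is.na(rk)
    ranked <- scores[ok, , drop = FALSE][order(rk[ok]), , drop = FALSE]
    nul <- tryCatch(shuffled_null(ranked, known, n_shuffles = n_shuffles,
                                  seed = seed),
                    error = function(e) NULL)
    if (!is.null(nul))
      null_summary <- list(mean_abs_max = max(abs(nul$mean)),
                           n_shuffles = n_shuffles)
  }
  list(summary = list(u = u, t = t, auc = auc, peak = peak,
                      null = null_summary),
       curves = curves)
}
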