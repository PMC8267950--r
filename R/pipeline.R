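# End-to-end orchestration: read inputs, run every analysis stage, write
# the summary artifacts (sample summary, CNA-call matrix, clone graph and
# tree exports, instability table, optional pair tests) into a run
# directory, together with the resolved configuration for provenance.

#' Build a pipeline run configuration
#'
#' All analysis thresholds live here with their standard defaults so that
#' sensitivity analyses are scriptable: CNA call fractions 0.15/0.85,
#' aneuploidy cutoff 2.2 on the one-decimal average ploidy, amplification
#' at twice the sample ploidy, WGD edges allowed in trees.
#'
#' @param signals path(s) to nucleus signal TSVs (named by sample id, or
#'   names derived from file names).
#' @param panel a [probe_panel()] or path to a panel YAML/JSON.
#' @param out output directory.
#' @param cna_minor,cna_major,aneuploid_cutoff see [sample_summary()].
#' @param allow_wgd,absorbing_zero see [build_fish_tree()].
#' @param patterns_gene_only see [sample_summary()].
#' @param min_nuclei see [validate_sample()].
#' @param events optional path to a samples x events 0/1 TSV for pair tests.
#' @param n_perm,seed permutation-test settings.
#' @return list of class `run_config`.
#' @export
run_config <- function(signals, panel = default_panel(), out = "mifish_run",
                       cna_minor = 0.15, cna_major = 0.85,
                       aneuploid_cutoff = 2.2, allow_wgd = TRUE,
                       absorbing_zero = TRUE, patterns_gene_only = FALSE,
                       min_nuclei = 250L, events = NULL, n_perm = 10000L,
                       seed = 1L) {
  stopifnot(cna_minor > 0, cna_minor < 1, cna_major >= cna_minor,
            cna_major <= 1, aneuploid_cutoff > 0)
  if (is.character(panel)) panel <- read_panel(panel)
  if (is.null(names(signals)))
    names(signals) <- sub("\\.tsv$", "", basename(signals))
  structure(list(signals = signals, panel = panel, out = out,
                 cna_minor = cna_minor, cna_major = cna_major,
                 aneuploid_cutoff = aneuploid_cutoff, allow_wgd = allow_wgd,
                 absorbing_zero = absorbing_zero,
                 patterns_gene_only = patterns_gene_only,
                 min_nuclei = as.integer(min_nuclei), events = events,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full miFISH analysis pipeline
#'
#' Per sample: validation, signal-pattern aggregation, sample summary
#' (ploidy, instability index, CNA and amplification calls), clone graph
#' and FISH tree exports. Across samples: a summary TSV, a CNA-call matrix
#' TSV (none/minor/major x gain/loss encoding), an instability-index table,
#' and, when an event matrix is supplied, the pairwise
#' exclusivity/co-occurrence TSV. A log file captures configuration and
#' warnings. Any stage failure aborts with the stage named.
#'
#' @param config a [run_config()].
#' @return the run directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("mifishr %s | %s\n",
              as.character(utils::packageVersion("mifishr")),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)
  cfg_dump <- config[setdiff(names(config), "panel")]
  yaml::write_yaml(cfg_dump, file.path(config$out, "config.yaml"))
  write_panel(config$panel, file.path(config$out, "panel.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  summaries <- list()
  cna_cols <- list()
  for (sid in names(config$signals)) {
    records <- stage("io", read_signal_table(config$signals[[sid]],
                                             config$panel))
    chk <- validate_sample(records, config$min_nuclei)
    logf("[%s] %s: %s", chk$level, sid, chk$message)
    if (chk$level == "error")
      stop(sprintf("pipeline stage 'validate' failed for %s: %s", sid,
                   chk$message), call. = FALSE)

    smry <- stage("summary",
                  sample_summary(records, config$panel,
                                 cna_minor = config$cna_minor,
                                 cna_major = config$cna_major,
                                 aneuploid_cutoff = config$aneuploid_cutoff,
                                 patterns_gene_only = config$patterns_gene_only))
    summaries[[sid]] <- summary_row(smry, sid)
    cna_cols[[sid]] <- stats::setNames(smry$cna_calls$call,
                                       smry$cna_calls$gene)

    graph <- stage("clone_graph", build_clone_graph(records, config$panel))
    write_clone_graph(graph, file.path(config$out,
                                       paste0(sid, "_clones.graphml")))

    pats <- stage("patterns", aggregate_patterns(records, config$panel))
    gene_pats <- pats[, gene_probes(config$panel), drop = FALSE]
    all_keys <- apply(gene_pats, 1L, paste, collapse = "-")
    dedup <- !duplicated(all_keys)
    gp <- as.matrix(gene_pats[dedup, , drop = FALSE])
    gmult <- vapply(all_keys[dedup], function(k) {
      sum(pats$multiplicity[all_keys == k])
    }, integer(1))
    tree <- stage("tree", build_fish_tree(gp, multiplicity = gmult,
                                          probe_names = colnames(gp),
                                          allow_wgd = config$allow_wgd,
                                          absorbing_zero = config$absorbing_zero))
    write_fish_tree(tree, file.path(config$out, paste0(sid, "_tree.graphml")))
    logf("[info] %s: tree depth %d, total events %d", sid, tree$tree_depth,
         tree$total_events)
  }

  summary_df <- do.call(rbind, summaries)
  utils::write.table(summary_df, file.path(config$out, "sample_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cna_mat <- do.call(cbind, cna_cols)
  cna_df <- data.frame(gene = rownames(cna_mat), cna_mat,
                       stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(cna_df, file.path(config$out, "cna_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary_df[, c("sample_id", "n_nuclei", "n_patterns",
                                    "instability_index")],
                     file.path(config$out, "instability_index.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(config$events)) {
    ev <- stage("events", {
      df <- utils::read.delim(config$events, row.names = 1L,
                              check.names = FALSE)
      event_matrix(df)
    })
    res <- stage("pair_tests",
                 pairwise_permutation_test(ev, n_perm = config$n_perm,
                                           seed = config$seed))
    utils::write.table(res$pairs, file.path(config$out, "pair_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(res$excluded_events))
      logf("[warning] untestable events excluded: %s",
           paste(res$excluded_events, collapse = ", "))
  }
  invisible(config$out)
}
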