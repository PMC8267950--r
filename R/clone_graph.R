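#' Build the imbalance clone graph of a sample
#'
#' Nuclei are grouped by their gain/loss pattern relative to their own
#' nucleus ploidy (not by raw signal counts, so ploidy-shifted clones with
#' the same relative imbalances collapse together). Each distinct pattern is
#' a clone node sized by its frequency; a directed edge connects two clones
#' when they differ in exactly one gene's state by a single step
#' (neutral <-> gain or neutral <-> loss; loss <-> gain passes through
#' neutral and counts as two changes, so it draws no edge). Edges point from
#' the clone with fewer aberrant genes to the one with more, so the graph is
#' a DAG and evolution reads outward from the most balanced clone.
#'
#' @param records a nucleus table.
#' @param panel a [probe_panel()].
#' @return A list of class `clone_graph` with `nodes` (data.frame `pattern`
#'   label like `"MYC+,DBC2-"`, `n_aberrant`, `multiplicity`, `frequency`,
#'   plus one state column per gene) and `edges` (data.frame `from`, `to`
#'   pattern labels).
#' @export
build_clone_graph <- function(records, panel) {
  if (nrow(records) == 0L) stop("no nuclei")
  m <- count_matrix(records, panel)
  ploidies <- nucleus_ploidies(records, panel)
  genes <- gene_probes(panel)
  states <- t(vapply(seq_len(nrow(m)), function(i) {
    gain_loss_pattern(m[i, ], ploidies[i], panel)
  }, character(length(genes))))
  colnames(states) <- genes

  key <- apply(states, 1L, paste, collapse = "|")
  uniq <- states[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  mult <- as.integer(table(key)[ukey])
  label <- apply(uniq, 1L, state_label)
  n_ab <- rowSums(uniq != "neutral")
  ord <- order(-mult, label)
  uniq <- uniq[ord, , drop = FALSE]
  nodes <- data.frame(pattern = label[ord], n_aberrant = n_ab[ord],
                      multiplicity = mult[ord],
                      frequency = mult[ord] / nrow(records),
                      stringsAsFactors = FALSE)
  nodes <- cbind(nodes, as.data.frame(uniq, stringsAsFactors = FALSE))
  rownames(nodes) <- NULL

  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  k <- nrow(nodes)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      a <- uniq[i, ]
      b <- uniq[j, ]
      diffs <- which(a != b)
      if (length(diffs) != 1L) next
      pair <- sort(unname(c(a[diffs], b[diffs])))
      if (identical(pair, c("gain", "loss"))) next  # two steps via neutral
      if (nodes$n_aberrant[i] < nodes$n_aberrant[j]) {
        edges <- rbind(edges, data.frame(from = nodes$pattern[i],
                                         to = nodes$pattern[j]))
      } else {
        edges <- rbind(edges, data.frame(from = nodes$pattern[j],
                                         to = nodes$pattern[i]))
      }
    }
  }
  structure(list(nodes = nodes, edges = edges, genes = genes),
            class = "clone_graph")
}

state_label <- function(states) {
  ab <- states != "neutral"
  if (!any(ab)) return("balanced")
  paste0(names(states)[ab], ifelse(states[ab] == "gain", "+", "-"),
         collapse = ",")
}

#' @export
print.clone_graph <- function(x, ...) {
  cat(sprintf("<clone_graph> %d clones, %d single-step edges\n",
              nrow(x$nodes), nrow(x$edges)))
  for (i in seq_len(min(nrow(x$nodes), 10L)))
    cat(sprintf("  %-30s %5.1f%%\n", x$nodes$pattern[i],
                100 * x$nodes$frequency[i]))
  if (nrow(x$nodes) > 10L) cat("  ...\n")
  invisible(x)
}

# igraph view of a clone graph (nodes keep pattern + frequency attributes)
clone_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    if (nrow(graph$edges)) graph$edges else
      data.frame(from = character(0), to = character(0)),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$pattern,
                          frequency = graph$nodes$frequency,
                          n_aberrant = graph$nodes$n_aberrant))
  g
}

#' Export a clone graph to GraphML or DOT
#' @param graph a `clone_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_clone_graph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(clone_igraph(graph), path, format = format)
  invisible(path)
}
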