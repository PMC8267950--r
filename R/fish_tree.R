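# Minimal-event copy-number phylogenies over FISH signal patterns.
#
# A tree starts at the all-2s (normal) root and reaches every observed
# pattern through edges that each change a single probe's copy number by one
# unit, or double every probe at once (whole-genome duplication, WGD).
# Unobserved intermediate patterns along an edge path are materialized as
# transit nodes. Under the absorbing-zero rule a probe lost entirely (count
# 0) can never be regained. Every edge costs one event, so minimizing the
# total number of copy-number alterations across the tree is minimizing the
# edge count.

#' Build a minimal-event FISH copy-number tree
#'
#' Greedy agglomeration: starting from the diploid root, repeatedly attach
#' the unattached observed pattern whose cheapest connection to any node
#' already in the tree (observed or transit) is smallest, and realize that
#' connection by inserting one-unit transit steps (plus at most one WGD
#' jump when `allow_wgd`). Ties are broken deterministically: smallest
#' distance, then lexicographically smallest pattern, then earliest-inserted
#' anchor node. Coordinates along a path are stepped in probe order. A
#' transit node whose pattern matches a still-unattached observed pattern is
#' promoted to observed on the spot.
#'
#' @param patterns integer matrix, one row per distinct observed pattern over
#'   the gene probes; or the data.frame from [aggregate_patterns()] (its
#'   count columns restricted to gene probes are used).
#' @param multiplicity integer vector of nuclei per pattern (defaults to 1s;
#'   taken from the `multiplicity` column when `patterns` is a data.frame).
#' @param probe_names optional probe names (defaults to pattern columns).
#' @param allow_wgd permit whole-genome-duplication edges (default TRUE).
#' @param absorbing_zero forbid raising a probe count from 0 (default TRUE).
#' @return An object of class `fish_tree`: list with `nodes` (data.frame
#'   `id`, `pattern`, `observed`, `multiplicity`, `depth`), `edges`
#'   (data.frame `parent`, `child`, `event`), `tree_depth`, `total_events`.
#' @export
build_fish_tree <- function(patterns, multiplicity = NULL, probe_names = NULL,
                            allow_wgd = TRUE, absorbing_zero = TRUE) {
  if (is.data.frame(patterns)) {
    if (is.null(multiplicity) && "multiplicity" %in% names(patterns))
      multiplicity <- patterns$multiplicity
    keep <- setdiff(names(patterns), c("pattern", "multiplicity", "frequency"))
    patterns <- as.matrix(patterns[, keep, drop = FALSE])
  }
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  if (any(patterns < 0)) stop("patterns must be non-negative")
  if (is.null(probe_names)) {
    probe_names <- colnames(patterns)
    if (is.null(probe_names)) probe_names <- paste0("p", seq_len(ncol(patterns)))
  }
  if (is.null(multiplicity)) multiplicity <- rep(1L, nrow(patterns))
  keys <- apply(patterns, 1L, paste, collapse = "-")
  if (anyDuplicated(keys)) stop("observed patterns must be distinct")

  d <- ncol(patterns)
  root <- rep(2L, d)

  # tree state: list of pattern vectors, parallel metadata vectors
  node_pat <- list(root)
  node_obs <- FALSE
  node_mult <- 0L
  node_depth <- 0L
  edges <- data.frame(parent = integer(0), child = integer(0),
                      event = character(0), stringsAsFactors = FALSE)
  node_key <- paste(root, collapse = "-")

  unattached <- seq_len(nrow(patterns))
  root_i <- match(paste(root, collapse = "-"), keys)
  if (!is.na(root_i)) {
    node_obs[1] <- TRUE
    node_mult[1] <- as.integer(multiplicity[root_i])
    unattached <- setdiff(unattached, root_i)
  }

  # cheapest connection from tree node `from` to pattern `to`;
  # returns c(cost, wgd) with wgd 1 when the path starts with a WGD jump
  conn <- function(from, to) {
    best <- c(Inf, 0)
    if (!absorbing_zero || !any(from == 0L & to > 0L)) {
      best <- c(sum(abs(to - from)), 0)
    }
    if (allow_wgd) {
      dbl <- 2L * from
      if (!absorbing_zero || !any(dbl == 0L & to > 0L)) {
        cost <- 1 + sum(abs(to - dbl))
        if (cost < best[1]) best <- c(cost, 1)
      }
    }
    best
  }

  add_node <- function(pat, obs, mult, parent, event) {
    node_pat[[length(node_pat) + 1L]] <<- pat
    node_obs[length(node_pat)] <<- obs
    node_mult[length(node_pat)] <<- mult
    node_depth[length(node_pat)] <<- node_depth[parent] + 1L
    node_key[length(node_pat)] <<- paste(pat, collapse = "-")
    edges <<- rbind(edges, data.frame(parent = parent,
                                      child = length(node_pat),
                                      event = event,
                                      stringsAsFactors = FALSE))
    length(node_pat)
  }

  while (length(unattached)) {
    # pick pattern with cheapest connection to the current tree
    best <- NULL
    for (pi in unattached[order(keys[unattached])]) {
      target <- patterns[pi, ]
      for (ni in seq_along(node_pat)) {
        cc <- conn(node_pat[[ni]], target)
        if (is.null(best) || cc[1] < best$cost) {
          best <- list(cost = cc[1], wgd = cc[2], pattern = pi, anchor = ni)
        }
      }
    }
    if (!is.finite(best$cost))
      stop(sprintf("pattern %s is unroutable under the absorbing-zero rule%s",
                   keys[best$pattern],
                   if (allow_wgd) "" else " with WGD disabled"))
    target <- patterns[best$pattern, ]
    cur_id <- best$anchor
    cur <- node_pat[[cur_id]]
    if (best$cost == 0) {
      # pattern matches an existing transit node: promote it to observed
      node_obs[cur_id] <- TRUE
      node_mult[cur_id] <- as.integer(multiplicity[best$pattern])
      unattached <- setdiff(unattached, best$pattern)
      next
    }

    claim <- function(pat) {
      # is this intermediate an unattached observed pattern?
      hit <- match(paste(pat, collapse = "-"), keys[unattached])
      if (is.na(hit)) list(obs = FALSE, mult = 0L, idx = NA_integer_)
      else list(obs = TRUE,
                mult = as.integer(multiplicity[unattached[hit]]),
                idx = unattached[hit])
    }

    if (best$wgd == 1) {
      nxt <- 2L * cur
      cl <- claim(nxt)
      cur_id <- add_node(nxt, cl$obs, cl$mult, cur_id, "WGD")
      if (cl$obs) unattached <- setdiff(unattached, cl$idx)
      cur <- nxt
    }
    for (i in seq_len(d)) {
      while (cur[i] != target[i]) {
        step <- sign(target[i] - cur[i])
        nxt <- cur
        nxt[i] <- cur[i] + step
        cl <- claim(nxt)
        ev <- paste0(probe_names[i], if (step > 0) "+1" else "-1")
        cur_id <- add_node(nxt, cl$obs, cl$mult, cur_id, ev)
        if (cl$obs) unattached <- setdiff(unattached, cl$idx)
        cur <- nxt
      }
    }
  }

  nodes <- data.frame(id = seq_along(node_pat),
                      pattern = node_key,
                      observed = node_obs,
                      multiplicity = node_mult,
                      depth = node_depth,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, probe_names = probe_names,
                 tree_depth = max(node_depth),
                 total_events = nrow(edges)),
            class = "fish_tree")
}

#' Depth and total-event metrics of a FISH tree
#'
#' Tree depth is the maximum number of edges from the root to any node;
#' total events is the number of edges (one unit copy-number change or one
#' WGD per edge).
#'
#' @param tree a `fish_tree`.
#' @return list with `tree_depth` and `total_events`.
#' @export
tree_metrics <- function(tree) {
  list(tree_depth = tree$tree_depth, total_events = tree$total_events)
}

#' @export
print.fish_tree <- function(x, ...) {
  cat(sprintf(
    "<fish_tree> %d nodes (%d observed, %d transit), depth %d, %d events\n",
    nrow(x$nodes), sum(x$nodes$observed), sum(!x$nodes$observed),
    x$tree_depth, x$total_events))
  invisible(x)
}

#' Export a FISH tree to GraphML or DOT
#'
#' Node attribute `observed` encodes solid (observed signal pattern) versus
#' dashed (inferred transit pattern) rendering; labels use hyphen notation.
#'
#' @param tree a `fish_tree`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_fish_tree <- function(tree, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  vertices <- data.frame(
    name = paste0("v", tree$nodes$id),
    label = tree$nodes$pattern,
    observed = as.integer(tree$nodes$observed),
    multiplicity = tree$nodes$multiplicity,
    style = ifelse(tree$nodes$observed, "solid", "dashed"))
  ed <- data.frame(from = paste0("v", tree$edges$parent, recycle0 = TRUE),
                   to = paste0("v", tree$edges$child, recycle0 = TRUE),
                   event = tree$edges$event)
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = vertices)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Exact minimum-event oracle for small instances
#'
#' Exhaustive minimal Steiner arborescence on the bounded copy-number
#' lattice: vertices are all count vectors within a per-coordinate cap,
#' directed edges are unit steps (up-steps forbidden from 0) and WGD jumps,
#' and a Dreyfus-Wagner dynamic program over terminal subsets yields the
#' exact minimum number of events connecting the diploid root to all
#' observed patterns. Intended as an independent check of
#' [build_fish_tree()]; instance size is strictly bounded.
#'
#' @param patterns integer matrix of observed patterns (rows), at most 4
#'   columns, entries at most `max_copy`, at most 4 patterns.
#' @param allow_wgd permit WGD jumps.
#' @param max_dim,max_copy enforced instance bounds (defaults 4 and 6).
#' @return minimal total event count (integer).
#' @export
steiner_oracle <- function(patterns, allow_wgd = FALSE, max_dim = 4L,
                           max_copy = 6L) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  d <- ncol(patterns)
  k <- nrow(patterns)
  if (d > max_dim || d > 4L) stop("instance exceeds oracle dimension bound")
  if (max(patterns) > max_copy || max_copy > 6L)
    stop("instance exceeds oracle copy-number bound")
  if (any(patterns < 0)) stop("patterns must be non-negative")
  if (k > 4L) stop("oracle handles at most 4 patterns")
  if (anyDuplicated(apply(patterns, 1L, paste, collapse = "-")))
    stop("patterns must be distinct")

  root <- rep(2L, d)
  cap <- pmax(2L, apply(patterns, 2L, max))
  if (allow_wgd) cap <- 2L * cap

  # vertex index <-> lattice point (mixed radix, coordinate 1 fastest)
  radix <- cap + 1L
  nv <- prod(radix)
  mult <- as.integer(cumprod(c(1, radix[-d])))
  to_idx <- function(p) as.integer(sum(p * mult)) + 1L
  grid <- as.matrix(expand.grid(lapply(radix, function(r) 0:(r - 1L))))

  # directed unit-step and WGD edges
  from <- integer(0); to <- integer(0)
  for (i in seq_len(d)) {
    ok_dn <- grid[, i] >= 1L
    from <- c(from, which(ok_dn))
    to <- c(to, which(ok_dn) - mult[i])
    ok_up <- grid[, i] >= 1L & grid[, i] < cap[i]
    from <- c(from, which(ok_up))
    to <- c(to, which(ok_up) + mult[i])
  }
  if (allow_wgd) {
    ok <- rowSums(2L * grid > matrix(cap, nv, d, byrow = TRUE)) == 0L
    w_from <- which(ok)
    w_to <- vapply(w_from, function(v) to_idx(2L * grid[v, ]), integer(1))
    keep <- w_to != w_from  # exclude the all-zero fixed point
    from <- c(from, w_from[keep]); to <- c(to, w_to[keep])
  }
  grev <- igraph::graph_from_edgelist(cbind(to, from), directed = TRUE)
  grev <- igraph::add_vertices(grev, max(0L, nv + 1L - igraph::vcount(grev)))
  igraph::E(grev)$weight <- 1

  # dist_to[v, t] = shortest directed path v -> terminal t in the lattice
  terms <- vapply(seq_len(k), function(i) to_idx(patterns[i, ]), integer(1))
  dist_from_terminal <- function(t) {
    as.numeric(igraph::distances(grev, v = t, to = igraph::V(grev),
                                 mode = "out"))[seq_len(nv)]
  }

  relax <- function(h) {
    # g[v] = min_u dist(v, u) + h[u], via multi-source Dijkstra on grev
    fin <- which(is.finite(h))
    src <- nv + 1L
    g2 <- igraph::add_edges(grev, rbind(src, fin), weight = h[fin])
    as.numeric(igraph::distances(g2, v = src, to = igraph::V(g2),
                                 mode = "out"))[seq_len(nv)]
  }

  nsub <- bitwShiftL(1L, k) - 1L
  f <- matrix(Inf, nv, nsub)
  for (i in seq_len(k))
    f[, bitwShiftL(1L, i - 1L)] <- dist_from_terminal(terms[i])
  if (k > 1L) {
    for (S in seq_len(nsub)) {
      if (sum(bitwAnd(S, bitwShiftL(1L, 0:(k - 1L))) > 0L) < 2L) next
      h <- rep(Inf, nv)
      A <- bitwAnd(S - 1L, S)
      while (A > 0L) {
        B <- S - A
        if (A < B) h <- pmin(h, f[, A] + f[, B])
        A <- bitwAnd(A - 1L, S)
      }
      f[, S] <- relax(h)
    }
  }
  res <- f[to_idx(root), nsub]
  if (!is.finite(res)) stop("instance is unroutable under absorbing zero")
  as.integer(res)
}
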