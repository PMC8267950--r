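# Pairwise mutual-exclusivity / co-occurrence permutation tests on binary
# alteration matrices (samples x events), in the spirit of MEMo's pairwise
# use: the null preserves every sample's alteration burden and every
# event's prevalence via edge-switching matrix randomization.

#' Assemble a binary event matrix
#'
#' @param values 0/1 matrix or data.frame, samples in rows, alteration
#'   events in columns (e.g. `"CNA:MYC:gain"`, `"MUT:PIK3CA"`).
#' @param samples optional sample ids (defaults to rownames or `s<row>`).
#' @return integer matrix with dimnames, validated to be 0/1.
#' @export
event_matrix <- function(values, samples = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("event matrix must be 0/1")
  if (is.null(colnames(m))) colnames(m) <- paste0("e", seq_len(ncol(m)))
  if (is.null(samples)) {
    samples <- rownames(m)
    if (is.null(samples)) samples <- paste0("s", seq_len(nrow(m)))
  }
  rownames(m) <- samples
  m
}

#' Pairwise co-occurrence and exclusivity permutation tests
#'
#' For every pair of testable events, compares the observed overlap (number
#' of samples carrying both) against a margin-preserving null generated by
#' edge-switching randomization of the whole matrix: every draw preserves
#' every row and column sum exactly. P-values use the add-one estimator
#' `(1 + #extreme) / (1 + n_perm)` (upper tail for co-occurrence, lower
#' tail for exclusivity) and are Benjamini-Hochberg adjusted across all
#' tested pairs, separately per direction. Events altered in no sample or
#' in every sample carry no information under fixed margins and are
#' excluded and reported.
#'
#' @param events a 0/1 matrix from [event_matrix()].
#' @param n_perm number of null draws (default 10000).
#' @param seed optional integer seed (applied via `set.seed`).
#' @param swaps_per_one switching steps per draw are `swaps_per_one` times
#'   the number of 1s in the matrix (default 10).
#' @return A list with `pairs` (data.frame `event_a`, `event_b`,
#'   `observed_overlap`, `p_cooccurrence`, `p_exclusivity`,
#'   `q_cooccurrence`, `q_exclusivity`) and `excluded_events`.
#' @export
pairwise_permutation_test <- function(events, n_perm = 10000L, seed = NULL,
                                      swaps_per_one = 10L) {
  events <- event_matrix(events)
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  cs <- colSums(events)
  constant <- cs == 0L | cs == nrow(events)
  excluded <- colnames(events)[constant]
  keep <- events[, !constant, drop = FALSE]
  if (ncol(keep) < 2L) stop("fewer than two testable events")

  n_swaps <- as.integer(swaps_per_one) * sum(keep)
  res <- .perm_pair_overlaps(keep, as.integer(n_perm), n_swaps)
  nm <- colnames(keep)
  p_co <- (1 + res$n_ge) / (1 + n_perm)
  p_ex <- (1 + res$n_le) / (1 + n_perm)
  pairs <- data.frame(
    event_a = nm[res$pair_a + 1L],
    event_b = nm[res$pair_b + 1L],
    observed_overlap = res$observed,
    p_cooccurrence = p_co,
    p_exclusivity = p_ex,
    q_cooccurrence = bh_adjust(p_co),
    q_exclusivity = bh_adjust(p_ex),
    stringsAsFactors = FALSE)
  list(pairs = pairs, excluded_events = excluded)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric p-values in (0, 1].
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sided group comparison helper
#'
#' Thin dispatcher over stock tests so cohort comparisons are scriptable:
#' `"t"` (two groups, two-sided Welch t-test), `"anova"` (one-way),
#' `"fisher"` and `"chisq"` (on a contingency table, or on grouped
#' categorical vectors tabulated first).
#'
#' @param values_by_group for `"t"`/`"anova"`: a named list of numeric
#'   vectors, one per group; for `"fisher"`/`"chisq"`: a contingency matrix,
#'   or a list of categorical vectors (tabulated group x value).
#' @param kind one of `"t"`, `"anova"`, `"fisher"`, `"chisq"`.
#' @return the test p-value (numeric scalar).
#' @export
compare_groups <- function(values_by_group,
                           kind = c("t", "anova", "fisher", "chisq")) {
  kind <- match.arg(kind)
  if (kind %in% c("t", "anova")) {
    if (!is.list(values_by_group) || length(values_by_group) < 2L)
      stop("need a list of >= 2 groups")
    if (any(vapply(values_by_group, length, integer(1)) < 2L))
      stop("degenerate group: fewer than 2 observations")
    if (kind == "t") {
      if (length(values_by_group) != 2L) stop("t-test needs exactly 2 groups")
      return(stats::t.test(values_by_group[[1]], values_by_group[[2]],
                           alternative = "two.sided")$p.value)
    }
    v <- unlist(values_by_group, use.names = FALSE)
    g <- factor(rep(seq_along(values_by_group),
                    vapply(values_by_group, length, integer(1))))
    return(summary(stats::aov(v ~ g))[[1]][["Pr(>F)"]][1])
  }
  tab <- if (is.matrix(values_by_group) || is.table(values_by_group)) {
    as.matrix(values_by_group)
  } else {
    g <- rep(seq_along(values_by_group),
             vapply(values_by_group, length, integer(1)))
    table(g, unlist(values_by_group, use.names = FALSE))
  }
  if (any(dim(tab) < 2L)) stop("degenerate contingency table")
  if (kind == "fisher") stats::fisher.test(tab)$p.value
  else stats::chisq.test(tab, correct = FALSE)$p.value
}
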