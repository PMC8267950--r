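# Per-nucleus ploidy annotation, gain/loss patterns, sample-level summaries.
#
# All thresholds carry the defaults used throughout the pipeline:
# aneuploid cutoff 2.2 on the one-decimal average ploidy, CNA call at >= 15%
# of nuclei, major call at >= 85%, amplification when the mean gene count
# strictly exceeds twice the assigned sample ploidy.

# round half away from zero (commercial rounding); R's round() is banker's.
# The epsilon guards exact halves held as one-ulp-short doubles (means of
# integer counts, e.g. 215/100): far smaller than any real data increment.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Annotate the ploidy of a single nucleus
#'
#' The baseline copy number of a nucleus is anchored by the centromere
#' reference probes and an average over gene probes after setting aside
#' amplified markers that would bias the mean. Concretely: a candidate
#' ploidy is the median centromere count (median gene count when the panel
#' has no centromeres); gene probes counting more than twice the candidate
#' are excluded as amplified; the ploidy is the pooled mean of centromere
#' counts and retained gene counts, rounded half-up to an integer.
#'
#' @param counts integer vector over the panel probes (panel order, or named).
#' @param panel a [probe_panel()].
#' @return A list with `ploidy` (integer >= 1), `excluded` (names of gene
#'   probes set aside as amplified) and `note`.
#' @examples
#' panel <- default_panel()
#' annotate_ploidy(c(8, 4, 4, 4, 3, 2, 4, 5, 4, 4), panel)$ploidy  # 4
#' @export
annotate_ploidy <- function(counts, panel) {
  counts <- align_counts(counts, panel)
  gene <- counts[panel$role == "gene"]
  cen <- counts[panel$role == "centromere"]
  if (length(gene) == 0L) stop("panel has no gene probes")
  p0 <- if (length(cen)) stats::median(cen) else stats::median(gene)
  excluded <- gene > 2 * p0
  retained <- gene[!excluded]
  pool <- c(cen, retained)
  if (length(pool) == 0L) {
    if (length(cen)) {
      pool <- cen
    } else {
      stop("all gene probes excluded as amplified and no centromere probes")
    }
  }
  ploidy <- max(1L, as.integer(round_half_up(mean(pool))))
  note <- if (any(excluded)) {
    sprintf("excluded as amplified: %s",
            paste(names(gene)[excluded], collapse = ", "))
  } else {
    "no probes excluded"
  }
  list(ploidy = ploidy, excluded = names(gene)[excluded], note = note)
}

align_counts <- function(counts, panel) {
  if (!is.null(names(counts)) && all(panel$name %in% names(counts))) {
    counts <- counts[panel$name]
  } else if (length(counts) == nrow(panel)) {
    names(counts) <- panel$name
  } else {
    stop(sprintf("counts has length %d; panel has %d probes",
                 length(counts), nrow(panel)))
  }
  counts
}

#' Gain/loss pattern of a nucleus relative to its ploidy
#'
#' Each gene probe is trichotomized against the nucleus baseline: `gain`
#' when the count exceeds the ploidy, `loss` when below, `neutral` when
#' equal. Centromere probes are reference-only and carry no state.
#'
#' @param counts integer vector over the panel probes.
#' @param ploidy nucleus ploidy (integer >= 1).
#' @param panel a [probe_panel()].
#' @return named character vector over gene probes with values
#'   `"gain"`/`"loss"`/`"neutral"`.
#' @examples
#' panel <- default_panel()
#' gain_loss_pattern(c(2, 1, 3, 2, 1, 2, 2, 2, 2, 2), 2, panel)
#' @export
gain_loss_pattern <- function(counts, ploidy, panel) {
  stopifnot(ploidy >= 1)
  counts <- align_counts(counts, panel)
  gene <- counts[panel$role == "gene"]
  state <- ifelse(gene > ploidy, "gain", ifelse(gene < ploidy, "loss",
                                                "neutral"))
  names(state) <- names(gene)
  state
}

# per-nucleus ploidies for a whole table (integer vector)
nucleus_ploidies <- function(records, panel) {
  m <- count_matrix(records, panel)
  vapply(seq_len(nrow(m)), function(i) annotate_ploidy(m[i, ], panel)$ploidy,
         integer(1))
}

#' Flag amplified gene probes at the sample level
#'
#' A gene is amplified when its mean signal count across all nuclei strictly
#' exceeds twice the assigned sample ploidy.
#'
#' @param records a nucleus table.
#' @param panel a [probe_panel()].
#' @param sample_ploidy assigned overall ploidy of the sample (integer >= 1).
#' @return character vector of amplified gene probe names (possibly empty).
#' @export
amplification_flags <- function(records, panel, sample_ploidy) {
  stopifnot(sample_ploidy >= 1)
  m <- count_matrix(records, panel)
  genes <- gene_probes(panel)
  means <- colMeans(m[, genes, drop = FALSE])
  genes[means > 2 * sample_ploidy]
}

#' Summarize a sample: ploidy, instability index, CNA calls
#'
#' Computes, over all enumerated nuclei of one sample:
#' \itemize{
#'   \item `average_ploidy`: mean of per-nucleus ploidies, rounded half-up to
#'     one decimal; `ploidy_class` is `"aneuploid"` iff `average_ploidy`
#'     >= 2.2 (2.0/2.1 read as diploid).
#'   \item `instability_index`: `I = N * 100 / n` with `N` the number of
#'     distinct signal patterns and `n` the number of nuclei. By default the
#'     pattern universe is the full probe vector; set
#'     `patterns_gene_only = TRUE` to restrict it to gene probes.
#'   \item per-gene CNA calls: the gain (loss) fraction is the share of
#'     nuclei whose count exceeds (falls short of) their own nucleus ploidy;
#'     a call is made when the fraction is >= `cna_minor` (default 0.15) and
#'     graded major when >= `cna_major` (default 0.85). When both gain and
#'     loss cross the minor threshold the larger fraction wins the single
#'     call (gain on an exact tie); both fractions are always reported.
#'   \item `amplified_genes` per [amplification_flags()], against the rounded
#'     modal per-nucleus ploidy.
#'   \item the major clone (most frequent signal pattern) and its fraction.
#' }
#'
#' @param records a nucleus table.
#' @param panel a [probe_panel()].
#' @param cna_minor,cna_major CNA call fractions (defaults 0.15 / 0.85).
#' @param aneuploid_cutoff average-ploidy cutoff (default 2.2).
#' @param patterns_gene_only count signal patterns over gene probes only.
#' @return An object of class `sample_summary`: a list with fields
#'   `n_nuclei`, `n_patterns`, `instability_index`, `average_ploidy`,
#'   `ploidy_class`, `sample_ploidy`, `cna_calls` (data.frame gene /
#'   gain_fraction / loss_fraction / call), `amplified_genes`,
#'   `major_clone` (pattern string) and `major_clone_fraction`.
#' @export
sample_summary <- function(records, panel, cna_minor = 0.15, cna_major = 0.85,
                           aneuploid_cutoff = 2.2,
                           patterns_gene_only = FALSE) {
  if (nrow(records) == 0L) stop("cannot summarize an empty sample")
  n <- nrow(records)
  m <- count_matrix(records, panel)
  ploidies <- nucleus_ploidies(records, panel)

  pat_cols <- if (patterns_gene_only) gene_probes(panel) else panel$name
  key <- apply(m[, pat_cols, drop = FALSE], 1L, paste, collapse = "-")
  n_patterns <- length(unique(key))
  instability <- n_patterns * 100 / n

  avg_ploidy <- round_half_up(mean(ploidies), 1L)
  ploidy_class <- if (avg_ploidy >= aneuploid_cutoff) "aneuploid" else "diploid"

  # sample ploidy for the amplification test: rounded modal nucleus ploidy
  tab <- table(ploidies)
  modal <- as.integer(names(tab)[which.max(tab)])

  genes <- gene_probes(panel)
  gm <- m[, genes, drop = FALSE]
  gain_frac <- colMeans(gm > ploidies)
  loss_frac <- colMeans(gm < ploidies)
  call <- mapply(function(g, l) {
    if (g < cna_minor && l < cna_minor) return("none")
    if (g >= l) {
      if (g >= cna_major) "gain_major" else "gain_minor"
    } else {
      if (l >= cna_major) "loss_major" else "loss_minor"
    }
  }, gain_frac, loss_frac)
  cna <- data.frame(gene = genes, gain_fraction = unname(gain_frac),
                    loss_fraction = unname(loss_frac), call = unname(call),
                    stringsAsFactors = FALSE)

  pats <- aggregate_patterns(records, panel)
  out <- list(
    n_nuclei = n,
    n_patterns = n_patterns,
    instability_index = instability,
    average_ploidy = avg_ploidy,
    ploidy_class = ploidy_class,
    sample_ploidy = modal,
    cna_calls = cna,
    amplified_genes = amplification_flags(records, panel, modal),
    major_clone = pats$pattern[1],
    major_clone_fraction = pats$frequency[1]
  )
  class(out) <- "sample_summary"
  out
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> n = %d nuclei, N = %d patterns\n",
              x$n_nuclei, x$n_patterns))
  cat(sprintf("  instability index I = %.1f\n", x$instability_index))
  cat(sprintf("  average ploidy %.1f (%s), sample ploidy %d\n",
              x$average_ploidy, x$ploidy_class, x$sample_ploidy))
  cat(sprintf("  major clone %s (%.1f%% of nuclei)\n", x$major_clone,
              100 * x$major_clone_fraction))
  called <- x$cna_calls[x$cna_calls$call != "none", ]
  if (nrow(called)) {
    cat("  CNA calls:\n")
    for (i in seq_len(nrow(called)))
      cat(sprintf("    %-7s %s (gain %.0f%%, loss %.0f%%)\n", called$gene[i],
                  called$call[i], 100 * called$gain_fraction[i],
                  100 * called$loss_fraction[i]))
  } else cat("  CNA calls: none\n")
  if (length(x$amplified_genes))
    cat("  amplified:", paste(x$amplified_genes, collapse = ", "), "\n")
  invisible(x)
}

#' One-row data.frame rendering of a sample summary
#' @param x a `sample_summary`.
#' @param sample_id optional id column value.
#' @return data.frame with one row.
#' @export
summary_row <- function(x, sample_id = NA_character_) {
  data.frame(sample_id = sample_id, n_nuclei = x$n_nuclei,
             n_patterns = x$n_patterns,
             instability_index = x$instability_index,
             average_ploidy = x$average_ploidy, ploidy_class = x$ploidy_class,
             sample_ploidy = x$sample_ploidy,
             major_clone = x$major_clone,
             major_clone_fraction = x$major_clone_fraction,
             amplified_genes = paste(x$amplified_genes, collapse = ","),
             stringsAsFactors = FALSE)
}
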