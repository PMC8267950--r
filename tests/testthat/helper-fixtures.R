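# Shared fixtures, built in code.

# gene-only panel matching the default panel's eight gene probes
gene_only_panel <- function() {
  p <- default_panel()
  probe_panel(gene_probes(p), p$locus[p$role == "gene"], rep("gene", 8),
              p$gene_class[p$role == "gene"])
}

# reconstruction of the diploid long-survival case with the lowest
# instability of the cohort: two printed clone patterns (217 and 29 of 250
# nuclei) plus three distinct minor patterns (2/1/1), centromeres at 2
case7L_records <- function(panel = default_panel()) {
  p1 <- c(2, 1, 3, 2, 1, 2, 2, 2, 2, 2)
  p2 <- c(2, 1, 4, 2, 1, 2, 2, 2, 2, 2)
  m1 <- c(2, 1, 3, 2, 1, 2, 2, 3, 2, 2)
  m2 <- c(2, 2, 3, 2, 1, 2, 2, 2, 2, 2)
  m3 <- c(2, 1, 3, 2, 2, 2, 2, 2, 2, 2)
  m <- rbind(matrix(p1, 217, 10, byrow = TRUE),
             matrix(p2, 29, 10, byrow = TRUE),
             matrix(m1, 2, 10, byrow = TRUE),
             matrix(m2, 1, 10, byrow = TRUE),
             matrix(m3, 1, 10, byrow = TRUE))
  nucleus_table(m, panel)
}

# nucleus table where every nucleus carries the same counts
uniform_records <- function(counts, n, panel = default_panel()) {
  nucleus_table(matrix(counts, n, length(counts), byrow = TRUE), panel)
}

# random copy-number patterns generated the way tumor clones arise: unit
# events accumulated along a random genealogy from the diploid root
evolved_patterns <- function(k = 3, d = 4, max_events = 3, max_copy = 6) {
  pool <- matrix(2L, 1, d)
  repeat {
    src <- pool[sample.int(nrow(pool), 1L), ]
    for (e in seq_len(sample.int(max_events, 1L))) {
      movable <- which(src > 0L & src < max_copy)
      if (!length(movable)) break
      g <- movable[sample.int(length(movable), 1L)]
      src[g] <- src[g] + sample(c(-1L, 1L), 1L)
    }
    pool <- rbind(pool, src)
    cand <- unique(pool[-1, , drop = FALSE])
    cand <- cand[apply(cand, 1L, function(r) !all(r == 2L)), , drop = FALSE]
    if (nrow(cand) >= k) {
      out <- unique(cand[sample.int(nrow(cand), k), , drop = FALSE])
      if (nrow(out) == k) return(out)
    }
    if (nrow(pool) > 60L) pool <- matrix(2L, 1, d)
  }
}

# a fully clean annotated variant record passing all 11 criteria
clean_variant <- function(i = 1L, ...) {
  r <- data.frame(
    sample_id = sprintf("S%02d", i), gene = "OTHER1",
    chrom = "chr1", pos = 1000L + 10L * i, ref = "A", alt = "T",
    caller_pass = TRUE, alt_fraction = 0.4, total_depth = 100L,
    alt_depth = 40L, qual = 90, mapq = 60, dbnsfp_impact = "high",
    is_common_snp = FALSE, af_exac = 0, af_esp_global = 0, maf_ea = 0,
    cosmic_case_count = 150L, stringsAsFactors = FALSE)
  mods <- list(...)
  for (f in names(mods)) r[[f]] <- mods[[f]]
  r
}

# bare-bones DNA histogram: dominant 2c line, optional extra line and
# optional cells above 5c, at 0.05c binning
toy_histogram <- function(n2 = 3000L, extra_c = NULL, n_extra = 0L,
                          n_above_5c = 0L) {
  cv <- seq(1.5, 2.5, by = 0.05)
  w <- dnorm(cv, 2, 0.08)
  cnt <- round(n2 * w / sum(w))
  if (!is.null(extra_c) && n_extra > 0L) {
    cv2 <- seq(extra_c - 0.5, extra_c + 0.5, by = 0.05)
    w2 <- dnorm(cv2, extra_c, 0.08)
    cv <- c(cv, cv2)
    cnt <- c(cnt, round(n_extra * w2 / sum(w2)))
  }
  if (n_above_5c > 0L) {
    cv <- c(cv, 5.5)
    cnt <- c(cnt, n_above_5c)
  }
  o <- order(cv)
  keep <- cnt[o] > 0
  dna_histogram(cv[o][keep], cnt[o][keep])
}
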