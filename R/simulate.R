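# Synthetic data generators with known ground truth, emulating the
# statistical structure of miFISH nucleus tables, annotated variant tables
# and DNA-content histograms. Every generator is deterministic under
# set.seed()-style seeding via its `seed` argument.

#' Simulation configuration for a synthetic miFISH sample
#'
#' Defaults describe a typical enumerated sample: 250 completely scored
#' nuclei, a clonal structure with a dominant clone (frequency forced to at
#' least 0.3) plus minor clones derived along a random single-step clone
#' tree, and a 2% per-probe miscount rate standing in for hybridization and
#' segmentation error (low enough that single-clone simulations land in the
#' instability-index range of stable tumors).
#'
#' @param seed integer RNG seed.
#' @param n_nuclei nuclei to draw (default 250).
#' @param founder `"diploid"` (all gene probes at 2), `"wgd_tetraploid"`
#'   (all at 4) or `"hypodiploid"` (single copies of DBC2, MYC, CDH1, TP53
#'   and HER2 on the default panel, patterned on a severely hypodiploid
#'   tumor).
#' @param n_clones clones including the founder (default 3).
#' @param clone_frequencies optional simplex vector (length `n_clones`);
#'   default: symmetric Dirichlet(1) draw, redrawn until the largest
#'   frequency is >= 0.3, largest assigned to the founder.
#' @param events_per_clone single-probe one-unit events separating each
#'   derived clone from its (randomly chosen) parent clone (default 2).
#' @param miscount_rate per-probe per-nucleus probability of a +/-1 miscount
#'   (default 0.02, must be in [0, 0.2]).
#' @param centromere_tracks_ploidy centromere counts follow the clone's
#'   baseline ploidy (default TRUE).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_nuclei = 250L,
                       founder = c("diploid", "wgd_tetraploid", "hypodiploid"),
                       n_clones = 3L, clone_frequencies = NULL,
                       events_per_clone = 2L, miscount_rate = 0.02,
                       centromere_tracks_ploidy = TRUE) {
  founder <- match.arg(founder)
  if (miscount_rate < 0 || miscount_rate > 0.2)
    stop("miscount_rate must be in [0, 0.2]")
  if (!is.null(clone_frequencies)) {
    if (length(clone_frequencies) != n_clones)
      stop("clone_frequencies length must equal n_clones")
    if (abs(sum(clone_frequencies) - 1) > 1e-9 || any(clone_frequencies <= 0))
      stop("clone_frequencies must be a positive simplex vector")
  }
  structure(list(seed = as.integer(seed), n_nuclei = as.integer(n_nuclei),
                 founder = founder, n_clones = as.integer(n_clones),
                 clone_frequencies = clone_frequencies,
                 events_per_clone = as.integer(events_per_clone),
                 miscount_rate = miscount_rate,
                 centromere_tracks_ploidy = centromere_tracks_ploidy),
            class = "sim_config")
}

founder_pattern <- function(founder, panel) {
  genes <- gene_probes(panel)
  g <- switch(founder,
    diploid = rep(2L, length(genes)),
    wgd_tetraploid = rep(4L, length(genes)),
    hypodiploid = {
      v <- rep(2L, length(genes))
      lost <- intersect(c("DBC2", "MYC", "CDH1", "TP53", "HER2"), genes)
      if (length(lost) == 0L) lost <- genes[seq_len(ceiling(length(genes) / 2))]
      v[match(lost, genes)] <- 1L
      v
    })
  names(g) <- genes
  g
}

founder_ploidy <- function(founder) {
  switch(founder, diploid = 2L, wgd_tetraploid = 4L, hypodiploid = 2L)
}

#' Simulate a miFISH nucleus table with known ground truth
#'
#' A clone tree is grown from the founder pattern: each derived clone picks
#' a random existing parent clone and applies `events_per_clone` random
#' single-probe one-unit changes (absorbing zero respected; re-draws avoid
#' colliding with an existing clone pattern). Nuclei are assigned to clones
#' by a multinomial draw from the clone frequencies, centromere counts are
#' set to the clone's baseline ploidy when tracking, and independent
#' per-probe miscount noise (+/-1 with equal probability, floored at 0) is
#' applied last.
#'
#' @param config a [sim_config()].
#' @param panel a [probe_panel()] (default [default_panel()]).
#' @return list with `records` (nucleus table) and `truth` (list: `clones`
#'   matrix of gene-probe patterns, `frequencies`, `assignment` per
#'   nucleus, `ploidy` baseline, `ploidy_class`, `parent` clone tree,
#'   `cna_fractions` per gene expected gain/loss fractions).
#' @export
simulate_sample <- function(config, panel = default_panel()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- gene_probes(panel)
  cens <- centromere_probes(panel)
  base <- founder_pattern(config$founder, panel)
  ploidy <- founder_ploidy(config$founder)

  k <- config$n_clones
  clones <- matrix(0L, k, length(genes), dimnames = list(NULL, genes))
  clones[1, ] <- base
  parent <- rep(NA_integer_, k)
  if (k > 1L) {
    for (ci in 2:k) {
      repeat {
        par <- sample.int(ci - 1L, 1L)
        pat <- clones[par, ]
        for (e in seq_len(config$events_per_clone)) {
          movable <- which(pat > 0L)
          g <- movable[sample.int(length(movable), 1L)]
          step <- sample(c(-1L, 1L), 1L)
          pat[g] <- max(0L, pat[g] + step)
        }
        dup <- any(apply(clones[seq_len(ci - 1L), , drop = FALSE], 1L,
                         function(r) all(r == pat)))
        if (!dup) break
      }
      clones[ci, ] <- pat
      parent[ci] <- par
    }
  }

  freqs <- config$clone_frequencies
  if (is.null(freqs)) {
    repeat {
      raw <- stats::rgamma(k, shape = 1)
      freqs <- raw / sum(raw)
      if (max(freqs) >= 0.3 || k == 1L) break
    }
    freqs <- sort(freqs, decreasing = TRUE)  # founder carries the major clone
  }

  assignment <- sample.int(k, config$n_nuclei, replace = TRUE, prob = freqs)
  counts <- matrix(0L, config$n_nuclei, nrow(panel),
                   dimnames = list(NULL, panel$name))
  counts[, genes] <- clones[assignment, , drop = FALSE]
  if (length(cens)) {
    cen_val <- if (config$centromere_tracks_ploidy) ploidy else 2L
    counts[, cens] <- cen_val
  }
  if (config$miscount_rate > 0) {
    flip <- matrix(stats::runif(length(counts)) < config$miscount_rate,
                   nrow(counts))
    delta <- matrix(sample(c(-1L, 1L), length(counts), replace = TRUE),
                    nrow(counts))
    counts <- pmax(counts + flip * delta, 0L)
  }
  records <- nucleus_table(counts, panel)

  gain_frac <- colSums((clones > ploidy) * freqs)
  loss_frac <- colSums((clones < ploidy) * freqs)
  truth <- list(clones = clones, frequencies = freqs,
                assignment = assignment, ploidy = ploidy,
                ploidy_class = if (ploidy >= 2.2) "aneuploid" else "diploid",
                parent = parent,
                cna_fractions = data.frame(gene = genes,
                                           gain_fraction = unname(gain_frac),
                                           loss_fraction = unname(loss_frac)))
  list(records = records, truth = truth)
}

#' Simulate an annotated variant table with known filter verdicts
#'
#' Builds `n_records` fully annotated variant records of which exactly
#' `round(pass_fraction * n_records)` pass the 11-criterion cascade. Passing
#' records are clean on every rule; each failing record is engineered to
#' trip one specific criterion, cycling through criteria 1-11 so every rule
#' is exercised whenever at least 11 records fail.
#'
#' @param n_records total records.
#' @param pass_fraction fraction passing, in [0, 1].
#' @param seed integer RNG seed.
#' @return list with `records` (data.frame for [filter_table()]) and
#'   `expected` (logical vector of intended verdicts, plus attribute
#'   `criterion` with the targeted failing rule, NA for passing records).
#' @export
simulate_variant_table <- function(n_records, pass_fraction, seed = 1L) {
  stopifnot(pass_fraction >= 0, pass_fraction <= 1)
  set.seed(seed)
  n_pass <- round(pass_fraction * n_records)
  passed <- rep(c(TRUE, FALSE), c(n_pass, n_records - n_pass))

  clean <- function(i) {
    data.frame(
      sample_id = sprintf("S%02d", i), gene = "OTHER1",
      chrom = "chr1", pos = 1000L + 10L * i, ref = "A", alt = "T",
      caller_pass = TRUE, alt_fraction = 0.4, total_depth = 100L,
      alt_depth = 40L, qual = 90, mapq = 60, dbnsfp_impact = "high",
      is_common_snp = FALSE, af_exac = 0, af_esp_global = 0, maf_ea = 0,
      cosmic_case_count = 150L, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(n_records), clean)
  criterion <- rep(NA_integer_, n_records)
  fail_idx <- which(!passed)
  for (j in seq_along(fail_idx)) {
    i <- fail_idx[j]
    crit <- ((j - 1L) %% 11L) + 1L
    criterion[i] <- crit
    r <- rows[[i]]
    r <- switch(crit,
      { r$caller_pass <- FALSE; r },
      { r$alt_fraction <- 0.04; r },
      { r$alt_depth <- 3L; r },
      { r$qual <- 20; r },
      { r$dbnsfp_impact <- "low"; r },
      { r$is_common_snp <- TRUE; r },
      { r$af_exac <- 0.01; r },
      { r$mapq <- 35; r },                     # heavy branch, MAPQ < 40
      { r$mapq <- 50; r$cosmic_case_count <- 5L; r },  # light branch < 55
      { r$cosmic_case_count <- 5L
        r$pos <- 999999L; r },                 # shared site, set below
      { r$cosmic_case_count <- 0L; r$dbnsfp_impact <- "moderate"; r })
    rows[[i]] <- r
  }
  # criterion-10 records share one site across their (distinct) samples
  c10 <- fail_idx[which(criterion[fail_idx] == 10L)]
  if (length(c10) == 1L) {
    # recurrence needs a second sample: add a clean-looking twin that also
    # fails criterion 10 cannot be made without changing counts, so instead
    # duplicate the site into another existing criterion-10 record slot or
    # flip to criterion 3 when impossible
    rows[[c10]]$alt_depth <- 3L
    criterion[c10] <- 3L
    rows[[c10]]$pos <- 1000L + 10L * c10
  }
  records <- do.call(rbind, rows)
  attr(passed, "criterion") <- criterion
  list(records = records, expected = passed)
}

#' Simulate a DNA-content histogram of known ploidy class
#'
#' Diploid samples mix a dominant 2c stem line with a small 4c
#' (G2/tetraploid-fraction) line and a light debris floor kept below 5c.
#' Aneuploid samples either add a stem line at a c-value outside the 2c/4c
#' windows or carry a heavy tail above 5c.
#'
#' @param ploidy_class `"diploid"` or `"aneuploid"`.
#' @param n_cells total cells (>= 100).
#' @param seed integer RNG seed.
#' @param aneuploid_mode `"stemline"` (extra line at a c-value drawn outside
#'   the 2c/4c windows) or `"tail_5c"` (heavy >5c tail).
#' @return a [dna_histogram()] binned at 0.05c.
#' @export
simulate_histogram <- function(ploidy_class = c("diploid", "aneuploid"),
                               n_cells = 5000L, seed = 1L,
                               aneuploid_mode = c("stemline", "tail_5c")) {
  ploidy_class <- match.arg(ploidy_class)
  aneuploid_mode <- match.arg(aneuploid_mode)
  if (n_cells < 100L) stop("n_cells must be >= 100")
  set.seed(seed)
  sd_line <- 0.08
  if (ploidy_class == "diploid") {
    n2 <- round(0.90 * n_cells); n4 <- round(0.07 * n_cells)
    nd <- n_cells - n2 - n4
    vals <- c(stats::rnorm(n2, 2, sd_line), stats::rnorm(n4, 4, sd_line),
              stats::runif(nd, 1.2, 4.8))
  } else if (aneuploid_mode == "stemline") {
    extra <- sample(c(stats::runif(1, 2.6, 3.6), stats::runif(1, 4.6, 4.9)),
                    1L)
    n2 <- round(0.45 * n_cells); ne <- round(0.45 * n_cells)
    nd <- n_cells - n2 - ne
    vals <- c(stats::rnorm(n2, 2, sd_line), stats::rnorm(ne, extra, sd_line),
              stats::runif(nd, 1.2, 4.8))
  } else {
    n2 <- round(0.85 * n_cells); nt <- round(0.10 * n_cells)
    nd <- n_cells - n2 - nt
    vals <- c(stats::rnorm(n2, 2, sd_line), stats::runif(nt, 5.2, 8),
              stats::runif(nd, 1.2, 4.8))
  }
  vals <- pmax(vals, 0.05)
  breaks <- seq(0, max(vals) + 0.05, by = 0.05)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0
  dna_histogram(h$mids[keep], h$counts[keep])
}
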