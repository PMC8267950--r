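test_that("each filter criterion is triggered by its dedicated violation", {
  base <- clean_variant()
  base$n_samples_with_variant <- 1L
  expect_true(apply_filters(base)$passed)

  trip <- list(
    list(crit = 1L, caller_pass = FALSE),
    list(crit = 2L, alt_fraction = 0.04),
    list(crit = 2L, alt_fraction = 0.05),          # inclusive <= 5%
    list(crit = 3L, total_depth = 5L, alt_depth = 2L),
    list(crit = 3L, alt_depth = 3L),
    list(crit = 4L, qual = 29.9),
    list(crit = 5L, dbnsfp_impact = "low"),
    list(crit = 6L, is_common_snp = TRUE),
    list(crit = 7L, af_exac = 0.0011),
    list(crit = 7L, maf_ea = 0.002),
    list(crit = 8L, mapq = 39),                    # COSMIC-heavy branch
    list(crit = 9L, mapq = 50, cosmic_case_count = 3L),
    list(crit = 11L, cosmic_case_count = 0L, dbnsfp_impact = "moderate")
  )
  for (tc in trip) {
    r <- base
    for (f in setdiff(names(tc), "crit")) r[[f]] <- tc[[f]]
    v <- apply_filters(r)
    expect_false(v$passed)
    expect_true(tc$crit %in% v$failed_criteria,
                label = sprintf("criterion %d in %s", tc$crit,
                                paste(v$failed_criteria, collapse = ",")))
  }
  # criterion 10 needs table context
  r10 <- base
  r10$n_samples_with_variant <- 2L
  r10$cosmic_case_count <- 50L
  expect_equal(apply_filters(r10)$failed_criteria, 10L)
})

test_that("the two-tier MAPQ rule exempts the hotspot/COSMIC-heavy branch", {
  r <- clean_variant(gene = "TP53", mapq = 45, cosmic_case_count = 500L)
  r$n_samples_with_variant <- 1L
  expect_true(apply_filters(r)$passed)  # 45 >= 40 on the heavy branch

  r2 <- clean_variant(gene = "OTHER2", mapq = 50, cosmic_case_count = 3L)
  r2$n_samples_with_variant <- 1L
  v <- apply_filters(r2)
  expect_true(9L %in% v$failed_criteria)

  # hotspot gene with few COSMIC cases still rides the lenient tier
  r3 <- clean_variant(gene = "PIK3CA", mapq = 45, cosmic_case_count = 0L)
  r3$n_samples_with_variant <- 1L
  expect_false(9L %in% apply_filters(r3)$failed_criteria)
})

test_that("verdicts record every violated rule, not just the first", {
  r <- clean_variant(alt_fraction = 0.04, qual = 10, is_common_snp = TRUE)
  r$n_samples_with_variant <- 1L
  expect_equal(apply_filters(r)$failed_criteria, c(2L, 4L, 6L))
})

test_that("missing annotation fields are an error naming the field", {
  r <- clean_variant()
  r$n_samples_with_variant <- 1L
  r$mapq <- NA_real_
  expect_error(apply_filters(r), "mapq")
  expect_error(filter_table(clean_variant()[, -which(names(clean_variant())
                                                     == "qual")]), "qual")
})

test_that("filter_table audits every record and recomputes recurrence globally", {
  recs <- rbind(
    clean_variant(1),
    clean_variant(2, gene = "TP53"),
    clean_variant(3, alt_fraction = 0.03),
    clean_variant(4, qual = 5),
    clean_variant(5, dbnsfp_impact = "low"),
    clean_variant(6, is_common_snp = TRUE))
  out <- filter_table(recs)
  expect_equal(nrow(out$kept), 2L)
  expect_equal(nrow(out$audit), 6L)
  expect_equal(out$audit$passed, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$audit$failed_criteria[3], "2")

  # shared site across three samples with no COSMIC support: all fail rule 10
  shared <- do.call(rbind, lapply(1:3, function(i) {
    clean_variant(i, pos = 5555L, cosmic_case_count = 0L)
  }))
  out2 <- filter_table(shared)
  expect_equal(nrow(out2$kept), 0L)
  expect_true(all(vapply(strsplit(out2$audit$failed_criteria, ","),
                         function(x) "10" %in% x, logical(1))))

  # order independence
  out3 <- filter_table(recs[sample.int(6), ])
  expect_equal(sort(out3$audit$pos), sort(out$audit$pos))
  expect_equal(out3$audit$passed[order(out3$audit$pos)],
               out$audit$passed[order(out$audit$pos)])

  # empty table passes through
  empty <- filter_table(recs[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$audit), 0L)
})

test_that("stricter data sweeps never increase the kept count", {
  fracs <- seq(0.30, 0.01, by = -0.01)
  kept <- vapply(fracs, function(f) {
    recs <- do.call(rbind, lapply(1:10, function(i) {
      clean_variant(i, alt_fraction = f + 0.02 * i)
    }))
    nrow(filter_table(recs)$kept)
  }, integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("VCF plus sidecar loading joins on site and carries the caller filter", {
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1010\t.\tA\tT\t90\tPASS\t.",
    "chr1\t1020\t.\tG\tC\t90\tq10\t."), vcf)
  ann <- withr::local_tempfile(fileext = ".tsv")
  side <- rbind(clean_variant(1, pos = 1010L),
                clean_variant(2, pos = 1020L, ref = "G", alt = "C"))
  side$caller_pass <- NULL
  utils::write.table(side, ann, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_variant_table(vcf, ann)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$caller_pass[order(tab$pos)], c(TRUE, FALSE))
  out <- filter_table(tab)
  expect_equal(nrow(out$kept), 1L)
  expect_equal(out$audit$failed_criteria[order(out$audit$pos)][2], "1")
})
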