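test_that("ploidy annotation reproduces the worked examples", {
  gp <- gene_only_panel()
  panel <- default_panel()
  # tetraploid major clone of the high-instability aneuploid case
  expect_equal(annotate_ploidy(c(8, 4, 4, 4, 3, 2, 4, 5), gp)$ploidy, 4L)
  # flat diploid
  expect_equal(annotate_ploidy(rep(2, 8), gp)$ploidy, 2L)
  expect_equal(annotate_ploidy(rep(2, 10), panel)$ploidy, 2L)
  # amplified marker excluded from the average: centromeres anchor 2,
  # the 20-count gene exceeds twice the candidate and is set aside
  ann <- annotate_ploidy(c(20, 2, 2, 2, 2, 2, 2, 2, 2, 2), panel)
  expect_equal(ann$ploidy, 2L)
  expect_equal(ann$excluded, "COX2")
})

test_that("gain/loss patterns are trichotomized against the nucleus ploidy", {
  gp <- gene_only_panel()
  s <- gain_loss_pattern(c(2, 1, 3, 2, 1, 2, 2, 2), 2, gp)
  expect_equal(unname(s[c("DBC2", "MYC", "CDH1")]), c("loss", "gain", "loss"))
  expect_equal(unname(s[c("COX2", "CCND1", "TP53", "HER2", "ZNF217")]),
               rep("neutral", 5))

  s4 <- gain_loss_pattern(c(8, 4, 4, 4, 3, 2, 4, 5), 4, gp)
  expect_equal(names(s4)[s4 == "gain"], c("COX2", "ZNF217"))
  expect_equal(names(s4)[s4 == "loss"], c("CDH1", "TP53"))

  expect_true(all(gain_loss_pattern(rep(3, 8), 3, gp) == "neutral"))
})

test_that("gain/loss is invariant under whole-genome doubling", {
  gp <- gene_only_panel()
  set.seed(4)
  for (i in 1:25) {
    v <- sample(1:4, 8, TRUE)
    p <- sample(2:3, 1)
    expect_equal(gain_loss_pattern(2L * v, 2L * p, gp),
                 gain_loss_pattern(v, p, gp))
  }
})

test_that("sample summary computes the instability index and its limits", {
  panel <- default_panel()
  s <- sample_summary(case7L_records(), panel)
  expect_equal(s$n_patterns, 5L)
  expect_equal(s$instability_index, 2)
  expect_equal(s$ploidy_class, "diploid")
  expect_equal(s$major_clone, "2-1-3-2-1-2-2-2-2-2")

  for (n in c(10, 250)) {
    same <- sample_summary(uniform_records(rep(2, 10), n), panel)
    expect_equal(same$instability_index, 100 / n)
  }
  set.seed(5)
  distinct <- nucleus_table(matrix(sample(0:60, 60), 6, 10), panel)
  expect_equal(sample_summary(distinct, panel)$instability_index, 100)
})

test_that("instability index ignores nucleus order and stays in range", {
  panel <- default_panel()
  set.seed(6)
  for (i in 1:10) {
    n <- sample(5:80, 1)
    rec <- nucleus_table(matrix(sample(1:3, n * 10, TRUE), n, 10), panel)
    s <- sample_summary(rec, panel)
    expect_gte(s$instability_index, 100 / n)
    expect_lte(s$instability_index, 100)
    shuf <- rec[sample.int(n), ]
    expect_equal(sample_summary(shuf, panel)$instability_index,
                 s$instability_index)
  }
})

test_that("CNA calls obey the 15%/85% fractions and are monotone in the fraction", {
  panel <- default_panel()
  make <- function(frac, n = 100) {
    k <- round(frac * n)
    m <- matrix(2L, n, 10)
    m[seq_len(k), 3] <- 3L  # MYC gain in a fraction of nuclei
    nucleus_table(m, panel)
  }
  call_at <- function(frac) {
    s <- sample_summary(make(frac), panel)
    s$cna_calls$call[s$cna_calls$gene == "MYC"]
  }
  expect_equal(call_at(0.60), "gain_minor")
  expect_equal(call_at(0.90), "gain_major")
  expect_equal(call_at(0.14), "none")
  expect_equal(call_at(0.15), "gain_minor")  # inclusive lower edge
  expect_equal(call_at(0.85), "gain_major")
  # monotone: growing the gain fraction never removes the call
  ranks <- c(none = 0, gain_minor = 1, gain_major = 2)
  calls <- vapply(seq(0.1, 1, by = 0.05), call_at, character(1))
  expect_true(all(diff(ranks[calls]) >= 0))
})

test_that("aneuploidy is called from the one-decimal average at 2.2", {
  panel <- default_panel()
  # 30% trisomic nuclei: mean ploidy 2.3 -> aneuploid
  m <- rbind(matrix(3L, 30, 10), matrix(2L, 70, 10))
  expect_equal(sample_summary(nucleus_table(m, panel), panel)$ploidy_class,
               "aneuploid")
  # 10% trisomic: mean 2.1 -> diploid
  m <- rbind(matrix(3L, 10, 10), matrix(2L, 90, 10))
  s <- sample_summary(nucleus_table(m, panel), panel)
  expect_equal(s$average_ploidy, 2.1)
  expect_equal(s$ploidy_class, "diploid")
  # 15% trisomic: mean 2.15 rounds half-up to 2.2 -> aneuploid
  m <- rbind(matrix(3L, 15, 10), matrix(2L, 85, 10))
  s <- sample_summary(nucleus_table(m, panel), panel)
  expect_equal(s$average_ploidy, 2.2)
  expect_equal(s$ploidy_class, "aneuploid")
})

test_that("amplification uses a strict twice-ploidy threshold on mean counts", {
  panel <- default_panel()
  m <- matrix(2L, 10, 10)
  m[, 7] <- 5L  # HER2 mean 5.0 at ploidy 2
  expect_equal(amplification_flags(nucleus_table(m, panel), panel, 2L), "HER2")
  m[, 7] <- 4L  # exactly twice: not amplified
  expect_equal(amplification_flags(nucleus_table(m, panel), panel, 2L),
               character(0))
  m2 <- matrix(4L, 10, 10)
  m2[, 7] <- 9L
  expect_equal(amplification_flags(nucleus_table(m2, panel), panel, 4L),
               "HER2")
  # and through sample_summary, against the modal nucleus ploidy
  m[, 7] <- 9L
  expect_equal(sample_summary(nucleus_table(m, panel), panel)$amplified_genes,
               "HER2")
})
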