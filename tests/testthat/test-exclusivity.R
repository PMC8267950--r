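test_that("switching randomization preserves all row and column sums", {
  set.seed(11)
  for (i in 1:5) {
    m <- sapply(1:5, function(j) {
      v <- integer(30); v[sample.int(30, sample(5:20, 1))] <- 1L; v
    })
    chk <- .perm_margin_check(m, 50L, 10L * sum(m))
    expect_true(chk$margins_ok)
    expect_equal(rowSums(chk$final), rowSums(m))
    expect_equal(colSums(chk$final), colSums(m))
    # and the chain actually moves
    expect_false(identical(chk$final, m))
  }
})

test_that("identical columns hit the co-occurrence floor, disjoint ones the exclusivity floor", {
  m <- matrix(0L, 30, 3)
  m[1:10, 1] <- 1L
  m[1:10, 2] <- 1L   # identical to column 1
  m[11:20, 3] <- 1L  # disjoint from both
  colnames(m) <- c("A", "B", "C")
  res <- pairwise_permutation_test(m, n_perm = 2000, seed = 1)
  ab <- res$pairs[res$pairs$event_a == "A" & res$pairs$event_b == "B", ]
  expect_equal(ab$observed_overlap, 10L)
  expect_equal(ab$p_cooccurrence, 1 / 2001)
  expect_lt(ab$q_cooccurrence, 0.05)
  ac <- res$pairs[res$pairs$event_a == "A" & res$pairs$event_b == "C", ]
  expect_equal(ac$observed_overlap, 0L)
  # zero is the minimal possible overlap; the null's small tie mass at zero
  # keeps the p-value near, but not necessarily at, the add-one floor
  expect_lt(ac$p_exclusivity, 0.02)
  expect_gt(ac$p_cooccurrence, 0.9)
})

test_that("an overlap at the null median gives p near one half", {
  # a pair of 20-of-40 events at their expected overlap of 10, embedded in
  # a wider matrix so switches can actually move mass between the columns
  # (for an isolated pair, fixed margins pin the overlap exactly); the
  # upper-tail p sits in [0.5, 0.5 + tie mass] ~ [0.5, 0.75]
  set.seed(2)
  m <- matrix(0L, 40, 4)
  m[1:20, 1] <- 1L
  m[11:30, 2] <- 1L
  m[sample.int(40, 15), 3] <- 1L
  m[sample.int(40, 12), 4] <- 1L
  res <- pairwise_permutation_test(m, n_perm = 10000, seed = 2)
  ab <- res$pairs[res$pairs$event_a == "e1" & res$pairs$event_b == "e2", ]
  expect_equal(ab$observed_overlap, 10L)
  expect_gt(ab$p_cooccurrence, 0.4)
  expect_lt(ab$p_cooccurrence, 0.85)
})

test_that("an isolated pair's overlap is pinned by its margins", {
  # with only two events every margin-preserving switch leaves the number
  # of doubly-altered samples unchanged: the conditional null is degenerate
  m <- matrix(0L, 40, 2)
  m[1:20, 1] <- 1L
  m[11:30, 2] <- 1L
  res <- pairwise_permutation_test(m, n_perm = 500, seed = 3)
  expect_equal(res$pairs$p_cooccurrence, 1)
  expect_equal(res$pairs$p_exclusivity, 1)
})

test_that("the test is valid and reproducible, and constant events are excluded", {
  set.seed(12)
  # validity: under an independent null the rejection rate stays below
  # alpha plus Monte-Carlo slack (the discrete statistic is conservative)
  nrej <- 0L; ntest <- 0L
  for (i in 1:30) {
    m <- sapply(1:4, function(j) {
      v <- integer(40); v[sample.int(40, sample(8:16, 1))] <- 1L; v
    })
    r <- pairwise_permutation_test(m, n_perm = 500)
    nrej <- nrej + sum(r$pairs$p_cooccurrence <= 0.05)
    ntest <- ntest + nrow(r$pairs)
  }
  expect_lte(nrej / ntest, 0.05 + 3 * sqrt(0.05 * 0.95 / ntest))

  m <- matrix(0L, 20, 4)
  m[1:7, 1] <- 1L; m[5:14, 2] <- 1L; m[, 3] <- 1L  # col 3 constant, col 4 empty
  colnames(m) <- c("A", "B", "full", "empty")
  r1 <- pairwise_permutation_test(m, n_perm = 500, seed = 7)
  r2 <- pairwise_permutation_test(m, n_perm = 500, seed = 7)
  expect_identical(r1$pairs, r2$pairs)
  expect_setequal(r1$excluded_events, c("full", "empty"))
  expect_equal(nrow(r1$pairs), 1L)
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("group comparison helpers delegate to the stock tests", {
  expect_lt(compare_groups(matrix(c(10, 0, 0, 10), 2), "fisher"), 0.001)
  expect_equal(compare_groups(matrix(c(10, 20, 5, 10), 2), "chisq"), 1)
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compare_groups(list(x, x), "t"), 1)
  expect_error(compare_groups(list(rep(1, 5), rep(1, 5)), "t"), "constant")
  expect_lt(compare_groups(list(rnorm(20), rnorm(20) + 5), "t"), 1e-6)
  expect_equal(compare_groups(list(x, x, x), "anova"), 1)
  expect_error(compare_groups(list(1:5), "t"), "2 groups")
})
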