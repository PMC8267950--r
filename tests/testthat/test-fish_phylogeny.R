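test_that("single patterns attach at their L1 distance with transit nodes", {
  # one step from the root
  t1 <- build_fish_tree(rbind(c(3, 2, 2, 2, 2, 2, 2, 2)))
  expect_equal(tree_metrics(t1), list(tree_depth = 1L, total_events = 1L))
  expect_equal(sum(!t1$nodes$observed & t1$nodes$depth > 0), 0L)

  # three steps away: two transit nodes on the path
  t3 <- build_fish_tree(rbind(c(2, 1, 3, 2, 1, 2, 2, 2)))
  expect_equal(t3$total_events, 3L)
  expect_equal(t3$tree_depth, 3L)
  expect_equal(sum(!t3$nodes$observed & t3$nodes$depth > 0), 2L)

  # root-only tree
  t0 <- build_fish_tree(matrix(integer(0), 0, 8))
  expect_equal(tree_metrics(t0), list(tree_depth = 0L, total_events = 0L))
})

test_that("chains and stars give the expected depth/event split", {
  chain <- build_fish_tree(rbind(c(5, 2, 2, 2)))
  expect_equal(tree_metrics(chain), list(tree_depth = 3L, total_events = 3L))
  star <- build_fish_tree(rbind(c(3, 2, 2, 2), c(1, 2, 2, 2), c(2, 3, 2, 2)))
  expect_equal(tree_metrics(star), list(tree_depth = 1L, total_events = 3L))
})

test_that("a WGD edge replaces per-probe doubling as a single event", {
  expect_equal(build_fish_tree(rbind(rep(4L, 4)))$total_events, 1L)
  expect_equal(build_fish_tree(rbind(rep(4L, 4)),
                               allow_wgd = FALSE)$total_events, 8L)
  # the 8-probe tetraploid pattern: one WGD versus 16 unit steps
  expect_equal(build_fish_tree(rbind(rep(4L, 8)))$total_events, 1L)
  expect_equal(build_fish_tree(rbind(rep(4L, 8)),
                               allow_wgd = FALSE)$total_events, 16L)
  wgd <- build_fish_tree(rbind(rep(4L, 4)))
  expect_equal(wgd$edges$event, "WGD")
})

test_that("observed patterns lying on another pattern's path are promoted", {
  tr <- build_fish_tree(rbind(c(0, 2), c(1, 2)), probe_names = c("a", "b"))
  expect_equal(tr$total_events, 2L)
  # every non-root node is observed: no transit node was needed
  expect_true(all(tr$nodes$observed | tr$nodes$depth == 0L))
  # the single-copy intermediate is the parent of the null-copy pattern
  kid <- tr$nodes$id[tr$nodes$pattern == "0-2"]
  par <- tr$edges$parent[tr$edges$child == kid]
  expect_equal(tr$nodes$pattern[tr$nodes$id == par], "1-2")
})

test_that("absorbing zero keeps lost probes lost along every path", {
  set.seed(8)
  for (i in 1:15) {
    pats <- evolved_patterns(k = 3, d = 4)
    tr <- build_fish_tree(pats, allow_wgd = sample(c(TRUE, FALSE), 1))
    pat_of <- function(id) as.integer(strsplit(tr$nodes$pattern[id],
                                               "-")[[1]])
    for (e in seq_len(nrow(tr$edges))) {
      p <- pat_of(tr$edges$parent[e])
      k <- pat_of(tr$edges$child[e])
      expect_false(any(p == 0L & k > p))
    }
    # every observed pattern appears exactly once
    obs_keys <- tr$nodes$pattern[tr$nodes$observed]
    expect_equal(sort(obs_keys[obs_keys != paste(rep(2, 4), collapse = "-")]),
                 sort(unique(apply(pats, 1, paste, collapse = "-"))))
  }
})

test_that("identical inputs yield identical trees", {
  pats <- rbind(c(3, 1, 2, 2), c(4, 4, 4, 4), c(2, 1, 1, 2))
  a <- build_fish_tree(pats)
  b <- build_fish_tree(pats[c(2, 3, 1), ])
  expect_equal(a$nodes, b$nodes)
  expect_equal(a$edges, b$edges)
})

test_that("the exact oracle reproduces hand-checked minima", {
  expect_equal(steiner_oracle(rbind(c(2, 1), c(2, 3))), 2L)
  expect_equal(steiner_oracle(rbind(c(4, 4)), allow_wgd = TRUE), 1L)
  # single pattern: minimum is the L1 distance when WGD cannot help
  set.seed(9)
  for (i in 1:10) {
    p <- sample(0:6, 3, TRUE)
    expect_equal(steiner_oracle(rbind(p)), sum(abs(p - 2)))
  }
  # bounds are enforced
  expect_error(steiner_oracle(rbind(rep(2, 5))), "dimension")
  expect_error(steiner_oracle(rbind(c(7, 2))), "copy-number")
})

test_that("oracle finds Steiner savings the per-pattern bound misses", {
  # two patterns sharing a two-step trunk: star would cost 6, tree 4
  pats <- rbind(c(4, 3, 2), c(4, 2, 3))
  expect_equal(steiner_oracle(pats), 4L)
  expect_equal(build_fish_tree(pats, allow_wgd = FALSE)$total_events, 4L)
})

test_that("heuristic trees are never better than the exact oracle and usually match", {
  set.seed(10)
  n_eq <- 0L
  n <- 40L
  for (i in seq_len(n)) {
    pats <- evolved_patterns(k = 3, d = 4)
    o <- steiner_oracle(pats)
    h <- build_fish_tree(pats, allow_wgd = FALSE)$total_events
    expect_gte(h, o)
    ub <- sum(apply(pats, 1, function(p) sum(abs(p - 2))))
    lb <- max(apply(pats, 1, function(p) sum(abs(p - 2))))
    expect_lte(h, ub)
    expect_gte(h, lb)
    if (h == o) n_eq <- n_eq + 1L
  }
  expect_gte(n_eq / n, 0.8)
})

test_that("tree export encodes observed versus transit nodes", {
  tr <- build_fish_tree(rbind(c(2, 1, 3, 2, 1, 2, 2, 2)),
                        probe_names = gene_probes(default_panel()))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_fish_tree(tr, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(unique(igraph::V(back)$style)), c("dashed", "solid"))
  expect_true("2-1-3-2-1-2-2-2" %in% igraph::V(back)$label)
})
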