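test_that("Newick parsing validates topology and labels", {
  tr <- parse_newick("((A:1,B:1):1,C:1,D:1);")
  expect_s3_class(tr, "ogd_tree")
  expect_equal(nrow(tree_branches(tr)), 5L)   # 2n-3 with n=4

  expect_error(parse_newick("((A:1,B:1)"), "parse error")
  expect_error(parse_newick("(A:1,B:1,C:1,D:1);"), "bifurcating")
  expect_error(parse_newick("((A:1,A:1):1,C:1,D:1);"), "Duplicate")
  expect_error(parse_newick("((A:-1,B:1):1,C:1,D:1);"), "Negative")
})

test_that("Newick round-trips preserve topology and lengths", {
  for (seed in 1:5) {
    tr <- simulate_tree(8 + seed, seed = seed)
    s <- write_newick(tr)
    tr2 <- parse_newick(s)
    b1 <- sorted_branches(tr)
    b2 <- sorted_branches(tr2)
    expect_equal(b1$key, b2$key)
    expect_equal(b1$length, b2$length, tolerance = 1e-9)
    # rooted emission bisects the designated branch and re-parses identically
    expect_equal(tr2$root$clade, tr$root$clade)
    expect_equal(tr2$root$fraction, tr$root$fraction, tolerance = 1e-9)
  }
})

test_that("branch enumeration is complete, stable and sized 2n-3", {
  for (n in c(4L, 10L, 50L)) {
    tr <- simulate_tree(n, seed = n)
    expect_equal(nrow(tree_branches(tr)), 2L * n - 3L)
  }
  tr <- simulate_tree(10, seed = 1)
  expect_identical(tree_branches(tr)$key,
                   tree_branches(parse_newick(write_newick(tr)))$key)
  expect_error(tree_branches(parse_newick("(A:1,B:1,C:1);")), "at least 4")
})

test_that("rooting re-derives clades but leaves geometry unchanged", {
  tr <- hand_tree()
  b <- tree_branches(tr)
  i <- which(b$key == "C,D")
  rt <- root_between(tr, i, 0.5)
  expect_equal(rt$root$clade, c("C", "D"))
  # clades are re-derived root-distally: rooting on the C,D branch turns the
  # rest of the tree into root-distal clades of the opposite side
  expect_setequal(tree_branches(rt)$key,
                  c("A", "B", "A,B", "C", "D", "C,D", "E", "F", "E,F"))
  # pairwise path lengths are a property of the unrooted geometry
  p1 <- new_tree_point(1, 0.05); p2 <- new_tree_point(4, 0.1)
  expect_equal(path_length(tr, p1, p2) >= 0, TRUE)
  a <- branch_midpoint_pt(tr, "A"); e <- branch_midpoint_pt(tr, "E")
  ar <- branch_midpoint_pt(rt, "A"); er <- branch_midpoint_pt(rt, "E")
  expect_equal(path_length(tr, a, e), path_length(rt, ar, er), tolerance = 1e-12)
  expect_equal(root_between(tr, i, 0)$root$fraction, 0)
})

test_that("pruning a leaf merges branches with exact bookkeeping", {
  tr <- parse_newick("((A:1,B:1):1,C:1,D:1);")
  pr <- prune_clade(tr, "A")
  expect_equal(pr$residual$n, 3L)
  att_branch <- pr$residual$branches[pr$attachment$branch, ]
  expect_equal(att_branch$length, 2)              # 1 + 1 merged
  expect_equal(pr$attachment$offset, 1)
  expect_equal(pr$subtree$stem, 1)

  pr2 <- prune_clade(hand_tree(), "C,D")          # prune a cherry
  expect_equal(pr2$residual$n, 4L)
  expect_true(pr2$attachment$key %in% pr2$residual$branches$key)
  expect_error(prune_clade(tr, "C,D"), "at least 3")  # n=4: clade limit is 1
})

test_that("prune -> regraft at the original point is the identity", {
  for (seed in 1:4) {
    tr <- simulate_tree(9, seed = seed)
    b <- tree_branches(tr)
    prunable <- which(b$size <= tr$n - 3L)
    for (i in prunable[seq(1, length(prunable), by = 3)]) {
      pr <- prune_clade(tr, i)
      tr2 <- regraft(pr, pr$attachment$branch, pr$attachment$offset)
      b1 <- canonical_splits(tr)
      b2 <- canonical_splits(tr2)
      expect_identical(b1$key, b2$key)
      expect_equal(b1$length, b2$length, tolerance = 1e-9)
    }
  }
})

test_that("insertion points number 2m-3 and include the original", {
  tr <- simulate_tree(10, seed = 2)
  b <- tree_branches(tr)
  for (i in which(b$size <= tr$n - 3L)) {
    pr <- prune_clade(tr, i)
    pts <- insertion_points(pr)
    expect_equal(nrow(pts), 2L * pr$residual$n - 3L)
    expect_equal(sum(pts$is_original), 1L)
  }
  # a regraft at a non-original point still yields a valid 2n-3 branch tree
  pr <- prune_clade(tr, which(b$size == 1L)[1L])
  pts <- insertion_points(pr)
  alt <- which(!pts$is_original)[1L]
  tr2 <- regraft(pr, pts$branch[alt], pts$offset[alt])
  expect_equal(nrow(tree_branches(tr2)), 2L * tr$n - 3L)
})

test_that("regrafting a leaf onto another leaf branch gives the expected topology", {
  tr <- parse_newick("((A:1,B:1):1,C:1,D:1);")
  pr <- prune_clade(tr, "A")
  pts <- insertion_points(pr)
  tr2 <- regraft(pr, pts$branch[pts$key == "C"], NULL)
  expect_true(has_split(tr2, c("A", "C")))         # topology ((A,C),B,D)
})

test_that("path_length is a tree metric", {
  tr <- simulate_tree(12, seed = 5)
  b <- tree_branches(tr)
  pts <- withr::with_seed(5, lapply(1:12, function(i) {
    j <- sample(nrow(b), 1L)
    new_tree_point(j, runif(1) * b$length[j])
  }))
  for (k in seq(1, 10, by = 3)) {
    a <- pts[[k]]; b2 <- pts[[k + 1L]]; c2 <- pts[[k + 2L]]
    expect_equal(path_length(tr, a, a), 0)
    expect_equal(path_length(tr, a, b2), path_length(tr, b2, a))
    expect_gte(path_length(tr, a, b2) + path_length(tr, b2, c2),
               path_length(tr, a, c2) - 1e-12)
  }
  # forced by definition: midpoints of two pendant branches through a center
  star <- parse_newick("((A:0.1,B:0.3):0.0,C:1,D:1);")
  d <- path_length(star, branch_midpoint_pt(star, "A"),
                   branch_midpoint_pt(star, "B"))
  expect_equal(d, 0.05 + 0.15, tolerance = 1e-12)
})

test_that("clade total length follows the stated convention", {
  tr <- root_between(hand_tree(), "E,F", 0.5)
  b <- tr$branches
  expect_equal(clade_total_length(tr, b$branch[b$key == "E"]), 0.8)
  expect_equal(clade_total_length(tr, b$branch[b$key == "A,B"]), 0.1 + 0.2)
  expect_equal(clade_total_length(tr, b$branch[b$key == "C,D"]), 0.4 + 0.5)
  # the root branch's designated clade sums its two pendant branches
  expect_equal(clade_total_length(tr, b$branch[b$key == "E,F"]), 0.8 + 0.9)
})

test_that("branch LCA finds the deepest shared node and flags nesting", {
  tr <- root_between(hand_tree(), "E,F", 0.5)
  b <- tr$branches
  cherry <- branch_lca(tr, b$branch[b$key == "A"], b$branch[b$key == "B"])
  expect_equal(cherry$clade, c("A", "B"))
  expect_true(is.na(cherry$nested))
  cross <- branch_lca(tr, b$branch[b$key == "A"], b$branch[b$key == "E"])
  expect_equal(cross$depth, 0)                 # LCA is the root point
  nest <- branch_lca(tr, b$branch[b$key == "A,B"], b$branch[b$key == "A"])
  expect_equal(nest$nested, "a")
})
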