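test_that("parse_newick builds valid unrooted trees and validates input", {
  tr <- parse_newick("((A:1,B:1):1,C:1,D:1);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(nrow(tr$edge), 5L)          # 2n - 3 edges once unrooted

  # degree-2 root is suppressed; one non-trivial split remains
  tr2 <- parse_newick("((A,B),(C,D));")
  expect_false(ape::is.rooted(tr2))
  expect_length(tree_splits(tr2), 1L)

  expect_error(parse_newick("((A,B),(A,C));"), "duplicate leaf label")
  expect_error(parse_newick("(A,B);"), "fewer than 3 leaves")
  expect_error(parse_newick("((A,B"), "malformed")
  # missing branch lengths default to 0
  expect_equal(parse_newick("(A,B,C);")$edge.length, rep(0, 3))
})

test_that("write_newick round trips topology and branch lengths", {
  for (seed in 1:5) {
    tr <- random_tree(4L + seed, bl_mean = 0.2, seed = seed)
    back <- parse_newick(write_newick(tr))
    expect_equal(rf_distance(tr, back)$raw, 0L)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-12)
    expect_setequal(as.character(tree_splits(back)),
                    as.character(tree_splits(tr)))
  }
  # high-precision lengths survive
  tr <- parse_newick("(A:0.123456789,B:1,C:1);")
  expect_match(write_newick(tr), "0.123456789", fixed = TRUE)
  # multifurcations are preserved, never resolved
  multi <- parse_newick("(A,B,C,D,(E,F));")
  expect_equal(parse_newick(write_newick(multi))$Nnode, multi$Nnode)
})

test_that("tree_splits enumerates exactly the non-trivial bipartitions", {
  tr <- parse_newick("((A,B),C,(D,(E,F)));")
  # canonical side excludes the lexicographically smallest leaf (A)
  expect_setequal(as.character(tree_splits(tr)),
                  c("E,F", "D,E,F", "C,D,E,F"))
  expect_length(tree_splits(parse_newick("(A,B,C,D);")), 0L)
  expect_setequal(as.character(tree_splits(parse_newick("((A,B),(C,D));"))),
                  "C,D")
  # binary tree: n - 3 splits
  tr8 <- random_tree(8, seed = 1)
  expect_length(tree_splits(tr8), 5L)
  expect_error(tree_splits(parse_newick("(A,B,C);")), "4 leaves")
})

test_that("rf_distance matches hand-derived and boundary cases", {
  a <- parse_newick("((A,B),(C,D));")
  b <- parse_newick("((A,C),(B,D));")
  expect_equal(rf_distance(a, b), list(raw = 2L, normalized = 1.0))
  expect_equal(rf_distance(a, a), list(raw = 0L, normalized = 0.0))
  x <- parse_newick("((A,B),C,(D,(E,F)));")
  y <- parse_newick("((A,C),B,(D,(E,F)));")
  expect_equal(rf_distance(x, y), list(raw = 2L, normalized = 1 / 3))
  expect_error(rf_distance(a, parse_newick("((A,B),(C,E));")),
               "leaf sets differ")
})

test_that("ntd_distance handles binary, multifurcating and star trees", {
  a <- parse_newick("((A,B),(C,D));")
  b <- parse_newick("((A,C),(B,D));")
  expect_equal(ntd_distance(a, a), 0)
  expect_equal(ntd_distance(a, b), 1)
  bin5 <- parse_newick("((A,B),C,(D,E));")
  star5 <- parse_newick("(A,B,C,D,E);")
  expect_equal(ntd_distance(bin5, star5), 1)   # |S1|/( |S1| + 0 )
  expect_equal(ntd_distance(star5, star5), 0)  # 0/0 defined as 0
  # equals normalized RF for two binary trees
  for (seed in 1:5) {
    t1 <- random_tree(7, seed = seed)
    t2 <- random_tree(7, seed = seed + 100)
    expect_equal(ntd_distance(t1, t2), rf_distance(t1, t2)$normalized)
  }
})

test_that("quartet_distance matches enumeration and hand-derived values", {
  a <- parse_newick("((A,B),(C,D));")
  b <- parse_newick("((A,C),(B,D));")
  expect_equal(quartet_distance(a, b), 1)
  x <- parse_newick("((A,B),C,(D,E));")
  y <- parse_newick("((A,C),B,(D,E));")
  expect_equal(quartet_distance(x, y), 0.4)   # ABCD and ABCE differ
  t7 <- random_tree(7, seed = 3)
  expect_equal(quartet_distance(t7, t7), 0)
  expect_error(quartet_distance(random_tree(10, seed = 1),
                                random_tree(10, seed = 2), max_leaves = 5),
               "capped")
})

test_that("topological distances agree with independent oracles", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:8, 1L)
    t1 <- random_tree(n, seed = rep)
    t2 <- random_tree(n, seed = rep + 500)
    # phangorn as RF oracle
    expect_equal(rf_distance(t1, t2)$raw,
                 as.integer(phangorn::RF.dist(t1, t2)))
    # four-point-condition oracle for quartets
    expect_equal(quartet_distance(t1, t2), quartet_distance_oracle(t1, t2))
  }
})

test_that("distances are symmetric, zero on identity and bounded", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:10, 1L)
    t1 <- random_tree(n, seed = rep * 3)
    t2 <- random_tree(n, seed = rep * 3 + 1)
    r12 <- rf_distance(t1, t2)$normalized
    expect_equal(r12, rf_distance(t2, t1)$normalized)
    expect_gte(r12, 0); expect_lte(r12, 1)
    expect_equal(ntd_distance(t1, t2), ntd_distance(t2, t1))
    q12 <- quartet_distance(t1, t2)
    expect_equal(q12, quartet_distance(t2, t1))
    expect_gte(q12, 0); expect_lte(q12, 1)
    expect_equal(rf_distance(t1, t1)$raw, 0L)
  }
})

test_that("unique_topology_count compares topologies only", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_equal(unique_topology_count(list(t1, t1, t1)), 1L)
  expect_equal(unique_topology_count(list(t1, t2, t1)), 2L)
  expect_equal(unique_topology_count(list()), 0L)
  # branch lengths must not matter
  copies <- lapply(1:20, function(i) {
    tr <- t1; tr$edge.length <- runif(nrow(tr$edge)); tr
  })
  expect_equal(unique_topology_count(copies), 1L)
})

test_that("mean_pairwise_rf averages over unordered pairs", {
  x <- parse_newick("((A,B),(C,D));")
  y <- parse_newick("((A,C),(B,D));")
  expect_equal(mean_pairwise_rf(list(x, x, x, x, x)), 0)
  expect_equal(mean_pairwise_rf(list(x, y)), 1)
  expect_equal(mean_pairwise_rf(list(x, x, y)), 2 / 3)
  expect_equal(mean_pairwise_rf(list(x)), 0)
})

test_that("random_tree draws valid reproducible topologies", {
  tr <- random_tree(4, seed = 1)
  expect_equal(nrow(tr$edge), 5L)
  expect_length(tree_splits(tr), 1L)
  expect_identical(write_newick(random_tree(50, seed = 9)),
                   write_newick(random_tree(50, seed = 9)))
  # all 15 unrooted 5-leaf topologies appear in 1000 draws
  keys <- vapply(1:1000, function(i)
    paste(sort(phybench:::split_strings(random_tree(5, seed = i))),
          collapse = ";"), character(1L))
  expect_equal(length(unique(keys)), 15L)
})
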