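test_that("JC distances follow the closed form with saturation clamping", {
  msa <- rbind(a = rep("A", 10), b = rep("A", 10))
  expect_equal(unname(jc_distance_matrix(msa)["a", "b"]), 0)
  # 10% mismatches
  set.seed(1)
  a <- sample(c("A", "C", "G", "T"), 1000, TRUE)
  b <- a
  flip <- sample(1000, 100)
  b[flip] <- vapply(a[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1L))
  d <- jc_distance_matrix(rbind(a = a, b = b))
  expect_equal(unname(d["a", "b"]), -0.75 * log(1 - 4 / 3 * 0.1),
               tolerance = 1e-9)
  # saturated pair clamps to 10
  sat <- rbind(a = c("A", "A", "A", "A"), b = c("C", "G", "T", "C"))
  expect_equal(unname(jc_distance_matrix(sat)["a", "b"]), 10)
  # gap/ambiguity sites are excluded pairwise
  gappy <- rbind(a = c("A", "-", "C"), b = c("A", "G", "C"))
  expect_equal(unname(jc_distance_matrix(gappy)["a", "b"]), 0)
  allgap <- rbind(a = c("-", "-"), b = c("A", "C"))
  expect_error(jc_distance_matrix(allgap), "no comparable sites")
})

test_that("BIONJ recovers three-point distances and additive trees", {
  dm <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- bionj_tree(dm)
  lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(sort(lens), c(0.1, 0.2, 0.3), tolerance = 1e-6)
  # additive matrices: exact topology recovery, order invariance
  for (seed in 1:10) {
    src <- random_tree(sample(5:12, 1L), bl_mean = 0.2, seed = seed)
    dmat <- stats::cophenetic(src)
    expect_equal(rf_distance(src, bionj_tree(dmat))$raw, 0L)
    perm <- sample(rownames(dmat))
    expect_equal(rf_distance(src, bionj_tree(dmat[perm, perm]))$raw, 0L)
  }
  asym <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  expect_error(bionj_tree(asym), "symmetric")
})

test_that("Fitch scores match hand passes and the brute-force oracle", {
  msa <- matrix(c("A", "A", "C", "C"), 4, 1,
                dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(parse_newick("((t1,t2),(t3,t4));"), msa), 1L)
  expect_equal(fitch_score(parse_newick("((t1,t3),(t2,t4));"), msa), 2L)
  const <- matrix("G", 4, 3, dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(parse_newick("((t1,t2),(t3,t4));"), const), 0L)
  set.seed(2)
  for (rep in 1:8) {
    n <- sample(4:6, 1L)
    tr <- random_tree(n, seed = rep * 13)
    msa <- random_msa(n, sample(2:4, 1L), chars = c("A", "C", "G", "T", "-"))
    rownames(msa) <- tr$tip.label
    expect_equal(fitch_score(tr, msa), fitch_oracle(tr, msa))
  }
})

test_that("parsimony_tree recovers strong-signal topologies deterministically", {
  # balanced tree with no short internal branches: unambiguous signal
  truth <- parse_newick(
    "((T1:0.15,T2:0.15):0.1,(T3:0.15,T4:0.15):0.1,(T5:0.15,T6:0.15):0.1);")
  model <- gtr_model()
  hits <- vapply(1:10, function(s) {
    msa <- simulate_gapless(truth, model, 800, seed = 700 + s)
    rf_distance(truth, parsimony_tree(msa, seed = s))$raw == 0L
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
  msa <- simulate_gapless(truth, model, 300, seed = 31)
  expect_identical(write_newick(parsimony_tree(msa, seed = 5)),
                   write_newick(parsimony_tree(msa, seed = 5)))
  p0 <- parsimony_tree(msa, seed = 5, nni_rounds = 0L)
  expect_s3_class(p0, "phylo")
  expect_true(all(p0$edge.length >= 1e-6))
})

test_that("stepwise-addition parsimony beats random topologies", {
  model <- gtr_model()
  wins <- vapply(1:10, function(s) {
    truth <- random_tree(8, bl_mean = 0.1, seed = 40 + s)
    msa <- simulate_gapless(truth, model, 300, seed = 900 + s)
    pt <- parsimony_tree(msa, seed = s)
    best_random <- min(vapply(1:100, function(r) {
      rt <- random_tree(8, seed = 5000 + 100 * s + r)
      rt$tip.label <- truth$tip.label
      fitch_score(rt, msa)
    }, numeric(1L)))
    attr(pt, "pscore") <= best_random
  }, logical(1L))
  expect_gte(mean(wins), 0.95)
})

test_that("NNI neighborhood has the right size and content", {
  tr <- parse_newick("((A,B),(C,D),E);")
  nbs <- nni_neighbors(tr)
  expect_length(nbs, 4L)          # 2 internal edges x 2 rearrangements
  keys <- vapply(nbs, function(x)
    paste(sort(phybench:::split_strings(x)), collapse = ";"), character(1L))
  self <- paste(sort(phybench:::split_strings(tr)), collapse = ";")
  expect_false(self %in% keys)
  # every neighbor is exactly one RF step away
  for (nb in nbs) expect_equal(rf_distance(tr, nb)$raw, 2L)
  # branch lengths are preserved as a multiset
  tr2 <- random_tree(8, seed = 50)
  for (nb in nni_neighbors(tr2))
    expect_equal(sort(nb$edge.length), sort(tr2$edge.length))
})

test_that("NNI hill climbing attains the ML topology on easy data", {
  truth <- random_tree(5, bl_mean = 0.2, seed = 60)
  model <- gtr_model()
  msa <- simulate_gapless(truth, model, 1000, seed = 61)
  # from the truth: stays at a local optimum at least as good
  start_lnl <- tree_log_likelihood(truth, msa, model)
  res <- nni_ml_search(msa, model, truth)
  expect_gte(res$lnl, start_lnl)
  expect_equal(rf_distance(truth, res$tree)$raw, 0L)
  # from a deliberately wrong start: reaches the true topology
  wrong <- random_tree(5, seed = 999)
  wrong$tip.label <- sample(truth$tip.label)
  res2 <- nni_ml_search(msa, model, wrong)
  expect_equal(rf_distance(truth, res2$tree)$raw, 0L)
  expect_gte(res2$lnl, tree_log_likelihood(wrong, msa, model))
})

test_that("tool dispatch separates built-ins, missing and unknown tools", {
  truth <- random_tree(5, seed = 70)
  msa <- simulate_gapless(truth, gtr_model(), 100, seed = 71)
  res <- run_inference_tool("bionj", msa, config = list(seed = 1L))
  expect_equal(res$status, "ok")
  expect_s3_class(res$tree, "phylo")
  expect_error(run_inference_tool("iqtree9", msa, config = list()),
               "not registered")
  cfg <- list(tools = list(ghost = list(cmd = c("no-such-binary-xyz",
                                                "{msa}"))))
  res2 <- run_inference_tool("ghost", msa, config = cfg,
                             msa_path = tempfile())
  expect_equal(res2$status, "skipped")
  expect_null(res2$tree)
})
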