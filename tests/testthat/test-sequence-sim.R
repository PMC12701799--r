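test_that("discrete Gamma rates are mean-of-bin with unit mean", {
  expect_equal(discrete_gamma_rates(3.7, 1L), 1)
  r <- discrete_gamma_rates(10000, 4L)
  expect_true(all(abs(r - 1) < 0.05))        # near-homogeneous limit
  for (alpha in c(0.2, 0.5, 1, 3)) {
    r <- discrete_gamma_rates(alpha, 4L)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
    # quadrature oracle: E[X | bin] via numeric integration
    q <- qgamma(seq(0, 1, length.out = 5L), alpha, rate = alpha)
    oracle <- vapply(1:4, function(i) {
      4 * integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                    q[i], q[i + 1L], rel.tol = 1e-10)$value
    }, numeric(1L))
    expect_equal(r, oracle, tolerance = 1e-7)
  }
})

test_that("GTR rate matrix is normalized, conservative and reversible", {
  jc <- gtr_model()
  Q <- gtr_rate_matrix(jc)
  expect_equal(unname(Q[1, 2]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(diag(Q)), rep(-1, 4), tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:5) {
    pi <- rgamma(4, 5); pi <- pi / sum(pi)
    m <- gtr_model(pi, rgamma(6, 2) + 0.1, alpha = 1)
    Q <- gtr_rate_matrix(m)
    expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
    expect_equal(as.vector(pi %*% Q), rep(0, 4), tolerance = 1e-10)
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    # detailed balance: diag(pi) Q is symmetric
    flux <- pi * Q
    expect_equal(flux, t(flux), tolerance = 1e-12)
  }
})

test_that("transition matrices are stochastic with correct limits", {
  jc <- gtr_model()
  expect_equal(unname(transition_matrix(jc, 0)), diag(4), tolerance = 1e-12)
  Pbig <- transition_matrix(jc, 100)
  expect_true(all(abs(Pbig - 0.25) < 1e-6))   # stationary limit
  P <- transition_matrix(jc, 0.1)
  expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-0.4 / 3), 4),
               tolerance = 1e-10)             # JC closed form
  m <- gtr_model(c(.4, .1, .3, .2), c(2, 5, 1, 1, 7, 1), alpha = 0.6)
  for (t in c(0.01, 0.5, 3)) {
    P <- transition_matrix(m, t, rate = 1.7)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("gapless simulation respects the substitution process", {
  tr <- random_tree(6, seed = 2)
  jc <- gtr_model()
  tr0 <- tr; tr0$edge.length <- rep(0, nrow(tr$edge))
  m0 <- simulate_gapless(tr0, jc, 30, seed = 1)
  expect_true(all(m0 == rep(m0[1, ], each = nrow(m0))))  # no substitutions
  expect_identical(simulate_gapless(tr, jc, 100, seed = 5),
                   simulate_gapless(tr, jc, 100, seed = 5))
  # long-branch star tree: per-row base frequencies near pi
  star <- parse_newick("(T1:8,T2:8,T3:8,T4:8);")
  big <- simulate_gapless(star, jc, 20000, seed = 3)
  se3 <- 3 * sqrt(0.25 * 0.75 / 20000)
  for (i in 1:4)
    expect_true(all(abs(table(big[i, ]) / 20000 - 0.25) < se3))
})

test_that("simulation is stationary in base composition", {
  pi <- c(0.4, 0.1, 0.2, 0.3)
  m <- gtr_model(pi, c(1, 3, 1, 1, 3, 1), alpha = 1, k = 2)
  star <- parse_newick("(T1:10,T2:10,T3:10);")
  # 100 seeded replicates so the 5% failure allowance comfortably covers
  # the 1% nominal rate of the chi-square criterion
  pass <- vapply(1:100, function(s) {
    sim <- simulate_gapless(star, m, 1000, seed = 1000 + s)
    # one row only: its sites are independent draws from the chain
    cnt <- table(factor(sim[1, ], levels = c("A", "C", "G", "T")))
    suppressWarnings(chisq.test(cnt, p = pi)$p.value) > 0.01
  }, logical(1L))
  expect_gte(mean(pass), 0.95)
})

test_that("Zipf sampling follows the truncated power law", {
  ind <- indel_model(0.1, 0.1, zipf_s = 1, max_len = 2L)
  expect_equal(ind$pmf, c(2 / 3, 1 / 3))
  set.seed(8)
  draws <- sample_zipf(ind, 1e5)
  se3 <- 3 * sqrt(2 / 3 * 1 / 3 / 1e5)
  expect_lt(abs(mean(draws == 1L) - 2 / 3), se3)
  expect_true(all(sample_zipf(indel_model(0, 0, 2, 1L), 100) == 1L))
  for (s in c(1.1, 2, 3.5))
    expect_equal(sum(indel_model(0, 0, s, 25L)$pmf), 1, tolerance = 1e-12)
})

test_that("indel simulation reduces exactly to gapless at zero rates", {
  tr <- random_tree(6, seed = 4)
  m <- gtr_model(alpha = 0.8)
  zero <- indel_model(0, 0, 1.5, 10L)
  a <- simulate_gapless(tr, m, 150, seed = 11)
  b <- simulate_msa(tr, m, 150, indel = zero, seed = 11)
  expect_identical(a, b)
  expect_equal(gap_fraction(a), 0)
  expect_equal(count_patterns(a), count_patterns(b))
})

test_that("deletions create gaps and insertions grow the alignment", {
  tr <- random_tree(8, bl_mean = 0.3, seed = 9)
  m <- gtr_model()
  del <- simulate_msa(tr, m, 300, indel_model(0, 0.05, 1.5, 10L), seed = 2)
  expect_gte(ncol(del), 1L)
  expect_gt(gap_fraction(del), 0)
  # mean column count strictly increases with the insertion rate
  mean_cols <- vapply(c(0, 0.01, 0.05), function(ir) {
    mean(vapply(1:30, function(s) {
      ncol(simulate_msa(tr, m, 100,
                        indel_model(ir, 0, 1.5, 5L), seed = 3000 + s))
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(mean_cols) > 0))
})

test_that("pattern counts and gap fractions follow their definitions", {
  m1 <- rbind(a = c("A", "A", "C"), b = c("A", "A", "C"))
  expect_equal(count_patterns(m1), 2L)
  m2 <- rbind(a = c("A", "-", "C"), b = c("A", "A", "C"))
  expect_equal(count_patterns(m2), 3L)
  expect_equal(count_patterns(m1[, 1, drop = FALSE]), 1L)
  expect_equal(gap_fraction(rbind(a = c("A", "-"), b = c("-", "-"))), 0.75)
  expect_equal(gap_fraction(m1), 0)
  expect_equal(gap_fraction(matrix("-", 2, 3,
                                   dimnames = list(c("a", "b"), NULL))), 1)
  # gaps are pattern-relevant symbols: masking a constant alignment yields
  # exactly the mask's own column patterns
  set.seed(10)
  const <- matrix("A", 4, 60, dimnames = list(paste0("t", 1:4), NULL))
  mask <- matrix(runif(240) < 0.3, 4, 60,
                 dimnames = list(rownames(const), NULL))
  masked <- superimpose_gaps(const, mask)
  mask_chars <- matrix(ifelse(mask, "-", "A"), 4, 60,
                       dimnames = dimnames(const))
  expect_equal(count_patterns(masked), count_patterns(mask_chars))
  expect_gte(count_patterns(masked), count_patterns(const))
})

test_that("superimpose_gaps places exactly the masked cells", {
  msa <- random_msa(3, 10)
  none <- matrix(FALSE, 3, 10, dimnames = list(rownames(msa), NULL))
  expect_identical(superimpose_gaps(msa, none), msa)
  one <- none; one[1, 2] <- TRUE
  out <- superimpose_gaps(msa, one)
  expect_equal(sum(out == "-"), 1L)
  expect_equal(unname(out[1, 2]), "-")
  set.seed(3)
  dens <- matrix(runif(30) < 0.31, 3, 10,
                 dimnames = list(rownames(msa), NULL))
  expect_equal(gap_fraction(superimpose_gaps(msa, dens)), mean(dens))
  expect_error(superimpose_gaps(msa, none[, 1:5]), "shape")
})

test_that("FASTA round trip preserves the alignment", {
  tr <- random_tree(5, seed = 6)
  msa <- simulate_msa(tr, gtr_model(), 120,
                      indel_model(0.02, 0.02, 1.5, 8L), seed = 7)
  f <- tempfile(fileext = ".fasta")
  write_fasta_msa(msa, f)
  expect_identical(read_fasta_msa(f), msa)
})
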