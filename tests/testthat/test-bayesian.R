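# Bayesian machinery: MCMC recovery and determinism, consensus
# counting, harmonic-mean stability, Bayes-factor arithmetic, partition
# comparison, and Mk ancestral-state reconstruction.

test_that("fixed-topology MCMC recovers branch lengths within posterior spread", {
  set.seed(30)
  tr <- ape::read.tree(text = "(a:0.06,b:0.09,c:0.12);")
  sm <- concatenate(simulate_alignments(
    sim_config(tr, 1, c(4000, 4000), model = subst_model("JC"),
               exon_fraction = 1, missing_fraction = 0, gene_rate_sd = 0,
               seed = 81)))
  trc <- mcmc_run(sm, "single", n_gens = 4000, sample_every = 20,
                  seed = 2, topology_fixed = TRUE, start_tree = tr)
  keep <- trc$samples[trc$samples$generation > 1000, ]
  ## posterior tree length against the true total of 0.27
  expect_lt(abs(mean(keep$tree_length) - 0.27),
            3 * stats::sd(keep$tree_length) + 1e-3)
})

test_that("MCMC is reproducible under a fixed seed", {
  set.seed(31)
  tr <- random_topology(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.15)
  sm <- concatenate(simulate_alignments(
    sim_config(tr, 1, c(150, 150), seed = 5)))
  a <- mcmc_run(sm, "single", n_gens = 300, sample_every = 20, seed = 7)
  b <- mcmc_run(sm, "single", n_gens = 300, sample_every = 20, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$trees, b$trees)
})

test_that("consensus posterior probabilities count split frequencies", {
  t1 <- "((a,b),(c,d),e);"
  t2 <- "((a,c),(b,d),e);"
  trees <- c(rep(t1, 6), rep(t2, 4))
  cons <- consensus_with_pp(trees, burn_in = 0)
  expect_equal(unname(cons$pp[["a|b"]]), 0.6)
  expect_equal(unname(cons$pp[["a|c"]]), 0.4)
  expect_true(all(cons$pp >= 0 & cons$pp <= 1))
  ## all trees identical: PP 1 everywhere and the same topology back
  cons1 <- consensus_with_pp(rep(t1, 10), burn_in = 2)
  expect_true(all(cons1$pp == 1))
  expect_true(same_topology(cons1$tree, ape::read.tree(text = t1)))
  ## consensus splits are pairwise compatible
  keys <- names(cons$pp[cons$pp > 0.5])
  taxa <- letters[1:5]
  for (i in seq_along(keys)) for (j in seq_len(i - 1)) {
    expect_true(splits_compatible(keys[i], keys[j], taxa))
  }
  expect_error(consensus_with_pp(rep(t1, 3), burn_in = 3), "burn-in")
})

test_that("harmonic mean is exact on closed-form cases and never overflows", {
  expect_equal(harmonic_mean_lnL(rep(-123.4, 10))$lnL, -123.4)
  ## two-sample closed form: ln HM = ln 2 - ln(e^10 + e^12)
  expected <- log(2) - (12 + log1p(exp(-2)))
  est <- harmonic_mean_lnL(c(-10, -12))
  expect_equal(est$lnL, expected, tolerance = 1e-12)
  ## estimate is bounded by the max sampled lnL
  set.seed(32)
  x <- rnorm(50, -5e5, 10)   # magnitudes like a 71 kb matrix
  hm <- harmonic_mean_lnL(x)
  expect_true(is.finite(hm$lnL))
  expect_lte(hm$lnL, max(x))
  expect_gte(hm$dominance, 1 / length(x))
  expect_error(harmonic_mean_lnL(-1), "2")
})

test_that("Bayes-factor arithmetic and verdicts follow the Kass-Raftery rule", {
  bf <- bayes_factor(-193798.37, -195500.09)
  expect_equal(bf$lnBF, 1701.72, tolerance = 1e-9)
  expect_equal(bf$twice_lnBF, 3403.44, tolerance = 1e-9)
  expect_equal(bf$verdict, "favor_model0")
  bf2 <- bayes_factor(-195500.09, -195549.60)
  expect_equal(bf2$twice_lnBF, 99.02, tolerance = 1e-9)
  expect_equal(bayes_factor(-10, -10)$twice_lnBF, 0)
  expect_equal(bayes_factor(-10, -10)$verdict, "inconclusive")
  expect_equal(bayes_factor(-20, -10)$verdict, "favor_model0_rejected")
  expect_equal(bayes_factor(-10, -14)$verdict, "inconclusive")  # 2lnBF = 8
  expect_error(bayes_factor(NA, -1), "finite")
})

test_that("rate-heterogeneous data favours the exon+intron partitioning", {
  set.seed(33)
  tr <- random_topology(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.04, 0.12)
  sm <- concatenate(simulate_alignments(
    sim_config(tr, 3, c(400, 500), model = subst_model("JC"),
               intron_rate_mult = 4, missing_fraction = 0, seed = 91)))
  cmp <- compare_partition_strategies(
    sm, strategies = c("exon_intron", "single"), n_gens = 1500,
    sample_every = 20, seed = 3, start_tree = ape::unroot(tr))
  expect_gt(cmp$twice_lnBF[cmp$strategy == "single"], 10)
  ## homogeneous data: the two schemes fit comparably
  sm0 <- concatenate(simulate_alignments(
    sim_config(tr, 3, c(400, 500), model = subst_model("JC"),
               intron_rate_mult = 1, missing_fraction = 0, seed = 92)))
  cmp0 <- compare_partition_strategies(
    sm0, strategies = c("exon_intron", "single"), n_gens = 1500,
    sample_every = 20, seed = 4, start_tree = ape::unroot(tr))
  expect_lt(abs(cmp0$twice_lnBF[cmp0$strategy == "single"]), 30)
})

test_that("Mk marginals equal enumeration and the ape::ace oracle", {
  set.seed(34)
  tr <- ape::rtree(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.3, 1)
  states <- c("0", "1", "0", "1", "1")
  names(states) <- tr$tip.label
  m <- matrix(states, ncol = 1, dimnames = list(tr$tip.label, "c1"))
  mine <- ancestral_states(tr, m, rate = 0.4)$c1$posterior
  ## enumeration over internal-node states
  k <- 2
  phy <- ape::reorder.phylo(tr, "postorder")
  internals <- sort(unique(phy$edge[, 1]))
  combs <- as.matrix(expand.grid(rep(list(1:k), length(internals))))
  probs <- apply(combs, 1, function(s) {
    st <- c(match(states[phy$tip.label], c("0", "1")), rep(NA, phy$Nnode))
    st[internals] <- s
    p <- 1 / k
    for (i in seq_len(nrow(phy$edge))) {
      P <- phylopipe:::mk_P(k, 0.4, phy$edge.length[i])
      p <- p * P[st[phy$edge[i, 1]], st[phy$edge[i, 2]]]
    }
    p
  })
  enum <- vapply(seq_along(internals), function(j)
    sum(probs[combs[, j] == 1]) / sum(probs), 0)
  expect_equal(unname(mine[as.character(internals), "0"]), enum,
               tolerance = 1e-10)
  expect_equal(unname(rowSums(mine)), rep(1, nrow(mine)))
  ## ML-rate mode against ape::ace (ER, marginal)
  est <- ancestral_states(tr, m)$c1
  a <- ape::ace(states[tr$tip.label], tr, type = "discrete", model = "ER")
  expect_equal(est$rate, a$rates, tolerance = 1e-3)
  expect_equal(unname(est$posterior[, "0"]), unname(a$lik.anc[, 1]),
               tolerance = 1e-4)
})

test_that("single-state characters are reported and skipped; MCMC mode runs", {
  tr <- ape::rtree(6)
  m <- matrix(c(rep("0", 6), c("0", "1", "0", "1", "0", "1")), 6, 2,
              dimnames = list(tr$tip.label, c("flat", "ok")))
  expect_warning(res <- ancestral_states(tr, m), "single observed state")
  expect_true(res$flat$skipped)
  expect_false(res$ok$skipped)
  mc <- ancestral_states(tr, m[, "ok", drop = FALSE], mode = "mcmc",
                         n_gens = 300, sample_every = 10, seed = 1)
  expect_equal(unname(rowSums(mc$ok$posterior)), rep(1, tr$Nnode),
               tolerance = 1e-9)
})
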