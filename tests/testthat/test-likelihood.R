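# Likelihood machinery: pruning vs enumeration and phangorn, branch
# optimisation closed forms, AIC, ML search, clock LRT, RELL topology
# tests and strict-clock dating.

test_that("degenerate trees give stationary-frequency likelihoods", {
  tr <- ape::read.tree(text = "(t1:0,t2:0,t3:0);")
  m <- subst_model("HKY", base_freq = c(0.4, 0.3, 0.2, 0.1))
  aln <- matrix("A", 3, 4, dimnames = list(paste0("t", 1:3), NULL))
  r <- pruning_lnL(tr, aln, m)
  expect_equal(r$site_lnl, rep(log(0.4), 4), tolerance = 1e-10)
  expect_equal(r$total, 4 * log(0.4), tolerance = 1e-10)
})

test_that("pruning equals brute-force state summation on random instances", {
  set.seed(202)
  models <- list(
    subst_model("JC"),
    subst_model("K80", kappa = 4),
    subst_model("HKY", base_freq = c(0.35, 0.15, 0.2, 0.3), kappa = 2.5),
    subst_model("GTR", base_freq = c(0.3, 0.25, 0.25, 0.2),
                rates = c(1.5, 4, 0.8, 1.2, 5, 1), p_inv = 0.2,
                gamma_shape = 0.6, n_cat = 3))
  for (i in 1:20) {
    n <- sample(4:5, 1)
    tr <- random_topology(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.4)
    aln <- random_alignment(n, 6, missing = 0.15)
    m <- models[[sample.int(4, 1)]]
    mine <- pruning_lnL(tr, aln, m)$total
    oracle <- brute_lnl(tr, aln, m)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under re-rooting for reversible models", {
  set.seed(12)
  tr <- random_topology(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.3)
  aln <- random_alignment(6, 100)
  m <- subst_model("GTR", base_freq = c(0.3, 0.2, 0.2, 0.3),
                   rates = c(1, 3, 1, 1, 3, 1), gamma_shape = 0.8)
  base <- pruning_lnL(tr, aln, m)$total
  for (tip in c("t2", "t5")) {
    rr <- ape::root(tr, tip, resolve.root = TRUE)
    expect_equal(pruning_lnL(rr, aln, m)$total, base, tolerance = 1e-8)
  }
})

test_that("discrete-gamma with a huge shape converges to homogeneous rates", {
  set.seed(13)
  tr <- random_topology(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.2)
  aln <- random_alignment(5, 200)
  flat <- pruning_lnL(tr, aln, subst_model("JC"))$total
  gam <- pruning_lnL(tr, aln, subst_model("JC", gamma_shape = 1e4))$total
  expect_equal(gam, flat, tolerance = 1e-4)
})

test_that("two-taxon branch optimisation recovers the JC distance closed form", {
  set.seed(14)
  p <- 0.12
  L <- 1000
  aln <- rbind(a = rep("A", L),
               b = c(rep("G", p * L), rep("A", (1 - p) * L)))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  fit <- optimize_branch_lengths(tr, aln, subst_model("JC"))
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("branch-length estimates recover and scale with the truth", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")  # path length 0.1
  cfg <- sim_config(tr, 1, c(1e5, 1e5), model = subst_model("JC"),
                    exon_fraction = 1, missing_fraction = 0,
                    gene_rate_sd = 0, seed = 31)
  aln <- simulate_alignments(cfg)[[1]]$aln
  fit <- optimize_branch_lengths(tr, aln, subst_model("JC"))
  d <- sum(fit$tree$edge.length)
  se <- sqrt(d / 1e5)   # Poisson-scale error on the path length
  expect_lt(abs(d - 0.1), 3 * se)
  ## doubling the true branch lengths roughly doubles the estimate
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
  cfg2 <- sim_config(tr2, 1, c(1e5, 1e5), model = subst_model("JC"),
                     exon_fraction = 1, missing_fraction = 0,
                     gene_rate_sd = 0, seed = 32)
  aln2 <- simulate_alignments(cfg2)[[1]]$aln
  fit2 <- optimize_branch_lengths(tr, aln2, subst_model("JC"))
  expect_lt(abs(sum(fit2$tree$edge.length) - 0.2), 3 * sqrt(0.2 / 1e5))
})

test_that("AIC model selection respects the formula and model nesting", {
  ## equal lnL, k differing by 1: smaller k wins by exactly 2 AIC units
  expect_equal((-2 * -100 + 2 * 5) - (-2 * -100 + 2 * 4), 2)
  set.seed(15)
  tr <- random_topology(4)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.15)
  aln <- simulate_alignments(sim_config(tr, 1, c(800, 800),
                                        model = subst_model("JC"),
                                        exon_fraction = 1, gene_rate_sd = 0,
                                        missing_fraction = 0,
                                        seed = 44))[[1]]$aln
  tab <- model_select_aic(aln, tr, families = c("JC", "HKY", "GTR"),
                          extras = c("", "IG"))
  fits <- attr(tab, "fits")
  ## nesting: richer models never fit worse (small numeric slack)
  expect_gte(fits[["GTR+I+G"]]$lnL, fits[["HKY+I+G"]]$lnL - 0.25)
  expect_gte(fits[["HKY+I+G"]]$lnL, fits[["HKY"]]$lnL - 0.25)
  expect_gte(fits[["GTR"]]$lnL, fits[["JC"]]$lnL - 0.25)
  ## data simulated under JC: JC wins on AIC
  expect_equal(tab$model[1], "JC")
})

test_that("ML search equals the exhaustive argmax and is self-consistent", {
  set.seed(16)
  tr <- random_topology(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.08, 0.2)
  aln <- simulate_alignments(sim_config(tr, 1, c(600, 600),
                                        model = subst_model("JC"),
                                        missing_fraction = 0,
                                        seed = 21))[[1]]$aln
  m <- subst_model("JC")
  res <- ml_tree_search(aln, m)
  ## oracle: optimise every topology
  lnls <- vapply(enumerate_topologies(rownames(aln)), function(tp)
    optimize_branch_lengths(tp, aln, m)$lnL, 0)
  expect_equal(res$lnL, max(lnls), tolerance = 1e-4)
  expect_true(same_topology(res$tree, tr))
  ## reported lnL matches a pruning recomputation on the returned tree
  expect_equal(res$lnL, pruning_lnL(res$tree, aln, m)$total,
               tolerance = 1e-9)
})

test_that("clock LRT is calibrated on clock data and powerful against violations", {
  set.seed(18)
  tr <- ape::rcoal(6)
  tr$edge.length <- tr$edge.length * 0.3
  m <- subst_model("JC")
  smc <- concatenate(simulate_alignments(
    sim_config(tr, 1, c(2000, 2000), model = m, exon_fraction = 1,
               missing_fraction = 0, gene_rate_sd = 0, seed = 61)))
  lrt <- clock_lrt(smc$matrix, tr, m)
  expect_equal(lrt$df, 4)          # n - 2
  expect_gt(lrt$p, 0.01)
  expect_true(ape::is.ultrametric(lrt$clock_tree, tol = 1e-6))
  ## one branch 10x faster: decisively rejected (avoid root-child edges,
  ## whose extension is absorbed by re-rooting the unrooted tree)
  trv <- tr
  nonroot <- which(trv$edge[, 1] != length(trv$tip.label) + 1L)
  pend <- nonroot[trv$edge[nonroot, 2] <= length(trv$tip.label)]
  long <- pend[which.max(trv$edge.length[pend])]
  trv$edge.length[long] <- trv$edge.length[long] * 10
  smv <- concatenate(simulate_alignments(
    sim_config(trv, 1, c(4000, 4000), model = m, exon_fraction = 1,
               missing_fraction = 0, gene_rate_sd = 0, seed = 62)))
  lrtv <- clock_lrt(smv$matrix, tr, m)
  expect_lt(lrtv$p, 0.001)
})

test_that("RELL topology tests give p = 1 for the best tree and SH >= KH", {
  set.seed(19)
  tr <- random_topology(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.2)
  aln <- simulate_alignments(sim_config(tr, 1, c(800, 800),
                                        model = subst_model("JC"),
                                        missing_fraction = 0,
                                        seed = 71))[[1]]$aln
  m <- subst_model("JC")
  cands <- c(list(ape::unroot(tr)), enumerate_topologies(rownames(aln))[1:3])
  sl <- vapply(cands, function(tp)
    pruning_lnL(optimize_branch_lengths(tp, aln, m, max_sweeps = 5)$tree,
                aln, m)$site_lnl, numeric(ncol(aln)))
  colnames(sl) <- paste0("tree", seq_along(cands))
  ## duplicate of the best tree: KH p must be 1
  sl2 <- cbind(sl, best_dup = sl[, which.max(colSums(sl))])
  tt <- topology_tests(sl2, n_rell = 2000, seed = 5)
  expect_equal(tt$p_kh[tt$tree == "best_dup"], 1)
  expect_true(all(tt$p_sh - tt$p_kh >= -1e-12))
  expect_equal(tt$p_sh[which.max(tt$lnL)], 1)
  ## the generating topology is not rejected
  expect_gt(tt$p_sh[1], 0.05)
  expect_error(topology_tests(sl[, 1, drop = FALSE]), "2")
})

test_that("fossil scaling converts relative heights to absolute ages", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
  d <- date_nodes(tr, c("a", "b"), min_age = 1.81)
  ## calibrated node at height 1, root at 2: root age 3.62
  expect_equal(unname(d$ages["5"]), 3.62, tolerance = 1e-9)
  d_root <- date_nodes(tr, c("a", "c"), min_age = 1.81)
  expect_equal(max(d_root$ages), 1.81, tolerance = 1e-9)
  ## ages decrease from root towards the tips along every edge
  phy <- d$tree
  ages <- c(rep(0, 4), unname(d$ages))
  expect_true(all(ages[phy$edge[, 1]] > ages[phy$edge[, 2]] - 1e-9))
  expect_error(date_nodes(ape::rtree(4), c("t1", "t2")), "ultrametric")
})
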