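# Parsimony engine: Fitch scoring against brute-force and phangorn
# oracles, exact vs heuristic searches, bootstrap behaviour, and the
# Bremer / partitioned-Bremer identities.

test_that("Fitch scoring handles constant, single-change and wildcard columns", {
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  m_const <- matrix("A", 4, 5, dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(tr, m_const), 0L)
  m1 <- matrix(c("A", "A", "C", "C"), 4, 1,
               dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(tr, m1), 1L)
  m2 <- matrix(c("A", "?", "-", "A"), 4, 1,
               dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(tr, m2), 0L)
  expect_error(fitch_score(tr, m1[1:3, , drop = FALSE]), "differ")
})

test_that("Fitch equals brute-force enumeration and phangorn on random instances", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(4:6, 1)
    tr <- random_topology(n)
    aln <- random_alignment(n, sample(8:20, 1), missing = 0.1)
    mine <- fitch_score(tr, aln)
    expect_identical(mine, as.integer(brute_fitch(tr, aln)))
    pd <- phangorn::phyDat(aln)
    expect_equal(mine, as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("exact searches agree with scoring every topology; TBR matches exact", {
  set.seed(55)
  ## 4 taxa: best of the 3 unrooted topologies
  aln4 <- random_alignment(4, 40)
  res <- mp_search(aln4, strategy = "exhaustive")
  scores <- vapply(enumerate_topologies(rownames(aln4)), fitch_score, 0L,
                   aln = aln4)
  expect_equal(res$score, min(scores))
  ## 7 taxa: branch-and-bound == exhaustive (scores and topology sets)
  aln7 <- random_alignment(7, 30)
  bb <- mp_search(aln7, strategy = "branch_and_bound")
  ex <- mp_search(aln7, strategy = "exhaustive")
  expect_equal(bb$score, ex$score)
  key <- function(tr) paste(sort(tree_splits(tr)), collapse = ";")
  expect_setequal(vapply(bb$trees, key, ""), vapply(ex$trees, key, ""))
  ## TBR heuristic attains the exact score
  hb <- mp_search(aln7, strategy = "tbr_heuristic", seed = 1,
                  n_addition_replicates = 5)
  expect_equal(hb$score, ex$score)
  expect_error(mp_search(random_alignment(11, 10), strategy = "exhaustive"),
               "refused")
})

test_that("clean synthetic signal recovers the generating topology", {
  set.seed(77)
  tr <- random_topology(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.15)
  sm <- concatenate(simulate_alignments(
    sim_config(tr, 4, c(400, 500), model = subst_model("JC"),
               missing_fraction = 0, seed = 12)))
  res <- mp_search(sm$matrix, strategy = "branch_and_bound")
  expect_length(res$trees, 1)
  expect_true(same_topology(res$trees[[1]], tr))
})

test_that("bootstrap support is deterministic, bounded and saturates on clean signal", {
  set.seed(42)
  tr <- random_topology(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.08, 0.2)
  sm <- concatenate(simulate_alignments(
    sim_config(tr, 2, c(300, 300), model = subst_model("JC"),
               missing_fraction = 0, seed = 4)))
  ref <- mp_search(sm$matrix)$trees[[1]]
  b1 <- bootstrap_support(sm$matrix, n_reps = 15, seed = 9, reference = ref)
  b2 <- bootstrap_support(sm$matrix, n_reps = 15, seed = 9, reference = ref)
  expect_identical(b1$table, b2$table)
  expect_true(all(b1$table$bootstrap >= 0 & b1$table$bootstrap <= 100))
  expect_setequal(b1$table$split, tree_splits(ref))
  expect_true(all(b1$table$bootstrap >= 80))   # clean signal
})

test_that("variable-length bootstrap reproduces the ordinary bootstrap at full length", {
  set.seed(17)
  tr <- random_topology(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.2)
  sm <- concatenate(simulate_alignments(
    sim_config(tr, 1, c(200, 200), model = subst_model("JC"),
               missing_fraction = 0, seed = 3)))
  ref <- mp_search(sm$matrix)$trees[[1]]
  vb <- variable_length_bootstrap(sm$matrix, sizes = ncol(sm$matrix),
                                  n_reps = 12, seed = 5, reference = ref)
  ob <- bootstrap_support(sm$matrix, n_reps = 12, seed = 5, reference = ref)
  expect_equal(vb$support[match(ob$table$split, vb$split)],
               ob$table$bootstrap)
  expect_error(variable_length_bootstrap(sm$matrix, sizes = integer(0)),
               "sizes")
})

test_that("Bremer decay counts uncontradicted characters exactly", {
  taxa <- paste0("t", 1:6)
  k <- 3
  ## k binary columns supporting {t1,t2,t3}; everything else constant
  m <- cbind(matrix(rep(c("A", "A", "A", "C", "C", "C"), k), 6, k),
             matrix("G", 6, 10))
  rownames(m) <- taxa
  best <- mp_search(m, strategy = "exhaustive")$trees[[1]]
  br <- bremer_support(m, best, exact_max = 6)
  key <- paste(sort(c("t1", "t2", "t3")), collapse = "|")  # canonical side
  expect_true(key %in% br$split)
  expect_equal(br$decay[br$split == key], k)
  ## zero-signal matrix: every decay 0
  m0 <- matrix("A", 6, 8, dimnames = list(taxa, NULL))
  tr0 <- random_topology(6)
  br0 <- bremer_support(m0, tr0, exact_max = 6)
  expect_true(all(br0$decay == 0))
  ## decay never exceeds the number of variable columns
  expect_true(all(br$decay <= sum(site_classes(m)$class != "constant")))
})

test_that("partitioned Bremer reproduces the two-gene toy and sums to decay", {
  taxa <- paste0("t", 1:6)
  g1 <- matrix(rep(c("A", "A", "A", "C", "C", "C"), 3), 6, 3,
               dimnames = list(taxa, NULL))           # supports t1t2t3
  g2 <- matrix(c("A", "A", "C", "A", "C", "C"), 6, 1,
               dimnames = list(taxa, NULL))           # supports t1t2t4
  m <- cbind(g1, g2)
  part <- c("gene1", "gene1", "gene1", "gene2")
  best <- mp_search(m, strategy = "exhaustive")$trees[[1]]
  key <- paste(sort(c("t1", "t2", "t3")), collapse = "|")
  pbs <- partitioned_bremer(m, part, best, exact_max = 6)
  row <- pbs[pbs$split == key, ]
  expect_equal(row$decay, 2)
  expect_equal(row$pbs.gene1, 3)
  expect_equal(row$pbs.gene2, -1)
  expect_equal(row$pbs.gene1 + row$pbs.gene2, row$decay)
  ## single-partition scheme: PBS equals decay everywhere
  pbs1 <- partitioned_bremer(m, rep("all", 4), best, exact_max = 6)
  expect_equal(pbs1$pbs.all, pbs1$decay)
  ## a partition with no variable sites contributes zero
  m2 <- cbind(m, matrix("T", 6, 5))
  part2 <- c(part, rep("flat", 5))
  pbs2 <- partitioned_bremer(m2, part2, best, exact_max = 6)
  expect_true(all(pbs2$pbs.flat == 0))
  expect_error(bremer_support(m, enumerate_topologies(taxa)[[1]],
                              exact_max = 6), "not optimal")
})

test_that("PBS sums to the decay index on random matrices (heuristic path too)", {
  set.seed(3)
  for (i in 1:4) {
    n <- sample(6:8, 1)
    aln <- random_alignment(n, 25)
    part <- sample(c("p1", "p2", "p3"), 25, TRUE)
    best <- mp_search(aln, strategy = "branch_and_bound")$trees[[1]]
    pbs <- bremer_support(aln, best, part = part,
                          exact_max = if (i %% 2) 9 else 4, seed = i)
    sums <- rowSums(pbs[, grep("^pbs\\.", names(pbs)), drop = FALSE])
    expect_equal(unname(sums), pbs$decay)
    expect_true(all(pbs$decay >= 0))
  }
})
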