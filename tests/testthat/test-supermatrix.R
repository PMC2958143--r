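# Supermatrix assembly, partition schemes, and the descriptive
# statistics (site classes, K2P, base composition, chi-square, Ti/Tv).

toy_genes <- function() {
  row <- strsplit("ACGTACGTAC", "")[[1]]
  a1 <- matrix(rep(row, each = 3), 3, 10,
               dimnames = list(c("t1", "t2", "t3"), NULL))
  g1 <- gene_alignment("g1", a1, paste0("exon", rep_len(1:3, 10)))
  a2 <- matrix("A", 2, 20, dimnames = list(c("t1", "t2"), NULL))
  g2 <- gene_alignment("g2", a2, rep("intron", 20))
  list(g1, g2)
}

test_that("concatenation lays genes end-to-end and fills missing taxa", {
  sm <- concatenate(toy_genes())
  expect_equal(ncol(sm$matrix), 30)
  expect_equal(sm$schemes$by_gene$g1, 1:10)
  expect_equal(sm$schemes$by_gene$g2, 11:30)
  expect_true(all(sm$matrix["t3", 11:30] == "?"))
  expect_equal(sm$schemes$exon_intron$exon, 1:10)
  expect_equal(sm$schemes$exon_intron$intron, 11:30)
  expect_error(concatenate(list(toy_genes()[[1]], toy_genes()[[1]])),
               "duplicate")
})

test_that("the seven-block scheme balances 71132 columns exactly", {
  blocks <- phylopipe:::balanced_blocks(71132, 7)
  sizes <- lengths(blocks)
  expect_equal(sum(sizes), 71132)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sort(unlist(blocks)), 1:71132)
})

test_that("site classification follows the two-states-twice rule", {
  m <- rbind(t1 = c("A", "A", "A", "A"),
             t2 = c("A", "A", "?", "C"),
             t3 = c("C", "A", "-", "G"),
             t4 = c("C", "C", "A", "T"))
  cls <- site_classes(m)$class
  expect_equal(cls, c("parsimony_informative", "variable", "constant",
                      "variable"))
  sc <- site_classes(m)
  expect_lte(sc$counts["parsimony_informative"], sc$counts["variable"])
  expect_equal(unname(sc$percent["variable"]), 100 * 3 / 4)
})

test_that("K2P distance matches its closed form and the ape oracle", {
  ## P = 0.1, Q = 0 over 100 sites: 10 transitions
  a <- rep("A", 100); b <- c(rep("G", 10), rep("A", 90))
  expect_equal(k2p_distance(a, b)$d, -0.5 * log(0.8), tolerance = 1e-12)
  ## P = 0, Q = 0.1: 10 transversions; 1-2P-Q = 0.9, 1-2Q = 0.8
  b2 <- c(rep("C", 10), rep("A", 90))
  expect_equal(k2p_distance(a, b2)$d, -0.5 * log(0.9) - 0.25 * log(0.8),
               tolerance = 1e-12)
  expect_equal(k2p_distance(a, a)$d, 0)
  ## random alignments against ape::dist.dna
  set.seed(20)
  for (rep in 1:5) {
    tr <- random_topology(5)
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.08)
    cfg <- sim_config(tr, 1, c(2000, 2000), model = subst_model("K80", kappa = 3),
                      missing_fraction = 0, gene_rate_sd = 0, seed = rep)
    aln <- simulate_alignments(cfg)[[1]]$aln
    mine <- distance_matrix(aln)$matrix
    oracle <- as.matrix(ape::dist.dna(ape::as.DNAbin(aln), model = "K80"))
    expect_equal(mine, oracle[rownames(mine), colnames(mine)],
                 tolerance = 1e-10)
    ## correction inflates: K2P >= p-distance
    pd <- distance_matrix(aln, "p")$matrix
    expect_true(all(mine - pd >= -1e-12))
    expect_true(isSymmetric(mine))
    expect_true(all(diag(mine) == 0))
  }
  expect_error(k2p_distance("?", "A"), "comparable")
})

test_that("saturated pairs are flagged rather than silently dropped", {
  set.seed(33)
  a <- sample(BASES, 100, TRUE)
  b <- vapply(a, function(x) sample(setdiff(BASES, x), 1), "")
  d <- k2p_distance(a, b)
  expect_true(d$saturated)
  expect_true(is.na(d$d))
})

test_that("base composition excludes missing data and sums to one", {
  m <- rbind(t1 = strsplit("ACGT", "")[[1]],
             t2 = c("A", "A", "A", "A"))
  bc <- base_composition(m)
  expect_equal(as.numeric(bc["t1", ]), rep(0.25, 4))
  m2 <- rbind(t1 = c("A", "A", "A", "A", "?", "?", "?", "?"))
  expect_equal(as.numeric(base_composition(m2)["t1", ]), c(1, 0, 0, 0))
  expect_error(base_composition(rbind(t1 = c("?", "?"))), "zero unambiguous")
})

test_that("chi-square homogeneity matches hand arithmetic and responds to GC shifts", {
  m_same <- rbind(t1 = rep(BASES, 25), t2 = rep(BASES, 25))
  r <- chi_square_homogeneity(m_same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 3)
  ## counts (90,10,0,0) vs (10,90,0,0): X2 = 4 * 40^2/50 = 128
  m2 <- rbind(t1 = c(rep("A", 90), rep("C", 10)),
              t2 = c(rep("A", 10), rep("C", 90)))
  r2 <- chi_square_homogeneity(m2)
  expect_equal(r2$statistic, 128)
  ## p decreases monotonically as one taxon's GC drifts from the pool
  ps <- vapply(c(0, 10, 20, 30), function(shift) {
    m <- rbind(t1 = c(rep("A", 50), rep("G", 50)),
               t2 = c(rep("A", 50 - shift), rep("G", 50 + shift)))
    chi_square_homogeneity(m)$p
  }, 0)
  expect_true(all(diff(ps) < 0))
  ## invariant under taxon reordering
  set.seed(4)
  m3 <- random_alignment(5, 200)
  expect_equal(chi_square_homogeneity(m3)$statistic,
               chi_square_homogeneity(m3[5:1, ])$statistic)
})

test_that("Ti/Tv counts pool over pairs and encode undefined ratios as NA", {
  m <- rbind(a = c("A", "C", "G", "T"), b = c("G", "C", "G", "A"))
  r <- ti_tv_ratio(m)
  expect_equal(r$transitions, 1)
  expect_equal(r$transversions, 1)
  expect_equal(r$ratio, 1)
  expect_true(is.na(ti_tv_ratio(rbind(a = c("A", "C"), b = c("A", "C")))$ratio))
  expect_true(is.na(ti_tv_ratio(rbind(a = c("A", "G"), b = c("G", "A")))$ratio))
})

test_that("per-gene report aggregates lengths and percentages", {
  genes <- toy_genes()
  rep_ <- per_gene_report(genes)
  expect_equal(nrow(rep_), 3)
  expect_equal(rep_$length[3], sum(rep_$length[1:2]))
  expect_equal(rep_$pct_exon[1], 100)
  expect_equal(rep_$pct_exon[2], 0)
  expect_equal(rep_$variable[2], 0)
  expect_equal(rep_$parsimony_informative[2], 0)
  expect_equal(rep_$mean_p_distance[2], 0)
})

test_that("supermatrix NEXUS and gene FASTA writers round-trip", {
  set.seed(6)
  tr <- random_topology(4)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.1)
  genes <- simulate_alignments(sim_config(tr, 2, c(30, 40), seed = 2,
                                          missing_fraction = 0.2))
  sm <- concatenate(genes)
  nex <- tempfile(fileext = ".nex")
  write_supermatrix_nexus(sm, nex)
  back <- read_nexus_matrix(nex)
  expect_equal(unname(back[sm$taxa, ]), unname(sm$matrix))
  cs <- attr(back, "charsets")
  expect_equal(unname(cs[["by_gene_gene001"]]), sm$schemes$by_gene$gene001)
  fa <- tempfile(fileext = ".fa"); an <- tempfile(fileext = ".tsv")
  write_gene_fasta(genes[[1]], fa, an)
  g2 <- read_gene_fasta(fa, an, id = genes[[1]]$id)
  expect_equal(g2$aln, genes[[1]]$aln)
  expect_equal(g2$annotation, genes[[1]]$annotation)
})
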