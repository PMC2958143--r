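## Synthetic-data generators: fixture proteomes with planted paralogs,
## multi-locus nucleotide alignments evolved along a known tree, and
## discrete trait matrices under the symmetric Mk model.  Every output
## carries machine-readable truth for downstream recovery tests.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a proteome fixture with planted paralog pairs
#'
#' Generates `n_single` unrelated random protein sequences plus
#' `n_pairs` duplicated-then-mutated pairs whose pairwise identity is
#' driven toward a target percentage by point substitution. Truth labels
#' (`single_copy` / `paralog_member`) are recorded for every record.
#'
#' @param n_single,n_pairs non-negative counts (at least one positive).
#' @param length_range integer range of sequence lengths.
#' @param similarity_targets target percent identities in (0, 100], one
#'   per pair (recycled).
#' @param seed optional integer seed.
#' @return object of class `genome_fixture`: `records` (named character
#'   vector of sequences), `truth` (named labels), `paralog_pairs`
#'   (data.frame id1, id2, target_similarity).
#' @export
simulate_genome <- function(n_single, n_pairs, length_range = c(200, 400),
                            similarity_targets = 80, seed = NULL) {
  stopifnot(n_single >= 0, n_pairs >= 0)
  if (n_single + n_pairs == 0) stop("empty fixture: n_single + n_pairs = 0")
  stopifnot(all(length_range >= 1), length_range[1] <= length_range[2])
  stopifnot(all(similarity_targets > 0), all(similarity_targets <= 100))
  if (!is.null(seed)) set.seed(seed)
  similarity_targets <- rep_len(similarity_targets, max(n_pairs, 1L))

  rand_seq <- function(len) paste(sample(AA_ALPHABET, len, TRUE), collapse = "")
  records <- character(0)
  truth <- character(0)
  for (i in seq_len(n_single)) {
    len <- sample(length_range[1]:length_range[2], 1)
    records[paste0("sc", i)] <- rand_seq(len)
    truth[paste0("sc", i)] <- "single_copy"
  }
  pairs <- data.frame(id1 = character(0), id2 = character(0),
                      target_similarity = numeric(0),
                      stringsAsFactors = FALSE)
  for (j in seq_len(n_pairs)) {
    len <- sample(length_range[1]:length_range[2], 1)
    a <- rand_seq(len)
    tgt <- similarity_targets[j]
    ## mutate a fraction 1 - tgt/100 of positions to a different residue
    chars <- strsplit(a, "")[[1]]
    n_mut <- round(len * (1 - tgt / 100))
    pos <- sample.int(len, n_mut)
    for (p in pos) {
      chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
    }
    b <- paste(chars, collapse = "")
    ida <- paste0("par", j, "a"); idb <- paste0("par", j, "b")
    records[ida] <- a; records[idb] <- b
    truth[ida] <- "paralog_member"; truth[idb] <- "paralog_member"
    pairs <- rbind(pairs, data.frame(id1 = ida, id2 = idb,
                                     target_similarity = tgt,
                                     stringsAsFactors = FALSE))
  }
  structure(list(records = records, truth = truth, paralog_pairs = pairs),
            class = "genome_fixture")
}

#' Simulation configuration for multi-locus alignments
#'
#' @param tree `phylo` with branch lengths in expected
#'   substitutions/site.
#' @param n_genes number of loci.
#' @param length_range per-locus length range (bp).
#' @param exon_fraction proportion of each locus annotated as exon.
#' @param model a [subst_model()] used for exon sites.
#' @param intron_rate_mult rate multiplier applied to intron sites
#'   (introns evolve faster than exons).
#' @param gene_rate_sd standard deviation of log-normal per-gene rate
#'   multipliers (mean 1 on the log scale; 0 = all genes equal rate).
#' @param missing_fraction probability that a (taxon, gene) cell is
#'   blanked to all-`?` (whole-locus absence).
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(tree, n_genes = 100, length_range = c(300, 1500),
                       exon_fraction = 0.7, model = subst_model("HKY"),
                       intron_rate_mult = 2, gene_rate_sd = 0.3,
                       missing_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  stopifnot(exon_fraction >= 0, exon_fraction <= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            intron_rate_mult > 0, gene_rate_sd >= 0, n_genes >= 1)
  stopifnot(inherits(model, "subst_model"))
  structure(list(tree = tree, n_genes = n_genes, length_range = length_range,
                 exon_fraction = exon_fraction, model = model,
                 intron_rate_mult = intron_rate_mult,
                 gene_rate_sd = gene_rate_sd,
                 missing_fraction = missing_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

## simulate one alignment (character matrix) of `len` sites on `tree`
## under `model`, site rates scaled by `site_rate` (vector) * `mult`
simulate_sites <- function(tree, model, len, site_rate, mult = 1) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- phy$edge[nrow(phy$edge), 1]
  Pfun <- model_P_fun(model)
  states <- matrix(0L, nnode, len)
  f <- model$base_freq
  states[root, ] <- sample.int(4, len, TRUE, prob = f)
  rates <- unique(site_rate)
  ## preorder: parents before children
  for (i in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    t_edge <- phy$edge.length[i] * mult
    for (r in rates) {
      idx <- which(site_rate == r)
      if (!length(idx)) next
      if (t_edge * r == 0) {
        states[ch, idx] <- states[p, idx]
      } else {
        P <- Pfun(t_edge * r)
        for (s in 1:4) {
          sel <- idx[states[p, idx] == s]
          if (length(sel))
            states[ch, sel] <- sample.int(4, length(sel), TRUE, prob = P[s, ])
        }
      }
    }
  }
  bases <- c("A", "C", "G", "T")
  m <- matrix(bases[states[1:ntip, , drop = FALSE]], nrow = ntip)
  rownames(m) <- phy$tip.label
  m
}

#' Simulate multi-locus alignments along a known tree
#'
#' Each locus draws a length, a per-gene rate multiplier and per-site
#' gamma categories (if the model has +G), evolves sites along the tree
#' from the stationary distribution, annotates the leading
#' `exon_fraction` of columns as exon (codon positions cycling 1,2,3)
#' and the remainder as intron (simulated at `intron_rate_mult` times
#' the exon rate), then blanks whole (taxon, gene) cells to `?` with
#' probability `missing_fraction`.
#'
#' @param config a [sim_config()].
#' @return list of `gene_alignment` objects; attribute `truth` records
#'   the generating tree, model and per-gene rate multipliers.
#' @export
simulate_alignments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  model <- config$model
  ntip <- length(tree$tip.label)
  stopifnot(ntip >= 2)
  genes <- vector("list", config$n_genes)
  gene_mult <- exp(stats::rnorm(config$n_genes, -config$gene_rate_sd^2 / 2,
                                config$gene_rate_sd))
  mix <- model_rate_mixture(model)
  for (g in seq_len(config$n_genes)) {
    len <- sample(config$length_range[1]:config$length_range[2], 1)
    n_exon <- round(len * config$exon_fraction)
    anno <- c(
      if (n_exon > 0) paste0("exon", rep_len(1:3, n_exon)),
      rep("intron", len - n_exon)
    )
    site_rate <- sample(mix$rates, len, TRUE, prob = mix$probs)
    site_rate[anno == "intron"] <- site_rate[anno == "intron"] *
      config$intron_rate_mult
    m <- simulate_sites(tree, model, len, site_rate, mult = gene_mult[g])
    drop <- stats::runif(ntip) < config$missing_fraction
    m[drop, ] <- "?"
    genes[[g]] <- gene_alignment(sprintf("gene%03d", g), m, anno)
  }
  attr(genes, "truth") <- list(tree = tree, model = model,
                               gene_rate_multipliers = gene_mult,
                               config = config)
  genes
}

## ---- discrete traits under Mk -----------------------------------------

## Mk transition probability of staying, k states, total leave rate r
mk_p_same <- function(k, r, t) 1 / k + (1 - 1 / k) * exp(-r * k / (k - 1) * t)

#' Simulate discrete traits under the symmetric Mk model
#'
#' Characters evolve independently on a rooted tree with a uniform root
#' state; true internal-node states are recorded for recovery tests.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param n_chars number of characters.
#' @param state_counts states per character (recycled; all >= 2).
#' @param rate total rate of leaving the current state.
#' @param seed optional integer seed.
#' @return object of class `trait_matrix`: `tips` (taxa x chars
#'   character matrix of states "0","1",...), `node_states` (true
#'   internal states), `state_counts`, `rate`, `tree`.
#' @export
simulate_traits <- function(tree, n_chars, state_counts = 2, rate = 0.1,
                            seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (rate <= 0) stop("rate must be positive")
  if (any(state_counts < 2)) stop("fewer than 2 states")
  if (!is.null(seed)) set.seed(seed)
  state_counts <- rep_len(as.integer(state_counts), n_chars)
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- phy$edge[nrow(phy$edge), 1]
  tips <- matrix(NA_character_, ntip, n_chars,
                 dimnames = list(phy$tip.label, paste0("char", seq_len(n_chars))))
  nodes <- matrix(NA_character_, phy$Nnode, n_chars,
                  dimnames = list(ntip + seq_len(phy$Nnode),
                                  paste0("char", seq_len(n_chars))))
  for (ch in seq_len(n_chars)) {
    k <- state_counts[ch]
    st <- integer(nnode)
    st[root] <- sample.int(k, 1)
    for (i in rev(seq_len(nrow(phy$edge)))) {
      p <- phy$edge[i, 1]; v <- phy$edge[i, 2]
      ps <- mk_p_same(k, rate, phy$edge.length[i])
      if (stats::runif(1) < ps) {
        st[v] <- st[p]
      } else {
        st[v] <- sample(setdiff(seq_len(k), st[p]), 1)
      }
    }
    tips[, ch] <- as.character(st[1:ntip] - 1L)
    nodes[, ch] <- as.character(st[(ntip + 1):nnode] - 1L)
  }
  structure(list(tips = tips, node_states = nodes,
                 state_counts = state_counts, rate = rate, tree = phy),
            class = "trait_matrix")
}

#' A 13-taxon study-shaped simulation preset
#'
#' A fixed 13-leaf generating tree shaped like a shallow ingroup
#' radiation (pairwise path lengths ~0.02-0.05 substitutions/site) with
#' a distant outgroup (~0.11 to the ingroup), matching the divergence
#' profile of a low-divergence multi-locus fish dataset.
#'
#' @param n_genes,length_scale number of loci and a multiplier on the
#'   default 300-1500 bp locus length range (use < 1 for quick runs).
#' @param seed integer seed.
#' @param ... passed on to [sim_config()].
#' @return a [sim_config()].
#' @export
preset_config <- function(n_genes = 100, length_scale = 1, seed = 1L, ...) {
  tree <- ape::read.tree(text = paste0(
    "(((((t1:0.008,t2:0.008):0.003,((t3:0.007,t4:0.007):0.003,t5:0.010):0.002):0.002,",
    "t6:0.013):0.002,(t7:0.009,(t8:0.010,(t9:0.008,t10:0.008):0.002):0.002):0.004):0.003,",
    "(t11:0.012,t12:0.013):0.003,outgroup:0.085);"))
  rng <- round(c(300, 1500) * length_scale)
  sim_config(tree, n_genes = n_genes, length_range = rng, seed = seed, ...)
}
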