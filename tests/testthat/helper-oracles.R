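# Independent oracles used across the suite: brute-force parsimony and
# likelihood by full enumeration of internal-node states, a plain
# dynamic-programming local aligner, and small random-instance factories.

BASES <- c("A", "C", "G", "T")

random_alignment <- function(ntaxa, nsites, missing = 0) {
  m <- matrix(sample(BASES, ntaxa * nsites, TRUE), ntaxa, nsites,
              dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  if (missing > 0) {
    idx <- which(stats::runif(length(m)) < missing)
    m[idx] <- "?"
  }
  m
}

random_topology <- function(ntaxa) {
  ape::unroot(ape::rtree(ntaxa, tip.label = paste0("t", seq_len(ntaxa))))
}

# minimum state changes over all internal-node assignments; tips with
# missing data pick their cheapest state per assignment
brute_fitch <- function(phy, aln) {
  phy <- ape::reorder.phylo(ape::unroot(phy), "postorder")
  ntip <- length(phy$tip.label)
  aln <- aln[phy$tip.label, , drop = FALSE]
  internals <- sort(unique(phy$edge[, 1]))
  n_int <- length(internals)
  assign <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  total <- 0
  for (col in seq_len(ncol(aln))) {
    obs <- aln[, col]
    allowed <- lapply(obs, function(ch)
      if (ch %in% BASES) match(ch, BASES) else 1:4)
    cost <- numeric(nrow(assign))
    for (i in seq_len(nrow(phy$edge))) {
      p <- phy$edge[i, 1]; v <- phy$edge[i, 2]
      ps <- assign[, match(p, internals)]
      if (v <= ntip) {
        cost <- cost + !(ps %in% allowed[[v]])
      } else {
        cost <- cost + (ps != assign[, match(v, internals)])
      }
    }
    total <- total + min(cost)
  }
  total
}

# likelihood by explicit summation over internal-node states
brute_lnl <- function(phy, aln, model) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  aln <- aln[phy$tip.label, , drop = FALSE]
  internals <- sort(unique(phy$edge[, 1]))
  n_int <- length(internals)
  root <- phy$edge[nrow(phy$edge), 1]
  mix <- phylopipe:::model_rate_mixture(model)
  Pfun <- phylopipe:::model_P_fun(model)
  f <- model$base_freq
  assign <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  total <- 0
  for (col in seq_len(ncol(aln))) {
    obs <- aln[, col]
    allowed <- lapply(obs, function(ch)
      if (ch %in% BASES) match(ch, BASES) else 1:4)
    site_l <- 0
    for (ci in seq_along(mix$rates)) {
      Ps <- lapply(seq_len(nrow(phy$edge)), function(i)
        Pfun(phy$edge.length[i] * mix$rates[ci]))
      lik <- f[assign[, match(root, internals)]]
      for (i in seq_len(nrow(phy$edge))) {
        p <- phy$edge[i, 1]; v <- phy$edge[i, 2]
        ps <- assign[, match(p, internals)]
        if (v <= ntip) {
          lik <- lik * vapply(seq_len(nrow(assign)), function(r)
            sum(Ps[[i]][ps[r], allowed[[v]]]), 0)
        } else {
          vs <- assign[, match(v, internals)]
          lik <- lik * Ps[[i]][cbind(ps, vs)]
        }
      }
      site_l <- site_l + mix$probs[ci] * sum(lik)
    }
    total <- total + log(site_l)
  }
  total
}

# plain affine-gap Smith-Waterman (Gotoh) for cross-checking scores
oracle_local_score <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- get("BLOSUM62", envir = environment())
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- X <- Y <- matrix(0, n + 1, m + 1)
  X[] <- Y[] <- -Inf
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
      M[i, j] <- max(0, S[a[i - 1], b[j - 1]] +
                       max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

# are two splits (logical masks over the same taxa) compatible?
splits_compatible <- function(key1, key2, taxa) {
  s1 <- taxa %in% strsplit(key1, "|", fixed = TRUE)[[1]]
  s2 <- taxa %in% strsplit(key2, "|", fixed = TRUE)[[1]]
  !all(c(any(s1 & s2), any(s1 & !s2), any(!s1 & s2), any(!s1 & !s2)))
}
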