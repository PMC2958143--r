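## Partitioned Bayesian MCMC over topology, branch lengths and
## substitution parameters (unlinked across partitions), majority-rule
## consensus with posterior probabilities, harmonic-mean marginal
## likelihoods with Kass-Raftery Bayes-factor comparisons, and Mk-model
## ancestral-state reconstruction.
##
## Priors: uniform over topologies, Exponential(10) branch lengths, flat
## Dirichlet frequencies/exchangeabilities, Uniform(0,1) p_inv,
## Exponential(1) gamma shape, flat Dirichlet on the weighted
## partition-rate simplex.

ldirichlet <- function(x, a) {
  sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
}

## random symmetric NNI proposal on a rooted-trifurcation phylo,
## preserving branch lengths (swap a child of the edge's lower node with
## another child of its upper node)
propose_nni <- function(phy) {
  e <- phy$edge
  ntip <- length(phy$tip.label)
  internal_edges <- which(e[, 2] > ntip)
  if (!length(internal_edges)) return(phy)
  i <- internal_edges[sample.int(length(internal_edges), 1)]
  u <- e[i, 1]; v <- e[i, 2]
  ch_v <- which(e[, 1] == v)
  ch_u <- setdiff(which(e[, 1] == u), i)
  if (!length(ch_v) || !length(ch_u)) return(phy)
  a <- ch_v[sample.int(length(ch_v), 1)]
  w <- ch_u[sample.int(length(ch_u), 1)]
  tmp <- phy$edge[a, 2]
  phy$edge[a, 2] <- phy$edge[w, 2]
  phy$edge[w, 2] <- tmp
  phy
}

## per-partition compressed patterns of a supermatrix under a scheme
partition_patterns <- function(sm, scheme) {
  sets <- if (is.character(scheme)) sm$schemes[[scheme]] else scheme
  if (is.null(sets)) stop("unknown partition scheme")
  cover <- as.integer(sort(unname(unlist(sets))))
  if (!identical(cover, seq_len(ncol(sm$matrix))))
    stop("scheme does not cover the matrix columns exactly")
  lapply(sets, function(cols)
    compress_patterns(encode_nuc(sm$matrix[, cols, drop = FALSE])))
}

## model log-prior (flat pieces are constant and omitted)
model_log_prior <- function(model) {
  lp <- 0
  if (!is.null(model$gamma_shape)) lp <- lp + stats::dexp(model$gamma_shape, 1, log = TRUE)
  lp
}

#' Partitioned Bayesian MCMC
#'
#' Metropolis-Hastings over topology (NNI proposals), branch lengths
#' (multiplier proposals), per-partition substitution parameters
#' (Dirichlet / sliding-window proposals, unlinked across partitions)
#' and partition rate multipliers constrained to mean rate 1.
#'
#' @param sm a [concatenate()] supermatrix.
#' @param scheme partition scheme name (e.g. `"exon_intron"`) or a named
#'   list of column sets covering the matrix.
#' @param model a [subst_model()] used (independently) for every
#'   partition.
#' @param n_gens generations; desk-scale default, scalable to the
#'   millions by configuration.
#' @param sample_every sampling interval.
#' @param n_runs independent runs (different seeds).
#' @param seed integer seed.
#' @param topology_fixed disable topology proposals.
#' @param start_tree starting tree (default: random coalescent-shaped
#'   starting tree per run).
#' @param rate_multipliers allow per-partition rate multipliers.
#' @return object of class `mcmc_trace`: `samples` (data.frame with
#'   generation, run, lnL, parameters), `trees` (Newick per sample),
#'   `asdsf` (average SD of split frequencies across runs, `NA` for one
#'   run), `scheme`, `n_partitions`.
#' @export
mcmc_run <- function(sm, scheme = "single", model = subst_model("JC"),
                     n_gens = 20000, sample_every = 100, n_runs = 1,
                     seed = 1L, topology_fixed = FALSE, start_tree = NULL,
                     rate_multipliers = TRUE) {
  stopifnot(inherits(sm, "supermatrix"), n_gens >= 1)
  pats <- partition_patterns(sm, scheme)
  np <- length(pats)
  w_len <- vapply(pats, function(p) sum(p$weights), 0)
  w_len <- w_len / sum(w_len)
  taxa <- sm$taxa
  what <- model_free_params(model)

  all_samples <- list()
  all_trees <- list()
  run_split_freqs <- list()

  for (run in seq_len(n_runs)) {
    set.seed(seed + 1000L * (run - 1L))
    phy <- if (is.null(start_tree)) {
      tr <- ape::rcoal(length(taxa), tip.label = sample(taxa))
      tr$edge.length <- pmax(tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.05, 1e-4)
      ape::unroot(tr)
    } else {
      st <- ape::unroot(start_tree)
      if (is.null(st$edge.length)) st$edge.length <- rep(0.02, nrow(st$edge))
      st
    }
    models <- rep(list(model), np)
    rmult <- rep(1, np)
    x_simplex <- w_len
    ## cached codes ordered by current topology's tip order
    codes_for <- lapply(pats, function(p) {
      rows <- match(phy$tip.label, taxa)
      p$codes[rows, , drop = FALSE]
    })
    part_lnl <- function(p_idx, tree = phy, mods = models, rm = rmult) {
      cp <- pats[[p_idx]]
      codes <- cp$codes[match(tree$tip.label, taxa), , drop = FALSE]
      sum(lnl_patterns(tree, codes, mods[[p_idx]], rate_mult = rm[p_idx]) *
            cp$weights)
    }
    lnl_p <- vapply(seq_len(np), part_lnl, 0)
    lp_branch <- sum(stats::dexp(phy$edge.length, 10, log = TRUE))
    lp_model <- vapply(models, model_log_prior, 0)

    samples <- list()
    trees <- character(0)
    for (gen in seq_len(n_gens)) {
      move <- sample.int(4L, 1)
      if (move == 1L && !topology_fixed) {
        cand <- propose_nni(phy)
        cand_lnl <- vapply(seq_len(np), part_lnl, 0, tree = cand)
        if (log(stats::runif(1)) < sum(cand_lnl) - sum(lnl_p)) {
          phy <- cand; lnl_p <- cand_lnl
        }
      } else if (move == 2L || (move == 1L && topology_fixed)) {
        i <- sample.int(nrow(phy$edge), 1)
        b <- phy$edge.length[i]
        bp <- b * exp(1.0 * (stats::runif(1) - 0.5))
        cand <- phy; cand$edge.length[i] <- bp
        cand_lnl <- vapply(seq_len(np), part_lnl, 0, tree = cand)
        lp_new <- lp_branch + stats::dexp(bp, 10, log = TRUE) -
          stats::dexp(b, 10, log = TRUE)
        lr <- sum(cand_lnl) - sum(lnl_p) + lp_new - lp_branch + log(bp / b)
        if (log(stats::runif(1)) < lr) {
          phy <- cand; lnl_p <- cand_lnl; lp_branch <- lp_new
        }
      } else if (move == 3L && length(what)) {
        p_idx <- sample.int(np, 1)
        m <- models[[p_idx]]
        m2 <- m
        hr <- 0
        pick <- sample(what, 1)
        if (pick == "kappa") {
          m2$kappa <- m$kappa * exp(0.4 * (stats::runif(1) - 0.5))
          m2$rates <- c(1, m2$kappa, 1, 1, m2$kappa, 1)
          hr <- log(m2$kappa / m$kappa)
        } else if (pick == "rates") {
          conc <- 200
          r <- m$rates / sum(m$rates)
          r2 <- as.numeric(stats::rgamma(6, conc * r, 1))
          r2 <- pmax(r2, 1e-8); r2 <- r2 / sum(r2)
          hr <- ldirichlet(r, conc * r2) - ldirichlet(r2, conc * r)
          m2$rates <- r2 / r2[6]
        } else if (pick == "p_inv") {
          x <- m$p_inv + (stats::runif(1) - 0.5) * 0.2
          if (x < 0) x <- -x
          if (x >= 1) x <- 2 - x - 1e-9
          m2$p_inv <- x
        } else if (pick == "shape") {
          m2$gamma_shape <- m$gamma_shape * exp(0.5 * (stats::runif(1) - 0.5))
          hr <- log(m2$gamma_shape / m$gamma_shape)
        }
        new_lnl <- part_lnl(p_idx, mods = `[[<-`(models, p_idx, m2))
        new_lp <- model_log_prior(m2)
        lr <- new_lnl - lnl_p[p_idx] + new_lp - lp_model[p_idx] + hr
        if (log(stats::runif(1)) < lr) {
          models[[p_idx]] <- m2; lnl_p[p_idx] <- new_lnl
          lp_model[p_idx] <- new_lp
        }
      } else if (move == 4L && np > 1 && rate_multipliers) {
        conc <- 500
        x2 <- as.numeric(stats::rgamma(np, conc * x_simplex, 1))
        x2 <- pmax(x2, 1e-8); x2 <- x2 / sum(x2)
        hr <- ldirichlet(x_simplex, conc * x2) - ldirichlet(x2, conc * x_simplex)
        rm2 <- x2 / w_len
        cand_lnl <- vapply(seq_len(np), part_lnl, 0, rm = rm2)
        if (log(stats::runif(1)) < sum(cand_lnl) - sum(lnl_p) + hr) {
          x_simplex <- x2; rmult <- rm2; lnl_p <- cand_lnl
        }
      }
      if (gen %% sample_every == 0) {
        samples[[length(samples) + 1L]] <- data.frame(
          run = run, generation = gen, lnL = sum(lnl_p),
          tree_length = sum(phy$edge.length),
          mean_rate_mult_sd = stats::sd(rmult))
        trees <- c(trees, ape::write.tree(phy))
      }
    }
    st <- do.call(rbind, samples)
    all_samples[[run]] <- st
    all_trees[[run]] <- trees
    keep <- trees[max(1, floor(length(trees) / 2)):length(trees)]
    run_split_freqs[[run]] <- split_frequencies(lapply(keep, function(s)
      ape::read.tree(text = s)))
  }

  asdsf <- NA_real_
  if (n_runs > 1) {
    keys <- unique(unlist(lapply(run_split_freqs, names)))
    fr <- sapply(run_split_freqs, function(f)
      ifelse(keys %in% names(f), f[keys], 0))
    asdsf <- mean(apply(matrix(fr, nrow = length(keys)), 1, stats::sd))
  }
  structure(list(samples = do.call(rbind, all_samples),
                 trees = unlist(all_trees), asdsf = asdsf,
                 scheme = if (is.character(scheme)) scheme else "custom",
                 n_partitions = np),
            class = "mcmc_trace")
}

## split relative frequencies of a list of trees
split_frequencies <- function(trees) {
  counts <- table(unlist(lapply(trees, tree_splits)))
  as.numeric(counts / length(trees)) -> fr
  names(fr) <- names(counts)
  fr
}

#' Majority-rule consensus with posterior probabilities
#'
#' @param trace an `mcmc_trace` (or list of Newick strings).
#' @param burn_in number of sampled trees discarded per run.
#' @return list: `tree` (50% majority-rule consensus, node labels =
#'   PP), `pp` (named split posterior probabilities).
#' @export
consensus_with_pp <- function(trace, burn_in = 0) {
  newicks <- if (inherits(trace, "mcmc_trace")) {
    runs <- split(trace$trees,
                  rep(unique(trace$samples$run),
                      each = length(trace$trees) / length(unique(trace$samples$run))))
    unlist(lapply(runs, function(tr) {
      if (burn_in >= length(tr)) stop("burn-in >= sample size")
      tr[(burn_in + 1):length(tr)]
    }))
  } else {
    if (burn_in >= length(trace)) stop("burn-in >= sample size")
    trace[(burn_in + 1):length(trace)]
  }
  trees <- lapply(newicks, function(s) ape::read.tree(text = s))
  pp <- split_frequencies(trees)
  cons <- ape::consensus(trees, p = 0.5)
  cons_keys <- tree_splits(cons)
  ## annotate consensus nodes in the order of their splits
  list(tree = cons, pp = pp,
       consensus_pp = pp[cons_keys])
}

#' Harmonic-mean marginal log-likelihood
#'
#' ln of the harmonic mean of sampled likelihoods, computed in log space
#' (stable log-sum-exp of negated log-likelihoods). The estimator is
#' known to be unstable; `dominance` reports the largest single-sample
#' weight share as a diagnostic.
#'
#' @param trace an `mcmc_trace` or numeric vector of sampled lnL (nats).
#' @param burn_in samples discarded from the start (per run for traces).
#' @return list: `lnL` (estimate), `n`, `dominance`.
#' @export
harmonic_mean_lnL <- function(trace, burn_in = 0) {
  lnl <- if (inherits(trace, "mcmc_trace")) {
    unlist(lapply(split(trace$samples$lnL, trace$samples$run), function(x) {
      if (burn_in >= length(x)) stop("burn-in >= sample size")
      x[(burn_in + 1):length(x)]
    }))
  } else {
    if (burn_in >= length(trace)) stop("burn-in >= sample size")
    trace[(burn_in + 1):length(trace)]
  }
  if (length(lnl) < 2) stop("need at least 2 post-burn-in samples")
  neg <- -lnl
  m <- max(neg)
  w <- exp(neg - m)
  est <- -(m + log(mean(w)))
  list(lnL = est, n = length(lnl), dominance = max(w) / sum(w))
}

#' Bayes factor from two marginal log-likelihoods
#'
#' `2lnBF = 2 (lnL0 - lnL1)`, read on the Kass-Raftery scale: model 0
#' is rejected when `2lnBF < 0`, the comparison is inconclusive for
#' `0 <= 2lnBF <= 10`, and model 0 is decisively favoured when
#' `2lnBF > 10`.
#'
#' @param lnL0,lnL1 marginal log-likelihoods of model 0 (null) and
#'   model 1.
#' @return object of class `bayes_factor`: `lnL0`, `lnL1`, `lnBF`,
#'   `twice_lnBF`, `verdict`.
#' @export
bayes_factor <- function(lnL0, lnL1) {
  if (!is.finite(lnL0) || !is.finite(lnL1)) stop("non-finite marginal lnL")
  lnbf <- lnL0 - lnL1
  t2 <- 2 * lnbf
  verdict <- if (t2 < 0) "favor_model0_rejected"
             else if (t2 > 10) "favor_model0" else "inconclusive"
  structure(list(lnL0 = lnL0, lnL1 = lnL1, lnBF = lnbf, twice_lnBF = t2,
                 verdict = verdict), class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("lnBF = %.2f, 2lnBF = %.2f (%s)\n", x$lnBF, x$twice_lnBF,
              x$verdict))
  invisible(x)
}

#' Compare partitioning strategies by Bayes factors
#'
#' Runs one MCMC per strategy, estimates harmonic-mean marginal
#' log-likelihoods, and reports `2lnBF` of the reference strategy
#' against each alternative.
#'
#' @param sm a [concatenate()] supermatrix.
#' @param strategies scheme names to compare.
#' @param reference the null-model scheme compared against each
#'   alternative.
#' @param model per-partition [subst_model()].
#' @param n_gens,sample_every,seed MCMC controls.
#' @param burn_in_frac fraction of samples discarded.
#' @param topology_fixed,start_tree fix the topology (speeds the
#'   comparison; model fit is what differs across schemes).
#' @return data.frame: strategy, n_partitions, harmonic_mean, lnBF,
#'   twice_lnBF, verdict (reference row has NA comparisons).
#' @export
compare_partition_strategies <- function(sm,
                                         strategies = c("exon_intron",
                                                        "single", "by_gene",
                                                        "codon_intron",
                                                        "equal7"),
                                         reference = "exon_intron",
                                         model = subst_model("JC"),
                                         n_gens = 10000, sample_every = 50,
                                         seed = 1L, burn_in_frac = 0.25,
                                         topology_fixed = TRUE,
                                         start_tree = NULL) {
  stopifnot(reference %in% strategies)
  hm <- list()
  for (s in strategies) {
    tr <- mcmc_run(sm, scheme = s, model = model, n_gens = n_gens,
                   sample_every = sample_every, seed = seed,
                   topology_fixed = topology_fixed, start_tree = start_tree)
    nb <- floor(burn_in_frac * nrow(tr$samples))
    hm[[s]] <- list(est = harmonic_mean_lnL(tr, burn_in = nb),
                    np = tr$n_partitions)
  }
  rows <- lapply(strategies, function(s) {
    est <- hm[[s]]$est$lnL
    if (s == reference) {
      data.frame(strategy = s, n_partitions = hm[[s]]$np,
                 harmonic_mean = est, lnBF = NA_real_,
                 twice_lnBF = NA_real_, verdict = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      bf <- bayes_factor(hm[[reference]]$est$lnL, est)
      data.frame(strategy = s, n_partitions = hm[[s]]$np,
                 harmonic_mean = est, lnBF = bf$lnBF,
                 twice_lnBF = bf$twice_lnBF, verdict = bf$verdict,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

## ---- Mk ancestral states ----------------------------------------------

## Mk transition matrix, k states, total leave rate r
mk_P <- function(k, r, t) {
  ps <- mk_p_same(k, r, t)
  po <- (1 - ps) / (k - 1)
  M <- matrix(po, k, k)
  diag(M) <- ps
  M
}

## pruning lnL of one character; states: integer 1..k or NA per tip
mk_lnL <- function(phy, states, k, rate) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  L <- matrix(1, ntip + phy$Nnode, k)
  for (i in seq_len(ntip)) {
    if (!is.na(states[i])) {
      L[i, ] <- 0; L[i, states[i]] <- 1
    }
  }
  up <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; v <- phy$edge[i, 2]
    M <- mk_P(k, rate, phy$edge.length[i])
    L[p, ] <- L[p, ] * as.numeric(M %*% L[v, ])
  }
  root <- phy$edge[nrow(phy$edge), 1]
  log(sum(L[root, ] / k))
}

## marginal posterior state probabilities at every internal node
mk_marginals <- function(phy, states, k, rate) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- phy$edge[nrow(phy$edge), 1]
  ## up pass: conditional likelihood of subtree below each node
  L <- matrix(1, nnode, k)
  for (i in seq_len(ntip)) {
    if (!is.na(states[i])) { L[i, ] <- 0; L[i, states[i]] <- 1 }
  }
  edge_M <- vector("list", nrow(phy$edge))
  msg <- matrix(1, nnode, k)   # message passed up each child edge
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; v <- phy$edge[i, 2]
    edge_M[[i]] <- mk_P(k, rate, phy$edge.length[i])
    msg[v, ] <- as.numeric(edge_M[[i]] %*% L[v, ])
    L[p, ] <- L[p, ] * msg[v, ]
  }
  ## down pass (preorder): G[v] = prob of rest-of-tree given state at v
  G <- matrix(NA_real_, nnode, k)
  G[root, ] <- 1 / k
  for (i in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[i, 1]; v <- phy$edge[i, 2]
    above <- G[p, ] * L[p, ] / msg[v, ]      # exclude v's own message
    G[v, ] <- as.numeric(t(edge_M[[i]]) %*% above)
  }
  post <- L * G
  post <- post / rowSums(post)
  internal <- (ntip + 1):nnode
  out <- post[internal, , drop = FALSE]
  rownames(out) <- internal
  colnames(out) <- as.character(seq_len(k) - 1L)
  out
}

#' Mk-model ancestral-state reconstruction
#'
#' Marginal posterior state probabilities at every internal node of a
#' fixed tree for each discrete character, under the symmetric Mk
#' model. The rate is either supplied, estimated by maximum likelihood
#' per character (empirical-Bayes mode, the default), or integrated
#' over by MCMC with an Exponential(1) prior (`mode = "mcmc"`).
#'
#' @param phy rooted `phylo` with branch lengths; leaves must cover the
#'   trait taxa.
#' @param traits a `trait_matrix` from [simulate_traits()] or a
#'   character matrix (rows = taxa, entries state codes, NA = missing).
#' @param rate fixed rate (overrides estimation).
#' @param mode `"pruning"` (empirical Bayes) or `"mcmc"`.
#' @param n_gens,sample_every,seed MCMC controls for `mode = "mcmc"`.
#' @return list per character: `posterior` (internal nodes x states,
#'   rows sum to 1), `rate`, `skipped` (TRUE with a reason for
#'   single-state characters).
#' @export
ancestral_states <- function(phy, traits, rate = NULL,
                             mode = c("pruning", "mcmc"), n_gens = 2000,
                             sample_every = 10, seed = 1L) {
  mode <- match.arg(mode)
  tips <- if (inherits(traits, "trait_matrix")) traits$tips else traits
  stopifnot(all(rownames(tips) %in% phy$tip.label))
  if (!ape::is.rooted(phy)) stop("ancestral-state reconstruction needs a rooted tree")
  out <- list()
  for (ch in colnames(tips)) {
    v <- tips[phy$tip.label, ch]
    obs <- sort(unique(stats::na.omit(v)))
    if (length(obs) < 2) {
      warning("character ", ch, " has a single observed state; skipped")
      out[[ch]] <- list(posterior = NULL, rate = NA_real_, skipped = TRUE)
      next
    }
    k <- if (inherits(traits, "trait_matrix")) {
      traits$state_counts[match(ch, colnames(tips))]
    } else length(obs)
    states <- match(v, as.character(seq_len(k) - 1L))
    if (mode == "pruning") {
      r <- rate
      if (is.null(r)) {
        op <- stats::optimize(function(lr) -mk_lnL(phy, states, k, exp(lr)),
                              c(log(1e-4), log(100)))
        r <- exp(op$minimum)
      }
      post <- mk_marginals(phy, states, k, r)
    } else {
      set.seed(seed)
      r <- if (is.null(rate)) 0.5 else rate
      cur <- mk_lnL(phy, states, k, r) + stats::dexp(r, 1, log = TRUE)
      acc <- matrix(0, phy$Nnode, k)
      ns <- 0
      for (gen in seq_len(n_gens)) {
        r2 <- r * exp(0.5 * (stats::runif(1) - 0.5))
        new <- mk_lnL(phy, states, k, r2) + stats::dexp(r2, 1, log = TRUE)
        if (log(stats::runif(1)) < new - cur + log(r2 / r)) {
          r <- r2; cur <- new
        }
        if (gen %% sample_every == 0) {
          acc <- acc + mk_marginals(phy, states, k, r)
          ns <- ns + 1
        }
      }
      post <- acc / ns
      rownames(post) <- length(phy$tip.label) + seq_len(phy$Nnode)
      colnames(post) <- as.character(seq_len(k) - 1L)
    }
    out[[ch]] <- list(posterior = post, rate = r, skipped = FALSE)
  }
  out
}
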