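## Felsenstein-pruning likelihood under JC/K80/HKY/GTR (+I, discrete-G),
## branch-length and model-parameter optimisation, AIC model selection,
## ML tree search, the molecular-clock likelihood-ratio test, RELL-based
## KH/SH/WSH topology tests, and strict-clock fossil scaling of node
## ages.

## tip partial-likelihood lookup: column j (bit code) has 1 for each
## base contained in the code
TIP_PARTIAL <- vapply(1:15, function(code)
  as.numeric(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0), numeric(4))

## Core pruning pass over compressed patterns.
## `codes`: tip-id-indexed 4-bit matrix whose rows follow phy$tip.label.
lnl_patterns <- function(phy, codes, model, rate_mult = 1) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  P <- ncol(codes)
  mix <- model_rate_mixture(model)
  Pfun <- model_P_fun(model)
  f <- model$base_freq
  root <- phy$edge[nrow(phy$edge), 1]
  cat_lnl <- matrix(NA_real_, length(mix$rates), P)
  for (ci in seq_along(mix$rates)) {
    partials <- vector("list", nnode)
    logscale <- numeric(P)
    for (i in seq_len(nrow(phy$edge))) {
      par <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
      t_eff <- phy$edge.length[i] * mix$rates[ci] * rate_mult
      M <- Pfun(t_eff)
      childp <- if (ch <= ntip) TIP_PARTIAL[, codes[ch, ], drop = FALSE]
                else partials[[ch]]
      contrib <- M %*% childp
      m <- pmax(contrib[1, ], contrib[2, ], contrib[3, ], contrib[4, ])
      if (any(!is.finite(m))) return(rep(-1e8, P))
      ## columns with m = 0 have zero likelihood in this rate category
      ## (e.g. a variable column under the invariant-sites class); they
      ## stay zero and contribute -Inf below, resolved by the mixture
      pos <- m > 0
      if (any(pos)) {
        sc <- rep(1, P); sc[pos] <- 1 / m[pos]
        contrib <- contrib * rep(sc, each = 4)
        logscale[pos] <- logscale[pos] + log(m[pos])
      }
      partials[[par]] <- if (is.null(partials[[par]])) contrib
                         else partials[[par]] * contrib
    }
    cat_lnl[ci, ] <- log(colSums(partials[[root]] * f)) + logscale
  }
  lw <- log(mix$probs)
  ## log-sum-exp over categories, tolerating -Inf categories
  tot <- cat_lnl + lw
  mx <- apply(tot, 2, max)
  out <- mx + log(colSums(exp(sweep(tot, 2, pmax(mx, -1e300), "-"))))
  out[!is.finite(mx)] <- -Inf
  out
}

#' Per-site log-likelihood by Felsenstein pruning
#'
#' @param phy tree (`phylo`) with branch lengths in expected
#'   substitutions/site.
#' @param aln character matrix, rows named by the tree's taxa.
#' @param model a [subst_model()].
#' @return list: `site_lnl` (nats, one per column), `total`.
#' @export
pruning_lnL <- function(phy, aln, model) {
  if (!setequal(phy$tip.label, rownames(aln)))
    stop("tree leaves and alignment taxa differ")
  if (is.null(phy$edge.length)) stop("tree needs branch lengths")
  cp <- compress_patterns(encode_nuc(aln[phy$tip.label, , drop = FALSE]))
  pat_lnl <- lnl_patterns(phy, cp$codes, model)
  if (any(!is.finite(pat_lnl))) stop("non-finite site likelihood")
  site <- pat_lnl[cp$index]
  list(site_lnl = site, total = sum(pat_lnl * cp$weights))
}

## total lnL on compressed patterns (fast path)
lnl_total <- function(phy, cp, model, rate_mult = 1) {
  sum(lnl_patterns(phy, cp$codes, model, rate_mult) * cp$weights)
}

#' Optimise branch lengths on a fixed topology
#'
#' Coordinate-wise Brent optimisation swept over branches until the
#' improvement per sweep falls below `tol` (relative). The likelihood
#' never decreases across sweeps.
#'
#' @param phy topology (`phylo`); existing branch lengths are the
#'   starting point (missing ones start at 0.05).
#' @param aln character matrix, rows named by taxa.
#' @param model a [subst_model()].
#' @param tol relative convergence tolerance.
#' @param max_sweeps sweep cap; non-convergence is reported via
#'   `converged = FALSE` with the partial result returned.
#' @param max_bl upper bound per branch.
#' @return list: `tree` (with optimised lengths), `lnL`, `converged`.
#' @export
optimize_branch_lengths <- function(phy, aln, model, tol = 1e-6,
                                    max_sweeps = 20, max_bl = 10) {
  stopifnot(setequal(phy$tip.label, rownames(aln)))
  cp <- compress_patterns(encode_nuc(aln[phy$tip.label, , drop = FALSE]))
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.05, nrow(phy$edge))
  cur <- lnl_total(phy, cp, model)
  converged <- FALSE
  for (sw in seq_len(max_sweeps)) {
    prev <- cur
    for (i in seq_len(nrow(phy$edge))) {
      obj <- function(b) {
        phy$edge.length[i] <- b
        -lnl_total(phy, cp, model)
      }
      op <- stats::optimize(obj, c(0, max_bl), tol = 1e-5)
      if (is.finite(op$objective) && -op$objective >= cur) {
        phy$edge.length[i] <- op$minimum
        cur <- -op$objective
      }
    }
    if (abs(cur - prev) < tol * (abs(prev) + 1)) { converged <- TRUE; break }
  }
  list(tree = phy, lnL = cur, converged = converged)
}

## transform model parameters to an unconstrained vector and back
model_par_vec <- function(model, what) {
  v <- numeric(0)
  if ("kappa" %in% what) v <- c(v, log(model$kappa))
  if ("rates" %in% what) v <- c(v, log(model$rates[1:5] / model$rates[6]))
  if ("p_inv" %in% what)
    v <- c(v, stats::qlogis(min(max(model$p_inv, 1e-4), 0.94) / 0.95))
  if ("shape" %in% what) v <- c(v, log(model$gamma_shape))
  v
}

model_par_update <- function(model, v, what) {
  i <- 0
  if ("kappa" %in% what) {
    i <- i + 1
    model$kappa <- exp(v[i])
    model$rates <- c(1, model$kappa, 1, 1, model$kappa, 1)
  }
  if ("rates" %in% what) {
    model$rates <- c(exp(v[i + 1:5]), 1)
    i <- i + 5
  }
  if ("p_inv" %in% what) {
    i <- i + 1
    model$p_inv <- 0.95 * stats::plogis(v[i])  # bounded away from 1
  }
  if ("shape" %in% what) { i <- i + 1; model$gamma_shape <- exp(v[i]) }
  model
}

## which parameters a model exposes for ML fitting
model_free_params <- function(model) {
  what <- character(0)
  if (model$family %in% c("K80", "HKY")) what <- c(what, "kappa")
  if (model$family == "GTR") what <- c(what, "rates")
  if (model$p_inv > 0) what <- c(what, "p_inv")
  if (!is.null(model$gamma_shape)) what <- c(what, "shape")
  what
}

#' Fit a substitution model on a fixed topology
#'
#' Alternates branch-length sweeps and quasi-Newton optimisation of the
#' model's free parameters (base frequencies are set empirically from
#' the data, the usual model-selection convention).
#'
#' @inheritParams optimize_branch_lengths
#' @param rounds alternation rounds.
#' @return list: `tree`, `model`, `lnL`, `k` (free parameter count
#'   including branch lengths).
#' @export
fit_model <- function(phy, aln, model, rounds = 2, tol = 1e-4) {
  if (model$family %in% c("HKY", "GTR")) {
    bc <- base_composition(aln, per_taxon = FALSE)
    model$base_freq <- as.numeric(bc[1, ]) / sum(as.numeric(bc[1, ]))
  }
  what <- model_free_params(model)
  fit <- optimize_branch_lengths(phy, aln, model, tol = tol)
  phy <- fit$tree
  cp <- compress_patterns(encode_nuc(aln[phy$tip.label, , drop = FALSE]))
  lnl <- fit$lnL
  if (length(what)) {
    obj <- function(v) {
      if (any(!is.finite(v)) || any(abs(v) > 12)) return(1e10)
      val <- -lnl_total(phy, cp, model_par_update(model, v, what))
      if (!is.finite(val)) 1e10 else val
    }
    for (r in seq_len(rounds)) {
      v0 <- model_par_vec(model, what)
      f0 <- obj(v0)
      op <- if (length(v0) == 1) {
        stats::optim(v0, obj, method = "Brent", lower = -12, upper = 12)
      } else {
        stats::optim(v0, obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))
      }
      if (op$value < f0) {
        op2 <- stats::optim(op$par, obj, method = "BFGS",
                            control = list(maxit = 50, reltol = 1e-10))
        if (op2$value < op$value) op <- op2
      }
      ## never accept a parameter move that lowers the likelihood
      if (op$value < f0) model <- model_par_update(model, op$par, what)
      fit <- optimize_branch_lengths(phy, aln, model, tol = tol)
      phy <- fit$tree
      if (abs(fit$lnL - lnl) < tol * (abs(lnl) + 1)) { lnl <- fit$lnL; break }
      lnl <- fit$lnL
    }
  }
  k <- model_n_param(model) + nrow(phy$edge)
  list(tree = phy, model = model, lnL = lnl, k = k)
}

#' AIC model selection over candidate substitution models
#'
#' Fits each candidate on the reference topology and ranks by
#' AIC = -2 lnL + 2k, with k the free model parameters plus branch
#' lengths.
#'
#' @param aln character matrix.
#' @param phy reference topology.
#' @param families model families to consider.
#' @param extras rate-variation variants per family: any of `""`
#'   (plain), `"I"`, `"G"`, `"IG"`.
#' @return data.frame ranked by AIC with the best model first; attribute
#'   `"fits"` holds the fitted objects keyed by model name.
#' @export
model_select_aic <- function(aln, phy,
                             families = c("JC", "K80", "HKY", "GTR"),
                             extras = c("", "I", "G", "IG")) {
  fits <- list()
  rows <- list()
  for (fam in families) for (ex in extras) {
    m <- subst_model(fam,
                     p_inv = if (grepl("I", ex)) 0.1 else 0,
                     gamma_shape = if (grepl("G", ex)) 0.5 else NULL)
    nm <- paste0(fam, if (grepl("I", ex)) "+I" else "",
                 if (grepl("G", ex)) "+G" else "")
    fit <- fit_model(phy, aln, m)
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(model = nm, lnL = fit$lnL, k = fit$k,
                             AIC = -2 * fit$lnL + 2 * fit$k,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), ]
  tab$best <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Maximum-likelihood tree search
#'
#' Exhaustive topology scan for small taxon sets; otherwise NNI
#' hill-climbing with branch-length re-optimisation starting from the
#' maximum-parsimony tree.
#'
#' @param aln character matrix (>= 4 taxa).
#' @param model a [subst_model()].
#' @param seed optional integer seed.
#' @param exhaustive_max exhaustive scan up to this many taxa.
#' @return list: `tree` (optimised branch lengths), `lnL`.
#' @export
ml_tree_search <- function(aln, model, seed = NULL, exhaustive_max = 7) {
  stopifnot(nrow(aln) >= 4)
  if (!is.null(seed)) set.seed(seed)
  taxa <- rownames(aln)
  if (length(taxa) <= exhaustive_max) {
    best <- NULL
    for (topo in enumerate_topologies(taxa)) {
      fit <- optimize_branch_lengths(topo, aln, model, max_sweeps = 10)
      if (is.null(best) || fit$lnL > best$lnL) best <- fit
    }
    return(list(tree = best$tree, lnL = best$lnL))
  }
  start <- mp_search(aln, seed = seed,
                     n_addition_replicates = 3)$trees[[1]]
  fit <- optimize_branch_lengths(start, aln, model)
  repeat {
    ## cheap screen: score every NNI neighbour at its inherited branch
    ## lengths, then fully re-optimise only the most promising one
    nbs <- nni_neighbors_phylo(fit$tree)
    cp <- compress_patterns(encode_nuc(aln[fit$tree$tip.label, , drop = FALSE]))
    screen <- vapply(nbs, lnl_total, 0, cp = cp, model = model)
    best <- which.max(screen)
    if (screen[best] <= fit$lnL - 20) break
    cfit <- optimize_branch_lengths(nbs[[best]], aln, model)
    if (cfit$lnL > fit$lnL + 1e-6) fit <- cfit else break
  }
  list(tree = fit$tree, lnL = fit$lnL)
}

## ---- molecular clock ---------------------------------------------------

## heights parameterisation of a rooted binary tree: root height +
## a fraction in (0,1) per non-root internal node (preorder)
clock_tree_from_par <- function(topo, par) {
  ntip <- length(topo$tip.label)
  topo <- ape::reorder.phylo(topo, "cladewise")
  root <- ntip + 1L
  h <- numeric(ntip + topo$Nnode)
  h[root] <- exp(par[1])
  internals <- setdiff(unique(topo$edge[, 1]), root)
  fr <- stats::plogis(par[-1])
  names(fr) <- internals
  for (i in seq_len(nrow(topo$edge))) {
    p <- topo$edge[i, 1]; v <- topo$edge[i, 2]
    h[v] <- if (v <= ntip) 0 else h[p] * fr[as.character(v)]
  }
  topo$edge.length <- h[topo$edge[, 1]] - h[topo$edge[, 2]]
  attr(topo, "heights") <- h
  topo
}

#' Likelihood-ratio test of a global molecular clock
#'
#' Compares free branch lengths against a rate-constant (ultrametric)
#' tree on the same topology: statistic = 2 (lnL_free - lnL_clock), df =
#' n_taxa - 2 (2n-3 free branch lengths vs n-1 node heights), p from the
#' chi-square upper tail.
#'
#' @param aln character matrix.
#' @param phy topology; rooted, or rooted at `outgroup`.
#' @param model a [subst_model()].
#' @param outgroup taxon used to root an unrooted topology.
#' @return list: `statistic`, `df`, `p`, `lnL_free`, `lnL_clock`,
#'   `clock_tree` (ultrametric, heights in substitutions/site).
#' @export
clock_lrt <- function(aln, phy, model, outgroup = NULL) {
  if (!is.null(outgroup)) {
    phy <- ape::root(ape::unroot(phy), outgroup, resolve.root = TRUE)
  }
  if (!ape::is.rooted(phy)) stop("clock fit needs a rooted topology")
  ntip <- length(phy$tip.label)
  free <- optimize_branch_lengths(ape::unroot(phy), aln, model,
                                  tol = 1e-8, max_sweeps = 40)
  cp <- compress_patterns(encode_nuc(aln[phy$tip.label, , drop = FALSE]))
  n_int <- phy$Nnode - 1L
  init <- c(log(max(sum(free$tree$edge.length) / (2 * ntip), 1e-3)),
            rep(stats::qlogis(0.7), n_int))
  obj <- function(par) {
    if (any(!is.finite(par)) || par[1] > 10) return(1e10)
    v <- -lnl_total(clock_tree_from_par(phy, par), cp, model)
    if (!is.finite(v)) 1e10 else v
  }
  op <- stats::optim(init, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10))
  op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))
  lnl_clock <- -op$value
  if (lnl_clock > free$lnL + 0.05)
    stop("clock likelihood exceeds unconstrained likelihood: optimizer failure")
  lnl_clock <- min(lnl_clock, free$lnL)
  stat <- max(2 * (free$lnL - lnl_clock), 0)
  df <- ntip - 2L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       lnL_free = free$lnL, lnL_clock = lnl_clock,
       clock_tree = clock_tree_from_par(phy, op$par))
}

## ---- topology tests (RELL) --------------------------------------------

#' KH, SH and WSH topology tests via RELL resampling
#'
#' Per-site log-likelihood vectors for each candidate tree are
#' bootstrap-resampled (resampling estimated log-likelihoods: no
#' re-optimisation). KH compares each tree with the ML tree; SH uses the
#' centred maximum over candidates (the ML tree's SH p is 1 by
#' construction); WSH standardises each pairwise difference by its
#' estimated standard deviation.
#'
#' @param site_lnl numeric matrix, sites x trees (named columns
#'   recommended).
#' @param n_rell number of RELL replicates.
#' @param seed optional integer seed.
#' @return data.frame: tree, lnL, delta (lnL distance from best), and
#'   p-values `p_kh`, `p_sh`, `p_wsh`.
#' @export
topology_tests <- function(site_lnl, n_rell = 10000, seed = NULL) {
  stopifnot(is.matrix(site_lnl), ncol(site_lnl) >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(site_lnl)
  K <- ncol(site_lnl)
  if (is.null(colnames(site_lnl))) colnames(site_lnl) <- paste0("tree", 1:K)
  tot <- colSums(site_lnl)
  best <- which.max(tot)
  delta <- tot[best] - tot
  ## RELL: resampled totals, K x B
  idx <- matrix(sample.int(n, n * n_rell, replace = TRUE), n, n_rell)
  R <- apply(idx, 2, function(ii) colSums(site_lnl[ii, , drop = FALSE]))
  C <- R - rowMeans(R)                       # centred
  p_kh <- p_sh <- p_wsh <- numeric(K)
  sd_pair <- function(k) {
    d <- site_lnl[, best] - site_lnl[, k]
    sqrt(max(n * stats::var(d), 0))
  }
  maxC <- apply(C, 2, max)
  for (k in 1:K) {
    Dk <- C[best, ] - C[k, ]
    p_kh[k] <- mean(Dk >= delta[k])
    p_sh[k] <- mean(maxC - C[k, ] >= delta[k])
    s <- sd_pair(k)
    if (s == 0) {
      p_wsh[k] <- 1
    } else {
      sds <- vapply(1:K, function(j) {
        d <- site_lnl[, j] - site_lnl[, k]
        sqrt(max(n * stats::var(d), 0))
      }, 0)
      sds[sds == 0] <- Inf
      Tw <- apply(sweep(C, 2, C[k, ]) / sds, 2, max)
      obs <- max((tot - tot[k]) / sds)
      p_wsh[k] <- mean(Tw >= obs)
    }
  }
  data.frame(tree = colnames(site_lnl), lnL = tot, delta = as.numeric(delta),
             p_kh = p_kh, p_sh = p_sh, p_wsh = p_wsh,
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---- dating ------------------------------------------------------------

#' Scale an ultrametric tree to absolute ages from one fossil calibration
#'
#' A simplified strict-clock dating: all node heights are multiplied by
#' the single factor that sets the calibrated node's age to exactly
#' `min_age` (the minimum fossil age treated as a point calibration).
#'
#' @param clock_tree rooted ultrametric `phylo` (e.g. from
#'   [clock_lrt()]).
#' @param calibration_taxa two or more taxa whose most recent common
#'   ancestor is the calibrated node.
#' @param min_age calibration age in million years.
#' @return list: `tree` (branch lengths in MY), `ages` (named node ages
#'   in MY), `scale_factor`.
#' @export
date_nodes <- function(clock_tree, calibration_taxa, min_age = 1.81) {
  phy <- clock_tree
  if (!ape::is.rooted(phy)) stop("dating needs a rooted ultrametric tree")
  if (!ape::is.ultrametric(phy, tol = 1e-6)) stop("tree is not ultrametric")
  node <- ape::getMRCA(phy, calibration_taxa)
  if (is.null(node) || node <= length(phy$tip.label))
    stop("calibration must identify an internal node")
  h <- ape::node.depth.edgelength(phy)      # root-to-node distances
  height <- max(h) - h                      # node heights above tips
  if (height[node] <= 0) stop("calibrated node has zero height")
  f <- min_age / height[node]
  phy$edge.length <- phy$edge.length * f
  ages <- height * f
  names(ages) <- c(phy$tip.label, length(phy$tip.label) + seq_len(phy$Nnode))
  list(tree = phy, ages = ages[(length(phy$tip.label) + 1):length(ages)],
       scale_factor = f)
}
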