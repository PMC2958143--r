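## Nucleotide substitution models: JC, K80, HKY, GTR, optionally with a
## proportion of invariant sites (+I) and discrete-gamma rate
## heterogeneity (+G).  Rate matrices are scaled to one expected
## substitution per site per unit branch length at stationarity.

#' Construct a substitution model
#'
#' @param family one of `"JC"`, `"K80"`, `"HKY"`, `"GTR"`.
#' @param base_freq stationary base frequencies (A,C,G,T), summing to 1.
#'   Ignored (fixed at 1/4) for JC and K80.
#' @param kappa transition/transversion rate ratio (K80, HKY).
#' @param rates GTR exchangeabilities in the order AC, AG, AT, CG, CT,
#'   GT (GT is conventionally fixed to 1).
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @param gamma_shape shape of the discrete-gamma rate distribution
#'   (`NULL` = homogeneous rates).
#' @param n_cat number of equal-probability gamma categories.
#' @return object of class `subst_model`.
#' @export
subst_model <- function(family = c("JC", "K80", "HKY", "GTR"),
                        base_freq = rep(0.25, 4), kappa = 2,
                        rates = c(1, 1, 1, 1, 1, 1),
                        p_inv = 0, gamma_shape = NULL, n_cat = 4) {
  family <- match.arg(family)
  if (family %in% c("JC", "K80")) base_freq <- rep(0.25, 4)
  stopifnot(length(base_freq) == 4, all(base_freq > 0))
  if (abs(sum(base_freq) - 1) > 1e-8) stop("base frequencies must sum to 1")
  stopifnot(p_inv >= 0, p_inv < 1)
  if (!is.null(gamma_shape)) stopifnot(gamma_shape > 0, n_cat >= 2)
  if (family %in% c("K80", "HKY")) {
    stopifnot(kappa > 0)
    rates <- c(1, kappa, 1, 1, kappa, 1)
  }
  if (family == "JC") rates <- rep(1, 6)
  stopifnot(length(rates) == 6, all(rates > 0))
  structure(list(family = family, base_freq = base_freq, kappa = kappa,
                 rates = rates, p_inv = p_inv, gamma_shape = gamma_shape,
                 n_cat = as.integer(n_cat)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  tag <- x$family
  if (x$p_inv > 0) tag <- paste0(tag, "+I")
  if (!is.null(x$gamma_shape)) tag <- paste0(tag, "+G")
  cat("substitution model:", tag, "\n")
  cat("  base freq:", sprintf("%.4f", x$base_freq), "\n")
  if (x$family != "JC") cat("  rates (AC,AG,AT,CG,CT,GT):",
                            sprintf("%.3f", x$rates), "\n")
  if (x$p_inv > 0) cat("  p_inv:", x$p_inv, "\n")
  if (!is.null(x$gamma_shape)) cat("  gamma shape:", x$gamma_shape,
                                   "(", x$n_cat, "categories )\n")
  invisible(x)
}

## Scaled GTR rate matrix (rows sum to 0, mean rate 1 at stationarity).
model_Q <- function(model) {
  f <- model$base_freq
  r <- model$rates
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- r[1] * f[2]; Q[1, 3] <- r[2] * f[3]; Q[1, 4] <- r[3] * f[4]
  Q[2, 1] <- r[1] * f[1]; Q[2, 3] <- r[4] * f[3]; Q[2, 4] <- r[5] * f[4]
  Q[3, 1] <- r[2] * f[1]; Q[3, 2] <- r[4] * f[2]; Q[3, 4] <- r[6] * f[4]
  Q[4, 1] <- r[3] * f[1]; Q[4, 2] <- r[5] * f[2]; Q[4, 3] <- r[6] * f[3]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q / mu
}

## Eigen-decomposition of Q exploiting reversibility (symmetrise with
## sqrt(pi)); returns a closure P(t) for transition probabilities.
model_P_fun <- function(model) {
  f <- model$base_freq
  Q <- model_Q(model)
  s <- sqrt(f)
  B <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / s) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(s)
  lam <- pmin(e$values, 0)   # guard numerical noise on the zero eigenvalue
  function(t) {
    P <- U %*% (exp(lam * t) * Uinv)
    P[P < 0] <- 0
    P
  }
}

## Mean rates of `n_cat` equal-probability discrete-gamma categories
## (mean-of-bin representatives, shape = rate so mean 1).
discrete_gamma_rates <- function(shape, n_cat) {
  q <- stats::qgamma(seq(0, 1, length.out = n_cat + 1), shape = shape,
                     rate = shape)
  p_up <- stats::pgamma(q[-1], shape = shape + 1, rate = shape)
  p_lo <- stats::pgamma(q[-(n_cat + 1)], shape = shape + 1, rate = shape)
  n_cat * (p_up - p_lo)
}

## Site-rate mixture of a model: category rates and probabilities.
## With +I the gamma rates are rescaled by 1/(1-p_inv) so the overall
## mean rate stays 1.
model_rate_mixture <- function(model) {
  if (is.null(model$gamma_shape)) {
    r <- 1; p <- 1
  } else {
    r <- discrete_gamma_rates(model$gamma_shape, model$n_cat)
    p <- rep(1 / model$n_cat, model$n_cat)
  }
  if (model$p_inv > 0) {
    r <- c(0, r / (1 - model$p_inv))
    p <- c(model$p_inv, p * (1 - model$p_inv))
  }
  list(rates = r, probs = p)
}

## number of free parameters of the substitution model (standard
## model-selection convention: frequencies count 3 when the family uses
## them, even when set empirically)
model_n_param <- function(model) {
  k <- switch(model$family, JC = 0, K80 = 1, HKY = 4, GTR = 8)
  if (model$p_inv > 0) k <- k + 1
  if (!is.null(model$gamma_shape)) k <- k + 1
  k
}
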