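## Constant-rate birth-death building blocks, parametrised by the net rate
## r = lambda - mu and the relative extinction eps = mu/lambda (so
## lambda = r/(1-eps)). All formulas are written on the log scale with
## log1p/expm1 so they stay finite for large r*t and accurate for small r*t.
##
## beta(t)  = (e^{rt}-1)/(e^{rt}-eps): success parameter of the geometric
##            distribution of standing richness conditional on survival
##            (Yule: beta = 1 - e^{-lambda t}).
## Ps(t)    = (1-eps)/(1-eps e^{-rt}): probability a lineage at age t
##            survives to the present.

log_beta <- function(t, r, eps) {
  log1p(-exp(-r * t)) - log1p(-eps * exp(-r * t))
}

log_one_minus_beta <- function(t, r, eps) {
  log1p(-eps) - r * t - log1p(-eps * exp(-r * t))
}

log_Ps <- function(t, r, eps) {
  log1p(-eps) - log1p(-eps * exp(-r * t))
}

## A(t1,t2): probability that a lineage observed (= having extant sampled
## descendants) at age t1 has exactly one observed descendant lineage at age
## t2 < t1. Equals [Ps(t1)/Ps(t2)] e^{-r(t1-t2)}; a probability, hence
## bounded, for every (r, eps) — this keeps partition likelihoods proper
## in the stepwise search even as eps approaches 1.
log_A <- function(t1, t2, r, eps) {
  log_Ps(t1, r, eps) - log_Ps(t2, r, eps) - r * (t1 - t2)
}

## Observed-split intensity lambda * Ps(x) = r / (1 - eps e^{-rx}): the rate
## at which an observed lineage at age x undergoes splits that leave both
## daughters observed. Finite as eps -> 1 for fixed r.
log_split_intensity <- function(x, r, eps) {
  log(r) - log1p(-eps * exp(-r * x))
}

#' Log-probability of clade richness under constant-rate birth-death
#'
#' Probability that a single lineage originating at stem age `t` has exactly
#' `S` extant descendant species, conditional on survival to the present:
#' a geometric law \eqn{P(S) = (1-\beta)\beta^{S-1}} with
#' \eqn{\beta = (e^{rt}-1)/(e^{rt}-\epsilon)} (Yule:
#' \eqn{\beta = 1 - e^{-\lambda t}}). This is the likelihood contribution of
#' a terminally unresolved tip clade with known richness.
#'
#' @param S Integer richness, `>= 1` (vectorised).
#' @param t Stem age in My, `> 0` (vectorised).
#' @param r Net diversification rate per My, `> 0`.
#' @param epsilon Relative extinction in `[0, 1)`.
#' @return Log-probability(ies).
#' @export
#' @examples
#' clade_richness_loglik(S = 1, t = 10, r = 0.1, epsilon = 0)  # -1
clade_richness_loglik <- function(S, t, r, epsilon = 0) {
  if (any(S < 1 | S != floor(S))) abort("S must be an integer >= 1")
  if (any(t <= 0)) abort("stem age t must be > 0")
  if (r <= 0) abort("net rate r must be > 0")
  if (epsilon < 0 || epsilon >= 1) abort("epsilon must be in [0, 1)")
  log_one_minus_beta(t, r, epsilon) + (S - 1) * log_beta(t, r, epsilon)
}

#' Log-likelihood of the resolved backbone of a dated tree
#'
#' Reconstructed-process likelihood of the internal (resolved) portion of an
#' ultrametric tree under a constant-rate birth-death model, conditioned on
#' the root (crown) age and on the survival of each observed lineage: every
#' internal branch spanning ages `t1 > t2` contributes the probability
#' \eqn{A(t_1,t_2) = [P_s(t_1)/P_s(t_2)]\,e^{-r(t_1-t_2)}} that an observed
#' lineage at `t1` has exactly one observed descendant lineage at `t2`, and
#' every internal node except the root contributes the observed-split
#' intensity \eqn{\lambda P_s(x) = r/(1-\epsilon e^{-rx})} at its age `x`
#' (\eqn{P_s(t) = (1-\epsilon)/(1-\epsilon e^{-rt})} is the probability a
#' lineage at age `t` survives to the present; for a pure-birth model these
#' reduce to \eqn{e^{-\lambda(t_1-t_2)}} and \eqn{\lambda}). Pendant
#' branches are excluded: a terminally unresolved tip's pendant span is
#' accounted for by [clade_richness_loglik()], so the full-tree
#' log-likelihood is the sum of the two parts.
#'
#' @param phy An ultrametric `phylo` object.
#' @param r Net diversification rate per My, `> 0`.
#' @param epsilon Relative extinction in `[0, 1)`.
#' @return Log-likelihood (scalar).
#' @export
backbone_loglik <- function(phy, r, epsilon = 0) {
  validate_dated_tree(phy)
  if (r <= 0) abort("net rate r must be > 0")
  if (epsilon < 0 || epsilon >= 1) abort("epsilon must be in [0, 1)")
  d <- bd_lik_data(phy, richness = NULL)
  int <- !d$is_tip
  sum(log_A(d$t1[int], d$t2[int], r, epsilon)) +
    sum(log_split_intensity(d$t2[int], r, epsilon))
}

## Per-node likelihood elements for a dated tree with unresolved tips.
## One element per non-root node v: the subtending branch of v, plus (if v
## is internal) the speciation factor at v. The root is conditioned on and
## contributes nothing. Arrays are indexed 1..n_elem parallel to `node`.
bd_lik_data <- function(phy, richness) {
  n_tip <- length(phy$tip.label)
  ages <- node_ages(phy)
  edge <- phy$edge
  node <- edge[, 2]
  t1 <- ages[edge[, 1]]
  t2 <- ages[node]
  is_tip <- node <= n_tip
  n <- rep(NA_integer_, length(node))
  if (!is.null(richness)) {
    if (is.data.frame(richness)) richness <- setNames(richness$S, richness$family)
    missing <- setdiff(phy$tip.label, names(richness))
    if (length(missing) > 0) {
      abort(paste0("No richness entry for: ", paste(missing, collapse = ", ")))
    }
    n[is_tip] <- pmax(1L, as.integer(round(richness[phy$tip.label[node[is_tip]]])))
  } else {
    n[is_tip] <- 1L
  }
  list(
    node = node, t1 = t1, t2 = t2, is_tip = is_tip, n = n,
    n_tip = n_tip, root = n_tip + 1L,
    n_obs = phy$Nnode + n_tip  # resolved internal nodes + unresolved tips
  )
}

## Log-likelihood of a set of elements (indices into the bd_lik_data arrays)
## under one (r, eps) model.
elements_loglik <- function(d, elems, r, eps) {
  if (length(elems) == 0) return(0)
  tip <- elems[d$is_tip[elems]]
  int <- elems[!d$is_tip[elems]]
  ll <- 0
  if (length(int) > 0) {
    ll <- sum(log_A(d$t1[int], d$t2[int], r, eps)) +
      sum(log_split_intensity(d$t2[int], r, eps))
  }
  if (length(tip) > 0) {
    st <- d$t1[tip]
    ll <- ll + sum(log_one_minus_beta(st, r, eps) +
                     (d$n[tip] - 1) * log_beta(st, r, eps))
  }
  ll
}

.r_lo <- 1e-7
.r_hi <- 20
.eps_max <- 1 - 1e-6

## Maximise elements_loglik over r (Yule: eps = 0), on the log-r scale.
fit_partition_yule <- function(d, elems) {
  f <- function(lr) elements_loglik(d, elems, exp(lr), 0)
  opt <- optimize(f, lower = log(.r_lo), upper = log(.r_hi),
                  maximum = TRUE, tol = 1e-9)
  r <- exp(opt$maximum)
  list(kind = "yule", r = r, epsilon = 0, logLik = opt$objective, k = 1,
       boundary = r <= .r_lo * 1.01 || r >= .r_hi * 0.99)
}

## Maximise over (r, eps) on (log r, logit eps) with grid multistart.
fit_partition_bd <- function(d, elems, start = NULL) {
  f <- function(par) {
    r <- exp(par[1])
    eps <- .eps_max * stats::plogis(par[2])
    -elements_loglik(d, elems, r, eps)
  }
  yu <- fit_partition_yule(d, elems)
  starts <- list(
    c(log(yu$r), stats::qlogis(0.05 / .eps_max)),
    c(log(yu$r), stats::qlogis(0.5 / .eps_max)),
    c(log(max(yu$r * 0.2, .r_lo * 2)), stats::qlogis(0.95 / .eps_max))
  )
  if (!is.null(start)) {
    starts <- c(list(c(log(max(start$r, .r_lo)),
                       stats::qlogis(min(max(start$epsilon, 1e-4), 0.999) / .eps_max))),
                starts)
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, f, method = "Nelder-Mead",
            control = list(reltol = 1e-12, maxit = 2000)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) abort("birth-death optimisation failed to converge")
  r <- exp(best$par[1])
  eps <- .eps_max * stats::plogis(best$par[2])
  list(kind = "bd", r = r, epsilon = eps, logLik = -best$value, k = 2,
       boundary = eps >= .eps_max - 1e-5 || r <= .r_lo * 1.01)
}

fit_partition <- function(d, elems, kinds = c("yule", "bd"), start = NULL) {
  fits <- list()
  if ("yule" %in% kinds) fits$yule <- fit_partition_yule(d, elems)
  if ("bd" %in% kinds) fits$bd <- fit_partition_bd(d, elems, start = start)
  fits
}

#' Combined backbone + richness log-likelihood of a tree with unresolved tips
#'
#' The full-data log-likelihood under one constant-rate model: the resolved
#' backbone ([backbone_loglik()]) plus one [clade_richness_loglik()] term
#' per terminally unresolved tip clade, evaluated at its stem age. This is
#' the objective maximised by [fit_constant_model()].
#'
#' @inheritParams backbone_loglik
#' @param richness Data frame (`family`, `S`) or named vector of per-tip
#'   richness (rounded to integer `>= 1`).
#' @return Log-likelihood (scalar).
#' @export
tree_richness_loglik <- function(phy, richness, r, epsilon = 0) {
  validate_dated_tree(phy)
  if (r <= 0) abort("net rate r must be > 0")
  if (epsilon < 0 || epsilon >= 1) abort("epsilon must be in [0, 1)")
  d <- bd_lik_data(phy, richness)
  elements_loglik(d, seq_along(d$node), r, epsilon)
}

#' Sample-size corrected Akaike information criterion
#'
#' \deqn{AICc = -2\,logLik + 2k + 2k(k+1)/(n_{obs}-k-1).}
#'
#' @param logLik Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param n_obs Number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-100, k = 2, n_obs = 10)  # 205.714...
aicc <- function(logLik, k, n_obs) {
  if (n_obs <= k + 1) abort("n_obs must exceed k + 1 for the AICc correction")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}
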