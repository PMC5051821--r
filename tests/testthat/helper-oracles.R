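## Independent oracles and small fixtures shared across test files.

toy_newick <- "((A:1,B:1):1,C:2);"

toy_tree <- function() read_dated_tree(toy_newick)

## Random bifurcating ultrametric tree with n tips (coalescent times),
## independent of the package's own simulators.
random_ultrametric <- function(n, seed = 1) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * 10
  tr
}

## Brute-force Benjamini-Hochberg step-up: for each i (in ascending p order)
## p_adj(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## Closed-form simple OLS via the normal equations.
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, R2 = r2)
}

## Clade table with disjoint taxon sets, ages and log-richness set directly.
flat_clade_table <- function(stem_age, ln_S) {
  n <- length(stem_age)
  tibble::tibble(
    clade_id = sprintf("c%03d", seq_len(n)),
    node = seq_len(n),
    n_tips = 1L,
    tip_families = as.list(sprintf("f%03d", seq_len(n))),
    stem_age = stem_age,
    crown_age = 0,
    S = exp(ln_S),
    ln_S = ln_S
  )
}
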