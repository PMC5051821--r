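test_that("clade richness log-probability matches the geometric closed form", {
  ## Yule, lambda = 0.1, t = 10, S = 1: P = 1 - beta = e^{-1}
  expect_equal(clade_richness_loglik(1, 10, 0.1, 0), -1, tolerance = 1e-12)
  ## general Yule closed form at arbitrary S
  lam <- 0.23; t <- 17; S <- 40
  beta <- 1 - exp(-lam * t)
  expect_equal(clade_richness_loglik(S, t, lam, 0),
               log(1 - beta) + (S - 1) * log(beta), tolerance = 1e-12)
  expect_error(clade_richness_loglik(0, 10, 0.1), "integer")
  expect_error(clade_richness_loglik(2, 10, -0.1), "r must be")
})

test_that("richness probabilities normalize to one over S", {
  set.seed(11)
  for (i in 1:20) {
    r <- runif(1, 0.01, 0.3)
    eps <- runif(1, 0, 0.95)
    t <- runif(1, 5, 60)
    beta <- exp(clade_richness_loglik(2, t, r, eps) -
                  clade_richness_loglik(1, t, r, eps))
    s_max <- ceiling(log(1e-12) / log(beta)) + 10
    total <- sum(exp(clade_richness_loglik(seq_len(s_max), t, r, eps)))
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("birth-death with zero extinction equals the pure-birth likelihood", {
  tr <- random_ultrametric(15, seed = 12)
  r <- 0.12
  ## independent Yule closed form for the backbone: each of the n_int - 1
  ## non-root nodes contributes log(lambda), each internal branch -lambda*len
  ages <- stem_crown_ages(tr)
  n_tip <- length(tr$tip.label)
  internal_edges <- tr$edge[, 2] > n_tip
  int_len <- sum(tr$edge.length[internal_edges])
  yule_backbone <- (tr$Nnode - 1) * log(r) - r * int_len
  expect_equal(backbone_loglik(tr, r, 0), yule_backbone, tolerance = 1e-10)

  S <- setNames(sample(1:30, n_tip, TRUE), tr$tip.label)
  for (eps in c(0, 1e-9)) {
    ll <- tree_richness_loglik(tr, S, r, eps)
    expect_equal(ll, tree_richness_loglik(tr, S, r, 0), tolerance = 1e-6)
  }
})

test_that("combined likelihood is the sum of backbone and richness parts", {
  fd <- simulate_family_dataset(25, r = 0.06, seed = 13)
  ages <- stem_crown_ages(fd$tree)
  n_tip <- length(fd$tree$tip.label)
  S <- pmax(1, round(fd$richness$S))
  for (pars in list(c(0.05, 0), c(0.08, 0.4), c(0.02, 0.9))) {
    combined <- tree_richness_loglik(fd$tree, fd$richness, pars[1], pars[2])
    parts <- backbone_loglik(fd$tree, pars[1], pars[2]) +
      sum(clade_richness_loglik(S, ages$stem_age[seq_len(n_tip)],
                                pars[1], pars[2]))
    expect_equal(combined, parts, tolerance = 1e-10)
  }
})

test_that("the likelihood is locally maximal at the fitted rate", {
  fd <- simulate_family_dataset(30, r = 0.08, seed = 14)
  fit <- fit_constant_model(fd$tree, fd$richness, "yule")
  r_hat <- fit$params$r
  ll <- function(r) tree_richness_loglik(fd$tree, fd$richness, r, 0)
  expect_lt(ll(r_hat * 1.05), fit$logLik)
  expect_lt(ll(r_hat * 0.95), fit$logLik)
})

test_that("fitted MLEs match brute-force grid maximization on a small tree", {
  tr <- read_dated_tree("(((A:8,B:8):12,(C:15,D:15):5):10,E:30);")
  S <- c(A = 4, B = 1, C = 12, D = 2, E = 7)
  ## Yule: two-stage grid over the rate
  fit <- fit_constant_model(tr, S, "yule")
  grid1 <- exp(seq(log(1e-4), log(5), length.out = 2000))
  ll1 <- vapply(grid1, function(r) tree_richness_loglik(tr, S, r, 0), numeric(1))
  r0 <- grid1[which.max(ll1)]
  grid2 <- seq(r0 * 0.8, r0 * 1.2, length.out = 4000)
  ll2 <- vapply(grid2, function(r) tree_richness_loglik(tr, S, r, 0), numeric(1))
  r_grid <- grid2[which.max(ll2)]
  expect_equal(fit$params$r, r_grid, tolerance = 1e-4)

  ## birth-death: optimiser must at least attain the grid maximum
  fit_bd <- fit_constant_model(tr, S, "bd")
  grid_r <- exp(seq(log(1e-3), log(1), length.out = 120))
  grid_e <- seq(0, 0.99, length.out = 80)
  ll_bd <- outer(grid_r, grid_e,
                 Vectorize(function(r, e) tree_richness_loglik(tr, S, r, e)))
  expect_gte(fit_bd$logLik, max(ll_bd) - 1e-4)
})

test_that("the Yule MLE on a fully resolved tree matches ape::yule", {
  tr <- random_ultrametric(30, seed = 15)
  fit <- fit_constant_model(tr, setNames(rep(1, 30), tr$tip.label), "yule")
  expect_equal(fit$params$r, ape::yule(tr)$lambda, tolerance = 1e-6)
})

test_that("AICc follows its definition and rejects tiny samples", {
  expect_equal(aicc(-100, 2, 10), 205.714286, tolerance = 1e-6)
  expect_equal(aicc(-50, 0, 10), 100)
  expect_error(aicc(-10, 4, 5), "n_obs")
  set.seed(16)
  for (i in 1:20) {
    ll <- -runif(1, 10, 500); k <- sample(1:5, 1); n <- k + 1 + sample(1:50, 1)
    expect_gte(aicc(ll, k, n), -2 * ll + 2 * k)
  }
})
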