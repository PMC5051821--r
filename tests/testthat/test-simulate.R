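test_that("birth-death simulation honours the stopping rule and seed", {
  s <- simulate_bd_tree(lambda = 0.1, mu = 0.03, n_tips = 40, seed = 21)
  expect_equal(s$n_extant, 40)
  expect_equal(length(s$reconstructed$tip.label), 40)
  expect_equal(s$reconstructed$Nnode, 39)
  expect_true(ape::is.ultrametric(s$reconstructed, tol = 1e-6))
  expect_silent(validate_dated_tree(s$reconstructed))

  s2 <- simulate_bd_tree(lambda = 0.1, mu = 0.03, n_tips = 40, seed = 21)
  expect_identical(ape::write.tree(s$reconstructed),
                   ape::write.tree(s2$reconstructed))
  expect_error(simulate_bd_tree(lambda = 0.1, mu = 0.2, n_tips = 10),
               "lambda > mu")
  expect_error(simulate_bd_tree(lambda = 0.1, n_tips = 10, max_age = 5),
               "exactly one")
})

test_that("fixed-age pure-birth tip counts match the closed-form mean", {
  lambda <- 0.05
  T_age <- 40
  counts <- vapply(1:300, function(s) {
    simulate_bd_tree(lambda = lambda, n_tips = NULL, max_age = T_age,
                     seed = 2000 + s)$n_extant
  }, numeric(1))
  ## from one origin lineage E[N] = e^{lambda T}
  expected <- exp(lambda * T_age)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3.5 * se + 1e-9)
})

test_that("planted shifts honour size constraints and nesting precedence", {
  ## empty shift list reduces to the plain simulator
  a <- plant_shifts(0.08, n_tips = 20, seed = 22)
  b <- simulate_bd_tree(0.08, n_tips = 20, seed = 22)
  expect_identical(ape::write.tree(a$reconstructed),
                   ape::write.tree(b$reconstructed))

  ps <- plant_shifts(
    0.05,
    shifts = list(shift_spec(at_n_alive = 8, multiplier = 5,
                             min_clade_tips = 20)),
    n_tips = 64, seed = 7
  )
  expect_gte(length(ps$shift_tips[[1]]), 20)
  expect_false(is.na(ps$shift_node))
  ## shifted tips are monophyletic in the reconstructed tree
  desc <- ape::extract.clade(ps$reconstructed, ps$shift_node)$tip.label
  expect_setequal(desc, ps$shift_tips[[1]])

  ## nested shifts: the innermost class governs doubly-shifted tips
  ps2 <- plant_shifts(
    0.06,
    shifts = list(shift_spec(at_n_alive = 4, multiplier = 2,
                             min_clade_tips = 12),
                  shift_spec(at_n_alive = 16, multiplier = 2)),
    n_tips = 48, seed = 30
  )
  both <- intersect(ps2$shift_tips[[1]], ps2$shift_tips[[2]])
  if (length(both) > 0) {
    rec <- attr(ps2$complete, "tip_record")
    pend <- match(match(both, ps2$complete$tip.label), ps2$complete$edge[, 2])
    expect_true(all(ps2$edge_class[pend] == 3))
  }
})

test_that("collapsing to families preserves richness and stem ages", {
  s <- simulate_bd_tree(lambda = 0.12, n_tips = 80, seed = 23)
  phy <- s$reconstructed
  cut <- tree_height(phy) * 0.4
  fam <- collapse_to_families(phy, cutoff = cut)
  expect_equal(sum(fam$richness$S), 80)
  expect_true(ape::is.ultrametric(fam$tree, tol = 1e-6))
  ## no family-tree node younger than the cutoff
  ages <- node_ages <- stem_crown_ages(fam$tree)
  internal <- ages$crown_age[-seq_along(fam$tree$tip.label)]
  expect_true(all(internal > cut))

  ## cutoff below every split: each species its own family
  tiny <- collapse_to_families(phy, cutoff = 1e-9)
  expect_equal(nrow(tiny$richness), 80)
  expect_true(all(tiny$richness$S == 1))

  expect_error(collapse_to_families(phy, cutoff = tree_height(phy) + 1),
               "root")
})

test_that("taxonomic count simulation matches its degenerate cases", {
  full <- simulate_taxonomic_counts(c(50L, 200L), eval_fraction = 1, seed = 24)
  expect_true(all(full$S_U == 0))
  expect_equal(corrected_richness(full)$S, full$S_true)

  nosyn <- simulate_taxonomic_counts(c(50L, 200L), synonym_rate = 0,
                                     eval_fraction = 0.3, seed = 25)
  expect_true(all(nosyn$S_R == 0))
  expect_equal(nosyn$S_A + nosyn$S_U, nosyn$S_true)

  expect_error(simulate_taxonomic_counts(10L, synonym_rate = -1), "synonym")
  expect_error(simulate_taxonomic_counts(10L, eval_fraction = 2), "eval")
})

test_that("the paperlike clade table has the intended structure", {
  cl <- simulate_clade_table(n_families = 100, seed = 26)
  expect_equal(nrow(cl), 199)
  expect_true(all(cl$S >= 1))
  ## family-level structure: no internal node younger than the floor
  expect_true(all(cl$stem_age >= 25 - 1e-9))
  expect_equal(max(cl$crown_age), 330, tolerance = 1e-6)

  shuffled <- simulate_clade_table(n_families = 100, seed = 26,
                                   shuffle_richness = TRUE)
  expect_setequal(shuffled$S, cl$S)
  expect_identical(shuffled$stem_age, cl$stem_age)
})

test_that("the full generator-to-estimator chain recovers the net rate", {
  lambda <- 0.09
  r_hats <- unlist(lapply(1:6, function(i) {
    s <- simulate_bd_tree(lambda = lambda, max_age = 70, seed = 400 + i)
    if (is.null(s$reconstructed) || length(s$reconstructed$tip.label) < 10) {
      return(NULL)
    }
    fam <- collapse_to_families(s$reconstructed, cutoff = 25)
    cnt <- simulate_taxonomic_counts(as.integer(fam$richness$S),
                                     synonym_rate = 0.5, eval_fraction = 0.6,
                                     seed = 500 + i)
    cnt$family <- fam$richness$family
    ## families with no evaluated names get direct published-style estimates,
    ## as the richness workflow prescribes
    bad <- cnt$S_A + cnt$S_R == 0
    tot <- total_richness(
      cnt[!bad, ],
      if (any(bad)) data.frame(family = cnt$family[bad],
                               S_direct = cnt$S_true[bad]) else NULL
    )
    cl <- enumerate_clades(fam$tree,
                           dplyr::mutate(tot$families, S = pmax(S, 1)))
    tips <- cl[cl$n_tips == 1, ]
    net_div_rate(pmax(tips$S, 1), tips$stem_age, 0)
  }))
  ## downward bias of order gamma/t is expected at these stem ages
  expect_equal(mean(r_hats), lambda, tolerance = 0.35)
  expect_gt(mean(r_hats), 0.04)
})
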