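test_that("Newick parsing validates the dated-tree invariants", {
  tr <- toy_tree()
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tree_height(tr), 2)

  expect_error(read_dated_tree("((A:1,B:1):1,C:2)"), "';'")
  expect_error(read_dated_tree("(A:1,B:2);"), "ultrametric")
  expect_error(read_dated_tree("((A:1,A:1):1,C:2);"), "Duplicate")
  expect_error(read_dated_tree("((A,B),C);"), "branch length")
})

test_that("small dating jitter warns instead of aborting", {
  expect_warning(read_dated_tree("((A:1,B:1.0005):1,C:2.0005);"),
                 "ultrametricity")
  expect_silent(read_dated_tree("((A:1,B:1.0000000001):1,C:2.0000000001);"))
})

test_that("stem and crown ages follow the stated conventions", {
  ages <- stem_crown_ages(toy_tree())
  ## tips A, B, C are nodes 1:3; root is 4; {A,B} ancestor is 5
  expect_equal(ages$crown_age[1:3], c(0, 0, 0))
  expect_equal(ages$stem_age[1:3], c(1, 1, 2))
  expect_equal(ages$crown_age[5], 1)
  expect_equal(ages$stem_age[5], 2)
  ## root convention: stem age equals crown age
  expect_equal(ages$stem_age[4], 2)
  expect_equal(ages$crown_age[4], 2)
})

test_that("clade enumeration sums richness and counts 2n-1 clades", {
  cl <- enumerate_clades(toy_tree(), c(A = 2, B = 3, C = 1))
  expect_equal(nrow(cl), 5)
  ab <- cl[cl$clade_id == "A_2", ]
  expect_equal(ab$S, 5)
  expect_equal(ab$ln_S, log(5))
  expect_equal(ab$stem_age, 2)
  expect_equal(ab$crown_age, 1)
  root <- cl[cl$n_tips == 3, ]
  expect_equal(root$S, 6)

  expect_error(enumerate_clades(toy_tree(), c(A = 2, B = 3)), "richness")
})

test_that("enumeration invariants hold on random bifurcating trees", {
  for (seed in 1:3) {
    n <- c(50, 120, 425)[seed]
    tr <- random_ultrametric(n, seed)
    rich <- setNames(sample(1:50, n, replace = TRUE), tr$tip.label)
    cl <- enumerate_clades(tr, rich)
    expect_equal(nrow(cl), 2 * n - 1)
    expect_equal(unique(cl$clade_id), cl$clade_id)
    ## richness conservation at the root
    expect_equal(max(cl$S), sum(rich))
    ## stem age non-increasing along every root-to-tip path:
    ## every child's stem age (= parent crown) <= parent's stem age
    ages <- cl$stem_age[order(cl$node)]
    crowns <- cl$crown_age[order(cl$node)]
    for (e in seq_len(nrow(tr$edge))) {
      expect_lte(ages[tr$edge[e, 2]], ages[tr$edge[e, 1]] + 1e-9)
    }
    expect_true(all(ages >= crowns))
  }
})

test_that("write/read round-trip preserves topology, labels and lengths", {
  tr <- random_ultrametric(40, seed = 7)
  txt <- ape::write.tree(tr)
  tr2 <- read_dated_tree(txt)
  expect_setequal(tr$tip.label, tr2$tip.label)
  d1 <- ape::cophenetic.phylo(tr)
  d2 <- ape::cophenetic.phylo(tr2)[rownames(d1), colnames(d1)]
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("clade table export writes the scalar columns", {
  cl <- enumerate_clades(toy_tree(), c(A = 2, B = 3, C = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clade_table(cl, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 5)
  expect_named(back, c("clade_id", "n_tips", "S", "ln_S",
                       "stem_age", "crown_age"))
})
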