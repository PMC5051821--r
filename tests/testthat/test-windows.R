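test_that("clades are binned into half-open windows with age limits", {
  cl <- flat_clade_table(c(26.9, 105, 30, 19.9, 99.9), rep(1, 5))
  w <- assign_windows(cl)
  expect_equal(nrow(w), 3)
  expect_equal(w$window[w$stem_age == 26.9], "20-30")
  expect_equal(w$window[w$stem_age == 30], "30-40")
  expect_equal(w$window[w$stem_age == 99.9], "90-100")
  ## ages < 20 and >= 100 are excluded
  expect_false(any(w$stem_age %in% c(105, 19.9)))
})

test_that("nested-clade pruning keeps exactly one member per overlap", {
  cl <- tibble::tibble(
    clade_id = c("A", "B", "D"),
    stem_age = c(25, 22, 24),
    tip_families = list(c("x", "y", "z"), c("x", "y"), c("u", "v"))
  )
  expect_setequal(prune_nested(cl, "older")$clade_id, c("A", "D"))
  expect_setequal(prune_nested(cl, "younger")$clade_id, c("B", "D"))

  ## three-deep chain: keep=older retains the oldest, keep=younger the youngest
  chain <- tibble::tibble(
    clade_id = c("A", "B", "C"),
    stem_age = c(30, 25, 21),
    tip_families = list(c("x", "y", "z"), c("x", "y"), "x")
  )
  expect_equal(prune_nested(chain, "older")$clade_id, "A")
  expect_equal(prune_nested(chain, "younger")$clade_id, "C")
})

test_that("pruned output never contains an overlapping pair", {
  tr <- random_ultrametric(60, seed = 3)
  cl <- enumerate_clades(tr, setNames(sample(1:20, 60, TRUE), tr$tip.label))
  for (keep in c("older", "younger")) {
    kept <- prune_nested(cl, keep)
    sets <- kept$tip_families
    for (i in seq_along(sets)) {
      for (j in seq_len(i - 1)) {
        expect_length(intersect(sets[[i]], sets[[j]]), 0)
      }
    }
  }
})

test_that("window fits agree with the normal-equations closed form", {
  set.seed(4)
  cl <- flat_clade_table(runif(48, 20, 30), rnorm(48, 3, 1))
  fit <- fit_window(cl)
  oracle <- ols_closed_form(cl$stem_age, cl$ln_S)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$R2, oracle$R2, tolerance = 1e-10)
  expect_equal(fit$n, 48)

  ## exact linear data
  ages <- seq(21, 29, length.out = 10)
  exact <- fit_window(flat_clade_table(ages, 1 + 0.1 * ages))
  expect_equal(exact$slope, 0.1, tolerance = 1e-12)
  expect_equal(exact$R2, 1, tolerance = 1e-12)

  ## constant response
  flat <- fit_window(flat_clade_table(ages, rep(2, 10)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$R2, 0)

  ## unfit cases
  expect_false(fit_window(flat_clade_table(c(21, 22), c(1, 2)))$fit_ok)
  expect_false(fit_window(flat_clade_table(rep(25, 5), rnorm(5)))$fit_ok)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.05)), c(0.01, 0.05))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:100) {
    p <- runif(sample(1:10, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    ## monotone in raw p order
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("window analysis runs both variants with a joint BH family", {
  set.seed(6)
  tr <- random_ultrametric(200, seed = 6)
  tr$edge.length <- tr$edge.length * 120 / tree_height(tr)
  cl <- enumerate_clades(tr, setNames(pmax(1, round(exp(rnorm(200, 3, 2)))),
                                      tr$tip.label))
  w <- window_analysis(cl)
  expect_s3_class(w, "window_analysis")
  expect_equal(nrow(w), 16)
  expect_setequal(unique(w$variant), c("younger-removed", "older-removed"))
  ok <- w$fit_ok & !is.na(w$p)
  expect_true(all(w$p_adj[ok] >= w$p[ok] - 1e-12))
  expect_equal(w$p_adj, bh_adjust(w$p))
  g <- glance(w)
  expect_equal(g$n_windows, 16)
})

test_that("a strong built-in slope is recovered in every window", {
  set.seed(7)
  ages <- runif(400, 20, 100)
  cl <- flat_clade_table(ages, pmax(0, 1 + 0.08 * ages + rnorm(400, 0, 0.2)))
  w <- window_analysis(cl)
  fit <- w[w$fit_ok, ]
  expect_true(all(abs(fit$slope - 0.08) < 0.05))
  expect_true(all(fit$p_adj[!is.na(fit$p_adj)] < 0.05))
})
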