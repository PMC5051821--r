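#' Assign clades to adjacent age windows
#'
#' Clades are binned by stem age into adjacent half-open windows
#' `[lo, lo + width)`. Clades younger than `min_age` or with stem age
#' `>= max_age` are excluded: very old clades sit in a node-poor, highly
#' nested part of the tree, and the youngest windows are dominated by single
#' families.
#'
#' @param clades A clade table (needs `clade_id`, `stem_age`).
#' @param width Window width in My (default 10).
#' @param min_age,max_age Analysis age range in My (defaults 20 and 100).
#' @return The included rows with added columns `window_lo`, `window_hi`,
#'   `window` (label `"lo-hi"`).
#' @export
assign_windows <- function(clades, width = 10, min_age = 20, max_age = 100) {
  stopifnot(width > 0, min_age < max_age)
  clades |>
    tibble::as_tibble() |>
    dplyr::filter(.data$stem_age >= min_age, .data$stem_age < max_age) |>
    dplyr::mutate(
      window_lo = width * floor(.data$stem_age / width),
      window_hi = .data$window_lo + width,
      window = paste0(.data$window_lo, "-", .data$window_hi)
    )
}

#' Remove nested clades from a clade set
#'
#' Clades on a tree have either disjoint or nested (ancestor-descendant)
#' taxon sets; nested pairs are statistically non-independent in age-richness
#' regressions. This drops one member of every overlapping pair, keeping
#' either the older or the younger clade. Processing is deterministic: clades
#' are scanned in descending stem age (ties by `clade_id`) when keeping the
#' older member, ascending when keeping the younger, and a clade is kept iff
#' its taxon set does not overlap any already-kept clade. On nested-or-
#' disjoint set systems this greedy scan matches the iterative rule "while
#' any ancestor-descendant pair co-occurs, drop the younger/older member".
#'
#' @param clades A clade table with `tip_families` list column, `stem_age`,
#'   `clade_id`.
#' @param keep `"older"` or `"younger"`.
#' @return The retained subset, no two rows of which overlap.
#' @export
prune_nested <- function(clades, keep = c("older", "younger")) {
  keep <- match.arg(keep)
  stopifnot("tip_families" %in% names(clades))
  cl <- tibble::as_tibble(clades)
  ord <- if (keep == "older") {
    order(-cl$stem_age, cl$clade_id)
  } else {
    order(cl$stem_age, cl$clade_id)
  }
  cl <- cl[ord, ]
  kept_tips <- character(0)
  kept <- logical(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    tips <- cl$tip_families[[i]]
    if (!any(tips %in% kept_tips)) {
      kept[i] <- TRUE
      kept_tips <- c(kept_tips, tips)
    }
  }
  cl[kept, ]
}

#' Fit the log-richness ~ age regression within one window
#'
#' Ordinary least squares of `ln_S` on `stem_age`. The fit is flagged unfit
#' (all statistics `NA`) when fewer than 3 clades are available or the ages
#' have zero variance.
#'
#' @param clades Clade subset (needs `ln_S`, `stem_age`).
#' @return One-row tibble: `mean_clade_age`, `slope`, `p`, `R2`, `n`, `fit_ok`.
#' @export
fit_window <- function(clades) {
  n <- nrow(clades)
  if (n < 3 || isTRUE(all.equal(var(clades$stem_age), 0)) ||
      var(clades$stem_age) == 0) {
    return(tibble::tibble(
      mean_clade_age = if (n > 0) mean(clades$stem_age) else NA_real_,
      slope = NA_real_, p = NA_real_, R2 = NA_real_, n = n, fit_ok = FALSE
    ))
  }
  fit <- lm(ln_S ~ stem_age, data = clades)
  sm <- suppressWarnings(summary(fit))  # exact-linear data warn harmlessly
  slope <- unname(coef(fit)[2])
  if (var(clades$ln_S) == 0) {
    ## constant response: no fit to speak of; slope 0, R2 0, p undefined
    return(tibble::tibble(
      mean_clade_age = mean(clades$stem_age),
      slope = 0, p = NA_real_, R2 = 0, n = n, fit_ok = TRUE
    ))
  }
  p <- sm$coefficients["stem_age", "Pr(>|t|)"]
  tibble::tibble(
    mean_clade_age = mean(clades$stem_age),
    slope = slope, p = p, R2 = sm$r.squared, n = n, fit_ok = TRUE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment: with m p-values sorted
#' ascending, `p_adj(i) = min over j >= i of m p(j)/j`, capped at 1 and
#' mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed, passed
#'   through).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Age-window regression analysis of the time-for-speciation prediction
#'
#' If clade richness is primarily a function of time available for
#' speciation, log richness should increase with stem age among clades of
#' comparable depth. This runs, for each adjacent age window, the OLS of
#' `ln_S` on stem age after removing nested clades — once keeping the older
#' member of each nested pair ("younger-removed") and once keeping the
#' younger ("older-removed") — and adjusts the slope p-values jointly across
#' all window x variant tests with the Benjamini-Hochberg correction.
#'
#' @inheritParams assign_windows
#' @return A tibble of class `window_analysis`: one row per window x variant
#'   with `variant`, `window`, `window_lo`, `window_hi`, `mean_clade_age`,
#'   `slope`, `p`, `p_adj`, `R2`, `n`, `fit_ok`. Unfit windows carry `NA`
#'   statistics and are excluded from the BH family.
#' @export
window_analysis <- function(clades, width = 10, min_age = 20, max_age = 100) {
  windowed <- assign_windows(clades, width = width, min_age = min_age,
                             max_age = max_age)
  los <- seq(min_age, max_age - width, by = width)
  variants <- c("younger-removed", "older-removed")
  res <- purrr::map_dfr(variants, function(v) {
    keep <- if (v == "younger-removed") "older" else "younger"
    purrr::map_dfr(los, function(lo) {
      sub <- dplyr::filter(windowed, .data$window_lo == lo)
      pruned <- if (nrow(sub) > 0) prune_nested(sub, keep = keep) else sub
      dplyr::bind_cols(
        tibble::tibble(variant = v, window = paste0(lo, "-", lo + width),
                       window_lo = lo, window_hi = lo + width),
        fit_window(pruned)
      )
    })
  })
  res$p_adj <- bh_adjust(res$p)
  res <- dplyr::relocate(res, "p_adj", .after = "p")
  class(res) <- c("window_analysis", class(res))
  res
}

#' @export
print.window_analysis <- function(x, ...) {
  cat("Age-window regressions of ln(S) on stem age\n")
  NextMethod()
  invisible(x)
}

#' @rdname window_analysis
#' @param x A `window_analysis` tibble.
#' @param ... Unused.
#' @method tidy window_analysis
#' @export
tidy.window_analysis <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "window_analysis")
  out
}

#' @rdname window_analysis
#' @method glance window_analysis
#' @export
glance.window_analysis <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    n_fit = sum(x$fit_ok),
    n_signif_05 = sum(x$p_adj < 0.05, na.rm = TRUE),
    min_p_adj = suppressWarnings(min(x$p_adj, na.rm = TRUE))
  )
}

#' Plot age-window regression slopes
#'
#' Slope against window midpoint per pruning variant; windows significant
#' after BH adjustment (p_adj < 0.05) are filled.
#'
#' @param x A `window_analysis` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_analysis
#' @export
autoplot.window_analysis <- function(x, ...) {
  dat <- dplyr::filter(tibble::as_tibble(x), .data$fit_ok)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = (.data$window_lo + .data$window_hi) / 2,
    y = .data$slope, shape = .data$variant
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$p_adj < 0.05), size = 3) +
    ggplot2::scale_shape_manual(values = c(21, 24)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               name = "BH p < 0.05") +
    ggplot2::labs(x = "Window midpoint (My)",
                  y = "Slope of ln(S) ~ stem age (per My)") +
    ggplot2::theme_minimal()
}
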