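#' Regression of log richness on net diversification rate
#'
#' OLS of `ln_S` on `r` over all clades at one extinction regime. Because
#' the stem-age rate estimator is itself a function of richness, this
#' correlation is expected to be strong even without any biological signal;
#' see [randomization_null()].
#'
#' @param rates A tibble from [rate_table()] filtered to (or containing)
#'   a single epsilon value; if several are present, supply `epsilon`.
#' @param epsilon Which regime to use when `rates` holds more than one.
#' @return A one-row tibble: `epsilon`, `slope`, `p`, `R2`, `n`.
#' @export
rate_richness_fit <- function(rates, epsilon = NULL) {
  eps <- unique(rates$epsilon)
  if (!is.null(epsilon)) {
    rates <- dplyr::filter(rates, .data$epsilon == !!epsilon)
  } else if (length(eps) > 1) {
    abort("rates contains several epsilon regimes; supply `epsilon`")
  }
  if (nrow(rates) < 3) abort("at least 3 clades are required")
  if (var(rates$r) == 0) abort("zero variance in r; regression undefined")
  fit <- lm(ln_S ~ r, data = rates)
  sm <- suppressWarnings(summary(fit))
  tibble::tibble(
    epsilon = rates$epsilon[1],
    slope = unname(coef(fit)[2]),
    p = sm$coefficients["r", "Pr(>|t|)"],
    R2 = sm$r.squared,
    n = nrow(rates)
  )
}

#' Randomization null for the rate-richness correlation
#'
#' The net diversification rate is computed from richness, so regressing
#' ln(S) on r reuses the response in the predictor. This null makes that
#' point explicit: per replicate, the richness values are permuted across
#' clades (stem ages fixed), rates are recomputed from the permuted richness
#' with the same estimator, and the ln(S) ~ r regression is refit. A high
#' permuted R-squared shows the observed correlation is expected by
#' construction.
#'
#' @param clades A clade table (needs `clade_id`, `stem_age`, `S`).
#' @param epsilon Relative extinction used for the rate estimator.
#' @param n_reps Number of permutation replicates (default 1000).
#' @param seed Integer seed; the replicate stream is fully reproducible.
#' @param permute `"richness"` (default) permutes S against fixed ages;
#'   `"age"` permutes ages instead — identical in distribution.
#' @return An object of class `randomization_null`: list with `observed`
#'   (one-row tibble from [rate_richness_fit()]), `permuted_R2` (length
#'   `n_reps`), `mean_permuted_R2`, `n_reps`, `epsilon`, `seed`.
#' @export
randomization_null <- function(clades, epsilon = 0, n_reps = 1000,
                               seed = 1L, permute = c("richness", "age")) {
  permute <- match.arg(permute)
  if (n_reps < 1) abort("n_reps must be >= 1")
  S <- clades$S
  t <- clades$stem_age
  obs <- rate_richness_fit(rate_table(clades, epsilons = epsilon))
  r2_of <- function(S, t) {
    r <- net_div_rate(S, t, epsilon)
    if (var(r) == 0) return(NA_real_)
    dat <- data.frame(ln_S = log(S), r = r)
    summary(lm(ln_S ~ r, data = dat))$r.squared
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  perm_r2 <- vapply(seq_len(n_reps), function(i) {
    idx <- sample.int(length(S))
    if (permute == "richness") r2_of(S[idx], t) else r2_of(S, t[idx])
  }, numeric(1))
  structure(
    list(
      observed = obs,
      permuted_R2 = perm_r2,
      mean_permuted_R2 = mean(perm_r2, na.rm = TRUE),
      n_reps = n_reps,
      epsilon = epsilon,
      seed = seed
    ),
    class = "randomization_null"
  )
}

#' @export
print.randomization_null <- function(x, ...) {
  cat("Randomization null for the ln(S) ~ r correlation\n")
  cat(sprintf("  observed R2:       %.3f (epsilon = %g, n = %d clades)\n",
              x$observed$R2, x$epsilon, x$observed$n))
  cat(sprintf("  mean permuted R2:  %.3f over %d replicates (seed %d)\n",
              x$mean_permuted_R2, x$n_reps, x$seed))
  invisible(x)
}

#' @rdname randomization_null
#' @param x A `randomization_null` object.
#' @param ... Unused.
#' @method tidy randomization_null
#' @export
tidy.randomization_null <- function(x, ...) {
  tibble::tibble(replicate = seq_len(x$n_reps), R2 = x$permuted_R2)
}

#' @rdname randomization_null
#' @method glance randomization_null
#' @export
glance.randomization_null <- function(x, ...) {
  tibble::tibble(
    observed_R2 = x$observed$R2,
    mean_permuted_R2 = x$mean_permuted_R2,
    sd_permuted_R2 = stats::sd(x$permuted_R2, na.rm = TRUE),
    n_reps = x$n_reps,
    epsilon = x$epsilon,
    seed = x$seed
  )
}

#' Plot the permuted R-squared distribution
#'
#' Histogram of permuted R-squared values with the observed value marked.
#'
#' @param x A `randomization_null` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot randomization_null
#' @export
autoplot.randomization_null <- function(x, ...) {
  ggplot2::ggplot(tidy(x), ggplot2::aes(x = .data$R2)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = x$observed$R2, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = expression(R^2~"of ln(S) ~ r under permutation"),
                  y = "Replicates") +
    ggplot2::theme_minimal()
}

#' Scatter plot of log richness against diversification rate
#'
#' @param rates A tibble from [rate_table()] at one epsilon.
#' @return A ggplot object with the fitted OLS line.
#' @export
plot_rate_richness <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$r, y = .data$ln_S)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "Net diversification rate r (per My)", y = "ln(S)") +
    ggplot2::theme_minimal()
}
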