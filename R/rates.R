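#' Stem-age net diversification rate under bounded relative extinction
#'
#' The Magallon-Sanderson stem-age estimator of the net diversification rate
#' \eqn{r = \lambda - \mu} for a clade of standing richness S and stem age t,
#' at relative extinction \eqn{\epsilon = \mu/\lambda}:
#' \deqn{\hat r = \log[S(1-\epsilon)+\epsilon] / t,}
#' with the natural logarithm. \eqn{\epsilon = 0} (no extinction) and
#' \eqn{\epsilon = 0.9} bracket plausible upper and lower bounds on the rate.
#' Monotypic clades (S = 1) have rate 0 under every regime.
#'
#' @param S Species richness, `>= 1` (vectorised).
#' @param t Stem age in My, `> 0` (vectorised).
#' @param epsilon Relative extinction rate in `[0, 1)`.
#' @return Net diversification rate(s), per My.
#' @export
#' @examples
#' net_div_rate(S = 148.413, t = 50, epsilon = 0)    # ~0.1
#' net_div_rate(S = 1, t = 37.2, epsilon = 0.9)      # exactly 0
net_div_rate <- function(S, t, epsilon = 0) {
  if (any(S < 1)) abort("Richness S must be >= 1")
  if (any(t <= 0)) abort("Stem age t must be > 0")
  if (any(epsilon < 0 | epsilon >= 1)) abort("epsilon must be in [0, 1)")
  log(S * (1 - epsilon) + epsilon) / t
}

#' Per-clade rate table across extinction regimes
#'
#' Evaluates the stem-age estimator for every clade at each requested
#' relative-extinction value, in long format (one row per clade x epsilon).
#'
#' @param clades A clade table from [enumerate_clades()] (columns `clade_id`,
#'   `stem_age`, `S`, `ln_S`).
#' @param epsilons Relative extinction rates; default `c(0, 0.9)`, the
#'   conventional lower/upper bracket.
#' @return A tibble `clade_id`, `stem_age`, `S`, `ln_S`, `epsilon`, `r`.
#' @export
rate_table <- function(clades, epsilons = c(0, 0.9)) {
  stopifnot(all(c("clade_id", "stem_age", "S") %in% names(clades)))
  bad <- clades$stem_age <= 0
  if (any(bad)) {
    abort(paste0("Non-positive stem age for clade(s): ",
                 paste(clades$clade_id[bad], collapse = ", ")))
  }
  bad <- clades$S < 1
  if (any(bad)) {
    abort(paste0("Richness < 1 for clade(s): ",
                 paste(clades$clade_id[bad], collapse = ", ")))
  }
  base <- dplyr::select(tibble::as_tibble(clades),
                        "clade_id", "stem_age", "S", "ln_S")
  tidyr::crossing(base, epsilon = epsilons) |>
    dplyr::mutate(r = net_div_rate(.data$S, .data$stem_age, .data$epsilon)) |>
    dplyr::arrange(.data$epsilon, .data$clade_id)
}

#' Summaries of a rate table
#'
#' Min/max/mean of the net diversification rate per extinction regime, and
#' of log richness over clades.
#'
#' @param rates A tibble from [rate_table()].
#' @return A list with `rates` (tibble `epsilon`, `min`, `max`, `mean`) and
#'   `ln_S` (tibble `min`, `max`, `mean`).
#' @export
summarize_rates <- function(rates) {
  per_eps <- rates |>
    dplyr::group_by(.data$epsilon) |>
    dplyr::summarise(
      min = min(.data$r), max = max(.data$r), mean = mean(.data$r),
      .groups = "drop"
    )
  one <- dplyr::filter(rates, .data$epsilon == rates$epsilon[1])
  list(
    rates = per_eps,
    ln_S = tibble::tibble(min = min(one$ln_S), max = max(one$ln_S),
                          mean = mean(one$ln_S))
  )
}

#' Overlap of top-ranked clades between two extinction regimes
#'
#' How many of the k fastest-diversifying clades under one extinction regime
#' are also among the k fastest under the other. Ties in rate are broken by
#' `clade_id` so the ranking is deterministic.
#'
#' @param rates A tibble from [rate_table()] containing exactly two epsilon
#'   values.
#' @param k Number of top clades to compare (default 10).
#' @return Integer: size of the intersection of the two top-k sets.
#' @export
top_rank_overlap <- function(rates, k = 10) {
  eps <- sort(unique(rates$epsilon))
  if (length(eps) != 2) abort("rate table must contain exactly two epsilon regimes")
  tops <- lapply(eps, function(e) {
    sub <- dplyr::filter(rates, .data$epsilon == e)
    if (k > nrow(sub)) abort("k exceeds the number of clades")
    sub <- dplyr::arrange(sub, dplyr::desc(.data$r), .data$clade_id)
    sub$clade_id[seq_len(k)]
  })
  length(intersect(tops[[1]], tops[[2]]))
}

#' Write a rate table in wide (one row per clade) form
#'
#' Columns `clade_id`, `stem_age`, `S`, `ln_S`, then one `r_eps<value>`
#' column per extinction regime.
#'
#' @param rates A tibble from [rate_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  wide <- rates |>
    dplyr::mutate(regime = paste0("r_eps", .data$epsilon)) |>
    dplyr::select(-"epsilon") |>
    tidyr::pivot_wider(names_from = "regime", values_from = "r")
  readr::write_csv(wide, path)
  invisible(path)
}
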