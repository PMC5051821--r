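#' Fit a single constant-rate diversification model to a tree with richness
#'
#' Maximum-likelihood fit of one birth-death (or pure-birth) model to a
#' dated tree whose tips are terminally unresolved clades with known
#' richness. The likelihood is the resolved-backbone part
#' ([backbone_loglik()]) plus one [clade_richness_loglik()] term per tip,
#' maximised numerically over `(r, epsilon)` (or `r` alone for Yule) on a
#' transformed scale (log r, logit epsilon) with grid multistart. Fits
#' pinned at the relative-extinction upper bound `1 - 1e-6` or at the rate
#' bounds are flagged with a boundary warning.
#'
#' @param phy A dated `phylo` object.
#' @param richness Data frame (`family`, `S`) or named vector of per-tip
#'   richness; values are rounded to the nearest integer `>= 1` for the
#'   likelihood.
#' @param model_kind `"yule"`, `"bd"`, or `"best"` (both fitted, lower AICc
#'   retained).
#' @return An object of class `bd_fit`: list with `params` (one-row tibble:
#'   `kind`, `r`, `epsilon`, `lambda`, `mu`), `logLik`, `k`, `n_obs`,
#'   `AICc`, `boundary`.
#' @export
fit_constant_model <- function(phy, richness, model_kind = c("best", "yule", "bd")) {
  model_kind <- match.arg(model_kind)
  validate_dated_tree(phy)
  d <- bd_lik_data(phy, richness)
  kinds <- if (model_kind == "best") c("yule", "bd") else model_kind
  fits <- fit_partition(d, seq_along(d$node), kinds = kinds)
  aiccs <- vapply(fits, function(f) aicc(f$logLik, f$k, d$n_obs), numeric(1))
  f <- fits[[which.min(aiccs)]]
  if (f$boundary) {
    warn(sprintf(
      "Fit at parameter boundary (r = %.3g, epsilon = %.6g); interpret with caution",
      f$r, f$epsilon
    ))
  }
  structure(
    list(
      params = tibble::tibble(
        kind = f$kind, r = f$r, epsilon = f$epsilon,
        lambda = f$r / (1 - f$epsilon),
        mu = f$r * f$epsilon / (1 - f$epsilon)
      ),
      logLik = f$logLik, k = f$k, n_obs = d$n_obs,
      AICc = min(aiccs), boundary = f$boundary
    ),
    class = "bd_fit"
  )
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf(
    "Constant-rate %s fit: r = %.4g, epsilon = %.4g (logLik %.3f, AICc %.3f)\n",
    x$params$kind, x$params$r, x$params$epsilon, x$logLik, x$AICc
  ))
  invisible(x)
}

#' @rdname fit_constant_model
#' @param x A `bd_fit` object.
#' @param ... Unused.
#' @method tidy bd_fit
#' @export
tidy.bd_fit <- function(x, ...) x$params

#' @rdname fit_constant_model
#' @method glance bd_fit
#' @export
glance.bd_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, k = x$k, n_obs = x$n_obs,
                 AICc = x$AICc, boundary = x$boundary)
}

## Descendant element lists: for each likelihood element (= non-root node
## and its subtending branch), the indices of all elements in its subtree,
## itself included.
descendant_elements <- function(phy, d) {
  elem_of_node <- integer(d$n_tip + phy$Nnode)
  elem_of_node[d$node] <- seq_along(d$node)
  children <- split(seq_along(d$node), phy$edge[, 1])
  desc <- vector("list", length(d$node))
  eo <- ape::reorder.phylo(phy, "postorder")
  ord <- match(eo$edge[, 2], d$node)
  for (e in ord) {
    v <- d$node[e]
    kids <- children[[as.character(v)]]
    desc[[e]] <- c(e, unlist(desc[kids], use.names = FALSE))
  }
  desc
}

#' Stepwise AICc search for diversification rate shifts
#'
#' MEDUSA-style greedy model selection. A constant-rate model is first fit
#' to the whole tree. Then, at each step, every node (internal nodes and tip
#' stems, evaluated exhaustively) is tried as a break-point: the node's
#' subtending branch and all its descendants still governed by the parent
#' model are carved into a new model, both affected partitions are refit,
#' and the single break-point giving the largest AICc improvement is
#' retained. The search stops when no candidate improves the AICc by more
#' than `aicc_threshold` (or `max_models` is reached, with a warning). Within each partition the
#' better of the allowed model kinds by AICc is retained. Each break-point
#' counts as one extra free parameter; `n_obs` for the AICc correction is
#' the number of resolved internal nodes plus unresolved tip clades.
#'
#' @inheritParams fit_constant_model
#' @param model_kinds Candidate model kinds per partition (default both
#'   `"yule"` and `"bd"`).
#' @param max_models Maximum number of models (partitions).
#' @param aicc_threshold Minimum AICc improvement required to retain a
#'   break-point (default 4 units, the conventional substantial-support
#'   cutoff used by stepwise rate-shift analyses; 0 accepts any
#'   improvement). A greedy scan over every node is a sup-likelihood-ratio
#'   test, so accepting arbitrarily small improvements plants spurious
#'   shifts on a large fraction of single-rate trees.
#' @return An object of class `shift_config`: list with `models` (tibble:
#'   `model`, `kind`, `r`, `epsilon`, `lambda`, `mu`, `n_elements`,
#'   `logLik`, `boundary`), `break_nodes` (tibble: `model`, `node`,
#'   `clade_id`; model 1 covers the root), `branch_map` (tibble: `node`,
#'   `clade_id`, `model` — the model governing each node's subtending
#'   branch), `logLik`, `k`, `n_obs`, `AICc`, `aicc_trace`.
#' @export
stepwise_shift_search <- function(phy, richness,
                                  model_kinds = c("yule", "bd"),
                                  max_models = 20, aicc_threshold = 4) {
  model_kinds <- match.arg(model_kinds, c("yule", "bd"), several.ok = TRUE)
  validate_dated_tree(phy)
  d <- bd_lik_data(phy, richness)
  desc <- descendant_elements(phy, d)
  all_elems <- seq_along(d$node)

  pick_best <- function(fits) {
    ## lowest AIC contribution; the shared AICc correction is handled at
    ## configuration level below
    scores <- vapply(fits, function(f) -2 * f$logLik + 2 * f$k, numeric(1))
    fits[[which.min(scores)]]
  }

  fits0 <- fit_partition(d, all_elems, kinds = model_kinds)
  f0 <- pick_best(fits0)
  models <- list(f0)
  elems <- list(all_elems)
  break_node <- c(NA_integer_)  # model 1 covers the root
  mod_of <- rep(1L, length(all_elems))

  config_aicc <- function(lls, ks) {
    k <- sum(ks) + (length(ks) - 1L)
    aicc(sum(lls), k, d$n_obs)
  }
  cur_aicc <- config_aicc(
    vapply(models, `[[`, numeric(1), "logLik"),
    vapply(models, `[[`, numeric(1), "k")
  )
  trace <- cur_aicc

  repeat {
    if (length(models) >= max_models) {
      warn("max_models reached; returning current configuration")
      break
    }
    lls <- vapply(models, `[[`, numeric(1), "logLik")
    ks <- vapply(models, `[[`, numeric(1), "k")
    best <- NULL
    for (e in all_elems) {
      v <- d$node[e]
      if (v %in% break_node) next
      src <- mod_of[e]
      elems_new <- desc[[e]][mod_of[desc[[e]]] == src]
      elems_rem <- setdiff(elems[[src]], elems_new)
      if (length(elems_rem) == 0) next
      f_new <- pick_best(fit_partition(d, elems_new, kinds = model_kinds,
                                       start = models[[src]]))
      f_rem <- pick_best(fit_partition(d, elems_rem, kinds = model_kinds,
                                       start = models[[src]]))
      lls2 <- c(lls[-src], f_rem$logLik, f_new$logLik)
      ks2 <- c(ks[-src], f_rem$k, f_new$k)
      cand_aicc <- config_aicc(lls2, ks2)
      if (is.null(best) || cand_aicc < best$aicc) {
        best <- list(aicc = cand_aicc, elem = e, src = src,
                     f_new = f_new, f_rem = f_rem,
                     elems_new = elems_new, elems_rem = elems_rem)
      }
    }
    if (is.null(best) || best$aicc >= cur_aicc - aicc_threshold) break
    models[[best$src]] <- best$f_rem
    elems[[best$src]] <- best$elems_rem
    models[[length(models) + 1]] <- best$f_new
    elems[[length(elems) + 1]] <- best$elems_new
    break_node <- c(break_node, d$node[best$elem])
    mod_of[best$elems_new] <- length(models)
    cur_aicc <- best$aicc
    trace <- c(trace, cur_aicc)
  }

  sets <- tip_label_sets(phy)
  ids <- clade_ids(phy, sets)
  models_tbl <- purrr::imap_dfr(models, function(f, i) {
    tibble::tibble(
      model = i, kind = f$kind, r = f$r, epsilon = f$epsilon,
      lambda = f$r / (1 - f$epsilon), mu = f$r * f$epsilon / (1 - f$epsilon),
      n_elements = length(elems[[i]]), logLik = f$logLik,
      boundary = f$boundary
    )
  })
  structure(
    list(
      models = models_tbl,
      break_nodes = tibble::tibble(
        model = seq_along(break_node),
        node = break_node,
        clade_id = ifelse(is.na(break_node), ids[d$root], ids[break_node])
      ),
      branch_map = tibble::tibble(
        node = d$node, clade_id = ids[d$node], model = mod_of
      ),
      logLik = sum(models_tbl$logLik),
      k = sum(vapply(models, `[[`, numeric(1), "k")) + (length(models) - 1L),
      n_obs = d$n_obs,
      AICc = cur_aicc,
      aicc_trace = trace
    ),
    class = "shift_config"
  )
}

#' @export
print.shift_config <- function(x, ...) {
  cat(sprintf(
    "Stepwise rate-shift configuration: %d model(s), AICc %.3f (logLik %.3f, k = %d)\n",
    nrow(x$models), x$AICc, x$logLik, x$k
  ))
  print(x$models)
  invisible(x)
}

#' @rdname stepwise_shift_search
#' @param x A `shift_config` object.
#' @param ... Unused.
#' @method tidy shift_config
#' @export
tidy.shift_config <- function(x, ...) {
  dplyr::left_join(x$models,
                   dplyr::select(x$break_nodes, "model", break_clade = "clade_id"),
                   by = "model")
}

#' @rdname stepwise_shift_search
#' @method glance shift_config
#' @export
glance.shift_config <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$models), logLik = x$logLik, k = x$k,
    n_obs = x$n_obs, AICc = x$AICc
  )
}

#' Write shift-search outputs
#'
#' `write_shift_models()` exports the per-model parameter table;
#' `write_branch_map()` exports the branch-to-model assignment used to
#' annotate figures.
#'
#' @param config A `shift_config` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shift_models <- function(config, path) {
  readr::write_csv(tidy(config), path)
  invisible(path)
}

#' @rdname write_shift_models
#' @export
write_branch_map <- function(config, path) {
  readr::write_csv(config$branch_map, path)
  invisible(path)
}
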