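## Seed discipline: every generator takes an explicit `seed`; the global RNG
## state is saved and restored so simulation never leaks into user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      else if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    )
    set.seed(seed)
  }
  force(code)
}

#' Specify a planted diversification rate shift
#'
#' @param time Forward time (My after the origin) at which the shift
#'   activates. Alternatively give `at_n_alive`.
#' @param at_n_alive Activate the shift as soon as this many lineages are
#'   concurrently alive (useful with an `n_tips` stopping rule, where the
#'   total duration is random).
#' @param multiplier Factor applied to the speciation rate of the affected
#'   lineage's current model; `> 0`.
#' @param epsilon Optional new relative extinction for the shifted model;
#'   default inherits the parent model's.
#' @param lineage Index (in birth order) of the lineage to shift among those
#'   alive at activation; `NULL` picks one uniformly at random.
#' @param min_clade_tips Minimum number of extant tips the shifted clade
#'   must have in the reconstructed tree; the simulation is retried until
#'   satisfied.
#' @return A `shift_spec` list.
#' @export
shift_spec <- function(time = NULL, multiplier = 2, epsilon = NULL,
                       lineage = NULL, min_clade_tips = 0,
                       at_n_alive = NULL) {
  if (multiplier <= 0) abort("shift multiplier must be > 0")
  if (is.null(time) == is.null(at_n_alive)) {
    abort("supply exactly one of time or at_n_alive")
  }
  if (!is.null(epsilon) && (epsilon < 0 || epsilon >= 1)) {
    abort("shift epsilon must be in [0, 1)")
  }
  structure(list(time = time, at_n_alive = at_n_alive,
                 multiplier = multiplier, epsilon = epsilon,
                 lineage = lineage, min_clade_tips = min_clade_tips),
            class = "shift_spec")
}

## Event-driven (Gillespie) birth-death simulation from a single origin
## lineage. Returns lineage records; each record is one branch of the
## complete tree.
sim_bd_core <- function(lambda, mu, n_tips, max_age, shifts) {
  classes <- data.frame(lambda = lambda, mu = mu)
  parent <- 0L; t_start <- 0; t_end <- NA_real_
  cls <- 1L; status <- "alive"
  alive <- 1L
  nrec <- 1L
  shift_done <- rep(FALSE, length(shifts))
  shift_class <- rep(NA_integer_, length(shifts))
  shift_record <- rep(NA_integer_, length(shifts))
  now <- 0

  apply_shift <- function(i) {
    sh <- shifts[[i]]
    tgt <- if (is.null(sh$lineage)) {
      if (length(alive) == 1) alive else sample(alive, 1)
    } else {
      if (sh$lineage > length(alive)) abort("shift lineage index out of range")
      sort(alive)[sh$lineage]
    }
    base <- classes[cls[tgt], ]
    new_lambda <- base$lambda * sh$multiplier
    new_eps <- if (is.null(sh$epsilon)) {
      if (base$lambda > 0) base$mu / base$lambda else 0
    } else sh$epsilon
    classes <<- rbind(classes,
                      data.frame(lambda = new_lambda, mu = new_lambda * new_eps))
    cls[tgt] <<- nrow(classes)
    shift_done[i] <<- TRUE
    shift_class[i] <<- nrow(classes)
    shift_record[i] <<- tgt
  }
  shift_time <- vapply(shifts, function(s) {
    if (is.null(s$time)) Inf else s$time
  }, numeric(1))
  shift_count <- vapply(shifts, function(s) {
    if (is.null(s$at_n_alive)) Inf else s$at_n_alive
  }, numeric(1))

  repeat {
    if (length(alive) == 0) break
    ## lineage-count shift triggers fire at the current moment
    pend_n <- which(!shift_done & shift_count <= length(alive))
    if (length(pend_n) > 0) {
      apply_shift(pend_n[1])
      next
    }
    rates <- classes$lambda[cls[alive]] + classes$mu[cls[alive]]
    total <- sum(rates)
    dt <- if (total > 0) rexp(1, total) else Inf
    t_next <- now + dt
    ## time-based shift triggers fire before the next event
    pend_t <- which(!shift_done & shift_time <= t_next)
    if (length(pend_t) > 0) {
      i <- pend_t[which.min(shift_time[pend_t])]
      now <- shift_time[i]
      apply_shift(i)
      next
    }
    if (!is.null(max_age) && t_next >= max_age) {
      now <- max_age
      break
    }
    if (!is.null(n_tips) && length(alive) >= n_tips) {
      ## stop strictly before the next event so pendant edges are positive
      now <- t_next
      break
    }
    if (!is.finite(t_next)) break
    now <- t_next
    who <- if (length(alive) == 1) alive else sample(alive, 1, prob = rates / total)
    lam <- classes$lambda[cls[who]]
    if (runif(1) < lam / (lam + classes$mu[cls[who]])) {
      ## speciation: close the record, open two daughters
      t_end[who] <- now; status[who] <- "split"
      for (k in 1:2) {
        nrec <- nrec + 1L
        parent[nrec] <- who; t_start[nrec] <- now; t_end[nrec] <- NA_real_
        cls[nrec] <- cls[who]; status[nrec] <- "alive"
      }
      alive <- c(setdiff(alive, who), nrec - 1L, nrec)
    } else {
      t_end[who] <- now; status[who] <- "extinct"
      alive <- setdiff(alive, who)
    }
  }
  t_end[alive] <- now
  status[alive] <- "extant"
  list(parent = parent, t_start = t_start, t_end = t_end, cls = cls,
       status = status, present = now, n_extant = length(alive),
       shift_class = shift_class, shift_record = shift_record)
}

## Assemble a phylo object from lineage records. Returns NULL when fewer
## than 2 leaves exist.
records_to_phylo <- function(rec) {
  leaves <- which(rec$status %in% c("extant", "extinct"))
  splits <- which(rec$status == "split")
  if (length(leaves) < 2) return(NULL)
  n_leaf <- length(leaves)
  nodeid <- integer(length(rec$parent))
  nodeid[leaves] <- seq_len(n_leaf)
  ## origin record splits first, so ordering internals by split time puts
  ## the root at n_leaf + 1 as ape expects
  splits <- splits[order(rec$t_end[splits])]
  nodeid[splits] <- n_leaf + seq_along(splits)
  nonroot <- which(rec$parent > 0)
  edge <- cbind(nodeid[rec$parent[nonroot]], nodeid[nonroot])
  edge.length <- rec$t_end[nonroot] - rec$t_start[nonroot]
  lab <- character(n_leaf)
  ext <- rec$status[leaves] == "extant"
  lab[ext] <- paste0("t", seq_len(sum(ext)))
  lab[!ext] <- paste0("x", seq_len(sum(!ext)))
  phy <- structure(
    list(edge = edge, edge.length = edge.length, tip.label = lab,
         Nnode = length(splits), root.edge = rec$t_end[1] - rec$t_start[1]),
    class = "phylo", order = "cladewise"
  )
  attr(phy, "tip_record") <- setNames(leaves, lab)
  attr(phy, "edge_class") <- rec$cls[nonroot]
  phy
}

## Extant tip labels descending from a record (itself included if a leaf).
extant_descendants <- function(rec, record_id) {
  children <- split(seq_along(rec$parent), rec$parent)
  out <- character(0)
  stack <- record_id
  ext <- which(rec$status == "extant")
  lab <- setNames(paste0("t", seq_along(ext)), ext)
  while (length(stack) > 0) {
    x <- stack[[1]]; stack <- stack[-1]
    if (rec$status[x] == "extant") out <- c(out, lab[[as.character(x)]])
    kids <- children[[as.character(x)]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  out
}

#' Simulate a constant-rate birth-death tree
#'
#' Event-driven forward simulation from a single origin lineage until either
#' a fixed number of concurrently alive lineages (`n_tips`) or a fixed age
#' (`max_age`) is reached. Returns both the complete tree (extinct lineages
#' included) and the reconstructed, extant-only ultrametric tree. If the
#' whole tree dies before the stopping condition the simulation is retried
#' up to `retries` times, then errors (never silently corrected).
#'
#' @param lambda Speciation rate per lineage per My, `> mu`.
#' @param mu Extinction rate per lineage per My, `>= 0`.
#' @param n_tips Stop when this many lineages are alive (exclusive with
#'   `max_age`).
#' @param max_age Stop at this age in My (exclusive with `n_tips`).
#' @param seed Integer seed for reproducibility.
#' @param retries Retry cap for whole-tree extinction (default 100).
#' @return A list: `complete` (phylo with extinct tips `x*`), `reconstructed`
#'   (extant-only phylo, `NULL` if fewer than 2 extant), `n_extant`,
#'   `present` (realised present time), `seed`.
#' @export
simulate_bd_tree <- function(lambda, mu = 0, n_tips = NULL, max_age = NULL,
                             seed = NULL, retries = 100) {
  if (lambda <= mu || mu < 0) abort("require lambda > mu >= 0")
  if (is.null(n_tips) == is.null(max_age)) {
    abort("supply exactly one of n_tips or max_age")
  }
  with_seed(seed, {
    for (i in seq_len(retries)) {
      rec <- sim_bd_core(lambda, mu, n_tips, max_age, shifts = list())
      if (is.null(n_tips) || rec$n_extant >= n_tips) break
    }
    if (!is.null(n_tips) && rec$n_extant < n_tips) {
      abort("whole-tree extinction in every retry; increase lambda - mu or retries")
    }
    complete <- records_to_phylo(rec)
    reconstructed <- reconstruct_extant(complete)
    list(complete = complete, reconstructed = reconstructed,
         n_extant = rec$n_extant, present = rec$present, seed = seed)
  })
}

reconstruct_extant <- function(complete) {
  if (is.null(complete)) return(NULL)
  extinct <- grep("^x", complete$tip.label, value = TRUE)
  if (length(complete$tip.label) - length(extinct) < 2) return(NULL)
  if (length(extinct) == 0) return(complete)
  ape::drop.tip(complete, extinct)
}

#' Simulate a birth-death tree with planted rate shifts
#'
#' As [simulate_bd_tree()], but with lineage-specific rate shifts applied
#' during the simulation: at each [shift_spec()]'s activation time one alive
#' lineage switches to a new model (speciation multiplied, optional new
#' relative extinction) which its descendants inherit; nested shifts apply
#' innermost-tipward. The true rate map is returned for recovery testing.
#'
#' @inheritParams simulate_bd_tree
#' @param shifts List of [shift_spec()] objects.
#' @return As [simulate_bd_tree()], plus `shift_tips` (list: per shift, the
#'   extant tip labels of the shifted clade), `shift_node` (per shift, the
#'   MRCA node number of those tips in the reconstructed tree, or `NA`),
#'   and `edge_class` (complete-tree per-edge model index; 1 = base model).
#' @export
plant_shifts <- function(lambda, mu = 0, shifts = list(), n_tips = NULL,
                         max_age = NULL, seed = NULL, retries = 100) {
  if (lambda <= mu || mu < 0) abort("require lambda > mu >= 0")
  if (is.null(n_tips) == is.null(max_age)) {
    abort("supply exactly one of n_tips or max_age")
  }
  stopifnot(all(vapply(shifts, inherits, logical(1), "shift_spec")))
  if (length(shifts) == 0) {
    return(simulate_bd_tree(lambda, mu, n_tips, max_age, seed, retries))
  }
  with_seed(seed, {
    min_tips <- vapply(shifts, `[[`, numeric(1), "min_clade_tips")
    shift_tips <- list()
    ok <- FALSE
    for (i in seq_len(retries)) {
      rec <- sim_bd_core(lambda, mu, n_tips, max_age, shifts)
      survived <- if (!is.null(n_tips)) rec$n_extant >= n_tips else rec$n_extant >= 2
      if (!survived) next
      if (anyNA(rec$shift_record)) next
      shift_tips <- lapply(rec$shift_record, function(id) {
        extant_descendants(rec, id)
      })
      if (all(lengths(shift_tips) >= min_tips)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not realise all planted shifts within the retry cap")
    }
    complete <- records_to_phylo(rec)
    reconstructed <- reconstruct_extant(complete)
    shift_node <- vapply(shift_tips, function(tips) {
      if (is.null(reconstructed) || length(tips) < 1) return(NA_integer_)
      if (length(tips) == 1) return(match(tips, reconstructed$tip.label))
      ape::getMRCA(reconstructed, tips)
    }, integer(1))
    list(complete = complete, reconstructed = reconstructed,
         n_extant = rec$n_extant, present = rec$present, seed = seed,
         shift_tips = shift_tips, shift_node = shift_node,
         edge_class = attr(complete, "edge_class"))
  })
}

#' Collapse a species-level tree into family tips by a time-slice cutoff
#'
#' Cuts an ultrametric (reconstructed) tree at `cutoff` My: every branch
#' crossing the cutoff defines one family, whose richness is its extant
#' species count and whose stem age (the age of the parent node of the
#' crossing branch) is preserved in the resulting family-level tree. The
#' family tree remains ultrametric with tips at the present.
#'
#' @param phy An extant-only ultrametric `phylo` object.
#' @param cutoff Slice age in My; must be younger than the root.
#' @return A list: `tree` (family-level phylo with tips `F001`, ...),
#'   `richness` (tibble `family`, `S`), `members` (list of original tip
#'   labels per family).
#' @export
collapse_to_families <- function(phy, cutoff = 30) {
  validate_dated_tree(phy)
  ages <- node_ages(phy)
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  if (cutoff >= ages[root]) abort("cutoff must be younger than the root age")
  if (cutoff < 0) abort("cutoff must be non-negative")
  crossing <- which(ages[phy$edge[, 1]] > cutoff & ages[phy$edge[, 2]] <= cutoff)
  sets <- tip_label_sets(phy)
  members <- lapply(phy$edge[crossing, 2], function(v) sets[[v]])
  reps <- vapply(members, min, character(1))
  fam <- sprintf("F%03d", seq_along(reps))
  tree <- ape::keep.tip(phy, reps)
  tree$tip.label <- fam[match(tree$tip.label, reps)]
  list(
    tree = tree,
    richness = tibble::tibble(family = fam, S = lengths(members)),
    members = setNames(members, fam)
  )
}

#' Simulate taxonomic evaluation counts for a family
#'
#' Emulates the nomenclatural evaluation process behind the richness
#' correction: a family of true richness `S_true` carries, in addition, a
#' Poisson number of synonym names (mean `S_true * synonym_rate`); each name
#' is independently evaluated with probability `eval_fraction`; evaluated
#' names are labelled accepted or rejected according to their true status
#' and the rest remain unevaluated.
#'
#' @param S_true True species richness (vectorised over families).
#' @param synonym_rate Expected synonyms per true species, `>= 0`.
#' @param eval_fraction Probability a name has been evaluated, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A tibble `family`, `S_A`, `S_R`, `S_U`, `S_true`.
#' @export
simulate_taxonomic_counts <- function(S_true, synonym_rate = 0.5,
                                      eval_fraction = 0.6, seed = NULL) {
  if (synonym_rate < 0) abort("synonym_rate must be >= 0")
  if (eval_fraction < 0 || eval_fraction > 1) {
    abort("eval_fraction must be in [0, 1]")
  }
  if (any(S_true < 1 | S_true != floor(S_true))) {
    abort("S_true must be integer >= 1")
  }
  with_seed(seed, {
    m <- length(S_true)
    n_syn <- rpois(m, S_true * synonym_rate)
    S_A <- rbinom(m, S_true, eval_fraction)
    S_R <- rbinom(m, n_syn, eval_fraction)
    tibble::tibble(
      family = sprintf("F%03d", seq_len(m)),
      S_A = S_A, S_R = S_R,
      S_U = (S_true - S_A) + (n_syn - S_R),
      S_true = S_true
    )
  })
}

#' Simulate a family-level dataset under the fitted likelihood's model
#'
#' Generates a family backbone tree by a (possibly shifted) pure-birth or
#' birth-death process and draws each family's richness from the geometric
#' stem-age law of [clade_richness_loglik()] under the model governing that
#' family. This is the well-specified generating process for validating
#' [fit_constant_model()] and [stepwise_shift_search()].
#'
#' @param n_families Number of family tips.
#' @param r Net diversification rate of the base model, per My.
#' @param epsilon Relative extinction of the base model.
#' @param shift Optional [shift_spec()] for a single planted shift.
#' @param seed Integer seed.
#' @return A list: `tree` (family phylo), `richness` (tibble `family`, `S`),
#'   `shift_node` (MRCA node of the shifted clade, or `NA`), `rates`
#'   (per-model `r` used), `seed`.
#' @export
simulate_family_dataset <- function(n_families = 64, r = 0.05, epsilon = 0,
                                    shift = NULL, seed = NULL) {
  lambda <- r / (1 - epsilon)
  mu <- lambda * epsilon
  sim <- if (is.null(shift)) {
    simulate_bd_tree(lambda, mu, n_tips = n_families, seed = seed)
  } else {
    plant_shifts(lambda, mu, shifts = list(shift), n_tips = n_families,
                 seed = seed)
  }
  phy <- sim$reconstructed
  phy$tip.label <- sprintf("F%03d", seq_along(phy$tip.label))
  ## re-derive tip labels of the shifted clade after renaming
  shift_node <- if (is.null(shift)) NA_integer_ else sim$shift_node
  ages <- stem_crown_ages(phy)
  n_tip <- length(phy$tip.label)
  stem <- ages$stem_age[seq_len(n_tip)]
  rate_mult <- rep(1, n_tip)
  if (!is.null(shift) && !is.na(shift_node)) {
    sub_tips <- if (shift_node <= n_tip) shift_node else {
      which(phy$tip.label %in% tip_label_sets(phy)[[shift_node]])
    }
    rate_mult[sub_tips] <- shift$multiplier
  }
  rates <- r * rate_mult
  ## S - 1 ~ geometric with success prob 1 - beta(stem age)
  S <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    prob <- exp(log_one_minus_beta(stem, rates, epsilon))
    1 + rgeom(n_tip, prob)
  })
  list(
    tree = phy,
    richness = tibble::tibble(family = phy$tip.label, S = S),
    shift_node = shift_node,
    rates = sort(unique(rates)),
    seed = seed
  )
}

#' Synthetic clade table with seed-plant-like marginals
#'
#' Builds a family backbone (pure-birth topology rescaled to `root_age`),
#' assigns independent log-normal family richness, and enumerates all
#' clades. With `shuffle_richness = TRUE` the richness column is permuted
#' across clades after enumeration, producing a clade table in which
#' richness is independent of age by construction — the null case for the
#' age-window analysis.
#'
#' @param n_families Number of family tips (default 425).
#' @param root_age Root age in My the backbone is rescaled to (default 330,
#'   a seed-plant-like depth).
#' @param min_node_age Age in My of the youngest internal node (default 25):
#'   a family-level tree is a tree collapsed at the family-origination
#'   depth, so it contains no near-present splits. The backbone is rescaled
#'   to `root_age - min_node_age` and every pendant branch is extended by
#'   `min_node_age`.
#' @param meanlog,sdlog Log-normal parameters of family richness (defaults
#'   4.0 and 2.3, giving family-level and total richness of the order seen
#'   in seed plants).
#' @param shuffle_richness Permute richness across clades after enumeration
#'   (breaks any age-richness association).
#' @param seed Integer seed.
#' @return A clade tibble as from [enumerate_clades()].
#' @export
simulate_clade_table <- function(n_families = 425, root_age = 330,
                                 min_node_age = 25, meanlog = 4.0,
                                 sdlog = 2.3, shuffle_richness = FALSE,
                                 seed = NULL) {
  stopifnot(min_node_age >= 0, min_node_age < root_age)
  sim <- simulate_bd_tree(lambda = 0.03, n_tips = n_families, seed = seed)
  phy <- sim$reconstructed
  phy$tip.label <- sprintf("F%03d", seq_along(phy$tip.label))
  phy$edge.length <- phy$edge.length *
    (root_age - min_node_age) / tree_height(phy)
  pendant <- phy$edge[, 2] <= length(phy$tip.label)
  phy$edge.length[pendant] <- phy$edge.length[pendant] + min_node_age
  phy$root.edge <- NULL
  S <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    pmax(1, round(stats::rlnorm(n_families, meanlog, sdlog)))
  })
  clades <- enumerate_clades(phy, setNames(S, phy$tip.label))
  if (shuffle_richness) {
    clades <- with_seed(if (is.null(seed)) NULL else seed + 2L, {
      idx <- sample.int(nrow(clades))
      dplyr::mutate(clades, S = .data$S[idx], ln_S = log(.data$S))
    })
  }
  clades
}
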