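#' Read and validate a dated (ultrametric) family-level tree
#'
#' Parses a Newick string or file into an `ape::phylo` object and checks the
#' invariants the downstream analysis relies on: branch lengths present and
#' non-negative, unique tip labels, and ultrametricity within tolerance.
#' Branch lengths are interpreted as millions of years (My); tips are
#' contemporaneous at the present. Polytomies are accepted.
#'
#' @param newick A Newick string (must end in `;`) or the path of a file
#'   containing one.
#' @param tol Relative ultrametricity tolerance: the spread of root-to-tip
#'   path lengths divided by tree height must not exceed `tol`. Deviations
#'   between `tol` and `max_tol` raise a warning (dating pipelines emit small
#'   numerical jitter); larger deviations are an error.
#' @param max_tol Relative deviation above which the tree is rejected.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- read_dated_tree("((A:1,B:1):1,C:2);")
#' tree_height(tr)
read_dated_tree <- function(newick, tol = 1e-6, max_tol = 1e-3) {
  txt <- newick
  if (length(txt) == 1 && !grepl(";", txt) && file.exists(txt)) {
    txt <- paste(readLines(txt, warn = FALSE), collapse = "")
  }
  if (!grepl(";\\s*$", txt)) {
    abort(paste0(
      "Malformed Newick: no terminating ';' (input ends at position ",
      nchar(txt), ")"
    ))
  }
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    abort("Malformed Newick: parse failed")
  }
  validate_dated_tree(phy, tol = tol, max_tol = max_tol)
  phy
}

#' Validate the dated-tree invariants
#'
#' @param phy A `phylo` object.
#' @inheritParams read_dated_tree
#' @return `phy`, invisibly, if valid; otherwise an error.
#' @export
validate_dated_tree <- function(phy, tol = 1e-6, max_tol = 1e-3) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) {
    abort("Tree has no branch lengths; a dated tree is required")
  }
  if (anyNA(phy$edge.length)) abort("Tree has missing branch lengths")
  if (any(phy$edge.length < 0)) abort("Tree has negative branch lengths")
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    abort(paste0("Duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  h <- max(depths)
  if (h <= 0) abort("Tree height is zero")
  dev <- (max(depths) - min(depths)) / h
  if (dev > max_tol) {
    abort(sprintf(
      "Tree is not ultrametric: relative root-to-tip spread %.3g exceeds %.3g",
      dev, max_tol
    ))
  }
  if (dev > tol) {
    warn(sprintf(
      "Tree deviates from ultrametricity (relative spread %.3g); treating as dated with tips at the present",
      dev
    ))
  }
  invisible(phy)
}

#' Tree height (root age) in My
#' @param phy A dated `phylo` object.
#' @return Root age, i.e. the maximum root-to-tip path length.
#' @export
tree_height <- function(phy) {
  max(ape::node.depth.edgelength(phy))
}

## Node ages measured backward from the present: age(node) = max path length
## from the node to its descendant tips, so tips are exactly 0 even under
## small dating jitter. Vector indexed by ape node number (tips first).
node_ages <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  ages <- numeric(n_node)
  ## postorder: children before parents
  eo <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1]
    chi <- eo$edge[i, 2]
    ages[par] <- max(ages[par], ages[chi] + eo$edge.length[i])
  }
  ages[seq_len(n_tip)] <- 0
  ages
}

#' Stem and crown ages for every clade in a dated tree
#'
#' The crown age of a node is its own age (maximum path length to its
#' descendant tips; 0 for tips by convention, since families are terminally
#' unresolved). The stem age is the age of the parent node, i.e. the time the
#' clade diverged from its sister lineage. The root carries no subtending
#' branch; its stem age is set equal to its crown age so that it can still
#' carry a rate estimate.
#'
#' @param phy A dated `phylo` object.
#' @return A tibble with columns `node`, `stem_age`, `crown_age`.
#' @export
stem_crown_ages <- function(phy) {
  validate_dated_tree(phy)
  ages <- node_ages(phy)
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  root <- n_tip + 1L
  parent <- integer(n_node)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  parent[root] <- root  # root convention: stem age = crown age
  stem <- ages[parent]
  tibble::tibble(
    node = seq_len(n_node),
    stem_age = stem,
    crown_age = ages
  )
}

## Stable clade identifier: tips use their label; an internal clade uses
## "<min member label>_<tip count>". On a tree this is unique: disjoint
## clades differ in their smallest member, nested clades differ in size.
clade_ids <- function(phy, tip_sets) {
  n_tip <- length(phy$tip.label)
  vapply(seq_along(tip_sets), function(i) {
    if (i <= n_tip) phy$tip.label[i]
    else paste0(min(tip_sets[[i]]), "_", length(tip_sets[[i]]))
  }, character(1))
}

## List of descendant-tip label sets per node (ape numbering).
tip_label_sets <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- phy$tip.label[i]
  eo <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1]
    chi <- eo$edge[i, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  lapply(sets, sort)
}

#' Enumerate all clades of a dated tree with ages and richness
#'
#' Every node of the tree — tips (families) and internal nodes alike —
#' defines one clade. For a fully bifurcating rooted tree with n tips this
#' yields 2n - 1 clades. The species richness of an internal clade is the sum
#' of the richness of its member families; `ln_S` is the natural logarithm of
#' richness.
#'
#' @param phy A dated `phylo` object with family names as tip labels.
#' @param richness A data frame with columns `family` and `S` (one row per
#'   tip label), or a named numeric vector.
#' @return A tibble with one row per clade: `clade_id`, `node`, `n_tips`,
#'   `tip_families` (list column), `stem_age`, `crown_age`, `S`, `ln_S`.
#' @export
#' @examples
#' tr <- read_dated_tree("((A:1,B:1):1,C:2);")
#' enumerate_clades(tr, c(A = 2, B = 3, C = 1))
enumerate_clades <- function(phy, richness) {
  if (is.data.frame(richness)) {
    stopifnot(all(c("family", "S") %in% names(richness)))
    richness <- setNames(richness$S, richness$family)
  }
  missing <- setdiff(phy$tip.label, names(richness))
  if (length(missing) > 0) {
    abort(paste0(
      "No richness entry for ", length(missing), " famil",
      if (length(missing) == 1) "y" else "ies", ": ",
      paste(head(missing, 10), collapse = ", "),
      if (length(missing) > 10) ", ..." else ""
    ))
  }
  if (any(richness[phy$tip.label] < 1)) {
    abort("All families must have richness S >= 1")
  }
  ages <- stem_crown_ages(phy)
  sets <- tip_label_sets(phy)
  S <- vapply(sets, function(s) sum(richness[s]), numeric(1))
  tibble::tibble(
    clade_id = clade_ids(phy, sets),
    node = ages$node,
    n_tips = lengths(sets),
    tip_families = sets,
    stem_age = ages$stem_age,
    crown_age = ages$crown_age,
    S = unname(S),
    ln_S = log(unname(S))
  )
}

#' Write a clade table to CSV
#'
#' Exports the scalar columns of a clade table (the `tip_families` list
#' column is dropped).
#'
#' @param clades A tibble from [enumerate_clades()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clade_table <- function(clades, path) {
  out <- dplyr::select(
    clades, "clade_id", "n_tips", "S", "ln_S", "stem_age", "crown_age"
  )
  readr::write_csv(out, path)
  invisible(path)
}
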