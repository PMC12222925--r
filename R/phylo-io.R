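#' Parse a Newick string into a validated rooted phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream likelihood machinery relies on: exactly one root, unique tip
#' labels, and non-negative branch lengths. Branch lengths are interpreted as
#' millions of years (Myr) throughout the package.
#'
#' @param text A Newick string (must include branch lengths).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:1.5);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n_open <- lengths(regmatches(text, gregexpr("\\(", text)))
  n_close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (n_open != n_close) {
    abort(sprintf(
      "unbalanced parentheses in Newick string: %d '(' vs %d ')'",
      n_open, n_close
    ), class = "pollshift_parse_error")
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(
      paste0("Newick parse failure: ", conditionMessage(e)),
      class = "pollshift_parse_error"
    )
  )
  if (is.null(tree)) {
    abort("Newick parse failure: unreadable string",
      class = "pollshift_parse_error"
    )
  }
  validate_phylogeny(tree)
  tree
}

#' Validate phylogeny invariants
#'
#' Checks tip-label uniqueness, branch-length sign and presence, and warns
#' (never errors) when a dated tree is not ultrametric within a relative
#' tolerance, since posterior summary trees are near- but rarely exactly
#' ultrametric.
#'
#' @param tree A `phylo` object.
#' @param ultra_rtol Relative tolerance for the ultrametricity warning.
#' @return `tree`, invisibly, if valid.
#' @export
validate_phylogeny <- function(tree, ultra_rtol = 1e-4) {
  if (!inherits(tree, "phylo")) abort("not a 'phylo' object")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0) {
    abort(paste0("duplicate tip labels: ", paste(unique(dup), collapse = ", ")),
      class = "pollshift_parse_error"
    )
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "pollshift_parse_error")
  }
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    abort(sprintf(
      "negative branch length %g on edge to node %d",
      tree$edge.length[bad], tree$edge[bad, 2]
    ), class = "pollshift_parse_error")
  }
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  if (h > 0 && (max(depths) - min(depths)) / h > ultra_rtol) {
    warn(sprintf(
      "tree is not ultrametric (relative tip-depth spread %.3g); dated-tree methods assume near-ultrametricity",
      (max(depths) - min(depths)) / h
    ))
  }
  invisible(tree)
}

#' Serialize a phylogeny to a Newick string
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Prune a phylogeny to a set of taxa
#'
#' Retains exactly the requested tips, suppressing unary internal nodes by
#' summing branch lengths so that root-to-tip path lengths of retained tips
#' are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' write_newick(prune_to_taxa(tr, c("A", "C")))
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0(
      "species not in tree: ", paste(missing, collapse = ", ")
    ), class = "pollshift_prune_error")
  }
  if (length(keep) < 2) abort("need at least 2 taxa to keep")
  ape::keep.tip(tree, keep)
}

#' Align a phylogeny with a species-level trait table
#'
#' Restricts both the tree and the table to the intersection of their species
#' names, logging what was dropped on each side rather than guessing at name
#' matches.
#'
#' @param tree A `phylo` object.
#' @param traits A data frame with a `species` column.
#' @param quiet Suppress the drop log.
#' @return A list with elements `tree`, `traits` (a tibble ordered as the tree
#'   tips), `dropped_from_tree`, `dropped_from_traits`.
#' @export
align_tree_and_traits <- function(tree, traits, quiet = FALSE) {
  stopifnot("species" %in% names(traits))
  common <- intersect(tree$tip.label, traits$species)
  if (length(common) == 0) {
    abort("no species shared between tree and trait table",
      class = "pollshift_align_error"
    )
  }
  dropped_tree <- setdiff(tree$tip.label, common)
  dropped_traits <- setdiff(traits$species, common)
  if (!quiet && (length(dropped_tree) || length(dropped_traits))) {
    inform(sprintf(
      "align: dropped %d tree tip(s) [%s]; %d trait row(s) [%s]",
      length(dropped_tree), paste(head(dropped_tree, 10), collapse = ", "),
      length(dropped_traits), paste(head(dropped_traits, 10), collapse = ", ")
    ))
  }
  out_tree <- if (length(dropped_tree)) ape::keep.tip(tree, common) else tree
  traits <- tibble::as_tibble(traits)
  traits <- traits[match(out_tree$tip.label, traits$species), , drop = FALSE]
  list(
    tree = out_tree, traits = traits,
    dropped_from_tree = dropped_tree, dropped_from_traits = dropped_traits
  )
}

#' Read a species trait table
#'
#' Expects columns `species, syndrome, petal_length_mm, pore_height_mm,
#' pore_width_mm, thecal_wall`. Syndrome must be one of `bee`, `generalist`,
#' `nectar_vertebrate`, `foodbody_vertebrate`; thecal wall one of `smooth`,
#' `ruminate`, or missing.
#'
#' @param path CSV file path.
#' @return A tibble, one row per species.
#' @export
read_trait_table <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_trait_table(df)
}

#' Validate a trait table
#' @param df Data frame of species traits.
#' @return The validated tibble.
#' @export
validate_trait_table <- function(df) {
  df <- tibble::as_tibble(df)
  req <- c("species", "syndrome")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort(paste0("trait table missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$species)) {
    abort(paste0(
      "duplicate species in trait table: ",
      paste(unique(df$species[duplicated(df$species)]), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(df$syndrome), SYNDROME_LEVELS)
  if (length(bad)) abort(paste0("unknown syndrome value(s): ", paste(bad, collapse = ", ")))
  if ("thecal_wall" %in% names(df)) {
    badw <- setdiff(setdiff(unique(df$thecal_wall), c("smooth", "ruminate")), NA)
    if (length(badw)) abort(paste0("unknown thecal_wall value(s): ", paste(badw, collapse = ", ")))
  }
  if ("petal_length_mm" %in% names(df) &&
    any(df$petal_length_mm <= 0, na.rm = TRUE)) {
    abort("petal_length_mm must be positive where present")
  }
  df
}

# Zero-length terminal branches make transition matrices singular in the
# likelihood; nudge them to a tiny fraction of tree height.
ensure_positive_branches <- function(tree, frac = 1e-8) {
  h <- max(ape::node.depth.edgelength(tree))
  zero <- tree$edge.length <= 0
  if (any(zero)) {
    warn(sprintf("replaced %d zero-length branch(es) with %g x tree height", sum(zero), frac))
    tree$edge.length[zero] <- frac * h
  }
  tree
}
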