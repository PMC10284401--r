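#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that validates the properties the
#' downstream mixed models require: a single rooted tree, unique tip labels,
#' and a branch length on every edge (the relatedness matrix is undefined
#' without them).
#'
#' @param path Path to a file containing one Newick string.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_balance(txt)
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("malformed Newick in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed Newick in '", path, "'", call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_tree(tree)
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `"phylo"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Bracket-balance pre-check so a truncated string errors with the offending
# position rather than whatever ape happens to report.
check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of string ",
         "(position ", length(chars), ")", call. = FALSE)
  if (!grepl(";", txt))
    stop("malformed Newick: no terminating ';' found", call. = FALSE)
  invisible(TRUE)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; the relatedness matrix is undefined",
         call. = FALSE)
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  invisible(tree)
}

#' Phylogenetic relatedness matrix
#'
#' Computes the tip-by-tip matrix `A` with `A[i, j]` equal to the summed
#' branch length from the root to the most recent common ancestor of tips
#' `i` and `j` (so `A[i, i]` is the root-to-tip distance). Under Brownian
#' motion this is the trait covariance up to a rate constant, and it is the
#' covariance structure `Vp %x% A` of the phylogenetic random effects in
#' [fit_phylo_mm()]. Unscaled by default; `scale_to_unit_depth = TRUE`
#' divides by the maximum root-to-tip depth.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param scale_to_unit_depth Divide the matrix by its largest diagonal
#'   entry so the deepest tip has unit variance.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames, in `tree$tip.label` order.
#' @export
relatedness_matrix <- function(tree, scale_to_unit_depth = FALSE) {
  validate_tree(tree)
  if (length(tree$tip.label) == 1L) {
    A <- matrix(sum(tree$edge.length), 1L, 1L,
                dimnames = list(tree$tip.label, tree$tip.label))
  } else {
    A <- ape::vcv(tree)
    A <- A[tree$tip.label, tree$tip.label, drop = FALSE]
  }
  if (max(diag(A)) <= 0)
    stop("all branch lengths are zero; relatedness matrix would be all-zero",
         call. = FALSE)
  if (scale_to_unit_depth) A <- A / max(diag(A))
  A
}

#' Export a relatedness matrix as labelled CSV
#'
#' @param A Matrix from [relatedness_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_relatedness <- function(A, path) {
  df <- data.frame(strain = rownames(A), A, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Induced subtree on a set of tips
#'
#' Drops all tips not in `keep`, suppressing the resulting degree-2 nodes
#' (their branch lengths are summed), so patristic distances among kept
#' tips are unchanged.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A `"phylo"` object on the kept tips.
#' @export
drop_tips <- function(tree, keep) {
  validate_tree(tree)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(keep) < 2L)
    stop("a subtree needs at least 2 tips; got ", length(keep), call. = FALSE)
  ape::keep.tip(tree, keep)
}

#' Patristic distance between two tips
#'
#' Summed branch length along the path between tips `a` and `b`. Used as
#' the distance-from-propagation-host fixed covariate in [fit_phylo_mm()].
#'
#' @param tree A `"phylo"` object.
#' @param a,b Tip labels.
#' @return A single non-negative number.
#' @export
patristic_distance <- function(tree, a, b) {
  validate_tree(tree)
  unknown <- setdiff(c(a, b), tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (a == b) return(0)
  D <- stats::cophenetic(tree)
  D[a, b]
}

#' Patristic distances from one tip to all tips
#'
#' @param tree A `"phylo"` object.
#' @param from Tip label to measure from (e.g. the phage propagation host).
#' @return A named numeric vector over `tree$tip.label` (0 for `from`).
#' @export
patristic_distances_from <- function(tree, from) {
  validate_tree(tree)
  if (!from %in% tree$tip.label)
    stop("unknown tip label(s): ", from, call. = FALSE)
  D <- stats::cophenetic(tree)
  D[from, tree$tip.label]
}

#' Check that a trait table and a tree refer to the same strains
#'
#' @param traits A trait table with a `strain` column.
#' @param tree A `"phylo"` object.
#' @return Invisibly, a list with `missing_from_tree` and
#'   `missing_from_traits` character vectors; errors if strains in the
#'   traits are absent from the tree.
#' @export
validate_panel <- function(traits, tree) {
  s_tr <- unique(as.character(traits$strain))
  miss_tree <- setdiff(s_tr, tree$tip.label)
  miss_traits <- setdiff(tree$tip.label, s_tr)
  if (length(miss_tree) > 0)
    stop("strain(s) absent from the tree: ",
         paste(miss_tree, collapse = ", "), call. = FALSE)
  invisible(list(missing_from_tree = miss_tree,
                 missing_from_traits = miss_traits))
}
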