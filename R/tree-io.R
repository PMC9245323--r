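#' Parse a Newick string into a phylogenetic tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' `ape` `phylo` object, the container used throughout the package. Beyond
#' parsing, this checks the contracts the downstream analyses rely on:
#' branch lengths must be present and non-negative, and tip labels unique.
#'
#' @param text Newick string (single tree, terminated by `;`). Comments in
#'   square brackets are ignored.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text) # strip comments
  if (!grepl(";", text)) stop("Newick string must end with ';'")
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(tr)) {
    # locate the first unbalanced token for a useful message
    chars <- strsplit(text, "")[[1]]
    depth <- cumsum((chars == "(") - (chars == ")"))
    bad <- which(depth < 0)[1]
    where <- if (!is.na(bad)) paste0(" near character ", bad, " ('", chars[bad], "')")
             else ""
    stop("Newick parse error: unbalanced parentheses", where)
  }
  validate_tree(tr)
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  validate_tree(tree)
  ape::write.tree(tree, digits = digits)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; all analyses require them")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and non-missing")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  invisible(tree)
}

#' Root-to-tip depths of every node
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over node ids (tips first), depth from the root.
#' @export
node_depths <- function(tree) {
  validate_tree(tree)
  ape::node.depth.edgelength(tree)
}

#' Is the tree ultrametric within an absolute tolerance?
#'
#' All tips must be equidistant from the root: returns `TRUE` iff the spread
#' (max minus min) of root-to-tip path lengths is at most `tol`.
#'
#' @param tree A `phylo` object.
#' @param tol Absolute tolerance on the tip-depth spread.
#' @return Logical scalar.
#' @examples
#' check_ultrametric(parse_newick("((A:1,B:1):1,C:2);"))
#' check_ultrametric(parse_newick("((A:1,B:2):1,C:2);"))
#' @export
check_ultrametric <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol
}

#' Rescale a tree so its maximum root-to-tip depth equals `depth`
#'
#' @param tree A `phylo` object.
#' @param depth Target depth (default 1, the fixed-root calibration used
#'   throughout the package).
#' @return Rescaled `phylo`.
#' @export
rescale_tree_depth <- function(tree, depth = 1) {
  validate_tree(tree)
  cur <- max(node_depths(tree))
  if (cur <= 0) stop("tree has zero depth")
  tree$edge.length <- tree$edge.length * (depth / cur)
  tree
}
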