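#' Phylogenetic covariance matrix
#'
#' Entry (i, j) is the depth of the most recent common ancestor of tips i and
#' j, i.e. the shared root-to-tip path length, the Brownian-motion trait
#' covariance implied by the tree. Rows and columns are named by tip label;
#' every consumer in this package aligns data by label, never by position.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Square numeric matrix with tip-label dimnames and attributes
#'   `lambda` (1) and `standardized` (`FALSE`).
#' @examples
#' phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  # star trees (a single basal polytomy) count as rooted here
  if (!ape::is.rooted(tree) && tree$Nnode > 1) stop("tree must be rooted")
  C <- ape::vcv.phylo(tree)
  attr(C, "lambda") <- 1
  attr(C, "standardized") <- FALSE
  C
}

#' Pagel's lambda transform and determinant standardization
#'
#' Multiplies the off-diagonal entries of a phylogenetic covariance matrix by
#' `lambda` in `[0, 1]` (0 = star phylogeny, 1 = full Brownian structure),
#' optionally followed by division by `det(C)^(1/n)` so the result has unit
#' determinant — the standardization used before inverting the matrix into a
#' phylogenetic precision matrix in the spatial-phylogenetic model.
#'
#' The lambda transform is only defined here on covariances of ultrametric
#' trees (constant diagonal up to `1e-6`); on non-ultrametric trees the
#' diagonal-preserving transform is ill-posed.
#'
#' @param C Covariance matrix from [phylo_vcv()].
#' @param lambda Scalar in `[0, 1]`.
#' @param standardize Divide by `det^(1/n)` so the determinant becomes 1.
#' @return Transformed matrix, with `lambda`/`standardized` attributes set.
#' @export
transform_vcv <- function(C, lambda = 1, standardize = FALSE) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a scalar in [0, 1]")
  d <- diag(C)
  if (lambda != 1 && (max(d) - min(d)) > 1e-6 * max(d))
    stop("lambda transform requires an ultrametric tree (constant diagonal)")
  out <- C * lambda
  diag(out) <- d
  if (standardize) {
    ld <- determinant(out, logarithm = TRUE)
    if (ld$sign <= 0 || !is.finite(ld$modulus))
      stop("cannot standardize a singular covariance matrix")
    out <- out / exp(as.numeric(ld$modulus) / nrow(out))
    attr(out, "standardized") <- TRUE
  } else {
    attr(out, "standardized") <- FALSE
  }
  attr(out, "lambda") <- lambda
  dimnames(out) <- dimnames(C)
  out
}
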