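#' Equal-splits measure per tip
#'
#' For each tip, walk the path from the tip to the root; the j-th edge on the
#' path (the pendant edge is j = 1) contributes its length times
#' `(1/2)^(j - 1)`. The sum is the equal-splits (ES) measure, whose inverse
#' is the DR tip speciation-rate statistic. A root edge, if present, is not
#' part of the path.
#'
#' @param tree Rooted `phylo` with strictly positive branch lengths on the
#'   pendant edges.
#' @return Named numeric vector of ES values, one per tip.
#' @examples
#' equal_splits_measure(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
equal_splits_measure <- function(tree) {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  parent <- integer(max(tree$edge))
  plen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  pend <- plen[seq_len(ntip)]
  if (any(pend <= 0))
    stop("zero-length pendant edge: ES undefined for tip(s) ",
         paste(tree$tip.label[pend <= 0], collapse = ", "))
  es <- vapply(seq_len(ntip), function(tip) {
    node <- tip
    w <- 1
    s <- 0
    while (node != root) {
      s <- s + plen[node] * w
      w <- w / 2
      node <- parent[node]
    }
    s
  }, numeric(1))
  names(es) <- tree$tip.label
  es
}

#' DR tip speciation-rate statistic
#'
#' The DR statistic is the inverse of the equal-splits measure: tips
#' subtended by many short, recent branches get high values. The natural log
#' of DR is also returned, the scale on which it enters the regressions.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @return A data frame with columns `tip`, `es`, `dr` (= 1/es) and
#'   `log_dr` (natural log); attribute `log_base = "natural"`.
#' @export
dr_statistic <- function(tree) {
  es <- equal_splits_measure(tree)
  out <- data.frame(tip = names(es), es = unname(es), dr = 1 / unname(es),
                    log_dr = -log(unname(es)), stringsAsFactors = FALSE)
  attr(out, "log_base") <- "natural"
  out
}
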