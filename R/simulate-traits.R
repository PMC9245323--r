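#' Simulate a continuous trait under Brownian motion with Pagel's lambda
#'
#' Draws one realization from a multivariate normal with mean `root` and
#' covariance `sigma2 * C(lambda)`, where `C` is the Brownian tree covariance
#' and `C(lambda)` has its off-diagonal entries multiplied by `lambda`. With
#' `lambda = 0` the tip values are i.i.d.; with `lambda = 1` this is plain
#' Brownian motion. The lambda transform requires an ultrametric tree when
#' `lambda < 1`.
#'
#' @param tree Ultrametric `phylo` (non-ultrametric allowed only when
#'   `lambda = 1`).
#' @param sigma2 Brownian rate (> 0), variance per unit branch length.
#' @param lambda Phylogenetic-signal multiplier in `[0, 1]`.
#' @param root Root (mean) value.
#' @param seed Integer seed.
#' @return Named numeric vector over tips.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, lambda = 1, root = 0,
                              seed = NULL) {
  stopifnot(sigma2 > 0, lambda >= 0, lambda <= 1)
  if (lambda < 1 && !check_ultrametric(tree, tol = 1e-6))
    stop("lambda < 1 requires an ultrametric tree")
  if (!is.null(seed)) set.seed(seed)
  C <- transform_vcv(phylo_vcv(tree), lambda = lambda)
  L <- t(chol(sigma2 * C))
  x <- root + as.numeric(L %*% stats::rnorm(nrow(C)))
  names(x) <- rownames(C)
  x
}

#' Simulate a binary character under a 2-state Markov (Mk) model
#'
#' States evolve along branches under a continuous-time Markov chain with
#' gain rate `q01` (0 to 1) and loss rate `q10`. Node states are sampled
#' exactly from the closed-form 2x2 transition-probability matrix over each
#' branch length, which gives the exact marginal law of the tip states.
#'
#' @param tree `phylo` with branch lengths.
#' @param q01,q10 Transition rates (>= 0; both 0 only with a fixed root).
#' @param root_freq Probability the root is in state 1.
#' @param seed Integer seed.
#' @return Named integer (0/1) vector over tips.
#' @export
simulate_mk_character <- function(tree, q01, q10, root_freq = 0.5,
                                  seed = NULL) {
  validate_tree(tree)
  stopifnot(q01 >= 0, q10 >= 0, root_freq >= 0, root_freq <= 1)
  if (q01 == 0 && q10 == 0 && root_freq > 0 && root_freq < 1)
    stop("q01 = q10 = 0 requires a fixed root state (root_freq 0 or 1)")
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  st <- integer(nnode)
  root <- ntip + 1L
  st[root] <- stats::rbinom(1, 1, root_freq)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edge))) {
    p1 <- mk_transition_prob(st[edge[e, 1]], elen[e], q01, q10)
    st[edge[e, 2]] <- stats::rbinom(1, 1, p1)
  }
  out <- st[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}

# P(state 1 after time t | start state), closed form for the 2-state chain
mk_transition_prob <- function(start, t, q01, q10) {
  q <- q01 + q10
  if (q == 0) return(as.numeric(start))
  pi1 <- q01 / q
  if (start == 1L) pi1 + (1 - pi1) * exp(-q * t) else pi1 * (1 - exp(-q * t))
}

#' Log-likelihood of a binary tip pattern under the Mk model
#'
#' Felsenstein pruning with the closed-form 2x2 transition matrix. Used to
#' calibrate the FiSSE null-character rate by maximum likelihood.
#'
#' @param tree `phylo`.
#' @param states Named 0/1 vector over tips.
#' @param q01,q10 Transition rates.
#' @param root_treatment `"stationary"` (weights from the stationary
#'   distribution), `"flat"` (1/2 each), or `"madfitz"` (weights
#'   proportional to the conditional likelihoods).
#' @return Log-likelihood.
#' @export
mk_loglik <- function(tree, states, q01, q10,
                      root_treatment = c("stationary", "flat", "madfitz")) {
  root_treatment <- match.arg(root_treatment)
  validate_tree(tree)
  states <- align_states(tree, states)
  ntip <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  L <- matrix(0, nnode, 2)
  L[cbind(seq_len(ntip), states + 1L)] <- 1
  tr <- ape::reorder.phylo(tree, "postorder")
  partial_done <- c(rep(TRUE, ntip), rep(FALSE, nnode - ntip))
  L[(ntip + 1):nnode, ] <- 1
  logcomp <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    t <- tr$edge.length[e]
    p1from0 <- mk_transition_prob(0L, t, q01, q10)
    p1from1 <- mk_transition_prob(1L, t, q01, q10)
    P <- rbind(c(1 - p1from0, p1from0), c(1 - p1from1, p1from1))
    contrib <- as.numeric(P %*% L[ch, ])
    L[par, ] <- L[par, ] * contrib
    sc <- sum(L[par, ])
    if (sc <= 0) return(-Inf)
    L[par, ] <- L[par, ] / sc
    logcomp <- logcomp + log(sc)
  }
  root <- tr$edge[nrow(tr$edge), 1]
  w <- switch(root_treatment,
    stationary = {
      q <- q01 + q10
      if (q == 0) c(0.5, 0.5) else c(q10, q01) / q
    },
    flat = c(0.5, 0.5),
    madfitz = {
      s <- sum(L[root, ])
      if (s > 0) L[root, ] / s else c(0.5, 0.5)
    })
  val <- sum(w * L[root, ])
  if (val <= 0) return(-Inf)
  log(val) + logcomp
}

align_states <- function(tree, states) {
  if (is.null(names(states)))
    stop("tip states must be a named vector (names = tip labels)")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("missing tip state for: ", paste(utils::head(miss, 5), collapse = ", "))
  st <- states[tree$tip.label]
  if (!all(st %in% c(0, 1))) stop("tip states must be 0/1")
  as.integer(st)
}
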