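#' @useDynLib rangediv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Generic k-state SSE log-likelihood. `obs_map` maps each observed tip state
# (as character) to the indices of compatible latent states; tips are
# initialized ambiguously over those states. Root treatments: "madfitz"
# weights root states by their conditional likelihoods; "flat" weights them
# equally. `condition_survival` divides by the probability that both root
# lineages survive and speciate.
sse_loglik_generic <- function(tree, states, lambda, mu, Q, obs_map,
                               root_treatment = c("madfitz", "flat"),
                               condition_survival = FALSE,
                               reltol = 1e-8, abstol = 1e-10) {
  root_treatment <- match.arg(root_treatment)
  validate_tree(tree)
  if (!check_ultrametric(tree, tol = 1e-6))
    stop("SSE likelihoods require an ultrametric tree")
  if (any(lambda < 0) || any(mu < 0) || any(Q[row(Q) != col(Q)] < 0))
    stop("rates must be non-negative")
  k <- length(lambda)
  ntip <- ape::Ntip(tree)
  if (is.null(names(states))) stop("tip states must be named")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("missing tip state for: ", paste(utils::head(miss, 5), collapse = ", "))
  st <- as.character(states[tree$tip.label])
  bad <- setdiff(unique(st), names(obs_map))
  if (length(bad)) stop("unknown observed state(s): ", paste(bad, collapse = ", "))
  tipD <- matrix(0, ntip, k)
  for (i in seq_len(ntip)) tipD[i, obs_map[[st[i]]]] <- 1
  tr <- ape::reorder.phylo(tree, "postorder")
  res <- sse_loglik_cpp(tr$edge, tr$edge.length, ntip, tipD,
                        as.numeric(lambda), as.numeric(mu),
                        matrix(as.numeric(Q), k, k), reltol, abstol)
  D <- res$D
  E <- res$E
  w <- if (root_treatment == "madfitz") {
    s <- sum(D)
    if (s <= 0) return(-Inf)
    D / s
  } else rep(1 / k, k)
  L <- sum(w * D)
  if (condition_survival) {
    denom <- sum(w * lambda * (1 - E)^2)
    if (denom <= 0) return(-Inf)
    L <- L / denom
  }
  if (L <= 0) return(-Inf)
  log(L) + res$logcomp
}

#' BiSSE log-likelihood
#'
#' Joint likelihood of an ultrametric tree and binary tip states under the
#' binary state-dependent speciation-extinction model. Along each branch the
#' coupled extinction/conditional-likelihood ODEs are integrated with an
#' adaptive embedded Runge-Kutta 4(5) scheme (relative tolerance 1e-8);
#' daughters are combined with the state's speciation rate at each node.
#' Zero-length branches are collapsed to 1e-9 inside the integration only.
#'
#' @param tree Ultrametric `phylo`.
#' @param states Named 0/1 vector over tips.
#' @param pars Named vector/list: `lambda0`, `lambda1`, `mu0`, `mu1`,
#'   `q01`, `q10`.
#' @param root_treatment `"madfitz"` (default: root states weighted by their
#'   conditional likelihoods) or `"flat"`.
#' @param condition_survival Condition on survival of both root lineages
#'   (default `FALSE`).
#' @param reltol,abstol Integrator tolerances.
#' @return Log-likelihood (scalar).
#' @export
bisse_loglik <- function(tree, states, pars,
                         root_treatment = c("madfitz", "flat"),
                         condition_survival = FALSE,
                         reltol = 1e-8, abstol = 1e-10) {
  pars <- unlist(pars)
  need <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
  if (!all(need %in% names(pars)))
    stop("pars must contain ", paste(need, collapse = ", "))
  Q <- matrix(c(0, pars[["q01"]], pars[["q10"]], 0), 2, 2, byrow = TRUE)
  sse_loglik_generic(tree, states,
                     lambda = c(pars[["lambda0"]], pars[["lambda1"]]),
                     mu = c(pars[["mu0"]], pars[["mu1"]]), Q = Q,
                     obs_map = list(`0` = 1L, `1` = 2L),
                     root_treatment = match.arg(root_treatment),
                     condition_survival = condition_survival,
                     reltol = reltol, abstol = abstol)
}

# latent-state bookkeeping for the 4-state hidden model (order 0A, 1A, 0B, 1B)
hisse_state_names <- c("0A", "1A", "0B", "1B")
hisse_obs_map <- list(`0` = c(1L, 3L), `1` = c(2L, 4L))
# transitions changing observed and hidden state simultaneously are forbidden
hisse_forbidden <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2))

#' HiSSE log-likelihood
#'
#' Four-state pruning over latent states 0A, 1A, 0B, 1B: each observed tip
#' state is ambiguous over its two hidden completions. The transition matrix
#' must have structural zeros for simultaneous observed-and-hidden changes
#' (0A-1B and 1A-0B). With hidden states tied (equal rates and symmetric
#' hidden transitions) this reduces exactly to [bisse_loglik()].
#'
#' @param tree Ultrametric `phylo`.
#' @param states Named observed 0/1 vector over tips.
#' @param pars List with `lambda` (length 4), `mu` (length 4), and `Q`
#'   (4x4 off-diagonal rates, order 0A, 1A, 0B, 1B).
#' @inheritParams bisse_loglik
#' @return Log-likelihood (scalar).
#' @export
hisse_loglik <- function(tree, states, pars,
                         root_treatment = c("madfitz", "flat"),
                         condition_survival = FALSE,
                         reltol = 1e-8, abstol = 1e-10) {
  stopifnot(length(pars$lambda) == 4, length(pars$mu) == 4,
            is.matrix(pars$Q), all(dim(pars$Q) == 4))
  if (any(pars$Q[hisse_forbidden] != 0))
    stop("Q must have structural zeros for simultaneous observed+hidden changes")
  sse_loglik_generic(tree, states, lambda = pars$lambda, mu = pars$mu,
                     Q = pars$Q, obs_map = hisse_obs_map,
                     root_treatment = match.arg(root_treatment),
                     condition_survival = condition_survival,
                     reltol = reltol, abstol = abstol)
}
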