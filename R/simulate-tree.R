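#' Simulate a constant-rate birth-death tree, rescaled to depth 1
#'
#' Wraps [ape::rphylo()] (constant-rate birth-death conditioned on the number
#' of extant tips) and rescales the result so the root-to-tip depth is
#' exactly 1, the fixed-root calibration every analysis in this package
#' assumes. Reported rates are therefore in units of the rescaled tree depth.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth Speciation rate (> death).
#' @param death Extinction rate (>= 0).
#' @param seed Integer seed; every simulator in this package is reproducible
#'   bit-for-bit under a fixed seed.
#' @param max_tries Attempts before giving up on non-viable parameters.
#' @return Ultrametric `phylo` with `n_tips` tips, depth 1, tip labels
#'   `t1..tn`.
#' @export
simulate_bd_tree <- function(n_tips, birth, death = 0, seed = NULL,
                             max_tries = 100) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0)
  if (birth <= death)
    stop("non-viable parameters: birth must exceed death for the process ",
         "to reach ", n_tips, " tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- NULL
  for (i in seq_len(max_tries)) {
    tr <- tryCatch(ape::rphylo(n_tips, birth = birth, death = death,
                               fossils = FALSE),
                   error = function(e) NULL)
    if (!is.null(tr) && ape::Ntip(tr) == n_tips) break
    tr <- NULL
  }
  if (is.null(tr))
    stop("birth-death simulation failed after ", max_tries, " attempts")
  tr$tip.label <- paste0("t", seq_len(n_tips))
  rescale_tree_depth(tr, 1)
}

#' Simulate tree and binary character jointly under a BiSSE process
#'
#' Event-driven (Gillespie) forward simulation of a binary state-dependent
#' birth-death process: each extant lineage in state s speciates at rate
#' `lambda[s+1]`, goes extinct at rate `mu[s+1]`, and flips state at rate
#' `q01`/`q10`. The simulation runs until `n_tips` extant lineages exist,
#' restarts (up to `max_retries`) on total extinction, and the surviving tree
#' is rescaled to depth 1. Rates interpreted on the original time scale; the
#' depth rescaling factor is recorded in attribute `time_scale` so rates can
#' be mapped to rescaled units (multiply by `time_scale`).
#'
#' @param pars Named list or vector with `lambda0`, `lambda1`, `mu0`, `mu1`,
#'   `q01`, `q10` (all >= 0, at least one speciation rate > 0).
#' @param n_tips Number of extant tips to stop at.
#' @param seed Integer seed.
#' @param root_state Starting state (0 or 1).
#' @param require_both_states Restart until both states occur among tips
#'   (bounded by `max_retries`).
#' @param max_retries Maximum restarts on extinction/monomorphism.
#' @return List with `tree` (`phylo`, depth 1) and `states` (named 0/1
#'   integer vector over tips).
#' @export
simulate_sse_tree <- function(pars, n_tips, seed = NULL, root_state = 0L,
                              require_both_states = FALSE, max_retries = 100) {
  pars <- unlist(pars)
  need <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
  if (!all(need %in% names(pars)))
    stop("pars must contain ", paste(need, collapse = ", "))
  p <- pars[need]
  if (any(p < 0)) stop("all rates must be >= 0")
  if (p[["lambda0"]] <= 0 && p[["lambda1"]] <= 0)
    stop("at least one speciation rate must be positive")
  stopifnot(n_tips >= 2, root_state %in% c(0L, 1L))
  if (!is.null(seed)) set.seed(seed)

  lam <- c(p[["lambda0"]], p[["lambda1"]])
  mu <- c(p[["mu0"]], p[["mu1"]])
  qq <- c(p[["q01"]], p[["q10"]]) # rate out of state 0, out of state 1

  for (attempt in seq_len(max_retries)) {
    sim <- gillespie_bisse_once(lam, mu, qq, n_tips, root_state)
    if (is.null(sim)) next
    if (require_both_states && length(unique(sim$states)) < 2L) next
    scale <- max(node_depths(sim$tree))
    tree <- rescale_tree_depth(sim$tree, 1)
    attr(tree, "time_scale") <- scale
    return(list(tree = tree, states = sim$states))
  }
  stop("state-dependent simulation failed after ", max_retries,
       " attempts (total extinction or single-state outcomes)")
}

# one forward Gillespie run; returns NULL on extinction before reaching n_tips
gillespie_bisse_once <- function(lam, mu, qq, n_tips, root_state) {
  # lineage bookkeeping: each active lineage has a state and an origin time
  max_nodes <- 8L * n_tips + 16L
  anc <- integer(0)          # parent lineage id per lineage
  born <- numeric(0)         # birth time per lineage
  died <- numeric(0)         # death/speciation time (NA while active)
  state <- integer(0)
  is_split <- logical(0)     # TRUE if lineage ended by speciation
  new_lineage <- function(parent, t0, s) {
    anc[length(anc) + 1L] <<- parent
    born[length(born) + 1L] <<- t0
    died[length(died) + 1L] <<- NA_real_
    state[length(state) + 1L] <<- s
    is_split[length(is_split) + 1L] <<- FALSE
    length(anc)
  }
  # two daughters of a virtual root so the crown is at time 0
  new_lineage(0L, 0, root_state)
  new_lineage(0L, 0, root_state)
  active <- c(1L, 2L)
  t <- 0
  repeat {
    ns <- c(sum(state[active] == 0L), sum(state[active] == 1L))
    rates <- c(lam * ns, mu * ns, qq * ns)
    tot <- sum(rates)
    if (length(active) == n_tips) {
      # stop just before the next event so pendant edges stay positive
      dt <- if (tot > 0) stats::rexp(1, tot) else 1
      died[active] <- t + dt
      return(build_phylo_from_lineages(anc, born, died, state, is_split,
                                       active))
    }
    if (tot <= 0) return(NULL) # frozen process cannot reach n_tips
    t <- t + stats::rexp(1, tot)
    ev <- sample.int(6L, 1L, prob = rates / tot)
    s <- if (ev %in% c(1L, 3L, 5L)) 0L else 1L
    cand <- active[state[active] == s]
    lin <- if (length(cand) == 1L) cand else sample(cand, 1L)
    if (ev <= 2L) { # speciation
      died[lin] <- t
      is_split[lin] <- TRUE
      d1 <- new_lineage(lin, t, s)
      d2 <- new_lineage(lin, t, s)
      active <- c(setdiff(active, lin), d1, d2)
      if (length(active) > max_nodes) return(NULL)
    } else if (ev <= 4L) { # extinction
      died[lin] <- t
      active <- setdiff(active, lin)
      if (length(active) == 0L) return(NULL)
    } else { # state flip
      state[lin] <- 1L - s
    }
  }
}

# assemble an ape tree from the lineage records, pruning extinct lineages.
# The full tree (extinct tips included) is built first, then extinct tips
# are removed with ape::drop.tip, which also collapses single-child nodes.
build_phylo_from_lineages <- function(anc, born, died, state, is_split,
                                      surviving) {
  n <- length(anc)
  tips <- which(!is_split)
  internals <- which(is_split)
  ntip <- length(tips)
  tip_id <- integer(n)
  tip_id[tips] <- seq_len(ntip)
  node_id <- integer(n)
  node_id[internals[order(born[internals])]] <- ntip + 1L + seq_along(internals)
  root_id <- ntip + 1L # crown node joining the two initial lineages
  parent_of <- function(i) if (anc[i] == 0L) root_id else node_id[anc[i]]
  edge <- matrix(0L, nrow = n, ncol = 2)
  elen <- numeric(n)
  for (i in seq_len(n)) {
    edge[i, 1] <- parent_of(i)
    edge[i, 2] <- if (is_split[i]) node_id[i] else tip_id[i]
    elen[i] <- died[i] - born[i]
  }
  tree <- list(edge = edge, edge.length = elen,
               tip.label = paste0("L", tips), Nnode = length(internals) + 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  extinct <- setdiff(tips, surviving)
  if (length(extinct))
    tree <- ape::drop.tip(tree, paste0("L", extinct))
  st <- state[as.integer(sub("^L", "", tree$tip.label))]
  tree$tip.label <- paste0("t", seq_along(tree$tip.label))
  names(st) <- tree$tip.label
  list(tree = tree, states = st)
}
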