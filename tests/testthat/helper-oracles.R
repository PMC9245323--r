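# Independent oracles used across the suite. Each reimplements a quantity by
# a different route than the package (closed forms, enumeration, or a
# different library code path), so agreement is evidence, not tautology.

# equal-splits by an explicit node-path walk through ape::nodepath
oracle_equal_splits <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  el <- numeric(max(tree$edge))
  el[tree$edge[, 2]] <- tree$edge.length
  vapply(seq_len(ntip), function(tip) {
    path <- rev(ape::nodepath(tree, root, tip)) # tip ... root
    edges <- path[-length(path)]                # nodes with a parent edge
    sum(el[edges] * 0.5^(seq_along(edges) - 1))
  }, numeric(1))
}

# Brownian covariance by brute-force MRCA depth per pair
oracle_vcv <- function(tree) {
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  M <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      m <- if (i == j) i else ape::getMRCA(tree, c(i, j))
      M[i, j] <- depth[m]
    }
  }
  M
}

# constant-rate birth-death log-likelihood from the closed-form solution of
# the pruning ODEs (unconditioned, speciation factor at every internal node)
oracle_bd_loglik <- function(tree, lambda, mu) {
  r <- lambda - mu
  stopifnot(r > 0)
  phi <- function(t) exp(-r * t) * ((lambda - mu) / (lambda - mu * exp(-r * t)))^2
  depth <- ape::node.depth.edgelength(tree)
  present <- max(depth[seq_len(ape::Ntip(tree))])
  ll <- 0
  for (e in seq_len(nrow(tree$edge))) {
    t_child <- present - depth[tree$edge[e, 2]]
    t_parent <- present - depth[tree$edge[e, 1]]
    ll <- ll + log(phi(t_parent) / phi(t_child))
  }
  ll + (ape::Ntip(tree) - 1) * log(lambda)
}

# binary Mk log-likelihood by matrix-exponential pruning (Matrix::expm),
# independent of the package's closed-form transition probabilities
oracle_mk_loglik <- function(tree, states, q01, q10,
                             root_treatment = "flat") {
  Qm <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  ntip <- ape::Ntip(tree)
  nn <- max(tree$edge)
  L <- matrix(1, nn, 2)
  L[seq_len(ntip), ] <- 0
  st <- states[tree$tip.label]
  L[cbind(seq_len(ntip), as.integer(st) + 1L)] <- 1
  tr <- ape::reorder.phylo(tree, "postorder")
  logcomp <- 0
  for (e in seq_len(nrow(tr$edge))) {
    P <- as.matrix(Matrix::expm(Qm * tr$edge.length[e]))
    contrib <- as.numeric(P %*% L[tr$edge[e, 2], ])
    L[tr$edge[e, 1], ] <- L[tr$edge[e, 1], ] * contrib
    sc <- sum(L[tr$edge[e, 1], ])
    L[tr$edge[e, 1], ] <- L[tr$edge[e, 1], ] / sc
    logcomp <- logcomp + log(sc)
  }
  root <- tr$edge[nrow(tr$edge), 1]
  w <- switch(root_treatment,
    flat = c(0.5, 0.5),
    stationary = if (q01 + q10 == 0) c(0.5, 0.5)
                 else c(q10, q01) / (q01 + q10),
    madfitz = L[root, ] / sum(L[root, ]))
  log(sum(w * L[root, ])) + logcomp
}

# enumerate tip-pattern probabilities of the 2-state Mk process on a small
# tree by summing over all interior-node state assignments
oracle_mk_pattern_probs <- function(tree, q01, q10, root_freq) {
  Qm <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  root <- ntip + 1L
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Qm * tree$edge.length[e])))
  patterns <- expand.grid(rep(list(0:1), ntip))
  probs <- numeric(nrow(patterns))
  interior <- expand.grid(rep(list(0:1), nint))
  for (pi in seq_len(nrow(patterns))) {
    tipst <- as.integer(patterns[pi, ])
    tot <- 0
    for (ii in seq_len(nrow(interior))) {
      intst <- as.integer(interior[ii, ])
      stateof <- function(node)
        if (node <= ntip) tipst[node] else intst[node - ntip]
      pr <- if (stateof(root) == 1) root_freq else 1 - root_freq
      for (e in seq_len(nrow(tree$edge))) {
        a <- stateof(tree$edge[e, 1])
        b <- stateof(tree$edge[e, 2])
        pr <- pr * Pm[[e]][a + 1, b + 1]
      }
      tot <- tot + pr
    }
    probs[pi] <- tot
  }
  list(patterns = as.matrix(patterns), probs = probs)
}

# Pybus-Harvey gamma from internode intervals (closed form)
oracle_gamma_stat <- function(tree) {
  n <- ape::Ntip(tree)
  bt <- sort(ape::branching.times(tree), decreasing = TRUE)
  g <- c(-diff(c(bt, 0))) # interval with k = 2..n lineages
  k <- 2:n
  T <- sum(k * g)
  inner <- cumsum(k * g)[1:(n - 2)]
  (mean(inner) - T / 2) / (T * sqrt(1 / (12 * (n - 2))))
}

# unrooted bipartition set for topology comparison
oracle_bipartitions <- function(tree) {
  ntip <- ape::Ntip(tree)
  labs <- sort(tree$tip.label)
  bp <- ape::prop.part(tree)
  sets <- lapply(bp, function(ix) sort(tree$tip.label[ix]))
  keep <- vapply(sets, function(s)
    length(s) > 1 && length(s) < ntip, logical(1))
  canon <- lapply(sets[keep], function(s) {
    comp <- setdiff(labs, s)
    if (paste(s, collapse = "|") < paste(comp, collapse = "|")) s else comp
  })
  sort(vapply(canon, paste, "", collapse = "|"))
}
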