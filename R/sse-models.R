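# Constrained SSE model specifications. A spec ties every rate of a k-state
# model to a free-parameter index (0 = structural zero), so one vector of
# free parameters determines lambda, mu and Q. Index maps double as the
# constraint record: two rates with the same index are constrained equal.

make_sse_spec <- function(name, lam_idx, mu_idx, q_idx, obs_map,
                          state_names = NULL, class_label = "hisse") {
  k <- length(lam_idx)
  stopifnot(length(mu_idx) == k, all(dim(q_idx) == k))
  diag(q_idx) <- 0L
  idx_all <- c(lam_idx, mu_idx, q_idx[q_idx > 0])
  used <- sort(unique(idx_all))
  if (!identical(used, seq_along(used)))
    stop("spec '", name, "': parameter indices must be 1..k with no gaps")
  spec <- list(name = name, nstates = k, lam_idx = as.integer(lam_idx),
               mu_idx = as.integer(mu_idx), q_idx = q_idx,
               obs_map = obs_map, state_names = state_names,
               n_free = length(used), class_label = class_label)
  class(spec) <- "sse_spec"
  spec
}

#' @export
print.sse_spec <- function(x, ...) {
  cat(sprintf("SSE model spec '%s' (%s): %d states, %d free parameters\n",
              x$name, x$class_label, x$nstates, x$n_free))
  invisible(x)
}

# expand free parameters (natural scale) into lambda/mu/Q
sse_spec_pars <- function(spec, theta) {
  stopifnot(length(theta) == spec$n_free)
  lambda <- theta[spec$lam_idx]
  mu <- theta[spec$mu_idx]
  Q <- matrix(0, spec$nstates, spec$nstates)
  pos <- spec$q_idx > 0
  Q[pos] <- theta[spec$q_idx[pos]]
  list(lambda = lambda, mu = mu, Q = Q)
}

# validate a spec's constraint map (used by tests and make_model_set)
validate_sse_spec <- function(spec) {
  stopifnot(inherits(spec, "sse_spec"))
  th <- seq_len(spec$n_free) + 0.5
  p <- sse_spec_pars(spec, th)
  stopifnot(all(p$lambda > 0), all(p$mu > 0 | spec$mu_idx > 0),
            all(diag(p$Q) == 0))
  # every observed state must map to valid latent states
  stopifnot(all(unlist(spec$obs_map) %in% seq_len(spec$nstates)))
  invisible(TRUE)
}

bisse_spec <- function(name = "bisse_full") {
  make_sse_spec(name,
                lam_idx = c(1L, 2L), mu_idx = c(3L, 4L),
                q_idx = matrix(c(0L, 5L, 6L, 0L), 2, 2, byrow = TRUE),
                obs_map = list(`0` = 1L, `1` = 2L),
                state_names = c("0", "1"), class_label = "bisse")
}

# 4-state HiSSE index helpers (state order 0A, 1A, 0B, 1B)
hisse_q_idx <- function(structure, base) {
  Q <- matrix(0L, 4, 4)
  obs_cells <- rbind(c(1, 2), c(2, 1), c(3, 4), c(4, 3))   # observed flips
  hid_cells <- rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))   # hidden flips
  if (structure == "equal") {
    Q[obs_cells] <- base + 1L
    Q[hid_cells] <- base + 1L
    n <- 1L
  } else if (structure == "two") {
    Q[obs_cells] <- base + 1L
    Q[hid_cells] <- base + 2L
    n <- 2L
  } else if (structure == "obsasym") {
    Q[rbind(c(1, 2), c(3, 4))] <- base + 1L # 0 -> 1
    Q[rbind(c(2, 1), c(4, 3))] <- base + 2L # 1 -> 0
    Q[hid_cells] <- base + 3L
    n <- 3L
  } else if (structure == "free") {
    Q[obs_cells] <- base + 1:4
    Q[hid_cells] <- base + 5:8
    n <- 8L
  } else stop("unknown q structure: ", structure)
  list(Q = Q, n = n)
}

#' Build the 20-model state-dependent diversification set
#'
#' Returns the full model battery: 16 hidden-state (HiSSE) variants in which
#' speciation depends on the observed character, crossed over speciation
#' structure (all four latent states free, or hidden heterogeneity only on
#' observed state 1), extinction structure (single rate or four free rates)
#' and transition-rate structure (all equal; observed vs hidden two-rate;
#' asymmetric observed plus hidden; all eight free) -- plus four
#' character-independent null models: two CID-2 variants (speciation depends
#' only on a two-level hidden state; parameter count matched to the plain
#' binary model) and two CID-4 variants (eight latent states, speciation
#' depending only on a four-level hidden factor).
#'
#' @param kind Only `"hisse_binary"` is defined.
#' @return Named list of 20 `sse_spec` objects.
#' @export
make_model_set <- function(kind = "hisse_binary") {
  if (!identical(kind, "hisse_binary")) stop("unknown model-set kind: ", kind)
  specs <- list()
  for (lam in c("full", "hid1")) {
    for (mus in c("equal", "free")) {
      for (qs in c("equal", "two", "obsasym", "free")) {
        lam_idx <- if (lam == "full") c(1L, 2L, 3L, 4L) else c(1L, 2L, 1L, 3L)
        nl <- max(lam_idx)
        mu_idx <- if (mus == "equal") rep(nl + 1L, 4) else nl + c(1L, 2L, 3L, 4L)
        nm <- max(mu_idx)
        qq <- hisse_q_idx(qs, nm)
        name <- paste0("hisse_lam.", lam, "_mu.", mus, "_q.", qs)
        specs[[name]] <- make_sse_spec(name, lam_idx, mu_idx, qq$Q,
                                       hisse_obs_map, hisse_state_names,
                                       class_label = "hisse")
      }
    }
  }
  # CID-2: speciation tied to the hidden state only; k = 6 matches BiSSE
  q1 <- matrix(0L, 4, 4)
  q1[rbind(c(1, 2), c(2, 1), c(3, 4), c(4, 3))] <- 5L
  q1[rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))] <- 6L
  specs[["cid2_a"]] <- make_sse_spec("cid2_a",
    lam_idx = c(1L, 1L, 2L, 2L), mu_idx = c(3L, 3L, 4L, 4L), q_idx = q1,
    obs_map = hisse_obs_map, state_names = hisse_state_names,
    class_label = "cid")
  q2 <- matrix(0L, 4, 4)
  q2[rbind(c(1, 2), c(3, 4))] <- 4L # 0 -> 1
  q2[rbind(c(2, 1), c(4, 3))] <- 5L # 1 -> 0
  q2[rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))] <- 6L
  specs[["cid2_b"]] <- make_sse_spec("cid2_b",
    lam_idx = c(1L, 1L, 2L, 2L), mu_idx = c(3L, 3L, 3L, 3L), q_idx = q2,
    obs_map = hisse_obs_map, state_names = hisse_state_names,
    class_label = "cid")
  # CID-4: 8 latent states (observed 0/1 x hidden A-D); speciation depends
  # on the hidden factor only. State order: 0A,1A,0B,1B,0C,1C,0D,1D.
  cid4 <- function(name, mu_equal) {
    lam_idx <- c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L)
    mu_idx <- if (mu_equal) rep(5L, 8) else 4L + c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L)
    base <- max(mu_idx)
    Q <- matrix(0L, 8, 8)
    obs0 <- seq(1, 8, by = 2) # 0A,0B,0C,0D
    obs1 <- seq(2, 8, by = 2)
    for (h in 1:4) { # observed flips within each hidden level
      Q[obs0[h], obs1[h]] <- base + 1L
      Q[obs1[h], obs0[h]] <- base + 1L
    }
    for (h1 in 1:4) for (h2 in 1:4) {
      if (h1 == h2) next # hidden flips at a shared rate
      Q[obs0[h1], obs0[h2]] <- base + 2L
      Q[obs1[h1], obs1[h2]] <- base + 2L
    }
    om <- list(`0` = as.integer(obs0), `1` = as.integer(obs1))
    sn <- paste0(rep(c("0", "1"), 4), rep(c("A", "B", "C", "D"), each = 2))
    make_sse_spec(name, lam_idx, mu_idx, Q, om, sn, class_label = "cid")
  }
  specs[["cid4_a"]] <- cid4("cid4_a", mu_equal = FALSE)
  specs[["cid4_b"]] <- cid4("cid4_b", mu_equal = TRUE)
  specs
}
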