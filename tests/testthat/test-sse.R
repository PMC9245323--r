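random_tree_states <- function(n, seed, q = 1.5) {
  set.seed(seed)
  tr <- simulate_bd_tree(n, 3, 1)
  st <- simulate_mk_character(tr, q, q)
  if (length(unique(st)) < 2) return(random_tree_states(n, seed + 1000, q))
  list(tree = tr, states = st)
}

test_that("state-independent BiSSE factorizes into birth-death times Mk", {
  for (seed in 101:105) {
    s <- random_tree_states(10, seed)
    lam <- stats::runif(1, 1, 4)
    mu <- stats::runif(1, 0, 0.8 * lam)
    q <- stats::runif(1, 0.3, 2)
    ll <- bisse_loglik(s$tree, s$states,
                       c(lambda0 = lam, lambda1 = lam, mu0 = mu, mu1 = mu,
                         q01 = q, q10 = q), root_treatment = "flat")
    oracle <- oracle_bd_loglik(s$tree, lam, mu) +
      oracle_mk_loglik(s$tree, s$states, q, q, "flat")
    expect_equal(ll, oracle, tolerance = 1e-6)
  }
})

test_that("degenerate chain reduces BiSSE to the constant-rate birth-death likelihood", {
  s <- random_tree_states(12, 111)
  states0 <- stats::setNames(rep(0L, 12), s$tree$tip.label)
  ll <- bisse_loglik(s$tree, states0,
                     c(lambda0 = 2.5, lambda1 = 9, mu0 = 0.7, mu1 = 5,
                       q01 = 0, q10 = 0), root_treatment = "madfitz")
  expect_equal(ll, oracle_bd_loglik(s$tree, 2.5, 0.7), tolerance = 1e-6)
})

test_that("tightening the integrator tolerance leaves the likelihood stable", {
  s <- random_tree_states(30, 112)
  pars <- c(lambda0 = 2, lambda1 = 4, mu0 = 0.5, mu1 = 1, q01 = 0.8,
            q10 = 0.6)
  l1 <- bisse_loglik(s$tree, s$states, pars, reltol = 1e-8, abstol = 1e-10)
  l2 <- bisse_loglik(s$tree, s$states, pars, reltol = 5e-9, abstol = 5e-11)
  expect_lt(abs(l1 - l2), 1e-6)
})

test_that("likelihood is invariant to tip order and child rotation", {
  s <- random_tree_states(25, 113)
  pars <- c(lambda0 = 2, lambda1 = 4, mu0 = 0.5, mu1 = 1, q01 = 0.8,
            q10 = 0.6)
  base <- bisse_loglik(s$tree, s$states, pars)
  rotated <- ape::rotateConstr(s$tree, rev(s$tree$tip.label))
  expect_equal(bisse_loglik(rotated, s$states, pars), base, tolerance = 1e-7)
  shuffled <- s$states[sample(names(s$states))]
  expect_equal(bisse_loglik(s$tree, shuffled, pars), base, tolerance = 1e-12)
})

test_that("HiSSE with tied hidden states equals BiSSE", {
  for (seed in 121:123) {
    s <- random_tree_states(15, seed)
    lam <- c(1.5, 3)
    mu <- c(0.4, 0.7)
    q01 <- 1.1
    q10 <- 0.6
    qh <- 0.9
    Q4 <- matrix(0, 4, 4)
    Q4[1, 2] <- Q4[3, 4] <- q01
    Q4[2, 1] <- Q4[4, 3] <- q10
    Q4[1, 3] <- Q4[3, 1] <- Q4[2, 4] <- Q4[4, 2] <- qh
    llh <- hisse_loglik(s$tree, s$states,
                        list(lambda = lam[c(1, 2, 1, 2)],
                             mu = mu[c(1, 2, 1, 2)], Q = Q4),
                        reltol = 1e-10, abstol = 1e-12)
    llb <- bisse_loglik(s$tree, s$states,
                        c(lambda0 = lam[1], lambda1 = lam[2], mu0 = mu[1],
                          mu1 = mu[2], q01 = q01, q10 = q10),
                        reltol = 1e-10, abstol = 1e-12)
    expect_equal(llh, llb, tolerance = 1e-8)
  }
})

test_that("CID likelihood touches the observed character only through its Mk factor", {
  # character independence: with speciation/extinction tied to the hidden
  # state alone, the joint likelihood factorizes into a hidden birth-death
  # part and an Mk factor for the observed pattern (exact under flat root
  # weighting), so loglik minus the Mk factor is permutation-invariant
  s <- random_tree_states(20, 131)
  spec <- make_model_set()[["cid2_a"]]
  theta <- c(1.8, 3.2, 0.4, 0.9, 0.7, 0.5)
  p <- rangediv:::sse_spec_pars(spec, theta)
  q_obs <- theta[5]
  part <- function(states) {
    rangediv:::sse_loglik_generic(s$tree, states, p$lambda, p$mu, p$Q,
                                  spec$obs_map, root_treatment = "flat") -
      mk_loglik(s$tree, states, q_obs, q_obs, root_treatment = "flat")
  }
  base <- part(s$states)
  set.seed(132)
  for (i in 1:5) {
    perm <- stats::setNames(sample(unname(s$states)), names(s$states))
    expect_equal(part(perm), base, tolerance = 1e-6)
  }
})

test_that("hisse rejects rates breaking the structural zeros", {
  s <- random_tree_states(10, 141)
  Qbad <- matrix(0.5, 4, 4)
  expect_error(hisse_loglik(s$tree, s$states,
                            list(lambda = rep(1, 4), mu = rep(0.1, 4),
                                 Q = Qbad)), "structural zeros")
  expect_error(bisse_loglik(s$tree, s$states[-1],
                            c(lambda0 = 1, lambda1 = 1, mu0 = 0, mu1 = 0,
                              q01 = 1, q10 = 1)), "missing tip state")
  nonult <- parse_newick("((A:1,B:2):1,C:2);")
  expect_error(bisse_loglik(nonult, c(A = 0L, B = 1L, C = 0L),
                            c(lambda0 = 1, lambda1 = 1, mu0 = 0, mu1 = 0,
                              q01 = 1, q10 = 1)), "ultrametric")
})

test_that("the model battery has the documented composition", {
  specs <- make_model_set("hisse_binary")
  expect_length(specs, 20)
  cls <- vapply(specs, function(s) s$class_label, character(1))
  expect_equal(sum(cls == "hisse"), 16)
  expect_equal(sum(cls == "cid"), 4)
  # CID-2 parameter count equals the matching binary SSE model
  expect_equal(specs[["cid2_a"]]$n_free, rangediv:::bisse_spec()$n_free)
  expect_equal(specs[["cid2_b"]]$n_free, rangediv:::bisse_spec()$n_free)
  for (s in specs) expect_true(rangediv:::validate_sse_spec(s))
  expect_error(make_model_set("other"), "unknown")
})

test_that("ML fitting is seeded-deterministic and finds a sane optimum", {
  sim <- simulate_sse_tree(c(lambda0 = 3, lambda1 = 8, mu0 = 1, mu1 = 1,
                             q01 = 1.5, q10 = 1.5), 120, seed = 151,
                           require_both_states = TRUE)
  spec <- rangediv:::bisse_spec()
  f1 <- fit_sse_model(sim$tree, sim$states, spec, n_starts = 2, seed = 5)
  f2 <- fit_sse_model(sim$tree, sim$states, spec, n_starts = 2, seed = 5)
  expect_identical(f1$theta, f2$theta)
  expect_equal(f1$AIC, 2 * f1$k - 2 * f1$loglik)
  # fitted state-1 speciation exceeds state-0 under a strong true contrast
  expect_gt(f1$pars$lambda[2], f1$pars$lambda[1])
  expect_false(f1$transition_rates_reliable) # 120 tips is far below 800
})

test_that("Akaike weights follow the closed form and its invariances", {
  f <- function(name, aic) list(name = name, k = 3, loglik = 0, AIC = aic)
  tab <- akaike_weights(list(f("a", 10), f("b", 10)))
  expect_equal(tab$weight, c(0.5, 0.5))
  tab2 <- akaike_weights(list(f("a", 10), f("b", 12)))
  expect_equal(tab2$weight[1], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(tab2$weight[2], exp(-1) / (1 + exp(-1)), tolerance = 1e-12)
  tab3 <- akaike_weights(list(f("a", 110), f("b", 112)))
  expect_equal(tab3$weight, tab2$weight)
  expect_equal(sum(tab2$weight), 1, tolerance = 1e-10)
  expect_equal(min(tab2$delta_aic), 0)
})

test_that("threshold binarization follows the stated conventions", {
  out <- binarize_by_threshold(c(a = 1, b = 2, c = 3, d = 4), "median")
  expect_equal(unname(out$states), c(0L, 0L, 1L, 1L))
  # strict 'less than' for fixed thresholds: the named empirical extremes
  fixed <- binarize_by_threshold(c(small = 42.4, big = 7306701), 1e5)
  expect_equal(unname(fixed$states), c(0L, 1L))
  qg <- binarize_by_threshold(stats::setNames(1:8, letters[1:8]),
                              "quartile-grouping")
  expect_equal(sum(qg$states == 1), 4) # outer quartiles
  expect_equal(unname(qg$states[c("d", "e")]), c(0L, 0L))
  expect_error(binarize_by_threshold(rep(2, 5), "median"), "constant")
  expect_error(binarize_by_threshold(1:4 + 0, 100), "degenerate")
})
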