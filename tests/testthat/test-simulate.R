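test_that("birth-death simulator meets its postconditions", {
  tr <- simulate_bd_tree(2, 1, 0, seed = 3)
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(unname(tr$edge.length), c(1, 1)) # depth 1 forces both pendants
  tr <- simulate_bd_tree(192, 1, 0, seed = 4)
  expect_equal(ape::Ntip(tr), 192)
  expect_true(check_ultrametric(tr, 1e-8))
  expect_true(all(tr$edge.length > 0))
  expect_equal(max(node_depths(tr)), 1)
  expect_error(simulate_bd_tree(50, 1, 1.5), "birth must exceed death")
  # bit-for-bit reproducibility
  expect_identical(write_newick(simulate_bd_tree(30, 2, 0.5, seed = 9)),
                   write_newick(simulate_bd_tree(30, 2, 0.5, seed = 9)))
})

test_that("pure-birth trees have mean gamma near zero", {
  set.seed(12)
  g <- replicate(150, oracle_gamma_stat(simulate_bd_tree(50, 1)))
  expect_lt(abs(mean(g)), 3 * stats::sd(g) / sqrt(length(g)) + 0.05)
})

test_that("state-dependent tree simulation respects symmetry and direction", {
  # symmetric rates: state-1 frequency centred on 1/2
  set.seed(13)
  freq <- replicate(60, {
    s <- simulate_sse_tree(c(lambda0 = 2, lambda1 = 2, mu0 = 0.4, mu1 = 0.4,
                             q01 = 1.5, q10 = 1.5), 40)
    mean(s$states)
  })
  expect_lt(abs(mean(freq) - 0.5), 3 * stats::sd(freq) / sqrt(length(freq)) + 0.02)
  # faster state-1 speciation raises state-1 tip rates in most replicates
  set.seed(14)
  wins <- replicate(40, {
    s <- simulate_sse_tree(c(lambda0 = 1, lambda1 = 2, mu0 = 0.2, mu1 = 0.2,
                             q01 = 0.5, q10 = 0.5), 60,
                           require_both_states = TRUE)
    dr <- dr_statistic(s$tree)
    drv <- stats::setNames(dr$dr, dr$tip)
    mean(drv[names(s$states)[s$states == 1]]) >
      mean(drv[names(s$states)[s$states == 0]])
  })
  expect_gt(mean(wins), 0.5)
})

test_that("state-dependent simulation output is well-formed and seeded", {
  s <- simulate_sse_tree(c(lambda0 = 1, lambda1 = 2, mu0 = 0.3, mu1 = 0.2,
                           q01 = 0.5, q10 = 0.5), 80, seed = 15)
  expect_true(check_ultrametric(s$tree, 1e-8))
  expect_equal(ape::Ntip(s$tree), 80)
  expect_setequal(names(s$states), s$tree$tip.label)
  s2 <- simulate_sse_tree(c(lambda0 = 1, lambda1 = 2, mu0 = 0.3, mu1 = 0.2,
                            q01 = 0.5, q10 = 0.5), 80, seed = 15)
  expect_identical(s$states, s2$states)
  expect_identical(write_newick(s$tree), write_newick(s2$tree))
  # no transitions, root state 0: every tip stays 0
  s0 <- simulate_sse_tree(c(lambda0 = 1, lambda1 = 2, mu0 = 0, mu1 = 0,
                            q01 = 0, q10 = 0), 30, seed = 16)
  expect_true(all(s0$states == 0))
})

test_that("Brownian trait simulation matches its covariance contract", {
  two <- parse_newick("(A:1,B:1);")
  set.seed(17)
  d <- replicate(1500, {
    x <- simulate_bm_trait(two, sigma2 = 2, lambda = 1)
    x[["A"]] - x[["B"]]
  })
  # Var(A - B) = 2 sigma2 under BM on a depth-1 two-tip tree
  expect_lt(abs(stats::var(d) - 4), 4 * sqrt(2 / 1500) * 4)
  # lambda = 0: tips i.i.d.; covariance of non-sister tips near zero
  tr <- simulate_bd_tree(60, 1, seed = 18)
  X <- replicate(400, simulate_bm_trait(tr, sigma2 = 1, lambda = 0))
  cv <- stats::cov(t(X))
  offdiag <- cv[upper.tri(cv)]
  expect_lt(max(abs(offdiag)), 0.35) # ~N(0, 1/sqrt(400)) scale
  expect_identical(simulate_bm_trait(tr, 1, 0.5, seed = 19),
                   simulate_bm_trait(tr, 1, 0.5, seed = 19))
  expect_error(simulate_bm_trait(parse_newick("((A:1,B:2):1,C:2);"), 1, 0.5),
               "ultrametric")
})

test_that("Mk character simulation matches enumeration on a 3-tip tree", {
  tr <- parse_newick("((A:0.6,B:0.6):0.7,C:1.3);")
  oracle <- oracle_mk_pattern_probs(tr, q01 = 0.8, q10 = 1.1, root_freq = 0.4)
  set.seed(20)
  nsim <- 4000
  counts <- integer(nrow(oracle$patterns))
  for (i in seq_len(nsim)) {
    st <- simulate_mk_character(tr, 0.8, 1.1, root_freq = 0.4)
    key <- st[c("A", "B", "C")]
    hit <- which(apply(oracle$patterns, 1, function(p) all(p == key)))
    counts[hit] <- counts[hit] + 1L
  }
  expect_gt(stats::chisq.test(counts, p = oracle$probs)$p.value, 1e-4)
})

test_that("Mk simulation limits behave", {
  tr <- simulate_bd_tree(100, 1, seed = 22)
  expect_true(all(simulate_mk_character(tr, 0, 0, root_freq = 0) == 0))
  set.seed(23)
  freq <- replicate(60, mean(simulate_mk_character(tr, 50, 50)))
  expect_lt(abs(mean(freq) - 0.5), 0.05)
})

test_that("Mk likelihood agrees with matrix-exponential and enumeration oracles", {
  set.seed(24)
  for (i in 1:5) {
    tr <- simulate_bd_tree(12, 1)
    st <- simulate_mk_character(tr, 1.2, 0.7)
    if (length(unique(st)) < 2) next
    expect_equal(mk_loglik(tr, st, 1.2, 0.7, root_treatment = "flat"),
                 oracle_mk_loglik(tr, st, 1.2, 0.7, "flat"), tolerance = 1e-9)
  }
  # enumeration on 3 tips with flat root: likelihood of the observed pattern
  tr <- parse_newick("((A:0.6,B:0.6):0.7,C:1.3);")
  st <- c(A = 1L, B = 0L, C = 1L)
  oracle <- oracle_mk_pattern_probs(tr, 0.8, 1.1, root_freq = 0.5)
  hit <- which(apply(oracle$patterns, 1, function(p)
    all(p == st[c("A", "B", "C")])))
  expect_equal(mk_loglik(tr, st, 0.8, 1.1, root_treatment = "flat"),
               log(oracle$probs[hit]), tolerance = 1e-9)
})

test_that("clade generator reproduces the configured composition", {
  cfg <- sim_config(n_tips = 192, seed = 42)
  out <- generate_clade_dataset(cfg)
  expect_equal(nrow(out$data), 192)
  expect_equal(ape::Ntip(out$tree), 192)
  expect_setequal(out$data$tip, out$tree$tip.label)
  expect_true(all(out$data$range_size > 0))
  expect_true(all(out$data$body_mass > 0))
  expect_true(all(out$data$hwi > 0))
  expect_false(anyNA(out$data))
  # island count near the binomial expectation 68
  n_isl <- sum(out$data$setting == "island")
  expect_gt(n_isl, 40)
  expect_lt(n_isl, 100)
  # island ranges systematically smaller on the log scale
  expect_lt(median(log(out$data$range_size[out$data$setting == "island"])),
            median(log(out$data$range_size[out$data$setting == "continental"])))
  # log-range roughly normal per setting: |skewness| small
  lr <- log(out$data$range_size[out$data$setting == "continental"])
  skew <- mean((lr - mean(lr))^3) / stats::sd(lr)^3
  expect_lt(abs(skew), 1)
  # determinism
  out2 <- generate_clade_dataset(cfg)
  expect_identical(out$data, out2$data)
})

test_that("clade generator supports missingness and the Mk island mode", {
  out <- generate_clade_dataset(sim_config(n_tips = 96, seed = 7,
                                           missing_fraction = 0.1))
  expect_equal(sum(is.na(out$data$hwi)), 9)
  expect_equal(sum(is.na(out$data$body_mass)), 9)
  mk <- generate_clade_dataset(sim_config(n_tips = 96, seed = 8,
                                          island_mode = "mk"))
  expect_true(all(mk$data$setting %in% c("island", "continental")))
})

test_that("iid-flag SSE simulation matches BD + Mk in tip-state frequency", {
  # state-independent rates: tip-state frequencies from the joint simulator
  # and from a BD tree with an Mk character drawn on top are one law
  set.seed(25)
  f_joint <- replicate(100, {
    s <- simulate_sse_tree(c(lambda0 = 2, lambda1 = 2, mu0 = 0.3, mu1 = 0.3,
                             q01 = 1, q10 = 1), 30, root_state = 0L)
    mean(s$states)
  })
  f_layer <- replicate(100, {
    tr <- ape::rphylo(30, 2, 0.3) # original time scale, matching the rates
    mean(simulate_mk_character(tr, 1, 1, root_freq = 0))
  })
  # frequencies are discrete, so ties are expected; the approximate
  # two-sample statistic is what we want
  ks <- suppressWarnings(stats::ks.test(f_joint, f_layer))
  expect_gt(ks$p.value, 0.01)
})
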