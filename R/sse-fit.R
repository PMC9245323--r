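#' Fit a constrained SSE model by maximum likelihood
#'
#' Bounded multi-start optimization of the free parameters of an `sse_spec`
#' in log space (bounds `[1e-6, 1e3]`, appropriate for trees rescaled to
#' depth 1), using `nlminb`. Starting values are derived from the tree (a
#' pure-birth speciation-rate guess `log(n)/depth`) and jittered per start
#' under the supplied seed, so refits with the same seed are identical.
#'
#' @param tree Ultrametric `phylo` (depth-1 rescaling recommended).
#' @param states Named observed 0/1 vector over tips.
#' @param spec An `sse_spec` from [make_model_set()] (or the internal
#'   plain-binary spec constructor).
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Integer seed for the start jitter.
#' @param root_treatment,condition_survival Passed to the likelihood.
#' @param reltol Integrator relative tolerance used during optimization.
#' @return Object of class `sse_fit`: list with `spec`, `pars` (lambda, mu,
#'   Q on the natural scale), `theta` (free parameters), `loglik`, `k`,
#'   `AIC`, `convergence` (0 = converged; best-so-far returned otherwise
#'   with a warning), `transition_rates_reliable` (FALSE below 800 tips).
#' @export
fit_sse_model <- function(tree, states, spec, n_starts = 5, seed = 1,
                          root_treatment = "madfitz",
                          condition_survival = FALSE, reltol = 1e-7) {
  stopifnot(inherits(spec, "sse_spec"))
  lb <- log(1e-6)
  qidx_all <- unique(spec$q_idx[spec$q_idx > 0])
  # transition rates are capped lower: beyond ~100 flips per unit tree depth
  # the character is effectively random and the ODEs only get stiffer
  ub <- rep(log(1e3), spec$n_free)
  ub[qidx_all] <- log(1e2)
  negll <- function(lth) {
    p <- sse_spec_pars(spec, exp(lth))
    ll <- tryCatch(
      sse_loglik_generic(tree, states, p$lambda, p$mu, p$Q, spec$obs_map,
                         root_treatment = root_treatment,
                         condition_survival = condition_survival,
                         reltol = reltol, abstol = reltol * 1e-2),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  ntip <- ape::Ntip(tree)
  depth <- max(node_depths(tree))
  lam0 <- log(max(log(ntip) / depth, 1e-3))
  base <- rep(lam0, spec$n_free)
  base[unique(spec$mu_idx)] <- lam0 + log(0.1)
  base[qidx_all] <- log(0.5 / depth)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- pmin(pmax(base + if (s == 1) 0 else stats::rnorm(spec$n_free, 0, 0.75),
                       lb + 1), ub - 1)
    o <- tryCatch(stats::nlminb(start, negll, lower = lb, upper = ub,
                                control = list(iter.max = 500, eval.max = 1000)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) stop("SSE optimization failed for model '", spec$name, "'")
  converged <- best$convergence == 0
  if (!converged) {
    # restart from the incumbent: converged in practice if nothing improves
    o2 <- tryCatch(stats::nlminb(best$par, negll, lower = lb, upper = ub,
                                 control = list(iter.max = 500,
                                                eval.max = 1000)),
                   error = function(e) NULL)
    if (!is.null(o2) && is.finite(o2$objective) &&
        o2$objective <= best$objective) {
      converged <- o2$convergence == 0 ||
        (best$objective - o2$objective) < 1e-4
      best <- if (o2$objective < best$objective) o2 else best
    }
  }
  if (!converged)
    warning("optimizer did not report convergence for '", spec$name,
            "'; best-so-far returned")
  theta <- exp(best$par)
  pars <- sse_spec_pars(spec, theta)
  ll <- -best$objective
  out <- list(spec = spec, pars = pars, theta = theta, loglik = ll,
              k = spec$n_free, AIC = 2 * spec$n_free - 2 * ll,
              convergence = if (converged) 0L else best$convergence,
              root_treatment = root_treatment,
              condition_survival = condition_survival,
              transition_rates_reliable = ntip >= 800)
  class(out) <- "sse_fit"
  out
}

#' @export
print.sse_fit <- function(x, ...) {
  cat(sprintf("SSE fit '%s': k = %d, logLik = %.3f, AIC = %.3f\n",
              x$spec$name, x$k, x$loglik, x$AIC))
  if (!x$transition_rates_reliable)
    cat("  note: individual transition-rate estimates unreliable at this tree size\n")
  invisible(x)
}

#' Akaike weights over a set of fitted models
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AIC_i - min(AIC)`; invariant to adding a constant to all AICs.
#'
#' @param fits List of `sse_fit` objects (or any objects with `$AIC`,
#'   `$loglik`, `$k` and a model name).
#' @return `data.frame` (model, class, k, loglik, AIC, delta_aic, weight),
#'   sorted by AIC; weights sum to 1.
#' @export
akaike_weights <- function(fits) {
  stopifnot(length(fits) >= 1)
  nm <- vapply(fits, function(f)
    if (!is.null(f$spec)) f$spec$name else f$name %||% "model", character(1))
  cl <- vapply(fits, function(f)
    if (!is.null(f$spec)) f$spec$class_label else "model", character(1))
  tab <- data.frame(model = nm, class = cl,
                    k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    stringsAsFactors = FALSE)
  tab$delta_aic <- tab$AIC - min(tab$AIC)
  w <- exp(-tab$delta_aic / 2)
  tab$weight <- w / sum(w)
  tab[order(tab$AIC), , drop = FALSE]
}

#' Binarize a positive variable by a threshold rule
#'
#' Rules: `"median"`, `"q25"`, `"q75"` (empirical quantiles),
#' `"quartile-grouping"` (state 1 for values in the outer quartiles, state 0
#' for the interquartile range), or a fixed numeric threshold (also accepted
#' as the string `"fixed:<value>"`). For single-threshold rules state 0
#' means strictly below the threshold ("less than" is strict) and values at
#' the threshold fall in the upper state.
#'
#' @param values Positive numeric vector, named by species.
#' @param rule Rule name or numeric threshold.
#' @return List with `states` (named 0/1 integer vector), `threshold`
#'   (numeric, or the two quartiles for the grouping rule) and `rule`.
#' @examples
#' binarize_by_threshold(c(a = 1, b = 2, c = 3, d = 4), "median")
#' @export
binarize_by_threshold <- function(values, rule = "median") {
  stopifnot(is.numeric(values), all(values > 0))
  if (length(unique(values)) < 2)
    stop("constant input: no threshold can split it")
  if (is.character(rule) && grepl("^fixed:", rule))
    rule <- as.numeric(sub("^fixed:", "", rule))
  if (is.numeric(rule)) {
    thr <- rule
    st <- as.integer(values >= thr)
    rule_name <- "fixed"
  } else if (rule %in% c("median", "q25", "q75")) {
    pr <- c(median = 0.5, q25 = 0.25, q75 = 0.75)[[rule]]
    thr <- as.numeric(stats::quantile(values, pr))
    st <- as.integer(values >= thr)
    rule_name <- rule
  } else if (rule == "quartile-grouping") {
    thr <- as.numeric(stats::quantile(values, c(0.25, 0.75)))
    st <- as.integer(values < thr[1] | values >= thr[2])
    rule_name <- rule
  } else stop("unknown threshold rule: ", rule)
  if (length(unique(st)) < 2)
    stop("degenerate split: all species on one side of the threshold")
  names(st) <- names(values)
  list(states = st, threshold = thr, rule = rule_name)
}
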