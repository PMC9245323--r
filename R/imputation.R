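#' Phylogenetic imputation of a continuous trait under Brownian motion
#'
#' Missing tip values are replaced by their conditional expectation under
#' Brownian motion given the observed tips (GLS kriging on the tree
#' covariance): with root value estimated by GLS, the missing block is
#' `mu + C_mo C_oo^{-1} (x_o - mu)`. Observed values are returned unchanged.
#'
#' @param tree `phylo` with branch lengths.
#' @param trait Named numeric vector over tips, `NA` where missing; at least
#'   2 observed values and under 50% missing.
#' @return Complete named vector in tree tip order.
#' @export
impute_trait_bm <- function(tree, trait) {
  validate_tree(tree)
  if (is.null(names(trait))) stop("trait must be named by tip label")
  trait <- trait[tree$tip.label]
  obs <- which(!is.na(trait))
  mis <- which(is.na(trait))
  if (length(obs) < 2) stop("at least 2 observed values required")
  if (length(mis) == 0) return(trait)
  if (length(mis) / length(trait) >= 0.5)
    stop("refusing to impute with >= 50% missing values")
  C <- phylo_vcv(tree)
  Coo <- C[obs, obs, drop = FALSE]
  Cmo <- C[mis, obs, drop = FALSE]
  R <- chol(Coo)
  one <- rep(1, length(obs))
  Vi_x <- backsolve(R, backsolve(R, trait[obs], transpose = TRUE))
  Vi_1 <- backsolve(R, backsolve(R, one, transpose = TRUE))
  mu <- sum(Vi_x) / sum(Vi_1) # GLS root estimate
  trait[mis] <- mu + as.numeric(Cmo %*% backsolve(
    R, backsolve(R, trait[obs] - mu, transpose = TRUE)))
  trait
}

#' Group-mean (genus-average) imputation
#'
#' Replaces missing values with the mean of the observed values in the same
#' group, the procedure used for body-mass gap filling.
#'
#' @param values Numeric vector with `NA`s.
#' @param group Grouping factor (e.g. genus), same length.
#' @return Completed vector; errors if a group with a missing value has no
#'   observed member.
#' @export
impute_group_mean <- function(values, group) {
  stopifnot(length(values) == length(group))
  mis <- which(is.na(values))
  if (!length(mis)) return(values)
  means <- tapply(values, group, mean, na.rm = TRUE)
  fill <- means[as.character(group[mis])]
  if (anyNA(fill) || any(is.nan(fill)))
    stop("group(s) with no observed value: ",
         paste(unique(group[mis][is.nan(fill) | is.na(fill)]), collapse = ", "))
  values[mis] <- fill
  values
}
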