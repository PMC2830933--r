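#' Prior specification for the Gibbs sampler
#'
#' All full conditionals are conjugate: inverted-Wishart priors on
#' unstructured covariance blocks, scaled inverse chi-square priors on
#' diagonal variances, independent normal priors on the structural
#' coefficients, and flat priors on fixed effects and free thresholds.
#' Defaults are weakly informative: IW degrees of freedom equal to the block
#' dimension plus one with scale 0.1 I, scaled inverse chi-square with
#' nu = 4 and s2 = 0.1, and an effectively flat N(0, 1e4) on each structural
#' coefficient.
#'
#' @param lambda_mean,lambda_var normal prior mean and variance for every
#'   structural coefficient.
#' @param iw_df_add IW degrees of freedom are \code{dim + iw_df_add}.
#' @param iw_scale scalar multiplying the identity IW scale matrix.
#' @param chisq_df,chisq_scale scaled inverse chi-square hyperparameters
#'   (nu, s2) for diagonal variances.
#' @return An object of class \code{"rmm_priors"}.
#' @export
rmm_priors <- function(lambda_mean = 0, lambda_var = 1e4,
                       iw_df_add = 1, iw_scale = 0.1,
                       chisq_df = 4, chisq_scale = 0.1) {
  stopifnot(lambda_var > 0, iw_df_add >= 1, iw_scale > 0,
            chisq_df > 0, chisq_scale > 0)
  structure(list(lambda_mean = lambda_mean, lambda_var = lambda_var,
                 iw_df_add = iw_df_add, iw_scale = iw_scale,
                 chisq_df = chisq_df, chisq_scale = chisq_scale),
            class = "rmm_priors")
}

#' MCMC configuration
#'
#' Defaults follow the reference analysis protocol: 5 independent chains of
#' 10,000 iterations each, the first 1,000 discarded as burn-in and one of
#' every 10 successive samples retained, so 4,500 draws are used for
#' posterior inference.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param burn_in burn-in iterations discarded per chain.
#' @param thin retain one of every \code{thin} post-burn-in iterations.
#' @param seed base seed; chain c uses \code{seed + c - 1}.
#' @param verbose print a progress line every 1,000 iterations.
#' @return An object of class \code{"rmm_control"} with an added
#'   \code{n_retained} field (\code{n_chains * floor((n_iter - burn_in)/thin)}).
#' @export
rmm_control <- function(n_chains = 5L, n_iter = 10000L, burn_in = 1000L,
                        thin = 10L, seed = 1L, verbose = FALSE) {
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  stopifnot(n_chains >= 1, thin >= 1, burn_in >= 0, burn_in < n_iter)
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = as.integer(seed), verbose = verbose,
                 n_retained = n_chains * ((n_iter - burn_in) %/% thin)),
            class = "rmm_control")
}
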