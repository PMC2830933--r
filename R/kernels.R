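#' Vectorized truncated-normal sampler
#'
#' Draws from N(mean, sd^2) truncated to (lower, upper) by inverse-CDF
#' sampling. Arguments are recycled to a common length. Draws are guaranteed
#' to lie strictly inside the interval; in extreme tails (where the CDF
#' saturates numerically) the draw collapses to just inside the nearer bound.
#'
#' @param n number of draws.
#' @param mean,sd,lower,upper numeric vectors.
#' @return numeric vector of length \code{n}.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(stats::runif(n, pa, pb), mean, sd)
  bad <- !is.finite(x) | x <= lower | x >= upper
  if (any(bad)) {
    # numerically degenerate tail: place the draw just inside the interval
    lo <- lower[bad]; up <- upper[bad]; mu <- mean[bad]; s <- sd[bad]
    near <- ifelse(mu >= up, up - 1e-8 * pmax(s, 1e-8),
                   ifelse(mu <= lo, lo + 1e-8 * pmax(s, 1e-8), mu))
    near <- pmin(pmax(near, ifelse(is.finite(lo), lo + 1e-12, -Inf)),
                 ifelse(is.finite(up), up - 1e-12, Inf))
    x[bad] <- near
  }
  x
}

# inverted-Wishart draw: Sigma with density |Sigma|^-((nu+p+1)/2) exp(-tr(S Sigma^-1)/2)
riw <- function(nu, S) {
  p <- ncol(S)
  W <- stats::rWishart(1, df = nu, Sigma = chol2inv(chol(S)))[, , 1]
  out <- chol2inv(chol(W))
  (out + t(out)) / 2
}

#' Inverted-Wishart draw with the last diagonal entry fixed
#'
#' Samples from the conditional distribution of an inverted-Wishart matrix
#' given that its last diagonal entry equals \code{corner} (default 1, the
#' identification constraint on the stillbirth residual variance). Uses the
#' exact factorization of the IW into the Schur complement of the fixed entry
#' (itself IW with the same degrees of freedom) and a conditionally normal
#' regression vector.
#'
#' @param nu degrees of freedom (density convention
#'   \code{|Sigma|^-((nu+p+1)/2) exp(-tr(S Sigma^-1)/2)}).
#' @param S p x p scale matrix.
#' @param corner fixed value of \code{Sigma[p, p]}.
#' @return p x p symmetric matrix with \code{Sigma[p, p] == corner} exactly.
#' @export
riw_corner <- function(nu, S, corner = 1) {
  S <- as.matrix(S)
  p <- ncol(S)
  stopifnot(p >= 2, corner > 0)
  i1 <- seq_len(p - 1)
  s12 <- S[i1, p, drop = FALSE]
  s22 <- S[p, p]
  S112 <- S[i1, i1, drop = FALSE] - s12 %*% t(s12) / s22
  Sig112 <- riw(nu, S112)
  gam_mean <- s12 / s22
  ch <- chol(Sig112 / s22)
  gam <- gam_mean + t(ch) %*% stats::rnorm(p - 1)
  Sigma <- matrix(0, p, p)
  Sigma[i1, i1] <- Sig112 + (gam %*% t(gam)) * corner
  Sigma[i1, p] <- gam * corner
  Sigma[p, i1] <- gam * corner
  Sigma[p, p] <- corner
  (Sigma + t(Sigma)) / 2
}

# scaled inverse chi-square posterior draw given prior (nu0, s20) and
# sum of squares over n observations
rsinvchisq_post <- function(nu0, s20, ss, n) {
  (nu0 * s20 + ss) / stats::rchisq(1, nu0 + n)
}

# draw x ~ N(Prec^-1 rhs, Prec^-1) from canonical (precision) form
rmvn_canonical <- function(Prec, rhs) {
  U <- tryCatch(chol(Prec), error = function(e) {
    chol(Prec + diag(1e-8 * max(diag(Prec)), ncol(Prec)))
  })
  m <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
  drop(m + backsolve(U, stats::rnorm(ncol(Prec))))
}
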