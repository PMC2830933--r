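# Independent oracle samplers and small data helpers used across tests.

# small default-condition data set
make_sim <- function(n, seed = 1, truth = true_params(), design = NULL) {
  if (is.null(design)) design <- sim_design(n)
  simulate_calving_data(design, truth = truth, seed = seed)
}

# truncated normal via inverse CDF (independent of the package's kernel)
oracle_rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, lo + 1e-10), hi - 1e-10)
}

# Single-trait Gibbs sampler: univariate mixed model with herd, and joint
# per-bull (sire, MGS) effects under a per-trait 2x2 IW prior -- the exact
# per-trait factor of the joint RMM3 model when all structural coefficients
# are zero. For the ordinal traits the phenotype is augmented with a latent
# liability (thresholds (0,1) for CD, 0 for SB; residual variance free for
# GL/CD, fixed at 1 for SB). Priors match the package defaults.
single_trait_gibbs <- function(records, trait = c("GL", "CD", "SB"),
                               n_iter = 2500, burn_in = 500, thin = 2,
                               seed = 1, gl_ref = NULL) {
  trait <- match.arg(trait)
  set.seed(seed)
  n <- nrow(records)
  sex <- factor(records$sex); age <- factor(records$age_class)
  ys <- factor(records$year_season)
  X <- stats::model.matrix(~ sex + age + ys)
  p <- ncol(X); XtX <- crossprod(X)
  herds <- sort(unique(records$herd_year_id))
  bulls <- sort(unique(c(records$sire_id, records$mgs_id)))
  hi <- match(records$herd_year_id, herds)
  si <- match(records$sire_id, bulls)
  mi <- match(records$mgs_id, bulls)
  nh <- tabulate(hi, length(herds))
  ls <- split(seq_len(n), factor(si, levels = seq_along(bulls)))
  lm_ <- split(seq_len(n), factor(mi, levels = seq_along(bulls)))
  ns <- lengths(ls); nm <- lengths(lm_)
  nsm <- tabulate(si[si == mi], nbins = length(bulls))

  if (trait == "GL") {
    if (is.null(gl_ref)) gl_ref <- round(mean(records$gl_days))
    y <- records$gl_days - gl_ref
    lo <- rep(-Inf, n); hi_b <- rep(Inf, n); r_free <- TRUE
  } else if (trait == "CD") {
    tau <- c(0, 1)
    sc <- records$cd_score
    lo <- c(-Inf, tau)[sc]; hi_b <- c(tau, Inf)[sc]
    y <- pmin(pmax(c(-0.5, 0.5, 1.5)[sc], lo + 0.1), hi_b - 0.1)
    r_free <- TRUE
  } else {
    lo <- ifelse(records$sb_score == 2, 0, -Inf)
    hi_b <- ifelse(records$sb_score == 2, Inf, 0)
    y <- ifelse(records$sb_score == 2, 0.5, -0.5)
    r_free <- FALSE
  }
  b <- rep(0, p); h <- rep(0, length(herds))
  u <- matrix(0, length(bulls), 2)
  s2h <- 0.1; B <- diag(c(1, 1)) * 0.1; r <- if (trait == "GL") max(stats::var(y), 1) else 1
  keep <- NULL
  for (it in seq_len(n_iter)) {
    mu <- drop(X %*% b) + h[hi] + u[si, 1] + u[mi, 2]
    if (trait != "GL") y <- oracle_rtnorm(n, mu, sqrt(r), lo, hi_b)
    # fixed effects
    e <- y - h[hi] - u[si, 1] - u[mi, 2]
    U <- chol(XtX / r)
    bm <- backsolve(U, backsolve(U, crossprod(X, e) / r, transpose = TRUE))
    b <- drop(bm + backsolve(U, stats::rnorm(p)))
    # herd effects
    e <- y - drop(X %*% b) - u[si, 1] - u[mi, 2]
    Sh <- rowsum(e, hi, reorder = TRUE)
    prec <- nh / r + 1 / s2h
    h <- stats::rnorm(length(herds), (Sh / r) / prec, sqrt(1 / prec))
    # bulls (joint sire/MGS 2-vectors, residuals kept current)
    e <- y - drop(X %*% b) - h[hi]
    rr <- e - u[si, 1] - u[mi, 2]
    Binv <- solve(B)
    for (q in seq_along(bulls)) {
      Ts <- sum(rr[ls[[q]]]); Tm <- sum(rr[lm_[[q]]])
      cs <- Ts + ns[q] * u[q, 1] + nsm[q] * u[q, 2]
      cm <- Tm + nm[q] * u[q, 2] + nsm[q] * u[q, 1]
      Prec <- Binv + matrix(c(ns[q], nsm[q], nsm[q], nm[q]), 2) / r
      Uq <- chol(Prec)
      mq <- backsolve(Uq, backsolve(Uq, c(cs, cm) / r, transpose = TRUE))
      newu <- drop(mq + backsolve(Uq, stats::rnorm(2)))
      if (ns[q]) rr[ls[[q]]] <- rr[ls[[q]]] - (newu[1] - u[q, 1])
      if (nm[q]) rr[lm_[[q]]] <- rr[lm_[[q]]] - (newu[2] - u[q, 2])
      u[q, ] <- newu
    }
    # dispersion
    s2h <- (4 * 0.1 + sum(h^2)) / stats::rchisq(1, 4 + length(herds))
    SB2 <- diag(0.1, 2) + crossprod(u)
    W <- stats::rWishart(1, 3 + nrow(u), solve(SB2))[, , 1]
    B <- solve(W)
    if (r_free) {
      e <- y - drop(X %*% b) - h[hi] - u[si, 1] - u[mi, 2]
      r <- (4 * 0.1 + sum(e^2)) / stats::rchisq(1, 4 + n)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0)
      keep <- rbind(keep, c(intercept = b[1], resid_var = r,
                            herd_var = s2h, sire_var = B[1, 1],
                            mgs_var = B[2, 2]))
  }
  keep
}

# 3-MCSE comparison of two posterior means
expect_mcse_match <- function(draws_a, draws_b, label) {
  d <- abs(mean(draws_a) - mean(draws_b))
  tol <- 3 * sqrt(mcse(draws_a)^2 + mcse(draws_b)^2)
  expect_lt(d, max(tol, 1e-8), label = label)
}
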