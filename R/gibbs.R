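# Gibbs sampler for the standard and recursive threshold mixed models.
#
# Internal layout: records are converted once into an indexed structure
# (design matrix, herd/sire/MGS indices, GL category, centred GL) and the
# sampler scans liabilities -> location effects -> structural coefficients ->
# thresholds -> dispersion matrices, all from closed-form full conditionals.

# build the fixed-effects design matrix from stored levels; unseen levels in
# newdata contribute only the intercept/baseline
build_X <- function(records, levels = NULL) {
  if (is.null(levels)) {
    levels <- list(sex = sort(unique(records$sex)),
                   age = sort(unique(records$age_class)),
                   year_season = sort(unique(records$year_season)))
  }
  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  add_factor <- function(cols, values, levs, prefix) {
    for (l in levs[-1]) {
      cols[[paste0(prefix, l)]] <- as.numeric(values == l)
    }
    cols
  }
  cols <- add_factor(cols, records$sex, levels$sex, "sex")
  cols <- add_factor(cols, records$age_class, levels$age, "age")
  cols <- add_factor(cols, records$year_season, levels$year_season, "ys")
  X <- do.call(cbind, cols)
  attr(X, "levels") <- levels
  X
}

# one-time data preparation for the sampler
prepare_rmm_data <- function(records, map, C_cd, gl_ref) {
  records <- validate_records(records, C_cd = C_cd)
  n <- nrow(records)
  X <- build_X(records)
  herds <- sort(unique(records$herd_year_id))
  bulls <- sort(unique(c(records$sire_id, records$mgs_id)))
  hi <- match(records$herd_year_id, herds)
  si <- match(records$sire_id, bulls)
  mi <- match(records$mgs_id, bulls)
  k <- gl_category(records$gl_days, map)
  if (is.null(gl_ref)) gl_ref <- round(mean(records$gl_days))
  glc <- records$gl_days - gl_ref
  ls <- split(seq_len(n), factor(si, levels = seq_along(bulls)))
  lm <- split(seq_len(n), factor(mi, levels = seq_along(bulls)))
  ns <- lengths(ls); nm <- lengths(lm)
  nsm <- tabulate(si[si == mi], nbins = length(bulls))
  nh <- tabulate(hi, nbins = length(herds))
  list(records = records, n = n, X = X, p = ncol(X),
       levels = attr(X, "levels"),
       herds = herds, bulls = bulls, hi = hi, si = si, mi = mi,
       k = k, K = map$n_categories, glc = glc, gl_ref = gl_ref, map = map,
       C_cd = as.integer(C_cd), ls = ls, lm = lm, ns = ns, nm = nm,
       nsm = nsm, nh = nh,
       cd = records$cd_score, sb = records$sb_score)
}

# initial chain state
init_state <- function(d, variant, C_cd, fix_lambda) {
  p <- d$p
  b <- matrix(0, p, 3)
  b[, 1] <- qr.solve(crossprod(d$X) + diag(1e-8, p), crossprod(d$X, d$glc))
  tau <- c(0, 1)
  if (C_cd > 3) tau <- c(tau, 1 + 0.5 * seq_len(C_cd - 3))
  mid <- c(tau[1] - 0.5, (tau[-length(tau)] + tau[-1]) / 2, tau[length(tau)] + 0.5)
  y <- cbind(d$glc, mid[d$cd], ifelse(d$sb == 2L, 0.5, -0.5))
  lam <- if (is.null(fix_lambda)) matrix(0, 3, d$K) else fix_lambda
  rownames(lam) <- c("cd_gl", "sb_gl", "sb_cd")
  list(b = b, h = matrix(0, length(d$herds), 3),
       u = matrix(0, length(d$bulls), 6),
       y = y, lam = lam, tau = tau,
       G0 = diag(rep(c(1, 0.1, 0.1), 2)),
       H0 = diag(c(1, 0.1, 0.1)),
       R0 = diag(c(max(stats::var(d$glc) * 0.8, 1), 1, 1)))
}

location_mu <- function(d, st) {
  d$X %*% st$b + st$h[d$hi, , drop = FALSE] +
    st$u[d$si, 1:3, drop = FALSE] + st$u[d$mi, 4:6, drop = FALSE]
}

# w = Lambda_k y per record (structural working variable)
working_w <- function(d, st) {
  l1 <- st$lam[1, d$k]; l2 <- st$lam[2, d$k]; l3 <- st$lam[3, d$k]
  cbind(d$glc,
        st$y[, 2] - l1 * d$glc,
        st$y[, 3] - l2 * d$glc - l3 * st$y[, 2])
}

# threshold interval per record for the CD and SB scores
cd_bounds <- function(d, tau) {
  lo <- c(-Inf, tau)[d$cd]
  up <- c(tau, Inf)[d$cd]
  list(lo = lo, up = up)
}

sb_bounds <- function(d) {
  list(lo = ifelse(d$sb == 2L, 0, -Inf), up = ifelse(d$sb == 2L, Inf, 0))
}

# liability update, recursive variants (diagonal R0). The CD conditional
# pools the CD equation with the information flowing back from the SB
# equation (where l_CD is a predictor); the SB conditional is a plain
# truncated normal around its structural mean.
sample_liabilities_rmm <- function(d, st, mu) {
  l1 <- st$lam[1, d$k]; l2 <- st$lam[2, d$k]; l3 <- st$lam[3, d$k]
  r2 <- st$R0[2, 2]; r3 <- st$R0[3, 3]
  m_cd <- mu[, 2] + l1 * d$glc
  m_sb0 <- mu[, 3] + l2 * d$glc          # SB mean excluding the l_CD term
  prec <- 1 / r2 + l3^2 / r3
  mean_cd <- (m_cd / r2 + l3 * (st$y[, 3] - m_sb0) / r3) / prec
  bc <- cd_bounds(d, st$tau)
  st$y[, 2] <- rtnorm(d$n, mean_cd, sqrt(1 / prec), bc$lo, bc$up)
  bs <- sb_bounds(d)
  st$y[, 3] <- rtnorm(d$n, m_sb0 + l3 * st$y[, 2], sqrt(r3), bs$lo, bs$up)
  st
}

# liability update, SMM: condition each trait's residual on the other two
# through the unstructured R0
sample_liabilities_smm <- function(d, st, mu) {
  R <- st$R0
  e <- st$y - mu
  # CD given (GL, SB)
  o <- c(1, 3)
  cf <- solve(R[o, o], R[o, 2])
  v <- R[2, 2] - sum(R[2, o] * cf)
  m <- mu[, 2] + e[, o, drop = FALSE] %*% cf
  bc <- cd_bounds(d, st$tau)
  st$y[, 2] <- rtnorm(d$n, m, sqrt(v), bc$lo, bc$up)
  e[, 2] <- st$y[, 2] - mu[, 2]
  # SB given (GL, CD)
  o <- c(1, 2)
  cf <- solve(R[o, o], R[o, 3])
  v <- R[3, 3] - sum(R[3, o] * cf)
  m <- mu[, 3] + e[, o, drop = FALSE] %*% cf
  bs <- sb_bounds(d)
  st$y[, 3] <- rtnorm(d$n, m, sqrt(v), bs$lo, bs$up)
  st
}

# fixed effects: flat prior, multivariate-normal full conditional over all
# traits jointly (precision R0^-1 (x) X'X)
sample_b <- function(d, st, w, R0inv) {
  e <- w - st$h[d$hi, , drop = FALSE] - st$u[d$si, 1:3, drop = FALSE] -
    st$u[d$mi, 4:6, drop = FALSE]
  XtX <- d$XtX
  Prec <- kronecker(R0inv, XtX)
  rhs <- as.vector(crossprod(d$X, e %*% R0inv))
  st$b <- matrix(rmvn_canonical(Prec, rhs), d$p, 3)
  st
}

# herd-year effects: N(0, H0) prior, per-level 3x3 conditionals
sample_h <- function(d, st, w, R0inv, H0inv) {
  e <- w - d$X %*% st$b - st$u[d$si, 1:3, drop = FALSE] -
    st$u[d$mi, 4:6, drop = FALSE]
  S <- rowsum(e, d$hi, reorder = TRUE)
  for (j in seq_along(d$herds)) {
    Prec <- d$nh[j] * R0inv + H0inv
    st$h[j, ] <- rmvn_canonical(Prec, R0inv %*% S[j, ])
  }
  st
}

# joint per-bull (sire, MGS) 6-vectors: N(0, G0) prior; residuals are kept
# current while scanning bulls so that the update is exact single-site Gibbs
sample_bulls <- function(d, st, w, R0inv, G0inv) {
  e <- w - d$X %*% st$b - st$h[d$hi, , drop = FALSE]
  s_eff <- st$u[, 1:3, drop = FALSE]
  m_eff <- st$u[, 4:6, drop = FALSE]
  r <- e - s_eff[d$si, , drop = FALSE] - m_eff[d$mi, , drop = FALSE]
  for (q in seq_along(d$bulls)) {
    is_ <- d$ls[[q]]; im <- d$lm[[q]]
    ns <- d$ns[q]; nm <- d$nm[q]; nsm <- d$nsm[q]
    Ts <- if (ns) colSums(r[is_, , drop = FALSE]) else numeric(3)
    Tm <- if (nm) colSums(r[im, , drop = FALSE]) else numeric(3)
    cs <- Ts + ns * s_eff[q, ] + nsm * m_eff[q, ]
    cm <- Tm + nm * m_eff[q, ] + nsm * s_eff[q, ]
    Prec <- G0inv + rbind(cbind(ns * R0inv, nsm * R0inv),
                          cbind(nsm * R0inv, nm * R0inv))
    newu <- rmvn_canonical(Prec, c(R0inv %*% cs, R0inv %*% cm))
    if (ns) r[is_, ] <- r[is_, , drop = FALSE] -
        rep(newu[1:3] - s_eff[q, ], each = ns)
    if (nm) r[im, ] <- r[im, , drop = FALSE] -
        rep(newu[4:6] - m_eff[q, ], each = nm)
    s_eff[q, ] <- newu[1:3]; m_eff[q, ] <- newu[4:6]
  }
  st$u <- cbind(s_eff, m_eff)
  st
}

# structural coefficients, recursive variants (R0 diagonal): per GL category,
# the CD<-GL rate is a normal regression draw on centred GL; the (SB<-GL,
# SB<-CD) pair is drawn jointly from its bivariate normal conditional
sample_lambda <- function(d, st, mu, priors) {
  r2 <- st$R0[2, 2]; r3 <- st$R0[3, 3]
  m0 <- priors$lambda_mean; v0 <- priors$lambda_var
  for (k in seq_len(d$K)) {
    idx <- which(d$k == k)
    if (!length(idx)) {
      warning("GL category ", k, " has no records; drawing lambda from prior",
              call. = FALSE)
      st$lam[, k] <- stats::rnorm(3, m0, sqrt(v0))
      next
    }
    x <- d$glc[idx]
    t2 <- st$y[idx, 2] - mu[idx, 2]
    prec <- sum(x^2) / r2 + 1 / v0
    mn <- (sum(x * t2) / r2 + m0 / v0) / prec
    st$lam[1, k] <- stats::rnorm(1, mn, sqrt(1 / prec))
    Z <- cbind(x, st$y[idx, 2])
    t3 <- st$y[idx, 3] - mu[idx, 3]
    Prec <- crossprod(Z) / r3 + diag(2) / v0
    rhs <- crossprod(Z, t3) / r3 + m0 / v0
    st$lam[2:3, k] <- rmvn_canonical(Prec, rhs)
  }
  st
}

# free CD thresholds (only when C_cd > 3): uniform between the extreme
# liabilities of the adjacent categories, clipped by the neighbouring
# thresholds
sample_thresholds <- function(d, st) {
  C <- d$C_cd
  if (C <= 3L) return(st)
  for (j in 3:(C - 1L)) {
    in_low <- d$cd == j
    in_up <- d$cd == j + 1L
    lo <- max(if (any(in_low)) max(st$y[in_low, 2]) else -Inf, st$tau[j - 1])
    up <- min(if (any(in_up)) min(st$y[in_up, 2]) else Inf,
              if (j + 1L <= C - 1L) st$tau[j + 1] else Inf)
    st$tau[j] <- if (up > lo) stats::runif(1, lo, up) else lo
  }
  st
}

# dispersion components from current effects and structural residuals
sample_dispersion <- function(d, st, mu, variant, priors) {
  w <- working_w(d, st)
  eps <- w - mu
  n <- d$n
  nu0 <- priors$chisq_df; s20 <- priors$chisq_scale
  # residual R0
  if (variant == "SMM") {
    S <- diag(priors$iw_scale, 3) + crossprod(eps)
    st$R0 <- riw_corner(3 + priors$iw_df_add + n, S, corner = 1)
  } else {
    st$R0 <- diag(c(rsinvchisq_post(nu0, s20, sum(eps[, 1]^2), n),
                    rsinvchisq_post(nu0, s20, sum(eps[, 2]^2), n), 1))
  }
  # herd-year H0
  n_h <- nrow(st$h)
  if (variant %in% c("SMM", "RMM1")) {
    S <- diag(priors$iw_scale, 3) + crossprod(st$h)
    st$H0 <- riw(3 + priors$iw_df_add + n_h, S)
  } else {
    st$H0 <- diag(vapply(1:3, function(t)
      rsinvchisq_post(nu0, s20, sum(st$h[, t]^2), n_h), numeric(1)))
  }
  # genetic G0
  n_b <- nrow(st$u)
  if (variant == "RMM3") {
    G0 <- matrix(0, 6, 6)
    for (t in 1:3) {
      ut <- st$u[, c(t, t + 3), drop = FALSE]
      S <- diag(priors$iw_scale, 2) + crossprod(ut)
      B <- riw(2 + priors$iw_df_add + n_b, S)
      G0[t, t] <- B[1, 1]; G0[t + 3, t + 3] <- B[2, 2]
      G0[t, t + 3] <- G0[t + 3, t] <- B[1, 2]
    }
    st$G0 <- G0
  } else {
    S <- diag(priors$iw_scale, 6) + crossprod(st$u)
    st$G0 <- riw(6 + priors$iw_df_add + n_b, S)
  }
  st
}

# parameter vector stored per retained draw
draw_names <- function(d, variant) {
  K <- d$K
  lam <- as.vector(outer(c("lambda_cd_gl", "lambda_sb_gl", "lambda_sb_cd"),
                         seq_len(K), function(a, k) paste0(a, "[", k, "]")))
  ut6 <- which(upper.tri(matrix(0, 6, 6), diag = TRUE), arr.ind = TRUE)
  g <- paste0("G0[", ut6[, 1], ",", ut6[, 2], "]")
  ut3 <- which(upper.tri(matrix(0, 3, 3), diag = TRUE), arr.ind = TRUE)
  h <- paste0("H0[", ut3[, 1], ",", ut3[, 2], "]")
  r <- c("R0[1,1]", "R0[2,2]", "R0[1,2]", "R0[1,3]", "R0[2,3]")
  bnm <- as.vector(outer(colnames(d$X), trait_names,
                         function(a, t) paste0("b[", a, ",", t, "]")))
  tau <- if (d$C_cd > 3L) paste0("tau_cd[", 3:(d$C_cd - 1L), "]") else character(0)
  c(lam, g, h, r, bnm, tau)
}

flatten_state <- function(d, st) {
  ut6 <- upper.tri(st$G0, diag = TRUE)
  ut3 <- upper.tri(st$H0, diag = TRUE)
  c(as.vector(st$lam),
    st$G0[ut6],
    st$H0[ut3],
    c(st$R0[1, 1], st$R0[2, 2], st$R0[1, 2], st$R0[1, 3], st$R0[2, 3]),
    as.vector(st$b),
    if (d$C_cd > 3L) st$tau[3:(d$C_cd - 1L)] else numeric(0))
}

# one full chain; returns draw matrix plus running means of the random
# effects over retained iterations
run_chain <- function(d, variant, priors, control, chain_seed, fix_lambda,
                      verbose = FALSE) {
  set.seed(chain_seed)
  st <- init_state(d, variant, d$C_cd, fix_lambda)
  nms <- draw_names(d, variant)
  n_keep <- (control$n_iter - control$burn_in) %/% control$thin
  draws <- matrix(NA_real_, n_keep, length(nms), dimnames = list(NULL, nms))
  h_sum <- st$h * 0; u_sum <- st$u * 0
  kept <- 0L
  update_lambda <- variant != "SMM" && is.null(fix_lambda)
  d$XtX <- crossprod(d$X)
  for (it in seq_len(control$n_iter)) {
    mu <- location_mu(d, st)
    st <- if (variant == "SMM") sample_liabilities_smm(d, st, mu)
          else sample_liabilities_rmm(d, st, mu)
    w <- working_w(d, st)
    R0inv <- chol2inv(chol(st$R0))
    st <- sample_b(d, st, w, R0inv)
    st <- sample_h(d, st, w, R0inv, chol2inv(chol(st$H0)))
    st <- sample_bulls(d, st, w, R0inv, chol2inv(chol(st$G0)))
    mu <- location_mu(d, st)
    if (update_lambda) st <- sample_lambda(d, st, mu, priors)
    st <- sample_thresholds(d, st)
    st <- sample_dispersion(d, st, mu, variant, priors)
    if (it > control$burn_in && (it - control$burn_in) %% control$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- flatten_state(d, st)
      h_sum <- h_sum + st$h
      u_sum <- u_sum + st$u
    }
    if (verbose && it %% 1000L == 0L)
      message(sprintf("chain seed %d: iteration %d/%d", chain_seed, it,
                      control$n_iter))
  }
  list(draws = draws, h_mean = h_sum / max(kept, 1L),
       u_mean = u_sum / max(kept, 1L))
}

#' Fit a standard or recursive threshold mixed model
#'
#' Fits a three-trait sire-maternal-grandsire model for gestation length
#' (GL, continuous), calving difficulty (CD) and stillbirth (SB) (ordinal, on
#' the liability scale) by Gibbs sampling with data augmentation. Four
#' variants are supported: the standard mixed model (\code{"SMM"}, no
#' recursion, unstructured covariance matrices) and three recursive models in
#' which GL affects the liabilities to CD and SB and the CD liability affects
#' the SB liability, with rates that change across GL categories:
#' \code{"RMM1"} (diagonal residual matrix), \code{"RMM2"} (diagonal residual
#' and herd-year matrices) and \code{"RMM3"} (additionally per-trait
#' sire/MGS genetic blocks). Identification: the first CD threshold and the
#' SB threshold are 0, the second CD threshold is 1, and the SB residual
#' variance is 1.
#'
#' @param records data.frame of calf records with columns \code{record_id},
#'   \code{sire_id}, \code{mgs_id}, \code{herd_year_id}, \code{sex},
#'   \code{age_class}, \code{year_season}, \code{gl_days}, \code{cd_score},
#'   \code{sb_score}.
#' @param variant model variant.
#' @param map GL category map (\code{\link{gl_category_map}}).
#' @param C_cd number of CD categories.
#' @param gl_ref reference gestation length (days) subtracted from GL in the
#'   recursive terms; defaults to the rounded sample mean.
#' @param priors a \code{\link{rmm_priors}} object.
#' @param control a \code{\link{rmm_control}} object.
#' @param fix_lambda optional 3 x K matrix (rows: CD<-GL, SB<-GL, SB<-CD) at
#'   which the structural coefficients are held fixed instead of sampled.
#' @return An object of class \code{"rmm"}: list with the retained
#'   \code{draws} matrix (named columns, all chains stacked), \code{chain}
#'   index per draw, posterior means of the random effects, the data
#'   preparation, and the fit configuration.
#' @seealso \code{\link{summary.rmm}}, \code{\link{fitted.rmm}},
#'   \code{\link{genetic_summary}}, \code{\link{goodness_of_fit}},
#'   \code{\link{cross_validate}}
#' @examples
#' \donttest{
#' sim <- simulate_calving_data(sim_design(400), seed = 1)
#' fit <- rmm(sim$records, "RMM3",
#'            control = rmm_control(n_chains = 1, n_iter = 300, burn_in = 100,
#'                                  thin = 5, seed = 1))
#' coef(fit)
#' }
#' @export
rmm <- function(records, variant = c("RMM1", "RMM2", "RMM3", "SMM"),
                map = gl_category_map(), C_cd = 3L, gl_ref = NULL,
                priors = rmm_priors(), control = rmm_control(),
                fix_lambda = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(priors, "rmm_priors"), inherits(control, "rmm_control"))
  if (!is.null(fix_lambda)) {
    fix_lambda <- as.matrix(fix_lambda)
    stopifnot(nrow(fix_lambda) == 3, ncol(fix_lambda) == map$n_categories)
  }
  d <- prepare_rmm_data(records, map, C_cd, gl_ref)
  chains <- vector("list", control$n_chains)
  for (cc in seq_len(control$n_chains)) {
    chains[[cc]] <- run_chain(d, variant, priors, control,
                              chain_seed = control$seed + cc - 1L,
                              fix_lambda = fix_lambda,
                              verbose = isTRUE(control$verbose))
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(control$n_chains), each = nrow(chains[[1]]$draws))
  h_mean <- Reduce(`+`, lapply(chains, `[[`, "h_mean")) / control$n_chains
  u_mean <- Reduce(`+`, lapply(chains, `[[`, "u_mean")) / control$n_chains
  rownames(h_mean) <- d$herds
  rownames(u_mean) <- d$bulls
  pm <- colMeans(draws)
  K <- d$K
  lam_hat <- matrix(pm[seq_len(3 * K)], 3, K,
                    dimnames = list(c("cd_gl", "sb_gl", "sb_cd"), NULL))
  if (!is.null(fix_lambda)) lam_hat <- fix_lambda
  tau_hat <- c(0, 1)
  if (d$C_cd > 3L)
    tau_hat <- c(tau_hat, pm[paste0("tau_cd[", 3:(d$C_cd - 1L), "]")])
  b_hat <- matrix(pm[paste0("b[", rep(colnames(d$X), 3), ",",
                            rep(trait_names, each = d$p), "]")],
                  d$p, 3, dimnames = list(colnames(d$X), trait_names))
  out <- list(call = match.call(), variant = variant, data = d,
              priors = priors, control = control, fix_lambda = fix_lambda,
              draws = draws, chain = chain_id,
              post_mean = list(b = b_hat, h = h_mean, u = u_mean,
                               lambda = lam_hat, tau_cd = tau_hat,
                               G0 = mean_matrix(draws, "G0", 6),
                               H0 = mean_matrix(draws, "H0", 3),
                               R0 = mean_R0(draws)))
  class(out) <- "rmm"
  out
}

mean_matrix <- function(draws, name, p) {
  M <- matrix(0, p, p)
  ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  v <- colMeans(draws[, paste0(name, "[", ut[, 1], ",", ut[, 2], "]"),
                      drop = FALSE])
  M[upper.tri(M, diag = TRUE)] <- v
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

mean_R0 <- function(draws) {
  R <- diag(3)
  R[1, 1] <- mean(draws[, "R0[1,1]"])
  R[2, 2] <- mean(draws[, "R0[2,2]"])
  R[1, 2] <- R[2, 1] <- mean(draws[, "R0[1,2]"])
  R[1, 3] <- R[3, 1] <- mean(draws[, "R0[1,3]"])
  R[2, 3] <- R[3, 2] <- mean(draws[, "R0[2,3]"])
  R
}
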