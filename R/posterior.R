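#' Highest posterior density interval
#'
#' Shortest interval containing \code{ceiling(mass * n)} of the sorted draws.
#'
#' @param draws numeric vector of posterior draws (at least 100).
#' @param mass probability mass in (0, 1).
#' @return numeric vector \code{c(lower, upper)}.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws for an HPD interval")
  stopifnot(mass > 0, mass < 1)
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  width <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + m])
}

#' Monte Carlo standard error (batch means)
#'
#' Batch-means estimator of the Monte Carlo standard error of the posterior
#' mean, with \code{floor(sqrt(n))} batches; robust to the autocorrelation a
#' Gibbs chain leaves after thinning.
#'
#' @param draws numeric vector (at least 100).
#' @return non-negative scalar.
#' @export
mcse <- function(draws) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws for an MCSE")
  nb <- floor(sqrt(n))
  m <- n %/% nb
  bm <- colMeans(matrix(draws[seq_len(nb * m)], m, nb))
  stats::sd(bm) / sqrt(nb)
}

# effective sample size implied by the batch-means MCSE
ess_batch <- function(draws) {
  s <- stats::sd(draws)
  if (s == 0) return(length(draws))
  (s / mcse(draws))^2
}

# split-Rhat across chains (each chain split in half)
split_rhat <- function(draws, chain) {
  halves <- list()
  for (c in unique(chain)) {
    x <- draws[chain == c]
    h <- length(x) %/% 2L
    if (h < 2L) return(NA_real_)
    halves <- c(halves, list(x[seq_len(h)], x[h + seq_len(h)]))
  }
  m <- length(halves); nn <- lengths(halves)[1]
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Posterior summary table for a fitted model
#'
#' Per parameter: posterior mean and SD, 95\% and 90\% HPD bounds, Monte
#' Carlo standard error (batch means), effective sample size and split R-hat
#' (values above ~1.05 flag non-convergence).
#'
#' @param object an \code{\link{rmm}} fit.
#' @param pars optional character vector of parameter names (default: all).
#' @param ... unused.
#' @return data.frame of class \code{"summary.rmm"}.
#' @export
summary.rmm <- function(object, pars = NULL, ...) {
  draws <- object$draws
  if (!is.null(pars)) draws <- draws[, pars, drop = FALSE]
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    t(apply(draws, 2, hpd_interval, mass = 0.95)),
    t(apply(draws, 2, hpd_interval, mass = 0.90)),
    mcse = apply(draws, 2, mcse),
    ess = apply(draws, 2, ess_batch),
    rhat = apply(draws, 2, split_rhat, chain = object$chain),
    row.names = NULL, check.names = FALSE)
  names(out)[4:7] <- c("hpd95_lo", "hpd95_hi", "hpd90_lo", "hpd90_hi")
  class(out) <- c("summary.rmm", "data.frame")
  attr(out, "variant") <- object$variant
  out
}

#' @export
print.summary.rmm <- function(x, digits = 4, ...) {
  cat("Posterior summaries (", attr(x, "variant"), ", ",
      nrow(x), " parameters)\n", sep = "")
  df <- x
  class(df) <- "data.frame"
  df[-1] <- lapply(df[-1], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

# rebuild (lambda, G0, H0, R0) from one draw row
state_from_draw <- function(row, K) {
  lam <- matrix(row[seq_len(3 * K)], 3, K)
  G0 <- matrix(0, 6, 6)
  ut <- which(upper.tri(G0, diag = TRUE), arr.ind = TRUE)
  G0[upper.tri(G0, diag = TRUE)] <-
    row[paste0("G0[", ut[, 1], ",", ut[, 2], "]")]
  G0[lower.tri(G0)] <- t(G0)[lower.tri(G0)]
  H0 <- matrix(0, 3, 3)
  ut <- which(upper.tri(H0, diag = TRUE), arr.ind = TRUE)
  H0[upper.tri(H0, diag = TRUE)] <-
    row[paste0("H0[", ut[, 1], ",", ut[, 2], "]")]
  H0[lower.tri(H0)] <- t(H0)[lower.tri(H0)]
  R0 <- diag(3)
  R0[1, 1] <- row["R0[1,1]"]; R0[2, 2] <- row["R0[2,2]"]
  R0[1, 2] <- R0[2, 1] <- row["R0[1,2]"]
  R0[1, 3] <- R0[3, 1] <- row["R0[1,3]"]
  R0[2, 3] <- R0[3, 2] <- row["R0[2,3]"]
  list(lam = lam, G0 = G0, H0 = H0, R0 = R0)
}

derived_names <- function() {
  pairs <- c("GL_CD", "GL_SB", "CD_SB")
  c(paste0("h2_direct_", trait_names), paste0("h2_maternal_", trait_names),
    paste0("cor_direct_", pairs), paste0("cor_maternal_", pairs),
    paste0("cor_dm_", trait_names),
    paste0("cor_herd_", pairs), paste0("cor_residual_", pairs),
    "overall_gl_sb")
}

derived_from_state <- function(stt, variant, k, include_herd = FALSE) {
  coeffs <- structural_coefficients(stt$lam[1, ], stt$lam[2, ], stt$lam[3, ])
  disp <- dispersion_set(stt$G0, stt$H0, stt$R0, variant)
  gp <- genetic_parameters(disp, coeffs, k, include_herd = include_herd)
  up <- cbind(c(1, 1, 2), c(2, 3, 3))
  c(gp$h2_direct, gp$h2_maternal,
    gp$cor_direct[up], gp$cor_maternal[up],
    diag(gp$cor_direct_maternal),
    gp$cor_herd[up], gp$cor_residual[up],
    overall_effect_gl_sb(coeffs, k))
}

#' Posterior distributions of derived genetic parameters
#'
#' Applies the reduced-form and direct/maternal transformations to every
#' retained draw (not to posterior means), per GL category: heritabilities,
#' genetic/herd/residual correlations and the overall GL->SB effect; then
#' summarizes each derived quantity with mean, SD, HPD intervals and MCSE.
#' Draws whose implied per-trait (direct, maternal) block is not positive
#' semidefinite are counted, never dropped.
#'
#' @param object an \code{\link{rmm}} fit.
#' @param include_herd include the herd-year variance in the phenotypic
#'   variance used for heritabilities.
#' @return list with \code{summary} (data.frame: category, parameter, mean,
#'   sd, hpd95/90 bounds, mcse), \code{draws} (list of matrices, one per GL
#'   category) and \code{n_not_psd}.
#' @export
genetic_summary <- function(object, include_herd = FALSE) {
  stopifnot(inherits(object, "rmm"))
  K <- object$data$K
  nms <- derived_names()
  n_draw <- nrow(object$draws)
  out <- lapply(seq_len(K), function(k)
    matrix(NA_real_, n_draw, length(nms), dimnames = list(NULL, nms)))
  n_not_psd <- 0L
  for (i in seq_len(n_draw)) {
    stt <- state_from_draw(object$draws[i, ], K)
    for (k in seq_len(K)) {
      v <- derived_from_state(stt, object$variant, k, include_herd)
      out[[k]][i, ] <- v
    }
    W <- willham_transform(reduced_form_covariances(
      dispersion_set(stt$G0, stt$H0, stt$R0, object$variant),
      structural_coefficients(stt$lam[1, ], stt$lam[2, ], stt$lam[3, ]),
      1)$genetic)
    if (!all(W$psd_ok)) n_not_psd <- n_not_psd + 1L
  }
  summ <- do.call(rbind, lapply(seq_len(K), function(k) {
    m <- out[[k]]
    data.frame(category = k, parameter = nms,
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               t(apply(m, 2, hpd_interval, 0.95)),
               t(apply(m, 2, hpd_interval, 0.90)),
               mcse = apply(m, 2, mcse), row.names = NULL,
               check.names = FALSE)
  }))
  names(summ)[5:8] <- c("hpd95_lo", "hpd95_hi", "hpd90_lo", "hpd90_hi")
  list(summary = summ, draws = out, n_not_psd = n_not_psd)
}
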