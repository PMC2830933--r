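#' Category probabilities from a liability expectation
#'
#' P(category c) = Phi(tau_c - lhat) - Phi(tau_{c-1} - lhat) with tau_0 =
#' -Inf and tau_C = +Inf, where Phi is the standard normal CDF.
#'
#' @param liability_mean numeric vector of expected liabilities.
#' @param thr increasing numeric vector of thresholds (length C - 1).
#' @return matrix (length(liability_mean) x C) of probabilities; rows sum
#'   to 1.
#' @examples
#' category_probabilities(0, c(0, 1))   # 0.5, 0.3413, 0.1587
#' @export
category_probabilities <- function(liability_mean, thr) {
  if (is.unsorted(thr, strictly = TRUE)) stop("thresholds must be increasing")
  cuts <- c(-Inf, thr, Inf)
  P <- vapply(seq_len(length(cuts) - 1L), function(c)
    stats::pnorm(cuts[c + 1] - liability_mean) -
      stats::pnorm(cuts[c] - liability_mean),
    numeric(length(liability_mean)))
  P <- matrix(P, nrow = length(liability_mean))
  colnames(P) <- paste0("cat", seq_len(ncol(P)))
  P
}

#' Expected ordinal score
#'
#' Weighted category score sum(c * P(c)) with categories coded 1..C; the
#' fitted/predicted phenotype for the ordinal traits.
#'
#' @param probabilities matrix of category probabilities (rows sum to 1) or a
#'   single probability vector.
#' @return numeric vector of expected scores.
#' @export
expected_score <- function(probabilities) {
  if (is.null(dim(probabilities)))
    probabilities <- matrix(probabilities, nrow = 1)
  if (any(abs(rowSums(probabilities) - 1) > 1e-8))
    stop("probabilities must sum to 1")
  drop(probabilities %*% seq_len(ncol(probabilities)))
}

# plug-in fitted values at posterior means of the unknowns, for the records
# used in the fit or for new data. Returns GL expectation (days), expected CD
# and SB liabilities and expected scores.
plugin_fitted <- function(object, records = NULL) {
  d <- object$data
  pm <- object$post_mean
  if (is.null(records)) {
    X <- d$X; hi <- d$hi; si <- d$si; mi <- d$mi
    k <- d$k; glc <- d$glc
    h <- pm$h; u <- pm$u
    mu <- X %*% pm$b + h[hi, , drop = FALSE] + u[si, 1:3, drop = FALSE] +
      u[mi, 4:6, drop = FALSE]
  } else {
    X <- build_X(records, levels = d$levels)
    k <- gl_category(records$gl_days, d$map)
    glc <- records$gl_days - d$gl_ref
    hz <- match(records$herd_year_id, d$herds)
    sz <- match(records$sire_id, d$bulls)
    mz <- match(records$mgs_id, d$bulls)
    eff <- function(tab, idx, cols) {
      out <- matrix(0, nrow(records), 3)
      ok <- !is.na(idx)
      out[ok, ] <- tab[idx[ok], cols, drop = FALSE]
      out
    }
    mu <- X %*% pm$b + eff(pm$h, hz, 1:3) + eff(pm$u, sz, 1:3) +
      eff(pm$u, mz, 4:6)
  }
  lam <- pm$lambda
  if (object$variant == "SMM") {
    l_cd <- mu[, 2]; l_sb <- mu[, 3]
  } else {
    l_cd <- lam[1, k] * glc + mu[, 2]
    l_sb <- lam[2, k] * glc + lam[3, k] * l_cd + mu[, 3]
  }
  data.frame(
    gl = mu[, 1] + d$gl_ref,
    l_cd = l_cd, l_sb = l_sb,
    cd = expected_score(category_probabilities(l_cd, pm$tau_cd)),
    sb = expected_score(category_probabilities(l_sb, 0)))
}

fit_metrics <- function(fitted, records) {
  obs <- cbind(GL = records$gl_days, CD = records$cd_score,
               SB = records$sb_score)
  pred <- cbind(GL = fitted$gl, CD = fitted$cd, SB = fitted$sb)
  do.call(rbind, lapply(1:3, function(t) {
    r <- if (stats::sd(obs[, t]) == 0 || stats::sd(pred[, t]) == 0)
      NA_real_ else stats::cor(obs[, t], pred[, t])
    data.frame(trait = colnames(obs)[t],
               mse = mean((obs[, t] - pred[, t])^2),
               pearson_r = r)
  }))
}

#' Goodness of fit at the posterior means
#'
#' Mean squared error and Pearson correlation between fitted and observed
#' phenotypes, per trait, evaluated at the posterior means of the unknowns.
#' GL is fitted by its expectation (linear predictor, no residual); CD and SB
#' by the expected category score implied by the plug-in liability
#' expectation and the thresholds.
#'
#' @param object an \code{\link{rmm}} fit.
#' @return data.frame with columns \code{trait}, \code{mse},
#'   \code{pearson_r}.
#' @export
goodness_of_fit <- function(object) {
  stopifnot(inherits(object, "rmm"))
  fit_metrics(plugin_fitted(object), object$data$records)
}

#' Random cross-validation folds
#'
#' @param n number of records.
#' @param n_folds number of folds (default 3).
#' @param seed integer seed.
#' @return integer vector of fold assignments; fold sizes differ by at most
#'   one.
#' @export
cv_folds <- function(n, n_folds = 3L, seed = 1L) {
  set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}

#' Cross-validated predictive ability
#'
#' Randomly partitions the records into three (by default) disjoint subsets
#' of near-equal size; for each fold, fits the model on the other folds and
#' predicts the held-out records using the posterior means of the training
#' fit (herd/sire/MGS levels unseen in training contribute 0). MSE and
#' Pearson correlation are computed once on the concatenation of the three
#' test sets.
#'
#' @inheritParams rmm
#' @param n_folds number of folds.
#' @param cv_seed seed for the fold assignment.
#' @return list with \code{metrics} (per-trait data.frame), \code{folds} and
#'   \code{predicted} (concatenated test-set predictions, in record order).
#' @export
cross_validate <- function(records, variant = c("RMM1", "RMM2", "RMM3", "SMM"),
                           map = gl_category_map(), C_cd = 3L, gl_ref = NULL,
                           priors = rmm_priors(), control = rmm_control(),
                           n_folds = 3L, cv_seed = 1L) {
  variant <- match.arg(variant)
  n <- nrow(records)
  folds <- cv_folds(n, n_folds, cv_seed)
  if (is.null(gl_ref)) gl_ref <- round(mean(records$gl_days))
  pred <- data.frame(gl = rep(NA_real_, n), l_cd = NA_real_, l_sb = NA_real_,
                     cd = NA_real_, sb = NA_real_)
  for (f in seq_len(n_folds)) {
    test <- folds == f
    if (!any(test)) stop("fold ", f, " has no records")
    fit <- rmm(records[!test, , drop = FALSE], variant, map = map,
               C_cd = C_cd, gl_ref = gl_ref, priors = priors,
               control = control)
    pred[test, ] <- plugin_fitted(fit, records[test, , drop = FALSE])
  }
  list(metrics = fit_metrics(pred, records), folds = folds, predicted = pred)
}

#' Concordance of fitted values between two models
#'
#' Pearson correlations between the plug-in fitted GL expectations and the
#' expected CD and SB liabilities of two fits on the same records; used to
#' compare the standard and recursive variants (the GL equation is identical
#' across variants, so its concordance is expected to be near 1).
#'
#' @param fit_a,fit_b \code{\link{rmm}} fits on identical records.
#' @return named numeric vector with entries \code{GL}, \code{CD}, \code{SB}.
#' @export
concordance <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "rmm"), inherits(fit_b, "rmm"))
  if (!identical(fit_a$data$records$record_id, fit_b$data$records$record_id))
    stop("fits are not on identical record sets")
  fa <- plugin_fitted(fit_a); fb <- plugin_fitted(fit_b)
  c(GL = stats::cor(fa$gl, fb$gl),
    CD = stats::cor(fa$l_cd, fb$l_cd),
    SB = stats::cor(fa$l_sb, fb$l_sb))
}
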