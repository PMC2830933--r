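#' @export
print.rmm <- function(x, ...) {
  d <- x$data
  cat("Recursive threshold mixed model (", x$variant, ")\n", sep = "")
  cat(sprintf("  %d records, %d sires/MGS bulls, %d herd-years, %d GL categories\n",
              d$n, length(d$bulls), length(d$herds), d$K))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d retained draws\n",
              x$control$n_chains, x$control$n_iter, x$control$burn_in,
              x$control$thin, nrow(x$draws)))
  cat(sprintf("  free dispersion + structural parameters: %d\n",
              count_free_parameters(x$variant, d$K, d$C_cd)))
  if (x$variant != "SMM") {
    cat("  posterior mean structural coefficients:\n")
    m <- x$post_mean$lambda
    colnames(m) <- paste0("k", seq_len(ncol(m)))
    print(round(m, 4))
  }
  invisible(x)
}

#' Posterior-mean coefficients
#'
#' @param object an \code{\link{rmm}} fit.
#' @param which \code{"lambda"} for the structural coefficients (default),
#'   \code{"b"} for fixed effects, \code{"all"} for every stored parameter.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.rmm <- function(object, which = c("lambda", "b", "all"), ...) {
  which <- match.arg(which)
  pm <- colMeans(object$draws)
  if (which == "all") return(pm)
  pref <- if (which == "lambda") "^lambda_" else "^b\\["
  pm[grepl(pref, names(pm))]
}

#' Fitted phenotypes at the posterior means
#'
#' @param object an \code{\link{rmm}} fit.
#' @param type \code{"score"} for the GL expectation and expected CD/SB
#'   category scores (the scale on which fit is assessed), or
#'   \code{"liability"} for the GL expectation and expected liabilities.
#' @param ... unused.
#' @return n x 3 matrix with columns GL, CD, SB.
#' @export
fitted.rmm <- function(object, type = c("score", "liability"), ...) {
  type <- match.arg(type)
  f <- plugin_fitted(object)
  out <- if (type == "score") cbind(GL = f$gl, CD = f$cd, SB = f$sb)
         else cbind(GL = f$gl, CD = f$l_cd, SB = f$l_sb)
  rownames(out) <- object$data$records$record_id
  out
}

#' Predict phenotypes for new records
#'
#' Plug-in prediction at the posterior means of the training fit. Herd, sire
#' or MGS identities unseen in training contribute 0; fixed-effect levels
#' unseen in training fall back to the baseline level.
#'
#' @param object an \code{\link{rmm}} fit.
#' @param newdata record data.frame (the phenotype columns \code{cd_score}
#'   and \code{sb_score} are not used; \code{gl_days} is, because observed GL
#'   drives the recursion).
#' @param type as in \code{\link{fitted.rmm}}.
#' @param ... unused.
#' @return matrix with columns GL, CD, SB.
#' @export
predict.rmm <- function(object, newdata = NULL,
                        type = c("score", "liability"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(fitted(object, type = type))
  f <- plugin_fitted(object, newdata)
  if (type == "score") cbind(GL = f$gl, CD = f$cd, SB = f$sb)
  else cbind(GL = f$gl, CD = f$l_cd, SB = f$l_sb)
}

#' Residuals on the phenotype scale
#'
#' Observed phenotype minus fitted value: days for GL, score units for CD and
#' SB.
#'
#' @param object an \code{\link{rmm}} fit.
#' @param ... unused.
#' @return n x 3 matrix.
#' @export
residuals.rmm <- function(object, ...) {
  f <- fitted(object)
  r <- object$data$records
  cbind(GL = r$gl_days - f[, "GL"], CD = r$cd_score - f[, "CD"],
        SB = r$sb_score - f[, "SB"])
}

#' Trace plots of retained draws
#'
#' @param x an \code{\link{rmm}} fit.
#' @param pars parameter names to plot (default: the structural coefficients,
#'   or the residual variances for SMM).
#' @param ... passed to \code{matplot}.
#' @export
plot.rmm <- function(x, pars = NULL, ...) {
  if (is.null(pars)) {
    pars <- if (x$variant == "SMM")
      c("R0[1,1]", "R0[2,2]", "R0[1,2]") else
      grep("^lambda_", colnames(x$draws), value = TRUE)[1:3]
  }
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  per_chain <- nrow(x$draws) / x$control$n_chains
  for (p in pars) {
    m <- matrix(x$draws[, p], per_chain, x$control$n_chains)
    graphics::matplot(m, type = "l", lty = 1, ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' @export
as.matrix.rmm <- function(x, ...) x$draws
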