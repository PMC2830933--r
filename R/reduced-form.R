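#' Reduced-form (co)variance matrices for one GL category
#'
#' Solving the recursion out of the structural system (premultiplying by
#' Lambda_k^-1) induces category-dependent covariance structures: the genetic
#' blocks become Lambda^-1 S0 Lambda^-T, Lambda^-1 M0 Lambda^-T and
#' Lambda^-1 C_sm Lambda^-T, the herd-year matrix Lambda^-1 H0 Lambda^-T and
#' the residual matrix Lambda^-1 R0 Lambda^-T. With all rates zero the
#' transformation is the identity (the standard mixed model embedding).
#'
#' @param disp a \code{\link{dispersion_set}}.
#' @param coeffs a \code{\link{structural_coefficients}} object.
#' @param k GL category index.
#' @return list with \code{genetic} (6x6), \code{herd} (3x3) and
#'   \code{residual} (3x3) reduced-form matrices.
#' @export
reduced_form_covariances <- function(disp, coeffs, k) {
  stopifnot(inherits(disp, "dispersion_set"))
  L <- build_lambda(coeffs, k)
  Li <- solve(L)
  stopifnot(all(is.finite(Li)))
  Li6 <- kronecker(diag(2), Li)
  genetic <- Li6 %*% disp$G0 %*% t(Li6)
  herd <- Li %*% disp$H0 %*% t(Li)
  residual <- Li %*% disp$R0 %*% t(Li)
  # congruence keeps exact symmetry up to round-off; tidy it
  genetic <- (genetic + t(genetic)) / 2
  herd <- (herd + t(herd)) / 2
  residual <- (residual + t(residual)) / 2
  nm6 <- paste(rep(c("s", "mgs"), each = 3), trait_names, sep = "_")
  dimnames(genetic) <- list(nm6, nm6)
  dimnames(herd) <- dimnames(residual) <- list(trait_names, trait_names)
  list(genetic = genetic, herd = herd, residual = residual)
}

#' Direct and maternal genetic (co)variances from sire-MGS components
#'
#' Under the sire-maternal-grandsire parameterization a sire transmits half
#' the direct breeding value (s = a_d / 2) and a maternal grandsire a quarter
#' of the direct plus half the maternal breeding value
#' (mgs = a_d / 4 + a_m / 2). Inverting, a_d = 2 s and a_m = 2 mgs - s, so
#' per trait sigma2_d = 4 sigma2_s, sigma_dm = 4 sigma_s,mgs - 2 sigma2_s and
#' sigma2_m = 4 sigma2_mgs + sigma2_s - 4 sigma_s,mgs; between-trait
#' (co)variances follow from the same bilinear expansion.
#'
#' @param G 6x6 genetic matrix over (s_GL, s_CD, s_SB, mgs_GL, mgs_CD,
#'   mgs_SB), structural or reduced-form scale.
#' @return An object of class \code{"willham_params"}: a list with the 6x6
#'   direct/maternal matrix \code{A} (ordered d_GL, d_CD, d_SB, m_GL, m_CD,
#'   m_SB), per-trait \code{var_direct}, \code{var_maternal},
#'   \code{cov_direct_maternal}, and a logical \code{psd_ok} flag per trait
#'   (FALSE when the implied per-trait (direct, maternal) 2x2 block is not
#'   positive semidefinite, which can happen for individual posterior draws).
#' @examples
#' G <- diag(6); G[1, 4] <- G[4, 1] <- 0.5
#' willham_transform(G)$var_maternal  # trait GL: 4*1 + 1 - 4*0.5 = 3
#' @export
willham_transform <- function(G) {
  G <- as.matrix(G)
  stopifnot(all(dim(G) == c(6, 6)))
  # (a_d, a_m) = T (s, mgs) with T = [[2, 0], [-1, 2]], applied per trait
  Tm <- kronecker(matrix(c(2, -1, 0, 2), 2, 2), diag(3))
  A <- Tm %*% G %*% t(Tm)
  A <- (A + t(A)) / 2
  nm <- paste(rep(c("d", "m"), each = 3), trait_names, sep = "_")
  dimnames(A) <- list(nm, nm)
  vd <- diag(A)[1:3]; vm <- diag(A)[4:6]
  cdm <- A[cbind(1:3, 4:6)]
  psd_ok <- vd >= 0 & vm >= 0 & (vd * vm - cdm^2) >= -1e-10 * pmax(vd * vm, 1)
  names(vd) <- names(vm) <- names(cdm) <- names(psd_ok) <- trait_names
  structure(list(A = A, var_direct = vd, var_maternal = vm,
                 cov_direct_maternal = cdm, psd_ok = psd_ok),
            class = "willham_params")
}

# inverse of willham_transform's linear map; used by tests and simulation
# set-up: from a 6x6 direct/maternal matrix back to sire-MGS scale
willham_inverse <- function(A) {
  Tm <- kronecker(matrix(c(2, -1, 0, 2), 2, 2), diag(3))
  Ti <- solve(Tm)
  G <- Ti %*% as.matrix(A) %*% t(Ti)
  (G + t(G)) / 2
}

#' Derived genetic parameters for one GL category
#'
#' Transforms the dispersion components to the reduced form for category k,
#' converts sire-MGS blocks to direct/maternal (co)variances, and reports
#' heritabilities and correlations. The phenotypic variance per trait is
#' sigma2_s + sigma2_mgs + sigma_s,mgs + sigma2_e on the reduced-form scale
#' (herd-year variance added when \code{include_herd} is TRUE).
#'
#' @inheritParams reduced_form_covariances
#' @param include_herd logical; add the herd-year variance to the phenotypic
#'   variance used in heritabilities.
#' @return list with elements \code{k}, the reduced-form matrices,
#'   \code{willham}, per-trait \code{h2_direct}, \code{h2_maternal},
#'   \code{var_phenotypic}, and correlation matrices \code{cor_direct},
#'   \code{cor_maternal}, \code{cor_direct_maternal} (direct trait i vs
#'   maternal trait j), \code{cor_herd}, \code{cor_residual}.
#' @export
genetic_parameters <- function(disp, coeffs, k, include_herd = FALSE) {
  rf <- reduced_form_covariances(disp, coeffs, k)
  W <- willham_transform(rf$genetic)
  S <- rf$genetic[1:3, 1:3]
  M <- rf$genetic[4:6, 4:6]
  C <- rf$genetic[1:3, 4:6]
  var_p <- diag(S) + diag(M) + diag(C) + diag(rf$residual)
  if (include_herd) var_p <- var_p + diag(rf$herd)
  if (any(var_p <= 0)) stop("non-positive phenotypic variance")
  h2_d <- W$var_direct / var_p
  h2_m <- W$var_maternal / var_p
  A <- W$A
  sd6 <- sqrt(pmax(diag(A), 0))
  denom <- outer(sd6, sd6)
  corA <- A / ifelse(denom > 0, denom, Inf)
  list(k = k,
       genetic = rf$genetic, herd = rf$herd, residual = rf$residual,
       willham = W,
       h2_direct = h2_d, h2_maternal = h2_m, var_phenotypic = var_p,
       cor_direct = corA[1:3, 1:3],
       cor_maternal = corA[4:6, 4:6],
       cor_direct_maternal = corA[1:3, 4:6],
       cor_herd = stats::cov2cor(rf$herd),
       cor_residual = stats::cov2cor(rf$residual))
}
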