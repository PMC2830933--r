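#' Structural (recursive) coefficients
#'
#' The recursive models postulate one-way phenotypic effects
#' GL -> l_CD, GL -> l_SB and l_CD -> l_SB, with rates that depend on the GL
#' category k. An object of this class holds one triplet of rates per
#' category: \code{cd_gl} (liability units of CD per day of GL),
#' \code{sb_gl} (liability units of SB per day of GL) and \code{sb_cd}
#' (liability units of SB per liability unit of CD).
#'
#' @param cd_gl,sb_gl,sb_cd numeric vectors of equal length (one value per
#'   GL category).
#' @return An object of class \code{"structural_coefficients"}.
#' @examples
#' structural_coefficients(cd_gl = c(0.005, 0.020, 0.032, 0.040),
#'                         sb_gl = rep(-0.03, 4),
#'                         sb_cd = rep(0.33, 4))
#' @export
structural_coefficients <- function(cd_gl, sb_gl, sb_cd) {
  n <- length(cd_gl)
  if (length(sb_gl) != n || length(sb_cd) != n)
    stop("'cd_gl', 'sb_gl' and 'sb_cd' must have one entry per GL category")
  if (!all(is.finite(c(cd_gl, sb_gl, sb_cd))))
    stop("structural coefficients must be finite")
  structure(list(cd_gl = as.numeric(cd_gl), sb_gl = as.numeric(sb_gl),
                 sb_cd = as.numeric(sb_cd), n_categories = n),
            class = "structural_coefficients")
}

#' @export
print.structural_coefficients <- function(x, ...) {
  m <- rbind(`lambda CD<-GL` = x$cd_gl, `lambda SB<-GL` = x$sb_gl,
             `lambda SB<-CD` = x$sb_cd)
  colnames(m) <- paste0("k", seq_len(x$n_categories))
  cat("Structural coefficients (", x$n_categories, " GL categories):\n",
      sep = "")
  print(round(m, 4))
  invisible(x)
}

trait_names <- c("GL", "CD", "SB")

#' Structural matrix for one GL category
#'
#' Builds the 3x3 lower-triangular matrix Lambda_k with unit diagonal that
#' encodes the recursive system Lambda_k y_i = mu_i + eps_i for records in GL
#' category k: the off-diagonal entries are the negated rates, and the GL row
#' is (1, 0, 0) because GL is upstream of both liabilities.
#'
#' @param coeffs a \code{\link{structural_coefficients}} object.
#' @param k GL category index.
#' @return 3x3 numeric matrix with rows/columns GL, CD, SB.
#' @examples
#' cf <- structural_coefficients(0.020, -0.028, 0.331)
#' build_lambda(cf, 1)
#' solve(build_lambda(cf, 1))  # accumulates positive recursion effects
#' @export
build_lambda <- function(coeffs, k) {
  stopifnot(inherits(coeffs, "structural_coefficients"))
  if (length(k) != 1L || is.na(k) || k < 1L || k > coeffs$n_categories)
    stop("invalid GL category index 'k'")
  L <- diag(3)
  L[2, 1] <- -coeffs$cd_gl[k]
  L[3, 1] <- -coeffs$sb_gl[k]
  L[3, 2] <- -coeffs$sb_cd[k]
  dimnames(L) <- list(trait_names, trait_names)
  L
}

#' Overall effect of gestation length on stillbirth liability
#'
#' The total rate of change of the SB liability per day of GL in category k is
#' the direct rate plus the indirect path through calving difficulty:
#' \code{sb_gl[k] + cd_gl[k] * sb_cd[k]}. It equals the (SB, GL) entry of
#' \code{solve(build_lambda(coeffs, k))}.
#'
#' @inheritParams build_lambda
#' @return numeric scalar, liability units of SB per day of GL.
#' @export
overall_effect_gl_sb <- function(coeffs, k) {
  stopifnot(inherits(coeffs, "structural_coefficients"))
  if (length(k) != 1L || is.na(k) || k < 1L || k > coeffs$n_categories)
    stop("invalid GL category index 'k'")
  coeffs$sb_gl[k] + coeffs$cd_gl[k] * coeffs$sb_cd[k]
}

#' Liability thresholds for the ordinal traits
#'
#' For identification, the first CD threshold and the SB threshold are fixed
#' at 0 and the second CD threshold at 1; with more than three CD categories
#' the remaining thresholds are free and sampled.
#'
#' @param C_cd number of calving-difficulty categories (>= 3).
#' @param cd_free numeric vector of free CD thresholds beyond the fixed
#'   (0, 1); length \code{C_cd - 3}.
#' @return list with \code{cd} (length \code{C_cd - 1}, first two fixed),
#'   \code{cd_fixed} (logical flags) and \code{sb} (0).
#' @export
thresholds <- function(C_cd = 3L, cd_free = numeric(0)) {
  C_cd <- as.integer(C_cd)
  if (C_cd < 3L) stop("'C_cd' must be at least 3 (thresholds 0 and 1 fixed)")
  if (length(cd_free) != C_cd - 3L)
    stop("need ", C_cd - 3L, " free CD thresholds")
  cd <- c(0, 1, as.numeric(cd_free))
  if (is.unsorted(cd, strictly = TRUE))
    stop("CD thresholds must be strictly increasing")
  list(cd = cd, cd_fixed = c(TRUE, TRUE, rep(FALSE, C_cd - 3L)), sb = 0)
}

model_variants <- c("SMM", "RMM1", "RMM2", "RMM3")

#' Dispersion (co)variance components
#'
#' Bundles the structural-scale covariance components of the model: the 6x6
#' genetic matrix \code{G0} over (sire GL, sire CD, sire SB, MGS GL, MGS CD,
#' MGS SB), the 3x3 herd-year matrix \code{H0} and the 3x3 residual matrix
#' \code{R0} whose (SB, SB) entry is fixed at 1 for identification, together
#' with the model variant whose constraint mask they must satisfy:
#' \describe{
#'   \item{SMM}{no recursion; all three matrices unstructured.}
#'   \item{RMM1}{\code{R0} diagonal (residual correlations arise only through
#'     the recursion).}
#'   \item{RMM2}{\code{R0} and \code{H0} diagonal.}
#'   \item{RMM3}{\code{R0}, \code{H0} diagonal and \code{G0} reduced to
#'     per-trait 2x2 (sire, MGS) blocks: the sire, MGS and sire-MGS blocks are
#'     all diagonal.}
#' }
#'
#' @param G0 6x6 symmetric positive-definite genetic matrix.
#' @param H0 3x3 herd-year matrix.
#' @param R0 3x3 residual matrix, \code{R0[3, 3] == 1}.
#' @param variant one of \code{"SMM"}, \code{"RMM1"}, \code{"RMM2"},
#'   \code{"RMM3"}.
#' @return An object of class \code{"dispersion_set"}.
#' @export
dispersion_set <- function(G0, H0, R0, variant = c("RMM1", "RMM2", "RMM3", "SMM")) {
  variant <- match.arg(variant)
  G0 <- as.matrix(G0); H0 <- as.matrix(H0); R0 <- as.matrix(R0)
  stopifnot(all(dim(G0) == c(6, 6)), all(dim(H0) == c(3, 3)),
            all(dim(R0) == c(3, 3)))
  if (max(abs(G0 - t(G0))) > 1e-8 || max(abs(H0 - t(H0))) > 1e-8 ||
      max(abs(R0 - t(R0))) > 1e-8)
    stop("G0, H0 and R0 must be symmetric")
  if (abs(R0[3, 3] - 1) > 1e-12)
    stop("R0[SB, SB] must be fixed at 1")
  x <- structure(list(G0 = G0, H0 = H0, R0 = R0, variant = variant),
                 class = "dispersion_set")
  check_variant_mask(x)
  x
}

#' @export
print.dispersion_set <- function(x, ...) {
  cat("Dispersion set (variant ", x$variant, ")\n", sep = "")
  cat("G0 (sire/MGS x GL,CD,SB):\n"); print(round(x$G0, 4))
  cat("H0 (herd-year):\n"); print(round(x$H0, 4))
  cat("R0 (residual, SB variance fixed at 1):\n"); print(round(x$R0, 4))
  invisible(x)
}

# zero masks implied by each variant; TRUE = entry must be zero
variant_mask <- function(variant) {
  off3 <- !diag(3) > 0
  G <- matrix(FALSE, 6, 6)
  H <- matrix(FALSE, 3, 3)
  R <- matrix(FALSE, 3, 3)
  if (variant %in% c("RMM1", "RMM2", "RMM3")) R <- off3
  if (variant %in% c("RMM2", "RMM3")) H <- off3
  if (variant == "RMM3") {
    G <- rbind(cbind(off3, off3), cbind(off3, off3))
  }
  list(G0 = G, H0 = H, R0 = R)
}

check_variant_mask <- function(x, tol = 1e-10) {
  m <- variant_mask(x$variant)
  if (any(m$G0) && max(abs(x$G0[m$G0])) > tol)
    stop("G0 violates the ", x$variant, " mask")
  if (any(m$H0) && max(abs(x$H0[m$H0])) > tol)
    stop("H0 violates the ", x$variant, " mask")
  if (any(m$R0) && max(abs(x$R0[m$R0])) > tol)
    stop("R0 violates the ", x$variant, " mask")
  invisible(TRUE)
}

#' Count free dispersion and structural parameters of a model variant
#'
#' Counts the free entries of the sire, MGS, sire-MGS, herd-year and residual
#' (co)variance blocks under the variant's constraint mask (the residual SB
#' variance, fixed at 1, is never counted) plus the structural coefficients
#' (three per GL category for the recursive variants, none for SMM). Location
#' parameters and free thresholds are not counted. With four GL categories the
#' counts are 41 (RMM1), 38 (RMM2), 26 (RMM3) and 32 (SMM).
#'
#' @param variant model variant name.
#' @param n_categories number of GL categories (default 4).
#' @param C_cd number of CD categories (unused in the count; retained so the
#'   signature states the model dimension explicitly).
#' @return integer.
#' @examples
#' vapply(c("RMM1", "RMM2", "RMM3", "SMM"), count_free_parameters, integer(1))
#' @export
count_free_parameters <- function(variant = c("SMM", "RMM1", "RMM2", "RMM3"),
                                  n_categories = 4L, C_cd = 3L) {
  variant <- match.arg(variant)
  n_lambda <- if (variant == "SMM") 0L else 3L * as.integer(n_categories)
  n_g <- switch(variant,
    SMM = 21L,          # full symmetric 6x6
    RMM1 = 21L,
    RMM2 = 21L,
    RMM3 = 9L)          # per-trait (s, mgs) 2x2 blocks: 3 traits x 3
  n_h <- if (variant %in% c("RMM2", "RMM3")) 3L else 6L
  n_r <- if (variant == "SMM") 5L else 2L   # SB residual variance fixed at 1
  n_g + n_h + n_r + n_lambda
}
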