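#' Simulation design for synthetic calving records
#'
#' Describes the layout of a synthetic data set with the structure of national
#' calving-ease programme records: calves distributed over sires, maternal
#' grandsires (MGS) and herd-year contemporary groups, with sex of calf
#' (2 levels), age at first calving (4 levels) and year-season (12 levels) as
#' systematic effects. A configurable fraction of MGS identities also appear
#' as sires so that the sire-MGS covariance is identifiable.
#'
#' @param n_records number of calf records.
#' @param n_sires number of service sires (default 60).
#' @param n_mgs number of maternal grandsires (default 120).
#' @param n_herd_years number of herd-year contemporary groups (default 40).
#' @param n_sex,n_age,n_year_season fixed-effect level counts (2/4/12).
#' @param gl_mean mean gestation length in days (default 278).
#' @param mgs_overlap fraction of MGS drawn from the sire list (default 0.3).
#' @return An object of class \code{"sim_design"}.
#' @export
sim_design <- function(n_records, n_sires = 60L, n_mgs = 120L,
                       n_herd_years = 40L, n_sex = 2L, n_age = 4L,
                       n_year_season = 12L, gl_mean = 278,
                       mgs_overlap = 0.3) {
  stopifnot(n_records >= 0, n_sires >= 1, n_mgs >= 1, n_herd_years >= 1,
            mgs_overlap >= 0, mgs_overlap <= 1)
  structure(list(n_records = as.integer(n_records),
                 n_sires = as.integer(n_sires), n_mgs = as.integer(n_mgs),
                 n_herd_years = as.integer(n_herd_years),
                 n_sex = as.integer(n_sex), n_age = as.integer(n_age),
                 n_year_season = as.integer(n_year_season),
                 gl_mean = gl_mean, mgs_overlap = mgs_overlap),
            class = "sim_design")
}

#' True parameters for the synthetic-data generator
#'
#' Defaults reproduce the magnitudes the recursive models estimate on US
#' Holstein first-calving data: structural coefficients near the RMM3
#' posterior means (a flat GL effect on CD liability below 268 d that rises to
#' about 0.04 liability units/day at long gestations, an SB<-CD rate of about
#' 0.32, and an overall GL->SB effect running from -0.044 to +0.025 l.u./day),
#' variance components giving a direct GL heritability near 0.39 and CD/SB
#' heritabilities below 0.1, a GL residual variance of about 16 d^2, and
#' liability intercepts placing roughly 70\% of calvings in the easiest CD
#' category and under 10\% stillbirths.
#'
#' @param b 16x3 matrix of fixed-effect values (rows: intercept, sex 2, age
#'   2..4, year-season 2..12; columns GL, CD, SB) or NULL for defaults.
#' @param coeffs a \code{\link{structural_coefficients}} object.
#' @param disp a \code{\link{dispersion_set}}.
#' @param thr output of \code{\link{thresholds}}.
#' @param gl_ref reference gestation length subtracted from GL inside the
#'   recursive terms (defaults to 278 d).
#' @return An object of class \code{"true_params"}.
#' @export
true_params <- function(b = NULL, coeffs = NULL, disp = NULL,
                        thr = thresholds(3L), gl_ref = 278) {
  if (is.null(coeffs))
    coeffs <- structural_coefficients(
      cd_gl = c(0.005, 0.021, 0.033, 0.041),
      sb_gl = c(-0.0457, -0.0277, -0.0185, 0.0119),
      sb_cd = c(0.330, 0.321, 0.319, 0.320))
  if (is.null(disp)) {
    # per-trait (sire, MGS) 2x2 blocks; diagonal across traits (RMM3-style)
    s2_s <- c(2.0, 0.030, 0.018)
    s2_m <- c(0.80, 0.022, 0.024)
    c_sm <- c(0.50, 0.008, 0.006)
    G0 <- matrix(0, 6, 6)
    diag(G0) <- c(s2_s, s2_m)
    G0[cbind(1:3, 4:6)] <- c_sm
    G0[cbind(4:6, 1:3)] <- c_sm
    H0 <- diag(c(2.0, 0.05, 0.04))
    R0 <- diag(c(16, 1.05, 1))
    disp <- dispersion_set(G0, H0, R0, "RMM3")
  }
  if (is.null(b)) {
    b <- matrix(0, 16, 3)
    b[1, ] <- c(0, -0.60, -1.45)   # intercepts; GL intercept added as gl_mean
    b[2, ] <- c(1.2, 0.25, 0.15)   # male calf: longer GL, harder calving
    b[3:5, 1] <- c(-0.5, -0.8, -1.0); b[3:5, 2] <- c(-0.10, -0.15, -0.20)
    b[6:16, 1] <- seq(-1, 1, length.out = 11)
    b[6:16, 2] <- 0.05 * sin(seq_len(11))
    b[6:16, 3] <- 0.04 * cos(seq_len(11))
  }
  stopifnot(is.matrix(b), ncol(b) == 3)
  structure(list(b = b, coeffs = coeffs, disp = disp, thr = thr,
                 gl_ref = gl_ref),
            class = "true_params")
}

#' Generate the record skeleton (ids and levels, no phenotypes)
#'
#' @param design a \code{\link{sim_design}}.
#' @param seed integer seed.
#' @return data.frame with record, sire, MGS, herd-year and fixed-effect
#'   level columns; deterministic given the seed.
#' @export
generate_design <- function(design, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n_records
  if (n > 0 && n < max(design$n_sires, design$n_mgs, design$n_herd_years))
    warning("fewer records than levels: some sires/MGS/herds will be empty")
  set.seed(seed)
  sires <- paste0("S", seq_len(design$n_sires))
  n_shared <- round(design$mgs_overlap * design$n_mgs)
  n_shared <- min(n_shared, design$n_sires)
  mgs <- c(sample(sires, n_shared),
           paste0("M", seq_len(design$n_mgs - n_shared)))
  data.frame(
    record_id = paste0("R", seq_len(n), recycle0 = TRUE),
    sire_id = sires[sample.int(design$n_sires, n, replace = TRUE)],
    mgs_id = mgs[sample.int(design$n_mgs, n, replace = TRUE)],
    herd_year_id = paste0("H", sample.int(design$n_herd_years, n, replace = TRUE),
                          recycle0 = TRUE),
    sex = sample.int(design$n_sex, n, replace = TRUE),
    age_class = sample.int(design$n_age, n, replace = TRUE),
    year_season = sample.int(design$n_year_season, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

fixed_design_matrix <- function(records, design_levels = NULL) {
  sex <- factor(records$sex, levels = design_levels$sex %||% sort(unique(records$sex)))
  age <- factor(records$age_class,
                levels = design_levels$age %||% sort(unique(records$age_class)))
  ys <- factor(records$year_season,
               levels = design_levels$year_season %||% sort(unique(records$year_season)))
  X <- stats::model.matrix(~ sex + age + ys)
  attr(X, "levels") <- list(sex = levels(sex), age = levels(age),
                            year_season = levels(ys))
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full 16-column design matrix on the truth parameterization (all levels,
# whether observed or not) for simulation
truth_design_matrix <- function(skeleton, design) {
  n <- nrow(skeleton)
  X <- matrix(0, n, 1 + (design$n_sex - 1) + (design$n_age - 1) +
                (design$n_year_season - 1))
  X[, 1] <- 1
  col <- 2L
  for (l in seq.int(2L, design$n_sex)) { X[, col] <- skeleton$sex == l; col <- col + 1L }
  for (l in seq.int(2L, design$n_age)) { X[, col] <- skeleton$age_class == l; col <- col + 1L }
  for (l in seq.int(2L, design$n_year_season)) { X[, col] <- skeleton$year_season == l; col <- col + 1L }
  X
}

#' Simulate calving records under the recursive threshold model
#'
#' Draws herd-year effects from N(0, H0), joint per-bull (sire, MGS) effects
#' from N(0, G0) — bulls present in both roles carry correlated sire and MGS
#' effects through the cross block — and residuals from N(0, R0); computes
#' gestation length, rounds it to integer days, determines its category from
#' the realized phenotype, propagates the recursion into the CD and SB
#' liabilities, and thresholds the liabilities into ordinal scores. GL is
#' never affected by the recursion.
#'
#' @param skeleton output of \code{\link{generate_design}} (or any data.frame
#'   with the same columns).
#' @param truth a \code{\link{true_params}} object.
#' @param map a \code{\link{gl_category_map}}.
#' @param gl_mean mean gestation length in days added to the GL linear
#'   predictor.
#' @param seed integer seed.
#' @return list with \code{records} (the observable data: ids, levels,
#'   \code{gl_days}, \code{cd_score}, \code{sb_score}) and \code{truth_table}
#'   (latent liabilities and simulated effects, for testing only — never read
#'   by the fitting functions).
#' @export
simulate_records <- function(skeleton, truth, map = gl_category_map(),
                             gl_mean = 278, seed = 1L) {
  stopifnot(inherits(truth, "true_params"))
  n <- nrow(skeleton)
  set.seed(seed)
  # fixed effects on the full truth parameterization
  des <- list(n_sex = max(skeleton$sex, 2L), n_age = max(skeleton$age_class, 4L),
              n_year_season = max(skeleton$year_season, 12L))
  X <- truth_design_matrix(skeleton, des)
  if (ncol(X) != nrow(truth$b))
    stop("truth$b has ", nrow(truth$b), " rows but the design implies ", ncol(X))
  xb <- X %*% truth$b

  herds <- sort(unique(skeleton$herd_year_id))
  h <- rmvn(length(herds), truth$disp$H0)
  rownames(h) <- herds

  bulls <- sort(unique(c(skeleton$sire_id, skeleton$mgs_id)))
  u <- rmvn(length(bulls), truth$disp$G0)   # cols: s_GL s_CD s_SB m_GL m_CD m_SB
  rownames(u) <- bulls

  eps <- rmvn(n, truth$disp$R0)

  hi <- match(skeleton$herd_year_id, herds)
  si <- match(skeleton$sire_id, bulls)
  mi <- match(skeleton$mgs_id, bulls)
  mu <- xb + h[hi, , drop = FALSE] + u[si, 1:3, drop = FALSE] +
    u[mi, 4:6, drop = FALSE]
  mu[, 1] <- mu[, 1] + gl_mean

  gl <- round(mu[, 1] + eps[, 1])
  k <- gl_category(gl, map)
  glc <- gl - truth$gl_ref
  l_cd <- truth$coeffs$cd_gl[k] * glc + mu[, 2] + eps[, 2]
  l_sb <- truth$coeffs$sb_gl[k] * glc + truth$coeffs$sb_cd[k] * l_cd +
    mu[, 3] + eps[, 3]

  cd <- findInterval(l_cd, truth$thr$cd, left.open = TRUE) + 1L
  sb <- ifelse(l_sb > truth$thr$sb, 2L, 1L)

  records <- cbind(skeleton,
                   data.frame(gl_days = as.integer(gl), cd_score = cd,
                              sb_score = sb))
  truth_table <- cbind(skeleton["record_id"],
                       data.frame(gl_category = k, l_cd = l_cd, l_sb = l_sb,
                                  mu_gl = mu[, 1], mu_cd = mu[, 2],
                                  mu_sb = mu[, 3]))
  list(records = records, truth_table = truth_table,
       effects = list(h = h, u = u), seed = seed)
}

#' One-call synthetic data set
#'
#' Convenience wrapper chaining \code{\link{generate_design}} and
#' \code{\link{simulate_records}} under the default study conditions.
#'
#' @inheritParams generate_design
#' @inheritParams simulate_records
#' @export
simulate_calving_data <- function(design = sim_design(5000),
                                  truth = true_params(),
                                  map = gl_category_map(), seed = 1L) {
  skel <- generate_design(design, seed = seed)
  simulate_records(skel, truth, map = map, gl_mean = design$gl_mean,
                   seed = seed + 1L)
}

# multivariate normal draws via Cholesky with PSD fallback
rmvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  if (n == 0) return(matrix(0, 0, p))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    e <- eigen(Sigma, symmetric = TRUE)
    ch <- t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), p))
  }
  matrix(stats::rnorm(n * p), n, p) %*% ch
}
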