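test_that("GL categorization uses <= boundaries and covers the integer line", {
  map <- gl_category_map()
  expect_equal(gl_category(265, map), 1L)
  expect_equal(gl_category(267, map), 1L)
  expect_equal(gl_category(268, map), 2L)
  expect_equal(gl_category(273, map), 2L)
  expect_equal(gl_category(274, map), 3L)
  expect_equal(gl_category(279, map), 3L)
  expect_equal(gl_category(280, map), 4L)
  expect_equal(gl_category(291, map), 4L)
  # total on integers, monotone
  g <- gl_category(200:350, map)
  expect_true(all(g %in% 1:4))
  expect_true(!is.unsorted(g))
  expect_error(gl_category_map(c(270, 267)), "increasing")
})

test_that("structural matrix is unit-lower-triangular with negated rates", {
  zero <- structural_coefficients(rep(0, 4), rep(0, 4), rep(0, 4))
  expect_equal(build_lambda(zero, 2), diag(3), ignore_attr = TRUE)

  a <- -0.02762
  cf <- structural_coefficients(0.020, a, 0.331)
  L <- build_lambda(cf, 1)
  expect_equal(L, matrix(c(1, -0.020, -a, 0, 1, -0.331, 0, 0, 1), 3),
               ignore_attr = TRUE)
  # GL row is recursion-free; unit determinant
  expect_equal(L[1, ], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(det(L), 1)
  # inverse accumulates the indirect path: (SB, GL) entry = a + 0.020 * 0.331
  Li <- solve(L)
  expect_equal(Li[3, 1], a + 0.020 * 0.331)
  expect_error(build_lambda(cf, 2), "invalid")
})

test_that("overall GL->SB effect is direct plus indirect path", {
  cf <- structural_coefficients(0, 0, 0.5)
  expect_equal(overall_effect_gl_sb(cf, 1), 0)
  cf2 <- structural_coefficients(0.020, -0.02762, 0.331)
  expect_equal(round(overall_effect_gl_sb(cf2, 1), 3), -0.021)
  # invariant to sb_cd when cd_gl = 0
  cf3 <- structural_coefficients(0, -0.01, 0.9)
  cf4 <- structural_coefficients(0, -0.01, -3)
  expect_equal(overall_effect_gl_sb(cf3, 1), overall_effect_gl_sb(cf4, 1))
})

test_that("overall effect equals the (SB, GL) entry of the inverse system", {
  set.seed(7)
  for (i in 1:25) {
    cf <- structural_coefficients(rnorm(4, 0, 0.05), rnorm(4, 0, 0.05),
                                  rnorm(4, 0, 0.4))
    k <- sample(4, 1)
    expect_equal(overall_effect_gl_sb(cf, k),
                 solve(build_lambda(cf, k))[3, 1])
  }
})

test_that("free-parameter counts match the model definitions", {
  expect_identical(count_free_parameters("RMM1"), 41L)
  expect_identical(count_free_parameters("RMM2"), 38L)
  expect_identical(count_free_parameters("RMM3"), 26L)
  expect_identical(count_free_parameters("SMM"), 32L)
  # three structural coefficients per extra GL category
  expect_identical(count_free_parameters("RMM1", n_categories = 5), 44L)
  expect_identical(count_free_parameters("SMM", n_categories = 5), 32L)
  expect_error(count_free_parameters("RMM4"))
})

make_disp <- function(variant = "RMM1", r_gl = 16, r_cd = 1.05) {
  G0 <- diag(rep(c(2, .03, .018), 2)); G0[1, 4] <- G0[4, 1] <- .5
  H0 <- diag(c(2, .05, .04))
  R0 <- diag(c(r_gl, r_cd, 1))
  dispersion_set(G0, H0, R0, variant)
}

test_that("reduced form is the identity map when all rates are zero", {
  disp <- make_disp()
  zero <- structural_coefficients(rep(0, 4), rep(0, 4), rep(0, 4))
  rf <- reduced_form_covariances(disp, zero, 3)
  expect_equal(rf$genetic, disp$G0, ignore_attr = TRUE)
  expect_equal(rf$herd, disp$H0, ignore_attr = TRUE)
  expect_equal(rf$residual, disp$R0, ignore_attr = TRUE)
})

test_that("reduced residual matches hand-multiplied triangular algebra", {
  # diagonal R0, only CD<-GL active: reduced (GL, CD) entry = c * r_GL
  cc <- 0.03
  cf <- structural_coefficients(rep(cc, 4), rep(0, 4), rep(0, 4))
  disp <- make_disp("RMM1", r_gl = 10, r_cd = 2)
  rf <- reduced_form_covariances(disp, cf, 2)
  expect_equal(rf$residual[1, 2], cc * 10)
  expect_equal(rf$residual[2, 2], cc^2 * 10 + 2)
  expect_equal(rf$residual[1, 1], 10)
  # congruence preserves positive definiteness
  expect_true(all(eigen(rf$residual, symmetric = TRUE)$values > 0))
  expect_true(all(eigen(rf$genetic, symmetric = TRUE)$values > 0))
})

test_that("Willham transform matches the sire-MGS identities", {
  # sigma2_s = 1, sigma2_mgs = 1, sigma_smgs = 0.5 per trait
  G <- diag(6); G[cbind(1:3, 4:6)] <- 0.5; G[cbind(4:6, 1:3)] <- 0.5
  W <- willham_transform(G)
  expect_equal(unname(W$var_direct), rep(4, 3))
  expect_equal(unname(W$cov_direct_maternal), rep(0, 3))
  expect_equal(unname(W$var_maternal), rep(3, 3))
  expect_true(all(W$psd_ok))
  expect_equal(unname(willham_transform(matrix(0, 6, 6))$A),
               matrix(0, 6, 6), ignore_attr = TRUE)
})

test_that("Willham forward map round-trips known direct/maternal inputs", {
  # construct sire-MGS components from direct/maternal truth, then recover it
  set.seed(4)
  for (i in 1:20) {
    A <- crossprod(matrix(rnorm(36), 6)) + diag(6) * 0.1
    G <- recalv:::willham_inverse(A)
    expect_equal(willham_transform(G)$A, A, ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
  # the forward example: sigma_smgs = sigma2_s/2 and
  # sigma2_mgs = sigma2_s/4 + sigma2_m/4 recovers sigma2_m with sigma_dm = 0
  s2s <- 0.8; s2m_true <- 1.7
  G <- matrix(0, 6, 6)
  G[1, 1] <- s2s; G[4, 4] <- s2s / 4 + s2m_true / 4; G[1, 4] <- G[4, 1] <- s2s / 2
  W <- willham_transform(G)
  expect_equal(unname(W$var_maternal[1]), s2m_true)
  expect_equal(unname(W$cov_direct_maternal[1]), 0)
})

test_that("derived genetic parameters use the stated phenotypic variance", {
  G0 <- matrix(0, 6, 6)
  G0[1, 1] <- 0.25; G0[4, 4] <- 0.0625; G0[1, 4] <- G0[4, 1] <- 0.125
  G0[2, 2] <- G0[5, 5] <- G0[3, 3] <- G0[6, 6] <- 0.01
  disp <- dispersion_set(G0, diag(c(1, 1, 1)) * 0.01,
                         diag(c(1, 1, 1)), "RMM3")
  zero <- structural_coefficients(rep(0, 4), rep(0, 4), rep(0, 4))
  gp <- genetic_parameters(disp, zero, 1, include_herd = FALSE)
  expect_equal(unname(gp$var_phenotypic[1]), 0.25 + 0.0625 + 0.125 + 1)
  expect_equal(unname(gp$h2_direct[1]), 4 * 0.25 / 1.4375, tolerance = 1e-10)
  # with zero rates, every category gives identical summaries
  gp4 <- genetic_parameters(disp, zero, 4)
  expect_equal(gp$h2_direct, gp4$h2_direct)
  expect_equal(gp$genetic, gp4$genetic)
  # diagonal RMM3 G0, zero rates: off-diagonal genetic correlations vanish
  expect_equal(unname(gp$cor_direct[1, 2]), 0)
  expect_equal(unname(gp$cor_maternal[1, 3]), 0)
})

test_that("dispersion sets enforce variant masks and the fixed SB variance", {
  G0 <- diag(rep(c(2, .03, .018), 2))
  H0 <- diag(c(2, .05, .04))
  R0d <- diag(c(16, 1.05, 1))
  expect_s3_class(dispersion_set(G0, H0, R0d, "RMM3"), "dispersion_set")
  R0bad <- R0d; R0bad[3, 3] <- 2
  expect_error(dispersion_set(G0, H0, R0bad, "RMM3"), "fixed at 1")
  R0off <- R0d; R0off[1, 2] <- R0off[2, 1] <- 0.5
  expect_error(dispersion_set(G0, H0, R0off, "RMM1"), "mask")
  expect_s3_class(dispersion_set(G0, H0, R0off, "SMM"), "dispersion_set")
  G0off <- G0; G0off[1, 2] <- G0off[2, 1] <- 0.1
  expect_error(dispersion_set(G0off, H0, R0d, "RMM3"), "mask")
  expect_s3_class(dispersion_set(G0off, H0, R0d, "RMM2"), "dispersion_set")
})

test_that("thresholds fix the identification constraints", {
  thr <- thresholds(3)
  expect_equal(thr$cd, c(0, 1))
  expect_equal(thr$sb, 0)
  thr5 <- thresholds(5, cd_free = c(1.8, 2.9))
  expect_equal(thr5$cd, c(0, 1, 1.8, 2.9))
  expect_equal(thr5$cd_fixed, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(thresholds(5, cd_free = c(2.9, 1.8)), "increasing")
  expect_error(thresholds(2), "at least 3")
})
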