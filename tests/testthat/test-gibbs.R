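test_that("truncated-normal kernel matches closed-form truncated moments", {
  set.seed(31)
  # below 0: mean -sqrt(2/pi)
  x <- rtnorm(20000, 0, 1, -Inf, 0)
  expect_lt(abs(mean(x) - (-sqrt(2 / pi))), 0.02)
  expect_true(all(x < 0))
  # between 0 and 1: (phi(0) - phi(1)) / (Phi(1) - Phi(0))
  x <- rtnorm(20000, 0, 1, 0, 1)
  m <- (dnorm(0) - dnorm(1)) / (pnorm(1) - pnorm(0))
  expect_lt(abs(mean(x) - m), 0.01)
  expect_true(all(x > 0 & x < 1))
  # unbounded reduces to a plain normal
  x <- rtnorm(50000, 2, 3, -Inf, Inf)
  expect_lt(abs(mean(x) - 2), 0.05)
  expect_lt(abs(sd(x) - 3), 0.05)
  # extreme tail stays strictly inside the interval and finite
  x <- rtnorm(100, 50, 1, -Inf, 0)
  expect_true(all(is.finite(x) & x < 0))
})

test_that("fixed-corner inverted-Wishart matches a rejection-sampling oracle", {
  set.seed(37)
  nu <- 8; S <- matrix(c(3, 0.8, 0.8, 1.5), 2)
  # oracle: unconstrained IW draws, keep those with corner within 1 +- 0.005
  W <- stats::rWishart(250000, nu, solve(S))
  s11 <- W[1, 1, ]; s12 <- W[1, 2, ]; s22 <- W[2, 2, ]
  det <- s11 * s22 - s12^2
  i11 <- s22 / det   # (1,1) of the inverse
  i22 <- s11 / det   # (2,2) of the inverse (the constrained corner)
  acc <- i11[abs(i22 - 1) < 0.005]
  expect_gt(length(acc), 80)
  mine <- replicate(4000, riw_corner(nu, S, 1)[1, 1])
  expect_gt(suppressWarnings(ks.test(mine, acc)$p.value), 0.01)
  # the corner is exact
  draw <- riw_corner(nu, S, 1)
  expect_identical(draw[2, 2], 1)
  expect_equal(draw[1, 2], draw[2, 1])
})

test_that("scaled inverse chi-square posterior has the stated moments", {
  set.seed(41)
  n <- 50; ss <- 120
  draws <- replicate(20000, recalv:::rsinvchisq_post(0, 0.1, ss, n))
  # nu0 = 0 limit: mean = SS / (n - 2)
  expect_lt(abs(mean(draws) - ss / (n - 2)) / (ss / (n - 2)), 0.02)
})

test_that("fixed-effect update equals the GLS solution under a flat prior", {
  set.seed(43)
  sim <- make_sim(50, seed = 43, design = sim_design(50, n_sires = 5,
                                                     n_mgs = 10,
                                                     n_herd_years = 4))
  d <- recalv:::prepare_rmm_data(sim$records, gl_category_map(), 3L, NULL)
  d$XtX <- crossprod(d$X)
  st <- recalv:::init_state(d, "RMM3", 3L, NULL)
  # fix liabilities and effects; known residual covariance
  st$y[, 2] <- rnorm(50); st$y[, 3] <- rnorm(50)
  st$R0 <- diag(c(4, 1.2, 1))
  R0inv <- solve(st$R0)
  w <- recalv:::working_w(d, st)
  bs <- replicate(3000, recalv:::sample_b(d, st, w, R0inv)$b)
  # GLS oracle per trait (R0 diagonal => trait-wise OLS on the working data)
  for (t in 1:3) {
    bhat <- qr.solve(d$X, w[, t])
    expect_equal(rowMeans(bs[, t, ]), unname(bhat), tolerance = 0.08)
  }
})

test_that("structural-coefficient update matches the OLS slope oracle", {
  set.seed(47)
  sim <- make_sim(400, seed = 47)
  # cutpoints near the GL quartiles so every category is well populated
  map <- gl_category_map(c(276, 279, 281))
  d <- recalv:::prepare_rmm_data(sim$records, map, 3L, NULL)
  st <- recalv:::init_state(d, "RMM1", 3L, NULL)
  st$y[, 2] <- rnorm(400); st$y[, 3] <- rnorm(400)
  st$R0 <- diag(c(16, 1, 1))
  mu <- recalv:::location_mu(d, st)
  pr <- rmm_priors(lambda_var = 1e8)  # effectively flat
  lams <- replicate(4000, recalv:::sample_lambda(d, st, mu, pr)$lam)
  for (k in 1:4) {
    idx <- which(d$k == k)
    x <- d$glc[idx]
    # CD equation: no-intercept regression of (l_CD - mu_CD) on centred GL
    ols1 <- sum(x * (st$y[idx, 2] - mu[idx, 2])) / sum(x^2)
    expect_equal(mean(lams[1, k, ]), ols1, tolerance = 0.05,
                 label = paste("cd_gl category", k))
    # SB equation: bivariate regression on (GL, l_CD)
    Z <- cbind(x, st$y[idx, 2])
    ols23 <- qr.solve(Z, st$y[idx, 3] - mu[idx, 3])
    expect_equal(mean(lams[2, k, ]), unname(ols23[1]), tolerance = 0.05)
    expect_equal(mean(lams[3, k, ]), unname(ols23[2]), tolerance = 0.12)
  }
})

test_that("duplicating every record halves the structural conditional variance", {
  set.seed(53)
  sim <- make_sim(300, seed = 53)
  r2 <- rbind(sim$records, transform(sim$records,
                                     record_id = paste0(record_id, "b")))
  map <- gl_category_map(c(276, 279, 281))
  d1 <- recalv:::prepare_rmm_data(sim$records, map, 3L, 278)
  d2 <- recalv:::prepare_rmm_data(r2, map, 3L, 278)
  pr <- rmm_priors(lambda_var = 1e8)
  st1 <- recalv:::init_state(d1, "RMM1", 3L, NULL)
  st1$y[, 2] <- rnorm(300); st1$y[, 3] <- rnorm(300)
  st2 <- st1; st2$y <- rbind(st1$y, st1$y)
  st2$h <- recalv:::init_state(d2, "RMM1", 3L, NULL)$h
  mu1 <- recalv:::location_mu(d1, st1)
  mu2 <- recalv:::location_mu(d2, st2)
  v1 <- var(replicate(3000, recalv:::sample_lambda(d1, st1, mu1, pr)$lam[1, 2]))
  v2 <- var(replicate(3000, recalv:::sample_lambda(d2, st2, mu2, pr)$lam[1, 2]))
  expect_equal(v2 / v1, 0.5, tolerance = 0.1)
})

test_that("retained-draw bookkeeping follows the chain configuration", {
  ctl <- rmm_control()
  expect_identical(ctl$n_retained, 4500L)
  expect_identical(rmm_control(n_chains = 1, n_iter = 3000, burn_in = 500,
                               thin = 5)$n_retained, 500L)
  expect_error(rmm_control(burn_in = 200, n_iter = 100))
})

test_that("chains are deterministic given seeds and masks are preserved", {
  sim <- make_sim(200, seed = 61, design = sim_design(200, n_sires = 15,
                                                      n_mgs = 30,
                                                      n_herd_years = 8))
  ctl <- rmm_control(n_chains = 2, n_iter = 80, burn_in = 20, thin = 3,
                     seed = 5)
  f1 <- rmm(sim$records, "RMM2", control = ctl)
  f2 <- rmm(sim$records, "RMM2", control = ctl)
  expect_identical(f1$draws, f2$draws)
  expect_identical(nrow(f1$draws), ctl$n_retained)
  # RMM2 mask: R0 and H0 off-diagonals identically zero, R0[SB,SB] = 1
  expect_true(all(f1$draws[, "R0[1,2]"] == 0))
  expect_true(all(f1$draws[, "R0[1,3]"] == 0))
  expect_true(all(f1$draws[, "H0[1,2]"] == 0))
  expect_true(all(f1$draws[, c("G0[1,2]", "G0[1,4]")] != 0))
  f3 <- rmm(sim$records, "RMM3", control = rmm_control(1, 60, 20, 2, seed = 3))
  expect_true(all(f3$draws[, "G0[1,2]"] == 0))  # cross-trait genetic zeroed
  expect_true(all(f3$draws[, "G0[1,4]"] != 0))  # per-trait s-mgs block kept
})

test_that("augmented liabilities always lie inside their category interval", {
  sim <- make_sim(300, seed = 67)
  d <- recalv:::prepare_rmm_data(sim$records, gl_category_map(), 3L, NULL)
  st <- recalv:::init_state(d, "RMM1", 3L, NULL)
  set.seed(1)
  for (i in 1:20) {
    mu <- recalv:::location_mu(d, st)
    st <- recalv:::sample_liabilities_rmm(d, st, mu)
    bc <- recalv:::cd_bounds(d, st$tau)
    expect_true(all(st$y[, 2] > bc$lo & st$y[, 2] <= bc$up + 1e-12))
    expect_true(all((d$sb == 2L) == (st$y[, 3] > 0)))
  }
})

test_that("joint sampler matches single-trait oracles when traits decouple", {
  # lambda fixed at zero, RMM3 (all-diagonal) dispersion: the three-trait
  # model factorizes exactly into three univariate models
  G0 <- diag(c(2, .03, .018, 0.8, .022, .024))
  G0[cbind(1:3, 4:6)] <- G0[cbind(4:6, 1:3)] <- c(.5, .008, .006)
  tp <- true_params(coeffs = structural_coefficients(rep(0, 4), rep(0, 4),
                                                     rep(0, 4)),
                    disp = dispersion_set(G0, diag(c(2, .05, .04)),
                                          diag(c(16, 1.05, 1)), "RMM3"))
  des <- sim_design(800, n_sires = 25, n_mgs = 50, n_herd_years = 15)
  sim <- simulate_calving_data(des, truth = tp, seed = 71)
  fit <- rmm(sim$records, "RMM3", gl_ref = 278,
             control = rmm_control(1, 3000, 500, 2, seed = 11),
             fix_lambda = matrix(0, 3, 4))
  for (tr in c("GL", "CD", "SB")) {
    o <- single_trait_gibbs(sim$records, tr, n_iter = 3000, burn_in = 500,
                            thin = 2, seed = 91, gl_ref = 278)
    t_idx <- match(tr, c("GL", "CD", "SB"))
    expect_mcse_match(fit$draws[, paste0("b[(Intercept),", tr, "]")],
                      o[, "intercept"], paste(tr, "intercept"))
    expect_mcse_match(fit$draws[, paste0("G0[", t_idx, ",", t_idx, "]")],
                      o[, "sire_var"], paste(tr, "sire variance"))
    if (tr != "SB")
      expect_mcse_match(fit$draws[, paste0("R0[", t_idx, ",", t_idx, "]")],
                        o[, "resid_var"], paste(tr, "residual variance"))
  }
})

test_that("free thresholds are sampled when the CD scale has extra categories", {
  # 4 CD categories: one free threshold above the fixed (0, 1)
  tp <- true_params(thr = thresholds(4, cd_free = 1.6))
  skel <- generate_design(sim_design(600), seed = 3)
  sim <- simulate_records(skel, tp, seed = 4)
  expect_true(any(sim$records$cd_score == 4))
  fit <- rmm(sim$records, "RMM3", C_cd = 4,
             control = rmm_control(1, 400, 100, 3, seed = 7))
  tau3 <- fit$draws[, "tau_cd[3]"]
  expect_true(all(tau3 > 1))
  expect_gt(sd(tau3), 0)  # genuinely sampled
  expect_lt(abs(mean(tau3) - 1.6), 0.4)
})
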