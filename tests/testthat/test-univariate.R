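test_that("likelihood reduces to the plain GP marginal without censoring", {
  par <- fix_uni_params()
  ser <- censored_series(t_obs = c(-1, 0, 2), y_obs = c(0.3, 0.8, -0.4))
  S <- exp_quad(ser$t_obs, ser$t_obs, par$kernel) + 0.04 * diag(3)
  expect_equal(gp_log_likelihood(par, ser), ref_lmvnorm(ser$y_obs, S),
               tolerance = 1e-10)
})

test_that("a single right-censored point gives the univariate survival", {
  par <- fix_uni_params()
  ser <- censored_series(t_cens = 0.5, lower = 0.75, upper = Inf)
  expect_equal(gp_log_likelihood(par, ser),
               pnorm(0.75 / sqrt(1 + 0.04), lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-7)
})

test_that("censoring terms only ever lower the observed-data likelihood", {
  par <- fix_uni_params()
  ser <- fix_series()
  ser0 <- censored_series(ser$t_obs, ser$y_obs)
  ll <- gp_log_likelihood(par, ser, cdf_control = list(seed = 1))
  expect_lt(ll, gp_log_likelihood(par, ser0))
  # limits pushed to -Inf: box probability -> 1, recovering the
  # exclude-likelihood of the observed points alone
  ser_far <- censored_series(ser$t_obs, ser$y_obs, ser$t_cens,
                             lower = rep(-40, 2), upper = c(Inf, Inf))
  expect_equal(gp_log_likelihood(par, ser_far, cdf_control = list(seed = 1)),
               gp_log_likelihood(par, ser0), tolerance = 1e-8)
})

test_that("likelihood matches a joint-simulation oracle on printed inputs", {
  # t = (0, 1, 2), yo = (0.3, -0.1) at (0, 2), right limit 0.75 at t = 1
  par <- fix_uni_params()
  ser <- censored_series(t_obs = c(0, 2), y_obs = c(0.3, -0.1),
                         t_cens = 1, lower = 0.75, upper = Inf)
  ll <- gp_log_likelihood(par, ser, cdf_control = list(seed = 2))
  # oracle: P(Yo in dy, Yc > 0.75) by Gaussian-kernel density estimation of
  # the joint simulation, evaluated at yo
  set.seed(77)
  N <- 4e5
  K <- exp_quad(c(0, 2, 1), c(0, 2, 1), par$kernel) + 1e-10 * diag(3)
  Y <- matrix(rnorm(N * 3), N) %*% chol(K) + matrix(rnorm(N * 3, sd = 0.2), N)
  keep <- Y[, 3] > 0.75
  h <- 0.08
  w <- dnorm(Y[keep, 1], 0.3, h) * dnorm(Y[keep, 2], -0.1, h)
  expect_equal(ll, log(sum(w) / N), tolerance = 0.05)
})

test_that("conditional moments match brute-force Gaussian conditioning", {
  par <- fix_uni_params()
  ser <- fix_series()
  grid <- c(-0.5, 0.5, 1.6)
  cm <- gp_conditional_moments(par, ser, grid)
  K <- function(a, b) exp_quad(a, b, par$kernel)
  Syy <- K(ser$t_obs, ser$t_obs) + 0.04 * diag(3)
  bf <- cond_gauss(rep(0, 3), rep(0, 3), K(grid, grid), K(grid, ser$t_obs),
                   Syy, ser$y_obs)
  expect_equal(cm$xi_f_o, bf$mean, tolerance = 1e-9)
  expect_equal(cm$S_f_o, bf$cov, tolerance = 1e-6)
  # censored-block moments the same way
  bf_c <- cond_gauss(rep(0, 2), rep(0, 3),
                     K(ser$t_cens, ser$t_cens) + 0.04 * diag(2),
                     K(ser$t_cens, ser$t_obs), Syy, ser$y_obs)
  expect_equal(cm$xi_c_o, bf_c$mean, tolerance = 1e-9)
  expect_equal(cm$S_c_o, bf_c$cov, tolerance = 1e-6)
})

test_that("conditioning on nothing returns the prior; sigma -> 0 interpolates", {
  par <- fix_uni_params()
  grid <- c(0, 1)
  ser0 <- censored_series()
  cm <- gp_conditional_moments(par, ser0, grid)
  expect_equal(cm$xi_f_o, c(0, 0))
  expect_equal(cm$S_f_o, exp_quad(grid, grid, par$kernel) + 1e-8 * diag(2),
               tolerance = 1e-12)
  small <- uni_gp_params(kernel_params(1, 1), 1e-6)
  ser <- censored_series(t_obs = c(0, 1), y_obs = c(0.4, -0.2))
  cmi <- gp_conditional_moments(small, ser, grid = ser$t_obs)
  expect_equal(cmi$xi_f_o, ser$y_obs, tolerance = 1e-4)
})

test_that("posterior density is normalized and Gaussian when uncensored", {
  par <- fix_uni_params()
  ser0 <- censored_series(t_obs = 0, y_obs = 0.2)
  cm <- gp_conditional_moments(par, ser0, grid = 0.7)
  expect_equal(gp_log_posterior_density(0.5, par, ser0, 0.7),
               dnorm(0.5, cm$xi_f_o, sqrt(cm$S_f_o[1, 1]), log = TRUE),
               tolerance = 1e-8)
  # one censored point: density integrates to 1 on a fine grid
  ser <- censored_series(t_obs = 0, y_obs = 0.2, t_cens = 1, lower = 0.5,
                         upper = Inf)
  fs <- seq(-4, 5, length.out = 1501)
  ld <- vapply(fs, function(f)
    gp_log_posterior_density(f, par, ser, 0.7,
                             cdf_control = list(seed = 5, rel_tol = 1e-6)), 1)
  expect_equal(pracma::trapz(fs, exp(ld)), 1, tolerance = 1e-3)
})

test_that("exact sampler matches moments, oracle, and the density", {
  par <- fix_uni_params()
  ser <- fix_series()
  grid <- c(-0.5, 0.5, 1.0, 1.6)
  # no censoring: draws are exactly Gaussian with the conditional moments
  ser0 <- censored_series(ser$t_obs, ser$y_obs)
  cm0 <- gp_conditional_moments(par, ser0, grid)
  pd0 <- gp_sample_posterior(par, ser0, grid, 40000, seed = 3)
  expect_lt(max(abs(colMeans(pd0$draws) - cm0$xi_f_o)), 0.015)
  expect_lt(max(abs(cov(pd0$draws) - cm0$S_f_o)), 0.015)
  # with censoring: importance-weighted prior-simulation oracle
  set.seed(42)
  N <- 2e5
  allt <- c(grid, ser$t_obs, ser$t_cens)
  K <- exp_quad(allt, allt, par$kernel) + 1e-10 * diag(length(allt))
  F_ <- matrix(rnorm(N * length(allt)), N) %*% chol(K)
  yc <- F_[, 8:9] + matrix(rnorm(N * 2, sd = 0.2), N)
  lw <- dnorm(ser$y_obs[1], F_[, 5], 0.2, log = TRUE) +
    dnorm(ser$y_obs[2], F_[, 6], 0.2, log = TRUE) +
    dnorm(ser$y_obs[3], F_[, 7], 0.2, log = TRUE)
  lw[!(yc[, 1] > 0.9 & yc[, 2] > 0.9)] <- -Inf
  w <- exp(lw - max(lw)); w <- w / sum(w)
  om <- colSums(w * F_[, 1:4])
  ov <- colSums(w * sweep(F_[, 1:4], 2, om)^2)
  ess <- 1 / sum(w^2)
  pd <- gp_sample_posterior(par, ser, grid, 40000, seed = 11)
  se <- sqrt(ov) * sqrt(1 / ess + 1 / nrow(pd$draws))
  expect_true(all(abs(colMeans(pd$draws) - om) < 3.5 * se))
  expect_true(all(abs(apply(pd$draws, 2, var) - ov) < 0.1 * ov + 0.01))
  # censoring raises the posterior mean near the censored times
  cm <- gp_conditional_moments(par, ser, grid)
  expect_gt(colMeans(pd$draws)[3], cm$xi_f_o[3])
  # density is higher at the sampler mean than far below it
  mhat <- colMeans(pd$draws)
  lo3 <- cm$xi_f_o - 3 * sqrt(diag(cm$S_f_o))
  expect_gt(gp_log_posterior_density(mhat, par, ser, grid,
                                     cdf_control = list(seed = 6)),
            gp_log_posterior_density(lo3, par, ser, grid,
                                     cdf_control = list(seed = 6)))
})

test_that("left-censoring equals right-censoring of the negated series", {
  par <- fix_uni_params()
  left <- censored_series(t_obs = c(0, 2), y_obs = c(-0.2, 0.4),
                          t_cens = 1, lower = -Inf, upper = -0.3)
  right <- censored_series(t_obs = c(0, 2), y_obs = c(0.2, -0.4),
                           t_cens = 1, lower = 0.3, upper = Inf)
  expect_equal(gp_log_likelihood(par, left, cdf_control = list(seed = 1)),
               gp_log_likelihood(par, right, cdf_control = list(seed = 1)),
               tolerance = 1e-9)
  grid <- c(0.5, 1.5)
  a <- gp_sample_posterior(par, left, grid, 30000, seed = 21)
  b <- gp_sample_posterior(par, right, grid, 30000, seed = 22)
  expect_lt(max(abs(colMeans(a$draws) + colMeans(b$draws))), 0.02)
  expect_lt(max(abs(cov(a$draws) - cov(b$draws))), 0.02)
})

test_that("posterior draws are reproducible given a seed", {
  par <- fix_uni_params()
  ser <- fix_series()
  a <- gp_sample_posterior(par, ser, c(0, 1), 20, seed = 123)
  b <- gp_sample_posterior(par, ser, c(0, 1), 20, seed = 123)
  expect_identical(a$draws, b$draws)
})
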