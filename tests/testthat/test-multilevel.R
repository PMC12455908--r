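test_that("multilevel covariance blocks follow the exchangeable structure", {
  pm <- fix_ml_params()
  ms2 <- fix_ms(n = 2)
  cb <- multilevel_cov(pm, ms2, grid = c(0.5))
  # n = 2: the eta cross-covariance factor is exactly -1
  Ke <- exp_quad(ms2$series[[1]]$t_obs, ms2$series[[2]]$t_obs, pm$kernel_eta)
  Km <- exp_quad(ms2$series[[1]]$t_obs, ms2$series[[2]]$t_obs, pm$kernel_mu)
  expect_equal(cb$omega_o[1:4, 5:8], Km - Ke, tolerance = 1e-12)
  expect_equal(diag(cb$omega_o), rep(1 + 0.25 + 0.04, 8))
  expect_error(multilevel_cov(pm, multi_series(list(fix_series())), 0.5),
               "n >= 2")
})

test_that("the joint multilevel covariance is PSD on random instances", {
  pm <- fix_ml_params()
  for (s in 1:2) {
    set.seed(s)
    ms <- multi_series(lapply(1:3, function(i) {
      to <- sort(runif(3, -2, 2)); tc <- runif(1, -2, 2)
      censored_series(to, rnorm(3), tc, 0.3, Inf, subject_id = paste0("s", i))
    }))
    grid <- c(-1, 0.7)
    cb <- multilevel_cov(pm, ms, grid)
    prior <- rbind(cbind(cb$omega_mu, matrix(0, 2, 4)),
                   cbind(matrix(0, 4, 2), cb$omega_etap))
    cross <- cbind(rbind(cb$omega_mu_o, cb$omega_etap_o),
                   rbind(cb$omega_mu_c, cb$omega_etap_c))
    datum <- rbind(cbind(cb$omega_o, t(cb$omega_co)),
                   cbind(cb$omega_co, cb$omega_c))
    J <- rbind(cbind(prior, cross), cbind(t(cross), datum))
    ev <- eigen((J + t(J)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("uncensored multilevel likelihood equals the joint normal density", {
  pm <- fix_ml_params()
  ms <- fix_ms(n = 3)
  st <- censgp:::stack_series(ms)
  S <- censgp:::stacked_cov(st$to, st$so, st$to, st$so, pm, 3) + 0.04 * diag(12)
  expect_equal(gp_log_likelihood_ml(pm, ms), ref_lmvnorm(st$yo, S),
               tolerance = 1e-9)
  # and the common-grid fast path equals the generic stacked computation
  expect_equal(gp_log_likelihood_ml(pm, ms),
               censgp:::ml_moments(pm, ms, numeric(), 1e-8)$ll_obs,
               tolerance = 1e-9)
})

test_that("two-subject single-point likelihood matches the bivariate formula", {
  pm <- fix_ml_params()
  ms2 <- multi_series(list(
    censored_series(0, 0.3, subject_id = "a"),
    censored_series(numeric(), numeric(), 0.5, 0.7, Inf, subject_id = "b")))
  v <- 1 + 0.25 + 0.04
  c12 <- exp(-0.5^2 / 2) - 0.25 * exp(-0.5^2 / (2 * 0.25))
  ref <- dnorm(0.3, 0, sqrt(v), log = TRUE) +
    pnorm(0.7, mean = c12 / v * 0.3, sd = sqrt(v - c12^2 / v),
          lower.tail = FALSE, log.p = TRUE)
  expect_equal(gp_log_likelihood_ml(pm, ms2), ref, tolerance = 1e-7)
})

test_that("a vanishing deviation process recovers the univariate model", {
  # magnitude_eta -> 0 with one subject's data duplicated across the stack
  pm <- multi_gp_params(kernel_params(1, 1), kernel_params(1e-8, 0.5), 0.2)
  ser <- censored_series(c(0, 1), c(0.4, -0.1), 2, 0.3, Inf, subject_id = "a")
  ser_b <- censored_series(c(0.25, 1.5), c(0.2, 0.05), subject_id = "b")
  ms <- multi_series(list(ser, ser_b))
  pooled <- censored_series(c(0, 1, 0.25, 1.5), c(0.4, -0.1, 0.2, 0.05),
                            2, 0.3, Inf)
  pu <- fix_uni_params()
  expect_equal(gp_log_likelihood_ml(pm, ms, cdf_control = list(seed = 1)),
               gp_log_likelihood(pu, pooled, cdf_control = list(seed = 1)),
               tolerance = 1e-5)
  # and the mu-block of the posterior covariance matches the univariate one
  grid <- c(0.5, 1.2)
  cm_ml <- gp_conditional_moments_ml(pm, ms, grid)
  cm_u <- gp_conditional_moments(pu, censored_series(
    c(0, 1, 0.25, 1.5), c(0.4, -0.1, 0.2, 0.05)), grid)
  expect_equal(cm_ml$Omega_post[1:2, 1:2], cm_u$S_f_o, tolerance = 1e-4)
  expect_equal(cm_ml$nu[1:2], cm_u$xi_f_o, tolerance = 1e-5)
})

test_that("multilevel conditional moments match brute-force conditioning", {
  pm <- fix_ml_params()
  ms <- fix_ms(n = 3)
  grid <- c(0.5, 1.5, 2.5)
  st <- censgp:::stack_series(ms)
  K <- function(a, b, kp) exp_quad(a, b, kp)
  Cyy <- censgp:::stacked_cov(st$to, st$so, st$to, st$so, pm, 3) + 0.04 * diag(12)
  jp <- 3
  Kee <- K(grid, grid, pm$kernel_eta)
  Cmm <- rbind(cbind(K(grid, grid, pm$kernel_mu), matrix(0, jp, 2 * jp)),
               cbind(matrix(0, 2 * jp, jp),
                     rbind(cbind(Kee, -0.5 * Kee), cbind(-0.5 * Kee, Kee))))
  wgt <- function(i) ifelse(st$so == i, 1, -0.5)
  Cmy <- rbind(K(grid, st$to, pm$kernel_mu),
               sweep(K(grid, st$to, pm$kernel_eta), 2, wgt(1), "*"),
               sweep(K(grid, st$to, pm$kernel_eta), 2, wgt(2), "*"))
  bf <- cond_gauss(rep(0, 3 * jp), rep(0, 12), Cmm, Cmy, Cyy, st$yo)
  cm <- gp_conditional_moments_ml(pm, ms, grid)
  expect_equal(cm$nu, bf$mean, tolerance = 1e-9)
  expect_equal(cm$Omega_post, bf$cov, tolerance = 1e-6)
  # no data: prior moments come back
  ms0 <- multi_series(list(censored_series(subject_id = "a"),
                           censored_series(subject_id = "b"),
                           censored_series(subject_id = "c")))
  cm0 <- gp_conditional_moments_ml(pm, ms0, grid)
  expect_equal(cm0$nu, rep(0, 9))
  expect_equal(cm0$Omega_post, Cmm + 1e-8 * diag(9), tolerance = 1e-7)
})

test_that("sum-to-zero prior simulation has the stated moments", {
  eta <- simulate_sum_to_zero_gp(kernel_params(0.5, 0.5), 4, c(0, 1),
                                 seed = 2, n_rep = 8000)
  expect_lt(max(abs(apply(eta, c(1, 3), sum))), 1e-10)
  expect_equal(var(eta[, 1, 1]), 0.25, tolerance = 0.03)
  expect_equal(cor(eta[, 1, 1], eta[, 2, 1]), -1 / 3, tolerance = 0.1)
  expect_error(simulate_sum_to_zero_gp(kernel_params(1, 1), 1, 0), "n >= 2")
})

test_that("posterior draws keep the sum-to-zero constraint exactly", {
  pm <- fix_ml_params()
  ms <- fix_ms(n = 3, cens = list(2, NULL, c(1, 3)))
  grid <- seq(0, 3, length.out = 5)
  pd <- gp_sample_posterior_ml(pm, ms, grid, 50, seed = 7)
  expect_lt(max(abs(apply(pd$eta_draws, c(1, 3), sum))), 1e-10)
  expect_equal(pd$f_draws[, 2, ], pd$mu_draws + pd$eta_draws[, 2, ])
  # reproducibility
  pd2 <- gp_sample_posterior_ml(pm, ms, grid, 50, seed = 7)
  expect_identical(pd$mu_draws, pd2$mu_draws)
})

test_that("uncensored posterior draws match the conditional moments", {
  pm <- fix_ml_params()
  ms <- fix_ms(n = 3)
  grid <- c(0.5, 2.5)
  cm <- gp_conditional_moments_ml(pm, ms, grid)
  pd <- gp_sample_posterior_ml(pm, ms, grid, 40000, seed = 13)
  Z <- cbind(pd$mu_draws, matrix(pd$eta_draws[, 1, ], nrow = 40000),
             matrix(pd$eta_draws[, 2, ], nrow = 40000))
  expect_lt(max(abs(colMeans(Z) - cm$nu)), 0.02)
  expect_lt(max(abs(cov(Z) - cm$Omega_post)), 0.02)
})

test_that("prior-predictive reconstruction has the sum-to-zero covariances", {
  pm <- fix_ml_params()
  ms0 <- multi_series(lapply(1:3, function(i)
    censored_series(subject_id = paste0("s", i))))
  pd <- gp_sample_posterior_ml(pm, ms0, grid = c(0, 0.25), n_draws = 30000,
                               seed = 5)
  # reconstructed eta_n has marginal variance K_eta(0) = 0.25 and
  # cross-covariance -K_eta/(n-1) with the sampled curves
  e3 <- pd$eta_draws[, 3, 1]
  expect_equal(var(e3), 0.25, tolerance = 0.03)
  expect_equal(cov(e3, pd$eta_draws[, 1, 1]), -0.25 / 2, tolerance = 0.06)
  expect_equal(var(pd$mu_draws[, 1]), 1, tolerance = 0.03)
})

test_that("subject order is exchangeable up to permutation", {
  pm <- fix_ml_params()
  ms <- fix_ms(n = 3, cens = list(2, NULL, NULL))
  perm <- c(3, 1, 2)
  msp <- multi_series(ms$series[perm])
  grid <- c(0.5, 1.5)
  a <- gp_sample_posterior_ml(pm, ms, grid, 30000, seed = 31)
  b <- gp_sample_posterior_ml(pm, msp, grid, 30000, seed = 32)
  expect_lt(max(abs(colMeans(a$mu_draws) - colMeans(b$mu_draws))), 0.02)
  for (i in 1:3) {
    ma <- colMeans(matrix(a$f_draws[, perm[i], ], nrow = 30000))
    mb <- colMeans(matrix(b$f_draws[, i, ], nrow = 30000))
    expect_lt(max(abs(ma - mb)), 0.03)
  }
})
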