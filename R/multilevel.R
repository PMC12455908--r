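# Multi-level censored GP regression: n curves f_i = mu + eta_i around a
# common mean, with a sum-to-zero joint prior on the deviations eta_i
# (cross-covariance -K_eta/(n-1)). The last subject's deviation is the one
# reconstructed from the constraint; exchangeability over subject order is a
# tested property.

#' Multi-level model parameters
#'
#' @param kernel_mu [kernel_params()] for the common mean process.
#' @param kernel_eta [kernel_params()] for the subject deviation processes.
#' @param sigma_noise Positive observation noise SD.
#' @return Object of class `multi_gp_params`.
#' @export
multi_gp_params <- function(kernel_mu, kernel_eta, sigma_noise) {
  stopifnot(inherits(kernel_mu, "kernel_params"),
            inherits(kernel_eta, "kernel_params"))
  if (!is.numeric(sigma_noise) || length(sigma_noise) != 1L ||
      !is.finite(sigma_noise) || sigma_noise <= 0)
    stop("'sigma_noise' must be a positive finite scalar", call. = FALSE)
  structure(list(kernel_mu = kernel_mu, kernel_eta = kernel_eta,
                 sigma_noise = sigma_noise),
            class = "multi_gp_params")
}

#' @export
print.multi_gp_params <- function(x, ...) {
  cat(sprintf(
    "<multi_gp_params> mu: (%g, %g); eta: (%g, %g); noise sd %g\n",
    x$kernel_mu$magnitude, x$kernel_mu$length_scale,
    x$kernel_eta$magnitude, x$kernel_eta$length_scale, x$sigma_noise))
  invisible(x)
}

# Flatten a multi_series into stacked time/value/bound vectors with subject
# indices, observed first within each kind, subjects in input order.
stack_series <- function(ms) {
  to <- unlist(lapply(ms$series, `[[`, "t_obs"))
  yo <- unlist(lapply(ms$series, `[[`, "y_obs"))
  so <- rep(seq_len(ms$n), vapply(ms$series, n_obs, 1L))
  tc <- unlist(lapply(ms$series, `[[`, "t_cens"))
  lo <- unlist(lapply(ms$series, `[[`, "lower"))
  up <- unlist(lapply(ms$series, `[[`, "upper"))
  sc <- rep(seq_len(ms$n), vapply(ms$series, n_cens, 1L))
  list(to = as.numeric(to), yo = as.numeric(yo), so = so,
       tc = as.numeric(tc), lo = as.numeric(lo), up = as.numeric(up), sc = sc)
}

# Cov between stacked observations: K_mu everywhere plus K_eta weighted by
# 1 (same subject) or -1/(n-1) (different subjects).
stacked_cov <- function(t1, s1, t2, s2, params, n) {
  K <- kernel_matrix(t1, t2, params$kernel_mu)
  if (length(t1) == 0 || length(t2) == 0) return(K)
  Ke <- kernel_matrix(t1, t2, params$kernel_eta)
  w <- matrix(-1 / (n - 1), length(t1), length(t2))
  w[outer(s1, s2, "==")] <- 1
  K + w * Ke
}

# Cov(eta'_i(grid), data at (t2, s2)): block rows i = 1..n-1.
eta_prime_cross <- function(grid, t2, s2, params, n) {
  jp <- length(grid)
  if (length(t2) == 0) return(matrix(0, (n - 1) * jp, 0))
  Ke <- kernel_matrix(grid, t2, params$kernel_eta)
  do.call(rbind, lapply(seq_len(n - 1), function(i) {
    w <- ifelse(s2 == i, 1, -1 / (n - 1))
    sweep(Ke, 2, w, "*")
  }))
}

#' Assemble all covariance blocks of the multi-level model
#'
#' Builds the stacked covariance blocks between observed data, censored
#' data, the mean process on the grid, and the reduced deviation vector
#' `eta' = (eta_1, ..., eta_{n-1})` on the grid. Subjects may have unequal,
#' irregular time grids and different censoring patterns. Diagonal subject
#' blocks use `K_mu + K_eta` (+ noise on data blocks); off-diagonal blocks
#' use `K_mu - K_eta/(n-1)`.
#'
#' @param params A [multi_gp_params()] object.
#' @param ms A [multi_series()] with `n >= 2` curves.
#' @param grid Prediction grid (shared by all subjects).
#' @param nugget Diagonal jitter for noise-free blocks.
#' @param include_prior Build the large prior blocks `omega_mu` and
#'   `omega_etap` on the grid (the sampler does not need them).
#' @return Object of class `multi_cov_blocks` with elements `omega_o`,
#'   `omega_c`, `omega_co`, `omega_mu`, `omega_mu_c`, `omega_mu_o`,
#'   `omega_etap`, `omega_etap_c`, `omega_etap_o` plus the stacked data.
#' @export
multilevel_cov <- function(params, ms, grid,
                           nugget = 1e-8 * params$kernel_mu$magnitude^2,
                           include_prior = TRUE) {
  stopifnot(inherits(params, "multi_gp_params"), inherits(ms, "multi_series"))
  if (ms$n < 2)
    stop("multi-level model needs n >= 2 curves; use the univariate model for one curve",
         call. = FALSE)
  st <- stack_series(ms)
  n <- ms$n; jp <- length(grid)
  s2 <- params$sigma_noise^2
  etap <- omega_mu <- NULL
  if (include_prior) {
    Kgg <- kernel_matrix(grid, grid, params$kernel_eta)
    etap <- matrix(0, (n - 1) * jp, (n - 1) * jp)
    if (jp > 0) {
      for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
        w <- if (i == j) 1 else -1 / (n - 1)
        etap[(i - 1) * jp + seq_len(jp), (j - 1) * jp + seq_len(jp)] <- w * Kgg
      }
      etap <- etap + nugget * diag(nrow(etap))
    }
    omega_mu <- kernel_matrix(grid, grid, params$kernel_mu) +
      nugget * diag(nrow = jp)
  }
  structure(list(
    omega_o = stacked_cov(st$to, st$so, st$to, st$so, params, n) +
      s2 * diag(nrow = length(st$to)),
    omega_c = stacked_cov(st$tc, st$sc, st$tc, st$sc, params, n) +
      s2 * diag(nrow = length(st$tc)),
    omega_co = stacked_cov(st$tc, st$sc, st$to, st$so, params, n),
    omega_mu = omega_mu,
    omega_mu_c = kernel_matrix(grid, st$tc, params$kernel_mu),
    omega_mu_o = kernel_matrix(grid, st$to, params$kernel_mu),
    omega_etap = etap,
    omega_etap_c = eta_prime_cross(grid, st$tc, st$sc, params, n),
    omega_etap_o = eta_prime_cross(grid, st$to, st$so, params, n),
    stacked = st, n = n, jp = jp), class = "multi_cov_blocks")
}

# Marginal log-likelihood with no censoring when all subjects share one time
# grid. Exchangeability lets the subject dimension be rotated so that the
# scaled subject average m^{-1/2} sum_i Y_i has covariance n K_mu + sigma^2 I
# while the n-1 orthogonal contrasts are iid with covariance
# n/(n-1) K_eta + sigma^2 I; the quadratic forms of the contrasts are
# recovered from the total without forming a contrast basis. Identical in
# value to the generic stacked computation, much cheaper.
ml_loglik_common_grid <- function(params, ms) {
  n <- ms$n
  t1 <- ms$series[[1]]$t_obs
  m <- length(t1)
  Y <- t(vapply(ms$series, `[[`, numeric(m), "y_obs"))   # n x m
  s2 <- params$sigma_noise^2
  Sw <- kernel_matrix(t1, t1, params$kernel_eta) * n / (n - 1) + s2 * diag(m)
  Sb <- n * kernel_matrix(t1, t1, params$kernel_mu) + s2 * diag(m)
  Rw <- chol(Sw); Rb <- chol(Sb)
  z1 <- colSums(Y) / sqrt(n)
  q_all <- sum(backsolve(Rw, t(Y), transpose = TRUE)^2)
  q_z1w <- sum(backsolve(Rw, z1, transpose = TRUE)^2)
  q_z1b <- sum(backsolve(Rb, z1, transpose = TRUE)^2)
  -0.5 * (n * m * log(2 * pi) + q_all - q_z1w + q_z1b) -
    (n - 1) * sum(log(diag(Rw))) - sum(log(diag(Rb)))
}

# Conditional moments of ((mu, eta')(grid), Yc) given Yo = yo.
ml_moments <- function(params, ms, grid, nugget) {
  cb <- multilevel_cov(params, ms, grid, nugget)
  st <- cb$stacked
  jo <- length(st$to); jc <- length(st$tc); jp <- cb$jp; n <- cb$n
  prior <- rbind(cbind(cb$omega_mu, matrix(0, jp, (n - 1) * jp)),
                 cbind(matrix(0, (n - 1) * jp, jp), cb$omega_etap))
  B <- rbind(cb$omega_mu_o, cb$omega_etap_o)      # Cov((mu,eta'), Yo)
  cross_c <- rbind(cb$omega_mu_c, cb$omega_etap_c) # Cov((mu,eta'), Yc)
  if (jo > 0) {
    Ro <- chol(cb$omega_o)
    AiY <- chol_solve(Ro, st$yo)
    nu <- drop(B %*% AiY)
    Omega_post <- prior - B %*% chol_solve(Ro, t(B))
    nu_c_o <- drop(cb$omega_co %*% AiY)
    Omega_c_o <- cb$omega_c - cb$omega_co %*% chol_solve(Ro, t(cb$omega_co))
    Omega_cross <- cross_c - B %*% chol_solve(Ro, t(cb$omega_co))
    ll_obs <- chol_dmvnorm(st$yo, 0, Ro)
  } else {
    nu <- rep(0, n * jp); Omega_post <- prior
    nu_c_o <- rep(0, jc); Omega_c_o <- cb$omega_c
    Omega_cross <- cross_c
    ll_obs <- 0
  }
  list(nu = nu, Omega_post = (Omega_post + t(Omega_post)) / 2,
       nu_c_o = nu_c_o, Omega_c_o = (Omega_c_o + t(Omega_c_o)) / 2,
       Omega_cross = Omega_cross, ll_obs = ll_obs, st = st, n = n, jp = jp)
}

#' Observed-data log-likelihood of the multi-level censored GP model
#'
#' As [gp_log_likelihood()] with the stacked multi-level covariance:
#' `log phi(y_obs; 0, Omega_o)` plus the log probability that the censored
#' responses fall in their censoring boxes under `Yc | Yo`.
#'
#' @inheritParams multilevel_cov
#' @param cdf_control Arguments forwarded to [log_mvn_cdf()].
#' @return Log-likelihood (scalar).
#' @export
gp_log_likelihood_ml <- function(params, ms,
                                 nugget = 1e-8 * params$kernel_mu$magnitude^2,
                                 cdf_control = list()) {
  stopifnot(inherits(params, "multi_gp_params"), inherits(ms, "multi_series"))
  if (sum(vapply(ms$series, n_cens, 1L)) == 0L) {
    t1 <- ms$series[[1]]$t_obs
    if (all(vapply(ms$series, function(s) identical(s$t_obs, t1), TRUE)))
      return(ml_loglik_common_grid(params, ms))
  }
  mom <- ml_moments(params, ms, numeric(), nugget)
  jc <- length(mom$st$tc)
  if (jc == 0) return(mom$ll_obs)
  cdf <- do.call(log_mvn_cdf,
                 c(list(upper = mom$st$up - mom$nu_c_o,
                        cov = mom$Omega_c_o + nugget * diag(jc),
                        lower = mom$st$lo - mom$nu_c_o), cdf_control))
  mom$ll_obs + cdf$log_prob
}

#' Conditional moments of (mu, eta') given the observed points
#'
#' @inheritParams multilevel_cov
#' @return List with `nu` (conditional mean of the stacked `(mu, eta')`
#'   vector), `Omega_post` (its covariance), `nu_c_o`, `Omega_c_o` (moments
#'   of `Yc | Yo`), and `Omega_cross` (cross-covariance).
#' @export
gp_conditional_moments_ml <- function(params, ms, grid,
                                      nugget = 1e-8 * params$kernel_mu$magnitude^2) {
  if (length(grid) == 0) stop("'grid' must be non-empty", call. = FALSE)
  mom <- ml_moments(params, ms, grid, nugget)
  mom[c("nu", "Omega_post", "nu_c_o", "Omega_c_o", "Omega_cross", "n", "jp")]
}

# Gaussian draws for possibly large, slightly indefinite covariances: small
# dimensions use eigenvalue clipping (with a warning above 1e-6 relative
# mass); large ones try Cholesky with escalating jitter first.
rmvn_big <- function(n, mean, cov) {
  d <- length(mean)
  if (d <= 400L) return(rmvn_psd(n, mean, cov))
  scale <- mean(diag(cov))
  for (j in c(0, 1e-10, 1e-8, 1e-6) * scale) {
    R <- tryCatch(chol(cov + j * diag(d)), error = function(e) NULL)
    if (!is.null(R))
      return(sweep(matrix(stats::rnorm(n * d), n, d) %*% R, 2, mean, "+"))
  }
  rmvn_psd(n, mean, cov)
}

#' Exact draws from the joint conditional posterior of (mu, eta_1..eta_n)
#'
#' Samples the stacked `(mu(grid), eta'(grid))` vector exactly as in the
#' univariate case -- a box-truncated normal draw for the censored responses
#' mapped through the regression coefficient plus an independent Gaussian
#' residual -- then reconstructs the last deviation curve from the
#' sum-to-zero constraint and returns the subject curves `f_i = mu + eta_i`.
#'
#' The Gaussian residual (whose covariance is the posterior covariance of
#' `(mu, eta')` given all responses uncensored) is drawn pathwise: a joint
#' prior replicate of the processes and the data vector is simulated and the
#' fitted conditional mean of the replicate is subtracted. This has exactly
#' the required law but never factorizes the `n Jp x n Jp` covariance.
#'
#' @inheritParams multilevel_cov
#' @param n_draws Number of posterior draws.
#' @param seed Optional integer seed.
#' @param tmvn_method,burn_in Passed to [sample_tmvn()].
#' @return Object of class `multi_posterior_draws`: list with `grid`,
#'   `mu_draws` (`n_draws x Jp`), `eta_draws` and `f_draws`
#'   (`n_draws x n x Jp` arrays). Every draw satisfies
#'   `sum_i eta_i(t) = 0` at every grid point.
#' @export
gp_sample_posterior_ml <- function(params, ms, grid, n_draws, seed = NULL,
                                   nugget = 1e-8 * params$kernel_mu$magnitude^2,
                                   tmvn_method = "auto", burn_in = 100L) {
  if (length(grid) == 0) stop("'grid' must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cb <- multilevel_cov(params, ms, grid, nugget, include_prior = FALSE)
  st <- cb$stacked
  jo <- length(st$to); jc <- length(st$tc); jp <- cb$jp; n <- cb$n
  B <- rbind(cb$omega_mu_o, cb$omega_etap_o)
  cross_c <- rbind(cb$omega_mu_c, cb$omega_etap_c)
  if (jo > 0) {
    Ro <- chol(cb$omega_o)
    AiY <- chol_solve(Ro, st$yo)
    nu <- drop(B %*% AiY)
    nu_c_o <- drop(cb$omega_co %*% AiY)
    Omega_c_o <- cb$omega_c - cb$omega_co %*% chol_solve(Ro, t(cb$omega_co))
    Omega_cross <- cross_c - B %*% chol_solve(Ro, t(cb$omega_co))
  } else {
    nu <- rep(0, n * jp); nu_c_o <- rep(0, jc)
    Omega_c_o <- cb$omega_c; Omega_cross <- cross_c
  }
  # censoring contribution: truncated draw mapped onto the grid
  WP <- matrix(0, n_draws, n * jp)
  if (jc > 0) {
    Sc <- (Omega_c_o + t(Omega_c_o)) / 2 + nugget * diag(jc)
    P <- sample_tmvn(n_draws, mean = rep(0, jc), cov = Sc,
                     lower = st$lo - nu_c_o, upper = st$up - nu_c_o,
                     method = tmvn_method, burn_in = burn_in)
    W <- t(chol_solve(chol(Sc), t(Omega_cross)))
    WP <- P %*% t(W)
  }
  # pathwise Gaussian residual: prior replicate minus its fitted value
  all_t <- c(grid, st$to, st$tc)
  m_all <- length(all_t)
  Rmu <- chol(kernel_matrix(all_t, all_t, params$kernel_mu) +
                nugget * diag(m_all))
  Reta <- chol(kernel_matrix(all_t, all_t, params$kernel_eta) * n / (n - 1) +
                 nugget * diag(m_all))
  mu_star <- matrix(stats::rnorm(n_draws * m_all), n_draws) %*% Rmu
  eta_star <- array(0, c(n_draws, n, m_all))
  em <- matrix(0, n_draws, m_all)
  for (i in seq_len(n)) {
    e_i <- matrix(stats::rnorm(n_draws * m_all), n_draws) %*% Reta
    eta_star[, i, ] <- e_i
    em <- em + e_i
  }
  em <- em / n
  for (i in seq_len(n))
    eta_star[, i, ] <- matrix(eta_star[, i, ], nrow = n_draws) - em
  io <- jp + seq_len(jo); ic <- jp + jo + seq_len(jc)
  data_star <- matrix(0, n_draws, jo + jc)
  if (jo > 0)
    data_star[, seq_len(jo)] <- mu_star[, io, drop = FALSE] +
      matrix(vapply(seq_len(jo), function(k) eta_star[, st$so[k], io[k]],
                    numeric(n_draws)), nrow = n_draws)
  if (jc > 0)
    data_star[, jo + seq_len(jc)] <- mu_star[, ic, drop = FALSE] +
      matrix(vapply(seq_len(jc), function(k) eta_star[, st$sc[k], ic[k]],
                    numeric(n_draws)), nrow = n_draws)
  data_star <- data_star +
    matrix(stats::rnorm(n_draws * (jo + jc), sd = params$sigma_noise), n_draws)
  x_star <- cbind(mu_star[, seq_len(jp), drop = FALSE],
                  do.call(cbind, lapply(seq_len(n - 1), function(i)
                    matrix(eta_star[, i, seq_len(jp)], nrow = n_draws))))
  Q <- if (jo + jc > 0) {
    Sigma_d <- rbind(cbind(cb$omega_o, t(cb$omega_co)),
                     cbind(cb$omega_co, cb$omega_c))
    Cjoint <- cbind(B, cross_c)
    x_star - data_star %*% chol_solve(chol(Sigma_d), t(Cjoint))
  } else x_star
  Z <- sweep(WP + Q, 2, nu, "+")
  mu_draws <- Z[, seq_len(jp), drop = FALSE]
  eta_draws <- array(0, c(n_draws, n, jp))
  for (i in seq_len(n - 1))
    eta_draws[, i, ] <- Z[, i * jp + seq_len(jp), drop = FALSE]
  eta_draws[, n, ] <- -apply(eta_draws[, seq_len(n - 1), , drop = FALSE],
                             c(1, 3), sum)
  f_draws <- array(0, c(n_draws, n, jp))
  for (i in seq_len(n)) f_draws[, i, ] <- mu_draws + eta_draws[, i, ]
  structure(list(grid = grid, mu_draws = mu_draws, eta_draws = eta_draws,
                 f_draws = f_draws), class = "multi_posterior_draws")
}

#' @export
print.multi_posterior_draws <- function(x, ...) {
  cat(sprintf("<multi_posterior_draws> %d draws, %d curves, %d grid points\n",
              nrow(x$mu_draws), dim(x$f_draws)[2], length(x$grid)))
  invisible(x)
}

#' Draw deviation curves from the sum-to-zero GP prior
#'
#' Simulates `n` dependent curves with marginal covariance `K_eta` and
#' cross-covariance `-K_eta/(n-1)`, so that the curves sum to zero exactly
#' at every time point. Uses the centering representation
#' `eta_i = e_i - mean(e)` with `e_i` iid `GP(0, n/(n-1) K_eta)`, which has
#' exactly the required joint law.
#'
#' @param kernel_eta [kernel_params()] of the deviation process.
#' @param n Number of curves (>= 2).
#' @param times Evaluation time points.
#' @param seed Optional integer seed.
#' @param n_rep Number of independent replicates.
#' @return For `n_rep = 1` an `n x length(times)` matrix; otherwise an
#'   `n_rep x n x length(times)` array.
#' @export
simulate_sum_to_zero_gp <- function(kernel_eta, n, times, seed = NULL,
                                    n_rep = 1L) {
  if (n < 2) stop("sum-to-zero prior needs n >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- length(times)
  K <- kernel_matrix(times, times, kernel_eta) * n / (n - 1) +
    1e-8 * kernel_eta$magnitude^2 * diag(nrow = m)
  R <- chol(K)
  out <- array(0, c(n_rep, n, m))
  for (r in seq_len(n_rep)) {
    e <- matrix(stats::rnorm(n * m), n, m) %*% R
    out[r, , ] <- sweep(e, 2, colMeans(e))
  }
  if (n_rep == 1L) out[1, , ] else out
}
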