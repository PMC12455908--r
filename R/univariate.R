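# Single-curve censored GP regression: observed-data likelihood, conditional
# posterior density, and the exact posterior sampler built from a truncated
# multivariate normal draw plus an independent Gaussian residual.

#' Single-curve model parameters
#'
#' @param kernel A [kernel_params()] object for the latent function prior.
#' @param sigma_noise Positive observation noise SD.
#' @return Object of class `uni_gp_params`.
#' @export
uni_gp_params <- function(kernel, sigma_noise) {
  stopifnot(inherits(kernel, "kernel_params"))
  if (!is.numeric(sigma_noise) || length(sigma_noise) != 1L ||
      !is.finite(sigma_noise) || sigma_noise <= 0)
    stop("'sigma_noise' must be a positive finite scalar", call. = FALSE)
  structure(list(kernel = kernel, sigma_noise = sigma_noise),
            class = "uni_gp_params")
}

#' @export
print.uni_gp_params <- function(x, ...) {
  cat(sprintf("<uni_gp_params> magnitude %g, length scale %g, noise sd %g\n",
              x$kernel$magnitude, x$kernel$length_scale, x$sigma_noise))
  invisible(x)
}

# Cholesky solve A^{-1} B with R = chol(A) (upper triangular).
chol_solve <- function(R, B) backsolve(R, backsolve(R, B, transpose = TRUE))

# log N(y; mu, A) with R = chol(A)
chol_dmvnorm <- function(y, mu, R) {
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + sum(z^2)) - sum(log(diag(R)))
}

# Moments of (f(grid), Yc) conditional on Yo = yo; grid may be empty.
uni_moments <- function(params, series, grid, nugget) {
  cb <- cov_blocks(series$t_obs, series$t_cens, grid, params$kernel,
                   params$sigma_noise, nugget = nugget)
  jo <- length(series$t_obs)
  if (jo > 0) {
    Ro <- chol(cb$sigma_o)
    Ai_yo <- chol_solve(Ro, series$y_obs)
    xi_c_o <- drop(cb$sigma_co %*% Ai_yo)
    S_c_o <- cb$sigma_c - cb$sigma_co %*% chol_solve(Ro, t(cb$sigma_co))
    xi_f_o <- drop(cb$sigma_fo %*% Ai_yo)
    S_f_o <- cb$sigma_f - cb$sigma_fo %*% chol_solve(Ro, t(cb$sigma_fo))
    S_fc_o <- cb$sigma_fc - cb$sigma_fo %*% chol_solve(Ro, t(cb$sigma_co))
    ll_obs <- chol_dmvnorm(series$y_obs, 0, Ro)
  } else {
    xi_c_o <- rep(0, length(series$t_cens)); S_c_o <- cb$sigma_c
    xi_f_o <- rep(0, length(grid)); S_f_o <- cb$sigma_f
    S_fc_o <- cb$sigma_fc
    ll_obs <- 0
  }
  list(xi_f_o = xi_f_o, S_f_o = (S_f_o + t(S_f_o)) / 2,
       xi_c_o = xi_c_o, S_c_o = (S_c_o + t(S_c_o)) / 2,
       S_fc_o = S_fc_o, ll_obs = ll_obs, blocks = cb)
}

#' Observed-data log-likelihood of the censored GP model
#'
#' `log L = log phi(y_obs; 0, Sigma_o) + log P(lower < Yc < upper | Yo)`,
#' where the second term is the probability that the censored responses fall
#' in their censoring boxes under the Gaussian conditional `Yc | Yo = y_obs`.
#' With no censored points this is exactly the standard GP marginal
#' log-likelihood; with no observed points the first term vanishes.
#'
#' @param params A [uni_gp_params()] object.
#' @param series A [censored_series()].
#' @param nugget Diagonal jitter on noise-free blocks.
#' @param cdf_control List of arguments passed to [log_mvn_cdf()]
#'   (`seed`, `rel_tol`, `n_points`, `n_rand`, `max_points`).
#' @return Log-likelihood (scalar).
#' @export
gp_log_likelihood <- function(params, series,
                              nugget = 1e-8 * params$kernel$magnitude^2,
                              cdf_control = list()) {
  stopifnot(inherits(params, "uni_gp_params"), inherits(series, "censored_series"))
  mom <- uni_moments(params, series, numeric(), nugget)
  jc <- length(series$t_cens)
  if (jc == 0) return(mom$ll_obs)
  cdf <- do.call(log_mvn_cdf,
                 c(list(upper = series$upper - mom$xi_c_o,
                        cov = mom$S_c_o + nugget * diag(jc),
                        lower = series$lower - mom$xi_c_o),
                   cdf_control))
  mom$ll_obs + cdf$log_prob
}

#' Conditional moments of the latent function given the observed points
#'
#' Returns the Gaussian conditional moments of `(f(grid), Yc)` given
#' `Yo = y_obs` (censoring not yet accounted for): the posterior mean and
#' covariance of `f(grid)` from the non-censored data alone, the conditional
#' mean and covariance of the censored responses, and their cross-covariance.
#' All solves are Cholesky-based; no explicit inverses are formed.
#'
#' @inheritParams gp_log_likelihood
#' @param grid Time points at which to evaluate the latent function.
#' @return Object of class `conditional_moments`: list with `xi_f_o`,
#'   `S_f_o`, `xi_c_o`, `S_c_o`, `S_fc_o`.
#' @export
gp_conditional_moments <- function(params, series, grid,
                                   nugget = 1e-8 * params$kernel$magnitude^2) {
  stopifnot(inherits(params, "uni_gp_params"), inherits(series, "censored_series"))
  if (length(grid) == 0) stop("'grid' must be non-empty", call. = FALSE)
  mom <- uni_moments(params, series, grid, nugget)
  structure(mom[c("xi_f_o", "S_f_o", "xi_c_o", "S_c_o", "S_fc_o")],
            class = "conditional_moments")
}

#' Log conditional posterior density of latent function values
#'
#' Evaluates the exact log posterior density of `f(grid)` given the observed
#' values and the censoring events: the Gaussian log-density from the
#' non-censored points plus the log-ratio of two normal box probabilities,
#' the numerator conditioning on both the observed data and the supplied
#' function values. The ratio up-weights functions that place the censored
#' responses deep inside their censoring boxes.
#'
#' @param f_values Numeric vector, one value per grid point.
#' @inheritParams gp_conditional_moments
#' @param cdf_control Arguments forwarded to [log_mvn_cdf()].
#' @return Log density (scalar).
#' @export
gp_log_posterior_density <- function(f_values, params, series, grid,
                                     nugget = 1e-8 * params$kernel$magnitude^2,
                                     cdf_control = list()) {
  stopifnot(length(f_values) == length(grid))
  mom <- uni_moments(params, series, grid, nugget)
  jc <- length(series$t_cens)
  lphi <- chol_dmvnorm(f_values, mom$xi_f_o, chol(mom$S_f_o))
  if (jc == 0) return(lphi)
  # condition Yc on (Yo, f(grid)) jointly
  cb <- mom$blocks
  A <- rbind(cbind(cb$sigma_o, t(cb$sigma_fo)),
             cbind(cb$sigma_fo, cb$sigma_f))
  Bc <- cbind(cb$sigma_co, t(cb$sigma_fc))   # Cov(Yc, (Yo, f))
  Ra <- chol(A)
  v <- c(series$y_obs, f_values)
  xi_c_of <- drop(Bc %*% chol_solve(Ra, v))
  S_c_of <- cb$sigma_c - Bc %*% chol_solve(Ra, t(Bc))
  S_c_of <- (S_c_of + t(S_c_of)) / 2 + nugget * diag(jc)
  num <- do.call(log_mvn_cdf,
                 c(list(upper = series$upper - xi_c_of, cov = S_c_of,
                        lower = series$lower - xi_c_of), cdf_control))
  den <- do.call(log_mvn_cdf,
                 c(list(upper = series$upper - mom$xi_c_o,
                        cov = mom$S_c_o + nugget * diag(jc),
                        lower = series$lower - mom$xi_c_o), cdf_control))
  lphi + num$log_prob - den$log_prob
}

#' Exact draws from the conditional posterior of the latent function
#'
#' Samples `f(grid) | data` exactly: a box-truncated multivariate normal
#' draw `P` for the censored responses (box = censoring bounds shifted by
#' their conditional mean) is mapped through the regression coefficient onto
#' the grid and an independent Gaussian residual `Q` is added:
#' `f = xi_f_o + S_fc_o S_c_o^{-1} P + Q`. With no censored points the draws
#' are exactly Gaussian with the no-censoring moments. Right-, left-, and
#' interval-censoring are all handled through the box bounds.
#'
#' @inheritParams gp_conditional_moments
#' @param n_draws Number of posterior draws.
#' @param seed Optional integer seed.
#' @param tmvn_method Passed to [sample_tmvn()].
#' @param burn_in Passed to [sample_tmvn()].
#' @return Object of class `posterior_draws`: list with `grid` and the
#'   `n_draws x length(grid)` matrix `draws`.
#' @export
gp_sample_posterior <- function(params, series, grid, n_draws, seed = NULL,
                                nugget = 1e-8 * params$kernel$magnitude^2,
                                tmvn_method = "auto", burn_in = 100L) {
  stopifnot(inherits(params, "uni_gp_params"), inherits(series, "censored_series"))
  if (length(grid) == 0) stop("'grid' must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mom <- uni_moments(params, series, grid, nugget)
  jc <- length(series$t_cens)
  if (jc == 0) {
    draws <- rmvn_psd(n_draws, mom$xi_f_o, mom$S_f_o)
  } else {
    Sc <- mom$S_c_o + nugget * diag(jc)
    P <- sample_tmvn(n_draws, mean = rep(0, jc), cov = Sc,
                     lower = series$lower - mom$xi_c_o,
                     upper = series$upper - mom$xi_c_o,
                     method = tmvn_method, burn_in = burn_in)
    Rc <- chol(Sc)
    W <- t(chol_solve(Rc, t(mom$S_fc_o)))        # S_fc_o S_c_o^{-1}
    Q_cov <- mom$S_f_o - W %*% t(mom$S_fc_o)
    Q <- rmvn_psd(n_draws, rep(0, length(grid)), Q_cov)
    draws <- sweep(P %*% t(W) + Q, 2, mom$xi_f_o, "+")
  }
  structure(list(grid = grid, draws = draws), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws on %d grid points\n",
              nrow(x$draws), length(x$grid)))
  invisible(x)
}
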