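# Small fixtures and oracles shared across the tests. Everything is built
# in code with fixed seeds; no data files.

# a random symmetric positive-definite matrix
rand_pd <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + diag(d)
}

# the mixed-censoring single curve used by several tests
fix_series <- function() {
  censored_series(t_obs = c(-1, 0, 2), y_obs = c(0.3, 0.8, -0.4),
                  t_cens = c(0.8, 1.2), lower = c(0.9, 0.9),
                  upper = c(Inf, Inf))
}

fix_uni_params <- function() uni_gp_params(kernel_params(1, 1), 0.2)

fix_ml_params <- function()
  multi_gp_params(kernel_params(1, 1), kernel_params(0.5, 0.5), 0.2)

# n subjects on a shared grid with optional per-subject censored times
fix_ms <- function(n = 3, times = c(0, 1, 2, 3), cens = list(), seed = 8) {
  set.seed(seed)
  multi_series(lapply(seq_len(n), function(i) {
    tc <- if (i <= length(cens) && !is.null(cens[[i]])) cens[[i]] else numeric()
    to <- setdiff(times, tc)
    censored_series(t_obs = to, y_obs = rnorm(length(to)), t_cens = tc,
                    lower = rep(0.5, length(tc)), upper = rep(Inf, length(tc)),
                    subject_id = paste0("s", i))
  }))
}

# brute-force conditional moments of x given y for a joint Gaussian
cond_gauss <- function(mu_x, mu_y, Sxx, Sxy, Syy, y) {
  list(mean = drop(mu_x + Sxy %*% solve(Syy, y - mu_y)),
       cov = Sxx - Sxy %*% solve(Syy, t(Sxy)))
}

# log N(y; 0, S) without package code (independent oracle)
ref_lmvnorm <- function(y, S) {
  R <- chol(S)
  z <- backsolve(R, y, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + sum(z^2)) - sum(log(diag(R)))
}
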