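# Empirical Bayes: maximize the observed-data log-likelihood over the kernel
# hyperparameters and the noise SD, on the log scale, with multi-start
# derivative-free optimization. The quasi-Monte Carlo CDF uses a fixed seed
# for the whole fit so the objective is deterministic (and smooth in the
# parameters, since the lattice shifts are held fixed).

#' Fitting options
#'
#' @param n_starts Number of optimizer starts (first is deterministic,
#'   data-driven; the rest are log-uniform perturbations of it).
#' @param optimizer `"nelder-mead"` or `"lbfgsb"` (numerical gradients).
#' @param maxit,reltol Passed to [stats::optim()].
#' @param seed Integer seed for the random starts.
#' @param cdf_seed Seed held fixed for all CDF evaluations during the fit;
#'   default `seed + 1000`.
#' @param cdf_points,cdf_rand,cdf_max_points,cdf_rel_tol Accuracy of the
#'   quasi-Monte Carlo CDF during optimization.
#' @param bound Log-parameters are confined to `[-bound, bound]`.
#' @return List of class `fit_opts`.
#' @export
fit_opts <- function(n_starts = 5L, optimizer = c("nelder-mead", "lbfgsb"),
                     maxit = 400L, reltol = 1e-7, seed = 1L, cdf_seed = NULL,
                     cdf_points = 128L, cdf_rand = 2L, cdf_max_points = 256L,
                     cdf_rel_tol = Inf, bound = 10) {
  optimizer <- match.arg(optimizer)
  if (is.null(cdf_seed)) cdf_seed <- seed + 1000L
  structure(list(n_starts = n_starts, optimizer = optimizer, maxit = maxit,
                 reltol = reltol, seed = seed, cdf_seed = cdf_seed,
                 cdf_points = cdf_points, cdf_rand = cdf_rand,
                 cdf_max_points = cdf_max_points, cdf_rel_tol = cdf_rel_tol,
                 bound = bound), class = "fit_opts")
}

cdf_control_from_opts <- function(opts) {
  list(seed = opts$cdf_seed, rel_tol = opts$cdf_rel_tol,
       n_points = opts$cdf_points, n_rand = opts$cdf_rand,
       max_points = opts$cdf_max_points)
}

# One finite representative value per censored point (its finite bound, or
# the interval midpoint), used only for data-driven optimizer starts.
censor_rep_values <- function(lower, upper) {
  ifelse(is.finite(lower) & is.finite(upper), (lower + upper) / 2,
         ifelse(is.finite(lower), lower, upper))
}

# Cached-likelihood factories for the optimizer inner loop: the squared
# time-distance matrices and subject masks do not change across objective
# evaluations, so they are precomputed once per fit. These reproduce
# gp_log_likelihood / gp_log_likelihood_ml exactly (tested), just faster.

eq_mat <- function(D2, m, l) m^2 * exp(-D2 / (2 * l^2))

uni_loglik_factory <- function(series, ctl) {
  jo <- n_obs(series); jc <- n_cens(series)
  yo <- series$y_obs
  D2oo <- outer(series$t_obs, series$t_obs, "-")^2
  D2cc <- outer(series$t_cens, series$t_cens, "-")^2
  D2co <- outer(series$t_cens, series$t_obs, "-")^2
  function(m, l, s) {
    nug <- 1e-8 * m^2
    if (jo > 0) {
      Ro <- chol(eq_mat(D2oo, m, l) + s^2 * diag(jo))
      ll_obs <- chol_dmvnorm(yo, 0, Ro)
    } else ll_obs <- 0
    if (jc == 0) return(ll_obs)
    Sc <- eq_mat(D2cc, m, l) + (s^2 + nug) * diag(jc)
    if (jo > 0) {
      Sco <- eq_mat(D2co, m, l)
      xi <- drop(Sco %*% chol_solve(Ro, yo))
      Sc <- Sc - Sco %*% chol_solve(Ro, t(Sco))
      Sc <- (Sc + t(Sc)) / 2
    } else xi <- rep(0, jc)
    cdf <- do.call(log_mvn_cdf,
                   c(list(upper = series$upper - xi, cov = Sc,
                          lower = series$lower - xi), ctl))
    ll_obs + cdf$log_prob
  }
}

ml_loglik_factory <- function(ms, ctl) {
  st <- stack_series(ms)
  n <- ms$n
  jo <- length(st$to); jc <- length(st$tc)
  # common-grid uncensored data get the rotated likelihood
  t1 <- ms$series[[1]]$t_obs
  common <- jc == 0L &&
    all(vapply(ms$series, function(s) identical(s$t_obs, t1), TRUE))
  if (common) {
    m1 <- length(t1)
    D2 <- outer(t1, t1, "-")^2
    Y <- t(vapply(ms$series, `[[`, numeric(m1), "y_obs"))
    return(function(mm, lm, me, le, s) {
      Rw <- chol(eq_mat(D2, me, le) * n / (n - 1) + s^2 * diag(m1))
      Rb <- chol(n * eq_mat(D2, mm, lm) + s^2 * diag(m1))
      z1 <- colSums(Y) / sqrt(n)
      q_all <- sum(backsolve(Rw, t(Y), transpose = TRUE)^2)
      q_z1w <- sum(backsolve(Rw, z1, transpose = TRUE)^2)
      q_z1b <- sum(backsolve(Rb, z1, transpose = TRUE)^2)
      -0.5 * (n * m1 * log(2 * pi) + q_all - q_z1w + q_z1b) -
        (n - 1) * sum(log(diag(Rw))) - sum(log(diag(Rb)))
    })
  }
  D2oo <- outer(st$to, st$to, "-")^2
  D2cc <- outer(st$tc, st$tc, "-")^2
  D2co <- outer(st$tc, st$to, "-")^2
  w_oo <- ifelse(outer(st$so, st$so, "=="), 1, -1 / (n - 1))
  w_cc <- ifelse(outer(st$sc, st$sc, "=="), 1, -1 / (n - 1))
  w_co <- ifelse(outer(st$sc, st$so, "=="), 1, -1 / (n - 1))
  function(mm, lm, me, le, s) {
    nug <- 1e-8 * mm^2
    if (jo > 0) {
      Ro <- chol(eq_mat(D2oo, mm, lm) + w_oo * eq_mat(D2oo, me, le) +
                   s^2 * diag(jo))
      ll_obs <- chol_dmvnorm(st$yo, 0, Ro)
    } else ll_obs <- 0
    if (jc == 0) return(ll_obs)
    Sc <- eq_mat(D2cc, mm, lm) + w_cc * eq_mat(D2cc, me, le) +
      (s^2 + nug) * diag(jc)
    if (jo > 0) {
      Sco <- eq_mat(D2co, mm, lm) + w_co * eq_mat(D2co, me, le)
      xi <- drop(Sco %*% chol_solve(Ro, st$yo))
      Sc <- Sc - Sco %*% chol_solve(Ro, t(Sco))
      Sc <- (Sc + t(Sc)) / 2
    } else xi <- rep(0, jc)
    cdf <- do.call(log_mvn_cdf,
                   c(list(upper = st$up - xi, cov = Sc, lower = st$lo - xi),
                     ctl))
    ll_obs + cdf$log_prob
  }
}

# First row is the data-driven start; the rest are log-uniform perturbations.
multistart_matrix <- function(base, opts) {
  k <- length(base)
  set.seed(opts$seed)
  extra <- if (opts$n_starts > 1)
    matrix(base, opts$n_starts - 1, k, byrow = TRUE) +
      matrix(stats::runif(k * (opts$n_starts - 1), -log(3), log(3)),
             opts$n_starts - 1, k)
  rbind(base, extra, deparse.level = 0)
}

# Shared multi-start driver. objective(logpar) returns a log-likelihood.
run_multistart <- function(objective, starts, opts) {
  neg <- function(lp) {
    if (any(abs(lp) > opts$bound))
      return(1e10 + sum(pmax(abs(lp) - opts$bound, 0)^2))
    v <- tryCatch(objective(lp), error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  method <- if (opts$optimizer == "nelder-mead") "Nelder-Mead" else "L-BFGS-B"
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    ctl <- list(maxit = opts$maxit, reltol = opts$reltol)
    if (method == "L-BFGS-B") ctl <- list(maxit = opts$maxit, factr = 1e7)
    r <- stats::optim(starts[i, ], neg, method = method,
                      lower = if (method == "L-BFGS-B") -opts$bound else -Inf,
                      upper = if (method == "L-BFGS-B") opts$bound else Inf,
                      control = ctl)
    if (method == "Nelder-Mead") {
      # restart with a fresh simplex at the endpoint: Nelder-Mead simplices
      # collapse on narrow likelihood ridges, and a restart escapes them
      r2 <- stats::optim(r$par, neg, method = method, control = ctl)
      if (r2$value < r$value) {
        r2$counts <- r$counts + r2$counts
        r <- r2
      }
    }
    r
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- which.min(vals)
  list(par = runs[[best]]$par, log_lik = -vals[best],
       convergence = runs[[best]]$convergence,
       converged_any = any(vapply(runs, `[[`, numeric(1), "convergence") == 0),
       iterations = sum(vapply(runs, function(r) r$counts[1], numeric(1))),
       start_values = -vals, best_start = best)
}

#' Fit the single-curve censored GP model by empirical Bayes
#'
#' Maximizes the observed-data log-likelihood ([gp_log_likelihood()]) over
#' `(log magnitude, log length_scale, log sigma)`.
#'
#' @param series A [censored_series()] with at least two points in total.
#' @param init Optional [uni_gp_params()] used as the first start.
#' @param opts A [fit_opts()] list.
#' @return List of class `gp_fit`: `params` (a `uni_gp_params`) and `report`
#'   (final log-likelihood, convergence flag, multi-start values, seeds).
#' @export
fit_gp <- function(series, init = NULL, opts = fit_opts()) {
  stopifnot(inherits(series, "censored_series"))
  if (n_obs(series) + n_cens(series) < 2)
    stop("need at least 2 observations (observed + censored)", call. = FALSE)
  pseudo <- c(series$y_obs, censor_rep_values(series$lower, series$upper))
  sd_y <- max(stats::sd(pseudo), 0.05)
  if (!is.finite(sd_y)) sd_y <- 1
  span <- diff(range(c(series$t_obs, series$t_cens)))
  if (span <= 0) span <- 1
  base <- if (!is.null(init))
    log(c(init$kernel$magnitude, init$kernel$length_scale, init$sigma_noise))
  else log(c(sd_y, span / 4, 0.15 * sd_y))
  starts <- multistart_matrix(base, opts)
  loglik <- uni_loglik_factory(series, cdf_control_from_opts(opts))
  objective <- function(lp) loglik(exp(lp[1]), exp(lp[2]), exp(lp[3]))
  res <- run_multistart(objective, starts, opts)
  if (!res$converged_any)
    warning("optimizer failed to converge from every start; returning best found")
  params <- uni_gp_params(kernel_params(exp(res$par[1]), exp(res$par[2])),
                          exp(res$par[3]))
  structure(list(params = params,
                 report = c(res[c("log_lik", "convergence", "converged_any",
                                  "iterations", "start_values", "best_start")],
                            list(cdf_seed = opts$cdf_seed, seed = opts$seed))),
            class = "gp_fit")
}

#' Fit the multi-level censored GP model by empirical Bayes
#'
#' Maximizes [gp_log_likelihood_ml()] over the five log-parameters
#' `(log m_mu, log l_mu, log m_eta, log l_eta, log sigma)`.
#'
#' @param ms A [multi_series()] with `n >= 2` curves.
#' @param init Optional [multi_gp_params()] used as the first start.
#' @param opts A [fit_opts()] list.
#' @return List of class `gp_fit`: `params` (a `multi_gp_params`) and `report`.
#' @export
fit_gp_ml <- function(ms, init = NULL, opts = fit_opts()) {
  stopifnot(inherits(ms, "multi_series"))
  if (ms$n < 2)
    stop("multi-level fit needs n >= 2 curves", call. = FALSE)
  st <- stack_series(ms)
  pseudo <- c(st$yo, censor_rep_values(st$lo, st$up))
  sd_y <- max(stats::sd(pseudo), 0.05)
  span <- diff(range(c(st$to, st$tc)))
  if (span <= 0) span <- 1
  base <- if (!is.null(init))
    log(c(init$kernel_mu$magnitude, init$kernel_mu$length_scale,
          init$kernel_eta$magnitude, init$kernel_eta$length_scale,
          init$sigma_noise))
  else log(c(0.8 * sd_y, span / 4, 0.4 * sd_y, span / 8, 0.15 * sd_y))
  starts <- multistart_matrix(base, opts)
  loglik <- ml_loglik_factory(ms, cdf_control_from_opts(opts))
  objective <- function(lp) loglik(exp(lp[1]), exp(lp[2]), exp(lp[3]),
                                   exp(lp[4]), exp(lp[5]))
  res <- run_multistart(objective, starts, opts)
  if (!res$converged_any)
    warning("optimizer failed to converge from every start; returning best found")
  params <- multi_gp_params(kernel_params(exp(res$par[1]), exp(res$par[2])),
                            kernel_params(exp(res$par[3]), exp(res$par[4])),
                            exp(res$par[5]))
  structure(list(params = params,
                 report = c(res[c("log_lik", "convergence", "converged_any",
                                  "iterations", "start_values", "best_start")],
                            list(cdf_seed = opts$cdf_seed, seed = opts$seed))),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("<gp_fit> log-likelihood", format(x$report$log_lik), "\n")
  print(x$params)
  invisible(x)
}
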