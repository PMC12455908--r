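# Simulation harness: synthetic censored GP data, the four competing
# estimators (oracle / include / exclude / censored-gp), trapezoid error
# metrics against the known truth, and frequentist coverage of credible
# intervals. All randomness is driven by (base_seed, dataset_index) so every
# per-dataset pipeline is reproducible in isolation.

#' Simulation scenario
#'
#' Describes one study condition. Defaults are the multi-curve benchmark
#' condition: `n_curves = 10` latent curves `f_i = mu + eta_i` with `mu` from
#' an exponentiated quadratic GP (magnitude 1, length scale 1), deviations
#' from a sum-to-zero GP (magnitude 0.5, length scale 0.5), observed at
#' `n_obs = 26` equidistant times on `[-10, 10]` with iid `N(0, 0.2^2)`
#' noise, right-censoring above the per-dataset 0.75 quantile (25%
#' censored), and truth stored on a 201-point equidistant grid. Set
#' `n_curves = 1` for the single-curve condition (then only `kernel_mu` is
#' used and the univariate model is fitted).
#'
#' @param n_curves Number of latent curves (1 = univariate model).
#' @param n_obs Observations per curve (equidistant).
#' @param t_min,t_max Time span.
#' @param kernel_mu,kernel_eta [kernel_params()] of mean and deviations.
#' @param sigma_noise Observation noise SD.
#' @param censor_side `"right"` or `"left"`.
#' @param censor_rule `"dataset_quantile"` (per-dataset empirical quantile so
#'   each dataset has exactly the target fraction censored),
#'   `"population_quantile"` (one threshold shared by all datasets, from
#'   [population_threshold()]), or `"threshold"` (fixed `censor_value`).
#' @param censor_frac Target censored fraction in (0, 1).
#' @param censor_value Threshold for `censor_rule = "threshold"`.
#' @param n_datasets Number of datasets in the study.
#' @param base_seed Base seed; dataset `i` uses a seed derived from
#'   `(base_seed, i)`.
#' @param grid_size Fine-grid size for truth and metrics.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(n_curves = 10L, n_obs = 26L, t_min = -10, t_max = 10,
                         kernel_mu = kernel_params(1, 1),
                         kernel_eta = kernel_params(0.5, 0.5),
                         sigma_noise = 0.2,
                         censor_side = c("right", "left"),
                         censor_rule = c("dataset_quantile",
                                         "population_quantile", "threshold"),
                         censor_frac = 0.25, censor_value = NULL,
                         n_datasets = 100L, base_seed = 1L, grid_size = 201L) {
  censor_side <- match.arg(censor_side)
  censor_rule <- match.arg(censor_rule)
  stopifnot(n_obs >= 2, censor_frac > 0, censor_frac < 1, n_curves >= 1)
  if (censor_rule == "threshold" && is.null(censor_value))
    stop("censor_rule = 'threshold' requires censor_value", call. = FALSE)
  structure(list(n_curves = as.integer(n_curves), n_obs = as.integer(n_obs),
                 t_min = t_min, t_max = t_max, kernel_mu = kernel_mu,
                 kernel_eta = kernel_eta, sigma_noise = sigma_noise,
                 censor_side = censor_side, censor_rule = censor_rule,
                 censor_frac = censor_frac, censor_value = censor_value,
                 n_datasets = as.integer(n_datasets),
                 base_seed = as.integer(base_seed),
                 grid_size = as.integer(grid_size)),
            class = "sim_scenario")
}

# Deterministic per-dataset seed stream, kept inside 32-bit integer range.
derive_seed <- function(base_seed, index, salt = 0L) {
  as.integer((as.double(base_seed) + 1000003 * index + 777767 * salt) %%
               2147483629 + 1)
}

# Latent curves + noisy values for dataset `index` (before censoring).
gen_values <- function(sc, index) {
  set.seed(derive_seed(sc$base_seed, index))
  times <- seq(sc$t_min, sc$t_max, length.out = sc$n_obs)
  grid <- seq(sc$t_min, sc$t_max, length.out = sc$grid_size)
  all_t <- c(times, grid)
  Kmu <- kernel_matrix(all_t, all_t, sc$kernel_mu) +
    1e-8 * sc$kernel_mu$magnitude^2 * diag(length(all_t))
  mu_all <- drop(rmvn_big(1, rep(0, length(all_t)), Kmu))
  if (sc$n_curves == 1) {
    f_all <- matrix(mu_all, 1)
  } else {
    eta <- simulate_sum_to_zero_gp(sc$kernel_eta, sc$n_curves, all_t)
    f_all <- sweep(eta, 2, mu_all, "+")
  }
  io <- seq_len(sc$n_obs)
  y <- f_all[, io, drop = FALSE] +
    matrix(stats::rnorm(sc$n_curves * sc$n_obs, sd = sc$sigma_noise),
           sc$n_curves)
  list(times = times, grid = grid,
       mu_obs = mu_all[io], mu_grid = mu_all[-io],
       f_obs = f_all[, io, drop = FALSE], f_grid = f_all[, -io, drop = FALSE],
       y = y)
}

#' Shared censoring threshold for the population censoring scheme
#'
#' Pools the pre-censoring values of all `n_datasets` datasets and returns
#' the single cut-off giving the target censored fraction overall.
#'
#' @param sc A [sim_scenario()].
#' @return Scalar threshold.
#' @export
population_threshold <- function(sc) {
  pooled <- unlist(lapply(seq_len(sc$n_datasets),
                          function(i) gen_values(sc, i)$y))
  p <- if (sc$censor_side == "right") 1 - sc$censor_frac else sc$censor_frac
  stats::quantile(pooled, p, names = FALSE)
}

#' Simulate one censored dataset
#'
#' Draws the latent curves and noisy observations for dataset `index`,
#' applies the scenario's censoring rule, and returns both the censored data
#' and the stored truth. The pre-censoring values are returned too so that
#' the oracle method can be run on the same noise realizations.
#'
#' @param sc A [sim_scenario()].
#' @param index Dataset index in `1..n_datasets`.
#' @param threshold Required for `censor_rule = "population_quantile"`:
#'   the value from [population_threshold()].
#' @return List with `ms` (the censored [multi_series()]), `truth` (list:
#'   `grid`, `mu_grid`, `f_grid`, `times`, `mu_obs`, `f_obs`), `y_full`
#'   (pre-censoring noisy values, curves in rows), `censored` (logical
#'   matrix), and `threshold`.
#' @export
simulate_dataset <- function(sc, index, threshold = NULL) {
  g <- gen_values(sc, index)
  th <- switch(sc$censor_rule,
    threshold = sc$censor_value,
    dataset_quantile = stats::quantile(
      g$y, if (sc$censor_side == "right") 1 - sc$censor_frac else sc$censor_frac,
      names = FALSE),
    population_quantile = {
      if (is.null(threshold))
        stop("population_quantile rule needs 'threshold' (see population_threshold)",
             call. = FALSE)
      threshold
    })
  cens <- if (sc$censor_side == "right") g$y > th else g$y < th
  series <- lapply(seq_len(sc$n_curves), function(i) {
    ci <- cens[i, ]
    if (sc$censor_side == "right") {
      lo <- rep(th, sum(ci)); up <- rep(Inf, sum(ci))
    } else {
      lo <- rep(-Inf, sum(ci)); up <- rep(th, sum(ci))
    }
    censored_series(t_obs = g$times[!ci], y_obs = g$y[i, !ci],
                    t_cens = g$times[ci], lower = lo, upper = up,
                    subject_id = sprintf("s%d", i))
  })
  list(ms = multi_series(series),
       truth = list(grid = g$grid, mu_grid = g$mu_grid, f_grid = g$f_grid,
                    times = g$times, mu_obs = g$mu_obs, f_obs = g$f_obs),
       y_full = g$y, censored = cens, threshold = th, index = index)
}

# The data each competing method actually sees.
method_data <- function(method, sim) {
  th <- sim$threshold
  series <- lapply(seq_along(sim$ms$series), function(i) {
    cs <- sim$ms$series[[i]]
    ci <- sim$censored[i, ]
    times <- sim$truth$times
    switch(method,
      censored_gp = cs,
      oracle = censored_series(times, sim$y_full[i, ], subject_id = cs$subject_id),
      include = censored_series(times, ifelse(ci, th, sim$y_full[i, ]),
                                subject_id = cs$subject_id),
      exclude = {
        if (all(ci)) stop("exclude method: all points censored", call. = FALSE)
        censored_series(times[!ci], sim$y_full[i, !ci], subject_id = cs$subject_id)
      },
      stop("unknown method: ", method, call. = FALSE))
  })
  multi_series(series)
}

#' Run one competing method on a simulated dataset
#'
#' Fits the scenario's model by empirical Bayes on the data as seen by
#' `method` (`"censored_gp"` uses the censored records; `"oracle"` sees the
#' pre-censoring values; `"include"` replaces censored values by the
#' censoring limit; `"exclude"` drops them) and returns posterior mean
#' curves on the truth grid. Methods whose posterior is exactly Gaussian use
#' the closed-form conditional mean; `censored_gp` averages `n_draws` exact
#' posterior draws.
#'
#' @param method One of `"censored_gp"`, `"oracle"`, `"include"`, `"exclude"`.
#' @param sim Output of [simulate_dataset()].
#' @param opts [fit_opts()] for the empirical Bayes fit.
#' @param n_draws Posterior draws for the censored-GP method.
#' @param seed Seed for posterior sampling.
#' @return List with `mu_mean` (length `grid_size`) and `f_mean`
#'   (`n_curves x grid_size`), plus the fitted `params`.
#' @export
apply_method <- function(method, sim, opts = fit_opts(), n_draws = 100L,
                         seed = 1L) {
  ms <- method_data(method, sim)
  grid <- sim$truth$grid
  n <- ms$n; jp <- length(grid)
  if (n == 1) {
    series <- ms$series[[1]]
    fit <- fit_gp(series, opts = opts)
    jc <- n_cens(series)
    if (jc == 0) {
      cm <- gp_conditional_moments(fit$params, series, grid)
      f_mean <- matrix(cm$xi_f_o, 1)
    } else {
      pd <- gp_sample_posterior(fit$params, series, grid, n_draws, seed = seed)
      f_mean <- matrix(colMeans(pd$draws), 1)
    }
    return(list(mu_mean = drop(f_mean), f_mean = f_mean, params = fit$params))
  }
  fit <- fit_gp_ml(ms, opts = opts)
  jc <- sum(vapply(ms$series, n_cens, 1L))
  if (jc == 0) {
    cm <- gp_conditional_moments_ml(fit$params, ms, grid)
    mu_mean <- cm$nu[seq_len(jp)]
    eta_mean <- matrix(0, n, jp)
    for (i in seq_len(n - 1)) eta_mean[i, ] <- cm$nu[i * jp + seq_len(jp)]
    eta_mean[n, ] <- -colSums(eta_mean[seq_len(n - 1), , drop = FALSE])
    f_mean <- sweep(eta_mean, 2, mu_mean, "+")
  } else {
    pd <- gp_sample_posterior_ml(fit$params, ms, grid, n_draws, seed = seed)
    mu_mean <- colMeans(pd$mu_draws)
    f_mean <- apply(pd$f_draws, c(2, 3), mean)
  }
  list(mu_mean = mu_mean, f_mean = f_mean, params = fit$params)
}

#' Error metrics of posterior mean curves against the truth
#'
#' Integrated squared error and integrated absolute error by the trapezoid
#' rule on the stored grid, and the sup-norm, for the mean curve and for the
#' subject curves (f-metrics summed over curves, sup maximized over curves
#' and times).
#'
#' @param mu_mean,f_mean Posterior means from [apply_method()].
#' @param truth Truth list from [simulate_dataset()].
#' @return One-row `data.frame` with `ISE_mu`, `IAE_mu`, `SUP_mu`, `ISE_f`,
#'   `IAE_f`, `SUP_f`.
#' @export
compute_metrics <- function(mu_mean, f_mean, truth) {
  grid <- truth$grid
  emu <- truth$mu_grid - mu_mean
  ef <- truth$f_grid - f_mean
  data.frame(
    ISE_mu = pracma::trapz(grid, emu^2),
    IAE_mu = pracma::trapz(grid, abs(emu)),
    SUP_mu = max(abs(emu)),
    ISE_f = sum(apply(ef, 1, function(e) pracma::trapz(grid, e^2))),
    IAE_f = sum(apply(ef, 1, function(e) pracma::trapz(grid, abs(e)))),
    SUP_f = max(abs(ef)))
}

#' Run the benchmark study
#'
#' Simulates `sc$n_datasets` datasets and runs each requested method on
#' every dataset, collecting error metrics. All four methods share the same
#' noise realizations within a dataset so they differ only in how censoring
#' is handled. A failing method on a dataset (e.g. `exclude` with everything
#' censored) yields `NA` metrics with a warning.
#'
#' @param sc A [sim_scenario()].
#' @param methods Character vector of methods to run.
#' @param opts [fit_opts()] shared by all fits.
#' @param n_draws Draws for the censored-GP posterior means.
#' @return `data.frame` with one row per (dataset, method).
#' @export
run_benchmark <- function(sc, methods = c("oracle", "censored_gp", "include",
                                          "exclude"),
                          opts = fit_opts(), n_draws = 100L) {
  threshold <- if (sc$censor_rule == "population_quantile")
    population_threshold(sc) else NULL
  out <- vector("list", sc$n_datasets * length(methods))
  k <- 0L
  for (i in seq_len(sc$n_datasets)) {
    sim <- simulate_dataset(sc, i, threshold = threshold)
    for (m in methods) {
      k <- k + 1L
      row <- tryCatch({
        res <- apply_method(m, sim, opts = opts, n_draws = n_draws,
                            seed = derive_seed(sc$base_seed, i, salt = match(m, methods)))
        compute_metrics(res$mu_mean, res$f_mean, sim$truth)
      }, error = function(e) {
        warning(sprintf("dataset %d, method %s failed: %s", i, m,
                        conditionMessage(e)))
        data.frame(ISE_mu = NA_real_, IAE_mu = NA_real_, SUP_mu = NA_real_,
                   ISE_f = NA_real_, IAE_f = NA_real_, SUP_f = NA_real_)
      })
      out[[k]] <- cbind(data.frame(dataset = i, method = m), row)
    }
  }
  do.call(rbind, out)
}

#' Frequentist coverage of credible intervals
#'
#' Simulates single-curve datasets, fits each by empirical Bayes (or uses
#' supplied true parameters), forms equal-tailed credible intervals at every
#' observation time from exact posterior draws, and reports the proportion
#' of intervals containing the true latent function value, pooled over
#' datasets, separately for censored and non-censored points.
#'
#' @param sc A [sim_scenario()] with `n_curves = 1`.
#' @param level Nominal credibility level.
#' @param n_draws Posterior draws per dataset.
#' @param opts [fit_opts()] for the per-dataset fits.
#' @param params Optional [uni_gp_params()]: skip fitting and use these.
#' @return List with `noncensored` and `censored` coverage proportions,
#'   the pooled point counts, and `level`.
#' @export
coverage_study <- function(sc, level = 0.95, n_draws = 1000L,
                           opts = fit_opts(), params = NULL) {
  stopifnot(sc$n_curves == 1)
  threshold <- if (sc$censor_rule == "population_quantile")
    population_threshold(sc) else NULL
  alpha <- (1 - level) / 2
  hits_c <- n_c <- hits_nc <- n_nc <- 0L
  for (i in seq_len(sc$n_datasets)) {
    sim <- simulate_dataset(sc, i, threshold = threshold)
    series <- sim$ms$series[[1]]
    p <- if (is.null(params)) fit_gp(series, opts = opts)$params else params
    pd <- gp_sample_posterior(p, series, grid = sim$truth$times, n_draws,
                              seed = derive_seed(sc$base_seed, i, salt = 31L))
    qs <- apply(pd$draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    hit <- sim$truth$f_obs[1, ] >= qs[1, ] & sim$truth$f_obs[1, ] <= qs[2, ]
    ci <- sim$censored[1, ]
    hits_c <- hits_c + sum(hit[ci]); n_c <- n_c + sum(ci)
    hits_nc <- hits_nc + sum(hit[!ci]); n_nc <- n_nc + sum(!ci)
  }
  list(noncensored = hits_nc / n_nc, censored = hits_c / n_c,
       n_noncensored = n_nc, n_censored = n_c, level = level)
}
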