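# Numerical engine: log-scale multivariate normal box probabilities and
# exact sampling from box-truncated multivariate normals. These two
# primitives sit under every likelihood evaluation and posterior draw.

# log(1 - exp(x)) for x <= 0, stable near both ends.
log1mexp <- function(x) {
  out <- numeric(length(x))
  small <- x > -log(2)           # exp(x) close to 1
  out[small] <- log(-expm1(x[small]))
  out[!small] <- log1p(-exp(x[!small]))
  out[x == -Inf] <- 0
  out
}

# One step of the separation-of-variables recursion: the log probability of
# the standard-normal interval (zlo, zhi) and, when `w` is supplied, the
# inverse-CDF draw at uniform w inside it. The log-scale branches keep far
# tails from underflowing, and the pnorm evaluations are shared between the
# probability and the draw.
interval_step <- function(w, zlo, zhi) {
  n <- max(length(zlo), length(zhi))
  zlo <- rep_len(zlo, n); zhi <- rep_len(zhi, n)
  li <- numeric(n)
  y <- if (!is.null(w)) numeric(n)
  up <- zhi <= 0
  dn <- zlo >= 0
  mid <- !up & !dn
  if (any(up)) {
    le <- stats::pnorm(zhi[up], log.p = TRUE)
    ld <- stats::pnorm(zlo[up], log.p = TRUE)
    li[up] <- le + log1mexp(ld - le)
    if (!is.null(w)) {
      r0 <- exp(ld - le)               # 0 when zlo = -Inf
      y[up] <- stats::qnorm(le + log(r0 + w[up] * (1 - r0)), log.p = TRUE)
    }
  }
  if (any(dn)) {
    ldc <- stats::pnorm(zlo[dn], lower.tail = FALSE, log.p = TRUE)
    lec <- stats::pnorm(zhi[dn], lower.tail = FALSE, log.p = TRUE)
    li[dn] <- ldc + log1mexp(lec - ldc)
    if (!is.null(w)) {
      s0 <- exp(lec - ldc)             # 0 when zhi = Inf
      y[dn] <- stats::qnorm(ldc + log(1 - w[dn] * (1 - s0)),
                            log.p = TRUE, lower.tail = FALSE)
    }
  }
  if (any(mid)) {
    d <- stats::pnorm(zlo[mid]); e <- stats::pnorm(zhi[mid])
    li[mid] <- log(e - d)
    if (!is.null(w)) {
      u <- pmin(pmax(d + w[mid] * (e - d), 1e-320), 1 - 1e-16)
      y[mid] <- stats::qnorm(u)
    }
  }
  li[is.nan(li)] <- -Inf
  if (!is.null(w)) {
    bad <- !is.finite(y)
    if (any(bad)) y[bad] <- (pmax(zlo[bad], -38) + pmin(zhi[bad], 38)) / 2
    y <- pmin(pmax(y, -38), 38)
  }
  list(li = li, y = y)
}

# Stable log(Phi(zhi) - Phi(zlo)), vectorized.
log_phi_diff <- function(zlo, zhi) interval_step(NULL, zlo, zhi)$li

# Variable-reordered Cholesky (Gibson-Glasbey-Elston): integration variables
# are pivoted so the least-probable intervals come first, which concentrates
# the sequential integrand. Compiled; errors on a non-PD covariance, to which
# we attach a condition-number report here.
reorder_cholesky <- function(cov, a, b) {
  tryCatch(cpp_reorder_chol(cov, a, b), error = function(e) {
    kappa <- tryCatch(base::kappa(cov, exact = FALSE), error = function(e2) Inf)
    stop(conditionMessage(e),
         sprintf(" (condition number ~ %.3g)", kappa), call. = FALSE)
  })
}

first_primes <- function(k) {
  n <- max(13, ceiling(k * (log(k + 2) + log(log(k + 3)) + 1)))
  sieve <- rep(TRUE, n); sieve[1] <- FALSE
  for (p in 2:floor(sqrt(n))) if (sieve[p]) sieve[seq(p * p, n, by = p)] <- FALSE
  which(sieve)[seq_len(k)]
}

#' Log probability of a multivariate normal box
#'
#' Computes `log P(lower < Z < upper)` for `Z ~ N(mean, cov)` by a
#' separation-of-variables quasi-Monte Carlo integrator (randomized
#' Richtmyer lattice after a variable-reordered Cholesky factorization),
#' carried out on the log scale throughout so that very small probabilities
#' do not underflow. Dimension 0 returns `log 1 = 0`; dimension 1 uses the
#' exact univariate normal CDF.
#'
#' @param upper Upper bounds (entries may be `Inf`).
#' @param mean Mean vector; default zero.
#' @param cov Positive-definite covariance matrix.
#' @param lower Lower bounds; default all `-Inf`, giving the CDF.
#' @param seed Optional integer seed for the randomization.
#' @param rel_tol Relative tolerance on the log probability; the point count
#'   is doubled (up to `max_points`) until the estimated Monte Carlo error is
#'   below `max(rel_tol * |log p|, rel_tol)`.
#' @param n_points Lattice points per randomization to start from.
#' @param n_rand Number of random shifts (error estimation).
#' @param max_points Cap on lattice points per randomization.
#' @return List with `log_prob`, `error` (standard error on the log scale),
#'   and `n_points` used.
#' @examples
#' log_mvn_cdf(c(0, 0), cov = diag(2))$log_prob  # log(1/4)
#' @export
log_mvn_cdf <- function(upper, mean = NULL, cov, lower = NULL, seed = NULL,
                        rel_tol = 1e-6, n_points = 256L, n_rand = 8L,
                        max_points = 4096L) {
  d <- length(upper)
  if (d == 0L) return(list(log_prob = 0, error = 0, n_points = 0L))
  if (is.null(mean)) mean <- rep(0, d)
  if (is.null(lower)) lower <- rep(-Inf, d)
  stopifnot(length(mean) == d, length(lower) == d)
  if (any(lower >= upper)) stop("lower >= upper in box bounds", call. = FALSE)
  a <- lower - mean; b <- upper - mean
  if (d == 1L)
    return(list(log_prob = log_phi_diff(a / sqrt(cov[1]), b / sqrt(cov[1])),
                error = 0, n_points = 0L))
  if (!is.null(seed)) set.seed(seed)
  ord <- reorder_cholesky(cov, a, b)
  q <- sqrt(first_primes(d - 1))
  logmeanexp <- function(x) {
    m <- max(x)
    if (m == -Inf) -Inf else m + log(mean(exp(x - m)))
  }
  repeat {
    # all randomizations run through the recursion together (rows grouped
    # by randomization: row block r is points 1..n_points with shift r)
    k <- rep(seq_len(n_points), times = n_rand)
    N <- n_points * n_rand
    shifts <- matrix(stats::runif(n_rand * (d - 1)), n_rand, d - 1)
    w <- (outer(k, q) + shifts[rep(seq_len(n_rand), each = n_points), ,
                               drop = FALSE]) %% 1
    logw <- cpp_sov_logweights(ord$L, ord$a, ord$b, w)
    logp_r <- vapply(split(logw, rep(seq_len(n_rand), each = n_points)),
                     logmeanexp, numeric(1))
    log_prob <- logmeanexp(logp_r)
    if (log_prob == -Inf)
      return(list(log_prob = -Inf, error = 0, n_points = n_points))
    err <- stats::sd(logp_r) / sqrt(n_rand)
    if (!is.finite(err)) err <- Inf
    if (err <= max(rel_tol * abs(log_prob), rel_tol) || n_points >= max_points)
      return(list(log_prob = log_prob, error = err, n_points = n_points))
    n_points <- min(2L * n_points, max_points)
  }
}

# Draw n samples from N(mean, cov) allowing a PSD cov: eigendecomposition with
# negative eigenvalues clipped at zero. Warns if the clipped mass is large.
rmvn_psd <- function(n, mean, cov, warn_tol = 1e-6) {
  d <- length(mean)
  if (d == 0L) return(matrix(0, n, 0))
  eg <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  ev <- eg$values
  neg <- -sum(pmin(ev, 0))
  if (neg > warn_tol * max(sum(pmax(ev, 0)), .Machine$double.eps))
    warning(sprintf("covariance clipped: negative eigenvalue mass %.3g", neg))
  ev <- pmax(ev, 0)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% (t(eg$vectors) * sqrt(ev)), 2, mean, "+")
}

#' Sample a box-truncated multivariate normal
#'
#' Draws from `N(mean, cov)` conditioned on `lower < Z < upper`. When the
#' box probability is large enough, exact accept-reject from the untruncated
#' normal is used; otherwise a parallel-chain Gibbs sampler (one independent
#' chain per requested draw, started from the componentwise truncated
#' marginals, `burn_in` full sweeps, univariate conditionals drawn with
#' \pkg{truncnorm}).
#'
#' @param n Number of draws.
#' @param mean,cov Mean vector and positive-definite covariance.
#' @param lower,upper Box bounds, entries may be infinite, `lower < upper`.
#' @param seed Optional integer seed.
#' @param method `"auto"`, `"rejection"`, or `"gibbs"`.
#' @param burn_in Gibbs burn-in sweeps per chain.
#' @return `n x length(mean)` matrix; every row lies strictly inside the box.
#'   Attribute `method` records the sampler used.
#' @export
sample_tmvn <- function(n, mean, cov, lower, upper, seed = NULL,
                        method = c("auto", "rejection", "gibbs"),
                        burn_in = 100L) {
  method <- match.arg(method)
  d <- length(mean)
  stopifnot(length(lower) == d, length(upper) == d, n >= 1)
  if (any(lower >= upper)) stop("lower >= upper in truncation box", call. = FALSE)
  if (d == 0L) return(structure(matrix(0, n, 0), method = "none"))
  if (!is.null(seed)) set.seed(seed)
  cov <- (cov + t(cov)) / 2
  lp <- log_mvn_cdf(upper, mean, cov, lower = lower, rel_tol = 1e-3,
                    n_points = 128L, n_rand = 4L, max_points = 512L)$log_prob
  if (lp < log(1e-300))
    stop("truncation box has numerically zero probability", call. = FALSE)
  if (method == "auto") method <- if (lp > log(0.02)) "rejection" else "gibbs"
  sdm <- sqrt(diag(cov))
  if (method == "rejection") {
    R <- chol(cov)
    out <- matrix(0, 0, d)
    tries <- 0L
    while (nrow(out) < n) {
      batch <- min(ceiling(1.5 * (n - nrow(out)) / max(exp(lp), 1e-4)), 2e6)
      z <- sweep(matrix(stats::rnorm(batch * d), batch, d) %*% R, 2, mean, "+")
      keep <- rowSums(sweep(z, 2, lower, ">") & sweep(z, 2, upper, "<")) == d
      out <- rbind(out, z[keep, , drop = FALSE])
      tries <- tries + 1L
      if (tries > 200L) { method <- "gibbs"; break }
    }
    if (method == "rejection")
      return(structure(out[seq_len(n), , drop = FALSE], method = "rejection"))
  }
  # parallel-chain Gibbs: one independent chain per requested draw
  H <- chol2inv(chol(cov))
  out <- cpp_gibbs_tmvn(H, mean, lower, upper, sdm, as.integer(n),
                        as.integer(burn_in))
  # numerical safety: keep draws strictly inside the box
  for (i in seq_len(d)) {
    eps <- 1e-12 * max(sdm[i], 1)
    out[, i] <- pmin(pmax(out[, i], lower[i] + eps), upper[i] - eps)
  }
  structure(out, method = "gibbs")
}
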