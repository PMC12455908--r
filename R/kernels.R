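#' Covariance kernel hyperparameters
#'
#' Bundles the hyperparameters of a stationary covariance kernel. Only the
#' exponentiated quadratic (squared exponential) kernel ships, but the kernel
#' is pluggable: any function `f(t1, t2, kp)` returning the
#' `length(t1) x length(t2)` cross-covariance matrix can be registered by name
#' via [register_kernel()].
#'
#' `magnitude` is on the standard-deviation scale: the prior variance of the
#' latent function is `magnitude^2`. At the common default `magnitude = 1`
#' the SD and variance conventions coincide; this package always means SD.
#'
#' @param magnitude Positive scalar, prior SD of the latent function
#'   (units of the response).
#' @param length_scale Positive scalar, correlation length (units of time).
#' @param kernel Name of a registered kernel; only `"exp_quad"` is built in.
#' @return An object of class `kernel_params`.
#' @examples
#' kp <- kernel_params(1, 1)
#' exp_quad(0, 1, kp)  # exp(-1/2)
#' @export
kernel_params <- function(magnitude, length_scale, kernel = "exp_quad") {
  if (!is.numeric(magnitude) || length(magnitude) != 1L || !is.finite(magnitude) ||
      magnitude <= 0)
    stop("'magnitude' must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(length_scale) || length(length_scale) != 1L ||
      !is.finite(length_scale) || length_scale <= 0)
    stop("'length_scale' must be a positive finite scalar", call. = FALSE)
  if (is.null(.kernel_registry[[kernel]]))
    stop("unknown kernel: ", kernel, call. = FALSE)
  structure(list(magnitude = magnitude, length_scale = length_scale,
                 kernel = kernel),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("<kernel_params> %s, magnitude %g, length scale %g\n",
              x$kernel, x$magnitude, x$length_scale))
  invisible(x)
}

#' Exponentiated quadratic kernel
#'
#' `K(s, t) = magnitude^2 * exp(-(s - t)^2 / (2 * length_scale^2))`.
#'
#' @param t1,t2 Numeric vectors of time points.
#' @param kp A [kernel_params()] object.
#' @return `length(t1) x length(t2)` covariance matrix.
#' @export
exp_quad <- function(t1, t2, kp) {
  stopifnot(inherits(kp, "kernel_params"))
  if (!all(is.finite(t1)) || !all(is.finite(t2)))
    stop("time points must be finite", call. = FALSE)
  d <- outer(as.numeric(t1), as.numeric(t2), "-")
  kp$magnitude^2 * exp(-d^2 / (2 * kp$length_scale^2))
}

.kernel_registry <- new.env(parent = emptyenv())
.kernel_registry[["exp_quad"]] <- exp_quad

#' Register a covariance kernel by name
#'
#' @param name Kernel name to register.
#' @param fn Function `(t1, t2, kp) -> matrix`.
#' @export
register_kernel <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .kernel_registry[[name]] <- fn
  invisible(name)
}

# Evaluate the kernel named in kp.
kernel_matrix <- function(t1, t2, kp) {
  fn <- .kernel_registry[[kp$kernel]]
  if (is.null(fn)) stop("unknown kernel: ", kp$kernel, call. = FALSE)
  fn(t1, t2, kp)
}

#' Assemble the covariance blocks of the single-curve model
#'
#' Builds all cross-covariance blocks between the fully observed points
#' `t_obs`, the censored points `t_cens`, and the prediction grid `t_pred`
#' under a latent GP with kernel `kp` plus iid Gaussian observation noise.
#' The noise variance `sigma_noise^2` enters only the diagonals of the two
#' noisy-data blocks (`sigma_o`, `sigma_c`); the latent block `sigma_f`
#' instead receives a small diagonal `nugget` because it is repeatedly
#' Cholesky-factored downstream. Any of the three point sets may be empty,
#' yielding zero-dimensional blocks.
#'
#' @param t_obs,t_cens,t_pred Numeric vectors of time points (may be empty).
#' @param kp A [kernel_params()] object.
#' @param sigma_noise Non-negative observation noise SD.
#' @param nugget Diagonal jitter added to the noise-free block; default
#'   `1e-8 * magnitude^2`.
#' @return An object of class `cov_blocks`: list with elements `sigma_o`,
#'   `sigma_c`, `sigma_f`, `sigma_co`, `sigma_fc`, `sigma_fo`.
#' @export
cov_blocks <- function(t_obs, t_cens, t_pred, kp, sigma_noise,
                       nugget = 1e-8 * kp$magnitude^2) {
  stopifnot(inherits(kp, "kernel_params"))
  if (!is.numeric(sigma_noise) || length(sigma_noise) != 1L ||
      !is.finite(sigma_noise) || sigma_noise < 0)
    stop("'sigma_noise' must be a non-negative finite scalar", call. = FALSE)
  jo <- length(t_obs); jc <- length(t_cens); jp <- length(t_pred)
  s2 <- sigma_noise^2
  structure(list(
    sigma_o  = kernel_matrix(t_obs, t_obs, kp) + s2 * diag(nrow = jo),
    sigma_c  = kernel_matrix(t_cens, t_cens, kp) + s2 * diag(nrow = jc),
    sigma_f  = kernel_matrix(t_pred, t_pred, kp) + nugget * diag(nrow = jp),
    sigma_co = kernel_matrix(t_cens, t_obs, kp),
    sigma_fc = kernel_matrix(t_pred, t_cens, kp),
    sigma_fo = kernel_matrix(t_pred, t_obs, kp)),
    class = "cov_blocks")
}
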