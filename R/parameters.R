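## Co-variance parameters of the transmissibility model with environment:
## sire/dam transmission path coefficients, transmissibility and residual
## variances, and the proportion r of transmissibility variance explained by
## the shared environment.

#' Parameter vector of the transmissibility model with environment
#'
#' Bundles and validates the five co-variance parameters: the sire and dam
#' path coefficients of transmission \eqn{\omega_s, \omega_d}, the variance
#' of the global transmissible potential \eqn{\sigma_t^2}, the residual
#' variance \eqn{\sigma_e^2}, and the proportion \eqn{r} of transmissibility
#' variance explained by the environment.  The constraint region is
#' \eqn{0 \le \omega_s, \omega_d}, \eqn{\omega_s + \omega_d \le 1},
#' \eqn{0 \le r \le 1 - \omega_d^2 - \omega_s^2} (so that the maximal
#' within-environment correlation \eqn{\rho \le 1}) and positive variances.
#'
#' @param omega_s,omega_d path coefficients of transmission from sire and dam.
#' @param sigma2_t variance of the global transmissible potential.
#' @param sigma2_e residual variance.
#' @param r proportion of transmissibility variance explained by the shared
#'   environment; `0` recovers the classical transmissibility model.
#' @return A `trans_par` object (named list).
#' @examples
#' trans_par(0.40, 0.25, sigma2_t = 5, sigma2_e = 10, r = 0.544)
#' @export
trans_par <- function(omega_s, omega_d, sigma2_t, sigma2_e, r = 0) {
  stopifnot(is.numeric(omega_s), is.numeric(omega_d), is.numeric(sigma2_t),
            is.numeric(sigma2_e), is.numeric(r))
  if (omega_s < 0 || omega_s > 1 || omega_d < 0 || omega_d > 1 ||
      omega_s + omega_d > 1 + 1e-12) {
    stop("path coefficients must satisfy 0 <= omega_s, omega_d and omega_s + omega_d <= 1")
  }
  rmax <- 1 - omega_d^2 - omega_s^2
  if (r < 0 || r > rmax + 1e-12) {
    stop(sprintf("r must lie in [0, 1 - omega_d^2 - omega_s^2] = [0, %.6g]", rmax))
  }
  if (sigma2_t <= 0 || sigma2_e <= 0) stop("variances must be strictly positive")
  structure(list(omega_s = omega_s, omega_d = omega_d,
                 sigma2_t = sigma2_t, sigma2_e = sigma2_e, r = r),
            class = "trans_par")
}

#' @method print trans_par
#' @export
print.trans_par <- function(x, ...) {
  cat(sprintf(
    "Transmissibility parameters: omega_s = %.4g, omega_d = %.4g, sigma2_t = %.4g, sigma2_e = %.4g, r = %.4g\n",
    x$omega_s, x$omega_d, x$sigma2_t, x$sigma2_e, x$r))
  if (x$r > 0) cat(sprintf("  (rho = %.4g)\n", compute_rho(x)))
  invisible(x)
}

#' Relative variance of the transmissibility sampling
#'
#' Returns \eqn{\delta_i}, the variance of the transmissibility sampling
#' relative to \eqn{\sigma_t^2}, under the no-inbreeding convention:
#' \eqn{1 - \omega_s^2 - \omega_d^2} when both parents are known,
#' \eqn{1 - \omega_d^2} when the sire is unknown, \eqn{1 - \omega_s^2} when
#' the dam is unknown, and 1 when both are unknown.  Vectorized over the
#' knowledge flags.
#'
#' @param omega_s,omega_d path coefficients of transmission.
#' @param sire_known,dam_known logical flags (vectors allowed).
#' @return numeric vector of \eqn{\delta} values.
#' @examples
#' compute_delta(0.40, 0.25, TRUE, TRUE)    # 0.7775
#' compute_delta(0.40, 0.25, FALSE, TRUE)   # 0.9375
#' @export
compute_delta <- function(omega_s, omega_d, sire_known, dam_known) {
  1 - omega_s^2 * as.numeric(sire_known) - omega_d^2 * as.numeric(dam_known)
}

#' Maximal correlation between transmissibility samplings
#'
#' \eqn{\rho = r / (1 - \omega_d^2 - \omega_s^2)}: the correlation between
#' the transmissibility samplings of two known-parent animals sharing an
#' environment, i.e. the maximal such correlation attainable.
#'
#' @param params a [trans_par()] object.
#' @return \eqn{\rho} in `[0, 1]`.
#' @examples
#' compute_rho(trans_par(0.40, 0.25, 5, 10, r = 0.544))  # 0.70
#' @export
compute_rho <- function(params) {
  stopifnot(inherits(params, "trans_par"))
  denom <- 1 - params$omega_d^2 - params$omega_s^2
  if (denom <= 0) stop("degenerate path coefficients: omega_s^2 + omega_d^2 >= 1")
  params$r / denom
}

#' Truth parameter sets of the mirrored-design simulation study
#'
#' The four (\eqn{\omega_s}, \eqn{\omega_d}, \eqn{r}) combinations used in
#' the power/type-I-error study, all with \eqn{\sigma_t^2 = 5} and
#' \eqn{\sigma_e^2 = 10}, chosen so that the maximal within-environment
#' correlation \eqn{\rho} spans 0.30 to 0.70.
#'
#' @return A `data.frame` with columns `set`, `omega_s`, `omega_d`, `r`,
#'   `rho`, `sigma2_t`, `sigma2_e`.
#' @export
parameter_sets <- function() {
  data.frame(
    set = 1:4,
    omega_s = c(0.40, 0.40, 0.40, 0.20),
    omega_d = c(0.25, 0.25, 0.25, 0.50),
    r = c(0.544, 0.389, 0.233, 0.213),
    rho = c(0.70, 0.50, 0.30, 0.30),
    sigma2_t = 5,
    sigma2_e = 10
  )
}

## trans_par for one row of parameter_sets()
par_from_set <- function(set) {
  ps <- parameter_sets()
  row <- ps[ps$set == set, ]
  if (nrow(row) != 1L) stop("unknown parameter set: ", set)
  trans_par(row$omega_s, row$omega_d, row$sigma2_t, row$sigma2_e, row$r)
}

#' Map an unconstrained vector onto the parameter region (and back)
#'
#' `free_to_par()` is a smooth bijection from `R^5` onto the interior of the
#' constraint region of [trans_par()]: the total transmission
#' \eqn{\omega_s + \omega_d} and its split are logistic-stick coordinates,
#' `r` is a logistic fraction of its upper bound
#' \eqn{1 - \omega_s^2 - \omega_d^2}, and the variances are log-scaled
#' around `var_init`.  The zero vector maps to the interior default start:
#' \eqn{\omega_s = \omega_d = 0.25}, `r` at mid-range, variances at
#' `var_init`.  `par_to_free()` is its inverse; the round trip is exact to
#' floating-point precision for interior points.
#'
#' @param free numeric vector of length 5:
#'   `(total-omega logit, split logit, r logit, log sigma2_t, log sigma2_e)`.
#' @param var_init variances mapped from the zero vector, typically a
#'   data-driven half/half split of the phenotypic variance.
#' @return `free_to_par()`: a [trans_par()]; `par_to_free()`: a numeric
#'   vector of length 5.
#' @export
free_to_par <- function(free, var_init = c(sigma2_t = 1, sigma2_e = 1)) {
  stopifnot(length(free) == 5L)
  u <- plogis(free[1L])            # omega_s + omega_d
  v <- plogis(free[2L])            # share of the total going to the sire
  omega_s <- u * v
  omega_d <- u * (1 - v)
  r <- plogis(free[3L]) * (1 - omega_s^2 - omega_d^2)
  trans_par(omega_s, omega_d,
            sigma2_t = var_init[[1L]] * exp(free[4L]),
            sigma2_e = var_init[[2L]] * exp(free[5L]),
            r = r)
}

#' @rdname free_to_par
#' @param params a [trans_par()] object strictly inside the constraint region.
#' @export
par_to_free <- function(params, var_init = c(sigma2_t = 1, sigma2_e = 1)) {
  stopifnot(inherits(params, "trans_par"))
  u <- params$omega_s + params$omega_d
  v <- if (u > 0) params$omega_s / u else 0.5
  rmax <- 1 - params$omega_s^2 - params$omega_d^2
  c(qlogis(u), qlogis(v), qlogis(params$r / rmax),
    log(params$sigma2_t / var_init[[1L]]),
    log(params$sigma2_e / var_init[[2L]]))
}
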