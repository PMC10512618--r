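## Tests for a transmitted environmental effect: the boundary LRT on r = 0
## (50:50 chi-square mixture null) and the classical paired line comparison.

new_trans_test <- function(statistic, p_value, reject, kind, df_or_pairs,
                           alpha, ...) {
  structure(list(statistic = statistic, p_value = p_value, reject = reject,
                 test_kind = kind, df_or_pairs = df_or_pairs, alpha = alpha,
                 ...),
            class = "trans_test")
}

#' @method print trans_test
#' @export
print.trans_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s at alpha = %g)\n",
              x$test_kind, x$statistic, x$p_value,
              if (x$reject) "reject" else "do not reject", x$alpha))
  invisible(x)
}

#' Critical value of the 50:50 mixture null distribution
#'
#' Testing `r = 0` places the parameter on the boundary of its space, so the
#' LRT statistic is asymptotically a 50:50 mixture of a point mass at zero
#' and \eqn{\chi^2_1}.  The level-\eqn{\alpha} critical value solves
#' \eqn{0.5\,P(\chi^2_1 > c) = \alpha}, i.e. the \eqn{1 - 2\alpha} quantile
#' of \eqn{\chi^2_1}; at \eqn{\alpha = 0.05} this is 2.706.
#'
#' @param alpha test level, `0 < alpha < 0.5` (for `alpha >= 0.5` the
#'   critical value degenerates to 0, with a warning).
#' @return the critical value.
#' @export
mixture_critical_value <- function(alpha) {
  stopifnot(alpha > 0, alpha < 1)
  if (alpha >= 0.5) {
    warning("alpha >= 0.5: the mixture point mass at zero already exceeds alpha")
    return(0)
  }
  qchisq(1 - 2 * alpha, df = 1)
}

#' Boundary likelihood-ratio test for a transmitted environmental effect
#'
#' Compares the classical transmissibility fit (null, `r` fixed at 0) with
#' the environment model fit on the same data and fixed effects.  The
#' statistic is \eqn{\max(0, -2\log L_R^{null} + 2\log L_R^{alt})}; its
#' p-value under the boundary null is \eqn{0.5\,P(\chi^2_1 > LRT)} for a
#' positive statistic and 0.5 at zero.  At \eqn{\alpha = 0.05} the null is
#' rejected when the statistic exceeds 2.706.
#'
#' A raw statistic below `-clamp_tol` means the alternative optimizer ended
#' above the null optimum, which is impossible at true optima; it is
#' reported with a warning and the statistic clamped to 0.
#'
#' @param fit_null,fit_alt [fit_reml()] results for the `"trans"` and
#'   `"trans-env"` models on the same data.
#' @param alpha test level.
#' @param clamp_tol tolerance for clamping a slightly negative raw statistic.
#' @return a `trans_test` with fields `statistic`, `p_value`, `reject`,
#'   `test_kind = "lrt_mixture"`, `df_or_pairs = 1`.
#' @export
lrt_mixture <- function(fit_null, fit_alt, alpha = 0.05, clamp_tol = 1e-6) {
  m2_null <- if (inherits(fit_null, "trans_fit")) fit_null$minus2_restricted_loglik else as.numeric(fit_null)
  m2_alt <- if (inherits(fit_alt, "trans_fit")) fit_alt$minus2_restricted_loglik else as.numeric(fit_alt)
  raw <- m2_null - m2_alt
  optimizer_failure <- raw < -clamp_tol
  if (optimizer_failure) {
    warning(sprintf(
      "alternative fit worse than null by %.3g: optimizer failure suspected", -raw))
  }
  statistic <- max(0, raw)
  p <- if (statistic > 0) 0.5 * pchisq(statistic, df = 1, lower.tail = FALSE) else 0.5
  new_trans_test(statistic, p,
                 reject = statistic > mixture_critical_value(alpha),
                 kind = "lrt_mixture", df_or_pairs = 1L, alpha = alpha,
                 optimizer_failure = optimizer_failure)
}

#' Paired T-test on the line contrast of the last generation
#'
#' The classical phenotype-based check for a transgenerational environmental
#' effect: compare the two lines (`E+`, `E-`) of a mirrored design in the
#' last simulated generation with a paired, two-sided T-test.  The default
#' pairing unit is the mirrored animal (animals paired by construction
#' position within mirrored families, `N * n_off` pairs), which treats
#' relatives as independent pairs and is therefore anti-conservative under
#' drift -- exactly the behaviour of phenotype-level line comparisons this
#' model is meant to replace.  `unit = "family"` pairs family-mean
#' phenotypes instead (`N` pairs).
#'
#' @param ped a mirrored-design [pedigree()] carrying `line`, `family` and
#'   `generation` columns (see [mirrored_design()]).
#' @param y phenotype vector aligned with `ped`.
#' @param unit pairing unit: `"family"` (default) or `"animal"`.
#' @param alpha test level.
#' @param generation generation to compare; default the last one.
#' @return a `trans_test` with `test_kind = "paired_t"`, `df_or_pairs` the
#'   number of pairs, and `line_diff`, the raw mean difference
#'   `mean(E+) - mean(E-)` of last-generation phenotypes.
#' @export
paired_line_ttest <- function(ped, y, unit = c("animal", "family"),
                              alpha = 0.05, generation = NULL) {
  unit <- match.arg(unit)
  if (is.null(ped$line) || is.null(ped$family) || is.null(ped$generation)) {
    stop("pedigree lacks line/family/generation design columns")
  }
  if (is.null(generation)) generation <- max(ped$generation)
  sel <- which(ped$generation == generation & !is.na(ped$line))
  lines <- sort(unique(ped$line[sel]))
  if (length(lines) != 2L) stop("expected exactly two lines, found: ",
                                paste(lines, collapse = ", "))
  plus <- sel[ped$line[sel] == "E+"]
  minus <- sel[ped$line[sel] == "E-"]
  if (length(plus) != length(minus)) stop("unequal line sizes in generation ", generation)
  line_diff <- mean(y[plus]) - mean(y[minus])

  if (unit == "family") {
    dp <- tapply(y[plus], ped$family[plus], mean)
    dm <- tapply(y[minus], ped$family[minus], mean)
    stopifnot(identical(names(dp), names(dm)))
    d <- dp - dm
  } else {
    ## construction order is mirrored, so position within (family, line)
    ## identifies the mirrored animal
    ord_p <- plus[order(ped$family[plus])]
    ord_m <- minus[order(ped$family[minus])]
    d <- y[ord_p] - y[ord_m]
  }
  k <- length(d)
  if (k < 2L) stop("paired T-test needs at least 2 pairs")
  se <- sd(d) / sqrt(k)
  tstat <- if (se == 0) 0 else mean(d) / se
  p <- if (se == 0) 1 else 2 * pt(abs(tstat), df = k - 1, lower.tail = FALSE)
  new_trans_test(tstat, p, reject = p <= alpha, kind = "paired_t",
                 df_or_pairs = k, alpha = alpha, line_diff = line_diff,
                 mean_pair_diff = mean(d))
}
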