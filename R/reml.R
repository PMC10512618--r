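## Restricted likelihood of y = X beta + Z t + e with t ~ N(0, M_E sigma_t^2)
## and e ~ N(0, I sigma_e^2).  Everything is evaluated through the
## mixed-model-equations identity
##   log|V| + log|X'V^-1 X| = log|R| + log|G| + log|C|,
## where C is the MME coefficient matrix, so that one sparse Cholesky
## factorization per evaluation yields the determinants, y'Py and the
## BLUE/BLUP solutions.  |M_E| = |D_E| because |L| = 1.

#' Control options for the REML fit
#'
#' @param starts `"default"` for the three canonical start points (interior
#'   default with \eqn{\omega_s=\omega_d=0.25}; near-zero transmission;
#'   near-additive \eqn{\omega_s+\omega_d \approx 1} split evenly), or a
#'   list of unconstrained start vectors as used by [free_to_par()] (the
#'   variance entries are interpreted on the profiled scale, see Details).
#' @param rel_tol relative convergence tolerance on \eqn{-2\log L_R}.
#' @param eval_max,iter_max optimizer budgets per start.
#' @param bound box half-width on the unconstrained scale; the logistic maps
#'   are numerically at their limits well inside it.
#' @param boundary_tol estimates of `r` below this are reported as exactly 0
#'   with a boundary flag (required for correct boundary LRT behaviour).
#' @return a list of class `reml_control`.
#' @export
reml_control <- function(starts = "default", rel_tol = 1e-8, eval_max = 200,
                         iter_max = 80, bound = 30, boundary_tol = 1e-6) {
  structure(list(starts = starts, rel_tol = rel_tol, eval_max = eval_max,
                 iter_max = iter_max, bound = bound,
                 boundary_tol = boundary_tol),
            class = "reml_control")
}

## default fixed-effect design: intercept plus the 0/1 exposure indicator
## when the pedigree carries one
default_design <- function(ped, nobs_mask) {
  if (!is.null(ped$exposed)) {
    X <- cbind(`(Intercept)` = 1, exposed = as.numeric(ped$exposed))
  } else {
    X <- cbind(`(Intercept)` = rep(1, nrow(ped)))
  }
  X[nobs_mask, , drop = FALSE]
}

check_design <- function(X, prune = FALSE) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (!prune) {
      stop("fixed-effect design matrix is rank deficient; redundant column(s): ",
           paste(dropped, collapse = ", "))
    }
    message("dropping redundant fixed-effect column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  X
}

## Precomputations shared by all likelihood evaluations on one dataset/model.
make_reml_context <- function(ped, y, X = NULL, include_environment = TRUE,
                              heterogeneous = "error") {
  n <- nrow(ped)
  stopifnot(length(y) == n)
  obs <- which(!is.na(y))
  nobs <- length(obs)
  if (nobs < 2L) stop("need at least two phenotyped animals")
  if (is.null(X)) X <- default_design(ped, obs) else {
    X <- as.matrix(X)
    if (nrow(X) == n) X <- X[obs, , drop = FALSE]
    stopifnot(nrow(X) == nobs)
  }
  X <- check_design(X)
  p <- ncol(X)
  yo <- y[obs]

  pk <- parent_known(ped)
  sk <- pk$sire
  dk <- pk$dam
  blocks <- if (include_environment) env_blocks(ped) else list()
  ## the closed-form block inverse needs one delta per block
  block_status <- lapply(blocks, function(b) {
    st <- paste(sk[b$members], dk[b$members])
    if (length(unique(st)) > 1L && heterogeneous == "error") {
      stop("shared environment '", b$label, "' mixes animals with different ",
           "parental-knowledge status (use heterogeneous = \"dense\")")
    }
    length(unique(st)) == 1L
  })

  env <- new.env(parent = emptyenv())
  env$ch <- NULL

  ## fixed sparsity patterns: off-diagonal index pairs of every block, and
  ## slot-order keys that let each evaluation refill template matrices
  ## without re-sorting triplets
  blocks <- lapply(blocks, function(b) {
    pair <- expand.grid(i = b$members, j = b$members)
    pair <- pair[pair$i != pair$j, ]
    b$off_i <- pair$i
    b$off_j <- pair$j
    b
  })
  Li <- c(seq_len(n), which(sk), which(dk))
  Lj <- c(seq_len(n), ped$sire_idx[sk], ped$dam_idx[dk])
  L_dup <- anyDuplicated(as.numeric(Li) * (n + 1) + Lj) > 0L  # sire == dam degeneracy
  L_template <- L_key <- NULL
  if (!L_dup) {
    L_template <- sparseMatrix(i = Li, j = Lj, x = as.numeric(seq_along(Li)),
                               dims = c(n, n))
    L_key <- as.integer(L_template@x)
  }
  Di <- c(seq_len(n), unlist(lapply(blocks, `[[`, "off_i")))
  Dj <- c(seq_len(n), unlist(lapply(blocks, `[[`, "off_j")))
  D_template <- sparseMatrix(i = Di, j = Dj, x = as.numeric(seq_along(Di)),
                             dims = c(n, n))
  D_key <- as.integer(D_template@x)

  ctx <- list(
    n = n, p = p, nobs = nobs, obs = obs,
    XtX = crossprod(X), Xty = drop(crossprod(X, yo)), yty = sum(yo^2),
    Zty = {
      z <- numeric(n)
      z[obs] <- yo
      z
    },
    ZtZdiag = {
      z <- numeric(n)
      z[obs] <- 1
      z
    },
    XZ = sparseMatrix(i = rep(seq_len(p), each = nobs),
                      j = rep(obs, p), x = as.numeric(X),
                      dims = c(p, n)),
    sk = sk, dk = dk,
    Li = Li, Lj = Lj, n_sk = sum(sk), n_dk = sum(dk),
    L_template = L_template, L_key = L_key,
    D_template = D_template, D_key = D_key,
    blocks = blocks, block_homog = unlist(block_status, use.names = FALSE),
    include_environment = include_environment,
    cache = env, X = X
  )
  ctx
}

## L' D_E^{-1} L and log|D_E| for one parameter point; NULL when infeasible
ctx_structure <- function(ctx, omega_s, omega_d, r) {
  n <- ctx$n
  delta <- 1 - omega_s^2 * ctx$sk - omega_d^2 * ctx$dk
  dinv <- 1 / delta
  logdetDE <- sum(log(delta))
  xx <- vector("list", length(ctx$blocks))
  k <- 1L
  for (b in ctx$blocks) {
    d <- delta[b$members]
    m <- b$m
    if (r > 0) {
      if (min(d) - r <= 1e-12 || min(d) + (m - 1) * r <= 1e-12) return(NULL)
      if (ctx$block_homog[k]) {
        ## compound symmetry (delta - r) I + r J: closed-form inverse
        db <- d[1L]
        a <- 1 / (db - r)
        bb <- -r / ((db - r) * (db + (m - 1) * r))
        dinv[b$members] <- a + bb
        logdetDE <- logdetDE - m * log(db) +
          (m - 1) * log(db - r) + log(db + (m - 1) * r)
        xx[[k]] <- rep(bb, m * (m - 1L))
      } else {
        B <- matrix(r, m, m)
        diag(B) <- d
        chB <- tryCatch(chol(B), error = function(e) NULL)
        if (is.null(chB)) return(NULL)
        binv <- chol2inv(chB)
        logdetDE <- logdetDE - sum(log(d)) + 2 * sum(log(diag(chB)))
        dinv[b$members] <- diag(binv)
        binv_off <- binv
        diag(binv_off) <- NA
        xx[[k]] <- binv_off[!is.na(binv_off)]  # column-major, matches off_i/off_j
      }
    } else {
      xx[[k]] <- rep(0, m * (m - 1L))
    }
    k <- k + 1L
  }
  Lx <- c(rep(1, n), rep(-omega_s, ctx$n_sk), rep(-omega_d, ctx$n_dk))
  if (!is.null(ctx$L_template)) {
    L <- ctx$L_template
    L@x <- Lx[ctx$L_key]
  } else {
    L <- sparseMatrix(i = ctx$Li, j = ctx$Lj, x = Lx, dims = c(n, n))
  }
  Dx <- c(dinv, unlist(xx))
  DEinv <- ctx$D_template
  DEinv@x <- Dx[ctx$D_key]
  list(MEinv = crossprod(L, DEinv %*% L), logdetDE = logdetDE)
}

## factorize the MME matrix, reusing the cached symbolic analysis
ctx_factor <- function(ctx, C) {
  C <- forceSymmetric(C)
  ch <- ctx$cache$ch
  ch <- if (is.null(ch)) {
    Cholesky(C, LDL = FALSE, perm = TRUE)
  } else {
    tryCatch(update(ch, C), error = function(e) Cholesky(C, LDL = FALSE, perm = TRUE))
  }
  ctx$cache$ch <- ch
  ch
}

## -2 log restricted likelihood profiled in the residual variance;
## lambda = sigma_t^2 / sigma_e^2.  Returns the value with the profiled
## sigma_e^2 as attribute, or +big when the point is infeasible.
ctx_profiled <- function(ctx, omega_s, omega_d, r, lambda) {
  st <- ctx_structure(ctx, omega_s, omega_d, r)
  if (is.null(st)) return(structure(1e10, sigma2 = NA_real_))
  n <- ctx$n
  Cn <- Diagonal(n, ctx$ZtZdiag) + st$MEinv / lambda
  C <- rbind(cbind(ctx$XtX, ctx$XZ), cbind(t(ctx$XZ), Cn))
  ch <- ctx_factor(ctx, C)
  rhs <- c(ctx$Xty, ctx$Zty)
  sol <- as.numeric(solve(ch, rhs, system = "A"))
  q <- ctx$yty - sum(sol * rhs)
  if (q <= 0) return(structure(1e10, sigma2 = NA_real_))
  s2 <- q / (ctx$nobs - ctx$p)
  ldC <- 2 * as.numeric(determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  val <- (ctx$nobs - ctx$p) * (log(s2) + 1 + log(2 * pi)) +
    n * log(lambda) + st$logdetDE + ldC
  structure(val, sigma2 = s2)
}

## full 5-parameter -2 log restricted likelihood (unprofiled)
ctx_neg2ll <- function(ctx, params) {
  s2t <- params$sigma2_t
  s2e <- params$sigma2_e
  st <- ctx_structure(ctx, params$omega_s, params$omega_d, params$r)
  if (is.null(st)) return(1e10)
  n <- ctx$n
  Cn <- Diagonal(n, ctx$ZtZdiag) / s2e + st$MEinv / s2t
  C <- rbind(cbind(ctx$XtX / s2e, ctx$XZ / s2e), cbind(t(ctx$XZ) / s2e, Cn))
  ch <- ctx_factor(ctx, C)
  rhs <- c(ctx$Xty, ctx$Zty) / s2e
  sol <- as.numeric(solve(ch, rhs, system = "A"))
  yPy <- ctx$yty / s2e - sum(sol * rhs)
  ldC <- 2 * as.numeric(determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  ctx$nobs * log(s2e) + n * log(s2t) + st$logdetDE + ldC + yPy +
    (ctx$nobs - ctx$p) * log(2 * pi)
}

#' Minus twice the restricted log-likelihood
#'
#' Evaluates \eqn{-2\log L_R = \log|V| + \log|X'V^{-1}X| + y'Py +
#' (n_{obs}-p)\log 2\pi} with \eqn{V = Z M_E Z' \sigma_t^2 + I \sigma_e^2},
#' through one sparse Cholesky factorization of the mixed-model-equations
#' coefficient matrix.  The additive constant is included identically for
#' the classical (`r = 0`) and environment models, so differences between
#' nested fits are valid likelihood-ratio statistics.  Animals with missing
#' phenotypes contribute through the pedigree only.
#'
#' @param params a [trans_par()].
#' @param ped a [pedigree()].
#' @param y phenotype vector aligned with `ped` rows (`NA` = not phenotyped).
#' @param X fixed-effect design matrix (rows = animals or = phenotyped
#'   animals); default: intercept plus the `exposed` indicator if present.
#' @param heterogeneous passed to the environment-block machinery, see
#'   [build_DE()].
#' @return the numeric value of \eqn{-2\log L_R}; a large sentinel (`1e10`)
#'   for infeasible parameter points.
#' @export
neg2_restricted_loglik <- function(params, ped, y, X = NULL,
                                   heterogeneous = "error") {
  stopifnot(inherits(params, "trans_par"))
  ctx <- make_reml_context(ped, y, X,
                           include_environment = params$r > 0,
                           heterogeneous = heterogeneous)
  ctx_neg2ll(ctx, params)
}

free_split <- function(free, include_environment) {
  if (include_environment) {
    list(a1 = free[1L], a2 = free[2L], b = free[3L], ll = free[4L])
  } else {
    list(a1 = free[1L], a2 = free[2L], b = -Inf, ll = free[3L])
  }
}

default_starts <- function(include_environment) {
  if (include_environment) {
    list(c(0, 0, 0, 0),
         c(qlogis(0.1), 0, 0, 0),
         c(qlogis(0.95), 0, 0, 0))
  } else {
    list(c(0, 0, 0), c(qlogis(0.1), 0, 0), c(qlogis(0.95), 0, 0))
  }
}

#' Fit the transmissibility model by REML
#'
#' Maximizes the restricted likelihood over the constraint region of
#' [trans_par()].  Internally the residual variance is profiled out in
#' closed form and the optimizer (quasi-Newton, [stats::nlminb()]) works on
#' an unconstrained scale: logistic-stick coordinates for
#' \eqn{(\omega_s, \omega_d)}, a logistic fraction of
#' \eqn{1 - \omega_s^2 - \omega_d^2} for `r`, and
#' \eqn{\log\lambda = \log(\sigma_t^2/\sigma_e^2)}, started from
#' \eqn{\lambda = 1} (a half/half split of the phenotypic variance).
#' Several start points are tried and the best minimum is kept.  With
#' `include_environment = FALSE`, `r` is fixed at 0 (the classical
#' transmissibility model, model tag `"trans"`).
#'
#' Estimates of `r` within `boundary_tol` of 0 are reported as exactly 0
#' with a boundary flag, as required for the boundary likelihood-ratio test.
#'
#' @inheritParams neg2_restricted_loglik
#' @param include_environment if `TRUE` (model tag `"trans-env"`), the
#'   environment covariance `r` is a free parameter.
#' @param control a [reml_control()].
#' @param extra_starts optional list of additional unconstrained start
#'   vectors (e.g. a warm start from the nested null fit).
#' @return An object of class `trans_fit`: `estimates` ([trans_par()]),
#'   `minus2_restricted_loglik`, `converged`, `n_function_evals`,
#'   `boundary_flags`, `start_points_used`, `model`, and the per-start
#'   objective values (`start_objectives`).
#' @export
fit_reml <- function(ped, y, X = NULL, include_environment = TRUE,
                     control = reml_control(), extra_starts = NULL,
                     heterogeneous = "error") {
  ctx <- make_reml_context(ped, y, X, include_environment, heterogeneous)
  vy <- var(y[ctx$obs])

  obj <- function(free) {
    fs <- free_split(free, include_environment)
    u <- plogis(fs$a1)
    v <- plogis(fs$a2)
    omega_s <- u * v
    omega_d <- u * (1 - v)
    rmax <- 1 - omega_s^2 - omega_d^2
    if (rmax <= 0) return(1e10)
    r <- plogis(fs$b) * rmax
    as.numeric(ctx_profiled(ctx, omega_s, omega_d, r, exp(fs$ll)))
  }

  starts <- if (identical(control$starts, "default")) {
    default_starts(include_environment)
  } else {
    control$starts
  }
  if (!is.null(extra_starts)) starts <- c(extra_starts, starts)

  runs <- lapply(starts, function(s0) {
    nlminb(s0, obj,
           lower = -control$bound, upper = control$bound,
           control = list(rel.tol = control$rel_tol,
                          eval.max = control$eval_max,
                          iter.max = control$iter_max))
  })
  objs <- vapply(runs, function(rn) rn$objective, numeric(1))
  best <- runs[[which.min(objs)]]

  fs <- free_split(best$par, include_environment)
  u <- plogis(fs$a1)
  v <- plogis(fs$a2)
  omega_s <- u * v
  omega_d <- u * (1 - v)
  rmax <- 1 - omega_s^2 - omega_d^2
  r <- plogis(fs$b) * rmax
  prof <- ctx_profiled(ctx, omega_s, omega_d, r, exp(fs$ll))
  s2e <- attr(prof, "sigma2")
  s2t <- exp(fs$ll) * s2e

  flags <- character(0)
  if (include_environment && r < control$boundary_tol) {
    r <- 0
    flags <- c(flags, "r=0")
  }
  if (u < control$boundary_tol) flags <- c(flags, "omega_total=0")
  if (u > 1 - control$boundary_tol) flags <- c(flags, "omega_total=1")
  if (omega_s < control$boundary_tol) flags <- c(flags, "omega_s=0")
  if (omega_d < control$boundary_tol) flags <- c(flags, "omega_d=0")
  if (abs(fs$ll) >= control$bound - 1e-6) flags <- c(flags, "lambda_bound")

  converged <- best$convergence == 0 ||
    grepl("relative convergence|both X-convergence|singular convergence",
          best$message %||% "")

  structure(list(
    estimates = trans_par(omega_s, omega_d, s2t, s2e, r),
    minus2_restricted_loglik = as.numeric(prof),
    converged = converged,
    message = best$message,
    n_function_evals = sum(vapply(runs, function(rn) sum(rn$evaluations), numeric(1))),
    boundary_flags = flags,
    start_points_used = length(starts),
    start_objectives = objs,
    model = if (include_environment) "trans-env" else "trans",
    n = ctx$n, n_phenotyped = ctx$nobs,
    phenotypic_variance = vy
  ), class = "trans_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method print trans_fit
#' @export
print.trans_fit <- function(x, ...) {
  cat(sprintf("REML fit of the %s model (%d animals, %d phenotyped)\n",
              if (x$model == "trans-env") "transmissibility-with-environment"
              else "classical transmissibility",
              x$n, x$n_phenotyped))
  print(x$estimates)
  cat(sprintf("  -2 log L_R = %.4f | converged: %s | evaluations: %d (%d starts)\n",
              x$minus2_restricted_loglik, x$converged, x$n_function_evals,
              x$start_points_used))
  if (length(x$boundary_flags)) {
    cat("  boundary:", paste(x$boundary_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a flat key-value fit report
#'
#' Serializes a [fit_reml()] result as a two-column `key,value` CSV block so
#' that fits can be archived and compared from the command line.
#'
#' @param fit a `trans_fit`.
#' @param path file to write / read.
#' @param extra named character/numeric vector of extra keys (e.g. `seed`).
#' @return `write_fit_report()`: `path`, invisibly. `read_fit_report()`: a
#'   named list with numeric values where possible.
#' @export
write_fit_report <- function(fit, path, extra = NULL) {
  est <- fit$estimates
  kv <- c(model = fit$model,
          omega_s = est$omega_s, omega_d = est$omega_d,
          sigma2_t = est$sigma2_t, sigma2_e = est$sigma2_e, r = est$r,
          minus2_restricted_loglik = fit$minus2_restricted_loglik,
          converged = fit$converged,
          n_function_evals = fit$n_function_evals,
          boundary_flags = paste(fit$boundary_flags, collapse = ";"),
          extra)
  write.csv(data.frame(key = names(kv), value = unname(unlist(kv))),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                   colClasses = "character")
  out <- as.list(df$value)
  names(out) <- df$key
  for (nm in names(out)) {
    num <- suppressWarnings(as.numeric(out[[nm]]))
    if (!is.na(num)) out[[nm]] <- num
  }
  out
}
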