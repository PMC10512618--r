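## Transmission relationship structure.  With t_i = omega_s t_{s(i)} +
## omega_d t_{d(i)} + eps_i, the covariance of t is M_E sigma_t^2 with
## M_E^{-1} = L' D_E^{-1} L: L carries the negated parent path coefficients,
## and D_E is the (block-diagonal) covariance of the transmissibility
## samplings relative to sigma_t^2 -- delta_i on the diagonal and r between
## animals sharing an environment.

#' Lower-triangular transmission coefficient matrix L
#'
#' Unit diagonal; entry `(i, sire(i))` is \eqn{-\omega_s} and
#' `(i, dam(i))` is \eqn{-\omega_d} for known parents; zero elsewhere.
#' Because the pedigree is topologically ordered the matrix is lower
#' triangular with at most two off-diagonal entries per row.
#'
#' @param ped a [pedigree()].
#' @param omega_s,omega_d path coefficients of transmission.
#' @return a sparse lower-triangular `Matrix`.
#' @export
build_L <- function(ped, omega_s, omega_d) {
  n <- nrow(ped)
  pk <- parent_known(ped)
  i <- c(seq_len(n), which(pk$sire), which(pk$dam))
  j <- c(seq_len(n), ped$sire_idx[pk$sire], ped$dam_idx[pk$dam])
  x <- c(rep(1, n), rep(-omega_s, sum(pk$sire)), rep(-omega_d, sum(pk$dam)))
  sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' Covariance structure D_E of the transmissibility samplings
#'
#' Relative to \eqn{\sigma_t^2}, the samplings of animals in singleton
#' environments are independent with variance \eqn{\delta_i}; within each
#' shared environment the block has \eqn{\delta} on the diagonal and the
#' covariance `r` off the diagonal.  The block closed-form inverse requires
#' all members of a shared environment to have the same parental-knowledge
#' status (hence a common \eqn{\delta}); heterogeneous blocks are a fatal
#' error by default, or are kept with per-animal \eqn{\delta_i} and inverted
#' densely when `heterogeneous = "dense"`.
#'
#' @param ped a [pedigree()] with environment labels.
#' @param params a [trans_par()].
#' @param heterogeneous `"error"` (default) or `"dense"`: handling of shared
#'   environments whose members differ in parental status.
#' @return A list with `D_diag` (per-animal \eqn{\delta_i}), `blocks` (one
#'   entry per shared environment: members, size `m`, `delta` -- scalar, or a
#'   vector for a heterogeneous block kept under `"dense"` -- and `r`) and
#'   `feasible` (`FALSE` when some block violates positive definiteness,
#'   i.e. `r >= delta`).
#' @export
build_DE <- function(ped, params, heterogeneous = c("error", "dense")) {
  heterogeneous <- match.arg(heterogeneous)
  stopifnot(inherits(params, "trans_par"))
  pk <- parent_known(ped)
  delta <- compute_delta(params$omega_s, params$omega_d, pk$sire, pk$dam)
  r <- params$r
  blocks <- list()
  if (r > 0) {
    blocks <- lapply(env_blocks(ped), function(b) {
      d <- delta[b$members]
      if (length(unique(d)) > 1L) {
        if (heterogeneous == "error") {
          stop("shared environment '", b$label, "' mixes animals with ",
               "different parental-knowledge status; the closed-form block ",
               "inverse requires a common delta (use heterogeneous = \"dense\")")
        }
      } else {
        d <- d[1L]
      }
      list(label = b$label, members = b$members, m = b$m, delta = d, r = r)
    })
  }
  feasible <- all(vapply(blocks, function(b) {
    min(b$delta) - b$r > 0 && min(b$delta) + (b$m - 1) * b$r > 0
  }, logical(1)))
  list(D_diag = delta, blocks = blocks, feasible = feasible)
}

#' Closed-form inverse of a compound-symmetry environment block
#'
#' A shared-environment block of `m` animals with common \eqn{\delta} is
#' \eqn{(\delta - r) I_m + r J_m}; its inverse is
#' \deqn{\frac{1}{\delta - r}\left[I_m - \frac{r}{\delta + (m-1)r} J_m\right].}
#' The block is positive definite iff \eqn{\delta - r > 0} and
#' \eqn{\delta + (m-1) r > 0}; otherwise an infeasible-parameter condition is
#' signalled (the REML optimizer treats it as a rejected point).
#'
#' @param m block size.
#' @param delta common diagonal value \eqn{\delta}.
#' @param r off-diagonal covariance.
#' @return an `m x m` symmetric matrix.
#' @export
invert_DE_block <- function(m, delta, r) {
  stopifnot(m >= 1, length(delta) == 1L)
  if (min(delta - r, delta + (m - 1) * r) <= 1e-12) {
    infeasible(sprintf(
      "environment block not positive definite (m = %d, delta = %g, r = %g)",
      m, delta, r))
  }
  a <- 1 / (delta - r)
  b <- -r / ((delta - r) * (delta + (m - 1) * r))
  out <- matrix(b, m, m)
  diag(out) <- a + b
  out
}

## dense numeric inverse for a heterogeneous block kept under "dense" mode
invert_DE_block_dense <- function(delta, r) {
  m <- length(delta)
  B <- matrix(r, m, m)
  diag(B) <- delta
  ev <- min(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-12) infeasible("heterogeneous environment block not positive definite")
  solve(B)
}

## sparse D_E^{-1} from a build_DE() structure
build_DE_inverse <- function(de) {
  n <- length(de$D_diag)
  dx <- 1 / de$D_diag
  ii <- jj <- xx <- list()
  k <- 1L
  for (b in de$blocks) {
    binv <- if (length(b$delta) == 1L) {
      invert_DE_block(b$m, b$delta, b$r)
    } else {
      invert_DE_block_dense(b$delta, b$r)
    }
    dx[b$members] <- diag(binv)
    off <- which(upper.tri(binv) | lower.tri(binv), arr.ind = TRUE)
    ii[[k]] <- b$members[off[, 1L]]
    jj[[k]] <- b$members[off[, 2L]]
    xx[[k]] <- binv[off]
    k <- k + 1L
  }
  sparseMatrix(i = c(seq_len(n), unlist(ii)),
               j = c(seq_len(n), unlist(jj)),
               x = c(dx, unlist(xx)), dims = c(n, n))
}

#' Inverse of the transmission relationship matrix with environment
#'
#' Assembles \eqn{M_E^{-1} = L' D_E^{-1} L} directly from the pedigree and
#' parameters, without ever forming \eqn{M_E}: the decomposition makes the
#' inverse sparse and cheap even for large pedigrees.  With `r = 0` this is
#' the classical transmissibility matrix inverse \eqn{L' D^{-1} L}.
#'
#' @inheritParams build_DE
#' @return a sparse symmetric positive-definite `Matrix`.
#' @export
build_ME_inverse <- function(ped, params, heterogeneous = c("error", "dense")) {
  de <- build_DE(ped, params, heterogeneous)
  L <- build_L(ped, params$omega_s, params$omega_d)
  forceSymmetric(crossprod(L, build_DE_inverse(de) %*% L))
}

#' Dense transmission relationship matrix (reference implementation)
#'
#' Forms \eqn{M_E = L^{-1} D_E L^{-T}} by dense triangular solves.  This is
#' the covariance (relative to \eqn{\sigma_t^2}) of the global transmissible
#' potentials implied by the transmission recursion; it is quadratic in
#' memory and intended for small pedigrees and for cross-checking
#' [build_ME_inverse()].  With \eqn{\omega_s = \omega_d = 0.5} and `r = 0`
#' on a non-inbred pedigree it equals the additive (numerator) relationship
#' matrix.
#'
#' @inheritParams build_DE
#' @return a dense `n x n` symmetric matrix.
#' @export
build_ME_dense <- function(ped, params, heterogeneous = c("error", "dense")) {
  n <- nrow(ped)
  de <- build_DE(ped, params, heterogeneous)
  DE <- diag(de$D_diag, n)
  for (b in de$blocks) {
    Bm <- matrix(b$r, b$m, b$m)
    diag(Bm) <- b$delta
    DE[b$members, b$members] <- Bm
  }
  Ld <- as.matrix(build_L(ped, params$omega_s, params$omega_d))
  A <- solve(Ld, DE)
  ME <- t(solve(Ld, t(A)))
  (ME + t(ME)) / 2
}
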