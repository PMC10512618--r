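# Independent reference implementations used to cross-check the package.
# Everything here is written from first principles with dense base-R
# linear algebra, deliberately not sharing code with the package.

# dense L, D_E and M_E = L^-1 D_E L^-T built by nested loops
oracle_ME <- function(ped, params) {
  n <- nrow(ped)
  os <- params$omega_s
  od <- params$omega_d
  L <- diag(n)
  delta <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]
    d <- ped$dam_idx[i]
    delta[i] <- 1
    if (!is.na(s)) {
      L[i, s] <- -os
      delta[i] <- delta[i] - os^2
    }
    if (!is.na(d)) {
      L[i, d] <- -od
      delta[i] <- delta[i] - od^2
    }
  }
  DE <- diag(delta)
  if (params$r > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && !is.na(ped$env[i]) && !is.na(ped$env[j]) &&
            ped$env[i] == ped$env[j]) {
          DE[i, j] <- params$r
        }
      }
    }
  }
  Linv <- solve(L)
  Linv %*% DE %*% t(Linv)
}

# additive numerator relationship matrix by the tabular method
oracle_A <- function(ped) {
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]
    d <- ped$dam_idx[i]
    for (j in seq_len(i - 1L)) {
      a <- 0
      if (!is.na(s)) a <- a + 0.5 * A[j, s]
      if (!is.na(d)) a <- a + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- a
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

# textbook dense REML evaluation: V = Z ME sigma_t^2 Z' + I sigma_e^2
oracle_neg2ll <- function(params, ped, y, X) {
  obs <- which(!is.na(y))
  yo <- y[obs]
  Xo <- as.matrix(X)
  if (nrow(Xo) == nrow(ped)) Xo <- Xo[obs, , drop = FALSE]
  ME <- oracle_ME(ped, params)
  V <- params$sigma2_t * ME[obs, obs, drop = FALSE] +
    diag(params$sigma2_e, length(obs))
  Vi <- solve(V)
  XVX <- t(Xo) %*% Vi %*% Xo
  P <- Vi - Vi %*% Xo %*% solve(XVX) %*% t(Xo) %*% Vi
  as.numeric(determinant(V, logarithm = TRUE)$modulus +
               determinant(XVX, logarithm = TRUE)$modulus +
               t(yo) %*% P %*% yo +
               (length(obs) - ncol(Xo)) * log(2 * pi))
}

# random toy pedigree: parents sampled among earlier animals, random
# unknowns, optional shared-environment blocks drawn within groups of
# identical parental-knowledge status
random_toy_pedigree <- function(n = 30, n_blocks = 1, p_unknown = 0.3) {
  id <- paste0("A", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (runif(1) > p_unknown) sire[i] <- id[sample.int(i - 1L, 1L)]
    if (runif(1) > p_unknown) {
      repeat {
        cand <- sample.int(i - 1L, 1L)
        if (is.na(sire[i]) || id[cand] != sire[i]) break
      }
      dam[i] <- id[cand]
    }
  }
  env <- rep(NA_character_, n)
  status <- paste(is.na(sire), is.na(dam))
  for (b in seq_len(n_blocks)) {
    grp <- sample(unique(status), 1L)
    pool <- setdiff(which(status == grp & is.na(env)), 1:2)
    if (length(pool) >= 2L) {
      members <- sample(pool, min(length(pool), sample(2:5, 1L)))
      env[members] <- paste0("blk", b)
    }
  }
  pedigree(id, sire, dam, env)
}

random_feasible_par <- function(max_rho = 0.9) {
  os <- runif(1, 0, 0.7)
  od <- runif(1, 0, 1 - os)
  rmax <- 1 - os^2 - od^2
  trans_par(os, od, sigma2_t = runif(1, 0.5, 5), sigma2_e = runif(1, 0.5, 5),
            r = runif(1, 0, max_rho) * rmax)
}

write_ped_file <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
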