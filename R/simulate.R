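## Mirrored two-line experimental design and phenotype simulation.
##
## The design: N founder couples (G0) each produce n_off offspring (G1).
## One G1 male per family is mated to two sisters of the next family
## (rotation f -> f+1 mod N), giving two groups of n_off offspring per
## family at G2.  One group per family is exposed to the particular shared
## environment; the exposed groups found line E+, the others line E-.  Each
## line is then propagated for n_generations_post generations by mirrored
## single-pair matings (first two offspring of the corresponding mating),
## keeping the two lines' pedigrees exactly parallel.

#' Build the mirrored two-line pedigree
#'
#' @param N number of founder couples (families); at least 2, so that G2
#'   matings can cross families.
#' @param n_off offspring per mating; at least 2 (the post-exposure
#'   single-pair matings use the first two offspring).  With `n_off = 2` a
#'   G1 animal serves as sire for its own family and as dam for the rotated
#'   one (parental roles, not sexes); `n_off >= 3` keeps roles
#'   sex-consistent.
#' @param n_generations_post generations bred after the exposure generation
#'   (default 3, the design's G3-G5).
#' @return a [pedigree()] with design columns `generation` (0-based), `line`
#'   (`"E+"`/`"E-"`, `NA` before the split), `family`, and `exposed`
#'   (`TRUE` exactly for the shared-environment G2 group of line E+); the
#'   exposed animals carry a common environment label, everyone else a
#'   singleton one.
#' @examples
#' ped <- mirrored_design(N = 20, n_off = 10)
#' nrow(ped)          # 1840
#' sum(ped$exposed)   # 200
#' @export
mirrored_design <- function(N = 20, n_off = 10, n_generations_post = 3) {
  stopifnot(N >= 2, n_off >= 2, n_generations_post >= 0)
  id <- character(0)
  sire <- character(0)
  dam <- character(0)
  generation <- integer(0)
  line <- character(0)
  family <- integer(0)
  exposed <- logical(0)
  add <- function(ids, s, d, g, l, f, e) {
    id <<- c(id, ids)
    sire <<- c(sire, s)
    dam <<- c(dam, d)
    generation <<- c(generation, rep(g, length(ids)))
    line <<- c(line, rep(l, length(ids)))
    family <<- c(family, rep(f, length(ids)))
    exposed <<- c(exposed, rep(e, length(ids)))
    ids
  }

  g0m <- g0f <- character(N)
  for (f in seq_len(N)) {
    g0m[f] <- add(sprintf("G0_M%d", f), NA, NA, 0L, NA, f, FALSE)
    g0f[f] <- add(sprintf("G0_F%d", f), NA, NA, 0L, NA, f, FALSE)
  }
  g1 <- matrix("", N, n_off)
  for (f in seq_len(N)) {
    g1[f, ] <- add(sprintf("G1_%d_%d", f, seq_len(n_off)),
                   rep(g0m[f], n_off), rep(g0f[f], n_off), 1L, NA, f, FALSE)
  }
  ## G2: sire = first offspring of family f; dams = two sisters of family
  ## f+1 (offspring 2 and 3, or 1 and 2 when n_off = 2)
  dam_slots <- if (n_off >= 3) c(2L, 3L) else c(1L, 2L)
  groups <- list(`E+` = matrix("", N, n_off), `E-` = matrix("", N, n_off))
  for (f in seq_len(N)) {
    fp <- f %% N + 1L
    groups[["E+"]][f, ] <- add(sprintf("G2_Ep_%d_%d", f, seq_len(n_off)),
                               rep(g1[f, 1L], n_off),
                               rep(g1[fp, dam_slots[1L]], n_off),
                               2L, "E+", f, TRUE)
    groups[["E-"]][f, ] <- add(sprintf("G2_Em_%d_%d", f, seq_len(n_off)),
                               rep(g1[f, 1L], n_off),
                               rep(g1[fp, dam_slots[2L]], n_off),
                               2L, "E-", f, FALSE)
  }
  if (n_generations_post > 0) {
    for (g in 2L + seq_len(n_generations_post)) {
      nxt <- list(`E+` = matrix("", N, n_off), `E-` = matrix("", N, n_off))
      for (l in c("E+", "E-")) {
        tag <- if (l == "E+") "Ep" else "Em"
        for (f in seq_len(N)) {
          nxt[[l]][f, ] <- add(sprintf("G%d_%s_%d_%d", g, tag, f, seq_len(n_off)),
                               rep(groups[[l]][f, 1L], n_off),
                               rep(groups[[l]][f, 2L], n_off),
                               g, l, f, FALSE)
        }
      }
      groups <- nxt
    }
  }
  env <- ifelse(exposed, "particular", NA_character_)
  pedigree(id = id, sire = sire, dam = dam, env = env,
           extra = data.frame(generation = generation, line = line,
                              family = family, exposed = exposed,
                              stringsAsFactors = FALSE))
}

## no-inbreeding delta for every animal of a pedigree
ped_delta <- function(ped, omega_s, omega_d) {
  pk <- parent_known(ped)
  compute_delta(omega_s, omega_d, pk$sire, pk$dam)
}

## run the transmission recursion t_i = w_s t_s + w_d t_d + eps_i given the
## per-animal innovations eps (pedigree is topologically ordered)
transmit <- function(ped, omega_s, omega_d, eps) {
  n <- nrow(ped)
  t <- numeric(n)
  si <- ped$sire_idx
  di <- ped$dam_idx
  for (i in seq_len(n)) {
    t[i] <- eps[i] +
      (if (is.na(si[i])) 0 else omega_s * t[si[i]]) +
      (if (is.na(di[i])) 0 else omega_d * t[di[i]])
  }
  t
}

#' Simulate one replicate of the mirrored-design study
#'
#' Draws transmissible potentials through the transmission recursion and
#' phenotypes `y = mu + [theta +] t + e` under the two study scenarios.  The
#' exposure effect is the constant \eqn{\theta_0 \sigma_t} with
#' \eqn{\theta_0 = \sqrt{r}}:
#' * **Scenario 1** (environmental effect on the phenotype only, not
#'   transmitted): `t` follows the classical recursion with sampling
#'   variance \eqn{\delta_i \sigma_t^2} everywhere, and the constant is
#'   added to the *phenotype* of exposed animals.
#' * **Scenario 2** (transmitted effect): the constant is added to the
#'   *transmissible potential* of exposed animals, whose remaining sampling
#'   variance is reduced to \eqn{(\delta_i - r)\sigma_t^2}.
#'
#' @param ped a [mirrored_design()] pedigree (any pedigree with a logical
#'   `exposed` column works).
#' @param params the truth [trans_par()]; `r` drives both the exposure
#'   constant and, in Scenario 2, the sampling-variance reduction.
#' @param scenario 1 or 2.
#' @param mu intercept of the phenotype model.
#' @param seed optional integer for reproducibility: the same seed yields a
#'   bit-identical replicate.
#' @return a `trans_sim` list: `ped`, `y`, `t`, `xi`, `theta` (per-animal
#'   constant actually applied), `e`, `scenario`, `params`.
#' @export
simulate_replicate <- function(ped, params, scenario, mu = 0, seed = NULL) {
  stopifnot(inherits(params, "trans_par"), scenario %in% c(1, 2))
  if (is.null(ped$exposed)) stop("pedigree lacks an 'exposed' column")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  exposed <- as.logical(ped$exposed)
  delta <- ped_delta(ped, params$omega_s, params$omega_d)
  r <- params$r
  if (scenario == 2 && any(delta[exposed] - r <= 0)) {
    stop("infeasible truth: r >= delta for some exposed animal")
  }
  theta0 <- sqrt(r) * sqrt(params$sigma2_t)
  theta <- ifelse(exposed, theta0, 0)

  xi_var <- delta * params$sigma2_t
  if (scenario == 2) xi_var[exposed] <- (delta[exposed] - r) * params$sigma2_t
  xi <- rnorm(n, 0, sqrt(xi_var))
  eps <- if (scenario == 2) xi + theta else xi
  t <- transmit(ped, params$omega_s, params$omega_d, eps)
  e <- rnorm(n, 0, sqrt(params$sigma2_e))
  y <- mu + t + e
  if (scenario == 1) y <- y + theta

  structure(list(ped = ped, y = y, t = t, xi = xi, theta = theta, e = e,
                 scenario = scenario, params = params),
            class = "trans_sim")
}

#' Simulate phenotypes in a population with many shared environments
#'
#' Generic multi-environment mode: one random transmitted effect
#' \eqn{\theta_k \sim N(0, r\sigma_t^2)} is drawn per shared environment
#' (labels held by two or more animals) and enters the transmissibility
#' sampling \eqn{\varepsilon_i = \xi_i + \theta_k} of each member, whose
#' remaining variance is \eqn{(\delta_i - r)\sigma_t^2}; animals in
#' singleton environments keep \eqn{\delta_i \sigma_t^2}.
#'
#' @param ped a [pedigree()] whose `env` column assigns the environments.
#' @inheritParams simulate_replicate
#' @return a `trans_sim` list as in [simulate_replicate()]; `theta` holds
#'   each animal's environment draw (0 for singleton environments).
#' @export
simulate_generic_environments <- function(ped, params, mu = 0, seed = NULL) {
  stopifnot(inherits(params, "trans_par"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  delta <- ped_delta(ped, params$omega_s, params$omega_d)
  r <- params$r
  blocks <- env_blocks(ped)
  shared <- logical(n)
  for (b in blocks) shared[b$members] <- TRUE
  if (any(delta[shared] - r <= 0)) {
    stop("infeasible truth: r >= delta inside a shared environment")
  }
  xi_var <- delta * params$sigma2_t
  xi_var[shared] <- (delta[shared] - r) * params$sigma2_t
  xi <- rnorm(n, 0, sqrt(xi_var))
  theta <- numeric(n)
  for (b in blocks) theta[b$members] <- rnorm(1, 0, sqrt(r * params$sigma2_t))
  t <- transmit(ped, params$omega_s, params$omega_d, xi + theta)
  e <- rnorm(n, 0, sqrt(params$sigma2_e))
  structure(list(ped = ped, y = mu + t + e, t = t, xi = xi, theta = theta,
                 e = e, scenario = "generic", params = params),
            class = "trans_sim")
}

#' Write a simulated replicate as a delimited pedigree/phenotype file
#'
#' Produces the tabular format read back by [read_pedigree()]: columns
#' `animal`, `sire`, `dam`, `environment`, `phenotype`, `exposed`, plus the
#' design tags when present.
#'
#' @param sim a `trans_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_replicate <- function(sim, path) {
  ped <- sim$ped
  df <- data.frame(animal = ped$id,
                   sire = ifelse(is.na(ped$sire), "0", ped$sire),
                   dam = ifelse(is.na(ped$dam), "0", ped$dam),
                   environment = ifelse(is.na(ped$env), ped$id, ped$env),
                   phenotype = sim$y,
                   stringsAsFactors = FALSE)
  for (nm in c("exposed", "line", "family", "generation")) {
    if (!is.null(ped[[nm]])) df[[nm]] <- ped[[nm]]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
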