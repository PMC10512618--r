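test_that("the default mirrored design has the published size", {
  ped <- mirrored_design(N = 20, n_off = 10, n_generations_post = 3)
  expect_equal(nrow(ped), 1840L)
  expect_equal(sum(ped$exposed), 200L)  # N * n_off exposed at G2
  expect_equal(max(ped$generation), 5L)
  # pedigree count identity: 2N + N n_off + 2N n_off + 3 * 2N n_off
  expect_equal(nrow(ped), 2 * 20 + 20 * 10 + 2 * 20 * 10 + 3 * 2 * 20 * 10)
  # one shared environment holding exactly the exposed animals
  blocks <- transenv:::env_blocks(ped)
  expect_length(blocks, 1L)
  expect_setequal(blocks[[1]]$members, which(ped$exposed))
})

test_that("the minimal N = 2, n_off = 2 design enumerates to 40 animals", {
  ped <- mirrored_design(N = 2, n_off = 2, n_generations_post = 3)
  expect_equal(nrow(ped), 40L)  # 4 + 4 + 8 + 3 x 8
  expect_equal(sum(ped$exposed), 4L)
  expect_error(mirrored_design(N = 1), "N")
  expect_error(mirrored_design(N = 2, n_off = 1), "n_off")
})

test_that("the two lines are mirrored: relabeling E+ <-> E- is an isomorphism", {
  ped <- mirrored_design(N = 4, n_off = 3, n_generations_post = 2)
  for (g in 2:4) {
    plus <- ped[ped$generation == g & ped$line == "E+", ]
    minus <- ped[ped$generation == g & ped$line == "E-", ]
    expect_equal(nrow(plus), nrow(minus))
    expect_equal(table(plus$family), table(minus$family))
    # parental structure is parallel: the sire families match pairwise
    sire_fam <- function(df) ped$family[match(df$sire, ped$id)]
    expect_equal(sire_fam(plus), sire_fam(minus))
  }
})

test_that("all G2 group members share both parents and the exposure block is G2 E+", {
  ped <- mirrored_design(N = 3, n_off = 4, n_generations_post = 1)
  g2 <- ped[ped$generation == 2, ]
  for (f in unique(g2$family)) {
    for (l in c("E+", "E-")) {
      grp <- g2[g2$family == f & g2$line == l, ]
      expect_equal(length(unique(grp$sire)), 1L)
      expect_equal(length(unique(grp$dam)), 1L)
    }
  }
  expect_true(all(ped$exposed[ped$generation == 2 & ped$line == "E+"]))
  expect_false(any(ped$exposed[ped$generation != 2 | ped$line != "E+"]))
})

test_that("replicates are reproducible and founders match the truth variances", {
  ped <- mirrored_design(N = 10, n_off = 4, n_generations_post = 1)
  par <- trans_par(0.4, 0.25, 5, 10, r = 0.544)
  s1 <- simulate_replicate(ped, par, scenario = 2, seed = 99)
  s2 <- simulate_replicate(ped, par, scenario = 2, seed = 99)
  expect_identical(s1$y, s2$y)
  expect_identical(s1$t, s2$t)
  # founder moments over replicates
  founders <- which(ped$generation == 0)
  tv <- ev <- numeric(60)
  set.seed(1234)
  for (k in seq_along(tv)) {
    s <- simulate_replicate(ped, par, scenario = 2)
    tv[k] <- var(s$t[founders])
    ev[k] <- var(s$e)
  }
  expect_equal(mean(tv), 5, tolerance = 0.15)
  expect_equal(mean(ev), 10, tolerance = 0.05)
})

test_that("scenario 2 shifts exposed potentials by sqrt(r) sigma_t, diluted by
           (omega_s + omega_d) per generation", {
  ped <- mirrored_design(N = 30, n_off = 8, n_generations_post = 3)
  par <- trans_par(0.40, 0.25, 5, 10, r = 0.544)
  shift0 <- sqrt(0.544 * 5)
  diffs <- matrix(0, 25, 4)
  set.seed(555)
  for (k in seq_len(nrow(diffs))) {
    s <- simulate_replicate(ped, par, scenario = 2)
    for (g in 2:5) {
      gp <- ped$generation == g
      diffs[k, g - 1] <- mean(s$t[gp & ped$line == "E+"]) -
        mean(s$t[gp & ped$line == "E-"])
    }
  }
  md <- colMeans(diffs)
  expect_equal(md[1], shift0, tolerance = 0.12)
  for (g in 2:4) {
    expect_equal(md[g] / md[g - 1], 0.65, tolerance = 0.15)
  }
  # scenario 1 leaves the potentials unshifted and moves the phenotype instead
  set.seed(556)
  s1 <- simulate_replicate(ped, par, scenario = 1)
  g2p <- ped$generation == 2 & ped$line == "E+"
  g2m <- ped$generation == 2 & ped$line == "E-"
  expect_equal(mean(s1$y[g2p] - s1$t[g2p]) - mean(s1$y[g2m] - s1$t[g2m]),
               shift0, tolerance = 0.3)
  expect_equal(s1$theta[g2p], rep(shift0, sum(g2p)))
})

test_that("an infeasible scenario-2 truth is fatal before any draw", {
  ped <- mirrored_design(N = 2, n_off = 3, n_generations_post = 0)
  # r at its bound equals delta of the known-parent exposed animals, so the
  # remaining sampling variance (delta - r) degenerates to zero
  par <- trans_par(0.6, 0.3, 5, 10, r = 1 - 0.6^2 - 0.3^2)
  expect_error(simulate_replicate(ped, par, scenario = 2), "infeasible")
})

test_that("generic environments induce the stated covariance structure", {
  # many parallel sib pairs sharing environments; independent families make
  # within- vs between-environment covariance estimable over replicates
  n_env <- 40
  ids <- sires <- dams <- env <- character(0)
  for (k in seq_len(n_env)) {
    s <- paste0("s", k)
    d <- paste0("d", k)
    ids <- c(ids, s, d, paste0("o", k, "_", 1:2))
    sires <- c(sires, NA, NA, s, s)
    dams <- c(dams, NA, NA, d, d)
    env <- c(env, NA, NA, paste0("e", k), paste0("e", k))
  }
  ped <- pedigree(ids, sires, dams, env)
  par <- trans_par(0.4, 0.25, 5, 10, r = 0.4)
  o1 <- which(grepl("^o.*_1$", ped$id))
  o2 <- which(grepl("^o.*_2$", ped$id))
  set.seed(808)
  R <- 150
  prods_within <- prods_between <- numeric(0)
  for (rep in seq_len(R)) {
    s <- simulate_generic_environments(ped, par)
    eps <- s$xi + s$theta
    prods_within <- c(prods_within, eps[o1] * eps[o2])
    prods_between <- c(prods_between, eps[o1] * eps[c(o2[-1], o2[1])])
  }
  expect_equal(mean(prods_within), 0.4 * 5, tolerance = 0.15)
  expect_lt(abs(mean(prods_between)), 0.15)
  # a single shared environment reduces to the special exposed-group case
  expect_equal(length(unique(s$theta[which(ped$env == "e1")])), 1L)
})
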