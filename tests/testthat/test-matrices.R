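trio <- pedigree(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
                 dam = c(NA, NA, "d"))

test_that("L carries the negated path coefficients below a unit diagonal", {
  L <- as.matrix(build_L(trio, 0.4, 0.25))
  expect_equal(L[3, ], c(s = -0.4, d = -0.25, o = 1),
               ignore_attr = TRUE)
  expect_equal(diag(L), rep(1, 3))
  # founders only
  f <- pedigree(c("a", "b"))
  expect_equal(as.matrix(build_L(f, 0.4, 0.25)), diag(2), ignore_attr = TRUE)
  # unknown sire: a single off-diagonal entry
  half <- pedigree(c("m", "k"), dam = c(NA, "m"))
  Lh <- as.matrix(build_L(half, 0.4, 0.25))
  expect_equal(Lh[2, 1], -0.25)
  expect_equal(sum(Lh != 0), 3)
})

test_that("D_E reduces to diagonal D for singleton labels or r = 0", {
  ped <- pedigree(c("a", "b", "c", "d"), sire = c(NA, NA, "a", "a"),
                  dam = c(NA, NA, "b", "b"), env = c(NA, NA, "k", "k"))
  p0 <- trans_par(0.4, 0.25, 5, 10, r = 0)
  de0 <- build_DE(ped, p0)
  expect_length(de0$blocks, 0L)
  expect_equal(de0$D_diag, c(1, 1, 0.7775, 0.7775))
  # all-singleton labels: no blocks even with r > 0
  ped2 <- pedigree(c("a", "b"), env = c("e1", "e2"))
  expect_length(build_DE(ped2, trans_par(0.4, 0.25, 5, 10, r = 0.5))$blocks, 0L)
})

test_that("a shared block of known-parent animals records (delta, r)", {
  n_mem <- 6
  ids <- c("s", "d", paste0("k", seq_len(n_mem)))
  ped <- pedigree(ids, sire = c(NA, NA, rep("s", n_mem)),
                  dam = c(NA, NA, rep("d", n_mem)),
                  env = c(NA, NA, rep("stress", n_mem)))
  par1 <- trans_par(0.40, 0.25, 5, 10, r = 0.544)
  de <- build_DE(ped, par1)
  expect_length(de$blocks, 1L)
  expect_equal(de$blocks[[1]]$delta, 0.7775)
  expect_equal(de$blocks[[1]]$r, 0.544)
  expect_equal(de$blocks[[1]]$m, n_mem)
  expect_true(de$feasible)
})

test_that("heterogeneous parental status in a block errors unless dense mode", {
  ped <- pedigree(c("s", "a", "b"), sire = c(NA, "s", NA),
                  env = c(NA, "k", "k"))
  par <- trans_par(0.4, 0.25, 5, 10, r = 0.2)
  expect_error(build_DE(ped, par), "parental")
  de <- build_DE(ped, par, heterogeneous = "dense")
  expect_length(de$blocks[[1]]$delta, 2L)
  # dense-mode inverse still matches the package inverse identity
  MEi <- build_ME_inverse(ped, par, heterogeneous = "dense")
  ME <- build_ME_dense(ped, par, heterogeneous = "dense")
  expect_lt(max(abs(as.matrix(MEi %*% ME) - diag(3))), 1e-10)
})

test_that("the compound-symmetry block inverse matches dense inversion", {
  expect_equal(invert_DE_block(1, 0.9, 0.5), matrix(1 / 0.9), tolerance = 1e-12)
  B2 <- matrix(c(0.7775, 0.544, 0.544, 0.7775), 2)
  expect_lt(max(abs(invert_DE_block(2, 0.7775, 0.544) - solve(B2))), 1e-10)
  set.seed(5)
  for (k in 1:20) {
    m <- sample(2:8, 1)
    delta <- runif(1, 0.4, 1)
    r <- runif(1, 0, delta * 0.95)
    B <- matrix(r, m, m)
    diag(B) <- delta
    expect_lt(max(abs(invert_DE_block(m, delta, r) - solve(B))), 1e-10)
  }
})

test_that("block inversion fails exactly on the positive-definiteness boundary", {
  expect_error(invert_DE_block(3, 0.5, 0.5), class = "transenv_infeasible")
  expect_error(invert_DE_block(3, 0.5, 0.6), class = "transenv_infeasible")
  expect_silent(invert_DE_block(3, 0.5, 0.499))
  # negative r: fails iff delta + (m-1) r <= 0
  expect_error(invert_DE_block(3, 0.5, -0.25), class = "transenv_infeasible")
  expect_silent(invert_DE_block(3, 0.5, -0.24))
})

test_that("M_E^-1 equals the inverse of the dense oracle on random pedigrees", {
  set.seed(101)
  worst <- 0
  for (k in 1:100) {
    ped <- random_toy_pedigree(n = sample(10:50, 1),
                               n_blocks = sample(0:2, 1))
    par <- random_feasible_par()
    ME <- oracle_ME(ped, par)
    MEi <- as.matrix(build_ME_inverse(ped, par))
    worst <- max(worst, max(abs(MEi %*% ME - diag(nrow(ped)))))
  }
  expect_lt(worst, 1e-8)
})

test_that("omega_s = omega_d = 0.5, r = 0 reproduces the numerator relationship matrix", {
  # non-inbred: founders crossed, no related matings
  ped <- pedigree(c("a", "b", "c", "d", "x", "y", "z"),
                  sire = c(NA, NA, NA, NA, "a", "a", "c"),
                  dam = c(NA, NA, NA, NA, "b", "d", "d"))
  par <- trans_par(0.5, 0.5, 1, 1, r = 0)
  expect_lt(max(abs(build_ME_dense(ped, par) - oracle_A(ped))), 1e-12)
})

test_that("r = 0 nesting: environment structures collapse to the classical ones", {
  set.seed(42)
  ped <- random_toy_pedigree(n = 25, n_blocks = 2)
  p0 <- trans_par(0.35, 0.3, 2, 3, r = 0)
  expect_equal(as.matrix(build_ME_inverse(ped, p0)),
               as.matrix(crossprod(build_L(ped, 0.35, 0.3),
                                   Matrix::Diagonal(x = 1 / transenv:::ped_delta(ped, 0.35, 0.3)) %*%
                                     build_L(ped, 0.35, 0.3))),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("founders-only pedigree gives the identity", {
  ped <- pedigree(paste0("f", 1:4))
  par <- trans_par(0.4, 0.25, 5, 10, r = 0)
  expect_equal(as.matrix(build_ME_inverse(ped, par)), diag(4),
               ignore_attr = TRUE)
})

test_that("the sampling-variance decomposition conserves diag(D_E) and, absent
           co-environed matings, diag(M_E)", {
  # D_E always keeps delta_i on its diagonal whatever r
  set.seed(7)
  ped <- random_toy_pedigree(n = 30, n_blocks = 2)
  par <- random_feasible_par()
  de <- build_DE(ped, par)
  expect_equal(de$D_diag,
               transenv:::ped_delta(ped, par$omega_s, par$omega_d))
  # diag(M_E) = diag(M) for animals with no pair of co-environed ancestors:
  # a design where block members never mate
  n_mem <- 4
  ids <- c("s", "d", paste0("k", 1:n_mem), "m1", "m2", "g1", "g2")
  ped2 <- pedigree(ids,
                   sire = c(NA, NA, rep("s", n_mem), NA, NA, "k1", "k2"),
                   dam = c(NA, NA, rep("d", n_mem), NA, NA, "m1", "m2"),
                   env = c(NA, NA, rep("blk", n_mem), rep(NA, 4)))
  parE <- trans_par(0.4, 0.25, 5, 10, r = 0.5)
  par0 <- trans_par(0.4, 0.25, 5, 10, r = 0)
  expect_equal(diag(build_ME_dense(ped2, parE)), diag(build_ME_dense(ped2, par0)),
               tolerance = 1e-12)
})
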