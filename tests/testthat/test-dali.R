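test_that("CA distance matrices are Euclidean, symmetric, zero-diagonal", {
  m <- build_toy_domain(small_blueprint(), seed = 1)
  dm <- ca_distance_matrix(m)
  expect_equal(dm[1, 2], ca_step_lengths(m)[1], tolerance = 1e-9)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))

  s <- build_ideal_sse("strand", 5)
  dm_s <- as.matrix(dist(s))
  # generator geometry: 3.35 A advance per residue along the strand axis
  expect_equal(dm_s[1, 5], sqrt((4 * 3.35)^2 + 0^2), tolerance = 1e-6)

  tiny <- build_random_coil(2, seed = 1)
  expect_error(ca_distance_matrix(tiny), "at least 3")
})

test_that("the elastic score matches hand-evaluated cases", {
  dm <- matrix(c(0, 10, 10, 0), 2)
  expect_equal(elastic_score(dm, dm, matrix(integer(0), ncol = 2)), 0)
  expect_equal(elastic_score(dm, dm, cbind(1L, 1L)), 0.20)
  # two identical 2-residue structures 10 A apart:
  # S = 2*0.20 + 2*0.20*exp(-0.25)
  expect_equal(elastic_score(dm, dm, cbind(1:2, 1:2)),
               2 * 0.2 + 2 * 0.2 * exp(-0.25), tolerance = 1e-9)

  expect_error(elastic_score(dm, dm, cbind(c(2L, 1L), c(1L, 2L))),
               "strictly increasing")
  expect_error(elastic_score(dm, dm, cbind(1L, 3L)), "out of range")
})

test_that("Z calibration reproduces plug-in values of the length polynomial", {
  # m(100) = 7.95 + 71 - 2.59 - 1.92 = 74.44
  expect_equal(calibrated_z(74.44, 100, 100), 0, tolerance = 1e-9)
  expect_equal(calibrated_z(111.66, 100, 100), 1, tolerance = 1e-9)
  # monotone in S at fixed lengths
  s <- seq(10, 200, by = 10)
  z <- vapply(s, calibrated_z, numeric(1), len_a = 80, len_b = 120)
  expect_true(all(diff(z) > 0))
  # continuous at the L = 400 polynomial boundary
  expect_equal(calibrated_z(100, 400, 400), calibrated_z(100, 400.001, 400.001),
               tolerance = 1e-4)
})

test_that("self-alignment short-circuits to the identity with closed-form score", {
  m <- build_toy_domain(toy_blueprint(), seed = 2)
  res <- align_structures(m, m)
  expect_equal(res$n_aligned, n_residues(m))
  expect_equal(res$pairing[, 1], res$pairing[, 2])
  expect_equal(res$z_score, dali_self_z(m), tolerance = 1e-9)
  expect_true(res$significant)
})

test_that("identity self-score bounds 1000 random sequential pairings", {
  m <- build_toy_domain(small_blueprint(), seed = 3)
  dm <- ca_distance_matrix(m)
  n <- n_residues(m)
  s_self <- dali_self_score(m)
  set.seed(40)
  for (k in 1:1000) {
    len <- sample(2:(n - 1), 1)
    pairing <- cbind(sort(sample.int(n, len)), sort(sample.int(n, len)))
    expect_lte(elastic_score(dm, dm, pairing), s_self + 1e-9)
  }
})

test_that("mildly perturbed structures align back onto themselves", {
  m <- build_toy_domain(toy_blueprint(), seed = 4)
  p <- perturb_structure(m, 0.3, seed = 21)
  res <- align_structures(m, p, seed = 1)
  identity_frac <- mean(res$pairing[, 1] == res$pairing[, 2])
  expect_gte(identity_frac, 0.95)
  expect_true(res$significant)
})

test_that("unrelated random coil scores below the significance threshold", {
  m <- build_toy_domain(toy_blueprint(), seed = 4)
  coil <- build_random_coil(n_residues(m), seed = 77)
  res <- align_structures(m, coil, seed = 1)
  expect_lt(res$z_score, 2.0)
  expect_false(res$significant)
})

test_that("alignment search is deterministic given its seed", {
  m <- build_toy_domain(small_blueprint(), seed = 4)
  p <- perturb_structure(m, 1.0, seed = 31)
  r1 <- align_structures(m, p, seed = 5)
  r2 <- align_structures(m, p, seed = 5)
  expect_identical(r1$pairing, r2$pairing)
  expect_identical(r1$elastic_score, r2$elastic_score)
})

test_that("Z decreases with increasing structural divergence", {
  m <- build_toy_domain(toy_blueprint(), seed = 4)
  sigmas <- c(0.2, 0.5, 1, 2, 4)
  z <- vapply(seq_along(sigmas), function(i) {
    align_structures(m, perturb_structure(m, sigmas[i], seed = 50 + i),
                     seed = 2)$z_score
  }, numeric(1))
  expect_lt(cor(sigmas, z, method = "spearman"), 0)
})

test_that("all-against-all matrices are symmetric with maximal diagonals", {
  m <- build_toy_domain(small_blueprint(), seed = 5)
  twin <- m; twin$id <- "twin"
  coil <- build_random_coil(n_residues(m), seed = 88)
  sm <- all_against_all(list(a = m, b = twin, c = coil), seed = 3)

  expect_equal(sm$z, t(sm$z))
  # the identical pair carries the largest off-diagonal Z
  off <- sm$z; diag(off) <- -Inf
  expect_equal(which(off == max(off), arr.ind = TRUE)[1, ], c(row = 2, col = 1),
               ignore_attr = TRUE)
  expect_true(sm$mask["a", "b"])
  expect_false(sm$mask["a", "c"])
  expect_equal(sm$z["a", "c"], 0)            # dash convention
  # self-similarity dominates each row (ties possible for exact twins)
  for (i in 1:3) expect_gte(sm$z[i, i], max(sm$z[i, ]) - 1e-9)

  expect_error(all_against_all(list(a = m, a = twin)), "duplicate")
})
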