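test_that("ideal helix geometry has CA-like bond lengths", {
  h <- build_ideal_sse("helix", 10)
  steps <- sqrt(rowSums((h[-1, ] - h[-10, ])^2))
  expect_true(all(steps >= 3.7 & steps <= 3.9))
  expect_error(build_ideal_sse("helix", 1), "at least 2")
})

test_that("ideal strand is extended", {
  s <- build_ideal_sse("strand", 5)
  # oracle: the zig-zag advances 3.35 A per residue along its axis, so the
  # end-to-end distance of 5 residues is at least 4 * 3.35 = 13.4 A
  expect_gt(sqrt(sum((s[5, ] - s[1, ])^2)), 13)
  steps <- sqrt(rowSums((s[-1, ] - s[-5, ])^2))
  expect_equal(steps, rep(3.8, 4), tolerance = 1e-9)
})

test_that("toy domains are deterministic, clash-free and chain-plausible", {
  bp <- toy_blueprint()
  m1 <- build_toy_domain(bp, seed = 5)
  m2 <- build_toy_domain(bp, seed = 5)
  expect_identical(ca_coords(m1), ca_coords(m2))
  expect_gte(n_residues(m1), sum(bp$elements$length))

  # all non-bonded pairs separated
  dm <- as.matrix(dist(ca_coords(m1)))
  nb <- abs(row(dm) - col(dm)) >= 2
  expect_gte(min(dm[nb]), 1.5)

  # chain plausibility invariant, across several seeds
  for (s in 1:5) {
    steps <- ca_step_lengths(build_toy_domain(bp, seed = s))
    expect_true(all(steps >= 2.8 & steps <= 4.2))
  }
})

test_that("only coil placement depends on the seed", {
  bp <- toy_blueprint()
  m1 <- build_toy_domain(bp, seed = 1)
  m2 <- build_toy_domain(bp, seed = 2)
  sse_res <- m1$residues$residue_name != "GLY"   # SSE residues are ALA
  expect_identical(ca_coords(m1)[sse_res, ], ca_coords(m2)[sse_res, ])
  expect_gt(max(abs(ca_coords(m1)[!sse_res, ] - ca_coords(m2)[!sse_res, ])), 0)
})

test_that("SSE and coil confidences straddle the segmentation thresholds", {
  m <- build_toy_domain(toy_blueprint(), seed = 1)
  conf <- m$residues$confidence
  coil <- m$residues$residue_name == "GLY"
  expect_true(all(conf[coil] == 60))
  expect_true(all(conf[!coil] == 92))
})

test_that("clashing packing offsets are rejected", {
  bp <- domain_blueprint(
    data.frame(kind = c("helix", "helix"), length = c(10, 10)),
    rbind(c(0, 0, 0), c(0.5, 0.5, 0)), name = "clash"
  )
  expect_error(build_toy_domain(bp, seed = 1), "too close|clash")
})

test_that("coordinate perturbation matches the Gaussian displacement law", {
  m <- build_random_coil(100, seed = 3)
  expect_identical(ca_coords(perturb_structure(m, 0, seed = 1)), ca_coords(m))
  p <- perturb_structure(m, 0.5, seed = 7)
  rmsd <- sqrt(mean(rowSums((ca_coords(m) - ca_coords(p))^2)))
  # E[RMSD] = sigma * sqrt(3) = 0.866 A
  expect_equal(rmsd, 0.5 * sqrt(3), tolerance = 0.15)

  p2 <- perturb_structure(m, 0.5, seed = 8)
  expect_gt(max(abs(ca_coords(p) - ca_coords(p2))), 0)
  expect_identical(p$residues$seq_number, p2$residues$seq_number)
  expect_error(perturb_structure(m, -1, seed = 1), "non-negative")
})

test_that("planted families carry correct bookkeeping and ground truth", {
  fam <- make_planted_family(small_blueprint(), c(3, 3, 3),
                             within_sigma = 0.3, between_sigma = 3, seed = 2)
  expect_length(fam$members, 9L)
  expect_equal(unname(table(fam$true_labels)), c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_setequal(names(fam$members), names(fam$true_labels))

  expect_error(make_planted_family(small_blueprint(), c(2),
                                   within_sigma = 0.3, between_sigma = 3),
               "at least 2 groups")
  expect_error(make_planted_family(small_blueprint(), c(2, 2),
                                   within_sigma = 1, between_sigma = 0.5),
               "between_sigma > within_sigma")
})

test_that("optional linkers add low-confidence coil at both ends", {
  fam <- make_planted_family(small_blueprint(), c(2, 2), seed = 4,
                             add_linkers = TRUE)
  m <- fam$members[[1]]
  conf <- m$residues$confidence
  expect_true(all(conf[1:20] == 45))
  expect_true(all(conf[(length(conf) - 19):length(conf)] == 45))
  # the linkers themselves (and their junctions to the domain) are
  # chain-plausible; the diverged domain interior is not constrained here
  steps <- ca_step_lengths(m)
  link_steps <- c(steps[1:20], steps[(length(steps) - 19):length(steps)])
  expect_true(all(link_steps >= 2.8 & link_steps <= 4.2))
})

test_that("generators are pure functions of their seeds", {
  f1 <- make_planted_family(small_blueprint(), c(2, 2), seed = 9)
  f2 <- make_planted_family(small_blueprint(), c(2, 2), seed = 9)
  expect_identical(lapply(f1$members, ca_coords), lapply(f2$members, ca_coords))
  c1 <- build_random_coil(30, seed = 5)
  c2 <- build_random_coil(30, seed = 5)
  expect_identical(ca_coords(c1), ca_coords(c2))
})
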