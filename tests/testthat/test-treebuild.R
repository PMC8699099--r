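strip_comments <- function(nwk) gsub("\\[[^]]*\\]", "", nwk)

test_that("the packaged family Z table parses to the printed values", {
  sm <- kctd_similarity()
  expect_length(sm$labels, 25L)
  expect_equal(sm$z["K7", "K14"], 13.4)
  expect_equal(sm$z["SHK", "K21"], 2.7)
  expect_equal(sm$z["K21", "SHK"], 2.7)
  expect_equal(sm$z["K1", "K1"], 23.3)
  # dash cells: zero and unmasked, symmetric
  expect_equal(sm$z["K9", "K1"], 0)
  expect_false(sm$mask["K9", "K1"])
  expect_equal(sm$z, t(sm$z))
  expect_true(all(diag(sm$z) > 0))
})

test_that("malformed similarity tables produce addressed parse errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tA\tB", "A\t10\tx", "B\t\t9"), f)
  expect_error(parse_similarity_table(f), "row A, column B")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tA\tB", "A\t10\t3", "C\t\t9"), f2)
  expect_error(parse_similarity_table(f2), "labels")
})

test_that("similarity TSV writing round-trips through the parser", {
  sm <- kctd_similarity()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_table(sm, f)
  back <- parse_similarity_table(f)
  expect_equal(back$z, sm$z, tolerance = 1e-9)
  expect_equal(back$mask, sm$mask)
})

test_that("average linkage on similarity merges in hand-computed order", {
  z <- matrix(c(20, 10, 2, 10, 20, 2, 2, 2, 20), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- average_linkage_tree(similarity_matrix(c("A", "B", "C"), z))
  expect_equal(tree$height, c(10, 2))
  expect_equal(tree$merge[1, ], c(-2, -1))      # A and B first
  expect_true(all(diff(tree$height) <= 1e-12))  # non-increasing
})

test_that("merge heights agree with hclust average linkage on distances", {
  # independent oracle: UPGMA on D = C - Z has the same merge structure
  sm <- kctd_similarity()
  tree <- average_linkage_tree(sm)
  cmax <- max(sm$z)
  hc <- stats::hclust(stats::as.dist(cmax - sm$z), method = "average")
  expect_equal(tree$height, cmax - hc$height, tolerance = 1e-9)
})

test_that("ties are broken lexicographically for reproducibility", {
  z <- matrix(0, 4, 4, dimnames = list(c("D", "C", "B", "A"),
                                       c("D", "C", "B", "A")))
  diag(z) <- 10
  z["D", "C"] <- z["C", "D"] <- 5
  z["B", "A"] <- z["A", "B"] <- 5
  tree <- average_linkage_tree(similarity_matrix(rownames(z), z))
  # the A/B pair has the lexicographically smaller representative
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(first, c("A", "B"))
})

test_that("Newick export is ultrametric and round-trips through ape", {
  z <- matrix(c(20, 10, 10, 20), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- average_linkage_tree(similarity_matrix(c("A", "B"), z))
  nwk <- tree_to_newick(tree)
  expect_equal(strip_comments(nwk), "(B:5,A:5);")
  expect_match(nwk, "\\[&Z=10\\]")

  sm <- kctd_similarity()
  big <- average_linkage_tree(sm)
  nwk_big <- tree_to_newick(big)
  ph <- ape::read.tree(text = strip_comments(nwk_big))
  expect_length(ph$tip.label, 25L)
  expect_setequal(ph$tip.label, sm$labels)
  expect_true(all(ph$edge.length >= -1e-9))
  # round trip preserves topology and branch lengths
  ph2 <- ape::read.tree(text = ape::write.tree(ph))
  expect_true(ape::all.equal.phylo(ph, ph2, use.edge.length = TRUE,
                                   tolerance = 1e-9))
  # leaves are all at the same depth (ultrametric construction, up to the
  # formatted branch-length precision)
  depths <- ape::node.depth.edgelength(ph)[seq_len(25)]
  expect_lt(diff(range(depths)), 1e-3)
})

test_that("labels with reserved characters are quoted in Newick", {
  z <- matrix(c(20, 10, 10, 20), 2,
              dimnames = list(c("A(1)", "B;x"), c("A(1)", "B;x")))
  tree <- average_linkage_tree(similarity_matrix(rownames(z), z))
  nwk <- tree_to_newick(tree, comments = FALSE)
  expect_match(nwk, "'A\\(1\\)'", fixed = FALSE)
  ph <- ape::read.tree(text = nwk)
  # ape keeps the protective quotes; the label text must survive inside them
  expect_setequal(gsub("'", "", ph$tip.label), c("A(1)", "B;x"))
})

test_that("tree cutting by level and by k give consistent partitions", {
  sm <- kctd_similarity()
  tree <- average_linkage_tree(sm)

  cl15 <- cut_tree(tree, level = 15)
  expect_equal(cl15[["K3"]], cl15[["SHK"]])
  expect_equal(sum(cl15 == cl15[["K3"]]), 2L)     # K3+SHK isolated
  expect_equal(sum(cl15 == cl15[["K9"]]), 1L)     # K9 singleton

  # level above the first merge: everything is a singleton
  all_single <- cut_tree(tree, level = tree$height[1] + 1)
  expect_equal(length(unique(all_single)), 25L)

  # k-cut equals the corresponding level cut
  k7 <- cut_tree(tree, k = 7)
  expect_equal(length(unique(k7)), 7L)
  expect_error(cut_tree(tree, k = 0), "between 1 and")
  expect_error(cut_tree(tree), "exactly one")
})

test_that("unachievable k due to ties errors with achievable counts", {
  z <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(z) <- 10
  z["A", "B"] <- z["B", "A"] <- 5
  z["C", "D"] <- z["D", "C"] <- 5
  tree <- average_linkage_tree(similarity_matrix(rownames(z), z))
  expect_error(cut_tree(tree, k = 3), "achievable")
  expect_equal(length(unique(cut_tree(tree, k = 2))), 2L)
})

test_that("UPGMA exactly recovers random ultrametric similarity structures", {
  for (trial in 1:100) {
    n <- 4 + (trial %% 9)
    sim <- random_ultrametric_similarity(n, seed = 3000 + trial)
    tree <- average_linkage_tree(similarity_matrix(rownames(sim), sim))
    coph <- cophenetic_similarity(tree)
    off <- upper.tri(sim)
    expect_equal(coph[off], sim[off], tolerance = 1e-9)
  }
})

test_that("correspondence analysis separates exchangeable blocks", {
  n <- 6
  z <- matrix(2, n, n)
  z[1:3, 1:3] <- 8
  z[4:6, 4:6] <- 8
  diag(z) <- 10
  labels <- paste0("s", 1:n)
  dimnames(z) <- list(labels, labels)
  emb <- correspondence_embedding(similarity_matrix(labels, z))
  ax1 <- emb$coords[, 1]
  expect_true(all(sign(ax1[1:3]) == sign(ax1[1])))
  expect_true(all(sign(ax1[4:6]) == -sign(ax1[1])))
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
})

test_that("embedding is equivariant under label permutation", {
  sm <- kctd_similarity()
  emb <- correspondence_embedding(sm)
  set.seed(4)
  perm <- sample(length(sm$labels))
  sm_p <- similarity_matrix(sm$labels[perm], sm$z[perm, perm],
                            sm$mask[perm, perm])
  emb_p <- correspondence_embedding(sm_p)
  # coordinates are identical up to per-axis sign
  for (ax in 1:2) {
    direct <- emb$coords[sm$labels[perm], ax]
    expect_true(isTRUE(all.equal(direct, emb_p$coords[, ax], tolerance = 1e-8)) ||
                isTRUE(all.equal(direct, -emb_p$coords[, ax], tolerance = 1e-8)))
  }
})

test_that("embedding axes are orthogonal in the chi-square metric", {
  sm <- kctd_similarity()
  emb <- correspondence_embedding(sm)
  r <- rowSums(sm$z) / sum(sm$z)
  expect_lt(abs(sum(r * emb$coords[, 1] * emb$coords[, 2])), 1e-8)
})

test_that("embedding agrees with an independent correspondence analysis", {
  sm <- kctd_similarity()
  emb <- correspondence_embedding(sm)
  # MASS::corresp returns standard row scores; scale by the canonical
  # correlations to obtain principal coordinates (warning about non-integer
  # input is expected: the table holds Z-scores, not counts)
  ca <- suppressWarnings(MASS::corresp(sm$z, nf = 2))
  principal <- sweep(ca$rscore, 2, ca$cor, "*")[sm$labels, ]
  for (ax in 1:2) {
    s <- sign(sum(emb$coords[, ax] * principal[, ax]))
    expect_equal(emb$coords[, ax], s * principal[, ax], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # the beta-propeller pair is mutually closest in the plane among all pairs
  # involving either structure
  d <- as.matrix(dist(emb$coords))
  diag(d) <- Inf
  expect_equal(rownames(d)[which.min(d["K3", ])], "SHK")
  expect_equal(rownames(d)[which.min(d["SHK", ])], "K3")
})
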