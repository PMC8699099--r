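# shared toy blueprints and independent test oracles

toy_blueprint <- function(name = "toy") {
  domain_blueprint(
    data.frame(kind = c("strand", "helix", "helix"), length = c(8, 12, 12)),
    rbind(c(0, 0, 0), c(28, 0, 0), c(52, 9, 0)),
    name = name
  )
}

small_blueprint <- function(name = "small") {
  domain_blueprint(
    data.frame(kind = c("strand", "helix"), length = c(6, 10)),
    rbind(c(0, 0, 0), c(24, 0, 0)),
    name = name
  )
}

# brute-force rigid superposition: random rotation restarts + Nelder-Mead
# refinement over Euler angles; independent of the SVD route under test
oracle_superpose_rmsd <- function(a, b, n_restarts = 60) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  rot_from_angles <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    rz %*% ry %*% rx
  }
  obj <- function(ang) {
    sqrt(mean(rowSums((a0 - b0 %*% t(rot_from_angles(ang)))^2)))
  }
  best <- Inf
  for (r in seq_len(n_restarts)) {
    start <- stats::runif(3, -pi, pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    if (fit$value < best) best <- fit$value
  }
  best
}

# adjusted Rand index between two partitions
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum_comb(as.vector(tab))
  b1 <- sum_comb(rowSums(tab))
  b2 <- sum_comb(colSums(tab))
  expected <- b1 * b2 / choose(n, 2)
  maxi <- (b1 + b2) / 2
  (a - expected) / (maxi - expected)
}

# cophenetic similarity matrix of a structure_dendrogram: the merge
# similarity of the lowest common ancestor of each leaf pair
cophenetic_similarity <- function(tree) {
  n <- length(tree$labels)
  coph <- matrix(NA_real_, n, n, dimnames = list(tree$labels, tree$labels))
  leaves <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    kids <- tree$merge[s, ]
    sides <- lapply(kids, function(k) if (k < 0L) -k else leaves[[k]])
    for (i in sides[[1]]) for (j in sides[[2]]) {
      coph[i, j] <- coph[j, i] <- tree$height[s]
    }
    leaves[[s]] <- unlist(sides)
  }
  coph
}

# random ultrametric similarity matrix with its generating merge heights
random_ultrametric_similarity <- function(n, seed) {
  set.seed(seed)
  heights <- sort(stats::runif(n - 1, 1, 20), decreasing = TRUE)
  labels <- sprintf("L%02d", seq_len(n))
  clusters <- as.list(seq_len(n))
  sim <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (s in seq_len(n - 1)) {
    pick <- sample.int(length(clusters), 2L)
    for (i in clusters[[pick[1]]]) for (j in clusters[[pick[2]]]) {
      sim[i, j] <- sim[j, i] <- heights[s]
    }
    clusters[[pick[1]]] <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters[[pick[2]]] <- NULL
  }
  diag(sim) <- max(heights) + 1
  sim
}

# local cache searched by the accession-based checks; these files are the
# published AlphaFold/PDB coordinate files, which must be fetched beforehand
# (e.g. with the CLI --fetch step) -- the package itself never downloads
find_cached_structure <- function(filename) {
  dirs <- c(file.path(tools::R_user_dir("domalign", "cache"), "structures"),
            system.file("extdata", "structures", package = "domalign"))
  for (d in dirs) {
    p <- file.path(d, filename)
    if (nzchar(d) && file.exists(p)) return(p)
  }
  NA_character_
}
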