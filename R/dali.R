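#' @title Elastic (distance-matrix) structural alignment
#' @description The computational core of the package: alignment of two CA
#'   domains by comparison of their intramolecular distance matrices, scored
#'   with the elastic similarity function of the Dali method and calibrated
#'   into a length-normalized Z-score. The search combines fragment and
#'   SSE-based seeding, iterative dynamic-programming extension, and
#'   simulated-annealing refinement of aligned blocks.
#' @name dali_align
NULL

# elastic-score constants of the published distance-matrix method:
# similarity threshold theta_E, Gaussian envelope width alpha (Angstrom),
# and the contribution of each diagonal (i = j) term.
DALI_THETA <- 0.20
DALI_ALPHA <- 20

#' Alignment search parameters
#'
#' @param n_seeds Number of top-ranked alignment seeds refined by dynamic
#'   programming.
#' @param anneal_steps Simulated-annealing refinement steps.
#' @param t_start,t_end Start/end temperature of the geometric cooling
#'   schedule (elastic-score units).
#' @param dp_rounds Rounds of compatibility-matrix dynamic programming per
#'   seed.
#' @param frag_len Fragment length for distance-submatrix seeding.
#' @param significance_z Z-score at or above which an alignment is called
#'   significant (the "dash" convention threshold).
#' @return A list of class `dali_params`.
#' @export
dali_params <- function(n_seeds = 20L, anneal_steps = 2000L, t_start = 2,
                        t_end = 0.05, dp_rounds = 3L, frag_len = 6L,
                        significance_z = 2.0) {
  structure(list(n_seeds = as.integer(n_seeds),
                 anneal_steps = as.integer(anneal_steps),
                 t_start = t_start, t_end = t_end,
                 dp_rounds = as.integer(dp_rounds),
                 frag_len = as.integer(frag_len),
                 significance_z = significance_z),
            class = "dali_params")
}

#' CA-CA distance matrix of a model
#'
#' @param model A [structure_model] with at least 3 residues.
#' @return Symmetric numeric matrix of Euclidean CA-CA distances (Angstrom),
#'   zero diagonal.
#' @export
ca_distance_matrix <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  if (n_residues(model) < 3L) stop("distance matrix needs at least 3 residues")
  as.matrix(stats::dist(ca_coords(model)))
}

validate_pairing <- function(pairing, n_a, n_b) {
  pairing <- matrix(as.integer(pairing), ncol = 2L)
  m <- nrow(pairing)
  if (m == 0L) return(pairing)
  if (any(pairing[, 1] < 1L) || any(pairing[, 1] > n_a) ||
      any(pairing[, 2] < 1L) || any(pairing[, 2] > n_b)) {
    stop("pairing indices out of range")
  }
  if (m > 1L) {
    if (any(diff(pairing[, 1]) <= 0L) || any(diff(pairing[, 2]) <= 0L)) {
      stop("pairing must be strictly increasing in both coordinates")
    }
  }
  pairing
}

#' Elastic similarity score of an alignment
#'
#' For aligned positions i, j (residue pairs (a_i, b_i), (a_j, b_j)) with
#' intramolecular distances dA = d(a_i, a_j), dB = d(b_i, b_j) and their mean
#' d* = (dA + dB)/2, every ordered pair i != j contributes
#' `(theta - |dA - dB| / d*) * exp(-(d*/alpha)^2)` with theta = 0.20 and
#' alpha = 20 Angstrom, and every diagonal term i = j contributes theta.
#' Identical substructures therefore score positively; distance
#' disagreements beyond the 20% tolerance are penalized, with long-range
#' pairs down-weighted by the Gaussian envelope.
#'
#' @param dm_a,dm_b Distance matrices from [ca_distance_matrix].
#' @param pairing m x 2 integer matrix, strictly increasing in both columns.
#' @return The elastic score S (dimensionless).
#' @export
elastic_score <- function(dm_a, dm_b, pairing) {
  pairing <- validate_pairing(pairing, nrow(dm_a), nrow(dm_b))
  m <- nrow(pairing)
  if (m == 0L) return(0)
  a <- dm_a[pairing[, 1], pairing[, 1], drop = FALSE]
  b <- dm_b[pairing[, 2], pairing[, 2], drop = FALSE]
  dstar <- (a + b) / 2
  term <- (DALI_THETA - abs(a - b) / dstar) * exp(-(dstar / DALI_ALPHA)^2)
  term[!is.finite(term)] <- DALI_THETA  # dA = dB = 0 limit
  diag(term) <- DALI_THETA
  sum(term)
}

# mean elastic self-score of an unrelated pair of structures of average
# length L: the published calibration polynomial, continued linearly beyond
# L = 400 with its slope at 400
dali_mean_score <- function(L) {
  poly <- function(x) 7.95 + 0.71 * x - 2.59e-4 * x^2 - 1.92e-6 * x^3
  slope400 <- 0.71 - 2 * 2.59e-4 * 400 - 3 * 1.92e-6 * 400^2
  ifelse(L <= 400, poly(L), poly(400) + slope400 * (L - 400))
}

#' Length-calibrated Z-score of an elastic score
#'
#' `Z = (S - m(L)) / (0.50 * m(L))` with `L = sqrt(len_a * len_b)` and
#' `m(L) = 7.95 + 0.71 L - 2.59e-4 L^2 - 1.92e-6 L^3` for `L <= 400`,
#' continued linearly beyond 400 with the slope at 400.
#'
#' @param score Elastic score S.
#' @param len_a,len_b Lengths (residues) of the two structures.
#' @return The Z-score.
#' @export
calibrated_z <- function(score, len_a, len_b) {
  if (len_a < 1L || len_b < 1L) stop("lengths must be >= 1")
  m <- dali_mean_score(sqrt(as.numeric(len_a) * as.numeric(len_b)))
  (score - m) / (0.50 * m)
}

#' Closed-form self-alignment score and Z
#'
#' The elastic score of the identity self-alignment needs no search:
#' `S = 0.2 n + 0.2 * sum_offdiag exp(-(d/20)^2)`.
#'
#' @param model A [structure_model] (or a distance matrix).
#' @return `dali_self_score`: the elastic score; `dali_self_z`: its
#'   calibrated Z.
#' @export
dali_self_score <- function(model) {
  dm <- if (is.matrix(model)) model else ca_distance_matrix(model)
  n <- nrow(dm)
  env <- DALI_THETA * exp(-(dm / DALI_ALPHA)^2)
  diag(env) <- DALI_THETA
  sum(env)
}

#' @rdname dali_self_score
#' @export
dali_self_z <- function(model) {
  dm <- if (is.matrix(model)) model else ca_distance_matrix(model)
  calibrated_z(dali_self_score(dm), nrow(dm), nrow(dm))
}

# ---- alignment search internals ------------------------------------------

# rank fragment seed positions by similarity of frag_len x frag_len distance
# submatrices; returns data.frame(i, j, diff) ascending in diff
fragment_seed_scores <- function(dm_a, dm_b, frag_len) {
  na <- nrow(dm_a) - frag_len + 1L
  nb <- nrow(dm_b) - frag_len + 1L
  acc <- matrix(0, na, nb)
  cnt <- 0L
  for (k in 0:(frag_len - 2L)) {
    for (l in (k + 1L):(frag_len - 1L)) {
      va <- dm_a[cbind(seq_len(na) + k, seq_len(na) + l)]
      vb <- dm_b[cbind(seq_len(nb) + k, seq_len(nb) + l)]
      acc <- acc + abs(outer(va, vb, "-"))
      cnt <- cnt + 1L
    }
  }
  ord <- order(acc)
  data.frame(i = row(acc)[ord], j = col(acc)[ord], diff = acc[ord] / cnt)
}

# seeds from matched secondary-structure segments of the same type
sse_seeds <- function(model_a, model_b, frag_len) {
  seg <- function(model) {
    s <- assign_secondary_structure(model)
    r <- rle(s)
    ends <- cumsum(r$lengths)
    data.frame(type = r$values, start = ends - r$lengths + 1L, len = r$lengths)
  }
  sa <- seg(model_a); sb <- seg(model_b)
  sa <- sa[sa$type %in% c("H", "E") & sa$len >= frag_len, , drop = FALSE]
  sb <- sb[sb$type %in% c("H", "E") & sb$len >= frag_len, , drop = FALSE]
  out <- list()
  for (p in seq_len(nrow(sa))) for (q in seq_len(nrow(sb))) {
    if (sa$type[p] != sb$type[q]) next
    out[[length(out) + 1L]] <- c(i = sa$start[p], j = sb$start[q])
  }
  out
}

# incremental compatibility of every candidate pair (a, b) with the current
# alignment (ia, ib): the elastic-score change from adding the pair
compat_matrix <- function(dm_a, dm_b, ia, ib) {
  na <- nrow(dm_a); nb <- nrow(dm_b)
  c_mat <- matrix(DALI_THETA, na, nb)
  for (k in seq_along(ia)) {
    da <- dm_a[, ia[k]]
    db <- dm_b[, ib[k]]
    dstar <- outer(da, db, "+") / 2
    term <- (DALI_THETA - abs(outer(da, db, "-")) / dstar) *
      exp(-(dstar / DALI_ALPHA)^2)
    term[!is.finite(term)] <- 0
    c_mat <- c_mat + 2 * term
  }
  c_mat
}

# monotone matching maximizing the summed compatibility; skips are free so
# negatively compatible pairs are left unaligned
dp_match <- function(c_mat) {
  na <- nrow(c_mat); nb <- ncol(c_mat)
  f <- matrix(0, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    fi <- f[i, ]
    fi1 <- f[i + 1L, ]
    for (j in seq_len(nb)) {
      best <- fi[j] + c_mat[i, j]
      if (fi[j + 1L] > best) best <- fi[j + 1L]
      if (fi1[j] > best) best <- fi1[j]
      fi1[j + 1L] <- best
    }
    f[i + 1L, ] <- fi1
  }
  # traceback
  ia <- integer(0); ib <- integer(0)
  i <- na; j <- nb
  while (i > 0L && j > 0L) {
    if (f[i + 1L, j + 1L] == f[i, j] + c_mat[i, j] && c_mat[i, j] > 0) {
      ia <- c(i, ia); ib <- c(j, ib)
      i <- i - 1L; j <- j - 1L
    } else if (f[i + 1L, j + 1L] == f[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  cbind(ia, ib, deparse.level = 0)
}

# contiguous aligned blocks (runs where both indices advance by one)
pairing_blocks <- function(pairing) {
  m <- nrow(pairing)
  if (m == 0L) return(integer(0))
  new_block <- c(TRUE, diff(pairing[, 1]) != 1L | diff(pairing[, 2]) != 1L)
  cumsum(new_block)
}

anneal_refine <- function(dm_a, dm_b, pairing, params, seed) {
  na <- nrow(dm_a); nb <- nrow(dm_b)
  s_cur <- elastic_score(dm_a, dm_b, pairing)
  best <- list(pairing = pairing, score = s_cur)
  steps <- params$anneal_steps
  if (steps < 1L) return(best)
  cool <- (params$t_end / params$t_start)^(1 / max(1L, steps - 1L))
  with_seed(seed, {
    temp <- params$t_start
    for (step in seq_len(steps)) {
      prop <- propose_move(pairing, na, nb)
      if (!is.null(prop)) {
        s_new <- elastic_score(dm_a, dm_b, prop)
        if (s_new >= s_cur || stats::runif(1) < exp((s_new - s_cur) / temp)) {
          pairing <- prop
          s_cur <- s_new
          if (s_cur > best$score) best <- list(pairing = pairing, score = s_cur)
        }
      }
      temp <- temp * cool
    }
  })
  best
}

# shift / extend / trim moves on aligned blocks
propose_move <- function(pairing, na, nb) {
  m <- nrow(pairing)
  if (m < 4L) return(NULL)
  blocks <- pairing_blocks(pairing)
  nblk <- blocks[m]
  b <- sample.int(nblk, 1L)
  idx <- which(blocks == b)
  move <- sample(c("shift", "extend", "trim"), 1L, prob = c(0.4, 0.3, 0.3))
  p <- pairing
  if (move == "shift") {
    col <- sample(1:2, 1L)
    delta <- sample(c(-1L, 1L), 1L)
    p[idx, col] <- p[idx, col] + delta
    limit <- if (col == 1L) na else nb
    if (p[idx[1], col] < 1L || p[idx[length(idx)], col] > limit) return(NULL)
    if (any(diff(p[, col]) <= 0L)) return(NULL)
    return(p)
  }
  if (move == "extend") {
    at_start <- sample(c(TRUE, FALSE), 1L)
    if (at_start) {
      newp <- pairing[idx[1], ] - 1L
      if (any(newp < 1L)) return(NULL)
      pos <- idx[1] - 1L
      if (pos >= 1L && (pairing[pos, 1] >= newp[1] || pairing[pos, 2] >= newp[2])) {
        return(NULL)
      }
      return(rbind(p[seq_len(idx[1] - 1L), , drop = FALSE], newp,
                   p[idx[1]:m, , drop = FALSE], deparse.level = 0))
    }
    last <- idx[length(idx)]
    newp <- pairing[last, ] + 1L
    if (newp[1] > na || newp[2] > nb) return(NULL)
    if (last < m && (pairing[last + 1L, 1] <= newp[1] ||
                     pairing[last + 1L, 2] <= newp[2])) {
      return(NULL)
    }
    return(rbind(p[seq_len(last), , drop = FALSE], newp,
                 if (last < m) p[(last + 1L):m, , drop = FALSE],
                 deparse.level = 0))
  }
  # trim one end pair of the block
  if (m <= 4L) return(NULL)
  drop <- if (sample(c(TRUE, FALSE), 1L)) idx[1] else idx[length(idx)]
  p[-drop, , drop = FALSE]
}

make_alignment_result <- function(pairing, score, len_a, len_b, significance_z) {
  z <- calibrated_z(score, len_a, len_b)
  structure(list(pairing = pairing, elastic_score = score, z_score = z,
                 n_aligned = nrow(pairing), len_a = len_a, len_b = len_b,
                 significant = z >= significance_z),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> Z = %.2f (S = %.1f), %d pairs aligned (%d x %d)%s\n",
              x$z_score, x$elastic_score, x$n_aligned, x$len_a, x$len_b,
              if (x$significant) "" else " [not significant]"))
  invisible(x)
}

#' Align two structures by distance-matrix comparison
#'
#' Searches sequential (order-preserving) residue pairings maximizing the
#' [elastic_score]: candidate seeds are collected from similar contiguous
#' fragment pairs (distance-submatrix comparison) and from matched
#' secondary-structure elements; each seed is grown by iterated
#' dynamic programming on an incremental compatibility matrix; the best
#' alignment is then refined by simulated annealing over shift/extend/trim
#' moves of aligned blocks. The result never scores below the best raw seed.
#' Aligning a structure with itself (identical coordinates) short-circuits
#' to the identity pairing with the closed-form self-score.
#'
#' @param model_a,model_b [structure_model] objects, both >= 10 residues.
#' @param params Search settings, see [dali_params].
#' @param seed Integer seed making the search deterministic.
#' @return An `alignment_result`: `pairing` (m x 2), `elastic_score`,
#'   `z_score`, `n_aligned`, `len_a`, `len_b`, `significant`.
#' @export
align_structures <- function(model_a, model_b, params = dali_params(),
                             seed = 0L) {
  stopifnot(inherits(model_a, "structure_model"),
            inherits(model_b, "structure_model"))
  na <- n_residues(model_a); nb <- n_residues(model_b)
  if (na < 10L || nb < 10L) stop("alignment needs structures of >= 10 residues")

  xa <- ca_coords(model_a); xb <- ca_coords(model_b)
  if (na == nb && max(abs(xa - xb)) < 1e-9) {
    pairing <- cbind(seq_len(na), seq_len(na))
    s <- dali_self_score(model_a)
    return(make_alignment_result(pairing, s, na, nb, params$significance_z))
  }

  dm_a <- ca_distance_matrix(model_a)
  dm_b <- ca_distance_matrix(model_b)
  fl <- params$frag_len

  frag <- fragment_seed_scores(dm_a, dm_b, fl)
  seeds <- list()
  for (r in seq_len(min(nrow(frag), 10L * params$n_seeds))) {
    cand <- c(i = frag$i[r], j = frag$j[r])
    if (length(seeds) > 0L) {
      dists <- vapply(seeds, function(s) abs(s["i"] - cand["i"]) +
                        abs(s["j"] - cand["j"]), numeric(1))
      if (min(dists) < 4) next
    }
    seeds[[length(seeds) + 1L]] <- cand
    if (length(seeds) >= params$n_seeds) break
  }
  for (s in sse_seeds(model_a, model_b, fl)) {
    seeds[[length(seeds) + 1L]] <- s
  }

  best <- NULL
  seed_pairings <- lapply(seeds, function(s) {
    cbind(s[["i"]] + 0:(fl - 1L), s[["j"]] + 0:(fl - 1L))
  })
  seed_scores <- vapply(seed_pairings, function(p) elastic_score(dm_a, dm_b, p),
                        numeric(1))
  ord <- order(seed_scores, decreasing = TRUE)
  keep <- ord[seq_len(min(length(ord), params$n_seeds))]

  for (k in keep) {
    pairing <- seed_pairings[[k]]
    score <- seed_scores[k]
    for (round in seq_len(params$dp_rounds)) {
      cm <- compat_matrix(dm_a, dm_b, pairing[, 1], pairing[, 2])
      new_pairing <- dp_match(cm)
      if (nrow(new_pairing) < 3L) break
      new_score <- elastic_score(dm_a, dm_b, new_pairing)
      if (new_score <= score) break
      pairing <- new_pairing
      score <- new_score
    }
    if (is.null(best) || score > best$score) {
      best <- list(pairing = pairing, score = score)
    }
  }
  if (is.null(best)) {
    stop("no alignment seeds found (structures may lack regular structure)")
  }

  refined <- anneal_refine(dm_a, dm_b, best$pairing, params,
                           seed = derive_seed(seed, 97L))
  if (refined$score > best$score) best <- refined

  make_alignment_result(best$pairing, best$score, na, nb,
                        params$significance_z)
}

#' All-against-all structural comparison
#'
#' Aligns every unordered pair of models in both directions, records the
#' larger Z of the two (enforcing exact symmetry), puts the closed-form
#' self-alignment Z on the diagonal, and masks pairs below the significance
#' threshold, storing them as `Z = 0` (the "dash" convention of printed
#' similarity tables, which also keeps the matrix non-negative for
#' clustering and embedding).
#'
#' @param models Named list of [structure_model] objects (>= 2, unique
#'   labels).
#' @param params See [dali_params].
#' @param seed Integer seed; each pair derives its own sub-seed.
#' @return A [similarity_matrix].
#' @export
all_against_all <- function(models, params = dali_params(), seed = 0L) {
  labels <- names(models)
  if (is.null(labels)) labels <- vapply(models, `[[`, "", "id")
  if (anyDuplicated(labels)) stop("duplicate structure labels")
  n <- length(models)
  if (n < 2L) stop("need at least 2 models")

  z <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) z[i, i] <- dali_self_z(models[[i]])
  pair_id <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pair_id <- pair_id + 1L
      r1 <- align_structures(models[[i]], models[[j]], params,
                             seed = derive_seed(seed, 2L * pair_id))
      r2 <- align_structures(models[[j]], models[[i]], params,
                             seed = derive_seed(seed, 2L * pair_id + 1L))
      z[i, j] <- z[j, i] <- max(r1$z_score, r2$z_score)
    }
  }
  mask <- z >= params$significance_z
  diag(mask) <- TRUE
  z[!mask] <- 0       # the "dash" convention: no detected similarity -> 0
  similarity_matrix(labels, z, mask)
}
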