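#' @title Similarity matrices, dendrograms and embeddings
#' @description Turns a labelled Z-score similarity matrix into a structure
#'   dendrogram by unweighted average-linkage agglomeration performed
#'   directly on similarity (merging the pair of clusters with maximal
#'   average pairwise Z), exports Newick, cuts the tree into clusters, and
#'   computes a two-dimensional correspondence-analysis embedding.
#' @name treebuild
NULL

#' Construct a labelled similarity matrix
#'
#' @param labels Character vector of structure labels.
#' @param z Symmetric numeric matrix of Z-scores; the diagonal holds
#'   self-alignment Z values.
#' @param mask Logical matrix, `TRUE` where the similarity is significant;
#'   non-significant ("dash") cells carry `Z = 0` in parsed tables.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(labels, z, mask = NULL) {
  labels <- as.character(labels)
  z <- as.matrix(z)
  n <- length(labels)
  if (!all(dim(z) == n)) stop("z must be square and match labels")
  if (anyDuplicated(labels)) stop("duplicate labels")
  if (max(abs(z - t(z))) > 1e-6) stop("z must be symmetric")
  if (is.null(mask)) mask <- z != 0
  mask <- as.matrix(mask)
  if (!all(dim(mask) == n)) stop("mask must match z")
  if (!identical(mask, t(mask))) stop("mask must be symmetric")
  dimnames(z) <- dimnames(mask) <- list(labels, labels)
  structure(list(labels = labels, z = z, mask = mask),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d labels, %d significant off-diagonal pairs\n",
              length(x$labels),
              sum(x$mask[upper.tri(x$mask)])))
  invisible(x)
}

#' Parse a tabular Z-score similarity table
#'
#' Reads a TSV with a header row of labels and one labelled row per
#' structure; the body may be square or upper-triangular (blank cells below
#' the diagonal). Dashes mark pairs with no detected similarity and become
#' `Z = 0` with `mask = FALSE`. The upper triangle is mirrored onto the
#' lower.
#'
#' @param path Path to the TSV file.
#' @return A [similarity_matrix].
#' @export
parse_similarity_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (!nzchar(trimws(header[1]))) header <- header[-1] else
    stop("similarity table header must start with an empty corner cell")
  labels <- trimws(header)
  n <- length(labels)
  if (length(cells) - 1L != n) {
    stop("similarity table has ", length(cells) - 1L, " rows for ", n, " labels")
  }
  z <- matrix(NA_real_, n, n)
  mask <- matrix(NA, n, n)
  row_labels <- character(n)
  for (r in seq_len(n)) {
    row <- cells[[r + 1L]]
    row_labels[r] <- trimws(row[1])
    vals <- row[-1]
    length(vals) <- n                    # pad short (triangular) rows
    for (cc in seq_len(n)) {
      v <- if (cc <= length(vals)) trimws(vals[cc]) else ""
      if (is.na(v) || !nzchar(v)) next
      if (v == "-") {
        z[r, cc] <- 0; mask[r, cc] <- FALSE
      } else {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) {
          stop("non-numeric cell '", v, "' at row ", row_labels[r],
               ", column ", labels[cc])
        }
        z[r, cc] <- num; mask[r, cc] <- TRUE
      }
    }
  }
  if (!identical(row_labels, labels)) {
    stop("row labels do not match column labels: ",
         paste(setdiff(row_labels, labels), collapse = ", "))
  }
  # mirror the upper triangle; verify agreement where both triangles present
  for (r in seq_len(n - 1L)) {
    for (cc in (r + 1L):n) {
      if (is.na(z[cc, r])) {
        z[cc, r] <- z[r, cc]; mask[cc, r] <- mask[r, cc]
      } else if (is.na(z[r, cc])) {
        z[r, cc] <- z[cc, r]; mask[r, cc] <- mask[cc, r]
      }
    }
  }
  if (any(is.na(diag(z)))) stop("missing diagonal (self-alignment) entries")
  if (any(is.na(z))) stop("incomplete similarity table")
  similarity_matrix(labels, z, mask)
}

#' Write a similarity matrix as TSV
#'
#' Square layout with dashes for masked (non-significant) off-diagonal
#' cells; bit-compatible with the format accepted by
#' [parse_similarity_table].
#'
#' @param sm A [similarity_matrix].
#' @param path Output path.
#' @param digits Decimal places for Z values.
#' @export
write_similarity_table <- function(sm, path, digits = 1L) {
  stopifnot(inherits(sm, "similarity_matrix"))
  n <- length(sm$labels)
  fmt <- paste0("%.", digits, "f")
  body <- matrix(sprintf(fmt, sm$z), n, n)
  body[!sm$mask] <- "-"
  diag(body) <- sprintf(fmt, diag(sm$z))
  lines <- c(paste(c("", sm$labels), collapse = "\t"),
             vapply(seq_len(n), function(r) {
               paste(c(sm$labels[r], body[r, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# smallest leaf label of each active cluster, used for deterministic
# tie-breaking
cluster_rep <- function(members, labels) {
  min(labels[members])
}

#' Average-linkage dendrogram on a similarity matrix
#'
#' Unweighted average linkage (UPGMA) run directly on similarity: at every
#' step the two clusters with the largest average pairwise Z over all
#' cross-pairs are merged, and that average is recorded as the node's merge
#' similarity. Masked cells participate with their stored value (Z = 0 for
#' parsed dashes) so the matrix is complete. Ties are broken by the
#' lexicographic order of the cluster representatives (their smallest leaf
#' labels), making the tree reproducible.
#'
#' @param sm A [similarity_matrix] (or a plain labelled symmetric matrix).
#' @return An object of class `structure_dendrogram`: `merge` (hclust-style,
#'   negative entries are leaves), `height` (merge similarities,
#'   non-increasing), `labels`, `z_ceiling` (max diagonal Z, used as the
#'   height reference for Newick export).
#' @export
average_linkage_tree <- function(sm) {
  if (!inherits(sm, "similarity_matrix")) {
    z <- as.matrix(sm)
    if (is.null(rownames(z))) stop("matrix must carry labels")
    if (max(abs(z - t(z))) > 1e-6) stop("input matrix must be symmetric")
    sm <- similarity_matrix(rownames(z), (z + t(z)) / 2)
  }
  labels <- sm$labels
  n <- length(labels)
  if (n < 2L) stop("need at least 2 labels")
  z <- sm$z

  sim <- z                       # current between-cluster average similarity
  active <- seq_len(n)
  members <- as.list(seq_len(n)) # leaf indices per active cluster
  sizes <- rep(1L, n)
  node_of <- -seq_len(n)         # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    # best pair among active clusters, ties by representative labels
    best <- NULL
    for (p in seq_len(k - 1L)) {
      for (q in (p + 1L):k) {
        s <- sim[active[p], active[q]]
        if (is.null(best) || s > best$s + 1e-12) {
          best <- list(p = p, q = q, s = s)
        } else if (abs(s - best$s) <= 1e-12) {
          rep_new <- sort(c(cluster_rep(members[[active[p]]], labels),
                            cluster_rep(members[[active[q]]], labels)))
          rep_old <- sort(c(cluster_rep(members[[active[best$p]]], labels),
                            cluster_rep(members[[active[best$q]]], labels)))
          if (rep_new[1] < rep_old[1] ||
              (rep_new[1] == rep_old[1] && rep_new[2] < rep_old[2])) {
            best <- list(p = p, q = q, s = s)
          }
        }
      }
    }
    ci <- active[best$p]; cj <- active[best$q]
    merge[step, ] <- sort(c(node_of[ci], node_of[cj]))
    height[step] <- best$s

    # unweighted (UPGMA) Lance-Williams update on similarities
    for (other in setdiff(active, c(ci, cj))) {
      s_new <- (sizes[ci] * sim[ci, other] + sizes[cj] * sim[cj, other]) /
        (sizes[ci] + sizes[cj])
      sim[ci, other] <- sim[other, ci] <- s_new
    }
    members[[ci]] <- c(members[[ci]], members[[cj]])
    sizes[ci] <- sizes[ci] + sizes[cj]
    node_of[ci] <- step
    active <- setdiff(active, cj)
  }

  structure(list(merge = merge, height = height, labels = labels,
                 z_ceiling = max(max(diag(z)), height[1])),
            class = "structure_dendrogram")
}

#' @export
print.structure_dendrogram <- function(x, ...) {
  cat(sprintf("<structure_dendrogram> %d leaves; merges from Z %.1f down to %.1f\n",
              length(x$labels), x$height[1], x$height[length(x$height)]))
  invisible(x)
}

# leaves under each internal node
node_leaves <- function(tree) {
  n <- length(tree$labels)
  out <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    kids <- tree$merge[s, ]
    out[[s]] <- unlist(lapply(kids, function(k) {
      if (k < 0L) -k else out[[k]]
    }))
  }
  out
}

newick_quote <- function(label) {
  if (grepl("[][():;,'\"[:space:]]", label)) {
    paste0("'", gsub("'", "''", label), "'")
  } else {
    label
  }
}

#' Export a dendrogram as Newick
#'
#' Ultrametric branch lengths are derived from node heights
#' `h(node) = (z_ceiling - merge_similarity) / 2` with leaves at height 0,
#' so more similar structures sit closer together; `z_ceiling` is the
#' maximal diagonal (self-alignment) Z of the input matrix. Merge
#' similarities are additionally emitted as square-bracket comments on
#' internal nodes (`[&Z=...]`), which standard Newick readers ignore or can
#' be stripped with `comments = FALSE`.
#'
#' @param tree A `structure_dendrogram`.
#' @param comments Emit `[&Z=...]` internal-node comments?
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (terminated by `;`).
#' @export
tree_to_newick <- function(tree, comments = TRUE, digits = 6L) {
  stopifnot(inherits(tree, "structure_dendrogram"))
  n <- length(tree$labels)
  h_node <- (tree$z_ceiling - tree$height) / 2
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  build <- function(node, parent_h) {
    if (node < 0L) {
      return(paste0(newick_quote(tree$labels[-node]), ":", fmt(parent_h)))
    }
    kids <- tree$merge[node, ]
    inner <- paste(vapply(kids, build, "", parent_h = h_node[node]),
                   collapse = ",")
    com <- if (comments) sprintf("[&Z=%s]", fmt(tree$height[node])) else ""
    paste0("(", inner, ")", com, ":", fmt(parent_h - h_node[node]))
  }
  root <- n - 1L
  kids <- tree$merge[root, ]
  inner <- paste(vapply(kids, build, "", parent_h = h_node[root]),
                 collapse = ",")
  com <- if (comments) sprintf("[&Z=%s]", fmt(tree$height[root])) else ""
  paste0("(", inner, ")", com, ";")
}

#' Cut a dendrogram into clusters
#'
#' Cutting at a similarity `level` keeps exactly the merges with similarity
#' `>= level`; the resulting connected subtrees are the clusters. A `k`-based
#' cut finds the level producing exactly `k` clusters and errors (listing
#' the achievable counts) when ties make that count unattainable.
#'
#' @param tree A `structure_dendrogram`.
#' @param k Desired number of clusters, or
#' @param level Similarity level (Z units) to cut at.
#' @return Named integer vector mapping each leaf label to a cluster id
#'   (numbered by first appearance in leaf order).
#' @export
cut_tree <- function(tree, k = NULL, level = NULL) {
  stopifnot(inherits(tree, "structure_dendrogram"))
  n <- length(tree$labels)
  h <- tree$height
  if (is.null(k) == is.null(level)) stop("give exactly one of k or level")
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L || k > n) stop("k must be between 1 and ", n)
    m <- n - k                        # merges to apply
    ok <- m == 0L || m == n - 1L || h[m] > h[m + 1L] + 1e-12
    if (!ok) {
      ach <- c(n, n - which(diff(h) < -1e-12), 1L)
      stop("no cut level yields exactly ", k, " clusters (ties); achievable: ",
           paste(sort(unique(ach)), collapse = ", "))
    }
  } else {
    m <- sum(h >= level - 1e-12)
  }
  assign <- seq_len(n)
  if (m > 0L) {
    leaves <- node_leaves(tree)
    for (s in seq_len(m)) {
      ids <- leaves[[s]]
      assign[ids] <- min(assign[ids])
    }
  }
  ids <- match(assign, unique(assign))
  names(ids) <- tree$labels
  ids
}

#' Two-dimensional correspondence-analysis embedding
#'
#' Standard correspondence analysis of the non-negative similarity matrix:
#' entries are divided by the grand total, standardized residuals
#' `(observed - expected) / sqrt(row mass * column mass)` are formed under
#' row-by-column independence, and the matrix of residuals is decomposed by
#' SVD. Principal row coordinates on the first two axes are returned;
#' structures with similar Z-score profiles land close together.
#'
#' @param sm A [similarity_matrix] with >= 3 labels and non-negative
#'   entries.
#' @return A list of class `embedding2d`: `coords` (n x 2 matrix with label
#'   rownames), `eigenvalues` (all principal inertias, decreasing).
#' @export
correspondence_embedding <- function(sm) {
  stopifnot(inherits(sm, "similarity_matrix"))
  z <- sm$z
  n <- length(sm$labels)
  if (n < 3L) stop("embedding needs at least 3 labels")
  if (any(z < 0)) stop("correspondence analysis needs a non-negative matrix")
  total <- sum(z)
  if (total <= 0) stop("zero grand total")
  p <- z / total
  r <- rowSums(p); cc <- colSums(p)
  if (any(r <= 0) || any(cc <= 0)) stop("zero row/column mass")
  expected <- outer(r, cc)
  s <- (p - expected) / sqrt(expected)
  dec <- svd(s)
  coords <- (dec$u[, 1:2, drop = FALSE] * rep(dec$d[1:2], each = n)) / sqrt(r)
  rownames(coords) <- sm$labels
  colnames(coords) <- c("axis1", "axis2")
  structure(list(coords = coords, eigenvalues = dec$d^2),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("<embedding2d> %d labels; first two inertias %.4f, %.4f (%.0f%% of total)\n",
              nrow(x$coords), ev[1], ev[2],
              100 * sum(ev[1:2]) / sum(ev)))
  invisible(x)
}

#' Write a 2-D embedding as TSV
#' @param emb An `embedding2d`.
#' @param path Output path.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(label = rownames(emb$coords),
                   axis1 = emb$coords[, 1], axis2 = emb$coords[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
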