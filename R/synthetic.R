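#' @title Synthetic toy structures
#' @description Generators for idealized CA traces with known domain
#'   architecture: ideal helices/strands packed into compact toy domains,
#'   disordered low-confidence linkers, and planted structural families
#'   diverged from a common template. They exist so that every pipeline stage
#'   (segmentation, alignment, clustering) can be exercised end-to-end with
#'   fully known ground truth and no downloaded models.
#' @name synthetic
NULL

# run expr with a private RNG stream; the global .Random.seed is restored
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Ideal secondary-structure element CA geometry
#'
#' Helix: canonical alpha-helix CA parameters -- 1.5 Angstrom rise per
#' residue, 100 degree twist, 2.3 Angstrom helical radius, giving
#' consecutive CA-CA distances of about 3.8 Angstrom. Strand: extended
#' zig-zag with exactly 3.8 Angstrom between consecutive CAs.
#'
#' @param kind `"helix"` or `"strand"`.
#' @param length Number of residues (>= 2).
#' @return A `length` x 3 matrix of CA positions.
#' @export
build_ideal_sse <- function(kind = c("helix", "strand"), length) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length < 2L) stop("an SSE needs at least 2 residues")
  i <- seq_len(length) - 1L
  if (kind == "helix") {
    theta <- i * 100 * pi / 180
    cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  } else {
    # along-axis step 3.35, alternating offset so each CA-CA bond is 3.8
    half <- sqrt(3.8^2 - 3.35^2) / 2
    cbind(3.35 * i, half * (-1)^i, 0 * i)
  }
}

#' Describe a toy domain as packed secondary-structure elements
#'
#' @param elements Data frame (or list coercible to one) with columns `kind`
#'   (`"helix"`, `"strand"` or `"coil"`) and `length` (residues).
#' @param packing_offsets Numeric matrix, one row per element: the 3-vector
#'   (Angstrom) at which the element is placed.
#' @param name Blueprint name.
#' @return An object of class `domain_blueprint`.
#' @export
domain_blueprint <- function(elements, packing_offsets, name = "toy") {
  elements <- as.data.frame(elements)
  stopifnot(all(c("kind", "length") %in% names(elements)))
  elements$kind <- match.arg(elements$kind, c("helix", "strand", "coil"),
                             several.ok = TRUE)
  elements$length <- as.integer(elements$length)
  if (any(elements$length <= 0L)) stop("element lengths must be positive")
  if (sum(elements$length) < 5L) stop("blueprint total length must be >= 5")
  packing_offsets <- as.matrix(packing_offsets)
  if (nrow(packing_offsets) != nrow(elements) || ncol(packing_offsets) != 3L) {
    stop("packing_offsets must be one 3-vector per element")
  }
  structure(list(elements = elements, packing_offsets = packing_offsets,
                 name = name),
            class = "domain_blueprint")
}

# persistent random walk with CA-like step; max turn keeps it clash-sparse
random_walk_coords <- function(length, step = 3.8, start = c(0, 0, 0),
                               dir = c(1, 0, 0), max_turn_deg = 40) {
  pts <- matrix(0, length, 3)
  pts[1, ] <- start
  d <- dir / sqrt(sum(dir^2))
  for (k in seq_len(length - 1L)) {
    # rotate current direction by a random small angle about a random axis
    ax <- stats::rnorm(3)
    ax <- ax - sum(ax * d) * d
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, max_turn_deg) * pi / 180
    d <- cos(ang) * d + sin(ang) * ax
    d <- d / sqrt(sum(d^2))
    pts[k + 1L, ] <- pts[k, ] + step * d
  }
  pts
}

#' Random-walk coil trace
#'
#' A seeded persistent random walk with 3.8 Angstrom steps, used as an
#' "unrelated structure" control and as a disordered-linker model.
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @param confidence Per-residue confidence assigned to the trace.
#' @param id Model id.
#' @return A [structure_model] with source `"predicted"`.
#' @export
build_random_coil <- function(length, seed, confidence = 45, id = "coil") {
  stopifnot(length >= 2L)
  pts <- with_seed(seed, random_walk_coords(length))
  structure_model(
    id = id,
    residues = data.frame(
      chain_id = "A", seq_number = seq_len(length), insertion_code = "",
      residue_name = "GLY", x = pts[, 1], y = pts[, 2], z = pts[, 3],
      confidence = confidence, stringsAsFactors = FALSE
    ),
    source = "predicted"
  )
}

# interior points of an equal-chord circular arc from p to q (chord length
# `chord` per step); bulge plane direction w must be unit and orthogonal to q-p
arc_linker <- function(p, q, n_interior, w, chord = 3.7) {
  n_c <- n_interior + 1L
  g <- sqrt(sum((q - p)^2))
  u <- (q - p) / g
  ratio <- g / chord
  f <- function(theta) sin(theta / 2) / sin(theta / (2 * n_c)) - ratio
  # f decreases from ~n_c (theta -> 0) to 0 (theta -> 2*pi)
  theta <- stats::uniroot(f, c(1e-8, 2 * pi - 1e-6), tol = 1e-12)$root
  r <- g / (2 * sin(theta / 2))
  m <- (p + q) / 2
  center <- m - w * r * cos(theta / 2)
  # p sits at angle pi/2 + theta/2 and q at pi/2 - theta/2 around the center
  # in the (u, w) basis; interior points are equally spaced in angle
  k <- seq_len(n_interior)
  ang <- pi / 2 + theta / 2 - theta * k / n_c
  t(vapply(ang, function(a) center + r * (cos(a) * u + sin(a) * w),
           numeric(3)))
}

#' Build a toy domain from a blueprint
#'
#' Secondary-structure elements are laid out at their packing offsets
#' (deterministically -- independent of the seed) and joined by short coil
#' linkers placed on smooth arcs whose out-of-plane orientation is drawn from
#' the seed. SSE residues get confidence 92, coil residues 60 (values chosen
#' to straddle the 70 and 50 pLDDT bin edges used by segmentation).
#'
#' @param blueprint A [domain_blueprint].
#' @param seed Integer seed (coil placement only).
#' @return A [structure_model] with source `"predicted"`.
#' @export
build_toy_domain <- function(blueprint, seed = 0L) {
  stopifnot(inherits(blueprint, "domain_blueprint"))
  el <- blueprint$elements
  n_el <- nrow(el)

  pieces <- vector("list", n_el)
  with_seed(derive_seed(seed, 1L), {
    for (e in seq_len(n_el)) {
      base <- switch(el$kind[e],
        helix = build_ideal_sse("helix", el$length[e]),
        strand = build_ideal_sse("strand", el$length[e]),
        coil = random_walk_coords(el$length[e])
      )
      pieces[[e]] <- sweep(base, 2, blueprint$packing_offsets[e, ], "+")
    }
  })

  coords <- pieces[[1]]
  kinds <- rep(el$kind[1], el$length[1])
  if (n_el > 1L) {
    for (e in 2L:n_el) {
      p <- coords[nrow(coords), ]
      q <- pieces[[e]][1, ]
      g <- sqrt(sum((q - p)^2))
      if (g < 2.8) {
        stop("packing offsets place element ", e, " too close to element ",
             e - 1L, " (gap ", round(g, 2), " A)")
      }
      n_interior <- as.integer(ceiling(g / 3.7)) - 1L
      if (n_interior > 0L) {
        u <- (q - p) / g
        # try several bulge orientations (deterministic in the seed) and keep
        # the first that stays clear of already-placed atoms
        link <- NULL
        context <- rbind(coords, pieces[[e]])
        for (attempt in 1:8) {
          w <- with_seed(derive_seed(seed, 100L * attempt + e), {
            v <- stats::rnorm(3)
            v <- v - sum(v * u) * u
            v / sqrt(sum(v^2))
          })
          cand <- arc_linker(p, q, n_interior, w)
          gap <- min(apply(cand, 1, function(pt) {
            min(sqrt(rowSums(sweep(context, 2, pt)^2)))
          }))
          if (gap >= 1.5) { link <- cand; break }
        }
        if (is.null(link)) {
          stop("could not route a clash-free linker between elements ",
               e - 1L, " and ", e, " of blueprint '", blueprint$name, "'")
        }
        coords <- rbind(coords, link)
        kinds <- c(kinds, rep("coil", n_interior))
      }
      coords <- rbind(coords, pieces[[e]])
      kinds <- c(kinds, rep(el$kind[e], el$length[e]))
    }
  }

  n <- nrow(coords)
  # clash rule: non-bonded CA pairs must stay >= 1.5 A apart
  dm <- as.matrix(stats::dist(coords))
  off <- abs(row(dm) - col(dm)) >= 2
  if (any(dm[off] < 1.5)) {
    stop("blueprint '", blueprint$name,
         "' produces steric clashes (non-bonded CA-CA < 1.5 A)")
  }

  conf <- ifelse(kinds == "coil", 60, 92)
  structure_model(
    id = blueprint$name,
    residues = data.frame(
      chain_id = "A", seq_number = seq_len(n), insertion_code = "",
      residue_name = ifelse(kinds == "coil", "GLY", "ALA"),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      confidence = conf, stringsAsFactors = FALSE
    ),
    source = "predicted"
  )
}

#' Add isotropic Gaussian coordinate noise to a model
#'
#' Each CA coordinate receives i.i.d. N(0, sigma^2) noise. Residue metadata
#' is untouched. For n residues the expected RMSD to the original is
#' sigma * sqrt(3).
#'
#' @param model A [structure_model].
#' @param sigma Noise standard deviation per coordinate (Angstrom, >= 0).
#' @param seed Integer seed.
#' @return A perturbed [structure_model].
#' @export
perturb_structure <- function(model, sigma, seed = 0L) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("sigma must be a single non-negative number")
  }
  if (sigma == 0) return(model)
  xyz <- ca_coords(model)
  noise <- with_seed(seed, matrix(stats::rnorm(length(xyz), sd = sigma),
                                  nrow = nrow(xyz)))
  set_ca_coords(model, xyz + noise)
}

#' Generate a planted structural family
#'
#' One diverged "group template" per group (the template domain perturbed at
#' `between_sigma`), each member perturbed from its group template at
#' `within_sigma`. Because `between_sigma > within_sigma`, members of the
#' same group are mutually more similar than members of different groups --
#' a known cluster structure for testing alignment and tree recovery.
#'
#' @param template A [domain_blueprint] shared by the whole family.
#' @param group_sizes Integer vector (>= 2 groups) of members per group.
#' @param within_sigma Within-group perturbation (Angstrom).
#' @param between_sigma Between-group divergence (Angstrom, > within_sigma).
#' @param seed Integer seed.
#' @param add_linkers If `TRUE`, a 20-residue low-confidence (45) coil linker
#'   is prepended and appended to every member, to exercise segmentation.
#' @return A list of class `planted_family`: `members` (named list of
#'   [structure_model]), `true_labels` (named integer vector of group ids),
#'   `divergence_schedule`, `seed`.
#' @export
make_planted_family <- function(template, group_sizes, within_sigma = 0.3,
                                between_sigma = 3.0, seed = 0L,
                                add_linkers = FALSE) {
  stopifnot(inherits(template, "domain_blueprint"))
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) < 2L) stop("a planted family needs at least 2 groups")
  if (any(group_sizes < 1L)) stop("group sizes must be positive")
  if (!(between_sigma > within_sigma) || within_sigma < 0) {
    stop("require between_sigma > within_sigma >= 0")
  }

  base <- build_toy_domain(template, seed = derive_seed(seed, 0L))
  members <- list()
  labels <- integer(0)
  for (g in seq_along(group_sizes)) {
    gtempl <- perturb_structure(base, between_sigma, seed = derive_seed(seed, 10L + g))
    for (m in seq_len(group_sizes[g])) {
      mem <- perturb_structure(gtempl, within_sigma,
                               seed = derive_seed(seed, 1000L * g + m))
      mem$id <- sprintf("g%d_m%d", g, m)
      if (add_linkers) mem <- add_coil_linkers(mem, 20L,
                                               seed = derive_seed(seed, 5000L + 100L * g + m))
      members[[mem$id]] <- mem
      labels[mem$id] <- g
    }
  }
  structure(list(members = members, true_labels = labels,
                 divergence_schedule = c(within = within_sigma,
                                         between = between_sigma),
                 seed = seed),
            class = "planted_family")
}

# prepend and append low-confidence random-coil linkers; residues renumbered 1..n
add_coil_linkers <- function(model, linker_length = 20L, seed = 0L,
                             confidence = 45) {
  xyz <- ca_coords(model)
  n <- nrow(xyz)
  d_start <- xyz[1, ] - xyz[2, ]
  d_end <- xyz[n, ] - xyz[n - 1, ]
  pre <- with_seed(derive_seed(seed, 1L),
                   random_walk_coords(linker_length + 1L, start = xyz[1, ],
                                      dir = d_start / sqrt(sum(d_start^2))))
  post <- with_seed(derive_seed(seed, 2L),
                    random_walk_coords(linker_length + 1L, start = xyz[n, ],
                                       dir = d_end / sqrt(sum(d_end^2))))
  pre <- pre[rev(seq_len(linker_length) + 1L), , drop = FALSE]
  post <- post[seq_len(linker_length) + 1L, , drop = FALSE]
  res <- model$residues
  mk <- function(p) data.frame(chain_id = res$chain_id[1], seq_number = 0L,
                               insertion_code = "", residue_name = "GLY",
                               x = p[, 1], y = p[, 2], z = p[, 3],
                               confidence = confidence, stringsAsFactors = FALSE)
  out <- rbind(mk(pre), res, mk(post))
  out$seq_number <- seq_len(nrow(out))
  structure_model(id = model$id, residues = out, source = model$source)
}
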