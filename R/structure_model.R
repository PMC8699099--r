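#' Construct a CA-trace structure model
#'
#' The central data container of the package: one protein chain reduced to its
#' C-alpha trace, with optional per-residue confidence (pLDDT for predicted
#' models, carried in the B-factor field of AlphaFold files). All downstream
#' computation -- distance matrices, alignment, superposition -- operates on
#' this object.
#'
#' @param id Character scalar identifying the model.
#' @param residues A data frame with columns `chain_id`, `seq_number`
#'   (author numbering, integer), `insertion_code` (character, `""` if none),
#'   `residue_name` (3-letter code), `x`, `y`, `z` (CA position, Angstrom)
#'   and `confidence` (numeric in \[0, 100\] or `NA`).
#' @param source Either `"experimental"` or `"predicted"`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(id, residues, source = c("experimental", "predicted")) {
  source <- match.arg(source)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  required <- c("chain_id", "seq_number", "insertion_code", "residue_name",
                "x", "y", "z", "confidence")
  missing_cols <- setdiff(required, names(residues))
  if (length(missing_cols) > 0L) {
    stop("residues is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  residues <- as.data.frame(residues)[, required]
  residues$seq_number <- as.integer(residues$seq_number)
  residues$insertion_code[is.na(residues$insertion_code)] <- ""
  if (nrow(residues) < 1L) stop("a structure model must contain at least one residue")
  xyz <- as.matrix(residues[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("CA positions must be finite")
  conf <- residues$confidence
  if (any(!is.na(conf) & (conf < 0 | conf > 100))) {
    stop("confidence values must lie in [0, 100]")
  }
  key <- paste(residues$chain_id, residues$seq_number, residues$insertion_code)
  if (anyDuplicated(key)) {
    stop("duplicate (chain_id, seq_number, insertion_code) residue identifiers")
  }
  rownames(residues) <- NULL
  structure(list(id = id, source = source, residues = residues),
            class = "structure_model")
}

#' Number of residues in a structure model
#' @param model A `structure_model`.
#' @return Integer residue count.
#' @export
n_residues <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  nrow(model$residues)
}

#' CA coordinates of a structure model
#' @param model A `structure_model`.
#' @return An n x 3 numeric matrix of CA positions (Angstrom), rows in chain order.
#' @export
ca_coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  m <- as.matrix(model$residues[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the CA coordinates of a model
#'
#' Residue metadata (numbering, names, confidence) is kept; only positions
#' change.
#' @param model A `structure_model`.
#' @param xyz An n x 3 numeric matrix.
#' @return A new `structure_model`.
#' @export
set_ca_coords <- function(model, xyz) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_residues(model) || ncol(xyz) != 3L) {
    stop("xyz must be an n x 3 matrix matching the model length")
  }
  model$residues$x <- xyz[, 1]
  model$residues$y <- xyz[, 2]
  model$residues$z <- xyz[, 3]
  model
}

#' @export
print.structure_model <- function(x, ...) {
  n <- n_residues(x)
  conf <- x$residues$confidence
  cat(sprintf("<structure_model> %s (%s), %d residues\n", x$id, x$source, n))
  cat(sprintf("  chain %s, residues %d..%d\n",
              x$residues$chain_id[1], x$residues$seq_number[1],
              x$residues$seq_number[n]))
  if (any(!is.na(conf))) {
    cat(sprintf("  confidence: mean %.1f, range [%.1f, %.1f]\n",
                mean(conf, na.rm = TRUE), min(conf, na.rm = TRUE),
                max(conf, na.rm = TRUE)))
  }
  invisible(x)
}

# consecutive CA-CA distances; used by generators and sanity checks
ca_step_lengths <- function(model) {
  xyz <- ca_coords(model)
  if (nrow(xyz) < 2L) return(numeric(0))
  sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
}
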