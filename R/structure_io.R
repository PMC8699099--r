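#' Read a structure coordinate file into a CA-trace model
#'
#' Parses a PDB or mmCIF (PDBx) file, selects one chain, and extracts its
#' C-alpha trace. For multi-model files only the first model is used.
#' Residues that lack a CA atom are dropped with a warning. Alternate
#' locations are resolved to the highest-occupancy conformer (ties: first
#' encountered). When `source = "predicted"` (or auto-detected from an
#' `AF-` filename prefix) per-residue confidence (pLDDT) is populated from
#' the B-factor column.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (extension-based; `.cif` /
#'   `.mmcif` are read as PDBx).
#' @param chain Optional chain identifier. Default: the first chain in the
#'   file. An absent chain is an error listing the available chains.
#' @param source `"experimental"`, `"predicted"`, or `"auto"`.
#' @param id Model identifier; defaults to the file name without extension.
#' @return A [structure_model].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain = NULL,
                           source = c("auto", "experimental", "predicted"),
                           id = NULL) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (source == "auto") {
    source <- if (grepl("^AF-", basename(path))) "predicted" else "experimental"
  }

  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "

  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    chain <- chains[1]
  } else if (!chain %in% chains) {
    stop("chain '", chain, "' not present in ", path,
         "; available chains: ", paste(chains, collapse = ", "))
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]

  # protein residues only; keep MSE (selenomethionine) which is HETATM in PDB
  is_protein <- atoms$type == "ATOM" | (atoms$type == "HETATM" & atoms$resid == "MSE")
  atoms <- atoms[is_protein, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no protein atoms found in chain ", chain, " of ", path)

  res_key <- paste(atoms$resno, atoms$insert)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  n_dropped <- length(unique(res_key)) - length(unique(paste(ca$resno, ca$insert)))
  if (n_dropped > 0L) {
    warning(n_dropped, " residue(s) without a CA atom dropped from ", id)
  }
  if (nrow(ca) == 0L) stop("no CA atoms found in chain ", chain, " of ", path)

  # altloc: within each residue keep the highest-occupancy CA (ties: first)
  occ <- ca$o
  occ[is.na(occ)] <- 1
  ord <- order(seq_len(nrow(ca)))             # stable file order
  ca_key <- paste(ca$resno, ca$insert)
  keep <- tapply(seq_len(nrow(ca)), factor(ca_key, levels = unique(ca_key)),
                 function(idx) idx[which.max(occ[idx])])
  ca <- ca[sort(unlist(keep)), , drop = FALSE]

  conf <- if (source == "predicted") ca$b else rep(NA_real_, nrow(ca))
  residues <- data.frame(
    chain_id = ca$chain,
    seq_number = as.integer(ca$resno),
    insertion_code = ca$insert,
    residue_name = ca$resid,
    x = ca$x, y = ca$y, z = ca$z,
    confidence = conf,
    stringsAsFactors = FALSE
  )
  structure_model(id = id, residues = residues, source = source)
}

#' Write a CA-trace model as a PDB file
#'
#' Emits one CA atom record per residue. Confidence is written to the
#' B-factor column (0.00 when absent). Round-tripping through
#' [read_structure] reproduces coordinates to 1e-3 Angstrom and confidence
#' to 1e-2 (PDB fixed-width precision).
#'
#' @param model A [structure_model].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  if (n_residues(model) < 1L) stop("cannot write an empty model")
  res <- model$residues
  b <- res$confidence
  b[is.na(b)] <- 0
  ins <- res$insertion_code
  ins[ins == ""] <- NA
  tryCatch(
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(res[, c("x", "y", "z")]))),
      type = rep("ATOM", nrow(res)),
      resno = res$seq_number,
      resid = res$residue_name,
      chain = res$chain_id,
      insert = ins,
      elety = rep("CA", nrow(res)),
      o = rep(1, nrow(res)),
      b = b
    ),
    error = function(e) stop("failed to write ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Resolve an accession-style identifier to a structure locator
#'
#' Pure name resolution -- no network access. UniProt-style accessions map
#' to AlphaFold Database naming (`AF-<acc>-F1-model_v<N>.pdb`), 4-character
#' codes to PDB naming (`<code>.cif`, lower case), and existing file paths
#' to local files. An identifier that is both an existing path and a valid
#' accession is ambiguous and an error.
#'
#' @param identifier Accession, PDB code, or file path.
#' @param afdb_version AlphaFold Database model version for the canonical
#'   filename (default 4).
#' @return A list of class `structure_locator` with elements `kind`
#'   (`"afdb"`, `"pdb"` or `"local"`), `identifier` and `filename`.
#' @export
resolve_model_source <- function(identifier, afdb_version = 4L) {
  stopifnot(is.character(identifier), length(identifier) == 1L)
  if (!nzchar(identifier)) stop("identifier must be non-empty")

  uniprot_re <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
  pdb_re <- "^[0-9][A-Za-z0-9]{3}$"
  is_path <- file.exists(identifier)
  is_uniprot <- grepl(uniprot_re, identifier)
  is_pdb <- grepl(pdb_re, identifier)

  if (is_path && (is_uniprot || is_pdb)) {
    stop("ambiguous identifier '", identifier, "': both an existing file and a ",
         if (is_uniprot) "UniProt accession" else "PDB code")
  }
  if (is_path) {
    loc <- list(kind = "local", identifier = identifier, filename = identifier)
  } else if (is_uniprot) {
    loc <- list(kind = "afdb", identifier = identifier,
                filename = sprintf("AF-%s-F1-model_v%d.pdb", identifier,
                                   as.integer(afdb_version)))
  } else if (is_pdb) {
    loc <- list(kind = "pdb", identifier = tolower(identifier),
                filename = paste0(tolower(identifier), ".cif"))
  } else {
    stop("cannot interpret identifier '", identifier,
         "' as a UniProt accession, PDB code, or existing file")
  }
  class(loc) <- "structure_locator"
  loc
}

#' Download URL for a structure locator
#'
#' String construction only; the package core never performs network access.
#' The optional fetch step of the command-line interface uses this.
#'
#' @param locator A `structure_locator` from [resolve_model_source].
#' @return Character URL, or `NA` for local files.
#' @export
locator_url <- function(locator) {
  stopifnot(inherits(locator, "structure_locator"))
  switch(locator$kind,
    afdb = paste0("https://alphafold.ebi.ac.uk/files/", locator$filename),
    pdb = paste0("https://files.rcsb.org/download/", locator$filename),
    local = NA_character_
  )
}
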