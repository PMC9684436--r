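#' Construct a CA-only structure model
#'
#' A `structure_model` is an ordered list of residues, each carrying the
#' author residue number, insertion code, one-letter residue type and the
#' alpha-carbon coordinate.  It is the coordinate container every
#' structural operation (superposition, SASA) consumes.
#'
#' @param id Model identifier.
#' @param resno Integer vector of author residue numbers.
#' @param restype Character vector of one-letter residue types.
#' @param xyz Numeric matrix, one row per residue, columns x, y, z in
#'   Angstrom.
#' @param chain Chain identifier (single string).
#' @param ins Insertion codes (default: none).
#' @param source One of `"experimental"`, `"predicted"`, `"synthetic"`.
#' @return An object of class `"structure_model"`.
#' @export
structure_model <- function(id, resno, restype, xyz, chain = "A",
                            ins = rep("", length(resno)),
                            source = c("synthetic", "experimental",
                                       "predicted")) {
  source <- match.arg(source)
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(resno),
            length(restype) == length(resno), length(ins) == length(resno))
  ord <- order(resno, ins)
  if (any(ord != seq_along(resno))) {
    stop("residues must be ordered by author numbering + insertion code",
         call. = FALSE)
  }
  if (anyDuplicated(paste(resno, ins))) {
    stop("duplicate residue (one CA per residue required)", call. = FALSE)
  }
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(
    list(id = id, chain = chain, resno = as.integer(resno), ins = ins,
         restype = restype, xyz = xyz, source = source),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s chain %s: %d CA residues (%s)\n",
              x$id, x$chain, length(x$resno), x$source))
  invisible(x)
}

#' @export
length.structure_model <- function(x) length(x$resno)

#' One-letter sequence of a structure model
#' @param model A [structure_model()].
#' @return Character scalar.
#' @export
model_sequence <- function(model) {
  paste(model$restype, collapse = "")
}

#' Read a CA-only structure model from PDB or mmCIF
#'
#' Parses the file with bio3d, keeps polymer `ATOM` records only (HETATM
#' and waters dropped), selects one chain, resolves alternate locations by
#' highest occupancy (ties broken alphabetically), and retains exactly one
#' CA per residue.  Missing residues are simply absent; no padding.
#' Non-standard residues are mapped to their parent one-letter code where
#' known, otherwise `X`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param chain Chain identifier; default the first chain containing CA
#'   atoms.
#' @param source Passed to [structure_model()]; default `"experimental"`.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain = NULL, source = "experimental") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- if (format == "pdb") {
    bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  } else {
    # read.cif prints advisory warnings for spartan files; not actionable
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }
  atoms <- parsed$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA" &
                   atoms$resid != "HOH", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("no CA atoms in ", path, call. = FALSE)
  }
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    chain <- chains[1L]
  } else if (!chain %in% chains) {
    stop(sprintf("chain '%s' not found in %s (available: %s)",
                 chain, path, paste(chains, collapse = ", ")),
         call. = FALSE)
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("no CA atoms on chain ", chain, call. = FALSE)
  }
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  key <- paste(atoms$resno, ins, sep = "_")
  # altloc resolution: highest occupancy, ties -> alphabetically first
  pick <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    idx[order(-occ[idx], alt[idx])][1L]
  }), use.names = FALSE)
  pick <- pick[order(atoms$resno[pick], ins[pick])]
  atoms <- atoms[pick, , drop = FALSE]
  structure_model(
    id = sub("\\.(pdb|cif|mmcif)$", "", basename(path), ignore.case = TRUE),
    resno = atoms$resno,
    restype = aa_three_to_one(atoms$resid),
    xyz = cbind(atoms$x, atoms$y, atoms$z),
    chain = chain,
    ins = ins[pick],
    source = source)
}

#' Write a CA-only PDB file
#'
#' Emits standard `ATOM` records (CA only, occupancy 1.00, B-factor 0.00)
#' via bio3d, with coordinates at the format's 3-decimal precision.
#'
#' @param model A [structure_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(model$xyz)),
    resno = model$resno,
    resid = aa_one_to_three(model$restype),
    elety = rep("CA", length(model$resno)),
    chain = rep(model$chain, length(model$resno)),
    insert = ifelse(nzchar(model$ins), model$ins, NA),
    o = rep(1, length(model$resno)),
    b = rep(0, length(model$resno)))
  invisible(path)
}

#' Map a protein sequence onto a structure model
#'
#' Globally aligns the record sequence against the model's residue-type
#' string with identity scoring (match +1, mismatch 0, gap -2) and returns
#' the monotone list of aligned (sequence position, structure index)
#' pairs.  Mismatched aligned positions are allowed — a QTY variant
#' differs from its native at every substituted position yet aligns
#' gaplessly — but they are counted.
#'
#' @param record A [protein_record()].
#' @param model A [structure_model()].
#' @param min_coverage Mapping fails below this coverage (guards against
#'   aligning the wrong chain or entry).  Coverage is the fraction of
#'   model residues aligned to an identical sequence letter: a QTY
#'   variant against its native still scores ~0.75, an unrelated chain
#'   ~0.05.
#' @return A list of class `"seq_struct_map"`: `pairs` (integer matrix
#'   with columns `seq_pos`, `struct_idx`), `coverage`, `n_mismatch`.
#' @export
map_sequence_to_structure <- function(record, model, min_coverage = 0.3) {
  stopifnot(inherits(record, "protein_record"),
            inherits(model, "structure_model"))
  a <- record$sequence
  b <- model_sequence(model)
  sub <- diag(1L, length(.AA_ALPHABET))
  dimnames(sub) <- list(.AA_ALPHABET, .AA_ALPHABET)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 2)
  pat <- aa_split(as.character(Biostrings::alignedPattern(pa)))
  subj <- aa_split(as.character(Biostrings::alignedSubject(pa)))
  i <- 0L; j <- 0L
  pairs <- matrix(integer(0), ncol = 2L)
  mism <- 0L
  rows <- vector("list", length(pat))
  k <- 0L
  for (col in seq_along(pat)) {
    if (pat[col] != "-") i <- i + 1L
    if (subj[col] != "-") j <- j + 1L
    if (pat[col] != "-" && subj[col] != "-") {
      k <- k + 1L
      rows[[k]] <- c(i, j)
      if (pat[col] != subj[col]) mism <- mism + 1L
    }
  }
  pairs <- do.call(rbind, rows[seq_len(k)])
  colnames(pairs) <- c("seq_pos", "struct_idx")
  coverage <- (k - mism) / length(model$resno)
  if (coverage < min_coverage) {
    stop(sprintf(
      "sequence-structure mapping failed: coverage %.2f < %.2f (wrong chain or entry?)",
      coverage, min_coverage), call. = FALSE)
  }
  structure(list(pairs = pairs, coverage = coverage, n_mismatch = mism),
            class = "seq_struct_map")
}

#' @export
print.seq_struct_map <- function(x, ...) {
  cat(sprintf("<seq_struct_map> %d pairs, coverage %.2f, %d mismatches\n",
              nrow(x$pairs), x$coverage, x$n_mismatch))
  invisible(x)
}
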