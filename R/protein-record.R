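#' Create a protein record with transmembrane annotations
#'
#' A `protein_record` bundles a one-letter amino-acid sequence with its
#' transmembrane (TM) helix intervals, the unit every sequence-level
#' operation in the package consumes.  Intervals follow the UniProt
#' TRANSMEM convention: 1-based, inclusive on both ends.
#'
#' @param id Record identifier (FASTA header word).
#' @param sequence One-letter amino-acid string (20 standard letters plus
#'   `X` for ambiguity).
#' @param tm_segments A two-column matrix or data frame of `(start, end)`
#'   intervals, 1-based inclusive, or `NULL` for a protein with no TM
#'   annotation.  Intervals must be sorted, non-overlapping, and inside the
#'   sequence.
#' @param description Free-text description carried into FASTA output.
#'
#' @return An object of class `"protein_record"`: a list with elements
#'   `id`, `description`, `sequence`, and `tm_segments` (an integer matrix
#'   with columns `start`, `end`; zero rows when unannotated).
#'
#' @examples
#' rec <- protein_record("demo", "GGLLIVFFGG", tm_segments = cbind(3, 8))
#' rec
#' tm_mask(rec)
#' @export
protein_record <- function(id, sequence, tm_segments = NULL,
                           description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) {
    stop("sequence must be non-empty", call. = FALSE)
  }
  check_alphabet(sequence, sprintf("sequence of '%s'", id))
  tm <- normalize_tm(tm_segments, nchar(sequence), id)
  structure(
    list(id = id, description = description, sequence = sequence,
         tm_segments = tm),
    class = "protein_record")
}

normalize_tm <- function(tm_segments, seq_len, id = "record") {
  if (is.null(tm_segments) || NROW(tm_segments) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  tm <- as.matrix(tm_segments)
  if (ncol(tm) != 2L) {
    stop("tm_segments must have two columns (start, end)", call. = FALSE)
  }
  storage.mode(tm) <- "integer"
  colnames(tm) <- c("start", "end")
  rownames(tm) <- NULL
  tm <- tm[order(tm[, "start"]), , drop = FALSE]
  if (any(tm[, "start"] < 1L) || any(tm[, "end"] > seq_len) ||
      any(tm[, "start"] > tm[, "end"])) {
    stop(sprintf("TM interval out of bounds for '%s' (length %d)",
                 id, seq_len), call. = FALSE)
  }
  if (nrow(tm) > 1L &&
      any(tm[-1L, "start"] <= tm[-nrow(tm), "end"])) {
    stop(sprintf("TM intervals of '%s' overlap", id), call. = FALSE)
  }
  tm
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  (%d aa, %d TM segment%s)\n",
              x$id, nchar(x$sequence), nrow(x$tm_segments),
              if (nrow(x$tm_segments) == 1L) "" else "s"))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

#' Logical mask of transmembrane positions
#'
#' @param record A [protein_record()].
#' @return Logical vector of sequence length; `TRUE` inside a TM segment.
#' @export
tm_mask <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  mask <- rep(FALSE, nchar(record$sequence))
  tm <- record$tm_segments
  if (nrow(tm) > 0L) {
    for (i in seq_len(nrow(tm))) {
      mask[tm[i, "start"]:tm[i, "end"]] <- TRUE
    }
  }
  mask
}

#' Read protein records from FASTA, optionally with TM annotations
#'
#' @param fasta Path to a FASTA file.
#' @param tm Optional path to TM annotations: either a TSV with columns
#'   `id`, `start`, `end` (header optional) or a UniProt-style GFF whose
#'   third column is `Transmembrane`.
#' @return A named list of [protein_record()] objects.
#' @export
read_protein_fasta <- function(fasta, tm = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  desc <- sub("^\\S+\\s*", "", names(seqs))
  tm_tab <- if (is.null(tm)) NULL else read_tm_table(tm)
  recs <- lapply(seq_along(seqs), function(i) {
    segs <- NULL
    if (!is.null(tm_tab)) {
      hit <- tm_tab[tm_tab$id == ids[i], c("start", "end"), drop = FALSE]
      if (nrow(hit) > 0L) segs <- as.matrix(hit)
    }
    protein_record(ids[i], as.character(seqs[[i]]), tm_segments = segs,
                   description = desc[i])
  })
  names(recs) <- ids
  recs
}

#' Write protein records to FASTA
#'
#' @param records A [protein_record()] or list of them.
#' @param path Output file.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# TM annotation input: plain TSV (id, start, end) or UniProt GFF.
read_tm_table <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[nzchar(first)]
  is_gff <- any(grepl("^##gff", first)) ||
    any(vapply(strsplit(first, "\t", fixed = TRUE),
               function(f) length(f) >= 5L && f[3] == "Transmembrane",
               logical(1)))
  if (is_gff) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) length(f) >= 5L &&
                     f[3] == "Transmembrane", logical(1))
    fields <- fields[keep]
    if (length(fields) == 0L) {
      return(data.frame(id = character(0), start = integer(0),
                        end = integer(0)))
    }
    data.frame(
      id = vapply(fields, `[[`, "", 1L),
      start = as.integer(vapply(fields, `[[`, "", 4L)),
      end = as.integer(vapply(fields, `[[`, "", 5L)))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (is.character(tab[[2]][1]) && is.na(suppressWarnings(
          as.integer(tab[[2]][1])))) {
      tab <- tab[-1L, , drop = FALSE]  # header row
    }
    data.frame(id = as.character(tab[[1]]),
               start = as.integer(tab[[2]]),
               end = as.integer(tab[[3]]))
  }
}

#' Write TM annotations as a simple TSV
#'
#' @param records A [protein_record()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tm_tsv <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  rows <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$tm_segments) == 0L) return(NULL)
    data.frame(id = r$id, start = r$tm_segments[, "start"],
               end = r$tm_segments[, "end"])
  }))
  if (is.null(rows)) {
    rows <- data.frame(id = character(0), start = integer(0),
                       end = integer(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
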