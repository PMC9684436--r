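#' The QTY substitution code
#'
#' The QTY code replaces the four hydrophobic residues that dominate
#' transmembrane helices with neutral-polar residues of closely matched
#' side-chain shape: leucine with glutamine, isoleucine and valine with
#' threonine, and phenylalanine with tyrosine.  Applied only inside TM
#' helices, it converts a membrane protein's lipid-facing surface into a
#' hydrogen-bonding one while leaving loops, termini and every charged
#' residue untouched.
#'
#' @param mapping Named character vector giving the substitutions; residues
#'   absent from the table map to themselves.  The image residues must be
#'   fixed points of the map so that conversion is idempotent.
#'
#' @return A named character vector over the full alphabet (class
#'   `"qty_code_map"`), mapping each residue to its replacement.
#'
#' @examples
#' qty_code_map()[c("L", "I", "V", "F", "G")]
#' @export
qty_code_map <- function(mapping = c(L = "Q", I = "T", V = "T", F = "Y")) {
  full <- stats::setNames(.AA_ALPHABET, .AA_ALPHABET)
  bad <- setdiff(names(mapping), .AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("unknown residues in mapping: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  full[names(mapping)] <- unname(mapping)
  img <- unique(unname(mapping))
  not_fixed <- img[full[img] != img]
  if (length(not_fixed) > 0L) {
    stop("mapping is not idempotent: image residue(s) ",
         paste(not_fixed, collapse = ", "), " are themselves remapped",
         call. = FALSE)
  }
  structure(full, class = "qty_code_map")
}

#' Convert a membrane protein to its water-soluble QTY variant
#'
#' Applies the QTY code to every position inside the record's TM segments;
#' positions outside TM segments are left byte-identical.  Returns the
#' variant sequence together with a complete per-position substitution
#' ledger and the variation statistics reported in water-solubilization
#' studies (percentage of TM residues substituted, and the same count as a
#' percentage of the whole chain).
#'
#' @param record A [protein_record()] with TM annotations.
#' @param code A [qty_code_map()]; the default is the canonical
#'   L→Q, I→T, V→T, F→Y table.
#'
#' @return An object of class `"qty_variant"`: list with
#'   \describe{
#'     \item{native}{the input record}
#'     \item{variant_sequence}{converted sequence, same length}
#'     \item{substitutions}{data frame `pos`, `from`, `to` (1-based)}
#'     \item{stats}{a `"variation_stats"` list, see [variation_stats()]}
#'   }
#'
#' @examples
#' rec <- protein_record("demo", "LIVF", tm_segments = cbind(1, 4))
#' qty_convert(rec)
#' @export
qty_convert <- function(record, code = qty_code_map()) {
  stopifnot(inherits(record, "protein_record"))
  if (!inherits(code, "qty_code_map")) code <- qty_code_map(code)
  chars <- aa_split(record$sequence)
  mask <- tm_mask(record)
  new_chars <- chars
  new_chars[mask] <- unname(code[chars[mask]])
  changed <- which(new_chars != chars)
  variant <- paste(new_chars, collapse = "")
  res <- list(
    native = record,
    variant_sequence = variant,
    substitutions = data.frame(
      pos = as.integer(changed),
      from = chars[changed],
      to = new_chars[changed],
      stringsAsFactors = FALSE),
    stats = variation_stats(record, variant))
  class(res) <- "qty_variant"
  res
}

#' @export
print.qty_variant <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<qty_variant> %s_QTY  (%d aa)\n", x$native$id,
              nchar(x$variant_sequence)))
  cat(sprintf("  substitutions : %d of %d TM residues (%d TM segments)\n",
              s$tm_substituted, s$tm_residues, nrow(x$native$tm_segments)))
  cat(sprintf("  TM variation  : %.2f %%\n",
              round_half_up(s$tm_variation_pct)))
  cat(sprintf("  overall       : %.2f %%\n",
              round_half_up(s$overall_variation_pct)))
  invisible(x)
}

#' @method summary qty_variant
#' @export
summary.qty_variant <- function(object, ...) {
  tab <- table(factor(paste0(object$substitutions$from, "→",
                             object$substitutions$to)))
  print(object)
  if (length(tab) > 0L) {
    cat("  by substitution:\n")
    for (nm in names(tab)) cat(sprintf("    %s : %d\n", nm, tab[[nm]]))
  }
  invisible(object)
}

#' Variation statistics between a native record and a variant sequence
#'
#' Counts how many TM residues differ between native and variant and
#' expresses the count both relative to the TM residues (TM variation) and
#' relative to the whole chain (overall variation).
#'
#' @param native A [protein_record()].
#' @param variant_sequence Character scalar of the same length.
#' @return A list of class `"variation_stats"`: `tm_residues`,
#'   `tm_substituted`, `tm_variation_pct`, `overall_variation_pct`.
#'   Percentages are kept as raw doubles; the print method rounds
#'   half-up to 2 decimals.
#' @export
variation_stats <- function(native, variant_sequence) {
  stopifnot(inherits(native, "protein_record"))
  if (nchar(variant_sequence) != nchar(native$sequence)) {
    stop("variant and native sequences differ in length", call. = FALSE)
  }
  a <- aa_split(native$sequence)
  b <- aa_split(variant_sequence)
  mask <- tm_mask(native)
  diff <- a != b
  tm_res <- sum(mask)
  tm_sub <- sum(diff & mask)
  out <- list(
    tm_residues = tm_res,
    tm_substituted = tm_sub,
    n_substituted = sum(diff),
    tm_variation_pct = if (tm_res > 0L) 100 * tm_sub / tm_res else 0,
    overall_variation_pct = 100 * tm_sub / length(a))
  class(out) <- "variation_stats"
  out
}

#' @export
print.variation_stats <- function(x, ...) {
  cat(sprintf("TM variation: %.2f %%   overall variation: %.2f %%\n",
              round_half_up(x$tm_variation_pct),
              round_half_up(x$overall_variation_pct)))
  invisible(x)
}

#' Render a native/variant alignment as text
#'
#' Produces the block layout used in water-solubilization figures: the
#' native sequence, a marker row (`|` identical, `*` substituted), and the
#' variant sequence, preceded by a span line marking TM helices with `=`.
#'
#' @param native A [protein_record()].
#' @param variant_sequence Character scalar, same length as the native.
#' @param line_width Columns per block (minimum 10).
#' @return A character scalar (multi-line) of the rendered alignment.
#' @examples
#' rec <- protein_record("demo", "GGLIVFGG", tm_segments = cbind(3, 6))
#' cat(render_alignment(rec, qty_convert(rec)$variant_sequence))
#' @export
render_alignment <- function(native, variant_sequence, line_width = 60L) {
  stopifnot(inherits(native, "protein_record"))
  if (line_width < 10L) {
    stop("line_width must be at least 10", call. = FALSE)
  }
  if (nchar(variant_sequence) != nchar(native$sequence)) {
    stop("variant and native sequences differ in length", call. = FALSE)
  }
  a <- aa_split(native$sequence)
  b <- aa_split(variant_sequence)
  marker <- ifelse(a == b, "|", "*")
  tm_row <- ifelse(tm_mask(native), "=", " ")
  n <- length(a)
  lab_w <- nchar(native$id) + 6L  # room for the "_QTY" suffix + 2 spaces
  lab <- function(s) formatC(s, width = -lab_w)
  starts <- seq(1L, n, by = line_width)
  blocks <- vapply(starts, function(s) {
    e <- min(s + line_width - 1L, n)
    idx <- s:e
    paste0(
      lab("TM"), paste(tm_row[idx], collapse = ""), "\n",
      lab(native$id), paste(a[idx], collapse = ""), "  ", e, "\n",
      lab(""), paste(marker[idx], collapse = ""), "\n",
      lab(paste0(native$id, "_QTY")),
      paste(b[idx], collapse = ""), "  ", e, "\n")
  }, "")
  paste(blocks, collapse = "\n")
}
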