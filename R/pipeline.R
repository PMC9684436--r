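#' Fetch a UniProt record with TRANSMEM annotations (cache-through)
#'
#' Looks for `<accession>.fasta` and `<accession>.gff` in `cache_dir`
#' first; on a miss, downloads both from the UniProt REST service and
#' writes them to the cache together with a retrieval-date stamp, so
#' repeat runs are fully offline and reproducible.  TM intervals are
#' parsed from GFF lines whose feature type is `Transmembrane`.
#'
#' @param accession UniProt accession (e.g. `"P11166"`).
#' @param cache_dir Directory for cached responses (created if needed).
#' @param offline When `TRUE`, never touch the network; a cache miss is an
#'   error.
#' @param timeout Download timeout in seconds.
#' @return A [protein_record()]; a missing TRANSMEM annotation yields a
#'   warning and an empty TM list.
#' @export
fetch_uniprot <- function(accession, cache_dir = "uniprot_cache",
                          offline = FALSE, timeout = 30) {
  if (!grepl(paste0("^([OPQ][0-9][A-Z0-9]{3}[0-9]|",
                    "[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"),
             accession, ignore.case = TRUE)) {
    stop("'", accession, "' is not a syntactically valid UniProt accession",
         call. = FALSE)
  }
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(cache_dir, paste0(accession, ".fasta"))
  gff <- file.path(cache_dir, paste0(accession, ".gff"))
  if (!file.exists(fasta) || !file.exists(gff)) {
    if (offline) {
      stop("no cached entry for ", accession, " and offline = TRUE",
           call. = FALSE)
    }
    base <- "https://rest.uniprot.org/uniprotkb/"
    old <- options(timeout = timeout); on.exit(options(old))
    ok <- tryCatch({
      utils::download.file(paste0(base, accession, ".fasta"), fasta,
                           quiet = TRUE, mode = "wb")
      utils::download.file(paste0(base, accession, ".gff"), gff,
                           quiet = TRUE, mode = "wb")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(fasta) || file.size(fasta) == 0L) {
      unlink(c(fasta, gff))
      stop("lookup failed for UniProt accession ", accession,
           " (network unavailable or unknown accession)", call. = FALSE)
    }
    writeLines(format(Sys.Date()),
               file.path(cache_dir, paste0(accession, ".retrieved")))
  }
  seqs <- Biostrings::readAAStringSet(fasta)
  sequence <- as.character(seqs[[1L]])
  desc <- names(seqs)[1L]
  tm <- parse_uniprot_gff_tm(gff)
  if (nrow(tm) == 0L) {
    warning("no TRANSMEM features for ", accession)
    segs <- NULL
  } else {
    segs <- as.matrix(tm[, c("start", "end")])
  }
  protein_record(accession, sequence, tm_segments = segs,
                 description = desc)
}

parse_uniprot_gff_tm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 5L &&
                   f[3] == "Transmembrane", logical(1))
  fields <- fields[keep]
  data.frame(
    start = as.integer(vapply(fields, `[[`, "", 4L)),
    end = as.integer(vapply(fields, `[[`, "", 5L)))
}

#' Configuration of a batch water-solubilization run
#'
#' @param targets Data frame with columns `name` (gene name), `accession`
#'   (UniProt accession, or `NA` when `fasta`/`tm` files are given),
#'   and optionally `fasta`, `tm`, `pdb`, `chain`, `model` (paths; `NA`
#'   when absent).
#' @param tm_source `"uniprot"` (intervals from the fetched annotation) or
#'   `"file"` (from the `tm` column).
#' @param out_dir Output directory for the reports.
#' @param seed Integer seed recorded in the run log.
#' @param cache_dir Passed to [fetch_uniprot()].
#' @param offline Passed to [fetch_uniprot()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(targets, tm_source = c("uniprot", "file"),
                       out_dir = "qtyshift_out", seed = 1L,
                       cache_dir = "uniprot_cache", offline = FALSE) {
  tm_source <- match.arg(tm_source)
  targets <- as.data.frame(targets)
  if (nrow(targets) == 0L) {
    stop("config must name at least one target", call. = FALSE)
  }
  if (!all(c("name") %in% names(targets))) {
    stop("targets need at least a 'name' column", call. = FALSE)
  }
  for (col in c("accession", "fasta", "tm", "pdb", "chain", "model")) {
    if (!col %in% names(targets)) targets[[col]] <- NA_character_
  }
  structure(list(targets = targets, tm_source = tm_source,
                 out_dir = out_dir, seed = as.integer(seed),
                 cache_dir = cache_dir, offline = offline),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file holds the [run_config()] fields, with `targets` as a list of
#' per-target mappings.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  targets <- do.call(rbind, lapply(cfg$targets, function(t) {
    as.data.frame(t[c("name", "accession", "fasta", "tm", "pdb", "chain",
                      "model")[c("name", "accession", "fasta", "tm", "pdb",
                                 "chain", "model") %in% names(t)]])
  }))
  run_config(targets,
             tm_source = cfg$tm_source %||% "uniprot",
             out_dir = cfg$out_dir %||% "qtyshift_out",
             seed = cfg$seed %||% 1L,
             cache_dir = cfg$cache_dir %||% "uniprot_cache",
             offline = isTRUE(cfg$offline))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_target_record <- function(target, config) {
  if (!is.na(target$fasta)) {
    tm <- if (config$tm_source == "file" && !is.na(target$tm)) {
      target$tm
    } else NULL
    rec <- read_protein_fasta(target$fasta, tm = tm)[[1L]]
    rec$id <- target$name
    rec
  } else if (!is.na(target$accession)) {
    rec <- fetch_uniprot(target$accession, cache_dir = config$cache_dir,
                         offline = config$offline)
    rec$id <- target$name
    if (config$tm_source == "file" && !is.na(target$tm)) {
      tab <- read_tm_table(target$tm)
      rec <- protein_record(rec$id, rec$sequence,
                            tm_segments = as.matrix(
                              tab[, c("start", "end")]),
                            description = rec$description)
    }
    rec
  } else {
    stop("target '", target$name, "' has neither accession nor fasta",
         call. = FALSE)
  }
}

#' Run the full water-solubilization report for a set of targets
#'
#' For every target: load the native record, convert it with
#' [qty_convert()], compute native and variant [sequence_properties()],
#' and — when structure paths are supplied — superpose the predicted
#' variant model on the native structure with [superpose_models()] and
#' compare surface hydrophobicity.  One failing target is recorded and
#' skipped; the run continues.
#'
#' Writes into `config$out_dir`:
#' \describe{
#'   \item{report.tsv}{per-target native/variant rows: name, rmsd_A, pI,
#'     MW_kDa, TM_variation_pct, overall_variation_pct (native rows leave
#'     variation and RMSD blank; 2-decimal formatting)}
#'   \item{structures.tsv}{one row per superposed pair: name, pdb,
#'     n_pairs, rmsd_all_A, rmsd_refined_A, surface index native/variant}
#'   \item{variants.fasta}{the converted sequences, headers suffixed
#'     `_QTY`}
#'   \item{run_log.txt}{seed, package version, per-target status and
#'     timing}
#' }
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `rows` (the report data frame),
#'   `structures`, `variants` (list of `"qty_variant"`), and `errors`
#'   (named character, empty on full success).
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); struct_rows <- list(); variants <- list()
  errors <- character(0)
  log <- c(sprintf("qtyshift %s  seed=%d  date=%s",
                   as.character(utils::packageVersion("qtyshift")),
                   config$seed, format(Sys.Date())))
  fmt <- function(x) sprintf("%.2f", round_half_up(x))
  for (i in seq_len(nrow(config$targets))) {
    target <- config$targets[i, , drop = FALSE]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      rec <- load_target_record(target, config)
      qv <- qty_convert(rec)
      props_n <- sequence_properties(rec$sequence)
      props_q <- sequence_properties(qv$variant_sequence)
      rmsd_txt <- ""
      if (!is.na(target$pdb) && !is.na(target$model)) {
        ref <- read_structure(target$pdb,
                              chain = if (is.na(target$chain)) NULL
                                      else target$chain)
        mob <- read_structure(target$model, source = "predicted")
        sup <- superpose_models(ref, mob, tm_record = rec)
        rmsd_txt <- sprintf("%.3f", sup$rmsd_refined)
        sr_ref <- surface_report(ref)
        sr_mob <- surface_report(mob)
        struct_rows[[length(struct_rows) + 1L]] <- data.frame(
          name = target$name, pdb = basename(target$pdb),
          n_pairs = sup$n_pairs_retained,
          rmsd_all_A = sprintf("%.3f", sup$rmsd_all),
          rmsd_refined_A = sprintf("%.3f", sup$rmsd_refined),
          index_native = fmt(sr_ref$index),
          index_variant = fmt(sr_mob$index))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = c(target$name, paste0(target$name, "_QTY")),
        rmsd_A = c("", rmsd_txt),
        pI = c(fmt(props_n$pi), fmt(props_q$pi)),
        MW_kDa = c(fmt(props_n$mw_kda), fmt(props_q$mw_kda)),
        TM_variation_pct = c("", fmt(qv$stats$tm_variation_pct)),
        overall_variation_pct = c("", fmt(qv$stats$overall_variation_pct)))
      variants[[target$name]] <- qv
      "ok"
    }, error = function(e) conditionMessage(e))
    dt <- proc.time()[["elapsed"]] - t0
    log <- c(log, sprintf("target %-12s %-6s (%.2fs)%s", target$name,
                          if (res == "ok") "ok" else "FAILED", dt,
                          if (res == "ok") "" else paste0("  ", res)))
    if (res != "ok") errors[target$name] <- res
  }
  report <- do.call(rbind, rows)
  structures <- if (length(struct_rows) > 0L) {
    do.call(rbind, struct_rows)
  } else {
    data.frame(name = character(0))
  }
  if (!is.null(report)) {
    utils::write.table(report, file.path(config$out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(structures,
                     file.path(config$out_dir, "structures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(variants) > 0L) {
    vrecs <- lapply(variants, function(qv) {
      protein_record(paste0(qv$native$id, "_QTY"), qv$variant_sequence,
                     tm_segments = qv$native$tm_segments,
                     description = "water-soluble QTY variant")
    })
    write_protein_fasta(vrecs, file.path(config$out_dir, "variants.fasta"))
  }
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(list(rows = report, structures = structures,
                 variants = variants, errors = errors))
}
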