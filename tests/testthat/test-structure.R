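write_lines_pdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

test_that("PDB write/read round-trips coordinates at format precision", {
  h <- generate_helix_coords(3, sequence = "LIV", id = "fix")
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(h, path)
  m <- read_structure(path, source = "synthetic")
  expect_equal(length(m$resno), 3L)
  expect_identical(model_sequence(m), "LIV")
  expect_equal(m$xyz, round(h$xyz, 3), ignore_attr = TRUE)
  # second round trip is bit-identical in coordinates
  path2 <- tempfile(fileext = ".pdb")
  write_structure_pdb(m, path2)
  expect_identical(read_structure(path2)$xyz, m$xyz)
})

test_that("altlocs resolve to highest occupancy, ties alphabetical", {
  f <- write_lines_pdb(c(
    "ATOM      1  CA ALEU A   1      11.104   6.134   1.000  0.60 10.00           C",
    "ATOM      2  CA BLEU A   1      99.000  99.000  99.000  0.40 10.00           C",
    "ATOM      3  CA  GLY A   2      12.000   7.000   2.000  1.00 10.00           C"))
  m <- read_structure(f)
  expect_equal(length(m$resno), 2L)
  expect_equal(m$xyz[1, ], c(x = 11.104, y = 6.134, z = 1.000))

  # higher occupancy on B wins over alphabetical order
  f2 <- write_lines_pdb(c(
    "ATOM      1  CA ALEU A   1      99.000  99.000  99.000  0.40 10.00           C",
    "ATOM      2  CA BLEU A   1      11.104   6.134   1.000  0.60 10.00           C"))
  # single-residue models are legal containers (superposition would not be)
  m2 <- read_structure(f2)
  expect_equal(m2$xyz[1, ], c(x = 11.104, y = 6.134, z = 1.000))

  # occupancy tie: alphabetically first altloc retained
  f3 <- write_lines_pdb(c(
    "ATOM      1  CA BLEU A   1      99.000  99.000  99.000  0.50 10.00           C",
    "ATOM      2  CA ALEU A   1      11.104   6.134   1.000  0.50 10.00           C"))
  expect_equal(read_structure(f3)$xyz[1, ],
               c(x = 11.104, y = 6.134, z = 1.000))
})

test_that("numbering gaps, HETATM and waters are handled", {
  f <- write_lines_pdb(c(
    "ATOM      1  CA  ALA A   8      1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  10      2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  MET A  15      3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A  99      4.000   0.000   0.000  1.00  0.00           O",
    "HETATM    5 FE   HEM A  98      5.000   0.000   0.000  1.00  0.00          FE"))
  m <- read_structure(f)
  # numbering span 8..15 but only 3 residues present, no padding
  expect_equal(m$resno, c(8L, 10L, 15L))
  expect_identical(model_sequence(m), "AGM")
})

test_that("chain selection and empty models error informatively", {
  f <- write_lines_pdb(c(
    "ATOM      1  CA  ALA A   1      1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY B   1      2.000   0.000   0.000  1.00  0.00           C"))
  expect_identical(model_sequence(read_structure(f, chain = "B")), "G")
  expect_error(read_structure(f, chain = "Z"), "chain 'Z' not found")
  f_empty <- write_lines_pdb(
    "HETATM    1  O   HOH A   1      0.000   0.000   0.000  1.00  0.00           O")
  expect_error(read_structure(f_empty), "no CA atoms")
})

test_that("mmCIF files parse to the same model as PDB", {
  h <- generate_helix_coords(4, sequence = "MLVF", id = "cf")
  cif <- c(
    "data_cf", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
             "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
    vapply(seq_len(4), function(i) {
      sprintf("ATOM %d C CA . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s A CA 1",
              i, c("MET", "LEU", "VAL", "PHE")[i], i,
              h$xyz[i, 1], h$xyz[i, 2], h$xyz[i, 3], i,
              c("MET", "LEU", "VAL", "PHE")[i])
    }, ""))
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  m <- read_structure(path)
  expect_identical(model_sequence(m), "MLVF")
  expect_equal(m$xyz, round(h$xyz, 3), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("sequence-structure mapping is monotone with counted mismatches", {
  rec <- random_records(1, seed = 80)[[1]]
  n <- nchar(rec$sequence)
  full <- generate_helix_coords(n, sequence = rec$sequence, id = "full")
  m1 <- map_sequence_to_structure(rec, full)
  expect_equal(m1$coverage, 1.0)
  expect_equal(m1$n_mismatch, 0L)
  expect_identical(m1$pairs[, "seq_pos"], m1$pairs[, "struct_idx"])

  # model missing the first 10 residues: pairs start at position 11
  # (a non-repetitive sequence, so the register is unambiguous)
  pep <- random_peptides(1, len = 80, seed = 81)
  prec <- protein_record("pep", pep)
  phel <- generate_helix_coords(80, sequence = pep)
  trunc <- structure_model("tr", resno = seq_len(70),
                           restype = strsplit(pep, "")[[1]][-(1:10)],
                           xyz = phel$xyz[-(1:10), ])
  m2 <- map_sequence_to_structure(prec, trunc)
  expect_equal(min(m2$pairs[, "seq_pos"]), 11L)
  expect_true(all(diff(m2$pairs[, "seq_pos"]) > 0))
  expect_true(all(diff(m2$pairs[, "struct_idx"]) > 0))

  # QTY variant vs native: gapless, mismatches exactly at the ledger
  qv <- qty_convert(rec)
  vmodel <- generate_helix_coords(n, sequence = qv$variant_sequence,
                                  id = "var")
  m3 <- map_sequence_to_structure(rec, vmodel)
  expect_equal(nrow(m3$pairs), n)
  expect_equal(m3$n_mismatch, nrow(qv$substitutions))

  # hopeless mapping fails with a coverage error
  junk <- structure_model("junk", resno = 1:40,
                          restype = rep(c("W", "C", "H", "M"), 10),
                          xyz = generate_helix_coords(40)$xyz)
  poly <- protein_record("poly", strrep("K", 200))
  expect_error(map_sequence_to_structure(poly, junk), "coverage")
})
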