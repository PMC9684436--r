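test_that("the canonical code maps LIVF to QTTY inside TM segments", {
  rec <- protein_record("t", "LIVF", tm_segments = cbind(1, 4))
  qv <- qty_convert(rec)
  expect_identical(qv$variant_sequence, "QTTY")
  expect_equal(nrow(qv$substitutions), 4L)
  expect_identical(qv$substitutions$to, c("Q", "T", "T", "Y"))
  expect_equal(qv$stats$tm_variation_pct, 100)

  unannotated <- protein_record("t0", "LIVF")
  qv0 <- qty_convert(unannotated)
  expect_identical(qv0$variant_sequence, "LIVF")
  expect_equal(nrow(qv0$substitutions), 0L)
  expect_equal(qv0$stats$overall_variation_pct, 0)
})

test_that("conversion is idempotent, local, length- and charge-conserving", {
  for (rec in random_records(50)) {
    qv <- qty_convert(rec)
    v <- qv$variant_sequence
    expect_equal(nchar(v), nchar(rec$sequence))
    # idempotence: Q, T, Y are fixed points of the map
    rec2 <- protein_record(rec$id, v, tm_segments = rec$tm_segments)
    expect_identical(qty_convert(rec2)$variant_sequence, v)
    # locality: differences only inside TM intervals
    a <- strsplit(rec$sequence, "")[[1]]
    b <- strsplit(v, "")[[1]]
    expect_true(all(tm_mask(rec)[a != b]))
    expect_true(all(qv$substitutions$pos %in% which(tm_mask(rec))))
    # charged residues are never touched
    for (res in c("D", "E", "K", "R", "H")) {
      expect_equal(sum(b == res), sum(a == res))
    }
  }
})

test_that("custom code maps must be idempotent and on-alphabet", {
  expect_error(qty_code_map(c(L = "I", I = "T")), "idempotent")
  expect_error(qty_code_map(c(B = "Q")), "unknown residues")
  # X passes through unchanged
  rec <- protein_record("x", "LXVF", tm_segments = cbind(1, 4))
  expect_identical(qty_convert(rec)$variant_sequence, "QXTY")
})

test_that("variation statistics count TM and overall percentages", {
  # 20 residues, TM covers 10, 5 of them LIVF
  rec <- protein_record("v", "GGGGGSSSSSLLIVFAAAAG",
                        tm_segments = cbind(11, 20))
  qv <- qty_convert(rec)
  expect_equal(qv$stats$tm_residues, 10L)
  expect_equal(qv$stats$tm_substituted, 5L)
  expect_equal(qv$stats$tm_variation_pct, 50)
  expect_equal(qv$stats$overall_variation_pct, 25)

  same <- variation_stats(rec, rec$sequence)
  expect_equal(same$tm_variation_pct, 0)
  expect_equal(same$overall_variation_pct, 0)
  expect_error(variation_stats(rec, "SHORT"), "length")

  # invariant: overall <= TM <= 100 whenever TM residues exist
  for (rec in random_records(10, seed = 3000)) {
    s <- qty_convert(rec)$stats
    expect_lte(s$overall_variation_pct, s$tm_variation_pct)
    expect_lte(s$tm_variation_pct, 100)
    expect_gte(s$overall_variation_pct, 0)
  }
})

test_that("record validation rejects malformed inputs", {
  expect_error(protein_record("b", "LIV8"), "alphabet")
  expect_error(protein_record("b", "LIVF", tm_segments = cbind(2, 9)),
               "out of bounds")
  expect_error(protein_record("b", "LIVFLIVF",
                              tm_segments = rbind(c(1, 4), c(3, 6))),
               "overlap")
})

test_that("alignment rendering marks substitutions and TM spans", {
  rec <- protein_record("t", "LIVF", tm_segments = cbind(1, 4))
  txt <- render_alignment(rec, "QTTY", line_width = 10)
  lines <- strsplit(txt, "\n")[[1]]
  expect_match(lines[1], "====")
  expect_match(lines[3], "\\*\\*\\*\\*")

  idn <- render_alignment(rec, "LIVF", line_width = 10)
  expect_match(strsplit(idn, "\n")[[1]][3], "\\|\\|\\|\\|")

  lg <- protein_record("t2", "LG", tm_segments = cbind(1, 1))
  mixed <- render_alignment(lg, "QG", line_width = 10)
  expect_match(strsplit(mixed, "\n")[[1]][3], "\\*\\|")

  expect_error(render_alignment(rec, "QTTY", line_width = 5), "at least 10")

  # blocks wrap at line_width and every sequence column appears once
  long <- random_records(1, seed = 77)[[1]]
  qv <- qty_convert(long)
  txt <- render_alignment(long, qv$variant_sequence, line_width = 60)
  native_rows <- grep(paste0("^", long$id, " "),
                      strsplit(txt, "\n")[[1]], value = TRUE)
  seq_cat <- gsub("[0-9 ]", "", paste(sub("^\\S+\\s+", "", native_rows),
                                      collapse = ""))
  expect_identical(seq_cat, long$sequence)
})
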