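test_that("match_brackets pairs nested brackets innermost-first", {
  p <- match_brackets("<<..>>")
  expect_equal(p$left, c(0L, 1L))
  expect_equal(p$right, c(5L, 4L))
  expect_equal(nrow(match_brackets("......")), 0L)
})

test_that("match_brackets rejects unbalanced lines", {
  expect_error(match_brackets("<<.>"), "unclosed")
  expect_error(match_brackets("<.>>"), "no open")
})

test_that("a minimal document parses", {
  aln <- parse_stockholm(c("# STOCKHOLM 1.0",
                           "seq1 GGGAAACCC",
                           "#=GC SS_cons <<<...>>>",
                           "//"))
  expect_s3_class(aln, "rna_msa")
  expect_equal(aln$seq_names, "seq1")
  expect_equal(n_columns(aln), 9L)
  expect_equal(aln$ss_cons, "<<<...>>>")
})

test_that("interleaved (wrapped) blocks are concatenated", {
  aln <- parse_stockholm(c("# STOCKHOLM 1.0",
                           "seq1 GGGAA",
                           "#=GC SS_cons <<<..",
                           "seq1 ACCC",
                           "#=GC SS_cons .>>>",
                           "//"))
  expect_equal(aln$rows, "GGGAAACCC")
  expect_equal(aln$ss_cons, "<<<...>>>")
})

test_that("labels, pseudoknot lines and commands are recognized", {
  aln <- parse_stockholm(c("# STOCKHOLM 1.0",
                           "#=GF R2R turn a 90",
                           "seq1 GGGAAACCC",
                           "seq2 GGGAAACCC",
                           "#=GC SS_cons ...<<.>>.",
                           "#=GC SS_cons_pkA <.......>",
                           "#=GC R2R_LABEL .a.......",
                           "//"))
  expect_equal(aln$labels, c(a = 1L))
  expect_named(aln$pk_lines, "A")
  expect_equal(nrow(match_brackets(aln$pk_lines[["A"]])), 1L)
  expect_equal(aln$commands$verb, "turn")
  expect_equal(aln$commands$args[[1]], c("a", "90"))
})

test_that("parse errors are informative", {
  expect_error(parse_stockholm(c("# STOCKHOLM 1.0", "seq1 AAA", "//")),
               "SS_cons")
  expect_error(parse_stockholm(c("# STOCKHOLM 1.0",
                                 "#=GC SS_cons ...", "//")),
               "no sequence rows")
  expect_error(parse_stockholm(c("# STOCKHOLM 1.0", "seq1 A A A",
                                 "#=GC SS_cons ...", "//")),
               "malformed sequence line")
  expect_error(parse_stockholm(c("# STOCKHOLM 1.0", "s1 AA",
                                 "#=GC SS_cons ..",
                                 "#=GC R2R_LABEL xx", "//")),
               "duplicate label")
})

test_that("unknown #=GF tags warn and are preserved on write", {
  expect_warning(
    aln <- parse_stockholm(c("# STOCKHOLM 1.0", "#=GF AU Someone",
                             "s1 AA", "#=GC SS_cons ..", "//")),
    "unknown #=GF tag")
  expect_true(any(grepl("^#=GF AU", write_stockholm(aln))))
})

test_that("write_stockholm round-trips through parse_stockholm", {
  for (tpl in c("hairpin", "junction3", "pk")) {
    aln <- generate_fixture(tpl, n_seq = 5, covary_rate = 0.4,
                            modular_frac = 0.4, seed = 7)
    back <- parse_stockholm(write_stockholm(aln))
    expect_equal(back, aln)
  }
})

test_that("write_stockholm writes to a file when given a path", {
  aln <- generate_fixture("hairpin", n_seq = 3, seed = 1)
  f <- withr::local_tempfile(fileext = ".sto")
  write_stockholm(aln, f)
  expect_equal(parse_stockholm(f), aln)
})
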