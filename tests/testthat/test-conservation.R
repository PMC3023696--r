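one_col <- function(chars) {
  parse_stockholm(c("# STOCKHOLM 1.0",
                    paste(sprintf("s%d", seq_along(chars)), chars),
                    "#=GC SS_cons .", "//"))
}

pair_aln <- function(types) {
  parse_stockholm(c("# STOCKHOLM 1.0",
                    paste(sprintf("s%d", seq_along(types)), types),
                    "#=GC SS_cons <>", "//"))
}

test_that("identity calls are tiered 75/90/97 with strict comparisons", {
  aln <- one_col(c("A", "C", "U"))
  call_at <- function(f)
    column_conservation(aln, weights = c(f, (1 - f) / 2, (1 - f) / 2), 0)
  expect_equal(call_at(0.80)$symbol, "A")
  expect_equal(call_at(0.80)$identity_tier, 75)
  expect_equal(call_at(0.95)$identity_tier, 90)
  expect_equal(call_at(0.98)$identity_tier, 97)
  # exactly at a threshold the higher tier must NOT fire
  expect_equal(call_at(0.75)$symbol, "presence")
  expect_equal(call_at(0.90)$identity_tier, 75)
  expect_equal(call_at(0.97)$identity_tier, 90)
})

test_that("purine/pyrimidine classes fire when no single identity does", {
  aln <- one_col(c("A", "G", "C"))
  cc <- column_conservation(aln, weights = c(0.4, 0.4, 0.2), 0)
  expect_equal(cc$symbol, "R")
  expect_equal(cc$identity_tier, 75)
  aln2 <- one_col(c("C", "U", "G"))
  cc2 <- column_conservation(aln2, weights = c(0.46, 0.46, 0.08), 0)
  expect_equal(cc2$symbol, "Y")
  expect_equal(cc2$identity_tier, 90)
})

test_that("presence-only columns are tiered 50/75/90/97 or absent", {
  aln <- one_col(c("A", "C", "G", "U", "-"))
  call_at <- function(f)
    column_conservation(aln, weights = c(rep(f / 4, 4), 1 - f), 0)
  expect_equal(call_at(0.45)$symbol, "absent")
  expect_equal(call_at(0.50)$symbol, "absent")   # strict at the 50% boundary
  expect_equal(call_at(0.60)$presence_tier, 50)
  expect_equal(call_at(0.80)$presence_tier, 75)
  expect_equal(call_at(0.95)$presence_tier, 90)
  expect_equal(call_at(0.99)$presence_tier, 97)
})

test_that("ambiguity codes count toward class or presence only", {
  # R rows support the purine class but not a specific nucleotide
  aln <- one_col(c("A", "R", "C"))
  cc <- column_conservation(aln, weights = c(0.5, 0.3, 0.2), 0)
  expect_equal(cc$symbol, "R")
  # N rows count toward presence only
  aln2 <- one_col(c("N", "N", "N"))
  cc2 <- column_conservation(aln2, weights = rep(1 / 3, 3), 0)
  expect_equal(cc2$symbol, "presence")
  expect_equal(cc2$presence_tier, 97)
})

test_that("column index is validated", {
  aln <- one_col(c("A", "A"))
  expect_error(column_conservation(aln, c(.5, .5), 1), "out of range")
})

test_that("pair classes follow the covariation rules", {
  expect_equal(classify_pair(pair_aln(c("GC", "GC", "GC")),
                             rep(1 / 3, 3), 0, 1), "invariant")
  expect_equal(classify_pair(pair_aln(c("GC", "GU", "GC")),
                             rep(1 / 3, 3), 0, 1), "compatible")
  expect_equal(classify_pair(pair_aln(c("GC", "AU", "GC")),
                             rep(1 / 3, 3), 0, 1), "covarying")
  # a gap at either position counts as non-canonical
  expect_equal(classify_pair(pair_aln(c("G-", "GC", "GC")),
                             c(0.2, 0.4, 0.4), 0, 1), "unshaded")
})

test_that("the non-canonical cutoff is strict at 10%", {
  aln <- pair_aln(c("AA", "GC"))
  expect_equal(classify_pair(aln, c(0.10, 0.90), 0, 1), "invariant")
  expect_equal(classify_pair(aln, c(0.11, 0.89), 0, 1), "unshaded")
})

test_that("classify_pair rejects columns that are not an annotated pair", {
  aln <- pair_aln(c("GC", "GC"))
  expect_error(classify_pair(aln, c(.5, .5), 0, 0), "not an annotated pair")
})

test_that("pairs on pseudoknot lines are annotated and classified", {
  aln <- parse_stockholm(c("# STOCKHOLM 1.0",
                           "s1 GAAC",
                           "s2 GCGC",
                           "#=GC SS_cons <..>",
                           "#=GC SS_cons_pkA .<>.",
                           "//"))
  ann <- annotate_consensus(aln, weights = c(0.5, 0.5))
  expect_setequal(ann$pairs$line, c("SS_cons", "pkA"))
  expect_equal(ann$pairs$class[ann$pairs$line == "pkA"], "unshaded")
})

test_that("annotate_consensus assembles per-column and per-pair tables", {
  aln <- generate_fixture("hairpin", n_seq = 6, covary_rate = 0.5, seed = 2)
  ann <- annotate_consensus(aln)
  expect_s3_class(ann, "rna_annotation")
  expect_equal(nrow(ann$columns), n_columns(aln))
  expect_equal(nrow(ann$pairs), nrow(match_brackets(aln$ss_cons)))
  expect_true(all(ann$pairs$class == "covarying"))
  td <- tidy(ann)
  expect_equal(nrow(td), n_columns(aln))
  expect_equal(sum(!is.na(td$partner)), 2 * nrow(ann$pairs))
})

test_that("modular frequency is weighted and labelled as a whole percent", {
  aln <- parse_stockholm(c("# STOCKHOLM 1.0",
                           "hasA AA", "hasB AA", "no1 A-", "no2 A-",
                           "#=GC SS_cons ..", "//"))
  f <- modular_frequency(aln, weights = c(.2, .11, .5, .19),
                         predicate = 'name_matches("^has")')
  expect_equal(as.numeric(f), 0.31, tolerance = 1e-12)
  expect_equal(attr(f, "label"), "31%")
})

test_that("variable-region length ranges use non-gap counts", {
  aln <- parse_stockholm(c("# STOCKHOLM 1.0",
                           "s1 AAAA", "s2 A--A", "s3 -A-A",
                           "#=GC SS_cons ....", "//"))
  rng <- var_region_range(aln, 0:2)
  expect_equal(rng$min, 1)
  expect_equal(rng$max, 3)
  expect_equal(rng$label, "1-3 nt")
  expect_equal(var_region_range(aln, 3L)$label, "1 nt")
  expect_error(var_region_range(aln, integer(0)), "empty")
})
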