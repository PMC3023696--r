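layout_of <- function(lines) layout_rna(parse_stockholm(lines))

hairpin_aln <- function() generate_fixture("hairpin", n_seq = 4, seed = 1)

test_that("backbone spacing is constant at d_nt outside variable regions", {
  for (tpl in c("hairpin", "internal")) {
    lay <- layout_rna(generate_fixture(tpl, n_seq = 4, seed = 1))
    sp <- layout_spacing(lay)
    expect_true(all(abs(sp$distance[!sp$exempt] - lay$params$d_nt) < 1e-6))
  }
})

test_that("base-paired nucleotides sit exactly d_bp apart", {
  aln <- hairpin_aln()
  lay <- layout_rna(aln)
  prs <- match_brackets(aln$ss_cons)
  co <- lay$coords
  for (z in seq_len(nrow(prs))) {
    a <- match(prs$left[z], co$col); b <- match(prs$right[z], co$col)
    expect_equal(sqrt((co$x[a] - co$x[b])^2 + (co$y[a] - co$y[b])^2),
                 lay$params$d_bp, tolerance = 1e-6)
  }
})

test_that("every column is placed exactly once", {
  aln <- generate_fixture("internal", n_seq = 4, seed = 2)
  lay <- layout_rna(aln)
  expect_setequal(lay$coords$col, seq_len(n_columns(aln)) - 1L)
  expect_false(anyDuplicated(lay$coords$col) > 0)
})

test_that("fixture layouts are overlap-free", {
  for (tpl in c("hairpin", "internal")) {
    lay <- layout_rna(generate_fixture(tpl, n_seq = 4, seed = 3))
    expect_equal(nrow(check_overlaps(lay)), 0)
  }
})

test_that("a turn command bends the exterior backbone", {
  base <- c("# STOCKHOLM 1.0",
            "s1 AAAAAAAA",
            "#=GC SS_cons ........",
            "#=GC R2R_LABEL ....t...",
            "//")
  straight <- layout_of(base)
  bent <- layout_of(append(base, "#=GF R2R turn t 90", after = 1))
  expect_equal(diff(range(straight$coords$y)), 0, tolerance = 1e-9)
  expect_gt(diff(range(bent$coords$y)), 2)
  # spacing still constant through the bend
  sp <- layout_spacing(bent)
  expect_true(all(abs(sp$distance - 1) < 1e-6))
})

test_that("var_backbone_range replaces a span with a fixed-sweep arc", {
  lines <- c("# STOCKHOLM 1.0",
             "#=GF R2R var_backbone_range a b",
             "s1 AAAAAAAAAA",
             "s2 AA----AAAA",
             "#=GC SS_cons ..........",
             "#=GC R2R_LABEL ..a...b...",
             "//")
  lay <- layout_of(lines)
  expect_true(all(lay$coords$in_var[lay$coords$col %in% 2:6]))
  expect_equal(nrow(lay$var_arcs), 1)
  # columns outside the span keep constant spacing
  sp <- layout_spacing(lay)
  expect_true(all(abs(sp$distance[!sp$exempt] - 1) < 1e-6))
})

test_that("unknown labels and command verbs are rejected", {
  lines <- c("# STOCKHOLM 1.0", "#=GF R2R turn q 90",
             "s1 AAA", "#=GC SS_cons ...", "//")
  expect_error(layout_of(lines), "unknown column label")
  expect_error(parse_stockholm(c("# STOCKHOLM 1.0", "#=GF R2R frobnicate x",
                                 "s1 AAA", "#=GC SS_cons ...", "//")),
               "unknown layout command verb")
})

test_that("plain multistem junctions fall back to a circular layout", {
  lines <- c("# STOCKHOLM 1.0",
             "s1 GGAAGGAAACCAGGAAACCAAGGAAACCACC",
             "#=GC SS_cons <<..<<...>>.<<...>>..<<...>>.>>",
             "//")
  lay <- layout_of(lines)
  expect_length(lay$junction_solutions, 0)
  sp <- layout_spacing(lay)
  expect_true(all(abs(sp$distance[!sp$exempt] - 1) < 1e-6))
  expect_equal(nrow(check_overlaps(lay)), 0)
})

test_that("a commanded junction uses the solver and honors stem directions", {
  aln <- generate_fixture("junction3", n_seq = 4, seed = 4)
  lay <- layout_rna(aln)
  expect_length(lay$junction_solutions, 1)
  expect_equal(nrow(check_overlaps(lay)), 0)
  sp <- layout_spacing(lay)
  expect_true(all(abs(sp$distance[!sp$exempt] - 1) < 1e-6))

  # commanded outward directions (180, 90, 0 degrees) are reproduced by the
  # placed child stems: direction from rung midpoint to next rung midpoint
  prs <- match_brackets(aln$ss_cons)
  co <- lay$coords
  pos <- function(col) {
    i <- match(col, co$col); c(co$x[i], co$y[i])
  }
  child_dirs <- c(180, 90, 0)
  child_left <- c(4L, 12L, 21L)   # 0-based first columns of the inner stems
  for (z in seq_along(child_left)) {
    l <- child_left[z]
    r <- prs$right[prs$left == l]
    m1 <- (pos(l) + pos(r)) / 2
    m2 <- (pos(l + 1L) + pos(r - 1L)) / 2
    ang <- atan2(m2[2] - m1[2], m2[1] - m1[1]) * 180 / pi
    wrapped <- ((ang - child_dirs[z] + 180) %% 360) - 180
    expect_equal(wrapped, 0, tolerance = 1e-4)
  }
})

test_that("tidy and the TSV export expose the coordinate table", {
  lay <- layout_rna(hairpin_aln())
  td <- tidy(lay)
  expect_true(all(c("col", "x", "y") %in% names(td)))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_layout_tsv(lay, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), nrow(lay$coords))
})
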