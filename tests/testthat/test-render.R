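hairpin_setup <- function(covary = 0.5, seed = 5) {
  aln <- generate_fixture("hairpin", n_seq = 6, covary_rate = covary,
                          seed = seed)
  ann <- annotate_consensus(aln)
  list(aln = aln, ann = ann, lay = layout_rna(aln))
}

prim_types <- function(drawing)
  vapply(drawing$primitives, `[[`, character(1), "type")

svg_texts <- function(svg) {
  doc <- xml2::read_xml(paste(svg, collapse = "\n"))
  xml2::xml_text(xml2::xml_find_all(doc, "//*[local-name()='text']"))
}

test_that("compose emits one glyph per shown column", {
  s <- hairpin_setup()
  dr <- compose(s$lay, s$ann, aln = s$aln)
  expect_s3_class(dr, "rna_drawing")
  n_shown <- sum(s$ann$columns$symbol != "absent")
  expect_equal(sum(prim_types(dr) == "glyph"), n_shown)
  # one rung per consensus pair
  rungs <- Filter(function(p) p$type == "line" && p$class == "rung",
                  dr$primitives)
  expect_length(rungs, nrow(s$ann$pairs))
})

test_that("covarying pairs are shaded, unshaded pairs are not", {
  s <- hairpin_setup(covary = 0.5)
  dr <- compose(s$lay, s$ann, aln = s$aln)
  shades <- Filter(function(p) p$type == "shade", dr$primitives)
  expect_length(shades, nrow(s$ann$pairs))
  expect_equal(unique(vapply(shades, `[[`, character(1), "color")),
               unname(style_map()$pair_shades[["covarying"]]))
})

test_that("mismatched layout and annotation are rejected", {
  s <- hairpin_setup()
  other <- annotate_consensus(generate_fixture("internal", n_seq = 4,
                                               seed = 1))
  expect_error(compose(s$lay, other), "column mismatch")
})

test_that("SVG output is well-formed XML and deterministic", {
  s <- hairpin_setup()
  svg1 <- to_svg(compose(s$lay, s$ann, aln = s$aln))
  svg2 <- to_svg(compose(s$lay, s$ann, aln = s$aln))
  expect_identical(svg1, svg2)
  doc <- xml2::read_xml(paste(svg1, collapse = "\n"))
  expect_equal(xml2::xml_name(doc), "svg")
})

test_that("the scale parameter is a pure homothety", {
  s <- hairpin_setup()
  svg10 <- to_svg(compose(s$lay, s$ann, style_map(scale = 10), s$aln))
  svg20 <- to_svg(compose(s$lay, s$ann, style_map(scale = 20), s$aln))
  dims <- function(svg) {
    doc <- xml2::read_xml(paste(svg, collapse = "\n"))
    as.numeric(c(xml2::xml_attr(doc, "width"), xml2::xml_attr(doc, "height")))
  }
  # width/height carry fixed 4-decimal formatting, hence the loose tolerance
  expect_equal(dims(svg20), 2 * dims(svg10), tolerance = 1e-5)
})

test_that("skeleton style draws one path per backbone run and no glyphs", {
  s <- hairpin_setup()
  dr <- compose(s$lay, s$ann, style_map(skeleton = TRUE), s$aln)
  types <- prim_types(dr)
  expect_equal(sum(types == "glyph"), 0)
  expect_equal(sum(types == "path"), 1)   # contiguous backbone, no var spans
  expect_equal(sum(types %in% c("shade", "line")), 0)
})

test_that("a JSON style file overrides palette entries", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"pair_shades": {"covarying": "#123456"}}', f)
  sm <- style_map(json = f)
  expect_equal(unname(sm$pair_shades[["covarying"]]), "#123456")
  expect_equal(sm$pair_shades[["compatible"]],
               style_map()$pair_shades[["compatible"]])
  s <- hairpin_setup()
  svg <- to_svg(compose(s$lay, s$ann, sm, s$aln))
  expect_true(any(grepl("#123456", svg)))
})

test_that("variable regions render as dashed arcs with a length label", {
  lines <- c("# STOCKHOLM 1.0",
             "#=GF R2R var_backbone_range a b",
             "s1 AAAAAAAAAA",
             "s2 AA----AAAA",
             "#=GC SS_cons ..........",
             "#=GC R2R_LABEL ..a...b...",
             "//")
  aln <- parse_stockholm(lines)
  dr <- compose(layout_rna(aln), annotate_consensus(aln), aln = aln)
  arcs <- Filter(function(p) p$type == "arc", dr$primitives)
  expect_length(arcs, 1)
  expect_true(arcs[[1]]$dashed)
  texts <- Filter(function(p) p$type == "text", dr$primitives)
  expect_equal(texts[[1]]$text, "1-5 nt")
})

test_that("pseudoknot callouts render a labelled side panel", {
  aln <- generate_fixture("pk", n_seq = 5, covary_rate = 0.4, seed = 8)
  svg <- to_svg(compose(layout_rna(aln), annotate_consensus(aln), aln = aln))
  expect_true("pseudoknot" %in% svg_texts(svg))
})

test_that("modular structures render a sub-panel with a percent label", {
  aln <- generate_fixture("hairpin", n_seq = 10, modular_frac = 0.3,
                          seed = 9)
  svg <- to_svg(compose(layout_rna(aln),
                        annotate_consensus(aln, uniform_weights = TRUE),
                        aln = aln))
  expect_true(any(grepl("%$", svg_texts(svg))))
  expect_true("30%" %in% svg_texts(svg))
})

test_that("shade commands add background circles", {
  lines <- c("# STOCKHOLM 1.0",
             "#=GF R2R shade a b #ffcc00",
             "s1 AAAAAA",
             "#=GC SS_cons ......",
             "#=GC R2R_LABEL .a..b.",
             "//")
  aln <- parse_stockholm(lines)
  dr <- compose(layout_rna(aln), annotate_consensus(aln), aln = aln)
  bgs <- Filter(function(p) p$type == "shade_bg", dr$primitives)
  expect_length(bgs, 4)
  expect_equal(bgs[[1]]$color, "#ffcc00")
})

test_that("write_svg writes the document to disk", {
  s <- hairpin_setup()
  f <- withr::local_tempfile(fileext = ".svg")
  write_svg(compose(s$lay, s$ann, aln = s$aln), f)
  expect_true(file.exists(f))
  expect_no_error(xml2::read_xml(f))
})
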