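# A fully symmetric junction (equally spaced stem directions, equal segment
# lengths) admits an exact common circle, so formulations 2 and 3 must reach
# an essentially zero objective and formulation 1 must close the sweep at
# exactly 360 degrees.
sym_spec <- function(k, n_seg = 3)
  junction_spec(dirs_deg = seq(0, by = 360 / k, length.out = k),
                seg_n = n_seg)

test_that("junction_spec validates and stores the description", {
  expect_error(junction_spec(0, 1), "at least two stems")
  spec <- junction_spec(c(0, 90, 180), seg_n = c(1, 2, 3), seg_var = c(0, 1, 0))
  expect_equal(spec$k, 3)
  expect_equal(spec$seg_kinds[[2]], c("nt", "nt", "var"))
})

test_that("formulation 1 exposes the documented variables", {
  spec <- junction_spec(c(0, 90, 180), seg_n = 2, seg_var = c(1, 0, 1))
  nlp <- junction_nlp(spec, formulation = 1)
  # r, theta0, one pair-chord offset per stem, one length per var region
  expect_equal(nlp$var_names,
               c("r", "theta0", "t1", "t2", "t3", "L1", "L2"))
  expect_length(nlp$x0, 7)
})

test_that("formulations 2/3 sample each segment at N + 2 + 3V points", {
  spec <- junction_spec(c(0, 90, 180), seg_n = c(3, 0, 2),
                        seg_var = c(0, 0, 1))
  for (f in 2:3) {
    nlp <- junction_nlp(spec, formulation = f)
    expect_equal(nlp$sample_counts, c(3 + 2, 0 + 2, 2 + 2 + 3))
  }
})

test_that("symmetric junctions solve to a perfect circle (formulations 2/3)", {
  for (k in c(3, 4)) {
    for (f in 2:3) {
      sol <- solve_junction(junction_nlp(sym_spec(k), formulation = f))
      expect_s3_class(sol, "rna_junction_solution")
      expect_lt(sol$objective, 1e-8)
      expect_lt(sol$max_violation, 1e-6)
      # every rung endpoint on the common circle
      rr <- sqrt((c(sol$stems$p5x, sol$stems$p3x) - sol$center[1])^2 +
                   (c(sol$stems$p5y, sol$stems$p3y) - sol$center[2])^2)
      expect_true(all(abs(rr - sol$radius) < 1e-4))
    }
  }
})

test_that("formulation 1 closes the swept angle at 360 degrees", {
  sol <- solve_junction(junction_nlp(sym_spec(3), formulation = 1))
  expect_equal(sol$swept_deg, 360, tolerance = 1e-5)
  expect_lt(sol$max_violation, 1e-6)
})

test_that("solutions respect the geometry invariants", {
  sol <- solve_junction(junction_nlp(sym_spec(3), formulation = 2))
  # rung lengths d_bp
  len <- sqrt((sol$stems$p5x - sol$stems$p3x)^2 +
                (sol$stems$p5y - sol$stems$p3y)^2)
  expect_true(all(abs(len - 1.6) < 1e-6))
  # consecutive backbone points d_nt apart within each segment
  for (seg in sol$segments) {
    pts <- lapply(seg$nt, `[[`, "pos")
    if (length(pts) >= 2) {
      for (z in seq_len(length(pts) - 1)) {
        gap <- sqrt(sum((pts[[z + 1]] - pts[[z]])^2))
        expect_equal(gap, 1, tolerance = 1e-6)
      }
    }
  }
})

test_that("solving is deterministic", {
  s1 <- solve_junction(junction_nlp(sym_spec(3), formulation = 2))
  s2 <- solve_junction(junction_nlp(sym_spec(3), formulation = 2))
  expect_identical(s1$x, s2$x)
  expect_identical(s1$objective, s2$objective)
})

test_that("alignment constraints are honored at the solution", {
  spec <- junction_spec(c(0, 100, 250), seg_n = 3,
                        aligns = list(list(stems = c(2, 3), angle_deg = 0)))
  nlp <- add_alignment_constraints(junction_nlp(spec, formulation = 2), spec)
  sol <- solve_junction(nlp)
  mid_y <- (sol$stems$p5y + sol$stems$p3y) / 2
  expect_equal(mid_y[2], mid_y[3], tolerance = 1e-6)
})

test_that("centroid constraints are honored at the solution", {
  spec <- junction_spec(c(0, 90, 180, 270), seg_n = 3,
                        centroids = list(list(group = c(2, 4), target = 3,
                                              angle_deg = 90)))
  nlp <- add_alignment_constraints(junction_nlp(spec, formulation = 2), spec)
  sol <- solve_junction(nlp)
  mid_x <- (sol$stems$p5x + sol$stems$p3x) / 2
  expect_equal(mean(mid_x[c(2, 4)]), mid_x[3], tolerance = 1e-6)
})

test_that("contradictory constraints raise an instructive error", {
  # aligning the same stems on two different axes forces their rung
  # midpoints to coincide, which the formulation-1 circle walk (exact
  # spacing between stems) cannot satisfy
  spec <- junction_spec(c(0, 120, 240), seg_n = 3,
                        aligns = list(list(stems = c(2, 3), angle_deg = 0),
                                      list(stems = c(2, 3), angle_deg = 90)))
  nlp <- add_alignment_constraints(junction_nlp(spec, formulation = 1), spec)
  expect_error(solve_junction(nlp), "no feasible junction layout")
})

test_that("alignment constraints referencing absent stems fail clearly", {
  spec <- junction_spec(c(0, 120, 240), seg_n = 2,
                        aligns = list(list(stems = c(1, 7), angle_deg = 0)))
  nlp <- add_alignment_constraints(junction_nlp(spec, formulation = 2), spec)
  expect_error(nlp$heq(nlp$x0), "absent stem")
})

test_that("variable-length regions get solved lengths within bounds", {
  spec <- junction_spec(c(0, 120, 240), seg_n = 1, seg_var = c(1, 0, 0))
  nlp <- junction_nlp(spec, formulation = 2)
  sol <- solve_junction(nlp)
  expect_lt(sol$max_violation, 1e-6)
  arcs <- sol$segments[[1]]$var
  expect_length(arcs, 1)
})

test_that("tidy and glance summarize a solution", {
  sol <- solve_junction(junction_nlp(sym_spec(3), formulation = 2))
  td <- tidy(sol)
  expect_true(all(c("element", "index", "x", "y") %in% names(td)))
  expect_equal(sum(td$element == "stem_p5"), 3)
  g <- glance(sol)
  expect_equal(nrow(g), 1)
  expect_equal(g$formulation, 2L)
})
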