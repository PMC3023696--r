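# Placement engine. Every nucleotide is positioned in the plane with a
# strictly constant backbone spacing d_nt: stems as parallel ladders, loop
# nucleotides on circles solved by binary search, multistem junctions either
# on a plain circle or through the constrained junction solver.

#' Layout parameters
#'
#' @param d_nt Distance between consecutive backbone positions, the internal
#'   unit (default 1). Constant over the whole drawing.
#' @param d_bp Distance between base-paired nucleotides (default 1.6 units;
#'   any fixed ratio above 1 works, 1.6 gives readable ladders).
#' @return List of class `layout_params`.
#' @export
layout_params <- function(d_nt = 1, d_bp = 1.6) {
  stopifnot(d_nt > 0, d_bp > 0)
  structure(list(d_nt = d_nt, d_bp = d_bp), class = "layout_params")
}

# ---- command resolution -----------------------------------------------------

# Turn the alignment's parsed commands into layout directives.
resolve_layout_commands <- function(aln) {
  extra_labels <- list()
  for (args in commands_of(aln, "label")) {
    col <- as.integer(args[2]) - 1L
    if (is.na(col) || col < 0 || col >= n_columns(aln))
      stop("label command: bad column '", args[2], "'", call. = FALSE)
    aln$labels[args[1]] <- col
  }
  turns <- tibble::tibble(col = integer(), deg = numeric())
  for (args in commands_of(aln, "turn"))
    turns <- rbind(turns, tibble::tibble(col = resolve_label(aln, args[1]),
                                         deg = as.numeric(args[2])))
  var_ranges <- list()
  for (args in commands_of(aln, "var_backbone_range")) {
    rng <- label_range(aln, args[1], args[2])
    var_ranges[[length(var_ranges) + 1L]] <- rng[1]:rng[2]
  }
  junctions <- list()
  for (args in commands_of(aln, "multistem_junction"))
    junctions[[length(junctions) + 1L]] <-
      parse_junction_command(args, aln)
  list(aln = aln, turns = turns,
       var_cols = as.integer(unlist(var_ranges)),
       junctions = junctions,
       skeleton = length(commands_of(aln, "skeleton")) > 0)
}

parse_junction_command <- function(args, aln) {
  cmd <- list(col = resolve_label(aln, args[1]), dirs = NULL,
              aligns = list(), centroids = list(), formulation = 2L)
  i <- 2
  while (i <= length(args)) {
    key <- args[i]
    if (key == "dirs") {
      cmd$dirs <- as.numeric(strsplit(args[i + 1], ",")[[1]])
      i <- i + 2
    } else if (key == "align") {
      cmd$aligns[[length(cmd$aligns) + 1L]] <-
        list(labels = strsplit(args[i + 1], "")[[1]],
             deg = as.numeric(args[i + 2]))
      i <- i + 3
    } else if (key == "align_centroid") {
      parts <- strsplit(args[i + 1], ":", fixed = TRUE)[[1]]
      cmd$centroids[[length(cmd$centroids) + 1L]] <-
        list(group = strsplit(parts[1], "")[[1]],
             target = parts[2], deg = as.numeric(args[i + 2]))
      i <- i + 3
    } else if (key == "formulation") {
      cmd$formulation <- as.integer(args[i + 1])
      i <- i + 2
    } else stop("multistem_junction: unknown clause '", key, "'",
                call. = FALSE)
  }
  if (is.null(cmd$dirs))
    stop("multistem_junction requires a dirs clause", call. = FALSE)
  cmd
}

# Split an unpaired run into nt items and variable-length spans.
plan_run <- function(cols, var_cols) {
  items <- list()
  i <- 1
  while (i <= length(cols)) {
    if (cols[i] %in% var_cols) {
      j <- i
      while (j < length(cols) && cols[j + 1] %in% var_cols &&
             cols[j + 1] == cols[j] + 1L) j <- j + 1
      items[[length(items) + 1L]] <- list(kind = "var", cols = cols[i:j])
      i <- j + 1
    } else {
      items[[length(items) + 1L]] <- list(kind = "nt", col = cols[i])
      i <- i + 1
    }
  }
  items
}

# effective backbone steps contributed by a run plan (var span = 3 steps)
eff_steps <- function(items) {
  sum(vapply(items, function(it) if (it$kind == "nt") 1L else 3L, integer(1)))
}

VAR_SWEEP_STEPS <- 3L   # fixed-sweep var arcs span 3 * d_nt of backbone

# ---- engine -----------------------------------------------------------------

#' Lay out an RNA structure
#'
#' Depth-first placement of a structure tree: stems are parallel ladders
#' (rungs of length `d_bp`, rung spacing `d_nt`), terminal loops, bulges and
#' internal loops are put on circles solved by [solve_loop_radius()], and
#' multistem junctions use either the plain circular layout or the
#' constrained junction solver when a `multistem_junction` command applies.
#' `turn` commands change the backbone direction at the exterior level;
#' `var_backbone_range` spans are drawn as fixed-sweep dashed arcs spanning
#' three backbone units.
#'
#' @param tree An `rna_structure_tree` from [build_structure_tree()].
#' @param params A [layout_params()] object.
#' @param commands Resolved layout directives (internal form); pass `NULL`
#'   for none. User code normally calls [layout_rna()] instead.
#' @param aln Optional [rna_msa] used to label variable-length arcs.
#' @return Object of class `rna_layout`: list with tibble `coords`
#'   (`col`, `x`, `y`, `dir`, `in_var`), tibble `var_arcs`, the `params`,
#'   and any junction solutions (`junction_solutions`).
#' @export
layout_structure <- function(tree, params = layout_params(), commands = NULL,
                             aln = NULL) {
  if (is.null(commands))
    commands <- list(turns = tibble::tibble(col = integer(), deg = numeric()),
                     var_cols = integer(), junctions = list(),
                     skeleton = FALSE)
  n <- tree_n_columns(tree)
  st <- new.env(parent = emptyenv())
  st$coords <- matrix(NA_real_, n, 2)
  st$dir <- rep(NA_real_, n)
  st$in_var <- rep(FALSE, n)
  st$var_arcs <- list()
  st$junction_solutions <- list()
  st$d_nt <- params$d_nt
  st$d_bp <- params$d_bp
  st$commands <- commands
  st$aln <- aln

  place_root(tree$elements, st)

  coords <- tibble::tibble(col = seq_len(n) - 1L,
                           x = st$coords[, 1], y = st$coords[, 2],
                           dir = st$dir, in_var = st$in_var)
  structure(list(coords = coords,
                 var_arcs = var_arcs_tibble(st$var_arcs),
                 params = params,
                 junction_solutions = st$junction_solutions,
                 pk = NULL, panels = list()),
            class = "rna_layout")
}

tree_n_columns <- function(tree) {
  mx <- -1L
  walk <- function(node) {
    for (f in c("cols", "p5", "p3", "side5", "side3"))
      if (!is.null(node[[f]]) && length(node[[f]]))
        mx <<- max(mx, node[[f]])
    for (k in c(node$elements, list(node$inner), list(node$stem)))
      if (!is.null(k)) walk(k)
  }
  walk(unclass(tree))
  mx + 1L
}

var_arcs_tibble <- function(arcs) {
  if (!length(arcs)) {
    return(tibble::tibble(id = integer(), cx = numeric(), cy = numeric(),
                          r = numeric(), theta0 = numeric(),
                          theta1 = numeric(), label = character(),
                          cols = list()))
  }
  dplyr::bind_rows(lapply(seq_along(arcs), function(i) {
    a <- arcs[[i]]
    tibble::tibble(id = i, cx = a$center[1], cy = a$center[2], r = a$radius,
                   theta0 = a$theta0, theta1 = a$theta1,
                   label = a$label, cols = list(a$cols))
  }))
}

set_nt <- function(st, col, pos, dir) {
  st$coords[col + 1L, ] <- pos
  st$dir[col + 1L] <- dir
}

# record a var arc and park its columns along the arc (no glyphs drawn there)
record_var_arc <- function(st, cols, center, radius, theta0, theta1) {
  label <- if (!is.null(st$aln)) var_region_range(st$aln, cols)$label
           else "var"
  st$var_arcs[[length(st$var_arcs) + 1L]] <-
    list(center = center, radius = radius, theta0 = theta0, theta1 = theta1,
         label = label, cols = cols)
  ths <- seq(theta0, theta1, length.out = length(cols) + 2)[-c(1, length(cols) + 2)]
  for (k in seq_along(cols)) {
    set_nt(st, cols[k], center + radius * unit_vec(ths[k]),
           ths[k] + sign(theta1 - theta0) * pi / 2)
    st$in_var[cols[k] + 1L] <- TRUE
  }
}

place_root <- function(elements, st) {
  pos <- c(0, 0)
  dirang <- 0
  turns <- st$commands$turns
  for (el in elements) {
    if (el$type == "run") {
      for (it in plan_run(el$cols, st$commands$var_cols)) {
        if (it$kind == "nt") {
          hit <- turns$deg[turns$col == it$col]
          if (length(hit)) dirang <- dirang + hit[1] * pi / 180
          set_nt(st, it$col, pos, dirang)
          pos <- pos + st$d_nt * unit_vec(dirang)
        } else {
          span <- VAR_SWEEP_STEPS * st$d_nt
          sag <- 0.5 * st$d_nt
          rho <- ((span / 2)^2 + sag^2) / (2 * sag)
          mid <- pos + (span / 2 - st$d_nt / 2) * unit_vec(dirang)
          # arc bulges to the left of travel
          ctr <- mid - (rho - sag) * rot90(unit_vec(dirang))
          th_a <- angle_of(pos - st$d_nt * unit_vec(dirang) - ctr)
          th_b <- angle_of(pos + (span - st$d_nt) * unit_vec(dirang) - ctr)
          record_var_arc(st, it$cols, ctr, rho, th_a,
                         th_a + ang_norm(th_b - th_a))
          pos <- pos + span * unit_vec(dirang)
        }
      }
    } else {  # stem, pointing 90 degrees left of the backbone direction
      u <- unit_vec(dirang + pi / 2)
      p5 <- pos
      p3 <- pos + st$d_bp * unit_vec(dirang)
      place_stem(el, p5, p3, u, st)
      pos <- p3 + st$d_nt * unit_vec(dirang)
    }
  }
}

place_stem <- function(stem, p5_0, p3_0, u, st) {
  L <- length(stem$p5)
  for (k in seq_len(L)) {
    off <- (k - 1) * st$d_nt * u
    set_nt(st, stem$p5[k], p5_0 + off, angle_of(u))
    set_nt(st, stem$p3[k], p3_0 + off, angle_of(-u))
  }
  A5 <- p5_0 + (L - 1) * st$d_nt * u
  A3 <- p3_0 + (L - 1) * st$d_nt * u
  inner <- stem$inner
  switch(inner$type,
         loop = place_loop(inner, A5, A3, u, st),
         internal = place_internal(inner, A5, A3, u, st),
         junction = place_junction(inner, A5, A3, u, st))
}

place_loop <- function(inner, A5, A3, u, st) {
  items <- plan_run(inner$cols, st$commands$var_cols)
  eff <- eff_steps(items)
  if (eff == 0) return(invisible(NULL))
  fit <- solve_loop_radius(c(rep(st$d_nt, eff + 1), st$d_bp), 2 * pi)
  r <- fit$radius
  h <- sqrt(max(r^2 - (st$d_bp / 2)^2, 0))
  ctr <- (A5 + A3) / 2 + h * u
  th <- angle_of(A5 - ctr)
  th3 <- angle_of(A3 - ctr)
  a_bp <- step_angle(st$d_bp, r)
  a_nt <- step_angle(st$d_nt, r)
  s <- choose_sweep(th, th3, 2 * pi - a_bp)
  for (it in items) {
    if (it$kind == "nt") {
      th <- th + s * a_nt
      set_nt(st, it$col, ctr + r * unit_vec(th), th + s * pi / 2)
    } else {
      record_var_arc(st, it$cols, ctr, r, th, th + s * VAR_SWEEP_STEPS * a_nt)
      th <- th + s * VAR_SWEEP_STEPS * a_nt
    }
  }
  invisible(NULL)
}

# flank separation of one internal-loop side: its nucleotides lie on a half
# circle, so the flanks span a diameter; an empty side is a plain d_nt step.
side_diameter <- function(eff, d_nt) {
  if (eff == 0) d_nt else 2 * solve_loop_radius(rep(d_nt, eff + 1), pi)$radius
}

place_internal <- function(inner, A5, A3, u, st) {
  items5 <- plan_run(inner$side5 %||% integer(0), st$commands$var_cols)
  items3 <- plan_run(inner$side3 %||% integer(0), st$commands$var_cols)
  eff5 <- eff_steps(items5); eff3 <- eff_steps(items3)
  D5 <- side_diameter(eff5, st$d_nt)
  D3 <- side_diameter(eff3, st$d_nt)
  if (abs(D5 - D3) / 2 < 0.999 * st$d_bp) {
    place_internal_trapezoid(inner, items5, items3, eff5, eff3, D5, D3,
                             A5, A3, u, st)
  } else {
    place_internal_bubble(inner, items5, items3, eff5, eff3, A5, A3, u, st)
  }
}

# Half-circle-per-side rule: the two pair rungs are the legs of an isosceles
# trapezoid whose parallel sides are the side diameters.
place_internal_trapezoid <- function(inner, items5, items3, eff5, eff3,
                                     D5, D3, A5, A3, u, st) {
  hT <- sqrt(st$d_bp^2 - ((D5 - D3) / 2)^2)
  A5l <- c(-D5 / 2, 0); B5l <- c(D5 / 2, 0)
  A3l <- c(-D3 / 2, -hT); B3l <- c(D3 / 2, -hT)
  phi <- angle_of(A3 - A5) - angle_of(A3l - A5l)
  map <- function(p) rotate_vec(p, phi) + (A5 - rotate_vec(A5l, phi))

  place_half_side <- function(items, eff, ctr_l, rho, th_start, st) {
    if (eff == 0) return(invisible(NULL))
    a <- step_angle(st$d_nt, rho)
    th <- th_start
    for (it in items) {
      if (it$kind == "nt") {
        th <- th - a
        set_nt(st, it$col, map(ctr_l + rho * unit_vec(th)),
               th - pi / 2 + phi)
      } else {
        w_ctr <- map(ctr_l)
        record_var_arc(st, it$cols, w_ctr, rho, th + phi,
                       th - VAR_SWEEP_STEPS * a + phi)
        th <- th - VAR_SWEEP_STEPS * a
      }
    }
  }
  place_half_side(items5, eff5, c(0, 0), D5 / 2, pi, st)
  place_half_side(items3, eff3, c(0, -hT), D3 / 2, 0, st)

  B5 <- map(B5l); B3 <- map(B3l)
  u_c <- rot90(B3 - B5) / vnorm(B3 - B5)
  place_stem(inner$stem, B5, B3, u_c, st)
}

# Fallback for strongly asymmetric loops: the helix continues straight and
# each non-empty side bows out on a circle whose flank chord closes the
# remaining angle.
place_internal_bubble <- function(inner, items5, items3, eff5, eff3,
                                  A5, A3, u, st) {
  B5 <- A5 + st$d_nt * u
  B3 <- A3 + st$d_nt * u
  place_bubble_side <- function(items, eff, Fa, Fb, left, st) {
    if (eff == 0) return(invisible(NULL))
    fit <- solve_loop_radius(rep(st$d_nt, eff + 2), 2 * pi)
    rho <- fit$radius
    h2 <- sqrt(max(rho^2 - (st$d_nt / 2)^2, 0))
    side_vec <- if (left) rot90(u) else -rot90(u)
    ctr <- (Fa + Fb) / 2 + h2 * side_vec
    th <- angle_of(Fa - ctr)
    a <- step_angle(st$d_nt, rho)
    s <- choose_sweep(th, angle_of(Fb - ctr), 2 * pi - a)
    for (it in items) {
      if (it$kind == "nt") {
        th <- th + s * a
        set_nt(st, it$col, ctr + rho * unit_vec(th), th + s * pi / 2)
      } else {
        record_var_arc(st, it$cols, ctr, rho, th, th + s * VAR_SWEEP_STEPS * a)
        th <- th + s * VAR_SWEEP_STEPS * a
      }
    }
  }
  place_bubble_side(items5, eff5, A5, B5, left = TRUE, st)
  place_bubble_side(items3, eff3, B3, A3, left = FALSE, st)
  place_stem(inner$stem, B5, B3, u, st)
}

place_junction <- function(inner, A5, A3, u, st) {
  stems <- Filter(function(e) e$type == "stem", inner$elements)
  junction_cols <- unlist(lapply(inner$elements, function(e)
    if (e$type == "run") e$cols else c(e$p5[1], e$p3[1])))
  cmd <- NULL
  for (jc in st$commands$junctions)
    if (jc$col %in% junction_cols) cmd <- jc

  # segment item plans: seg 0 before the first child stem, seg i after child i
  segs <- list(); k <- 0L
  segs[[1]] <- list()
  for (e in inner$elements) {
    if (e$type == "stem") {
      k <- k + 1L
      segs[[k + 1L]] <- list()
    } else {
      segs[[k + 1L]] <- c(segs[[k + 1L]],
                          plan_run(e$cols, st$commands$var_cols))
    }
  }

  if (is.null(cmd)) {
    place_junction_circular(stems, segs, A5, A3, u, st)
  } else {
    place_junction_solved(stems, segs, cmd, A5, A3, u, st)
  }
}

place_junction_circular <- function(stems, segs, A5, A3, u, st) {
  effs <- vapply(segs, eff_steps, integer(1))
  chords <- c(st$d_bp)
  for (i in seq_along(stems))
    chords <- c(chords, rep(st$d_nt, effs[i] + 1), st$d_bp)
  chords <- c(chords, rep(st$d_nt, effs[length(segs)] + 1))
  fit <- solve_loop_radius(chords, 2 * pi)
  r <- fit$radius
  h <- sqrt(max(r^2 - (st$d_bp / 2)^2, 0))
  ctr <- (A5 + A3) / 2 + h * u
  a_bp <- step_angle(st$d_bp, r)
  a_nt <- step_angle(st$d_nt, r)
  th <- angle_of(A5 - ctr)
  s <- choose_sweep(th, angle_of(A3 - ctr), 2 * pi - a_bp)
  walk_seg <- function(items, th) {
    for (it in items) {
      if (it$kind == "nt") {
        th <- th + s * a_nt
        set_nt(st, it$col, ctr + r * unit_vec(th), th + s * pi / 2)
      } else {
        record_var_arc(st, it$cols, ctr, r, th, th + s * VAR_SWEEP_STEPS * a_nt)
        th <- th + s * VAR_SWEEP_STEPS * a_nt
      }
    }
    th
  }
  for (i in seq_along(stems)) {
    th <- walk_seg(segs[[i]], th)
    th <- th + s * a_nt
    q5 <- ctr + r * unit_vec(th)
    th <- th + s * a_bp
    q3 <- ctr + r * unit_vec(th)
    u_child <- (q5 + q3) / 2 - ctr
    u_child <- u_child / vnorm(u_child)
    place_stem(stems[[i]], q5, q3, u_child, st)
  }
  walk_seg(segs[[length(segs)]], th)
  invisible(NULL)
}

place_junction_solved <- function(stems, segs, cmd, A5, A3, u, st) {
  if (length(cmd$dirs) != length(stems))
    stop("multistem_junction dirs clause lists ", length(cmd$dirs),
         " direction(s) for ", length(stems), " stem(s)", call. = FALSE)
  # the engine walks junction interiors clockwise (A5 the long way to A3);
  # the solver's backbone order is counterclockwise, so the problem is posed
  # in a y-mirrored frame (all angles negated) and the solution reflected back
  mcmd <- cmd
  mcmd$dirs <- -cmd$dirs
  mcmd$aligns <- lapply(cmd$aligns, function(al) { al$deg <- -al$deg; al })
  mcmd$centroids <- lapply(cmd$centroids, function(ct) { ct$deg <- -ct$deg
                                                         ct })
  spec <- junction_spec(
    dirs_deg = c(-angle_of(-u) * 180 / pi, mcmd$dirs),
    seg_n = vapply(segs, function(it) sum(vapply(it, function(x)
      x$kind == "nt", logical(1))), integer(1)),
    seg_var = vapply(segs, function(it) sum(vapply(it, function(x)
      x$kind == "var", logical(1))), integer(1)),
    d_nt = st$d_nt, d_bp = st$d_bp)
  spec <- junction_spec_align(spec, mcmd, stems, st$aln)
  nlp <- junction_nlp(spec, formulation = cmd$formulation)
  sol <- solve_junction(nlp)
  st$junction_solutions[[length(st$junction_solutions) + 1L]] <- sol

  refl <- function(p) c(p[1], -p[2])
  Tr <- A5 - refl(c(sol$stems$p3x[1], sol$stems$p3y[1]))
  world <- function(p) refl(p) + Tr
  for (i in seq_along(stems)) {
    q5 <- world(c(sol$stems$p5x[i + 1], sol$stems$p5y[i + 1]))
    q3 <- world(c(sol$stems$p3x[i + 1], sol$stems$p3y[i + 1]))
    place_stem(stems[[i]], q5, q3, unit_vec(cmd$dirs[i] * pi / 180), st)
  }
  for (i in seq_along(segs)) {
    pts <- sol$segments[[i]]
    nt_idx <- 0L
    for (it in segs[[i]]) {
      if (it$kind == "nt") {
        nt_idx <- nt_idx + 1L
        p <- pts$nt[[nt_idx]]
        set_nt(st, it$col, world(p$pos), -p$dir)
      } else {
        a <- pts$var[[1]]
        record_var_arc(st, it$cols, world(a$center), a$radius, -a$theta0,
                       -a$theta1)
      }
    }
  }
  invisible(NULL)
}

# Map a stem-identifying label character to the junction stem index.
junction_spec_align <- function(spec, cmd, stems, aln) {
  if (!length(cmd$aligns) && !length(cmd$centroids)) return(spec)
  stem_of_label <- function(lab) {
    col <- resolve_label(aln, lab)
    for (i in seq_along(stems))
      if (col %in% c(stems[[i]]$p5, stems[[i]]$p3)) return(i + 1L)
    stop("align label '", lab, "' is not inside a junction stem",
         call. = FALSE)
  }
  spec$aligns <- lapply(cmd$aligns, function(al)
    list(stems = vapply(al$labels, stem_of_label, integer(1)),
         angle_deg = al$deg))
  spec$centroids <- lapply(cmd$centroids, function(ct)
    list(group = vapply(ct$group, stem_of_label, integer(1)),
         target = stem_of_label(ct$target), angle_deg = ct$deg))
  spec
}

# ---- user-facing wrapper and diagnostics ------------------------------------

#' Lay out an annotated alignment
#'
#' Convenience wrapper: matches the consensus-structure brackets, builds the
#' structure tree and runs [layout_structure()] with the alignment's layout
#' commands resolved.
#'
#' @param aln An [rna_msa] object.
#' @param params A [layout_params()] object.
#' @return An `rna_layout` object.
#' @export
layout_rna <- function(aln, params = layout_params()) {
  cmds <- resolve_layout_commands(aln)
  tree <- build_structure_tree(match_brackets(aln$ss_cons), n_columns(aln))
  layout <- layout_structure(tree, params, cmds, aln = cmds$aln)
  apply_pseudoknots(layout, cmds$aln)
}

#' Backbone spacing of a layout
#'
#' Distances between consecutive backbone positions; steps adjacent to a
#' variable-length arc are exempt from the constant-spacing invariant.
#'
#' @param layout An `rna_layout` object.
#' @return Tibble with `from`, `to`, `distance`, `exempt`.
#' @export
layout_spacing <- function(layout) {
  co <- layout$coords
  n <- nrow(co)
  if (n < 2) return(tibble::tibble(from = integer(), to = integer(),
                                   distance = numeric(), exempt = logical()))
  d <- sqrt(diff(co$x)^2 + diff(co$y)^2)
  tibble::tibble(from = co$col[-n], to = co$col[-1], distance = d,
                 exempt = co$in_var[-n] | co$in_var[-1])
}

#' Glyph overlap check
#'
#' Reports pairs of non-adjacent glyph centers closer than
#' `min_sep * d_nt` (default 0.8).
#'
#' @param layout An `rna_layout` object.
#' @param min_sep Minimum separation in units of `d_nt`.
#' @return Tibble of violations (`col_a`, `col_b`, `distance`).
#' @export
check_overlaps <- function(layout, min_sep = 0.8) {
  co <- layout$coords[!layout$coords$in_var, ]
  n <- nrow(co)
  lim <- min_sep * layout$params$d_nt
  out <- list()
  if (n >= 2) {
    dm <- as.matrix(stats::dist(cbind(co$x, co$y)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(co$col[i] - co$col[j]) <= 1) next
        if (dm[i, j] < lim - 1e-9)
          out[[length(out) + 1L]] <- tibble::tibble(
            col_a = co$col[i], col_b = co$col[j], distance = dm[i, j])
      }
    }
  }
  if (!length(out)) tibble::tibble(col_a = integer(), col_b = integer(),
                                   distance = numeric())
  else dplyr::bind_rows(out)
}

#' @export
print.rna_layout <- function(x, ...) {
  cat("<rna_layout> ", nrow(x$coords), " columns, ",
      nrow(x$var_arcs), " variable-length arc(s)\n", sep = "")
  invisible(x)
}

#' Tidy an RNA layout into its coordinate table
#' @param x An `rna_layout` object.
#' @param ... Unused.
#' @return Tibble with one row per alignment column.
#' @method tidy rna_layout
#' @export
tidy.rna_layout <- function(x, ...) x$coords

#' Layout dump as TSV (column, x, y, direction)
#' @param layout An `rna_layout` object.
#' @param path Output file path.
#' @return Invisibly the tibble written.
#' @export
export_layout_tsv <- function(layout, path) {
  tab <- layout$coords[, c("col", "x", "y", "dir")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
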