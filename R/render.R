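# Rendering: layout + annotation -> renderer-neutral drawing primitives ->
# SVG. Internal coordinates are y-up; the y axis is flipped at emission.

#' Style map
#'
#' Colors and glyph styles used by [compose()]. Identity-tier letters use
#' three colors (75/90/97), presence-only columns four ring styles
#' (50/75/90/97), pair shading three fills (covarying/compatible/invariant);
#' unshaded pairs get no shade primitive. All entries can be overridden by a
#' JSON file holding a subset of the same fields.
#'
#' @param json Optional path to a JSON file with overrides.
#' @param skeleton Draw only the backbone path (no glyphs, rungs or shades).
#' @param scale Points per internal unit in the SVG output (default 10).
#' @return List of class `style_map`.
#' @export
style_map <- function(json = NULL, skeleton = FALSE, scale = 10) {
  sm <- list(
    identity_colors = c("75" = "#777777", "90" = "#000000",
                        "97" = "#c00000"),
    presence_rings = list(
      "50" = list(stroke = "#bbbbbb", fill = "none", dashed = TRUE),
      "75" = list(stroke = "#777777", fill = "none", dashed = FALSE),
      "90" = list(stroke = "#000000", fill = "none", dashed = FALSE),
      "97" = list(stroke = "#000000", fill = "#e0e0e0", dashed = FALSE)),
    pair_shades = c(covarying = "#2e9f4e", compatible = "#8fd5e8",
                    invariant = "#d9d9d9"),
    skeleton = isTRUE(skeleton),
    modular_label_format = "%s",
    font_family = "Helvetica",
    scale = scale)
  if (!is.null(json)) {
    ov <- jsonlite::read_json(json, simplifyVector = TRUE)
    for (nm in intersect(names(ov), names(sm))) {
      if (is.list(sm[[nm]]) && is.list(ov[[nm]])) {
        sm[[nm]] <- utils::modifyList(sm[[nm]], ov[[nm]])
      } else if (is.character(sm[[nm]]) && !is.null(names(sm[[nm]]))) {
        v <- unlist(ov[[nm]])
        sm[[nm]][names(v)] <- v
      } else {
        sm[[nm]] <- ov[[nm]]
      }
    }
  }
  structure(sm, class = "style_map")
}

#' Compose a drawing from a layout and an annotation
#'
#' Emits an ordered list of drawing primitives: one glyph per shown column
#' (a letter for specific/R/Y calls, a ring for presence-only tiers, nothing
#' for absent columns), the backbone, one rung plus an optional covariation
#' shade per consensus pair, dashed variable-length arcs with their
#' `"m-M nt"` labels, in-line pseudoknot rungs, pseudoknot callout
#' sub-panels with a connector labelled `"pseudoknot"`, modular-structure
#' sub-panels labelled with their percent frequency, and `shade` command
#' backgrounds. With the skeleton flag only the backbone paths are drawn.
#'
#' @param layout An `rna_layout` (optionally with pseudoknots applied).
#' @param annotation The matching [annotate_consensus()] result.
#' @param style A [style_map()].
#' @param aln The [rna_msa]; required for `shade`, `modular` and
#'   `var_hairpin` commands, otherwise optional.
#' @return Object of class `rna_drawing`: `primitives` (ordered list),
#'   `style`, `scale`.
#' @export
compose <- function(layout, annotation, style = style_map(), aln = NULL) {
  co <- layout$coords
  cols <- annotation$columns
  if (!setequal(co$col, cols$col))
    stop("annotation/layout column mismatch: layout has ", nrow(co),
         " columns, annotation ", nrow(cols), call. = FALSE)
  d_nt <- layout$params$d_nt
  e <- new.env(parent = emptyenv())
  e$prims <- list()
  add <- function(p) e$prims[[length(e$prims) + 1L]] <- p

  crow <- function(col) cols[match(col, cols$col), ]
  pos <- function(col) { i <- match(col, co$col); c(co$x[i], co$y[i]) }
  shown <- !co$in_var &
    cols$symbol[match(co$col, cols$col)] != "absent" & !is.na(co$x)

  if (style$skeleton) {
    emit_backbone_paths(co, add)
    emit_var_arcs(layout, add, labels = FALSE)
    return(finish_drawing(e$prims, style))
  }

  # z-order: command shades, pair shades, backbone, rungs, arcs, connectors,
  # glyphs, texts
  if (!is.null(aln)) emit_shade_commands(aln, co, d_nt, add)

  pair_of_line <- split(seq_len(nrow(annotation$pairs)),
                        annotation$pairs$line)
  main_pairs <- annotation$pairs[pair_of_line[["SS_cons"]] %||% integer(0), ]
  for (z in seq_len(nrow(main_pairs)))
    emit_pair(main_pairs[z, ], pos, style, add, panel = NA_character_)

  # in-line pseudoknot rungs, classes joined from the annotation
  for (pkset in layout$pk %||% list()) {
    pk_rows <- annotation$pairs[annotation$pairs$line ==
                                  paste0("pk", pkset$name), ]
    for (z in seq_len(nrow(pk_rows)))
      emit_pair(pk_rows[z, ], pos, style, add, panel = NA_character_,
                dashed = TRUE)
  }

  emit_backbone_segments(co, add)
  emit_var_arcs(layout, add, labels = TRUE, d_nt = d_nt)

  for (i in which(shown)) {
    cr <- crow(co$col[i])
    emit_glyph(cr, c(co$x[i], co$y[i]), style, add, panel = NA_character_)
  }

  for (panel in layout$panels %||% list())
    emit_pk_panel(panel, annotation, style, d_nt, add)

  if (!is.null(aln)) emit_modular_panels(aln, annotation, layout, style, add)

  finish_drawing(e$prims, style)
}

finish_drawing <- function(prims, style) {
  structure(list(primitives = prims, style = style, scale = style$scale),
            class = "rna_drawing")
}

emit_glyph <- function(cr, p, style, add, panel) {
  if (cr$symbol %in% c("A", "C", "G", "U", "R", "Y")) {
    add(list(type = "glyph", kind = "letter", x = p[1], y = p[2],
             text = cr$symbol,
             color = unname(style$identity_colors[as.character(
               cr$identity_tier)]),
             panel = panel))
  } else if (cr$symbol == "presence") {
    ring <- style$presence_rings[[as.character(cr$presence_tier)]]
    add(list(type = "glyph", kind = "ring", x = p[1], y = p[2],
             stroke = ring$stroke, fill = ring$fill,
             dashed = isTRUE(ring$dashed), panel = panel))
  }
}

emit_pair <- function(pr, pos, style, add, panel, dashed = FALSE) {
  a <- pos(pr$left); b <- pos(pr$right)
  if (anyNA(c(a, b))) return(invisible(NULL))
  if (pr$class != "unshaded")
    add(list(type = "shade", x1 = a[1], y1 = a[2], x2 = b[1], y2 = b[2],
             color = unname(style$pair_shades[pr$class]), panel = panel))
  add(list(type = "line", class = "rung", x1 = a[1], y1 = a[2],
           x2 = b[1], y2 = b[2], dashed = dashed, panel = panel))
}

backbone_runs <- function(co) {
  ok <- !co$in_var & !is.na(co$x)
  runs <- list(); cur <- integer(0)
  for (i in seq_len(nrow(co))) {
    if (ok[i]) cur <- c(cur, i)
    else { if (length(cur) > 1) runs[[length(runs) + 1L]] <- cur
           cur <- integer(0) }
  }
  if (length(cur) > 1) runs[[length(runs) + 1L]] <- cur
  runs
}

emit_backbone_paths <- function(co, add) {
  for (run in backbone_runs(co))
    add(list(type = "path", x = co$x[run], y = co$y[run],
             panel = NA_character_))
}

emit_backbone_segments <- function(co, add) {
  for (run in backbone_runs(co))
    for (k in seq_len(length(run) - 1)) {
      i <- run[k]; j <- run[k + 1]
      add(list(type = "line", class = "backbone",
               x1 = co$x[i], y1 = co$y[i], x2 = co$x[j], y2 = co$y[j],
               dashed = FALSE, panel = NA_character_))
    }
}

emit_var_arcs <- function(layout, add, labels = TRUE, d_nt = 1) {
  va <- layout$var_arcs
  for (i in seq_len(nrow(va))) {
    add(list(type = "arc", cx = va$cx[i], cy = va$cy[i], r = va$r[i],
             theta0 = va$theta0[i], theta1 = va$theta1[i], dashed = TRUE,
             panel = NA_character_))
    if (labels) {
      mid <- (va$theta0[i] + va$theta1[i]) / 2
      p <- c(va$cx[i], va$cy[i]) + (va$r[i] + 0.9 * d_nt) * unit_vec(mid)
      add(list(type = "text", x = p[1], y = p[2], text = va$label[i],
               size = 0.7, panel = NA_character_))
    }
  }
}

emit_shade_commands <- function(aln, co, d_nt, add) {
  for (args in commands_of(aln, "shade")) {
    rng <- label_range(aln, args[1], args[2])
    for (col in rng[1]:rng[2]) {
      i <- match(col, co$col)
      if (is.na(i) || co$in_var[i] || is.na(co$x[i])) next
      add(list(type = "shade_bg", x = co$x[i], y = co$y[i],
               r = 0.55 * d_nt, color = args[3], panel = NA_character_))
    }
  }
}

emit_pk_panel <- function(panel, annotation, style, d_nt, add) {
  pc <- panel$coords
  ppos <- function(col, strand) {
    i <- which(pc$col == col & pc$strand == strand)
    c(pc$x[i], pc$y[i])
  }
  pk_rows <- annotation$pairs[annotation$pairs$line ==
                                paste0("pk", panel$name), ]
  for (z in seq_len(nrow(pk_rows))) {
    a <- ppos(pk_rows$left[z], "p5"); b <- ppos(pk_rows$right[z], "p3")
    if (pk_rows$class[z] != "unshaded")
      add(list(type = "shade", x1 = a[1], y1 = a[2], x2 = b[1], y2 = b[2],
               color = unname(style$pair_shades[pk_rows$class[z]]),
               panel = panel$name))
    add(list(type = "line", class = "rung", x1 = a[1], y1 = a[2],
             x2 = b[1], y2 = b[2], dashed = FALSE, panel = panel$name))
  }
  for (i in seq_len(nrow(pc))) {
    cr <- annotation$columns[match(pc$col[i], annotation$columns$col), ]
    emit_glyph(cr, c(pc$x[i], pc$y[i]), style, add, panel = panel$name)
  }
  cn <- panel$connector
  add(list(type = "line", class = "connector", x1 = cn$from[1],
           y1 = cn$from[2], x2 = cn$to[1], y2 = cn$to[2], dashed = TRUE,
           panel = panel$name))
  mid <- (cn$from + cn$to) / 2
  add(list(type = "text", x = mid[1], y = mid[2] + 0.6 * d_nt,
           text = cn$label, size = 0.7, panel = panel$name))
}

# Modular structures and optional (var_hairpin) hairpins as sub-panels: the
# element's columns redrawn below the main drawing, labelled with the
# weighted occurrence frequency.
emit_modular_panels <- function(aln, annotation, layout, style, add) {
  co <- layout$coords
  d_nt <- layout$params$d_nt
  specs <- list()
  for (args in commands_of(aln, "modular")) {
    if (length(args) < 5 || args[4] != "predicate")
      stop("modular command must be: modular <name> <label1> <label2> ",
           "predicate <expr>", call. = FALSE)
    rng <- label_range(aln, args[2], args[3])
    f <- modular_frequency(aln, annotation$weights,
                           paste(args[-(1:4)], collapse = " "))
    specs[[length(specs) + 1L]] <- list(name = args[1],
                                        cols = rng[1]:rng[2], freq = f)
  }
  for (args in commands_of(aln, "var_hairpin")) {
    if (length(args) < 3 || args[2] != "predicate")
      stop("var_hairpin command must be: var_hairpin <label> predicate ",
           "<expr>", call. = FALSE)
    rng <- hairpin_span(aln, resolve_label(aln, args[1]))
    f <- modular_frequency(aln, annotation$weights,
                           paste(args[-(1:2)], collapse = " "))
    specs[[length(specs) + 1L]] <- list(name = paste0("hairpin_", args[1]),
                                        cols = rng[1]:rng[2], freq = f)
  }
  if (!length(specs)) return(invisible(NULL))

  y_base <- min(co$y, na.rm = TRUE) - 4 * d_nt
  x_at <- min(co$x, na.rm = TRUE)
  prs <- annotation$pairs[annotation$pairs$line == "SS_cons", ]
  for (spm in specs) {
    sel <- match(spm$cols, co$col)
    sel <- sel[!is.na(sel) & !is.na(co$x[sel])]
    if (!length(sel)) next
    dx <- x_at - min(co$x[sel]); dy <- y_base - max(co$y[sel])
    ppos <- function(col) {
      i <- match(col, co$col)
      c(co$x[i] + dx, co$y[i] + dy)
    }
    inside <- prs$left %in% spm$cols & prs$right %in% spm$cols
    for (z in which(inside)) {
      a <- ppos(prs$left[z]); b <- ppos(prs$right[z])
      if (prs$class[z] != "unshaded")
        add(list(type = "shade", x1 = a[1], y1 = a[2], x2 = b[1], y2 = b[2],
                 color = unname(style$pair_shades[prs$class[z]]),
                 panel = spm$name))
      add(list(type = "line", class = "rung", x1 = a[1], y1 = a[2],
               x2 = b[1], y2 = b[2], dashed = FALSE, panel = spm$name))
    }
    for (i in sel) {
      cr <- annotation$columns[match(co$col[i], annotation$columns$col), ]
      emit_glyph(cr, c(co$x[i] + dx, co$y[i] + dy), style, add,
                 panel = spm$name)
    }
    lab <- sprintf(style$modular_label_format, attr(spm$freq, "label"))
    add(list(type = "text",
             x = mean(co$x[sel]) + dx,
             y = min(co$y[sel]) + dy - 1.2 * d_nt,
             text = lab, size = 0.8, panel = spm$name))
    x_at <- x_at + (max(co$x[sel]) - min(co$x[sel])) + 5 * d_nt
  }
}

# Column span of the hairpin stem enclosing a column: the minimal enclosing
# pair widened outward over stacked pairs.
hairpin_span <- function(aln, col) {
  prs <- match_brackets(aln$ss_cons)
  enc <- prs[prs$left <= col & prs$right >= col, ]
  if (!nrow(enc))
    stop("var_hairpin label column ", col, " is not inside a stem",
         call. = FALSE)
  i <- which.min(enc$right - enc$left)
  l <- enc$left[i]; r <- enc$right[i]
  has_pair <- function(a, b) any(prs$left == a & prs$right == b)
  while (has_pair(l - 1L, r + 1L)) { l <- l - 1L; r <- r + 1L }
  c(l, r)
}

#' @export
print.rna_drawing <- function(x, ...) {
  tab <- table(vapply(x$primitives, `[[`, character(1), "type"))
  cat("<rna_drawing> ", length(x$primitives), " primitives (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# ---- SVG serialization ------------------------------------------------------

fmt_num <- function(v) formatC(v, format = "f", digits = 4)

# bounding box over all primitive coordinates (internal units)
drawing_bbox <- function(drawing) {
  xs <- numeric(0); ys <- numeric(0)
  for (p in drawing$primitives) {
    switch(p$type,
           glyph = , shade_bg = , text = { xs <- c(xs, p$x); ys <- c(ys, p$y) },
           line = , shade = { xs <- c(xs, p$x1, p$x2); ys <- c(ys, p$y1, p$y2) },
           path = { xs <- c(xs, p$x); ys <- c(ys, p$y) },
           arc = { xs <- c(xs, p$cx - p$r, p$cx + p$r)
                   ys <- c(ys, p$cy - p$r, p$cy + p$r) })
  }
  if (!length(xs)) xs <- ys <- 0
  list(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

#' Serialize a drawing to SVG
#'
#' Produces well-formed SVG 1.1 with a single root group; the y axis is
#' flipped from the internal y-up convention at emission, the viewBox is
#' fitted to the content with a 2-unit margin, and text is anchored at the
#' glyph centers. Output is deterministic (fixed 4-decimal formatting).
#'
#' @param drawing An `rna_drawing` from [compose()].
#' @return SVG document text (single string).
#' @export
to_svg <- function(drawing) {
  S <- drawing$scale
  bb <- drawing_bbox(drawing)
  tx <- function(x) (x - bb$xmin + 2) * S
  ty <- function(y) (bb$ymax - y + 2) * S
  W <- (bb$xmax - bb$xmin + 4) * S
  H <- (bb$ymax - bb$ymin + 4) * S
  font <- drawing$style$font_family

  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    viewBox = paste(0, 0, fmt_num(W), fmt_num(H)),
    width = fmt_num(W), height = fmt_num(H))
  g <- xml2::xml_add_child(doc, "g")

  lw <- function(f) fmt_num(f * S)
  for (p in drawing$primitives) {
    switch(
      p$type,
      shade_bg = xml2::xml_add_child(
        g, "circle", cx = fmt_num(tx(p$x)), cy = fmt_num(ty(p$y)),
        r = fmt_num(p$r * S), fill = p$color, "fill-opacity" = "0.45"),
      shade = xml2::xml_add_child(
        g, "line", x1 = fmt_num(tx(p$x1)), y1 = fmt_num(ty(p$y1)),
        x2 = fmt_num(tx(p$x2)), y2 = fmt_num(ty(p$y2)),
        stroke = p$color, "stroke-width" = lw(0.55),
        "stroke-linecap" = "round", "stroke-opacity" = "0.8"),
      line = {
        nd <- xml2::xml_add_child(
          g, "line", x1 = fmt_num(tx(p$x1)), y1 = fmt_num(ty(p$y1)),
          x2 = fmt_num(tx(p$x2)), y2 = fmt_num(ty(p$y2)),
          stroke = "#000000",
          "stroke-width" = lw(if (identical(p$class, "backbone")) 0.07
                              else 0.05))
        if (isTRUE(p$dashed))
          xml2::xml_set_attr(nd, "stroke-dasharray",
                             paste0(lw(0.2), ",", lw(0.15)))
      },
      path = xml2::xml_add_child(
        g, "path",
        d = paste0("M ", paste(fmt_num(tx(p$x)), fmt_num(ty(p$y)),
                               sep = ",", collapse = " L "),
                   collapse = ""),
        fill = "none", stroke = "#000000", "stroke-width" = lw(0.1),
        "stroke-linejoin" = "round"),
      arc = {
        a0 <- c(p$cx + p$r * cos(p$theta0), p$cy + p$r * sin(p$theta0))
        a1 <- c(p$cx + p$r * cos(p$theta1), p$cy + p$r * sin(p$theta1))
        delta <- p$theta1 - p$theta0
        large <- if (abs(delta) > pi) 1 else 0
        sweep <- if (delta > 0) 0 else 1   # y-flip reverses orientation
        nd <- xml2::xml_add_child(
          g, "path",
          d = paste("M", fmt_num(tx(a0[1])), fmt_num(ty(a0[2])),
                    "A", fmt_num(p$r * S), fmt_num(p$r * S), 0, large,
                    sweep, fmt_num(tx(a1[1])), fmt_num(ty(a1[2]))),
          fill = "none", stroke = "#000000", "stroke-width" = lw(0.05))
        if (isTRUE(p$dashed))
          xml2::xml_set_attr(nd, "stroke-dasharray",
                             paste0(lw(0.2), ",", lw(0.15)))
      },
      glyph = if (p$kind == "letter") {
        nd <- xml2::xml_add_child(
          g, "text", x = fmt_num(tx(p$x)), y = fmt_num(ty(p$y)),
          "text-anchor" = "middle", "dominant-baseline" = "central",
          "font-family" = font, "font-size" = fmt_num(0.9 * S),
          fill = p$color %||% "#000000")
        xml2::xml_set_text(nd, p$text)
      } else {
        nd <- xml2::xml_add_child(
          g, "circle", cx = fmt_num(tx(p$x)), cy = fmt_num(ty(p$y)),
          r = fmt_num(0.32 * S), stroke = p$stroke, fill = p$fill,
          "stroke-width" = lw(0.06))
        if (isTRUE(p$dashed))
          xml2::xml_set_attr(nd, "stroke-dasharray",
                             paste0(lw(0.12), ",", lw(0.1)))
      },
      text = {
        nd <- xml2::xml_add_child(
          g, "text", x = fmt_num(tx(p$x)), y = fmt_num(ty(p$y)),
          "text-anchor" = "middle", "dominant-baseline" = "central",
          "font-family" = font,
          "font-size" = fmt_num((p$size %||% 0.7) * S), fill = "#000000")
        xml2::xml_set_text(nd, p$text)
      })
  }
  as.character(doc)
}

#' Write a drawing to an SVG file
#'
#' @param drawing An `rna_drawing`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_svg <- function(drawing, path) {
  writeLines(to_svg(drawing), path)
  invisible(path)
}

#' Plot a layout with ggplot2
#'
#' Quick diagnostic plot of the backbone and pair rungs; requires ggplot2
#' (suggested, not imported).
#'
#' @param object An `rna_layout`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rna_layout <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot", call. = FALSE)
  co <- object$coords[!object$coords$in_var & !is.na(object$coords$x), ]
  ggplot2::ggplot(co, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
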