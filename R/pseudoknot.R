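# Pseudoknot drawing styles. Pseudoknot pairs cross the nested consensus
# structure, so they are carried on separate bracket lines and added to a
# finished layout either in-line (pair rungs drawn directly between the
# already-placed nucleotides) or as a callout (a separate duplex sub-panel
# joined to the main drawing by a connector labelled "pseudoknot").

#' Add pseudoknot pairs to a layout
#'
#' In-line style draws the pseudoknot pair rungs directly between the main
#' layout's nucleotide positions, without moving them; it is feasible only
#' when every rung stays clear of the other glyphs (pairwise overlap check:
#' no non-endpoint glyph center within `0.4 * d_nt` of a rung segment).
#' Callout style copies the pseudoknot duplex into a small sub-panel placed
#' beside the drawing and records a connector line labelled "pseudoknot".
#'
#' @param layout An `rna_layout`.
#' @param pk_pairs Tibble with 0-based `left`/`right` columns, e.g. from
#'   [match_brackets()] on a `SS_cons_pk` line. Zero rows is a no-op.
#' @param style `"inline"` or `"callout"`.
#' @param name Pseudoknot name (used in messages and panel labels).
#' @return The layout with either `pk` rungs or a callout panel appended.
#' @export
layout_pseudoknot <- function(layout, pk_pairs, style = c("inline", "callout"),
                              name = "pk") {
  style <- match.arg(style)
  if (is.null(pk_pairs) || nrow(pk_pairs) == 0) return(layout)
  co <- layout$coords
  missing_cols <- setdiff(c(pk_pairs$left, pk_pairs$right), co$col)
  if (length(missing_cols))
    stop("pseudoknot '", name, "' references unplaced column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (style == "inline") {
    layout_pk_inline(layout, pk_pairs, name)
  } else {
    layout_pk_callout(layout, pk_pairs, name)
  }
}

pk_point <- function(co, col) {
  i <- match(col, co$col)
  c(co$x[i], co$y[i])
}

layout_pk_inline <- function(layout, pk_pairs, name) {
  co <- layout$coords[!layout$coords$in_var, ]
  lim <- 0.4 * layout$params$d_nt
  for (z in seq_len(nrow(pk_pairs))) {
    a <- pk_point(co, pk_pairs$left[z])
    b <- pk_point(co, pk_pairs$right[z])
    others <- co[!co$col %in% c(pk_pairs$left[z], pk_pairs$right[z]), ]
    dmin <- Inf
    for (i in seq_len(nrow(others))) {
      d <- point_segment_distance(c(others$x[i], others$y[i]), a, b)
      if (d < dmin) dmin <- d
    }
    if (dmin < lim)
      stop("pseudoknot '", name, "' cannot be drawn in-line: the rung for ",
           "columns ", pk_pairs$left[z], "-", pk_pairs$right[z], " passes ",
           signif(dmin, 3), " units from another nucleotide (< ",
           signif(lim, 3), "); use the callout style (command: pk ", name,
           " style callout)", call. = FALSE)
  }
  layout$pk <- c(layout$pk %||% list(),
                 list(list(name = name, style = "inline",
                           pairs = pk_pairs)))
  layout
}

layout_pk_callout <- function(layout, pk_pairs, name) {
  co <- layout$coords
  d_nt <- layout$params$d_nt
  d_bp <- layout$params$d_bp
  pk_pairs <- pk_pairs[order(pk_pairs$left), ]
  L <- nrow(pk_pairs)

  # duplex ladder, local frame: 5' strand along +x at y = 0, partners below
  local5 <- cbind(x = (seq_len(L) - 1) * d_nt, y = rep(0, L))
  local3 <- cbind(x = (seq_len(L) - 1) * d_nt, y = rep(-d_bp, L))

  # panel to the right of the current drawing, vertically centered on the
  # pseudoknot's 5' columns
  margin <- 4 * d_nt
  x0 <- max(co$x) + margin
  y0 <- mean(co$y[match(pk_pairs$left, co$col)])
  panel_coords <- tibble::tibble(
    col = c(pk_pairs$left, pk_pairs$right),
    strand = rep(c("p5", "p3"), each = L),
    x = x0 + c(local5[, "x"], local3[, "x"]),
    y = y0 + c(local5[, "y"], local3[, "y"]))

  anchor_main <- c(mean(co$x[match(pk_pairs$left, co$col)]),
                   mean(co$y[match(pk_pairs$left, co$col)]))
  anchor_panel <- c(x0 - 0.5 * d_nt, y0 - d_bp / 2)
  panel <- list(kind = "pk", name = name, pairs = pk_pairs,
                coords = panel_coords,
                connector = list(from = anchor_main, to = anchor_panel,
                                 label = "pseudoknot"))
  layout$panels <- c(layout$panels %||% list(), list(panel))
  layout
}

#' Resolve and apply all pseudoknot lines of an alignment
#'
#' Matches every `SS_cons_pk<NAME>` bracket line, looks up a
#' `pk <name> style inline|callout` command (default in-line) and applies
#' [layout_pseudoknot()] for each.
#'
#' @param layout An `rna_layout`.
#' @param aln The [rna_msa] the layout came from.
#' @return The augmented layout.
#' @export
apply_pseudoknots <- function(layout, aln) {
  if (!length(aln$pk_lines)) return(layout)
  styles <- list()
  for (args in commands_of(aln, "pk")) {
    if (length(args) < 3 || args[2] != "style" ||
        !args[3] %in% c("inline", "callout"))
      stop("pk command must be: pk <name> style inline|callout",
           call. = FALSE)
    styles[[args[1]]] <- args[3]
  }
  for (nm in names(aln$pk_lines)) {
    pairs <- match_brackets(aln$pk_lines[[nm]])
    layout <- layout_pseudoknot(layout, pairs,
                                style = styles[[nm]] %||% "inline",
                                name = nm)
  }
  layout
}
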