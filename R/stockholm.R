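#' Match bracket pairs in an aligned structure line
#'
#' Stack-based innermost-first matching of `<`/`>` brackets. All non-bracket
#' characters are treated as unpaired.
#'
#' @param bracket_line Aligned structure string.
#' @return A tibble with integer columns `left` and `right` (0-based column
#'   indices, `left < right`), sorted by `left`. Pairs from one line are
#'   properly nested.
#' @examples
#' match_brackets("<<..>>")
#' @export
match_brackets <- function(bracket_line) {
  chars <- strsplit(bracket_line, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  left <- integer(0); right <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "<") {
      stack <- c(stack, i - 1L)
    } else if (chars[i] == ">") {
      if (!length(stack))
        stop("unbalanced brackets: '>' with no open '<' at column ", i - 1L,
             call. = FALSE)
      left <- c(left, stack[length(stack)])
      right <- c(right, i - 1L)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("unbalanced brackets: unclosed '<' at column ", stack[length(stack)],
         call. = FALSE)
  out <- tibble::tibble(left = left, right = right)
  out[order(out$left), ]
}

# Inverse of match_brackets over a line of given width.
pairs_to_brackets <- function(pairs, n) {
  chars <- rep(".", n)
  chars[pairs$left + 1L] <- "<"
  chars[pairs$right + 1L] <- ">"
  paste(chars, collapse = "")
}

#' Parse a Stockholm alignment with structure and layout annotation
#'
#' Reads Stockholm 1.0 text carrying at least one sequence row and a
#' `#=GC SS_cons` consensus-structure line. Also recognized:
#' `#=GC R2R_LABEL` (one-character column labels), `#=GC SS_cons_pk<NAME>`
#' (independently nested pseudoknot bracket lines), `#=GF R2R <verb> ...`
#' layout commands, and `#=GS <seq> R2R <verb> ...` per-sequence commands.
#' Interleaved (wrapped) blocks are concatenated on read. Unknown `#=GF`
#' tags are preserved verbatim and reported with a warning.
#'
#' @param text Stockholm document as a single string or character vector of
#'   lines; alternatively a file path (a single string naming an existing
#'   file).
#' @return An [rna_msa] object.
#' @examples
#' doc <- c("# STOCKHOLM 1.0",
#'          "seq1 GGGAAACCC",
#'          "#=GC SS_cons <<<...>>>",
#'          "//")
#' parse_stockholm(doc)
#' @export
parse_stockholm <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*$", lines)]
  lines <- lines[!grepl("^# STOCKHOLM", lines)]
  lines <- lines[lines != "//"]

  seq_names <- character(); seqs <- list()
  gc <- list(); gf_cmd <- list(); gs_cmd <- list(); other_gf <- character()

  for (ln in lines) {
    if (grepl("^#=GC\\s", ln)) {
      tok <- strsplit(sub("^#=GC\\s+", "", ln), "\\s+")[[1]]
      if (length(tok) < 2) stop("malformed #=GC line: ", ln, call. = FALSE)
      tag <- tok[1]
      gc[[tag]] <- paste0(gc[[tag]] %||% "", tok[2])
    } else if (grepl("^#=GF\\s+R2R\\s", ln)) {
      gf_cmd[[length(gf_cmd) + 1L]] <- strsplit(
        sub("^#=GF\\s+R2R\\s+", "", ln), "\\s+")[[1]]
    } else if (grepl("^#=GF\\s", ln)) {
      tag <- strsplit(ln, "\\s+")[[1]][2]
      warning("ignoring unknown #=GF tag '", tag, "'", call. = FALSE)
      other_gf <- c(other_gf, ln)
    } else if (grepl("^#=GS\\s", ln)) {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) >= 4 && tok[3] == "R2R") {
        gs_cmd[[length(gs_cmd) + 1L]] <- list(seq = tok[2], tok = tok[-(1:3)])
      } else {
        warning("ignoring #=GS line: ", ln, call. = FALSE)
      }
    } else if (grepl("^#", ln)) {
      # plain comment; skip
    } else {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(tok) != 2)
        stop("malformed sequence line: ", ln, call. = FALSE)
      seqs[[tok[1]]] <- paste0(seqs[[tok[1]]] %||% "", tok[2])
      if (!tok[1] %in% seq_names) seq_names <- c(seq_names, tok[1])
    }
  }

  if (is.null(gc[["SS_cons"]]))
    stop("no consensus structure (missing #=GC SS_cons line)", call. = FALSE)
  if (!length(seq_names))
    stop("no sequence rows found", call. = FALSE)

  labels <- integer()
  if (!is.null(gc[["R2R_LABEL"]])) {
    lab_chars <- strsplit(gc[["R2R_LABEL"]], "", fixed = TRUE)[[1]]
    keep <- !(lab_chars %in% c(".", "-"))
    labels <- stats::setNames(which(keep) - 1L, lab_chars[keep])
    if (anyDuplicated(names(labels)))
      stop("duplicate label character '",
           names(labels)[duplicated(names(labels))][1], "'", call. = FALSE)
  }

  pk_tags <- grep("^SS_cons_pk", names(gc), value = TRUE)
  pk_lines <- stats::setNames(unlist(gc[pk_tags], use.names = FALSE) %||%
                                character(),
                              sub("^SS_cons_pk", "", pk_tags))

  cmds <- empty_commands()
  for (tok in gf_cmd)
    cmds <- rbind(cmds, parse_command(tok, scope = "file", seq = NA_character_))
  for (g in gs_cmd)
    cmds <- rbind(cmds, parse_command(g$tok, scope = "seq", seq = g$seq))

  rna_msa(seq_names = seq_names,
          rows = unlist(seqs[seq_names], use.names = FALSE),
          ss_cons = gc[["SS_cons"]],
          labels = labels, pk_lines = pk_lines, commands = cmds,
          other_gf = other_gf)
}

#' Write an annotated alignment as a Stockholm document
#'
#' The output round-trips through [parse_stockholm()] to an equal value.
#' Wrapped input blocks are normalized: output is always single-block.
#'
#' @param aln An [rna_msa] object.
#' @param path Optional file path; when `NULL` the document is returned as a
#'   character vector of lines.
#' @return Invisibly (or visibly when `path` is `NULL`) the document lines.
#' @export
write_stockholm <- function(aln, path = NULL) {
  n <- n_columns(aln)
  gc_tags <- c("SS_cons",
               if (length(aln$labels)) "R2R_LABEL",
               paste0("SS_cons_pk", names(aln$pk_lines)))
  width <- max(nchar(aln$seq_names), nchar(paste("#=GC", gc_tags)))
  pad <- function(s) formatC(s, width = -width)

  out <- "# STOCKHOLM 1.0"
  for (i in seq_len(nrow(aln$commands))) {
    cm <- aln$commands[i, ]
    args <- paste(cm$args[[1]], collapse = " ")
    if (cm$scope == "file") {
      out <- c(out, trimws(paste("#=GF R2R", cm$verb, args)))
    } else {
      out <- c(out, trimws(paste("#=GS", cm$seq, "R2R", cm$verb, args)))
    }
  }
  out <- c(out, aln$other_gf)
  out <- c(out, paste(pad(aln$seq_names), aln$rows))
  out <- c(out, paste(pad("#=GC SS_cons"), aln$ss_cons))
  if (length(aln$labels)) {
    lab <- rep(".", n)
    lab[aln$labels + 1L] <- names(aln$labels)
    out <- c(out, paste(pad("#=GC R2R_LABEL"), paste(lab, collapse = "")))
  }
  for (nm in names(aln$pk_lines))
    out <- c(out, paste(pad(paste0("#=GC SS_cons_pk", nm)), aln$pk_lines[[nm]]))
  out <- c(out, "//")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
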