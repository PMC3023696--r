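# Layout-command grammar.
#
# One command per `#=GF R2R` line, whitespace-tokenized. Supported verbs
# (a documented compatible subset of the original markup language):
#
#   label <char> <col1based>
#   multistem_junction <label> dirs <deg,deg,...> [align <labels> <deg>]
#       [align_centroid <labels>:<label> <deg>] [formulation 1|2|3]
#   var_backbone_range <label1> <label2>
#   var_hairpin <label> predicate <expr>
#   modular <name> <label1> <label2> predicate <expr>
#   pk <name> style inline|callout
#   skeleton on
#   turn <label> <deg>
#   thresholds <t50> <t75> <t90> <t97>
#   shade <label1> <label2> <color>
#
# Label references are single characters resolved against the R2R_LABEL line.
# Predicates are sequence-name regular expressions or Boolean combinations of
# per-column content tests (see parse_predicate()).

command_verbs <- c("label", "multistem_junction", "var_backbone_range",
                   "var_hairpin", "modular", "pk", "skeleton", "turn",
                   "thresholds", "shade")

parse_command <- function(tokens, scope = "file", seq = NA_character_) {
  verb <- tokens[1]
  if (!verb %in% command_verbs)
    stop("unknown layout command verb '", verb, "'", call. = FALSE)
  tibble::tibble(scope = scope, seq = seq, verb = verb,
                 args = list(tokens[-1]))
}

# Resolve a single-character label to a 0-based column index.
resolve_label <- function(aln, label) {
  if (!label %in% names(aln$labels))
    stop("unknown column label '", label, "'", call. = FALSE)
  unname(aln$labels[[label]])
}

# 0-based inclusive column range between two labels.
label_range <- function(aln, l1, l2) {
  a <- resolve_label(aln, l1); b <- resolve_label(aln, l2)
  sort(c(a, b))
}

#' Parse a row predicate
#'
#' Predicates select alignment rows for modular structures and optional
#' hairpins. The expression language is a restricted subset of R syntax
#' supporting `&`, `|`, `!`, parentheses, string comparison with `==`/`!=`,
#' and three primitives:
#'
#' * `name_matches("regex")` — `TRUE` when the sequence identifier matches,
#' * `col("x")` — the row's character at the column labelled `x`,
#' * `present("a", "b")` — `TRUE` when the row has any non-gap character in
#'   the label range `a..b`.
#'
#' @param expr Predicate source text.
#' @return A function `f(aln, row_index)` returning a logical scalar.
#' @examples
#' p <- parse_predicate('present("1", "2") & col("T") == "G"')
#' @export
parse_predicate <- function(expr) {
  lang <- tryCatch(str2lang(expr),
                   error = function(e) stop("cannot parse predicate: ", expr,
                                            call. = FALSE))
  check_predicate_lang(lang)
  function(aln, i) {
    env <- new.env(parent = baseenv())
    env$name_matches <- function(re) grepl(re, aln$seq_names[i])
    env$col <- function(label) {
      j <- resolve_label(aln, label)
      substr(aln$rows[i], j + 1L, j + 1L)
    }
    env$present <- function(l1, l2) {
      rng <- label_range(aln, l1, l2)
      seg <- substr(aln$rows[i], rng[1] + 1L, rng[2] + 1L)
      grepl("[ACGUNRY]", seg)
    }
    isTRUE(eval(lang, env))
  }
}

# Allow only a safe subset of call targets inside predicates.
check_predicate_lang <- function(lang) {
  allowed <- c("&", "|", "!", "(", "==", "!=", "&&", "||",
               "name_matches", "col", "present")
  walk <- function(e) {
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (!fn %in% allowed)
        stop("disallowed function '", fn, "' in predicate", call. = FALSE)
      lapply(as.list(e)[-1], walk)
    } else if (is.symbol(e)) {
      stop("bare symbol '", as.character(e), "' in predicate", call. = FALSE)
    }
    invisible(NULL)
  }
  walk(lang)
  invisible(TRUE)
}

# Evaluate a predicate over all rows -> logical vector.
predicate_rows <- function(aln, predicate) {
  if (is.character(predicate)) predicate <- parse_predicate(predicate)
  vapply(seq_along(aln$rows), function(i) predicate(aln, i), logical(1))
}

# Commands of one verb, as a list of token vectors.
commands_of <- function(aln, verb) {
  rows <- aln$commands[aln$commands$verb == verb & aln$commands$scope == "file", ]
  rows$args
}

# Consensus-annotation thresholds: defaults, overridable by a `thresholds`
# command (t50 t75 t90 t97, fractions or percents).
command_thresholds <- function(aln) {
  th <- c(t50 = 0.50, t75 = 0.75, t90 = 0.90, t97 = 0.97)
  for (args in commands_of(aln, "thresholds")) {
    v <- as.numeric(args[1:4])
    if (anyNA(v)) stop("thresholds command needs four numbers", call. = FALSE)
    if (any(v > 1)) v <- v / 100
    if (any(diff(v) <= 0) || any(v <= 0) || any(v >= 1))
      stop("thresholds must be strictly increasing in (0,1)", call. = FALSE)
    th[] <- v
  }
  th
}
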