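#' Annotated RNA alignment
#'
#' Container for a multiple-sequence alignment together with the per-column
#' annotation this package draws from: the consensus secondary-structure line
#' (`SS_cons`, matched angle brackets), an optional column-label line
#' (`R2R_LABEL`), any number of independently nested pseudoknot bracket lines,
#' and parsed layout/annotation commands.
#'
#' A single sequence is represented as the degenerate one-row alignment.
#'
#' @param seq_names Character vector of sequence identifiers.
#' @param rows Character vector of aligned sequence strings (same length as
#'   `seq_names`), over the alphabet `A C G U N R Y - .` after normalization
#'   (`T` is converted to `U` on construction, lower case is raised).
#' @param ss_cons Consensus structure string; `<` and `>` are pair brackets,
#'   every other character (`. - _ : ,`) means unpaired.
#' @param labels Named integer vector mapping single-character labels to
#'   0-based column indices.
#' @param pk_lines Named character vector of additional bracket lines, one per
#'   pseudoknot (each independently nested).
#' @param commands Tibble of parsed layout commands with columns
#'   `scope` ("file" or "seq"), `seq` (sequence name or `NA`), `verb`,
#'   and `args` (list column of character token vectors).
#' @param other_gf Character vector of unrecognized `#=GF` lines carried
#'   through verbatim on write.
#'
#' @return An object of class `rna_msa`.
#' @export
rna_msa <- function(seq_names, rows, ss_cons, labels = integer(),
                    pk_lines = character(), commands = empty_commands(),
                    other_gf = character()) {
  rows <- normalize_seq(rows)
  x <- structure(
    list(seq_names = as.character(seq_names), rows = rows,
         ss_cons = ss_cons, labels = labels, pk_lines = pk_lines,
         commands = commands, other_gf = other_gf),
    class = "rna_msa")
  validate_rna_msa(x)
}

empty_commands <- function() {
  tibble::tibble(scope = character(), seq = character(),
                 verb = character(), args = list())
}

# Uppercase, T->U; loud failure on anything outside the alphabet.
normalize_seq <- function(rows) {
  rows <- toupper(rows)
  rows <- gsub("T", "U", rows, fixed = TRUE)
  bad <- gsub("[ACGUNRY.\\-]", "", rows)
  if (any(nchar(bad) > 0)) {
    i <- which(nchar(bad) > 0)[1]
    stop("invalid sequence character(s) '", bad[i], "' in row ", i,
         call. = FALSE)
  }
  rows
}

validate_rna_msa <- function(x) {
  n <- nchar(x$ss_cons)
  widths <- nchar(x$rows)
  if (length(x$rows) < 1) stop("alignment must contain at least one sequence",
                               call. = FALSE)
  if (any(widths != n)) {
    i <- which(widths != n)[1]
    stop("column count mismatch: sequence '", x$seq_names[i], "' has ",
         widths[i], " columns, SS_cons has ", n, call. = FALSE)
  }
  if (!grepl("^[<>._:,\\-]*$", x$ss_cons))
    stop("invalid character in SS_cons line", call. = FALSE)
  for (nm in names(x$pk_lines)) {
    if (nchar(x$pk_lines[[nm]]) != n)
      stop("column count mismatch: pseudoknot line '", nm, "'", call. = FALSE)
  }
  if (length(x$labels)) {
    if (anyDuplicated(names(x$labels)))
      stop("duplicate label character '",
           names(x$labels)[duplicated(names(x$labels))][1], "'", call. = FALSE)
    if (any(x$labels < 0 | x$labels >= n))
      stop("label column out of range", call. = FALSE)
  }
  # bracket lines must be balanced; match_brackets() errors otherwise
  match_brackets(x$ss_cons)
  lapply(x$pk_lines, match_brackets)
  x
}

#' @export
print.rna_msa <- function(x, ...) {
  cat("<rna_msa> ", length(x$rows), " sequence(s), ", nchar(x$ss_cons),
      " columns, ", nrow(match_brackets(x$ss_cons)), " consensus pairs",
      if (length(x$pk_lines)) paste0(", ", length(x$pk_lines),
                                     " pseudoknot line(s)"), "\n", sep = "")
  if (nrow(x$commands))
    cat("  commands:", paste(unique(x$commands$verb), collapse = ", "), "\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln An [rna_msa] object.
#' @return Integer column count.
#' @export
n_columns <- function(aln) nchar(aln$ss_cons)

# Alignment rows as a columns-in-cells character matrix (rows x columns).
seq_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

is_gap_char <- function(ch) ch == "-" | ch == "."
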