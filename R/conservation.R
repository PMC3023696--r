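# Per-column conservation tiers, per-pair covariation classes, modular
# frequencies and variable-length-region ranges.

canonical_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Conservation call for one alignment column
#'
#' Weighted decision cascade with strict ("exceeds") threshold comparisons:
#'
#' 1. if some nucleotide's weighted identity frequency (among non-gap rows)
#'    exceeds the 75% threshold, the column gets that specific nucleotide
#'    symbol, tiered by the highest of 75/90/97 strictly exceeded;
#' 2. otherwise, if the purine (A+G) or pyrimidine (C+U) frequency exceeds
#'    75%, the column gets `R` or `Y` with the same tiering;
#' 3. otherwise the column is presence-only, tiered by the highest of
#'    50/75/90/97 strictly exceeded by the weighted non-gap fraction over
#'    all rows, or `absent` when that fraction is at or below 50%.
#'
#' Ambiguity codes in rows contribute as follows: `R`/`Y` count toward the
#' purine/pyrimidine frequency only; `N` counts toward presence only.
#'
#' @param aln An [rna_msa] object.
#' @param weights Sequence weights summing to 1 (default: GSC weights).
#' @param col 0-based column index.
#' @param thresholds Numeric vector `c(t50, t75, t90, t97)`; the defaults
#'   `(0.50, 0.75, 0.90, 0.97)` can be adjusted.
#' @return One-row tibble with `col`, `symbol` (one of `A C G U R Y`,
#'   `"presence"`, `"absent"`), `identity_tier` (`NA` or 75/90/97 as percent
#'   of the corresponding threshold slot) and `presence_tier` (`NA` or
#'   50/75/90/97).
#' @export
column_conservation <- function(aln, weights = NULL, col,
                                thresholds = c(0.50, 0.75, 0.90, 0.97)) {
  if (col < 0 || col >= n_columns(aln))
    stop("column index out of range: ", col, call. = FALSE)
  if (is.null(weights)) weights <- alignment_weights(aln)
  th <- unname(thresholds)
  ch <- substr(aln$rows, col + 1L, col + 1L)
  gap <- is_gap_char(ch)
  presence <- sum(weights[!gap])

  tier_of <- function(f, cuts, labels) {
    hit <- which(f > cuts)
    if (!length(hit)) NA_real_ else labels[max(hit)]
  }

  if (any(!gap)) {
    wng <- weights[!gap] / sum(weights[!gap])
    cng <- ch[!gap]
    idf <- vapply(c("A", "C", "G", "U"), function(nt) sum(wng[cng == nt]),
                  numeric(1))
    purine <- idf[["A"]] + idf[["G"]] + sum(wng[cng == "R"])
    pyrimidine <- idf[["C"]] + idf[["U"]] + sum(wng[cng == "Y"])
    if (max(idf) > th[2]) {
      return(tibble::tibble(
        col = col, symbol = names(idf)[which.max(idf)],
        identity_tier = tier_of(max(idf), th[2:4], c(75, 90, 97)),
        presence_tier = NA_real_))
    }
    if (max(purine, pyrimidine) > th[2]) {
      f <- max(purine, pyrimidine)
      return(tibble::tibble(
        col = col, symbol = if (purine >= pyrimidine) "R" else "Y",
        identity_tier = tier_of(f, th[2:4], c(75, 90, 97)),
        presence_tier = NA_real_))
    }
  }
  pt <- tier_of(presence, th, c(50, 75, 90, 97))
  tibble::tibble(col = col,
                 symbol = if (is.na(pt)) "absent" else "presence",
                 identity_tier = NA_real_, presence_tier = pt)
}

#' Covariation class of an annotated base pair
#'
#' Canonical pairs are the Watson-Crick and G-U wobble pairs. Rows whose two
#' characters do not form a canonical pair (a gap at either position counts
#' as non-canonical) are weighted; when their total frequency exceeds 10%
#' the pair is `unshaded`. Otherwise, among canonical rows: two observed
#' pair types differing at both positions make the pair `covarying`;
#' differing at exactly one position, `compatible`; a single observed type,
#' `invariant`.
#'
#' @inheritParams column_conservation
#' @param left,right 0-based columns forming a pair annotated in `SS_cons`
#'   or one of the pseudoknot lines (checked; error otherwise).
#' @param noncanonical_cutoff Frequency above which the pair is unshaded
#'   (default 0.10).
#' @return Character scalar: `"covarying"`, `"compatible"`, `"invariant"` or
#'   `"unshaded"`.
#' @export
classify_pair <- function(aln, weights = NULL, left, right,
                          noncanonical_cutoff = 0.10) {
  all_pairs <- annotated_pairs(aln)
  if (!any(all_pairs$left == left & all_pairs$right == right))
    stop("columns (", left, ",", right, ") are not an annotated pair",
         call. = FALSE)
  if (is.null(weights)) weights <- alignment_weights(aln)
  a <- substr(aln$rows, left + 1L, left + 1L)
  b <- substr(aln$rows, right + 1L, right + 1L)
  type <- paste0(a, b)
  canon <- type %in% canonical_pairs
  if (sum(weights[!canon]) > noncanonical_cutoff) return("unshaded")
  types <- unique(type[canon])
  if (length(types) <= 1) return("invariant")
  cmb <- utils::combn(types, 2)
  ndiff <- apply(cmb, 2, function(p)
    (substr(p[1], 1, 1) != substr(p[2], 1, 1)) +
      (substr(p[1], 2, 2) != substr(p[2], 2, 2)))
  if (any(ndiff == 2)) "covarying" else "compatible"
}

# All annotated pairs: consensus structure plus pseudoknot lines.
annotated_pairs <- function(aln) {
  main <- match_brackets(aln$ss_cons)
  main$line <- rep("SS_cons", nrow(main))
  pks <- lapply(names(aln$pk_lines), function(nm) {
    p <- match_brackets(aln$pk_lines[[nm]])
    p$line <- rep(paste0("pk", nm), nrow(p))
    p
  })
  dplyr::bind_rows(c(list(main), pks))
}

#' Full consensus annotation table
#'
#' Per-column conservation calls and per-pair covariation classes for a whole
#' alignment, the input the renderer styles glyphs and pair shading from.
#'
#' @inheritParams column_conservation
#' @param uniform_weights Use equal sequence weights instead of GSC.
#' @return Object of class `rna_annotation`: list with tibbles `columns`
#'   (`col`, `symbol`, `identity_tier`, `presence_tier`) and `pairs`
#'   (`left`, `right`, `line`, `class`), plus the weights used.
#' @export
annotate_consensus <- function(aln, weights = NULL,
                               thresholds = c(0.50, 0.75, 0.90, 0.97),
                               uniform_weights = FALSE) {
  if (is.null(weights)) weights <- alignment_weights(aln, uniform_weights)
  cols <- dplyr::bind_rows(lapply(seq_len(n_columns(aln)) - 1L, function(j)
    column_conservation(aln, weights, j, thresholds)))
  prs <- annotated_pairs(aln)
  prs$class <- vapply(seq_len(nrow(prs)), function(i)
    classify_pair(aln, weights, prs$left[i], prs$right[i]), character(1))
  structure(list(columns = cols, pairs = prs, weights = weights,
                 thresholds = thresholds),
            class = "rna_annotation")
}

#' @export
print.rna_annotation <- function(x, ...) {
  cat("<rna_annotation> ", nrow(x$columns), " columns, ", nrow(x$pairs),
      " pairs (", paste(names(table(x$pairs$class)),
                        table(x$pairs$class), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a consensus annotation into a per-column tibble
#' @param x An `rna_annotation` object.
#' @param ... Unused.
#' @return The per-column tibble, with pair partner and class joined in.
#' @method tidy rna_annotation
#' @export
tidy.rna_annotation <- function(x, ...) {
  prs <- tibble::tibble(
    col = c(x$pairs$left, x$pairs$right),
    partner = c(x$pairs$right, x$pairs$left),
    pair_class = rep(x$pairs$class, 2))
  dplyr::left_join(x$columns, prs, by = "col")
}

#' Write the annotation as a TSV file
#' @param x An `rna_annotation` object.
#' @param path Output file path.
#' @return Invisibly, the tibble written.
#' @export
export_annotation_tsv <- function(x, path) {
  tab <- tidy(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Weighted frequency of a modular structure
#'
#' Fraction of alignment rows (weighted) satisfying a membership predicate;
#' for display the fraction is shown rounded to a whole percent.
#'
#' @inheritParams column_conservation
#' @param predicate A predicate function from [parse_predicate()] or its
#'   source text.
#' @return Numeric fraction in `[0, 1]` with attribute `label` holding the
#'   display string (e.g. `"31%"`).
#' @export
modular_frequency <- function(aln, weights = NULL, predicate) {
  if (is.null(weights)) weights <- alignment_weights(aln)
  hits <- predicate_rows(aln, predicate)
  f <- sum(weights[hits])
  structure(f, label = paste0(round(100 * f), "%"))
}

#' Length range of a variable-length region
#'
#' Minimum and maximum number of non-gap characters per row over a
#' contiguous column range; rendered as `"m-M nt"` (or `"m nt"` when equal).
#'
#' @param aln An [rna_msa] object.
#' @param cols Integer vector of 0-based columns (contiguous, non-empty).
#' @return List with `min`, `max` and display `label`.
#' @export
var_region_range <- function(aln, cols) {
  if (!length(cols)) stop("empty column range", call. = FALSE)
  m <- seq_matrix(aln)[, cols + 1L, drop = FALSE]
  counts <- rowSums(!is_gap_char(m))
  lo <- min(counts); hi <- max(counts)
  list(min = lo, max = hi,
       label = if (lo == hi) paste0(lo, " nt") else paste0(lo, "-", hi, " nt"))
}
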