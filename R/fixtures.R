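# Synthetic fixture generator: tiny annotated alignments with known ground
# truth, in the style of a contrived RNA motif family. Covariation is
# injected by substituting canonical pair types that differ at both
# positions, so the expected covariation class of every pair is known by
# construction.

fixture_templates <- list(
  hairpin = list(
    ss = "....<<<<<.....>>>>>....",
    commands = character(0), labels = NULL),
  internal = list(
    ss = "..<<<..<<<....>>>...>>>..",
    commands = character(0), labels = NULL),
  junction3 = list(
    ss = "<<..<<...>>.<<...>>..<<...>>.>>",
    commands = "multistem_junction j dirs 180,90,0 formulation 2",
    labels = c(j = 2L)),
  junction4 = list(
    ss = "<<..<<...>>.<<...>>.<<...>>..<<...>>.>>",
    commands = "multistem_junction j dirs 198,126,54,-18 formulation 2",
    labels = c(j = 2L)),
  pk = list(
    ss = "<<<<<.....>>>>>...<<<<<.....>>>>>",
    pk = "......<<<...............>>>......",
    commands = "pk A style callout", labels = NULL))

#' Generate a synthetic annotated alignment
#'
#' Seeded generation of a small alignment whose true structure matches the
#' chosen template. Paired columns start as `G-C`; `covary_rate` substitutes
#' the `A-U` type (differing at both positions) into
#' `min(n_seq - 1, round(covary_rate * n_seq))` rows per pair, so every pair
#' with a positive rate is covarying by construction and every pair at rate
#' 0 is invariant. `modular_frac` appends an optional 3' hairpin carried by
#' exactly `round(modular_frac * n_seq)` rows (others gapped) together with
#' a `modular` command whose predicate tests its presence. `gap_rate` puts
#' gaps into unpaired main-structure columns at random.
#'
#' @param template One of `"hairpin"`, `"internal"`, `"junction3"`,
#'   `"junction4"`, `"pk"`.
#' @param n_seq Number of sequences (at least 2).
#' @param covary_rate,modular_frac,gap_rate Rates in `[0, 1]`.
#' @param seed Integer seed; the same seed reproduces the fixture exactly,
#'   and the caller's random state is left untouched.
#' @return An [rna_msa] object.
#' @export
generate_fixture <- function(template = c("hairpin", "internal", "junction3",
                                          "junction4", "pk"),
                             n_seq = 10L, covary_rate = 0, modular_frac = 0,
                             gap_rate = 0, seed = 1L) {
  template <- match.arg(template)
  stopifnot(n_seq >= 2, covary_rate >= 0, covary_rate <= 1,
            modular_frac >= 0, modular_frac <= 1,
            gap_rate >= 0, gap_rate <= 1)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  tpl <- fixture_templates[[template]]
  ss <- tpl$ss
  n_main <- nchar(ss)
  prs <- match_brackets(ss)
  paired <- c(prs$left, prs$right)
  unpaired <- setdiff(seq_len(n_main) - 1L, paired)

  cons <- rep("A", n_main)
  cons[unpaired + 1L] <- sample(c("A", "C", "G", "U"), length(unpaired),
                                replace = TRUE)
  cons[prs$left + 1L] <- "G"
  cons[prs$right + 1L] <- "C"

  rows <- matrix(rep(cons, each = n_seq), nrow = n_seq)
  k_cov <- min(n_seq - 1L, round(covary_rate * n_seq))
  for (z in seq_len(nrow(prs))) {
    hit <- sample(n_seq, k_cov)
    rows[hit, prs$left[z] + 1L] <- "A"
    rows[hit, prs$right[z] + 1L] <- "U"
  }
  if (gap_rate > 0 && length(unpaired)) {
    for (j in unpaired) {
      g <- stats::runif(n_seq) < gap_rate
      rows[g, j + 1L] <- "-"
    }
  }
  pk_line <- if (!is.null(tpl$pk)) tpl$pk else NULL
  commands <- tpl$commands
  labels <- tpl$labels

  # optional 3' hairpin carried by an exact count of rows
  mod_ss <- NULL
  if (modular_frac > 0) {
    mod_ss <- ".<<<...>>>."
    n_mod <- nchar(mod_ss)
    mod_cons <- rep("A", n_mod)
    mod_prs <- match_brackets(mod_ss)
    mod_cons[mod_prs$left + 1L] <- "G"
    mod_cons[mod_prs$right + 1L] <- "C"
    carriers <- sample(n_seq, round(modular_frac * n_seq))
    ext <- matrix("-", n_seq, n_mod)
    ext[carriers, ] <- rep(mod_cons, each = length(carriers))
    rows <- cbind(rows, ext)
    ss <- paste0(ss, strrep(".", n_mod))
    if (!is.null(pk_line)) pk_line <- paste0(pk_line, strrep(".", n_mod))
    labels <- c(labels, m = n_main, n = n_main + n_mod - 1L)
    commands <- c(commands,
                  'modular opt m n predicate present("m", "n")')
  }

  seq_names <- sprintf("seq%02d", seq_len(n_seq))
  label_line <- NULL
  if (length(labels)) {
    lab <- rep(".", nchar(ss))
    lab[unname(labels) + 1L] <- names(labels)
    label_line <- paste(lab, collapse = "")
  }
  lines <- c("# STOCKHOLM 1.0",
             if (length(commands)) paste("#=GF R2R", commands),
             paste(seq_names, apply(rows, 1, paste, collapse = "")),
             paste("#=GC SS_cons", ss),
             if (!is.null(pk_line)) paste("#=GC SS_cons_pkA", pk_line),
             if (!is.null(label_line)) paste("#=GC R2R_LABEL", label_line),
             "//")
  parse_stockholm(paste(lines, collapse = "\n"))
}
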