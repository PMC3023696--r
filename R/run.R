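# End-to-end pipeline: parse -> weights -> annotation -> layout (-> junction
# solve when commanded) -> compose -> SVG, with per-stage timing logged to
# standard error.

run_log <- function(verbose, stage, t0) {
  message(sprintf("[%s] %s (%.2fs)",
                  "INFO", stage, as.numeric(Sys.time() - t0, units = "secs")))
  invisible(NULL)
}

#' Draw a consensus diagram from a Stockholm file
#'
#' Runs the whole pipeline and writes the SVG (and optionally a layout TSV
#' dump). Each stage is timed and logged to standard error.
#'
#' @param input Path to a Stockholm file (or its text).
#' @param output Output SVG path.
#' @param style Optional path to a JSON style override file.
#' @param skeleton Draw the backbone-only skeleton style.
#' @param dump_layout Optional path for a TSV layout dump.
#' @param uniform_weights Use equal sequence weights instead of GSC.
#' @param verbose Log per-stage geometry diagnostics.
#' @return Invisibly, a list with the `rna_msa`, annotation, layout and
#'   drawing.
#' @export
rna_run <- function(input, output, style = NULL, skeleton = FALSE,
                    dump_layout = NULL, uniform_weights = FALSE,
                    verbose = FALSE) {
  t0 <- Sys.time()
  aln <- parse_stockholm(input)
  run_log(verbose, paste0("parsed ", length(aln$rows), " sequences x ",
                          n_columns(aln), " columns"), t0)

  t0 <- Sys.time()
  weights <- alignment_weights(aln, uniform = uniform_weights)
  run_log(verbose, "sequence weights", t0)

  t0 <- Sys.time()
  th <- command_thresholds(aln)
  ann <- annotate_consensus(aln, weights = weights, thresholds = unname(th))
  run_log(verbose, paste0("annotation (", nrow(ann$pairs), " pairs)"), t0)

  t0 <- Sys.time()
  layout <- layout_rna(aln)
  run_log(verbose, paste0("layout (", length(layout$junction_solutions),
                          " junction solve(s))"), t0)
  if (verbose) {
    ov <- check_overlaps(layout)
    message(sprintf("[INFO] overlap check: %d violation(s)", nrow(ov)))
  }

  t0 <- Sys.time()
  sm <- style_map(json = style, skeleton = skeleton)
  drawing <- compose(layout, ann, style = sm, aln = aln)
  svg <- to_svg(drawing)
  writeLines(svg, output)
  run_log(verbose, paste0("svg written to ", output), t0)

  if (!is.null(dump_layout)) {
    export_layout_tsv(layout, dump_layout)
    message("[INFO] layout dump written to ", dump_layout)
  }
  invisible(list(aln = aln, annotation = ann, layout = layout,
                 drawing = drawing))
}

#' Command-line entry point
#'
#' Implements the CLI contract; called by the shipped
#' `inst/scripts/draw-rna.R` wrapper. Main form:
#' `draw-rna.R <input.sto> <output.svg> [--style file.json] [--skeleton]
#' [--seed N] [--dump-layout tsv]`; fixture form: `draw-rna.R fixtures make
#' --template hairpin|internal|junction3|junction4|pk --n 10 --seed 1 -o
#' demo.sto`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly. Errors are reported on
#'   standard error with a non-zero status.
#' @export
rna_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) >= 1 && args[1] == "fixtures") {
      rna_cli_fixtures(args[-1])
    } else {
      rna_cli_draw(args)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_flag_value <- function(args, flag) {
  i <- which(args == flag)
  if (!length(i)) return(NULL)
  if (i[1] == length(args)) stop(flag, " needs a value", call. = FALSE)
  args[i[1] + 1L]
}

rna_cli_draw <- function(args) {
  pos <- args[!startsWith(args, "--") &
                !seq_along(args) %in% (which(startsWith(args, "--") &
                  !args %in% c("--skeleton", "--verbose")) + 1L)]
  if (length(pos) < 2)
    stop("usage: draw-rna.R <input.sto> <output.svg> [--style file.json] ",
         "[--skeleton] [--seed N] [--dump-layout tsv]", call. = FALSE)
  if (!file.exists(pos[1]))
    stop("input file not found: ", pos[1], call. = FALSE)
  seed <- cli_flag_value(args, "--seed")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rna_run(input = pos[1], output = pos[2],
          style = cli_flag_value(args, "--style"),
          skeleton = "--skeleton" %in% args,
          dump_layout = cli_flag_value(args, "--dump-layout"),
          verbose = "--verbose" %in% args)
  invisible(NULL)
}

rna_cli_fixtures <- function(args) {
  if (!length(args) || args[1] != "make")
    stop("usage: draw-rna.R fixtures make --template <tpl> --n <N> ",
         "--seed <S> -o <out.sto>", call. = FALSE)
  out <- cli_flag_value(args, "-o") %||% cli_flag_value(args, "--out")
  if (is.null(out)) stop("fixtures make needs -o <out.sto>", call. = FALSE)
  aln <- generate_fixture(
    template = cli_flag_value(args, "--template") %||% "hairpin",
    n_seq = as.integer(cli_flag_value(args, "--n") %||% "10"),
    covary_rate = as.numeric(cli_flag_value(args, "--covary") %||% "0"),
    modular_frac = as.numeric(cli_flag_value(args, "--modular") %||% "0"),
    gap_rate = as.numeric(cli_flag_value(args, "--gaps") %||% "0"),
    seed = as.integer(cli_flag_value(args, "--seed") %||% "1"))
  writeLines(write_stockholm(aln), out)
  message("[INFO] fixture written to ", out)
  invisible(NULL)
}
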