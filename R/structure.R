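# Recursive decomposition of a nested pair list into stems, loops,
# internal loops/bulges and multistem junctions.

#' Build the structure tree of a nested pair list
#'
#' Decomposes a properly nested pair list into the unique tree of maximal
#' stems (runs of stacked pairs) and the regions they enclose: terminal
#' loops (no inner stem), internal loops/bulges (exactly one inner stem)
#' and multistem junctions (two or more inner stems). The root holds the
#' exterior elements in column order.
#'
#' @param pairs Tibble with 0-based `left`/`right` columns, e.g. from
#'   [match_brackets()]. Crossing pairs are an error; pseudoknots must be
#'   carried on separate bracket lines.
#' @param n Number of alignment columns.
#' @return Nested list of class `rna_structure_tree`. Node types: `root`
#'   (`elements`), `stem` (`p5`, `p3` column vectors, `inner`), `loop`
#'   (`cols`), `internal` (`side5`, `side3`, `stem`), `junction`
#'   (`elements`), `run` (`cols`, exterior unpaired).
#' @export
build_structure_tree <- function(pairs, n) {
  pmap <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    if (any(duplicated(c(pairs$left, pairs$right))))
      stop("column in more than one pair", call. = FALSE)
    pmap[pairs$left + 1L] <- pairs$right
    pmap[pairs$right + 1L] <- pairs$left
    # crossing check
    o <- pairs[order(pairs$left), ]
    stack <- integer(0)
    for (i in seq_len(nrow(o))) {
      while (length(stack) && stack[length(stack)] < o$left[i])
        stack <- stack[-length(stack)]
      if (length(stack) && o$right[i] > stack[length(stack)])
        stop("crossing pairs (pseudoknot) at columns ", o$left[i], ",",
             o$right[i], "; use a separate pseudoknot line", call. = FALSE)
      stack <- c(stack, o$right[i])
    }
  }
  root <- list(type = "root", elements = region_elements(0L, n - 1L, pmap))
  structure(root, class = "rna_structure_tree")
}

# Elements (unpaired runs + stems) of region [lo, hi], in column order.
region_elements <- function(lo, hi, pmap) {
  elements <- list()
  run <- integer(0)
  j <- lo
  flush <- function() {
    if (length(run)) elements[[length(elements) + 1L]] <<-
        list(type = "run", cols = run)
    run <<- integer(0)
  }
  while (j <= hi) {
    partner <- pmap[j + 1L]
    if (is.na(partner) || partner < j) {       # unpaired (partner<j impossible here)
      run <- c(run, j)
      j <- j + 1L
    } else {
      flush()
      b <- partner
      L <- 1L
      while (j + L <= hi && !is.na(pmap[j + L + 1L]) &&
             pmap[j + L + 1L] == b - L && b - L > j + L)
        L <- L + 1L
      stem <- list(type = "stem",
                   p5 = j + 0:(L - 1L),
                   p3 = b - 0:(L - 1L),
                   inner = classify_region(j + L, b - L, pmap))
      elements[[length(elements) + 1L]] <- stem
      j <- b + 1L
    }
  }
  flush()
  elements
}

# A stem's enclosed region, classified.
classify_region <- function(lo, hi, pmap) {
  els <- if (lo > hi) list() else region_elements(lo, hi, pmap)
  stems <- Filter(function(e) e$type == "stem", els)
  if (length(stems) == 0) {
    list(type = "loop", cols = if (lo > hi) integer(0) else lo:hi)
  } else if (length(stems) == 1) {
    k <- which(vapply(els, function(e) e$type == "stem", logical(1)))
    side5 <- unlist(lapply(els[seq_len(k - 1)], `[[`, "cols"))
    side3 <- unlist(lapply(els[-seq_len(k)], `[[`, "cols"))
    list(type = "internal",
         side5 = side5 %||% integer(0), side3 = side3 %||% integer(0),
         stem = els[[k]])
  } else {
    list(type = "junction", elements = els)
  }
}

#' @export
print.rna_structure_tree <- function(x, ...) {
  count <- function(node) {
    if (is.null(node$type)) return(c(stem = 0, loop = 0, junction = 0))
    kids <- switch(node$type,
                   root = , junction = node$elements,
                   stem = list(node$inner),
                   internal = list(node$stem),
                   list())
    acc <- c(stem = as.numeric(node$type == "stem"),
             loop = as.numeric(node$type == "loop"),
             junction = as.numeric(node$type == "junction"))
    for (k in kids) acc <- acc + count(k)
    acc
  }
  cnt <- count(unclass(x))
  cat("<rna_structure_tree> ", cnt[["stem"]], " stem(s), ", cnt[["loop"]],
      " terminal loop(s), ", cnt[["junction"]], " junction(s)\n", sep = "")
  invisible(x)
}
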