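#' Pairwise fractional-identity distances
#'
#' Distance between two aligned rows is one minus the fraction of matching
#' characters among columns where both rows are non-gap. Rows sharing no
#' non-gap column are at distance 1; self-distance is 0.
#'
#' @param aln An [rna_msa] object.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to the
#'   sequence names.
#' @export
pairwise_identity_distances <- function(aln) {
  m <- seq_matrix(aln)
  gap <- is_gap_char(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$seq_names, aln$seq_names))
  if (n == 1) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !gap[i, ] & !gap[j, ]
      d[i, j] <- d[j, i] <-
        if (!any(both)) 1 else 1 - sum(m[i, both] == m[j, both]) / sum(both)
    }
  }
  d
}

#' Gerstein-Sonnhammer-Chothia sequence weights
#'
#' Tree-based weighting that down-weights redundant sequences: a rooted
#' guide tree is built by UPGMA on the identity distances, each tree edge's
#' length is shared equally among the leaves below it, and a leaf's weight is
#' the sum of its shares along the path to the root. Weights are normalized
#' to sum to one; when every edge has zero length (identical sequences) the
#' weights are uniform.
#'
#' @param distances Symmetric distance matrix, e.g. from
#'   [pairwise_identity_distances()].
#' @param tree_builder Function mapping a [stats::dist] object to an
#'   [stats::hclust] tree; defaults to UPGMA (average linkage).
#' @return Numeric weight vector summing to 1, named like the matrix rows.
#' @examples
#' d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3)
#' gsc_weights(d)  # c(0.25, 0.25, 0.5)
#' @export
gsc_weights <- function(distances,
                        tree_builder = function(d) stats::hclust(d, "average")) {
  n <- nrow(distances)
  nms <- rownames(distances)
  if (n == 1) return(stats::setNames(1, nms))
  hc <- tree_builder(stats::as.dist(distances))

  # leaves below and height of every hclust node; node k merges at height[k],
  # leaves at height 0; ultrametric edge length parent->child is half the
  # height difference.
  n_int <- nrow(hc$merge)
  below <- vector("list", n_int)
  node_height <- function(id) if (id < 0) 0 else hc$height[id]
  w <- numeric(n)
  # accumulate edge shares root-down
  for (k in seq_len(n_int)) {
    below[[k]] <- unlist(lapply(hc$merge[k, ], function(id)
      if (id < 0) -id else below[[id]]))
  }
  add_share <- function(id, parent_h) {
    leaves <- if (id < 0) -id else below[[id]]
    edge <- (parent_h - node_height(id)) / 2
    w[leaves] <<- w[leaves] + edge / length(leaves)
    if (id > 0) for (ch in hc$merge[id, ]) add_share(ch, hc$height[id])
  }
  for (ch in hc$merge[n_int, ]) add_share(ch, hc$height[n_int])

  if (sum(w) <= 0) w <- rep(1 / n, n) else w <- w / sum(w)
  stats::setNames(w, nms)
}

# Weights for an alignment; uniform = TRUE bypasses GSC.
alignment_weights <- function(aln, uniform = FALSE) {
  n <- length(aln$rows)
  if (uniform) return(stats::setNames(rep(1 / n, n), aln$seq_names))
  gsc_weights(pairwise_identity_distances(aln))
}
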