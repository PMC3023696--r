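# Independent oracle for GSC weights: walk an ape phylo tree (converted from
# the same UPGMA clustering) and share each branch length equally among the
# tips below it, then normalize.
gsc_oracle <- function(distances) {
  hc <- stats::hclust(stats::as.dist(distances), "average")
  tr <- ape::as.phylo(hc)
  ntip <- length(tr$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tr$edge[tr$edge[, 1] == node, 2], tips_below))
  }
  w <- numeric(ntip)
  for (i in seq_len(nrow(tr$edge))) {
    tips <- tips_below(tr$edge[i, 2])
    w[tips] <- w[tips] + tr$edge.length[i] / length(tips)
  }
  if (sum(w) <= 0) w <- rep(1 / ntip, ntip)
  stats::setNames(w / sum(w), tr$tip.label)[rownames(distances)]
}

rand_dist <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, 0.1, 1), n, n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d
}

test_that("documented example: two identical sequences and one distinct", {
  d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unname(gsc_weights(d)), c(0.25, 0.25, 0.5))
})

test_that("GSC weights match an independent tree-walk oracle", {
  for (seed in 1:5) {
    d <- rand_dist(6 + seed, seed)
    expect_equal(gsc_weights(d), gsc_oracle(d), tolerance = 1e-12)
  }
})

test_that("weights are a probability vector", {
  for (seed in 1:3) {
    w <- gsc_weights(rand_dist(8, seed))
    expect_equal(sum(w), 1)
    expect_true(all(w > 0))
  }
})

test_that("weights are equivariant under row permutation", {
  d <- rand_dist(7, 42)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  dp <- d[perm, perm]
  expect_equal(gsc_weights(dp)[rownames(d)], gsc_weights(d),
               tolerance = 1e-12)
})

test_that("identical sequences fall back to uniform weights", {
  d <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_equal(unname(gsc_weights(d)), rep(0.25, 4))
})

test_that("a duplicated sequence is down-weighted", {
  # s1/s2 identical, s3/s4 mutually distant singletons
  d <- matrix(c(0,  0, .8, .9,
                0,  0, .8, .9,
                .8, .8, 0, .7,
                .9, .9, .7, 0), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  w <- gsc_weights(d)
  expect_lt(w[["s1"]], w[["s3"]])
  expect_lt(w[["s2"]], w[["s4"]])
  expect_equal(w[["s1"]], w[["s2"]])
})

test_that("pairwise distances are fractional mismatch over shared columns", {
  aln <- parse_stockholm(c("# STOCKHOLM 1.0",
                           "s1 AAGG",
                           "s2 AAGC",
                           "s3 --GC",
                           "s4 CC--",
                           "#=GC SS_cons ....",
                           "//"))
  d <- pairwise_identity_distances(aln)
  expect_equal(d["s1", "s2"], 0.25)   # 1 mismatch over 4 shared
  expect_equal(d["s2", "s3"], 0)      # both shared columns match
  expect_equal(d["s3", "s4"], 1)      # no shared non-gap column
  expect_equal(diag(d), stats::setNames(rep(0, 4), aln$seq_names))
  expect_equal(d, t(d))
})
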