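# Independent oracles and small fixtures used across the suite.

# Brute-force split enumeration by graph traversal: for every edge, find
# the leaf set of the component containing the child endpoint after
# deleting that edge. Deliberately independent of bipartition_set()'s
# postorder accumulation.
brute_splits <- function(tree) {
  tr <- if (length(tree$tip.label) >= 3) ape::unroot(tree) else tree
  labs <- tr$tip.label
  ntip <- length(labs)
  keys <- character(0)
  edges <- tr$edge
  for (k in seq_len(nrow(edges))) {
    el <- edges[-k, , drop = FALSE]
    seen <- edges[k, 2]
    frontier <- seen
    while (length(frontier)) {
      nb <- c(el[el[, 1] %in% frontier, 2], el[el[, 2] %in% frontier, 1])
      nb <- setdiff(unique(nb), seen)
      seen <- c(seen, nb)
      frontier <- nb
    }
    side <- sort(labs[seen[seen <= ntip]])
    if (length(side) < 2 || length(side) > ntip - 2) next
    other <- sort(setdiff(labs, side))
    key_a <- paste(side, collapse = "\x1f")
    key_b <- paste(other, collapse = "\x1f")
    key <- if (length(side) < length(other)) key_a
           else if (length(other) < length(side)) key_b
           else min(key_a, key_b)
    keys <- c(keys, key)
  }
  sort(unique(keys))
}

brute_rf <- function(t1, t2) {
  k1 <- brute_splits(t1)
  k2 <- brute_splits(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# Random unrooted binary tree with all branch lengths >= min_len.
random_metric_tree <- function(n, min_len = 0.05, max_len = 1) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# Tiny handmade alignment: named sequences, one gene.
toy_alignment <- function(gene_id, ...) {
  gene_alignment(gene_id, c(...))
}

# Restrict a list of gene alignments to a species subset.
restrict_alns <- function(alignments, species) {
  out <- lapply(alignments, function(a) {
    keep <- intersect(names(a$seqs), species)
    gene_alignment(a$gene_id, a$seqs[keep])
  })
  names(out) <- names(alignments)
  out
}
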