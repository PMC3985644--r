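# Topological distances and certainty measures: bipartition extraction,
# Robinson-Foulds distance, nodal distance, and internode/tree certainty.

canonical_side <- function(side, universe) {
  side <- sort(side)
  other <- sort(setdiff(universe, side))
  if (length(side) < length(other)) return(side)
  if (length(other) < length(side)) return(other)
  # tie: lexicographically smaller side wins
  key_a <- paste(side, collapse = KEY_SEP)
  key_b <- paste(other, collapse = KEY_SEP)
  if (key_a <= key_b) side else other
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One bipartition (split) per internal edge, canonicalized so equal splits
#' compare equal: the stored side is the smaller of the two leaf subsets
#' (lexicographically smaller on ties). Trees with fewer than 4 leaves have
#' no non-trivial splits and yield an empty set; a binary unrooted tree on
#' n leaves yields exactly n - 3.
#'
#' @param tree A `phylo` tree; any root is collapsed first.
#' @return An object of class `bipartitions`: list with `sides` (list of
#'   character vectors), `keys` (canonical string keys) and `universe`.
#' @export
bipartition_set <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  universe <- sort(tree$tip.label)
  n <- length(universe)
  empty <- structure(list(sides = list(), keys = character(0),
                          universe = universe), class = "bipartitions")
  if (n < 4L) return(empty)
  tr <- as_unrooted(tree)
  tr <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(tr$tip.label)
  tips_below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- tr$tip.label[i]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  root <- tr$edge[nrow(tr$edge), 1]
  sides <- list()
  for (k in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[k, 2]
    if (ch <= ntip) next                      # trivial split
    sz <- length(tips_below[[ch]])
    if (sz < 2L || sz > n - 2L) next
    sides[[length(sides) + 1L]] <- canonical_side(tips_below[[ch]], universe)
  }
  keys <- vapply(sides, paste, character(1), collapse = KEY_SEP)
  dup <- duplicated(keys)
  structure(list(sides = sides[!dup], keys = keys[!dup], universe = universe),
            class = "bipartitions")
}

#' @export
print.bipartitions <- function(x, ...) {
  cat(sprintf("<bipartitions> %d non-trivial splits over %d leaves\n",
              length(x$keys), length(x$universe)))
  invisible(x)
}

check_same_leaves <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop(sprintf("leaf sets differ: only in tree 1 [%s]; only in tree 2 [%s]",
                 paste(only1, collapse = ", "),
                 paste(only2, collapse = ", ")))
  }
  invisible(l1)
}

#' Robinson-Foulds distance
#'
#' RF distance as the size of the symmetric difference between the two
#' trees' non-trivial bipartition sets, with a normalized variant dividing
#' by |S1| + |S2| (the maximum attainable; equal to 2(n-3) for two binary
#' trees, i.e. the fraction of wrong splits). Defined as 0 when both split
#' sets are empty. Leaf sets must match exactly; use
#' [restrict_to_common_leaves()] first to compare trees on different taxa.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return A list with integer `rf` and `normalized` in \[0, 1\].
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  k1 <- bipartition_set(t1)$keys
  k2 <- bipartition_set(t2)$keys
  rf <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  denom <- length(k1) + length(k2)
  list(rf = as.integer(rf),
       normalized = if (denom == 0L) 0 else rf / denom)
}

#' Prune two trees to their shared leaves
#'
#' @param t1,t2 `phylo` trees.
#' @return A list of the two pruned trees.
#' @export
restrict_to_common_leaves <- function(t1, t2) {
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 3L) stop("fewer than 3 shared leaves")
  list(ape::keep.tip(t1, common), ape::keep.tip(t2, common))
}

#' Nodal distance between two trees
#'
#' Computed from topological leaf-to-leaf path lengths (edge counts on the
#' unrooted topologies): the default `l2` variant is the root of the sum of
#' squared differences over unordered leaf pairs; `l1` is the sum of
#' absolute differences.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @param variant `"l2"` (default) or `"l1"`.
#' @return Non-negative numeric.
#' @export
nodal_distance <- function(t1, t2, variant = c("l2", "l1")) {
  variant <- match.arg(variant)
  labs <- check_same_leaves(t1, t2)
  path_mat <- function(t) {
    t <- as_unrooted(t)
    t$edge.length <- rep(1, nrow(t$edge))
    m <- ape::cophenetic.phylo(t)
    m[labs, labs]
  }
  dif <- (path_mat(t1) - path_mat(t2))[upper.tri(diag(length(labs)))]
  switch(variant, l2 = sqrt(sum(dif^2)), l1 = sum(abs(dif)))
}

#' Internode certainty for observed split frequencies
#'
#' IC of a split supported by `f1` trees against its strongest conflicting
#' split observed in `f2` trees: IC = 1 + p1 log2 p1 + p2 log2 p2 with
#' p_k = f_k / (f1 + f2). IC is 1 when the split is observed and
#' unconflicted, and 0 when it is unobserved and unconflicted.
#'
#' @param f1 Support count of the split.
#' @param f2 Count of the strongest conflicting split.
#' @return IC value in (-Inf, 1\]; 0 at maximal conflict (f1 = f2).
#' @export
internode_certainty <- function(f1, f2) {
  stopifnot(f1 >= 0, f2 >= 0)
  if (f1 == 0 && f2 == 0) return(0)
  if (f2 == 0) return(1)
  if (f1 == 0) return(0)   # unobserved-but-conflicted: conservative 0
  p1 <- f1 / (f1 + f2); p2 <- f2 / (f1 + f2)
  1 + p1 * log2(p1) + p2 * log2(p2)
}

splits_conflict <- function(a, b, universe) {
  # two splits are incompatible iff all four pairwise side intersections
  # are non-empty
  ac <- length(intersect(a, b))
  a_only <- length(setdiff(a, b))
  b_only <- length(setdiff(b, a))
  rest <- length(universe) - ac - a_only - b_only
  ac > 0 && a_only > 0 && b_only > 0 && rest > 0
}

#' Tree certainty of a reference tree against a gene-tree set
#'
#' For each internal branch (non-trivial split) of the reference, counts
#' how many gene trees contain the split (f1) and how many contain its
#' most frequent conflicting split (f2), and scores the branch with
#' [internode_certainty()]. The tree certainty is the sum of per-branch IC
#' values; it equals the number of reference internal branches exactly when
#' every reference split is observed and unconflicted. A reference split
#' absent from every gene tree but conflicted is scored 0 with a warning
#' (the certainty formalism assumes splits drawn from the gene-tree set,
#' where support is positive).
#'
#' Gene trees with multifurcations contribute only the splits they contain;
#' no resolution is imputed.
#'
#' @param reference A `phylo` tree.
#' @param gene_trees Non-empty list of `phylo` trees over the reference's
#'   leaf set.
#' @return An object of class `certainty_report`: data.frame `per_branch`
#'   (split, f1, f2, ic) and numeric `tree_certainty`.
#' @export
tree_certainty <- function(reference, gene_trees) {
  if (length(gene_trees) == 0L) stop("empty gene-tree collection")
  for (gt in gene_trees) check_same_leaves(reference, gt)
  ref_b <- bipartition_set(reference)
  universe <- ref_b$universe
  gene_b <- lapply(gene_trees, bipartition_set)
  all_keys <- unlist(lapply(gene_b, `[[`, "keys"))
  counts <- table(all_keys)
  observed_sides <- list()
  for (gb in gene_b) {
    new <- !(gb$keys %in% names(observed_sides))
    observed_sides[gb$keys[new]] <- gb$sides[new]
  }
  per <- data.frame(split = character(0), f1 = numeric(0), f2 = numeric(0),
                    ic = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_along(ref_b$keys)) {
    key <- ref_b$keys[i]
    side <- ref_b$sides[[i]]
    f1 <- if (key %in% names(counts)) as.numeric(counts[[key]]) else 0
    f2 <- 0
    for (k in names(observed_sides)) {
      if (k == key) next
      if (splits_conflict(side, observed_sides[[k]], universe)) {
        f2 <- max(f2, as.numeric(counts[[k]]))
      }
    }
    if (f1 == 0 && f2 > 0) {
      warning(sprintf(
        "reference split {%s} unobserved in gene trees but conflicted; IC set to 0",
        paste(side, collapse = ",")))
    }
    per[nrow(per) + 1L, ] <- list(paste(side, collapse = ","), f1, f2,
                                  internode_certainty(f1, f2))
  }
  structure(list(per_branch = per, tree_certainty = sum(per$ic)),
            class = "certainty_report")
}

#' @export
print.certainty_report <- function(x, ...) {
  cat(sprintf("<certainty_report> tree certainty %.4f over %d branches\n",
              x$tree_certainty, nrow(x$per_branch)))
  invisible(x)
}

#' Tree-distance report over a collection of trees
#'
#' Convenience table of RF, normalized RF, nodal distance and shared-split
#' counts of each tree against a reference; optionally written as TSV.
#'
#' @param reference A `phylo` tree.
#' @param trees Named list of `phylo` trees over the same leaf set.
#' @param out Optional TSV output path.
#' @return A data.frame with columns `tree_id`, `rf`, `normalized_rf`,
#'   `nodal`, `n_shared_splits`.
#' @export
treedist_report <- function(reference, trees, out = NULL) {
  stopifnot(length(trees) >= 1L)
  ids <- names(trees) %||% as.character(seq_along(trees))
  ref_keys <- bipartition_set(reference)$keys
  rows <- lapply(seq_along(trees), function(i) {
    rf <- rf_distance(reference, trees[[i]])
    data.frame(tree_id = ids[i], rf = rf$rf, normalized_rf = rf$normalized,
               nodal = nodal_distance(reference, trees[[i]]),
               n_shared_splits = length(intersect(
                 ref_keys, bipartition_set(trees[[i]])$keys)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
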