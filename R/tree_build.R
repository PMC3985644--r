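# Built-in distance-based tree inference (p/Poisson-corrected protein
# distances + classical neighbor joining), and the contract for delegating
# tree building to an external maximum-likelihood engine.

#' Pairwise protein distance matrix
#'
#' Distances are computed with pairwise deletion: columns where either row
#' has a gap `-` or unknown `X` are skipped for that pair. The `p`
#' correction is the raw mismatch fraction over compared columns; `poisson`
#' applies d = -ln(1 - p). Pairs with `p >= p_cap` or with zero comparable
#' columns are capped at `d_cap` and recorded in `saturated_pairs`.
#'
#' @param aln A [gene_alignment()] or `concat_alignment` with at least two
#'   species.
#' @param correction `"poisson"` (default) or `"p"`.
#' @param p_cap Saturation threshold on the mismatch fraction.
#' @param d_cap Distance assigned to saturated pairs.
#' @return An object of class `dist_matrix`: `labels`, symmetric numeric
#'   matrix `d` with zero diagonal, and `saturated_pairs`.
#' @export
protein_distance_matrix <- function(aln, correction = c("poisson", "p"),
                                    p_cap = 0.95, d_cap = 10) {
  correction <- match.arg(correction)
  seqs <- aln$seqs
  if (length(seqs) < 2L) stop("need at least 2 species for distances")
  pc <- pair_counts(seqs)
  dist_from_counts(pc$ncomp, pc$nmis, correction = correction,
                   p_cap = p_cap, d_cap = d_cap)
}

# Shared by protein_distance_matrix() and the cached subset builder:
# turn comparable/mismatch count matrices into a dist_matrix.
dist_from_counts <- function(ncomp, nmis, correction = "poisson",
                             p_cap = 0.95, d_cap = 10) {
  labels <- rownames(ncomp)
  n <- length(labels)
  p <- matrix(0, n, n)
  ok <- ncomp > 0
  p[ok] <- nmis[ok] / ncomp[ok]
  sat <- (!ok) | (p >= p_cap)
  diag(sat) <- FALSE
  d <- switch(correction,
              p = p,
              poisson = ifelse(p < 1, -log(1 - p), Inf))
  d[sat] <- d_cap
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  sat_idx <- which(sat & upper.tri(sat), arr.ind = TRUE)
  structure(list(labels = labels, d = d,
                 saturated_pairs = data.frame(
                   sp1 = labels[sat_idx[, 1]],
                   sp2 = labels[sat_idx[, 2]],
                   stringsAsFactors = FALSE)),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d labels, %d saturated pairs\n",
              length(x$labels), nrow(x$saturated_pairs)))
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$d

#' Classical neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix. The result is an
#' unrooted tree (binary up to the basal trifurcation) with branch lengths;
#' negative estimated branch lengths are clamped to 0. Ties in the Q
#' criterion are broken deterministically by joining the pair whose
#' (lexicographically smallest leaf label in each cluster) pair sorts
#' first, so permuting input label order never changes the returned splits.
#'
#' @param dm A `dist_matrix` (or a plain symmetric matrix with dimnames)
#'   over at least 3 labels.
#' @return A `phylo` tree over all labels.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist_matrix")) {
    D <- dm$d
  } else {
    D <- as.matrix(dm)
  }
  labs <- rownames(D)
  n <- length(labs)
  if (n < 3L) stop("neighbor joining needs at least 3 labels")
  # active nodes carry a partial newick string and the smallest leaf label
  # in their cluster (tie-break key)
  nwk <- labs
  minlab <- labs
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)) & upper.tri(Q),
                  arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      k1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
      k2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
      cand <- cand[order(k1, k2), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt_num(bi),
                       nwk[j], fmt_num(bj))
    new_min <- min(minlab[i], minlab[j])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    minlab <- c(minlab[keep], new_min)
    n <- n - 1L
  }
  va <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  nwk[1], fmt_num(va), nwk[2], fmt_num(vb),
                  nwk[3], fmt_num(vc))
  parse_newick(text)
}

#' Built-in neighbor-joining tree builder
#'
#' Returns a builder function (alignment -> `phylo`) that computes a
#' protein distance matrix and applies [neighbor_joining()]. This is the
#' default, self-contained inference strategy; a maximum-likelihood engine
#' can be plugged in via [external_builder()] instead.
#'
#' @param correction,p_cap,d_cap Passed to [protein_distance_matrix()].
#' @return A function of class `c("nj_builder", "tree_builder")`.
#' @export
nj_builder <- function(correction = "poisson", p_cap = 0.95, d_cap = 10) {
  f <- function(aln) {
    neighbor_joining(protein_distance_matrix(aln, correction = correction,
                                             p_cap = p_cap, d_cap = d_cap))
  }
  structure(f, class = c("nj_builder", "tree_builder", "function"),
            correction = correction, p_cap = p_cap, d_cap = d_cap)
}

#' External tree-engine adapter
#'
#' Contract for delegating tree inference to an external program (e.g. a
#' PhyML-style maximum-likelihood engine). The command template must
#' contain the placeholders `{alignment}` and `{output}`; the adapter
#' writes the alignment as FASTA, substitutes the paths, runs the command,
#' and reads the resulting Newick tree, which must cover exactly the
#' alignment's species.
#'
#' A faithful reproduction of the classic protein ML protocol would
#' configure the engine as: BioNJ starting tree; likelihood of that
#' topology evaluated under JTT, LG, WAG, Blosum62, MtREV, VT and Dayhoff;
#' the two models best by AIC refined to full ML trees and the better
#' likelihood kept; NNI rearrangements for single genes and SPR for
#' concatenations; discrete gamma with four rate categories plus invariant
#' sites estimated from the data. None of that is re-implemented here; it
#' is the engine's job.
#'
#' @param command Command template string with `{alignment}` and `{output}`
#'   placeholders.
#' @return A function of class `c("external_builder", "tree_builder")`.
#' @export
external_builder <- function(command) {
  stopifnot(is.character(command), length(command) == 1L)
  if (!grepl("{alignment}", command, fixed = TRUE) ||
      !grepl("{output}", command, fixed = TRUE)) {
    stop("command template must contain {alignment} and {output}")
  }
  f <- function(aln) {
    fa <- tempfile(fileext = ".fasta")
    out <- tempfile(fileext = ".nwk")
    on.exit(unlink(c(fa, out)))
    write_fasta_alignment(aln, fa)
    cmd <- gsub("{alignment}", fa, command, fixed = TRUE)
    cmd <- gsub("{output}", out, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) stop(sprintf("external tree engine failed (exit %d)", status))
    if (!file.exists(out)) stop("external tree engine produced no output tree")
    tr <- parse_newick(paste(readLines(out), collapse = ""))
    if (!setequal(tr$tip.label, names(aln$seqs))) {
      stop("external engine tree does not cover the alignment's species")
    }
    tr
  }
  structure(f, class = c("external_builder", "tree_builder", "function"),
            command = command)
}
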