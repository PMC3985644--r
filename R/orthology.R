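# Widespread single-copy gene selection from seed-species BLAST hit
# tables, with union/intersection merging across multiple seeds.

#' Orthology filter configuration
#'
#' Defaults follow the classic single-copy screen: hits must have e-value
#' <= 1e-5 and query coverage > 50%, and a gene qualifies when it has
#' exactly one surviving hit in every other genome. `min_species_fraction`
#' relaxes the presence requirement when too few genes meet the strict
#' criterion.
#'
#' @param e_value_max Maximum e-value for a hit to survive.
#' @param min_coverage Query-coverage threshold; hits must exceed it
#'   (strict `>`, matching "coverage > 50%").
#' @param min_species_fraction Fraction of genomes in (0, 1\] that must
#'   carry exactly one surviving hit.
#' @param merge_mode `"union"` or `"intersection"`, used by
#'   [merge_seed_groups()].
#' @return An object of class `orthology_config`.
#' @export
orthology_config <- function(e_value_max = 1e-5, min_coverage = 0.5,
                             min_species_fraction = 1.0,
                             merge_mode = c("union", "intersection")) {
  merge_mode <- match.arg(merge_mode)
  stopifnot(e_value_max >= 0, min_coverage >= 0, min_coverage <= 1,
            min_species_fraction > 0, min_species_fraction <= 1)
  structure(list(e_value_max = e_value_max, min_coverage = min_coverage,
                 min_species_fraction = min_species_fraction,
                 merge_mode = merge_mode),
            class = "orthology_config")
}

#' Widespread single-copy genes from one seed species
#'
#' A seed protein qualifies iff, after discarding hits that fail the
#' e-value or coverage filter, it has exactly one surviving hit (one
#' distinct target protein; multiple HSPs to the same target are not
#' merged) in at least `ceiling(min_species_fraction * |genomes|)` genomes
#' and at most one in every genome. Hits back to the seed's own genome are
#' ignored; the seed protein represents its own genome in the group.
#'
#' @param seed Seed species label.
#' @param hits A `hit_table` data.frame of seed-protein hits (columns
#'   `qseqid`, `sseqid`, `target_genome`, `e_value`, `query_coverage`).
#' @param genomes Species labels searched against, excluding the seed.
#' @param cfg An [orthology_config()].
#' @return Named list of `ortholog_group` objects (`gene_id`, `seed`,
#'   `members`: species -> member protein id), sorted by gene id.
#' @export
single_copy_from_seed <- function(seed, hits, genomes,
                                  cfg = orthology_config()) {
  if (length(genomes) == 0L) stop("empty genome set")
  genomes <- setdiff(genomes, seed)
  if (length(genomes) == 0L) stop("genome set contains only the seed")
  unknown <- setdiff(unique(hits$target_genome), c(genomes, seed))
  if (length(unknown)) {
    stop(sprintf("unknown genome label in hits: %s",
                 paste(unknown, collapse = ", ")))
  }
  h <- hits[hits$target_genome != seed &
              hits$e_value <= cfg$e_value_max &
              hits$query_coverage > cfg$min_coverage, , drop = FALSE]
  need <- ceiling(cfg$min_species_fraction * length(genomes))
  groups <- list()
  for (q in sort(unique(hits$qseqid))) {
    hq <- h[h$qseqid == q, , drop = FALSE]
    if (nrow(hq) == 0L) next
    n_targets <- tapply(hq$sseqid, hq$target_genome,
                        function(x) length(unique(x)))
    if (any(n_targets > 1L)) next            # not single copy somewhere
    if (sum(n_targets == 1L) < need) next    # not widespread enough
    members <- vapply(split(hq$sseqid, hq$target_genome), `[`, character(1), 1L)
    members <- c(stats::setNames(q, seed), members)
    groups[[q]] <- structure(list(gene_id = q, seed = seed,
                                  members = members),
                             class = "ortholog_group")
  }
  groups[order(names(groups))]
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat(sprintf("<ortholog_group> %s (seed %s): %d species\n",
              x$gene_id, x$seed, length(x$members)))
  invisible(x)
}

# Two groups are deemed the same gene when their member maps coincide on
# every shared species (and they share at least one species).
groups_coincide <- function(g1, g2) {
  shared <- intersect(names(g1$members), names(g2$members))
  length(shared) > 0L && all(g1$members[shared] == g2$members[shared])
}

#' Merge ortholog groups found from multiple seeds
#'
#' `union` deduplicates groups from all seeds, keeping the
#' lexicographically smallest gene id among coinciding groups;
#' `intersection` keeps only groups recovered (as coinciding member sets)
#' from every seed. Groups whose members disagree on any shared species are
#' treated as distinct.
#'
#' @param per_seed Named list: seed label -> list of `ortholog_group`.
#' @param mode `"union"` or `"intersection"`.
#' @return Named list of `ortholog_group` objects sorted by gene id.
#' @export
merge_seed_groups <- function(per_seed, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(length(per_seed) >= 1L)
  per_seed <- lapply(per_seed, function(gs) {
    stats::setNames(gs, vapply(gs, `[[`, character(1), "gene_id"))
  })
  if (length(per_seed) == 1L) {
    g <- per_seed[[1]]
    return(g[order(names(g))])
  }
  if (mode == "union") {
    all_groups <- unlist(per_seed, recursive = FALSE, use.names = FALSE)
    all_groups <- all_groups[order(vapply(all_groups, `[[`, character(1),
                                          "gene_id"))]
    kept <- list()
    for (g in all_groups) {
      dup <- any(vapply(kept, groups_coincide, logical(1), g))
      if (!dup) kept[[g$gene_id]] <- g
    }
    if (length(kept) == 0L) return(kept)
    return(kept[order(names(kept))])
  }
  # intersection: a group counts iff every seed recovered a coinciding one
  base <- per_seed[[1]]
  others <- per_seed[-1]
  kept <- list()
  for (g in base) {
    matches <- list(g)
    ok <- TRUE
    for (s in others) {
      hit <- Filter(function(x) groups_coincide(g, x), s)
      if (length(hit) == 0L) { ok <- FALSE; break }
      matches <- c(matches, hit[1])
    }
    if (!ok) next
    ids <- vapply(matches, `[[`, character(1), "gene_id")
    best <- matches[[order(ids)[1]]]
    kept[[best$gene_id]] <- best
  }
  if (length(kept) == 0L) return(kept)
  kept[order(names(kept))]
}

#' Tabulate ortholog groups
#'
#' @param groups List of `ortholog_group` objects.
#' @param path Optional TSV output path.
#' @return A data.frame with columns `gene_id`, `seed`, `species`,
#'   `member_id`.
#' @export
ortholog_table <- function(groups, path = NULL) {
  rows <- lapply(groups, function(g) {
    data.frame(gene_id = g$gene_id, seed = g$seed,
               species = names(g$members), member_id = unname(g$members),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- data.frame(gene_id = character(0), seed = character(0),
                     species = character(0), member_id = character(0))
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
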