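# Hold-out validation of a selected marker set: one-species-at-a-time
# placement (test A) and cross-validation on an independent species set
# (test B).

#' Extract held-out species' homolog sequences from full alignments
#'
#' Builds the per-species homolog structure consumed by
#' [one_species_at_a_time()] from alignments that already contain the
#' held-out species (the situation in simulated benchmarks, where homolog
#' detection is exact).
#'
#' @param alignments Named list of [gene_alignment()] objects over all
#'   species.
#' @param v_species Held-out species labels.
#' @return Named list: species -> named list (gene id -> character vector
#'   of aligned homolog sequences; length one means usable single copy).
#' @export
holdout_homologs <- function(alignments, v_species) {
  out <- lapply(v_species, function(sp) {
    genes <- Filter(function(a) sp %in% names(a$seqs), alignments)
    stats::setNames(lapply(genes, function(a) unname(a$seqs[sp])),
                    names(genes))
  })
  stats::setNames(out, v_species)
}

# Append the held-out species' single-copy homolog row to a training
# alignment; genes without exactly one homolog are left unchanged (the
# species is gap-filled at concatenation time).
append_holdout_row <- function(aln, species, hom) {
  if (is.null(hom) || length(hom) != 1L) return(aln)
  if (nchar(hom) != aln$length) {
    stop(sprintf("homolog for %s in %s has length %d, alignment has %d",
                 species, aln$gene_id, nchar(hom), aln$length))
  }
  seqs <- c(aln$seqs, stats::setNames(hom, species))
  gene_alignment(aln$gene_id, seqs)
}

splits_containing <- function(tree, species) {
  b <- bipartition_set(tree)
  keep <- vapply(b$sides, function(s) species %in% s, logical(1))
  b$keys[keep]
}

#' One-species-at-a-time validation (test A)
#'
#' For each held-out species x, the training reference tree is expanded by
#' re-inferring over the training species plus x from the concatenation of
#' ALL widespread genes (x's homolog rows appended where available, gap
#' filled otherwise). A marker tree over the same species is inferred from
#' the marker genes alone, dropping for that species any marker without
#' exactly one homolog. The species is considered correctly placed when
#' the bipartitions whose canonical (smaller) side contains x are identical
#' in the two trees; the fraction of wrong splits over the whole tree is
#' reported separately as the normalized RF distance.
#'
#' @param marker_set Selected marker gene ids.
#' @param t_alignments Named list of all widespread gene alignments over
#'   the training species.
#' @param v_homologs Per-species homolog lists, as from
#'   [holdout_homologs()].
#' @param builder Tree builder (default [nj_builder()]).
#' @return An object of class `validation_report` with `mode = "one_species"`,
#'   a `per_species` data.frame (species, markers_found, markers_total,
#'   placement_correct, wrong_split_fraction, untestable) and a `pass`
#'   flag (all testable species placed correctly).
#' @export
one_species_at_a_time <- function(marker_set, t_alignments, v_homologs,
                                  builder = nj_builder()) {
  stopifnot(length(marker_set) >= 1L, length(t_alignments) >= 1L)
  missing_markers <- setdiff(marker_set, names(t_alignments))
  if (length(missing_markers)) {
    stop(sprintf("marker genes absent from training alignments: %s",
                 paste(missing_markers, collapse = ", ")))
  }
  per <- data.frame(species = character(0), markers_found = integer(0),
                    markers_total = integer(0), placement_correct = logical(0),
                    wrong_split_fraction = numeric(0), untestable = logical(0),
                    stringsAsFactors = FALSE)
  trees <- list()
  for (x in names(v_homologs)) {
    hx <- v_homologs[[x]]
    usable <- names(hx)[vapply(hx, length, integer(1)) == 1L]
    found <- intersect(marker_set, usable)
    if (length(found) == 0L) {
      per[nrow(per) + 1L, ] <- list(x, 0L, length(marker_set), NA, NA_real_,
                                    TRUE)
      next
    }
    expanded <- lapply(t_alignments, function(a) {
      hom <- if (a$gene_id %in% usable) hx[[a$gene_id]] else NULL
      append_holdout_row(a, x, hom)
    })
    t_species <- sort(unique(unlist(lapply(t_alignments,
                                           function(a) names(a$seqs)))))
    ref_x <- builder(concatenate_alignments(expanded,
                                            species = c(t_species, x)))
    mk_tree <- builder(concatenate_alignments(expanded[found],
                                              species = c(t_species, x)))
    wsf <- rf_distance(ref_x, mk_tree)$normalized
    placed <- setequal(splits_containing(ref_x, x),
                       splits_containing(mk_tree, x))
    per[nrow(per) + 1L, ] <- list(x, length(found), length(marker_set),
                                  placed, wsf, FALSE)
    trees[[x]] <- list(reference = ref_x, marker = mk_tree)
  }
  testable <- !per$untestable
  structure(list(mode = "one_species", per_species = per, trees = trees,
                 pass = all(per$placement_correct[testable])),
            class = "validation_report")
}

#' Cross-validation on the held-out species set (test B)
#'
#' Using only the validation species: a new reference topology is inferred
#' from the concatenation of all single-copy genes, a marker topology from
#' the marker-gene concatenation, and the two are compared by RF distance.
#'
#' @param marker_set Selected marker gene ids (markers absent from
#'   `v_alignments` are dropped with a warning).
#' @param v_alignments Named list of gene alignments over the validation
#'   species (at least 4 species).
#' @param builder Tree builder (default [nj_builder()]).
#' @param threshold Maximum normalized RF for a pass (default 0).
#' @return An object of class `validation_report` with `mode = "cross"`,
#'   fields `reference_tree`, `marker_tree`, `rf`, `normalized_rf`,
#'   `markers_used` and `pass`.
#' @export
cross_validate <- function(marker_set, v_alignments, builder = nj_builder(),
                           threshold = 0) {
  stopifnot(length(v_alignments) >= 1L)
  v_species <- sort(unique(unlist(lapply(v_alignments,
                                         function(a) names(a$seqs)))))
  if (length(v_species) < 4L) {
    stop("cross-validation needs at least 4 held-out species")
  }
  present <- intersect(marker_set, names(v_alignments))
  absent <- setdiff(marker_set, present)
  if (length(absent)) {
    warning(sprintf("markers absent from the validation gene set: %s",
                    paste(absent, collapse = ", ")))
  }
  if (length(present) == 0L) stop("no marker genes in the validation set")
  ref <- builder(concatenate_alignments(v_alignments, species = v_species))
  mk <- builder(concatenate_alignments(v_alignments[present],
                                       species = v_species))
  rf <- rf_distance(ref, mk)
  structure(list(mode = "cross", reference_tree = ref, marker_tree = mk,
                 rf = rf$rf, normalized_rf = rf$normalized,
                 markers_used = present, threshold = threshold,
                 pass = rf$normalized <= threshold),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$mode == "cross") {
    cat(sprintf(
      "<validation_report: cross> rf %d, normalized %.4f, %d markers, pass: %s\n",
      x$rf, x$normalized_rf, length(x$markers_used), x$pass))
  } else {
    p <- x$per_species
    cat(sprintf(
      "<validation_report: one-species> %d species (%d untestable), %d correctly placed, pass: %s\n",
      nrow(p), sum(p$untestable), sum(p$placement_correct, na.rm = TRUE),
      x$pass))
  }
  invisible(x)
}
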