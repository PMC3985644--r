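# Marker selection: rank genes by the topological distance of their trees
# to a concatenation-based reference, grow an initial marker set by
# progressive concatenation, and minimize it by randomized and exhaustive
# subset search.

#' Selection configuration
#'
#' @param measure Distance used to score candidate trees against the
#'   reference: `"rf"` (Robinson-Foulds, default), `"nrf"` (normalized RF)
#'   or `"nodal"`.
#' @param cutoff Maximum acceptable distance to the reference (default 0:
#'   exact topology recovery).
#' @param start_n First concatenation size tried by the progressive phase
#'   (default 2).
#' @param max_random_iterations Number of distinct subsets the random
#'   search evaluates before stopping (default 100); the search never
#'   stops on a found-smaller success before this many evaluations unless
#'   the candidate space is exhausted first.
#' @param restart_rounds Number of times a found smaller set may seed a new
#'   search round (default 0: single round).
#' @param constrain_to_current Restrict random subsampling to the current
#'   marker set instead of the whole gene pool.
#' @param rng_seed Seed driving the random search.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(measure = c("rf", "nrf", "nodal"), cutoff = 0,
                             start_n = 2L, max_random_iterations = 100L,
                             restart_rounds = 0L,
                             constrain_to_current = FALSE, rng_seed = 1L) {
  measure <- match.arg(measure)
  stopifnot(cutoff >= 0, start_n >= 1, max_random_iterations >= 1,
            restart_rounds >= 0)
  structure(list(measure = measure, cutoff = cutoff,
                 start_n = as.integer(start_n),
                 max_random_iterations = as.integer(max_random_iterations),
                 restart_rounds = as.integer(restart_rounds),
                 constrain_to_current = isTRUE(constrain_to_current),
                 rng_seed = as.integer(rng_seed)),
            class = "selection_config")
}

#' Distance between a candidate tree and the reference
#'
#' @param tree,reference `phylo` trees over the same leaf set.
#' @param measure `"rf"`, `"nrf"` or `"nodal"`.
#' @return Non-negative numeric.
#' @export
tree_distance <- function(tree, reference, measure = "rf") {
  switch(measure,
         rf = rf_distance(tree, reference)$rf,
         nrf = rf_distance(tree, reference)$normalized,
         nodal = nodal_distance(tree, reference),
         stop(sprintf("unknown measure '%s'", measure)))
}

# Returns a function(gene_ids) -> phylo building the tree of the
# concatenation of those genes. For the built-in NJ builder, per-gene
# pairwise comparable/mismatch counts are cached once; counts are additive
# across concatenated blocks under pairwise deletion, so summing them is
# exactly equivalent to concatenating and recomputing (verified in the
# test suite). Any other builder falls back to explicit concatenation.
make_subset_builder <- function(alignments, builder) {
  stopifnot(length(alignments) >= 1L)
  if (!inherits(builder, "nj_builder")) {
    force(builder)
    return(function(gene_ids) {
      builder(concatenate_alignments(alignments[gene_ids]))
    })
  }
  correction <- attr(builder, "correction")
  p_cap <- attr(builder, "p_cap")
  d_cap <- attr(builder, "d_cap")
  all_sp <- sort(unique(unlist(lapply(alignments, function(a) names(a$seqs)))))
  nsp <- length(all_sp)
  zero <- matrix(0, nsp, nsp, dimnames = list(all_sp, all_sp))
  counts <- lapply(alignments, function(a) {
    pc <- pair_counts(a$seqs)
    sp <- rownames(pc$ncomp)
    nc <- zero; nm <- zero
    nc[sp, sp] <- pc$ncomp
    nm[sp, sp] <- pc$nmis
    list(ncomp = nc, nmis = nm, species = sp)
  })
  function(gene_ids) {
    stopifnot(all(gene_ids %in% names(alignments)))
    nc <- zero; nm <- zero
    present <- character(0)
    for (g in gene_ids) {
      nc <- nc + counts[[g]]$ncomp
      nm <- nm + counts[[g]]$nmis
      present <- union(present, counts[[g]]$species)
    }
    present <- sort(present)
    dm <- dist_from_counts(nc[present, present, drop = FALSE],
                           nm[present, present, drop = FALSE],
                           correction = correction, p_cap = p_cap,
                           d_cap = d_cap)
    neighbor_joining(dm)
  }
}

#' Build the reference phylogeny from all genes
#'
#' The reference topology is the tree inferred from the concatenation of
#' every available gene alignment.
#'
#' @param alignments Non-empty list of [gene_alignment()] objects.
#' @param builder A tree builder (default [nj_builder()]).
#' @return A `phylo` tree.
#' @export
build_reference <- function(alignments, builder = nj_builder()) {
  builder(concatenate_alignments(alignments))
}

#' Rank marker genes by informativeness
#'
#' Builds one tree per gene and scores it by its distance to the reference;
#' genes are ranked in ascending distance order (most informative first),
#' ties broken by gene id. Genes missing any reference species are excluded
#' with a warning; gene trees carrying extra species are pruned to the
#' reference leaf set before comparison.
#'
#' @param alignments Named list of [gene_alignment()] objects.
#' @param reference Reference `phylo` tree.
#' @param builder Tree builder (default [nj_builder()]).
#' @param measure `"rf"`, `"nrf"` or `"nodal"`.
#' @param .subset_fn Internal: reuse a cached subset builder.
#' @return A data.frame of class `marker_ranking` with columns `gene_id`,
#'   `distance`, `rank`.
#' @export
rank_markers <- function(alignments, reference, builder = nj_builder(),
                         measure = "rf", .subset_fn = NULL) {
  ref_sp <- sort(reference$tip.label)
  covered <- vapply(alignments, function(a) all(ref_sp %in% names(a$seqs)),
                    logical(1))
  if (any(!covered)) {
    warning(sprintf("genes excluded (missing reference species): %s",
                    paste(names(alignments)[!covered], collapse = ", ")))
  }
  alignments <- alignments[covered]
  if (length(alignments) == 0L) stop("no scorable genes")
  fn <- .subset_fn %||% make_subset_builder(alignments, builder)
  dist <- vapply(names(alignments), function(g) {
    tr <- fn(g)
    if (length(tr$tip.label) > length(ref_sp)) tr <- ape::keep.tip(tr, ref_sp)
    tree_distance(tr, reference, measure)
  }, numeric(1))
  ord <- order(dist, names(alignments))
  df <- data.frame(gene_id = names(alignments)[ord],
                   distance = unname(dist[ord]),
                   rank = seq_along(ord), stringsAsFactors = FALSE)
  class(df) <- c("marker_ranking", "data.frame")
  df
}

#' Progressive concatenation of top-ranked genes
#'
#' Concatenates genes in decreasing informativeness order and finds the
#' smallest n (from `cfg$start_n` up) whose top-n concatenation tree is
#' within `cfg$cutoff` of the reference. Distances are re-evaluated at
#' every n, never assumed monotone. If no n reaches the cutoff all genes
#' are returned flagged as not converged.
#'
#' @param ranked A [rank_markers()] result.
#' @param alignments Named list of alignments covering the ranked genes.
#' @param reference Reference `phylo` tree.
#' @param cfg A [selection_config()].
#' @param builder Tree builder.
#' @param .subset_fn Internal: reuse a cached subset builder.
#' @return List with `initial_set` (gene ids in rank order), `converged`
#'   flag and a `trace` data.frame (n, distance).
#' @export
progressive_concatenation <- function(ranked, alignments, reference,
                                      cfg = selection_config(),
                                      builder = nj_builder(),
                                      .subset_fn = NULL) {
  stopifnot(nrow(ranked) >= 1L)
  genes <- ranked$gene_id
  fn <- .subset_fn %||% make_subset_builder(alignments[genes], builder)
  trace <- data.frame(n = integer(0), distance = numeric(0))
  for (n in seq(min(cfg$start_n, length(genes)), length(genes))) {
    d <- tree_distance(fn(genes[seq_len(n)]), reference, cfg$measure)
    trace[nrow(trace) + 1L, ] <- list(n, d)
    if (d <= cfg$cutoff) {
      return(list(initial_set = genes[seq_len(n)], converged = TRUE,
                  trace = trace))
    }
  }
  list(initial_set = genes, converged = FALSE, trace = trace)
}

new_selection_result <- function(initial_set, final_set, trace, termination,
                                 rng_seed, qualifying = NULL) {
  structure(list(initial_set = initial_set, final_set = final_set,
                 trace = trace, termination = termination,
                 rng_seed = rng_seed, qualifying = qualifying),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d -> %d genes [%s], %d subsets evaluated (seed %s)\n",
    length(x$initial_set), length(x$final_set), x$termination,
    nrow(x$trace), x$rng_seed %||% "NA"))
  invisible(x)
}

empty_trace <- function() {
  data.frame(round = integer(0), subset = character(0), size = integer(0),
             distance = numeric(0), accepted = logical(0),
             stringsAsFactors = FALSE)
}

#' Randomized search for smaller qualifying marker sets
#'
#' Draws subsets of size 2..m-1 (m the current set size) from the gene
#' pool: the size is sampled uniformly among non-exhausted sizes, then
#' members uniformly. No subset is evaluated twice, so exhaustion of the
#' candidate space is decidable. The round stops when (i) all combinations
#' have been explored or (iii) `cfg$max_random_iterations` distinct subsets
#' have been evaluated; a qualifying smaller subset (ii) is reported after
#' the iteration budget so that at least that many combinations are always
#' explored. If one was found and `cfg$restart_rounds > 0`, it becomes the
#' new current set and the search repeats with the remaining restart
#' budget (constrained to the current set when
#' `cfg$constrain_to_current`).
#'
#' @param pool Gene ids to sample from (ignored and replaced by `current`
#'   when `cfg$constrain_to_current`).
#' @param current Current marker set (the initial marker set).
#' @param alignments Named list of alignments covering the pool.
#' @param reference Reference `phylo` tree.
#' @param cfg A [selection_config()].
#' @param builder Tree builder.
#' @param .subset_fn Internal: reuse a cached subset builder.
#' @return A `selection_result`: `initial_set`, `final_set`, `trace`
#'   (round, subset, size, distance, accepted), `termination` one of
#'   `"exhausted"`, `"found_smaller"`, `"iteration_cap"`, and `rng_seed`.
#' @export
random_subset_search <- function(pool, current, alignments, reference,
                                 cfg = selection_config(),
                                 builder = nj_builder(),
                                 .subset_fn = NULL) {
  if (cfg$constrain_to_current) pool <- current
  pool <- sort(union(pool, current))
  fn <- .subset_fn %||% make_subset_builder(alignments[pool], builder)
  initial <- current
  trace <- empty_trace()
  termination <- "exhausted"
  withr::with_seed(cfg$rng_seed, {
    rounds_left <- cfg$restart_rounds
    round_i <- 0L
    repeat {
      round_i <- round_i + 1L
      m <- length(current)
      if (m < 3L) {
        # nothing left to search; keep the cause from a previous round's
        # success if one shrank the set already
        if (length(current) >= length(initial)) termination <- "exhausted"
        break
      }
      round_pool <- if (cfg$constrain_to_current) sort(current) else pool
      sizes <- 2:(m - 1L)
      totals <- choose(length(round_pool), sizes)
      names(totals) <- as.character(sizes)
      seen <- new.env(hash = TRUE, parent = emptyenv())
      evaluated <- stats::setNames(rep(0, length(sizes)),
                                   as.character(sizes))
      enum <- list()   # lazily enumerated candidate lists for small spaces
      best <- NULL
      n_eval <- 0L
      exhausted_all <- FALSE
      while (n_eval < cfg$max_random_iterations) {
        open <- sizes[evaluated[as.character(sizes)] <
                        totals[as.character(sizes)]]
        if (length(open) == 0L) { exhausted_all <- TRUE; break }
        k <- if (length(open) == 1L) open else sample(open, 1L)
        kc <- as.character(k)
        subset <- NULL
        if (totals[[kc]] <= 5000) {
          if (is.null(enum[[kc]])) {
            combos <- utils::combn(round_pool, k, simplify = FALSE)
            enum[[kc]] <- combos
          }
          remaining <- Filter(function(s) {
            is.null(seen[[subset_key(s)]])
          }, enum[[kc]])
          subset <- remaining[[sample.int(length(remaining), 1L)]]
        } else {
          repeat {
            cand <- sample(round_pool, k)
            if (is.null(seen[[subset_key(cand)]])) { subset <- cand; break }
          }
        }
        key <- subset_key(subset)
        seen[[key]] <- TRUE
        evaluated[[kc]] <- evaluated[[kc]] + 1
        n_eval <- n_eval + 1L
        d <- tree_distance(fn(subset), reference, cfg$measure)
        ok <- d <= cfg$cutoff
        trace[nrow(trace) + 1L, ] <- list(round_i, paste(sort(subset),
                                                         collapse = "+"),
                                          as.integer(k), d, ok)
        if (ok) {
          if (is.null(best) ||
              length(subset) < length(best$subset) ||
              (length(subset) == length(best$subset) &&
                 (d < best$distance ||
                    (d == best$distance && key < best$key)))) {
            best <- list(subset = sort(subset), distance = d, key = key)
          }
        }
      }
      if (!is.null(best)) {
        termination <- "found_smaller"
        current <- best$subset
        if (rounds_left > 0L) { rounds_left <- rounds_left - 1L; next }
        break
      }
      termination <- if (exhausted_all) "exhausted" else "iteration_cap"
      break
    }
  })
  new_selection_result(initial, sort(current), trace, termination,
                       cfg$rng_seed)
}

#' Exhaustive search over all subsets of given sizes
#'
#' Evaluates every subset of the current marker set at each requested size
#' and records all distances. The final set is the smallest qualifying
#' subset, ties broken by best distance and then lexicographic gene ids;
#' all qualifying subsets are retained in the result so a larger set can be
#' kept deliberately when it performs better across validation tests.
#'
#' @param current Current marker set gene ids.
#' @param alignments Named list of alignments covering `current`.
#' @param reference Reference `phylo` tree.
#' @param cfg A [selection_config()].
#' @param sizes Integer vector of subset sizes (default 2..m-1).
#' @param budget Maximum number of subsets allowed (error above; use the
#'   random search instead).
#' @param builder Tree builder.
#' @param .subset_fn Internal: reuse a cached subset builder.
#' @return A `selection_result` whose `qualifying` field tabulates every
#'   subset within the cutoff.
#' @export
exhaustive_subset_search <- function(current, alignments, reference,
                                     cfg = selection_config(),
                                     sizes = NULL, budget = 1e5,
                                     builder = nj_builder(),
                                     .subset_fn = NULL) {
  m <- length(current)
  stopifnot(m >= 2L)
  if (is.null(sizes)) sizes <- seq(2L, max(2L, m - 1L))
  sizes <- sort(unique(as.integer(sizes)))
  sizes <- sizes[sizes >= 2L & sizes <= m]
  if (length(sizes) == 0L) stop("no valid subset sizes")
  total <- sum(choose(m, sizes))
  if (total > budget) {
    stop(sprintf(
      "exhaustive search would evaluate %.0f subsets (budget %.0f); use random_subset_search",
      total, budget))
  }
  fn <- .subset_fn %||% make_subset_builder(alignments[current], builder)
  trace <- empty_trace()
  best <- NULL
  for (k in sizes) {
    combos <- utils::combn(sort(current), k, simplify = FALSE)
    for (subset in combos) {
      d <- tree_distance(fn(subset), reference, cfg$measure)
      ok <- d <= cfg$cutoff
      trace[nrow(trace) + 1L, ] <- list(1L, paste(subset, collapse = "+"),
                                        as.integer(k), d, ok)
      if (ok) {
        key <- subset_key(subset)
        if (is.null(best) ||
            length(subset) < length(best$subset) ||
            (length(subset) == length(best$subset) &&
               (d < best$distance ||
                  (d == best$distance && key < best$key)))) {
          best <- list(subset = subset, distance = d, key = key)
        }
      }
    }
  }
  qualifying <- trace[trace$accepted, c("subset", "size", "distance")]
  if (is.null(best)) {
    res <- new_selection_result(current, sort(current), trace, "exhausted",
                                NULL, qualifying)
  } else {
    term <- if (length(best$subset) < m) "found_smaller" else "exhausted"
    res <- new_selection_result(current, best$subset, trace, term, NULL,
                                qualifying)
  }
  res
}

#' Select a minimal marker gene set
#'
#' End-to-end selection: build the reference from the concatenation of all
#' genes (unless one is supplied), rank genes by informativeness, grow the
#' initial marker set by progressive concatenation, then minimize it by
#' random or exhaustive subset search. The final set's distance to the
#' reference is re-evaluated after selection.
#'
#' @param alignments Named list of [gene_alignment()] objects.
#' @param reference Optional reference `phylo` tree; built from all genes
#'   when `NULL`.
#' @param cfg A [selection_config()].
#' @param builder Tree builder (default [nj_builder()]).
#' @param search `"random"` (default), `"exhaustive"` or `"none"` (keep the
#'   initial marker set).
#' @param exhaustive_sizes Sizes for the exhaustive search (default
#'   2..m-1).
#' @return An object of class `marker_selection`: `reference`, `ranking`,
#'   `initial_set`, `converged`, `progressive_trace`, `selection` (a
#'   `selection_result` or `NULL`), `final_set`, `final_distance`, `cfg`.
#' @export
select_minimal_set <- function(alignments, reference = NULL,
                               cfg = selection_config(),
                               builder = nj_builder(),
                               search = c("random", "exhaustive", "none"),
                               exhaustive_sizes = NULL) {
  search <- match.arg(search)
  stopifnot(length(alignments) >= 1L)
  if (is.null(names(alignments))) {
    names(alignments) <- vapply(alignments, `[[`, character(1), "gene_id")
  }
  if (is.null(reference)) reference <- build_reference(alignments, builder)
  fn <- make_subset_builder(alignments, builder)
  ranking <- rank_markers(alignments, reference, builder, cfg$measure,
                          .subset_fn = fn)
  prog <- progressive_concatenation(ranking, alignments, reference, cfg,
                                    builder, .subset_fn = fn)
  sel <- NULL
  final <- prog$initial_set
  if (prog$converged && search != "none") {
    sel <- if (search == "random") {
      random_subset_search(ranking$gene_id, prog$initial_set, alignments,
                           reference, cfg, builder, .subset_fn = fn)
    } else {
      exhaustive_subset_search(prog$initial_set, alignments, reference, cfg,
                               sizes = exhaustive_sizes, builder = builder,
                               .subset_fn = fn)
    }
    final <- sel$final_set
  }
  final_distance <- tree_distance(fn(final), reference, cfg$measure)
  if (prog$converged && final_distance > cfg$cutoff) {
    stop("internal error: selected set no longer meets the cutoff")
  }
  structure(list(reference = reference, ranking = ranking,
                 initial_set = prog$initial_set, converged = prog$converged,
                 progressive_trace = prog$trace, selection = sel,
                 final_set = final, final_distance = final_distance,
                 cfg = cfg),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf(
    "<marker_selection> %d genes ranked; initial set %d%s; final set %d (distance %.4g)\n",
    nrow(x$ranking), length(x$initial_set),
    if (x$converged) "" else " (not converged)",
    length(x$final_set), x$final_distance))
  cat("final set:", paste(x$final_set, collapse = ", "), "\n")
  invisible(x)
}
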