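# Ranking, progressive concatenation, random and exhaustive subset search.

# Small concordant benchmark reused across tests (genes g01..g06 all evolve
# on the species tree, so each individually recovers it).
concordant_bench <- function(seed = 21, n_genes = 6) {
  cfg <- simulation_config(n_species = 10, n_genes = n_genes,
                           n_concordant = n_genes,
                           gene_length_range = c(1500, 1500),
                           mean_rate = 0.5)
  synthesize_benchmark(cfg, seed = seed)
}

test_that("cached NJ subset evaluation equals explicit concatenation", {
  ds <- concordant_bench()
  alns <- ds$alignments
  bld <- nj_builder()
  fn <- phylomarkr:::make_subset_builder(alns, bld)
  for (subset in list("g01", c("g02", "g05"), names(alns))) {
    direct <- bld(concatenate_alignments(alns[subset]))
    cached <- fn(subset)
    expect_identical(write_newick(cached), write_newick(direct))
  }
})

test_that("rank_markers orders by distance then gene id", {
  ds <- concordant_bench()
  ref <- build_reference(ds$alignments)
  # duplicate alignments force ties; tie-break must be lexicographic
  twins <- list(gB = gene_alignment("gB", ds$alignments$g01$seqs),
                gA = gene_alignment("gA", ds$alignments$g01$seqs))
  rk <- rank_markers(twins, ref)
  expect_identical(rk$gene_id, c("gA", "gB"))
  expect_identical(rk$rank, 1:2)
  expect_equal(rk$distance[1], rk$distance[2])

  # genes missing reference species are excluded with a warning
  partial <- gene_alignment("gP", ds$alignments$g01$seqs[1:5])
  expect_warning(rk2 <- rank_markers(c(twins, list(gP = partial)), ref),
                 "gP")
  expect_false("gP" %in% rk2$gene_id)
  expect_error(suppressWarnings(rank_markers(list(gP = partial), ref)),
               "no scorable genes")
})

test_that("progressive concatenation stops at the first qualifying n", {
  # canned builder: distance to ref depends only on how many genes are in
  # the concatenation (4, 2, 0 wrong splits for n = 2, 3, 4)
  ref <- parse_newick("((A,B),((C,D),(E,F)));")
  by_n <- list(`1` = "((A,C),((B,E),(D,F)));",
               `2` = "((A,C),((B,D),(E,F)));",
               `3` = "((A,B),C,(D,(E,F)));",
               `4` = "((A,B),((C,D),(E,F)));",
               `5` = "((A,B),((C,D),(E,F)));")
  fake_builder <- function(aln) {
    parse_newick(by_n[[as.character(nrow(aln$partitions))]])
  }
  seqs <- c(A = "AC", B = "AD", C = "CE", D = "CA", E = "KK", F = "KL")
  alns <- lapply(paste0("g", 1:5), function(g) gene_alignment(g, seqs))
  names(alns) <- paste0("g", 1:5)
  rk <- data.frame(gene_id = names(alns), distance = 0, rank = 1:5)
  prog <- progressive_concatenation(rk, alns, ref, selection_config(),
                                    builder = fake_builder)
  expect_true(prog$converged)
  expect_identical(prog$initial_set, c("g1", "g2", "g3", "g4"))
  expect_equal(prog$trace$distance, c(4, 2, 0))

  # unreachable cutoff: all genes, flagged not converged
  ref2 <- parse_newick("((A,E),((C,B),(D,F)));")
  prog2 <- progressive_concatenation(rk, alns, ref2, selection_config(),
                                     builder = fake_builder)
  expect_false(prog2$converged)
  expect_identical(prog2$initial_set, names(alns))

  # start_n = 1 permitted via explicit config
  prog3 <- progressive_concatenation(rk, alns, ref,
                                     selection_config(start_n = 1),
                                     builder = fake_builder)
  expect_equal(prog3$trace$n[1], 1)
})

test_that("random subset search finds a smaller qualifying set and dedups", {
  ds <- concordant_bench(n_genes = 3)
  alns <- ds$alignments
  ref <- build_reference(alns)
  cfg <- selection_config(rng_seed = 5)
  res <- random_subset_search(names(alns), names(alns), alns, ref, cfg)
  # only C(3,2) = 3 candidate subsets exist; dedup forces full coverage,
  # and every pair of concordant genes recovers the reference
  expect_equal(res$termination, "found_smaller")
  expect_length(res$final_set, 2)
  expect_lte(nrow(res$trace), 3)
  expect_false(any(duplicated(res$trace$subset)))
  expect_true(all(res$trace$accepted))

  # determinism: identical trace and final set for the same seed
  res2 <- random_subset_search(names(alns), names(alns), alns, ref, cfg)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$final_set, res2$final_set)

  # m < 3: nothing to search
  res3 <- random_subset_search(names(alns), names(alns)[1:2], alns, ref, cfg)
  expect_equal(res3$termination, "exhausted")
  expect_identical(res3$final_set, sort(names(alns)[1:2]))
  expect_equal(nrow(res3$trace), 0)
})

test_that("constrained search samples only within the current set", {
  ds <- concordant_bench(n_genes = 6)
  alns <- ds$alignments
  ref <- build_reference(alns)
  current <- c("g01", "g02", "g03", "g04")
  cfg <- selection_config(rng_seed = 3, constrain_to_current = TRUE,
                          max_random_iterations = 20)
  res <- random_subset_search(names(alns), current, alns, ref, cfg)
  subsets <- strsplit(res$trace$subset, "+", fixed = TRUE)
  expect_true(all(vapply(subsets, function(s) all(s %in% current),
                         logical(1))))
})

test_that("restart rounds refine the current set with remaining budget", {
  ds <- concordant_bench(n_genes = 5)
  alns <- ds$alignments
  ref <- build_reference(alns)
  cfg <- selection_config(rng_seed = 9, restart_rounds = 3,
                          max_random_iterations = 50)
  res <- random_subset_search(names(alns), names(alns), alns, ref, cfg)
  # every pair qualifies, so the search shrinks 5 -> 2 genes
  expect_length(res$final_set, 2)
  expect_equal(res$termination, "found_smaller")
  expect_false(any(duplicated(
    res$trace$subset[res$trace$round == 1])))
})

test_that("exhaustive search enumerates exactly the requested subsets", {
  ds <- concordant_bench(n_genes = 3)
  alns <- ds$alignments
  ref <- build_reference(alns)
  res <- exhaustive_subset_search(names(alns), alns, ref,
                                  selection_config(), sizes = 2)
  expect_equal(nrow(res$trace), 3)

  # no subset qualifies against a conflicting reference -> keep current
  ref_far <- nni_perturb(ref, 3, seed = 1)
  res2 <- exhaustive_subset_search(names(alns), alns, ref_far,
                                   selection_config(), sizes = 2)
  if (nrow(res2$qualifying) == 0) {
    expect_identical(res2$final_set, sort(names(alns)))
    expect_equal(res2$termination, "exhausted")
  }

  expect_error(exhaustive_subset_search(paste0("x", 1:30), alns, ref,
                                        selection_config(), budget = 100),
               "budget")
})

test_that("select_minimal_set orchestrates and re-validates the result", {
  ds <- concordant_bench(n_genes = 5)
  alns <- ds$alignments
  sel <- select_minimal_set(alns, cfg = selection_config(rng_seed = 2))
  expect_true(sel$converged)
  expect_lte(length(sel$final_set), length(sel$initial_set))
  expect_lte(length(sel$initial_set), length(alns))
  expect_equal(sel$final_distance, 0)
  # reference built from all genes recovers the species tree
  expect_equal(rf_distance(sel$reference, ds$species_tree)$rf, 0)

  # skip minimization: final = initial
  sel2 <- select_minimal_set(alns, cfg = selection_config(rng_seed = 2),
                             search = "none")
  expect_identical(sel2$final_set, sel2$initial_set)

  # same seed, same inputs -> identical results
  sel3 <- select_minimal_set(alns, cfg = selection_config(rng_seed = 2))
  expect_identical(sel3$final_set, sel$final_set)
  expect_identical(sel3$selection$trace, sel$selection$trace)
})
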