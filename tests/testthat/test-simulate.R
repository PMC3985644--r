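# Simulator: Yule trees, NNI perturbation, sequence evolution, benchmarks
# and planted hit tables.

test_that("yule_tree is deterministic and has the right shape", {
  t3 <- yule_tree(3, seed = 1)
  expect_setequal(t3$tip.label, c("S1", "S2", "S3"))
  expect_length(bipartition_set(t3)$keys, 0)  # unique unrooted topology

  expect_identical(write_newick(yule_tree(10, seed = 9)),
                   write_newick(yule_tree(10, seed = 9)))
  expect_false(identical(write_newick(yule_tree(10, seed = 9)),
                         write_newick(yule_tree(10, seed = 10))))

  t20 <- yule_tree(20, seed = 2)
  expect_length(bipartition_set(t20)$keys, 17)  # n - 3 splits
  expect_true(all(t20$edge.length >= 0))
  expect_error(yule_tree(2), "at least 3")
})

test_that("nni_perturb moves topology by one split per effective move", {
  tr <- yule_tree(8, seed = 4)
  expect_identical(bipartition_set(nni_perturb(tr, 0))$keys,
                   bipartition_set(tr)$keys)
  for (s in 1:10) {
    p1 <- nni_perturb(tr, 1, seed = s)
    expect_equal(rf_distance(tr, p1)$rf, 2)  # a single NNI always shifts one split
    expect_setequal(p1$tip.label, tr$tip.label)
  }
  p5 <- nni_perturb(tr, 5, seed = 1)
  expect_setequal(p5$tip.label, tr$tip.label)
  expect_error(nni_perturb(parse_newick("(A,B,C,D,E);"), 1), "binary")
})

test_that("evolve_sequences follows the equal-rates model", {
  tr <- yule_tree(6, seed = 3)
  a0 <- evolve_sequences(tr, 50, rate_multiplier = 0, seed = 1)
  expect_length(unique(a0$seqs), 1)  # rate 0: all identical
  expect_equal(a0$length, 50)

  # determinism and gap-free output
  a1 <- evolve_sequences(tr, 100, 0.5, seed = 7)
  a2 <- evolve_sequences(tr, 100, 0.5, seed = 7)
  expect_identical(a1$seqs, a2$seqs)
  expect_false(any(grepl("[-X]", a1$seqs)))

  notree <- parse_newick("(A,B,(C,D));")
  expect_error(evolve_sequences(notree, 10), "branch lengths")
})

test_that("mismatch fraction matches the closed-form p(t)", {
  # two leaves at total path length t = 0.3
  tr <- parse_newick("(A:0.15,B:0.15);")
  L <- 1e5
  aln <- evolve_sequences(tr, L, 1, seed = 42)
  a <- strsplit(aln$seqs[["A"]], "")[[1]]
  b <- strsplit(aln$seqs[["B"]], "")[[1]]
  p_obs <- mean(a != b)
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * 0.3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("synthesize_benchmark keeps its books and splits 2:1", {
  cfg <- simulation_config(n_species = 24, n_genes = 8, n_concordant = 3,
                           gene_length_range = c(50, 80),
                           discordance_nni_range = c(1, 4))
  ds <- synthesize_benchmark(cfg, seed = 6)
  expect_length(ds$alignments, 8)
  expect_equal(sum(ds$truth$concordant), 3)
  expect_length(ds$t_set, 16)
  expect_length(ds$v_set, 8)
  expect_length(intersect(ds$t_set, ds$v_set), 0)
  expect_setequal(c(ds$t_set, ds$v_set), ds$species_tree$tip.label)
  expect_true(all(ds$truth$nni_moves[ds$truth$concordant] == 0))
  expect_true(all(ds$truth$nni_moves[!ds$truth$concordant] >= 1))
  expect_true(all(ds$truth$length >= 50 & ds$truth$length <= 80))
  # both sets intersect every basal clade of size >= 2
  root <- ds$species_tree$edge[1, 1]
  kids <- ds$species_tree$edge[ds$species_tree$edge[, 1] == root, 2]
  ntip <- length(ds$species_tree$tip.label)
  for (k in kids) {
    cl <- if (k <= ntip) ds$species_tree$tip.label[k]
          else ape::extract.clade(ds$species_tree, k)$tip.label
    if (length(cl) >= 2) {
      expect_gt(length(intersect(cl, ds$t_set)), 0)
      expect_gt(length(intersect(cl, ds$v_set)), 0)
    }
  }
  # determinism
  ds2 <- synthesize_benchmark(cfg, seed = 6)
  expect_identical(ds$alignments$g01$seqs, ds2$alignments$g01$seqs)
  expect_identical(ds$t_set, ds2$t_set)
})

test_that("concordant genes sit closer to the species tree than 2+ NNI genes", {
  cfg <- simulation_config(n_species = 12, n_genes = 12, n_concordant = 4,
                           gene_length_range = c(2000, 2000),
                           discordance_nni_range = c(2, 5))
  for (seed in 1:3) {
    ds <- synthesize_benchmark(cfg, seed = seed)
    bld <- nj_builder()
    rfs <- vapply(names(ds$alignments), function(g) {
      rf_distance(bld(ds$alignments[[g]]), ds$species_tree)$rf
    }, numeric(1))
    conc <- ds$truth$concordant
    expect_lt(mean(rfs[conc]), mean(rfs[!conc & ds$truth$nni_moves >= 2]))
  }
})

test_that("synthesized hit tables plant paralogs and losses as recorded", {
  cfg <- simulation_config(n_species = 9, n_genes = 20, n_concordant = 20,
                           gene_length_range = c(60, 90))
  ds <- synthesize_benchmark(cfg, seed = 2)
  ht <- synthesize_hit_tables(ds, paralog_rate = 0.15, loss_rate = 0.1,
                              seed = 2)
  expect_true(all(ht$hits$e_value <= 1e-20))
  expect_true(all(ht$hits$query_coverage > 0.5))
  n_par <- sum(ht$planted$type == "paralog")
  n_loss <- sum(ht$planted$type == "loss")
  expect_gt(n_par, 0)
  expect_gt(n_loss, 0)
  # planted paralogs appear as a second target in that genome
  pr <- ht$planted[ht$planted$type == "paralog", ][1, ]
  in_gen <- ht$hits[ht$hits$target_genome == pr$genome &
                      grepl(paste0("\\|", pr$gene_id, "($|\\|)"),
                            ht$hits$sseqid), ]
  expect_equal(nrow(in_gen), 2)
  # planted losses leave no hit for that gene x genome
  lo <- ht$planted[ht$planted$type == "loss", ][1, ]
  gone <- ht$hits[ht$hits$target_genome == lo$genome &
                    grepl(paste0("\\|", lo$gene_id, "($|\\|)"),
                          ht$hits$sseqid), ]
  expect_equal(nrow(gone), 0)
  # clean_genes is the complement of planted gene ids
  expect_setequal(ht$clean_genes,
                  setdiff(ds$truth$gene_id, ht$planted$gene_id))
  # determinism
  ht2 <- synthesize_hit_tables(ds, 0.15, 0.1, seed = 2)
  expect_identical(ht$hits$sseqid, ht2$hits$sseqid)
})

test_that("write_benchmark persists a loadable dataset", {
  cfg <- simulation_config(n_species = 8, n_genes = 3, n_concordant = 2,
                           gene_length_range = c(40, 40),
                           discordance_nni_range = c(1, 2))
  ds <- synthesize_benchmark(cfg, seed = 5)
  dir <- file.path(tempdir(), "bench_out")
  write_benchmark(ds, dir)
  expect_true(file.exists(file.path(dir, "species_tree.nwk")))
  back <- parse_newick(readLines(file.path(dir, "species_tree.nwk")))
  expect_identical(bipartition_set(back)$keys,
                   bipartition_set(ds$species_tree)$keys)
  g1 <- read_fasta_alignment(file.path(dir, "genes", "g01.fasta"))
  expect_identical(g1$seqs, ds$alignments$g01$seqs)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 3)
  unlink(dir, recursive = TRUE)
})
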