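# Newick / FASTA / hit-table IO and supermatrix construction.

test_that("parse_newick reads topology and branch lengths", {
  tr <- parse_newick("(A,B,(C,D));")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  b <- bipartition_set(tr)
  expect_length(b$keys, 1)
  # {A,B}|{C,D}: on a size tie the lexicographically smaller side is stored
  expect_equal(b$sides[[1]], c("A", "B"))

  tr2 <- parse_newick("(A:0.1,B:0.2,(C:0.3,D:0.4):0.5);")
  expect_length(tr2$edge.length, 5)
  expect_setequal(tr2$edge.length, c(0.1, 0.2, 0.3, 0.4, 0.5))
})

test_that("parse_newick rejects malformed input with positions", {
  expect_error(parse_newick("((A,B),(C,A));"), "duplicate leaf label: A")
  expect_error(parse_newick("((A,B),(C,D);"), "unbalanced")
  expect_error(parse_newick("(A,B)),C;"), "position 6")
  expect_error(parse_newick("(A,B),(C,D));(E,F);"), "single Newick")
  expect_error(parse_newick("(A,B)"), "terminated by ';'")
  expect_error(parse_newick("(,B);"), "empty leaf label|malformed")
})

test_that("write_newick round trips splits and branch lengths", {
  tr <- parse_newick("((A:0.123456789,B:1e-05):0.5,(C:2,D:3):0.25);")
  back <- parse_newick(write_newick(tr))
  expect_identical(bipartition_set(back)$keys, bipartition_set(tr)$keys)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  # single-leaf degenerate case
  expect_identical(write_newick(parse_newick("A;")), "A;")
})

test_that("newick round trip preserves 1000 random simulated trees", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(4:20, 1)
    tr <- random_metric_tree(n, 1e-4, 2)
    back <- parse_newick(write_newick(tr))
    expect_identical(bipartition_set(back)$keys, bipartition_set(tr)$keys)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("read_fasta_alignment validates and upper-cases", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">sp1 some description", "acdefghikl",
               ">sp2", "ACDEFGHIK-", ">sp3", "acdefgh--x"), fa)
  aln <- read_fasta_alignment(fa, gene_id = "g1")
  expect_equal(aln$length, 10)
  expect_named(aln$seqs, c("sp1", "sp2", "sp3"))
  expect_identical(unname(aln$seqs["sp1"]), "ACDEFGHIKL")
  expect_identical(unname(aln$seqs["sp3"]), "ACDEFGH--X")

  writeLines(c(">a", "ACDEFGHIKL", ">b", "ACDEFGHIK"), fa)
  expect_error(read_fasta_alignment(fa), "not aligned")
  writeLines(c(">a", "ACDEF", ">a", "ACDEF"), fa)
  expect_error(read_fasta_alignment(fa), "duplicate header")
})

test_that("concatenation tiles partitions and gap-fills missing species", {
  sp5 <- c(s1 = "AAAAA", s2 = "CCCCC", s3 = "DDDDD", s4 = "EEEEE",
           s5 = "FFFFF")
  g1 <- gene_alignment("g1", vapply(sp5, function(s) strrep(s, 20),
                                    character(1)))  # length 100
  g2 <- gene_alignment("g2", vapply(sp5, function(s) strrep(s, 10),
                                    character(1)))  # length 50
  cc <- concatenate_alignments(list(g1, g2))
  expect_equal(cc$length, 150)
  expect_equal(cc$partitions$gene_id, c("g1", "g2"))
  expect_equal(cc$partitions$start, c(1, 101))
  expect_equal(cc$partitions$end, c(100, 150))

  # species X present only in g1 -> 50-gap block in g2's partition
  g1x <- gene_alignment("g1", c(g1$seqs, X = strrep("K", 100)))
  ccx <- concatenate_alignments(list(g1x, g2))
  expect_identical(substring(ccx$seqs[["X"]], 101, 150), strrep("-", 50))

  # single alignment: identity with one partition
  cc1 <- concatenate_alignments(list(g1))
  expect_identical(cc1$seqs, g1$seqs)
  expect_equal(nrow(cc1$partitions), 1)

  expect_error(concatenate_alignments(list()), "no alignments")
  expect_warning(concatenate_alignments(list(g1), species = c(names(sp5), "Z")),
                 "absent from every alignment")
})

test_that("extract_partition reproduces the original alignment", {
  set.seed(7)
  alns <- lapply(1:4, function(i) {
    sp <- paste0("s", sample(1:6, sample(4:6, 1)))
    seqs <- vapply(sp, function(s) {
      paste(sample(c("A", "C", "D", "E"), 30, replace = TRUE), collapse = "")
    }, character(1))
    gene_alignment(paste0("g", i), seqs)
  })
  cc <- concatenate_alignments(alns)
  expect_equal(cc$length, sum(vapply(alns, `[[`, integer(1), "length")))
  for (a in alns) {
    got <- extract_partition(cc, a$gene_id)
    expect_identical(got$seqs[sort(names(a$seqs))],
                     a$seqs[sort(names(a$seqs))])
  }
})

test_that("partition maps are written in both formats", {
  g1 <- toy_alignment("g1", a = "ACDE", b = "ACDF")
  g2 <- toy_alignment("g2", a = "KL", b = "KM")
  cc <- concatenate_alignments(list(g1, g2))
  tsv <- tempfile(); rax <- tempfile()
  write_partitions(cc, tsv, "tsv")
  got <- read.delim(tsv)
  expect_equal(got$start, c(1, 5))
  write_partitions(cc, rax, "raxml", model = "LG")
  expect_identical(readLines(rax), c("LG, g1 = 1-4", "LG, g2 = 5-6"))
})

test_that("read_hit_table computes coverage and reports bad lines", {
  f <- tempfile()
  line <- function(q, s, qs, qe, ev) {
    paste(q, s, "90.0", "160", "16", "0", qs, qe, "1", "160", ev, "300",
          sep = "\t")
  }
  writeLines(line("q1", "genomeA|p1", 1, 160, "1e-20"), f)
  h <- read_hit_table(f, c(q1 = 200), genome = "genomeA")
  expect_equal(h$query_coverage, 0.8)
  expect_equal(h$e_value, 1e-20)
  expect_identical(h$target_genome, "genomeA")

  writeLines("q1\ta\t90\t10\t1\t0\t1\t10\t1\t10\t1e-5", f)  # 11 columns
  expect_error(read_hit_table(f, c(q1 = 200), genome = "A"),
               "line 1: expected 12 columns")
  writeLines(line("q1", "x", 1, 160, "abc"), f)
  expect_error(read_hit_table(f, c(q1 = 200), genome = "A"),
               "non-numeric evalue")

  writeLines(character(0), f)
  empty <- read_hit_table(f, c(q1 = 200), genome = "A")
  expect_s3_class(empty, "hit_table")
  expect_equal(nrow(empty), 0)
})

test_that("hit tables round trip through the 12-column format", {
  cfg <- simulation_config(n_species = 9, n_genes = 5, n_concordant = 5,
                           gene_length_range = c(60, 80))
  ds <- synthesize_benchmark(cfg, seed = 3)
  ht <- synthesize_hit_tables(ds, 0.2, 0.1, seed = 3)
  f <- tempfile()
  write_hit_table(ht$hits, f)
  back <- read_hit_table(f, ht$query_lengths,
                         genome_map = function(id) {
                           strsplit(id, "|", fixed = TRUE)[[1]][1]
                         })
  expect_equal(nrow(back), nrow(ht$hits))
  expect_equal(sort(back$e_value), sort(ht$hits$e_value), tolerance = 1e-6)
  expect_equal(back$query_coverage, ht$hits$query_coverage,
               tolerance = 1e-9)
  expect_identical(sort(unique(back$target_genome)),
                   sort(unique(ht$hits$target_genome)))
})
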