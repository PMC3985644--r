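# Synthetic-data generator: Yule species trees, NNI-perturbed gene trees,
# equal-rates amino-acid sequence evolution, and hit tables with planted
# orthology structure. Every generator is deterministic per (config, seed).

#' Simulate a Yule (pure-birth) species tree
#'
#' Branch lengths come from exponential waiting times of a pure-birth
#' process; the tree is rescaled to unit height (so per-gene rate
#' multipliers control sequence divergence directly) and returned unrooted.
#' Leaves are labelled S1..Sn.
#'
#' @param n Number of species (>= 3).
#' @param birth_rate Birth rate of the pure-birth process; affects relative
#'   node depths only, since the tree is rescaled to unit height.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An unrooted `phylo` with branch lengths.
#' @export
yule_tree <- function(n, birth_rate = 1, seed = NULL) {
  if (n < 3L) stop("need at least 3 species")
  with_seed_if(seed, {
    tr <- ape::rphylo(n, birth = birth_rate, death = 0)
    tr$tip.label <- paste0("S", seq_len(n))
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / h
    as_unrooted(tr)
  })
}

#' Perturb a tree by random NNI moves
#'
#' Applies `k` successive nearest-neighbor-interchange moves at uniformly
#' chosen internal edges (via [phangorn::rNNI()]), modelling gene-tree
#' discordance. Branch lengths and the leaf set are preserved.
#'
#' @param tree A binary `phylo` tree with at least 4 leaves.
#' @param k Number of NNI moves (>= 0); `k = 0` returns the input.
#' @param seed Optional integer seed.
#' @return A `phylo` tree.
#' @export
nni_perturb <- function(tree, k, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), k >= 0)
  if (length(tree$tip.label) < 4L) stop("need at least 4 leaves for NNI")
  if (!ape::is.binary(tree)) stop("NNI perturbation requires a binary tree")
  if (k == 0L) return(tree)
  with_seed_if(seed, {
    out <- phangorn::rNNI(tree, moves = k, n = 1)
    if (inherits(out, "multiPhylo")) out <- out[[1]]
    out
  })
}

#' Evolve amino-acid sequences along a tree
#'
#' Simulates a continuous-time equal-rates model over the 20 amino acids:
#' the root sequence is uniform over states, and along a branch of length b
#' each site changes to a uniformly chosen different state with probability
#' p(b) = (19/20)(1 - exp(-(20/19) b r)), the exact matrix-exponential form
#' of the equal-rates model at rate multiplier r (branch lengths are in
#' expected substitutions per site at r = 1). Output is gap-free.
#'
#' @param tree A `phylo` with branch lengths.
#' @param length Number of alignment columns (>= 1).
#' @param rate_multiplier Per-gene rate scaling.
#' @param seed Optional integer seed.
#' @param gene_id Gene identifier for the returned alignment.
#' @return A [gene_alignment()] over the tree's leaves.
#' @export
evolve_sequences <- function(tree, length, rate_multiplier = 1, seed = NULL,
                             gene_id = "gene") {
  stopifnot(inherits(tree, "phylo"), length >= 1)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  with_seed_if(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    ntip <- base::length(tr$tip.label)
    nnode <- ntip + tr$Nnode
    states <- vector("list", nnode)
    root <- tr$edge[1, 1]
    states[[root]] <- sample.int(20L, length, replace = TRUE)
    for (k in seq_len(nrow(tr$edge))) {
      p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
      b <- tr$edge.length[k] * rate_multiplier
      pch <- (19 / 20) * (1 - exp(-(20 / 19) * b))
      s <- states[[p]]
      hit <- stats::runif(length) < pch
      nh <- sum(hit)
      if (nh > 0L) {
        shift <- sample.int(19L, nh, replace = TRUE)
        s[hit] <- ((s[hit] - 1L + shift) %% 20L) + 1L
      }
      states[[ch]] <- s
    }
    seqs <- vapply(seq_len(ntip), function(i) {
      paste(AA_ALPHABET[states[[i]]], collapse = "")
    }, character(1))
    names(seqs) <- tr$tip.label
    gene_alignment(gene_id, seqs)
  })
}

#' Simulation configuration
#'
#' Defaults describe the standard benchmark: 24 species split 2:1 into
#' training and validation sets, 40 genes of 2000 aligned amino acids of
#' which 10 are concordant with the species tree and 30 evolve on trees
#' perturbed by 2-6 NNI moves. Per-gene rates are `mean_rate` times a
#' Gamma(shape, shape) multiplier (mean 1).
#'
#' @param n_species Number of species.
#' @param n_genes Number of genes.
#' @param n_concordant Number of genes evolving on the species tree itself.
#' @param gene_length_range Inclusive range of alignment lengths.
#' @param rate_gamma_shape Shape of the per-gene rate multiplier
#'   distribution (Gamma with mean 1).
#' @param mean_rate Mean substitutions per site from root to tip (the
#'   species tree has unit height).
#' @param discordance_nni_range Inclusive range of NNI moves applied per
#'   discordant gene.
#' @param birth_rate Yule birth rate.
#' @param tv_split_fraction Fraction of species assigned to the training
#'   set (default 2/3).
#' @param rng_seed Default seed for [synthesize_benchmark()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 24, n_genes = 40,
                              n_concordant = 10,
                              gene_length_range = c(2000, 2000),
                              rate_gamma_shape = 2, mean_rate = 0.5,
                              discordance_nni_range = c(2, 6),
                              birth_rate = 1, tv_split_fraction = 2 / 3,
                              rng_seed = 1L) {
  stopifnot(n_species >= 4, n_genes >= 1, n_concordant >= 0,
            n_concordant <= n_genes,
            length(gene_length_range) == 2, all(gene_length_range >= 1),
            gene_length_range[1] <= gene_length_range[2],
            rate_gamma_shape > 0, mean_rate >= 0,
            length(discordance_nni_range) == 2,
            all(discordance_nni_range >= 1),
            tv_split_fraction > 0, tv_split_fraction < 1)
  structure(list(n_species = as.integer(n_species),
                 n_genes = as.integer(n_genes),
                 n_concordant = as.integer(n_concordant),
                 gene_length_range = as.integer(gene_length_range),
                 rate_gamma_shape = rate_gamma_shape,
                 mean_rate = mean_rate,
                 discordance_nni_range = as.integer(discordance_nni_range),
                 birth_rate = birth_rate,
                 tv_split_fraction = tv_split_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

# Training/validation split stratified over the subtrees hanging off the
# basal node, so that both sets intersect every major clade (of size >= 2).
stratified_tv_split <- function(tree, fraction) {
  sp <- tree$tip.label
  n <- length(sp)
  n_t <- round(fraction * n)
  n_t <- min(max(n_t, 1L), n - 1L)
  root <- tree$edge[1, 1]
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  clades <- lapply(kids, function(k) {
    if (k <= n) sp[k] else ape::extract.clade(tree, k)$tip.label
  })
  t_set <- character(0)
  for (cl in clades) {
    take <- round(fraction * length(cl))
    if (length(cl) >= 2L) take <- min(max(take, 1L), length(cl) - 1L)
    t_set <- c(t_set, sample(cl, take))
  }
  # adjust to the global training-set size, keeping >= 1 per side per
  # clade where the clade is big enough
  while (length(t_set) > n_t) {
    pool <- t_set[vapply(t_set, function(s) {
      cl <- clades[[which(vapply(clades, function(x) s %in% x, logical(1)))[1]]]
      sum(cl %in% t_set) > 1L || length(cl) < 2L
    }, logical(1))]
    if (!length(pool)) break
    t_set <- setdiff(t_set, sample(pool, 1))
  }
  while (length(t_set) < n_t) {
    v <- setdiff(sp, t_set)
    pool <- v[vapply(v, function(s) {
      cl <- clades[[which(vapply(clades, function(x) s %in% x, logical(1)))[1]]]
      sum(cl %in% v) > 1L || length(cl) < 2L
    }, logical(1))]
    if (!length(pool)) pool <- v
    t_set <- c(t_set, sample(pool, 1))
  }
  list(t_set = sort(t_set), v_set = sort(setdiff(sp, t_set)))
}

#' Generate a benchmark dataset with planted ground truth
#'
#' Simulates a species tree, partitions the species into training and
#' validation sets (stratified so both sets intersect every basal clade),
#' and evolves `n_genes` alignments: the first `n_concordant` genes on the
#' species tree itself, the rest on NNI-perturbed copies. The per-gene
#' generating tree, NNI count and rate are recorded as ground truth.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (defaults to `cfg$rng_seed`).
#' @return An object of class `simulated_dataset`: `species_tree`, `t_set`,
#'   `v_set`, `alignments` (named list of [gene_alignment()]),
#'   `gene_trees`, `truth` (data.frame), `config`, `seed`.
#' @export
synthesize_benchmark <- function(cfg = simulation_config(),
                                 seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed_if(seed, {
    sp_tree <- yule_tree(cfg$n_species, cfg$birth_rate, seed = NULL)
    split <- stratified_tv_split(sp_tree, cfg$tv_split_fraction)
    wid <- max(2L, nchar(as.character(cfg$n_genes)))
    gids <- sprintf(paste0("g%0", wid, "d"), seq_len(cfg$n_genes))
    alignments <- vector("list", cfg$n_genes)
    gene_trees <- vector("list", cfg$n_genes)
    truth <- data.frame(gene_id = gids, concordant = FALSE,
                        nni_moves = 0L, rate = NA_real_, length = NA_integer_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(cfg$n_genes)) {
      len <- if (cfg$gene_length_range[1] == cfg$gene_length_range[2]) {
        cfg$gene_length_range[1]
      } else {
        sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1L)
      }
      rate <- cfg$mean_rate *
        stats::rgamma(1, shape = cfg$rate_gamma_shape,
                      rate = cfg$rate_gamma_shape)
      concordant <- i <= cfg$n_concordant
      if (concordant) {
        k <- 0L
        gt <- sp_tree
      } else {
        rng <- cfg$discordance_nni_range
        k <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
        gt <- nni_perturb(sp_tree, k, seed = NULL)
      }
      alignments[[i]] <- evolve_sequences(gt, len, rate, seed = NULL,
                                          gene_id = gids[i])
      gene_trees[[i]] <- gt
      truth$concordant[i] <- concordant
      truth$nni_moves[i] <- k
      truth$rate[i] <- rate
      truth$length[i] <- len
    }
    names(alignments) <- gids
    names(gene_trees) <- gids
    structure(list(species_tree = sp_tree, t_set = split$t_set,
                   v_set = split$v_set, alignments = alignments,
                   gene_trees = gene_trees, truth = truth,
                   config = cfg, seed = seed),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %d species (%d train / %d validation), %d genes (%d concordant), seed %d\n",
    length(x$species_tree$tip.label), length(x$t_set), length(x$v_set),
    nrow(x$truth), sum(x$truth$concordant), x$seed))
  invisible(x)
}

#' Synthesize BLAST-style hit tables with planted orthology structure
#'
#' For every gene and every training genome other than the seed, emits one
#' strong hit (e-value <= 1e-20, query coverage >= 0.7). With probability
#' `paralog_rate` a second qualifying hit is added in that genome (planting
#' a single-copy violation); with probability `loss_rate` the hit is
#' omitted (planting an absence). Genes with no planted violation anywhere
#' are recorded in `clean_genes`: these are exactly the genes a strict
#' single-copy filter should recover.
#'
#' @param ds A [synthesize_benchmark()] dataset.
#' @param paralog_rate,loss_rate Planting probabilities in \[0, 1).
#' @param seed Integer seed.
#' @return List with `hits` (a `hit_table` data.frame), `query_lengths`,
#'   `seed_species`, `genomes`, `planted` (data.frame gene_id, genome,
#'   type) and `clean_genes`.
#' @export
synthesize_hit_tables <- function(ds, paralog_rate = 0, loss_rate = 0,
                                  seed = 1L) {
  stopifnot(inherits(ds, "simulated_dataset"),
            paralog_rate >= 0, paralog_rate < 1,
            loss_rate >= 0, loss_rate < 1)
  with_seed_if(seed, {
    seed_sp <- ds$t_set[1]
    genomes <- setdiff(ds$t_set, seed_sp)
    gids <- ds$truth$gene_id
    qlen <- stats::setNames(as.numeric(ds$truth$length),
                            paste0(seed_sp, "|", gids))
    rows <- list()
    planted <- data.frame(gene_id = character(0), genome = character(0),
                          type = character(0), stringsAsFactors = FALSE)
    mk_row <- function(q, s, ql) {
      span <- round(stats::runif(1, 0.7, 1) * ql)
      data.frame(qseqid = q, sseqid = s,
                 pident = round(stats::runif(1, 60, 95), 2),
                 length = span, mismatch = round(span * 0.2),
                 gapopen = sample(0:3, 1),
                 qstart = 1, qend = span, sstart = 1, send = span,
                 evalue = 10^stats::runif(1, -50, -20),
                 bitscore = round(stats::runif(1, 200, 1000), 1),
                 stringsAsFactors = FALSE)
    }
    for (i in seq_along(gids)) {
      g <- gids[i]
      q <- paste0(seed_sp, "|", g)
      for (gen in genomes) {
        if (stats::runif(1) < loss_rate) {
          planted[nrow(planted) + 1L, ] <- list(g, gen, "loss")
          next
        }
        r <- mk_row(q, paste0(gen, "|", g), qlen[[q]])
        r$target_genome <- gen
        rows[[length(rows) + 1L]] <- r
        if (stats::runif(1) < paralog_rate) {
          r2 <- mk_row(q, paste0(gen, "|", g, "|p2"), qlen[[q]])
          r2$target_genome <- gen
          rows[[length(rows) + 1L]] <- r2
          planted[nrow(planted) + 1L, ] <- list(g, gen, "paralog")
        }
      }
    }
    hits <- do.call(rbind, rows)
    hits$query_coverage <- pmin((abs(hits$qend - hits$qstart) + 1) /
                                  qlen[hits$qseqid], 1)
    hits$e_value <- hits$evalue
    hits$bit_score <- hits$bitscore
    class(hits) <- c("hit_table", "data.frame")
    clean <- setdiff(gids, unique(planted$gene_id))
    list(hits = hits, query_lengths = qlen, seed_species = seed_sp,
         genomes = genomes, planted = planted,
         clean_genes = sort(clean))
  })
}

#' Write a benchmark dataset to disk
#'
#' Writes `species_tree.nwk`, `genes/<gene>.fasta`, `truth.tsv` and
#' `tv_split.tsv` (plus `hits/<genome>.tsv` and `query_lengths.tsv` when a
#' hit-table set is supplied) under `dir`.
#'
#' @param ds A [synthesize_benchmark()] dataset.
#' @param dir Output directory (created if needed).
#' @param hit_tables Optional result of [synthesize_hit_tables()].
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(ds, dir, hit_tables = NULL) {
  stopifnot(inherits(ds, "simulated_dataset"))
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  writeLines(write_newick(ds$species_tree), file.path(dir, "species_tree.nwk"))
  for (g in names(ds$alignments)) {
    write_fasta_alignment(ds$alignments[[g]],
                          file.path(dir, "genes", paste0(g, ".fasta")))
  }
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  split_df <- data.frame(species = c(ds$t_set, ds$v_set),
                         set = c(rep("T", length(ds$t_set)),
                                 rep("V", length(ds$v_set))),
                         stringsAsFactors = FALSE)
  utils::write.table(split_df, file.path(dir, "tv_split.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(hit_tables)) {
    dir.create(file.path(dir, "hits"), showWarnings = FALSE)
    for (gen in unique(hit_tables$hits$target_genome)) {
      write_hit_table(hit_tables$hits[hit_tables$hits$target_genome == gen, ],
                      file.path(dir, "hits", paste0(gen, ".tsv")))
    }
    utils::write.table(
      data.frame(query_id = names(hit_tables$query_lengths),
                 length = unname(hit_tables$query_lengths)),
      file.path(dir, "query_lengths.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
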