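# Input/output for the standard formats the pipeline touches: Newick trees,
# aligned FASTA, BLAST tabular hit tables, and partition-tracked
# supermatrices. Trees are ape "phylo" objects throughout; all topological
# comparisons treat them as unrooted.

#' Parse a Newick string into a tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree is stored as
#' parsed (a rooted input stays rooted), but every comparison in the package
#' treats topology as unrooted, collapsing any degree-2 root.
#'
#' @param text A single well-formed Newick statement terminated by `;`.
#' @return An object of class `phylo`. A degenerate single-leaf input such
#'   as `"A;"` yields a minimal one-tip tree.
#' @examples
#' tr <- parse_newick("(A,B,(C,D));")
#' bipartition_set(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  if (!grepl(";", text)) stop("Newick string must be terminated by ';'")
  body <- sub(";[^;]*$", "", text)
  if (grepl(";", body)) stop("expected a single Newick statement")
  # balanced-parenthesis scan with 1-based character positions
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") depth <- depth + 1L
    if (chars[pos] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("unbalanced parentheses: unmatched ')' at position %d", pos))
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf("unbalanced parentheses: %d '(' left open", depth))
  }
  if (!any(chars == "(")) {
    # single-leaf degenerate tree, e.g. "A;" or "A:0.1;"
    lab <- sub(":.*$", "", body)
    if (!nzchar(lab)) stop("empty leaf label at position 1")
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         tip.label = lab, Nnode = 1L),
                    class = "phylo")
    return(tr)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string")
  labs <- tr$tip.label
  if (any(!nzchar(labs)) || anyNA(labs)) {
    stop(sprintf("empty leaf label (leaf index %d)",
                 which(!nzchar(labs) | is.na(labs))[1]))
  }
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    stop(sprintf("duplicate leaf label: %s", paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    warning("negative branch lengths in Newick input")
  }
  tr
}

#' Serialize a tree to Newick
#'
#' Branch lengths, when present, are written with 10 significant digits so
#' that a parse/write round trip preserves both the split set and the
#' lengths to serialization precision.
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 1L) return(paste0(tree$tip.label, ";"))
  ape::write.tree(tree, digits = digits)
}

# Collapse any degree-2 root: RF on splits is root-agnostic and the
# comparison layer is defined on unrooted topologies.
as_unrooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) return(tree)
  ape::unroot(ape::collapse.singles(tree))
}

#' Construct a gene alignment
#'
#' A fixed-length amino-acid multiple sequence alignment for one gene:
#' a named character vector of equal-length sequences over the 20 IUPAC
#' one-letter codes plus gap `-` and unknown `X`. Sequences are upper-cased.
#'
#' @param gene_id Gene identifier.
#' @param seqs Named character vector, species label -> aligned sequence.
#' @return An object of class `gene_alignment` with fields `gene_id`,
#'   `seqs` and `length`.
#' @export
gene_alignment <- function(gene_id, seqs) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  sp <- names(seqs)
  if (is.null(sp) || any(!nzchar(sp))) stop("sequences must be named by species")
  if (anyDuplicated(sp)) {
    stop(sprintf("duplicate species in alignment '%s': %s", gene_id,
                 paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("'%s' is not aligned: row lengths %s", gene_id,
                 paste(unique(lens), collapse = ", ")))
  }
  bad <- grepl(sprintf("[^%sX-]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    warning(sprintf("alignment '%s': unexpected residue codes in %s",
                    gene_id, paste(sp[bad], collapse = ", ")))
  }
  structure(list(gene_id = gene_id, seqs = seqs, length = unname(lens[1])),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d species x %d columns\n",
              x$gene_id, length(x$seqs), x$length))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Headers are species labels (first whitespace-delimited token). Rows must
#' all have the same length; residues are case-folded to upper case.
#'
#' @param path Path to an aligned FASTA file.
#' @param gene_id Gene identifier; defaults to the file name without its
#'   extension.
#' @return A [gene_alignment()].
#' @export
read_fasta_alignment <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is.null(gene_id)) {
    gene_id <- sub("\\.(fa|fasta|faa|afa|aln)$", "", basename(path),
                   ignore.case = TRUE)
  }
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop(sprintf("no sequences in %s", path))
  labs <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(labs)) {
    stop(sprintf("duplicate header in %s: %s", path,
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  }
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1L) {
    stop(sprintf("%s is not aligned: sequence lengths %s", path,
                 paste(unique(w), collapse = ", ")))
  }
  seqs <- as.character(x)
  names(seqs) <- labs
  gene_alignment(gene_id, seqs)
}

#' Write an alignment as FASTA
#'
#' @param aln A [gene_alignment()] or [concatenate_alignments()] result.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, width = 60) {
  seqs <- aln$seqs
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in names(seqs)) {
    writeLines(paste0(">", sp), con)
    s <- seqs[[sp]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Concatenate gene alignments into a partitioned supermatrix
#'
#' Genes are laid side by side in input order; a partition map records, in
#' 1-based inclusive coordinates, which columns belong to which gene.
#' A species absent from a gene receives an all-gap block for that
#' partition.
#'
#' @param alignments A list of [gene_alignment()] objects (at least one).
#' @param species Optional explicit species set defining the rows. Species
#'   absent from every alignment get all-gap rows with a warning.
#' @return An object of class `concat_alignment` with fields `seqs`,
#'   `partitions` (data.frame `gene_id`, `start`, `end`) and `length`.
#' @export
concatenate_alignments <- function(alignments, species = NULL) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  stopifnot(all(vapply(alignments, inherits, logical(1), "gene_alignment")))
  gids <- vapply(alignments, `[[`, character(1), "gene_id")
  if (anyDuplicated(gids)) stop("duplicate gene ids in concatenation")
  seen <- sort(unique(unlist(lapply(alignments, function(a) names(a$seqs)))))
  if (is.null(species)) {
    species <- seen
  } else {
    missing_sp <- setdiff(species, seen)
    if (length(missing_sp)) {
      warning(sprintf("species absent from every alignment (all-gap rows): %s",
                      paste(missing_sp, collapse = ", ")))
    }
  }
  lens <- vapply(alignments, `[[`, integer(1), "length")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- vapply(alignments, function(a) {
    gap <- strrep("-", a$length)
    out <- a$seqs[species]
    out[is.na(out)] <- gap
    unname(out)
  }, character(length(species)))
  if (length(species) == 1L) blocks <- matrix(blocks, nrow = 1L)
  rows <- apply(blocks, 1L, paste, collapse = "")
  names(rows) <- species
  structure(list(seqs = rows,
                 partitions = data.frame(gene_id = gids,
                                         start = as.integer(starts),
                                         end = as.integer(ends),
                                         stringsAsFactors = FALSE),
                 length = as.integer(ends[length(ends)])),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment> %d species x %d columns, %d partitions\n",
              length(x$seqs), x$length, nrow(x$partitions)))
  invisible(x)
}

#' Extract one gene's partition from a supermatrix
#'
#' Recovers the original alignment restricted to the species that carry
#' sequence in that partition (all-gap fill rows are dropped).
#'
#' @param concat A `concat_alignment`.
#' @param gene_id Partition to extract.
#' @return A [gene_alignment()].
#' @export
extract_partition <- function(concat, gene_id) {
  stopifnot(inherits(concat, "concat_alignment"))
  p <- concat$partitions[concat$partitions$gene_id == gene_id, ]
  if (nrow(p) != 1L) stop(sprintf("no partition '%s'", gene_id))
  block <- substring(concat$seqs, p$start, p$end)
  names(block) <- names(concat$seqs)
  gap <- strrep("-", p$end - p$start + 1L)
  block <- block[block != gap]
  gene_alignment(gene_id, block)
}

#' Write a partition map
#'
#' Writes the partition map of a supermatrix either as a TSV
#' (`gene_id`, `start`, `end`) or as a RAxML-style partition file
#' (`MODEL, gene = start-end`).
#'
#' @param concat A `concat_alignment`.
#' @param path Output path.
#' @param format `"tsv"` or `"raxml"`.
#' @param model Substitution model name used in RAxML format lines.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(concat, path, format = c("tsv", "raxml"),
                             model = "WAG") {
  stopifnot(inherits(concat, "concat_alignment"))
  format <- match.arg(format)
  p <- concat$partitions
  if (format == "tsv") {
    utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(sprintf("%s, %s = %d-%d", model, p$gene_id, p$start, p$end),
               path)
  }
  invisible(path)
}

# Standard 12-column BLAST tabular field names (outfmt 6 defaults).
BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a BLAST tabular hit table
#'
#' Reads the standard 12-column BLAST tabular dialect (`-outfmt 6`).
#' Query coverage is computed as aligned query span / query length, so a
#' query-length table is required. The target genome is resolved either by
#' a single `genome` label for the whole file or by a `genome_map` applied
#' per target id.
#'
#' @param path Path to a tab-separated hit table. Empty files yield an
#'   empty table.
#' @param query_lengths Named numeric vector (query id -> length), or a
#'   two-column data.frame (id, length).
#' @param genome Single genome label for all hits in the file.
#' @param genome_map Named character vector (target id -> genome) or a
#'   function of the target id returning the genome label. Exactly one of
#'   `genome` / `genome_map` must be given.
#' @return A data.frame of class `hit_table` with the 12 standard columns
#'   plus `query_coverage`, `target_genome`, `e_value` and `bit_score`.
#' @export
read_hit_table <- function(path, query_lengths, genome = NULL,
                           genome_map = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is.null(genome) == is.null(genome_map)) {
    stop("supply exactly one of 'genome' or 'genome_map'")
  }
  if (is.data.frame(query_lengths)) {
    query_lengths <- stats::setNames(as.numeric(query_lengths[[2]]),
                                     as.character(query_lengths[[1]]))
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_hit_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stop(sprintf("%s line %d: expected 12 columns, got %d",
                 path, lineno[i], nf[i]))
  }
  m <- do.call(rbind, fields)
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  num_cols <- c(pident = 3, length = 4, mismatch = 5, gapopen = 6,
                qstart = 7, qend = 8, sstart = 9, send = 10,
                evalue = 11, bitscore = 12)
  for (nm in names(num_cols)) {
    v <- suppressWarnings(as.numeric(m[, num_cols[[nm]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("%s line %d: non-numeric %s value '%s'",
                   path, lineno[i], nm, m[i, num_cols[[nm]]]))
    }
    df[[nm]] <- v
  }
  if (any(df$evalue < 0)) stop("negative e-value in hit table")
  qlen <- query_lengths[df$qseqid]
  if (anyNA(qlen)) {
    stop(sprintf("no query length for: %s",
                 paste(unique(df$qseqid[is.na(qlen)]), collapse = ", ")))
  }
  span <- abs(df$qend - df$qstart) + 1
  df$query_coverage <- pmin(span / as.numeric(qlen), 1)
  if (!is.null(genome)) {
    df$target_genome <- genome
  } else if (is.function(genome_map)) {
    df$target_genome <- vapply(df$sseqid, genome_map, character(1))
  } else {
    df$target_genome <- unname(genome_map[df$sseqid])
    if (anyNA(df$target_genome)) {
      stop(sprintf("no genome mapping for target: %s",
                   paste(unique(df$sseqid[is.na(df$target_genome)]),
                         collapse = ", ")))
    }
  }
  df$e_value <- df$evalue
  df$bit_score <- df$bitscore
  class(df) <- c("hit_table", "data.frame")
  df
}

empty_hit_table <- function() {
  df <- data.frame(qseqid = character(), sseqid = character(),
                   pident = numeric(), length = numeric(),
                   mismatch = numeric(), gapopen = numeric(),
                   qstart = numeric(), qend = numeric(),
                   sstart = numeric(), send = numeric(),
                   evalue = numeric(), bitscore = numeric(),
                   query_coverage = numeric(), target_genome = character(),
                   e_value = numeric(), bit_score = numeric(),
                   stringsAsFactors = FALSE)
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Write a hit table in 12-column BLAST tabular format
#'
#' @param hits A `hit_table` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  m <- as.data.frame(hits)[, BLAST6_COLS]
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
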