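# Internal helpers shared across modules.

# The 20 standard amino acids, one-letter codes, fixed order used by the
# simulator and by alignment encoding.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed when one is given; otherwise use
# the current RNG stream (callers embedded in an outer with_seed block pass
# seed = NULL so one master seed drives the whole generation).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Separator used in canonical subset / bipartition keys; assumed absent
# from species and gene labels (opaque exact-match strings).
KEY_SEP <- "\x1f"

subset_key <- function(ids) paste(sort(ids), collapse = KEY_SEP)

# Encode a named character vector of equal-length sequences as an integer
# matrix (rows = species, columns = alignment positions). Gap '-' and
# unknown 'X' become NA so that pairwise deletion is a plain is.na() test.
aln_int_matrix <- function(seqs) {
  len <- nchar(seqs[[1]])
  m <- matrix(NA_integer_, nrow = length(seqs), ncol = len,
              dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    v <- as.integer(charToRaw(seqs[[i]]))
    v[v == 45L | v == 88L] <- NA_integer_  # '-' = 45, 'X' = 88
    m[i, ] <- v
  }
  m
}

# Per-pair comparable-column and mismatch counts for one alignment.
# These counts are additive across concatenated gene blocks (pairwise
# deletion is columnwise), which is what makes cached subset evaluation
# exact.
pair_counts <- function(seqs) {
  m <- aln_int_matrix(seqs)
  n <- nrow(m)
  sp <- rownames(m)
  ncomp <- matrix(0, n, n, dimnames = list(sp, sp))
  nmis <- matrix(0, n, n, dimnames = list(sp, sp))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      a <- m[i, ]
      for (j in (i + 1):n) {
        b <- m[j, ]
        ok <- !is.na(a) & !is.na(b)
        nc <- sum(ok)
        nm <- if (nc) sum(a[ok] != b[ok]) else 0L
        ncomp[i, j] <- ncomp[j, i] <- nc
        nmis[i, j] <- nmis[j, i] <- nm
      }
    }
  }
  list(ncomp = ncomp, nmis = nmis)
}

fmt_num <- function(x) sprintf("%.10g", x)
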