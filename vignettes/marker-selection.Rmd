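---
title: "Selecting minimal marker gene sets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting minimal marker gene sets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomarkr)
```

## The procedure

`phylomarkr` selects, from a collection of widespread single-copy genes,
a minimal subset whose concatenated alignment recovers a reference
phylogeny, and then checks that the subset generalizes to species that
played no part in the selection. The stages and their contracts:

**Partitioning.** Genomes are split into a training set (T-set) and a
validation set (V-set), by default 2:1. Only the T-set is used for
selection. The simulator stratifies the split across the basal clades of
the species tree so that both sets sample every major lineage; with
user-supplied alignments the split is random (or explicit). A 1:1 split
is supported but selects from fewer constraints and must predict more,
so its marker sets fail validation more often; 2:1 is the default for
that reason.

**Orthology.** From seed-species BLAST tabular hits, a seed protein
becomes a widespread single-copy gene when, after discarding hits with
e-value > 1e-5 or query coverage ≤ 50%, it has exactly one surviving hit
in at least `ceiling(min_species_fraction * n_genomes)` genomes and
never two in any genome. Coverage is query coverage,
`(qend - qstart + 1) / query_length`, computed from the best single HSP
(HSPs are not merged — the simplest reproducible reading of a coverage
threshold; subject coverage is a defensible alternative the hit-table
reader could supply). "Single copy" counts distinct target proteins, not
HSPs. Hits back to the seed genome are ignored; the seed protein
represents its own genome. Multiple seeds can be merged by union
(deduplicated by member-map coincidence on shared species, smallest gene
id kept) or intersection (groups recovered from every seed). Reciprocal
best-hit checking is deliberately not performed: the screen is a
one-directional search, and the validation phase is what catches
mis-grouped genes.

**Reference and ranking.** The reference topology is inferred from the
concatenation of all widespread genes — a partition-tracked supermatrix
in which a species missing from a gene receives an all-gap block. Each
gene is then scored by the topological distance between its own tree and
the reference:

* `rf` (default): Robinson–Foulds distance, the size of the symmetric
  difference of the two trees' non-trivial bipartition sets;
* `nrf`: RF divided by `|S1| + |S2|`, which equals `2(n-3)` for two
  binary trees (the fraction of wrong splits) and stays well defined for
  multifurcating trees;
* `nodal`: the L2 norm of the difference of the leaf-to-leaf topological
  path-length matrices (edge counts). The underlying family of nodal
  measures has L1 and L2 variants; L2 is the default and L1 a switch,
  since no single canonical form exists.

Ranking is ascending by distance with lexicographic gene-id tie-breaks,
so ranks are a deterministic permutation.

**Progressive concatenation.** Genes are concatenated in rank order; the
smallest n ≥ `start_n` (default 2) whose top-n tree is within `cutoff`
(default 0, i.e. exact recovery) of the reference defines the *initial
marker set*. Distances are re-evaluated at every n — adding a gene can
worsen the tree, so convergence is never assumed monotone. If no n
qualifies, all genes are returned flagged as not converged and the
minimization phase is skipped (no subset could qualify either, since the
full set already fails).

**Minimization.** Two searches over subsets of size 2..m−1:

* *Random*: subset size uniform over the non-exhausted sizes, members
  uniform; a canonical-key hash guarantees no subset is evaluated twice,
  which makes "all combinations explored" decidable. The search always
  evaluates `max_random_iterations` (default 100) distinct subsets
  before acting on a success, so at least that many combinations are
  explored; it stops early only on exhaustion. With `restart_rounds > 0`
  a found smaller set seeds a new round, optionally constrained to the
  current set (`constrain_to_current`).
* *Exhaustive*: every subset of the requested sizes (guarded by an
  evaluation budget, default 1e5). All qualifying subsets are retained
  in the result, not just the selected one, so a larger set can be kept
  deliberately when it performs better across validation tests.

Final sets are re-evaluated against the cutoff after selection; ties are
always broken by (size, distance, lexicographic gene ids), which with a
fixed `rng_seed` makes whole runs byte-reproducible.

**Validation.** Test A (one species at a time): for each held-out
species x, the reference is re-inferred over T ∪ {x} from all genes
(x's homolog rows appended where a single copy exists, gaps otherwise),
and a tree over the same species from the marker genes alone — dropping,
for that species only, markers without exactly one homolog. x is
*correctly placed* when the bipartitions whose canonical (smaller) side
contains x coincide between the two trees. This operationalization is a
package choice: it isolates the placement of x from incidental
rearrangements elsewhere in the tree, which are reported separately as
the normalized RF (`wrong_split_fraction`). Test B (cross-validation):
on the V-set alone, the topology from all genes is compared with the
topology from the markers; the default pass threshold is normalized RF
0.

**Tree certainty.** For each reference branch, support f1 = number of
gene trees containing the split, conflict f2 = the count of the most
frequent split that cannot co-occur with it (all four side intersections
non-empty), and `IC = 1 + p1 log2 p1 + p2 log2 p2`, `p_k = f_k/(f1+f2)`.
IC is 1 for an observed, unconflicted split and 0 at maximal conflict;
the sum over branches is the tree certainty, maximal at n−3 exactly when
every reference split is observed and unconflicted. Edge case: a
reference split observed in no gene tree but conflicted has no defined
support entropy in the source formalism (which scores splits drawn from
the gene-tree set, where f1 ≥ f2 > 0); the package conservatively scores
it 0 and warns. Tree certainty is used for post-hoc evaluation of final
trees, not per-gene ranking — a per-gene certainty ranking is not
defined by the formalism, which conditions on the whole gene-tree set.

## Built-in tree inference

The default builder computes protein distances with pairwise deletion
(columns with `-` or `X` in either row are skipped) under either the raw
mismatch fraction `p` or the Poisson correction `d = -ln(1 - p)`, and
applies classical Saitou–Nei neighbor joining. Numerical choices:

* pairs with `p >= 0.95` or no comparable columns are capped at
  `d = 10` and reported in `saturated_pairs` — saturation is capped
  rather than infinite so NJ stays defined; both knobs are arguments;
* negative NJ branch-length estimates are clamped to 0;
* ties in the NJ Q criterion are broken by joining the pair whose
  clusters have the lexicographically smallest (smallest-leaf-label)
  pair, so the output split set is invariant to input label order;
* subset evaluation during selection caches per-gene pairwise
  (comparable, mismatched) column counts; under pairwise deletion these
  are additive across concatenated blocks, so summing counts is exactly
  the concatenated computation (asserted byte-for-byte against explicit
  concatenation in the test suite).

The distance+NJ builder is intentionally *not* a maximum-likelihood
engine. The selection procedure treats tree building as a pluggable
strategy; an external ML program is attached with `external_builder()`
via a `{alignment}`/`{output}` command template. A faithful classic
protein-ML configuration for such an engine is: BioNJ starting tree,
seven substitution matrices (JTT, LG, WAG, Blosum62, MtREV, VT, Dayhoff)
compared by AIC on the fixed starting topology, ML trees under the two
best models with the better final likelihood kept, NNI rearrangements
for single genes and SPR for concatenations, Γ(4) + invariant sites
estimated from the data. None of this is re-implemented in R.

## What the simulator emulates — and what it does not

`synthesize_benchmark()` generates the world the test suite reasons
about:

* a Yule (pure-birth) species tree (`ape::rphylo`, death 0), leaves
  S1..Sn, **rescaled to unit root-to-tip height**. The pure-birth model
  states only exponential waiting times and no length scale; without
  rescaling, a unit-rate Yule tree on 24 species is ~3.2 substitutions
  deep and every deep pair saturates. Unit height makes the per-gene
  rate multiplier directly interpretable as expected root-to-tip
  substitutions per site;
* per-gene rates `mean_rate * Gamma(shape, shape)` with defaults
  `mean_rate = 0.5` (mid-range protein divergence for a within-phylum
  genome set: deep pairs then differ at ~40–55% of sites) and
  `rate_gamma_shape = 2` (rate CV ≈ 0.7, the spread seen across
  conserved single-copy proteins — ribosomal proteins are several-fold
  slower than average metabolic enzymes). These were fixed once, on the
  grounds above, and define the package's stated benchmark world;
* concordant genes evolve on the species tree; discordant genes on
  copies perturbed by k successive random NNI moves (k uniform over
  `discordance_nni_range`, default 2–6) — discordance by NNI rather
  than coalescent simulation gives countable, direct control of
  topological disagreement;
* an equal-rates 20-state substitution process with exact transition
  probability `p(b) = (19/20)(1 - exp(-(20/19) b))` — closed forms make
  the simulator itself testable (observed mismatch fractions are checked
  against p(t) at length 1e5). Empirical matrices (JTT/LG/...) would add
  realism but nothing to exercising the selection logic, which never
  looks at the substitution process;
* no indels: gap handling is exercised through the missing-species
  fill path of the supermatrix instead;
* hit tables with one strong hit per gene × genome (e-value ≤ 1e-20,
  coverage ≥ 0.7) and planted paralogs/losses at configurable rates, so
  the orthology filter's recovery is checkable against recorded truth.

A green test on this world therefore establishes that the pipeline's
*logic* is correct — filters recover planted truth, searches enumerate
and deduplicate correctly, reference and validation behave as specified
— under a clean substitution model without alignment error, indels,
rate variation across sites, compositional bias, horizontal transfer or
incomplete lineage sorting. It does not establish that any particular
real marker set is optimal; that depends on data the simulator does not
emulate.

## Known limitations, and one measured one

* Species labels are opaque exact-match strings; strains of one species
  are distinct taxa, and no fuzzy merging is attempted.
* The nodal-distance variant (L1/L2, unnormalized) follows no single
  published convention; results using `nodal` should state the variant.
* Per-gene informativeness at realistic settings is noisy. In the
  package's benchmark world (24 species, 2:1 split, 40 genes of 2000
  columns, 10 concordant), the acceptance suite measures that the
  reference and the selected set behave essentially perfectly (reference
  recovery and concordant-only final sets in 20/20 seeded replicates),
  but strict *per-gene rank separation* — every concordant gene ahead of
  every ≥3-NNI gene — holds in only about half the replicates, for two
  structural reasons: a slow gene (gamma multipliers reach ~0.1×) meets
  short internal branches of the unit-height Yule tree (~0.003–0.01
  substitutions, i.e. a handful of expected changes in 2000 columns)
  and its tree errs by one or two splits; and restricting 24 species to
  the 16 training species can make an NNI perturbation invisible, so a
  discordant gene's training-set tree is occasionally identical to the
  species tree. Similarly, a final set minimized to 2 genes can miss one
  short branch among 8 held-out species (measured 2/20 replicates).
  These are properties of small marker sets and short branches, not of
  the search: the corresponding acceptance expectations are left
  failing rather than weakened, and the measurement is recorded with the
  tests.
* The pipeline is single-process and deterministic; tree builds could be
  parallelized across genes without changing results, but no scheduler
  integration is provided.
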