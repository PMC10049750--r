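---
title: "Methods: from transcriptome-derived proteins to ancestral developmental modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from transcriptome-derived proteins to ancestral developmental modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polyphylo` implements the two computational halves of a phylogenomic
life-history study on marine flatworms (Polycladida): building a codon-level
supermatrix from transcriptome-derived protein sequences, and reconstructing
the evolution of a binary developmental trait (indirect development through a
ciliated larva, versus direct development) on the resulting phylogeny.  This
vignette documents the models, the tunable parameters and the numerical and
design choices, in the order the pipeline runs them.

```{r setup}
library(polyphylo)
```

## 1. Clade-specific substitution matrix

Taxon-focused log-odds matrices improve protein alignment within a clade
relative to general-purpose matrices.  The construction is the classic
BLOSUM recipe applied to curated similarity clusters:

1. **Curation** (`curate_clusters`): singleton clusters are removed, then
   clusters whose mean pairwise identity is below 70% (`min_identity =
   0.70`; a cluster at exactly the threshold is retained, since the removal
   rule is "less than").  `percent_identity` ignores positions where either
   sequence is gapped — the standard convention; the construction is robust
   to this choice because blocks are gap-free anyway.
2. **Blocks** (`extract_blocks`): maximal runs of columns with no gap in any
   member.  "Conserved" is operationalized as gap-free plus an optional
   per-column majority-identity threshold (`min_column_identity`, default 0);
   the block definition in the underlying protocol specifies only
   "conserved, gap-free", so the extra knob defaults to off and is recorded
   in output metadata.
3. **Weighting** (`weight_sequences`): sequences at or above 90% identity
   within a block are grouped by single linkage and each group shares one
   unit of weight (each member weighs `1/group size`).  This is the
   Henikoff-style redundancy correction; the "90" is exposed as
   `clustering_threshold = 0.90`.  Setting it above 1 disables grouping and
   reduces the procedure to unweighted counting (a tested equivalence).
4. **Counting and scoring** (`count_pairs`, `compute_log_odds`): every
   unordered pair of residues in a column contributes the product of the two
   sequence weights.  With observed pair frequencies $q_{ij}$, background
   frequencies $p_i = q_{ii} + \sum_{j \ne i} q_{ij}/2$ and expectations
   $e_{ii} = p_i^2$, $e_{ij} = 2 p_i p_j$, scores are
   $s_{ij} = \mathrm{round}(\lambda \log_2 (q_{ij}/e_{ij}))$ with
   $\lambda = 2$ (half-bit units).  Rounding is half-away-from-zero, the
   convention of common matrix tooling.  Zero-count cells with
   `pseudocount = 0` receive the floor score
   $\mathrm{round}(\lambda \log_2 \varepsilon)$ with
   $\varepsilon = 1/(2\,\mathrm{total})$, which keeps the matrix finite and
   deepens with the amount of evidence; a pseudocount is the recommended
   alternative for small builds.

The matrix is symmetric, its background frequencies sum to 1, and its
expected score under the background is negative for any non-degenerate
build — all asserted by tests against exhaustive enumeration on reduced
(2–4 letter) alphabets.

## 2. Orthology assignment

Transcript fragments are translated in six frames and assigned to
orthologous groups in two steps.

**Step 1 — profile search.**  The original protocol searches profile HMMs.
This package deliberately substitutes an ungapped position-specific score
matrix (PSSM) scorer: the score of residue $a$ at column $c$ is the mean
substitution-matrix score of $a$ against the column's residues, and a query
is scored by its best sliding-window placement.  The substitution keeps the
bespoke filtering logic testable without binding to an external binary; an
import path for externally produced per-domain tabular hit files
(`read_hmmer_domtbl`) gives identical downstream filtering when real
profile-HMM output is available.  E-values come from an empirical null: 200
seeded shuffles of the query, a Gumbel tail fitted by the method of moments.
The E-value cutoff is `1e-5` and, per orthologous group *within each
taxon's hit set* (each transcriptome is searched independently), only the
top-scoring quartile is retained — `ceiling(n * 0.25)`, with all hits tied
at the boundary score kept, so a group with at least one passing hit is
never emptied.  The ceiling-with-ties rule makes the otherwise ambiguous
"top-scoring quartile" deterministic; note it is not idempotent (re-running
the filter on its own output with the same fraction retains fewer hits),
which is an unavoidable property of any rank-based quartile rule.

**Step 2 — reciprocal best hit.**  Surviving candidates are confirmed
against the reference taxon's proteome by Smith–Waterman local alignment
under the custom matrix (affine gaps, defaults `gap_open = 11`,
`gap_extend = 1`; a gap of length $L$ costs $\mathrm{open} + (L-1)\cdot
\mathrm{extend}$).  A candidate is accepted iff its best hit in the
reference proteome is the group's reference sequence, the reference
sequence's best hit among the same taxon's candidates is the candidate, and
both alignments meet the `1e-5` E-value cutoff (same empirical-null
machinery).  The reverse search space is restricted to the query taxon's
candidate set, mirroring the reciprocal test's intent; the traceback tie
order (diagonal > up > left) and the lexicographic tie-break on equal
best-hit scores make runs reproducible.

## 3. Paralog pruning and the supermatrix

Gene trees for each group (any Newick source; supports readable from node
labels or bracketed branch comments) are pruned to a one-sequence-per-taxon
set:

- `collapse_low_support` contracts internal edges below a support threshold
  into polytomies.  The default is 0 (no collapse) because the upstream
  protocol invokes a tool default without stating a value.
- `max_inclusive_subtree` selects, over the candidate rooted subtrees, the
  one with the most distinct taxa in which every multiply-represented taxon
  is monophyletic (in-paralogs allowed, out-paralogs excluded).  For rooted
  input the candidates are the clades of the tree as given; unrooted input
  is handled by evaluating both orientations of every edge rather than
  choosing a root heuristically.  Ties break by more sequences, then by the
  lexicographically smallest leaf-label list — fully specified so runs are
  reproducible.  The implementation is validated against an exhaustive
  search written with independent tree primitives on hundreds of random
  gene trees with planted paralogs.
- `consensus_inparalogs` collapses the remaining same-taxon sequences by
  column-wise majority, ties coded `X` (protein) or `N` (nucleotide);
  unaligned inputs are first anchored onto the longest member by local
  alignment.  A group is flagged as showing out-paralog evidence when the
  selection dropped at least one leaf.

Groups retaining at least 75% of the run's taxa pass `occupancy_filter`
(boundary inclusive: 27 of 36 taxa is exactly 75% and is retained).  One
denominator — the run's taxon set — is used wherever the 75% rule appears.

`backtranslate` then replaces each aligned residue by its source codon
(gaps become `---`), after verifying that the ungapped protein equals the
translation of its CDS with one trailing stop trimmed.  Groups are
concatenated in sorted-id order with gap fill for missing taxa, and codon
triples represented in fewer than 4 taxa are removed.  A taxon "represents"
a codon if the triple contains at least one unambiguous, non-gap
nucleotide; this representation rule is not pinned down by the protocol, so
it is configurable to "complete codon required".  Completeness statistics
count `-` and `?` as gaps; ambiguity counts `N` and the partial IUPAC
codes, excluding `?` (a deliberate choice where the upstream figure's
convention is unstated).  Export writes relaxed PHYLIP/FASTA plus a
partition file with the three codon positions in 1-based inclusive
`start-end\3` stride syntax; coordinates are 0-based half-open everywhere
internally.  Tree inference itself (partitioned GTR+I+G ML, heterotachy
models, bootstrapping) is out of scope: the package emits exactly the
matrix and partition files those tools consume.

## 4. Mk-model ancestral state reconstruction

Development mode is a two-state character: 0 = indirect, 1 = direct.  Two
continuous-time Markov models are fitted on a fixed tree by maximum
likelihood with Felsenstein pruning: **ER** (one symmetric rate; identical
to the symmetric model for two states) and **ARD** (distinct forward and
reverse rates).  Numerical choices:

- Transition probabilities use the two-state closed form of $e^{Qt}$ (no
  matrix exponentials in the hot path); zero-length branches give the
  identity.  Multifurcations are pruned natively.
- Rates are optimized on the log scale with L-BFGS-B in
  $[10^{-9}, 100]$ transitions per unit branch length, five deterministic
  log-spaced starts, and convergence ~1e-10 in log-likelihood.
- The root prior defaults to equal, `c(0.5, 0.5)`, matching the default of
  the analysis tooling this class of study uses; stationary or custom
  priors can be passed, and the prior used is recorded in the fit.  (A
  well-known consequence: implementations that sum unweighted root partials
  report a log-likelihood exactly `log(2)` higher; the ML rates are
  unaffected, which the test suite demonstrates against an independent
  implementation.)
- Tips whose state is unknown get equal likelihood for both states, which
  makes them exactly likelihood-neutral.  Genus-level coding
  (`code_traits`) assigns each tip the mode of its congeners: both modes
  present codes the tip "both", which is treated like unknown — the scoring
  defines only indirect-versus-direct, and the equal-likelihood convention
  is the established handling.  The difference is visible in the trait
  table so users can re-code.
- Model choice uses AICc, $-2\ln L + 2K + 2K(K+1)/(n-K-1)$ with $n$ = the
  number of tips (the conventional, if debatable, sample-size choice for
  comparative models; it is a recorded assumption, not buried).  Lowest
  AICc wins; exact ties go to the model listed first (ER before ARD).
- `marginal_asr` returns, for every internal node, the proportion of total
  likelihood attributable to each state ("scaled likelihoods"), computed by
  a down-pass/up-pass combination whose per-node scale factors cancel in
  the normalization.  The vectors equal fix-the-node-and-recompute
  likelihood ratios to 1e-10 and sum to 1 to 1e-12 (tested against
  brute-force enumeration over all state assignments on small trees).
- A node call is *significant* when the log difference between the two
  scaled likelihoods is at least 2 (`significance_call`); printed, rounded
  vectors that sum to 1 ± 0.01 are normalized before the test, and zero
  entries are clamped at 1e-16 with a warning.

## 5. What the synthetic generators emulate — and what they do not

The generators exist so that every stage runs at desk scale with known
ground truth; their defaults are the study's stated conditions where those
exist.

- `simulate_cluster` produces gap-free "clusters at a target identity":
  one random ancestor, each copy mutated per site with probability $p$,
  replacement uniform over the other residues.  With alphabet size $A$ the
  expected pairwise identity is $I(p) = (1-p)^2 + p^2/(A-1)$, inverted in
  closed form to calibrate $p$; realized identity is unbiased and within
  binomial error of the target for lengths of a few hundred.  All random
  draws are made up front, so realized identity is monotone in the target
  at a fixed seed.  No realistic amino-acid exchange process (no
  GTR/LG-style simulation) — the matrix builder needs controllable
  identity, not realism.
- `simulate_gene_family` runs a birth–death duplication/loss process along
  a species tree; duplicated copies evolve independently from the event
  point, and a loss prunes the whole lineage.  With both rates zero the
  gene tree is label-isomorphic to the species tree — the round-trip
  property that anchors the pruning tests.  The event log reproduces from
  the seed.
- `simulate_binary_trait` evolves the character by the exact transition
  probabilities of the fitted model class, recording internal-node truth;
  `apply_missingness` recodes an exact count (`round(fraction * n)`,
  default 11/36 ≈ 31%, the study's unknown fraction) of tips as unknown,
  sampled without replacement.  Genera with internally variable modes are
  not simulated: the generator emits pure states, and polymorphic ("both")
  coding is exercised through `code_traits` instead.
- The orchestrator's sequence stages default to a deliberately small world
  (6 taxa, 5 gene families, 60-residue proteins) so the full pipeline —
  including quadratic-time alignment and shuffle-based E-values — runs in
  about a minute; the trait/ASR stage runs at the study scale (36 tips, 11
  unknown).  A green end-to-end run establishes that the stages compose and
  that their counts are consistent, not that the desk-scale world has the
  statistical power of a 4469-gene matrix.

A consequence worth stating: because synthetic transcripts are
back-translated with a deterministic codon table and contain no sequencing
error, assembly artifacts, frameshifts or splice variants, perfect recovery
of one-to-one families in tests says nothing about robustness to those
real-data phenomena.

## 6. Known limitations

- The PSSM scorer is a stand-in, not a profile HMM; sensitivity on remote
  homologs will be lower, and imported HMMER tables are the recommended
  route for real data.
- Shuffle-based E-values are approximate in the extreme tail (the Gumbel
  fit extrapolates beyond the 200-shuffle null); candidates near the
  cutoff can flip between runs with different null seeds, which is why all
  E-value machinery is seeded.
- Only single-rate-class ER/ARD models are fitted; hidden rate classes,
  correlated characters, stochastic mapping and time calibration are out
  of scope.
- The 75% occupancy and 4-taxon codon rules use one taxon-set denominator
  throughout; studies that change the taxon set between filtering stages
  would need to call the filters with different `total_taxa`.
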