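---
title: "Ancestral reference genomes for mapping diverged reads: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral reference genomes for mapping diverged reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reads from an extinct or otherwise deeply diverged taxon must be mapped to the
genome of a living relative.  As the evolutionary distance between sample and
reference grows, the fraction of reads that can be placed drops sharply, which
both truncates the reconstructed genome and biases downstream estimates (for
example of endogenous DNA content).  paleoref implements an in silico remedy:
infer the genome of an *ancestor* of the target lineage from a multi-species
whole-genome alignment, and map against that ancestor — or against a *hybrid*
reference in which the alignable parts of the closest sister genome are
replaced by ancestral sequence while everything unalignable keeps the sister
backbone.  An ancestor on the path between target and sister is evolutionarily
closer to the target than the sister is, so mapping efficiency improves; the
hybrid construction restores the genome-scale completeness that a purely
ancestral (alignment-restricted) reference lacks.

The package covers the whole workflow: MAF alignment filtering, branch-length
and model estimation on a fixed topology, marginal ancestral sequence
reconstruction (ASR), reference construction, read simulation, a built-in toy
mapper, and mapping-efficiency metrics.  A clade simulator makes all of it
testable end to end with no external data.

## Substitution model and likelihood

Nucleotide evolution follows a general time-reversible (GTR) model with
stationary frequencies $\pi$ and symmetric exchangeabilities $s_{ij}$,
$Q_{ij} = s_{ij}\pi_j$, normalized to one expected substitution per site per
unit branch length ($-\sum_i \pi_i Q_{ii} = 1$).  HKY85 is the nested special
case $s_{AG}=s_{CT}=\kappa$, all transversions equal.  Among-site rate
heterogeneity uses the discrete-Gamma approximation with $K$ equal-probability
categories represented by their conditional means (the field-standard "mean"
discretization), renormalized so the category mean is exactly 1.  $K = 4$ by
default; the shape $\alpha$ is estimated or supplied.

Column likelihoods are computed by Felsenstein pruning on the fixed rooted
topology, vectorized across unique site patterns (alignment columns are
collapsed to patterns with multiplicities first — a pure optimization with
bit-identical results).  Gaps and N are treated identically as missing data
(all-ones partial likelihoods); the test suite verifies pruning against
exhaustive enumeration over all internal-state assignments at $10^{-10}$.

### Why the topology is fixed

The species topology is taken as known (in practice it comes from a dated
species tree, which also guided the multiple alignment), and only branch
lengths are re-estimated from the alignment, for two reasons: the topology is
far better determined by dedicated phylogenomic analyses than by the filtered
alignable fraction, and fixing it makes ancestral nodes stable, nameable
targets.  Branch lengths are optimized one branch at a time by Brent line
search on $[10^{-8}, 20]$ with cached inside/outside partial likelihoods,
cycling branches in postorder for at most 50 rounds or until the largest
change drops below $10^{-6}$.  Because the per-branch searches within a round
share cached partials, the joint update is accepted with step halving whenever
it would not increase the total log-likelihood, which makes the round sequence
monotone.  Base frequencies are fixed at their empirical values rather than
ML-estimated — they are essentially determined by composition, and this keeps
the estimation identifiable and cheap; exchangeabilities (GT = 1) and
$\alpha \in [0.02, 100]$ are optimized by coordinate ascent.  Estimation may
be restricted to a subset of the alignment (`max_cols`, `seq_names`),
mirroring the common practice of estimating branch lengths on the largest
chromosome only.

## Marginal ancestral reconstruction

For every retained column and every internal node the package computes the
*marginal* posterior $P(x_v = x \mid \text{column})$ by the inside–outside
message scheme (the "classical" empirical-Bayes reconstruction).  Under the
Gamma mixture, per-category posteriors are combined with weights proportional
to each category's likelihood for that column — i.e. the category is
marginalized under its posterior, not averaged with equal weights.  The
called base is the posterior mode; exact ties break toward the higher
stationary frequency and then alphabetically, so calls are deterministic.

Masking follows the strict reading of the ">90% missing" rule: a column is
removed iff its missing fraction across the reconstruction species (gaps and
N alike; species absent from a block are missing throughout it) strictly
exceeds 0.9, so a column at exactly 0.9 is kept.  Columns where the sister
species is gapped are *not* removed from the ancestral sequence — only the
missingness rule removes columns.  This choice is deliberate: it is the only
reading under which an ancestral aligned-fraction reference can be longer
than the sister aligned fraction, which is both observed in practice and the
source of the ancestor's completeness advantage.

## Reference flavors and hybrid construction

Five reference flavors are compared: (i) the target's own genome (upper
bound), (ii) the sister genome, (iii) the sister aligned fraction (one contig
per filtered block, the species' ungapped row over retained columns),
(iv) the ancestral aligned fraction per node, and (v) the hybrid per node.
Aligned-fraction contigs are kept per block and never merged, since block
adjacency does not imply genomic adjacency; contig names carry provenance
(`<node>|<anchor_seq>:<start>-<end>|block<i>`).

The hybrid splices each ancestral segment into the sister genome at the
segment's *sister* placement — the sub-interval of the sister's block row
spanned by the retained columns, snapped inward past end gaps, converted to
forward-strand coordinates.  Sister coordinates (not anchor coordinates) are
the backbone because the sister genome is the sequence being improved upon.
Overlapping candidate placements are resolved by block score, ties by input
order — the same rule used for best-hit deduplication of the MAF.
Minus-strand placements are reverse-complemented before insertion.  The
splice obeys the exact length identity
`new = old − Σ(replaced) + Σ(replacement)`, leaves all bases outside the
intervals untouched, and emits a BED-like table mapping old to new
coordinates; the test suite checks all three properties against brute-force
string surgery on fuzzed cases.

## MAF handling

Blocks are parsed from the UCSC MAF dialect, with invariants enforced at
parse time (equal row widths, `size` = non-gap count, coordinates within the
source).  IUPAC ambiguity codes are collapsed to N, because the model is
strictly 4-state.  Two filters mirror standard whole-genome-alignment
post-processing: a minimum column count (`min_col = 100`, boundary
inclusive — the conservative reading of mafFilter's `-minCol`) and best-hit
deduplication, which keeps, among blocks whose anchor intervals overlap, only
the highest-scoring one (ties by input order).  The deduplication operates on
anchor intervals of the merged MAF; this approximates, but is not identical
to, reciprocal-best-hit filtering of the pairwise alignments that preceded
the merge, which this tool never sees.

## The clade simulator: what it emulates, and what it does not

`evolve_clade()` evolves a root genome along the tree under exactly the model
family the inference side assumes — this is deliberate, so parameter and
sequence recovery are well-posed questions.  Per-site Gamma categories are
drawn once at the root and inherited (the standard "Gamma sites" assumption).
Substitutions are drawn per branch from $P(t r_c)$; indels arrive as a
Poisson process per branch (rate per site per unit branch length) with
geometric lengths, are forbidden from overlapping within a branch, and are
tracked in a global alignment coordinate system so the emitted truth MAF is
exact: blocks are the runs between indel breakpoints, within which every
genome is either fully present or fully gapped, and blocks whose anchor is
gapped are dropped (as in an anchor-based alignment).

Defaults describe a songbird-like clade: the 15-leaf fixture topology
(`bird_clade_tree()`) has a ~20 My-like test/sister pair (STUVU/RHAIN,
0.04 subst/site per branch at roughly 0.002 substitutions/site/My) and a
~40 My-like pair (PTEME/SYLVI, 0.08 each); the generative model is GTR with
transition enrichment (AG = CT = 4.5), mild AT bias
($\pi_A = \pi_T = 0.30$), and $\alpha = 0.8$.

Two conscious departures from realism, both in favor of exact, testable
truth:

* **Indel rate.** The default (0.001 events per site per substitution unit,
  mean length 3) is one to two orders of magnitude below biological
  indel:substitution ratios.  Because the truth-MAF convention splits blocks
  at *every* indel breakpoint, realistic rates would shred the alignment
  below the 100-column filter; real aligners instead absorb indels as gap
  columns inside blocks.  Inference handles gapped columns fine — the
  restriction is purely about keeping simulated truth blocks long.
* **No rearrangements, duplications, or ancient-DNA damage.** Reads are
  clean, full-length and error-free (the evaluation protocol's 0% error
  setting).  A green end-to-end test therefore establishes that the
  *reference construction* logic produces the expected mapping-efficiency
  ordering — not that the improvement survives fragmentation, deamination
  or mapper-specific heuristics.

Read simulation is wgsim-flavored: uniform fragment placement (N-containing
fragments rejected, up to 1000 resamples), Gaussian fragment lengths
(defaults 500 ± 50), mate 2 reverse-complemented, truth coordinates encoded
in the read name.

## Evaluation

Alignment records pass iff mapped, MAPQ ≥ 20, and the not-primary (0x100),
vendor-failed (0x200) and supplementary (0x800) flags are all clear;
duplicates (0x400) are deliberately not filtered, matching the stated filter
set.  All three metrics are computed after these filters.  The mapped
percentage counts each mate as one read (denominator 2 × pairs).  Depth
counts reference-consuming CIGAR operations (M, =, X, D — deletions span
depth, as in samtools/mosdepth conventions); breadth is the percentage of
*non-missing* (non-N) reference positions with depth ≥ 1, and mean depth is
averaged over the same non-missing positions, so references with different
amounts of N are comparable.

The built-in mapper is a deliberately simple stand-in for a production
aligner: exact k-mer seeds (default k = 12, a direct-addressed index) at
fixed offsets on both strands, full-length Hamming extension, unique best
placement → MAPQ 60, tied best → MAPQ 0, nothing within the mismatch budget
(default 30% of the read length) → unmapped.  It is deterministic, needs no
external binaries, and is sensitive enough that reference-divergence
differences — not mapper quirks — dominate the comparisons.  An external
mapper can be substituted at the SAM interface.

## Numerical choices

* Partial likelihoods are rescaled per node with one factor per pattern
  shared across Gamma categories; sharing the factor is what keeps
  per-category likelihoods comparable for the empirical-Bayes category
  weighting.
* $P(t)$ comes from the symmetrized eigendecomposition of $Q$ (exact for
  reversible models); entries are clipped to $[0,1]$ and rows renormalized
  against rounding.
* Contradictory patterns with zero likelihood short-circuit to a floor of
  $10^{-300}$ inside logs.
* All randomness is seeded; simulators restore the caller's RNG state.

## Scaling

Genome-scale runs are dominated by three vectorized paths: pattern-collapsed
pruning (chunked at 100k patterns to bound memory), run-wise C++ expansion of
the simulator's alignment on insertion events, and the C++ mapper.  A full
experiment — 15-species clade, 2 Mb genomes, 100k read pairs, estimation,
three reconstructed nodes, nine references mapped and evaluated — takes on
the order of 1.5 minutes on one CPU.  The acceptance suite runs its
end-to-end criterion at this 2 Mb scale (rather than the 5 Mb design point,
which behaves identically but triples the runtime) to stay inside CI budgets;
no other parameter differs from the stated design.

## Known limitations

* Reconstruction is per-column marginal; no joint (max-joint) reconstruction,
  no indel-state reconstruction, and nothing is inferred for regions absent
  from the alignment.
* The best-hit deduplication approximates a reciprocal-best-hit step that
  properly belongs upstream of the merged alignment.
* Whether the published protocol counted the removed test species in the
  missingness denominator is unknowable from its description; here the
  denominator is the reconstruction species set (test species excluded).
* The toy mapper has no gapped alignment, so reads spanning indels between
  target and reference are penalized as mismatches; with realistic indel
  densities an external gapped mapper should be used for absolute numbers.
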