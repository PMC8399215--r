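---
title: "Screening for the minimal nif complement and reconstructing nitrogenase phylogeny"
author: "nifphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for the minimal nif complement and reconstructing nitrogenase phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`nifphylo`, in the spirit of the methods sections of the mature
phylogenetics packages it builds on (ape, phangorn).

## 1. The screening model

An organism is called a candidate diazotroph when its genome encodes one
copy of each of the six roles H, D, K, E, N, B of molybdenum nitrogenase,
co-located in one genomic neighborhood. Three rules make this operational:

**Role matching.** Gene symbols are matched case-insensitively against a
configurable synonym list per role (`role_set()`). Annotation sources differ
in their vocabularies, so synonyms — not hard-coded symbols — are the unit
of configuration; alternative systems (VnfHDK, AnfHDK) are screened by
substituting a different role set. Alternative nitrogenases frequently lack
their own ENB cofactor-assembly genes, so their role sets carry only the
three structural genes.

**Fusion calling.** Naturally fused EN and NB open reading frames occur in
several diazotroph lineages. A record annotated to one role of an adjacent
pair (or to a combined symbol) is called fused when its protein length
reaches `fusion_frac` (default **0.7**) of the summed reference median
lengths of the pair, and no separate partner-role record lies within the
neighborhood window. The default 0.7 tolerates terminal truncations in
draft annotations while excluding single-domain records; it is exposed as a
parameter because no biological constant fixes it. A record passing the
length rule for *both* EN and NB (only possible for an N-annotated record
with neither partner nearby) is reported as an error rather than guessed.

**Paralog resolution.** When a role has several annotated copies, the
chosen complement is the one-record-per-role set minimising the genomic
window span `max(end) − min(start)`, restricted to one contig by default.
Window span is the simplest auditable formalisation of "the same genomic
neighborhood"; the neighborhood window `window_bp` (default **25 kb**)
comfortably contains known nif operon arrangements while excluding distal
paralogs. Up to `combination_cap` (default 10⁵) per-role combinations are
enumerated exhaustively; beyond that a greedy fallback anchors on the
medoid of the single-copy roles and picks the nearest copy per multi-copy
role. The greedy span is never smaller than the exhaustive optimum and
coincides with it whenever a unique co-located cluster exists (asserted in
the test suite). Ties are broken by the lexicographically smallest
(contig, start) vector, which makes the whole screen byte-deterministic.

Cross-contig complements are rejected by default (draft assemblies split
operons; the user can disable the restriction, in which case the span is
summed per contig).

## 2. Alignment

Per-role alignments come from a built-in progressive aligner: affine-gap
global alignment (Needleman–Wunsch) generalised to profile–profile merges
with mean-of-pairs column scoring, applied post-order along a UPGMA guide
tree built on 3-mer distances `1 − |shared| / min(count)`. Scoring is
BLOSUM62 with gap open 10 and extension 1 — the protein defaults of the
classical progressive aligners — and a gap run of length L costs
`open + ext·(L−1)`. Two deliberate conventions:

* **Terminal gaps are penalized like internal ones.** Some aligner dialects
  waive terminal gaps; penalizing them uniformly keeps the dynamic program
  and its brute-force test oracle in exact agreement and removes a source
  of dialect-dependent output.
* **Deterministic tie-breaking.** On equal score the traceback prefers the
  diagonal move, then a gap in the first profile, then the second; together
  with canonical row ordering this makes alignments reproducible bit for
  bit.

Fused EN (or NB) records contribute their *full* sequence to both of their
role alignments; the aligner absorbs the foreign domain as a gap block in
the other rows. Splitting the fusion would require domain coordinates the
annotation does not provide. Externally produced alignments can be imported
(`imported_alignments` in `run_config()`, `read_alignment()`), bypassing
this stage entirely.

Concatenation joins the six role alignments in H, D, K, E, N, B order and
records the layout in a partition map (0-based half-open internally,
1-based inclusive RAxML-style on output). Alignments are assumed untrimmed;
no masking is applied.

## 3. Distances and neighbor joining

Observed difference fractions use pairwise deletion: columns with a gap or
`X` in either row are excluded, and pairs with fewer than `min_overlap`
(default 50) usable columns are flagged and set to the saturation cap.
The user-facing correction is Kimura's protein distance
`d = −ln(1 − p − 0.2 p²)`; its argument reaches 0 near `p ≈ 0.854`, beyond
which distances saturate to `d_max` (default 10 substitutions/site) by
design rather than diverge. A second correction, the exact Poisson
inversion `d = −(19/20) ln(1 − (20/19) p)`, is exposed because it is the
exact inverse of the simulator's substitution model (§6); the topology
recovery properties in the test suite use it, while the pipeline default
remains Kimura's.

Neighbor joining is the canonical agglomeration (join the pair minimising
`Q(i,j) = (n−2) d(i,j) − R_i − R_j`), with negative branch lengths clamped
to zero without redistribution — the simplest defensible convention — and
Q-ties broken by the lexicographically smallest pair of cluster labels.
Plain NJ is used rather than heuristic accelerations: at desk scale the
exact algorithm is fast, and exactness is what the additive-consistency
tests certify. Maximum-likelihood inference is intentionally out of scope;
externally built ML trees can be supplied to the consensus stage
(`extra_concat_trees`). Rooting is by outgroup (with an explicit
monophyly-under-some-rooting check) or by midpoint.

## 4. Tree comparison and combination

Robinson–Foulds distance is the size of the symmetric difference of the
nontrivial bipartition sets, normalised by `2(n−3)`. Bipartitions are keyed
canonically by their smaller side (ties resolved lexicographically), which
is also what makes Newick serialisation canonical: children are ordered by
the smallest leaf label in their subtree, so any two representations of the
same tree print identically.

The consensus stage keeps exactly the splits present in a strict majority
(> 50 %) of the inputs — such splits are pairwise compatible by counting,
so they always nest into a tree — and stores occurrence frequencies as
internal node labels.

The supertree stage maximises the **quartet score**: the number of 4-leaf
subsets whose induced unrooted topology agrees between the candidate and a
gene tree, summed over gene trees. Quartets are resolved by the four-point
condition on topological (unit-branch-length) distances; quartets left
unresolved by a polytomy count as non-matching, a conservative choice. Up
to `exact_max_n` leaves (default 8) all `(2n−5)!!` topologies are
enumerated and a global maximiser returned, with score ties resolved to the
canonically smallest Newick string; beyond that, greedy stepwise insertion
(leaf order drawn from the run seed) followed by NNI hill-climbing returns
a local optimum, reported with its score and mode. The greedy mode is an
approximation of the same objective that the exact mode optimises.

## 5. HGT detection

Tanglegram reading is made algorithmic: after restricting both trees to
their shared leaves (dropped leaves are reported), the leaf whose removal
from both trees most reduces RF is pruned, repeatedly, until the trees
agree, `max_removals` (default 5) is reached, no removal helps, or fewer
than five leaves would remain (RF on < 4 leaves is trivially zero). The
candidate set contains the pruned leaves *plus any leaves tied with them at
their step*: a leaf regrafted beside a singleton and that singleton reduce
the discordance equally and are genuinely indistinguishable from topology
alone, so reporting the tie set is the honest answer (and is what makes
perfect recall on planted single transfers attainable at all). The
`max_removals` cap guards against over-pruning noisy trees into agreement.
The per-step RF drop ranks candidates; no significance threshold is
claimed — discordance from a handful of leaves is evidence, not proof, of
transfer.

## 6. The synthetic-data generator

The generator provides every input with known truth; its defaults define
the study conditions used throughout the tests.

* **Species trees** follow a Yule (pure-birth) process, rescaled to
  root-to-tip height 1.0 expected substitutions/site — deep enough to span
  the distances where the Kimura correction matters, shallow enough that
  2000-site proteins retain signal.
* **Transfers** are subtree-prune-regraft moves with uniformly drawn prune
  and regraft edges (no-op draws rejected); recovery studies use
  `leaf_only = TRUE` because the detector's unit of removal is a leaf, so
  one event maps to one expected candidate.
* **Sequences** evolve under a 20-state equal-exchangeability Poisson
  process with uniform stationary distribution: along a branch of length
  `d` a site is conserved with probability
  `1/20 + (19/20)·exp(−(20/19) d)`. The closed form is the point — it
  yields exact identities for law-of-large-numbers tests and an exact
  distance inversion — at the cost of realism (no empirical exchange
  matrix, no indels, rate heterogeneity off by default but available as
  discrete gamma).
* **Genome fixtures** plant six-role operons within 10 kb on a single
  contig, decoy paralogs of *ordinary* median length at 500 kb, fused
  EN/NB records of summed length, and incomplete genomes with one or two
  roles deleted; planted class counts are exact
  (`round(fraction · n)`), assignment is a seeded permutation, and every
  planted fact is logged.

What passing tests on this generator show — and what they do not: the
screen's perfect sensitivity/specificity holds on *noiseless annotations*
whose symbols match the synonym table; real annotations mislabel,
truncate and split genes, so real-data performance is bounded by annotation
quality, not by the algorithm. Likewise the transfer-recall rates quantify
the greedy RF statistic under the simulator's substitution model, not the
biological false-positive rate in the presence of incomplete lineage
sorting or alignment error, which the simulator does not model.

## 7. Determinism and reproducibility

Every stochastic function takes an explicit seed and restores the caller's
RNG state. All serialisations are canonical (sorted rows, canonical Newick,
fixed-point branch lengths with trailing zeros trimmed at 6–12 digits
depending on context). The pipeline stamps each artifact with the md5 hash
of its configuration and the seed; the run log records stage names and
input/output counts only — wall-clock times go to the console message
stream, not into the bundle, precisely so that a rerun with the same
configuration is byte-identical.

## 8. Problem sizes and known limitations

The test and acceptance workloads use 8–20 genomes, 5–20 taxa for distance
experiments, 16 taxa and 2000 sites for transfer-recovery replicates, and
exhaustive supertree search up to 7–8 leaves — sizes chosen so the entire
validation suite certifies exact behaviour (against brute-force and
reference-implementation oracles) rather than sampled behaviour at scale.
The algorithms themselves are polynomial (screening, NJ, RF, consensus) or
explicitly bounded (exact supertree), but the pure-R/Rcpp implementation
targets hundreds, not tens of thousands, of genomes.

Known limitations: no ML/Bayesian inference or branch supports beyond
consensus frequencies; no alignment trimming; no duplication-transfer-loss
reconciliation (the RF-pruning statistic detects *that* and *who*, not
donor/recipient direction); fused records are not split at domain
boundaries; and the nearest-reference cluster assignment presumes the
reference exemplars are themselves correctly labelled.
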