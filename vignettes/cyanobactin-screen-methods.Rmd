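---
title: "Methods: in-silico screening and phylogenetics of cyanobactin protease genes"
author: "cyanoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico screening and phylogenetics of cyanobactin protease genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoscreen)
```

## The problem

Cyanobactins are ribosomally synthesized, post-translationally modified
cyclic peptides made by cyanobacteria from a conserved biosynthetic gene
cluster. The cluster's *N*-terminal protease gene (the "A-gene") is the
standard marker for detecting cyanobactin capacity: it is conserved enough
to amplify with degenerate PCR primers across genera, yet variable enough
that its phylogeny separates chemotypes. Two complications shape the whole
workflow. First, the cluster's *C*-terminal protease gene (the "G-gene") is
homologous to the A-gene over part of its length, so an amplicon must be
assigned to one family before it enters a phylogeny. Second, the cluster
moves between lineages by horizontal transfer, so the A-gene tree and a 16S
rRNA (species) tree disagree in characteristic ways — that disagreement is
itself the signal used to flag transfer events.

`cyanoscreen` implements this screen end to end at desk scale: degenerate
primer design from an alignment, in-silico PCR, A/G classification,
alignment, maximum-likelihood phylogenetics with bootstrap, and gene-tree /
species-tree incongruence analysis. A seeded generator produces synthetic
datasets with recorded ground truth, which is what every statistical claim
in the test suite is measured against.

## Primer design and in-silico PCR

Candidate priming windows are scored on a per-column conservation profile:
each alignment column is summarized by the *minimal* IUPAC code covering
every observed base (not a majority consensus), because a screening primer
must anneal to every known template. A window qualifies when its product of
column degeneracies stays under a cap (default 96, twice the degeneracy of
the published forward screening primer), no column exceeds a gap fraction
of 0.10 (indels break annealing; the threshold is ours), and its 3'-terminal
three positions each have degeneracy at most 2 (polymerase extension is most
sensitive there). Pairs are ranked by total degeneracy, then mean gap
fraction, then 3'-end degeneracy, with ties going to the leftmost window.
Melting temperatures use the Wallace rule ($T_m = 2(A{+}T) + 4(G{+}C)$):
deterministic and parameter-free, which is all ranking requires; it is
documented as replaceable rather than thermodynamically serious.

The nominal product length is measured on the consensus with majority-gap
columns dropped, so one number is reported even though real amplicons vary.
We treat the published 804 bp figure as footprint-inclusive (both primer
footprints counted); with a 17-base forward and an 18-base reverse primer
that leaves a 769-base core, and the synthetic generator uses exactly that
geometry.

In-silico PCR matches primers under IUPAC semantics: a primer position
mismatches only when its base set and the template's base set are disjoint,
so degenerate positions already tolerate their encoded variants at the
default of zero mismatches. The allowance is configurable up to 3 to mimic
relaxed annealing. Products form between any plus-strand site and any
downstream minus-strand site, which makes the operation symmetric under
reverse-complementing the template (the two strands of one molecule give the
same products) and reports primer self-pairings rather than hiding them.

## A/G classification

The published screen confirmed amplicon identity with BLASTn and discarded
G-gene hits. We replace that service call with a transparent classifier:
each class keeps the union of canonical 11-mers over its reference set, and
a query is scored by containment — the fraction of its own canonical k-mers
present in each class profile. Containment rather than Jaccard because an
804 bp amplicon against full-length references should not be penalized for
the references' extra length. k = 11 balances sensitivity and specificity at
the 20–40% divergence that separates the paralog families; the monotone
degradation of scores with divergence is property-tested. Calls with a
winning margin under 0.05 are labelled `ambiguous` and surfaced instead of
silently dropped. A sliding-window version (`scan_genome`) stands in for
genome-mining service searches, merging same-label windows into maximal
intervals.

## Alignment

The progressive aligner is a deliberate, deterministic stand-in for MUSCLE:
a guide tree from average-linkage clustering of canonical k-mer Jaccard
distances (lexicographic tie-breaks), then profile–profile global alignment
with affine gaps (match +1, mismatch −1, gap open −4, gap extend −1; a gap
of length $L$ costs $open + (L-1) \cdot extend$). Traceback ties prefer the
diagonal, then consuming from the first profile, so output is reproducible
to the byte. Pairwise scores are verified against exhaustive enumeration of
all alignments for short sequences. Externally computed alignments can
always be imported as gapped FASTA. Column-for-column reproduction of any
particular MUSCLE output is explicitly not a goal.

## The substitution model and likelihood

Phylogenetics uses K2P+Γ+I: Kimura's two-parameter model (transition /
transversion ratio $\kappa$, equal base frequencies fixed at ¼ by the model)
with discrete-gamma rate variation and a proportion of invariant sites.
Gamma discretization uses the means of $K$ equal-probability slices of a
$\mathrm{Gamma}(\alpha, \alpha)$ density, renormalized to average exactly 1;
$K = 5$ by default throughout. Transition probabilities are the K80 closed
form, tested to $10^{-10}$ against a numeric matrix exponential, reducing to
Jukes–Cantor at $\kappa = 1$.

Site likelihoods come from Felsenstein pruning over compressed site
patterns, with gaps and ambiguity codes entering as partial vectors (a 1
for each compatible base). The invariant-sites term contributes
$p_{inv} \cdot m/4$ where $m$ counts the bases compatible with every leaf at
that column — 1 for an ordinary constant column, 0 for a variable one, and
the natural generalization when ambiguity codes are present. The gamma
rates are *not* rescaled by $1/(1-p_{inv})$; branch lengths are therefore in
expected substitutions per variable-class site, a documented choice that the
brute-force oracle in the test suite pins down exactly.

Distances use the closed-form K2P estimator with pairwise deletion of
gapped/ambiguous sites. Saturated pairs raise an error by default; the
bootstrap path substitutes a fixed cap (5 substitutions/site) because
column-resampled replicates can saturate by chance and a replicate must not
abort the run.

## Search, optimization, bootstrap

The starting tree is neighbor joining (via ape) with negative branch length
estimates clamped to zero. Branch lengths and model parameters are fitted by
coordinate ascent: golden-section search per branch on $[10^{-8}, 10]$, then
$\kappa$ on $[0.1, 100]$, $\alpha$ on $[0.05, 50]$, $p_{inv}$ on
$[0, 0.99]$, sweeping until the log-likelihood gain drops below $10^{-6}$
(cap 50 sweeps, with a warning). Per-branch objectives are evaluated from
cached inside/outside partial vectors, so one branch update costs a single
cheap vectorized evaluation rather than a full pruning pass; the cached form
is mathematically identical and the ascent property (log-likelihood never
decreases) is property-tested.

Topology search is nearest-neighbor interchange: both rearrangements of
every internal edge (edges visited in the deterministic order of their
label-sorted bipartitions), each candidate rescored after re-optimizing the
five branches of the affected quartet, accepting the best strict
improvement until none exists. SPR/TBR and model selection across
substitution models are out of scope; the model family is taken as given.

Bootstrap supports resample alignment columns with replacement; replicate
$r$ seeds its stream with $seed + r$, so runs are reproducible and
replicates independent. Each replicate reruns distance → NJ → branch-length
optimization → NNI with model parameters held at the values fitted on the
original alignment (a documented 10–50× shortcut; `refit_per_replicate`
restores the full procedure). Supports are mapped onto the single best ML
tree, matching the usual presentation of one tree annotated with bootstrap
percentages, and displayed at thresholds of 70 (gene trees) and 50
(reference trees) by default.

## Incongruence analysis

Tree comparison restricts both trees to shared leaves (degree-2 nodes
suppressed, branch lengths summed) and uses the Robinson–Foulds distance on
unrooted splits, checked against an independent implementation. Lateral
transfer candidates are found greedily: repeatedly remove the leaf whose
removal most reduces RF (ties alphabetical) until the trees agree or a
budget is exhausted. Greedy removal is transparent and testable against
simulation truth, which is why it was chosen over maximum-agreement-subtree
machinery. A supported gene-tree clade is flagged *novel* when it contains
at least two query taxa, no taxon with a known chemotype, and is maximal
with that property; query taxa in no such clade are reported separately as
"loner" candidates. Because clades are reported as the smaller side of each
bipartition, a novel group can only be detected when the tree contains more
annotated background than query taxa — as in any realistically sized
screen.

## The synthetic generator

`emit_dataset()` produces, from one seed: a Yule species tree (labels
`t001…`), rescaled so the mean root-to-tip depth is 0.3 substitutions/site —
strong but unsaturated signal; horizontal transfers as leaf
prune-and-regraft moves, redrawn until the unrooted topology actually
changes, with recipients recorded; an A-gene core family evolved on the
gene tree under K2P+Γ+I (defaults $\kappa = 4$, $\alpha = 0.5$,
$p_{inv} = 0.1$, $K = 5$ — rate heterogeneity typical of a protein-coding
marker); primer-binding sites implanted as random expansions of the
published degenerate pair, flanking the 769-base core inside random flanks
(so in-silico PCR recovers exactly the recorded 804-base footprint); and a
G-paralog family made by duplicating the A root, evolving it along a branch
of length 1.0 substitutions/site, then down the species tree. Indels
default to off so the true alignment is known exactly, separating alignment
error from phylogenetic error in tests; a nonzero rate produces single-base
deletions to exercise the aligner. The per-site rate category (or invariant
status) is drawn once and shared across the whole tree, matching the
likelihood being fitted.

What the generator does **not** emulate: real genomic composition (GC skew,
codon structure), recombination within the gene, partial-cluster transfer,
sequencing error, or chimeric amplicons. Passing tests therefore demonstrate
internal correctness and statistical calibration under the model's own
assumptions, not performance on real survey data.

In the pipeline's synthetic mode the *true* species tree serves as the
16S-side reference for the incongruence analysis. Re-estimating a reference
tree from a simulated conserved marker would conflate 16S estimation error
with the transfer signal being measured; using the truth isolates the
quantity under test.

## Problem sizes and numerical choices

The test suite and the acceptance script run deliberately scaled studies:
exhaustive likelihood oracles on all 4- and 5-leaf topologies (internal
state enumeration), 100 seeded 4-taxon recovery runs at 2000 sites, 20
parameter-recovery fits at 6 taxa × 2000 sites, bootstrap calibration at
100 replicates (standing in for the conventional 1000), and pipeline runs at
12 taxa. Branch lengths below $10^{-8}$ are treated as zero; likelihood
partials are rescaled when they underflow $10^{-200}$; Newick output rounds
branch lengths to 6 decimals, which bounds round-trip error; all
coordinates anywhere in the package are 0-based half-open; `-` is the only
gap character, and `U` is normalized to `T` on input.

## A worked example

```{r example, eval = FALSE}
res <- run_pipeline(pipeline_config(taxa = 12, hgt = 2, bootstrap = 100,
                                    seed = 1, out_dir = "screen_out"))
sum(res$report$positive)                  # strains with an A-gene amplicon
res$fitted_model$kappa                    # fitted transition/transversion
robinson_foulds(res$tree, res$truth$gene_tree)$rf_distance
res$displaced                             # lateral-transfer candidates
```

Every number above is recomputed by `scripts/acceptance.R`; the vignette
itself asserts nothing the tests do not measure.

## Known limitations

The NNI search can stall in local optima that SPR would escape; NJ starting
trees make that rare at these problem sizes but not impossible. The
classifier is nucleotide-only (the published confirmation was BLASTn, also
nucleotide-level) and will not separate families at divergences where 11-mer
containment vanishes for both. The greedy displaced-taxon heuristic can
split one transferred clade into several removals or mask overlapping
transfers. The aligner has no iterative refinement and is not intended for
deep or heavily gapped families.
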