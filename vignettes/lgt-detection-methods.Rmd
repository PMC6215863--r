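---
title: "Methods: compositional and phylogenetic LGT detection in xenocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional and phylogenetic LGT detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

xenocomp detects candidate lateral gene transfer (LGT) of multi-gene
operons — the motivating case is the three-gene *xmoCAB* operon encoding
copper membrane monooxygenases — by combining two independent lines of
evidence: compositional anomaly of the operon relative to its host genome,
and incongruence or rate anomalies among the per-gene phylogenies. This
vignette is the package's account of the underlying models, the parameters
that matter, and the design decisions taken where the methodology was
genuinely open.

## 1. Compositional model

**Profiles.** A composition profile is a frequency vector over a fixed,
ordered alphabet. Two alphabets are used:

* *Tetranucleotides* (`kmer_profile`, `k = 4`, 256 categories): every
  window of 4 consecutive unambiguous bases is counted. Windows containing
  `N` or any other ambiguity code are skipped whole — no fractional
  attribution — because a partially ambiguous window carries no usable
  signature. Before counting, the sequence is "extended by its reverse
  complement": the reverse complement is counted as a *second independent
  sequence*, never literally concatenated, so no artifactual junction
  k-mers arise. This makes the profile exactly strand-symmetric, which is
  the purpose of the extension (an operon's strand is arbitrary relative
  to the genome's).
* *Codons* (`codon_profile`, 64 categories): codons are read in frame
  within each CDS independently, never across gene boundaries; a trailing
  partial codon is dropped with a warning. Frequencies are
  count/total-codons, the standard normalization for a probability vector
  over codons. (A normalization by the constant 64 appears in some
  descriptions of codon-usage output; it does not produce a probability
  distribution and is not used.)

**The divergence statistic.** For region profile *p* and genome profile
*q* over the same alphabet,

$$D_{KL}(\mathrm{region}\,\|\,\mathrm{genome}) = \sum_i p_i \ln(p_i/q_i)$$

in nats, with *p* the first argument: the statistic asks how surprised the
genome's signature is by the region, which is the direction the
region-versus-genome label denotes. Both profiles are smoothed by a
Laplace pseudocount (default 1 count per category) before normalization.
The pseudocount matters because a ~2.7-kb operon populates only a fraction
of the 256 tetranucleotide categories a genome populates; without
smoothing a single empty category makes the divergence infinite. Gibbs'
inequality guarantees $D_{KL} \ge 0$ with equality iff the smoothed
profiles coincide.

**Bounded score.** Divergences are easier to compare across genomes on a
bounded scale. The package reports `score01 = 1 − exp(−D_KL)`, a strictly
monotone map of the raw nats onto [0, 1) with `score01 = 0` exactly when
the profiles agree. The raw nats are always reported alongside; the
bounded score is a presentation convention, not a different statistic.
The genome profile always includes the operon itself (no leave-one-out):
for megabase genomes and kilobase operons the operon's contribution to the
genome profile is negligible, and the whole-genome comparison matches how
such screens are conventionally run.

**Why whole operons, not single genes.** A single ~750-bp gene populates
the 256-category tetranucleotide space too sparsely for a stable estimate;
the spanning operon (~2.7 kb) is the smallest unit profiled. The spanning
sequence feeds the tetranucleotide method; the concatenated coding
sequences feed the codon method, which by definition needs CDS. Both
extraction modes are available in `operon_sequence` because the choice is
not forced by the data model.

## 2. Window scan and alien-region calls

`window_scan` slides a 2500-bp window (the classical alien-region window
size) along the genome with a default step of 500 bp (window/5 — "moving"
window methods rarely publish their step; window/5 balances resolution
against cost). For each word size $k = 2..8$ it computes the smoothed KL
of the window against the whole genome and combines orders with weights
$w_k \propto 4^{-(k-2)}$, normalized to sum to 1. The geometric
down-weighting reflects estimation noise: a 2500-bp window offers ~2500
observations against $4^k$ categories, so an order-8 profile (65,536
categories) is mostly pseudocount and would otherwise dominate the sum
with noise. A trailing partial window is kept when it is at least half a
window long; shorter tails are unmeasurable and dropped.

`call_alien_regions` needs a threshold. Published island-finders select an
internal significance threshold by unpublished rules; xenocomp uses a
deterministic, documented one: a 1-D 2-means split of the combined window
scores, with the threshold at the smallest upper-cluster score, accepted
only if the upper cluster's mean exceeds the overall mean by more than two
overall standard deviations. The guard is an effect-size criterion that
returns *no calls* on homogeneous genomes, where 2-means would otherwise
split noise. Supra-threshold windows that touch or overlap are merged, and
calls are annotated with the operon loci they intersect — an operon inside
a called region is the scan's criterion for compositional LGT support.

## 3. Phylogenetic machinery

**Distances.** `poisson_distance` uses pairwise gap deletion (each pair is
compared over the columns where both are non-gap), $p$ = proportion of
differing sites, $d = -\ln(1-p)$. Pairwise deletion keeps all taxa usable
when gap patterns differ across sequences. Saturated pairs ($p \ge 0.95$,
i.e. $d \ge 3$) raise an error naming the pair rather than clamping:
distances that deep carry no topological information and the correct
remedy is excluding the sequence, as is standard practice for
deeply-diverged outgroups.

**Neighbor joining** is implemented in-package (Saitou–Nei agglomeration
on the Q-criterion) rather than delegated, because the package fixes two
behaviors that library implementations leave unspecified: ties in Q are
broken by the lowest index pair, making runs bit-reproducible, and
negative branch estimates are clamped to zero with the clamped deficit
reported. `ape::nj` serves as an independent cross-check in the test
suite, never as the implementation. On additive matrices NJ is consistent,
and the tests verify exact recovery (path lengths to 1e-9).

**Incongruence.** `rf_distance` prunes both trees to their shared leaves
and counts the symmetric difference of non-trivial splits, normalized by
the maximum $2(n-3)$. The discordant splits are listed so a conflict can
be traced to the clade that moved — the analysis pattern for a single
operon gene (e.g. *xmoB* in verrucomicrobial methanotrophs) having its own
transfer history.

**Rates.** Bayesian relaxed-clock per-branch rates are out of scope (they
require full MCMC machinery); the package's rate contrast is the
root-to-tip rate ratio: root the tree on a named outgroup and divide the
focal clade's mean root-to-tip path length by the background's. On a
clock-like tree the ratio is 1; a clade whose branches evolved $m\times$
faster over essentially its whole root-to-tip path shows a ratio near $m$.
Equivalence with relaxed-clock posterior rates is claimed only at the
level of *detecting* the accelerated lineage, not reproducing posterior
rate values.

## 4. The synthetic-data generator

The generator produces every input the pipeline consumes, with recorded
ground truth, under one user seed (child seeds are derived per stage, so
partial reruns reproduce byte-for-byte).

* **Host/donor genomes** are order-0 (optionally higher-order) Markov
  chains. The default contrast is host GC 40% vs donor GC 60% — the
  separation scale of a strongly foreign operon in a low-GC host, and
  clearly resolvable at desk scale.
* **Operon inserts** (`gen_operon_insert`) span Normal(2730, 300) nt
  truncated at ≥ 1500 — 2730 nt is the average *xmoCAB* operon length —
  with three same-strand genes in CAB order (ABC available for the
  pxm-like arrangement), CDS lengths multiples of 3 apportioned roughly as
  xmoC:xmoA:xmoB = 0.28:0.27:0.45, and 15-nt intergenic spacers.
* **Implantation** places inserts uniformly at random, ≥ 5 kb apart,
  conserving every host base and recording final insert coordinates. The
  `lgt` scenario adds two matched *native* operon-shaped loci carved from
  host background (the negative controls ranking tests need) and ~150
  background CDS so the genome-wide codon profile is dominated by host
  usage, as in a real genome.
* **Gene families** (`sim_gene_families`) evolve ungapped amino-acid
  alignments along a known tree under the Poisson model: per site,
  substitution events arrive with rate = branch length and each event
  jumps uniformly to one of the 19 other residues (implemented as
  mod-20 addition of uniform increments, which is exactly that jump
  chain). This matches the $-\ln(1-p)$ estimator by construction up to
  finite-state back-substitution: at the default depths (root-to-tip
  ≤ ~0.4, ≤ ~1.2 for the accelerated clade) the resulting downward bias in
  estimated depths is a few percent, and it largely cancels in the
  rate *ratio*.
* **Default tree**: 12 taxa — one outgroup, a 3-leaf focal clade emulating
  a third operon copy, 8 background taxa — with an ultrametric ingroup
  (depth 0.35) and internal branches ≥ 0.05, long enough for NJ on
  500-site alignments to recover the topology in essentially every
  replicate. The `incongruence` scenario regrafts the focal clade into the
  background for gene 2; the `rates` scenario multiplies the focal clade's
  branch lengths (stem included) by 3.46 for gene 3 — the acceleration
  magnitude reported for the third operon copy's *xmoC* in
  verrucomicrobial methanotrophs, adopted as the generator's default so
  recovery is tested at a realistic effect size. Because the clade is
  scaled stem-included and the ingroup is ultrametric, the expected
  root-to-tip ratio equals the multiplier.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: genomes are stationary Markov chains without
replication-strand skew, repeats or mobile elements, so the false-call
rate on real genomes will exceed the synthetic one; amelioration (the
gradual compositional assimilation of transferred DNA) is absent, so
synthetic inserts are uniformly "recent"; alignments are ungapped with
equal substitution rates across sites and residues, so real-protein
distance biases (site-rate heterogeneity, exchangeability structure) are
unmodelled; and primer targets are unstructured random sequence.

## 5. Numerical choices and degenerate inputs

* Pseudocount 1 per category, both profiles, before normalization; terms
  with $p_i = 0$ contribute 0 (cannot arise after smoothing).
* Internal coordinates are 0-based half-open; GenBank (1-based inclusive)
  and loci TSV files convert at the boundary.
* Circular topology is honored only when declared; intervals may wrap once.
* An operon with genes on both strands is extractable in spanning mode
  only when its order tag is recognized; otherwise it is rejected as
  ambiguous rather than silently strand-guessed.
* `call_alien_regions` requires ≥ 10 windows; scanning a sequence barely
  longer than one window cannot estimate a background, and the error
  directs the user to the direct operon table.
* NJ tie-break: lowest (i, j) pair; negative branches clamped to 0 with
  the deficit reported via `message()`.
* Concatenation drops taxa under 910 non-gap residues by default — the
  minimum-information filter used for concatenated three-gene operon
  trees; `min_len = 0` disables it.
* Primer matching is ungapped with no 3'-end weighting: plain mismatch
  counts, minimum over all placements, both strands, leftmost tie-break.
  The mismatch threshold for calling a group "covered" has no defensible
  universal default and is a required parameter.

## 6. Problem sizes

The shipped tests exercise: 20 replicates of the 200-kb/two-insert LGT
scan (full k = 2..8 combined scan per replicate); 50 replicates each of
the incongruence and rate-recovery simulations at 500 sites on the
12-taxon tree; 100 additive-matrix NJ recoveries on 5–8 taxa; 1,000
random profile pairs for the divergence bounds; 200 random primer/target
pairs against the exhaustive-expansion oracle; and 500 insert draws for
the length calibration. These sizes give stable pass/fail behavior for
the stochastic checks (binomial noise well below the asserted margins)
while keeping a full run in minutes on one core.

## 7. Known limitations

Compositional evidence is correlational: unusual composition has causes
other than transfer (strand skew, highly expressed genes, low-complexity
regions), and recent transfers from compositionally similar donors are
invisible. The window scan's threshold is scan-wide, not per-window
significance. The root-to-tip ratio detects acceleration but cannot
localize it to particular branches, and is diluted when the accelerated
clade attaches far from the root. RF distance treats all splits equally
regardless of support. None of the methods models within-operon
recombination.
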