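# xenocomp

Compositional and phylogenetic detection of lateral gene transfer (LGT) of
multi-gene operons.

## The problem

Copper membrane monooxygenases (pMMO, AMO and relatives) are encoded by a
three-gene operon, generically *xmoCAB*, scattered across distantly related
bacteria and archaea. Whether a given lineage acquired its operon vertically
or by lateral transfer is read from two independent signals:

1. **Composition.** Foreign DNA carries the k-mer and codon-usage signature
   of its donor. For a region *R* inside a genome *G*, xenocomp computes the
   Kullback–Leibler divergence of the region's composition from the
   genome's,

   D_KL(R‖G) = Σᵢ pᵢ ln(pᵢ/qᵢ)  (nats),

   where *p* and *q* are Laplace-smoothed frequency vectors over the 256
   tetranucleotides (strand-symmetrized by counting the reverse complement
   as a second sequence) or the 64 codons (read in-frame per CDS). A
   bounded score `score01 = 1 − exp(−D_KL) ∈ [0, 1)` is reported alongside
   the raw nats: 0 means the operon looks native, values near 1 mean
   strongly foreign. A sliding-window variant (2500-bp windows, combined
   2- to 8-mers with geometrically down-weighted higher orders) scans whole
   genomes and calls "alien" regions against a 2-means threshold with an
   effect-size guard.

2. **Phylogeny.** Per-gene trees are built by neighbor joining on
   Poisson-corrected amino-acid distances, d = −ln(1 − p) with pairwise gap
   deletion. Incongruence between the *xmoA*/*xmoB*/*xmoC* trees is
   quantified by Robinson–Foulds distances with the discordant splits
   listed, and lineage rate acceleration by the root-to-tip rate ratio of a
   focal clade against the background after rooting on an outgroup.

A degenerate-primer screen (exhaustive IUPAC mismatch counting, amplifiable
fwd/rev orientation, per-group coverage fractions) and a fully seeded
synthetic-genome generator (Markov-chain hosts, compositionally distinct
operon inserts of mean length 2730 nt, codon-biased CDS, gene families
evolved on known trees with topology swaps and clade rate multipliers)
complete the toolkit, so every stage is testable against known ground
truth.

## Worked example

```r
library(xenocomp)

# A 200-kb host genome (GC 40%) with two implanted donor operons (GC 60%)
# and two matched native loci, with ground truth recorded:
sc <- simulate_scenario("lgt", seed = 7)

tab <- operon_kl_table(list(sc$genome), sc$loci)
tab[tab$method == "tetra", c("operon_id", "kl_nats", "score01")]
#   operon_id    kl_nats    score01
#   implant_1 0.33636198 0.28563553
#   implant_2 0.33198316 0.28250060
#    native_1 0.01795110 0.01779094
#    native_2 0.02344569 0.02317298

scan <- window_scan(sc$genome)          # 2500-bp windows, k = 2..8
call_alien_regions(scan, sc$loci)
#    start    end peak_score  threshold overlapping_operons
#    54500  58500  0.1978494 0.08478871           implant_1
#   101500 106000  0.1929867 0.08478871           implant_2
```

Both implanted operons score an order of magnitude above the native loci
(tetranucleotide KL ≈ 0.33 vs ≈ 0.02 nats) and the window scan calls
exactly two alien regions, each containing one implant — the compositional
signature of recent lateral transfer.

The phylogenetic side, on three simulated gene families where gene 2
evolved with the focal clade regrafted elsewhere:

```r
ic <- simulate_scenario("incongruence", seed = 3)
trees <- lapply(ic$alignments, function(a) nj_tree(poisson_distance(a)))
incongruence_table(trees)
#   gene1 gene2 n_shared rf rf_normalized
#   gene1 gene2       12  6     0.3333333
#   gene1 gene3       12  0     0.0000000
#   gene2 gene3       12  6     0.3333333
```

Genes 1 and 3 agree perfectly (RF = 0) while gene 2 conflicts with both —
the signature of a single gene with its own transfer history inside an
otherwise co-inherited operon.

A full report bundle (KL table, alien-call BED, newick trees, incongruence,
rates, primer coverage, log and config echo) is produced by `run_full()`,
or from a shell via the thin wrapper `inst/scripts/xenocomp.R`.

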