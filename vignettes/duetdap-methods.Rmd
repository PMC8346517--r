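---
title: "duetdap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duetdap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`duetdap` compares the genome-wide binding of two related MADS
transcription-factor complexes assayed by seq-DAP-seq in triplicate. This
vignette records the models, the conventions and the places where the
design was genuinely open, so a maintainer can tell a principled choice
from an arbitrary one. No empirical claims are made here beyond what the
test suite and `scripts/acceptance.R` compute.

## Coordinates and containers

All coordinates are 0-based half-open, BED-native, everywhere in memory;
conversion happens only inside readers and writers. A genome is a named
character vector of chromosome sequences over `ACGTN` plus a category
annotation (promoter / exon / intron / intergenic blocks that must tile
each chromosome exactly). Coverage is a per-base numeric vector per
chromosome with an explicit `library_size`. N bases are allowed but never
match any motif window and are excluded from GC computation.

## From coverage to peaks

The upstream peak caller is a declared stand-in: a peak is a maximal run
of bases at or above `min_height` (default 5 read-depth units, ~10x the
default Poisson background mean of 0.5) of length at least `min_width`
(50 bp), with the leftmost maximum as summit. Replicate consensus keeps a
first-replicate peak iff it overlaps (>= 1 bp) a peak in every other
replicate — the replicate-intersection reading of "present in all
replicates" — and represents the kept locus by the overlapping peak with
the highest summit signal, so a well-defined summit survives. Consensus
peaks are scanned for subpeaks on the replicate-mean track: the peak is
split at any local minimum below `valley_fraction` (0.5) times the
smaller flanking local maximum. Peaks are then resized to a summit-centred
401-bp window (+-200 bp) and annotated with per-replicate normalised
coverage: `count / ((length/1000) * (total/1e6))`, where `total` is that
replicate's summed count over the complex's own final peak list ("reads
mapped in bound regions"). The subpeak threshold and the representative
rule are not prescribed anywhere we could follow; both are exposed as
parameters.

## Merging and the CFR

Two resized peak sets are merged by reciprocal overlap fractions
(`overlap / own length`). A pair with both fractions > 0.5 becomes one
`common` entry over the union interval, paired greedily by descending
overlap; `high_confidence` records whether the larger fraction reached
0.8. Everything else stays as a set-specific entry over its own interval.
Practitioner descriptions of this merge step usually state an 80%
reciprocal-overlap clause alongside a 50% clause; the two are redundant
for equal-width peaks, so we reconciled them as above with both
thresholds exposed. Mean normalised
coverage of *both* complexes is recomputed over every merged interval,
and

`CFR = (cov_B + 0.01) / (cov_A + 0.01)`

with the pseudocount guarding zero coverage. Specific sets are the
lowest and highest `ceiling(0.15 * N)` entries by CFR, ties broken by
larger |log10 CFR| then leftmost; `ceiling` (rather than rounding) is a
convention.

## Binding-site models

**PWM.** Width 16, palindromic — the natural settings for a MADS
dimer binding a CArG box. Discovery is a deterministic beam search rather than the
single-seed scheme one might first write: the top 16 over-represented
8-mers (vs the 0-order background; near-duplicates sharing a >= 6-base
exact overlap collapsed) are each placed mid-matrix, refined for 3
iterations (align every sequence's best window either strand;
re-estimate with pseudocount 0.25; average with the reverse complement
when palindromic), the best 3 by *median* best-window log2-odds are
refined to an alignment fixpoint, and finally the winner is re-refined
from +-4-column shifts to fix the alignment register. The median
objective is the load-bearing choice: training sets contain sporadic
high-ratio words (in our synthetic world, the planted differential
k-mers; in real data, repeats) whose refined matrices score a few
sequences extremely highly, and a mean objective — let alone raw seed
over-representation — selects them. A majority-support objective selects
the motif present in every sequence, which is the palindromic CArG core.

**First-order positional model.** A counting-estimated position-specific
dinucleotide model (initial distribution + one 4x4 transition matrix per
adjacent position pair, pseudocount-smoothed), scored as the best-window
log2 ratio against a 0-order background chain. This is a declared
simplified stand-in for HMM-trained flexible models; it captures the
dinucleotide dependence without Baum-Welch.

**KSM.** For every k in 4..20, k-mers are counted by per-sequence
containment (either strand, once per sequence) in bound vs unbound
sequences centre-trimmed to 300 bp; enrichment is the hypergeometric
upper tail, Benjamini-Hochberg-corrected across all tested k-mers, kept
at adjusted p < 1e-3 (capped at the 1000 most significant before
clustering). Retained k-mers cluster greedily in significance order: a
k-mer joins the first cluster where it overlaps a member by >= k-2
identical bases at a consistent offset (either strand), else it seeds a
new cluster scored `-log10 p(seed)`. A sequence's KSM score is the sum of
scores of clusters with at least one member present. This keeps the
set-of-aligned-k-mers idea exact and oracle-testable; gapped and
mismatch-tolerant matching, as in the full KMAC-style tools, is
deliberately out of scope, so cluster counts from those tools are not
expected to reproduce.

## Evaluation

Unbound backgrounds match each bound region in length, origin category
(at the region midpoint) and GC decile bin of the bound set's GC
distribution, by rejection sampling, one discovery and one disjoint
evaluation region per bound region (1:1 by choice; decile binning is
our concretisation of "similar GC content").
AUROC is the Mann-Whitney pair-counting form — identical to trapezoidal
ROC integration, trivially oracle-checkable. Note the discovery role is
consumed by KSM training and the evaluation role by AUROC negatives, and
the two never overlap; with few bound regions on a small genome the
second role can exhaust the matching territory, which is reported as an
error rather than relaxed silently.

## Spacing preferences

CArG sites are consensus matches (`CC(A/T)6GG`, <= 1 mismatch by
default); the family is its own reverse complement so one strand
suffices. Distances are start-to-start of the 10-bp boxes, counted once
per ordered pair within a region, over 10-100 bp. The null redraws each
region's site positions uniformly (site counts preserved, 100 shuffles);
counts are smoothed +-1 bp, z = (obs - expected)/sd with the SD floored
at 0.5 pairs. Calls are one per contiguous z >= 3 run, placed at the
run's raw-count maximum. Two details differ from the obvious first
implementation and matter: the SD floor prevents infinite z at distances
the null never populates, and calling per run (not per local z maximum)
prevents the smoothing from shifting a sharp planted distance by +-1 bp.
The distance convention itself is a declared choice, but the generator
and detector share it, so recovery is self-consistent.

## Enrichment

Peaks map to the gene with the nearest TSS within 3 kb of the summit
(ties to all tied genes); the universe is all genes in the supplied
annotation; `fold = (k/n)/(K/N)`; p is the hypergeometric upper tail
with BH correction. Assignment rule and universe are the standard promoter-proximal
conventions and are parameters; no attempt is made to pin enrichment
values on any particular real annotation.
The "most differentially bound" study set is the top `enrich_top_n`
regions by CFR rank per side (250 at genome-wide scale; the bundled
demo uses 60, proportionate to its merged-list size).

## What the generator emulates — and what it does not

`synth_spec()` states the world once: a 1 Mb i.i.d. genome at GC 0.36
(plant-like) tiled with 200-2000-bp category blocks (0.2/0.3/0.2/0.3);
260 common + 40 + 40 specific regions of 400 bp, >= 500 bp apart; two
CArG boxes per region at start-to-start spacings 47/57 bp (complex A),
25/34 bp (complex B), common regions drawing from the equal mixture; two
differential 10-mers per complex planted at probability 0.7 in own
specific regions and 0.05 elsewhere; log-normal affinities with the
off-complex affinity suppressed 10-fold in specific regions; triangular
signal bumps (height = affinity x 50, per-replicate gamma factor of
dispersion 0.1) over Poisson(0.5) background, in triplicate. The class
counts keep most binding shared (the typical situation for two closely
related complexes)
and respect two arithmetic constraints: each side's specific-set
capacity `ceiling(0.15 N)` must hold the planted specific regions, and
KSM's BH correction across ~2.4M k-mer tests needs a few hundred bound
training sequences to detect k-mers at these planting rates.

Not emulated: read-level artefacts (duplicates, mappability, adapter
noise), fragment-size structure, spatially autocorrelated GC, chromatin
context, and motif affinity gradation (all planted boxes are consensus).
A green recovery test therefore establishes that the *pipeline logic*
recovers planted differential structure under realistic noise — not that
the stand-in peak caller or the simplified KSM matches external tools on
real sequencing data.

## Numerical conventions

Window codes pack k-mers (k <= 20) into exact base-4 doubles
(4^20 < 2^53), and (sequence, k-mer) pairs pack into one double for
per-sequence dedup — bit-exact, no hashing. Cluster p-values are clamped
at 1e-300 before `-log10`. Model writers emit full-precision (`%.17g`)
numbers so read(write(x)) is bit-identical. All randomness flows through
explicit seeds; `run_pipeline()` derives per-stage seeds from the master
seed, and identical config + seed gives byte-identical outputs.

## Known limitations

Peak calling and replicate consensus are intentionally simple stand-ins;
with strongly overlapping or nested real peaks the representative rule
can merge loci a model-based caller would keep apart. The first-order
model is not an HMM and will underfit motifs with variable-length
spacers. KSM containment is exact, so sites carrying a single variant
base are missed where mismatch-tolerant tools would hit. Background
matching can fail loudly on small or compositionally extreme genomes
(by design). Dataset-level numbers from external tools (peak counts,
cluster counts, absolute AUROCs) depend on those tools' internals and
on real sequencing data and are out of scope; the package's claims are
the recoverable qualitative patterns its tests assert.
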