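---
title: "Models and methods behind centeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind centeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`centeline` packages the computational workflow for studying a
centromere-colonizing LINE retrotransposon family: mining element copies
from a genome assembly with an anchor sequence, classifying them,
detecting target-site duplications (TSDs), dating insertions under a
linear molecular clock, quantifying CENH3-domain targeting against a
random-placement null, calling CENH3-binding domains from windowed
ChIP/input read densities, converting fiber-FISH measurements, and
building bootstrap-supported neighbor-joining trees of
reverse-transcriptase (RT) domains. A synthetic-genome generator with a
full truth table makes every stage testable without any external data.

This vignette records the models, the parameter choices that matter, and
the design decisions made where the problem left the design open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

# Coordinates, alignment and identity

All internal coordinates are 1-based and inclusive on both ends, so the
representative element at 10,103,867..10,109,980 spans 6,114 bp; BED I/O
converts to 0-based half-open at the file boundary (via `rtracklayer`).

Pairwise alignment uses match +1, mismatch −1, and affine gaps in which a
run of length $k$ costs $\mathrm{open} + k\cdot\mathrm{extend}$ (defaults
2 and 1). `N` is treated as unknown and never matches anything, including
another `N`. Identity is the fraction of identical columns among counted
columns; the default mode excludes terminal gap overhangs (so a truncated
copy compared with a full-length copy is scored over their overlap) while
internal gap columns count as non-identical. The underlying dynamic
program is `Biostrings::pairwiseAlignment`; ties between co-optimal
alignments are broken deterministically by that implementation, which is
all the downstream statistics require. For all-versus-all comparisons of
full-length (~6 kb) copies the package adds a banded Needleman–Wunsch in
C++ (`alignBandedGlobal`), exact whenever the optimal path stays within
the band; the tests verify score agreement with the full dynamic program
on randomly mutated pairs, and the band is widened automatically to cover
any length difference.

The identity denominator (the treatment of gaps and terminal
overhangs) is a declared package convention, stated above rather than
inferred from anywhere.

# The synthetic-genome generator

`simulateGenome()` draws i.i.d. background sequence at a configurable GC
content (default 0.338, the genome-wide GC of the study system) and
places one centromeric domain per chromosome. `plantInsertions()` then
inserts copies of a master element, oldest first, with full coordinate
bookkeeping: every earlier feature that starts at or after an insertion
point is shifted, and features spanning the point (domains, donor
elements, earlier insertions) are extended, so nesting is geometrically
consistent and every truth interval can be re-extracted verbatim.

**Scale.** The defaults are a desk-top-scale caricature of the study
system: 3 chromosomes × 500 kb with domains drawn from 10.4–30.9 kb.
That domain range is the study system's reported 427–1,267 kb range scaled by the same
factor (~1/41) as the chromosomes themselves (~20.5 Mb in the real
genome), which preserves the quantity that matters downstream: the
domain fraction of the genome (~3%). Keeping that fraction realistic is
essential for the ChIP model — with domains at, say, 17% of the genome,
an in-domain enrichment of 30× normalizes to a ChIP/input fold below 5
and no caller with the stated fold/FDR thresholds could (or should)
find anything.

**The clock.** Divergence is modeled as substitutions only, uniform
across sites, with no multiple-hit correction, because the dating
arithmetic it must reproduce converts identity to time linearly. Between
consecutive births the source lineage accumulates
$\mathrm{Poisson}(\mu\,\Delta t\,L)$ substitutions and each copy
accumulates $\mathrm{Poisson}(\mu\,t\,L)$ private ones after its birth,
so a copy of age $t$ differs from its closest younger relative by
$2\mu t L$ substitutions in expectation — the premise of the
highest-pairwise-identity estimator. The default
$\mu = 1.3\times10^{-8}$ substitutions/bp/year.

**TSDs and the nick motif.** TSD lengths are drawn on [10, 30] bp with
mean 15 (binomially thinned). The 5′ junction is matched to a sampled
nick motif (AAGA or AATA spanning junction positions −1..2) when one
occurs within ±150 bp of the sampled site, with a uniform fallback
otherwise; the window is wide enough that most insertions find a motif,
emulating the strong observed junction bias (e.g. G/T at position 1 in
90% of the real insertions). Insertion sites whose flanking base would
extend the duplication by accident are resampled, so the emitted TSD is
exactly the maximal duplication — without this, roughly a quarter of
detected TSDs would be one base longer than planted and exact recovery
would be unattainable by construction rather than by any fault of the
detector.

**Targeting and nesting.** The in-domain decision (default probability
0.84) is drawn first; the nesting decision (default 0.65) then chooses a
donor element in the already-chosen stratum, so the two marginals are
controlled independently and can be recovered separately. Donor
(LTR-like) elements are planted first at AT-biased sites with 5-bp TSDs.
Truncation affects the 5′ end only (probability and length range
configurable), mirroring the biology of LINE insertion.

**What the generator does not emulate:** indels and rate heterogeneity in
the mutation process, recombination, solo-LTR formation, satellite
arrays, sequencing error, and mappability structure. Tests passing on
these genomes therefore demonstrate the correctness of the algorithms
under the stated generative model, not performance on real assemblies.

# Mining and classification

`findElementCopies()` is a seed-and-extend search: exact 14-mers of the
anchor (both strands) are located with a `PDict`, chained by diagonal
(genomic position minus anchor offset) so tandem and nested copies
separate into distinct candidates, and each candidate region is refined
by local alignment of the anchor. Hits shorter than 200 bp or below 80%
identity are dropped — thresholds that replace the E-value cutoff of a
BLAST-based search with a self-contained deterministic rule of the same
intent. Same-strand hits closer than 50 bp are merged.

`classifyElement()` aligns the full reference element into the hit's
neighborhood and applies the field's thresholds: full-length requires
less than 100 bp of 5′ truncation and less than 500 bp of internal
deletion with the 3′ end present; a copy with the 3′ end but more damage
is truncated; anything without the 3′ end is a fragment and is excluded
from copy counts. Two operationalizations are deliberate package choices: "3′ end present" means the alignment reaches
within 50 bp of the reference 3′ terminus, and the classification
alignment uses length-lenient gap costs (open 10, extend 0.1) so that
internal deletions of hundreds of bp are bridged and measured rather
than clipped by the local alignment.

`assessOrfIntactness()` projects both reference ORFs onto the copy
(ends-free alignment) and requires, within each ORF: full coverage,
every indel a multiple of 3, an ATG start, a stop at the end, and no
premature stop in the reference frame. This is sequence-level only; no
protein-domain models are consulted.

# TSD detection and junction composition

`detectTsd()` returns the longest suffix of the upstream flank equal to
a prefix of the downstream flank, with up to 2 bp of boundary-offset
slack per side to tolerate imperfect boundary refinement; ties prefer
the smallest offset, then lexicographic order. Duplications of at least
10 bp are flagged high confidence, and only those enter the junction
matrices; shorter ones (≥ 5 bp) are reported but flagged.

Junction matrices use the field's position numbering: position 1 is the
first TSD base and position 0 the base immediately upstream, so the 5′
window (10 bp of flank + 10 bp of TSD) is labeled −9..0, 1..10. Matrices
are per-position base fractions over A, C, G, T, with per-position
observation counts; columns with data sum to 1 within $10^{-9}$.

# Dating

`ageFromIdentity()` implements $t = (1 - \mathrm{id})/(2\mu)$. The
divisor $2\mu$ is not a guess: it is the only constant that reproduces
the green-ash identity-age pairs (84% identity ↔ 6.2 My requires both
lineages to mutate).
`highestPairwiseIdentity()` computes the full symmetric matrix once and
takes each element's best partner; `ltrInsertionAge()` applies the same
kernel to an LTR pair, with identities below 0.80 flagged as beyond the
method's detection limit (there is no standardized definition of that
limit; 0.80 is the package's exposed, configurable default).

The estimator has an intrinsic, documented softness: an element's best
partner is the *minimum* over many divergence draws that share the same
expectation $2\mu t L$, so estimates are biased slightly downward (order
$1.5/\sqrt{2\mu t L}$, relatively) and noisy for young or short
elements. The package's recovery study therefore runs at the element's
full 6,114-bp length with a burst age structure — 40% of copies young
($10^4$–$10^5$ yr) and 60% old ($5\times10^5$–$4\times10^6$ yr),
spanning the recent-burst regime of the poplar family and the older
green-ash-like regime — with $n = 58$ copies, a realistic full-length
family size. Under these conditions (fixed before the tests were written, on
the basis of an analytic error model and a mismatch-count pilot) the
median relative error on ages ≥ $10^5$ yr is comfortably below the 15%
tolerance the tests assert. Dated sets are restricted to copies whose
extracted length is within 500 bp of the master (the full-length rule);
copies inflated by nested insertions are excluded, as the counting
rules require.

# Targeting statistics

`assignDomainRelation()` classifies each element as inside (≥ 1 bp
overlap), near (within 20 kb), or outside. `randomPlacementNull()`
re-places the domain set uniformly without overlap, preserving each
domain's length and chromosome (a stricter, documented choice than
matching only the total re-placed length), and scores the element percentage falling in the random regions;
its expectation is the covered genome fraction. `binnedDensity()`
reports per-100-kb covered fractions rescaled so the densest bin is 100.
`detectNested()` aligns the 150 bp downstream of each element (3′,
strand-aware, both orientations) against a labeled donor library and
requires ≥ 50 aligned bp at ≥ 80% identity.

# ChIP window model and island calling

`windowDensity()` counts unique read starts per 1-kb window divided by
the window's mappable bp (fully mappable unless a mappability track is
given). `callDomains()` tests each window's ChIP count against a Poisson
expectation scaled from the input count and the library-size ratio,
adjusts p-values by Benjamini–Hochberg across windows with at least one
input read, and merges windows passing fold > 5 and FDR < 0.001 into
islands across at most one failing window. This is deliberately a
simplified caller implementing the stated thresholds, not a
re-implementation of an existing broad-domain caller's island
statistic. Input
adjustment is a ratio (fold); windows without input coverage are not
testable. Library sizes default to the track totals but can be supplied
explicitly when the tracks cover only part of a genome.

# Fiber-FISH quantitation

Measurements in μm convert to kb at 3.21 kb/μm. Summaries use the sample
(n − 1) standard deviation — a declared convention — and the
genome-wide total is mean kb × chromosome number. Note that rounding
matters at reporting precision: 690.5 kb × 19 = 13.12 Mb, whereas the
same total computed from unrounded per-signal values can land at
13.11 Mb; the package reports exact arithmetic on its inputs.

# Phylogeny

`pDistance()` computes amino-acid (or nucleotide) p-distances with
pairwise gap deletion by default (complete deletion available), with no
substitution-model correction — consistent with the linear-divergence
treatment used everywhere else. `njTree()` wraps neighbor-joining
(`ape::nj`); negative branch lengths are clamped to zero with the
deficit shifted to a sister branch. Neighbor joining is the
implemented tree method; minimum-evolution refinements are out of
scope. `bootstrapSupport()` resamples columns, counts original
bipartitions among replicate trees, writes supports as node labels and
collapses branches under the cutoff (default 50%) into polytomies by
explicit edge contraction. Correctness anchors: the 3-taxon closed form,
recovery of additive topologies up to 8 taxa, and invariance of supports
to taxon order.

# Pipeline and reproducibility

`runPipeline()` chains simulate → mine → TSD → date → target → ChIP →
report, writing each stage's outputs under stable names plus a summary
table. All randomness flows from one seed through fixed per-stage
derived seeds, so re-running with the same seed is byte-identical and
toggling one stage does not perturb another. Problem sizes in the test
suite and the acceptance script (chromosomes of 0.1–1.2 Mb, tens of
insertions, $10^5$ reads) were chosen as the smallest scales at which
each statistical check retains its power; they are package choices, and
the generator accepts larger configurations unchanged.

# Known limitations

* The dating estimator's downward bias is inherent to
  highest-pairwise-identity dating and grows for short or young
  elements; it is measured, not corrected.
* Mining assumes the anchor is not dominated by low-complexity sequence;
  highly repeated seeds are dropped rather than resolved.
* The island caller's Poisson model ignores overdispersion; on real
  ChIP data its FDR is nominal, not calibrated.
* `detectNested()` cannot see a nesting donor whose downstream remnant
  is shorter than the alignment threshold or is occupied by a younger
  tandem insertion; the truth table records such cases, the detector
  reports what the sequence supports.
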