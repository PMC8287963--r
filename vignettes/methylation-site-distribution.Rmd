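---
title: "Methylation-site distribution analysis with MethylSites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-site distribution analysis with MethylSites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylSites)
```

## The biological question

Type I restriction-modification systems (RMSs) deposit N6-methyladenine
(6mA) on both strands of a bipartite recognition sequence: two short
specified half-sites separated by a fixed-length unspecified spacer, such
as `CCA(N7)CTTC` or `AAC(N6)GTGC`. Because DNA methylation in or near a
promoter can change the binding of RNA polymerase or transcription
factors, a natural question for any methyltransferase is whether its
target sites are unusually common (enrichment) or unusually rare
(depletion) in promoter regions, compared with what the genome-wide site
density would predict. Orphan methyltransferases with short palindromic
targets (Dam, `GATC`; Dcm, `CCWGG`) methylate thousands of sites and are
established regulators; Type I systems, with seven specified bases,
methylate an order of magnitude fewer sites, and whether those few sites
do anything regulatory is exactly the kind of question this package's
statistics address.

MethylSites implements the full chain: degenerate motif scanning on
circular bacterial genomes, strand-aware promoter windows upstream of
transcription start sites (TSSs) or ORF starts, genic/intergenic
classification, and a circular-shift permutation test of promoter
overlap, together with the small wet-lab assay statistics that accompany
such studies (competitive index, transformation efficiency,
delta-delta-Ct).

## Motifs and duplex counting

A `BipartiteMotif` is two IUPAC half-sites plus a spacer length; plain
motifs are the special case with an empty second half. A *site* is one
physical duplex occurrence: a match of the written motif **or** of its
reverse complement on the forward strand, counted once. This matters for
non-palindromic motifs — per-strand counting would double every count and
could only ever produce even totals, whereas genome-wide counts of
bipartite Type I sites are routinely odd. Palindromic patterns (equal to
their own IUPAC reverse complement, e.g. `GATC`, `CCWGG`) match both
strands at the same position and are counted once with orientation `+`.

```{r}
m <- parseMotif("CCA(N7)CTTC")
m
motifString(reverseComplement(m))
```

The scanner encodes bases as 4-bit masks (A=1, C=2, G=4, T=8); a pattern
position matches when the bitwise AND of its IUPAC mask with the genome
base is non-zero. Genome `N` bases get an empty mask, so they can never
satisfy a specified position, while spacer positions are skipped and
therefore match anything, including `N` — gaps in an assembly cannot
fabricate sites but do not break spacers. Circular genomes are scanned
with the first span−1 bases appended, so origin-wrapping occurrences are
found; overlapping occurrences are all reported. The suite verifies the
scanner against two independent oracles (a per-position naive matcher and
a character-set matcher) on hundreds of random genomes, and checks the
rotation and mirror symmetries a circular scan must satisfy.

## Coordinates

Internally everything is 0-based half-open; 1-based conventions (GFF3,
TSS tables) are converted only at file boundaries, and the converters are
round-trip tested. A site's `start` is the leftmost base of the duplex
occurrence; wrapped circular sites have `start + span > L` and are
written to BED as two lines sharing a name.

## Promoter windows

The putative promoter of a TSS at 0-based position $p$ is the $w$-bp
window immediately upstream ($w = 50$ by default): $[p-w, p)$ for a `+`
TSS, $[p+1, p+1+w)$ for a `-` TSS. The TSS base itself is excluded —
"upstream of" is read strictly — and the choice is confined to one
helper, so the inclusive variant is a one-line change if a user wants it.
On circular genomes windows wrap; on linear ones they are truncated and
flagged. ORF promoters are built the same way from the annotated 5' end
of each ORF.

Overlap between a window and a site can be counted in two modes:
`span` (default; any base of the motif interval inside the window — the
inclusive reading of "the location of a methylation site") and `start`
(only the site's leftmost base counts). `start` counts are never larger
than `span` counts, and both are validated against an all-pairs
brute-force oracle.

## The analytic expectation

Under uniform independent bases, a motif with $k$ specified positions
starts at a given position with probability $4^{-k}$ in one orientation,
so a $w$-bp window contains a motif start with probability approximately

$$\Pr(\text{window hit}) \approx w \cdot 4^{-k},$$

capped at 1. For $k = 7$, $w = 50$ this is $50/16384 \approx 0.31\%$ —
the baseline rarity of bipartite Type I sites in promoters.

```{r}
100 * expectedPromoterFraction(k = 7, w = 50)  # percent
```

Note this is a *single-orientation* start count. A duplex scan of a
non-palindromic motif sees both orientations and roughly doubles the
rate; the Monte-Carlo check of this formula in the test suite therefore
uses a palindromic motif (`CCA(N1)TGG`, 6 specified bases), for which the
duplex count and the single-orientation count coincide.

## The rotation null

To test enrichment or depletion, `runPermutation()` compares the observed
overlap statistic with its distribution under rigid circular shifts: each
replicate draws one offset $\delta$ uniform on $\{1, \dots, L\}$, adds it
to **all** TSS positions modulo $L$, rebuilds the windows and recounts.
The shift preserves the complete spatial structure of both point patterns
(TSS clustering, site clustering, chromosomal domains) and randomizes
only their relative phase, which is precisely the quantity under test.
The default statistic is the number of windows containing at least one
site; the pair count is available as an alternative. Both are computed by
a counter that reduces one replicate to two `findInterval()` lookups on
the sorted site starts per distinct span, so $B = 10{,}000$ replicates on
genome-scale inputs take seconds; the suite checks the fast counter
against explicit shift-and-recount.

P-values are one-sided empirical tail probabilities with the add-one
convention $p = (k+1)/(B+1)$, never zero; the raw tie-inclusive counts
(`kLe`, replicates with null $\le$ observed; `kGe`) are kept in the
result so the plain replicate-counting convention is recoverable.
Depletion (the "equal or fewer" tail) is the headline direction; the
enrichment tail is always reported too. With `exhaustive = TRUE` all $L$
rotations are enumerated and the P-values are exact fractions. Bonferroni
correction multiplies the depletion P by the family size $m$, defaulting
in the pipeline to (number of motifs) × (number of TSS sources); the
family definition is a documented choice, not asserted as unique, and is
overridable.

## The synthetic generator

`syntheticScenario()` describes a dataset with known truth: an i.i.d.
random genome of configurable length and GC, `nSites` non-overlapping
planted motif occurrences, a non-overlapping ORF annotation, and a TSS
set drawn uniformly — except that with probability `avoidProb` a draw
whose upstream window would overlap a site is rejected and redrawn.
`avoidProb = 0` makes TSS placement independent of sites (the exact
rotation null); values near 1 plant depletion of known strength.
Rejection sampling, rather than post-hoc filtering, keeps the marginal
TSS distribution near-uniform, so the null machinery remains
approximately valid under the alternative.

Planting scrubs the background first: chance occurrences are removed by
resampling one specified-position base per off-target occurrence (never
inside a planted footprint) until a scan returns exactly the planted set,
within a bounded number of rounds. Site positions for the large
calibration and power studies are drawn by a positions-only gap-insertion
construction (`randomSites()`): the permutation test consumes positions,
not sequence, and the sequence-level plant → scan → recover round trip is
exercised separately, including at megabase scale.

What the generator deliberately does **not** emulate: codon structure,
GC skew, repeats, operon organization, or any correlation between ORFs
and TSSs. Passing calibration on this null therefore shows the test is
correct *given* exchangeability under rotation; on a real genome, large
scale compositional structure is exactly what the rigid shift preserves,
which is why the rotation null (and not i.i.d. site resampling) is the
right comparison.

## Calibration and power, at the scale we run them

The acceptance suite runs, with fixed seeds:

* **Calibration** — 200 independent null scenarios (100 kb, 300 sites of
  span 14, 500 TSSs, `avoidProb = 0`, $B = 1000$): the depletion P-values
  must pass a Kolmogorov–Smirnov uniformity test at $\alpha = 0.01$ and
  the empirical type-I rate at 0.05 must fall inside its binomial 95%
  interval.
* **Power** — 100 scenarios with `avoidProb = 0.9` at the same scale:
  depletion must be detected ($p < 0.05$) in at least 80% of runs.
* **Exactness** — on a 20-base toy genome the sampled P converges to the
  exhaustive-enumeration fraction within $1/(B+1)$ plus three Monte-Carlo
  standard errors.

These problem sizes are the package's chosen test scale: large enough
that the discrete null has resolution, small enough that the whole suite
runs in a couple of minutes.

## Assay statistics

* `competitiveIndex()`: CI = (output wt / output mutant) / (input wt /
  input mutant); label-swap inversion ($\mathrm{CI} \to 1/\mathrm{CI}$)
  holds exactly. Zero outputs are censored at the detection limit (one
  CFU by default) and flagged, not dropped, so every animal stays in the
  group test.
* `wilcoxonSignedRankVsZero()`: two-sided one-sample signed-rank test on
  log CI. Zeros are dropped; for $n \le 25$ the exact null distribution
  of the rank sum is computed by convolution over sign flips (valid with
  tied midranks, on a half-integer grid), above that a tie-corrected
  normal approximation is used. The exact branch is verified against full
  $2^n$ enumeration for all $n \le 10$ and against `wilcox.test` where
  the latter supports exact computation.
* `transformationEfficiency()`: (cfu/ml selective / cfu/ml non-selective)
  per ng of plasmid DNA, with log10 values for t-tests.
* `ddctFoldChange()`: $2^{-\Delta\Delta C_t}$ against a reference gene
  and control condition; invariant to a constant added to all four Ct
  values.

## A worked example

```{r}
sc <- syntheticScenario(L = 30000L, nSites = 60L, nOrfs = 20L,
                        nTss = 150L, avoidProb = 0.9, seed = 42L)
files <- simulateScenario(sc, file.path(tempdir(), "demo"))
genome <- readFasta(files$paths$fasta)[[1]]
sites <- scanGenome(genome, sc@motif)
nrow(sites)
tss <- readTssTable(files$paths$tss, genomeId = "synthetic")
res <- runPermutation(sites, tss, L = genomeLength(genome),
                      width = 50, B = 2000, seed = 7L)
res
```

With `avoidProb = 0.9` the observed window-hit count falls far below the
null mean and the depletion P-value is small; rerunning with
`avoidProb = 0` gives a P-value that is uniform across seeds.

## Numerical choices and degenerate inputs

* Seeds: every stochastic routine takes an explicit integer seed and
  restores the caller's RNG state; the pipeline expands one global seed
  into per-(motif × TSS-set) seeds by a single `sample.int()` draw.
* Ties: `kLe + kGe >= B` always (ties fall in both tails), hence
  $p_{\mathrm{depl}} + p_{\mathrm{enr}} \ge 1 + 1/(B+1)$.
* Empty inputs: an empty TSS set warns and returns observed = 0; zero
  sites give an all-tie null with depletion P = 1; a degenerate all-zero
  signed-rank sample returns P = 1 with a flag.
* A genome with no annotation still runs the scan and permutation stages;
  context columns are NA.
* Windows wider than the genome are refused; linear-genome windows
  truncate and flag instead.

## Limitations

* No mismatch-tolerant or probabilistic (PWM) matching: recognition
  motifs are treated as exact degenerate patterns, which is how Type I
  specificities are defined.
* The null is pure rotation; GC-matched or gap-aware shuffles are out of
  scope by design.
* Reproducing published genome-wide site counts requires the user to
  supply the corresponding assemblies; results on one assembly version
  may differ by a handful of sites from counts derived from
  modification-calling pipelines (predicted motif occurrences versus
  detected modified sites — published figures for the same strain differ
  the same way, e.g. 754 predicted vs 747 detected), and chromosome-only
  versus chromosome-plus-plasmid counting is exposed as an explicit mode
  because published totals rarely state it.
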