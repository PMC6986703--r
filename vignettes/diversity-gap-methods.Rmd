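---
title: "Diversity-Gap marker discovery: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-Gap marker discovery: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeDivGap)
```

## The problem and the statistic

Closely related congeners with near-identical plastomes are hard to
separate with universal barcodes, and the plastome regions that *do*
differ between species are often heteroplasmic — multiple sequence
variants coexist among the many plastid copies in a cell — which makes
PCR/Sanger sequencing of those regions unreliable. A useful barcode
region must therefore combine **high interspecific divergence** with
**low intraspecific (heteroplasmic) diversity**.

The package scores sliding windows by the Diversity Gap

$$G(w) = \pi_\mathrm{inter}(w) - \max_s \pi_{\mathrm{intra},s}(w),$$

with both diversities defined as average pairwise differences per site
(Nei–Li):

* $\pi_\mathrm{inter}$: over gap-free, `N`-free alignment columns of the
  window, the mean per-site mismatch fraction over all pairs of genome
  rows. Columns touched by a gap or an ambiguity code are excluded
  (the conservative behaviour of classical polymorphism software;
  ambiguity codes collapse to `N` on input).
* $\pi_{\mathrm{intra},s}$: from the read pileup of species $s$ on its
  own genome. At a column with coverage $c$ (bases plus deletions) and
  base counts $c_b$, the site heterozygosity is the fraction of
  mismatching unordered read pairs,
  $h = \sum_{b<b'} c_b c_{b'} / \binom{c}{2}$; $\pi_{\mathrm{intra},s}$
  is the mean of $h$ over qualifying sites. This estimates
  within-sample heteroplasmic diversity **plus sequencing error**; no
  error correction is attempted (see *Limitations*). Read insertions
  relative to the reference are tallied but never enter $\pi$.

Aggregating intraspecific diversity with `max` is the conservative
choice: a window is only as good as its worst species. `mean` is
available via the `aggregate` argument; with short allele-frequency
spectra the two rarely reorder the top windows, and `max` cannot
overrate a window that is clean in two species but heteroplasmic in the
third.

## Window screening and ranking

`rankWindows()` slides a `windowLen = 200` bp window in `step = 50` bp
increments (alignment columns). Published amplicons in this problem
domain are a few hundred bp, so 200 bp windows with 20 bp flanks
approximate an amplifiable unit; both are tunable. Two screens mirror
practical sequencing failure modes:

* **Homopolymer screen** (`homopolymerMax = 8`): a single-base run of
  ≥ 8 bp in any row, inside the window or its flanks, disqualifies the
  window. Polynucleotide stretches vary in length within species and
  abort Sanger reads; the threshold mirrors the mononucleotide SSR
  threshold, since such runs are exactly the mononucleotide
  microsatellites.
* **Flank conservation** (`flankLen = 20`, `flankMaxPi = 0`): both
  flanks must be gap-free with $\pi_\mathrm{inter}$ at or below the
  cutoff, so primers land on conserved sequence. Flank $\pi$ is
  computed without a minimum-site requirement (the flank is only 20
  columns).

Windows with defined statistics and $G > 0$ are sorted by $G$
(descending; ties broken by smaller start), overlapping candidates are
merged keeping the higher-$G$ window, and ranks run from 1.

Estimation floors: sites qualify for $\pi_\mathrm{intra}$ at coverage
≥ `minCov = 10` with deletion fraction ≤ 0.5, and a window needs
≥ `minSites = 20` usable/qualifying sites for either $\pi$ to be
defined — below that the window is excluded rather than estimated
noisily. Both are configurable.

## Read mapping

The pileup mapper places each read (either strand) by k-mer seeding
(`seedLength = 15`), scores the ungapped placement, and falls back to a
banded gapped alignment around the seed when the ungapped identity
fails `minIdentity = 0.9`. Reads below `minIdentity` over their aligned
span are discarded. Circular references are handled by extending the
sequence across the origin and reducing positions modulo the genome
length. Mapping qualities and base qualities are not modelled; FASTQ
qualities are parsed and ignored. Pre-mapped SAM text is accepted as an
alternative pileup source (`pileupFromSam`, via Rsamtools), honouring
M/=/X/I/D/S CIGAR operations, and agrees with the internal mapper on
clean fixtures — a two-path check in the test suite.

## Allele profiling

`extractTargetFragment()` cuts a `fragmentLen = 600` bp fragment with
the target region centred (left pad $\lfloor(600 - |t|)/2\rfloor$),
wrapping through the origin of circular genomes. `recruitReads()`
replaces a BLAST e-value cutoff with an explicit, database-free
criterion: best local alignment (either strand) of at least
`minHitLen = 50` columns at identity ≥ `minIdentity = 0.8` — sized so a
250 bp read with up to ~20% divergence is still recruited. A
shared-k-mer screen (k = 11, every read offset) rejects unrelated reads
before alignment; a read passing the identity criterion without sharing
any 11-mer with the fragment is not meaningfully possible.

`tabulateAlleles()` aligns recruited reads to the fragment and keeps
only reads **fully spanning** the target window; each contributes one
allele string (aligned characters over the target columns, `-` for
deletions, insertions spliced after the column they follow). The total
mapped count is fixed *before* any `minCount` filter, so reported
shares always refer to all spanning reads. Published allele tables of
this kind list rows with count ≥ 2 whose sums fall short of the stated
totals; the generator models the remainder as singleton alleles, and
`minCount` exposes the same filtering. Note that two display rows of a
gapped allele table can be the same ungapped sequence (gap placement in
a tandem repeat is not unique); profiling merges them, which changes no
dominant share.

## Diagnostic-indel rules

`deriveRules()` star-aligns the per-species dominant alleles (centre =
shortest sequence) and turns every maximal column range whose
gap/non-gap pattern differs between species into a diagnostic region
with per-species presence/absence motifs. Pairwise alignments use
match +1 / mismatch −3 / gap open 4 / gap extend 0.5: the strong
mismatch penalty makes two same-length alleles align via their true
double-indel structure instead of a run of mismatches, and gap open >
extend keeps a 5–6 bp insertion a single event. Gap runs are
right-normalised (shifted as far right as score-equivalence allows) so
indel placement inside tandem repeats is deterministic; an insertion
recovered inside a repeat is reported at the right-most equivalent
junction, which may be a rotation of the motif that was inserted.
Regions narrower than 3 bp are ignored as diagnostics — single-base
indels also arise within species (e.g. one published *A. chinensis*
minor allele), so keying identity on them would misclassify.

`classifyQuery()` aligns a query to each species' dominant allele and
checks each region's polarity: the motif must be present (no gap across
the region) where the species carries it and absent (no comparable
insertion at the junction) where it does not. Substitutions never
decide identity; they accumulate into a background-divergence check
outside the regions, with default ceiling 0.15. The ceiling is sized
from the published amplicon variants themselves: a field sample with
three substitutions over the ~27 bp tabulated window (divergence 0.11)
must still be identified, so 0.1 would be too tight at window scale.
When no species matches every region, species whose own motifs are all
present in the query are reconsidered; a query carrying the insertions
of two species is therefore reported `"ambiguous"` — a first-class
outcome, since field samples genuinely present foreign patterns — and a
query matching nothing is `"unclassified"` rather than forced to a
nearest label.

## Comparative statistics

* **SSRs**: maximal perfect tandem runs, thresholds 8/4/4/3/3/3 units
  for motif lengths 1–6; one mismatch terminates a run (compound SSRs
  appear as adjacent hits); motifs are canonicalised to their least
  rotation and periodic motifs are reported at their smallest period
  only. Partial trailing units are not counted.
* **Long repeats**: exact forward and palindromic (reverse-complement)
  maximal repeats ≥ 30 bp via k-mer anchoring; overlapping-copy tandem
  hits sharing a merged span collapse to the smallest-offset pair.
  Approximate (90%-similarity) and reverse/complement repeat classes
  are out of scope; in practice plastome repeat surveys find almost
  exclusively forward/palindromic hits.
* **Variants**: a SNP site is a gap-free, `N`-free column with ≥ 2
  distinct bases; an indel event is one maximal run of gap columns
  sharing a single gap/non-gap row pattern (a 5-column gap is one 5 bp
  event, matching how indel lengths are reported in plastome
  comparisons). Whether classical tools exclude sites adjacent to
  indels is version-dependent; this package's convention is exactly the
  above, so counts on real alignments may differ slightly from theirs.
* **Codon usage**: RSCU$(c) = $ count$(c) \cdot k / \sum_{c' \in
  \mathrm{syn}(c)}$ count$(c')$, amino-acid grouping per the
  bacterial/plastid table (same codon→amino-acid map as the standard
  table), stop codons as their own group, undefined RSCU reported as
  missing.

## The synthetic-data generator

`simulateGenomeTrio()` draws a uniform-random circular ancestor and
derives three species:

* **Background divergence**: each species receives
  Poisson($\mu L / 2$) substitutions, so each species *pair* diverges
  at $\approx \mu$ per site — $\mu$ is specified as a pairwise rate
  (default 0.005, the scale of plastome divergence between close
  congeners).
* **Implants**: each implant window receives its configured pairwise
  divergence exactly (count = divergence × window length / 2 per
  species, placed in the window core), plus species-specific motif
  insertions — by default a 5 bp tail-type and a 6 bp head-type
  insertion near the window centre, the shape of the cz11 diagnostic
  indels. Background substitutions are kept out of a 60 bp pad around
  implants so implanted flanks stay conserved, mirroring a marker
  worth finding.
* **Decoys**: homopolymer runs written into all species (flagged, never
  ranked).

The true multiple alignment is assembled from the edit log (no aligner
in the loop), and every edit is in the truth log.

`simulateHeteroplasmicReads()` draws single-end reads uniformly along
the circular genome, picks each read's template from an allele pool by
frequency, applies i.i.d. substitution errors at ε, and logs each
read's source allele, start and strand. Single-end is deliberate: no
implemented statistic uses pairing. The error model is
substitution-only; with a single allele the expected read-pair
heterozygosity is $2\varepsilon(1-\varepsilon) + 2\varepsilon^2/3$,
which the test suite verifies by simulation (ε = 0.01). Indel
sequencing errors and coverage/GC bias are not modelled, so passing
tests bound behaviour under clean Illumina-like data, not under
platform-specific artefacts.

Default desk scale is deliberately small (3–5 kb genomes, 15–40×
depth, 20-seed batches), chosen so the full pipeline and the
acceptance script run in minutes on one core while leaving every
statistic's sampling noise well inside the tested tolerances; the
study-scale configuration (~150 kb, 250 bp reads) differs only in
parameters.

`makeCz11Fixture()` embeds the published cz11 allele strings in a
fixed random 600 bp flank context, emits error-free spanning reads with
exactly the published per-allele counts, and pads each species with
distinct singleton variants so totals reach 445/620/762. Profiling the
fixture reproduces the published dominant shares (80.00%, 94.84%,
55.12%/40.55%) exactly, which is the package's primary end-to-end
acceptance check.

## Known limitations

* $\pi_\mathrm{intra}$ absorbs sequencing error; at low true
  heteroplasmy the estimate is error-dominated, which biases $G$
  downward uniformly but can reorder windows only through coverage
  differences.
* The read mapper is a deterministic best-placement mapper without
  mapping qualities; reads from exact repeats (e.g. the two IR copies)
  pile on the first-best copy.
* `deriveRules()` is designed for allele-scale sequences (tens to a few
  hundred bp); it is not a general MSA engine, and queries to
  `classifyQuery()` are expected at amplicon/allele scale (queries
  shorter than half the longest rule allele are rejected).
* Exact-match repeat finding understates repeat counts relative to
  90%-similarity surveys; SSR and variant conventions are documented
  above and may differ from specific legacy tools at boundary cases.
* Accession-scale validation (genome lengths, GC, SSR/indel/SNP totals
  of the three deposited plastomes) requires the GenBank records to be
  supplied locally; the corresponding acceptance test reports the
  missing inputs when they are absent.
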