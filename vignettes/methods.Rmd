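---
title: "Methods: binding-site annotation, TGA-repeat scanning, super-enhancer calling and cross-species synteny"
author: "ccsRegulome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ccsRegulome` packages the regulatory-genomics analyses used to characterise
where a fusion transcription factor binds the genome and what that binding
does to transcription, in the setting of clear cell sarcoma (CCS) driven by
the EWSR1::ATF1 (EA1) fusion oncoprotein. The pipeline covers six stages:

1. genomic-interval handling and binding-site annotation against gene models;
2. a gap-tolerant trinucleotide (TGA/TCA) repeat-tract scanner and
   fixed-motif classification of binding-site sequences;
3. ROSE-style super-enhancer (SE) calling from H3K27ac peaks and coverage;
4. chain-based liftover and reciprocal cross-species SE synteny;
5. integration of binding sites and chromatin loops with
   differential-expression (DE) results;
6. seeded synthetic-data generators that emulate every input with
   machine-readable ground truth, so each stage is testable without any
   sequencing download.

Read alignment, peak calling, de novo motif discovery, DE model fitting and
enrichment analysis are out of scope: the package consumes their standard
outputs (BED, bedGraph, GTF, chain, BEDPE, TSV).

# Coordinate conventions

All intervals are BED-style: 0-based, half-open `[start, end)`. GTF input
(1-based, closed) is converted on read. Abutting intervals never overlap;
overlap means at least one shared base on the same chromosome, strand-blind
(peak sets carry no strand). Using a single internal convention removes the
classic off-by-one drift between formats; the conversion sites are exactly
two (GTF read, GRanges construction for the overlap engine).

# Binding-site annotation

A peak is classified `promoter` when it overlaps the closed window
`[TSS - h, TSS + h]` of any gene, with `h = 3000` bp by default (the +/-3 kb
convention used by ChIPseeker-style annotators); otherwise `intragenic` when
it overlaps any gene body; otherwise `intergenic`. Promoter takes precedence,
which makes the three categories a partition — a property the tests assert on
every generated peak set. Category membership is decided by any-overlap, not
by midpoint position: a wide peak touching the edge of a promoter window is
promoter-associated. Distances to the TSS are measured from the peak
midpoint (left-biased for even widths), signed in gene orientation with
upstream negative; nearest-gene ties are broken lexicographically by gene id
so results are deterministic. GREAT-style assignment reports up to two genes
per peak within 500 kb.

# The TGA/TCA repeat-tract scanner

The scanner is the package's bespoke algorithm. It slides a 3 bp window with
a 1 bp step across a sequence and matches the pattern set {TGA, TCA} (the
two patterns are reverse complements, and can never overlap each other, so
gaps between matches are well defined). Matches accumulate into a tract
while each gap — the start of the next match minus the end of the previous —
is at most the gap tolerance; a larger gap closes the tract and the scan
re-seeds from the match that broke the chain, which makes tracts maximal and
non-overlapping. A tract is reported when it contains at least `threshold`
matches ("4 or more" 3-mers by default). `N` never matches.

Two gap-tolerance values are in published use for this statistic: 5 bp and
2 bp. Both are exposed through `scanner_config()`; the default is 5. On
uniform random sequence the two settings almost always agree (chance tracts
are rare), and tract counts are empirically monotone: non-increasing in the
threshold and non-decreasing in the gap tolerance. Strictly, increasing the
gap tolerance could merge two qualifying tracts into one; with random
background the configurations where that happens are vanishingly rare, which
is why the monotonicity property is asserted over seeded random sequences
rather than claimed universally.

Because the pattern set is closed under reverse complement, the scanner is
reverse-complement invariant: tract counts and unit counts are identical on
a sequence and its reverse complement, with mirrored spans. The test suite
verifies the scanner against an independent brute-force oracle (explicit
window loop plus greedy chaining) on 10,000 seeded random 200-mers.

Motif classification runs on the central 100 bp of each peak (repeats and
motifs concentrate at peak centres; the window is configurable, left-biased
by 1 bp when parity forces a choice, clipped to short peaks with a warning).
Motif matching is double-stranded with palindromes counted once. The
exclusive motif partition reports the canonical ATF/CREB 8-mer (TGACGTCA)
with precedence over the flexible-core variant (TGANNTCA, which the
canonical motif also matches), then the AP1 7-mer (TGAGTCA), then `none`.

# Super-enhancer calling

H3K27ac peaks within 12.5 kb (inclusive) are stitched into candidate
regions; a region's signal is total ChIP coverage minus total input coverage
over its span (depth x width summed over bedGraph steps), floored at zero —
the subtraction convention of ROSE, chosen over a ratio because the
published method normalises "by the input" without further specification.
Regions are ranked ascending by net signal, rank and signal are scaled to
[0, 1], and the cutoff is placed at the point of the ranked curve lying
furthest below the diagonal — the point where the tangent of the
(piecewise-linear) curve has slope 1, found by an exhaustive scan with ties
resolved toward fewer supers. Regions with signal strictly above the cutoff
signal are super-enhancers. When every region has the same signal the curve
is degenerate and nothing is called (with a warning).

A property worth knowing: on a background whose top order-statistic spacings
are heavy (e.g. exponential background), the slope-1 point lands a few ranks
inside the background tail, so a handful of the strongest background regions
are called super along with all truly high-signal regions. The planted
simulation in the tests therefore asserts full recall of the planted supers
(and cutoff equality with the exhaustive scan) rather than zero false
positives; with 500 exponential-background regions and 20 planted supers at
50 +/- 5, recall is 100% across seeds while 2-12 background regions ride
above the cutoff. The super set is invariant to positive rescaling of all
signals, and stitching is idempotent.

An optional TSS-exclusion filter removes peaks falling fully inside promoter
windows before stitching, for intergenic-SE analyses; it is off by default.

# Liftover and SE synteny

Chain files are parsed with full block bookkeeping (header spans validated
against block sums). An interval is lifted by mapping every base inside an
aligned block through the block offset, strand-aware (minus-strand query
coordinates are flipped against the chromosome length, per the chain
specification), applying chains in descending score order so each base is
mapped by the best chain covering it. The mapped interval is the hull of
mapped bases on the majority target strand; the interval is unmapped — a
value, not an error — when the mapped-base fraction falls below `min_match`
(default 0.95, the reference tool's default) or the mapped bases split
across target chromosomes.

SE synteny is computed in both directions: species-A SEs lifted onto B SEs
and vice versa, overlap meaning at least one shared base. Matching is
many-to-many, so the two species' matched-SE counts may differ; pairs
connected in both directions are flagged reciprocal, and reciprocity rather
than single-direction overlap is the headline synteny count. For each
reciprocal pair, the nearest gene per species (by midpoint-to-TSS distance)
and its signed distance are tabulated; when the two nearest genes are listed
homologs, the pair is scored for whether the SE sits on the same side of the
gene in both species. Non-homologous nearest genes are flagged and excluded
from orientation tallies.

# DE integration

The three expression datasets carry different DEG rules, applied
per dataset: the two tumor-versus-muscle contrasts (mouse and human CCS) use
|log2FC| > 1, the cell-line knockdown contrast uses any fold change
(log2FC > 0 or < 0), all with adjusted p < 0.05 and missing adjusted p
treated as non-significant. The knockdown contrast is coded control versus
knockdown, so positive log2FC means fusion-activated; a `flip_sign` flag
covers tables coded the other way. Mouse ids are translated into the shared
namespace through a homolog map before set operations; multi-homolog genes
resolve deterministically to the first mapping, with a message. Alongside
the three-way intersection, at-least-two and exactly-two tallies are both
reported, since "shared in two datasets" is used in both senses in the
field.

Binding/expression integration reports: the fraction of a DEG set with at
least one peak in its promoter window; mean peak score by expression class
of the bound gene (log2FC above 1, between, below -1) with pairwise Welch
t-tests (the unequal-variance form is the robust default wherever an
"unpaired t-test" is called for); and Tukey HSD comparisons (via
`stats::aov` + `stats::TukeyHSD`) between promoter-associated, distal and
SE-associated site classes. SE-associated means inside the SE span. A loop
connects an SE to a gene when one anchor overlaps the SE span and the other
overlaps the gene's promoter window, in either anchor order; looped genes
with |log2FC| beyond 2 are tallied.

# The synthetic-data generators

Every generator is a pure function of the configuration, including the seed:
identical configuration gives byte-identical files. Defaults are the study
conditions the pipeline is designed around:

* 2 chromosomes x 3 Mb of uniform random sequence, 150 non-overlapping genes
  (8-20 kb, 10-30 kb gaps, random strands);
* 1,000 binding sites planted at category proportions 34.7 / 36.5 / 28.8 %
  (promoter / intragenic / intergenic) — placement is constructive, so the
  planted label is provably the annotation outcome;
* motif classes planted at 6 / 34 / 13 % (canonical / variant / AP1) and
  TGA/TCA tracts of 4-12 units at 30% prevalence. The class rates mirror the
  reported motif-class partition of binding sites (1267, 7139 and 2735 of
  21,237); the repeat prevalence is not printed numerically anywhere, and
  30% was chosen once as a realistic distal-enriched prevalence. Planted
  windows overwrite genome bases (never insert), keeping all coordinates
  stable, and each planted 100 bp window is rejection-sampled until the
  classifiers recover exactly the planted state, so categorical ground truth
  is exact by construction;
* 500 background enhancer regions (net signal ~ Exponential(mean 1)) plus 20
  planted supers (Normal(50, 5)) on a dedicated coverage chromosome, gaps
  above the stitch distance, ChIP depth set to input + signal/width so
  scoring recovers each planted signal exactly; one binding site planted in
  every super;
* a second species derived by cutting the genome into 20-60 kb blocks with
  8% deletions, 8% insertions and 10% inversions, exact chain files in both
  directions (one chain per conserved block; inverted blocks map on the
  minus strand), homologs for genes fully inside conserved blocks, 50
  planted syntenic SE pairs and 10 unmappable decoy SEs per species;
* three DE tables over a 2,000-gene shared universe with planted sets:
  432 shared-up and 194 shared-down across all three datasets (honoring each
  dataset's own cutoff rule), 120/80 exactly-two genes, 100/80
  single-dataset genes per dataset; null genes draw adjusted p >= 0.05 so
  planted counts are exact (an idealisation — real null genes occasionally
  reach significance);
* 20 SE-looped genes (5 with knockdown log2FC > 2, 2 with < -2) plus 30
  decoy loops that connect no SE to a promoter.

What the generators do *not* emulate: read-level noise, GC or nucleosome
structure, correlated replicate structure, overdispersed DE statistics, or
multi-isoform gene models. Passing tests on this synthetic data demonstrate
the correctness of the interval arithmetic, scanning, calling, mapping and
set logic — not the biological error rates any of these stages would face on
real sequencing data.

Problem sizes in the test suite (10,000-sequence scanner oracle runs, 100
random interval instances up to 500 intervals, the full seed-7 study run
twice for byte-level determinism) were chosen so the whole suite exercises
every stage at meaningful scale while completing in a few minutes.

# Numerical and degenerate-input choices

* Stitch gap comparison is inclusive (`<= 12500`), so the boundary case
  merges; tests pin both sides of the boundary.
* The SE cutoff scan resolves ties toward fewer supers; all-equal signals
  yield zero supers with a warning.
* Welch t-tests on identical constant indicator vectors (e.g. both sets all
  contain tracts) are reported as t = 0, p = 1 rather than erroring.
* Groups or classes with fewer than two members are excluded from tests
  with a warning; empty DEG sets give `NA` fractions; empty SE sets are an
  error for overlap fractions (the quantity is undefined).
* Peaks on chromosomes absent from the annotation are intergenic with no
  nearest gene, and a warning.
* `sign(0)` counts as downstream agreement in orientation comparisons; SE
  midpoints exactly on a TSS are a measure-zero case in practice.

# Worked example

```{r example}
library(ccsRegulome)
study <- file.path(tempdir(), "study")
simulate_study(sim_config(seed = 7), study)
res <- run_study_pipeline(study, file.path(tempdir(), "results"))
res$category_fractions
sum(res$superenhancers$is_super)
res$degs$up$counts
```

The `scripts/acceptance.R` script in the source repository runs exactly this
pipeline plus two small planted layouts (promoter binding 44-of-100,
score-by-expression-class) and writes every headline quantity as JSON.
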