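---
title: "Identifying and validating triplex-forming lncRNAs with TriplexKit"
author: "TriplexKit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and validating triplex-forming lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TriplexKit)
```

## The scientific problem

Some long noncoding RNAs regulate chromatin by binding double-stranded DNA
directly: the RNA lies in the major groove of the duplex and forms
Hoogsteen or reverse-Hoogsteen hydrogen bonds with the purine-rich strand,
producing a DNA:DNA:RNA triplex. Establishing that a given lncRNA works
this way requires a chain of evidence: a sequencing-based screen that the
RNA is enriched in RNase-H-resistant RNA-DNA complexes (RNase H destroys
the RNA of Watson-Crick DNA-RNA heteroduplexes, so surviving RNA is
triplex-like); computational prediction of which region of the RNA (the
triplex-forming region, TFR) binds which genomic target sites (TTS);
quantitative qPCR statistics for the immunoprecipitation experiments; and
a biophysical signature, the biphasic thermal melting transition, in which
the Hoogsteen-bound third strand dissociates at a lower temperature than
the Watson-Crick duplex.

TriplexKit implements that entire computational chain as reusable,
seed-reproducible components, together with a synthetic-data module that
generates every input with known ground truth, so each stage can be
validated without any external download.

## The pairing code and the target-site search

A triplex motif is a set of allowed (third-strand base, duplex
purine-strand base) combinations. The package ships the two canonical
codes:

* antiparallel purine motif: G·G:C, A·A:T, T·A:T (third strand
  antiparallel to the purine strand);
* parallel pyrimidine motif: C·G:C, T/U·A:T (parallel orientation).

U and T are equivalent at comparison time only; stored sequences keep
their alphabet. IUPAC ambiguity codes are rejected rather than expanded so
that hit sets are deterministic.

`findTTS()` enumerates *gapless* (collinear) alignments between windows of
the query RNA/DNA and both strands of a duplex — Hoogsteen pairing is
positionally collinear, so no gaps or bulges are modelled. A window is a
hit when its length is at least `minLen` (default 12 nt) and its mismatch
fraction is at most `maxErrorRate` (default 0.2). Only *maximal* windows
are reported: extending a reported hit by one base on either side would
violate the error constraint or run off a sequence end. Overlapping hits
of the same motif and strand that overlap on both the RNA and DNA side
are collapsed to the highest-scoring one (score = matched positions),
with ties broken by leftmost DNA, then leftmost RNA coordinate. The
defaults (12 nt, 20% error, both motifs) sit in the mid-range of published
triplex-search conventions; the internal parameters of the tool that
inspired this stage are not public, so all of them are exposed.

Two consequences of these semantics are worth knowing when testing.
First, the tie-break rule makes the *merged* hit set orientation
dependent: reverse-complementing the duplex mirrors the raw maximal hit
set exactly (`merge = FALSE`), but merged output can keep the mirror-image
member of a tied pair. Second, "loosening never loses a hit" holds as
containment: every maximal hit at stricter settings lies inside some
maximal hit at looser settings, but its exact coordinates may grow.

The inner scan is implemented in C++ (per-diagonal prefix mismatch counts
with an exact suffix-minimum pruning rule), because the randomization null
below re-scans thousands of shuffled region sets.

```{r}
ol <- referenceOligos()
tfo <- subset(ol, name == "TFO2-23")$sequence
target <- subset(ol, name == "EPHA2_pyrimidine")$sequence
findTTS(tfo, target, tfoId = "TFR2-core")
```

The 23-nt third strand and the 25-nt duplex above are the constructs used
for the in vitro validation of the lncRNA this package grew out of; they
are packaged as plain-text fixtures. (The printed GC content of the
23-mer, 50.9%, does not match the printed sequence, whose computed GC is
13/23 = 56.5%; the package reports computed values. The two 25-nt target
strands are named here by computed composition — `EPHA2_purine` is the
GA-rich strand — because the source labels are internally inconsistent.)

## TFR discovery with a shuffle-based empirical null

`discoverTFRs()` asks: which part of an RNA hits *more target regions than
chance would allow*? Candidate TFR windows are the maximal runs of RNA
positions covered by at least one hit against the observed region set.
Each window's statistic is the number of regions containing a hit that
overlaps the window. Its null distribution comes from re-scoring against
`nRandomizations` (default 200) region sets shuffled by
`shuffleRegions()`: placement is uniform, mutually non-overlapping, and
chromosome-preserving — the stricter null when the original description
says only "shuffled in the genome". The empirical p-value uses the
plus-one estimator $(1 + \#\{null \ge obs\})/(1 + n)$, which is
conservative and can never return 0; its smallest attainable value is
$1/(n+1)$. Windows with $p < \alpha$ (default 0.05, raw — no
multiple-testing correction across windows, a documented caveat) are
merged into maximal TFR intervals. `overlapTTS()` intersects the genomic
hit intervals of several TFRs and counts shared loci (counting genomic
intervals, not per-gene entries, which is one of two readings of a
"shared target" count).

Two statistical properties are enforced by tests. *Calibration*: when the
observed regions are themselves drawn from the shuffle null, empirical
p-values must be approximately uniform. Because the estimator is discrete,
this comparison only works if the count statistic rarely ties between the
observed and null draws; the test therefore uses a GA-rich 40-nt query
against 200 regions of 200 nt on a 90-kb chromosome, where the hit-count
variance is large enough (about 19) that a Kolmogorov–Smirnov test against
the uniform has nothing arithmetic to object to. *Power*: an RNA with an
embedded 23-nt TFR whose matching target sites sit in all 10 of 10
regions on a 10-kb background genome is recovered at $\alpha = 0.05$ in at
least 95 of 100 seeds at 50 randomizations.

## The candidate screen

`poissonEnrichment()` computes, per peak, the fold enrichment
$\mathrm{observed}/\mathrm{expected}$ and the upper-tail probability
$P(X \ge \mathrm{observed})$ for $X \sim \mathrm{Poisson}(\lambda =
\mathrm{expected})$ — the tail is closed at the observed count, and
$-\log_{10} p$ is capped at 300 for numeric safety. `applyScreen()` runs
the high-stringency cascade on a per-lncRNA table: presence in both cell
lines, fold $> 10$ (strict), $-\log_{10} p > 20$ (strict), nuclear signal
$> 0$, every tissue signal $> 0$, coding probability below 0.364 (the
published human CPAT cutoff; the source pipeline states only "predicted
non-coding"), and no overlapping-gene conflict. The conflict flag encodes
a manual genome-browser inspection step (a candidate whose
triplex-associated regions lie entirely within an overlapping snoRNA gene
is excluded); the pipeline consumes it as an input column rather than
inferring it from annotation. Whether the fold and p cuts apply to the
best peak per lncRNA or to any peak is not specified upstream; this
implementation cuts on the best peak, via the `best_*` columns. Each
row's fate is a pure function of the row and the thresholds, so the
retained set is independent of row order; the attrition report attributes
each removed row to the first filter (in cascade order) that rejects it.

The genome-wide catalog counts that motivated the screen (989 and 1363
lncRNAs in two cell lines, 280 shared, 11 high-stringency candidates, 5
expressed) depend on external sequencing accessions and annotation
versions and are not reproducible at desk scale; the package covers the
self-contained arithmetic (the set intersection) with constructed
catalogs of those sizes.

## qPCR validation statistics

`ddctFold()` implements $2^{-\Delta\Delta Ct}$ with
$\Delta\Delta Ct = (Ct_{target} - Ct_{ref}) - (Ct_{target,ctrl} -
Ct_{ref,ctrl})$; the amplification efficiency is fixed at 2.0 per cycle
(no efficiency curve is fitted) but configurable. Replicates aggregate as
the arithmetic mean of $\Delta\Delta Ct$, i.e. the geometric mean of
folds, keeping averaging in the log domain. `percentInput()` converts
RIP/ChIP Cts to percent of input with the standard dilution adjustment
$100 \times 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}$ for an input
fraction $f$ (10% for cellular RIP, 5% for the in vitro assays); the
adjustment can be switched off since the upstream protocol does not state
whether input Cts were pre-adjusted. `rnasehRatio()` forms the ratio of
percent-input with/without RNase H — the quantity whose value near 1
separates triplex-held RNA from heteroduplex-like signal. Group
significance testing (the ANOVAs and t tests behind figure asterisks) is
deliberately out of scope.

## The biphasic melting model

Normalized ellipticity against temperature is modelled as a sum of two
logistic transitions

$$f(x) = \frac{a}{1 + e^{-(x - x_0)/b}} + \frac{c}{1 + e^{-(x - x_2)/d}},$$

with midpoints $x_0 < x_2$ reported as tm1 and tm2 and slopes $b, d$ in
degrees C. Tm is the midpoint *parameter*, not a derivative maximum,
matching how fitted values are usually quoted with standard errors; the
reported uncertainties are asymptotic standard errors from the fit
curvature. `fitMelting()` uses Levenberg–Marquardt from a deterministic
coarse grid (midpoints every 5 °C, pairs with $x_0 < x_2$; amplitudes from
the observed range; slopes starting at 3 °C), refining the best few starts
and returning the lowest-SSE converged fit with the transitions in
canonical order. Midpoints are constrained to within 10 °C of the measured
range and slopes to at most 30 °C: outside those bounds a sigmoid is
indistinguishable from a baseline, which invites degenerate fits.

`classifyTransition()` fits both models on the normalized signal (so the
call is invariant to affine transforms of the raw ellipticity) and calls
*biphasic* only when three conditions hold: the corrected information
criterion (AICc) improves by more than 10; the fitted midpoints are more
than 5 °C apart; and each transition carries at least 10% of the total
amplitude $a + c$. The first two guards are against over-fitting broad
single transitions — a genuinely hard case, since a real triplex can show
"a very broad second melting point". The third is needed because min–max
normalization of a noisy monophasic curve leaves a small positive plateau
offset at low temperature (the model has no baseline term), which a
near-zero-amplitude sigmoid pushed against the parameter bounds would
otherwise absorb, flipping the call. A numerically perfect monophasic fit
(SSE per point below $10^{-12}$) short-circuits to monophasic, because
information criteria are meaningless at zero residual — this also handles
the $x_0 = x_2$ degenerate case.

```{r}
mref <- meltingReference()
tm <- mref$tm_c[mref$construct == "EPHA2_CTGA_triplex"]
cv <- makeMeltingCurve(0.5, tm[1], 3, 0.5, tm[2], 3)
fitMelting(cv, "biphasic")
```

## The synthetic-data module

Every generator takes a seed and returns its ground truth; identical
calls are byte-identical.

* `makeGenome()` draws i.i.d. bases at a requested GC fraction. There is
  deliberately no dinucleotide or repeat structure: that is sufficient to
  test a pattern search, but it means passing tests say nothing about hit
  *rates* in real genomes, whose purine-run statistics differ. The
  shuffle-null stage inherits the same caveat — the upstream method gives
  no background model for "random" genomic sequence, and i.i.d. placement
  is this package's stand-in.
* `plantTTS()` writes duplex target sites whose purine strand
  Hoogsteen-matches a given TFO under the chosen motif. Third-strand
  bases with no purine partner under the code (cytosines, for the purine
  motif) are unavoidable mismatches: they are filled with pyrimidines and
  counted against the per-site mismatch budget, so a TFO with 2 C in 23 nt
  needs `mismatchRate >= 2/23`. Sites are placed non-overlapping on a
  uniformly chosen strand, and the purine-strand orientation is recorded
  so strand handling is testable.
* `makeLncRNA()` embeds a TFO in random background RNA and records the
  interval — the planted TFR for recovery tests.
* `makePeakTable()` draws Poisson background counts (and
  Poisson($\lambda \cdot$ fold) for planted enriched rows) with the
  background rate as the expected column.
* `makeCtTable()` builds replicated Ct tables in which the treated target
  Ct is lowered by $\log_2(\mathrm{fold})$ cycles, with homoscedastic
  Gaussian noise per measured Ct.
* `makeMeltingCurve()` evaluates the double-sigmoid model on a 5–95 °C
  grid read every 0.25 °C — a typical density for a 1 °C/min CD melt —
  with homoscedastic Gaussian noise. The read density matters: at this
  grid, noiseless refits recover midpoints to well under 0.1 °C and
  noise-0.02 refits to under 0.5 °C in ≥95% of seeds, which is the
  precision the validation tests assert.

Coordinates are held internally as 1-based closed `GRanges`/`IRanges`
(the Bioconductor convention) and converted at the file boundary: written
BED is standard 0-based half-open, and `parseGenomicSpan()` ingests
browser-style 1-based inclusive spans (`"chr1:16,478,543-16,478,567"` is
25 nt).

## The orchestrated run

`runPipeline()` chains simulate → screen → scan → enrich → qpcr →
melt-fit under one global seed. Per-stage child seeds are derived by a
fixed affine rule (`(seed * 97 + stageIndex) mod (2^31 - 1)`), so any
stage can be re-run standalone and reproduce its slice of a full run.
Unknown configuration keys are rejected before any stage executes. The
run directory receives FASTA/BED/TSV/CSV outputs, a JSON ground-truth
manifest, and a run manifest with the package version, seed, effective
configuration and md5 checksum of every output; two runs with the same
configuration have identical checksums. The default demo scale (10-kb
genome, 5 planted sites, 200-row peak table, 50 randomizations) completes
in well under a minute on one CPU. There is no shell executable: the
exported functions are the interface, and `scripts/acceptance.R` shows
the non-interactive usage pattern.

## Known limitations

* Gapless matching only; no bulged triplexes, no thermodynamic stability
  or pH-dependent C⁺·G:C protonation modelling.
* The i.i.d. background (genome generator and shuffle null) understates
  the purine-run clustering of real genomes; empirical p-values on real
  data should be interpreted against that caveat.
* No multiple-testing correction across TFR windows (raw α matches the
  upstream convention); users screening many RNAs should correct across
  RNAs themselves.
* The melting model has no baseline/drift term; strongly drifting raw
  ellipticity should be detrended before fitting.
* Coding potential, expression values and the overlapping-gene flag are
  consumed as input columns; the tools that produce them are not
  re-implemented.
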