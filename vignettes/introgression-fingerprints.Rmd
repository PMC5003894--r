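---
title: "Characterizing introgression lines from dominant marker fingerprints"
author: "introscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing introgression lines from dominant marker fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

Asymmetric somatic hybridization fuses protoplasts of a crop (recurrent)
parent with irradiated protoplasts of a donor species, so that only fragments
of the donor genome persist in the regenerated plants. The resulting
introgression lines (ILs) are characterized at the DNA level with dominant
molecular markers — SSR, AFLP and MSAP — scored as presence/absence of bands.
Bands of identical mobility under the same primer combination are treated as
the same locus ("co-migrating"). Three fixed profiles anchor the analysis:
the recurrent parent, the donor parent, and optionally a natural
allotetraploid reference carrying both genomes, which flags convergent
changes.

`introscan` implements the full desk-side analysis of such fingerprints:

1. **marker I/O** — a validated presence/absence container (`BandSet`, built
   on `SummarizedExperiment`) with long-format TSV import/export;
2. **origin classification** — each SSR/AFLP locus is placed in the 2×2
   parental presence table, giving the informative-locus denominators;
3. **genetic event calling** — per-IL introgression, loss, novel-band and
   reference-co-migrating counts with publication-style summaries;
4. **MSAP epigenotyping** — dual-digest (HpaII/MspI) methylation states and
   per-IL hyper-/hypomethylation frequencies;
5. **synthetic data** — a generator with ground truth, so every stage is
   testable without any external dataset.

## The genetic model

With recurrent parent $K$ and donor $G$, a locus is *shared* ($K{=}1,
G{=}1$), *recurrent-specific* ($1,0$), *donor-specific* ($0,1$) or *absent in
both parents* ($0,0$). The informative denominators are the counts of
donor-specific loci ($D_{don}$, introgression), recurrent-specific loci
($D_{rec}$, loss) and parent-absent loci co-migrating with the reference
($D_{ref}$). For IL $j$ with event count $k_{ij}$ in class $i$, the reported
aggregate over $N$ ILs is

$$\text{mean}_i = \frac{1}{N}\sum_j k_{ij}, \qquad
  \text{freq}_i = \frac{100 \sum_j k_{ij}}{N \cdot D_i}\ \%$$

with means and frequencies rounded to one decimal, halves away from zero
(R's banker's rounding would turn $231/12 = 19.25$ into 19.2; published
marker tables round it to 19.3). Frequencies are always computed from the
unrounded sums.

Two definitions were genuinely open and are resolved as follows:

* **Novel bands** are loci present in an IL but absent from *both* parents,
  regardless of reference status. Reference-co-migrating presences therefore
  appear in both the novel and the reference tallies; published tables list
  individual bands under both columns, so the overlap is deliberate and the
  two lists are not disjoint.
* **Novel-band denominator.** No denominator for novel bands exists a
  priori (any fragment could in principle appear). The default uses
  $D_{rec}$, which reproduces published aggregates exactly; it can be
  switched to $D_{ref}$ or any custom value (`novelN`).

A documented inconsistency: with the bundled per-IL counts the
reference-specific frequency computes to $100 \cdot 424/(12 \cdot 226) =
15.6\%$, while the source table prints 15.5%. The package implements the
formula and reports 15.6; the column's reproducible aggregate is its mean,
35.3. Similarly, two per-IL MSAP rows (a hyper frequency of 13.5 and a hypo
frequency of 3.5) are inconsistent with $100\cdot 39/290 = 13.4$ and
$100\cdot 10/290 = 3.4$ under any rounding of the printed counts; the
computed values are reported.

## The MSAP model

Each MSAP locus is scored in two lanes: EcoRI+HpaII (H) and EcoRI+MspI (M).
The band pattern maps to a state: **A** $(1,1)$ unmethylated (or methylation
confined to one strand), **B** $(1,0)$ hemi-methylated, **C** $(0,1)$ fully
methylated at the internal cytosine, **D** $(0,0)$ no band in either lane.
States are ordered $A < B < C$; an IL above the recurrent parent's state is a
hypermethylation event, below it a hypomethylation event.

State D is ambiguous — it can mean methylation of both cytosines beyond
either enzyme's tolerance *or* loss of the restriction site. The default
policy (`dPolicy = "uninformative"`) excludes any comparison involving D
from the event counts; `dPolicy = "top_level"` instead ranks D as the most
methylated level ($A<B<C<D$), as parts of the MSAP literature do. Both
policies are exhaustively tested against a hand-built 16-pair transition
table.

Events are counted over the *informative* MSAP loci: banded in the recurrent
parent (either lane) and absent from the donor in both lanes, so that a
change is attributable to the IL rather than to donor chromatin. Frequencies
use this count as denominator (overridable for replicating published
tables), and the total methylation change is the sum of the two *rounded*
overall frequencies — matching how such tables are totalled (12.4 + 4.8 =
17.2).

## The synthetic-data generator

`generateBandSet()` emulates the study design at the fingerprint level.
Parents are noise-free fixed profiles; only ILs draw stochastic events,
independently per (IL, locus):

* a donor-specific band is present with `pIntrogress` (default 0.075);
* a recurrent-specific band is lost with `pLoss` (0.051);
* novel bands arise as brand-new loci, Binomial(`nRecurrentSpecific`,
  `pNovel` = 0.014) per IL, so the expected count per IL is ≈ 5.3;
* a reference-specific band appears with `pReferencePresent` (0.155);
* an MSAP locus moves one methylation level up with `pHyper` (0.124) or
  down with `pHypo` (0.048), else keeps the parental state. A locus already
  at a boundary (parent C cannot gain, parent A cannot lose) stays
  unchanged; `msapTwoStep` optionally lets an upward move from A reach C.

The default locus counts (1117 shared, 376 recurrent-specific, 306
donor-specific, 226 reference-specific, 290 informative MSAP loci plus 111
parental-shared MSAP fragments, 12 ILs) are the observed structure of a
typical screen of this kind. Two values are not fixed by any published
structure and were chosen once as field-realistic: the recurrent parent's
MSAP state distribution, set to A/B/C = 0.50/0.30/0.20 (plant MSAP profiles
typically show a majority of unmethylated bands with sizable hemi- and
fully-methylated fractions), and the fraction of novel bands co-migrating
with the reference (default 0, keeping novel and reference events separable
in recovery tests).

What the generator deliberately does **not** model: linkage and segment
structure of introgressions (loci are independent), scoring noise and
replicate disagreement (input is treated as consolidated calls), size
co-migration artifacts (band identity is exact), and multi-generation
inheritance. Passing parameter-recovery tests therefore demonstrates that
the estimators are consistent for the generative model's rates — not that
real gels are free of those complications.

## Rate recovery

`recoverRates()` estimates each generating rate as events/exposure with
normal-approximation binomial confidence intervals clipped to $[0,1]$. The
genetic point estimates equal the pipeline's unrounded frequencies. Two
estimators are refined so that they are consistent for the generating rates:

* the novel rate excludes reference-co-migrating bands from the numerator
  (those presences are driven by `pReferencePresent`);
* the MSAP rates are per *opportunity*: a locus whose parental state is C
  cannot gain methylation, so the naive frequency over all informative loci
  underestimates `pHyper` by the factor $P(\text{parent} < C)$. The
  hypermethylation exposure counts only parental states A/B, and the
  hypomethylation exposure only B/C.

At the default scale, all six rates fall within three binomial standard
errors of their generating values in ≥ 99% of 200 seeds; the test suite runs
this experiment at a reduced size (200 loci per class, 100 reference loci)
to keep it in the seconds range.

## Worked example

```{r example}
toy <- system.file("extdata", "toy_matrix.tsv", package = "introscan")
x <- readBandMatrix(toy)
x

org <- classifyLoci(x)
originDenominators(org)[c("n_donor_specific", "n_recurrent_specific",
                          "n_reference_specific")]

summarizeGenetic(callEvents(x, org), org)
summarizeMsap(x)
```

And the bundled per-IL count fixtures reproduce the published aggregates:

```{r fixtures}
t2 <- read.delim(system.file("extdata", "table2_genetic_events.tsv",
                             package = "introscan"), row.names = 1)
summarizeGenetic(t2, denominators = list(donor = 306, recurrent = 376,
                                         reference = 226))

t3 <- read.delim(system.file("extdata", "table3_msap_events.tsv",
                             package = "introscan"), row.names = 1)
msapSummaryFromCounts(t3$n_hyper, t3$n_hypo, dMsap = 290,
                      sampleId = rownames(t3))

parentalAccountingFromTotals(nRecurrent = 1493, nDonor = 1423,
                             nShared = 1117)
```

## Numerical and degenerate-input choices

* All table values round half away from zero at one decimal; the rule lives
  in a single function (`roundHalfUp()`) used by every summary.
* Missing REFERENCE sample: reference-dependent categories are `NA` ("not
  assessable"), never silently zero; summaries warn.
* Zero denominators: frequencies are omitted with a warning, never divided.
* Strict import rejects incomplete loci, conflicting duplicates, non-binary
  presence and sub-100 bp size-labelled AFLP/MSAP bands; lenient import
  drops offending loci with a message. Named SSR markers are exempt from
  the size rule.
* Import is row-order independent: the container is canonically ordered
  (loci by id, samples by role), making write∘read an identity.

## Limitations

Band-level analysis cannot distinguish co-migrating non-homologous
fragments, place introgressed segments on a genetic map, or separate true
novel bands from reference-derived chromatin biologically; MSAP states are
locus-level restriction readouts, not bisulfite-resolution methylation
levels. These are analysis non-goals here, as they are in the underlying
experimental practice.
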