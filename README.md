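# introscan

Marker-fingerprint characterization of introgression lines (ILs) from
dominant molecular markers: SSR, AFLP and MSAP presence/absence band
matrices scored on two fusion parents, an optional allotetraploid reference,
and a panel of ILs. The package is for plant geneticists analyzing
asymmetric somatic hybrids (or any backcross-style introgression panel
genotyped with dominant markers) who need per-line tallies of alien-chromatin
introgression, parental band loss, novel bands and reference-co-migrating
bands, plus isoschizomer (HpaII/MspI) methylation-state profiling — with the
exact denominators and rounding conventions of published IL tables.

## The model

Each SSR/AFLP locus falls in one cell of the 2×2 parental presence table:
shared, recurrent-parent-specific, donor-specific, or absent in both
parents. The class sizes are the informative denominators *D*: donor-specific
loci for introgression calling, recurrent-specific for loss, parent-absent ∧
reference-co-migrating for reference bands. For event counts *k&#x2097;ⱼ* of class
*i* in IL *j*,

    mean_i = (1/N) Σ_j k_ij
    freq_i = 100 · Σ_j k_ij / (N · D_i)  %

reported at one decimal, halves rounded away from zero, frequencies always
computed from unrounded sums.

MSAP loci carry two presence channels per sample (EcoRI+HpaII "H",
EcoRI+MspI "M"); the pattern maps to a methylation state A=(1,1) < B=(1,0) <
C=(0,1), with D=(0,0) ambiguous (excluded as uninformative by default, or
ranked topmost with `dPolicy = "top_level"`). An IL state above/below the
recurrent parent's state at an informative locus is a hyper-/hypomethylation
event.

A seedable synthetic-fingerprint generator (`generateBandSet()`) emulates
this whole structure with per-locus Bernoulli events and returns ground
truth, and `recoverRates()` estimates the generating rates with binomial
confidence intervals.

## Worked example

```r
library(introscan)
toy <- system.file("extdata", "toy_matrix.tsv", package = "introscan")
x <- readBandMatrix(toy)
x
#> BandSet: 17 loci x 5 samples
#>   loci:    SSR=7, AFLP=6, MSAP=4
#>   samples: RECURRENT_PARENT=1, DONOR_PARENT=1, REFERENCE=1, IL=2

org <- classifyLoci(x)
summarizeGenetic(callEvents(x, org), org)
#> Genetic event summary over 2 ILs
#> (denominators: donor-specific = 3 | recurrent-specific = 4 | novel = 4 | reference-specific = 2 )
#>               n_introgressed n_lost n_novel n_reference
#> IL1                        1      1       1           0
#> IL11                       3      1       1           1
#> Average                  2.0    1.0     1.0         0.5
#> Frequency (%)           66.7   25.0    25.0        25.0

summarizeMsap(x)
#> MSAP methylation-change summary over 2 ILs (informative loci D = 3)
#>         n_hyper freq_hyper_pct n_hypo freq_hypo_pct
#> IL1           1           33.3      0           0.0
#> IL11          0            0.0      1          33.3
#> Average     0.5           16.7    0.5          16.7
#> Total methylation change: 33.4 %
```

Reading the genetic table: IL11 carries 3 donor-specific bands
(introgression), lost 1 recurrent-parent band, shows 1 band absent from both
parents (novel — here one that also co-migrates with the reference, so it
appears in the reference column too). The Average row is the per-IL mean;
the Frequency row divides each column's total by (number of ILs × that
column's informative-locus denominator). In the MSAP table, IL1 has one
locus shifted up in methylation level relative to the recurrent parent
(14.5% of informative loci would read 42/290 at publication scale; here 1/3).

`runReport(input, outPrefix)` runs the whole pipeline and writes the origins,
events, genetic-summary and MSAP-summary TSVs plus a plain-text report;
`inst/scripts/introscan.R` wraps it for shell use
(`Rscript introscan.R report matrix.tsv --out-prefix out`).

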