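# spliceRELI

Resampling-based enrichment of RNA-binding-protein (RBP) CLIP peaks around
differentially spliced cassette exons, with positional motif maps and a
Beta-posterior differential-splicing caller.

## The problem

Cell lineages are shaped not only by transcription but by alternative
splicing programs, and those programs are steered by RBPs binding in and
around the regulated exons (the classic example being Quaking/QKI, whose
ACUAA-directed binding upstream of or within an exon promotes skipping,
while binding in the downstream intron promotes inclusion). Given

* junction read counts (two inclusion junctions and one skipping junction)
  for cassette-exon events in two conditions,
* a library of CLIP peak datasets (BED intervals, one file per dataset), and
* optionally a genome FASTA,

the package answers: **which exons change** between the conditions, **which
RBP datasets bind them more often than expected by chance**, **where**
(upstream intron, exon body, downstream intron), and whether a short binding
motif shows position-dependent enrichment.

## The statistics

**PSI and the differential call.** Percent spliced in is estimated per
replicate as PSI = 100 · Ī/(Ī + S), Ī = (inc1 + inc2)/2. For each posterior
draw, every replicate's inclusion proportion is drawn from its
Beta(Ī + 1, S + 1) posterior, replicate draws are averaged per condition,
and dPSI = 100 · (p̄_B − p̄_A). An event is differential when
MV[|dPSI|]\_0.95 > 0 — the 95% credible bound on dPSI excludes zero with a
consistent sign — **and** |mean dPSI| > 10, after an event-level filter of
≥ 10 junction reads in at least one replicate.

**RELI-style enrichment.** For each CLIP dataset, each direction (more
included / more skipped) and each region class (250-bp upstream flank, exon,
250-bp downstream flank, and their merged union), the observed number of
events with ≥ 1 overlapping peak is compared with an empirical null built by
resampling, 2000 times, the same number of background events — expressed
(base mean > 50) but unchanged exons — and scoring the matching region
class. The null is summarised as a normal: z = (obs − μ)/σ, one-sided
P = 1 − Φ(z), enrichment = obs/μ, and the *ratio* is the fraction of input
events whose merged region is bound at all. After Benjamini–Hochberg
correction across all tests of the run, a dataset-stratum is significant
when **adjusted P < 0.05, ratio > 0.05 and enrichment ≥ 2**. RBPs are ranked
by their number of significant dataset-strata.

**Motif maps.** Sliding-window (50 nt) densities of a motif (default ACTAA,
the DNA form of the QKI element ACUAA) are profiled along a transcript-
oriented axis — upstream flank | first 50 nt of exon | last 50 nt |
downstream flank — and compared per position between regulated and
background events with Wilcoxon rank-sum tests.

Every stage is verifiable offline: `simulateStudy()` generates a genome,
annotation, beta-binomial junction counts, CLIP datasets with one true
regulator planted at configurable odds among decoys, and planted motifs,
together with the ground truth.

## Worked example

```r
library(spliceRELI)

study <- simulateStudy(nGenes = 400L, nIncluded = 40L, nSkipped = 40L,
                       nDecoys = 4L, seed = 7L)
cfg <- analysisConfig(seed = 7L)
run <- runPipeline(study$events, study$peakSets, cfg,
                   genome = study$genome, outDir = "demo")

run$events
#> SplicingEventSet: 400 cassette-exon events, 6 samples (conditions: A, B )
#>   differential calls: included=45, skipped=46, unchanged=309

subset(run$results, significant)[, c("dataset_id", "rbp_name", "region_class",
                                     "direction", "z", "p_adj", "enrichment",
                                     "ratio")]
#>    dataset_id  rbp_name region_class direction     z    p_adj enrichment ratio
#> 5        ds01 REGULATOR     upstream   skipped 12.26 2.96e-33      10.40 0.457
#> 8        ds01 REGULATOR       merged   skipped  5.74 9.47e-08       2.95 0.457
#> 25       ds04   DECOY03     upstream  included  2.94 2.22e-02       3.09 0.178

run$ranking
#>    rbp_name n_significant best_z best_p_adj max_fraction_bound n_datasets
#> 1 REGULATOR             2  12.26   2.96e-33              0.457          1
#> 2   DECOY03             1   2.94   2.22e-02              0.178          1
```

Of the 400 events, 91 are called differential (80 were truly regulated at
|dPSI| = 40). The planted regulator — 8× placement odds in upstream flanks
of skipped exons over a 5% baseline — is recovered in exactly that stratum
(z = 12.3, enrichment 10.4) and binds 46% of the skipped events' merged
regions; one decoy scrapes past the cutoff in a single stratum, which is the
kind of marginal call the triple cutoff is designed to keep rare. The motif
map of the same run places its minimum rank-sum P (1.7e−48) at offset 44 of
the downstream flank, inside the planted 20–80 nt window:

```r
mm <- run$motif_maps$included
mm[which.min(mm$p), ]
#>     position    segment offset target_mean background_mean        p motif direction
#> 394      394 downstream     44      0.0178        0.000717 1.69e-48 ACTAA  included
```

`runPipeline()` also writes `events_called.tsv`, `enrichment_results.tsv`,
`rbp_ranking.tsv`, `report_zmatrix.tsv`, per-direction motif-map TSVs and a
JSON run manifest; identical inputs and seed reproduce them byte-for-byte.

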