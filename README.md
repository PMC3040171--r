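# chipmotif

An integrated R pipeline for transcription-factor ChIP-Seq analysis:
peak calling from directional reads, de novo motif discovery in the
enriched regions, and motif annotation with distance-distribution
statistics — with a synthetic-data module so that every stage can be
exercised and validated end to end with known ground truth.

## Who it is for

Computational biologists analyzing point-source ChIP-Seq experiments
(transcription factors, not broad histone marks) who want a single,
scriptable workflow from aligned reads (BED) to annotated motifs, and
methods developers who need a fully synthetic, truth-tracked test bed for
peak callers and motif finders.

## What it computes

**Peak calling.** Within candidate regions, forward and reverse 5' read
positions are modelled as a K-component mixture of strand-shifted t
distributions: forward positions concentrate at μ − δ/2 and reverse
positions at μ + δ/2, where μ is the binding position and δ the fragment
length. Fitting is MAP-EM with a Normal(ξ, s²) prior on δ and
inverse-gamma priors on the spreads; K is selected by BIC, which resolves
binding events only ~300 bp apart. Read-mappability gaps are handled by
truncated-data EM: component densities are renormalized over the mappable
subset and the masked mass is restored in expectation, correcting the
position bias that one-sided read loss otherwise causes. Events get
control-relative enrichment scores and an FDR estimated by exchanging
treatment and control.

**Motif discovery.** A genetic algorithm over spaced dyads (two short
words plus a spacer) seeds candidate PWMs that are refined by ZOOPS
expectation-maximization and scored by a calibrated log E-value combining
a Poisson tail on the site count with a selection-corrected tail on the
mean site score; PWM score p-values are exact (dynamic-programming
convolution on a discretized score grid). Reported motifs are
width-trimmed, their occurrences masked, and discovery repeats. A seeded
mode refines a user-supplied PWM directly — roughly an order of magnitude
faster — for recovering weak expected motifs.

**Annotation.** Discovered PWMs are aligned to reference databases
(TRANSFAC and JASPAR flat formats) by ungapped column-correlation
alignment with Gumbel-calibrated similarity E-values; motifs can be
filtered by name/E-value, virtually combined under one label, and screened
by distance-to-peak and motif-pairwise distance distributions — relevant
motifs concentrate near peak centers, artifacts are flat.

## Worked example

Simulate three binding events on a 120-kb chromosome, call peaks against
the simulated input control, then discover the motif planted in a set of
peak-centered regions:

```r
library(chipmotif)

events <- data.frame(chrom = "chr1", mu = c(30000, 62000, 90500),
                     n_frag = c(150, 100, 80))
sim <- sim_reads(events, c(chr1 = 120000), noise_rate = 1e-3, seed = 42)
peaks <- call_peaks(sim$treatment, sim$control)
head(peaks[, c("chrom", "mu", "delta", "score", "ci_lo", "ci_hi")], 3)
#>   chrom    mu delta score ci_lo ci_hi
#> 1  chr1 29999 173.4   150 29997 30002
#> 2  chr1 62001 174.7   100 61998 62005
#> 3  chr1 90498 172.5    80 90494 90501
```

All three planted positions are recovered within a couple of base pairs
(the 95% intervals are ±3 bp), the estimated fragment lengths sit at the
simulated ~175 bp, and the scores equal the estimated fragment counts
ranked in the planted order.

```r
motif <- trim_pwm(read_jaspar("my_db.txt")[["AP1"]])   # or any 4 x w PWM
simseq <- sim_sequences(200, 400,
                        list(list(pwm = motif, occupancy = 0.7,
                                  dist = "center", sd = 25)), seed = 7)
res <- discover_motifs(simseq$sequences,
                       discovery_config(n_pop = 50, n_gen = 3, seed = 11))
res[[1]]
#> Motif AGCTGAGTCA: 148 sites, logE -144.76, fold enrichment 4.73 (round 1)

ds <- distance_to_peak(res[[1]]$occurrences,
                       data.frame(seq_id = simseq$sequences$id, center = 200))
sum(ds$counts[abs(ds$mids) <= 60]) / sum(ds$counts)
#> 0.84
```

The discovered motif is the reverse complement of the planted consensus
(strands are equivalent), found in 148 of 200 sequences at 4.7-fold
enrichment over the background expectation with a decisive fitness
(logE ≪ 0), and 84% of its occurrences lie within 60 bp of the region
centers — the spatial signature of a directly bound motif.

A thin command-line wrapper over these functions is installed at
`inst/scripts/chipmotif` (`extract`, `callpeaks`, `discover`, `annotate`,
`simulate` subcommands).

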