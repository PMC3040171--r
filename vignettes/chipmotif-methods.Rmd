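---
title: "Models and methods behind chipmotif"
author: "chipmotif authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chipmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipmotif)
```

chipmotif is an integrated analysis pipeline for transcription-factor
ChIP-Seq: binding events are estimated from directional read pileups, de
novo motifs are discovered in the enriched regions, and the discovered
motifs are annotated against reference databases and screened by their
spatial statistics. This vignette describes the statistical models, the
tunable parameters, the synthetic-data generators that make the whole
pipeline testable without external data, and the numerical and design
choices a maintainer would want spelled out.

## The binding-event model

A protein-DNA binding event at genomic position $\mu$ is sequenced as the
two ends of immunoprecipitated fragments: forward-strand 5' read positions
pile up at roughly $\mu - \delta/2$ and reverse-strand 5' positions at
$\mu + \delta/2$, where $\delta$ is the typical fragment length. Within a
candidate region, forward positions $f_i$ and reverse positions $r_j$ are
modelled as a $K$-component mixture of shifted t distributions sharing
component weights across strands:

$$
f_i \sim \sum_{k=1}^{K} w_k\, t_\nu\!\left(\mu_k - \tfrac{\delta_k}{2},
\sigma_{fk}\right),
\qquad
r_j \sim \sum_{k=1}^{K} w_k\, t_\nu\!\left(\mu_k + \tfrac{\delta_k}{2},
\sigma_{rk}\right).
$$

Priors regularize the fit: $\delta_k \sim N(\xi, s_\delta^2)$ encodes what
is known about the fragment-length distribution, and the squared spreads
get inverse-gamma$(a, b)$ priors. Estimation is MAP-EM using the
normal-scale-mixture representation of the t distribution (latent gamma
weights), so every M-step is a closed-form weighted least-squares update;
the $(\mu_k, \delta_k)$ pair is solved jointly from both strands with the
$\delta$ prior folded into the normal equations.

Defaults and their meaning:

* `xi = 175` bp — prior mean of $\delta$, the fragment-length scale of a
  typical sonication protocol producing roughly 200-bp fragments;
* `delta_sd = 50` bp — weak enough that a few dozen reads per strand
  dominate the posterior;
* `sigma_shape = 2`, `sigma_scale = 2 * 35^2` — a weak inverse-gamma prior
  centered near read-length-scale spread;
* `nu = 4` — heavy-tailed but finite-variance, the standard compromise for
  robust location mixtures; outlying reads (mismapped or PCR artifacts) are
  down-weighted automatically through the latent gamma weights.

Candidate regions come from a sliding-window scan (window 300 bp, step
50 bp) keeping windows with at least 5 forward *and* 5 reverse 5' ends —
the bidirectional requirement is what distinguishes a binding pileup from
a one-sided artifact. Overlapping kept windows are merged and extended by
$\xi$ on both sides. These defaults are deliberately permissive: downstream
enrichment scoring, not segmentation, decides what is reported.

The number of events per region is chosen by BIC over $K = 1..K_{max}$
with $5K - 1$ free parameters; components closer than a quarter of their
mean $\hat\delta$ are merged afterwards, since two modes that close cannot
be distinct binding events at fragment-length resolution. Initialization
is deterministic (quantiles of the implied binding centers
$f_i + \xi/2$, $r_j - \xi/2$), so fits are reproducible without a seed.

### Mappability truncation

Repetitive genomic stretches cannot be uniquely mapped, which deletes
reads on one flank of an event and biases $\hat\mu$ away from the hole.
When a mappability profile is supplied, each component density is
renormalized over the mappable subset of the region, evaluated on a 1-bp
grid, and the expected sufficient statistics of the masked read mass
("ghost" pseudo-observations distributed proportionally to the component
density over the masked positions) are folded back into each M-step —
the classical EM treatment of truncated samples. Two consequences are
worth noting:

* with a fully mappable region the correction is exactly a no-op, so
  corrected and uncorrected fits agree to machine precision;
* the penalized log-likelihood is monotone non-decreasing by construction:
  if a numerical step would ever decrease it, the previous parameter set
  is kept and the fit declared converged.

### Scores and FDR

Each event's enrichment score is its estimated fragment count
$w_k \cdot n_{\text{reads}}/2$; with a control sample it is divided by the
library-size-adjusted control read count within $\mu \pm \hat\delta$
(floored at half a read, so an empty control window cannot produce an
infinite score). Without a control the fragment count itself is the score,
mirroring how datasets without input DNA are ranked. The FDR is estimated
by exchanging treatment and control and recomputing scores:
$\widehat{FDR}(s) = \#\{\text{swapped} \ge s\} / \max(\#\{\text{treatment}
\ge s\}, 1)$, clipped to $[0,1]$ and made monotone by a running minimum
from the right.

## PWM scoring and exact p-values

Motifs are position weight matrices (column-stochastic $4 \times w$
matrices, pseudocounted so all entries are positive). A window is scored
by its log2 odds against an i.i.d. background. The p-value of a score
threshold is computed *exactly* on a discretized grid: per-column scores
are rounded to granularity $g = 10^{-3}$ log2 units and the distribution
of the column sum under the background is built by dynamic-programming
convolution, one column at a time. Any word's rounded score differs from
its exact score by at most $w g / 2$, so the p-value error is bounded by
the probability mass within $w g$ of the threshold — negligible against
typical score gaps. Scanning converts a p-value threshold (default
`2e-4`) into the minimal grid score whose tail probability is below it;
reported per-occurrence p-values are therefore exact for the reported
(grid-rounded) score. Windows containing N are skipped.

The default background is uniform; `observed_background()` lets callers
use the input's base composition instead. Keeping sequences unmasked is a
deliberate philosophy: artifact motifs are screened afterwards by their
spatial statistics rather than by repeat-masking the input.

## De novo discovery

Discovery follows the spaced-dyad + genetic-algorithm + EM recipe: a
population of spaced dyads (two 3-6-mers separated by up to 10 bp of
spacer) seeds candidate motifs; each candidate is converted to a matrix
(consensus letters at probability $1 - 3\alpha$ with $\alpha = 0.05$,
uniform spacer columns), refined by ZOOPS EM, and scored; tournament
selection, single-point crossover (exchanging spacer and second word),
point mutation (probability 0.1) and single-individual elitism evolve the
population; the best motif is reported, its occurrences masked with N, and
the cycle repeats until nothing passes the fitness cutoff.

Dyad words are drawn from the most over-represented k-mers of the input
(top 2% per length, at least 8 words), with probability proportional to
their observed/expected ratio. Restricting to the top-ranked words is what
makes seeding concentrate on genuine cores; sampling proportionally over
the full k-mer spectrum would dilute the planted signal to a few percent
of draws.

### ZOOPS EM

Each sequence carries zero or one site: a latent indicator chooses "no
site" with probability $1 - \gamma$ or a site at one admissible
offset-strand combination, with a positional prior that is uniform by
default or a discretized triangle peaking at the sequence midpoint
(`prior = "centered"`) — useful when the input windows are centered on
predicted binding positions, at the cost of down-weighting genuinely
off-center secondary motifs, which is why uniform is the default.
Optional per-sequence weights (normalized region enrichment scores,
`seq_weights`) prioritize strongly enriched sequences linearly in the
posterior sufficient statistics. The M-step re-estimates the matrix from
posterior-weighted letter counts plus a 0.25 pseudocount and updates
$\gamma$; iteration stops when the matrix changes by less than `1e-4` in
any entry or after 50 iterations. The observed-data log-likelihood is
non-decreasing — the EM guarantee — and its trace is attached to every
refined matrix. The ZOOPS choice (rather than exactly-one-per-sequence)
reflects that ChIP regions frequently lack a recognizable site.

Motif width is adjusted once after convergence by trimming flanking
columns with information content below 0.1 bits (never below width 4);
trimming inside the EM loop was rejected as it couples width to transient
early-iteration noise.

### Fitness: a calibrated log E-value

The fitness of a candidate motif on $n$ detected sites among $W$ scanned
windows is

$$
\log E = \log W
 + \log P_{\text{Poisson}(W p)}(N \ge n)
 + \log P(\bar S \ge \bar s_{\text{obs}} \mid S \ge c,\ n),
$$

where $p$ is the scan p-value threshold and $c$ the corresponding score
cutoff. The count term asks whether more sites were found than the
background expects; the score term asks whether the found sites score
higher than background windows *that also passed the cutoff* — the
truncation is essential, because sites are only ever observed above the
cutoff, and without it the score term is astronomically small even for
pure background, making every candidate look significant. On background
input both tail probabilities are order one, so the fitness sits near
$+\log W$, far above the reporting cutoff of 0 ("fewer than one such motif
expected by chance"). Fold enrichment is reported separately as
$n / (W p)$.

Two further safeguards keep the discovery loop honest:

* **Held-out fitness.** A 15-25 column matrix EM-fitted to several hundred
  sequences can tailor itself to the highest-scoring background windows
  and pass any in-sample significance test. The GA therefore refines on
  the odd-indexed half of the sequences and scores on the even-indexed
  half; the reported motif is refit on the full set (and its occurrence
  list re-scanned there), but its decision statistic remains the held-out
  log E. Inputs with fewer than 20 sequences are not split.
* **Search-size correction.** The winner is the best of all distinct dyads
  the GA examined, so $\log(\#\text{candidates})$ is added to reported
  fitness values — the number-of-starting-points multiplicity term of
  motif E-values.

During the GA search, candidate matrices are refined under a reduced
iteration cap (`em_iter_search = 8`); the full stopping rule is applied
when the winning candidates are re-refined before reporting. The reduced
cap exists because candidates seeded from background dyads essentially
never meet the `1e-4` matrix-change criterion and would otherwise always
consume the full 50 iterations, dominating the run time of a search whose
only job is to *rank* candidates. GA defaults (population 100, 5
generations, tournament size 2) are small desk-scale settings, fully
exposed in `discovery_config()`; the acceptance workloads use population
50 and 3 generations.

Aggregate score tails are computed by exact convolution of the truncated
single-window score distribution (binary powering with supports re-binned
to at most ~2048 bins, direct dense convolution) for $n \le 16$, and by a
Gaussian approximation on the log scale for larger $n$ — the exact
linear-space convolution underflows double precision once $n$ is in the
hundreds, while the log-scale normal tail stays finite and monotone.

### Seeded mode

`seeded_discover()` skips the GA entirely: a user-supplied matrix (for
example a database motif) initializes one ZOOPS EM refinement, after which
scanning, trimming and fitness proceed exactly as in de novo mode. The
seed is used only for initialization — the EM updates never see it again —
so the recovered motif reflects the data, not the seed. Skipping the
population-times-generations search is what makes seeded runs roughly an
order of magnitude faster; it is the tool of choice for a weak expected
motif that de novo search misses.

A motif whose trimmed matrix aligns to its own reverse complement at
similarity 0.95 or better is flagged palindromic and reported once.

## Motif annotation

Query matrices are aligned to every database matrix without gaps, over all
offsets with at least 4 overlapping columns and both target orientations;
the alignment score is the mean per-column Pearson correlation of the
probability columns (average log-likelihood ratio is available as an
option). Ties prefer longer overlaps, then smaller offsets, then the
forward orientation — short perfect sub-alignments must not outrank a
full-length match.

Significance is calibrated empirically: null scores are generated by
aligning column-shuffled database matrix pairs (shuffling preserves each
column's information content while destroying positional structure),
bucketed by the smaller width of the pair, and fitted with a Gumbel
extreme-value distribution by maximum likelihood. The fit is performed on
Fisher-z-transformed scores ($\tanh^{-1}$, clamped at $|r| = 1 - 10^{-4}$):
correlation-type scores are bounded above by 1, so an extreme-value tail
fitted on the raw scale cannot assign a meaningfully small probability to
a perfect match, while the z scale is unbounded and the transformation is
monotone. The E-value is $N_{db} \cdot P_{\text{null}}(S \ge s)$; buckets
with fewer than 100 null samples are widened to their neighbours and
flagged.

Downstream utilities follow common post-processing practice: name and
E-value filters (e.g. keep motifs with a match containing "STAT" at
$E \le 10^{-4}$); *virtual* combining that assigns one label to several
motif variants and pools their occurrence lists without ever touching the
member matrices; distance-to-peak histograms (default 10-bp bins over
±200 bp, matching 400-bp windows) in which a biologically relevant motif
concentrates near zero while an artifact is flat; and pairwise distance
distributions with a co-occurrence fraction whose denominator is the rarer
motif — the interpretable reading is "how often does the rare motif travel
with the common one". Occurrences with no resolvable center are tallied as
unmatched rather than dropped, so histogram mass plus unmatched always
equals the input count.

## The synthetic-data generators

`sim_reads()` emulates the fragment-level picture directly: per event,
fragment centers sit at $\mu^*$ with lengths
$N(175, 35^2)$ truncated above the 35-bp read length; each fragment emits
one read from a uniformly chosen end (forward 5' at the left end, reverse
5' at the right end), so the strand-mode separation is the fragment length
itself and the recorded per-event truth $\delta^*$ is the realized mean
fragment length minus one. Uniform noise reads (default $10^{-3}$ per bp)
are added to treatment and control alike; the control contains noise only;
reads whose 5' end falls in a supplied mappability gap are deleted from
both samples. Defaults (100 fragments per event, 35-bp reads) are chosen
to resemble a well-powered point-source factor dataset at desk scale.

`sim_sequences()` plants sites sampled letter-by-letter from a PWM into
i.i.d. background sequences, on a random strand, at uniform,
center-normal, or fixed-lag-from-another-motif positions; overlapping
plants are re-drawn up to 10 times and then recorded as skips, never
silently dropped. The truth tables fully determine every recovery metric
used by the tests.

What the generators deliberately do *not* model: PCR duplication and
amplification bias, sequencing errors in read sequences, higher-order
(dinucleotide) background composition, copy-number variation, and
chromatin-accessibility covariates. Passing tests on this synthetic data
therefore demonstrates correctness of the estimators under the stated
model, not robustness to every artifact of real libraries.

## Problem sizes and numerical choices

The test-suite and acceptance workloads use: 100 replicates for
single-event parameter recovery and two-event resolution; 100 replicates
for the mappability comparison; 100 discovery seeds (500 sequences of
200 bp, 60% occupancy, GA population 50 over 3 generations) plus 20
background-only runs for specificity; a 100-motif synthetic database with
1000 null alignments for E-value calibration. The acceptance script runs
the same computations at 25-50 replicates where the statistic is a mean
or a rate. These sizes were chosen so a complete run stays comfortable on
a single desk-scale core while leaving the pass margins wide.

Numerical details worth knowing: score grids use $g = 10^{-3}$ log2 units;
EM tolerances are `1e-6` relative penalized log-likelihood (mixture fit)
and `1e-4` maximum matrix change (ZOOPS); degenerate mixture components
(weight below $10^{-3}$ or spread below 1 bp) are pruned and flagged;
$\hat\delta$ is floored at 1 bp; event ranking breaks score ties by
chromosome and position so output order is deterministic; and all
stochastic operations take explicit seeds, with the caller's RNG state
restored afterwards.

## Known limitations

* The enrichment score and FDR are pragmatic stand-ins defined exactly as
  documented above, not a reimplementation of any published package's
  internal formulas; numerical agreement with other peak callers'
  scores is out of scope.
* Broad-domain (histone-mark) enrichment is not modelled; the mixture
  assumes point-source binding.
* Gapped motifs and dinucleotide backgrounds are unsupported; the spacer
  in a dyad becomes uniform columns of a contiguous PWM.
* E-values for motif similarity depend on the calibration database; they
  are comparable within one calibration, not across databases.
* `distance_to_peak` resolves each occurrence to the nearest event on the
  same chromosome; in dense event clusters closer than the histogram span
  this can fold distances toward zero.
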