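---
title: "Methods: lateralized transcriptomes, handedness inference, variant integration, and vocalization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lateralized transcriptomes, handedness inference, variant integration, and vocalization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hemivox implements a four-part analysis of hemispheric lateralization in
speech-related biology: donor-paired differential expression over a
bilateral cortical atlas, summary statistics of lateralization,
probabilistic handedness inference, a variant-to-enhancer integration
cascade, and an ultrasonic-vocalization (USV) pipeline for mouse vocal
behavior. Because the human RNA-seq data this style of analysis is built
for are access-restricted, every stage ships with a synthetic-data
generator whose ground truth is known exactly; the test suite and the
acceptance script run the real analysis code against those generators.

## The bilateral cohort model

`simulate_expression()` draws counts from a negative-binomial model with
log2-scale effects:

$$K_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi), \qquad
  \mu_{gs} = m_g \cdot 2^{d_{D(s)} + a_{g,A(s)} + \delta_{g,A(s)}[H(s)=R]}
  \cdot \lambda_s$$

where $m_g$ is a per-gene baseline (log-normal around `baseline_mean`,
default 100 counts), $d$ a donor effect (sd 0.2 log2), $a$ an optional
gene-by-area effect, $\delta$ the injected right-over-left
lateralization in a target area, and $\lambda_s$ a log-normal
library-size multiplier (sd 0.2) so that normalization is genuinely
exercised. $\phi$ is the usual dispersion in
$\mathrm{Var} = \mu + \phi\mu^2$; the default 0.05–0.1 spans what bulk
brain RNA-seq typically shows for moderately expressed genes. The
default cohort mirrors the study design the package targets: five
donors, both hemispheres of each listed Brodmann area, with sex, age,
handedness, family-history and language-disorder covariates carried at
the donor level; a missingness mask supports incomplete designs (the
motivating atlas has 125 of 130 possible samples). An optional `donors`
column in the effect table restricts an effect to a donor subset, which
is how trait-linked lateralization (e.g. handedness-dependent asymmetry)
is simulated.

What the generator does *not* emulate: correlated transcriptome
structure (co-expression modules), compositional outliers, GC/length
biases, or batch effects. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under its own model
assumptions — not that those assumptions hold on any particular real
dataset.

## Donor-paired differential expression

Two contrast families are supported: left-versus-right within an area
(LR) and area-versus-area within a hemisphere (WH_L, WH_R). A contrast
is always paired at the donor level: only donors contributing both
conditions enter, at least two are required, and donor is a fixed
blocking factor. Factor references are fixed so the reported `log2fc`
is right-minus-left (LR) or `area_a`-minus-`area_b` (WH).

Genes are filtered per contrast subset: total count at least 10 and a
positive count in at least 3 samples.

Sample-level covariates are admitted only when they vary among the
donors used; constant or all-missing covariates are dropped, and the
decision is recorded in a per-contrast ledger. Numeric covariates are
median-imputed and scaled by 1.4826·MAD (falling back to the sd when the
MAD is zero); categorical covariates are mode-imputed and one-hot coded.
Because these covariates live at the donor level, they are exactly
collinear with the donor blocks whenever each donor carries a single
value; the design is rank-checked and aliased covariate columns are
dropped with a message by default (`on_aliased = "error"` restores a
strict check). The donor blocks then carry the adjustment, which is the
statistically correct behavior for a paired design.

The default `moderated_t` engine works on TMM-scaled log-CPM:

1. **TMM size factors** — the classic trimmed mean of M-values with the
   package's own, deliberately simple definition: reference sample =
   library closest to the median depth; per sample, M- and A-values over
   genes positive in both libraries; two-sided trims of 0.30 (M) and
   0.05 (A); plain (unweighted) mean of the surviving M-values; factors
   rescaled to geometric mean 1. The unweighted form is chosen because
   it is exactly reproducible by a brute-force sort-and-drop oracle,
   which the test suite enforces on toy instances.
2. **log-CPM** with a prior count of 0.5 against the effective library
   size (column sum × factor).
3. **Mean-variance precision weights** — a first unweighted pass gives
   per-gene residual sds; a binned running median of sd against average
   log-CPM (equal-count bins, at least 10, linearly interpolated and
   held flat outside the bin range) defines the trend; each
   observation's weight is the inverse squared trend value at its fitted
   log-CPM. With fewer than 10 genes a constant trend is used.
4. **Empirical-Bayes moderation** — residual variances are shrunk
   toward a common prior, posterior variance
   $(d_0 s_0^2 + d s^2)/(d_0 + d)$, with $(d_0, s_0^2)$ estimated by
   moments of $\log s^2$ (the excess of its spread over
   $\psi'(d/2)$ identifies $d_0$ through the inverse trigamma). The
   moderated t has $d_0 + d$ degrees of freedom; `prior_df = 0` switches
   moderation off, and the tests verify that this limit reproduces the
   ordinary paired t-test to 1e-10 and matches limma's unmoderated
   statistics on the same fit.

Counts-constant genes are flagged (`zero_variance`) with p = 1 rather
than dropped, so result tables keep the full filtered universe.

The `nb_wald` engine delegates to DESeq2 (donor-blocked design matrix,
Wald test on the condition coefficient, outlier replacement and Cook
filtering disabled, no independent filtering) for users who want
count-scale inference; the contrast logic, filtering and adjustment
levels are identical. The moderated-t engine is the default because its
every component is verifiable against closed-form oracles, and the
handedness machinery (below) is defined in terms of moderated t
statistics.

### Multi-level false discovery control

Four Benjamini–Hochberg levels are reported per gene: `q_contrast`
(within contrast), `q_global` (pooling all genes × contrasts),
`q_family` (pooling contrasts of the same family — all LR contrasts
across areas, all WH_L, all WH_R), and `q_module` (pooling contrasts
whose areas fall within one functional module: Broca, Wernicke,
Geschwind, primary auditory, ventral sensorimotor, other). A WH pair
spanning two modules is labeled `mixed` and receives no module-level q.
The family level is interpreted as pooled BH across the family's
contrasts; BH (not Bonferroni) is used at every level, and a single
contrast collapses all levels to the same value, which the tests
assert.

## Lateralization summaries

Significant-gene counts (default rule: `q_contrast < 0.05`) feed a
log10(n+1) map. For every WH area pair tested in both hemispheres, the
dumbbell statistic records the two significant-gene sets, their sizes
$n_L, n_R$, $\Delta = |n_L - n_R|$, and the Jaccard distance
$J = 1 - |A \cap B| / |A \cup B|$; pairs are ranked by $\Delta$
descending with ties broken by $J$ then by label. Two empty sets are
defined as $J = 0$ (they are equal) with a warning — continuity with the
equal-sets case. The disease-overlap report is plain counting: the
fraction of cohort DEGs present in at least one external gene set,
rounded to one decimal in percent.

Per-gene left-right tests use the Wilcoxon signed-rank on per-donor
right-minus-left differences (zero differences dropped first, standard
practice; the reported n is post-drop), with the exact null for small
tie-free samples and the continuity-corrected normal approximation
otherwise, via `stats::wilcox.test`. The paired form is the default
because the design is donor-paired; the unpaired rank-sum form is
exposed for completeness.

## Handedness inference

The leave-one-donor-out procedure, per fold: fit the R-vs-L moderated-t
contrast within each region on the training donors only; the moderated
t statistics form a signed weight vector $w$. The held-out donor's
right-minus-left log-CPM differences $d$ are projected onto $w$; the
default score is the cosine $\sum w_g d_g / (\|w\|\|d\|)$ so that scores
are comparable across regions before averaging (dot-product projection
is available). Region scores are averaged into a language index
(default regions BA44, BA45, BA22, BA21, BA39, BA40) and a motor index
(BA4, BA6, BA3/1/2); only the language index enters the Bayes mapping,
the motor index is reported.

The posterior of right handedness is a two-class Gaussian model with
shared sd:

$$P(R \mid s) = \frac{\pi\,\phi(s;\mu_R,\sigma)}
  {\pi\,\phi(s;\mu_R,\sigma) + (1-\pi)\,\phi(s;\mu_L,\sigma)}$$

computed in log space (the likelihood ratio exponent feeds a logistic),
which matters because calibrated $\sigma$ can be small enough for both
densities to underflow. The prior defaults to $\pi = 0.9$, the
approximate population rate of right-handedness. $(\mu_R, \mu_L,
\sigma)$ are calibrated per fold on the training donors' own language
indices by handedness class — computed by *nested* leave-one-out
(weights retrained without that donor), because in-sample projections
are systematically inflated relative to held-out ones and would shift
the class means off the scale the held-out donor is scored on. When a
class is absent among training donors the fallback is
$(+\hat\sigma, -\hat\sigma, \hat\sigma)$ with $\hat\sigma$ the sd of all
training indices. Nothing in the fold ever reads the held-out donor's
data; the tests assert this by hashing the weight vectors before and
after perturbing the held-out donor's counts.

## Variant integration

Coordinate conventions: variant, GWAS and eQTL positions are 1-based;
enhancer intervals are 0-based half-open (BED); all interval logic runs
through IRanges/GenomicRanges with conversion at the boundary, and GFF3
gene models are read with rtracklayer.

* **Sentinels** — associations with $P < 10^{-5}$ (strict), deduplicated
  by rsID keeping the smallest p.
* **LD expansion** — proxies with $r^2 > 0.8$ (strict) within a
  symmetric 500 kb window (the window size is a configurable default;
  the method description it follows names only "a symmetric window").
  $r^2 = D^2 / (p_A p_a p_B p_b)$ from haplotype counts, undefined when
  a locus is monomorphic — such pairs are recorded as missing, matching
  the minor-allele-frequency-zero situation that arises in real
  ancestry-matched panels.
* **eQTL intersection** — inner join on rsID (positional fallback with
  allele consistency), deduplicated per (variant, gene, tissue); eGenes
  are the distinct genes.
* **Region annotation** — precedence exonic > UTR > intronic >
  up/downstream (2 kb, strand-respecting) > intergenic; UTRs are only
  distinguished when the gene model provides UTR features (otherwise
  they are exonic); the classes partition the variant set.
* **Enhancer colocalization** — per-variant SE/TE membership flags,
  percentage summaries to one decimal, and McNemar's exact test on the
  discordant counts: $p = \min(1, 2 P(X \le \min(b,c)))$,
  $X \sim \mathrm{Bin}(b+c, 1/2)$, verified against full enumeration for
  all $b + c \le 20$.
* **PWM allele scoring** — JASPAR-style frequency matrices with a 0.01
  pseudocount and uniform background by default; the motif is placed at
  every offset and strand covering the variant, the best reference-score
  placement is kept, and $\Delta$ is the alt-minus-ref log2-odds at that
  placement. Scores are strand-symmetric by construction, which the
  tests verify via reverse-complemented windows.
* **DEG events** — a (gene, contrast) pair with nominal $p < 0.05$ and
  $|\mathrm{log2fc}| \ge \log_2 1.5$ (the fold-change threshold is taken
  on the linear scale); events are counted by family and collapsed to
  distinct genes.

## The USV pipeline

Spectrograms use a 512-point Hann window with 50% overlap; analysis is
restricted to 25–110 kHz. (A wider 10–150 kHz coarse band appears in
some detection descriptions; the package treats 25–110 kHz as the
analysis band and leaves both configurable.) At the 375 kHz recording
rate this gives a frequency bin of ≈732 Hz and a hop of ≈0.68 ms.

Detection: frames whose in-band summed power exceeds 1.5× the mean frame
power are active; runs of active frames bridged across gaps ≤ 5 ms form
candidates; candidates survive iff duration > 5 ms and spectral purity
(mean per-frame fraction of power in the peak bin) > 25%. Segment
boundaries are refined below the frame grid: an edge frame triggers when
the Hann²-weighted energy of its signal coverage crosses the threshold,
so inverting the Hann² energy CDF at threshold/segment-power gives the
trigger coverage, and correcting by it removes a duty-cycle-dependent
bias that would otherwise reach a full window length. After refinement,
onset error is bounded by about one hop and duration error by about two
hops on the synthetic fixtures.

Features are computed from the contour (per-frame argmax frequency):
duration; peak frequency at the global power maximum; mean, max, min,
start, end, median and sd of contour frequency; delta frequency
(|start − end|); bandwidth (max − min); pause duration to the previous
call and the pause-to-duration ratio; jitter and shimmer as the relative
mean absolute successive difference of contour frequency and contour
peak amplitude respectively (these two are named but not defined in the
methods literature the package follows; the chosen forms are the
standard relative successive-difference measures and are recorded in
output metadata). All features except the detection threshold itself
are invariant to global amplitude scaling, shimmer by construction
(it is ratio-normalized).

A physical note on accuracy: a frequency-modulated call sweeps
slope × window ≈ 1.37 ms worth of frequency within a single analysis
window, so contour extrema of a sweep cannot be localized better than
that smear — about 2 bins per kHz/ms of slope. The synthetic fixtures
used for the one-bin accuracy checks therefore use sweeps of 0.5 kHz/ms
(7.5 kHz over 15 ms), for which the within-window sweep stays below one
bin; steeper sweeps are still detected and clustered correctly, but
their endpoint frequencies carry the windowing smear on top of the bin
quantization.

Clustering: contours are linearly resampled to 32 points, z-scored per
position, and clustered with Lloyd's k-means, three seeded restarts,
best inertia kept. k is either fixed or chosen by mean silhouette width
over 2..min(100, n−1, #distinct contours). Identical contours collapse
to a single flagged cluster, and a fixed k exceeding the number of
distinct contours is reduced with a flag. Silhouette selection is the
default; note that exact duplicate contours degenerate the silhouette
toward oversplitting (a duplicate's within-cluster distance is 0), which
is why the selection caps k at the distinct-contour count.

Group comparisons aggregate to per-animal means first — the animal, not
the call, is the unit of analysis — then apply two-sided Mann–Whitney
tests per feature, exact for combined n ≤ 20 without ties.

## Orchestration and reproducibility

`validate_config()` fills a complete default configuration from a YAML
file, rejecting unknown keys; `run_pipeline()` executes the configured
stages in dependency order and writes a manifest with the package
version, the global seed, per-stage seeds, and the MD5 of every output
file. Per-stage seeds derive from the global seed by a counter scheme
(seed × 101 + stage index, mod 2³¹−1) so stages can be re-run in
isolation. The test suite asserts byte-identical outputs across two
runs of the same configuration.

## Problem sizes used in simulations

The simulation-based checks use: 2,000 genes × 5 donors × 20 seeds for
null calibration of the moderated-t engine (type-I error and realized
FDR); 1,000 genes with 100 carrying a +2 log2 effect for effect-size
recovery (a 10% affected fraction keeps TMM's most-genes-unchanged
assumption realistic); 300 genes × 3 areas × 50 seeds for dumbbell
ranking recovery; 200 genes × 6 donors × 50 seeds for handedness
ordering; and a 20-syllable audio fixture (15 ms calls, 70 ms apart,
~37 dB SNR) for detection, feature accuracy and clustering. These sizes
were chosen as the smallest at which the Monte-Carlo error of each check
is comfortably below its decision margin.

## Known limitations

* The generator's independence across genes means FDR calibration is
  demonstrated under independence; correlated transcriptomes can inflate
  the variance of the false-discovery proportion.
* The handedness likelihood (Gaussian classes, shared sd, literature
  prior 0.9) is an implementation choice — the procedure it follows
  does not specify the likelihood form — and is flagged as such in
  output headers; with five-donor cohorts the calibration rests on very
  few points.
* The enhancer "colocalization" is interval/identifier overlap, not a
  probabilistic colocalization posterior.
* LiftOver is not executed; coordinate-mapping tables must be applied
  upstream.
* The USV detector is a threshold detector by design; it will not match
  learned detectors on low-SNR or overlapping calls, and reverberant
  acoustics are out of scope.
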