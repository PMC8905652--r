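---
title: "Design, simulation and analysis of transitional-probability speech streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design, simulation and analysis of transitional-probability speech streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syllastream)
```

This vignette is the package's own account of its methods: the
combinatorial design it constructs, the generative model behind the
synthetic data, the numerical choices in the ERP pipeline, the statistical
conventions, and the limits of what the simulations can show.

## The material design

A syllabary holds 16 CV syllables. Four **high-TP words** partition 12 of
them into ordered triples, so every internal bigram has transitional
probability

$$\mathrm{TP}(y \mid x) = \frac{n(x \rightarrow y)}{n(x)} = 1,$$

because each of those syllables exists in exactly one word at one
position. The four **low-TP words** use the remaining 4 syllables in a
Latin-rectangle design: each word omits one syllable, each syllable
occupies each of the three positions exactly once across the set, and the
8 internal bigrams are pairwise distinct. Every low syllable then occurs
in three words (three times the token frequency of a high syllable), and
with uniform word frequencies each internal bigram has TP
$60/180 = 1/3$. `design_tp()` counts word-final tokens of the antecedent
in its denominator, which is what makes the low value 1/3 rather than
1/2; word frequency is fixed at the stream's value of 60 tokens but
parameterized.

**Foils** reuse the same syllables at the same positions with the same
class frequencies (high syllables once, low syllables three times across
the foil set), while none of their internal bigrams ever occurs inside a
word (TP = 0). The construction rules are reverse-engineered from the
published material table and verified against it in the test suite: a low
foil keeps its source word's initial and final syllables and replaces the
medial with a position-2 high syllable (a bijection over the four high
words); a high foil keeps its initial, takes a position-compatible low
medial, and borrows its final from a *different* high word (a derangement
over finals). Because the replacement syllable always comes from the
other frequency class, the zero-bigram property holds automatically; the
validator still checks it directly. Both canonical syllabaries pass every
invariant, and the solver (`build_lexicon()`, `build_foils()`) finds
fresh designs by bounded randomized search — the 2-AFC analyses never
depend on the solver because the canonical foils load verbatim.

Two decisions the source material leaves open: (1) "never presented
together" is enforced for within-word bigrams only — foil bigrams may
still arise across word boundaries in the stream, where every syllable
pair eventually co-occurs; (2) the four counterbalancing lists per
syllabary are not specified anywhere, so `rotate_lexicon()` implements
them as position rotations and is documented as a guess.

## The familiarization stream

Each word occurs exactly 10 times per block in 6 blocks (480 tokens).
Two adjacency constraints hold everywhere, including across block joins
(the blocks are contiguous audio): no immediate word repetition, and no
word may follow one whose final syllable equals its own initial syllable.
The generator fills each block by weighted random sampling with
backtracking restarts; exact per-block counts are hard constraints. Every
generated sequence is re-audited by an independent scan
(`audit_word_sequence()` and, separately, a brute-force scan in the test
suite) rather than trusted.

Boundary statistics are computed at the word-transition level: for a word
$A$, $\mathrm{TP}(B \mid A)$ over its successors, averaged (unweighted)
over $A$'s *legal* successors and then over the class. High-TP words have
7 legal successors (only self-repetition is excluded; their final
syllables begin no word), low-TP words 6 (the word beginning with their
final syllable is also excluded), so the summaries are $1/7 \approx 0.14$
and $1/6 \approx 0.17$ by construction, exact up to the single
stream-final token. Raw syllable-token TPs are reported separately
(`token_tp_table()`); there, low internal bigrams gain mass from boundary
coincidences (about 0.39 on a default stream instead of the design 1/3),
which is worth knowing when interpreting "design" versus "experienced"
statistics.

Timing: one 50 ms silence after every 300 ms syllable — three gaps per
word — because $3 \times (300 + 50) = 1050$ ms matches the printed word
period; a between-syllable-only reading would give 1,000 ms and
contradict it. The total duration identity
$\text{words} \times 3 \times (\text{syl} + \text{gap})$ holds for any
parameters.

**Chirps.** 15% of the 1,440 syllable tokens (216) carry the cover-task
chirp, exactly 9 per word × position cell, so the flag carries no
segmentation cue; non-divisible totals are spread round-robin. The
source description is internally inconsistent — 15% of syllables is 216,
yet detection is reported out of 144 — so the rate default is 0.15 and an
explicit `total = 144` override is provided; neither is asserted as
ground truth. Chirp adjacency is left unconstrained. Audio rendering uses
one fixed synthetic tone per syllable (these are *not* recorded
Portuguese syllables) and superimposes a 0.1 s sawtooth sweep from 450 to
1,450 Hz on flagged syllables.

## The behavioural model

Each subject × task × word-type score is $100 \times k/8$ with $k$
beta-binomial: the cell mean comes from the published group table and the
dispersion is solved from the published SD
($\rho = (\mathrm{Var}/npq - 1)/(n-1)$). Three cells are *under*-dispersed
relative to a binomial at $n = 8$ trials, where no beta-binomial can
match the printed SD; those cells floor the dispersion at zero (plain
binomial), so their simulated SDs are slightly above the targets while
all means are matched. A Gaussian copula (default correlation 0.5) links
a subject's latent ability across cells, giving the within-subject
covariance a repeated-measures ANOVA expects; the published table
contains no information about that correlation, so 0.5 is a moderate
default, not a calibrated value. Chirp detection is Bernoulli hits on
flagged tokens and false alarms on unflagged ones.

## The EEG model

Each word onset injects two components, Gaussian bumps in time with
negative polarity: N100 (peak 100 ms, width 25 ms) and N400 (peak 400 ms
for adults, 450 ms for children — mirroring the later analysis window
used for children; width 70 ms). The widths are Gaussian SDs. A
component's epoch amplitude is

$$a = \text{base} + \Delta_\text{task} + \Delta_\text{type} +
\Delta_\text{half} + u_\text{subject}, \qquad u \sim N(0, 0.5^2),$$

in μV at the template peak, applied uniformly over the scalp channels
(mastoids weighted 0 so re-referencing cannot remove signal). All
magnitudes are simulation parameters, not published values: the source
specifies windows and ROIs, never component shapes or amplitudes. The
defaults mirror the direction of the reported effects (adults: −2 μV
N400 high-vs-low word-type delta; explicit-task and second-half
enhancements of −0.5 to −1 μV). Noise is white Gaussian (default SD
10 μV) with an optional 1/f mode; no published noise model exists.
Artifacts: a per-epoch Bernoulli (default rate 0.15, a calibration choice
— the source reports only 85% average retention) adds a ±150 μV transient
placed 150–750 ms post-onset, which confines it to a single epoch even
though the 1,500 ms epochs of consecutive words overlap.

## The ERP pipeline: numerical choices

* Re-reference: subtract $(M1 + M2)/2$ sample-wise.
* Band-pass 0.1–30 Hz, zero phase, as separate forward–backward
  high-pass and low-pass Butterworth passes (order 4 each). A single
  8th-order band-pass polynomial with a 300× corner ratio is numerically
  fragile; the split design measures 1.001 gain at 10 Hz and 0.014 at
  50 Hz.
* Epochs −300..1200 ms; the onset sample is $t = 0$; at 512 Hz an epoch
  is exactly 768 samples. Baseline and analysis windows use inclusive
  bounds at sample resolution — the convention must be pinned for
  reproducibility and is configurable.
* Rejection: an epoch is excluded iff any channel at any sample
  *strictly* exceeds ±100 μV on the baseline-corrected signal (literal
  reading of "exceeding"; threshold configurable).
* Inclusion: every task × word-type × half cell must retain at least
  $\lceil 2/3 \times \text{cell size}\rceil$ epochs. The source says only
  "in any condition"; the cells actually analyzed are the natural
  reading.
* ROIs are explicit configuration (frontal, central, fronto-central as
  published). The original choice of per-component/group "maximal" ROIs
  was data-driven; re-deriving it from data is deliberately out of scope.
* ICA ocular correction is out of scope; the synthetic data contains no
  ocular components, and threshold rejection is the implemented path.

Every step is linear except rejection, so scaling the input scales every
measured amplitude — a property the tests exercise directly.

## Statistical conventions

All p-values are two-tailed (the published t/p pairs are not internally
consistent under either convention, so the standard choice is pinned).
The mixed/RM ANOVA uses the multivariate-model route with Type III
sums of squares and sum-to-zero contrasts, which tests unweighted
marginal means under unequal group sizes — this is what reproduces the
published marginals (58.1, 58.775) from the cell table with 21 vs 20
subjects. It is validated against an independent contrast-score oracle to
1e-9. Greenhouse–Geisser epsilon is computed from the within-factor
covariance via normalized orthogonal contrasts,
$\varepsilon = \mathrm{tr}(M)^2 / ((k-1)\,\mathrm{tr}(M^2))$, clipped to
$[1/(k-1), 1]$; with the all-two-level factors here it is identically 1,
and the >2-level path is tested separately. Observed power uses the
noncentral F with $\lambda = F \cdot df_1$ at $\alpha = 0.05$, the
convention that reproduces the published power values (0.569, 0.921).
Zero-variance t-tests report signed infinity with $p = 0$.

## Calibration studies and problem sizes

Two simulation studies exercise the entire chain
(simulate → re-reference → filter → epoch → reject → include → extract →
ANOVA):

* **Type-I error**: no injected condition effects; the N400 word-type
  test rejects at ≈ 0.05 over 500 replicates.
* **Effect recovery**: the default −2 μV N400 delta, with noise and
  artifacts on, is recovered with < 5% bias over 200 replicates. The
  estimator rescales the ROI window-mean difference by the analytic
  template window gain (`template_window_gain()`), the mean of the
  unit Gaussian over the sampled window — without that rescaling a
  window mean systematically understates a peaked component.

These studies run at 128 Hz with a central-ROI montage, 48-word streams
(one repetition per block) and 6–8 subjects per replicate — sizes chosen
so hundreds of full-pipeline replicates remain cheap while every stage
still executes; the statistical structure (cells, filters, thresholds,
tests) is identical to the full-scale configuration, and the full scale
remains the package default (`default_config()`: 480-word streams,
512 Hz, 21 + 20 subjects).

## What the synthetic data does and does not show

The generator reproduces the *statistical structure* the analysis
assumes: calibrated 2-AFC cell means, condition-dependent component
amplitudes, subject-level variation, threshold-crossing artifacts, and
deterministic seeding. It does not emulate real EEG spectra (noise is
white by default), volume conduction or realistic topographies (spatial
weights are uniform over the scalp set), ocular or muscle components,
latency jitter, or natural speech acoustics. Passing tests therefore
demonstrate that the pipeline is *correct and calibrated* — unbiased
under the null, accurate on known effects — not that the published group
findings would replicate on new recordings; those depend on the original
data, which the package does not contain.
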