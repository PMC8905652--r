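# syllastream

Design, simulation and analysis of auditory statistical-learning (aSL)
experiments of the triplet-embedded ("artificial language") family, for
cognitive-electrophysiology researchers who want a fully testable,
end-to-end pipeline without a recording session.

In these experiments listeners hear a continuous stream of trisyllabic
nonsense words and the only cue to word boundaries is distributional: the
transitional probability

TP(y | x) = count(x → y) / count(x)

between consecutive syllables is high inside words and low across word
boundaries. The package builds the complete material set and analysis
chain around that statistic:

* **Lexicons** — 8 words per syllabary: 4 *high-TP* words made of
  syllables unique to one word (internal TP = 1.00) and 4 *low-TP* words
  whose 4 syllables each occur in three words at three different
  positions, a Latin-rectangle design giving internal TPs of 1/3 ≈ 0.33;
  plus 8 *foils* reusing the same syllables at the same positions and
  frequencies but with internal TPs of 0. The two published syllabaries
  are shipped verbatim; a constraint solver builds fresh ones from any 12
  + 4 syllable tokens.
* **Streams** — each word 60 times in 6 blocks under constrained
  pseudo-randomization (no immediate repetition; no cross-boundary
  syllable repetition), 300 ms syllables + 50 ms gaps (1,050 ms per word,
  8.4 min per stream), with a chirp cover task flagged on 15% of
  syllables, balanced over words and positions. Word-level
  across-boundary TPs come out at 1/7 ≈ 0.14 (high) and 1/6 ≈ 0.17 (low).
* **Synthetic data** — beta-binomial 2-AFC accuracies calibrated to the
  published group-level means/SDs, and continuous 512 Hz multichannel EEG
  whose word onsets carry N100/N400-like Gaussian components with
  condition-dependent amplitudes, sensor noise and occasional >100 μV
  artifacts.
* **ERP pipeline** — mastoid re-reference, 0.1–30 Hz zero-phase
  Butterworth band-pass, −300..1200 ms word-locked epochs with
  −300..0 ms baseline, strict ±100 μV rejection, the two-thirds
  inclusion rule, and mean-amplitude extraction over canonical frontal /
  central / fronto-central ROIs (N100: 80–120 ms; N400: 350–450 ms
  adults, 400–500 ms children).
* **Statistics** — one-sample t-tests against 50% chance, mixed and
  repeated-measures ANOVA (Type III, unweighted marginals) with
  Greenhouse–Geisser correction, Bonferroni pairwise adjustment, partial
  eta squared, and observed power under the λ = F·df1 convention.

## Worked example

```r
library(syllastream)

lex <- canonical_syllabary("A")
design_tp(lex, "tu", "ci")   # inside the high-TP word "tucida"
#> [1] 1
design_tp(lex, "do", "ti")   # inside the low-TP word "dotige"
#> [1] 0.3333333

sq <- generate_word_sequence(lex, seed = 1)  # 480 words, constraints on
word_boundary_tp(sq, "high")
#> [1] 0.1428571
word_boundary_tp(sq, "low")
#> [1] 0.1666667

tl <- build_timeline(sq, assign_chirps(sq, seed = 2))
attr(tl, "word_period_ms"); attr(tl, "total_ms") / 60000
#> [1] 1050
#> [1] 8.4
```

The design values say exactly what a learner faces: within a high-TP word
each syllable predicts the next with certainty; within a low-TP word with
probability 1/3; across word boundaries with probability ≈ 0.14 / 0.17.
An end-to-end synthetic run (`reproduce(demo_config())`) then carries
those streams through simulated EEG and behaviour to the final ANOVA
tables; on the demo scale it prints, for example, a recovered adult N400
word-type effect of `F(1,3) = 92.5, p = 0.002` against an injected
−2 μV amplitude difference.

## Analysis workflow

The numbered scripts under `analysis/` run the study as a narrative, each
writing its tables under `results/`:

| script | what it does |
| --- | --- |
| `01_design.R` | canonical lexicons, invariant audit, design TPs, 2-AFC lists |
| `02_stream.R` | constrained streams, TP audits, chirps, events TSV, demo WAV |
| `03_behavior.R` | simulated 2-AFC sample, t-tests vs chance, mixed ANOVA |
| `04_erp.R` | synthetic EEG through the full ERP pipeline + RM ANOVAs |
| `05_calibration.R` | type-I error and effect-recovery preview studies |

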