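---
title: "Window-based differential A-to-I editing: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based differential A-to-I editing: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(widee)
```

## The model

A-to-I editing by ADAR enzymes appears in RNA-seq as A→G mismatches
against the genome. `widee` quantifies editing per sample as a sum of
per-position mismatch ratios over a genomic window, compares the two
sample-set means of that signal, and judges significance against empirical
null distributions built from the eleven mismatch classes that editing
does not produce.

For position $i$ and sample $s$, with $m^{x\to y}_{i,s}$ the count of
reads observing base $y$ over reference base $x$ and $c_{i,s}$ the
coverage (all matches plus mismatches at $i$),

$$r^{A\to G}_{i,s} = \frac{m^{A\to G}_{i,s}}{c_{i,s}}, \qquad
  e_{s,w} = \sum_{i \in w} r^{A\to G}_{i,s}, \qquad
  z_{S,w} = \frac{1}{|S|}\sum_{s \in S} e_{s,w}, \qquad
  \delta_w = z_{S',w} - z_{S,w}.$$

Windows are non-overlapping tiles of the annotated regions. The editing
signal $e$ is a *sum*, not a mean, of ratios: a window with many weakly
edited positions scores like one with a few strongly edited positions,
which matches how ADAR1 distributes editing over double-stranded repeat
regions, and keeps $\delta$ roughly proportional to the total editing
change in the window.

For significance, the identical computation runs for every one of the 12
ordered mismatch classes. The eleven non-focal collections
$D^{x \to y}$ contain, by assumption, no editing signal — only the shared
error processes (sequencing error, PCR error, misalignment, SNPs). The
per-decoy estimate for a focal delta $\delta$ is the tail-count ratio

$$\hat q(\delta) = \frac{\#\{d \in D^{x\to y} : d \text{ as extreme as } \delta\}}
                        {\#\{d \in D^{A\to G} : d \text{ as extreme as } \delta\}},$$

where "as extreme" means $\le \delta$ for $\delta < 0$ and $\ge \delta$
for $\delta > 0$. The median of the eleven estimates, capped at 1, is the
window's raw q; within each sign tail a running minimum in order of
increasing $|\delta|$ yields the final q, so that a more extreme delta
never carries a larger q than a less extreme one. A selection at
$q \le t$ targets a false-discovery rate of $t$.

### Assumptions

1. **Decoy validity**: non-focal mismatch deltas are exchangeable with
   focal deltas under the null. This holds when errors are approximately
   symmetric across base substitutions and fails if some class has a
   strongly inflated error mode (e.g. oxidative damage producing G→T).
   The synthetic generator's `error_skew` knob exists to probe that
   failure mode.
2. **Coverage comparability**: requiring the minimum coverage in *every*
   sample of both sets makes every sample's $e_{s,w}$ a sum over the same
   position set, so $z$ values are comparable and coverage imbalance alone
   cannot generate $\delta$.
3. **Reference orientation**: mismatch classes are defined on the
   reference strand. For unstranded libraries, minus-strand A→G editing
   surfaces as T→C; the focal class is configurable (`focal = "TC"`) but
   no reverse-complement folding is performed.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_size` | 51 | nt | resolution/sensitivity trade-off; small enough to localize edited repeats, large enough to pool sites |
| `min_coverage` | 10 | reads | below this, single reads move ratios by ≥ 10% and dominate $\delta$ |
| `min_base_quality` | 20 | phred | mirrors common q20 read trimming; errors above this rate would contaminate ratios |
| `min_mapping_quality` | 0 | phred | aligner-scored multimappers are kept; raise to restrict to unique alignments |
| `snp_filter` | off | — | the ≥ 80% rule discards likely genomic variants; off by default because shared variants cancel in $\delta$ anyway (see invariance below) and the rule can discard fully edited sites |
| `snp_freq_threshold` | 0.80 | fraction | inclusive; evaluated per mismatch class and only in samples meeting `min_coverage`, so a 1/1 observation cannot trigger it |
| `min_sites_per_window` | 1 | positions | weakest defensible choice; windows with a single eligible site are noisy but real |
| `normalize_decoy_size` | off | — | the tail-count ratio is used literally by default; enabling rescales decoy counts by $|D^{A\to G}|/|D^{x\to y}|$ when class window counts differ strongly |

## Numerical conventions

- $\delta = 0$ windows belong to neither tail; their tail count is defined
  as the full collection size (maximally non-extreme), so their raw q is
  the capped ratio of collection sizes and monotonization leaves them at
  $\min(1, q_{raw})$.
- The focal window itself is a member of its tail, so the denominator of
  $\hat q$ is at least 1 and the estimate is always defined.
- $\hat q$ can exceed 1 when a decoy class is larger or noisier than the
  focal class; since q is a proportion it is capped at 1 before the
  median.
- Ties in $|\delta|$ within a tail are monotonized together: equal deltas
  always receive equal final q, independent of input order.
- Windows are anchored at each region's start, not at genome coordinate 0,
  so tiles never span annotation gaps; the final partial tile of a region
  is kept so short exons are not dropped.
- Coordinates are 0-based half-open everywhere internally and in output;
  GFF input is converted at load, the only conversion point.
- Duplicate-flagged reads are counted (configurable), and both mates of an
  overlapping pair count independently; pre-collapse pairs upstream if
  double-counted fragments are a concern.

A useful exact property follows from the construction: adding the same
mismatch fraction at a position in *every* sample of both sets (a shared
homozygous variant) shifts every $e_{s,w}$ equally and cancels exactly in
$\delta$. SNPs private to one set do not cancel, which is what the
frequency filter is for.

```{r snp-invariance}
cov <- matrix(200L, 1, 4)
ag  <- matrix(c(20L, 24L, 60L, 70L), 1, 4)  # differential editing, 2 vs 2
# a shared variant adds 120/200 = 60% mismatch in all four samples: the
# per-sample signals move, the delta does not
```

## The synthetic generator as the study design

`simulate_editing_counts()` draws a uniform-random reference, negative
binomial per-site coverage and multinomial base counts with mass
$(1 - \text{error} - \text{level})$ on the reference base, the editing
level (plus error/3) on the editing target and error/3 elsewhere. Its
defaults describe a deliberately simple bulk RNA-seq-like condition:
3 vs 3 samples, coverage mean 50 (dispersion 10), background error
$5\times10^{-3}$ per base spread symmetrically over the twelve classes,
and editing restricted to reference-A positions.

Design choices worth stating explicitly:

- **Noise symmetry is the default** because it is precisely the condition
  under which the decoy classes are a valid null; `error_skew` violates it
  on purpose.
- **Planted windows are densely edited**: every reference-A position in a
  planted window becomes an editing site and the set-2 level is shifted by
  the planted amount (clipped to [0, 1]). This emulates the repeat-like,
  regionally dense editing the window statistic is designed for, and it
  makes the per-window expected delta available in closed form (the sum of
  per-site level differences, recorded in the returned ground truth).
- **Calibration experiments use a pure error background** (no baseline
  editing): the realized false-positive proportion at $q \le 0.1$ is then
  measured under exactly the exchangeability assumption the estimator
  makes. The suite's calibration run uses ten replicates of roughly 2,040
  51-nt windows (40 regions of 2,601 nt) at coverage mean 30, and the
  recovery run plants a +0.2 level difference in 5% of about 1,020
  windows at coverage mean 50.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: transcript structure and splicing,
alignment artifacts near repeats (the dominant real-world false-positive
source for editing callers), strand-specific library chemistry,
PCR-duplicate clustering, overdispersed site-level editing across
replicates (biological variance beyond the binomial), and reference bias.
Real analyses should still restrict regions to well-annotated genes and
treat hits in low-complexity regions with suspicion.

`emit_micro_bam()` materializes any small count table as single-base
reads in standards-conformant, indexed BAM files plus a matching FASTA, so
the pileup front end can be tested for integer-exact agreement with the
counts that generated the files, including reads at the base-quality
boundary.

## Known limitations

- **False positives carry arbitrary signs.** A q ≤ 0.1 selection targets
  a 10% false-discovery rate; the admitted false positives are extreme
  noise deltas and are equally likely to be positive or negative. When a
  true effect is unidirectional, occasional contrary-sign windows at small
  q are expected behavior, not evidence of a second effect — at realistic
  window counts a handful of noise windows can exceed every decoy's
  support and receive q = 0.
- The empirical q is granular at small window counts (few hundred windows
  or fewer): tail counts are small integers and q jumps in large steps.
- With very unequal class abundances (e.g. an AT-poor annotation), decoy
  classes can be much smaller than the focal class; consider
  `normalize_decoy_size = TRUE` there.
- Single-sample comparisons (|S| = |S'| = 1) run and detect strong
  signals, but q values then reflect only error-process variation, not
  biological replication.
- The method reports *windows*; resolving which site(s) inside a window
  drive a change needs a site-level follow-up (e.g. inspecting the pileup
  in a browser).
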