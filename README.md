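# widee — window-based detection of differential A-to-I RNA editing

`widee` detects differences in adenosine-to-inosine (A-to-I) RNA editing
between two sets of RNA-seq samples. ADAR enzymes deaminate adenosine to
inosine in double-stranded RNA; inosine is read as guanosine by the
sequencer, so editing surfaces as A→G mismatches against the genome. ADAR1
edits promiscuously across repeat regions, which makes single-site callers
struggle: individual sites are weakly edited and shift between replicates
even when a whole region's editing clearly changes. `widee` therefore works
at the level of small genomic windows and asks whether the *aggregate*
editing of a window differs between two conditions, attaching an empirical
q value to every window. It is aimed at anyone comparing editing between
conditions — knockdown vs control, tumor subgroups, treated vs untreated —
from coordinate-sorted BAM files.

## The statistic

Let *S* and *S′* be two sets of samples. For genomic position *i* and
sample *s*, with m<sup>x→y</sup><sub>i,s</sub> the count of reads showing
base *y* where the reference has *x*, and c<sub>i,s</sub> the position's
total coverage (all matches plus all mismatches):

- **editing ratio** r<sup>A→G</sup><sub>i,s</sub> = m<sup>A→G</sup><sub>i,s</sub> / c<sub>i,s</sub>
- **window signal** e<sub>s,w</sub> = Σ<sub>i∈w</sub> r<sup>A→G</sup><sub>i,s</sub>, over
  non-overlapping windows *w* (default 51 nt) tiled across annotated regions
- **set mean** z<sub>S,w</sub> = mean of e<sub>s,w</sub> over the samples of *S*
- **delta** δ<sub>w</sub> = z<sub>S′,w</sub> − z<sub>S,w</sub>, positive when
  editing is higher in the condition set

Positions enter a window only if covered by ≥ 10 reads (default) in *every*
sample of both sets, so coverage differences alone cannot create a delta.

Significance is empirical: the same computation is repeated for the eleven
non-A→G mismatch classes (C→T, G→A, …), which are dominated by sequencing
and PCR errors and SNPs rather than editing, giving eleven decoy null
collections D<sup>x→y</sup>. For a focal delta δ the per-decoy estimate is

&nbsp;&nbsp;q̂(δ) = (# decoy deltas as extreme as δ) / (# focal deltas as extreme as δ)

with "as extreme" meaning ≤ δ for δ < 0 and ≥ δ for δ > 0. The median of
the eleven estimates, capped at 1, is the window's raw q; a running minimum
within each sign tail (by growing |δ|) keeps q from increasing as deltas
get more extreme. Selecting windows at q ≤ t targets a false-discovery
rate of t among the selection.

An optional SNP heuristic (`--rm-snps` / `snp_filter = TRUE`) excludes
positions whose mismatch frequency reaches 80% in any adequately covered
sample, which flags genomic variants rather than editing. Homozygous
variants shared by all samples cancel in δ even without the filter.

## Worked example

The package ships a seeded generator that produces per-position count
tables (and matching micro-BAM fixtures) with known ground truth. Here two
windows get a planted +0.25 editing-level difference in set 2:

```r
library(widee)
plant <- data.frame(window = c(3L, 14L), delta_level = 0.25)
sim <- simulate_editing_counts(n_set1 = 3, n_set2 = 3, n_regions = 2,
                               region_length = 510, coverage_mean = 50,
                               error_rate = 0.005, editing_site_density = 0,
                               planted_windows = plant, seed = 7)
fit <- widee_counts(sim$counts, regions = sim$regions)
fit
#> Differential editing analysis (focal class A->G)
#>   samples: 3 (set1) vs 3 (set2)
#>   windows analyzed (focal): 20 of 20 tiled
#>   q <= 0.1: 3 windows (3 with delta > 0, 0 with delta < 0)

res <- as.data.frame(fit)
head(res[order(res$q, -abs(res$delta)),
         c("window_id", "delta", "n_sites", "q_raw", "q")], 4)
#>       window_id      delta n_sites q_raw    q
#>  sim002:153-204 5.18167116      21  0.00 0.00
#>  sim001:102-153 3.13113220      13  0.00 0.00
#>  sim002:255-306 0.04577873      20  0.00 0.00
#>     sim001:0-51 0.02639567       4  0.25 0.25
```

The two planted windows (`sim001:102-153`, `sim002:153-204`) top the
ranking with deltas near their expectation (≈ 0.25 × number of reference-A
positions in the window) while unplanted windows sit near 0. `delta` is in
units of summed per-position editing ratios; `q` is the final monotonized
q value. `summary(fit)` reports per-class window counts and the q ≤ 0.1
tally split by delta sign; `plot(fit, decoy = "GA")` draws the
Bland–Altman-style view of focal versus decoy deltas.

On real data, start from BAMs instead:

```r
fit <- widee(set1 = c("ctrl1.bam", "ctrl2.bam"),
             set2 = c("cond1.bam", "cond2.bam"),
             ref_fasta = "genome.fa", regions = "genes.bed")
```

or from a shell (writes one BED-like table per mismatch class plus a JSON
run manifest and log):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "widee-run.R", package = "widee"))') \
  --set1 ctrl1.bam,ctrl2.bam --set2 cond1.bam,cond2.bam \
  --ref genome.fa --regions genes.bed --out results/
```

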