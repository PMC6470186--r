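---
title: "Methods: enrichment and gene prioritization for suggestive GWAS loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment and gene prioritization for suggestive GWAS loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subloci)
```

## The problem

For complex diseases with modest cohort sizes — the motivating case is
distinguishing psoriatic arthritis from cutaneous-only psoriasis among
psoriasis patients — a GWAS contrast between two patient groups may yield
no genome-wide-significant loci outside the MHC, yet the sub-threshold
("suggestive", p < 1e-4) signal still carries biology. `subloci`
implements an integrative pipeline that extracts it: markers that just
miss significance are intersected with cell-type-specific active-enhancer
annotation (H3K27ac peak tracks), tested for per-cell-type enrichment,
stress-tested against linkage disequilibrium (LD), and attached to
candidate genes, drugs, and differential-expression evidence.

## The model, stage by stage

### Indirect meta-analysis

Two case-vs-control results (group A vs control; group B vs control) are
contrasted per marker by the Wald difference statistic

$$\chi^2 \;=\; \frac{(\beta_1 - \beta_2)^2}{se_1^2 + se_2^2 - 2\,\mathrm{cov}},
\qquad \chi^2 \sim \chi^2_1 \text{ under } H_0,$$

the unique 1-df chi-square consistent with two independent effect
estimates. The covariance term is a configuration hook for shared
controls and defaults to 0 (the two estimates treated as independent).
Alleles are harmonized before differencing: a ref/alt swap negates the
second beta; strand flips are never guessed at and raise an error,
because silent strand resolution is a known source of sign errors.

### Suggestive markers and loci

Markers with indirect p strictly below `p_thresh` (default 1e-4, the
conventional suggestive cutoff) and outside the MHC mask
(chr6:26,000,000–34,000,000, inclusive bounds, configurable) are grouped
into loci: on each chromosome, sorted markers join one locus while the
gap to the previous member is strictly less than `max_gap` (default
500 kb). This equals the connected components of the "closer than
max_gap" graph, so the result is independent of input order; the test
suite checks this equivalence against a brute-force
connected-components oracle. Single-marker loci are permitted.
`locus_windows()` offers the alternative lead-marker ± 500 kb window
report seen in published locus tables, without conflating it with the
marker-span hull.

### Enhancer overlap

Markers are points (an indel is represented by its leftmost base);
enhancer tracks are BED intervals (0-based, half-open), merged on load —
abutting half-open intervals merge because adjacency carries no gap. A
1-based position `pos` overlaps `[s, e)` iff `s <= pos - 1 < e`. The
incidence matrix over all markers and all tracks, plus its row-wise OR
(`any_overlap`), feeds the enrichment stage.

### Enrichment with the any-cell-type baseline

The baseline reference is the set of markers overlapping an active
enhancer of *any* cell type; this conditions the test on being in
regulatory sequence at all, so a cell type is only called enriched if
suggestive markers prefer *its* enhancers beyond that baseline. For
cell type $k$, among baseline markers:

|              | overlaps $k$ | does not |
|--------------|--------------|----------|
| suggestive   | a            | b        |
| non-suggestive | c          | d        |

Fisher's exact test (hypergeometric enumeration conditional on margins;
two-sided p sums table probabilities not exceeding the observed one,
with relative tolerance 1e-7 on the comparison) gives the p-value; the
headline odds ratio is the sample cross-product `a*d/(b*c)`, with the
conditional MLE available via `conditional_mle = TRUE`. Sidedness
defaults to two-sided — the conventional default — with `"greater"`
available. The default baseline includes the tested cell type
(`baseline = "any"`); a strict `"any_other"` mode is provided.
Bonferroni correction divides by the number of cell types with at least
one overlapping baseline marker: a track that cannot produce a test
contributes no test.

The binned fold-change profile bins *all* markers by
$-\log_{10}(p)$ into `[0,1), [1,2), …` (last bin open-ended, default at
4) and reports, per cell type, the overlap proportion in each bin
divided by the `[0,1)` reference-bin proportion, so the reference bin
has fold change 1 by construction. Proportions are computed among the
bin's any-overlap markers, consistent with the Fisher baseline; an
all-markers denominator is available by flag. Bins with an empty
denominator are emitted with `defined = FALSE` rather than dropped.

### LD sensitivity analysis

Overlapping positions make marker-level counts vulnerable to LD
double-counting, so the suggestive markers are re-analyzed at the
cluster level: pairwise r² is the squared Pearson correlation of allele
dosages over pairwise-complete samples (markers with more than 20%
missingness are rejected; monomorphic markers are an error), and
markers are clustered on the distance `1 - r²` with the squared-distance
Ward update

$$d(ij,k) = \sqrt{\frac{(n_i+n_k)\,d(i,k)^2 + (n_j+n_k)\,d(j,k)^2 - n_k\,d(i,j)^2}{n_i+n_j+n_k}}$$

(the `ward.D2` criterion), cut at height `1 - r2_threshold` (default
0.1, i.e. r² = 0.9). The cut-height reading of the r² threshold is a
design choice; a `"complete"` linkage mode guarantees instead that every
within-cluster pair satisfies r² ≥ threshold. One representative per
cluster (smallest association p, ties by position) is carried into a
permutation test: the observed per-cell-type statistic is the number of
representatives overlapping the track, and the null draws equally many
markers uniformly without replacement from the non-suggestive pool.
Empirical p-values use add-one smoothing,
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$, so
they are never zero and attain $1/(n_\text{perm}+1)$ exactly when the
observed statistic beats every permutation. Density-matched sampling is
deliberately not the default: the null is plain uniform draws, which is
the simplest defensible reading of "randomly sampled loci".

### Candidate genes and drugs

For each locus with at least one marker overlapping an enriched cell
type's enhancers, one candidate gene is chosen, eQTL-first: among eQTL
records of the overlapping markers, the smallest p wins (ties broken by
smaller marker-to-gene distance, then lexicographic symbol — fully
deterministic). With no eQTL record the fallback is the gene nearest
the lead overlapping marker, distance measured to the nearest end of
the 1-based inclusive gene span (0 inside the gene), within a 1 Mb
window. eQTL records are trusted as given, with an optional cis-window
filter, since external whole-blood eQTL tables are already
distance-curated. Candidates are annotated with drugs whose indication
matches a filter (default "arthritis"), deduplicated
case-insensitively. eQTL-before-proximity is a documented precedence
choice; no claim is made that it reconstructs any particular published
table's rule.

### Differential-expression overlay

The two-group comparison (default 3 + 3) uses empirical-Bayes moderated
t-statistics implemented from the published hierarchical form: per gene
$g$, $s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_d/d$ and
$\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$. Hyperparameters are estimated
by moment matching on $z_g = \log s_g^2$: $d_0$ solves
$\psi'(d_0/2) = \widehat{\mathrm{Var}}(z) - \psi'(d/2)$ by monotone
bisection on $(10^{-6}, 10^{6})$ with tolerance $10^{-10}$ ($d_0 =
\infty$ when the right side is non-positive, collapsing every posterior
variance to $s_0^2$), and $s_0^2$ follows from the mean of $z$ with the
matching digamma corrections. The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ is a convex
combination of prior and sample variance; the moderated t has
$d_0 + d$ degrees of freedom. Setting `d0 = 0` recovers the classical
pooled t exactly, which the tests assert to 1e-10; the estimated fit is
also cross-checked against limma on shared simulations. Zero residual
variances are allowed (shrunk to the prior) and flagged. Probesets
collapse to genes by keeping the smallest p (ties: larger |t|, then
probeset id); DEGs are genes with Benjamini–Hochberg FDR strictly below
0.05. Input is assumed to be normalized log2 intensities — no
background correction or normalization is performed, and ratio-scale
fold changes are reported as $2^{\log FC}$ on that assumption.

## The synthetic-data generator

Every input has a seeded generator (`gen_bundle()` writes a complete
bundle plus ground truth), emulating the statistical structure the
analysis assumes:

* **Summary statistics** — null markers share a true beta per marker
  with independent per-comparison N(0, se²) noise, so the indirect
  chi-square is central; planted loci carry a between-comparison beta
  difference `delta`. Defaults: 49 planted loci of 2–5 markers
  (about 170 suggestive markers), 5,000 null markers, se = 0.1,
  delta = 0.9 (per-marker power ≈ 0.99 at p < 1e-4). Null positions sit
  on a 5 kb grid kept clear of planted-locus slots so generated
  enhancer intervals (≤ 2 kb) can never bridge two markers, keeping
  per-marker overlap truth exact.
* **Enhancer tracks** — marker-level Bernoulli overlap, base rate 0.3
  per cell type, 20 cell types of which 2 are planted at odds ratio 3
  on the realized suggestive set (the odds ratio is planted on the
  odds scale: $q'/(1-q') = \mathrm{OR}\cdot q/(1-q)$). Each positive
  draw becomes a 200–2,000 bp interval covering the marker. Generating
  overlap at the marker level rather than as a genome-wide peak field
  matches the enrichment model being tested and keeps ground truth
  exact; with 20 tracks at rate 0.3 nearly every marker enters the
  any-overlap baseline, which is the intended calibration condition,
  not an attempt to mimic any particular empirical baseline fraction.
* **Genotype panel** — 200 samples; within a locus, markers copy a
  latent haplotype with flip noise $\varepsilon = (1 -
  \rho^{1/4})/2$ targeting within-block r² $\rho$ = 0.95; blocks are
  independent.
* **Tables and expression** — each planted locus gets a "near" gene
  spanning it and a "far" causal gene 30–300 kb away; with probability
  0.8 the locus carries eQTL evidence (causal eQTL p between 1e-20 and
  1e-8, decoys no stronger than 1e-4), otherwise the near gene is
  causal by proximity and the locus has no eQTL rows, so both evidence
  types appear in every default report. Causal genes link to arthritis
  drugs; decoy rows carry other indications. Expression uses the
  scaled inverse-chi-square variance prior (d0 = 4, s0² = 0.05),
  3 + 3 samples, 2 probesets per gene, 10% background differential
  expression with N(0, 1) log2 fold changes, and planted |log2 FC| ~
  U(1, 2) on causal genes — fold-change magnitudes comparable to what
  osteoblast-differentiation experiments report.

What the generator does **not** emulate: realistic human LD maps and
allele-frequency spectra, correlated overlap across cell types,
genomic inflation, peak-width distributions of real H3K27ac data, and
array-level artifacts. Passing tests therefore demonstrate the
correctness and calibration of the *procedure* under its assumed
model, not performance on any particular real cohort.

## Numerical and degenerate-input choices

* Fisher's two-sided p compares table probabilities with relative
  tolerance 1e-7 to make the "as extreme" set robust to floating-point
  ties; odds ratios 0, ∞ are reported for empty diagonals.
* Duplicate-position markers collapse to the smaller p, then the
  lexicographically smaller id (deterministic, logged).
* Tests against a zero margin are skipped and excluded from the
  Bonferroni denominator rather than forced.
* Markers on chromosomes absent from a track count as non-overlapping
  and are logged once per chromosome.
* The permutation seed is derived from the pipeline seed, and every
  generator restores the caller's RNG state, so reports regenerate
  byte-identically from one seed (asserted in the tests).

## Problem sizes used by the test suite

The simulation-based checks run at the scale of the default scenario:
500 null replicates (20 cell types, 200 suggestive + 5,000
non-suggestive markers, overlap rate 0.3) for family-wise error
calibration; 200 replicates for odds-ratio recovery; 10,000 probesets
for hyperparameter recovery; 100 replicates for FDR control; 200
replicates for permutation-null uniformity; 1,000 random instances for
each combinatorial oracle. These sizes give Monte-Carlo error
comfortably below the asserted tolerances while keeping the suite
quick to run.

## Known limitations

* The shared-control correlation between the two comparisons is
  ignored by default (covariance hook available); with substantially
  shared controls the indirect chi-square is conservative in one
  direction and anti-conservative in the other.
* Gene-level FDR after min-p probeset collapse is anti-conservative:
  picking the most significant probeset per gene before BH inflates
  the realized gene-level false-discovery proportion above the nominal
  level (the acceptance report shows this on synthetic truth).
  Probeset-level BH is properly controlled; the collapse rule is kept
  because it is the field's common reporting convention.
* Cross-product odds ratios are unstable for small cells; the
  conditional MLE is available where that matters.
* Ward clustering of `1 - r²` treats the LD matrix as a distance,
  which is standard but not metric; the complete-linkage mode is the
  conservative alternative when a hard within-cluster r² guarantee is
  needed.
* The pipeline is two-group and single-trait: no multi-factor
  expression designs, no fixed/random-effects meta-analysis across
  cohorts, no colocalization or fine-mapping.
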