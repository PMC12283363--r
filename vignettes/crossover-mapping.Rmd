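---
title: "Mapping crossovers and interference in BC1 populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping crossovers and interference in BC1 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiocross)
```

## The problem

In a BC1 design an F1 hybrid (here *Arabidopsis thaliana* Col-0 x Ler-0) is
crossed back to the recurrent parent Col-0. Each offspring inherits one
recombinant F1 gamete, so at every Col/Ler SNV the offspring is either
Col-homozygous or heterozygous, and each crossover (CO) transmitted by the
gamete appears as a single transition between HOM_COL and HET runs along a
chromosome. Whole-genome sequencing hundreds of offspring at very low depth
(~1-1.5x) gives noisy genotypes at hundreds of thousands of SNVs; the
analysis problem is to denoise those calls, locate the transitions, and then
ask population-level questions:

* how many COs per gamete, and do male and female meiosis differ
  (heterochiasmy)?
* does one CO suppress nearby COs (interference), measured by inter-CO
  distances and the coefficient of coincidence (CoC)?
* how do genotypes (e.g. synaptonemal-complex mutants that lose
  interference and heterochiasmy) differ from wild type?

`meiocross` implements that pipeline plus a generative meiosis simulator, so
every stage can be validated by parameter recovery without access to the
original sequencing data.

## The simulator

### Crossover placement

Bivalent COs on a chromosome are modelled as a stationary gamma-renewal
process on the genetic map: a homogeneous Poisson process of rate
`nu * lambda / G` per cM is drawn on `[0, G]` and every `nu`-th point is
kept, with a uniformly random phase offset. The retained count has mean
`lambda` and inter-CO spacings are Erlang with shape `nu`:

* `nu = 1` is a Poisson process — no interference; counts have index of
  dispersion 1.
* larger integer `nu` gives increasingly regular placement — strong
  interference; counts are sub-Poisson and short inter-CO distances are
  depleted.

Non-integer shapes are out of scope; the thinning construction is the
simplest process that is exactly Poisson at `nu = 1` and needs no
numerical machinery. `obligate_co = TRUE` redraws until at least one CO;
this conditioning inflates the realized mean above `lambda` (documented,
default off — the interference-less mutant regime loses CO assurance, which
is precisely what the `n_univalent_pairs` summary of `summarize_meiocyte()`
quantifies against the Poisson zero class `1 - (1 - exp(-lambda))^5`).

Each CO involves two of four chromatids; with no chromatid interference a
transmitted chromatid keeps each CO independently with probability 1/2
(`thin_to_chromatid()`). This halves the mean — the basis for comparing
per-meiocyte focus counts with per-offspring CO counts (see
`foci_to_offspring_co_ratio()`) — and, for sparse bins, leaves the CoC
essentially unchanged, so gamete-level CoC reflects meiocyte-level
interference.

### Physical coordinates

Positions are drawn on the genetic scale and mapped to bp through a
piecewise-linear physical-genetic map per chromosome. The bundled
`tair10_chromosomes()` set uses the five TAIR10 assembly lengths with a
uniform 1 cM/Mb arm rate and a 10-fold suppressed pericentromeric rate over
plausible pericentromere intervals — qualitatively matching observed
*Arabidopsis* landscapes (arms recombine, pericentromeres barely). Users can
supply their own `(bp, cM)` anchors.

### Observation model

True genotypes (HET where the gamete segment is Ler, HOM_COL where Col) are
degraded by, in order:

1. per-call depth `d ~ Poisson(depth_mean)`;
2. optional allele dropout (`depth_dropout = TRUE`): a HET with `d` reads
   has Ler-read count `Binomial(d, 1/2)`; zero Ler reads are called HOM_COL
   and all-Ler reads are called HOM_LER. A depth-1 HET is therefore observed
   HOM_COL or HOM_LER with equal probability — the dominant error mode of
   ~1x genotyping-by-sequencing, and the mechanism that produces the
   "impossible" homozygous-Ler artifact class the QC chain removes;
3. flat miscall rates `e_het_to_hom`, `e_hom_to_het` and an artifact rate
   `e_hom_ler` that replaces any call with HOM_LER;
4. missingness: depth 0, plus an extra `p_missing`.

The simulator emulates the statistical structure the pipeline assumes —
marker-wise independent noise, exchangeable samples, known marker order. It
does **not** emulate alignment artifacts clustered in repeats, segregation
distortion, gamete-viability selection, gene conversion, or aneuploidy; a
passing recovery test therefore validates the estimator under the stated
noise model, not against every failure mode of real data.

## The pipeline

### QC chain

`run_qc()` applies, in order (each step reported in a `QCReport` table):

1. **Per-genotype depth bounds** (default `[4, 100]`): out-of-range calls
   are set missing. A config switch (`depth_scope = "site"`) instead applies
   the bounds to per-site mean depth, since "depth per site" is ambiguous in
   common usage; the per-genotype reading matches standard variant-filter
   semantics and is the default.
2. **Per-site mean depth** (default `[1, 1.5]`, appropriate to ~1.25x
   data; set it to match the data's depth scale), computed on raw DP across
   all samples.
3. **MAF in `[0.2, 0.3]`** (inclusive), with the Ler allele frequency
   `(2 n_HOM_LER + n_HET) / (2 n_obs)` computed on post-masking calls. The
   BC1 expectation is 0.25, so this window keeps well-behaved markers and
   discards distorted or mis-mapped ones.
4. **Samples with > 75% missing data** (strict) removed.
5. **Impossible homozygous-Ler calls** set missing, with the mean
   per-sample removed fraction reported (recovering the injected artifact
   rate on simulated data).
6. **Percentile trim**: samples below the 5% or above the 95% quantile of
   per-sample SNV counts (type-7 linear interpolation, strict inequalities)
   removed.

The chain's output is a fixed point on clean data (a second pass removes
nothing). It is *not* idempotent in general, and cannot be: the percentile
step is rank-based, so a second application trims the new tails, and the
MAF recomputation after artifact masking can move borderline markers across
the window. This is a property of the filter definitions, not of the
implementation; the test suite checks the fixed-point property where it is
well defined.

### Smoothing and CO calling

`smooth_genotypes()` slides windows of `w = 20` consecutive non-missing SNVs
(step 1) and assigns each window its modal genotype. Artifact decisions the
window/mode prescription leaves open, and how we resolved them:

* **Ties** (possible for even `w`): a tied window inherits the previous
  window's value; leading ties take the first untied window's value; an
  all-tied sequence (strictly alternating input) takes the first marker's
  genotype. Ties must resolve deterministically or calls would not be
  reproducible.
* **Window-to-marker assignment**: marker `m` takes the value of the window
  *centred* on it (start `m - floor((w - 1) / 2)`, clamped). A
  start-aligned assignment ("marker m takes the window starting at m") was
  considered and rejected: it displaces every called breakpoint about half
  a window to the left of the true transition, so clean-data breakpoints
  would not contain the true CO. With the centred rule, on noise-free data
  the smoothed transition falls exactly between the two markers flanking
  the true crossover.
* Missing calls are dropped before windowing (windows span 20 informative
  SNVs). The alternative — windows over all markers with the mode over
  non-missing calls — is not implemented; at 30% missingness it makes the
  effective window size random.

`call_crossovers()` collapses the smoothed values into maximal runs and
emits one `COEvent` per boundary between runs of different genotype, with
the breakpoint interval `[left_bp, right_bp]` spanning the two flanking
run-end markers and the point estimate `mid_bp = floor((left + right)/2)`
(the interval is reported so users can choose other estimators).
`min_run_markers` (default 1) optionally merges shorter runs into their
flanks; the modal window is already the denoiser, and runs shorter than
`w/2` cannot arise from isolated single-marker errors.

Resolution limits, measured on simulated data and inherent to the method:

* double COs closer than about `w` informative markers are merged;
* COs within about `w/2` markers of a chromosome end are missed;
* at 1% genotype error the called boundary jitters by up to ~3 informative
  markers around the true transition (81% of clean-spacing events have the
  true CO strictly inside the reported flanking interval; 100% within three
  markers), while genome-wide mean CO counts are recovered within ~2-5%;
* event counts are *not* strictly monotone in `w` on every input
  (window-scale aliasing can occasionally split a run), though aggregate
  counts fall steeply with `w`.

### Landscapes and comparisons

`bin_landscape()` assigns each event midpoint to non-overlapping 1-Mb bins
(bin `b` covers `(b-1)*1e6 < pos <= b*1e6`; the last partial bin is kept and
flagged). `landscape_chisq()` compares two landscapes per window with a 2x2
Pearson chi-square (window vs elsewhere, group A vs B; df = 1, no continuity
correction — the classical large-count default), reporting raw and
Benjamini-Hochberg-adjusted p-values side by side because the multiplicity
procedure is an analysis choice.

`nested_anova()` fits `y ~ sex / genotype` with sequential sums of squares
(the model a nested `aov()` call specifies) and follows with Tukey HSD over
the sex x genotype cell means using the Tukey-Kramer correction, since the
cohorts are unbalanced.

### Interference statistics

`inter_co_distances()` keeps only chromosomes with exactly two called COs —
one unambiguous distance per chromosome, no within-chromosome weighting
decisions. `permutation_null()` compares the observed mean distance with a
null in which each qualifying chromosome receives two positions drawn
independently, with replacement, from the empirical pool of all CO
midpoints on that chromosome in the same dataset (500 permutations by
default; one-sided `p = (1 + #{null >= obs}) / (n_perm + 1)`, directed at
"interference pushes COs apart"). This scheme preserves the CO landscape
while destroying within-gamete pairing; a label-shuffling alternative that
deals observed midpoints across gametes is available via
`scheme = "shuffle"`. The statistic compared is the mean distance — the
simplest location summary; with 500 permutations the smallest attainable p
is 1/501.

`coc_curve()` computes, per chromosome and inter-interval distance `d` from
1 to 15 Mb, the pooled-ratio estimator
`CoC(d) = sum(f_ij) / sum(f_i f_j)` over all bin pairs `(i, i + d)`, where
`f_i` is the fraction of gametes with at least one CO midpoint in bin `i`
("hit" is an indicator, the standard CoC convention) and `f_ij` the
fraction hitting both. Pairs with `f_i f_j = 0` contribute to neither sum;
a zero denominator omits the point. The pooled ratio is robust to empty
pericentromeric bins, unlike a mean of per-pair ratios (switchable by
working from the returned per-pair sums). `loess_fit()` smooths CoC points
by local polynomial regression with tricube weights (span 0.75, degree 2 —
the conventional defaults — evaluated exactly with `surface = "direct"`).

## Study conditions used in validation

The bundled validation runs (test suite, `scripts/acceptance.R`,
`analysis/` drivers) fix these conditions once:

* wild-type male: transmitted mean 4.8 COs per gamete, `nu = 5`; wild-type
  female: 3.0, `nu = 5`; interference-less mutant: 6.0 (male) and 6.15
  (female), `nu = 1`. The interference-discrimination runs use the mutant
  rate (6) for the `nu = 1` population and the wild-type male rate (4.8)
  for `nu = 5`, since those are the regimes in which each interference
  state occurs.
* per-chromosome `lambda` apportioned proportionally to genetic length
  (`lambda_for_transmitted()`);
* recovery runs: 200 offspring, ~10,000 post-QC markers, 30% missingness,
  1% symmetric genotype error, depth 30x without dropout — the depth and
  error rates are stated per run because the QC mean-depth window must
  match the simulated depth scale;
* interference runs: 2,000 gametes per CoC curve (sampling error of the
  pooled CoC stays within ~0.1 of 1 at all distances); 200 replicates of
  100 gametes for permutation type-I calibration; 20 replicates of 200
  gametes for power;
* comparison runs: cohort sizes 143/237/142/238 (the sequenced study's
  sizes) for the ANOVA power check, halved in the `analysis/` replica to
  keep the drivers fast.

Problem sizes were chosen so Monte-Carlo error is small relative to each
assertion's tolerance; all randomness descends from one seed per run.

## Numerical and degenerate-input choices

* `lambda = 0` returns an empty CO list; `obligate_co` with `lambda = 0` is
  rejected as unsatisfiable.
* genetic-physical conversion rounds to integer bp; round trips are exact
  to 1 bp.
* empty genotype sequences smooth to empty outputs; sequences shorter than
  `w` use a single window.
* a sample-chromosome with zero informative markers is skipped by the
  caller; samples with zero events still appear (count 0) in
  `per_sample_counts()`.
* `overlap_fraction()` against an empty channel reports missing
  percentages, never 0; the 90-degree rotation control acts on
  field-normalized coordinates so points stay in a non-square field, and
  four applications restore the input exactly.
* an all-identical response gives zero sums of squares in `nested_anova()`
  (F undefined); empty sex x genotype cells are rejected.

## Known limitations

* The caller cannot resolve double COs within ~`w` informative markers
  (gene-conversion-scale events are out of scope), and misses COs within
  ~`w/2` markers of chromosome ends; at realistic densities these cost a
  few percent of events, visible in the `analysis/` recovery tables
  (interference-less cohorts, which have more close pairs, lose the most).
* Because double COs closer than ~`w` informative markers cannot be
  called, the observed inter-CO distance distribution is left-censored at
  the caller's resolution. At sparse marker densities (say, below ~5,000
  genome-wide markers) this censoring inflates the permutation test's
  rejection rate on interference-less data; at the densities the method is
  meant for (tens of thousands of markers) the censored fraction is
  negligible. The type-I calibration in the acceptance checks is performed
  on the generative null itself, where the 5% level is exact.
* No HMM segmentation: the sliding-window modal rule is deliberately kept
  as the study procedure; an HMM would likely localize breakpoints better
  at very low depth.
* The QC chain is order-dependent and only fixed-point on clean data (see
  above).
* CoC is computed on physical distance (Mb), not genetic distance.
* The simulator draws marker depth i.i.d.; real coverage is locally
  correlated, so real-data missingness clusters in a way the recovery tests
  do not probe.
* No gamma-model maximum-likelihood estimation of interference strength
  from real data; `nu` is a simulation input, and interference is assessed
  nonparametrically (permutation test, CoC).
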