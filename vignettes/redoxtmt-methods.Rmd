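---
title: "Quantifying site-specific cysteine oxidation from sequential iodoTMT data"
author: "redoxtmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying site-specific cysteine oxidation from sequential iodoTMT data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Sequential iodoTMT labelling quantifies the redox state of individual
cysteine thiols. Free thiols are blocked with a first iodoacetyl isobaric
tag (the **SH** channel); reversibly oxidized thiols are then reduced and
labelled with a second tag (the **Sox** channel). After multiplexing and
LC-MS/MS, each Cys peptide yields one reporter intensity per channel, and
every biological sample contributes one SH and one Sox channel. The core
statistic is the per-site, per-sample oxidation level

$$\mathrm{ox} \,(\%) = \frac{\mathrm{Sox}}{\mathrm{SH} + \mathrm{Sox}} \times 100,$$

the fraction of a site's thiols that carried a reversible modification
(disulfide, S-glutathionylation, sulfenylation, nitrosylation, ...) at
lysis. The quantified unit is the *unique Cys peptide*, keyed by protein
accession and the sorted 1-based coordinates of its cysteines
(`"P04406:Cys152"`); PSM-level rows quantifying the same key are summed,
the usual reporter-ion roll-up, which is monotone in spectral evidence.

```{r, eval = FALSE}
library(redoxtmt)
sim <- simulate_redox_experiment(synthetic_redox_config(seed = 1))
ox <- sim$reporter |>
  normalize_channels(sim$design) |>
  compute_oxidation(sim$design)
```

## Normalization

Channels are normalized per **label class** within each **plex run**: for
every channel, the median of its log2-transformed non-zero intensities is
shifted additively (a multiplicative correction on the linear scale) to
the mean of the medians of its class, SH channels against SH channels and
Sox against Sox. Two properties motivate this:

* SH and Sox channels have systematically different intensity scales (a
  mostly reduced proteome puts far less signal into Sox), so a global
  median alignment would erase the biology; per-class alignment only
  removes labelling-efficiency and loading differences *between samples*.
* Channel medians are only comparable within one multiplexed run. Across
  runs, comparability comes from shared bridging conditions in the
  experimental design, which are reported, not re-corrected.

Three facts about this normalization are worth stating precisely, because
they shape the tests:

1. It cancels exactly any set of per-channel multiplicative biases whose
   log2 values are mean-centered within a label class. The class-mean
   component of a bias vector is **not identifiable** from reporter data —
   it is indistinguishable from a genuinely different global SH or Sox
   label recovery — and correspondingly the synthetic generator plants
   only the identifiable, class-centered component.
2. It is exactly neutral under a global intensity rescale, and it pins
   every channel's post-normalization log2 median to its class target
   (both are tested invariants). It is *not* invariant to rescaling a
   single channel in isolation: the class target tracks the data, so a
   lone biased channel also drags its class's target by `b/n`. This is an
   intrinsic property of median-to-class-mean alignment, not an
   implementation artifact.
3. With heterogeneous oxidation across peptides it is not perfectly
   composition-neutral even at zero noise (medians of
   `log2 A + log2 ox` do not separate), leaving a small residual
   distortion of roughly a quarter percentage point under the default
   generator; with homogeneous composition the noise-free pipeline is
   exact to machine precision. Both regimes are tested.

## Zeros and missingness

Zero reporter intensities encode "not observed". Zeros are excluded from
normalization medians (a location estimate should not be dragged by
missingness), remain zero through normalization, and control how
oxidation values become missing. By default a pair with *either* channel
zero yields `NA` (`strict_pair_na = TRUE`): an unobserved reporter ion is
evidence of detection failure, not of a fully reduced or fully oxidized
site, and under channel-level dropout treating it as an exact 0 % or
100 % injects extreme artifact values into replicate means and variances
— on default synthetic data this single choice is the difference between
a ~0.7-point and a ~5-point recovery error. The alternative convention —
only a zero SH + Sox sum is missing, a single zero gives the exact
boundary value 0 % or 100 % — keeps fully reduced/oxidized sites
representable and is available as `strict_pair_na = FALSE`; it is the
right choice when zeros are believed to be true absence of the labelled
form rather than dropout.

Sparse designs are filtered with `filter_min_valid()`: at least
`min_valid` non-missing oxidation values, counted within every condition
(`per_condition`) or across all samples (`overall`). The patient-style
"at least one of three quantitative values" filter is `min_valid = 1`
per condition.

## Differential oxidation

Per site, conditions are compared with the classic equal-variance
two-sided Student's t-test (a Welch option exists but is off by default,
following the field's convention for balanced replicate designs). Sites
with fewer than two values in a group are undefined, not errors. When
both groups have zero variance the statistic is defined as `t = 0, p = 1`
for equal means — this keeps saturated 0 %/100 % sites from producing
spurious infinities — and as a signed infinity with `p = 0` otherwise.

Multiple testing is controlled with a permutation-based FDR in the
Perseus style. The null pool collects |t| recomputed under balanced
relabelings of the samples of the two compared groups; with
`choose(n, n_A)` small the enumeration is exhaustive, otherwise
assignments are sampled uniformly under the run's seed. The observed
assignment and, for equal group sizes, its complement are **excluded**
from the null: they reproduce the observed statistics rather than draws
from the null, and for a 3 vs 3 design their inclusion caps every
attainable q-value at exactly the 0.1 threshold (each site's own |t|
appears twice among 20 assignments), making FDR-level discovery
structurally impossible. For each site

$$q = \frac{\text{mean over permutations of } \#\{|t|_{null} \ge |t|\}}
          {\#\{|t|_{obs} \ge |t|\}},$$

clipped to [0, 1] and made monotone non-increasing in |t|. An
independent brute-force enumerator reproduces these q-values exactly in
the test suite.

A site is *called* by a dual criterion: the oxidation change must exceed
`delta_min = 5` percentage points in magnitude, and the significance
criterion must hold — primarily `q < 0.1`, falling back (once per
comparison, not per site) to `p < 0.05` when no site passes the primary
rule. The active criterion is recorded in the result
(`glance()$criterion_used`). At 3 vs 3 the exhaustive null has only 18
informative relabelings, so q-values are coarse and whole comparisons
legitimately fall back; with more replicates the primary criterion
dominates.

## Annotation and the P-SSG index

`map_sites_to_annotations()` joins quantified sites to RedoxDB-style
annotation tables by exact accession and 1-based position; peptides
spanning several cysteines match if any position matches (the permissive
reconciliation between peptide-level quantification and site-level
annotation), and the matched position is recorded. The same operation
serves domain tables (zinc fingers etc.). The global
S-glutathionylation index (`pssg_index()`) aggregates oxidation over
S-glutathionylation-annotated sites per sample; both the median and the
mean are reported, because which aggregate best summarizes "global
P-SSG" is a reporting choice, not a fixed convention — with few
annotated sites the median is robust, the mean more sensitive.

## Oxidation-profile clustering

Sites are clustered on their mean-oxidation profiles across conditions
or datasets with agglomerative hierarchical clustering, average linkage
on Euclidean distances, cut to exactly `k` clusters (default `k = 10`).
Rows with missing entries are dropped and reported; rows are sorted by
site key first, so the result is independent of input order. Optional
per-row z-scoring (`standardize = TRUE`) clusters profile *shape* rather
than absolute level. Linkage and metric are configuration parameters
with these defaults, since profile-heatmap practice varies.

Clusters with similar profiles are merged into lettered groups by
single-linkage on centroid Pearson correlation at a threshold (default
0.8): connected components of the threshold graph become groups A, B,
C, ... in decreasing size order. Single linkage guarantees that raising
the threshold never merges groups, and is computed by cutting the
single-linkage tree of `1 - r` at height `1 - threshold`. The lettered
grouping automates what is usually a visual judgement on the heatmap;
the threshold is exposed rather than claimed to reproduce any particular
manual grouping.

## The protein-abundance track

The quantitative 16-plex track mirrors standard isobaric practice:
zeros to `NA`, log2 transform (with a flag for exports already on log2
scale), a valid-value filter of at least 9 non-missing values across all
16 channels (counted across all channels, not per group, since the
filter precedes any comparison), and per-channel median centering to the
grand mean of channel medians — which removes additive per-channel log2
bias exactly and leaves group log2 differences invariant. Differential
abundance reuses the same t-test and permutation FDR; a protein is
significant at `q < 0.1` with no minimum fold-change.

## The synthetic generator

`simulate_redox_experiment()` emulates the statistical structure of a
sequential iodoTMT experiment: per peptide and sample a log-normal total
abundance `A = 2^N(20, 2)` is split into Sox `= A·ox·ε` and SH
`= A·(1−ox)·ε'` with independent log-normal noise of mean 1 and CV
`replicate_cv` (default 0.10, matching the 7–12 % replicate CVs typical
of these experiments); channels carry multiplicative biases
`2^N(0, 0.3)` mean-centered per label class (see above); cells drop out
independently at `missing_rate = 0.05`. Baseline oxidation is drawn from
a mixture of Beta(1.2, 10) with a 5 % Beta(5, 1.5) high-oxidation tail,
the right-skewed shape of cellular redox proteomes (mostly reduced, a
small nearly-fully-oxidized population); a 5 % fraction of peptides
carries a planted +15-point shift in the last condition, clipped to
[0, 100]. Defaults give two conditions of three biological replicates,
2,000 peptides — desk-scale versions of the study conditions the
pipeline targets. Random draws are consumed in a fixed order independent
of parameter values, so paired configs (for instance bias on/off at one
seed) share every other random component.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: co-isolation interference and
ratio compression, intensity-dependent (MNAR) missingness, peptide
misidentification, shared peptides across proteins, retention-time or
batch drift, and any correlation structure between peptides of one
protein. `simulate_abundance_experiment()` analogously plants log2
fold-changes (default |log2FC| = 1 on 5 % of 3,000 proteins, noise sd
0.25, 8 vs 8 channels) with additive channel biases and dropout.

## Numerical choices

* Normalization is computed on log2 scale and applied as an exact
  multiplicative correction; oxidation values are clamped to [0, 100]
  to absorb one-ulp float spill when one channel is denormal-small.
* Quartiles use R's default (type 7) quantile; distribution interval
  bins are right-open with the final bin closed, so edges
  `c(0, 50, 100)` count `[0, 50)` and `[50, 100]`.
* CV uses the sample (n−1) standard deviation and is undefined (NA) with
  fewer than two values or a zero mean.
* Cluster ids are deterministic given the sorted site keys; group
  letters break size ties by smallest member cluster id.
* Fisher's LSD uses the pooled within-group mean square with unprotected
  pairwise t-tests; groups with fewer than two values are excluded with
  a warning.

## Scale of the built-in checks

The test suite and the acceptance script run entirely on synthetic data:
oxidation recovery and CV realism at 2,000 peptides; type-I error and
null q-rates at 10,000 sites over 10 seeds; FDR control and power at
2,000 sites (5 % planted +15-point shifts) over 10 seeds; the
permutation oracle at 50 sites, 3 vs 3; clustering recovery at 200 sites
in 4 planted archetypes; the abundance track at 3,000 proteins, 8 vs 8.
These sizes make the whole suite run in well under a minute while
keeping Monte-Carlo error comfortably inside the asserted bounds.

## Limitations

Protein-level roll-up of oxidation, isotopic impurity correction,
imputation, moderated variance estimators, and identification-level FDR
are out of scope: the pipeline starts from a search engine's peptide
export and quantifies, tests and annotates at the Cys-site level. The
permutation FDR at three replicates per group is coarse by construction;
interpret `criterion_used` accordingly.
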