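---
title: "Quantifying longitudinal microbiome stability with microdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying longitudinal microbiome stability with microdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

## The analytical problem

Longitudinal microbiome studies sample the same subjects repeatedly —
here, cohorts of toddlers, adolescents and adults followed across ten
visits — and ask how much each subject's community reorganizes between
visits, whether volatility differs between age groups, and whether
developmental events (weaning, menarche) leave a compositional mark. The
data unit is a samples × features contingency table of counts (ASVs for
taxonomic composition, protein-family annotations for function) plus
per-sample metadata (subject, group, time point, optional event side).
`microdyn` implements three complementary stability measures and the
nonparametric testing machinery around them.

## Models and procedures

### Taylor's power law

For one subject, each feature's relative abundance has a temporal mean
$\mu_i$ and temporal standard deviation $\sigma_i$ (denominator $n-1$,
over at least three time points). Communities in which fluctuation scales
with abundance follow

$$\sigma_i = V \,\mu_i^{\beta},$$

estimated by ordinary least squares of $\log_{10}\sigma$ on
$\log_{10}\mu$. $V$ (dimensionless, since both axes are relative
abundances) is the dispersion a hypothetical feature of abundance 1 would
attain — the community-level volatility amplitude. $\beta$ is the scale
index: $1/2$ is the Poisson-like regime, $1$ the exponential-like regime.
Features with $\mu_i = 0$ or $\sigma_i = 0$ carry no information on the
log–log line and are excluded (their count is reported); the fit refuses
to run below `min_features` (default 20) usable features. Standard errors
come from the OLS fit; the error of $V$ uses the delta method on
$10^{\text{intercept}}$. The regression is unweighted — no weighting
scheme is part of the model, and adding one would change the meaning of
$V$ silently.

The fitted slope is invariant to the logarithm base and $V$ transforms
consistently; the test suite checks this identity explicitly. The law is
stated on the SD, not the variance: that is what makes $\beta = 1/2$
correspond to Poisson-like counts on the relative-abundance scale.

Subjects are compared in a standardized parameter space: with a declared
reference group (adults by default), $z_V = (V - \bar V_{\rm ref}) /
s_{V,\rm ref}$ and likewise $z_\beta$, so reference subjects have mean 0
and SD 1 on both axes. Coverage regions at 68% and 98% are
bivariate-normal confidence ellipses at the $\chi^2_2$ quantile of the
requested coverage, built from the reference mean and covariance. Such
regions are often drawn as circles; we deliberately fit ellipses, because
the empirical $(z_V, z_\beta)$ cloud has a covariance and a circle only
covers the nominal fraction when that covariance is isotropic.

### Rank stability index

At each time point the unit's features are ranked by decreasing abundance
(rank 1 = most abundant). A feature's total rank hops are
$D = \sum_k |r_{k+1} - r_k|$, and

$$\mathrm{RSI} = \left(1 - \frac{D}{(N-1)(t-1)}\right)^{p},$$

with $N$ ranked features and $t$ time samples: exactly 1 for a feature
whose rank never changes, exactly 0 for one oscillating between the
extreme ranks — $(N-1)(t-1)$ is precisely the hop count of that extreme
trajectory, which fixes the reading of $D$ as summed absolute consecutive
rank changes. $D$ is symmetric under time reversal, and RSI is monotone
non-increasing in $D$.

Numerical choices that the formula leaves open:

* **Tie-breaking.** Ties (including all-zero time points) are broken by
  ascending feature identifier — fully deterministic, so a series always
  yields the same rank matrix.
* **Feature space per unit.** Features never observed in a scope unit
  carry no dynamics and are excluded from that unit's ranking (reported
  `NA`); features observed at least once are ranked at every time point,
  zeros tying at the bottom.
* **Scope.** Whether stability should be scored per subject or per age
  group (pooling samples by mean relative abundance per time point) is
  genuinely ambiguous; both are provided (`scope = "subject"` /
  `"group"`).
* **Exponent.** $p$ (default 1) is exposed as a parameter; it sharpens
  ($p > 1$) or flattens ($p < 1$) the index without changing its order.

Group comparison uses a PERMANOVA on Euclidean distances between RSI
profile vectors; `stats::dist` handles the `NA`-marked features by
pairwise-complete scaling.

### Consecutive-pair Jaccard stability

For each subject and each *adjacent* pair of time points actually present,
the Jaccard similarity (shared fraction of present features; presence
means abundance strictly above a configurable threshold, default 0) gives
a local stability series. A missing time point breaks adjacency — we do
not bridge $T_1 \to T_3$ when $T_2$ is absent, since such a pair spans
twice the time and would not be comparable with true consecutive pairs.
Two test families follow, both Mann–Whitney U with BH-FDR applied within
each family: all interval pairs within each group, and all group pairs at
each interval.

### Supporting statistics

* **Alpha diversity**: Shannon in natural log (the base is a convention;
  nats are stated explicitly) and the bias-corrected Chao1
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, which stays defined with no
  doubletons; both computed through vegan. Chao1 requires integer counts
  and the package refuses relative input. Counts are not rarefied by
  default; an optional rarefy-to-minimum flag exists, and the choice is
  deliberately visible rather than silent.
* **Endpoint differences**: per-subject (last − first) changes, tested
  against zero within groups (Wilcoxon signed-rank, zeros dropped) and
  between groups (Mann–Whitney), BH-FDR across the family. A group whose
  differences are all zero is reported with `NA` rather than an error.
* **PERMANOVA**: pseudo-F from squared-distance sums
  ($SS_W$ per group, $SS_B = SS_T - SS_W$, $F = (SS_B/(a-1)) /
  (SS_W/(n-a))$), null distribution by free label permutation. The
  p-value uses the $+1$ convention, so $p \ge 1/(n_{\rm perm}+1)$ and a
  zero p-value is impossible. An exhaustive mode enumerates all $n!$
  relabelings for small $n$; the test suite verifies exact agreement with
  an independent brute-force oracle and with `vegan::adonis2`'s F. Free
  permutation is appropriate because group comparisons run on one
  aggregated row per subject (or per subject × event side); no
  repeated-measures structure remains.
* **Aggregation**: per-subject median relative profiles (midpoint
  convention at even counts). Median rows generally do not sum to 1; rows
  are re-normalized after aggregation because the downstream distances
  assume compositional rows. Event-side aggregation drops subjects
  without an event and refuses subjects observed on only one side.
* **PCoA**: Gower-centered eigendecomposition via `cmdscale`; negative
  eigenvalues of semimetrics are reported, never used for coordinates.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised, with
known truth, on data shaped like the study's: three groups of 12/13/35
subjects, ten time points, counts at a depth of 100,000 reads per sample
(the order of magnitude of typical 16S runs), a few hundred taxonomic
features projected onto a few dozen functions.

Per subject, a baseline composition is drawn log-normal (`baseline_log_sd
= 2`, giving a realistic rare tail whose presence/absence flickers at
finite depth — this is what makes Jaccard informative) and feature
abundances fluctuate independently around it with target moments
$\sigma = V\mu^\beta$. The latent distribution is a moment-matched scaled
Beta, bounded at `bound_factor = 4` times the mean-implied bound, and when
counts are drawn the multinomial sampling variance $m(1-m)/\text{depth}$
is subtracted from the latent target so the *realized* count moments match
the law. The bounded family was chosen over log-normal deliberately: with
only 10 time points, heavy-tailed latent noise makes the sample moments of
high-CV features collapse onto the $\sigma \propto \mu$ diagonal and
biases the fitted slope toward 1; the bounded family keeps the
moment-recovery regime as wide as the data permit (see Limitations).
Two degenerate mechanisms provide analytically known anchors: Poisson
counts (scale index exactly $1/2$) and exponential draws (SD equals mean,
$\beta = 1$, $V = 1$).

Group-level defaults make toddlers the volatile group ($V = 0.4$ vs 0.2,
$\beta = 0.75$ everywhere), with subject-level jitter (log-SD 0.15 on $V$,
SD 0.03 on $\beta$) so groups form clouds rather than points. Two optional
perturbations emulate the study's qualitative findings:

* **Instability window** (`log_sd = 2.5` by default): at the first time
  point of a designated interval, the designated group's baseline is
  perturbed by extra log-normal noise, lowering that interval's Jaccard
  only. The magnitude was fixed once so that the between-group test at
  the window interval detects it in well over 80% of seeds at the scaled
  test sizes, per the package's power checks.
* **Event** (`effect = 1.5`, probability 0.75, time uniform over interior
  time points; some subjects never undergo it): from the event on, the
  baseline is tempered (flattened, raising evenness and hence Shannon and
  detected richness) and mixed toward a cohort-level target profile, so
  the after-side is both more diverse and compositionally shifted in a
  consistent direction — detectable by the event PERMANOVA. Effect sizes
  have no empirical anchor and are chosen for testability.

Functional counts are the exact matrix projection of taxonomic counts
through a binary redundancy map in which every taxon has a function and
functions average `redundancy` (default 4) contributing taxa. Redundancy
is what makes functional profiles more stable than taxonomic ones: a
function's presence survives turnover among its contributors.

What the generator does **not** emulate: phylogenetic structure, primer or
extraction bias, compositional correlations between features (features
fluctuate independently before closure), autocorrelated dynamics (the
latent noise is memoryless between visits), uneven sampling schedules, and
subject dropout. Passing tests therefore demonstrate correctness of the
estimators and tests under the package's own model, not robustness to
every property of real sequencing data.

## Problem sizes and tolerances in the test suite

The checks run at deliberately scaled sizes chosen as the smallest that
make the assertions statistically stable: Taylor-recovery checks use 200
features × 10 time points (50 seeds for the mechanism anchors, ±0.05 on
the mean $\beta$); coverage of the 68% region uses 100 reference subjects
× 50 seeds (±6 percentage points); qualitative cohort checks use 12–16
subjects, 120–200 features, depth 2×10⁴–10⁵; PERMANOVA null uniformity
uses 500 replicates of 99 permutations. Exact identities (RSI bounds,
Jaccard bound, enumeration oracles) are asserted without tolerance.

## Known limitations

* **Identifiability boundary of the Taylor fit.** A nonnegative series of
  $n$ samples cannot have sample CV above $\sqrt{n-1}$ (= 3 at ten time
  points). Grid cells combining $\beta = 0.5$ with $V \ge 0.1$ at
  compositional abundances (~5×10⁻³) demand per-feature CVs of 1.4–12:
  the generating moments exist, but no 10-point series can realize them,
  and the OLS moment fit is biased toward $\beta \approx 1$ there
  regardless of the latent family. Parameter recovery is therefore
  assessed as a median across the grid, and per-subject $(V,\beta)$
  estimates in that corner of parameter space should be read as
  qualitative. Real fits at $\beta \approx 0.75{-}1$ are unaffected.
* **Exact-test discreteness.** Mann–Whitney and signed-rank p-values are
  discrete at small n; their null distribution is sub-uniform rather than
  uniform. Uniformity checks in the suite use sizes (30 per group / 50
  pairs) at which the lattice is fine enough for a KS check.
* **No blocking structure.** PERMANOVA permutes labels freely; family
  membership or other blocking factors are not modeled.
* **UniFrac and ordination-based inference** (CCA biplots, mixed models,
  volatility regressions) are out of scope; PCoA plus PERMANOVA covers
  the inferential need without a phylogeny.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(
  n_subjects = c(toddler = 6, adolescent = 6, adult = 10),
  n_features = 150, sequencing_depth = 5e4, n_functions = 40,
  instability_window = list(group = "toddler", interval = 1),
  seed = 42
)
cohort <- simulate_cohort(cfg)
fits <- standardize_params(fit_taylor_subjects(cohort$taxa, cohort$metadata), "adult")
region <- reference_region(fits, coverage = 0.98)
table(fits$group, outside = !in_region(region, fits))

series <- consecutive_stability(cohort$taxa, cohort$metadata)
stability_tests(series)$between

prof <- rsi_profile(cohort$taxa, cohort$metadata)
permanova(distance_matrix(prof$rsi, "euclidean"), prof$info$group,
          n_perm = 600, seed = 1)
```

The README shows this example with its printed output.
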