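---
title: "Mixture-deconvolution identification and differential abundance for untargeted LC-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-deconvolution identification and differential abundance for untargeted LC-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomix)
```

## The identification problem

Untargeted LC-MS profiling yields thousands of peaks characterized by m/z,
retention time and per-sample areas. Annotating a peak by mass alone means
recovering its neutral monoisotopic mass from the observed m/z under a
charge-carrier hypothesis (protonation, sodiation, potassiation,
deprotonation; charge 1 or 2) and finding the nearest entry of a
formula-mass database. The matching statistic is the signed relative mass
error in parts per million,

$$e = \frac{M_\text{obs} - M_\text{db}}{M_\text{db}} \times 10^6 .$$

A nearest-database-entry match is not an identification: in a database with
tens of thousands of formulas, a spurious peak will also have a "best"
match, just at a larger and essentially random error. `metabomix` therefore
models the best-match errors of all peaks as a two-component mixture

$$e \sim \pi_1 f_1(e) + (1 - \pi_1) f_0(e),$$

where $f_1$ is the error distribution of correct matches (Gaussian with
free location and scale, allowing for calibration bias), $f_0$ is the error
distribution of false matches, and $\pi_1$ is the fraction of peaks whose
best match is correct. The key device is empirical: $f_0$ is learned from
the *second-best* matches — the nearest database entry of a *distinct*
formula — of all peaks. For a peak sitting on a genuine database mass, the
distance to the next distinct formula follows the same nearest-neighbour
law as the best-match error of a spurious peak, so the second-best errors
form a data-driven null that requires no decoy database. Given the fitted
mixture, each peak receives a posterior probability of true identification

$$P(\text{true} \mid e) = \frac{\pi_1 f_1(e)}{\pi_1 f_1(e) + (1 - \pi_1) f_0(e)},$$

and assignments are accepted at posterior 0.8 or above. Peaks matched to
isotopic standards are identified with full confidence and bypass the
model; assignments whose formula maps to two or more database compounds
(isomers, indistinguishable by mass) are removed.

## Fitting details and numerical choices

- $f_0$ is a Gaussian kernel density over all second-best signed errors,
  bandwidth by the Sheather-Jones plug-in rule (falling back to the normal
  reference rule if that fails on degenerate samples). It is held fixed
  during fitting.
- $(\pi_1, \mu_1, \sigma_1)$ are estimated by expectation-maximization on
  the best-match signed errors, with deterministic initialization
  ($\pi_1 = 0.5$, $\mu_1 = 0$, $\sigma_1 = \mathrm{median}\,|e|$),
  convergence when the log-likelihood changes by less than $10^{-8}$, and a
  500-iteration cap. $\sigma_1$ is floored at $10^{-3}$ ppm and $f_0$ at
  $10^{-300}$ to keep the likelihood finite.
- The mixture is fitted on *all* best-match errors (standards excluded).
  The 50-ppm capture window gates assignment eligibility only. Fitting a
  windowed subsample against a full-support $f_0$ is misspecified — the EM
  would have to explain in-window false matches with only the in-window
  fraction of $f_0$'s mass — and measurably distorts $\pi_1$.
- Signed rather than absolute errors are modeled so that instrument
  calibration bias appears as a non-zero $\mu_1$ instead of a distorted
  shape. One model is fitted per (organ, ionization mode) stratum; positive
  and negative modes never share a fit.
- Nearest-match ties are broken by database order, making results
  reproducible for byte-identical inputs.

## From peaks to differential compounds

Peak tables are filtered to retention times 2-13 min and absolute heights
above 1000 counts (strict inequality), then technical triplicates are
collapsed by geometric mean. Zeros are dropped from the geometric mean and
counted: a single missed injection would otherwise zero out real signal
from the remaining two. Identified peaks are summed per compound and
sample (abundant species elute over several peaks), log2-transformed after
adding a fudge factor equal to the 10th percentile (linear-interpolation
definition) of the stratum's values — this tames fold changes driven by
near-zero areas. Contrasts use equal-variance two-sample t tests on the
transformed values (Welch and paired variants are available as sensitivity
switches), with the fold change $F_c$ computed as the ratio of raw-scale
group means. Multiple testing uses Storey q-values with the fixed-lambda
null-proportion estimate
$\hat\pi_0 = \#\{p > \lambda\}/(m(1-\lambda))$ at $\lambda = 0.5$, capped
at 1; the fixed-lambda form is chosen over the spline-smoothed estimator
for determinism and robustness at small $m$. A compound is called
significant when $q \le q^*$ *and* $\max(F_c, 1/F_c) \ge 1.2$ (a minimal
20% change); $q^*$ defaults to 0.15 for sparse tissue data and 0.05 for
plasma-scale data.

## 16S taxon comparison

Taxon tables (semicolon taxonomy paths over seven ranks, Greengenes
prefixes accepted) are normalized to per-sample relative abundances,
aggregated at a chosen rank by summing over shared path prefixes, and
compared between groups with a one-sided equal-variance t test taken in
the direction of the observed change, flagged at $p < 0.1$ and ranked by
percent change. Choosing the test direction from the observed sign is
anti-conservative; it mirrors how such screens report both increases and
decreases and should be read as a ranking device, not confirmatory
inference. Sankey edge lists decompose group-mean abundance from domain to
species, with missing ranks carried by explicit `unclassified` children so
child weights always sum to the parent weight.

## What the synthetic generator emulates

`sim_config()` fixes the study conditions: six biological and three
technical replicates per genotype arm (three biological for the plasma
configuration), biological CV 20% and technical CV 10% (multiplicative
log-normal, matching the log2 analysis scale), 60% of peaks drawn from a
real database compound with 2-ppm Gaussian mass error, the remainder
spurious at masses uniform between database entries, one compound spiked
11-fold in the knockout arm, a 10% bacterial-origin compound class
suppressed 100-fold under antibiotic treatment, and Dirichlet taxon
compositions with genus-level concentration shifts. The database holds 400
CHNOPS formulas (10% isomer collisions, 5% with isotopic standards) plus
10,000 mass-only decoy entries — the unique-formula scale of a merged
composite metabolite database over 50-1700 Da. Peaks of effect-target
compounds are always emitted so recovery is measurable at any peak count.

The generator reproduces the statistical structure the pipeline exercises,
not the physics: no chromatographic peak shapes, no isotopologue
envelopes, no adduct correlation between co-eluting features, no
retention-time information, and by default only protonated species, so
that identification errors reflect mass coincidence rather than
charge-carrier ambiguity (multi-adduct enumeration is exercised
separately). Passing tests on these data therefore demonstrate the
statistical machinery under its own assumptions; they do not certify
performance on real acquisitions, where adduct ambiguity and correlated
noise add failure modes the mass-only posterior cannot see.

## Known limitations

Two properties were measured on the synthetic conditions and are worth
stating plainly (the acceptance script recomputes both):

1. **The second-best null is anti-conservative.** A peak's second-best
   match is by construction farther than its best match. Only the truly
   identified peaks contribute nearest-neighbour-distributed second-best
   errors; false peaks contribute a second-*nearest* law that vanishes at
   zero error. The learned $f_0$ therefore under-represents the center of
   the false best-match distribution by roughly a factor $\pi_1$, and
   kernel smoothing of the central cusp compounds this. Posteriors are
   consequently overconfident: the realized false-discovery proportion
   among assignments exceeds one minus the mean assigned posterior by
   about a factor of two whenever $1 - \pi_1$ is appreciable. The ranking
   of candidates and the recovery of $\pi_1$ itself are much less
   affected. Users should read the posterior as a well-ordered score with
   an optimistic absolute scale.
2. **Fold-change precision at small n.** The ratio of arithmetic means of
   two six-sample log-normal groups at 20% CV has a relative SD near
   11.5%, so an 11-fold effect is estimated within ±20% in roughly 92% of
   replicates — a sampling-theory floor, not an implementation artifact.

Other limitations: mass-only identity cannot separate isomers (removed by
rule) or resolve near-isobaric formulas a few ppm apart; the q-value
procedure assumes a roughly uniform null p-value distribution, which
two-sample t tests on six-vs-six log-normal data satisfy only
approximately; and the one-sided taxon screen is intentionally liberal.

## A compact example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
db <- simulate_database(cfg)
design <- simulate_design(cfg)
pk <- simulate_peaks(cfg, db, design)

matches <- match_candidates(pk$peaks, db, adducts = cfg$adduct_names)
fit <- fit_error_mixture(matches)
fit
posteriors <- compute_posteriors(fit, matches)
idents <- assign_identifications(matches, posteriors)
attr(idents, "summary")
```

Problem sizes throughout the test suite and the acceptance script — 2000
peaks per identification run, 20 mixture replicates, 50 differential
replicates of 800 peaks — were chosen so each check measures the intended
quantity with Monte-Carlo error well below its tolerance.
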