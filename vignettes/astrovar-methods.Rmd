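---
title: "Differential variability and recovery profiling in small longitudinal cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential variability and recovery profiling in small longitudinal cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astrovar)
```

## The analysis problem

Short-duration perturbation studies on very small human cohorts — the
motivating case is a four-person, three-day orbital spaceflight mission
sampled at ten timepoints from 92 days before launch to 194 days after
return — pose two statistical questions that standard differential-abundance
machinery does not answer directly:

1. **Which analytes become more variable across individuals after the
   perturbation?** With four subjects there is little power for mean shifts,
   but the *spread* across crew members is itself the biological signal:
   an analyte that is tightly regulated pre-flight and erratic post-flight
   marks an individualized response.
2. **How does the molecular state recover?** Differential expression at the
   immediate post-return timepoint must be compared against later recovery
   draws to distinguish transient responses, rebounds past baseline, and
   persistent changes.

`astrovar` implements both analyses on any analyte-by-sample table (RNA
counts, protein or metabolite intensities, cytokine panels, species-level
microbiome relative abundances), plus the pathway-level readouts
(preranked gene-set enrichment and hypergeometric overrepresentation) and a
promoter accessibility–expression concordance check. A seeded synthetic
cohort generator reproduces the statistical structure the pipeline assumes,
so every stage is testable without access to controlled human data.

## Mission phases and intervals

Timepoints map to four phases: pre-flight (L-92, L-44, L-3), in-flight
(FD1–FD3), post-flight (R+1) and recovery (R+45, R+82, R+194). The
variability analysis runs on the pre-flight, post-flight and recovery
intervals; microbiome tables additionally include the FD2 and FD3
collections. R+194 belongs to the recovery phase but is excluded from the
default CV mask: the analysed recovery interval stops at R+82, while the
label stays usable for contrasts and plotting. Unicode minus signs in
timepoint labels ("L−44") are accepted as aliases of the ASCII form, since
real tables mix both.

## Abundance-standardized coefficient of variation

For each analyte and phase the raw CV is the population standard deviation
(denominator $n$) of its normalized values divided by their mean. Raw CVs
are confounded by abundance — count-like noise makes low-abundance analytes
intrinsically noisier — so CVs are standardized against a mean-abundance
reference: all records are pooled (across phases), split into approximately
100 equal-frequency bins on mean abundance, with the bin count reduced so
that no bin holds fewer than 10 records ($k = \min(100, \lfloor n/10
\rfloor)$), and each record's CV becomes a z-score against its bin:

$$z = \frac{\mathrm{CV} - \mathrm{CV}^{mean}_q}{\mathrm{CV}^{sd}_q}.$$

Numerical choices: bin statistics use the population (denominator-$n$)
standard deviation, matching the CV definition; bin assignment for new
records uses half-open intervals with the last bin closed, and records
outside the reference range clamp to the end bins (permuted recomputations
shift means slightly). A zero-spread bin yields $z = 0$ when the CV equals
the bin mean and a missing sentinel otherwise — never $\pm\infty$, and
sentinels propagate rather than silently becoming zero.

## The shuffled-label permutation test

The test statistic per analyte is $\Delta z = z_{\text{post}} -
z_{\text{pre}}$. The null distribution is built by shuffling the phase
labels among the pooled pre/post samples and repeating the *entire*
procedure — interval CVs, reference construction, standardization — on each
of `n_perm` shuffles (10,000 by default; tests and the bundled acceptance
analyses use 500, which leaves the 0.05-level granularity at 1/501).
Shuffling is global across subjects by default, with a within-subject
stratified option; the exchangeability unit is genuinely ambiguous for a
cohort of four, so both are offered and the default documented. Outputs per
analyte: observed $\Delta z$, null mean/sd, a permutation z-score, the rank
of the observed value among the null draws, and the one-sided add-one
empirical p-value $(1 + \#\{\text{null} \ge \text{obs}\})/(1 +
n_{perm})$. An exhaustive mode enumerates all label assignments when the
group sizes make that feasible, giving exact p-values on tiny designs.
Ranking analytes by the permutation z-score (ties broken by id) produces
the input for preranked enrichment.

## Recovery profiles and contrasts

The contrast registry names five profiles: FP1 (pre-flight vs R+1), RP1
(vs R+45), RP2 (vs R+82), LP1 (vs R+45 and R+82 pooled) and LP2 (vs R+82).
Only LP2's composition is fixed by the published convention; the others are
registry defaults, overridable per run. Differential testing is a
two-sided Wilcoxon rank-sum test with fold change $\log_2((\bar{x}_{comp} +
\varepsilon)/(\bar{x}_{base} + \varepsilon))$ (pseudocount 1 for counts, 0
recommended for log-scale intensities) and Benjamini–Hochberg adjustment;
DEGs require adjusted $p < 0.05$ and $|\log_2\mathrm{FC}| > 0.5$, both
strict. The rank-sum p uses exact enumeration whenever both sides are
untied and below 50 observations. This matters: a normal approximation
floors the 12-vs-4 two-sided p at roughly 0.004, and after BH correction
across 2000 analytes *no* gene could ever be called differential no matter
how large its effect — the exact floor of $2/\binom{16}{4} \approx 0.0011$
keeps genome-scale DEG calling possible at this design size, though it
still requires on the order of 45 near-floor genes before the BH cascade
admits any.

Recovery analytics follow: the fraction of a target profile's DEGs shared
with the reference profile (normalized by the *target* set, matching the
"shared with FP1 at RP1" reading; an empty target is reported as undefined,
not zero), directionality classification (reversed when the log2FC sign
flips between profiles, persistent otherwise), and unique-vs-shared
membership percentages across per-cell-type DEG sets, reported to one
decimal.

## Enrichment

Preranked enrichment uses the weighted running-sum statistic: walking the
ranked list, the sum rises by $|s_i|^w / \sum_{hits}|s|^w$ at set members
and falls by $1/(N - N_{hit})$ elsewhere; the enrichment score is the
signed extremum, and at $w = 0$ the statistic reduces to the classical
two-sample Kolmogorov–Smirnov statistic on hit/miss ranks (a property the
tests exploit as an oracle). The null permutes gene labels — draws of $k$
ids without replacement — because the ranked list is the hand-off interface
from the variability module; NES divides the observed score by the mean
|null score| of matching sign, and the p-value is the add-one tail among
matching-sign draws. The default weight is 1, with $w = 0$ exposed.
Overrepresentation analysis is the hypergeometric upper tail with
enrichment ratio observed/expected overlap, BH FDR across sets, and the
conventional reporting filter (union of the 40 lowest-FDR records and
everything under FDR 0.05). Gene sets come from user-supplied GMT files; no
collection is bundled, avoiding licensing and version drift.

## Promoter concordance

Accessibility is summed over TSS ± 500 bp windows — realized as 0-based
half-open intervals of 1001 positions, clamped at zero, symmetric and hence
strand-independent — then CPM-normalized, log2-differenced between
conditions with a pseudocount of 1, and compared across
differential-expression strata: a one-sided rank-sum test that up-DEGs gain
more promoter accessibility than down-DEGs, plus the Spearman correlation
between accessibility change and expression change. Fragment input is
either BED-like interval records or a precomputed gene-by-condition count
table; overlap means any shared base under half-open coordinates, so a
fragment abutting the window end contributes nothing.

## The synthetic cohort generator

The generator draws $x_{ist} = \exp(\mu_i + b_s + \varepsilon_{ist})$ with
analyte baselines $\mu_i \sim N(\text{meanlog}, \text{sdlog}^2)$, subject
effects $b_s \sim N(0, \sigma_{subj}^2)$ and noise variance chosen so the
abundance-scale CV is $\sqrt{1/e^{\mu_i} + \varphi}$ — count-like at low
abundance, flattening to the dispersion floor $\varphi$. One log-normal
model serves both intensity and count modalities because the CV pipeline
consumes normalized continuous values either way. Defaults: 4 subjects,
the ten-timepoint schedule, $\varphi = 0.05$, $\sigma_{subj} = 0.15$,
meanlog $= \log 100$ and sdlog $= 3$. The wide sdlog matters: analyte
abundances spanning about five orders of magnitude (typical of normalized
bulk RNA-seq) put enough analytes on the steep part of the CV law that the
raw mean–CV Spearman correlation is clearly negative (about $-0.55$ at
2000 analytes) while the standardized z is decoupled (about $0.02$); with a
narrow baseline spread most analytes sit on the flat $\varphi$ floor and the
trend drowns in CV estimation noise.

Spike-ins perturb selected analytes in one phase, multiplying the mean by
`mean_effect` and the CV by `disp_effect`. After the affected phase the
log-scale effect relaxes along a damped homeostatic trajectory: $(1 +
r)\,2^{-\Delta t/h} - r\,2^{-\Delta t/(5h)}$ for $\Delta t$ days past the
phase end, half-life $h$ and rebound coefficient $r$. With $r = 0$ this is
plain exponential return to baseline. The rebound term exists because pure
decay can never produce the directionality reversal seen between flight and
recovery profiles: a decaying effect keeps its sign, so any gene still
differential at R+45 would be classified persistent. A rebound of
comparable amplitude to the original response ($r = 1$), decaying five
times slower, reproduces the observed dynamic — recovery-timepoint DEGs
with flipped sign that fade by R+82.

One global seed expands to per-modality child seeds through a fixed
splitting rule (`seed + 7919 * modality index`, mod $2^{31}-1$), so adding a
modality never changes another's draws; identical configurations are
bitwise-reproducible.

**What the generator does not emulate:** real astronaut effect sizes or
taxa, sequencing-level counts (no library-size gradients or zero
inflation), batch structure, or correlated analyte modules. Passing tests
on this generator demonstrate that the statistics are implemented correctly
and calibrated under the model's assumptions — not that the model captures
every feature of real multi-omic data.

## Design decisions taken where the procedure was open

- **Intensity normalization.** Proteomic/metabolomic tables default to log2
  with per-sample median centering, recorded in the output's metadata
  attribute — the simplest defensible stand-in where only a package name,
  not settings, is conventionally reported.
- **Size factors.** Median-of-ratios with the median taken on the log scale
  (geometric midpoint for even reference counts) and factors rescaled to
  geometric mean 1; scaling one sample's counts by $c$ then shifts the whole
  normalized table by the shared constant $c^{1/m}$ and changes nothing
  relative.
- **Per-subject averaging.** The microbiome convention (average each
  subject's values within an interval, then CV across subjects) is exposed
  for all modalities via `averaging = "per_subject_mean"`; the default for
  non-microbiome assays is pooled, the more literal reading.
- **Permutation p convention.** One-sided with add-one smoothing and the
  $\ge$ tie convention; two-sided behaviour is available by ranking
  $|\Delta z|$.
- **Reference rebuilt per shuffle.** The quantile reference is recomputed
  inside every permutation, since the standardization is part of the
  procedure being permuted; reusing the observed reference would be faster
  but anti-conservative, and is not offered as a default.

## Problem sizes and power

The bundled analyses (tests and `scripts/acceptance.R`) run the cohort at
1000–2000 analytes with 500 permutations; at this size the null rejection
rate at $\alpha = 0.05$ lands at the theoretical $25/501 \approx 0.05$,
with seed-to-seed spread of roughly $\pm 0.01$ because all analytes share
each iteration's shuffle.

A hard limit worth knowing: with a single post-flight timepoint, the
post-phase CV is estimated from 4 values. For a 3-fold variability
spike in 100 of 2000 analytes, even a perfect classifier applied directly
to the true post-phase CVs captures only about three quarters of the spiked
analytes in the top decile of the ranking — the CV estimator's sampling
noise at $n = 4$ overlaps the null too heavily. The package's $\Delta z$
ranking, which additionally subtracts pre-phase noise, lands around half.
Detecting variability shifts reliably at this effect size needs more
post-perturbation replication than one timepoint across four subjects;
the permutation machinery is calibrated, the design is simply
information-poor for this target.

## Limitations

- The contrast registry's RP1/RP2/LP1 compositions are sensible defaults,
  not published definitions; override them when the convention differs.
- The enrichment null permutes gene labels, not sample labels; it matches
  the preranked interface but cannot capture inter-gene correlation.
- No variance-stabilizing transform, quantile normalization or batch
  correction is provided; inputs are assumed already comparable across
  samples apart from library size.
- Exact rank-sum enumeration is used below 50 per side without ties; tied
  data fall back to the midrank normal approximation with continuity
  correction, whose p floor may be too high for BH at genome scale on very
  small designs.
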