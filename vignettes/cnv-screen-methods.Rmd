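---
title: "Methods: targeted CNV screening of dosage-assay data"
author: "rctcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted CNV screening of dosage-assay data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rctcnv)
```

## The problem

Multiplex ligation-dependent probe amplification (MLPA) measures the copy
number of a panel of loci: paired probe oligos ligate on denatured genomic
DNA, are co-amplified with universal primers, and are read out as
capillary-electrophoresis peak heights whose relative intensity is
proportional to template copies. `rctcnv` implements the full analysis of
such a screen for the sixteen reverse cholesterol transport (RCT) pathway
genes (ABCA1, CETP, LCAT, the apolipoproteins, the lipases, LDLR, PLTP,
SRBI), in a cohort selected for extreme serum lipid phenotypes: peak
normalization, copy-number ratio calling, probe and sample QC, confirmation
on an orthogonal molecular-count platform, lipid phenotype classification,
and CNV–expression dosage association.

Because whole-gene CNV in these genes is rare, the pipeline's statistical
job is mostly to *not* call variation: to keep the false-positive rate of
ratio outliers very low while retaining sensitivity to true single-copy
losses, and to distinguish genuine losses from platform artifacts.

## Signal model and normalization

The raw peak height for probe $p$ in sample $s$ is modeled as

$$y_{sp} = A_s \, E_p \, \frac{c_{s,g(p)}}{2} \, b_{sp}\, e^{\varepsilon_{sp}},
\qquad \varepsilon_{sp} \sim N(0, \sigma^2),$$

where $A_s$ is a per-sample amplification factor, $E_p$ a per-probe
efficiency, $c_{s,g}$ the integer copy number of gene $g$ (2 in the diploid
state), and $b_{sp}$ a binding factor that is 0.5 when the sample is
heterozygous for a variant under the probe's ligation site and 1 otherwise.
Noise is multiplicative and lognormal: peak heights are positive and
instrument noise scales with signal.

Normalization removes the nuisance factors in two steps:

1. **Intra-sample**: divide by the geometric mean of the sample's
   reference-probe signals (loci assumed two-copy in everyone). This
   cancels $A_s$ exactly; the geometric mean is the natural location
   statistic under multiplicative noise.
2. **Inter-sample**: divide by the mean normalized signal of the
   *reference samples* — experimental samples whose normalized profile
   lies closest to the cohort mean, scored by
   $\mathrm{mean}_p |n_{sp} - \bar n_p| / \bar n_p$. This cancels $E_p$ and
   anchors the modal ratio at 1, on the assumption that the most frequent
   ratio corresponds to two copies. Ties in the score break by sample id
   so selection is invariant to row order.

The workflow is two-pass: provisional normalization, sample QC, then final
reference selection and ratios among the survivors. In the noiseless limit
the resulting ratio equals $c/2$ exactly, and rescaling any sample's whole
peak vector leaves its ratio row unchanged — both asserted to $10^{-9}$ in
the test suite.

**Reference-sample count** `k` defaults to $\max(5, \lceil 0.1 n\rceil)$
for MLPA and 34 for the count platform. The distance measure and `k` are
genuinely open choices; the mean-relative-deviation score is simple,
symmetric, and puts no weight on control probes.

**Sample QC** excludes a sample when (a) the CV of its raw reference-probe
signals exceeds 0.30, (b) its denaturation-control signal exceeds 10% of
its mean reference signal (incomplete denaturation), or (c) its
ligation-control signal falls below 10% of that level. The 0.30/10%
cut-offs are pragmatic defaults — the assay literature specifies the
failure modes but not numeric limits — and each exclusion carries its
reason code.

**Probe QC** compares each probe's cohort IQR of ratios to the median
reference-probe IQR; a target probe is flagged over-dispersed beyond 1.5×
that envelope. Replicate runs yield a per-cell standard deviation; a
flagged ratio with across-run sd below 0.05 is regarded as reproducible
and hence likely genuine.

## Copy-number calling

**Threshold calling** uses the standard MLPA interpretation cut-offs: loss
below 0.7, gain above 1.3, normal in between. A ratio *exactly on* a
cut-off (within $10^{-9}$) is classed `borderline_loss`/`borderline_gain`:
it still counts as flagged and is sent to confirmation, but it is a weaker
claim than a clear threshold crossing. This boundary class matters in
practice — a ratio of exactly 0.70 is a possible loss, not a normal call,
and downstream it is the class that confirmation most often overturns. No
multiple-testing correction is applied: the method is a fixed ratio rule,
not a per-probe hypothesis test.

**Anchored cluster calling** converts raw ratios to discrete copies where
known-copy referents exist (the multicopy control panel). A scale factor
is calibrated as the geometric mean of the anchors' ratio/(copies/2);
centers sit at $(c/2)\cdot\text{scale}$ for every integer $c$ up to 12;
samples are assigned to the nearest center on the log scale (zero copies
when the ratio falls below half the one-copy center); occupied centers are
refined by one cluster-mean pass and samples reassigned once. One pass
suffices: with well-separated 1-D centers further iterations are a fixed
point, and determinism is preserved. Anchors whose implied scales disagree
by more than 25% are rejected as contradictory. The cap at 12 copies
covers the defensin-like range the QC panel targets.

On noiseless data this assignment coincides with brute-force
nearest-integer search over copies 0–12 (tested). At $\sigma = 0.05$ the
half-copy spacing between 6 and 7 copies is only about 1.5 noise sd on
the log scale, so the *expected* recovery accuracy of a 2–7-copy panel is
about 94% — the information limit of a single noisy measurement, not an
algorithmic shortfall; the tests assert the analytically derived accuracy
band rather than an arbitrary round number, and perfect recovery in the
noiseless limit.

## Cross-platform confirmation and artifact diagnosis

Flagged MLPA calls are re-examined on an orthogonal hybridization-count
platform whose probes bind different regions of each gene. Verdicts
partition the flagged set: losses/gains seen on both platforms are
confirmed; a clear MLPA loss with a normal orthogonal ratio is
`artifact_suspected` — the signature of a ligation-site SNP that halves
the MLPA signal of heterozygotes while leaving the count probe untouched;
a borderline MLPA call with a normal orthogonal ratio is
`unconfirmed_borderline`; anything else is `discordant_unexplained`, and
missing orthogonal data yields `untested`. Sequencing of the probe's
ligation site is not simulated; its role is collapsed into the
artifact verdict, whose caveat field records the alternative explanation
(a rare small CNV under only the MLPA probe) that only sequencing or
probe redesign could exclude.

The confirmed-CNV percentage divides confirmed losses+gains by a
caller-supplied cohort size, since the two platforms typically type
different subsets; the report does not try to reconcile those
denominators.

## Lipid phenotypes and association

NCEP ATP III cut-offs classify phenotypes with inclusive bounds:
atheroprotective = HDL-C ≥ 60 and LDL-C ≤ 100 mg/dL; atherogenic =
HDL-C ≤ 40 and LDL-C ≥ 160 mg/dL; screen eligibility requires only a
single criterion (HDL-C ≤ 40 or ≥ 60; LDL-C ≤ 100 or ≥ 130). Inclusive
bounds are used throughout because the extreme-group definitions that
carry the headline group sizes are stated inclusively; samples without an
LDL measurement are `unclassified` but may still be eligible on HDL alone.

Carrier-versus-non-carrier lipid comparisons report median (IQR) per
group and a two-sided Wilcoxon rank-sum test *only* when at least three
carriers exist; below that the row is marked underpowered rather than
tested — with one or two carriers a p-value would be noise.

CNV–expression association regresses log2 expression on
$\log_2(\text{ratio})$ per gene (and per splice-variant column, mapped by
the `GENE_variant` naming convention). On this scale the slope estimates
the generative dosage coefficient directly: a one-copy loss is one log2
unit of dosage, so proportional expression gives slope 1. Regressing on
the raw ratio instead would simply rescale slopes (the design is
two-point for rare CNV: ratio 0.5 vs 1.0), and measurement noise in the
ratio attenuates slopes by a few percent — the simulation-based
unbiasedness check therefore uses the exact dosage regressor. Genes whose
ratios are constant across the cohort are reported as not assessable: no
association is estimable from a zero-variance regressor, which is the de
facto situation for most genes in a rare-CNV screen. Unadjusted p-values
are the primary surface (a fixed-threshold screen, not a discovery scan),
with a Benjamini–Hochberg column alongside.

## The synthetic cohort generator

Every stage is exercised against generated data because the real cohort
is access-controlled. The generator's defaults describe the screen's
study conditions: 320 samples, 16 genes, per-gene single-copy loss
frequency 0.003 and no gains (rare-CNV regime), ligation-site
heterozygote frequency 0.006 at the APOA4-like probe, lognormal noise
$\sigma = 0.05$ on both platforms, per-sample amplification spread 0.3
and per-probe efficiency spread 0.2 (log scale), 1% denaturation
failures, and expression with dosage slope 0 (the observed regime) and
noise 0.2 log2 units. HDL-C ~ N(45, 12) and LDL-C ~ N(125, 25) truncated
positive span both NCEP extreme strata while keeping mid-range controls;
10% of LDL values are missing; 60% of samples are HIV-positive with 70%
of those on therapy, predominantly potent regimens. The known-copy
control panel defaults to copies 2–7 at a defensin-like locus; its copy
values are user-set, not asserted as properties of any historical control
samples.

Deliberate simplifications: ligation-site heterozygosity is a fixed 0.5
binding factor (matching observed artifact ratios ~0.55) rather than a
chemistry model; denaturation failures emit control signal *and* halve
target signal so sample QC has a real failure mode to catch;
$\log_2(0/2)$ is floored at −5; fragment sizing, PCR kinetics and
sequence-level binding are not modeled. Passing tests on this generator
show the pipeline recovers the truth of its own generative model — they
cannot show robustness to real-instrument effects such as size-dependent
signal decay or batch chemistry drift, which the QC stages can only
partially absorb.

## Numerical choices and problem sizes

Boundary tolerance $10^{-9}$ defines "exactly on a threshold"; exactness
properties are asserted to the same tolerance. Stage-specific seed
offsets make each generator individually reproducible and mutually
independent; all randomness flows from one integer seed. The test suite
runs cohorts of 40–320 samples, a 120-sample control panel, and 200
replicate mini-cohorts (n = 60) for the type-I-error and slope-recovery
checks of the association stage — sizes chosen to make binomial bands
informative while keeping the suite quick. Reported ratios are printed to
two decimals in TSV output; full precision is kept internally.

## Known limitations

Single probe per gene: intragenic CNV away from the probe is invisible,
and a confirmed-loss verdict still concerns only the probed region.
Cluster calling near 7+ copies approaches the resolution limit of a
single measurement at $\sigma = 0.05$ (see above). QC cut-offs are
defaults to be tuned per laboratory. Therapy and ancestry labels are
carried as covariate outputs, not modeled.
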