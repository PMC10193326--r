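---
title: "Immune-cell deconvolution, validation and treatment effects: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-cell deconvolution, validation and treatment effects: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunomix)
```

# The problem

Bulk blood gene expression is a mixture: each gene's measured intensity is
a cell-fraction-weighted combination of that gene's expression across the
immune cell types present. Deconvolution inverts this mixture to recover
the cellular composition, giving flow-cytometry-like immunophenotyping
from stored expression data. `immunomix` implements two conceptually
different routes to that inversion, the machinery to validate either route
against matched flow cytometry, and a cohort stage that tests whether a
treatment shifted the composition.

# The SVR route: fractions from a signature matrix

The mixture model is $m = f \times B$, with $m$ the observed expression
vector over the signature genes (linear scale), $B$ the reference
signature matrix (genes $\times$ cell types, LM22 layout: 547 genes
distinguishing 22 immune subtypes in the canonical instance), and $f$ the
unknown fraction vector. Per sample:

1. **Standardization.** Genes are intersected, then $B$ is z-scored over
   all its entries and $m$ over the shared genes. This removes scale:
   multiplying a sample by any positive constant leaves $f$ unchanged,
   which matters because array intensities are only relatively
   quantitative. Whether the reference should be standardized globally or
   per column is genuinely open; we default to global (it preserves the
   relative magnitudes of cell-type profiles, which carry signal) and
   expose `scheme = "per-column"` for the alternative.
2. **Regression.** A linear $\nu$-SVR of $m^\*$ on $B^\*$ is fitted for
   each $\nu \in \{0.25, 0.5, 0.75\}$ with cost $C = 1$ (the grid and
   constant of the standard algorithm; both overridable). $\nu$ bounds the
   support-vector fraction, i.e. how many genes influence the fit, making
   the regression robust to genes that deviate from the mixture model.
3. **Projection onto the simplex.** The primal weight vector over cell
   types is clipped at zero *before* renormalization — fractions are
   physical proportions, and clipping first prevents a large negative
   weight from inflating the others. Weights are then renormalized to sum
   to exactly 1 (machine precision; the suite asserts 1e-9).
4. **Model selection.** The $\nu$ whose clipped, unnormalized
   reconstruction $B^\* w$ has the lowest RMSE against $m^\*$ wins; its
   RMSE and Pearson r are reported per sample as QC.

Linear $\nu$-SVR on fixed input is deterministic, so this module needs no
seed. Against a non-negative least squares solution of the same
standardized system (an independent oracle in the test suite), fractions
agree within 0.05 mean absolute error on noiseless full-rank mixtures —
the two estimators differ in loss, so exact equality is not expected.
Permutation p-values for deconvolution significance are deliberately
omitted; the downstream validation and cohort stages carry the inference.

# The ssGSEA route: enrichment scores with spillover compensation

The second route never inverts anything: each cell type is represented by
gene signatures, and each signature is scored in each sample by a
single-sample gene-set enrichment statistic.

**The enrichment score.** Genes are ordered by descending expression,
ties broken by the stable input gene order (microarray data rarely tie;
when more than 10% of genes do, the score is flagged because the tie rule
then matters). Walking down the list, a signature gene at position $i$
adds a hit increment proportional to $(G - i + 1)^{\alpha}$ (normalized
to sum to 1 over the signature; $\alpha = 0.25$ by default, so top ranks
are up-weighted but not dominant), and a non-signature gene subtracts
$1/(G - k)$. The score is the *integral* of this running sum over all $G$
positions rather than its maximal deviation — the integral form is
smoother in small universes and is the convention for single-sample use.
It depends on expression only through ranks, so any strictly monotone
per-sample transform (log, power, affine) leaves scores untouched; the
suite verifies this and checks every placement of a 3-gene signature in a
10-gene universe against a naive position-by-position oracle.

**Aggregation and calibration.** A cell type's raw score is the mean
enrichment score over its signatures. Raw scores are then min-shifted to
zero per cell type and optionally passed through a monotone power law
`(x + shift)^exponent / scale`. Identity is the default: published
per-platform calibration constants exist for the 64-type taxonomy but are
not reproducible from first principles here, and since the map is
strictly monotone it cannot change any rank-based downstream result —
only the numeric scale.

**Exclusion.** For whole blood, 20 cell types that live outside the
bloodstream (chondrocytes, osteoblasts, fibroblasts, ...) are removed
from the 64-type inventory before scoring, retaining 44. The exclusion is
strict by default — a misspelled name is an error, because silently
scoring an unintended cell type is worse than failing.

**Spillover.** Closely related cell types share signature genes, so a
sample rich in type $j$ inflates type $i$'s score. Compensation subtracts
a weighted share of the neighbours:
$t_i' = \max(0,\; t_i - \alpha \sum_{j \ne i} K_{ij}\, t_j)$ with
$\alpha = 0.5$ by default (the established default for this correction;
configurable, and assumed on for cohort scoring). $K$ is derived by
scoring every cell type on synthetic pure-type samples: $K_{ij}$ is the
mean score of type $i$ on pure-$j$ samples, row-scaled so the diagonal is
1 and clipped to $[0, 1]$. A near-singular $K$ is flagged — it means the
reference types are too similar to separate, and compensation cannot fix
that.

# Validation against flow cytometry

Mapped (signature, phenotype) pairs are compared by Spearman rank
correlation across shared samples. Spearman is the right tool because the
two measurement scales are incommensurate (fractions or enrichment scores
vs percent-of-parent) and only monotone association is claimed; the suite
checks that monotone transforms of either side leave every category call
unchanged.

* r uses tie-corrected (average) ranks. The p-value is the two-sided t
  approximation $t = r\sqrt{(n-2)/(1-r^2)}$; an exact full-enumeration
  permutation p is available for $n \le 7$, where enumeration is instant
  and the approximation is weakest.
* Adjustment is across exactly the tested pairs: BH FDR for
  GSE93777-style runs, Bonferroni for trial-cohort-style runs. Untestable
  pairs (missing signature or phenotype, constant vector, $n < 4$) are
  reported with a flag, never silently dropped, and stay out of the
  adjustment family.
* Each pair is assessed on a four-level scale: **strong** $(r > 0.5)$,
  **moderate** $(0.3 < r \le 0.5)$, **weak** $(r \le 0.3$ with adjusted
  $p < 0.1)$, **none** (adjusted $p > 0.1$, or any $r \le 0$). Two
  boundary decisions were open and are fixed here: the printed rule uses
  strict inequalities, so $r = 0.5$ is moderate and $r = 0.3$ is weak;
  and a negative r is "none" regardless of significance — a significantly
  *anti*-correlated signature is not a validated one.

Feeding the bundled published tables (14 SVR-method pairs, 25
ssGSEA-method pairs, with their printed r and FDR values) through this
rule reproduces the published category counts; `scripts/acceptance.R`
recomputes exactly that.

# The treatment-effect stage

For a three-arm cohort (placebo / low dose / high dose), each signature
is tested per contrast (each dose vs placebo, and both doses combined):

1. **Zero filter.** A signature whose scores are zero in more than 99% of
   samples carries no usable variation (rare cell types are often
   estimated at exactly zero) and is dropped, with the boundary strict:
   198 zeros in 200 is kept, 199 is dropped.
2. **Models.** `score ~ treated + age + gender` (placebo and F as
   reference levels) and the treatment-only model `score ~ treated`. Age
   and gender are the two demographic factors plausibly confounded with
   immune composition; comparing the two models shows when an apparent
   treatment effect is really demography (the suite constructs exactly
   such an age-confounded cohort and checks the attenuation).
3. **Adjustment and the dual rule.** P-values are adjusted across
   signatures *within* each contrast and p-type family (treatment
   coefficient, overall F-test, simple-model coefficient) — BH by
   default; the adjustment method for this stage is not externally fixed,
   and BH matches the FDR lens used everywhere else, with Bonferroni
   selectable. A signature is significant only when both the adjusted
   treatment-coefficient p and the adjusted overall-F p are below 0.1
   (strictly; the threshold statement appears both as $<$ and $\le$ in
   different places and the strict form is adopted). The F-test guards
   the conjunction: a treatment coefficient can reach $p < 0.1$ while the
   model as a whole explains nothing.
4. **Family membership.** Signatures dropped by the zero filter or
   flagged constant never enter the adjustment family; adjusting over
   tests that were never performed would only dilute the ones that were.

# What the generators emulate — and what they do not

`make_signature_matrix` produces marker-window reference profiles on a
lognormal background, with `overlap` sliding adjacent windows together to
mimic related subtypes. `make_mixtures` draws fractions from a symmetric
Dirichlet and forms $B f$ with multiplicative lognormal noise —
scale-dependent error is the realistic microarray regime, which is why
the noise is multiplicative rather than additive. `make_flow` converts
true fractions to percentages with multiplicative Gaussian measurement
noise, clipped to $[0, 100]$. `make_cohort` defaults to arm sizes
57 / 62 / 70 and 88.6% female — the realistic trial-subset demography —
with injectable per-signature arm effects and optional age/gender
dependence for confounding experiments. All generators restore the global
RNG state, and record their seed in the ground truth.

What they do **not** emulate: probe-level artefacts, batch structure,
cross-hybridization, longitudinal repopulation kinetics, or the
correlation structure of real immune repertoires (fractions of real cell
types co-vary; Dirichlet draws do not). Passing recovery tests on these
mixtures therefore demonstrates algorithmic correctness — the solver
inverts the model it assumes — not field performance on real arrays,
which is what the flow-cytometry validation stage is for.

# Numerical choices and problem sizes

Degenerate inputs fail loudly: missing values in expression are rejected
rather than imputed, a zero-variance mixture cannot be standardized, an
all-negative SVR weight vector is an error carrying diagnostics. Input
expression with a global maximum below 50 is treated as log2-scaled
(linear microarray intensities run to the thousands) — warned, and
anti-logged by default.

The test suite runs at deliberately small scale: 10-gene universes where
enrichment scores are checked against exhaustive enumeration, 40–120-gene
signature matrices with 3–5 cell types, 20–50-sample mixture panels, 200
replicate null cohorts at 60 per arm for type-I calibration, and the
full three-arm cohort at 57 / 62 / 70. These sizes make every oracle
comparison exact or exhaustive while keeping the default run fast.

# Known limitations

* Numeric parity with the published 64-type scoring tool is out of scope:
  its scores depend on internal calibration fixtures; this implementation
  reproduces the method, not the constants.
* The trial-cohort mapping table is a documented reconstruction from
  printed counts and examples, not a transcription (the full table was
  never printed); it is marked as such in its fixture.
* The SVR stage estimates relative fractions only — no absolute
  cells-per-µL mode, no batch correction, no reference construction from
  single-cell data.
* The cohort stage models a single timepoint; longitudinal or
  mixed-effects designs are out of scope.
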