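---
title: "The rhizorank selection framework: models, scoring and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rhizorank selection framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizorank)
```

# Overview

`rhizorank` turns heterogeneous PGPR phenotype assays into one comparable
score per strain. The pipeline has three stages: **quantify** (statistical
models per assay, producing adjusted performance values), **score**
(exponential single-attribute value functions mapping each value to 0–1),
and **aggregate** (weighted sums under criterion-weight scenarios, with
ranks). This vignette documents the models, the tunable parameters, the
synthetic-data generator, and the design choices made where the design was
genuinely open.

# Assay quantification

## Halo areas

Clearance and colony halos are quantified as $A = r_1 \times r_2$ from two
perpendicular radii. Lab protocols usually record *diameters*; the readers
accept `d1_cm`/`d2_cm` columns and halve them, reconciling diameter
measurement with the area formula. Areas (and concentrations) are
$\log(x+1)$-transformed before fitting — the natural logarithm, chosen
because the base is a free convention and `log1p` is the numerically stable
form; the inverse `expm1()` is applied to adjusted means before scoring, so
performance values live on the measurement scale and inherit non-negativity
from the fitted mean.

## Linear and mixed models

`fit_assay_model()` supports exactly the structures the assays need:
categorical factors with treatment coding (alphabetically first level as
reference), continuous covariates, pairwise interactions, and one optional
random intercept over the repeated-measures unit (plate or tube). The
per-assay defaults used by `estimate_performance()` are:

| assay | model | performance value |
|---|---|---|
| halo (NBRIP agar) | log1p area ~ strain × source + time | expm1 adjusted mean per strain × source |
| broth solubilization | log1p conc ~ strain × medium | expm1 adjusted mean per strain × medium |
| CAS siderophore | absorbance ~ strain | 100 × adjusted mean absorbance |
| swimming | log1p area ~ strain + time | expm1 adjusted mean per strain |
| surface spreading | log1p area ~ strain × time(h, continuous) + (1 \| plate) | expm1 adjusted mean at the mean time |
| H₂O₂ sensitivity | log1p area ~ strain + concentration(mM) | expm1 adjusted mean at the mean concentration |
| biofilm | absorbance ~ strain × condition | adjusted mean per strain × condition |
| Eco plate | OD ~ time + (1 \| plate), per strain × substrate | gated slope (OD/h) |

Mixed fits use REML profiled to a one-dimensional optimization over the
variance ratio $\lambda = \sigma_b^2/\sigma_e^2$: with indicator random
effects the marginal covariance $\sigma_e^2(I + \lambda ZZ')$ has
closed-form inverse and determinant in the group sizes (Woodbury), so each
profile evaluation costs a few vector operations. The optimizer searches
$\log\lambda \in [-15, 15]$; the lower boundary is collapsed to
$\lambda = 0$. Degrees of freedom for fixed-effect contrasts use a
Satterthwaite-style approximation — $\mathrm{df} = 2f^2/\mathrm{Var}(f)$
with $f$ the contrast variance and $\mathrm{Var}(f)$ from the inverse
curvature of the REML deviance (central finite differences) — rather than
Kenward–Roger: at this package's design sizes (3 replicates, ≤ 5 time
points) the two are practically indistinguishable, and the approximation is
disclosed here. When the curvature is not usable the residual df is the
documented fallback. The test suite cross-checks coefficients, variance
components, standard errors and df against `lme4`/`lmerTest`, and marginal
means against `emmeans`, on fixtures; those packages are oracles only, not
the implementation.

Adjusted (estimated marginal) means average the full factor grid with equal
weight — in unbalanced designs they are cell-mean averages, not raw means.
Tukey all-pairs comparisons use the studentized range (`ptukey` over the
number of means); the compact letter display is built by the
insertion–absorption algorithm over the significant-pair graph with ties
broken by level order, so letters are deterministic.

## Degradation velocities

For every strain × substrate cell, `degradation_velocities()` fits OD
against time in hours with a plate random intercept and reports the slope.
A cell counts as degradation only when the two-sided slope test is
significant at `alpha` (default 0.05, the threshold used throughout) *and*
the slope is positive — a significant negative slope is not degradation.
Everything else is gated to zero and flagged. Two numerical guards matter
here: numerically exact fits (zero residual variance) short-circuit the
REML profile, and a slope below `1e-12 × max(1, max |OD|)` is snapped to
zero so that perfectly flat noiseless series are gated rather than declared
"significant" by floating-point dust.

## Siderophore percent

The screening protocol defines percent siderophore units as 100 × the
blank-zeroed CAS absorbance. That literal rule is the default, clipped to
[0, 100] with a warning, because fidelity to the stated protocol comes
first. It conflicts with the conventional CAS formula
$(A_r - A_s)/A_r \times 100$ and can exceed 100; the conventional formula
is available via `method = "reference"`. Neither is silently "corrected".

# Utility scoring and aggregation

The exponential SAVF
$v(x) = \bigl(1 - e^{-(x - v_{\min})/\rho}\bigr)/\bigl(1 - e^{-(v_{\max} -
v_{\min})/\rho}\bigr)$ is the standard midpoint-elicited member of the
exponential family: $\rho$ is solved by bisection on the signed ratio
$(v_{\max}-v_{\min})/\rho \in [10^{-6}, 10^{6}]$ so that
$v(v_{\mathrm{mid}}) = 0.5$ to $10^{-13}$; a midpoint within $10^{-8}$ of
the interval center returns the linear limit ($\rho = \infty$) exactly.
Decreasing-preference attributes evaluate the same function at
$v_{\min} + v_{\max} - x$, keeping anchors on the measurement scale.
Performance values outside the anchor interval are **clamped** (score 0 or
1, flagged per cell): anchors are elicited bounds and extrapolating
preference beyond them is undefined.

Scenario weights are normalized criterion weights split *equally* across
each criterion's attributes (explicit per-attribute weights can be supplied
instead); totals are linear weighted sums, per-criterion weighted subtotals
are reported alongside, and ranks sort by descending total with
lexicographic strain-id tie-breaking plus an explicit tie flag —
determinism without hiding ties. Default scenarios: S1 = (0.5, 0.25, 0.25),
S2 = (0.4, 0.4, 0.2), S3 = (⅓, ⅓, ⅓). The published analysis states only
the verbal ordering of its scenario weights (its numeric table is in
unavailable supplementary material), so these are the minimal weight sets
satisfying that ordering, and they are config-overridable.

## Attribute set and criteria

The default study has 38 attributes: 8 phosphate (3 halo media + 5 broths),
siderophore, swimming, spreading, ROS sensitivity, 4 biofilm conditions and
22 Eco-plate substrates. Criterion assignment: phosphate + siderophore →
plant growth (9); motility + ROS → colonization (3); biofilm + substrates →
persistence (26). Biofilm contributes to both colonization and persistence
biologically; it is assigned to persistence because biofilm is the primary
persistence defense, and the weight machinery allows any reassignment. ROS
sensitivity is the one decreasing attribute (a smaller inhibition halo
means a more resistant strain).

Anchor defaults are declared elicitation choices, not measured facts: halo
areas use a concave function (min 0, mid 0.5, max 5 cm² — any clear halo is
already informative, extra area has diminishing value); broths are linear
on 0–80 mg/L; siderophore linear on 0–100 %; motility and biofilm linear on
0 to roughly twice a typical value; substrate velocities linear on 0–0.012
OD/h. The per-attribute scores of the published figures are graphical only,
so exact reproduction of them is not claimed anywhere in the package.

# The synthetic-data generator

`generate_full_study()` emulates the *statistical structure* the estimators
assume — Gaussian noise on the analysis scale (log1p for areas and
concentrations, raw for absorbances and OD), truncated at zero for physical
non-negativity, with random plate intercepts where the design has repeated
measures — calibrated to the published summary statistics: 48-h halo means
1.5/2.03/2.09 cm² with source multipliers proportional to the printed
per-source means; a broth matrix whose maximum is B02's 72.6 mg/L in
mannitol/ammonium; CAS absorbances 0.861/0.884/0.594; biofilm cell means
and SE-derived replicate sds (SE × √3, the only dispersion information
published); and a 31-substrate usability pattern with 17/15/13 usable
substrates and 13 unusable by all. Usable substrates get slope
0.01 OD/h scaled by strain multipliers (0.95/1.2/0.7) — the published heat
map shows clear between-strain velocity differences, and the multipliers
encode the L3-like strain's higher metabolic activity. Dispersions that are
unpublished (halo, Eco-plate, broth) are declared assumptions chosen at
realistic bench scales (log-scale sd 0.05; OD noise 0.005; plate sd
0.02–0.05).

Each assay draws from its own stream, derived from the master seed by a
stable polynomial hash of the assay id, so adding an assay never perturbs
the others and a fixed config is byte-identical on disk.

What the generator does **not** emulate: mechanistic growth kinetics
(logistic/Monod OD curves — series are linear in time), non-Gaussian error,
plate spatial effects, or measurement censoring. Passing tests therefore
show that the *estimators and the decision layer* behave correctly under
the assumed error model, not that real assay data meet those assumptions;
with real data the Levene check (`levene_check()`, Brown–Forsythe) and
residual inspection carry that burden.

# Problem sizes and runtime choices

The default study is the published design: 3 strains × 3 replicates, 31
substrates × 7 read times. Property suites use 50 random anchor sets, 200
seeded slope-recovery simulations (one Eco-plate cell each) and 200
replicate full studies for the rank-reversal frequency — sizes chosen so
the whole suite runs in a few minutes on one core while keeping Monte Carlo
error on a 95 %-frequency check below ~1.5 %.

# Known limitations

* Only one random-intercept term is supported — exactly what the assays
  need, by design; no crossed or nested random effects.
* Kenward–Roger df are not implemented; Satterthwaite is the approximation
  throughout, with residual df as fallback.
* No MCDA sensitivity analysis and no hierarchical attribute interactions:
  both are deliberately outside the framework's scope.
* Whether scoring should use response-scale (back-transformed) or
  model-scale adjusted means is an open convention; response scale is the
  default because anchors are naturally elicited in measurement units.
* The generator's unpublished dispersions are assumptions; conclusions
  about power (e.g. the 17/15/13 recovery) are conditional on them.
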