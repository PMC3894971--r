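---
title: "Estimating two-compartment NO parameters from multiple-flow FeNO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating two-compartment NO parameters from multiple-flow FeNO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feno2c)
```

## The model

Fractional exhaled nitric oxide (FeNO, in ppb) falls steeply as the
exhalation flow rate rises, because at high flow the air spends less time
picking up NO from the airway wall. The two-compartment model of NO
exchange summarizes this flow dependence with three physiologic
parameters: the alveolar NO concentration $C_A$ (ppb), the maximum airway
NO flux $J'_{aw}$ (pl/s), and the airway tissue diffusing capacity
$D_{aw}$ (pl·s$^{-1}$·ppb$^{-1}$). Its closed-form solution at constant
flow $V$ (ml/s) is

$$\mathrm{FeNO}(V) = C_{aw} + (C_A - C_{aw})\, e^{-D_{aw}/V},
  \qquad C_{aw} = J'_{aw}/D_{aw},$$

where $C_{aw}$ (ppb) is the airway wall concentration — the low-flow
plateau of FeNO — and $C_A$ is the high-flow limit. Units are fixed
throughout the package (flow ml/s, FeNO ppb, flux pl/s, diffusing
capacity pl·s$^{-1}$·ppb$^{-1}$); no unit conversion layer exists because
the whole literature this package serves uses exactly these units.

```{r}
truth <- no_params(ca_no = 2, jaw_no = 800, daw_no = 5, is_truth = TRUE)
feno_two_compartment(truth, c(30, 50, 100, 300))
```

Estimation uses a subject's maneuvers — one plateau FeNO reading per
constant-flow exhalation — collected at several target flows; the
standard design has 2 maneuvers at each of 30, 50, 100, 300 ml/s. When
the achieved flow during the plateau is recorded it is used as the
regressor; flow-subset rules (e.g. "flows above 30") always refer to the
protocol target flow, because subsets are defined by protocol, not by
how well a child hit the target.

## The estimator families

**Linear approximations (linP, linT).** Expanding $e^{-x}\approx 1-x$
(valid for $D_{aw}/V \le 0.1$) and assuming $C_A \ll C_{aw}$ gives a
straight line on either the FeNO scale against inverse flow (the "P",
Pietropaoli, formulation) or the NO output scale $V\cdot\mathrm{FeNO}$
against flow (the "T", Tsoukias, formulation). Ordinary least squares
yields $C_A$ and $J'_{aw}$; $D_{aw}$ is not estimable. The small-$C_A$
assumption is adopted so the flux coefficient is interpreted as the
maximum flux $J'_{aw}$, keeping it comparable across methods. Because
the validity condition fails at 30 ml/s for typical $D_{aw}$, the
`min_flow_exclusive = 30` variants fit only the 50/100/300 maneuvers.

**Quadratic approximations (quadP, quadT).** The second-order expansion
($D_{aw}/V \le 1/3$) needs no small-$C_A$ assumption and identifies all
three parameters. On the P scale the mean is
$\beta_0 + \beta_1/V + \beta_2/V^2$ with $\beta_0 = C_A$,
$\beta_1 = J'_{aw} - C_A D_{aw}$, $\beta_2 = -\beta_1 D_{aw}/2$; the T
scale has the same $\beta_1,\beta_2$ with the flow slope equal to $C_A$.
The inverse map ($D_{aw} = -2\beta_2/\beta_1$,
$J'_{aw} = \beta_1 + C_A D_{aw}$) is exact, and standard errors for the
derived parameters come from the delta method applied to the OLS
coefficient covariance.

**Nonlinear least squares (nonLin, nonLinLog, nonLinLogC).** The closed
form can be fit directly to all flows. On the natural scale (nonLin) the
implicit assumption is constant error variance in FeNO across flows; in
field data the FeNO error SD *decreases* strongly with flow, and FeNO at
a given flow is right-skewed. Log-transforming both sides (nonLinLog)
addresses both at once while preserving the physiologic meaning of the
parameters. Fits use Gauss–Newton (`stats::nls`), which is the standard
tool for this model family, with the quadratic estimates as starting
values (quadP for the natural scale, quadT for the log scale) and the
generic fallback start (2, 800, 10) when the quadratic start is
non-finite or has $D_{aw}\le 0$. When Gauss–Newton fails the nl2sol
(`algorithm = "port"`) solver is tried; `nonLinLogC` constrains
$C_A \ge 0.1$ ppb (the analyzer detection limit is about 0.06 ppb)
through the same solver's lower-bound support. We deliberately did not
hand-roll the optimizer: the model is smooth and three-parameter, and
the nls/nl2sol pair is both battle-tested and exactly what practitioners
fit, so estimates are comparable run for run with published analyses. A
`scaleOffset` of 1 in the convergence control makes the relative-offset
criterion well-defined on noise-free data (where the residual sum of
squares is zero), and a tolerance of `1e-9` keeps parameter recovery on
such data below the 1e-6 level. nl2sol's "false convergence" diagnostic
near an active bound is accepted as converged when the solution is
finite and feasible, since it reports the minimizer to within tolerance.
Datasets on which no solver converges are flagged and excluded from
summaries (a handful per 10,000 simulated datasets), with counts
reported.

$D_{aw}$ is never sign-constrained — only $C_A$ has a physiologic bound
imposed, matching how the constrained estimator is used in practice.

**The Hogman–Merilainen algorithm (HMA).** An iterative three-flow
method operating on mean FeNO at low/medium/high flows (here 30/100/300
ml/s, configurable). Writing $g(V) = V\,\mathrm{FeNO}(V)$ and
$f(d,V) = 1 - d/2V + d^2/6V^2$, the third-order T-formulation model is
$g(V) = C_A V + (J'_{aw} - C_A d)f(d, V)$. The iteration starts from a
linT fit to the medium/high means ($d = 0$), then alternates between
solving the cubic low-flow equation for $d$ (tracking the real root
nearest the previous iterate; smallest positive root on the first pass)
and re-solving the two medium/high equations exactly for $C_A$ and
$J'_{aw}$. A damping factor of 0.5 on the $d$ update stabilizes the
fixed point; the tolerance is $10^{-6}$ on $d$ with at most 200
iterations — tight, because each iteration is a cubic root and a 2-by-2
solve. On noise-free input from the canonical truth the algorithm
recovers (2.000, 800.1, 5.020): the residual error is pure third-order
truncation at the 30 ml/s flow, as an exact solve of the three-equation
system confirms. Noisy datasets do not always admit a stable fixed
point; those return `converged = FALSE` with no estimates rather than a
forced value, because forcing an estimate from an unstable root produces
wild $D_{aw}$ values that would dominate every summary. The standard
screening criteria (internal consistency, which guarantees $D_{aw} > 0$
and an estimable $C_{aw}$ above the low-flow plateau, and $C_A \ge 0$)
are evaluated and reported but not imposed by default: imposing them
discards datasets informatively and biases the retained estimates. HMA
reports no fit statistics or standard errors by design — it has no
explicit regression form.

**Back-diffusion corrections (Condorelli, Kerckx).** The two-compartment
model ignores axial diffusion of NO from the NO-rich airway down to the
alveolar region. The Condorelli two-step method first fits linT to the
100/300 ml/s maneuvers, then applies the trumpet-model adjustment
factors $X = 740$ ml/s and $Y = 1.7$: the flux is revised upward
($J'_{aw} \leftarrow 1.7\,J'_{aw}$) and the alveolar concentration down
($C_A \leftarrow C_A - J'_{aw}/X$). The Kerckx in-situ estimator
subtracts a back-diffusion term driven by the conventional 50 ml/s
measurement: here it is implemented as
$C_A \leftarrow C_A - 50\cdot\mathrm{FeNO}_{50}/X$, i.e. the measured NO
output at 50 ml/s scaled by the same axial-diffusion factor; this is a
reconstruction of the published estimator from its description, and is
labelled as such in the documentation. $\mathrm{FeNO}_{50}$ is the mean
of the first pair of 50 ml/s maneuvers (in maneuver order) agreeing
within 15% relative difference — the conventional repeatability rule
relaxed from 10%, appropriate for field studies in children. The
first-qualifying-pair rule is a deliberate choice where the convention
is silent; averaging all pairwise-consistent values is a noted
alternative but not the default, to keep the statistic a function of the
protocol order. Neither corrected estimator is flow-independent in
conception, and neither is directly comparable to the two-compartment
estimates; negative results are reported, never clamped.

## The synthetic-data generator

`make_scenario("main")` encodes the study conditions under which the
estimator comparison is defined: truth $C_A = 2$ ppb,
$J'_{aw} = 800$ pl/s, $D_{aw} = 5$; two maneuvers at each of 30, 50,
100, 300 ml/s; additive zero-mean normal error with per-flow SDs 3.1,
1.4, 0.8, 0.5 ppb (matching within-subject SDs estimated from field
data, hence decreasing in flow); 10,000 datasets. Sensitivity scenarios
vary the truth ($C_A = 1$ or $4$), flatten the error SD to a constant
1 ppb, or lower the first flow to 20 ml/s (SD 4 ppb). Target flows are
the design points; achieved-flow jitter is not modeled. Non-positive
FeNO draws are redrawn with the next stream draw and counted — under
every named scenario the smallest model mean (≈4.6 ppb at 300 ml/s)
sits more than 9 SDs above zero, so the counter is, in practice, always
zero, and the redraw rule exists only to keep dataset sizes fixed and
log-scale fits well-defined in pathological custom scenarios.

Randomness uses one master seed expanded into per-dataset
L'Ecuyer-CMRG substreams (`parallel::nextRNGStream`), so batches are
bit-reproducible and dataset $i$ does not depend on the batch size.

What the generator does **not** emulate: within-subject correlation of
maneuvers, between-subject parameter heterogeneity, achieved-flow
variation, skewness of the measurement error, or data generated from
richer axial-diffusion models. Passing the simulation checks therefore
demonstrates correct behavior *under the two-compartment model with
independent normal heteroscedastic errors*, not on arbitrary field data
— indeed the published comparison itself notes that normal errors
likely flatter the interval coverage relative to real data.

## The Monte Carlo study

`run_study()` applies a method list to every simulated dataset and
reports empirical bias (mean of estimate minus truth, with a 1.96-SE
normal CI of the mean — t and z are indistinguishable at $n = 10{,}000$)
and the coverage of the nominal 95% CIs (closed intervals; an endpoint
hit counts as covered). Non-converged datasets are excluded from the
affected method's summaries with counts reported. Linear methods
contribute no $D_{aw}$ rows, and methods without interval estimates
(HMA, refined) appear in the bias table only — absent, not zero.

Confidence intervals everywhere use the Student t quantile on the
residual degrees of freedom ($n-2$ for linear fits, $n-3$ otherwise)
rather than a normal quantile: with 8 maneuvers the difference is
material, and small-sample fits are the norm here. Whether the published
intervals used t or z is not stated; at these sample sizes the choice
shifts coverage by roughly 0.01–0.02, which is within the tolerance of
the reproduction checks.

Diagnostics mirror those used on field data: adjusted $R^2$ on each
method's own fitting scale (so methods with different parameter counts
are comparable), the SD of pooled within-fit-standardized residuals per
target flow (flat ≈ homoscedastic on that scale), the Shapiro–Wilk
rejection rate (≈ the test level under correct normality), and Spearman
rank correlations of estimates across methods (with Fisher-z intervals;
a simple approximation is sufficient because the correlations are used
descriptively).

## Problem sizes and reproduction

The package's test suite reruns the main scenario at 2,000 datasets —
large enough that every published bias and coverage value is checked
within Monte Carlo tolerances widened by $\sqrt{5}$, small enough to
keep the suite under about a minute — plus exact noise-free checks that
are free of Monte Carlo error altogether (the mean of an OLS estimator
over noise equals its noiseless fit, so the linear-method bias rows are
checked analytically). `scripts/acceptance.R` reruns the full
10,000-dataset study. Simulation checks of the generator's moments use
a few hundred datasets with chi-square bounds.

## Known limitations

* The HMA transcription: the third-order update and the exact algebraic
  form of the published consistency inequalities exist only in
  supplementary material of the originating literature; the
  implementation here follows the documented structure (linT start,
  third-order low-flow solve, iterative refinement) and reproduces the
  published no-criteria bias profile and Monte Carlo spread, but
  individual-dataset estimates need not match other implementations,
  and roughly 30% of main-scenario datasets have no stable fixed point
  and return no estimate.
* The Kerckx equation is a reconstruction (see above); treat its output
  as indicative.
* Estimation is per-subject; pooling across subjects (mixed models),
  weighted least squares, and formal variance-function modeling are out
  of scope.
* Coverage statements rely on asymptotic theory applied at $n = 8$;
  they transfer to real data only approximately.
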