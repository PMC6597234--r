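---
title: "Model and methods behind dipsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind dipsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipsim)
```

# What the model is

dipsim is a desk-scale hybrid simulator of diabetes in pregnancy (DIP): the
combination of gestational diabetes and pre-existing diabetes among women
giving birth. It joins three modelling styles that are usually kept apart:

* a **system-dynamics ageing chain** holds the aggregate female population
  as stocks by 5-year age band and risk group, linked by ageing and exit
  flows;
* women entering the reproductive window are **budded** out of the
  aggregate stocks and become **agents** — individually tracked women with
  continuous BMI, a latent metabolic state, and pregnancy/weight/diagnosis
  state charts;
* screening, diagnosis and treatment are **discrete events** on each
  agent's pregnancy timeline.

The purpose is policy experimentation: screening rules, diagnostic
thresholds and pre-/inter-/during-pregnancy interventions can be changed in
a configuration file and compared against a baseline run that shares the
same random streams.

# The latent metabolic model

Each woman carries a latent state $(S, B, E)$:

* **Insulin sensitivity** $S \in (0, 1]$ responds to weight and pregnancy:
  $$S = \operatorname{clamp}\!\big(s_0 \, e^{-k_{\mathrm{bmi}} \max(0,
  \mathrm{BMI} - \mathrm{BMI}_{\mathrm{ref}})} \cdot m_{\mathrm{preg}},\;
  s_{\min}, 1\big),$$
  where $m_{\mathrm{preg}} = 1 - \rho \, w/40$ ramps down linearly to
  $1-\rho$ at term ($w$ = gestational week, $\rho = 0.5$ by default):
  the physiological insulin resistance of late pregnancy. $s_0$ is an
  individual baseline.
* **Beta-cell function** $B \in [0, 1]$ erodes under sustained
  hyperglycemia and can regenerate while the damage is still recoverable.
* **Glycemic index** $G = 1/(S B)$, normalised so $G = 1$ for a fully
  sensitive, fully functional woman, capped at `g_max` as $B \to 0$. This
  is a unitless severity index, *not* a mmol/L glucose value; diagnostic
  thresholds live on the same latent scale.
* **Cumulative dysglycemia exposure** $E$ integrates the excess
  $y = \max(0, G - g_{\mathrm{thr}})$ over time:
  $$\dot E = y, \qquad
  \dot B = r_{\mathrm{regen}} (1 - B)\,\mathbb{1}[E < e_{\mathrm{rev}}]
  - k_{\mathrm{decay}}\, y \, B .$$
  The indicator implements the clinically motivated asymmetry: a woman
  whose cumulative exposure is still below the reversibility ceiling
  $e_{\mathrm{rev}}$ can rebuild beta-cell function when an intervention
  restores her glycemic control, while a woman beyond the ceiling has lost
  that capacity — so the *same* intervention is systematically less
  effective when it arrives late. This ordering is asserted by the test
  suite at both the module level and the cohort level.

Three aetiological phenotypes seed heterogeneity: a resistance-driven group
(lowered $s_0$), a secretion-driven group (lowered baseline $B$), and a
mixed group with both moderately lowered, in equal thirds by default. The
baseline distributions (0.85 ± 0.05 on the driving axis, 0.90 ± 0.04 for
mixed, 0.97 ± 0.02 otherwise) were chosen so that the bulk of the
week-26 screening-$G$ distribution sits between ~1.5 and ~3 with a
progressed tail, which is where the diagnostic thresholds operate.

Integration is explicit Euler at monthly steps ($dt = 1/12$ year). All
rates are slow relative to a month; a convergence check (halving $dt$
changes a 5-year $B$ trajectory under a fixed glycemic load by < 1%) is
part of the acceptance suite. A known limitation: for an agent inside the
runaway regime (high BMI, low $B$, regeneration switched off), the *timing*
of collapse is sensitive to the step size even though the destination is
not; trajectories there should be read qualitatively.

# BMI dynamics

BMI is continuous and changes through four channels:

1. an **age drift** spline (0.15 units/yr at 15 falling to zero around 55,
   mildly negative in old age);
2. a **calendar-anchored secular trend** `bmi_secular` (units/yr) applied
   to every living agent and to the starting BMI of later entry cohorts.
   The calendar anchoring matters: if each cohort merely repeated the same
   age trajectory, cross-sections would never change and recorded
   incidence could not trend. `bmi_secular` is one of the calibrated
   parameters;
3. **random noise** (sd 0.25 units/$\sqrt{\mathrm{yr}}$);
4. **pregnancy**: gestational weight gain of 12 ± 3 kg, of which 30% is
   retained postpartum, converted to BMI units as $\Delta\mathrm{BMI} =
   \mathrm{kg}/\mathrm{height}^2$ — a 5 kg change at 1.65 m is 1.8 units,
   within the familiar "one to two BMI units" rule of thumb.

Initial BMI is drawn by weight category (healthy / overweight / obese, WHO
cut-points at 25 and 30 with inclusive lower bounds), with category
probabilities by age group and risk group describing late-1980s prevalence
(6–18% obese depending on stratum), then uniform within the category range
(obese truncated at 45). The secular trend, not the initial table, builds
modern levels during the run. Children grow from a neonatal index of 14
toward the adult range with a constant childhood drift; babies flagged for
in-utero dysglycemia exposure carry a 1.3× drift multiplier (the
interpretation chosen for the elevated childhood weight risk — a drift,
not a setpoint shift).

# Life course and intergenerational endowment

Conception follows age-specific hazards (5-year bands, roughly two births
per woman over a reproductive life). Gestation is fixed at 40 weeks;
delivery moves the mother to POSTPARTUM for 26 weeks before she can
conceive again. Twins, pregnancy loss and preterm birth are out of scope.

At delivery the mother's mean pregnancy $G$ determines (i) the probability
of a composite adverse perinatal outcome, logistic between 5% and 45% with
midpoint at $G = 1.8$; and (ii) the baby's endowment: babies of mothers
whose mean $G$ reached the dysglycemia threshold start with 10% lower
baseline beta-cell function and the childhood drift multiplier, and a
family-history flag follows maternal impairment or prior GDM. Female
babies (49.3%) become agents for life, which is what lets long runs show
intergenerational amplification; male births are recorded as events only,
since the male population is out of scope.

A **legacy comparator** (`etiology: "risk_count"`) reproduces the
first-generation design in which DIP risk was a linear function of the
count of risk flags and a single Bernoulli draw per pregnancy, with the
latent physiology bypassed. It exists for exactly the comparison that
motivated the mechanistic redesign: the risk-count model cannot express
exposure duration or counterfactual intervention effects.

# Screening, diagnosis, treatment

Screening policy is `universal` (one OGTT at week 26) or `selective`
(adds an early screen at week 12 for women meeting the high-risk
definition: high-risk ethnicity, age ≥ 40, prior GDM, family history, or
BMI ≥ 35). Attendance is Bernoulli with probability `participation`
(default 0.95). The OGTT is a deterministic inclusive threshold on latent
$G$; the threshold is read from a piecewise-constant **diagnostic
schedule** keyed by calendar year, which is how changes to the diagnostic
standard create steps in *recorded* incidence with no change in underlying
physiology. Diagnosis triggers lifestyle management (and pharmacotherapy
when test $G$ exceeds a second threshold), modelled as a multiplier on $G$
ramping from 1 to 0.8 over four weeks and lasting until delivery —
treatment during pregnancy only, which is the interpretation taken for the
open question of insulin effect timing. Each service event carries a unit
cost; tallies are additive and kinds missing from the cost table are
counted with cost flagged unknown.

# Interventions

An intervention specification has a target (`population`, `high_risk`,
`post_gdm`), a timing gate (`pre_pregnancy`, `inter_pregnancy`,
`during_pregnancy`), an uptake probability, and two mechanistic channels:
a weight channel (kg change, converted by height, ramped over 6 months)
and an activity channel (a direct multiplier on baseline insulin
sensitivity) — so a program can improve metabolic function with no weight
change at all. Effects persist for the configured duration and then decay
at `adherence_decay` per year. Stacked interventions combine through the
shared BMI/sensitivity pathways; no interaction coefficients exist, and
comparisons report (never assume) sub- or super-additivity.

Scenario pairs share the master seed. Random draws come from substreams
keyed by (seed, purpose, step) and are indexed by agent, so a policy
change perturbs only the draws it logically touches; a baseline and an
intervention arm with zero-effect interventions are bit-identical, which
the test suite asserts.

# The simulated experiment and calibration

The shipped configuration is a desk-scale jurisdiction: 10,000 women, 20%
in the high-risk-ethnicity group, simulated from 1988 over 29 years with a
20-year burn-in so that reporting covers 2008–2016. Burn-in serves two
purposes: pregnancy/parity histories accumulate, and the cold-start
exposure state ($E = 0$ everywhere) washes out; `burn_in_check()` gives a
plateau statistic for choosing the length. At this population size the
model produces roughly 200 births per year, so a single year's DIP
fraction carries Monte-Carlo noise of about ±1.7 percentage points per
seed (±0.8 pp over 5 replicate averages) — the reason calibration and
comparisons always average replicate seeds.

Calibration fits three free parameters spanning the behavioural and
artefactual drivers of the recorded trend:

| parameter | bounds | role |
|---|---|---|
| `bmi_secular` | 0.02–0.18 units/yr (linear) | population weight change |
| `k_decay` | 0.01–0.40 /index-yr (log) | speed of beta-cell loss |
| post-change threshold | 2.4–4.2 (linear) | diagnostic-standard artefact |

The pre-change threshold (4.2) and the change year (2014) stay fixed in
the configuration. The loss is the replicate-mean sum of squared
differences between simulated and observed DIP fractions at the target
years; the optimiser is Latin-hypercube screening over the bounds (60% of
the evaluation budget) followed by Nelder–Mead refinement from the best
point on the unit-scaled space. Because administrative data cannot
separate real from artefactual trend components, the split the calibration
recovers is reported but never asserted against a truth.

One-at-a-time sensitivity analysis perturbs each parameter up and down,
reports the elasticity of final-year DIP %, and sorts by magnitude
(tornado order); a parameter with no causal path to incidence (a unit
cost, say) gets elasticity exactly zero. The readiness report scores a run
against anchor years (pass within ±1.5 pp, which is the 2σ Monte-Carlo
noise at this scale) and against reference weight-category and
age-structure distributions by L1 distance when they are supplied,
marking indicators without references "not assessed" rather than failed.

# What the synthetic population does and does not emulate

`synthetic_population()` produces a stylised age-by-risk-group table with
exact totals (largest-remainder apportionment). It emulates the *shape* of
a developed jurisdiction's female age structure and an ethnicity-based
risk stratification; it does not emulate migration waves, cohort-specific
fertility change, socioeconomic gradients, under-ascertainment in
administrative data, or assay-level measurement error (an optional
measurement-noise flag exists but defaults off). Passing tests on this
fixture therefore demonstrates internal consistency and mechanism
plausibility — not predictive validity for any real jurisdiction.

# Numerical and engineering choices

* Monthly fixed-step updates; discrete events within a step execute in
  (time, agent id, kind) order, so results are independent of internal
  collection order.
* The monthly per-agent update (metabolism, BMI, milestone scan) runs in
  a small compiled kernel; the exported R functions are the reference
  implementations and a test asserts the kernel reproduces their
  composition to 1e-12.
* Agents created during a year (entrants at 15, newborn girls) are
  appended in one batch at the year boundary; below 15 no pathway touches
  them, so this is observationally equivalent. Child BMI updates annually
  (the childhood drift is linear and noise-free). Mortality applies
  annually with per-band probabilities.
* Women past 65 retain their last metabolic state; they cannot be
  pregnant or screened, and only contribute to the age structure.
* State thresholds are inclusive on the upper state ($G = g_{\mathrm{dm}}$
  classifies as DIABETES); flows are capped so no stock or state leaves
  its domain; fractional stocks bud via stochastic rounding so expected
  persons are conserved and realised persons are conserved exactly.

# Known limitations

* The latent $G$ scale is unitless; thresholds are not mmol/L values and
  should be compared only within the model.
* Untreated progression outside pregnancy is unchecked by care-seeking
  (no out-of-pregnancy treatment pathway), so long horizons overstate
  late-life diabetes severity in the untreated tail.
* Health-care-worker agents, queueing/capacity effects, costs beyond unit
  tallies, twin births, preterm delivery and maternal mortality are out
  of scope by design.
* Parity initialises at zero; the burn-in builds realistic histories for
  the cohorts that dominate reporting-era births, but women already past
  their reproductive window at start never acquire one.

# A worked example

```{r example, eval = FALSE}
cfg <- default_scenario()
run <- run_scenario(cfg, seed = 1)
run$annual[, c("year", "births", "dip_frac", "prop_obese")]

## calibrate to two administrative anchors and inspect the fit
targets <- calibration_targets(c(2008, 2016), c(0.06, 0.16))
cal <- calibrate_model(cfg, targets, budget = 200, n_replicates = 5,
                       seed = 1)
cal$fitted

## one woman's life story
story_id <- run$events$agent_id[run$events$kind == "diagnosis"][1]
render_life_story(story_id, run$events)
```

(The chunks are not evaluated at build time; the full calibration takes
on the order of fifteen minutes.)
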