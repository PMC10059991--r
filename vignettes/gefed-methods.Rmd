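---
title: "Methods: federated grammatical evolution for glycemic-band forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated grammatical evolution for glycemic-band forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gefed)
```

## The problem and the model

A CGM sensor reports subcutaneous glucose every 5 minutes; insulin pumps
log boluses and basal rates, and patients log meal carbohydrates. The task
is a 30-minute-ahead forecast of the *glycemic band* — seven ordered
classes from "very low" (< 3.0 mmol/L) to "very high" (≥ 13.9 mmol/L),
with half-open-right boundaries and thin warning bands flanking the normal
range so that a drift towards hypo- or hyperglycemia is announced before
the event. Band prediction, rather than exact regression, matches the
clinical use: what triggers action is the class.

Each model is an explicit arithmetic expression constrained by a
context-free grammar to the shape

$$\hat G(t+h\Delta t) = \bigl(\Gamma(G) - \Theta(I) + \Omega(C)\bigr) \diamond \Phi(dG),$$

where the four blocks operate on disjoint variable families: past glucose
`g0..g12`, future plasma-insulin values `i0..i6`, future carbohydrate
absorption `c0..c6`, and backward differences `dg1..dg12`
(`dgj = g0 - gj`, current minus past). The signs build the physiology into
the search space: insulin lowers glucose, carbohydrates raise it. Insulin
and carbohydrate *futures* are legitimate covariates because dosing and
meals are logged events whose absorption curves are known ahead.

The exact production set inside each block is this package's own
reconstruction: the top level is fully constrained by the model shape, and
each block gets symmetric arithmetic (`+`, `-`, `*`), the protected
functions, and digit-built constants over its own variables only.
Constants in every block make degenerate blocks expressible (e.g.
`(g0 - 0 + 0) * 1`, the persistence model), which keeps simple,
readable models reachable.

### Protected functions

Evolved expressions must be total: `plog(x) = log(1+|x|)`,
`psqrt(x) = sqrt(|x|)`, and the analytic quotient
`aq(x, y) = x / sqrt(1 + y^2)` replace their partial counterparts. A
forecast that is nevertheless non-finite or non-positive (e.g. after
catastrophic cancellation) is mapped to a sentinel "invalid" class that
counts as a miss for the true class and can never be a true positive, so
such models are penalised, not crashed.

## Preprocessing

Dosing events become a continuous plasma-insulin concentration through the
two-compartment subcutaneous absorption chain
$\dot S_1 = U - S_1/t_{maxI}$, $\dot S_2 = (S_1 - S_2)/t_{maxI}$,
$\dot I = S_2/(V_I\,t_{maxI}) - k_e I$ with $t_{maxI} = 55$ min,
$k_e = 0.138\,\mathrm{min^{-1}}$, $V_I = 0.12$ L/kg. The system is linear
and time-invariant, so the per-5-minute update is computed *exactly* from
the matrix exponential (boluses as impulses into $S_1$, basal as
piecewise-constant infusion): there is no integration step-size error, the
closed-form steady state $I_{ss} = U/(V_I k_e)$ and superposition hold to
floating precision, and the test oracles can be tight. Long-acting/basal
insulin is routed through the same chain as boluses — a documented
simplification; no separate model is used. $V_I$ is per-kg and the default
body weight is 1, i.e. doses and concentrations are per-kg quantities;
the evolved models only require a consistent covariate scale, and a
`weight` argument exists for users who want absolute units.

Meals follow the gut absorption kernel
$C(t) = D_g A_g (t-t_0) e^{-(t-t_0)/t_{max}} / t_{max}^2$ with
$t_{max} = 40$ min and bioavailability $A_g = 0.8$; it peaks at lag
$t_{max}$ with value $D_g A_g/(t_{max} e)$ and integrates to $D_g A_g$.
Events are aligned to the nearest CGM reading time (midpoint ties go to
the earlier reading). Missing glucose readings are represented explicitly
and never imputed: any training window touching one is discarded, there is
no smoothing, outlier removal, or normalisation.

Units are canonical throughout: glucose in mmol/L (mg/dL divided by
exactly 18, the factor implied by the paired band bounds 54 ↔ 3.0),
boluses in mU, basal in mU/min. The Ohio-style XML reader takes explicit
unit arguments rather than guessing, because the source schema declares
none.

## Fitness and scoring

Fitness is the class-frequency-weighted F1 over the seven bands:
per-class one-vs-rest $F_1 = tp/(tp + 0.5(fp+fn))$, averaged with weights
$p_i$ = fraction of samples truly in class $i$. The weights already sum to
one, so the weighted average itself (not a further division by the class
count) is used — the only reading under which a perfect classifier scores
1. A class absent from both truth and prediction contributes 0 with weight
0. Weighted precision and recall use the same weights; accuracy is
trace/total. Dispersion margins use the population (n) standard
deviation, the convention that reproduces the published cross-evaluation
margins this package checks itself against.

## The evolutionary engine

Standard grammatical evolution: integer codon genomes (codon size
100 000), leftmost-derivation mapping where a nonterminal with `m`
productions consumes a codon `c` and picks `c mod m`, with up to 2 genome
wraps; a non-terminating derivation is an invalid individual with fitness
0 rather than an error. Initial genomes come from a grow-style random
derivation bounded at depth 10, serialised to codons in leftmost order, so
every initial individual is valid. Variation is one-point variable-length
crossover at 90% (cut points within the used codons; a cut pair that
would empty a child degenerates to parent copies) and per-individual
int-flip mutation at 10% with exactly one mutation event — the "one
event" is read as at most one codon changing per mutated individual, with
the 10% an application probability per individual. Selection is
tournament of 4 with ties to the earlier index. Elitism of 1 is adopted
(it is an extension knob, `elitism = 0` disables it): the protocol's
best-local-model bookkeeping presumes the best is tracked, and elitism
makes best-so-far monotonicity a testable invariant. Full-scale defaults
are population 200 for 500 generations; tests and examples scale down.

Fitness evaluations are memoised per phenotype within a run, and
expressions are evaluated vectorised over the whole sample table, which is
what keeps desk-scale federation experiments in CPU-minutes.

## The federation protocol

An in-process synchronous master/slave orchestrator implements the
protocol; the contribution is the message contract, not the wire, so no
network transport, encryption, or fault tolerance is included. After
generations `interval, 2·interval, …, ≤ g_max` each slave sends its best
model (expression + sender-side fitness — never samples) to the master,
receives the other slaves' bests, scores them on its *local* training
data, and integrates them best-first by replacing its current worst member
whenever the immigrant's local fitness is strictly higher; population size
never changes, and a slave never receives its own model back.

The published pseudocode migrates at the top of the generation loop
(`g mod interval == 0` over `g = 0..g_max−1`, which includes the random
initial population at `g = 0`), while the communication count is stated as
five phases for 500 generations at interval 100. This package schedules
migration *after* evaluating generations `interval, …, ≤ g_max`: that
yields exactly `floor(g_max/interval)` rounds (five for 500/100), never
exchanges random initial individuals, and makes an interval larger than
`g_max` exactly equivalent to the isolated baseline — an equivalence the
test suite asserts seed-for-seed. Each slave owns a private RNG stream
(derived deterministically from the master seed), so migration events
never perturb a slave's random sequence and single-slave federations are
bit-identical to isolated runs.

At termination each slave's final best is cross-evaluated on every
patient's test set; the model with the best row mean is the global model
(ties to the lower patient index). `flea_experiment()` runs the federated
and isolated arms with identical per-slave seeds and measures both global
models on held-out patients, emitting per-seed subjects × algorithms
matrices for the Quade machinery.

## The statistical comparison

The Quade test weights subjects by the within-subject score range, so
subjects on which the algorithms differ more count more: range ranks
$Q_i$, within-subject ranks $r_{ij}$ (rank 1 = higher F1 — the
orientation that reproduces the published rank of the federated arm),
$S_{ij} = Q_i(r_{ij} - (k+1)/2)$, statistic $(n-1)B/(A-B)$ against
$F_{k-1,(n-1)(k-1)}$. Ties use midranks (the published data have none;
midranks match common implementations). An all-tied matrix makes the
statistic 0/0 and is reported as an explicit error. Post-hoc comparisons
against a control use $z = (T_j - T_{ctrl})/SE$ with
$SE = \sqrt{k(k+1)(2n+1)(k-1)/(18\,n(n+1))}$ and *two-sided* normal
p-values (required to reproduce the published adjusted p-value), adjusted
by Bonferroni–Dunn, Holm, Hochberg, Finner and Li; with one comparison all
five coincide with the raw p. Decisions reject at adjusted p strictly
below α (default 0.05). Whether the published summary scores use weighted
or macro averaging is not stated; weighted is chosen for consistency with
the fitness function.

The twelve-subject matrix behind the published comparison is
reconstructed as: each arm's selected global model (best cross-evaluation
row mean) over the six learning subjects, concatenated with the two
models' scores on the six held-out subjects. This reconstruction
reproduces the published ranks, statistic and post-hoc p-value exactly to
print precision, which validates it:

```{r}
qt <- quade_test(ohio_result_matrix())
qt
quade_posthoc(qt, "flea")
```

## The synthetic cohort generator

The real CGM benchmark data are access-restricted, so development and
testing run on a synthetic cohort that emulates its *structure*: a
5-minute grid over configurable days, glucose clipped to [2, 25] mmol/L,
Poisson meal schedules (3/day, 20–100 g, thinned to ≥ 90 min apart)
with boluses dosed by a per-patient carbohydrate ratio corrupted by
per-meal dosing error, a constant basal rate, randomly missing readings
(3%), and a chronological train/test split (final quarter). Glucose
follows a deliberately simple linear response

$$G(t+\Delta t) = G(t) + \alpha C(t) - \beta I(t) + \gamma(G_b - G(t)) + \varepsilon,$$

*not* a full metabolic model: the learning experiments only need data with
known, learnable structure, and the linear form makes ground truth and
oracle re-simulation exact. Per-patient draws of $\alpha, \beta, \gamma$,
the carb ratio, the basal rate and the set point $G_b$ make patients
distinct but related tasks — the regime in which sharing models across
patients can help. The default coefficient ranges were chosen so that the
generated data sit inside the stated physiological magnitudes (insulin
signal within about [0, 10] mU/L, carbohydrate signal within [0, 3] g)
and show the hypo-rare class imbalance of real cohorts (the two hypo
bands jointly under 10% of samples, normal and hyper bands dominating,
set-point heterogeneity spreading band occupancy across patients); a
single bolus is capped at 18 mU, as pumps cap boluses, which also keeps
plasma insulin in range when meals cluster.

What the generator does *not* emulate: circadian structure (dawn
phenomenon, nocturnal stability), sensor artefacts beyond missingness
(drift, compression lows), exercise and stress effects, biphasic meals,
and real inter-event correlations. Passing tests on synthetic cohorts
therefore demonstrate the machinery — preprocessing, evolution,
federation, statistics — under controlled conditions, not clinical
performance; absolute F1 levels on real CGM data are expected to differ.

## Problem sizes and numerical choices

The package's own test experiments use desk-scale settings chosen to keep
a full run in CPU-minutes while preserving the protocol's structure:
cohorts of 4 learning + 2 held-out patients of 2 simulated days,
population 50 for 100 generations with migration every 25 (so four
exchanges), five master seeds; the grammar-recovery check uses population
50 for 50 generations. The full-scale defaults (200 × 500, interval 100,
20 runs) remain available through `ge_control()`/`flea_control()`.

Other numerical decisions: exact matrix-exponential stepping for the
insulin chain (see above); carbohydrate kernels evaluated in closed form
and summed over meals; the chronological split floors the train side on
odd counts; windows inherit the anchor's split tag; `k+1` past glucose
values are used (`g0..g12`), following the model shape's enumeration of
$G(t)$ through $G(t-k\Delta t)$; bolus record units in Ohio-style files
default to U (converted ×1000 to mU) with an explicit override, since the
schema does not declare them.

## Known limitations

- The federation is in-process; distributed deployment, secure transport
  and adversarial robustness are out of scope by design.
- The grammar's block interiors are a reconstruction (see above); other
  production sets satisfying the same model shape are possible.
- The synthetic generator supports structural, not clinical, validation.
- Cross-evaluation uses each patient's chronological test window; no
  multi-horizon or rolling-origin evaluation is provided.
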