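---
title: "Filter-cascade cost-effectiveness models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-cascade cost-effectiveness models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filtercascade)
```

## The model

A filter cascade is the simplest useful decision-analytic model of a care
pathway. A population of size $N$ flows through an ordered sequence of
filters; filter $i$ passes a fixed proportion $p_i \in [0,1]$ of its
entrants. The expected person-count after filter $i$ is

$$ n_i = N \prod_{j \le i} p_j, $$

and the final count $n_k$ is the expected number of successful outcomes
(e.g. patients in remission at follow-up). Counts are continuous
expectations of a cohort, not integers: this is a deterministic
cohort-expectation model, not a microsimulation. Three assumptions are
load-bearing:

- **Independence.** Filters operate independently: changing one step's
  proportion never alters another's. Real interventions can violate this
  (training clinicians to offer treatment may also improve adherence);
  if so, the user must fold the spill-over into the affected proportions
  themselves.
- **Homogeneity.** Every person at a step has the same pass probability;
  there is no severity stratification or patient heterogeneity.
- **Single implicit time horizon.** The final filter *is* the endpoint
  (here, six-month remission); there is no discounting and no modelling
  of events beyond it.

The model deliberately excludes detection inaccuracy (false
positives/negatives), downstream health-system cost offsets and
patient-perspective costs. It answers one question well: given believed
stage proportions and per-person intervention costs, where in the
pathway does a dollar buy the most additional successes?

### Costs

A step may carry a per-person intervention unit cost $c_i \ge 0$. The
step cost is $c_i$ times the expected person-count at the step's **cost
basis**:

- `post_step` (default): the count *after* the filter,
  $c_i \, n_i$. This is the convention used by the bundled worked
  example — e.g. a $5 screening cost applied to the 835,715 patients
  detected.
- `pre_step`: the count *entering* the step, $c_i \, n_{i-1}$ — arguably
  the right basis for a screening cost paid for everyone screened, not
  only those screening positive. It is offered as an explicit
  alternative; the default follows the worked example's arithmetic.

The scenario's total cost is the sum of step costs. Two per-unit outputs
are derived: **cost per participant exposed** (total cost divided by the
costed step's basis count — under the post-step basis this equals the
unit cost itself; defined only when exactly one step carries a cost) and
**cost per successful outcome** (total cost / successes; 0 for zero-cost
scenarios, undefined when successes are zero with positive cost).

### Comparison and policy classification

For a scenario $s$ against a designated baseline $b$:
$\Delta C = C_s - C_b$, $\Delta E = E_s - E_b$, and when
$\Delta E \neq 0$ the ICER $= \Delta C / \Delta E$. The signs of
$(\Delta C, \Delta E)$ place the scenario on the cost-effectiveness
plane: more effective and cheaper is *dominant*, less effective and
costlier is *dominated*, the two mixed quadrants are trade-offs, and
$(0,0)$ is *equivalent*. Axis ties follow conventional practice (the
worked example never encounters them): a free improvement
($\Delta C = 0$, $\Delta E > 0$) or a pure saving ($\Delta C < 0$,
$\Delta E = 0$) is dominant; a pure cost or a costless loss is
dominated. The ICER is computed in every quadrant with a nonzero
$\Delta E$ but flagged as *not meaningful* outside the trade-off
quadrants, where decisions do not turn on it.

## Numerical conventions

All arithmetic is carried at full double precision; the per-step chain is
computed by sequential multiplication so that each step's resulting
count is exactly `entering * proportion`. Rounding happens **only at
report time**: person-counts and currency to the nearest whole unit,
half-up (0.5 away from zero, unlike base R's round-half-even — scenario
tables in the field are presented that way). This matters: the worked
example's derived outputs are only reproducible from unrounded
intermediates (e.g. 44,156 successes = 835,714.88 × 0.28 × 0.51 × 0.37),
and re-rounding rounded intermediates drifts by whole persons.

Degenerate inputs are well-defined rather than errors: a proportion of 0
annihilates the rest of the cascade (and post-step costs with it), a
proportion of 1 is the identity, and comparing a scenario with itself
yields the equivalent quadrant with an undefined ICER.

## Interval bounds (deterministic sensitivity analysis)

Point estimates of stage proportions and costs are often the weakest
part of such models, so any input parameter (a step's proportion or unit
cost, or the population) can be given an interval. A set of intervals
defines a box; `bounds_joint()` reports, for every output, an envelope
over the box.

Expected counts, total cost and both incrementals are *multilinear* in
the inputs (linear in each parameter with the others held fixed), so
their extrema over a box are attained at corners; corner enumeration
(all $2^k$ corners, capped at $k \le 12$ by default, configurable) gives
exact envelopes for those outputs. Ratio outputs (cost per success,
ICER) are ratios of multilinear functions; their corner evaluation is
exact only while the denominator keeps one sign over the box, and rather
than relying on that argument alone the module additionally evaluates a
seeded Latin-hypercube sample of the box (default 1,000 points,
`lhs::randomLHS`) and widens the envelope to cover the samples — hence
the reported method `"corner+sampled"`. Two honesty rules apply:

- if the incremental successes change sign inside the box the ICER is
  unbounded there, and its envelope is reported as **undefined** with a
  diagnostic instead of a misleading finite range;
- if the denominator *touches* zero at a box corner, the ICER is
  undefined at that point and can grow without bound approaching it; the
  envelope then covers the defined evaluations and says so in its note.

Both joint boxes and one-at-a-time intervals (`bounds_one_way()`, the
building block of tornado-style reporting) are provided, since either
may be wanted and they answer different questions. Shrinking an interval
never widens the exact (multilinear) envelopes; the sampled refinement
of ratio envelopes is deterministic given its seed.

## Configurations, reports and the CLI

Models are YAML documents (`schema_version: 1`): a population, an
ordered step list, named scenarios as *sparse overrides* of the shared
steps (matching the "no change to baseline" idiom of scenario tables and
preventing transcription drift), exactly one baseline designation, and
optional bounds intervals. `load_config()` validates every field and
reports failures with their field path; `write_config()` round-trips.
Reports come in three formats — a human-readable scenario table, CSV
with stable column names, and JSON-lines — and every rendered number is
exactly `round_for_report()` of the in-memory full-precision value;
undefined values render as `n/a`. The `filtercascade` script under
`exec/` wraps this as `run`, `bounds` and `example` subcommands, writing
results to standard output (or `--out`) and log messages to standard
error.

## The bundled worked example and its parameters

`depression_config()` ships a national-scale model of depression
management in Australian general practice (currency AUD):

| step | meaning | baseline | intervention |
|---|---|---|---|
| population | adults 18–75 | 15,055,403 | — |
| target_group | current depression prevalence | 0.089 | — |
| attendance | sees a GP at least once/year | 0.81 | — |
| detection | detected as at risk by GP | 0.47 | 0.77 at $5 (screening) |
| reach | offered evidence-based treatment | 0.28 | 0.69 at $247 (GP training) |
| adherence | complies with offered treatment | 0.51 | 0.65 at $98 (telephone follow-up) |
| outcome | remission at 6 months | 0.37 | — |

Each intervention scenario changes exactly one filter; the proportions
and unit costs are literature-derived point estimates and the three
scenarios are deliberately hypothetical illustrations, not evaluated
programmes. Recomputing the published totals at full precision shows the
source spreadsheet's currency outputs carry a few dollars of internal
rounding (e.g. the GP-training incremental cost computes to $86,938,334
against a printed $86,938,336), so the package's regression tests hold
currency totals to within $5 and every person-count exactly after
rounding.

## The microsimulation oracle

`microsimulate()` realises the cascade at the individual level: each of
$n$ simulated persons passes filter $i$ independently with probability
$p_i$, and costs accrue per costed individual at the configured basis.
It exists to validate the expectation model (empirical pass fractions
converge binomially to $\prod p_i$; the test suite checks agreement
within $3\sigma$ at $n = 200{,}000$) and as an optional CLI-adjacent
utility — it is never the primary computation path. Its single seed is
recorded in the result for reproducibility. Because individuals are
independent across steps by construction, it cannot emulate correlated
behaviour (e.g. patients likely to attend also likely to adhere); that
is a feature, since the deterministic model assumes exactly this
independence, and a limitation of both.

## What the tests do and do not show

The randomised property suites (closed-form successes on 1,000 generated
scenarios, ICER scale-invariance, quadrant exhaustiveness, envelope
containment on 10,000 sampled parameter vectors per box, microsimulation
agreement) exercise the *arithmetic* under the model's own assumptions.
Problem sizes were chosen to probe those properties densely at desk
scale: cascades of 1–8 steps, populations up to $10^7$, 3-parameter
boxes. Passing them shows the implementation is faithful to the model;
it says nothing about whether any real care pathway satisfies
independence and homogeneity, nor about the quality of the input
estimates — the model's outputs are only as strong as its inputs.

## Known limitations

- Effectiveness is a dichotomous success count: no QALYs, utilities, net
  monetary benefit or willingness-to-pay thresholds.
- No probabilistic sensitivity analysis (distributions,
  cost-effectiveness acceptability curves); intervals give bounds, not
  probabilities.
- One cost basis per step and a single currency label; no discounting,
  exchange rates or inflation.
- Ratio-output envelopes are corner+sampled, not symbolic optimisation;
  pathological ratios inside a box are covered by the undefined-ICER
  diagnostics rather than tight bounds.
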