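# filtercascade

Filter-cascade cost-effectiveness models for care pathways.

Many care pathways act as a sequence of filters: of everyone with a
condition, only some attend the relevant care setting, only some of those
are detected, only some detected patients are offered evidence-based
treatment, only some offered patients adhere, and only some adherent
patients achieve a successful outcome. Each stage passes a proportion of
its entrants to the next, so the expected number of successes under a
scenario with population *N* and step proportions *p₁ … pₖ* is

```
E[successes] = N · p₁ · p₂ · … · pₖ
```

An intervention scenario raises one (or more) of the proportions at a
per-person cost; attaching unit costs to steps gives a total intervention
cost, and comparing a scenario *s* with a baseline (usual care) *b* gives
the standard cost-effectiveness quantities

```
ΔC = C(s) − C(b)         incremental cost
ΔE = E(s) − E(b)         incremental successes
ICER = ΔC / ΔE           cost of one additional success
```

plus the cost-effectiveness-plane classification (dominant / dominated /
trade-off / equivalent). The package is aimed at policy analysts,
health-services researchers and modellers who want this desk-scale
decision-analytic arithmetic to be scripted, validated and reproducible
rather than living in a spreadsheet. It supports:

- arbitrary-length cascades with per-step unit costs (post-step or
  pre-step cost basis), evaluated at full floating-point precision with
  rounding only at report time;
- scenario comparison: incrementals, ICER, quadrant classification and
  policy advice;
- deterministic sensitivity analysis: interval bounds on any input
  parameter propagated to lower/upper envelopes on every output (exact
  corner evaluation for the multilinear outputs, corner-plus-sampled for
  ratio outputs);
- YAML model configurations with scenarios expressed as sparse overrides
  of a shared step list, plus table / CSV / JSON-lines reports and a
  command-line interface (`exec/filtercascade`);
- an individual-level Bernoulli microsimulation used as a stochastic
  oracle for the cohort-expectation arithmetic;
- a bundled worked example: depression management in Australian general
  practice.

## Worked example

The bundled model filters the Australian adult population (15,055,403)
through depression prevalence (8.9%), annual GP attendance (81%), GP
detection (47%), offer of treatment (28%), adherence (51%) and six-month
remission (37%). Three intervention scenarios each improve one filter:
routine waiting-room screening (detection 47% → 77% at $5/person
screened positive), GP education and training (reach 28% → 69% at $247),
and telephone follow-up (adherence 51% → 65% at $98). All amounts AUD.

```r
library(filtercascade)
run <- run_model(depression_config())
run$comparisons$filter1
#> <comparison_result> 'filter1' vs 'baseline'
#>   incremental cost:      AUD 4,178,574
#>   incremental successes: 17,204
#>   ICER: AUD 243 per additional success
#>   trade_off_more_costly_more_effective
```

Under usual care 26,952 people are expected to reach remission; the
screening scenario raises this to 44,156 (17,204 additional remissions)
for a total cost of $4,178,574, i.e. $243 per additional remission — the
cheapest of the three options per extra success. GP training buys the
most additional remissions (39,466) but at the highest ICER ($2,203);
telephone follow-up sits between ($1,230). All three are more effective
and more expensive than usual care, so none dominates: the choice depends
on willingness to pay per remission.

The same run from the shell:

```sh
Rscript exec/filtercascade run inst/extdata/depression.yaml --format table
Rscript exec/filtercascade bounds inst/extdata/depression.yaml   # interval analysis
Rscript exec/filtercascade example > my-model.yaml               # config template
```

Interval sensitivity analysis, e.g. detection anywhere between the
baseline 47% and the screening scenario's 77%:

```r
base <- config_scenario(depression_config(), "baseline")
bounds_one_way(base, base,
               interval_spec("proportion", 0.47, 0.77, step = "detection"))
#> successes  [26952.26, 44155.83]  ...
```

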