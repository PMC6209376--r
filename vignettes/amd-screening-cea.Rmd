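---
title: "A Markov cohort model for AMD screening cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for AMD screening cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(amdscreen)
```

## The decision problem

Age-related macular degeneration (AMD) progresses silently: most cases are
found only after symptomatic vision loss, when treatment (typically
anti-VEGF therapy) is less able to preserve sight. Population screening can
pull diagnosis forward, but at the cost of annually testing a mostly healthy
population. `amdscreen` models this trade-off for a cohort of 100,000
40-year-olds followed to age 100, comparing five strategies: no screening
(status quo), opportunistic examination (whoever visits an ophthalmologist
is checked), opportunistic treatment (only symptomatic patients who present
are checked), annual systematic fundus photography with confirmatory
examination of positives, and annual systematic examination by an
ophthalmologist (gold standard).

## Model structure

### State space

The disease has five clinical states -- no AMD, mild, moderate, severe, and
dead -- but two pieces of history matter that a five-state chain cannot
carry:

* **Diagnosis.** Costs and treatment apply only after diagnosis, so each
  living severity is split into *undiagnosed* and *diagnosed*.
* **Complication origin.** A treated patient who develops a treatment
  complication must, on recovery, return to the state they came from. Three
  *tunnel states* (one per diagnosed AMD severity) remember that origin.

That yields 4 severities x 2 statuses + 3 tunnels + death = 12 states
(`model_states()`), death last and absorbing.

### Transitions

Mortality depends on age only -- AMD confers no excess death risk -- so every
living state dies with the life-table probability `qx(age)` and the disease
dynamics apply conditionally on survival:

* Undiagnosed disease only progresses, at the natural annual rates
  (no→mild 0.01, mild→moderate 0.0022, moderate→severe 0.0015).
* Diagnosed (treated) disease progresses at those rates scaled by the
  treatment effect (0.5), regresses one level with probability 0.1 per year
  (mild may regress to no AMD), and enters its complication tunnel with
  probability 0.005 per year; the three events are mutually exclusive within
  a cycle.
* Tunnels return to their origin state with probability 0.4 per year.
* Diagnosed patients who regressed to no AMD stay under follow-up: if they
  re-develop AMD (probability 0.01/year) they are detected immediately.
  They are treated as off active therapy, so they carry no complication
  risk.

Because treatment status is encoded in the state space, one conditional
matrix serves every strategy; `transition_matrix()` composes it with the
age-specific mortality and is row-stochastic to 1e-12 by construction.

### Within-cycle event order

The cycle length is one year and each cycle applies, in this order:

1. the strategy's screening/diagnosis update, with screening and
   confirmatory examination costs;
2. cost and utility accrual on the post-screening occupancy;
3. the transition, charging the one-off complication cost (3,000,000 KRW) on
   tunnel entry.

The order is a modelling choice (screen-then-accrue-then-move); it is fixed
in code rather than configuration so that results are deterministic and
comparable. There is no half-cycle correction: each cycle accrues a full
year at the start-of-cycle occupancy, and cycle *t* is discounted by
$(1+r)^{-t}$ with $t=0$ for the first cycle. The horizon runs until age 100,
where the life table's terminal death probability of 1 absorbs any
survivors.

### Costs and utilities

Utilities per year: 1 (no AMD), 0.81 (mild), 0.57 (moderate), 0.51
(severe), 0.4 (complication tunnel), 0 (dead). Annual costs in 2018 KRW
apply to *diagnosed* disease: 620,702 (mild), 1,757,690 (moderate),
5,145,366 (severe). Screening units: 8,930 per fundus photograph, 111,958
per ophthalmologist examination.

Two cost rules are genuine open points resolved here and exposed as
switches:

* `charge_low_vision` (default on): undiagnosed severe AMD accrues the
  1,000,000 KRW/year low-vision cost. Without some such charge a
  never-screened cohort would accrue no cost at all, which is implausible
  for untreated severe disease.
* `follow_up_cost` (default on): diagnosed patients who regressed to no AMD
  accrue one examination per year as follow-up.
* Tunnel states keep their origin state's annual care cost in addition to
  the one-off complication cost, since AMD management continues during the
  complication episode.

## Screening strategies

Photography screens all undiagnosed persons annually; disease is detected
with sensitivity 0.86 and healthy persons test falsely positive with
probability 1 − 0.79. All positives, true and false, incur the confirmatory
examination; false positives remain undiagnosed and negatives are re-screened
the following year. The annual re-screening reading matters: it makes an
86%-sensitive annual photograph nearly as effective as the gold standard in
steady state, which drives this model's finding that photography, not
examination, is the net-benefit-optimal arm at the 30M KRW/QALY threshold.

The opportunistic arms apply the presentation probability
(1 − 0.34 = 0.66) independently every year (`opportunistic_mode =
"annual"`); a once-at-baseline mode exists for scenario analysis. The
"symptomatic" pool for opportunistic treatment defaults to severe AMD only
(`symptomatic_states`), the narrow reading consistent with that arm's small
incremental cost over no screening.

## Mortality input and the synthetic life table

The only external data the model consumes is an age-indexed table of annual
death probabilities. The package ships a synthetic stand-in for the 2015
Korean period life table generated by a Gompertz–Makeham law,
$q_x = 1 - \exp(-(a + b\,e^{c\,x}))$ with $a = 2\times10^{-4}$,
$b = 3\times10^{-5}$, $c = 0.090$, capped at 1 at age 100. The constants
were calibrated against a curtate life-expectancy oracle so that $e_0$ falls
in the 80–83-year band and $e_{40}$ in 40–46 years, matching Korean 2015
longevity:

```{r}
lt <- default_life_table()
c(e0 = life_expectancy(lt, 0), e40 = life_expectancy(lt, 40))
```

The synthetic table reproduces the level and adult age-gradient of real
mortality but none of its fine structure (infant mortality, accident hump,
cohort effects, sex differences). Tests passing on it therefore validate the
model mechanics and the qualitative economics, not Korean-specific absolute
cost/QALY totals; a real life table can be supplied as a CSV
(`load_life_table()`, columns `age,qx`).

## Economic analysis

Both costs and QALYs are discounted at 5% per year. For strategies sorted by
cost, `dominance_frontier()` removes strongly dominated entries (another
strategy costs no more and yields no less), then iteratively removes
extended-dominated entries until incremental ICERs strictly increase along
the frontier. `net_monetary_benefit()` is $\lambda E - C$ at threshold
$\lambda$ (30,000,000 KRW/QALY in the base case) and `optimal_strategy()`
maximizes it, breaking ties toward lower cost and then input order. The
package also reproduces the frontier algebra on the published base-case
(cost, QALY) pairs shipped in `published_strategy_results()`.

## Sensitivity analyses

* **One-way (tornado).** Default ranges are ±25% of base, clipped to the
  legal domain -- the conventional default when no ranges are published --
  overridable per parameter via the config `ranges` block. The varied set is
  the uncertain model inputs: probabilities, utilities except the
  perfect-health anchor `u_no`, and non-zero costs; the WTP threshold,
  discount rate and cohort structure are treated as analysis constants, not
  uncertainty parameters. The outcome is the base-case optimal strategy's
  NMB at the threshold, with strategy-switch annotations.
* **Two-way.** The shipped analysis varies mild-AMD utility over
  \[0.5, 1.0\] against the annual complication probability over \[0, 0.10\].
  Those axes are deliberately wider than ±25%: the clinically debated region
  discussed for this decision problem reaches 10% complication risk and a
  mild-AMD utility down to 0.6, and the strategy switches of interest only
  appear at that scale.
* **PSA / CEAC.** Parameter distributions are not published for this
  problem, so the package uses the standard stand-in: moment-matched beta
  for probabilities/utilities and gamma for costs, both with SD equal to 20%
  of the base mean, sampled independently. The CEAC grid spans 0 to 60M
  KRW/QALY in 1M steps. The shipped analyses and acceptance checks use 1,000
  seeded draws, a problem size chosen to make the acceptability
  probabilities stable to a few percent while keeping the full pipeline
  quick to re-run; the `n_draws` argument scales to the 10,000 draws typical
  of a full analysis.

## Validation

Three independent routes check the engine:

* **Closed-form limits.** An undiscounted, immortal, disease-free cohort
  accrues exactly horizon × u_no = 60 QALYs under every strategy; with
  certain death each year, exactly one cycle's accrual.
* **Microsimulation oracle.** `microsim_oracle()` pushes individuals through
  the identical per-cycle event logic with random draws; its mean cost and
  QALY estimate the cohort expectations with $1/\sqrt{n}$ standard errors.
  The test suite compares it to `run_cohort()` at n = 20,000 per strategy.
  One calibration caveat: per-person cost in the cheap arms is extremely
  right-skewed (most individuals accrue nothing), so a normal-theory 3-SE
  band on a single 20,000-person draw occasionally rejects even though the
  estimators agree in expectation.
* **Natural history.** Under opportunistic examination the ever-AMD
  prevalence among survivors (current disease plus regressed patients under
  follow-up) rises from 6.6% at baseline to about 24% by year 20, the level
  implied by a 1%/year incidence; external cohort data for 20-year combined
  AMD incidence sit near 29%, so the model is conservative by a few
  percentage points at that horizon.

## Known limitations

* Absolute lifetime cost and QALY totals depend on the mortality table and
  on structural readings (re-screening of test negatives, low-vision and
  follow-up charging) that published summary tables do not pin down; the
  package's own totals are internally consistent but not comparable
  digit-for-digit with any specific published table.
* Incidence, progression and presentation probabilities are age- and
  sex-constant; mortality is the only age-varying input.
* PSA draws are independent across parameters; no correlation structure, and
  no value-of-information analysis.
* Screening adherence is perfect; there is no misdiagnosis by
  ophthalmologists, no attrition, and no budget-impact scaling beyond
  per-person expectations.

## A worked run

```{r, eval = FALSE}
params <- amd_parameters()
lt <- default_life_table()
base <- run_all_strategies(params, lt)
dominance_frontier(base)
optimal_strategy(base, params$wtp)

tor <- one_way_sa(params, default_ranges(params), lt)
head(tor)

draws <- psa_run(params, default_ranges(params), lt, n_draws = 1000, seed = 1)
head(ceac(draws, wtp_grid = c(0, 3e7)))
```

The numbered scripts under `analysis/` run these end to end and write all
tables under `results/`.
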