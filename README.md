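# wardopt

Decision support for hospital bed management with **shared ward
resources**. Hospitals increasingly pool beds across clinics: a ward holds
contingents of beds per preference class (single room, female double, male
double) that several clinical units draw on. `wardopt` schedules elective
admission requests against the *expected* future occupancy of those
contingents, models the uncertainty of every patient's recovery, and lets
you compare an exact optimiser against fast list-scheduling heuristics and
a status-quo baseline in a discrete-event simulation of a synthetic
university hospital.

It is written for health operations researchers and clinical-informatics
teams who want a reproducible sandbox for admission-planning policies,
in tidyverse style: tibbles in, tibbles out, `tidy()`/`glance()` accessors
and `autoplot()` methods for every result type.

## The model in brief

* **Length of stay.** Patient $i$'s stay is log-normal $D_i$, elicited as
  an expected discharge time and an uncertainty (both in days) and
  moment-matched to the log scale. The survival probability
  $p_{it} = P(D_i \ge t)$ says how likely the patient still holds a bed
  $t$ days after admission.
* **Expected capacity.** Occupancy of a contingent $(j, b)$ is a
  Poisson-binomial count with exact mean
  $E[U_{jtb}] = \sum_i p_{it}$; the expected free capacity is
  $K_{jb} - E[U_{jtb}]$ and the usage rate $c_{jtb} = E[U_{jtb}]/K_{jb}$.
  Revising one LoS estimate updates every downstream quantity.
* **Assignment cost.** A candidate (patient, ward, admission day $t$) costs
  the weighted sum of four factors: affinity
  $m_\alpha(1-\mathrm{AFF}(C_i, j))$, occupancy
  $m_\beta \sum_{m=t}^{t+\lceil E(V_i) \rceil - 1} c_{jmb}$, occupancy
  change $m_\gamma \sum |c_{j,m+1,b} - c_{jmb}|$, and delay
  $m_\delta \frac{1}{1+\mathrm{Prio}(i)}(1 - \frac{1}{1+t})$.
* **Exact strategy.** A binary integer program over $x_{ijt}$ with
  completeness, uniqueness and windowed capacity constraints
  $\sum_i \sum_{t_1=\max(1, t-L_{\max})}^{t} x_{ijt_1} \le K_{jb} -
  E[U_{jtb}]$, a high-capacity dummy ward for dismissals, and a pluggable
  MILP backend (HiGHS via the system `python`, or a pure-R branch and
  bound) under a time limit.
* **Heuristics.** LEPT / SEPT (longest / shortest expected processing time
  first) and RAND order the collective and place each patient greedily at
  the cheapest feasible candidate; STATQUO is the baseline that keeps only
  the affinity and occupancy factors.
* **Simulation.** A discrete-event simulation runs planning cycles against
  a synthetic hospital (27 clinics, 43 wards, 72 clinic-ward affinities)
  with common random numbers across strategies, and reports dismissal
  ratios, cost decompositions and runtimes.

## Worked example

```r
library(wardopt)

hospital <- default_hospital(seed = 1)
#> <ward_hospital> 27 clinics, 43 wards (+1 dummy), 72 affinities, 1268 contingent beds

# a planning collective of 12 admission requests
query <- sample_collective(hospital, population_config(), size = 12, seed = 42)
ledger <- new_ledger(hospital)

exact <- solve_bip(build_bip(query, hospital, ledger), time_limit = 60)
glance(exact)
#> # A tibble: 1 × 5
#>   status  objective_value assigned dismissed solve_seconds
#>   <chr>             <dbl>    <int>     <int>         <dbl>
#> 1 optimal             2.5       12         0         0.524
tidy(exact)
#> # A tibble: 12 × 9
#>   patient_id status   ward_id     t alpha  beta gamma delta total
#>   <chr>      <chr>      <int> <int> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 p00001     assigned      14     1     0     0     0 0.125 0.125
#> 2 p00002     assigned      13     1     0     0     0 0.167 0.167
#> 3 p00003     assigned       8     1     0     0     0 0.125 0.125
#> 4 p00004     assigned       7     1     0     0     0 0.5   0.5
#> # ℹ 8 more rows
```

Into an empty hospital all 12 patients fit on day 1; the only cost is the
delay factor, discounted by each patient's priority, and the exact optimum
(2.5) coincides with the greedy heuristic's plan.

A paired mini-study on the loaded hospital (the stationary regime needs a
warm-up; see the methods vignette):

```r
cfg <- simulation_config(hospital, "RAND", ppy = 2000, mxp = 110, cpd = 5,
                         spf = 1, seed = 7, warmup_days = 45)
sweep <- strategy_sweep(cfg, c("STATQUO", "RAND"))
compare_strategies(sweep)
#> # A tibble: 2 × 10
#>   strategy cycles patients mean_dismissal median_dismissal sd_dismissal
#>   <chr>     <int>    <int>          <dbl>            <dbl>        <dbl>
#> 1 STATQUO      35     2048          0.460            0.452        0.161
#> 2 RAND         35     2048          0.465            0.477        0.152

cost_summary(sweep$RAND)[c("factor", "mean", "share")]
#> # A tibble: 5 × 3
#>   factor  mean  share
#>   <chr>  <dbl>  <dbl>
#> 1 alpha  0.182 0.0355
#> 2 beta   4.36  0.813
#> 3 gamma  0.539 0.102
#> 4 delta  0.265 0.0495
#> 5 total  5.35  1
```

At this demand level (~277 requests/day against 1,268 beds) the system is
saturated: roughly 46% of requests cannot be placed, the occupancy factor
β carries ~81% of the realised assignment cost, and the baseline performs
close to the min-cost heuristics. `autoplot(sweep)` draws the boxplot
comparison; `autoplot(sweep$RAND)` refines one strategy by collective
size.

A thin command-line front end ships in `inst/cli/`:

```sh
wardopt generate --seed 1 --size 20 --out query.json
wardopt solve --strategy exact --time-limit 300 --query query.json
wardopt simulate --strategy rand --ppy 1000 --out log.csv
wardopt summarize --log log.csv
```

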