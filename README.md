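# arhlce — early health-economic modeling of regenerative hearing therapeutics

`arhlce` is a decision-analytic model of the UK NHS hearing-care pathway
for adults aged 50+ with age-related hearing loss (ARHL), built for *early*
health-technology assessment: valuing hypothetical regenerative hearing
therapeutics before clinical efficacy data exist. It is aimed at health
economists and therapeutic developers who need headroom, scenario and
value-based-pricing estimates for this indication.

## The model

An annual-cycle Markov cohort model with eleven mutually exclusive states —
normal hearing; mild/moderate/severe/profound hearing loss, each unaided or
with a hearing aid (HA); profound loss with a cochlear implant (CI); and
death — followed from age 50 over a lifetime horizon. Severity never
improves under standard care; age-band transition probabilities drive
progression, all-cause mortality varies by single year of age, and the
care pathway (HA uptake, CI candidacy, device non-use and failure,
maintenance and upgrades) is applied per cycle. States accrue HUI-3
utilities with functional-impairment mixtures and 2018-GBP NHS costs, both
discounted at 3.5%/year.

A therapy scenario (eligible severities, recovery rule, per-administration
efficacy and price) treats each cycle's incident hearing-loss cases.
Strategies are compared by incremental net monetary benefit at
willingness-to-pay λ = £20,000/QALY:

    iNMB = (Q_n − Q_c)·λ − (C_n − C_c)

Probabilistic sensitivity analysis samples transition rows from Dirichlet
distributions, probabilities and utilities from Betas, and unit costs from
Gammas (10% coefficient of variation), with common random numbers across
compared strategies. `threshold_search()` bisects the per-administration
price to the point where the mean iNMB is zero — the value-based ceiling
price.

See the methods vignette (`vignettes/model-methods.Rmd`) for the full
model description, parameter provenance, and design choices.

## Worked example

```r
library(arhlce)

params <- load_config(default_config_path())  # the bundled parameter set
print(params)
#> Hearing-loss pathway model parameters
#>   entry age 50, horizon to age 110, discount 3.5%, WTP GBP 20,000/QALY
#>   mortality: e(50) = 32.5 years

psa <- psa_spec(iterations = 2000, seed = 7)
run_headroom(params, psa)
#> Incremental result at GBP 20,000/QALY (2000 draws)
#>   incremental cost  GBP     -3357 [-6730, -1282]
#>   incremental QALYs         0.732 [-0.972, 1.708]
#>   iNMB              GBP     18006 [-16986, 39342]
#>   mean administrations per person 1.216

threshold_search(params, c("moderate", "severe", "profound"),
                 "to_normal", efficacy = 0.5, psa = psa)
#> Ceiling price (to_normal / moderate+severe+profound, efficacy 50%)
#>   per administration GBP 29297 (mean iNMB there: -31.4)
#>   administrations per person 0.415 -> per-person spend GBP 12144
```

Reading the output: a perfect (100% effective, zero-cost, all-severity)
regenerative therapy would *save* the NHS about £3,360 per patient and add
0.73 QALYs over a lifetime, for a headroom iNMB of roughly £18,000 per
patient — the upper bound on what such a therapy is worth at the NICE
threshold. If the therapy is only 50% effective per administration and
restricted to moderate-or-worse hearing loss, its value-based ceiling
price is about £29,000 per treatment course (patients average 0.4 courses
over a lifetime, since most never progress to moderate loss).

`run_scenarios(params, psa)` tabulates the six published eligibility /
recovery scenarios against a shared standard-care arm.

A thin command-line wrapper ships in `inst/cli/arhl-model.R`:

```sh
Rscript inst/cli/arhl-model.R scenarios --iterations 2000 --seed 7 --out out/
Rscript inst/cli/arhl-model.R threshold --eligibility severe,profound --out out/
```

## Configuration

All inputs live in one YAML document (see
`inst/extdata/params_paper2018.yaml`): severity transition rows by age
band, pathway probabilities, utilities, unit costs, economic settings, a
mortality schedule (Gompertz–Makeham parameters or a lifetable CSV), and
an optional `therapy:` block. Any field omitted falls back to the bundled
default; every invariant is validated on load. Printed transition rows
with impossible sums are repaired and the repairs logged
(`repair_severity_table()`).

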