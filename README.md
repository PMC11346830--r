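# greycast

Grey GM(1,1) forecasting for short annual resource series.

Regional health-resource planners routinely need to extrapolate head-counts
— institutions, beds, physicians, nurses, pharmacists — from very short
annual records: eight points or fewer, strictly positive, growing a few
percent a year. That is too little data for ARIMA and too irregular for
plain regression. The grey model GM(1,1) (first-order, one-variable) was
built for this regime, and `greycast` implements the complete workflow:

* **Fitting.** The raw series \(x^{(0)}\) is accumulated (AGO) to
  \(x^{(1)}\); with the equal-weight background sequence
  \(z^{(1)}(k) = \tfrac12(x^{(1)}(k-1)+x^{(1)}(k))\) the grey difference
  equation \(x^{(0)}(k) + a\,z^{(1)}(k) = b\) is solved by least squares,
  \(\hat{\boldsymbol a} = (B^\top B)^{-1}B^\top Y\), for the development
  coefficient \(a\) and grey input \(b\).
* **Forecasting.** The time response
  \(\hat x^{(1)}(k+1) = (x^{(0)}(1) - b/a)\,e^{-ak} + b/a\) is differenced
  back to the level scale (IAGO) for fitted values and multi-step
  forecasts.
* **Adequacy grading.** Posterior error ratio
  \(C = \mathrm{Var}(\text{residuals})/\mathrm{Var}(\text{actuals})\) and
  small-error probability \(P\) (fraction of residuals within
  \(0.6745\,S_1\) of the mean residual) map to a four-level grade;
  development-coefficient applicability screens are reported alongside.
* **Plan-gap indicators.** Forecast head-counts become
  per-thousand-population rates and the doctor–nurse ratio, compared
  against 5-year-plan targets with met/unmet flags.
* **Synthetic data.** An exact grey-recursion generator (refits recover
  \((a,b)\) to machine precision) plus lognormal-noise simulation and
  seeded parameter-recovery experiments.

The 2015–2022 Jilin Province (China) health-resource series and the
province's 14th 5-Year-Plan 2025 targets are built in as a worked example.
Everything is data-frame-in / tibble-out and pipe-friendly, with
`tidy()` / `glance()` / `augment()` methods and `autoplot()` figures.

## Worked example

```r
library(greycast)
library(dplyr)

fit <- jilin_health_resources() |>
  filter(indicator == "registered_nurses") |>
  gm11()
fit
#> GM(1,1) grey model - registered_nurses
#>   years: 2015-2022 (n = 8)
#>   development coefficient a = -0.0766
#>   grey input             b = 57921.8695
#>   C = 0.0562, P = 1.000, accuracy: level 1 (Excellent)
```

The negative development coefficient means the nurse workforce is growing
(about `exp(0.0766) - 1` ≈ 8 % per year on the accumulated scale); C far
below 0.35 and P = 1 grade the fit Excellent, so extrapolation is
trustworthy. Three years ahead:

```r
predict(fit, horizon = 3) |> tail(3)
#> # A tibble: 3 × 4
#>    year value predicted type
#>   <int> <dbl>     <dbl> <chr>
#> 1  2023    NA   111179. forecast
#> 2  2024    NA   120030. forecast
#> 3  2025    NA   129586. forecast
```

The full per-indicator pipeline — six fits, adequacy grades, forecasts, and
the 2025 plan comparison at the projected population of 22,343,500 —
is one call:

```r
gm11_report()$plan
#> # A tibble: 8 × 4
#>   indicator                target_2025 projected_2025 met
#>   <chr>                          <dbl>          <dbl> <lgl>
#> 1 beds_per_thousand               7.5           8.79  TRUE
#> 2 physicians_total            85100        101273.    TRUE
#> 3 physicians_per_thousand         3.54          4.53  TRUE
#> 4 nurses_total               110000        129586.    TRUE
#> 5 nurses_per_thousand             4.2           5.80  TRUE
#> 6 doctor_nurse_ratio              1.2           1.28  TRUE
#> 7 pharmacists_total           13000          9469.    FALSE
#> 8 pharmacists_per_thousand        0.54          0.424 FALSE
```

Every projection clears its plan target except the two pharmacist rows:
the projected 9,469 pharmacists (0.42 per thousand) fall well short of the
13,000 (0.54 per thousand) target, flagging a staffing gap the other five
resource categories do not have.

`ggplot2::autoplot(fit)` draws the fit with its forecast;
`autoplot(gm11_report()$plan)` draws the target-vs-projection comparison.
A thin command-line front end with `fit` / `forecast` / `diagnose` /
`report` / `simulate` subcommands ships in `inst/cli/greycast.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","greycast.R",package="greycast"))')" report --out results/
```

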