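# propelicit

Expert-elicited Bayesian priors for daily response propensity
prediction in survey data collection.

## The problem

Responsive survey designs tailor field effort using case-level
predictions — above all the probability that an active case responds to
the screener interview at its next contact attempt. Models fit only to
the paradata accumulated so far in the current collection period are
unreliable early and mid-collection, exactly when design decisions are
made. When historical data from the same survey exist, they can supply
informative priors; when they do not (new surveys, major redesigns),
the experience of survey managers can. propelicit is for survey
methodologists who want to turn structured expert judgments about
attempt-level response rates into priors on propensity-model
coefficients, and to measure what those priors buy.

## The model

Contact attempts are stacked into a person-attempt file and response is
modeled by discrete-time logistic regression: for case *i* on day *d*,

    p_id = exp(Σ_v β_v X_idv) / (1 + exp(Σ_v β_v X_idv)),

with fixed covariates (geography, sampling domain, household
characteristics) and time-varying attempt history (prior contact,
expressed concerns, attempt count). Each expert's elicited rate for
category *k* of item *j* becomes a coefficient via the log odds ratio
against that expert's reference-category rate,

    β̂_ijk = ln[ p̂_ijk/(1−p̂_ijk) ÷ p̂_ijR/(1−p̂_ijR) ],

(for continuous items, against the overall 24% attempt-level baseline);
coefficients are pooled across experts by arithmetic mean with standard
error sd/√n, giving a diagonal normal prior — applied only where at
least three experts contributed. The posterior is maximised
(Newton–Raphson MAP with a Laplace covariance), and a day-by-day replay
scores each method's next-attempt predictions against the
end-of-collection benchmark fit by daily bias and RMSE, summarised over
the early (7–30), middle (31–60) and late (61–84) phases of the
84-day quarter. A precision-weighted prior built from historical
quarters serves as the comparator, and a synthetic paradata generator
stands in for restricted production data.

## Worked example

```r
library(propelicit)

# the two elicitation conversions
round(categorical_beta(0.85, 0.70), 4)   # female 85% vs male 70%
#> [1] 0.8873
round(continuous_beta(0.05, 0.24), 4)    # +5 points per attempt at 24%
#> [1] 0.2573

# a synthetic quarter and a simulated 20-expert panel
cfg      <- truth_config(n_cases = 1000, seed = 2024)
attempts <- simulate_quarter(cfg)
panel    <- simulate_expert_panel(cfg, expert_panel_config(seed = 7))
prior    <- build_prior_table(panel, cfg$schema)
prior
#> # A tibble: 14 × 5
#>   term                           mean     se n_contributors source
#>   <chr>                         <dbl>  <dbl>          <int> <chr>
#> 1 (Intercept)                 -1.15   0.5                 0 intercept_anchor
#> 2 domain=moderate_minority    -0.0868 0.0729             20 expert
#> 3 domain=high_minority        -0.258  0.0631             20 expert
#> 4 msa_status=msa_non_self_rep -0.0674 0.0558             19 expert
#> 5 msa_status=non_msa           0.107  0.0508             19 expert
#> # ...

# replay the quarter day by day and score against the benchmark
replay <- replay_daily(attempts, cfg$schema,
                       priors = list(expert = prior),
                       methods = c("standard", "expert"))
target <- fit_target(attempts, cfg$schema)
ev     <- evaluate_replay(replay, target)
ps     <- phase_summary(ev)
ps[ps$metric == "rmse", c("method", "phase", "n_days", "median", "mean")]
#> # A tibble: 6 × 5
#>   method   phase  n_days median   mean
#> 1 expert   early      24 0.106  0.106
#> 2 standard early      24 0.116  0.122
#> 3 expert   middle     30 0.0877 0.0889
#> 4 standard middle     30 0.0940 0.0935
#> 5 expert   late       24 0.0479 0.0502
#> 6 standard late       24 0.0472 0.0498

autoplot(ev)  # phase boxplots of daily bias and RMSE, methods side by side
```

Reading the table: each row summarises the daily RMSE of a method's
next-attempt propensity predictions against the end-of-quarter
benchmark over one collection phase. Here the expert-prior method
tracks the benchmark more closely than the current-data-only method
through the early and middle phases (mean RMSE 0.089 vs 0.094
mid-collection) and the two converge late, once the accumulated data
dominate any prior.

A thin command-line front end over the same functions is installed at
`exec/propelicit` (subcommands `simulate`, `elicit`, `pwp`, `fit`,
`replay`); the methods vignette
(`vignettes/expert-priors-methods.Rmd`) documents the models, the
synthetic-data design and the package's numerical choices.

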