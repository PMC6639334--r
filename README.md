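# gainloss

Analysis of gain-loss asymmetry in risky binary choice, for behavioural
datasets in which a subject repeatedly chooses between two two-outcome
token lotteries — the paradigm used to ask whether non-human primates,
like humans, are risk-averse for gains but risk-seeking for losses.

Each lottery pays a non-zero integer token amount
$x \in \{\pm1, \pm2, \pm3\}$ with probability
$p \in \{0.25, 0.5, 0.75, 1\}$ and nothing otherwise, against a 3-token
per-trial stock (so "losses" are reference-dependent, never absolute).
Pairs with a stochastically dominant member (types 1–5) measure task
performance; risky-vs-safe pairs in the gain (type 6) and loss (type 7)
domains feed a prospect-theory-style decision model:

* utility $u(x) = x^{1-\omega_G}$ (gains), $-|x|^{1+\omega_L}$ (losses),
  on amounts normalized to $[-1, 1]$;
* Prelec probability weighting $w(p) = \exp(-(-\ln p)^{\alpha})$,
  with separate $\alpha_G$, $\alpha_L$;
* a monotone stochastic choice rule
  $P(\text{risky}) = \mathrm{logistic}\big(\lambda\,(\omega^* - \omega)\big)$,
  where $\omega^*$ is the pair's risk-attitude indifference point
  (closed form), with separate precisions $\lambda_G$, $\lambda_L$.

The six parameters $\theta = (\omega_G, \omega_L, \alpha_G, \alpha_L,
\lambda_G, \lambda_L)$ are estimated by binomial maximum likelihood over
per-pair choice counts, with 20-chunk chronological cross-validation,
Mann–Whitney gain-vs-loss contrasts under Bonferroni correction, a
certainty-risk chi-square contrast, per-type dominance performance
summaries, and a model-free sigmoid of risky-choice frequency on the
expected-value difference. A synthetic-agent simulator generates trial
tables with the task's session structure and token-gauge reward
bookkeeping, for validation and power analysis.

## Worked example

Simulate a synthetic subject with the published Monkey-H parameter
values over 30 sessions, then run the full analysis pipeline:

```r
library(gainloss)

cfg    <- run_config(seed = 42, n_days = 30)
trials <- run_simulation(cfg, quiet = TRUE)   # 6,195 trials
report <- run_analysis(trials, cfg)

report$certainty_risk
#> Certainty-risk trade-off contrast
#>   chi-square = 36.339, df = 1, p = 1.66e-09 (threshold 0.01) *
#>   risky-choice frequency: gains 0.244, losses 0.902

report$fit
#> Chunked decision-model fit: 20 chronological chunks
#>      omega_G omega_L alpha_G alpha_L lambda_G lambda_L
#> mean  0.3621 -0.6375  0.5874  0.2943   2.6132   2.9318
#> sd    0.1641  0.2252  0.2389  0.1998   1.0050   2.3673

report$contrasts
#> Gain-vs-loss parameter contrasts (Mann-Whitney, Bonferroni m = 3, threshold 0.01)
#>   family   u p_value p_adjusted significant n_gain n_loss
#> 1  omega   0  0.0000      0e+00        TRUE     20     20
#> 2  alpha  61  0.0002      5e-04        TRUE     20     20
#> 3 lambda 188  0.7455      1e+00       FALSE     20     20
```

Reading the output: the subject chooses the risky option far more often
for losses (0.90) than for gains (0.24) on the matched certainty pairs —
the human-like asymmetry. The chunked fit recovers a positive
$\omega_G$ (risk-averse for gains) against a strongly negative
$\omega_L$ (risk-seeking for losses) and a much stronger probability
distortion for losses ($\alpha_L \ll \alpha_G$); the Mann–Whitney
contrasts flag the $\omega$ and $\alpha$ asymmetries while the
precision family ($\lambda$) does not separate. `report$sigmoid`,
`report$dominance` and `report$trends` hold the remaining analyses;
`run_analysis(trials, cfg, out = "report/")` writes every table plus a
key-value summary to disk.

Lower-level entry points mirror the analysis steps: `design_table()`,
`classify_pair()`, `choice_prob_risky()`, `aggregate_choices()`,
`fit_mle()` (a classed fit with `coef`, `predict`, `residuals`,
`simulate`, `plot` methods), `chunked_fit()`,
`compare_gain_loss_params()`, `fit_risk_sigmoid()`,
`parameter_trend()`. A thin command-line wrapper lives at
`inst/cli/gainloss-cli.R` (`simulate` / `analyze` subcommands).

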