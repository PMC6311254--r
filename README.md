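# mlrldacp

Sparse multiple linear regression of clinical survival time on long
noncoding RNA (lncRNA) expression, for survival prediction and
lncRNA–disease association scoring.

## The problem

Most lncRNA–disease association predictors learn from networks of known
associations and similarity scores; few exploit clinical prognosis data
directly.  `mlrldacp` takes the opposite route: among candidate lncRNA
transcripts that are differentially expressed between normal and tumor
samples, it searches for the small subset whose expression best explains
patients' survival time, and uses the fitted regression both to predict
survival and to rank lncRNAs by disease relevance.  The intended user is
a computational biologist with a samples × transcripts expression matrix
(normal and tumor groups) and a TCGA-style clinical table
(`submitter_id`, `vital_status`, `days_to_death`,
`days_to_last_follow_up`).

## The method

The survival response is $La_i = Dd_i\,\alpha_i + Dl_i\,\beta_i$ — days
to death for deceased patients ($\alpha=1,\beta=0$), days to last
follow-up for living ones ($\alpha=0,\beta=1$) — modeled as

$$La = \Theta_0 + Led^{sub}\,\Theta + \varepsilon,$$

where $Led^{sub}$ holds the expression of a selected subset of $\Delta$
transcripts and $\Theta$ is the coefficient vector (survival-days per
expression unit).  Selection works on a binary inclusion vector over
candidates ranked by ascending differential-expression $P$ (Welch $t$,
retained at raw $P < 10^{-3}$):

1. seed with every candidate at $P < 10^{-12}$ (the seed size becomes
   the retention cap $\theta$);
2. for $d = 1,\dots,D{=}10$: flip all bits in a window whose center
   alternates around the vector midpoint and whose width shrinks with a
   decay coefficient $\xi(d) = \tanh(2(D-d)/(D+1))$ (floored at exactly
   0.1 in the last iteration); kick stalled configurations by inverting
   the leading $\theta$ bits; cap the active set at $\theta$;
3. reduce each active set by bidirectional stepwise selection under the
   Gaussian AIC, and keep the best reduced set seen on a bulletin board;
4. refit the winning subset by OLS to obtain $\Theta$, its residual
   standard error on $n-\Delta-1$ degrees of freedom, and the overall
   $F$-test $P$.

Evaluation harnesses compute fixed-horizon survival ROC/AUC (default 5
years) and leave-one-out cross-validation of lncRNA–disease association
ranking.  A synthetic cohort generator produces expression + clinical
data with planted differential and causal transcripts, so the entire
pipeline is testable without any download.  See the methods vignette
(`vignettes/mlrldacp-methods.Rmd`) for assumptions, parameter choices,
and limitations.

## Worked example

```r
library(mlrldacp)

spec <- cohort_spec(n_normal = 40, n_tumor = 120, n_transcripts = 150,
                    n_differential = 30, n_causal = 5,
                    effect_size = 5, noise_sd = 10, seed = 7)
cohort  <- generate_cohort(spec)
ranking <- differential_screen(cohort$normal, cohort$tumor, alpha = 0.001)
led <- build_led(cohort$tumor, ranking)
la  <- build_survival_vector(cohort$clinical, rownames(led))
fit <- run_search(led, la, ranking, gamma_config())
fit
#> Survival regression on 9 selected transcript(s)
#>   residual SE 9.557 on 110 degrees of freedom
#>   overall F-test P = 1.917e-182
#>   best stepwise AIC 893.84
round(fit$coefficients, 2)
#> (Intercept)     LNC0148     LNC0070     LNC0085     LNC0106     LNC0006
#>     1983.84      149.48       50.16      100.01     -124.30        1.01
#>     LNC0080     LNC0071     LNC0041     LNC0048
#>       -1.07      -75.40        0.86        1.23
cohort$truth$coefficients
#> LNC0070 LNC0071 LNC0085 LNC0106 LNC0148
#>      50     -75     100    -125     150
```

All five planted causal transcripts are recovered with coefficients
within a fraction of a day of truth (true intercept 2000); the four
extra retentions carry near-zero coefficients.  The residual SE (9.56
days) matches the planted noise SD of 10, and the fixed-horizon survival
ROC on this cohort is perfect:

```r
survival_roc(fit, led, cohort$clinical, horizon = median(la))
#> ROC curve: 97 threshold(s), AUC = 1.0000
```

The same pipeline is scriptable from a shell:

```sh
Rscript inst/exec/mlrldacp run-all --out results/demo \
    --n_tumor 120 --n_normal 40 --n_transcripts 150 \
    --n_differential 30 --n_causal 5 --effect_size 5 \
    --noise_sd 10 --seed 7 --horizon 2800
```

which writes the ranking, coefficient table, diagnostics, per-iteration
search trace, ROC points, and a run manifest.

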