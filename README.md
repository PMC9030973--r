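# engagetraj

Engagement-profile discovery and outcome prediction for multicomponent
digital mental health interventions.

## The problem

Long-running digital interventions that combine interactive therapy modules
("steps" and their behavioural "actions") with a moderated social network
generate rich per-day telemetry, but raw totals (log-ins, clicks) say
little about *how* someone engages. For cohorts such as young people
recovering from first-episode psychosis, the clinically interesting
question is whether distinct patterns of sustained engagement — with the
therapy content, the social network, or both — predict change in outcomes
like social functioning (PSP), psychotic symptoms (PANSS), depression
(CDSS) and anxiety (DASS).

`engagetraj` implements that analysis end to end:

1. **Daily categorization** — 13 raw per-day usage metrics are mapped to an
   ordinal activity level on each of two dimensions. Therapy:
   1 inactive, 2 passive (visits only), 3 engaged (exactly one step started
   or one action done), 4 highly engaged (>1 step, >1 action, or one of
   each). Social: 1 inactive, 2 passive, 3 moderate (liked/reacted only),
   4 active (posted or commented). Days always take the highest level whose
   condition they meet.
2. **Weekly joint trajectories** — each user's days 2–155 of trial
   involvement (154 days; day 1 is the platform induction) aggregate into
   22 weekly scores per dimension, each the *maximum* daily level in its
   7-day block; missing days count as inactive.
3. **Joint-trajectory k-means** — users are partitioned on the flattened
   44-entry trajectory under Euclidean distance
   `d(u, v) = sqrt(sum_{d,w} (u_dw - v_dw)^2)`, Lloyd's algorithm with 100
   restarts over three initialization schemes. Candidate k are compared by
   Calinski–Harabasz (higher better), Ray–Turi and Davies–Bouldin (lower
   better), a small-cluster exclusion rule, and Rand-index stability over
   100 resamples (80% subsampling), with majority vote across the indices.
4. **Outcome models** — baseline profile characterization (one-way ANOVA,
   chi-square, Tukey HSD) and, per outcome, the linear mixed model
   `value ~ group * time + sex + age + dup_days + (1 | user)` fitted by
   REML with Type III Satterthwaite F tests, model-implied cell means, and
   post-hoc contrasts (change within group; groups at a timepoint).

A synthetic-cohort generator (`simulate_cohort()`) with known latent
engagement archetypes and planted group-by-time effects makes the whole
chain verifiable by parameter recovery.

## Worked example

```r
library(engagetraj)

cohort <- simulate_cohort(seed = 1)       # 82 intervention users + 84 TAU
tm     <- build_trajectory_matrix(cohort$usage_log)
sel    <- select_solution(tm, k_range = 2:4, seed = 1)
print(sel)
```

```
Cluster-solution selection
 k calinski_harabasz ray_turi davies_bouldin min_size excluded mean_rand votes
 2            135.79    0.142          0.751       33    FALSE     1.000     3
 3             99.23    0.325          0.846       14    FALSE     1.000     0
 4             70.46    1.139          1.540        6     TRUE     0.939     0
 - excluded k = 4 (small cluster) 
 - calinski_harabasz favours k = 2 
 - ray_turi favours k = 2 
 - davies_bouldin favours k = 2 
 - selected k = 2 by majority vote 
```

The k = 4 solution is excluded (a 6-member cluster, below 15% of the
sample). The indices vote for k = 2: the default generator plants one large
disengaging archetype and two *maintained* archetypes that are closer to
each other than to the disengaged mass, so merging them is index-optimal —
the classic situation in which an analyst overrides the vote on
interpretability grounds. The 3-cluster solution is in the same report, and
here it recovers the planted archetypes perfectly:

```r
sol3  <- sel$solutions[["3"]]
truth <- setNames(as.integer(factor(cohort$truth$archetype)), cohort$truth$user_id)
adjusted_rand_index(sol3$labels, truth)
#> [1] 1

outcomes <- assign_groups(cohort$outcomes, sol3$labels)
fit <- fit_group_time_model(outcomes[outcomes$group != "TAU", ], "psp")
print(fit)
```

```
Linear mixed model for 'psp' (group * time + covariates + (1 | user))
       term     F df1 df2        p
      group 9.839   2  76 0.000158
       time 6.562   1  79 0.012300
        sex 1.575   1  76 0.213000
        age 0.334   1  76 0.565000
   dup_days 0.474   1  76 0.493000
 group:time 1.549   2  79 0.219000
Model-implied cell means (95% CI):
     group time  mean   se lower upper
 profile_1   t0 68.46 1.90 64.71 72.22
 profile_2   t0 56.79 3.05 50.75 62.84
 profile_3   t0 71.29 3.52 64.31 78.27
 profile_1   t6 69.77 1.90 66.01 73.52
 profile_2   t6 59.99 3.05 53.95 66.04
 profile_3   t6 79.60 3.52 72.62 86.58
```

`profile_3` is the planted maintained therapy-and-social archetype (14
users, planted +11-point PSP improvement). In this replicate the omnibus
interaction is not significant at the 5% level (F(2, 79) = 1.55, p = .22)
— at these group sizes the test has moderate power — while the post-hoc
within-profile change is:

```r
posthoc_time_within_group(fit, "profile_3")
#>       group estimate       se        F df1 df2          p
#> 1 profile_3 8.307796 3.515453 5.584818   1  79 0.02057546
```

i.e. an estimated 8.3-point (SE 3.5) baseline-to-6-month improvement for
that profile (the estimate equals the difference of its two cell means
above). Calibration of these tests — type-I error, bias and CI coverage
against planted effects — is established in the test suite, not from any
single replicate.

The one-command pipeline writes the full artifact bundle (trajectory CSV,
solution and results JSON, Markdown report, figures):

```r
run_pipeline(pipeline_config(output_dir = "demo_run", seed = 1))
```

A thin CLI over the same functions lives at `inst/cli/engagetraj.R`
(subcommands `simulate`, `trajectories`, `cluster`, `analyze`, `run-all`).

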