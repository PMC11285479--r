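# skewnet

Social control and reproductive skew in animal social networks.

In matrilineal, group-living mammals, a few females often wean most of a
group's offspring. `skewnet` asks whether that *reproductive skew* tracks
how concentrated social influence is within the group — not just who
outranks whom, but who can reach whom, directly or through intermediaries,
in the network of agonistic interactions. It implements the full analysis
chain for annually resolved colony data (built around long-term
yellow-bellied marmot field protocols) and a synthetic colony generator so
the entire chain can be exercised and validated without field data.

## The statistics at the core

* **Global reaching centrality (GRC).** For each individual, the local
  reaching centrality C_R(i) is the fraction of the other N − 1 group
  members reachable from i via directed paths in the (binarised) agonistic
  network. Then

  GRC = Σᵢ (C_R^max − C_R(i)) / (N − 1),

  0 for egalitarian structures (everyone reaches everyone), 1 for a
  despotic out-star (one female reaches all, nobody reaches anyone else).
* **Dominance linearity.** Landau's h = (12/(N³ − N)) Σᵢ (Sᵢ − (N−1)/2)²
  for complete tournaments, and de Vries's h′ — the mean of h over 10,000
  seeded random completions of matrices containing tied or unknown dyads.
* **The multinomial skew index.** M_raw = N Σᵢ (sᵢ/S_T − eᵢ/E_T)²
  compares offspring shares with exposure shares;
  M = M_raw − (N/S_T)(1 − Σᵢ pᵢ²) subtracts the exact expectation under
  exposure-proportional multinomial reproduction, so M ≈ 0 means "no skew
  beyond chance".
* **Group detection.** Simple-ratio association indices
  (SRI = x/(x + y_A + y_B + y_AB)) from daily space-use overlap, partitioned
  by greedy two-level map-equation (codelength) minimisation within each
  colony.
* **Inference.** Linear mixed models for standardised M with GRC, h′ and
  group size (all log-transformed, then z-scored) as fixed effects and
  crossed colony and year random intercepts, via lme4: a four-model ladder
  with marginal/conditional R², semi-partial R² (95% CI from 100 parametric
  bootstraps), AICc and VIFs.

See the methods vignette (`vignettes/social-control-and-skew.Rmd`) for the
models, their assumptions, and every numerical choice.

## Input formats

Four CSV schemas (RFC 4180, UTF-8, header row; see `?read_records` and the
bundled fixtures under `inst/extdata/toy/`):

| schema         | columns                                                              |
|----------------|----------------------------------------------------------------------|
| `registry`     | `individual_id, year, sex, age_class, colony, n_traps`               |
| `copresence`   | `individual_id, date, location`                                      |
| `interactions` | `timestamp, initiator_id, recipient_id, itype, location`             |
| `reproduction` | `mother_id, year, offspring[, exposure]`                             |

Malformed rows are rejected with line numbers in `attr(x, "problems")`;
`initiator_id`/`recipient_id` may be the sentinel `UNKNOWN` (such acts are
dropped by the eligibility filter, which also requires both parties to be
adult females trapped more than 5 times that year).

## Worked example

From the bundled toy colony (one colony-year, seven adult females):

```r
library(skewnet)
toy <- system.file("extdata", "toy", package = "skewnet")
reg    <- read_records(file.path(toy, "registry.csv"),     "registry")
ints   <- read_records(file.path(toy, "interactions.csv"), "interactions")
cp     <- read_records(file.path(toy, "copresence.csv"),   "copresence")
repr   <- read_records(file.path(toy, "reproduction.csv"), "reproduction")

filt   <- filter_agonistic_study_set(ints, reg, 2010)
groups <- detect_social_groups(cp, reg, 2010, seed = 1)
for (gid in unique(groups$group_id)) {
  net <- build_agonistic_network(filt, groups$individual_id[groups$group_id == gid],
                                 year = 2010, colony = "picnic", group_id = gid)
  print(hierarchy_metrics(net, n_perm = 10000, seed = 1))
}
skew_by_group(repr, groups, 2010)
```

```
Hierarchy metrics for picnic.g1 (N = 4)
  GRC = 0.556   h' = 1.000 (10000 completions, 0 undecided dyads)
Hierarchy metrics for picnic.g2 (N = 3)
  GRC = 0.500   h' = 1.000 (10000 completions, 1 undecided dyads)
   group_id colony year n_females total_offspring     m_raw null_expectation
1 picnic.g1 picnic 2010         4               9 0.7283951        0.3333333
2 picnic.g2 picnic 2010         3               7 0.2857143        0.2857143
        m_index
1  3.950617e-01
2 -5.551115e-17
```

Group g1 is moderately despotic (GRC 0.56) with skew well beyond chance
(M = 0.40: its raw deviation 0.73 is more than double the 0.33 expected
from whole-pup randomness alone), while g2's offspring division is exactly
at its chance expectation (M = 0).

At study scale, the same chain runs end to end on a synthetic world with
despotism–skew coupling switched on:

```r
world <- generate_colony_data(synthetic_config(n_groups = 100), seed = 42)
res <- run_pipeline(world, outdir = "runs/demo", seed = 42,
                    n_perm = 1000, n_boot = 20)   # demo-sized settings
print(res$ladder)
summary(res$ladder$fits$full)
```

```
Skew model ladder (100 group-years)

       model n_fixed aicc r2_marginal r2_conditional
        full       3  202       0.609          0.613
    grc_size       2  209       0.571          0.585
 hprime_size       2  225       0.504          0.519
   size_only       1  232       0.455          0.490

Group-level skew mixed model: m_std ~ grc_ls + hprime_ls + gsize_ls + (1 | colony) + (1 | year_f) 
n = 100 group-years; R2 marginal = 0.609, conditional = 0.613; AICc = 202.11

            estimate       se     z       p    
(Intercept) -0.00037  0.06536 -0.01  0.9955    
grc_ls       0.33521  0.06407  5.23 1.7e-07 ***
hprime_ls   -0.31144  0.09982 -3.12  0.0018 ** 
gsize_ls     0.39273  0.09971  3.94 8.2e-05 ***
```

The planted coupling is recovered: one standard deviation of
log-despotism (GRC) buys 0.34 standard deviations of skew (p ≈ 2 × 10⁻⁷),
and the GRC models dominate the AICc ladder. The run directory contains
tidy CSVs for every stage, a plain-text model report, and a JSON manifest
recording seeds and the row-count funnel.

A thin shell wrapper is provided for whole runs:

```sh
Rscript scripts/run_pipeline.R --outdir runs/demo --seed 1
```

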