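---
title: "Group-level social control and female reproductive skew: models and methods"
author: "skewnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level social control and female reproductive skew: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewnet)
```

## The scientific question

In many group-living mammals, same-sex reproduction is unevenly shared:
a few females wean most of the offspring. A long-standing hypothesis is
that this *reproductive skew* is produced by social control — dominant
individuals suppressing the reproduction of subordinates. Dominance rank,
however, only describes *direct* dyadic relationships. An individual can
also exert influence through intermediaries, so a group-level measure of
how concentrated social influence is — accounting for paths through the
whole agonistic network — may capture control that rank-based measures
miss.

`skewnet` implements that analysis chain for annually resolved colonies of
a facultatively social, harem-polygynous rodent (matrilineal female groups
of roughly 3–11 adults, such as yellow-bellied marmots), from raw field
records to a mixed-model variance decomposition:

1. **records** — validated CSV input for individual-year registries,
   co-presence sightings, directed social interactions, and pedigree-based
   reproduction counts; eligibility filtering (adult females, trapped more
   than `min_traps = 5` times, known initiator and recipient, active-season
   dates).
2. **grouping** — simple-ratio association indices from daily space-use
   overlap, and social-group detection by two-level map-equation
   minimisation, colony by colony.
3. **hierarchy** — directed, weighted agonistic networks per group-year;
   local and global reaching centrality; Landau's h and de Vries's
   randomised h′.
4. **skew** — the multinomial M index with its exact null correction.
5. **inference** — linear mixed models for standardised M with crossed
   colony and year random intercepts; marginal, conditional and
   semi-partial R²; AICc; VIF.
6. **synthetic_data** — a colony generator with tunable despotism–skew
   coupling, used throughout the tests.

## Statistics implemented

### Global reaching centrality

For a directed graph on $N$ nodes, the *local reaching centrality*
$C_R(i)$ is the fraction of the other $N-1$ individuals reachable from $i$
along directed paths. The *global reaching centrality* is

$$\mathrm{GRC} \;=\; \frac{\sum_i \left(C_R^{\max} - C_R(i)\right)}{N - 1},$$

which is 0 when everyone reaches everyone (directed cycles, strongly
connected "egalitarian" structures) and 1 for an out-star (one despot
reaches all; nobody else reaches anyone). By default the agonistic network
is binarised before reachability is computed — any act $i \to j$ creates
an edge — because reachability, not interaction volume, is the quantity of
interest; a weighted variant (mean normalised edge weight along shortest
paths) is available behind `weighted = TRUE` but is not the default.
Networks with fewer than three members are ineligible, and a network with
no interactions at all has every $C_R = 0$, hence GRC $= 0$: egalitarian
by absence of evidence, flagged in the pipeline log as low-information.

### Dominance linearity

From the directed act counts, each dyad is classified *win/loss* (strict
majority), *tie* (equal non-zero counts), or *unknown* (no acts). For a
complete tournament Landau's index is

$$h = \frac{12}{N^3 - N} \sum_i \left(S_i - \tfrac{N-1}{2}\right)^2,$$

with $S_i$ the number of dyads $i$ wins. Real matrices contain ties and
unknowns, so the package reports de Vries's corrected index $h'$: every
unknown dyad is assigned a random direction, every tied dyad a fair coin,
and $h'$ is the mean of $h$ over `n_perm = 10000` random completions. One
seeded generator fills dyads in fixed row-major order, so results are
bit-reproducible. We use simple random fill, matching the index's plain
definition, rather than the improved randomisation variant.

### The M index of reproductive skew

With offspring counts $s_i$ (total $S_T$) and exposures $e_i$ (total
$E_T$, default equal):

$$M_{\mathrm{raw}} = N \sum_i \left(\frac{s_i}{S_T} - \frac{e_i}{E_T}\right)^2,
\qquad
M = M_{\mathrm{raw}} - \mathbb{E}\!\left[M_{\mathrm{raw}}\,\middle|\,\text{null}\right],$$

where the null assigns each of the $S_T$ offspring independently to mother
$i$ with probability $p_i = e_i/E_T$. Because
$\operatorname{Var}(s_i/S_T) = p_i(1-p_i)/S_T$ under that multinomial
null, the correction has the closed form

$$\mathbb{E}[M_{\mathrm{raw}}] = \frac{N}{S_T}\Bigl(1 - \sum_i p_i^2\Bigr),$$

so $M \approx 0$ for chance-level sharing, $M > 0$ for skew, and slightly
negative values for more-even-than-chance sharing. The test suite
validates the closed form against a Monte-Carlo oracle
(`null_m_distribution()`, $10^5$ draws, 3-standard-error tolerance) and
against exhaustive enumeration when $S_T = 1$. All adult females of a
group enter the computation, including non-breeders; breeding groups need
at least three females and at least one assigned offspring.

### Map-equation group detection

Social groups are detected from the simple-ratio association matrix
(association = recorded at the same location on the same day;
$\mathrm{SRI} = x/(x + y_A + y_B + y_{AB})$). The two-level map equation
scores a partition $M$ of the network by the description length of a
random walk,

$$L(M) = q_\curvearrowright H(Q) + \sum_m p^\circlearrowright_m H(P_m),$$

with node visit rates proportional to strength and module exit rates
proportional to boundary weight. The optimiser sweeps nodes in a seeded
random order, moving each to the neighbouring module that lowers $L$ most
(ties to the lowest module index), then attempts whole-module merges, and
alternates until neither step improves. We deliberately evaluate merges on
the original network rather than on an aggregated super-node graph: the
two-level codelength has no self-loop term, so naive aggregation discards
within-module flow and systematically over-merges. On graphs small enough
for exhaustive search (all partitions, $n \le 7$) the greedy optimum
matches the global optimum in the large majority of random instances, and
the detected codelength never exceeds the one-module baseline. Isolated
individuals become singleton groups; detection runs within colonies, which
are treated as containers of groups. Because the optimiser is ours and
seeded, group assignments are reproducible but can differ from other map
equation implementations on ambiguous data.

### The mixed model

Group-years with GRC, h′ and M all defined enter the analysis table. GRC,
h′ and group size are log-transformed — zeros (legitimate for GRC) are
replaced by half the smallest positive observed value of that column
before the log — and all variables, M included, are z-standardised. The
headline model is

$$M^{std}_{gct} = \beta_0 + \beta_1\,\mathrm{GRC}^{ls} + \beta_2\,h'^{ls} +
\beta_3\,\mathrm{size}^{ls} + u_c + v_t + \varepsilon,$$

with crossed random intercepts for colony ($u_c$) and year ($v_t$), fitted
by REML with lme4; the model ladder refits with GRC + size, h′ + size, and
size only. Reported alongside the coefficients:

* **Marginal / conditional R²** — fixed-effect variance over total
  variance, and fixed-plus-random over total.
* **Semi-partial R²** — each predictor's drop in marginal R² upon removal,
  with 95% confidence intervals from 100 parametric bootstrap iterations
  (response simulated from the fitted model with fresh random effects and
  residuals, all models refitted).
* **AICc** — $\mathrm{AIC} + 2k(k+1)/(n-k-1)$ from a maximum-likelihood
  refit, where $k$ counts fixed effects, variance components and the
  residual variance. When $n \le k + 1$ the correction is undefined:
  `aicc()` errors, and `fit_skew_model()` records `NA` with a warning so
  tiny datasets still produce the rest of the readout.
* **VIF** — from the inverse correlation matrix of the fixed-effect
  columns; perfectly collinear designs are reported capped at $10^6$ with
  a warning.

Defaults the data do not dictate, chosen once and exposed as arguments:
REML for reported estimates with an ML refit only for AICc; Wald $z$
p-values (Satterthwaite degrees of freedom available via
`pvalues = "satterthwaite"` when lmerTest is installed — $t$-based
p-values are never smaller, so the default is the anti-conservative
choice at small $n$); crossed rather than nested random intercepts.

## The synthetic colony generator

`generate_colony_data()` emulates the structure of the field data so every
stage is testable without any download. Defaults mirror the study
conditions the pipeline was designed around: 25 adult-female group-years
spread over 3 colonies and 11 years; group sizes 3–11 from a shifted,
truncated negative binomial (size 0.3, mean parameter 20, shifted by +3,
achieved moments ≈ 4.8 ± 2.4 — the family cannot quite reach the observed
4.68 ± 2.58, which we accept rather than switching to an ad-hoc mixture);
about 140 observation days per season with daily detection probability
0.35 at the group's home burrow and 0.05 at a shared colony location, so
within-group association dwarfs between-group association.

Each group receives latent ranks $1..N$ and a despotism level $\delta$
(by default drawn uniformly from $[0, 2]$). The female of rank $r$
initiates aggression at Poisson rate
$\lambda\,e^{-\delta (r-1)}$ toward each lower-ranked female, and at
`noise_frac` times that rate toward each higher-ranked female. Making the
up-hierarchy ("retaliation") rate proportional to the initiator's own
despotism-damped rate — rather than a constant — is deliberate: with a
constant retaliation rate, high-$\delta$ networks accumulate upward edges
that give subordinates full reach (one edge to the despot suffices) while
$\delta = 0$ networks stay asymmetric, and mean GRC is then not monotone
in $\delta$. With the damped form, mean generated GRC rises strictly
through ≈ 0.08, 0.32, 0.52, 0.85 along $\delta \in \{0, 0.5, 1, 2\}$, and
dominance matrices still contain realistic fractions of tied and unknown
dyads (≈ 7–35%), exercising the h′ permutation machinery. `noise_frac`
defaults to 0.3 so that $\delta = 0$ groups are genuinely egalitarian.

Reproduction is Dirichlet-multinomial: the group total is Poisson with
mean $N \times$ `mean_litter` (default 3 weaned offspring per female-year,
a typical weaned-litter contribution once non-breeders are averaged in),
and concentration $\alpha_i \propto e^{-\kappa\,\delta\,(r_i - 1)}$, so
the coupling parameter $\kappa$ links despotism to skew ($\kappa = 0$ is
the null world). Colony, year and group effects act multiplicatively on
the concentration scale (log-normal, SDs 0.4/0.4/0.3), creating the
random-effect structure the mixed model partitions. Ground truth
($\delta$, $\kappa$, ranks, latent scales) is emitted in a sidecar table
the pipeline never reads.

### What the generator does and does not show

Passing tests on this world demonstrate that the statistics are computed
correctly, that the detection–measurement–model chain recovers a planted
despotism–skew coupling at realistic sample sizes (positive, significant
GRC coefficient at 100 group-years; null behaviour controlled at
$\kappa = 0$), and that every seeded stage is reproducible. They do not
demonstrate field realism: the generator has no demography (no survival,
dispersal, age structure, male behaviour), independent group-years rather
than persistent matrilines, a single home location per group, and equal
exposure for all females. One synthetic-world artefact deserves note: h′
inherits a strong *inverse* despotism signal, because high $\delta$
thins the dominance matrix (many unknown dyads) and random completion
pulls h′ toward its chance level. In small analysis sets h′ can therefore
out-compete GRC for the same latent signal in the conditional
coefficients, with a negative sign — a pattern that says more about this
generator than about any real population, where near-complete matrices
with high linearity co-occur with despotic structure.

## Numerical and degenerate-input choices

* Reaching centralities come from per-node breadth-first search and are
  tested exactly against an independent transitive-closure oracle on
  hundreds of random digraphs.
* Codelength uses the $0 \log 0 = 0$ convention; edge-free networks have
  codelength 0 and all-singleton groups.
* Move acceptance in the optimiser requires improvement beyond $10^{-12}$
  bits, so floating-point ties cannot cycle.
* h′ completions are drawn by one generator in fixed dyad order, making
  every reported h′ a deterministic function of (matrix, n_perm, seed).
* Standardisation refuses constant columns (zero SD) rather than emitting
  NaN; assembly refuses analysis sets of fewer than three group-years.
* Bootstrap iterations whose refit fails are skipped and counted, with a
  warning past 10%.
* All seeded entry points restore the caller's RNG state on exit.

## Problem sizes used in validation

The shipped test-and-validation suite works at deliberately modest sizes
chosen to pin each property with comfortable statistical margins: 500
random digraphs ($N \le 6$) for the reachability oracle; exhaustive
digraph enumeration at $N = 3$ and partition enumeration to $n = 7$;
$10^5$ multinomial draws per M-index calibration point at
$(N, S_T) \in \{(3,6), (5,10), (8,24)\}$; 20 seeds on the planted
15-node, 3-block association matrix; 100 replicates of 100 group-years
for the mixed model's power (effect 0.6, observed 100/100) and size
(observed 2/100) properties; and 120 groups per despotism level for the
monotone-coupling ladder. The acceptance script runs the full pipeline at
the default study scale of 25 group-years with 10,000 h′ permutations and
100 bootstrap iterations.

## Known limitations

* The greedy map-equation optimiser is exactly that — greedy; on
  ambiguous association structure it may return a partition other
  implementations would not, and group-dependent quantities inherit that
  choice. Seeds make it reproducible, not canonical.
* The weighted GRC variant is one defensible generalisation among
  several; conclusions in the default analysis never depend on it.
* Wald $z$ p-values are anti-conservative at very small numbers of
  group-years; use the Satterthwaite option when that matters.
* Exposure defaults to equal across females within a group-year; if
  residency varies, supply an exposure column.
* M is undefined for groups whose females weaned nothing in a year; such
  group-years are excluded rather than imputed, which can bias analysis
  sets toward more successful groups in sparse data.
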