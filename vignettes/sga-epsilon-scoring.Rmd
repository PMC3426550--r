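---
title: "Quantitative genetic-interaction scoring for colony-array screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetic-interaction scoring for colony-array screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(data.table)
library(sgaepsilon)
```

## The measurement

A synthetic genetic array (SGA) screen crosses a *query* deletion strain
into a genome-wide collection of *array* deletion strains and pins the
resulting double (or triple) mutants as colonies on high-density agar
plates.  Colony area is the fitness readout.  The quantity of interest for
each (array gene *x*, query *q*) pair is the genetic-interaction score

$$\varepsilon = W_{xq} - W_x \cdot W_q,$$

the deviation of the observed combined-mutant fitness $W_{xq}$ from the
multiplicative expectation given the single-mutant fitnesses $W_x$ (array
strain) and $W_q$ (query strain).  Fitness is colony size relative to a
neutral reference: the median colony size of a `his3`-deletion
border-control strain in the control screens, so the wild-type reference has
$W \equiv 1$.  Negative $\varepsilon$ is an aggravating (synthetic sick)
interaction, positive $\varepsilon$ an alleviating one.  The same formula
scores trigenic interactions when the query is itself a double mutant —
$W_q$ is then the double-mutant query fitness.

The screen design this package emulates and analyses: 4292 array strains in
duplicate on 32 x 48 (1536-colony) plates, a two-colony border-control
perimeter on every plate, 5 replicate control screens (neutral query) and 3
replicate screens per deletion query, so each array strain is measured by
10 control colonies and 6 colonies per query.

## Plate normalization, and why the query fitness is measured separately

Of each plate's two control rings only the *inner* perimeter (148 positions
on a 32 x 48 plate) competes for nutrients the way interior colonies do; the
outermost ring grows larger for lack of neighbors and is excluded from all
statistics.  Each plate's median inner-perimeter control size is its *plate
median*, and the median of all plate medians across every screen is the
*experimental median*.  Every colony is rescaled:

$$\text{normalized size} = \text{raw size} \times
  \frac{\text{experimental median}}{\text{plate median}}.$$

This removes per-plate effects (pinning density, agar batch, incubation
position) exactly: any multiplicative per-plate distortion cancels in the
ratio.  `normalize_screens()` also accepts a fixed `reference_median`, which
makes normalized sizes exactly invariant to such distortions rather than
invariant up to one global factor.

There is a subtlety that shapes the whole scoring stage.  In a query screen
the border-control colonies are themselves crosses of the control strain
with the query, so they carry the query's fitness $W_q$ — and pinning each
plate to its own inner-perimeter median therefore **divides $W_q$ out of
every query-screen colony**.  Two consequences:

* $W_q$ can only be measured on **raw** sizes: `score_screens()` takes the
  ratio of the raw inner-perimeter medians of the query screens (3108
  colonies per query under the default design) to those of the control
  screens (5180 colonies).
* The observed combined fitness must re-introduce the factor the plate
  scaling removed:
  $W_{xq} = W_q \times \text{(normalized query mean)} / \text{(control median)}$.

Under the multiplicative null this construction centers $\varepsilon$ at
zero; without the $W_q$ correction the null distribution would sit at
$W_x(1 - W_q) \approx +0.05$, visibly biased.  The package checks this
calibration on full-size null simulations (fitted center below 0.01 in
absolute value).

## Replicate aggregation and hit calling

Within each screen group (pooled control screens, or one group per query) a
strain's normalized colony sizes are aggregated with a single-pass outlier
filter: mean and sample SD over all sizes, removal of values more than 2 SD
from the mean, then one recomputation on the survivors
(`aggregate_strain()`).  The filter is deliberately not iterated.  Control
and query groups are then compared with a two-tailed Welch (unequal
variance) *t*-test computed from the post-filter summary statistics; the
degenerate all-equal cases use the convention $p = 1$ for equal means and
$p = 0$ otherwise.

A stringent hit must satisfy all three criteria jointly:

| criterion | default | units |
|---|---|---|
| mean size difference (absolute) | >= 40 | pixels |
| Welch p-value | <= 0.01 | — |
| epsilon | <= -0.12 or >= 0.2 | — |

Values exactly at a threshold are included.  The asymmetric epsilon cutoffs
reflect the asymmetry of the score's empirical distribution in this screen
design.  No multiple-testing correction enters the call — the raw p-gate is
part of the joint criterion — but a Benjamini–Hochberg column is emitted for
information.  Array strains whose control fitness falls below a floor
(default $W_x < 0.05$) are flagged dead and excluded from calling; strains
annotated as dubious ORFs are scored and flagged but removed from the
verified gene set, since their deletion phenotype duplicates the overlapping
neighbor gene's.  That duplication is exploited as a reproducibility check:
the Pearson correlation of $\varepsilon$ across queries between dubious
ORFs and their neighbors (`correlate_epsilon_vectors()`).

## The synthetic screen generator

To make every stage testable without experimental data,
`simulate_screen_set()` generates complete screen sets whose defaults *are*
the target design and its observed noise scales:

* 4292 array strains, duplicate copies on the same plate (7 plates of 1232
  interior positions), 5 control + 3 x 3 query screens = 98 plates;
* query fitness defaults 0.95, 0.96 and 0.89 for the two single-deletion
  queries and the double-deletion query — mild growth defects, as required
  for the multiplicative model's additive approximation to be comfortable;
* per-colony multiplicative log-normal noise with CV 0.12, the typical
  average replicate CV for healthy deletion strains in this format; colony
  areas are positive and right-skewed, which a log-normal captures with an
  exact mean;
* one multiplicative log-normal plate effect per (screen, plate), log-scale
  sd 0.10 — per-plate normalization exists precisely because such effects
  are real, though their magnitude is rarely reported; 10% is a realistic
  batch scale and gives the normalization real work to do;
* gross outliers: 1% of colonies multiplied or divided by 3, emulating
  pinning failures and satellite colonies, and exercising the 2-SD filter;
* border-control colonies in query screens drawn at mean
  $\text{baseline} \times W_q$, so query fitness is recoverable exactly the
  way the analysis measures it;
* planted true interactions via `planted_effects`, with the ground truth
  returned for recovery checks; 40 dubious/neighbor strain pairs by
  default, the dubious partner mirroring the neighbor's planted effect.

Colony sizes are kept continuous (not rounded to integer pixels); at a
343-pixel baseline rounding would perturb sizes by under 0.2% and only blur
the exactness of the mean.

What the generator does **not** emulate: within-plate spatial gradients
(row/column or edge effects beyond the perimeter construction — the analysis
performs no spatial correction either), strain-specific noise heterogeneity
(every strain shares one CV, so the simulated CV distribution is narrower
than a real screen's), pinning-order or batch drift across replicates,
linkage between neighboring array positions, and competition coupling
between adjacent colonies.  Passing tests therefore demonstrate the
*pipeline's* correctness and calibration under the stated noise model, not
robustness to every artifact of real plates.

## Numerical and design choices

* **Experimental median**: the median of the per-plate medians over every
  plate of every screen, control and query pooled (even counts: mean of the
  two central values).  A pooled-colony alternative is available
  (`experimental_median = "pooled"`); the two differ only in how plates of
  unequal noise are weighted.
* **Welch test from summary statistics**: the scoring stage operates on
  filtered means/SDs/counts, so the Welch statistic and Welch–Satterthwaite
  degrees of freedom are computed vectorized from those summaries (verified
  to machine precision against `stats::t.test` and against a permutation
  oracle in the tests).  Post-filter counts enter the degrees of freedom.
* **Gaussian fit of the epsilon histogram**: left-closed, right-open bins of
  width 0.025 anchored at 0; `minpack.lm` Levenberg–Marquardt fit of
  $A\exp(-(x-\mu)^2/2\sigma^2)$ to bin counts at bin midpoints, initialized
  from the sample moments; adjusted $r^2$ with 3 fitted parameters.
* **Cross-query overlap**: membership uses the pixel and p gates only (the
  epsilon cutoffs are applied afterwards when compiling the stringent set),
  so the overlap diagnostic is not circular in epsilon.
* **Hypergeometric enrichment**: one-sided upper tail $P(X \ge k)$,
  `stats::phyper`; terms with no annotated universe genes are skipped; BH
  column informational.
* **Recovery accounting**: a planted strain counts as recovered when it
  passes the stringent criteria with the correct epsilon sign in at least
  one query screen — the strain (gene) level at which screen hit lists are
  compiled.  Per-(strain, query) recall is intrinsically limited for
  alleviating effects: a +0.30 interaction moves a query colony mean by
  roughly $343\,\varepsilon/W_q \approx 108$ px against a standard error of
  ~25 px with 6 replicates, so single-screen power at the joint criteria is
  well below 1, while three screens together detect essentially all such
  strains.
* **Problem sizes in the tests**: full-design simulations (98 plates,
  ~150k colonies) are used for the calibration and bookkeeping checks;
  parameter-recovery bias uses 10x replication; unit fixtures use 1-plate
  layouts with the plate-effect sd reduced to 0.02–0.03 because a single
  plate per screen leaves the raw-median query-fitness measurement with
  almost nothing to average over.

## Limitations

The query-fitness measurement inherits plate-effect noise (it is the one
quantity that cannot be read off normalized sizes), adding a shared relative
error of a few percent per query at the default design; it attenuates or
inflates all of that query's epsilon scores proportionally.  The epsilon
cutoffs, pixel gate and p gate are calibrated for this colony format and
noise scale and should be revisited for other densities.  The enrichment
stage assumes pre-flattened annotation terms; no ontology propagation is
performed.

```{r quick-example}
cfg <- sga_sim_config(n_array_strains = 200, seed = 1,
  planted_effects = data.frame(strain_id = "STR0001",
                               query_name = "scs3d", epsilon = -0.35))
sim <- simulate_screen_set(cfg)
nr <- normalize_screens(sim$colonies, sim$layout)
sc <- score_screens(nr$colonies, sim$layout)
sc$records[array_gene == "STR0001" & query == "scs3d",
           .(delta_pixels, p_value, epsilon, class, stringent_flag)]
```
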