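---
title: "Compartmentalized host-parasite replicator networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmentalized host-parasite replicator networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replinet)
```

## The system being modelled

`replinet` simulates a translation-coupled RNA replication system dispersed
in water-in-oil droplets. Two classes of RNA replicators live in the
droplets: *hosts*, which encode a replicase and can therefore drive the
copying of any template in the same droplet, and *parasites*, which are
copied by host-derived replicase but encode nothing themselves. The central
scientific question the package addresses is how such a system can grow in
network complexity — from a single self-replicating host, through
two-member host-parasite (HP) or host-host (HH) networks, to three-member
networks (HHP, HPP, HHH) — despite competitive exclusion and parasite
exploitation.

## Within-compartment dynamics

Inside one compartment the copy numbers follow coupled logistic
cross-replication equations. For host $i$ and parasite $h$:

$$\frac{dH_i}{dt} = H_i \Big(\sum_j k_{ji}^H H_j\Big)
  \Big(1 - \frac{\sum_j H_j + \sum_h P_h}{N}\Big), \qquad
\frac{dP_h}{dt} = P_h \Big(\sum_j k_{jh}^P H_j\Big)
  \Big(1 - \frac{\sum_j H_j + \sum_h P_h}{N}\Big),$$

where $k_{ji}^H$ is the dimensionless coefficient with which host $j$'s
replicase copies host $i$ (and $k_{jh}^P$ likewise for parasite $h$), and
$N$ is the carrying capacity shared by all compartments (default 100
copies). There is no degradation term — decay is negligible on the
time scale of one replication step in the experimental system the model
mirrors. Parasites appear only in the template sums, never as replicase.

Three consequences the implementation preserves exactly:

* an empty compartment stays empty (no spontaneous generation);
* parasites without a co-residing host do not change;
* a compartment whose total equals $N$ is a fixed point, and a compartment
  pushed above $N$ by fusion decays toward $N$, never below zero.

### Integration horizon

The duration of the replication step is a genuinely open design choice:
the serial cycle only requires that replication runs "to completion". We
integrate over one model-time unit. Because the dynamics saturate at the
carrying capacity (the logistic factor vanishes), the final composition is
insensitive to the horizon once the compartment has saturated; the test
suite verifies directly that horizons of 1 and 10 give the same continuous
endpoint to within $10^{-3}$ copies for the coefficient magnitudes of the
study designs (roughly 1.7–2.6 for hosts, up to 20 for parasites). The
insensitivity argument does *not* hold for very small coefficients
($k \approx 0.2$) seeded with very few copies — such compartments have not
saturated at horizon 1 — which is intended: those are exactly the cells of
the sweep designs in which replication is too slow to outrun dilution.

### Solver and discretization

The equations are smooth and non-stiff at these magnitudes, so an adaptive
explicit Dormand–Prince 5(4) pair is used, with relative tolerance
$10^{-6}$ and absolute tolerance $10^{-9}$, and an early exit once the
largest remaining possible change falls far below the absolute tolerance.
The test suite pins the solver against an independent fixed-step RK4
integrator at step $10^{-5}$ to a relative error below $10^{-4}$.

Compartment contents must re-enter the stochastic cycle as integers. The
default conversion is stochastic rounding — floor plus a Bernoulli draw on
the fractional part — which is unbiased in expectation, so repeated
rounding adds no systematic drift to population sizes. A deterministic
nearest-integer mode exists for exactly reproducible unit checks.

Because the continuous endpoint is a deterministic function of the integer
initial counts for a fixed coefficient matrix, the engine memoizes that map
within a run (invalidating on any coefficient change). This changes no
computed value — the rounding draw stays per-compartment — and removes the
large majority of integrations.

## The serial cycle

One round applies three steps to all $C$ compartments (defaults in
parentheses are the study conditions):

1. **Replication** in every compartment, as above.
2. **Culling**: $\lfloor C S \rfloor$ compartments chosen uniformly keep
   their contents; the rest are replaced by empty compartments
   ($C = 3000$, $S = 0.25$, i.e. 750 survivors — the analogue of a 4-fold
   serial dilution of droplets).
3. **Fusion–division**, repeated $A$ times ($A = 5000$): two distinct
   compartments are chosen uniformly, their contents pooled, and each
   species' copies redistributed by a Binomial$(n, 1/2)$ draw. This is the
   model's only mixing mechanism and conserves every species' global total
   exactly.

A run lasts 100 rounds by default, starting from every compartment filled
with equal shares of all founders ($\lfloor N/n \rfloor$ copies each). A
species is *sustained* if its global total strictly exceeds $C$ after the
final complete round; evaluating after the full round (rather than before
the last fusion–division) is immaterial for the totals, since
fusion–division conserves them.

When the compartment number is changed, the fusion–division frequency
should scale with it to keep the mixing rate per compartment constant;
`scale_fusion_divisions()` implements the scaling used for the published
configuration pairs (3000 events pair with 5000, 10000 with 16500 — i.e.
proportional scaling rounded down to a multiple of 500).

## Sustainability sweeps

`topology_spec()` / `run_sweep()` reproduce the parameter screens: each
grid cell runs `n_runs` independent simulations (default 100; 10 is
conventional for supplementary-scale screens) and tallies outcomes by the
exact set of sustained species. Host coefficient axes use
$\{1.7, 2.0, 2.3, 2.6\}$ (bracketing the experimentally estimated 2.0–2.3)
with extremes 0.2 and 4.1, and parasite axes extend to 20. The two-host
diagonal on which hosts 1 and 2 are interchangeable is flagged rather than
dropped. Per-cell seeds derive deterministically from (master seed, cell,
run), so any subset of cells reproduces in isolation and execution order
never matters.

`check_hhp_condition()` encodes the empirical sustainability condition for
two-host/one-parasite networks: asymmetric parasite resistance
($k_{11}^P > k_{21}^P$), the resistant host feeding the susceptible one
more than itself ($k_{21}^H > k_{22}^H$), and the susceptible host
receiving at least as much replication in total
($k_{11}^H + k_{21}^H \ge k_{12}^H + k_{22}^H$).

## Evolutionary transitions

`run_evolution()` starts from a single host (self-replication coefficient
2.0) filling all compartments and adds an appearance step immediately
before each replication step. Appearance is driven by the previous round's
replication tallies — the mutation step precedes replication, and
replication counts are only defined by a completed replication step, so
round 1 has no appearance. For each (species, compartment) the appearance
probability is $\min(1, n \times \text{rate})$ with $n$ the replication
count there: hosts spawn new hosts at 0.02 per replication (the replicase
error rate of roughly $9.1 \times 10^{-6}$ per nucleotide over a
$\sim$2000-nt host RNA, see `mutations_per_replication()`) and new
parasites at 0.001; parasites spawn new parasites at 0.002 (their RNA is
roughly 10-fold shorter). At most one new host type and one new parasite
type arise per round; all firings of one class in a round belong to the
same new species. New coefficients are drawn uniformly — host coefficients
from $[1, 3]$, parasite coefficients from $[0, 10]$ — and the step is
skipped entirely while the concurrent species count is at the cap
(3 species, a deliberate economy of the original design).

### Seeding policy (a design decision)

Two readings of the appearance step are defensible, and they differ
materially. Taken literally, every firing (species, compartment) pair
contributes one copy of the round's new species; at study scale the firing
probability is near 1 in thousands of compartments, so a new species would
enter with thousands of copies spread across the population, and rescue of
a collapsing population by fresh hosts becomes near-certain. The
documented behaviour of the system, however, is that a new replicator
starts from a single copy and, when lucky, "replicates from 1 to above
100" within its appearance round. The package therefore defaults to
`seeding = "single_compartment"`: the new species receives one copy in one
compartment chosen uniformly among the firing compartments. The literal
variant is available as `seeding = "all_firing"`. Under the default the
package reproduces the directional compartment-number effect on extinction
(C = 1000 > 3000 > 5000) and the dominance of HHP among maintained
three-member networks, but measures a global extinction fraction roughly
0.2 below the full-scale reference at every compartment number — the
appearance rates imply a steadier supply of rescue hosts than the
reference statistics suggest. We keep the stated rates rather than tuning
them.

A second interpretation question is flagged by the coefficient ranges: the
design specifies draws for a new host *as template* ($k_{ji}^H$), but a
complete matrix also needs the new host *as replicase* on existing
templates. Those are drawn at creation time from the range matching the
template's class ($[1,3]$ for hosts, $[0,10]$ for parasites). Drawing (as
opposed to inheriting a parent's row) is required for the observed
evolutionary route to exist at all: parasite-resistant hosts can only
arise if a new host's parasite-replication coefficient is free to be
small.

### Classification and statistics

Each round, the network composition is the set of species whose global
total strictly exceeds 1000 copies, labelled by its host/parasite
multiset (H, HP, HH, HHP, ...). A *maintained network* is a maximal
interval with an identical above-threshold species-id set lasting strictly
more than 100 rounds. For each maintained HHP network the package records
the composition immediately preceding the interval (the default
predecessor definition; the latest earlier maintained network is also
recorded, since "preceded by" admits both readings) and its six-slot
coefficient set with the elder host as host 1 — in the HP-to-HHP route the
elder host is the established, parasite-susceptible partner, which is what
makes birth order the right labelling for `check_hhp_condition()`.

## Coefficient estimation from assays

The two-step assay translates replicase from one RNA (RNA I), then lets it
replicate RNA I together with a second template (RNA II). Fold values are
common logs of the concentration increase over the replication step. Self
coefficients are the self-assay folds, $k_{ii}^H = v_{ii}^i$; cross
coefficients remove the competition between the two templates by
normalizing with the replicase's own fold in the same reaction:

$$k_{ij} = k_{ii}^H \, \frac{v_{ij}^{\,j}}{v_{ij}^{\,i}}.$$

The estimator averages replicate folds, reports their spread, keeps full
precision (presentation rounding is not inherited by simulations), returns
`NA` with a warning when the competitive fold is zero, and warns on
negative folds. Its validity rests on the modelling assumption that the
ratio of competitive fold values equals the ratio of the underlying
coefficients; that assumption is taken as given here, and the test suite
instead verifies the algebra by exact round trips through constructed fold
tables.

`hamming_distance()` is the deliberately alignment-free companion utility
for comparing representative sequences of equal length; comparisons across
indels must be resolved upstream.

## What the synthetic data do and do not show

`make_fixture()` builds every external input the tests need: random
coefficient matrices in the evolutionary draw ranges, fold tables that
invert the estimator exactly, sequence pairs at a prescribed Hamming
distance, and coefficient tables shaped like an evolutionary-simulation
export with a prescribed condition-pass count. The two files shipped under
`inst/extdata/` (a host sequence pair at distance 7 and a 218-row table
with 148 passing sets) are synthetic stand-ins with the relevant statistic
holding *by construction*; they exercise the utilities end-to-end but are
not the original laboratory sequences or simulation exports, and tests
against them validate code paths, not biology. The statistics that *are*
recomputed from the model itself (extinction fractions, maintained-network
and predecessor tallies, the condition fraction among simulated maintained
HHP networks) come from `run_evolution_batch()` at desk scale: 100-run
batches rather than 1000, compared against the full-scale reference values
with 3-standard-error bands.

## Numerical and scale choices

* Engine randomness uses a dedicated xoshiro256++ generator seeded from
  the R-supplied integer seed; Binomial$(n, 1/2)$ draws are exact popcounts
  of random bits. A run is a single stream, so identical seed and
  configuration reproduce bit-for-bit; batch and sweep work units use
  seeds derived by `derive_seed()` so execution order is irrelevant.
* Problem sizes in the tests: full study geometry ($C = 3000$, $A = 5000$,
  $N = 100$) wherever a conclusion depends on it (sweep exclusion checks,
  round-1 survival, extinction statistics), and a reduced geometry
  ($C = 200$, $A = 300$) for checks whose conclusion is
  scale-free (conservation laws, determinism, fixed points).
* Known limitations: no trade-off structure between coefficients, no
  sequence-level mutation model, at most three concurrent species, no
  resource accounting, no spatial structure beyond well-mixed compartments
  coupled by fusion–division.
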