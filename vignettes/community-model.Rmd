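---
title: "A length-structured multispecies community model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A length-structured multispecies community model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lencomm)
```

## The model

`lencomm` simulates an interacting fish community on a shared grid of
discrete body-length classes. Length, rather than age or weight, is the
structuring variable: it is what surveys measure and what fishing-gear
selectivity is expressed in, which makes the fisheries layer direct to
parameterise. The model is deterministic throughout: a configuration and an
effort schedule fix every output bit-for-bit.

A year is divided into `1 / dt` equal steps (default `dt = 0.1` yr, ten
steps). Each step applies three phases to the numbers matrix $N_{j,i}$
(class $j$, species $i$):

1. **Recruitment** (first step of each year only). Spawning stock biomass
   at the start of the year, $SSB_i = \sum_j N_{j,i} w_{j,i} m_{j,i}$,
   sets the year's recruitment through one of five stock-recruitment
   functions (hockey-stick by default, plus Ricker, Beverton–Holt, linear,
   constant). Recruits enter the first length class.
2. **Mortality**. Exponential survival under the summed rate
   $Z = M1 + M2 + F$: background mortality $M1$, predation mortality
   $M2$, fishing mortality $F = \sum_k e_k\, q_{j,i,k}$ over gears $k$
   with effort $e_k$ and catchability $q$. Deaths are partitioned exactly
   by the Baranov shares $F_k / Z$ (catch of gear $k$) and
   $(M1 + M2)/Z$ (natural), so numbers are conserved to rounding error.
3. **Growth**. A proportion $\phi_{j,i}$ of survivors moves up one class,
   derived from the von Bertalanffy transit time
   $t_{j,i} = \tfrac{1}{k_i}\log\frac{L_{\infty,i} - l_j}{L_{\infty,i} - u_j}$
   as $\phi = dt / t$, capped at 1. Classes a species cannot traverse
   ($u_j \ge L_{\infty,i}$) have $\phi = 0$; fish accumulate in their
   terminal class.

All weight-based quantities use the convention that a fish "in class $j$"
has the class-midpoint length and weight $w = W_a L^{W_b}$ grams.

### Predation

Species preference is a predator–prey interaction matrix $\tau$ (who eats
whom, 0–1); size preference is a log-normal kernel in the predator/prey
weight ratio, peaking at the preferred mass ratio $\mu$ with log-scale
width $\sigma$, truncated to zero where the prey is at least as heavy as
the predator. Each predator cell demands a ration equal to the weight it
must grow in the step divided by a conversion efficiency that declines
linearly in weight from $g_0$ at weight zero to zero at the asymptotic
weight. The ration is apportioned over suitable prey biomass plus an
"other food" pool, giving

$$M2_{j,i} = \frac{1}{dt} \sum_{m,n}
  \frac{I_{n,m}\, N_{n,m}\, s_{m,n,i,j}}
       {O + \sum_{i',j'} s_{m,n,i',j'}\, N_{j',i'}\, w_{j',i'}},$$

with suitability $s$, ration $I$ and other food $O$. Dividing demand by
availability means a predator cell with nothing to eat exerts (and
suffers) nothing; `other` acts as a dilution term — as $O \to \infty$,
$M2 \to 0$. The implementation flattens the four-index suitability tensor
to a matrix once at assembly, so each step costs one matrix–vector
product; the test suite checks it against a literal quadruple-sum oracle
to $10^{-10}$ relative.

The exact ration and background-mortality forms are deliberately isolated
behind `calc_M2()` and `calc_M1()` so alternative formulations can be
swapped in without touching the engine.

### Fishing

Catchability curves per species × gear come in three families — logistic
(steepness `eta`, `L50`), log-Gaussian (modal length, log-sd), and
knife-edge (minimum landing size; fish below it are never selected, i.e.
discards survive). Each curve is rescaled to unit maximum over the classes
the species can occupy, so *effort is fishing mortality on the
most-selected class*: effort 0.25 produces a maximum F of exactly
0.25 yr⁻¹. Selectivity on classes a species never reaches is zeroed —
those classes hold no fish, and leaving the logistic tail there would
break the effort/F correspondence. Effort is piecewise-constant within a
year (one row per year, one column per gear); raw catchability arrays are
accepted verbatim for users who want none of this.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `n_l` | – | 32 | length classes, equal width over $(0, \max L_\infty]$ |
| `phi_min` (= `dt`) | yr | 0.1 | time step; 10 steps per year |
| `mu` | – | 30 | preferred predator/prey mass ratio |
| `sigma` | – | 1 | log-scale width of the size-preference kernel |
| `g0` | – | 0.5 | growth (conversion) efficiency at weight zero |
| `other` | g | fixture: $n_s \times 10^9$ | other-food biomass diluting predation |
| `kappa` | 1/cm | $10 / L_{mat}$ | maturity-ogive steepness |
| `Nmort`, `prop` | 1/yr, – | 0.8, 0.75 | `std_RNM` background mortality: constant below `prop`·Linf, zero above |

`mu`, `sigma` and `g0` are species-independent; their defaults are
conventional size-spectrum magnitudes and every one is surfaced in
`pred_params()`. The background-mortality default (`std_RNM`) matches the
convention that residual natural mortality acts on sizes the modelled
predators do not reach; note that it leaves the largest classes of apex
species with zero total mortality, under which an unfished community has
no finite equilibrium (numbers accumulate). Communities meant to
equilibrate should give every class some mortality, which is why the
synthetic generator uses per-species constant $M1 = \min(1.5k, 1.2)$ —
the classic $M \approx 1.5k$ life-history invariant.

## Initialisation

`get_N0()` builds an unfished quasi-equilibrium deterministically:

1. an analytic steady state of the mortality + growth update per species
   under $M1$ alone, fed by the species' recruitment plateau spread evenly
   over the year's steps (`steady_state_numbers()`);
2. a damped fixed-point iteration folding the predation mortality implied
   by the current state back into the steady-state solve;
3. Aitken-accelerated iteration of the unfished decade map (simulate ten
   years, extrapolate each cell geometrically) until per-species SSB
   drifts less than 0.5% per decade, followed by the conventional ten-year
   unfished burn-in.

Stages 1–2 alone are not sufficient: annual recruitment pulses make the
dynamic equilibrium differ by tens of percent from any time-averaged
analytic solve, which is why the final stage iterates the actual dynamics.
On the bundled 21-species community the whole procedure takes about a
second and the resulting state drifts by less than 0.1% per decade.

## Indicators

Biomass and SSB per species; and at community level the Large Fish
Indicator (biomass fraction above a length threshold, conventionally
40 cm), Mean Maximum Length (biomass-weighted mean of species'
$L_\infty$), Typical Length (biomass-weighted geometric mean of class
midpoints), and Length Quantiles (interpolated linearly within a class, so
the series are smooth rather than jumping between class labels). Catch per
gear and CPUE (undefined, not zero, where effort is zero) summarise the
fishery. All are available per step — spawning pulses show up as
within-year structure — with an option to average annually.

Typical Length is computed over length classes, not species means; the
class-level form uses strictly more of the state and reduces to the
species-level one when each species occupies one class.

## Reference points

Long-term yield of a fishing-mortality vector is operationalised as the
mean annual catch over the final 10 years of a 50-year run started from
the unfished state (both configurable; the case studies in this vignette's
test suite use 20-year runs with 5-year windows on small communities to
keep runtimes in seconds — the algorithms are horizon-agnostic).
Reference-point analyses fish each species with its own unit-normalised
logistic gear (L50 at the maturity length), so the vector of efforts *is*
the vector of F's.

`calc_FMSY()` maximises one species' long-term yield over a coarse F grid
and refines by golden-section search between the best grid point's
neighbours (tolerance 0.005 yr⁻¹); with ties or a non-concave profile it
returns the smallest maximiser and warns. `calc_nash()` finds the
multispecies equilibrium by best-response iteration — cycling over
species, replacing each $F_i$ by its FMSY given the others — until no
component moves more than 0.01 yr⁻¹ in a sweep. At the result, no stock's
yield can be improved by changing only its own F: the test suite verifies
this fixed-point property directly, and that the equilibrium decouples
into independent FMSYs when the interaction matrix is zero. Best-response
iteration realises the definition of the equilibrium but is not guaranteed
to converge for arbitrary communities; non-convergence is reported, not
hidden.

`run_scenario_grid()` runs the full factorial of per-fleet effort levels
(the canonical set `c(0, 0.5, 1, 1.5, 2)` over four fleets gives 625
scenarios), each held constant from a common initial state, and flags a
stock as collapsed when its SSB — averaged over the final simulated year,
which removes within-year phase effects — falls strictly below 10% of its
unfished SSB from a zero-effort run of the same length.

## The synthetic community generator

`generate_fixture()` draws a reproducible North-Sea-like parameter set: 21
species with log-uniform $L_\infty$ over 15–150 cm, near-cubic
length–weight relations, growth rate falling with size
($k = 3.2 L_\infty^{-0.57}$, jittered), maturity at 45–65% of $L_\infty$,
and hockey-stick recruitment whose plateau scales inversely with adult
weight (small species are numerous) and whose breakpoint sits at 5% of a
nominal virgin biomass, giving resilience high enough to persist unfished
but low enough that heavy fishing depresses recruitment. The interaction
matrix is sparse with larger species as predators (a predator needs at
least twice the prey's asymptotic weight); four idealised fleets —
Industrial, Otter, Beam, Pelagic — partition the species by size and a
drawn pelagic habit, so each species is caught by exactly one fleet, with
logistic selectivity around 55% of $L_\infty$. An optional Recreational
fleet applies knife-edge retention at a minimum landing size to the larger
species. Everything is drawn under one seed and regenerating with the same
seed is byte-identical; the written `config.yaml` carries a manifest
stating the values are synthetic, not calibrated to any survey.

What the generator does *not* emulate: real diet fractions (its $\tau$ is
drawn, not estimated), environmental variability (recruitment is
deterministic), spatial structure, and any resemblance of its absolute
abundances to a particular sea. Tests passing on these communities
demonstrate the mechanics and invariants of the model, not skill against
data.

## Numerical notes

* Time stepping is exact exponential survival — numbers can never
  overshoot zero regardless of rate magnitudes.
* $\phi > 1$ (a species crossing a whole class in under one step) is
  capped at 1 with a warning; choose finer steps or wider classes if it
  fires.
* A predator cell with zero available food contributes zero predation
  (guarded division).
* The `linear` background-mortality family reaches zero at $L_\infty$, so
  a species' terminal class can retain (near-)zero mortality; prefer
  `constant` per-species rates when an unfished equilibrium is required.
* Golden-section refinement only ever searches between the best grid
  point's neighbours; a multimodal yield profile is resolved at the grid
  resolution, which is why the grid is exposed as an argument.
* Runs are deterministic; the only randomness anywhere is inside
  `generate_fixture()`, which restores the caller's RNG state.

## A worked example

```{r example, eval = FALSE}
fx <- generate_fixture(seed = 1)
params <- community_params(fx$species, gears = fx$gears, tau = fx$tau,
                           pred = fx$pred)
N0 <- get_N0(params)                       # unfished quasi-equilibrium
effort <- make_case_study_efforts(1, n_gears = dim(params@Q)[3])
run <- run_community(params, N0, years = 50, effort = effort)
head(indicator_table(run, params, annual = TRUE))
```

The same pipeline is scriptable from a shell through the bundled
command-line entry point (`system.file("cli", "lencomm")`; `fixture`,
`setup`, `run`, `indicators`, `fmsy`, `nash`, `scenarios` subcommands).

## Known limitations

Growth is food-independent (rations feed mortality, not growth);
recruitment is deterministic and within-year seasonality is limited to the
annual recruitment pulse; catchability is fixed in time (only effort is
dynamic); and the Nash solver assumes best-response iteration converges,
which it reports but cannot force.
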