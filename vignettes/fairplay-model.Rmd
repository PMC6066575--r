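---
title: "The fairplay model: how pooling, thresholds and delays select for juvenile play"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fairplay model: how pooling, thresholds and delays select for juvenile play}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairplay)
```

## The question the model asks

Juvenile social play is costly — playing animals are more exposed to
predation and injury — and "fair" play in particular (role reversals,
self-handicapping) has no obvious immediate payoff. One long-standing
hypothesis is that juveniles playing fairly learn to *behave* fairly as
adults, pooling and sharing resources equitably. The puzzle is that fair
sharing has no expected-payoff advantage: if every adult succeeds in
foraging with probability $p$ for a resource of size $R$, a selfish adult
expects $pR$ per step, and a fair adult who pools with $m-1$ others and
takes an equal share of the pool $mpR/m$ expects exactly the same $pR$.

What pooling does change is the *variance*. A selfish forager's per-round
payoff has variance

$$\mathrm{var}(R, p) = (1 - p)\,p\,R^2,$$

(`payoff_variance()`), while the members of a pool all receive the pool
mean, with zero within-pool variance each round. The model asks whether
this variance difference alone — routed through a reproductive threshold,
fractional parental investment, and a minimum delay between reproductive
events — can select for a heritable propensity for juvenile play.

## The agent-based model

Agents live in groups (at most $G$ groups, at most $K$ adults in total)
and carry a single binary **play gene**. Each simulation step runs seven
phases in a fixed order:

1. **Juvenile play.** Gene-carrying juveniles, in random order within each
   group, seek one play bout each. A partner search scans the group's other
   juveniles in uniformly random order and stops at the first that carries
   the gene and has not yet played this step; juveniles that find no willing
   partner do not play and pay no cost. Both participants of a bout add one
   to their bout count, and each independently dies with probability $c$.
2. **Maturation.** Juveniles reaching age $j$ become adults — in random
   order across the whole population — while the adult count is below $K$;
   at the cap they die instead, so the cap introduces no group-level bias.
   A maturing juvenile becomes **fair** iff learning is enabled, it carries
   the gene, and it has played at least $\alpha$ bouts.
3. **Foraging.** Each adult succeeds with probability $p$; a success yields
   $\max(0, R + \mathcal{N}(0, 0.1R))$ resource units.
4. **Pooling.** Within each group, the *current step's* gains of the fair
   adults are summed and divided equally among them; selfish adults keep
   their own gains. Pooling uses only per-step gains, never accumulated
   holdings — the equal-expected-payoff argument above only holds for
   per-round gains.
5. **Reproduction.** An adult with at least $T$ accumulated units, whose
   last reproduction is at least $d$ steps past, produces exactly one
   offspring. The offspring receives a fraction $P$ of the parent's
   accumulated resources; the gene is copied and flipped with probability
   $r$; the birth is logged with the post-mutation gene state.
6. **Aging and death.** Agents that have reached their assigned lifespan
   (drawn at birth as $\mathrm{round}(l + \mathcal{N}(0, \mathit{sd}_l))$,
   clamped at 1) die; dependent juveniles die with a parent that dies of
   old age. An agent at age `lifespan - 1` survives the current step and
   dies on the next.
7. **Fission.** A group reaching $f$ adults buds off $g$ randomly chosen
   adults into a new group while fewer than $G$ groups exist; moved adults
   take their dependent juveniles. Empty groups disappear.

The dependent variable is the **play-gene birth frequency**: the fraction
of agents born during the measurement window (after a burn-in of 10,000
steps, up to step 25,000) that carried the gene at birth.

## Why the delay matters

A parent at the threshold $T$ invests $P\,T$ units in an offspring, so it
needs to re-accumulate about $P\,T$ before its next chance to reproduce,
which arrives after the delay $d$. A fair adult accumulates the pool mean
$pR$ every step and reliably restocks whenever $d \cdot pR \gtrsim P\,T$.
A selfish adult's income instead arrives in rare chunks of size $R$: the
probability of collecting the $k = \lceil P T / R \rceil$ successes it
needs within the delay is the binomial tail `prob_reach_threshold(d, p, k)`,
which stays below 0.4 for every matched $(d, p)$ pair at the standard
thresholds. Selection for fairness is therefore strongest near

$$d^\ast = \frac{P\,T}{pR}$$

(`predicted_peak_delay()`): about 14.3 steps at the defaults, matching the
observed peak at $d = 15$, and scaling to roughly 9 at $P = 0.3$ and 20 at
$P = 0.7$. For delays much shorter than $d^\ast$ the threshold, not the
delay, is binding and variance hardly matters; for much longer delays both
strategies restock comfortably and the play gene's mortality cost dominates.

## Parameters

| Field | Default | Meaning |
|---|---|---|
| `K` | 1000 | maximum adults in the population |
| `G` | 50 | maximum number of groups |
| `f`, `g` | 40, 20 | group fission size and offspring-group size |
| `j` | 50 | juvenile-stage length (steps) |
| `alpha` | 5 | bouts needed to learn fairness |
| `P` | 0.5 | fraction of parental resources invested per offspring |
| `T` | 100 | resource threshold for one offspring |
| `r` | 0.01 | per-birth gene-flip probability |
| `l`, `sd_l` | 150, 25 | lifespan mean and SD (steps) |
| `R`, `p` | 40, 0.0875 | resource size and success probability |
| `c` | varies | per-bout play mortality (0 to 0.003) |
| `d` | 15 | reproductive delay (steps) |
| `F0` | 0.05 | initial play-gene frequency |
| `tau`, `burn_in` | 25000, 10000 | run length and measurement-window start |

The foraging noise SD is always derived as `0.1 * R` and cannot be set
independently, and the expected payoff $pR$ is never stored — both are
recomputed from `(R, p)` so the paired representations cannot drift apart.
The package defaults to `R = 40, p = 0.0875, d = 15`, the condition at
which selection for fairness is strongest and which the sweep experiments
use as their reference point.

## Design choices where the model was open

Several details are under-determined by the model sketch above; the
package resolves them as follows, and keeps each choice in one place:

* **Initial adults.** Initial agents are adults (ages uniform on
  $[50, 150]$, resources uniform on $[50, 150]$) and may reproduce at step
  0. Gene-carrying initial adults count as fair when learning is enabled
  (`seed_adults_fair`, configurable): they had no juvenile phase, and at
  $F_0 = 0.05$ the choice only affects a short transient.
* **Offspring custody of resources.** Juveniles keep their birth endowment
  and carry it into adulthood; juveniles never forage.
* **One offspring per event.** Even with resources $\ge 2T$ an adult
  produces a single offspring; the delay then gates the next event.
* **Bout symmetry.** A bout counts toward $\alpha$ for both participants
  and the mortality draw is applied independently to each.
* **Partner eligibility.** A juvenile that already played this step cannot
  be chosen again (one bout per participant per step); a juvenile that
  failed to find a partner can still be chosen later in the same step.
* **Lifespan clamp.** Lifespans are clamped at 1 step (not at $j$):
  initial agents whose drawn lifespan falls below their initial age simply
  die on the first aging pass.
* **Extinction.** A population with zero adults is extinct: the run halts
  and is flagged, and aggregation excludes extinct runs from means while
  reporting their count. At $P = 0.1$, delay averages use $d \le 45$ only,
  because longer delays frequently drive those populations extinct.
* **Mortality denominator.** The realized play-mortality percentage is
  play deaths over juveniles that entered at least one bout. At the
  defaults a playing juvenile accumulates roughly 35 bouts, so $c = 0.003$
  realizes close to $1 - (1 - c)^{35} \approx 10\%$ mortality, which is
  what the calibration checks expect.

## Numerical and reproducibility choices

All randomness flows from R's RNG through a single seeded stream per run;
`run_simulation(params, seed)` is bit-for-bit deterministic in
`(params, seed)`. The order in which draws are consumed is part of the
engine's contract (documented phase by phase in the source); partner
search uses a lazy Fisher–Yates scan that visits candidates in uniformly
random order but stops at the first willing partner — the same
distribution as a full shuffle at a fraction of the draws. Sweep seeds are
derived as `base_seed + config_index * 2048 + replicate`, which is
injective for fewer than 2048 replicates per condition, so every run of a
sweep has a distinct seed that does not depend on execution order.
Pooling conserves each group's per-step gains exactly up to floating
point; the test suite checks conservation at a relative tolerance of
1e-9 on every step of fuzzed runs.

## What the tests do and do not show

The simulations *are* the study system — there is no external data — so
the tests operate at three levels. Closed-form quantities are checked
exactly, with the binomial tail verified against brute-force enumeration
of all $2^d$ outcome sequences for $d \le 12$. Engine semantics are
checked on hand-built scenario populations (forced pairings, caps,
fission, dependent removal). Population-level outcomes are checked on
full-length runs (25,000 steps, populations of ~1000 adults) with 5
replicates per condition instead of the 20 used for the archival sweeps:
the evolved frequency at the reference condition exceeds 80% for all
sub-maximal mortality settings and 70% at ~10% realized play mortality,
learning-off controls at zero cost drift to 50% within ±10 percentage
points, and $c = 0.003$ realizes 8–12% play mortality. Shorter runs
(1,500–6,000 steps) are used where only a direction, not an equilibrium,
is asserted — e.g. that learning beats its matched control. Replicate
counts were sized to the variance observed across seeds, not the other
way around: no generator parameter, seed or tolerance is tuned to test
outcomes.

The full archival design — two factorial sweeps over $(R, p) \times d
\times c \times P$ with 20 replicates, 342,720 runs — is enumerable and
runnable (`sweep_set1()`, `sweep_set2()`, `run_sweep()` with resumable
checkpoints) but is cluster-scale; the suite verifies its enumeration
(1785 and 2499 condition sets) and spot-checks reduced grids.

## Known limitations

* Fairness is all-or-nothing: a single gene, a hard bout threshold, an
  even split. Real play and sharing are graded; the model shows the
  variance mechanism in its starkest form.
* No cheating, punishment, inter-group migration (beyond fission), sexual
  reproduction, or individual differences in foraging skill. The
  equal-success assumption is what justifies the even split.
* Lifespans are assigned at birth and independent of condition, so
  "living longer by eating better" feedbacks are absent by construction —
  that is what makes the dependent-offspring rule innocuous.
* The closed-form variance assumes exactly $pm$ of $m$ foragers succeed
  per round; empirical per-round variance converges to it only in
  expectation, which is how the property tests compare the two.
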