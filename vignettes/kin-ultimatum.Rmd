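---
title: "Evolving conditional Ultimatum Game strategies with kin recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving conditional Ultimatum Game strategies with kin recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugevolve)
```

## The model

In the one-shot anonymous Ultimatum Game a *proposer* offers a fraction of a
unit resource and a *responder* either accepts — the resource is split
accordingly — or rejects, in which case neither side receives anything. A
deterministic strategy is a vector $(\mathit{offer}, \mathit{demand}) \in
[0,1]^2$: the fraction offered when proposing and the minimum acceptable
offer when responding. The subgame-perfect (Nash) strategy is
$(\mathit{offer} \approx 0, \mathit{demand} \approx 0)$; observed human play
is instead *generous* (offers well above zero), *demanding*
($\mathit{demand} > 0.5$) and *unfair* ($\mathit{offer} < \mathit{demand}$).

`ugevolve` studies whether kin recognition can account for that gap. Agents
carry either

* **baseline** genomes — a single unconditional $(\mathit{offer},
  \mathit{demand})$ pair, or
* **kin** genomes — two strategy branches $(\mathit{offer}_{kin},
  \mathit{demand}_{kin})$ and $(\mathit{offer}_{other},
  \mathit{demand}_{other})$, plus a heritable *tag* $\in [0,1]$ and a
  recognition *threshold* $t \in [0,1]$.

Agent $A$ treats agent $B$ as kin iff $|tag_A - tag_B| < t_A$ (strictly;
the boundary counts as non-kin). The judgement is one-sided: $B$, applying
its own threshold, may disagree. In a game each side selects its branch
from its *own* classification of the partner — the proposer's verdict picks
the offer branch, the responder's verdict picks the demand branch. Because
tags mutate, non-kin can be misclassified as kin and vice versa.

An offer is accepted when it *meets* the demand, i.e. `offer >= demand`
with ties accepting. This convention makes the degenerate self-play of the
Nash corner $(0, 0)$ deliver the whole resource to the proposer, which is
what the subgame-perfect argument requires; with a strict rule the corner
would pay nothing to anyone and the equilibrium analysis would change
character at a measure-zero boundary.

## Evolutionary dynamics

Each generation every ordered pair of distinct agents plays exactly one
game (so each agent proposes to, and responds to, every other agent once).
An agent's *score* is its mean payoff per game played, hence in $[0,1]$.
Using the mean rather than the sum keeps the selection-strength parameter
$w$ comparable across population sizes.

Reproduction is Wright–Fisher with full generational replacement: each of
the $N$ offspring draws its parent with replacement with probability

$$p_i = \frac{e^{w \, s_i}}{\sum_j e^{w \, s_j}},$$

the standard exponential-fecundity form for selection of tunable strength.
$w = 0$ is neutral drift; the form needs no special case for all-zero
payoff populations. A linear alternative $1 - w + w s_i$ (valid for
$w \le 1$) is available via `selection_scheme = "linear"` for comparison.
Offspring then mutate each locus independently with probability `mu`
(default 0.01), replacing the value with a fresh uniform draw on $[0,1]$;
the tag and threshold mutate at the same per-site rate as the strategy
loci.

Defaults follow the study conditions: $N = 100$, $\mu = 0.01$, 200
replicates per condition. Each replicate is driven by a single seeded RNG
stream (`withr::with_seed`), so a trajectory is a deterministic function of
`(config, seed)` and replays bit-identically; sweep replicates draw their
seeds from the master seed in a fixed order, which also makes interrupted
sweeps resumable from their on-disk LOD files without changing any result.

## Line-of-descent analysis

Rather than summarising noisy population snapshots, runs are summarised
along the **line of descent** (LOD): the chain of ancestors from a
final-generation individual back to the founding population. Long runs
coalesce — all final individuals share the same ancestor path except for
the last few generations — so the anchor individual is immaterial and is
chosen uniformly at random (seeded). `coalescence_generation()` reports the
latest generation at which all final individuals still share one ancestor.

`summarize_lod()` averages each locus along the chain. The default is plain
averaging over the whole LOD. For desk-scale runs (20,000 generations
instead of the 100,000-generation default) the package's convention is to
discard the first 25% as burn-in, which removes most of the imprint of the
random founding state at the shorter length; population-mean averaging and
LOD averaging agree to within 0.05 on such runs, which the test suite
checks.

## Inferring a human strategy vector from acceptance rates

Behavioural studies report demand only indirectly, as acceptance rates
conditioned on the offers that happened to be made. The inference module
turns such a table into a single offer-independent demand:

1. **Logistic fit.** Acceptance rates are fitted to
   $f(x) = 1/(1 + e^{-k(x - X_0)})$ by nonlinear least squares
   (`minpack.lm::nlsLM`; start $k = 10$, $X_0 = \overline{x}$, coarse
   multi-start on failure). Because offers above half the resource are
   nearly always accepted but rarely observed, the fit by default appends
   synthetic rate-1.0 points at offers $\{0.6, 0.7, 0.8, 0.9, 1.0\}$. The
   exact placement is a modelling choice: the grid is configurable and a
   sensitivity test confirms that when the data already saturate, fits with
   and without augmentation agree within 5% on $k$. Count-form tables are
   weighted by bin sample size (augmentation points receive the median
   weight); rate-form tables are fitted unweighted.
2. **Demand threshold.** The demand is the offer $d$ that splits the
   accepted-offer mass in half under uniformly distributed offers:
   $\int_0^d f = \tfrac12 \int_0^1 f$, solved by adaptive quadrature plus
   bisection to $10^{-6}$. Limits behave as expected: a flat curve gives
   $d = 0.5$, a step at $0.5$ gives $d = 0.75$.
3. **Optimal offer.** The proposer's expected payoff is
   $(1 - x) f(x)$ — the retained share times the acceptance probability —
   and `optimal_offer()` maximises it by bracketed golden-section search
   cross-checked against an exhaustive $10^{-4}$ grid. For steep fits in
   the empirically relevant range ($k \approx 15$, $X_0 \approx 0.2$) the
   maximiser lands near 0.35, a little below the midpoint between the
   demand threshold and the typical observed offer.

`simulate_acceptance_data()` provides the synthetic stand-in for such
tables: independent binomial draws per offer bin from a known logistic
curve, by default on bins 0.05–0.50 (where real studies concentrate their
observations) with 100 responders per bin, a realistic size for a
laboratory study. It emulates binned sampling noise only: real data also
carry within-subject correlation, heaping on round offers, and cultural and
contextual covariates, none of which the generator reproduces — parameter
-recovery results on synthetic tables therefore speak to estimator
correctness, not to robustness against those features.

## What the simulator reproduces, and a known limitation

With the scaled conditions used throughout the tests ($N = 100$, 20,000
generations, 10 replicates per condition, 25% burn-in), the package
reproduces the canonical qualitative results:

* **Baseline Nash approach.** Without kin recognition, mean evolved offers
  and demands fall monotonically as $w$ rises, reaching below 0.2 at
  $w = 10$; at $w = 0$ both drift around 0.5.
* **Kin-branch Nash approach.** With kin recognition, the branch played
  against perceived kin collapses to the Nash corner (means below 0.1 at
  $w = 10$).
* **Branch divergence.** The non-kin branch stays far more generous and
  demanding than the kin branch (gaps above 0.3 at $w = 10$), and the
  non-kin *offer* settles near 0.4.

One documented expectation is **not** met under these exact dynamics: the
non-kin *demand* settles just below 0.5 (about 0.45–0.49 across $w \in
\{1, 10\}$) rather than near 0.6, and evolved recognition thresholds drift
high (median ≈ 0.7) rather than low. The mechanism is instructive: a
population that maintains high non-kin demands must keep *rejecting*
outsider offers, which is individually costly spite — an agent that
accepts those offers always outscores its rejecting clone-mates, and under
global Wright–Fisher competition at $N = 100$ that advantage erodes the
discriminating state. The population instead settles into an efficient
"call everyone kin" configuration: thresholds drift upward, the kin branch
(played against almost everyone) carries the Nash-corner selection
pressure, and the rarely expressed non-kin branch hovers near its drift
centre. Seeding runs directly at the discriminating state (kin branch at
the corner, non-kin branch at $(0.4, 0.6)$, thresholds near 0) confirms it
is not stable under these dynamics; variants probed during development
(strict acceptance, signed tag comparison, alternative branch wirings,
mean-over-accepted-games scoring, other $\mu$, $N$, and $w$ values) either
do not change this or break the kin-branch results. The corresponding
acceptance checks are left failing rather than weakened, and the numbers
above are exactly those the test suite and `scripts/acceptance.R` compute.

## Numerical and design notes

* All loci live on the closed unit interval forever; mutation redraws are
  uniform, so drift centres every unexpressed locus at 0.5.
* The O($N^2$) round-robin payoff kernel is implemented in C++ (Rcpp) and
  verified element-wise against a plain-R double-loop oracle in the tests;
  a 20,000-generation kin-mode replicate at $N = 100$ takes a few seconds.
* The evolutionary-stability predicate uses the classical two-condition
  definition: resident stable if $E(r,r) > E(i,r)$, with the tie broken by
  $E(r,i)$ vs $E(i,i)$, neutral only if both tie. The second condition is
  an extension beyond the first-order definition, applied only on exact
  ties.
* Threshold histograms use right-closed bins $(\ell, u]$ with the first
  bin closed on both sides, 20 equal bins on $[0,1]$ by default.
* Degenerate inputs fail loudly: populations of one agent, mode
  mismatches, out-of-range loci, empty post-burn-in windows, dangling
  parent indices, and non-converged fits all raise informative errors
  rather than returning partial results.
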