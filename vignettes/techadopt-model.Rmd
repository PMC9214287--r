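---
title: "The techadopt model: actions, attitudes and skills in innovation diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The techadopt model: actions, attitudes and skills in innovation diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(techadopt)
```

## The model

`techadopt` simulates a society of $N$ agents each of whom uses either an
old technology ($x = 0$) or a new one ($x = 1$). Three per-agent variables
co-evolve in discrete time:

* the **action** $x \in \{0, 1\}$,
* the **attitude** $y \in [0, 1]$ — the perceived desirability of the new
  technology,
* the **benefit/skill** $b \in [b_{\min}, b_{\max}]$ — what the new
  technology currently yields to this agent.

The old technology pays a constant $b_0$, with
$b_{\min} \le b_0 \le b_{\max}$.

**Skills.** Use of the new technology improves skills by learning-by-doing;
disuse erodes them by knowledge depreciation:

$$
b' = \begin{cases}
b + a\,(b_{\max} - b), & x = 1,\\
b - c\,(b - b_{\min}), & x = 0,
\end{cases}
\qquad a = a_0 + a_1 p ,
$$

where $p$ is the adopter frequency: learning accelerates when more peers
use the technology (more guides, forums, courses). The generator enforces
$a_0 + a_1 \le 1$ so the rate stays a valid proportion. Under continuous
use, $b_t = b_{\max} - (1-a)^t (b_{\max} - b_{\text{start}})$ — a classic
learning curve, which the test suite checks exactly.

**Decisions.** With probability $\nu$ per step an agent reconsiders its
technology, comparing utilities
$U(x, y, b) = \Pi(x, b) + \epsilon V(x, y)$. The material part weighs the
present against the mastered future with foresight $\omega$:

$$
\Delta\Pi(b) = (1 - \omega) b + \omega b_{\max} - b_0 ,
$$

and the normative part collects four forces:

$$
\Delta V(y) = f_0\, v\,(2y - 1) + f_1\, k_1 (2p - 1)
            + f_2\, k_2 (2\bar y - 1) + f_3\, k_3 ,
$$

cognitive dissonance (alignment of action with own attitude), conformity
with peers' actions, conformity with peers' average attitude $\bar y$, and
conformity with an authority promoting adoption. The choice is a logit
("myopic best response with errors") with precision $\lambda$:
$\Pr(x = 1) = 1/(1 + e^{-\lambda \Delta U})$, where
$\Delta U = \Delta\Pi + \epsilon\,\Delta V$. $\lambda = 0$ is a fair coin;
$\lambda = \infty$ adopts deterministically whenever $\Delta U \ge 0$ (the
tie goes to adoption, matching the printed decision rule).

**Attitudes.** After acting, agents revise attitudes by a linear
social-influence rule pulling $y$ towards the own action, the peer action
frequency, the peer mean attitude and the authority's message ($x = 1$):

$$
y' = y + s\left[f_0\,\alpha (x - y) + f_1\,\beta_1 (p - y)
  + f_2\,\beta_2 (\bar y - y) + f_3\,\beta_3 (1 - y)\right].
$$

Both four-way weight vectors, $(v, k_1, k_2, k_3)$ and
$(\alpha, \beta_1, \beta_2, \beta_3)$, are non-negative and sum to one per
agent.

## Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| $b_0$ | benefit of old technology (currency/step) | 1 |
| $b_{\min}, b_{\max}$ | novice / mastery benefit of new technology | 0.5, 1.5 |
| $a_0$, $\bar a_1$ ($\sigma_{a_1}$) | baseline learning rate; frequency sensitivity | 0.05; 0.05 (0.005) |
| $c$ | knowledge depreciation rate (per step) | 0.1 |
| $\bar\omega$ ($\sigma_\omega$) | foresight weight | 0.25 (0.025) |
| $\bar\epsilon$ ($\sigma_\epsilon$) | strength of normative factors | 0.5 (0.05) |
| $s$ | attitude adjustment speed | 0.1 |
| $\nu$ | revision probability per step | 0.1 |
| $\lambda$ | decision precision | 15 (heterogeneous runs); $\infty$ (analytic case) |
| $N$ | population size | 1000 |
| $\bar y_0$ (sd) | initial-attitude beta moments | 0.1 (0.2) |
| $p_0$, $b_s$ | trained fraction; early-adopter subsidy | 0, 0 |
| $f_0..f_3$ | dissonance / peer-action / peer-attitude / authority factors | 1 |

These defaults are the baseline study conditions; sweeps move one of them
at a time. The intervention factors also read as culture knobs:
individualist societies have small $f_1, f_2$, collectivist ones large;
large $f_3$ is strong trust in authority; $f_0$ scales how strongly people
need their attitudes and actions to agree.

## Population synthesis

`generate_population()` draws, independently per agent:

* $(v, k_1, k_2, k_3)$ and $(\alpha, \beta_1, \beta_2, \beta_3)$ from two
  independent four-part **broken sticks** (uniform spacings of $[0,1]$, the
  flat Dirichlet). The distribution has no parameters, which keeps the
  heterogeneity assumption minimal. The two sticks are independent of each
  other; nothing couples an agent's utility-side and attitude-side weights.
* $a_1$, $\omega$, $\epsilon$ from truncated normals. The truncation
  intervals are $[0, 1 - a_0]$ for $a_1$ and $[0, 1]$ for $\omega$ and
  $\epsilon$, chosen so every formula's domain stays valid (the learning
  rate can never leave $[0,1]$, foresight is a weight). At the default sds
  the truncation is far in the tails, so the sampled means are essentially
  the nominal means.
* initial attitudes from a beta law moment-matched to mean $\bar y_0$ and
  sd 0.2 (`beta_params_from_moments()`); values near 0 and 1 are legitimate
  sampled extremes.

Everyone starts as a non-adopter with minimal skill ($x = 0$,
$b = b_{\min}$). Training (`apply_training()`) flips a uniformly chosen
`round(p0 * N)` subset to $x = 1$, $b = b_{\max}$, $y = 1$; the count is
rounded, the subset drawn without replacement, and trained agents keep
their drawn psychological parameters — training changes state, not
personality.

**Subsidy semantics.** An agent that has never adopted carries a pending
entitlement; while $t <$ `subsidy_window` (default 10 steps — "the first
few time steps" made concrete and configurable) the amount $b_s$ is added
to the perceived pay-off of adopting, and the entitlement is consumed on
first adoption. The subsidy enters as one-time framing of the decision,
not as an accumulating income stream.

## The update scheme

Each step is synchronous, for reproducibility, in this order: (i) record
$p_t$ and $\bar y_t$ from the incoming state; (ii) revising agents decide
using $p_t$, $\bar y_t$ and their current $y, b$; (iii) compute the
post-revision frequency $p_{\text{new}}$; (iv) update every benefit with
the learning rate $a_0 + a_1 p_t$ (the pre-revision frequency — a one-step
lag that is immaterial at equilibrium and avoids circularity) and the
action just taken; (v) update every attitude using the new own action,
$p_{\text{new}}$ and $\bar y_t$. Actions precede attitude revision, as in
the underlying psychology; which aggregate each stage observes is a
convention, and the equilibrium tests confirm the fixed points do not
depend on it.

Numerical choices: the attitude update is clipped to $[0, 1]$; with all
$f_i \le 1$ the update is a convex combination and the clip provably never
binds (tested), it exists only because factors above 1 (e.g. an amplified
authority) can overshoot. $\lambda = \infty$ is an explicit branch, not a
large number, so ties resolve exactly as printed. The step function can be
handed its uniform draws, making it a pure function; the test suite uses
this to compare the vectorised implementation against an independent
scalar loop written term by term from the equations (agreement to
1e-12 on random instances).

## Symmetric-case equilibria

With no parameter variation and $\lambda = \infty$ the model admits
closed-form long-run results, implemented in the analytic module and used
throughout the tests as the simulator's oracle:

* **Extinction** ($p^* = 0$): attitudes settle at
  $y^* = \beta_3 / (1 - \beta_2)$ — positive because the authority keeps
  pulling attitudes up even when nobody adopts. A *sufficient* condition
  for this equilibrium to be unstable is
  $\Delta\Pi(b_{\min}) + \epsilon k_3 > \epsilon (v + k_1 + k_2)$,
  evaluated at the most hostile attitude $y = 0$. It is not necessary: the
  system can take off from friendlier initial attitudes even when the
  inequality fails. At the baseline benefit set
  ($b_{\min} = 0.5, b_0 = 1, b_{\max} = 1.5$, weights $0.25$,
  $\epsilon = 0.5$) it flips exactly at $\omega = 0.75$, while a start at
  $y_0 = y^*$ already takes off for $\omega > 7/12$.
* **Full adoption** ($p^* = 1$): everyone at $y^* = 1$, $b = b_{\max}$;
  always locally stable, and the simulator is attracted back to it from
  small attitude perturbations.
* **Coexistence** ($0 < p^* < 1$): a line of equilibria. The stationary
  class attitudes solve a linear system whose solution is
  $y_n^* = (\beta_1 p^* + \beta_2 \alpha p^* + \beta_3)/(1 - \beta_2)$ and
  $y_a^* = y_n^* + \alpha$: adopters and non-adopters always differ by
  exactly the dissonance weight $\alpha$. At $\beta_2 = 0$ this reduces to
  $y_a^* = \alpha + (1 - \alpha - \beta_3) p^* + \beta_3$,
  $y_n^* = (1 - \alpha - \beta_3) p^*+ \beta_3$. Although a numerical
  fixed-point solver was an option for $\beta_2 > 0$, the system is linear
  and the two-line closed form above is exact, so `coexistence_range()`
  intersects the two affine utility conditions (stationary adopter weakly
  prefers adopting, stationary non-adopter strictly prefers not to)
  analytically. An empty band is a legitimate outcome and is returned as
  `NULL`.

```{r analytic}
cfg <- symmetric_config(omega = 0.25,
                        global = global_params(b_max = 2.4, lam = Inf))
equilibrium_report(cfg, p_star = 0.1)
```

## A heterogeneous run

```{r run}
base <- adoption_config(global = global_params(N = 500))
sim <- simulate_adoption(base, T = 100, seed = 42)
summary(sim)
```

```{r plot, fig.width = 6, fig.height = 4}
plot(sim, main = "baseline adoption dynamics")
```

## Experiments: replicates, sweeps, profiles, variants

`run_replicates()` runs independent seeded replicates (substreams derived
from one master seed via `derive_seeds()`, a stable mapping) and records
$p$ and the class attitudes at the observation times, conventionally
$T = 50, 100, 200$. `sweep_parameter()` repeats this along a value grid
**reusing the same replicate seeds at every grid value**, so directional
comparisons are paired and sampling noise largely cancels; the study this
package replicates averaged independent runs instead, which needs more
replicates for the same power.

`compare_adopter_profiles()` asks who adopts early, in terms of the
composite strengths $D = (v + \alpha)/2$, $K_1 = (k_1+\beta_1)/2$,
$K_2 = (k_2+\beta_2)/2$, $K_3 = (k_3+\beta_3)/2$, plus $\omega$ and
$\epsilon$. The comparison is a Welch two-sample t-test on *per-run class
means* across replicates (the underlying study did not name its test;
Welch on run-level means is robust to the strong within-run dependence of
agents, and the choice is isolated in one function if a user prefers
another). Empty classes yield `NA` for that run and a diagnostic error
when a class is empty everywhere. The expected pattern — early adopters
have higher $K_3$ and lower $D, K_1, K_2$, with no difference in $\omega$
or $\epsilon$ — is asserted in the test suite at 200 replicates of
$N = 1000$ observed at $T = 10$ (the original comparison used 1000 runs;
200 keeps the default test run quick while leaving the differences many
standard errors wide).

`model_variant()` nests two reduced models used to show why dynamic
attitudes matter: `fixed_attitudes` freezes them ($s = 0$) and
`no_attitudes` additionally deletes every attitude-coupled term
($v = k_2 = \alpha = \beta_2 = 0$, deliberately *not* renormalising the
remaining weights — the variant zeroes terms, it does not redistribute
them). Both variants' adoption curves diverge measurably from the full
model in the regimes exercised by the tests.

## What the generator does and does not emulate

The synthetic population *is* the study system — there is no external
data. It reproduces the stated heterogeneity (broken-stick weights,
truncated-normal traits, beta initial attitudes) under well-mixed
interaction: every agent sees the same $p$ and $\bar y$. Passing tests
therefore say nothing about structured populations (networks, opinion
leaders, targeted training), correlated traits, agent turnover, or
strategic authorities; all interaction terms are linear by construction,
so the results cannot validate nonlinear conformity either.

## Problem sizes and determinism

Default experiment sizes in the package's tests: $N = 1000$ agents for
replicate experiments (matching the study), $N = 500$ for single
convergence runs, 20 matched-seed replicates per sweep point, 200
replicates for adopter profiling. Every stochastic entry point takes a
seed; a master seed spawns per-replicate substreams deterministically, so
every table and trajectory is bit-reproducible from its seed and
configuration, and `write_results()` stores both next to the data.

## Known limitations

* The instability condition is sufficient only; the package deliberately
  does not claim the converse (see above), and the local-stability
  boundary for general parameters is explored by perturb-and-simulate
  rather than symbolically.
* With $p$ close to 1 the mean attitude of the few remaining non-adopters
  is a heavily selected, high-variance quantity; replicate tables report
  it as `NA` when the class is empty rather than imputing zero.
* The logit noise at the default $\lambda = 15$ means every finite run
  eventually absorbs at $p^* \in \{0, 1\}$; transient snapshots at fixed
  $T$ are the meaningful observable, which is why the harness reports
  times rather than waiting for convergence.
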