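---
title: "The communication model and its simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The communication model and its simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culturesim)
```

## The model

`culturesim` simulates agents that hold a belief about one binary idea —
the *status quo* versus an *alternative* — as a categorical probability
distribution, and that communicate by exchanging noisy expressions of
support together with affective cues. Every agent runs the same deep
generative model with individualized parameters; all population-level
phenomena are emergent.

### Perception: coupled belief updating

An agent's core belief $x$ is initialized from its prior $D$ and, after a
conversation in which it emitted expression $o_{self}$ and heard
$o_{other}$, is updated in log space:

$$x' = \sigma\!\left(\ln x + \gamma_{self}\,\ln o_{self}
        + \gamma_{other}\,\ln o_{other}\right)$$

where $\sigma$ is the softmax. The likelihood precisions $\gamma$ weigh the
evidence carried by each utterance; $\gamma_{other}$ is the explicit
coupling between interlocutors. With $\gamma_{other}$ high, a listener
adopts a confident speaker's position almost entirely within one exchange;
with $\gamma_{other}$ near zero the claims of others carry no weight. The
dyadic experiment (`simulate_dyad()`) isolates exactly this recursion: two
agents starting at support 0.9 and 0.1 alternate speaking and updating. The
test suite cross-checks the simulator against an independently written
two-line implementation of the recursion, and verifies the two regimes —
convergence of the belief gap under high symmetric coupling, persistence of
disagreement under low coupling — within 18 exchanges.

Between meetings beliefs decay toward uniform under a symmetric two-state
transition with switch probability $v$: confidence erodes without fresh
evidence. Each agent's $v$ derives from a transition precision
$\gamma_B \sim \mathrm{Gamma}(3, 2)$ via $v = 0.5/(1+\gamma_B)$, so precise
transition models decay slowly. Deviations from uniform contract by
$(1 - 2v)$ per day; the tests check this closed form.

### Affect and expression

Valence (positive/negative) is inferred from the core belief through a
row-stochastic likelihood map that is itself learned: the concentration
matrix $\alpha$ accumulates precision-weighted co-occurrences of observed
expressions and affective cues, $\alpha' = \alpha + \gamma_{A2}\,
(o_{expr} \otimes o_{affect})$, one update per conversation, so total count
mass grows by exactly $\gamma_{A2}$ per meeting (an invariant the tests
assert). New agents map the idea congruent with their phenotype to positive
valence at 4:1 counts and the unfamiliar idea to a near-flat row with small
total mass (0.5 per cell), so the emotional value of the alternative idea is
initially uncertain and is learned chiefly from interlocutors' cues.

Valence controls expressive confidence. The rate
$\beta = 0.25\,x_{sat}^{+} + 2.0\,x_{sat}^{-}$ parameterizes
$\gamma_{expr} \sim \mathrm{Gamma}(1, \beta)$ (mean $1/\beta$, so positive
valence means sharp expression), the expression policy is

$$u_{expr} = \sigma\!\left(\gamma_{expr}\,\ln x + \gamma_{E}\,E_{expr}\right)$$

and the emitted expression is a Dirichlet draw with concentration
$12\,u_{expr}$ (the affective cue analogously uses $12\,x_{sat}$). The
multiplier 12 keeps utterances in $(0,1)$ at moderate variance
($\approx 0.019$ for a maximally uncertain policy).

Two conventions deserve note. First, the belief term enters with a positive
sign, so agents express the claim they believe; the opposite sign (which
would make agents systematically voice the claim they believe *less*) is
available behind `printed_sign = TRUE` for comparison. Second, the habit
term $E_{expr}$ is the normalized habit-count vector itself, a probability
on $(0,1)$, not its logarithm. This keeps habitual bias bounded by
$\gamma_E$ logits. We initially implemented $\ln E$ and found it pathological:
log-counts grow without bound ($\sim \ln k$ after $k$ actions), so after a
few weeks of simulated time habit dictated every utterance regardless of
belief, and an agent that had genuinely changed its mind could never say so —
which forecloses any spread of a new idea. The bounded form matches the
description of $E$ as a probability and restores the intended role of habit
as a bias, not a dictator. The visitation habit enters the visit policy the
same way.

### Social choice: whom to talk to

Each day every agent scores all candidates (itself included — choosing
oneself means staying home) with an expected free energy

$$G_j = \underbrace{o_j \cdot (\ln o_j - C)}_{\text{pragmatic risk}}
      \; - \; \underbrace{h_j}_{\text{epistemic bonus}}$$

where $o_j$ is the candidate's expected expression (the agent's decayed
belief about $j$, passed through the travel transition and the expression
likelihood), $C = \ln(A_C\,x)$ are log-preferences biased toward
belief-confirming expressions by the map $A_C$, and $h_j$ is 0.1 for
candidates not conversed with in the last `memory_window` (default 5) days
and 0 otherwise. The visit policy is
$\sigma(-\gamma_G G + \gamma_E E_{visit})$.

The ambiguity term is implemented as a *bonus* (it lowers $G$): novelty
must attract for epistemic value to mean anything, and the package's
exploration test — zero the pragmatic term, pick the argmin of $G$ — shows
an agent touring all unseen candidates before any revisit, while the
exploitation test shows a strongly biased agent repeatedly revisiting the
best-matching known interlocutor. An additive-penalty convention is kept
behind `novelty_bonus = FALSE` for comparison.

$\gamma_G$ is valence-conditioned exactly like the expression precision
(drawn daily from $\mathrm{Gamma}(1,\beta)$, scaled by the configuration
multiplier `gamma_g_visit`): contented agents deliberate, dissatisfied or
uncertain agents fall back on habit and chance. Agents have no ambiguity
about themselves ($h_{self} = 0$).

## The community generator

`generate_population()` *is* the study condition, not a tunable fixture. It
creates `n_agents` (default 50) agents:

* **Sensitivity**: $\gamma_{A,other} \sim \mathrm{Gamma}(4, 0.75)$ —
  right-skewed, most agents quite sensitive to others' claims.
  $\gamma_{A,self}$ is fixed at 0.5: re-hearing one's own utterance is
  weaker evidence than a partner's claim.
* **Volatility**: $\gamma_B \sim \mathrm{Gamma}(3, 2)$ per agent, one kernel
  shared by the core belief and the beliefs about others.
* **Confirmation bias**: a fraction `high_bias_fraction` of agents (nearest
  integer, half rounded up) receive a near-identity preference map
  ($0.95\,I + 0.05\,U$); the rest a mild one ($0.6\,I + 0.4\,U$).
* **Initial beliefs**: all but one agent support the status quo with
  strength drawn uniformly from $[0.6, 0.98]$, yielding the spectrum from
  strict conservatives through centrists to skeptics. The last agent is the
  *rogue*: initial support 0.02 for the status quo, both belief-update
  precisions frozen at zero (fully resistant — its belief follows the pure
  decay recursion, which the tests verify exactly), and a mirrored valence
  prior (the alternative idea feels good to it).
* **Beliefs about others** start at a shared consensus prior $[0.8, 0.2]$:
  everyone knows the status quo prevails, and nobody can see an opinion
  before conversing.

Each simulated day: (1) all beliefs decay; (2) all agents select partners
simultaneously from start-of-day states; (3) visitor–host conversations
resolve in random order, one expression exchange per meeting, with hosts
accepting any number of visitors; both parties update beliefs, counts, and
visit memory. Habit counts increase by 1 per action taken (the expressed
claim; the selected partner, including staying home).

## Numerical choices

* All probabilities are clamped to $[10^{-6}, 1-10^{-6}]$ before any
  logarithm; saturated beliefs therefore remain finite in log space.
* Dirichlet concentrations are floored at $10^{-3}$ so degenerate policies
  still define valid distributions.
* Deterministic test modes replace the Gamma draw by its mean, emissions by
  their Dirichlet means, and categorical selection by the argmax with ties
  broken toward the lowest index. Production runs always sample.
* Subgroup sizes round half up (`floor(x + 0.5)`), so 15% of 50 is 8 agents.
* One master seed drives everything: per-agent parameter substreams are
  derived at fixed offsets, and the day-by-day dynamics run on a stream
  seeded from the master seed, so a configuration plus seed reproduces a
  trajectory bit for bit.

## Problem sizes

The default community is 50 agents for 100 days. The package's own
verification runs use 10 replicate seeds per condition for the
population-level claims (bias-composition ordering at fractions 0.15 vs
0.85 on matched seeds; mid-band fraction in the reference half-and-half
configuration), 12-agent/15-day runs for structural invariants (which are
size-free), and $10^4$–$10^5$ Monte-Carlo draws for distributional moments.

## What the generator does and does not emulate

The generator reproduces the *structure* of a heterogeneous opinionated
community — skewed sensitivities, graded conservatism, a bias split, a lone
immovable dissenter — under procedurally generated parameters. It does not
emulate features of real social data: network topology (any agent can visit
any other), broadcast or group communication (dyads only), demographic
turnover, external shocks, or any practical payoff for holding an idea.
Passing tests therefore demonstrate internal consistency of the mechanism
and reproducibility of its emergent regimes, not quantitative fit to
empirical opinion data.

## Known limitations

* **Transient conversions under the default sensitivities.** With mean
  sensitivity 3, a confident speaker effectively overwrites a listener's
  belief, so an agent converted to the alternative is usually reclaimed the
  next time a status-quo neighbor visits. In the default 50-agent community
  the alternative therefore stabilizes as a small cluster around the rogue
  rather than capturing a large faction, and the effect of confirmation-bias
  composition on final support, while present in the verification runs, is
  small relative to seed noise. Larger composition effects would require
  either weaker coupling (so beliefs integrate evidence over many meetings)
  or stronger assortment than the 0.1 epistemic scale and the
  valence-conditioned deliberation provide; both are exposed in the
  configuration for study.
* Habits only accumulate; there is no forgetting mechanism for concentration
  counts.
* Valence influences action top-down only; action outcomes do not feed back
  into valence.
* The two volatility kernels (core belief, beliefs about others) default to
  equal; nothing in the model fixes their ratio.
* Preferences concern expressed ideas only, not expected affective cues.

## Reproducing the headline quantities

`scripts/acceptance.R --seed <s> --out <path>` regenerates everything from
scratch: the dyadic gaps at couplings 3 and 0.05, the community composition
(49 of 50 status-quo initializers), the expression-rate constants at the
valence extremes (0.25 and 2.0), the novelty bonus (0.1), the mean final
status-quo support at strong-bias fractions 0.85 and 0.15 over 10 matched
seeds, and the median mid-band fraction in the reference configuration.
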