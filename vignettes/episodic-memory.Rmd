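---
title: "A deep temporal active-inference model of episodic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deep temporal active-inference model of episodic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimem)
```

## The model

`epimem` simulates episodic memory as inference in a two-timescale
("deep temporal") discrete generative model. A synthetic agent lives through
a short narrative of three epochs: it walks a Y-junction task, is asked a
question about what it did, and answers. The claim embodied by the model is
that remembering is *active construction*: the answer epoch re-instantiates
(replays) the walk from a compressed slow-level description rather than from
a stored recording, and speaking the answer is itself evidence that can
reshape the memory.

**Fast level.** Within an epoch, hidden states factorize into

* `location` — junction, signpost, left path end, right path end. The only
  controllable factor (actions: stay, go to the signpost, go left, go
  right); path ends are absorbing.
* `context` — whether home lies left or right. This factor doubles as the
  semantic slot for the spoken context word, so hearing "right" at step 6 of
  the answer is direct evidence about the spatial context.
* `syntax` — a deterministic chain: `no-speech` (walking), a 5-state
  question chain ("what was your *first/second* move"), a 10-state answer
  chain ("I *knew / didn't know* the route home was on the *left/right*, so
  I *checked / found it* by going *back / to the left / to the right*"),
  and a `pause` state that absorbs the remainder of an interview epoch.
  The longest chain has 10 positions, which fixes the episode horizon at 10
  time-steps, with the context word at answer position 6.
* semantic slots — `knowledge`, `method`, `moveword`, `query`, each static
  within an epoch.

Four modalities hang off these states: `vision` (scene and signpost cue; the
cue reveals the context only at the signpost, the junction view is
context-blind), `feedback` (neutral / home / flooded at path ends),
`audition` (words heard) and `proprioception` (words spoken). Preferences
`C` live on feedback only: home +2 nats, flooded −6 nats against neutral 0.

**Slow level.** Across epochs the model keeps a joint belief over the
narrative stage (a deterministic chain walk → listen → answer) and four
time-invariant "compression" factors: first move, second move, context, and
query topic. Link tables map slow states to fast initial states and to a
prior over fast policies ("what I would do"): each slow state is a
compressed description of a fast trajectory.

## Message passing

State inference is **exact**: for each candidate policy, forward–backward
smoothing runs on the joint (all-factor) chain, implemented as tensor
contractions over the factored transition tables (the built-in task has a
3264-cell joint space — small enough that nothing need be approximate).
Unobserved steps contribute no likelihood message and yield pure
predictions, so a single pass provides filtering, smoothing and forecasting
simultaneously. The package chooses exact smoothing over iterative marginal
message passing because it makes the enumeration oracle in the test suite a
tight equality (to 1e-6) and every run bit-reproducible.

Policies are scored by expected free energy

$$G(\pi)=\sum_{\tau>t}\sum_m \underbrace{\mathrm{KL}\!\left[Q(o^m_\tau\mid\pi)\,\|\,\sigma(C^m)\right]}_{\text{risk}}+\underbrace{\mathbb{E}_{Q(s_\tau\mid\pi)} H\!\left[P(o^m_\tau\mid s_\tau)\right]}_{\text{ambiguity}}$$

Because risk is measured against the *normalized* preference
$\sigma(C)$, it contains a negative predicted-outcome-entropy term — the
epistemic drive. At the junction with an unknown context, visiting the
signpost (whose cue outcome is maximally uncertain *a priori*) lowers risk
relative to staring at a known view, and this is what sends the healthy
agent back to check before committing to a path.

The policy posterior is $q(\pi)=\mathrm{softmax}(\ln E-\gamma G)$ with
policy precision $\gamma$. The empirical prior $E$ carries two things:
the descending "what I would do" message from the slow level, and the log
marginal likelihood each policy has accumulated from the observations so
far (without the latter, the agent would be unable to infer retrospectively
which policy it had pursued, and the end-of-epoch ascending message about
its own moves would be uninformative). Actions are the argmax of the
action-marginalized policy posterior, ties broken at the lowest index, so
the default task never touches the random-number generator.

**Descending and ascending messages.** Descending, each link column set is
averaged under the slow joint belief and precision-scaled to give fast
initial priors and the policy prior. Ascending, the end-of-epoch fast
marginals act as soft evidence through the transposed (and identically
precision-scaled) link tables. The evidence passed up is the *net*
evidence — the fast posterior divided elementwise by its own descending
prior, renormalized. Without this, a factor that received no observations
during an epoch would echo its prior back up and spuriously re-sharpen the
slow beliefs every epoch, masking exactly the between-epoch forgetting the
retain lesion is supposed to produce. Net evidence reduces to ordinary
soft evidence under a uniform prior and to exact Bayes for one-hot fast
posteriors.

**Sensory attenuation.** The vision (and feedback) likelihood columns are
conditioned on syntax: precise while no speech is in play, flattened by the
attenuation precision `zeta_att` during the question/answer chains and the
interview pause. At the default `zeta_att = 0` the interview scene — pinned
to a junction view — carries no information about location, so the early
steps of epochs 2 and 3 are driven purely by the descending episodic priors:
this *is* the replay. Feedback is attenuated alongside vision (the model
treats the whole non-speech scene as static during conversation); without
this, the neutral feedback of the interview room would contradict the
replayed path-end beliefs. Speech is produced actively: at each step of the
answer epoch the emitted word is the agent's most probable predicted
utterance, which it then hears — so telling the story can sharpen (or, under
lesions, distort) the memory of it.

## Precisions and lesions

Precision scaling is an elementwise power followed by renormalization:
`apply_precision(d, zeta) = normalize(d^zeta)`; `zeta = 1` is the identity
and `zeta = 0` the uniform distribution. A lesion of severity $s$ moves a
targeted precision to $1-s(1-\text{floor})$; the reference severity is 0.8
(so lesioned pathways run at `zeta = 0.2`), the single value at which all
four phenotypes separate simultaneously:

| lesion | pathway | phenotype |
|---|---|---|
| encode | descending/ascending links for initial location, context, policy | imprecise epoch-1 slow beliefs; context recovered only at answer step 6, on hearing the self-spoken context word |
| retrieve | links for the semantic slots (knowledge, method, move word, query) | replay intact, but the answer addresses the unasked second-move question |
| attenuate | raises `zeta_att` toward 1 | replay corrupted by the junction view; transcript unchanged |
| retain | slow transition precision of the invariant factors | episode content and eventually the question itself leak away between epochs |

Each precision carries a display-only neuromodulator label (likelihood —
acetylcholine; transitions — noradrenaline; policies — dopamine;
preferences — serotonin), reflecting the conventional pharmacological
reading of these parameters.

## Design constants and why

Power scaling is a no-op on degenerate (0/1) columns, so every table on the
lesion surface is built mildly soft; the softness values are model design
constants, fixed once:

| constant | value | role |
|---|---|---|
| `gamma` | 16 | policy precision; makes healthy action selection effectively deterministic |
| `C` (feedback) | home +2, flooded −6 | calibrated so a certain neutral outcome (risk 2.13 nats) beats a 50/50 home/flooded gamble (3.43 nats): checking dominates guessing iff the context is uncertain |
| vision/feedback softness | 0.98 | leaves room for partial attenuation under the attenuate lesion |
| walk transition softness (agent) | 0.95 | lets conflicting evidence re-route replayed trajectories |
| spatial/policy link softness | 0.96 | healthy descending context prior lands at ~0.92, precise from step 1 |
| answer-slot link softness | 0.90 | graded mixing of the two answer frames under query uncertainty |
| query link softness | 0.70 | the noisiest pathway: what a question *was about* is harder to pin than what was seen |
| slow query prior | (0.4 first, 0.6 second) | recency bias: absent evidence, a question is assumed to concern the latest move — this is what pulls lesioned answers toward the second-move frame |
| slow invariant-transition softening | 0.01 | identity at `zeta = 1` to within 1e-2; meaningful decay at `zeta = 0.2` |

The true environment uses fully deterministic tables, so all headline runs
are seed-independent; seeds only matter for user-supplied stochastic tables.

## What the simulation does and does not emulate

The generative process *is* the study condition: a single deterministic
agent, one walk (junction → signpost → right path, home to the right), one
posed question (the first move), three 10-step epochs. There is no
plasticity (the tables are fixed — this is short-term episodic memory, not
consolidation), no event segmentation from continuous experience, no
acoustics (words are symbolic outcomes), no population variability and no
measurement noise. Passing tests therefore demonstrate the internal logic
of the precision-lesion taxonomy, not claims about empirical patient data.

## Numerical choices and degenerate inputs

* Every returned distribution is renormalized; validators enforce column
  sums within 1e-10.
* `normalize` rejects all-zero or negative input with a
  degenerate-distribution error; `softmax` subtracts the maximum before
  exponentiating.
* The oracle-equivalence tests compare smoothing to full sequence
  enumeration at 1e-6 on randomized models with up to 4 states per factor,
  2 factors and horizon 4 (the scale at which enumeration stays cheap).
* Ties in action selection and transcript word choice resolve to the lowest
  index, deterministically.
* In the ascending net-evidence ratio, `0/0` (a state excluded by both
  prior and posterior) counts as 0.
* Time is reported 1-based everywhere (step 6 means the sixth observation
  of an epoch).
* Problem sizes: the narrative is 3 epochs x 10 steps over a 3264-state
  joint fast space with 4 policies; a full five-condition suite runs in
  well under two minutes on one CPU.

## Limitations

The semantic state inventory is the minimal one generating the three answer
sentences and both questions; richer grammars would need a larger syntax
chain and lexicon (the declarative YAML/JSON schema accepts such models,
but the built-in links are specific to this task). The two-level hierarchy
is fixed; there is no online re-planning of the slow level within an epoch,
and slow evidence is assimilated once per epoch, at its end. Lesions are
single-pathway and symmetric (the same link table is scaled in both
directions); mixed or asymmetric deficits are out of scope.
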