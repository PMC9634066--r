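---
title: "A fuzzy-oscillatory model of map-based navigation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fuzzy-oscillatory model of map-based navigation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navsim)
```

This vignette documents the model implemented by `navsim`, its assumptions,
the parameters that matter, and the design decisions taken where the
architecture left genuine freedom. Nothing here asserts an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The modeling problem

Map-based navigation needs two interacting memory systems: a hippocampal
cognitive map holding *where things are* and a prefrontal controller deciding
*which memory to retrieve next* given the current location, the goal, and
the navigator's attentional state. `navsim` implements this loop as four
components — a cognitive-map data model, a "where" stream (egocentric
geometry), a "what" stream (landmark identity), and a fuzzy retrieval
controller — plus a closed-loop agent that exercises them together. The
model assumes learning is complete: routes, landmark codes, and retrieval
rules already exist; the package simulates retrieval, not acquisition.

## Cognitive map

Landmarks carry integer ids, grid coordinates, a role (`route`,
`wrong_path`, `distractor`), and a symbolic identification frequency code.
On the default map the six route landmarks LM1–LM6 carry codes 4–9. The
printed sources define no codes for the wrong-path branches, so the package
extends the same affine mapping, code = id + 3 (LM7–LM11 ↦ 10–14): the
conversion between the rule-table axis (ids) and the stimulus axis (codes)
stays total, and branch codes remain off-resonant for the P = 4…9 bank.

The exact grid coordinates are presentation geometry, not model substance:
they affect path rendering and the angular tie-break of path competition,
but no rule count, recognition outcome, or spectral quantity. The default
layout is an orthogonal staircase from LM1 at the origin (x right, y up) to
LM6 at (12, 8), with a turn at every landmark and each wrong-path branch
continuing 3 units straight where the correct route turns — the geometry
that makes the "slightest angle to the previous heading" fallback
meaningful. All coordinates are overridable (`build_default_map(coords =)`,
or a YAML map file).

Long-term memory is a matrix with one row per route step:
`(x_lm_next, y_lm_next, w_lm_next, x_motor, y_motor)`. Amnesia (`lesion()`)
zeroes the rows targeting the lesioned landmarks; the landmark stays in the
environment and still emits its stimulus, but retrieval returns nothing.

## Where stream

A polar grid of `36 × 10 = 360` radial-basis neurons covers bearings
`[0, 2π)` at 10° resolution and radii `(0, r_max]` in 10 rings
(`r_max = 10` map units by default, chosen to cover every step length on
the default map with margin). Activation is the product of two Gaussians
with the printed variances `σ_r² = 0.06` (map units²) and `σ_θ² = 0.002`.
Two reading decisions are documented here because they fix the numbers the
tests assert:

* the variances enter the exponent directly (`exp(−Δ²/σ²)`, no factor 2),
* `σ_θ²` is read in radians² — in degrees² the tuning curves would be
  absurdly narrow (σ_θ ≈ 0.045° versus the 10° neuron spacing),
* angular differences are wrapped to `[−π, π]` before squaring, and the
  decoder uses the circular (vector) mean, so encoding and decoding are
  seam-safe at 0/2π.

With these choices the decode of an encode lands within half a grid bin
(0.5 map units radially, 5° in bearing) for every target within half a bin
of the covered radial band, which the test suite verifies over random
sweeps. Targets far inside the innermost ring (r < 0.25 or so) decode
toward the first ring; the closed-loop agent never produces them because
inter-landmark distances are ≥ 3 units.

## What stream

Each unit integrates

$$\dot X = (\lambda - Y^2)X - P^2 Y + B A_s \sin(\omega_s t), \qquad
  \dot Y = X,$$

a Van der Pol oscillator in `Y` with bifurcation parameter `λ`, natural
angular frequency `P`, and stimulus coupling `B`. The printed healthy
parameter set is `λ = 0.2`, `B = 1.5`, `A_s = 1`, `P = 4…9`.

**Frequency axis.** The `P²Y` term makes `P` an angular frequency. All
spectra are therefore reported on an angular-frequency axis ("code units"),
on which a unit with parameter `P` peaks at the value `P`. No claim of SI
hertz is made; the code-unit identities (peaks at 4–9) are what matters.

**Amplitude law.** Energy-balance averaging of the unforced equation gives
a steady envelope of `2√λ` for small positive `λ` (the sources also print
`2λ` once; the derivation and direct integration both support `2√λ`, which
the tests assert to 5 % across `λ ∈ {0.1, 0.2, 0.5, 1}`).

**Integration.** `deSolve::ode` with `lsoda` (adaptive, `rtol = atol =
1e-8`) on a uniform output grid, falling back to fixed-step `rk4` if the
adaptive run fails; a guard rejects output steps with
`dt · max(P, ω_s) > 0.1`. Defaults are `t_end = 100`, `dt = 0.002`,
transient discard 30 %. Initial state is `(0.1, 0)` unforced (a limit cycle
needs a nonzero seed) and `(0, 0)` driven.

**Envelope and recognition.** The instantaneous amplitude is the
analytic-signal magnitude (FFT Hilbert transform) of the post-transient
window. Two summary levels are kept:

* `peak_envelope` — the 99th percentile, an edge-robust "how high does it
  get" figure;
* `sustained_envelope` — the median, the level the unit actually holds.

Recognition uses the *sustained* level, for a quantitative reason: an
off-resonant unit superposes its own limit cycle (amplitude `2√0.2 ≈
0.894`) with the forced component (amplitude `≈ B A_s / |P² − ω_s²|`, up to
0.17 for neighboring codes), and the beat crests of that two-tone signal
transiently reach ≈ 1.04 — above threshold — even though the unit plainly
does not resonate. The sustained level separates the regimes cleanly
(matched ≈ 1.16–1.38 across codes 4–9, mismatched < 0.9). A landmark is
recognized only when **exactly one** unit crosses the unity threshold. This
uniqueness requirement is what makes the high-`λ` regime fail correctly: at
`λ = 15.2` every unit rides a relaxation limit cycle of amplitude
`≈ 2√15.2 ≈ 7.8`, all six cross the threshold, the response carries no
landmark-specific information, and recognition returns none rather than an
arbitrary winner.

**Spectra.** The PSD is a Hann-windowed Welch average over the
post-transient window; the dominant frequency comes from a 4× zero-padded
periodogram with parabolic peak interpolation (resolution well under the
2 % tolerances the tests use). Band powers integrate the Welch PSD below
and above a split of 3 code units — below the slowest natural frequency of
the bank, so the healthy units keep essentially no low-band power while the
relaxation regime concentrates power there. `spectral_summary()` refuses
windows shorter than 20 cycles of the slowest component.

**Alzheimer regime.** Raising `λ` through `{0.2, 2, 8, 15.2}` monotonically
lowers the dominant frequency of an unforced `P = 4` unit and raises its
low-band power share (the spectral-slowing signature), and at `λ = 15.2`
abolishes specific recognition as described above. Both are verified by
direct integration in the test suite.

## Retrieval controller

The controller is a fuzzy lookup-table system over (here, goal, attention).
Landmark dimensions use Gaussian membership functions with `σ = 0.15` on
the landmark-id axis — effectively non-overlapping at unit spacing
(membership of a neighboring landmark ≈ `exp(−1/0.045) ≈ 2·10⁻¹⁰`) yet wide
enough to absorb appearance changes of ±0.2 code units. Attention uses the
standard quadratic-spline S/Z pair with foot 1 and shoulder 2; the
crossover 1.5 is the attention-deficit threshold (the rule tables use 2 =
attentive, 1 = inattentive, and the healthy scenario runs at 2.3). Inputs
arriving on the frequency-code axis are converted to the id axis through
the map (code 4.2 → id 1.2), matching the convention of the printed rule
tables, which index landmarks by id.

The complete base enumerates every (here, goal) pair of route landmarks
under both attention states — 72 rules, 36 antecedent pairs for six
landmarks. Consequents follow the learned topology: with attention, the
next landmark along the route toward the goal (stay when here = goal);
without attention, the wrong-path branch attached at the current landmark
(stay where none is attached, i.e. at the final landmark). The two printed
route tables emerge as the active subsets (10 rules for LM1→LM6, 6 for
LM4→LM1). One printed consequent is ambiguous ("10/5" for here = 4,
goal = 1, inattentive); the package defaults to 10 — the wrong-path entry,
consistent with the other table's pattern — and exposes `overrides =` for
the alternative reading.

Inference is product firing strength and center-average defuzzification.
The raw output is a convex combination of firing consequents; the discrete
routing decision snaps it to the nearest consequent center, and both values
are kept in the trace. Completeness over the operating region (here, goal
codes in [3.8, 9.2], attention in [0.5, 2.5]) holds because Gaussians never
vanish within it and one of the two attention functions is ≥ 0.5
everywhere; the suite audits this on a grid and cross-checks the engine
against an independent double-loop implementation to 10⁻¹².

## Closed-loop agent

Each decision cycle: perceive → check expectation → retrieve → load
short-term memory → move. The short-term memory discipline is explicit:
loading the next-subgoal buffer shifts its previous content to the
previous-subgoal buffer, and the trace records both so the invariant is
checkable row by row.

Design choices the architecture left open, with the package's resolutions:

* **Perception window.** Recognition inside the loop only needs the
  envelope level, not spectral resolution, so the agent perceives with
  `t_end = 30`, `dt = 0.005` (margins re-verified at that window in the
  tests); spectral analyses use the full defaults. Bank runs are memoized
  per stimulus code within a scenario.
* **Attention-deficit threshold** = 1.5, the S/Z crossover: below it the
  "without attention" rules dominate the defuzzified output.
* **Wrong-branch dwell and recovery.** A drop is specified as (landmark,
  value, number of decisions). While attention stays below threshold the
  agent remains on the branch (one trace row per decision); on recovery it
  backtracks to the branch's decision landmark and re-retrieves under the
  attentive rule. The sources state that recovery happens but not its
  mechanics; backtracking to the attachment point is the minimal mechanism
  consistent with the branch being a dead end.
* **Competition cue.** When recognition fails entirely (Alzheimer regime)
  the next-subgoal buffer never loads, so the "lost information" driving
  weighted path competition defaults to the goal code — the only retrieval
  target still held; when a specific landmark's row is lesioned, the lost
  code is that landmark's code. Ties in the weights break by the smallest
  angle to the previous heading, then by the lowest id; no randomness is
  used anywhere, so identical configurations yield identical traces.
* **Step budget** = 4 × route length: an agent that has not confirmed the
  goal within it is recorded as lost (the Alzheimer outcome), keeping every
  run bounded.
* **Goal confirmation is perceptual**: arrival counts only when the goal
  landmark is recognized, which is why the Alzheimer agent can cross the
  goal's coordinates and still be lost.

Movement is landmark-to-landmark (one trace row per decision), with each
target routed through the where stream (encode → decode) and the decode
error recorded; per-cell animation is deliberately out of scope.

## What the scenarios show — and what they do not

The packaged presets exercise the three study conditions: `fig12` (healthy,
initial perceived code 4.2, goal code 9, attention 2.3 — reaches LM6 in
five decisions despite the start mismatch), `fig13` (attention drop to 1.0
for two decisions at LM4 — enters LM10, holds, recovers, finishes), and
`ad` (`λ = 15.2` — no recognition, competition wandering, lost at budget).

These are simulations of an idealized grid world with noiseless perception
apart from the modeled failure modes. Passing tests demonstrate the
internal consistency of the mechanism — resonance selectivity, spectral
slowing, rule-table reproduction, trace invariants — not correspondence to
human behavioral or electrophysiological data. Real EEG, pharmacology, and
learning are outside the model's scope, as are emotional modulation and
striatal route habits.

## Problem sizes

Default simulations integrate 100 time units at `dt = 0.002` (50 001
samples); the closed-loop perception window is 30 units at `dt = 0.005`;
property sweeps use 100–1000 random cases under fixed seeds. These sizes
were chosen so that every quantity is estimated with at least an order of
magnitude more resolution than the tolerance applied to it.
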