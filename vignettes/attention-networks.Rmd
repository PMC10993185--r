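---
title: "Gaze-based attention networks: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-based attention networks: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazenet)
```

## The problem

Head-mounted VR eye trackers report where the eyes point *relative to the
headset* — a unit "local gaze" vector in the tracker's own coordinate
frame. On its own this says nothing about *what* the user is looking at.
To recover the attended object one must combine the local gaze with the
head's position and orientation, project the resulting ray into the
virtual scene, and find the first object it hits ("gaze-ray casting").
Once every logged frame carries a gaze-target label, attention can be
summarized as a weighted directed graph — a *gaze-based attention
network* — whose nodes are objects of interest (OOIs) and whose edge
weights count gaze transitions between them. Structural variables of that
graph (centrality, distribution, interconnectedness) are interpretable,
statistically testable summaries of visual attention, and the whole
construction avoids fixation/saccade event detection, which is fragile in
3D environments.

`gazenet` implements this pipeline end to end in plain R, replacing the
game-engine line trace with an analytic ray caster, so recorded logs (or
synthetic ones) can be analyzed without any VR runtime.

## Coordinate frames and the gaze ray

Two frames are involved:

* **local (eye tracker)** — right-handed, z forward, x left, y up; gaze
  directions are unit vectors here;
* **world (engine)** — left-handed, x forward, y right, z up; lengths in
  unreal units (uu), 1 uu = 1 cm.

From a normalized local gaze $g = (x_g, y_g, z_g)$ the horizontal and
vertical rotation angles are

$$\mathrm{yaw} = -\cos^{-1}\!\left(\frac{z_g}{\sqrt{x_g^2+z_g^2}}\right)
  \frac{180}{\pi}\,\operatorname{sgn}(x_g), \qquad
  \mathrm{pitch} = \cos^{-1}\!\left(\sqrt{x_g^2+z_g^2}\right)
  \frac{180}{\pi}\,\operatorname{sgn}(y_g),$$

with $\operatorname{sgn}(0) := +1$. The leading minus and the signum
absorb the handedness change between the two frames, so the angles can be
applied directly to the head's forward vector: yaw rotates about the
head's up axis, then pitch about the (post-yaw) right axis. The global
gaze ray is $g_{\mathrm{global}} = h_{\mathrm{location}} +
f_{\mathrm{rotated}} \cdot k$; the default length $k = 25000$ uu is
effectively "very far", since the ray stops at the first hit anyway.
Although the arccos expressions are formally ±180° constructions, the
pitch form can only produce values in $[-90°, 90°]$, and that range is
enforced.

Design choices worth stating explicitly:

* **Rotation composition.** The engine's vector-rotation primitive leaves
  its frame semantics implicit. We fix intrinsic yaw-about-head-up
  followed by pitch-about-head-right. For roll-free head poses — the
  seated scenario this package targets — this equals applying the head
  rotation to the frame-converted local gaze exactly (a tested identity);
  under head roll the two decompositions diverge, and the intrinsic
  composition is the documented behavior.
* **Degenerate vertical gaze** ($x_g = z_g = 0$): any yaw is
  geometrically equivalent; we define yaw = 0.
* **Shapes.** OOIs are spheres or axis-aligned boxes — enough to model a
  classroom (board, people) without triangle meshes. Sphere hits use the
  ray quadratic, box hits the slab method; a ray starting inside an
  object hits it at distance 0.
* **Ties and hidden objects.** Exact distance ties are broken by scene
  declaration order (deterministic); non-collidable OOIs are skipped
  entirely, mirroring the practice of disabling colliders of hidden
  objects so they cannot occlude tracked ones.

## From frames to transitions

Cleaning removes rows whose validity columns (by default the two pupil
diameters) equal the missing-data placeholder (−1 by convention): the ray
caster reports a target whenever a head direction exists, so
placeholder-coded frames carry meaningless labels and must go. Cleaning
also reduces the log to the columns the analysis needs (time and gaze
target). Duplicate or unsorted timestamps are errors, not silently
merged.

A transition is a change of gaze target between successive samples *on
analysis OOIs*, timed from the last sample on the source to the first on
the target. Samples on non-analysis objects (walls, scenery, ray misses)
are not endpoints but do elapse time inside the enclosing transition;
likewise dropped invalid frames. The **maximum-duration filter** is the
single mechanism excluding indirect shifts: if the gaze wandered over
non-OOIs for long, the recorded duration is large and the transition is
discarded (and counted). The threshold is a required parameter with
default **1000 ms** — a generous allowance for a saccade plus a blink;
every transition table records the value used. Conservation holds by
construction: kept transitions + duration-excluded = number of target
changes in the OOI-restricted subsequence.

## Networks and structural variables

Counting transitions per ordered (source, target) pair yields one
weighted directed graph per participant and session. A supplied node
roster keeps never-gazed OOIs as isolated nodes, so variables are
comparable across participants. The undirected collapse sums reciprocal
weights — the only convention under which undirected strength equals
total transition involvement.

* **Strength** (weighted degree centrality of a node): sum of incoming
  and outgoing edge weights. Group strength sums it over a node group; by
  default within-group edges count at both endpoints (the literal sum of
  per-node centralities), with a flag to count only boundary-crossing
  edges once.
* **Candeloro weighted degree centrality (WDC)**: with a node's DC
  outgoing weights sorted *ascending* and $F_c(i)$ the cumulative weight
  share of the $i$ smallest edges, $\mathrm{WDC} = 1 + 2\sum_{i=1}^{DC-1}
  F_c(i)$. It equals DC iff the weights are uniform and falls toward 1 as
  weight concentrates on one edge; it is scale- and order-invariant. The
  ascending sort is what makes values comparable across participants
  whose heaviest edge sits elsewhere — with a descending sort the scale
  would invert.
* **Uniformity** $U = -\sum_e (w_e - \bar w)^2 / \bar w$, the negated
  chi-square statistic of the edge weights against a uniform expectation.
  $U = 0$ iff all weights are equal; more negative means gaze
  concentrated on fewer OOI pairs. Only edges present in the graph enter:
  absent pairs are not zero-count categories, a deliberate reading that
  makes $U$ a property of the realized transition distribution rather
  than of the node roster.
* **Cut size** over a two-set node partition: total weight of crossing
  edges, both directions. The normalized form divides by the *total edge
  weight of the network* — not by group volumes as in the spectral
  clustering literature — answering "what share of all transitions
  crossed between the groups?". This divergence from common library
  conventions is intentional and worth double-checking when comparing
  with other tools.
* **Maximal cliques** on the undirected collapse: OOI subsets pairwise
  connected by at least one transition that cannot be extended. Isolated
  nodes are size-1 maximal cliques by the mathematical definition;
  because treating them as "cliques" is interpretively ambiguous,
  `clique_stats()` reports counts and mean sizes both over all maximal
  cliques and restricted to size ≥ 2. Directed networks are rejected
  with a pointer to `to_undirected()` rather than silently converted.

Enumeration is delegated to igraph's maximal-clique routine and verified
in the test suite against an exhaustive subset search on small random
graphs.

## The synthetic session generator

The generator exists so every stage can be validated against ground
truth without hardware. It emulates a seated VR lecture:

* a **Markov attention process** over the analysis OOIs — a
  row-stochastic transition matrix with zero diagonal (a gaze "shift" to
  the same object is no shift) and per-state dwell times drawn from a
  truncated normal (lower bound one frame). Truncated normal is a
  deliberate simplicity: positive, two parameters, not claimed to match
  human dwell-time distributions;
* per frame, the true direction from the head to the attended OOI's
  center, perturbed by Gaussian **angular noise** about a random
  orthogonal axis, then converted into the local eye-tracker frame — so
  the log looks exactly like hardware output and must survive the full
  geometry on the way back;
* **invalid frames**: with the configured probability, pupil fields are
  set to −1 while the gaze target is still computed, matching loggers
  that report a target whenever head direction is valid;
* **fixed-rate mode** (default) places frames exactly every 1000/fps ms —
  a 15-minute session at 40 FPS has exactly 36,000 rows, one minute
  2,400 — while jitter mode draws exponential inter-frame gaps around the
  nominal period for realism.

Default study conditions, chosen once: 40 FPS, 15-minute session, dwell
mean 2000 ms / sd 1000 ms (a few hundred transitions per session, the
order of magnitude a lecture-listening task produces), gaze noise 1°
(typical consumer-HMD accuracy), invalid rate 2.5%, head fixed at a
student seat facing the board. The classroom scene (a board box, a
teacher sphere, up to four peer spheres) uses OOIs large enough that 1°
of noise essentially never flips the hit target — which is also why
passing tests here say nothing about small-OOI regimes, where real
tracker noise causes rapid alternation between neighboring labels.
What the generator does *not* emulate: saccade kinematics and smooth
pursuit (gaze jumps instantaneously between dwells), head movement
following attention, pupil-size artifacts beyond the placeholder code,
and moving OOIs.

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle: the
geometry against the closed-form frame conversion (round trip within
1e−6 over 1,000 random directions), the ray caster against brute-force
minimum-distance intersection with every object (1,000 random scenes of
up to 10 shapes), clique enumeration against exhaustive subset search
(500 random graphs of ≤ 8 nodes), and the worked examples of the
transition extractor, WDC and uniformity against hand-computed values.
End to end, a 30-minute 3-OOI synthetic session is pushed through
ray casting, cleaning, transition extraction and network construction,
and the row-normalized edge weights recover the generating Markov matrix
within total-variation distance 0.05 per state (seeded; at ~900
transitions the binomial sampling error alone is of that order, so the
tolerance is a statistical necessity, not slack). These problem sizes
keep the whole suite under two minutes while leaving each property
enough randomization to bite.

## Numerical and degenerate-input conventions

Arccos arguments are clamped to [−1, 1] against rounding; unit-vector
preconditions are checked at 1e−6, orthonormality of pose triads at
1e−9. A zero-length gaze vector cannot be normalized and is an error,
not a silent forward. Empty transition tables produce valid edgeless
networks (isolated-node rosters permitting), on which uniformity is
undefined (error) rather than 0. The uniform-weights case returns
exactly 0, not −0. Serialization sorts edges by (source, target) so
repeated runs are byte-identical; reading rejects negative, fractional
or duplicate edge weights with the offending line number.

## Known limitations

Triangle-mesh OOIs, binocular vergence, head-following-attention
dynamics, temporal (sliding-window) networks and cross-participant
statistical inference are out of scope. The normalized cut differs from
volume-normalized definitions elsewhere (see above). WDC is defined only
for nodes with at least one outgoing edge; reports simply omit WDC for
sink or isolated nodes.
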