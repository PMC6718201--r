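---
title: "Lattice finding for still diffraction patterns: model and methods"
author: "snapindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice finding for still diffraction patterns: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapindex)
```

## The estimation problem

A still diffraction pattern yields a set of reciprocal-space nodes
$\mathbf{q}_1, \dots, \mathbf{q}_K$ (units 1/Å, crystallographic convention
without the $2\pi$ factor), obtained from Bragg-peak detector positions by
the Ewald construction: a peak seen along the unit direction
$\hat{\mathbf{s}}$ gives $\mathbf{q} = (\hat{\mathbf{s}} -
\hat{\mathbf{s}}_0)/\lambda$, which lies on the Ewald sphere of radius
$1/\lambda$. The nodes are noisy samples of an unknown reciprocal lattice,
possibly contaminated by spurious detections and mixed with nodes of other
crystals. The estimand is the real-space basis $\mathbf{a}, \mathbf{b},
\mathbf{c}$ (rows of $B$) such that $B\mathbf{q} \in \mathbb{Z}^3$ for the
lattice's nodes — the Laue equations. Every node defines a family of
parallel real-space planes $\mathbf{q}\cdot\mathbf{t} = m$ with spacing
$1/|\mathbf{q}|$; lattice vectors are common intersections of all families.

## The score transform

Closeness of a trial vector $\mathbf{t}$ to a node's plane family is scored
by a periodic *proximity function* $c(x)$ on $[-\tfrac12, \tfrac12]$ with
$c(0)=1$, $c(\pm\tfrac12)=-1$, even and non-increasing away from 0, applied
to the fractional offset $x = \mathbf{q}\cdot\mathbf{t} -
\operatorname{round}(\mathbf{q}\cdot\mathbf{t})$ (midway ties broken toward
$+\tfrac12$). The plain score is the normalised weighted sum
$S(\mathbf{t}) = \sum_k w_k\, c(x_k) / \sum_k w_k \in [-1, 1]$. With the
cosine kind and unit weights this is exactly the real part of the Fourier
transform of the node arrangement, which connects the method to classical
Fourier indexing; the generalisation to other proximity kinds trades
convergence radius (broad, smooth kinds) against noise suppression and peak
sharpness (narrow kinds).

The texts that define this family fix only those properties, so the package
implements four conformant members: `cosine` ($\cos 2\pi x$), `triangle`
($1-4|x|$), `sharp_a` (a Gaussian bump of width $\sigma = 0.1$, affinely
rescaled to the $[-1,1]$ range) and `sharp_b` (a triangle of half-width
$0.15$).

The tolerant variant excludes nodes with $|x_k| > \varepsilon$ and rescales
included offsets by $1/2\varepsilon$, so the proximity function spans its
full range inside the inclusion band. Two normalisation choices were open:
dividing by the included weight rewards solutions that explain a single
node perfectly, so the package divides by the *total* weight of all nodes
and floors an empty inclusion set at $-1$; solutions explaining few nodes
are thereby penalised. The default $\varepsilon = 0.15$ (configuration key
`epsilon`) balances robustness — smaller values resist spurious peaks more
strongly — against the shrinking convergence basins; the value is exposed
because heavily contaminated data benefit from smaller tolerances.

## Locating maxima: extended gradient descent

Near a maximum the score's gradient is typically *large*, so plain
gradient steps overshoot. The step rule therefore derives the next step
length from the previous length, the turn angle and the score:
$\ell' = \operatorname{clip}(\ell \cdot f(\cos\theta) \cdot (1 +
\gamma(1-S)/2),\ \ell_{\min}, \ell_{\max})$ with $f = 1.5$ on straight runs
($\cos\theta > 0.7$), $0.5$ on reversals ($\cos\theta < 0$), $1$ otherwise:
steps grow on straight runs, halve on turns, and slow as $S \to 1$. When
the proposed direction nearly reverses the previous one
($\cos\theta < -0.8$), the direction is replaced by the normalised sum of
the two unit vectors, turning the path roughly orthogonal to the
oscillation; an exactly antipodal pair falls back to a deterministic
orthogonal direction. Defaults: $\gamma = 1$, $\ell_{\min} = 0.01$ Å,
$\ell_{\max} = 2$ Å, with later stages clipping to finer ranges. These
constants reproduce the qualitative behaviour the method calls for; they
are exposed through `descent_config()` but rarely need changing.

Starting points fill the search volume — a spherical shell from the
smallest to the largest plausible lattice-vector length (defaults 20–300 Å
with no prior; thin shells at the axis lengths, optionally extended by the
110/011/101 diagonals, with a known cell) — as Fibonacci-spiral point sets
on concentric spheres. The spiral construction replaces precomputed
electrostatic-repulsion point sets: it is deterministic, $O(n)$, and meets
the only requirement that matters here, approximately uniform spacing. The
radial increment between spheres equals the local in-sphere point spacing
(a geometric radius progression), each sphere receives an independent
random rotation, and because even proximity functions make $S$
centrosymmetric, only one point of each antipodal pair is kept.

The five-stage heuristic then runs: (i) cosine proximity, plain score,
inverse-radial weights $w_k = 1/|\mathbf{q}_k|$ (down-weighting
high-resolution nodes smooths the score and widens basins); (ii) `sharp_b`
and (iii) `sharp_a` under the tolerant score; (iv) sparse peak finding —
only points carrying the maximal score within a 2 Å environment survive,
at most 50 of them; (v) many fine `sharp_a` steps to polish the survivors.
Two profiles set the budgets: `fast` uses 12000 starting points and
40/14/8/24 stage steps, `precise` 50000 points and 60/20/10/40 steps. The
fast budget is the package's own calibration on the synthetic conditions
below: with this staging, smaller budgets leave too few sampled basins
around the short lattice vectors. Three further choices proved necessary
and are package design decisions: surviving peaks are ranked with the score
quantised to $10^{-3}$ and ties broken toward shorter vectors (near-tied
maxima are otherwise ordered by numerical noise, starving the fundamental
vectors out of the 50-peak cap); peaks outside the search shell are
discarded (a candidate lattice vector shorter than the assumed minimum
contradicts the prior); and near-duplicate candidate bases are collapsed to
one representative per quantised cell so a dominant lattice cannot flood
the selection shortlists in multi-lattice patterns.

## Basis assembly, selection and refinement

Candidate bases are triples of the surviving peaks, pruned in order:
one-vector prediction counts (a vector must fit at least 5 nodes), a
determinant guard ($|\det| \ge \max(1000\ \text{Å}^3,\ 0.2\,|a||b||c|)$),
two- then three-vector counts, the prior-cell filter when given (5% on
lengths, 2.5° on angles, after reduction), then ranking by summed peak
scores capped at 500. A node is "correctly predicted" when the
max-component distance of its fractional Miller indices to the nearest
integer triple is at most `relative_tol` (default 0.15; the source texts do
not quantify this).

Each kept basis is reduced to shortest vectors by iterated pairwise
Lagrange–Gauss steps plus small integer cross-corrections until no norm
decreases — conformance is defined against a brute-force successive-minima
oracle in the tests, not against any particular reduction recipe. The final
selection shortlists the 15 best candidates by score and the 50 smallest
relative defects (the mean fractional-index residual over predicted nodes);
for the shortlist ranking only, unpredicted nodes enter the defect at the
typical residual (0.3) of an unrelated node, so a basis cannot buy a small
defect by predicting a handful of nodes. Candidates then compete greedily
in order of descending prediction count (ties: smaller determinant, then
smaller defect): a candidate is accepted if it predicts at least five nodes
no accepted basis predicts, and it replaces an accepted basis covering
essentially the same nodes (Jaccard overlap of the predicted sets at least
0.8) when its relative defect is below 0.7 of the incumbent's, or when it
is the incumbent's primitive-cell version (determinant below 0.6 of the
incumbent's at a comparable count). Shortlisted candidates receive a light
refinement before this ranking, because raw peak triples systematically
under-count the nodes their lattice explains.

Refinement minimises the mean reciprocal-space distance between observed
nodes and predicted lattice points over the inlier nodes. For a fixed
Miller assignment the optimal basis solves a linear least-squares problem
in the reciprocal basis exactly, so the implementation alternates
{assign inliers, solve}, accepting an iteration only if the objective does
not increase; the reported objective trajectory is non-increasing by
construction and iteration stops at a $10^{-8}$ 1/Å decrease or 100
iterations.

Finally, a rational-index correction guards against cell-multiplicity
errors. A supercell basis predicts every node but assigns Miller indices
confined to a proper sublattice of $\mathbb{Z}^3$; an over-dense basis
leaves many nodes near rational indices with a small denominator. Both are
detected by triangularising (Hermite-style) the integer lattice spanned by
$\operatorname{round}(s M)$ over the tightly fitting nodes for scales
$s = 1, 2, 3$, rebuilding the cell from the result, and accepting the
candidate only if, after refinement, it keeps every tightly fitting node
and either shrinks the cell or gains at least three tight predictions.
"Tight" means a fractional residual within half the tolerance — such
predictions are almost never coincidental, which makes the comparison
robust against the chance captures that inflate plain prediction counts.

Multi-lattice patterns are handled natively: the greedy selection can
accept several disjoint lattices in one pass. Delete-and-retry (remove an
accepted lattice's nodes, re-run, at most 5 rounds) is available behind
`multi = "delete_and_retry"` and tends to be slightly more reliable at
extra cost. One-pass is the default because it is the algorithm's native
mode; the delete-and-retry loop re-runs the full pipeline per round.

## The synthetic generator and what it does (not) show

`simulate_scene()` generates the ground-truth scenes used throughout the
tests: for each of 1–3 lattices it draws a uniformly random orientation
(quaternion method), enumerates the reciprocal-lattice points within a
resolution limit `q_max` (default 0.25 1/Å, i.e. 4 Å), optionally restricts
them to a thin Ewald shell (half-thickness 0.002 1/Å at wavelength 1 Å —
the still-exposure geometry), samples `n_nodes` distinct points, adds
isotropic Gaussian noise, and appends spurious nodes uniform in the
resolution ball. The default cell is triclinic 35/45/60 Å with angles
85/95/100°, chosen so that no accidental symmetry confounds the
basis-equivalence checks. The default noise sigma is 1% of the smallest
reciprocal basis-vector norm and the default spurious count is 30% of the
per-lattice node count, the contamination regime of the worked examples.
Noise is truncated at $5\sigma$ so that labelled nodes remain attributable
to their lattice.

The generator emulates geometry, noise and contamination — not physics. It
produces no intensities (all nodes weigh equally unless the caller supplies
weights), no partiality, mosaicity or bandwidth effects, no detector point
spread, and spurious nodes are uniform rather than clustered at shadows or
powder rings as in real data. Passing tests therefore demonstrate the
lattice-fitting machinery under controlled conditions; they do not
establish indexing rates on any particular beamline's data.

Evaluation uses the Kabsch superposition angle between basis triads
(computed by SVD with the proper-rotation constraint, checked in the tests
against an independent quaternion oracle): a solution counts as correct
when, after reduction and the best of the 48 signed axis permutations with
matching cell lengths (5%), it rotates onto the truth by no more than 3°.

## Numerical choices and degenerate inputs

* Peaks at zero scattering angle map to $\mathbf{q} = 0$, carry no
  information, and are dropped with a warning rather than failing the
  pattern; a peak behind the tilted detector plane is an error.
* `fractional_offset()` breaks the midway tie toward $+\tfrac12$ so the
  offset is single-valued on $(-\tfrac12, \tfrac12]$.
* Patterns with fewer than 5 usable nodes return an empty solution list —
  a data outcome, not an error — as does a pattern where no basis predicts
  5 nodes.
* Pure-noise patterns may still return a small lattice that chance-fits
  five or more random nodes; this is a property of the "five predicted
  nodes" acceptance rule itself (real indexers show the same behaviour on
  weak patterns), and downstream consumers should treat low
  prediction-count solutions with corresponding scepticism.
* Refinement aborts (with a warning, returning the last valid basis) if
  fewer than 5 inliers remain; a singular least-squares system stops the
  iteration.
* All randomness — sphere rotations, scene generation, per-round seeds of
  delete-and-retry — derives from the caller's seed; fits are bitwise
  reproducible.

## Problem sizes used in the tests

The bundled checks run at desk scale, as the package's own choice of study
size: 100 clean and 100 noisy single-lattice scenes, 50 scenes per spot
count for the few-peak comparison, 50 two-lattice scenes per multi-lattice
mode (all 25 nodes per lattice, fast profile), 500 random lattices for the
reduction oracle, 50 point clouds for the sparse-peak oracle, 1000 random
instances for the Fourier identity and 100 seeded refinement trials.
`scripts/acceptance.R` recomputes the headline quantities at similar sizes
from a single command-line seed.

## Known limitations

Single flat detector panel only (no multi-panel geometry files);
no per-event wavelength jitter, polarisation or solid-angle corrections;
no space-group or centring determination beyond the primitive reduced
cell; no intensity-based weighting by default (the option exists); the
equivalence check enumerates signed axis permutations, which is sufficient
for primitive cells but not for centred-lattice reindexing ambiguities.
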