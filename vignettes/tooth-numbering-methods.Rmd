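---
title: "Prior-knowledge tooth numbering: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-knowledge tooth numbering: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentition)
```

## The problem

Object detectors applied to dental panoramic radiographs emit one bounding
box per recognized tooth, labelled with a universal tooth number (UTN, 1-32)
and a confidence score. Raw detector output is unreliable exactly where it
matters clinically: a single tooth may be detected twice, neighbouring
premolars get confused, teeth altered by prosthetic work (crowns, inlays,
bridges) are missed more often, and complete restorations -- implants and
the artificial denture tooth of a bridge -- are not teeth at all for a
tooth detector, so the resulting chart undercounts missing teeth. This
package post-processes such detections, together with the output of a
separate four-class prosthesis detector (inlay, crown, implant, bridge),
into a consistent 32-slot dental chart: for every UTN slot either one box or
an explicit "missing".

Coordinates follow the image convention (origin top-left, x rightward, y
downward, absolute pixels); boxes are centre-format with half-open pixel
intervals for area computations. Panoramic images mirror left and right, so
T1 appears at image-left of the upper arch through T16 at image-right, and
T17 at image-right of the lower arch through T32 at image-left.

## Pipeline

`runPipeline()` chains four stages.

**1. Positional filtering** (`filterToothCandidates`). The tooth-bearing
region occupies roughly the central 55% of the image width, which bounds
where each tooth number can plausibly appear: candidates numbered T10-T24
with a centre left of 40% of the width, and T1-T7 / T26-T32 right of 60%,
are discarded. T8, T9 and T25 sit near the midline and are exempt. Boundary
comparisons are strict; a centre exactly on the cutoff is kept.

**2. Occlusal geometry** (`fitOcclusalModel`). The maxillary and mandibular
candidate centres are fitted with quadratics `y = a2 x^2 + a1 x + a0` by
unweighted ordinary least squares (confidence-weighted fitting is
deliberately not used; the candidate set is already thresholded). The
occlusion line is the coefficient-wise mean of the two curves and the
dentition centre is its apex, `-a1 / (2 a2)`, unless the apex deviates from
the image-width centre by more than 5% of the width (or `|a2| < 1e-12`,
when the vertex is undefined), in which case the image centre is used.
Boxes are assigned to a jaw by comparing their centre y with the occlusion
line; a centre exactly on the line goes to the mandible (a documented
constant -- with continuous coordinates the tie has measure zero). A jaw
with fewer than three distinct x positions cannot support the fit; the
pipeline then falls back to a flat model (horizontal rows at each jaw's
mean y, centre at width/2) rather than failing. Candidates removed by stage
1 are excluded from the fit, since filtering precedes it in the flow.

**3. Prosthesis numbering** (`splitBridge`, `assignToothNumbers`). Bridge
boxes -- this package only handles bridges replacing a single missing tooth
-- are partitioned along x in the ratio 33:30:33 (normalized to 33/96,
30/96, 33/96 so the sections tile the box exactly; the alternative
"33%/30%/33% of the width" reading leaves 4% undefined and was rejected),
with the middle section the denture and the outer sections the abutment
teeth. Each prosthesis-derived box is then fanned out into one candidate
per tooth number in its applicable range -- maxilla left of the dentition
centre 1-13, maxilla right 3-16, mandible left 20-32, mandible right 17-29
-- all sharing the box and confidence. Fanning out the whole range, rather
than guessing a single number, is a deliberate reading: the downstream
optimizer is exactly the mechanism for resolving the number, and the ranges
overlap near the midline for the same reason. When a prosthesis box
overlaps a step-1 tooth candidate with IOU at least 0.5, the tooth is
considered already detected and the confidence of all its fan-out copies is
halved, once per box. The overlap rule operationalizes "already detected"
spatially; the detector gives no other linkage between the two candidate
streams. Abutment sections inherit the full bridge confidence.

**4. Combinatorial selection** (`optimizeCombination`). One candidate (or
the missing option &phi;) is chosen per slot by maximizing

$$f(P) = \omega_p f_p(P) + \omega_c f_c(P), \qquad
  \omega_p = 0.8,\ \omega_c = 0.2,$$

where $f_c(P)$ is the mean confidence over the 32 slots with $\mu(\phi) =
0$, and $f_p(P)$ is the mean over slots of a per-tooth positional score

$$f_p(x) = \frac{1}{|\Omega|} \sum_{y \in \Omega} \delta(x, y), \qquad
  \Omega = \{x\!-\!2, x\!-\!1, x\!+\!1, x\!+\!2\} \cap \text{jaw}(x).$$

$\delta$ is a piecewise score of the separation $g$ between the two chosen
centres: $-4$ for $g < a$ (too close or reversed), $0$ on $[a, b)$, a
linear ramp up on $[b, c)$, $1$ on the plateau $[c, d)$, a ramp down on
$[d, e)$, $0$ on $[e, f)$, $-4$ beyond $f$, and $\kappa$ when either tooth
is missing. Setting $\mu(\phi) = 0$ makes "declare missing" cost confidence
mass, which is what counterbalances it against the $-4$ positional
penalties a wrong candidate would incur.

### The distance thresholds

With 16 teeth per row in the central 55% of the width, the nominal station
spacing is `width * 0.55 / 16`. The base thresholds are

| quantity | value | meaning |
|---|---|---|
| `b` | `spacing * 0.4` | start of the ramp up |
| `e` | `spacing * 2` | end of the plausible range |
| `Range` | `e - b` | plausible-presence span |
| `a` | `b / 2` | too-close / reversal cutoff |
| `c` | `b + Range/4` | plateau start (Q1) |
| `d` | `c + 3 Range/4` (printed) or `b + 3 Range/4` (quartile) | plateau end |
| `f` | `e + Range/4` | too-far cutoff |

Two parameterisations of `d` are provided because the source material is
internally inconsistent: the printed formula implies `d = e` identically
(making the ramp-down segment empty), while the accompanying description of
the plateau as "first to third quartile of the Range" implies `d = b + 3
Range/4`. The printed form is the default (`variant = "as_printed"`) for
fidelity; the quartile form is available.

Three adjustments apply in order: (i) when both teeth lie in the crowded
mandibular centre (21-28), `b` is halved and `a, c, d, f` are recomputed
from it; (ii) when either tooth is a mandibular molar (17-19, 30-32), `e`
is multiplied by 1.5 and the dependent values recomputed; (iii) for
next-nearest pairs (`|x - y| = 2`) the too-close cutoff becomes the
unshifted `c` and `b..f` all shift outward by that `c` (one tooth lies
between the pair, so every plausible distance grows by about one plateau
start).

### Signed separations

$\delta$ is evaluated on the *direction-corrected* separation
(`directedSeparation`): positive when the higher-numbered tooth lies on the
side its jaw's numbering runs toward, negative when the pair is reversed.
Reversed pairs therefore land in the $g < a$ branch and score $-4$. An
absolute-value reading was tried first and is measurably wrong: it lets
blocks of candidates occupy slots in reversed order with full positional
credit, which in noisy benchmarks collapses precision. The ordering
expectation (T1 left of T2, and mirrored in the mandible) is the stated
core of the prior; the signed form is the only one that encodes it.

$\kappa$ defaults to 0 -- missing neighbours neither reward nor penalize a
placement. No value is prescribed by the source material; 0 is the neutral
choice and is configurable (`pipelineControl(kappa = ...)`).

### The search

The search is deterministic coordinate ascent: initialize every slot with
its highest-confidence candidate (&phi; where empty); sweep slots 1..32
trying every option and keeping strict improvements; repeat until a sweep
makes no update (at most `maxSweeps = 10`; convergence is typically within
3 sweeps); then, for every slot still missing despite having candidates,
run an exhaustive joint search over that slot and its four same-jaw
neighbours' option sets (capped at `5^5` combinations, falling back to
pairwise joint searches beyond that -- the 13-slot prosthesis fan-out can
otherwise explode the product). Ties keep the incumbent, so the objective
never decreases and identical inputs give identical outputs.

Two details are this package's own:

* **Box identity.** All fan-out copies of one prosthesis-derived box share
  an identity, and the search never selects the same physical box into two
  slots. Without this, one detection can be double-counted in slots three
  or more apart, where the local &Omega; window is blind.
* **Isolation exception** (Step 7, `enableStep7`). When a chosen tooth is
  flanked by missing slots and exactly one tooth is present on each side of
  it within the jaw, the candidate may be renumbered one slot toward the
  spatially nearer flanking tooth if that strictly improves the objective.
  The source description of this exception is ambiguous; this reading is an
  interpretation and the step can be disabled.

## Evaluation metrics

`evaluateDetections()` implements the standard detection protocol: a
prediction is a true positive when it overlaps an unmatched same-class
ground-truth box with IOU &ge; 0.5 (greedy matching in descending
confidence, each ground truth matched at most once -- the convention of the
common open-source evaluation toolkits; the matching order is otherwise
unspecified in the source), otherwise a false positive; unmatched ground
truths are false negatives. AP uses all-point interpolation,
$\sum_n (R_{n+1} - R_n) \max_{R' \ge R_{n+1}} P(R')$; mAP averages
per-class APs, with classes that have detections but no ground truth
contributing 0 and classes absent from both excluded. Micro
precision/recall/F1 pool counts over classes and scenes.

## The synthetic dentition simulator

No radiographs or trained detector weights ship with the package;
`generateScene()` produces everything the pipeline and its tests consume.
A scene places 16 stations per jaw along two quadratic arches inside the
central 55% of a 640 x 640 frame (the usual detector input resolution),
with the occlusion apex near the image centre, a 90 px vertical jaw gap and
20 x 44 px tooth boxes. Station status is sampled in order: missing teeth
(`missingProb = 0.10`, matching a reported average of about 28.6 teeth per
image in comparable clinical material); bridges over single missing teeth
with both neighbours present; implants on remaining missing stations;
crowns and inlays on remaining teeth. The per-tooth incidence defaults
(`inlay 0.016, crown 0.066, implant 0.03, bridge 0.05`) are derived from
per-image prosthesis counts in comparable clinical test material. At least
five teeth are retained per jaw, mirroring the data-selection rule the
occlusal fit relies on.

Three ground-truth views mirror the annotation practice the pipeline is
evaluated against: the *tooth* view omits complete restorations (implants,
bridge dentures), the *all* view includes them numbered by station, and the
*prosthesis* view labels the four prosthesis classes with the bridge box
spanning both abutments and the denture.

The detector noise model is invented -- the real counterpart is a trained
CNN -- and aims to reproduce the qualitative failure modes of such
detectors as controllable parameters: centre jitter (std 0.10 of tooth
width, both axes), size jitter (0.05), duplicate detections (0.10),
adjacent-number confusion (0.05), misses at 0.02 for untreated and 0.15
for treated teeth, and Beta-distributed confidences (Beta(14, 2) for
genuine, Beta(5, 5) for spurious detections). What passing tests under
this model shows is that the *refinement logic* behaves as designed under
these failure modes; it does not validate performance on real radiographs,
whose detectors have correlated, image-dependent errors the simulator does
not emulate (superimpositions, braces, residual roots, resolution
variation).

## Benchmark problem sizes and numerical choices

The packaged benchmarks (also recomputed by `scripts/acceptance.R`) use 100
seeded small instances for the optimizer-versus-enumeration check (at most
6 two-candidate slots, so the exact optimum is enumerable), 50 zero-noise
scenes for the perfect-recovery limit, and 200 noisy scenes at the default
noise for the robustness benchmark, where proposed-mode micro-F1 is
expected at 0.95 or above and at least the earlier (tooth-only) mode.
Score comparisons in the search use strict `>` (ties keep the incumbent);
floating-point equality in tests allows 1e-9. All randomness flows through
explicit integer seeds; scenes are pure functions of their spec.

## Known limitations

* Adjacent-number confusions are generally unrecoverable: a box carries its
  detector label, and short of the isolation exception the search cannot
  renumber it. Such errors appear as misses (and occasionally FP/FN pairs)
  in the benchmarks.
* Under the printed `d = e` parameterisation the nominal station spacing
  falls on the ramp (not the plateau) for mandibular-molar pairs after the
  1.5x stretch, so a jaw-end restoration adjacent to a second missing tooth
  can score marginally higher one slot inward; rare one-slot shifts of
  jaw-end implants/dentures are a genuine optimum of the objective, not a
  search failure.
* Bridges replacing more than one tooth are out of scope, as is any use of
  y-coordinates in the positional prior.
* The prior's thresholds scale only with image width; strongly non-standard
  magnifications would need re-derived constants.
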