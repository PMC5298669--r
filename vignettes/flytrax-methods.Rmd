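---
title: "Tracking many flies with heading-direction confirmation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking many flies with heading-direction confirmation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flytrax)
```

This vignette explains the science inside `flytrax`: the imaging model the
detector assumes, the posture and tracking models, every tunable that
matters, what the synthetic generator does and does not emulate, and the
design decisions taken where more than one reasonable choice existed. It
states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## 1. The imaging model

The detector assumes top-down grayscale footage of a circular arena:
fly bodies are the darkest objects in the scene, the arena floor is
bright, and the wings — translucent but not invisible — render at an
intensity strictly between body and background. Everything except the
flies is static. Two consequences drive the design:

* Because the flies move and occupy any given pixel a minority of the
  time, the per-pixel **mode** of sampled frames is the background. The
  estimate is exact wherever the fly-occupancy of a pixel stays under
  50% of the sampled frames; the default of 100 sampled frames keeps the
  sample representative without scanning the whole video.
* Because wing intensity is sandwiched between body and background,
  band-pass thresholds can isolate wing pixels, and wings betray which
  end of the body is the tail.

Intensity arithmetic is floating point throughout; values are clipped and
quantized to 8 bits only at I/O boundaries (and in the renderer, which
emulates a camera). Illumination drift is cancelled before subtraction by
shifting each frame to the background's mean intensity — a global additive
correction, which is the right model for lamp drift but not for vignetting
or flicker gradients.

Background subtraction returns `255 - |frame - plate|`: the absolute
difference is reversed so that flies are dark on a light field no matter
the original polarity. The LoG filter then yields positive peaks at
body-sized dark spots. The kernel's σ (default 6 px) should be about the
body's half-width; its zero circle at σ√2 matches the body scale, and the
response at a full-contrast body peaks around 1.5 response units while the
flat field sits near zero, which is why the default soft threshold is 0.5.
The threshold deliberately preserves response values above the cut —
merged-blob splitting needs the peak structure, not a binary mask.

### Merged-blob splitting

The expected single-fly area is the mean blob area of the frame. A blob
whose area rounds to *m* > 1 expected flies is re-thresholded within its
own pixel set at cut-offs rising by a fixed fraction (default 5%) of its
response span per iteration, up to `max_iter` (default 20). The escalation
stops as soon as at least *m* components of non-trivial area appear; if
more than *m* appear the *m* largest are kept. Near the separating
threshold the surviving components are necessarily small cores around each
fly's response peak, so the fragment filter (`min_frag_frac`, default 5% of
the expected area) exists only to ignore noise specks, not to enforce
fly-sized fragments. When two bodies overlap heavily their peaks fuse into
one mountain and no threshold separates them; the blob is then kept whole,
and resolving it becomes the tracker's job.

## 2. Posture

Centroid and normalized second central moments use the standard region
formulas with the +1/12 unit-pixel term on the squared moments (a single
pixel behaves as a unit square, not a point). No such correction applies
to the cross moment: adding 1/12 there would tilt every axis-aligned
region, and the fit would no longer equal the eigendecomposition of the
second-moment matrix — an equivalence the test suite enforces to 1e-9.
With Δ = √((uxx−uyy)² + 4uxy²), the full axis lengths are
a = 2√2·√(uxx+uyy+Δ) and b = 2√2·√(uxx+uyy−Δ) (these equal 4√λ of the
moment matrix's eigenvalues, the familiar region-ellipse axes), and θ
follows the half-angle rule with the circular case (uxy = 0 and
uxx = uyy) mapped to 0. The degenerate-case ordering matters: a vertical
region also has uxy = 0 but must take the uyy > uxx branch, giving π/2.

### Heading

The ellipse gives an axis; wings give the sign. Two search points sit at
the vertices of the fitted ellipse (centroid ± a/2 along the major axis;
the offset fraction is configurable). For each (floor, ceiling) threshold
couple, pixels of the *raw* patch — not the LoG response, which has no
wing contrast — inside the band are marked, and each search point counts
marked pixels within its search radius (default 0.35·a, at least 3 px,
scaling with the animal). Marked pixels outside both discs are
"environment" evidence: if they exceed `env_reject_ratio` (default 0.5) of
the band's marked pixels, that couple is discarded as background texture.
The automatic couples tile the band between the blob's dark decile
(the body proper — the blob's support spills past the body, so a high
percentile of support intensities would sit at background level) and just
below the local background (the patch's upper quartile minus a margin),
using `n_couples` windows (default 6) of width at least 10 gray levels.
The end with the higher accumulated score marks the wings, provided it
beats `min_score` (default 3 pixels); the heading points the other way.
Ties, sub-threshold scores, and near-circular fits (`a/b` below 1.1)
return no verdict — the tracker treats heading as unavailable rather than
guessing, because a confidently wrong heading is what causes identity
errors downstream. Flies with laterally extended wings or mid-air blurs
violate the wings-behind-the-head premise; on such frames the verdict is
withheld or can be wrong, which is the known failure mode of any
wing-position method.

## 3. Tracking

Each identity carries a constant-velocity Kalman filter over
(x, y, vx, vy), velocities in px/frame internally and reported in px/s.
Newborn trackers start at the detection with zero velocity, position
variance equal to the measurement variance, and velocity variance
`v0_var` (default 25).

* **Measurement noise** `r_sd` = 2 px reflects the centroid scatter of the
  detector on body-sized blobs.
* **Process noise** comes from a white-acceleration model with SD
  `q_accel_sd` (default 0.1 px/frame²). This is deliberately smooth: a
  walking fly between manoeuvres is very nearly constant-velocity, and the
  smooth filter recovers position to well under the measurement noise and
  velocity to within a few percent — properties the test suite checks.
  The price is lag during jumps and scripted steering; association
  survives because the gate (50 px) dwarfs any one-frame displacement, and
  the filter re-converges within a few frames. Raising `q_accel_sd` trades
  estimate quality for manoeuvre agility; both regimes are legitimate, and
  the parameter is exposed.

Association is three-staged, per frame:

1. **Hungarian assignment** of predicted positions to detections on a
   Euclidean cost matrix padded square with dummies at
   `dummy_cost_factor × gate` (default 75 px), so any tracker or detection
   can stay unmatched when no plausible partner exists.
2. **Heading confirmation**: a matched pair is kept only if the angle
   between the tracker's stored heading and the detection's heading is
   within `heading_tolerance_deg` (default 90°). Pairs with an unavailable
   heading pass — heading is confirmatory evidence, not a requirement.
   Dummy pairs are rejected by construction.
3. **Closest-neighbor reassignment** of the rejected pool against the
   trackers' *pre-prediction* positions. This is the backward-motion cure:
   when a fly stops and retreats, the constant-velocity prediction
   overshoots past its neighbour and the optimal-by-distance pairing is
   the swap; the heading gate vetoes it (the swapped pair is anti-parallel),
   and greedy matching to where the flies actually were restores identity.
   The test suite constructs exactly this scenario and verifies that the
   full tracker holds identities while a Hungarian-only ablation swaps
   them.

Lifecycle: unmatched trackers coast on prediction and retire after
`max_missed` (default 10) consecutive unmatched frames; unmatched
detections spawn new identities in birth order. Two extensions handle
unsplittable merges, where several flies yield one detection:

* **Sharing**: a detection at least `oversized_frac` (default 1.3) times
  the frame's median area with two or more tracker predictions inside its
  extent is *shared*: it is excluded from assignment, updates no tracker
  (its centroid is the pair's midpoint, a position belonging to no single
  fly), spawns no identity, and the trackers near it coast without aging.
  Their separately predicted paths carry the identities through the merge,
  and when the blob splits, each prediction is nearest its own fly. The
  1.3 factor is below the nominal 2 because overlapping bodies shadow each
  other — a merged pair's area is typically 1.5–1.8 singles, dipping lower
  mid-merge.
* **Occlusion grace**: any unmatched tracker whose prediction lies within
  1.5 major-axis lengths of some detection is plausibly hidden inside that
  blob and does not age toward retirement. This keeps identities alive
  through long merges without making lost trackers immortal (a tracker
  adrift in empty arena still retires).

## 4. The synthetic generator

`scene_spec()` fixes the study conditions; `simulate_motion()` and
`render_video()` realize them deterministically from one seed. Defaults:
a 240×240 px frame, arena radius 105 px, background 200, body 40, wings
140 gray levels, bodies 8×3 px semi-axes, 20 fps, Gaussian pixel noise
SD 2, and a correlated random walk with 2 px/frame mean step (≈40 px/s,
inside the 13–94 px/s range typical of walking-fly arena recordings at
similar scales), heading turn SD 0.25 rad/frame, and a 0.5% per-frame jump
probability (jumps of 5–15 steps in a random direction). A soft repulsion
keeps unscripted flies at least `min_separation` (4 semi-major axes)
apart, so merges happen only when scripted — that is what makes "no
crossings ⇒ no identity pressure" a meaningful baseline condition rather
than luck. Wings are drawn as two small ellipses fanned ±25° about the
anti-heading axis, centred 0.9 semi-major lengths behind the centroid;
compositing is min() (darkest wins), so touching flies fuse into one dark
region exactly as real silhouettes do.

Scripted crossings place the pair on straight, equal-speed paths whose
closest approach (default 8 px, half a body length) occurs exactly at the
scripted frame, with the approach beginning at full `min_separation` so
the only close encounter is the scripted one; the meeting point is clamped
near the arena centre so the paths fit inside the wall, and a steering
phase beforehand walks each fly to its path start on its own side (the
side and path assignment minimize steering, so the steering legs never
cross each other).

What the generator does **not** emulate: body texture and limb detail,
wing articulation (grooming, wing extension), perspective and lens
distortion, shadows and reflections, vignetting, compression artifacts,
and flies on the arena wall seen side-on. Passing tests therefore
demonstrate the algorithmic machinery — background modelling, splitting,
heading scoring, association logic — under the stated imaging model, not
robustness to every artifact of real footage; on real videos the detection
threshold, σ, and the wing band typically need adjustment, for which
`threshold_preview()` exists.

## 5. Numerical and design choices

* **Mode ties** resolve to the smallest tied value — any deterministic
  rule works; determinism is what matters for reproducible plates.
* **Convolution borders** are handled by reflection padding, which avoids
  the spurious border response of zero padding on bright fields.
* **Soft thresholds below zero** clamp to zero so the blob image is
  nonnegative for the labelling stage.
* **Splitting step size** is relative (a fraction of the blob's response
  span) rather than one gray level, because LoG response units scale with
  image contrast; a fixed absolute step would be contrast-dependent in
  iteration count.
* **If escalation over-splits** (more than *m* components), the *m*
  largest by area are kept.
* **Greedy ties** (equal minimal costs) break toward the lowest row, then
  the lowest column — again, any fixed rule works, determinism matters.
* **Evaluation** associates each trajectory point with the nearest true
  fly within 10 px (about a body length); frames where the second-nearest
  fly is also within that radius are ambiguous and excluded from swap
  counting, mirroring how a human scorer attributes identities only after
  flies separate. A swap is a confident association change; a loss is an
  identity that had to be re-born after the first frame; a track mostly
  associated with no fly is a false positive.
* **Problem sizes** used by the test suite and acceptance script — 1000
  random cost matrices up to 6×6 against exhaustive permutation minima,
  500 random blobs against the eigen oracle, 200 single-fly images for
  heading accuracy, a 200-frame background fixture, and 10 flies over 300
  frames end to end — are chosen so the whole battery runs in a few
  minutes on one core while keeping every estimate's sampling error well
  inside the margins being asserted.

## 6. Known limitations

* Heading is undefined (by design) for near-circular blobs and withheld
  on ties; a fly that grooms with both wings extended sideways defeats
  the wings-behind-head premise.
* The mode background requires each pixel to be fly-free most of the
  time; a fly that sits still through the sampled frames becomes part of
  the plate and turns invisible there (and its departure leaves a ghost).
  Mode exactness also presumes quantized intensities; under continuous
  noise the plate is correct only to the nearest gray level.
* The splitter resolves touching flies, not heavily overlapping ones;
  those are tracked as one detection until they separate, and identity
  across such merges rests on the coasting predictions being roughly
  right, which degrades for long merges with manoeuvring flies.
* A single static plate assumes a static scene; slow scene changes
  (condensation, food smears) call for re-extraction, which the two-phase
  design makes cheap.
* The constant-velocity model is wrong during jumps; the tracker relies
  on gating rather than dynamics there, so two simultaneous jumps landing
  near each other's origins can still swap.
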