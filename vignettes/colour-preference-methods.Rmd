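---
title: "Methods: colour-preference analysis in CIE LCh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour-preference analysis in CIE LCh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colourpref)
```

## The scientific setting

`colourpref` analyses unrestricted colour-choice experiments: each
participant uses a sequential colour picker to produce the colour they
prefer *most* and the colour they prefer *least*, in three object
contexts (a context-free "general" preference, imagined interior walls,
and an imagined t-shirt).  Each of the six choices is recorded as a
colour, together with process measures (selection time, click count) and
an optional valenced association (an object or concept the colour
reminded the participant of, rated for pleasantness on a -45 to +45
scale).

The analysis currency is CIE LCh -- lightness `L` (0-100), chroma `C`
(0-141), hue angle `h` (0-360 degrees) -- the cylindrical form of CIE
1976 L\*a\*b\*.  Hue is treated categorically, lightness and chroma
continuously.

## Colour conversion

Measured colours enter as CIE xyY and pass through
`xyY_to_XYZ() |> XYZ_to_Lab() |> Lab_to_LCh()`, with the standard CIE
1976 cube-root transform and its linear branch below the ratio
`(6/29)^3`.  The reference white is always an explicit argument -- in the
experimental setting it is the white background panel against which
patches are shown, measured per monitor -- and white maps exactly to
`(L, a, b) = (100, 0, 0)`.

Device RGB values can be converted through a parameterised
`display_model()` (primaries, white point, transfer function; the
default is an sRGB/D65 monitor).  This is an explicit approximation: a
software model cannot reproduce the photometric measurement of a
physical screen, so the pipeline records a `colour_source` flag for
every row and prefers measured xyY whenever both representations are
present.  Achromatic colours (`a = b = 0`) are assigned `h = 0` by
convention; the convention is inert because categorisation never
consults the hue of a colour at or below the achromatic chroma cut-off.

## Hue categories

`default_hue_scheme()` bins the hue circle into eight chromatic
categories (Red 346-40, Orange 40-72, Yellow 72-105, Yellow-Green
105-130, Green 130-166, Green-Blue 166-220, Blue 220-275, Purple
275-346, each with a focal hue) plus an achromatic category for chroma
at or below 5.  Two conventions required a decision:

* **Boundary inclusivity.** The published category table prints shared
  endpoints (Red ends at 40, Orange starts at 40) without stating which
  side owns the boundary.  Arcs here are half-open and lower-inclusive
  (`[lo, hi)`), so 40 degrees is Orange.  Any convention would do; this
  one makes the arcs a deterministic partition, which
  `validate_scheme()` verifies exactly.
* **Achromatic cut-off.** The source material states both "chroma < 5"
  (in prose) and "<= 5" (in its category table).  The tabulated rule is
  taken as normative: `C <= 5` is achromatic.

Schemes are data, not code: they serialise to JSON and alternative
binnings can be supplied for sensitivity analyses.

## Bootstrap pairwise comparison of hue shares

For one condition with counts `n_1..n_9` over the nine categories
(total `n`), `bootstrap_pairwise()` draws `B` multinomial resamples of
size `n` from the observed proportions and, for each of the 36
unordered category pairs, builds a confidence interval for
`p_i - p_j` at the multiplicity-corrected level
`alpha_c = alpha / (k (k - 1))` (0.05/72 here).  A pair differs when its
interval excludes zero, and `letter_display()` encodes the full
significance pattern with the insert-and-absorb algorithm: categories
share a letter exactly when they do not differ.

The interval construction was genuinely open: the motivating study
states only that a corrected confidence interval was computed.  We
compared four candidate readings (percentile vs normal-approximation
intervals, corrected alpha split across the two tails vs applied per
tail) against all six published letter columns -- 216 pairwise outcomes.
The normal-approximation interval with bounds at
`mean +/- qnorm(1 - alpha_c) * sd` reproduces 215 of 216; every other
variant mismatches at least four pairs.  It is therefore the default
(`method = "normal"`), with the percentile interval available as an
option.  The single irreproducible pair (Blue vs Achromatic, 2 vs 14 of
85, most-preferred wall colours; published as significant) sits at a
bootstrap `z` of 3.18 against a criterion of 3.20 under every variant
we tried, and is treated as a borderline discrepancy rather than
evidence for yet another construction.  Note also that
`0.05/72 = 6.9e-4`, although the source text prints the corrected level
as "<= .0006".

Because `36 * 2 * alpha_c = alpha`, the construction is a Bonferroni
bound and the familywise error under a uniform null stays at or below
`alpha` up to Monte-Carlo error; `simulate_fwer()` checks this by
simulation (500 datasets of `n = 85`, `B = 10^4` resamples each -- the
sizes used by the test suite and acceptance script; the estimate is
typically near 0.04).

Letter glyphs are assigned in display order and are arbitrary; only the
shared-letter *partition* is meaningful, and tests compare partitions,
never glyphs.

## Marginal homogeneity, signed ranks, within-subject ANOVA

* `stuart_maxwell()` tests whether the association-type distribution
  (object / concept / none) differs between most- and least-preferred
  choices, accounting for pairing: `chi^2 = d' S^{-1} d` with `d` the
  marginal differences (one category dropped) and `S` its
  null covariance, `df = k - 1`.  On 2 x 2 tables it reduces exactly to
  McNemar's `(b - c)^2 / (b + c)`.  Categories with empty margins are
  dropped; a singular `S` falls back to a Moore-Penrose inverse with the
  rank as effective df.
* `wilcoxon_signed_rank()` reports the signed-rank `V`, a standardised
  `Z` with the usual tie correction, and a two-sided p-value -- exact
  (via the signed-rank distribution) for 50 or fewer untied differences,
  normal-approximate otherwise.
* `rm_anova_2x3()` implements the classical fully-within two-factor
  decomposition: each effect is tested against its own
  effect-by-subject interaction.  Greenhouse-Geisser epsilon is computed
  from the covariance of orthonormalised effect contrast scores,
  reported for every effect, and applied to the df of effects with more
  than one numerator df -- it is *always* applied there, rather than
  conditionally on a sphericity pre-test, matching how such analyses
  are conventionally reported.  Effect sizes are partial eta squared.
  Degenerate inputs (zero effect variance) return `F = 0`, `p = 1`
  rather than 0/0.  `bonferroni_posthoc()` multiplies paired-t p-values
  by the comparison count, capped at 1.

Each of these is cross-checked in the test suite against an independent
route: `stats::mcnemar.test`, exhaustive `2^8` sign enumeration and
`stats::wilcox.test`, `stats::aov` with `Error()` strata, and Box's
element-wise epsilon formula.

## The picker engine

`picker_config()` / `run_agent()` re-implement the colour picker as a
headless state machine.  The palette screen shows nine patches (the
eight focal hues at `L = 60`, `C = 60`, plus mid grey -- stand-ins, since
the original starting RGB values are appendix material).  Refinement
moves the centre colour along clean CIE Lab axes: corners change `b`
(yellow-blue) and `a` (red-green), vertical neighbours change `L`,
horizontal neighbours change chroma radially.  The original tool's axes
were only *related* to Lab dimensions, so exact step geometry is
unrecoverable; clean Lab moves are the reconstruction.

Step sizes start at 25 Lab units, shrink by a factor of 0.5 on every
refinement click (on the centre as well as on an outer patch), and
patches closer to the centre than the renderable threshold of 2 Lab
units are omitted.  When all variations vanish, the centre is proposed
as final; clicking it reopens refinement at the last renderable step
sizes.  None of these numbers is published; all are configuration.

Two analytic guarantees follow and are tested:

* **Termination.** Within one refinement visit started at step size
  `s`, all steps fall below the threshold `t` after
  `ceil(log(t / s) / log(shrink))` clicks (4 clicks with the defaults).
* **Convergence.** A zero-noise greedy agent reopens the proposal only
  while a renderable move strictly reduces its Lab distance to the
  target.  At its stopping point no axis move of the reopen step size
  `s_r` helps, so each axis error is at most `s_r / 2`, and since
  `s_r < t / shrink`, the final distance to any in-gamut target is
  below `sqrt(3) t / (2 shrink)` (about 3.46 Lab units with defaults).
  Observed worst-case distances over random targets are near 2.3.

Selection *times* are never produced by the engine; synthetic durations
are clicks times a lognormal per-click latency, and only ordinal
most-versus-least claims about them are ever asserted.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of the
participant table: per-condition hue-category weights default to the
observed frequency table of the motivating study (via
`table2_counts()`); hue angles are uniform within each category's arc
(maximum-entropy choice -- the within-category spread was not
published); lightness and chroma are truncated normals whose
condition-specific means encode the qualitative findings (walls-most
light at 75, t-shirt-most dark at 45 and unchromatic at 40,
general-most chromatic at 65; SDs 15 and 18); association types are
imbalanced (object-rich for most-preferred at 0.5/0.3/0.2
object/concept/none, none-rich for least-preferred at 0.25/0.3/0.45);
valence is positive-truncated (mean 20, SD 12 on [0, 45]) for
most-preferred and mirrored for least-preferred; click counts are
`1 + Poisson` with means 25 vs 17.  The figure-only quantities of the
source (association percentages, valence distributions) are qualitative
stand-ins, deliberately not presented as ground truth, and all of this
is configuration, not code.

What passing recovery tests show -- and what they do not: the pipeline
recovers configured hue weights within binomial sampling error at
`n = 850`, reproduces the configured lightness ordering with the
expected interaction, and separates valence signs.  This validates the
*machinery* end-to-end.  It cannot validate the substantive findings on
real participants: real data have inter-individual correlation
structure, context-order effects and response styles that the generator
deliberately omits.

`generate_via_picker()` additionally routes every record through a
greedy noisy agent, so final colours and click counts arise
mechanistically from the selection process.

## Numerical choices and problem sizes

* Percentages are rounded half-up to one decimal (`percent()`),
  validated against all 54 printed fixture percentages.
* Bootstrap defaults `B = 10^5`; the calibration simulation uses
  `B = 10^4` within 500 replicates, and the parameter-recovery check
  uses 850 synthetic participants -- sizes at which the Monte-Carlo
  error is far below the tested margins.
* All randomness is seeded; reports are byte-identical across reruns
  with the same seed.
* Achromatic hue, arc boundaries and the chroma cut-off follow the
  conventions above; ties in the greedy agent resolve to the first
  minimum in patch display order.

## Known limitations

* The RGB route is a display-model approximation, flagged per row;
  only measured xyY reproduces the original conversion chain.
* One published pairwise outcome (walls/most Blue vs Achromatic) is not
  reproduced by any bootstrap variant tried (z = 3.18 vs 3.20).
* The marginal multinomial models and multilevel logistic regressions
  reported alongside the bootstrap in the source material require the
  unpublished raw data and are out of scope here.
* Exact picker step geometry, palette RGB values and per-monitor white
  points are reconstructions driven by configuration defaults.
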