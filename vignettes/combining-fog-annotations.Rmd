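---
title: "Combining two raters' freezing-of-gait annotations: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining two raters' freezing-of-gait annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogcombine)
```

## The problem

Freezing of gait (FOG) episodes have no crisp boundaries: freezing can evolve
out of a gradually worsening gait pattern, and it is often unclear whether
normal gait was restored between two near-by episodes. The accepted standard
is therefore double video annotation: two independent raters mark every FOG
episode (with a phenotype — trembling, shuffling or akinesia — and a trigger
such as a doorway or a 180° turn), and the two annotation sets are then
reconciled. Wherever the raters disagree, a *gray area* appears, and labs
have historically handled these ad hoc. This package implements a
deterministic, fully reportable reconciliation driven by two parameters, so
that a methods section can state exactly how the combined annotation was
produced.

## The procedure

All times are **integer milliseconds** and all intervals **half-open**
`[begin, end)`. This is the representation ELAN uses internally; it makes
abutting episodes non-overlapping, durations additive, and removes any need
for epsilon handling — a zero-length gray segment cannot exist.

1. *Normalization* (`normalize_track`). Overlapping or abutting episodes
   within one rater are merged first, since the comparison presupposes each
   rater contributes disjoint episodes. Conflicting labels merge to
   `"unspecified"` with a warning.
2. *Partition* (`partition_timeline`). The trial `[0, N)` is cut at every
   episode boundary of either rater and adjacent pieces of equal colour are
   merged, giving the unique maximal partition into **black** (both raters
   annotate FOG), **white** (neither) and **gray** (exactly one) segments.
3. *Classification* (`classify_gray`). A gray segment that touches a black
   segment is *non-isolated* (`preceding`, `following` or `enclosed`
   depending on which side the black is); one that touches no black on
   either side is *isolated* — an episode only one rater saw.
4. *Resolution* (`resolve_partition`). Isolated grays always go to
   third-rater discussion, however short. A non-isolated gray longer than
   the tolerance goes to discussion; otherwise the correction parameter
   decides: `include` turns it into FOG (absorbed by the bordering agreed
   episode), `exclude` into no-FOG.
5. *Merging and flagging* (`merge_episodes`, `flag_label_disagreements`).
   Maximal runs of resolved FOG become combined episodes; an enclosed gray
   resolved to FOG fuses its two black neighbours into one episode. An
   episode whose raters' phenotype (trigger) label sets differ is flagged
   `check_type` (`check_trigger`) for review during the discussion session.

## Parameters that matter

* **`tolerance_ms`** (default **2000 ms**). Separates annotation imprecision
  from substantive disagreement. The default follows the convention that an
  episode ends once the participant performs two effective alternating
  steps, which takes roughly two seconds; boundary disagreements within
  that window carry no clinical information. The comparison is
  `duration > tolerance → discussion`: a gray of *exactly* the tolerance is
  resolvable. This tie rule is deliberate (the discussion list should hold
  strictly substantial disagreements) and is pinned by a dedicated boundary
  test at 2000 vs 2001 ms. `Inf` is legal and leaves only isolated grays in
  discussion.
* **`correction`** (default **`"exclude"`**). `exclude` counts only certain
  FOG — the conservative choice for fundamental research into FOG
  mechanisms, and therefore the package default; `include` keeps every
  potential FOG epoch, appropriate when e.g. training an on-demand cueing
  detector where a miss is costlier than a false alarm. The FOG time-set
  under `include` is always a superset of that under `exclude`.

Both parameters are echoed verbatim into `metrics.json` and the discussion
list header by `run_combine`, so any published combined annotation carries
the configuration that produced it.

## Agreement statistics

Agreement is tabulated from the **pre-resolution** partition: the initial
overlap between the raters is what reflects their reliability, and it would
be circular to grade raters on a table the tolerance/correction machinery
has already cleaned up. (`run_config(metric_scope = "post")` exposes the
post-resolution table as a sensitivity analysis: corrected gray time moves
into the agreed cells and only discussion time remains as disagreement.)

The unit of observation is the millisecond, i.e. metrics are
duration-weighted; an optional epoch mode (`tabulate_partition(p, epoch_ms)`,
majority rule per epoch) exists only for comparability with epoch-based
literature. From the 2×2 table (`a` both-FOG, `b`/`c` single-rater,
`d` neither):

* `PA = 2a/(2a+b+c)`, `NA = 2d/(2d+b+c)` — the specific agreements for the
  FOG and no-FOG category;
* `PI = (a−d)/N` — prevalence index, −1 when no rater annotates any FOG,
  +1 under continuous agreed FOG (positive = FOG-heavy, matching those
  anchors);
* Cohen's `κ` — reported for comparison only: it is *undefined* when the
  chance agreement `p_e = 1` (e.g. a trial in which neither rater annotates
  FOG — common in practice), and it underestimates agreement when FOG is
  rare or near-continuous. Undefined values propagate as explicit `NA` with
  a `*_defined = FALSE` column, never as silent zeros, and pooled metrics
  are computed on the cellwise-summed (duration-weighted) table.
* `ICC(2,1)` on per-trial summary scores (e.g. % time frozen): pinned to
  the two-way random-effects, absolute-agreement, single-rater variant, and
  the variant name travels with the value because ICC variants are easy to
  confuse and materially differ.

## What the simulator states, and what a green test establishes

`simulation_spec()` is a stated world, not a tuning knob: a 60 s trial with
5 episodes, log-normal episode durations with 3 s mean (`sdlog` 0.4 — FOG
durations are right-skewed), log-normal 6 s mean gaps, truncated-normal
boundary jitter with 300 ms sd (comfortably inside the half-second
imprecision regarded as unremarkable between raters, and below half the
default tolerance), and 10% rates for missing an episode, splitting one long
episode into two epochs, and mislabelling. Splits emulate the documented
disagreement mode where one expert annotates one long episode and another
several short epochs. All draws come from one seeded stream per simulated
track, and the seed is recorded in the fixtures manifest.

The generator emulates *annotation* imperfection only. It does not model
gait physiologically, correlations between raters' errors (real raters
often err in the same direction at ambiguous boundaries), drifting
attention, or systematic rater bias. A green recovery test therefore
establishes that the interval algebra and resolution logic are correct under
the stated noise model — not that any particular pair of human raters will
reach a given agreement level.

## Numerical and degenerate-input choices

* Half-open integer-ms intervals everywhere; times parsed from the `s.ms`
  and `hh:mm:ss.ms` dialects are rounded to the nearest millisecond, and
  formatting inverts parsing exactly, so file round trips are boundary-exact.
* Auto dialect sniffing is per-field and ordered: `":"` → `hh:mm:ss.ms`,
  else `"."` → `s.ms`, else `ms`.
* An empty annotation table is legal (a rater may see no FOG); an empty
  trial (`N = 0`) is not.
* Each maximal gray segment is one unit of decision, even when its
  single-rater coverage alternates between the raters; when one rater's
  single episode encloses the other's two, the enclosed gray is judged once.
* An included gray inherits phenotype/trigger from its bordering black
  segment; an *enclosed* gray inherits from the earlier black. The choice is
  arbitrary but deterministic, and any disagreement between the two black
  neighbours surfaces as `check_type`/`check_trigger` on the merged episode
  anyway.
* Gray classification counts only black segments as "definite FOG"
  neighbours: a gray abutting another, discussion-bound gray is still
  isolated. Likewise a non-isolated gray longer than the tolerance goes to
  discussion *alone* — its black neighbour stays agreed FOG, since both
  raters did annotate it. (The alternative, dragging the neighbour into
  discussion, would let one rater's sloppiness invalidate agreed data.)
* The trial duration is taken from the caller when known and only falls
  back to the maximum end time across both raters; it is the denominator of
  negative agreement, so passing the true observed duration matters.
* The template layout with phenotype and trigger on one tier versus two is
  left to the `tier_map` argument rather than guessed; triggers attach to an
  episode by majority overlap (more than half of the episode's duration).

## Limitations

* Two raters only; no three-or-more generalization and no automation of the
  third-rater consensus itself.
* Tab-delimited ELAN exports only (no binary/XML `.eaf` parsing, no video).
* No confidence intervals or prevalence-adjusted kappa variants; the
  package reports the recommended trio (PA, NA, PI) plus κ and ICC(2,1)
  for comparison.
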