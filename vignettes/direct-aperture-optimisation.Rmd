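---
title: "Direct aperture optimisation with variable neighbourhood search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct aperture optimisation with variable neighbourhood search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(daovns)
```

## The model

An IMRT treatment plan for a beam-angle configuration of `U` gantry angles is
a set of aperture shapes and intensities per beam,
`H = {(P^1, I^1), ..., (P^U, I^U)}`. Each aperture is a matrix over the
beam's beamlet grid with entries in `{-1, 0, 1}`: `-1` cells lie outside the
usable field (their rays never cross the target), `1` cells are open, `0`
cells are blocked by a leaf. Because each row is shaped by two opposing MLC
leaves, its open cells form one contiguous run — the consecutive-ones (C1)
property. `daovns` stores apertures as one half-open interval per row
(`aperture_shape()`), which makes C1 structural: a fully closed row keeps its
leaf meeting column so re-opening is well defined.

A beam's fluence is the intensity-weighted sum of its aperture matrices;
flattening all valid cells row-major (beams concatenated in configuration
order) yields the beamlet vector `x`, and per-region doses are
`d^r = D^r x` with non-negative sparse dose-deposition matrices. Plan quality
is the convex one-sided quadratic penalty

$$z(x) = \sum_r \frac{1}{m_r} \sum_{v=1}^{m_r}
  \left[\underline\lambda_r (Y_r - d^r_v)_+^2
      + \bar\lambda_r (d^r_v - Y_r)_+^2\right],$$

zero exactly when every penalised voxel sits at (or on the unpenalised side
of) its prescription. The default prescription
(`objective_params_prostate()`) is 76 Gy to the PTV with symmetric weight 5,
and 65 Gy over-dose-only limits (weight 1) on bladder and rectum; intensities
live in [0, 20] MU with at most five apertures per beam, so a five-beam plan
never exceeds twenty-five apertures.

## Search components

**Initial solution.** Five predetermined apertures per beam — half-open
bottom, top, right, left, and fully open — with intensities then set by the
aperture-weight optimiser. The construction is deterministic, so random
seeds affect only the neighbourhood draws.

**Aperture weight optimisation (AWO).** With shapes fixed, `z` is a smooth
convex piecewise-quadratic function of the intensities (the `(·)₊²` terms
are continuously differentiable), minimised over the box
`[γmin, γmax]^K` by L-BFGS-B plus a projected-gradient polish
(`optimise_weights()`, tolerance `1e-6` on the projected-gradient residual,
iteration cap 500). Apertures whose open cells touch no penalised voxel are
flat directions of the objective; they are resolved to `γmin`, which
minimises beam-on time at no cost. The solver is guaranteed never to return
something worse than its starting intensities — the search drivers rely on
this monotonicity. Whether weights should be optimised per beam or jointly
is a genuinely open choice; `daovns` optimises all apertures jointly, since
the objective couples beams through the shared dose.

**Neighbourhoods.** `N1` draws one aperture uniformly at random and emits,
for every row, each feasible unit leaf move — open-by-one or close-by-one on
either leaf. Interior rows thus have four neighbours, fully closed and fully
open rows two (one when a closed row sits against the field edge). `N2`
makes the same per-row moves but draws the aperture holding each row's moves
independently, so the modified leaves belong to different shapes; with a
single aperture the two neighbourhoods coincide. Neighbour objectives are
evaluated at the parent's intensities — the schedule only re-optimises
weights for the single best candidate, which keeps neighbourhood evaluation
cheap. Improving neighbours are *intensified* (the same leaf keeps moving one
column at a time while the objective strictly improves) and then *merged*
into one extra candidate combining all improving moves; same-leaf conflicts
keep the best-improving move, and crossing leaf pairs drop moves in order of
worst improvement until the row is C1-valid. The merged candidate competes
in best-neighbour selection rather than being auto-accepted, and merging is
applied once per movement application, not recursively.

## Drivers

`run_vnd()` follows the descent schedule: generate neighbourhood `k`
(`vnd12` = N1 then N2, `vnd21` the reverse), accept the best neighbour if it
strictly improves and reset to the first neighbourhood; otherwise re-weight
that best neighbour and accept on improvement (without resetting `k`, per
the schedule); otherwise advance `k`, terminating at `k = 2`. `run_rvns()`
pools both neighbourhoods each iteration and stops the first time neither
the best candidate nor its re-weighted version improves. Acceptance is
strict with `epsilon = 1e-9` — a literal "accept on ties" rule can cycle. A
safety cap (default 10,000 iterations) is flagged in the trace if ever hit.

One structural consequence of the schedule is worth knowing: weights are
re-optimised only for *candidate* plans, never for the incumbent, so a run
can terminate with intensities that were optimal for an earlier shape. The
enumeration oracle in the test suite (which re-weights every shape) is
therefore matched exactly on a toy whose optimum has a bound-active weight;
on interior-optimum instances the schedule may stop a weight-optimisation
step short of the enumerated optimum. This is the intended control flow,
not a defect.

## The synthetic phantom

No patient data ships with the package. `build_phantom()` rasterises a
prostate-like geometry — an elliptical PTV flanked by an anterior bladder
and posterior rectum — onto an in-plane voxel lattice replicated across
`mlc_rows` out-of-plane slabs, one slab per MLC leaf pair (a strictly 2-D
lattice cannot give leaf rows dosimetric meaning). A seeded Gaussian jitter
(sd 0.04 on the normalised ellipsoid radius) roughens region boundaries;
generation is bit-reproducible per seed. Defaults: 31×31 voxels of 0.6 cm,
5 slabs, 1.2 cm beamlets — about 200–400 voxels per region and ~135 valid
beamlets over five beams. These sizes were chosen so that a full search run
completes in seconds while the dose matrices retain realistic structure
(overlapping target/organ shadows, partial-volume rows near the target
poles); they are far below clinical voxel counts, so absolute objective
values are not comparable to published clinical tables — only orderings and
structural counts are.

Dose deposition uses a pencil-beam kernel: parallel rays, exponential depth
attenuation (`mu = 0.05`/cm, typical of ~6 MV photons), Gaussian lateral
spread (`sigma = 0.5` cm, slightly under half a beamlet width, giving
nearest-neighbour spill), entries truncated below `1e-3` of the surface dose
for sparsity. `sigma = 0` degenerates to a top-hat of one beamlet width —
the delta-kernel limit used by the tests. A beamlet belongs to the usable
field when its ray passes within 1 cm of the target's projection in its
slab; everything outside is a `-1` cell. What the phantom does *not*
emulate: 3-D CT heterogeneity, beam divergence, scatter tails, couch/collimator
rotations, and clinically realistic voxel counts — so green tests demonstrate
algorithmic correctness, not clinical performance.

The 14 equidistant five-beam configurations are generated from the printed
rule — configuration `k` starts at `5(k−1)°` with 70° spacing — reproducing
all 70 published angles exactly (70°, not the exact 72° equidistance, is
the printed convention and is followed as printed).

## Sequential baseline

`solve_fmo()` minimises the same objective over beamlet intensities in
`[0, x_max]` (default `x_max = γmax · 5`, making FMO a true relaxation:
its optimum lower-bounds every deliverable plan). `round_fluence()` rounds
to the nearest multiple with half-way cases up (3 → 4 at multiple 2; the
convention is documented since either choice is defensible).
`sequence_sweep()` decomposes each beam's rounded fluence with the classical
unidirectional sweep: layer `t` of a row opens where cumulative positive
increments reach `t` and closes where cumulative decrements do, identical
consecutive layers are pooled into one segment, and reconstruction is exact
in integer arithmetic. The sweep's beam-on time equals the maximum over rows
of the summed positive increments. A published optimal sequencer would give
fewer segments; the sweep is used deliberately because the baseline only
needs honest `#ap`/BoT accounting, and its exactness is testable.

Note that rounding can move the objective either way relative to the FMO
optimum, so the tests assert convergence `z(r_m(x*)) → z(x*)` as `m → 0`
rather than a one-sided bound.

## Indicators and comparison arithmetic

`dvh()` is the right-continuous cumulative volume histogram; `D_x` is the
largest dose received by at least x% of the region, evaluated on the
empirical distribution without interpolation (matching the verbal
definition); `V_t` is reported as a fraction of region volume; the
homogeneity index is `100 (D_5 − D_95) / D_ref`. `percent_reduction()`
implements `100 (ref − new) / ref` with half-up rounding to two decimals for
display, and `build_comparison()` takes per-configuration means before
pairwise percentages. The shipped
`inst/extdata/cerr_benchmark_averages.csv` transcribes the published summary
averages for the CERR prostate benchmark as printed (including the printed
average rows), from which the standard headline percentages — 62.75% fewer
apertures and 63.93% lower beam-on time than the best sequential case,
3.51%/1.58% objective improvements of rVNS over the VND variants, 0.123%
against the round-to-2 sequential plan — are recomputed by
`scripts/acceptance.R` at run time. Two published BoT percentages (5.18%,
1.48%) do not recompute from the printed averages (4.93% and 1.42% do) and
are deliberately excluded from the tests.

## Numerical choices and limitations

* Ties in `best_neighbour()` break by generation order (first wins), making
  runs reproducible under a fixed seed.
* Neighbourhood indices are 0-based with `k_max = 2`; the variant flag maps
  the index to the N1/N2 order.
* Intensification steps one column at a time and requires strict
  improvement; merge conflict resolution is improvement-ranked as described
  above. Both rules fill gaps the schedule leaves open, and are exercised by
  dedicated tests.
* Beam-on time is the plain sum of aperture intensities; per-aperture
  overheads and gantry travel are out of scope. Reported aperture counts
  distinguish stored shapes (`n_apertures`, always ≤ 5 per beam) from
  shapes that actually deliver radiation (`n_active`), the quantity
  clinically quoted as "#ap".
* The weight optimiser treats the problem as smooth convex box-constrained
  minimisation; on degenerate instances where L-BFGS-B stalls above the
  `1e-6` residual target the result is flagged `iteration-limited` but is
  still never worse than the input.
* The 10-seed directional benchmark in the acceptance tests (mean z of rVNS
  against both VND variants) uses a reduced 21×21×3 phantom so thirty full
  runs stay inexpensive; it checks ordering, not published magnitudes.
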