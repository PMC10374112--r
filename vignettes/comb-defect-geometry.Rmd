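---
title: "Joining unequal hexagons: defect geometry of size-dimorphic comb"
author: "hexcomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joining unequal hexagons: defect geometry of size-dimorphic comb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexcomb)
```

Honey bees and many social wasps rear workers in small hexagonal cells and
reproductives in large ones, inside a single lattice. Joining two hexagonal
patches whose cell widths differ by a linear factor $\alpha$ is a tiling
problem: a regular connection pattern cannot be sustained indefinitely, and
the lattice must absorb the size mismatch either with pairs of non-hexagonal
cells or with rows of intermediate-sized cells. `hexcomb` implements the
geometric theory of these transitions, a synthetic comb generator that
emulates the structure of annotated nest images, the per-comb measurement
pipeline, model comparison across candidate defect-rate laws, and the
phylogenetic regression used for cross-species inference.

## The dual representation and the defect model

A comb is represented by its cell centres, in units of the worker
wall-to-wall cell width. Cell walls are recovered as the Voronoi partition
of the centres, and the neighbour graph of centres is then a Delaunay
triangulation: the circumscribing circle of any triangle contains no other
centre. Wall counts, areas and adjacency all derive from this dual pair.

The dimorphism score is the relative area surplus of reproductive cells,
$D = \text{area ratio} - 1$, so the linear scale ratio is
$\alpha = \sqrt{D + 1}$. Along a straight transition between a worker patch
(spacing 1) and a reproductive patch (spacing $\alpha$), the lateral
mismatch between facing cell centres accumulates by $\Delta = \alpha - 1$
per worker cell. Once the mismatch exceeds half a reproductive cell width
(strictly: the Delaunay condition is violated when
$N(\alpha - 1) > \alpha/2$), one worker cell must lose a wall and the
adjacent reproductive cell gain one — a 5–7 defect pair. This yields

* one dislocation per $L_{\max} = \alpha/(\alpha-1)$ worker widths, i.e.
  a rate $(\alpha - 1)/\alpha$ per worker cell, twice that in non-hexagonal
  cells;
* $\lfloor (1 - 1/\alpha) L \rfloor$ pairs over a line of length $L$
  (the fractional remainder has not yet forced a pair);
* a largest defect-free step $\alpha_L = L/(L-1)$ for a given $L$, so a
  dislocation-free transition to $\alpha$ needs
  $T = \lceil \ln\alpha / \ln\alpha_L \rceil$ successive layers of
  intermediate-sized cells ($\alpha_L^T = \alpha$ in the exact case);
* an effective scale $\alpha_E = \alpha / \alpha_L^{T_{obs}}$ remaining
  after $T_{obs}$ observed layers, clamped at 1.

```{r theory}
theory_params(D = 1.70, L = 10)
```

## The synthetic comb generator

`one_step_merge()` and `layered_merge()` build what the analysis assumes of
real comb: two triangular-lattice patches with a common cell orientation,
joined along a straight horizontal line, with Gaussian positional jitter
proportional to the local cell width (default `jitter_sigma = 0.02` for
fixtures, matching the mild irregularity of well-built comb; seeds are
always explicit). The first row of the larger patch sits at the mean of the
two row pitches, $(1+\alpha)/2 \cdot \sqrt3/2$, above the last worker row —
no measurement pins this distance down, and the mean is the symmetric
choice — and one centre of that row is laterally registered on the
bisecting normal of a worker edge, the "0" alignment from which mismatch
accumulates. The line window of length $L$ is centred on that point so the
mismatch budget $\tfrac{L}{2}(\alpha-1)$ is identical on both sides;
layered merges step the spacing geometrically, $\alpha^{t/T}$ for layer
$t$, with each row registered on a bisecting normal of the row below.

Two generator details deserve explanation because they exist purely to
handle degeneracy:

* **Commensurate tie-break.** At exactly commensurate ratios (e.g.
  $\alpha = 2$, where $\Delta$ is a whole worker width) every dislocation
  coincides with a four-point cocircular configuration; its Voronoi vertex
  has degree four and the wall that distinguishes a 5–7 pair from two
  defect-free hexagons has length zero. Rigidly generated lattices then
  collapse into unpaired pentagons. `one_step_merge()` therefore applies a
  deterministic lateral `phase_nudge` (default 0.015 worker widths) at each
  scale-change interface — the geometric counterpart of the strict
  inequality in the Delaunay-violation rule, under which a mismatch of
  exactly half a cell is not yet a violation. Real comb is never exactly
  commensurate, so the nudge removes an artefact rather than adding
  realism. Its size is set by geometry: the walls it creates must exceed
  the `edge_tol` merging threshold (about 0.006 worker widths at the
  default `edge_tol = 0.01`) while staying far below any physical scale.
* **Margins.** `one_step_merge()` pads the line laterally by `margin = 3`
  local cell widths per patch so the cells on the line are interior to the
  point set (reproductive cells need proportionally more padding before
  their polygons clear the convex hull). `layered_merge()` defaults to
  `margin = 0` and no nudge: the line length $L$ is precisely the budget
  from which $\alpha_L = L/(L-1)$ is computed, and lateral padding would
  lengthen the interface past that budget and create real dislocations.

What the generator does *not* emulate: construction dynamics, wall-level
relaxation, curved or branched transition fronts, damaged or occluded
regions, and double-sided comb. Passing tests on synthetic combs therefore
validate the measurement pipeline and the geometry of the theory, not the
full variability of photographed nests.

## The measurement pipeline

`analyze_comb()` reconstructs polygons and wall counts with `edge_tol`
merging (Voronoi edges shorter than `edge_tol` times the median edge are
collapsed before walls are counted; the annotation software behind the
original data must apply some such tolerance, but its value is not
reported, so `edge_tol = 0.01` is this package's free parameter). Cells
whose polygon is unbounded or touches the convex hull are excluded from
every statistic.

`dimorphism_score()` is the ratio of median reproductive to median worker
hexagon area minus one. The medians are taken in the far field of each
patch — at least one row away from the transition line — because boundary
rows are systematically deformed towards the other patch's pitch (worker
cells enlarged, reproductive cells compressed), which otherwise biases $D$
downward by 5–10% under realistic jitter. This matches the model's own
premise that patches are regular far from the transition.

`fit_transition_line()` estimates the transition as a total-least-squares
line through midpoints of label-discordant neighbour pairs; it is symmetric
in the two classes and rotation-equivariant. `fit_transition()` then fits
the four-parameter plateau–ramp–plateau profile
$(A_{worker}, A_{rep}, O_{worker}, O_{rep})$ to hexagonal-cell areas versus
signed distance from the line, by profile least squares over the two
offsets (25×25 grid scan, then Nelder–Mead; the plateau areas are linear
given the offsets). Among equal-residual fits the narrowest ramp wins via a
vanishing width penalty ($10^{-7}\,\mathrm{sd}(y)$ per worker width), which
resolves the degeneracy of noiseless sudden transitions.

Two length scales come out of this fit and they are deliberately kept
apart: the **depth** $O_{rep} - O_{worker}$, perpendicular to the line, is
the extent of the intermediate-size region and feeds `observed_layers()`;
the **lateral length** `L_obs`, the extent of the discordant boundary along
the line, is the length over which mismatch accumulates and feeds every
defect-count prediction. Conflating the two (the written description of the
original procedure is ambiguous) would make the pair-count predictions
dimensionally wrong.

`observed_layers()` fills the fitted depth with optimally stepped layers —
layer $t$ occupies a row pitch $\sqrt3/2 \cdot (\alpha_L^{t-1} +
\alpha_L^t)/2$ — and counts the last layer fractionally. When fewer than
50% of the cells between the offsets are hexagonal the estimate is forced
to zero: such regions are dominated by the deformed neighbours of 5–7
pairs, not by deliberate intermediate-sized cells.

`detect_57_pairs()` pairs 5- and 7-walled interior cells that share a wall,
greedily by centre distance with an id-order tie-break (the data format
does not define pairing when one pentagon touches two heptagons), and
orients each pair along the growth direction: the pentagon should precede
the heptagon, the order in which the builders truncate one cell and seed
the next.

```{r pipeline}
cb <- one_step_merge(L = 10, alpha = dimorphism_to_scale(1.70),
                     jitter_sigma = 0.02, seed = 7)
dimorphism_score(cb)
detect_57_pairs(cb)
```

## Model comparison and the synthetic study

`simulate_study()` generates a ten-species study spanning $D = 0$ to
$1.70$. The five reported dimorphism scores (0.0, 0.01, 0.05, 0.34, 1.70)
are used directly; the remaining species receive representative values
within the moderate and high bands, since their scores are not printed.
Strategy follows the observed pattern: negligible ($D < 0.10$) and high
($D > 1.50$) dimorphism build sudden transitions; moderate dimorphism
builds layered transitions, complete or one layer short of complete —
moderate species show few but nonzero defects, which pure complete layering
cannot reproduce. Line lengths are drawn from 7–13 worker widths and
patches are 5 rows deep, commensurate with the transition regions visible
in annotated images while keeping a 40-comb study fast to regenerate.

`compare_models()` regresses observed non-hexagonal counts on four
predictions: proportional to $D$, proportional to $\Delta$, the one-step
rate $2(\alpha-1)/\alpha \cdot L$, and the mixed-strategy rate
$2(\alpha_E-1)/\alpha_E \cdot L$. The first two carry a free
proportionality constant absorbed by the regression slope; the last two are
parameter-free, so their slope tests direct proportionality.

Two behaviours of this synthetic study differ from annotated real combs,
and both are structural rather than incidental:

* **Area ordering of defect cells.** In real comb, 5-sided cells are
  smaller than worker hexagons (their lower vertex is truncated) and
  7-sided cells larger even than reproductive cells. In a Voronoi
  tessellation of near-lattice centres the ordering reverses: the
  dislocation leaves a gap whose territory falls mostly to the pentagon
  (its lost neighbour is the farthest), making pentagons *larger* than
  worker hexagons, while the heptagon is squeezed by its extra neighbour.
  Centroidal (Lloyd) relaxation of the centres does not flip this. The
  real-comb ordering reflects wall-level building behaviour outside the
  scope of a centre-based generator, and the package reports it as such
  rather than imitating it.
* **Regression slopes at 1, not above it.** For real combs the
  parameter-free models underestimate the observed counts (slope above 1)
  because real builders are not perfectly optimal. The synthetic builders
  *are* the optimum the theory describes, so observed counts sit at the
  floor of the continuous prediction and the slopes settle at or just
  below 1.

## Phylogenetic regression

`build_timetree()` converts a topology plus dated splits into an
ultrametric tree; clades without literature dates can use the taxon-count
heuristic (node age = descendant species − 1) linearly rescaled to an
anchored age, as done for the *Vespula* clade (anchor 8 My). Only the
179-My bees–wasps split and that 8-My anchor are reported values; the other
dates shipped in `divergence_dates_example.csv` are illustrative, so the
bundled tree supports method checks and worked examples, not biological
inference.

`pgls_fit()` is generalized least squares under the Brownian covariance of
the tree with the off-diagonal entries scaled by Pagel's $\lambda$,
estimated by profile maximum likelihood over $[0, 1]$ (25-point grid
pre-scan, then bounded scalar optimization; boundary values are preferred
when they fit at least as well). ML is used rather than REML because the
comparative analysis being mirrored states a maximum-likelihood
$\lambda$. At $\lambda = 0$ on an ultrametric tree the fit reduces exactly
to OLS; the implementation is cross-checked in the test suite against
`nlme::gls` with a Pagel correlation at fixed $\lambda$.

```{r pgls}
tr <- study_timetree()
set.seed(1)
x <- sim_brownian(tr, sigma2 = 1 / 179)
y <- 1 + 0.3 * x + sim_brownian(tr, sigma2 = 0.25 / 179)
pgls_fit(x, y, tr)
```

## Numerical conventions and limitations

* Exact cocircularity (ubiquitous in perfect lattices) is resolved by a
  deterministic low-discrepancy perturbation of $10^{-6}$ lattice spacings
  before tessellation; the near-zero walls this creates are merged away by
  `edge_tol`. Tie-breaks are therefore fixed and runs are byte-reproducible
  at a given seed.
* Circumcircle tests use a strict-interior convention with a relative
  tolerance of $10^{-9}$ scaled by the circumradius.
* Grids of scale ratios in tests and scripts are built as
  `round(seq(...), 2)`: the binary floating-point error of `seq()` is
  enough to push exactly-critical layered cases across the Delaunay
  boundary.
* Problem sizes in the bundled tests and scripts (40-comb studies, 5–10
  rows per patch, lines of 3–20 worker widths, 60–200 simulation
  replicates) were chosen so each check exercises the relevant regime with
  stable statistics while a full run stays interactive.
* Unlabelled combs are not auto-classified: separating worker from
  reproductive cells in real images used context (cappings, brood) that
  coordinates alone do not carry. A future kernel-density split would need
  bimodality checks before it could be trusted.
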