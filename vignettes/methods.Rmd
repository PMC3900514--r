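---
title: "Methods: spatial bio-economic simulation of a demersal trawl fishery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial bio-economic simulation of a demersal trawl fishery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trawlsim` couples three models on a shared lon/lat grid: a statistical
description of where the fish are (survey interpolation plus cohort
decomposition), a statistical description of where the fleet fishes
(VMS-derived effort maps and a recurrent network linking the two), and a
deterministic accounting of what that combination yields (catches,
revenue, fuel cost, gains). A stochastic optimiser then searches the
space of effort patterns under management constraints. This vignette
records the model, its assumptions, the tunable parameters, and the
design choices made where the design was genuinely open.

## 1. The spatial backbone

The analysis unit is a square cell of 6 arc-minutes (about 6 nautical
miles), indexed row-major from the north-west corner. All distances are
great-circle kilometres; no projection is used, which is adequate at the
~100 km extent of a shelf fishery and keeps the grid logic trivial.

Survey stations are interpolated to cell centres by inverse-distance
weighting,
\[
\hat v_c = \frac{\sum_i d_{ic}^{-p}\, v_i}{\sum_i d_{ic}^{-p}},
\]
over stations within a search radius of `radius_cells` cell widths
(default 3). Cells with no station in the radius are removed from the
analysis mask altogether rather than extrapolated. IDW was preferred to
kriging because it needs no stationarity or isotropy assumptions; the
distance power \(p\) is not dictated by the method and defaults to 2,
and interpolation is done on raw (not log) abundance — both are
configurable because neither choice is canonical.

Per-cell abiotic covariates are the mean and standard deviation of the
36 one-arc-minute bathymetry pixels inside the cell (the sd acting as a
roughness proxy) and the annual mean sea-surface temperature.

## 2. Survey indices and cohort decomposition

The survey follows the standard Mediterranean stratified-random design
over five depth strata (10–50, 51–100, 101–200, 200–500, 500–800 m) with
station counts proportional to stratum area. Design-based totals are
\(N_{l,t} = \sum_i A_i \bar d_{i,l,t}\), with \(\bar d\) the mean
standardised density (N/km²) over the stratum's hauls. Strata that end
up with no haul are excluded with a warning: their contribution is
undefined, and silently imputing it would bias the total.

Length-frequency distributions are decomposed into normal cohort
components by EM on the binned data — 3 components for shrimp and hake
(the last pooling all older ages), 2 for red mullet; the component count
is fixed a priori rather than selected, because the biological cohort
structure is known and model selection on yearly LFDs is unstable. Two
EM flavours are provided:

* `method = "midpoint"` (default): each bin's count is treated as that
  many observations at the bin midpoint. This is the classical grouped
  fit, fast and accurate when bins are narrow relative to component
  sds.
* `method = "cdf"`: the E-step uses exact bin probabilities (CDF
  differences) and the M-step the corresponding truncated-normal
  moments. Far-tail bins whose probability underflows fall back to
  flat-bin moments for numerical stability.

Label switching is resolved by always reporting components in ascending
mean. Multiple restarts (a deterministic quantile-spread start plus
seeded jittered starts) guard against local optima; the best
log-likelihood wins. The likelihood is asserted non-decreasing at every
iteration. A fit whose components collapse onto each other is flagged
non-identifiable rather than rejected. The Kolmogorov–Smirnov distance
between the binned empirical CDF and the mixture CDF is reported
descriptively; no correction for estimated parameters is applied, so the
accompanying decision threshold should be read as a heuristic, not a
calibrated test.

Station densities are split across cohorts by posterior responsibility
at the class midpoint (totals conserved exactly; classes where all
component densities underflow are split equally with a warning), sexes
are processed separately and summed only in the per-cell matrices, and
the interpolated per-cell densities are converted to absolute abundance
by the cell surface (km², latitude-corrected).

One unit note: all lengths are handled in mm — carapace length for the
shrimp, total length for hake and mullet. The reference cohort table
mixes magnitudes (shrimp 14–31, hake 100–340) consistent with this
reading even where the source material's column label suggests cm; the
package treats mm as authoritative and does not rescale.

## 3. Effort from vessel tracks

Harbour-to-harbour trips are linearly interpolated in time at 10-minute
steps; each regularised ping's speed is derived from the segment to the
next ping. A ping is "fishing" iff its speed lies in the trawling window,
default [2.0, 4.5] knots — a conventional bottom-trawl range; the window
is configuration, not a claim, and the synthetic generator uses the same
defaults so the filter is exactly testable. Fishing pings are counted
per cell; the count is the effort proxy \(e_{c,t}\), and its grid-wide
sum \(T_f\) the annual total effort. Trip segmentation is taken as given
in the input data; harbour detection on real tracks is out of scope.

## 4. The Elman predictor

Next-year cohort abundance per cell is modelled as an unknown function
of four lag years of: own-cell cohort abundances (sexes as separate
inputs/outputs — 4 for mullet, 6 for shrimp/hake), neighbour-mean
abundances (Chebyshev ray 2, excluding the cell), fishing effort, and
the abiotic covariates. The network is an Elman recurrent perceptron:
one hidden layer, an equally sized bank of context units that copies the
hidden activations after each lag step (reset to zero per sample), and
logistic activations; the output is read after the last lag. Training is
full-batch gradient descent with backpropagation through the four
unrolled steps.

The original training protocol's details are not available, so the
hyperparameters are the package's own documented defaults: 10 hidden
units, learning rate 0.1, at most 500 epochs, stop when the loss change
drops below 1e-5, a 70/30 train/test split by cells, and 100 random
restarts (reduced in tests) with the best held-out pooled Pearson r
kept. Nothing downstream depends on these specific values; the
acceptance properties test recovery behaviour, not hyperparameter
fidelity.

Abundances and effort are `log10(x+1)`-transformed before min-max
scaling to [0, 1] — the `+1` admits genuinely zero cells, where a bare
log would be undefined; this is a deliberate, documented deviation from
a bare log10. Scaling is per variable with lags pooled; zero-range
variables map to 0. The scaling parameters are stored so predictions can
be inverted to individuals.

Input relevance is summarised by the Garson decomposition
\(c_i=\sum_h \frac{|w_{ih}|}{\sum_k |w_{kh}|}\sum_o |w_{ho}|\),
aggregated over input groups and normalised to sum to 100. Context
weights carry no input identity and do not enter the decomposition.

## 5. The bio-economic engine

Catch accounting uses the classic relations: logistic selectivity with
steepness fixed by the two stated quantiles (\(S(L_{50})=0.5\),
\(S(L_{75})=0.75\), hence \(a=\ln 3/(L_{75}-L_{50})\) — the unique
logistic through both points; the steepness formula is a reconstruction,
as only the quantile conditions are stated in the source material);
spatial fishing mortality \(f_{c,l}=q\,S(l)\,e_c\) under the assumption
of uniform catching power across vessels; survey indices converted to
absolute standing numbers with the survey-gear catchability
\(q_M = N_{\mathrm{abs}}/N_{\mathrm{swept}}\); catches \(c = n\,f\) with
\(f\) capped at 1 (a warning names the cells) because the linear harvest
relation can otherwise exceed standing numbers at extreme effort;
weights from \(w = a L^b\) at the class midpoint (grams, with a single
central g→kg→t conversion).

The fleet catchability \(q\) is estimated by 1-D least squares against a
reference total mortality \(F\) from external assessment:
\(\min_q \sum_c (F n_c - q e_c n_c)^2\), solved numerically and checked
against the closed form \(q^\* = F\sum n^2 e / \sum n^2 e^2\). The von
Bertalanffy parameters are carried as cohort-age bookkeeping
(`length_at_age`) and natural mortality is stored but unused — it
belongs to the upstream assessment, not to these catch equations.

Revenue applies banded per-kg prices by size class; gains are
\(G = R - TC\) with the fuel cost \(TC=\beta_0+\beta_{PS}PS+\beta_E E\)
fitted by OLS on annual records. The Pattern Score
\(PS=\sum_c \log_{10}(n_c)\,\overline{d3}(c)\) (mean distance to the
three nearest harbours, km, cell centre to harbour) proxies steaming
cost; zero-effort cells contribute nothing and single-point cells
contribute \(\log_{10}1=0\), which avoids \(-\infty\) and matches
logging counts of occupied cells. Fuel is the dominant operational cost
for this fleet, so no capital or fixed costs are modelled.

The overall mortality reported per scenario is the number-weighted
harvest ratio \(F_s=\sum c/\sum n\). Note the source text describes the
50% retention length once as "25%" in passing; the standard 50%
definition is used throughout.

## 6. Scenario simulation

The observed pattern defines cell probabilities \(p_c=n_c/T_f\). A
scenario modifies either \(T_f\) (effort scaling, probabilities fixed;
scaled totals rounded to integers since the multinomial needs integer
trials) or \(p\) (box closure: \(p'_c=0\) inside,
\(p'_c=p_c/(1-\sum_{box}p)\) outside — proportional redistribution, the
simplest rule consistent with "effort moves outside the closed area";
the exact redistribution rule was not recoverable from the source, so a
kernel hook allows alternatives such as distance-weighted
redistribution). Each run draws multinomial patterns and accepts a
proposal iff its gains strictly exceed the incumbent's, stopping after
`stop_k` (default 100) consecutive rejections — so accepted-gain
sequences are strictly increasing and termination is guaranteed. Run
\(i\) uses seed `seed + i`, making the whole summary reproducible from
`(config, seed)`.

Biomass consequences are evaluated on the final pattern only (not
re-evaluated inside the acceptance loop): the optimised pattern replaces
the last lag year's effort layer, the trained networks predict next-year
cohort abundances, and biomass is evaluated at cohort mean lengths with
sex-specific length-weight laws. Gains used for acceptance are computed
with fixed prices and the fitted cost model at a constant scenario fuel
price.

## 7. The synthetic world: what it emulates, what it does not

`generate_world` builds a stylised shelf: depth ramping from a northern
coast to 800 m with two shallow banks, so that all five survey strata
are populated (a degenerate field raises an error naming the empty
strata); SST with a weak latitudinal and interannual signal; four coastal
harbours; species depth preferences (shrimp ~260 m, hake ~200 m, mullet
~80 m) shaping smooth abundance surfaces with static lognormal spatial
noise (sd 0.3) and small independent year noise (sd 0.1); survey hauls
allocated to strata by largest-remainder proportional allocation with
counts drawn as Poisson at density × swept area (0.05 km²) and
standardised back to N/km²; lengths drawn from the reference cohort
mixtures with equal proportions (the source prints only means and sds,
so equal weights are the neutral default, recorded in the ground truth);
vessel trips that steam at 8–12 kn to abundance hotspots, trawl a
correlated random walk at 2.0–4.5 kn, and steam home, with ping speeds
and states recomputed from realised positions so the speed filter
recovers the generating state exactly; and fuel records generated from
the reference cost plane (β₀ = −1.607×10⁷, β_PS = 220,
β_E = 1.321×10⁷) plus Gaussian noise (sd 1e5 €, 0 for exact tests).

Peak densities (30 000 / 2 000 / 2 000 N/km² for shrimp/hake/mullet, per
sex) were chosen once as order-of-magnitude matches of survey indices
for a heavily exploited Mediterranean shelf so that fleet revenue and
fuel cost are commensurate; no attempt is made to reproduce real
regional magnitudes, and scenario outputs on synthetic worlds are
meaningful in ordering, not in euros.

Two realism gaps matter for interpreting green tests. First, the
generator's abundance dynamics do not react to effort (year-to-year
variation is imposed, not harvest-driven), so a trained network
correctly learns a weak effort effect and predicted biomass differs
little across effort scenarios — monotonicity of fishing mortality, not
biomass response, is the meaningful scenario check here. Second, there
is no intra-annual structure, recruitment, or species interaction, so
multi-year or trophic conclusions are out of reach by construction, as
they are for the one-year-ahead design generally.

## 8. Numerical choices and degenerate inputs

* EM: component sds floored at bin/10; proportions floored at 1e-12 and
  renormalised; a likelihood decrease beyond rounding noise warns.
* IDW: a station within 1e-9 km of a cell centre returns the station
  value directly (d→0 limit), averaging if several coincide.
* Masking is monotone in the search radius (enlarging it never loses a
  cell), and interpolation exactness at stations is tested to 1e-9.
* `estimate_q` falls back to the closed form if the bracketed 1-D search
  loses precision; all-zero effort raises an unidentifiability error.
* Ties in restart selection (network training and EM alike) go to the
  earlier restart, making selection deterministic under a seed.
* Neighbourhood means of isolated cells are 0 with a warning rather
  than NA, keeping downstream feature matrices complete.
* Scaled effort totals are rounded to the nearest integer; a closure
  covering all observed effort is an error.

## 9. Known limitations

Single-year forecasting only; no fleet-behaviour feedback (fishers do
not relocate in response to simulated abundance change within a run);
prices and fuel price are exogenous constants per scenario; hake and
mullet price schedules in the default tables are synthetic stand-ins
(flagged in the data) because only the shrimp schedule was recoverable;
the cost model is fleet-aggregate and linear; and the K-S check is
descriptive. The network's restart count trades compute for optimism
bias in the reported best r — at the desk scales used in the tests,
10–20 restarts already saturate performance on learnable targets.
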