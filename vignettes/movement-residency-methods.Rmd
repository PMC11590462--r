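---
title: "Methods: variogram-based residency classification for GPS telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variogram-based residency classification for GPS telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, numerical choices, and
design decisions behind `movresid`, and states precisely what the synthetic
data do and do not establish.

## 1. The movement model and its simulator

Resident movement is modelled per axis by the
Ornstein–Uhlenbeck–Foraging (OUF) process: a stationary Gaussian process
with autocovariance

$$C(\tau) = \sigma^2\,\frac{\tau_p e^{-\tau/\tau_p} - \tau_v e^{-\tau/\tau_v}}{\tau_p - \tau_v},$$

where $\sigma^2$ (km²) is the stationary per-axis positional variance,
$\tau_p$ (h) the positional decorrelation timescale (how long the animal
"remembers" where its range centre is), and $\tau_v$ (h) the velocity
timescale (ballistic persistence; $\tau_p > \tau_v > 0$). The semivariance
function (SVF) is $\gamma(\tau) = C(0) - C(\tau)$, which flattens to the
asymptote $\sigma^2$ for range-resident animals and keeps growing for
nomadic ones — that contrast is the entire basis of the classifier.

`simulate_ouf_track()` is *exact*: the OUF process is the stationary
solution of $(d/dt + 1/\tau_p)(d/dt + 1/\tau_v)\,x = w(t)$, a linear
Gaussian system in the state $(x, v)$ with stationary covariance
$\mathrm{diag}(\sigma^2, \sigma^2/(\tau_p\tau_v))$. We sample its exact
discrete-time transition $\Phi = e^{A\,\Delta t}$ (closed form for the two
distinct eigenvalues $-1/\tau_p$, $-1/\tau_v$) with innovation covariance
$\Pi - \Phi\Pi\Phi^\top$. There is no Euler discretisation error at any fix
interval, which is what makes the closed-form SVF a legitimate oracle for
the estimator tests. Simulation happens on a local azimuthal-equidistant
plane (km) about the home centre and is inverse-projected to lon/lat;
projection distortion is negligible at home-range scales (tens of km).

The nomadic generator is a correlated-heading random walk (turning angles
wrapped-normal with $E[\cos] =$ `heading_persistence`). It is a *stand-in*
negative control — nothing in the source data constrains what nomadic ibis
movement actually looks like generatively — chosen only to have the one
property the classifier keys on: unbounded net displacement, hence no SVF
asymptote within a month. The diel generator places the bird at its roost
at every local midnight and at a daily foraging site (drawn at an exact,
known distance) during local daytime, so daily-metric truths are constructed
rather than estimated.

`simulate_mixed_track()` concatenates resident and nomadic segments with
positional continuity (each segment starts where the last ended; resident
segments re-centre there). Truth labels use a majority-of-month rule,
matching the month-granular classifier downstream.

## 2. Preprocessing

Fixes are parsed from CSV (standard or Movebank column names), rows with
unparseable coordinates/timestamps dropped with a logged count, duplicate
timestamps dropped with a warning. Birds tracked fewer than 30 days (after
removing user-supplied nesting / pre-dispersal exclusion windows) are
removed. Exclusion windows are deliberately *user input*: nesting periods
come from field knowledge and cannot be inferred reproducibly from the
fixes.

Regularization assigns, for each slot of a UTC-midnight-anchored 6-hourly
grid, the nearest raw fix within a tolerance (default 90 min; the source
procedure states the grid but not the tolerance, so it is exposed in the
API and recorded here as an artifact choice). Positions are never
interpolated — manufacturing positions would bias the variogram at exactly
the short lags that identify $\tau_v$. Ties between slots go to the earlier
slot; when two fixes compete, the nearer then earlier wins; leading and
trailing empty slots are trimmed so the grid spans the observed range, which
also makes regularization idempotent. Month membership is judged in local
time (`timestamp + utc_offset_h`): seasons and midnights are biologically
local. Seasons follow the southern-hemisphere convention (Dec–Feb summer,
Mar–May autumn, Jun–Aug winter, Sep–Nov spring).

## 3. Distance metrics and permutation tests

All distances are great-circle (haversine, Earth radius 6371.0088 km). A
day's roost is the raw fix nearest local midnight within ±3 h (a 6-h grid
always offers a candidate); roost-shift distance is the displacement
between successive midnight fixes, and a day's maximum-distance-from-roost
uses that day's roost fix. Days without a midnight fix keep their
cumulative distance but have undefined roost metrics. Each movement step is
attributed to the local day in which it starts. Annual totals are reported
only when at least 365 distinct days carry data.

Percentiles use linear interpolation between order statistics (R's type 7)
throughout; the 80th percentile of a right-skewed distance distribution
depends visibly on this choice, so it is fixed and documented. Group
comparisons use two-sided label-permutation tests of a percentile statistic
with the +1-corrected p-value $p = (1 + \#\{|\Delta^*| \ge
|\Delta_{obs}|\})/(1 + n_{perm})$, default $n_{perm} = 1000$, and Holm's
step-down adjustment for pairwise matrices (the source states only
"adjusted for multiple testing"; Holm is conservative and assumption-free).
Two facts about this p-value worth knowing:

* With the $\ge$ convention, a pool like $\{1,2,3\}$ vs $\{101,102,103\}$
  does **not** attain the minimal p-value $1/(1+n_{perm})$: 4 of the 20
  label splits reproduce the observed $|\Delta_{median}| = 100$, so the
  exact p-value is near 0.2. The test suite freezes the exhaustively
  enumerated value.
* On binary data (the two-proportion seasonal test) the permutation
  distribution has large atoms, so the test is slightly conservative: its
  measured type-I error at $\alpha = 0.05$ sits near 0.03–0.04 rather
  than 0.05. This is a property of permutation tests on proportions, not a
  defect of the implementation. The month-level permutation null also
  assumes exchangeability across months, ignoring within-bird correlation —
  a stated limitation shared with the classical two-proportion permutation
  test.

Where type-I error is itself simulated (acceptance checks), the tests are
run with $n_{perm} = 199$: because $\alpha(n_{perm}+1)$ is then an integer,
the +1-corrected test has exactly the same size as at $n_{perm} = 1000$,
at a fifth of the cost.

## 4. Residency classification

The per-axis SVF convention is $\gamma(\tau) = E\|r(t+\tau) -
r(t)\|^2/(2d)$ with $d = 2$, so that $\gamma(\infty) = \sigma^2$ equals the
per-axis variance used by the Gaussian range-area formula later. The OUF
model is fitted to the empirical variogram by weighted least squares
(weights ∝ pair counts) over $(\log\sigma^2, \log\tau_v,
\log(\tau_p-\tau_v))$ — the reparameterisation enforces $\tau_p > \tau_v$ —
from a deterministic multi-start grid $\tau_p \in \{6, 24, 96, 384\}$ h
$\times$ $\tau_v \in \{0.25, 1, 4\}$ h covering the diel-to-monthly range,
with an L-BFGS-B pass and a Nelder–Mead polish. Variogram regression
rather than state-space likelihood is deliberate: it matches the stated
procedure ("fitted to the empirical variogram") and is what the acceptance
oracles certify. $\sigma^2$ is bounded above at 100× the largest empirical
semivariance; a fit pinned there (diffusive or ballistic data) is flagged
non-converged, which downstream maps to non-resident.

A converged fit is called **resident** when the fitted SVF has reached its
asymptote by the check lag $T$ (default half the month window), assessed by
three scale-free diagnostics all at tolerance 0.05:

* $d_1 = \gamma'(T)\,T/\hat\sigma^2$,
* $d_2 = |\gamma''(T)|\,T^2/\hat\sigma^2$,
* $\mathrm{gap} = 1 - \gamma(T)/\hat\sigma^2$.

The gap criterion is load-bearing. For $x = T/\tau_p$, the first-derivative
diagnostic behaves like $x e^{-x}$, which is small both when $x \gg 1$
(genuinely at the asymptote) *and* when $x \ll 1$ (a fit whose range memory
dwarfs the month — strongly non-resident). A derivative-only rule therefore
cannot separate the classes and is not even monotone in $\tau_p$; the
relative gap to the asymptote is what restores a monotone, discriminating
rule (e.g. $\tau_p = 10^4$ h in a 720-h month gives gap ≈ 0.93 — flagged
non-resident — while $\tau_p = 24$ h gives gap ≈ $10^{-7}$). The check lag
and tolerances are artifact choices (the source names the derivative checks
but no thresholds) and are reported in every residency call.

Months with fewer than 20 usable 6-h fixes are *unusable*, not
non-resident, and are excluded from all odds denominators; below that the
variogram is uninformative. An all-stationary month (zero scatter) is
trivially resident.

## 5. AKDE areas, overlap, and blocks

Residency areas use Gaussian-kernel density estimation on the local plane
with the bivariate-normal reference bandwidth corrected for
autocorrelation: $h^2 = s^2 N_{eff}^{-1/3}$ per axis, with $N_{eff} =
\mathrm{span}/\tau_p$ (floored at 1, capped at $n$) the effective number of
independent locations. This is the reference-function flavour of AKDE; the
full optimal-weighting machinery of specialised packages is out of scope,
and the approximation is declared rather than hidden.

Two debiasing steps matter at monthly $N_{eff} \approx 30$:

* *mean-estimation bias*: under autocorrelation the sample covariance loses
  about $\mathrm{var}(\bar x) = (2/N_{eff})(1 - 1/N_{eff})\,\sigma^2$ per
  axis; the covariance is scaled back up accordingly;
* *bandwidth-area bias*: the kernel smears the UD by $h^2$ per axis, so the
  raw 95% highest-density-region area overestimates the range area by
  roughly $\sqrt{\det(S + h^2 I)/\det S}$ (≈ +32% at $N_{eff} = 30$);
  `contour_area(debias = TRUE)` multiplies the raw cell-count area by the
  inverse factor. Both the raw and debiased areas are returned.

With both corrections the median 95% area over simulated resident months
recovers the Gaussian closed form $\chi^2_{2,0.95}\,\pi\,\sigma^2 \approx
1882$ km² (at $\sigma^2 = 100$) to better than 10%; without them it would
be ~30% high, outside any stated tolerance. The 95% contour is the smallest
set of grid cells holding 95% of mass; its polygon is extracted by contour
tracing at the bounding density and returned in geographic coordinates.

Overlap between months uses the Bhattacharyya coefficient. The grid-sum
path ($\sum_i \sqrt{p_i q_i}$ on a common grid) is the oracle; the
confidence-interval path uses the Gaussian closed form $BC = e^{-D_B}$ so
that a parametric bootstrap is cheap: means resampled from $N(\hat\mu,
\hat\Sigma/N_{eff})$, covariances from a Wishart with $N_{eff}-1$ degrees
of freedom, 200 replicates, percentile CI. The CI method is an artifact
choice (the source cites a BC test but not its mechanics). With $N_{eff} <
2$ the CI is undefined and the overlap test *fails closed* (no merge).
Consecutive resident months merge into a block when the lower CI bound
exceeds 0.01 (the threshold is fixed by the source, after Winner et al.
2018); chaining is transitive along consecutive pairs by default ("sets of
months" is read as chains), with a `chain = FALSE` flag for pairwise-only
merging since the source wording admits both readings. Months separated by
a non-resident month are never merged. Each closed block gets a fresh OUF
fit and AKDE on the pooled fixes.

## 6. Odds, percentages, seasonal tests

Per-calendar-month odds are the ratio of resident to non-resident
classified months, computed directly from counts. The CI comes from the
delta method on the proportion scale: $SE(\hat p) = \sqrt{\hat p(1-\hat
p)/n}$, mapped via $d/dp\,[p/(1-p)] = (1-p)^{-2}$ to $SE(odds) =
SE(\hat p)/(1-\hat p)^2$, interval floored at 0. Coverage at $p = 0.3$,
$n = 100$ is ~0.94 by simulation. With zero non-resident months the odds
are infinite and flagged undefined rather than fabricated. Percentages of
months resident are rounded to integers only at presentation.

## 7. Site revisitation

Visits are maximal runs of fixes inside a site polygon; an outside
excursion shorter than `min_gap_h` (default 12 h) does not split a visit.
The excursion duration is estimated as the inter-run gap minus one nominal
(median) fix interval, floored at zero — so a single outside fix at 6-h
sampling counts as a 6-h excursion, and `min_gap_h = 0` never merges,
which is what makes the brute-force-scan oracle an exact check. Visit
timing uses fix timestamps, not interpolated boundary crossings: with 6-h
grids, interpolation would imply precision the data lack. Layer
association is non-empty geometric intersection (closed-set convention:
edge-touching counts), not containment or centroid rules; a missing layer
yields `NA`, never `FALSE`. Counting distinct residency areas across birds
uses union-find over pairwise-intersecting polygons — a declared rule, as
the source does not fully specify how shared areas were merged. Polygon
holes are not modelled.

## 8. What the synthetic world does and does not establish

The generators reproduce the *stated* world: σ² = 100 km², τ_p = 24 h,
τ_v = 1 h, 6-h fixes, 30-day months for resident months; ballistic walks
for nomadic ones; exact roost/forage geometry for diel structure. Real
telemetry has GPS error (15–26 m — negligible at km scales and not
simulated), irregular duty cycles, habitat-driven anisotropy, and
behaviour that mixes modes within months. A green suite therefore
establishes that the *estimators and decision rules are correct on their
own model*, and that the classifier separates clear residency from clear
nomadism; it does not certify performance on boundary behaviours (slow
drift, multi-centre ranges) that the source data may contain. Headline
field results (species-level percentages, 147 areas, median km/day) derive
from undeposited tracking data and are deliberately not reproduction
targets.

## 9. Known limitations

* Variogram WLS is less efficient than state-space ML; τ_v is weakly
  identified at 6-h sampling (τ_v = 1 h is far below the Nyquist scale),
  which is why only σ² and τ_p carry recovery criteria.
* The Gaussian-reference AKDE understates multimodal ranges.
* The permutation nulls treat bird-months as exchangeable.
* GeoJSON I/O reads outer rings only.
* No model selection among OU/OUF/IID and no sub-month segmentation, both
  deliberately out of scope.
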