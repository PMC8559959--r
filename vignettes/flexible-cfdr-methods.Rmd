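---
title: "Flexible cFDR: model, estimator and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible cFDR: model, estimator and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flexcfdr)
```

## The model

For m SNPs we observe two-sided GWAS p-values $p_1,\dots,p_m$ for a
principal trait and a continuous auxiliary covariate $q_1,\dots,q_m$
(functional scores, fold changes, a related trait's statistics, ...). Under
the null hypothesis $H_0$ of no association the p-value is uniform and
independent of the covariate:

$$P \mid H_0 \sim U(0,1), \qquad P \perp Q \mid H_0 .$$

The conditional false discovery rate extends the Bayesian FDR by
conditioning on the covariate,

$$\mathrm{cFDR}(p,q) = \Pr(H_0 \mid P \le p,\, Q \le q)
  \approx \frac{p \, \Pr(Q \le q \mid H_0)}{\Pr(P \le p, Q \le q)},$$

where $\Pr(H_0) \approx 1$ is the usual conservative approximation for
GWAS, where true signals are rare. The estimator assumes *positive
stochastic monotonicity*: SNPs with smaller covariate values are enriched
for smaller p-values. If the empirical Pearson correlation of $(p, q)$ over
the density-fitting subset is strictly negative, the covariate sign is
reversed before fitting (`align_covariate_sign()`; the estimate is taken on
the independent subset for consistency with the density fits — the full
table's LD-duplicated rows would only pseudo-replicate the same signal).
Covariates related to $p$ non-monotonically (both extremes interesting) are
outside the model.

## The estimator, step by step

**Densities on the Z scale.** P-values are mapped to absolute Z-scores
$z = -\Phi^{-1}(p/2)$; the sign of a GWAS Z-score is an artefact of allele
labelling, so only the magnitude carries information. Because $|Z|$ is
bounded below by zero, a plain kernel estimate would lose mass at the
boundary; the data are therefore mirrored to $\{\pm z_i\}$ and the fitted
mass at $-z$ folded back (Silverman's reflection), giving

$$\hat f(x,y) = \frac1n \sum_i \big[\phi_{\sigma_p}(x - z_i) +
  \phi_{\sigma_p}(x + z_i)\big]\, \phi_{\sigma_q}(y - q_i),$$

a proper (normalised) product-Gaussian kernel density. The normalisation
matters: the numerator and denominator of the cFDR ratio use different
integrals of this one object, so an unnormalised kernel would not cancel.
Bandwidths follow the normal-reference rule
$1.06\,\min(\hat\sigma, \mathrm{IQR}/1.34)\, n^{-1/5}$, computed on the
mirrored sample actually passed to the kernel — the folded $|Z|$ sample
would halve the spread estimate and visibly under-smooth. The rule assumes
roughly independent observations, so the fit uses an LD-pruned subset of
SNPs (and, when minor allele frequencies are supplied, that subset is
down-sampled within 50 equal-probability MAF bins to match the full panel's
MAF distribution, because LD-independence weights and p-values are both
confounded by allele frequency; missing MAFs are imputed from the empirical
distribution).

**The null covariate distribution.** Instead of the hard threshold
$Q \mid P > 1/2$ used by earlier cFDR estimators, the probability of the
null at each Z value is estimated by a local false discovery rate:
mirrored-|Z| histogram counts (120 equal-width bins spanning
$[-z_{max}, z_{max}]$) are smoothed by Poisson regression on a natural
cubic spline with 7 degrees of freedom **in $z^2$**. The mirrored sample is
exactly symmetric, so its log-density is a function of $z^2$; a basis in
$z$ itself would spend half its flexibility re-learning the symmetry and
demonstrably under-resolves the null-to-alternative transition. The spline's
boundary knots are pinned to the data range so that the (empty) outer bins
of the mandated support are handled by linear-in-$z^2$ — i.e.
Gaussian-like — extrapolation rather than by an unconstrained tail segment,
which the Poisson fit would otherwise blow up against zero counts. The null
is the theoretical N(0,1): mirroring an exactly-uniform two-sided p-value
produces exactly standard-normal mass, so no empirical-null estimation is
needed. The zero-assumption estimate $\hat\pi_0 = \min(1, \hat f(0)/\phi(0))$
caps the fdr at one. Weighting the joint density by this fdr and
integrating over Z gives $\hat f_{0q}(y)$, its CDF $F_{0q}$, and the null
mass $\pi_0^{mass}$.

**The surface and v-values.** On a rectangular grid (defaults 501 × 501;
Z axis $[0, \max(1.1\,z_{max}^{obs}, 10)]$ so that p-values down to
~1e-22 are representable, covariate axis 10% wider than the data in total)
the estimated surface is

$$\widehat{\mathrm{cFDR}}(x_i, y_j) = \frac{2(1-\Phi(x_i))\,F_{0q}(y_j)}
  {T[i,j]}, \qquad T[i,j] = \Pr(|Z| \ge x_i, Q \le y_j),$$

with $T$ from cumulative trapezoidal integration of the KDE. Rather than
thresholding the surface directly (which does not control frequentist FDR),
each observed pair is mapped to the probability, under the null, of a fresh
pair being at least as extreme: the **v-value**

$$v(p,q) = \Pr\big((P,Q) \in L(p,q) \mid H_0\big)
         = \int p_L(y)\, f_{0q}(y)\, dy,$$

where $L(p,q)$ is the L-region of points with estimated cFDR at most the
observed level and $p_L(y)$ its rightmost p-boundary per covariate row (the
inner integral is exactly $p_L(y)$ because $P \mid H_0$ is uniform). Two
details make this an exact probability integral transform and hence make v
uniform under the null:

* The boundary takes the *rightmost* crossing: scanning from $p = 1$
  downward, the first grid node whose cFDR drops to the level, located via
  the running minimum along Z and linearly interpolated in p between the
  raw bracketing nodes. Non-monotone dips further along cannot exclude a
  point with larger p than an already-qualifying point.
* The level of an observed pair is read off the same running-minimum
  surface (bilinear interpolation). Reading levels off the raw surface
  instead leaves every point that sits on a local noise bump with a level
  above the whole $p=1$ edge, collapsing its region to the full strip and
  producing a point mass of v-values at 1.

For the same reason the surface is floored (at 1e-300) but *not* capped at
one: under a global null the raw estimates hover around 1 and the noise
above 1 is exactly what separates the contours of near-null points. SNPs
sharing a level share an L-curve; levels are deduplicated before curve
construction, and the per-row crossings for all levels are found with a
vectorised search (cost O(grid + m log grid) per row), which the test suite
checks against a brute-force double-loop oracle at 1e-6.

## Sparse-region adaptations

**Left-censoring.** The covariate support is deliberately wider than the
data, so its left tail can be too sparse for stable estimation; all
$q < q_{low}$ are moved to $q_{low}$, the left edge of the first cell
containing at least `gridp` points (default 50). The counting cells are one
covariate *bandwidth* wide, not one evaluation-grid cell wide: the count is
meant to measure local data support for the kernel, and a criterion tied to
the (arbitrarily fine) evaluation grid stops being meaningful at moderate
sample sizes, where a 500-cell grid holds only tens of points per cell and
a 50-point rule would censor entire mixture components. The right tail
needs no treatment because only cumulative quantities are used there.

**Spline correction.** Where $(p, q)$ are jointly sparse a v-value can sit
far off the overall trend. A cubic regression spline with 5 interior knots
at the 1/6, ..., 5/6 quantiles of q is fitted once to $\log_{10}(v/p)$
against q; points deviating by more than `dist_thr` (default 0.5) are
mapped back onto the spline, $v \leftarrow p\,10^{s(q)}$. Both directions
of deviation are corrected by default — the correction is a smoothness
prior, not a one-sided penalty — with `inflation_only = TRUE` available to
restrict it to the anti-conservative side. Fewer than 7 distinct covariate
values skip the correction with a warning.

**Degenerate inputs.** p = 1 is allowed (Z = 0); p = 0 is rejected at
load (infinite Z). Zero-variance covariates error at sign alignment. Grid
nodes whose tail integral falls below 1e-12 (empty corners) inherit the
value of the nearest valid node toward smaller Z. Queries outside the grid
are clamped to the boundary with a warning. A p-value smaller than the grid
can represent is clamped to the last Z node, which can only make its
v-value conservative.

## Iteration

`run_pipeline()` consumes a table of p-values and several covariate
columns; iteration k > 1 uses iteration k−1's v-values as its principal
"p-values". Iterating over covariates that capture the same genomic feature
compounds the same evidence and erodes FDR control (the simulation harness
reproduces this failure mode), so the pipeline warns when two successive
covariates have |Pearson r| > 0.3 — a warning rather than an error, since
the judgement is ultimately the analyst's.

## The simulation harness

The generator stands in for a haplotype-based chromosome-22 simulation at
desk scale:

* **LD**: 24 independent blocks of 420 SNPs with AR(1) correlation
  $\rho^{|i-j|}$, $\rho = 0.9$, so $r^2(i,j) = \rho^{2|i-j|}$ in closed
  form. SNP spacing defaults to 440 bp, matching the density of a
  chromosome-22 common-SNP panel (~80,000 SNPs over 35 Mb). This spacing
  matters: "truly not-associated" SNPs ($r^2 \le 0.01$ with every causal
  variant) sit at least 22 SNPs from any causal SNP, and only at real-panel
  density does a 10-kb functional window reach them — the configuration in
  which repeatedly leveraging the same functional mark can manufacture
  false discoveries, as it can on real haplotypes.
* **Effects**: per block, 2–4 causal SNPs with log-OR effects from
  N(0, 0.2²), propagated through LD: $Z \sim N(\Sigma\gamma, \Sigma)$ with
  $\gamma$ the per-SNP non-centralities. The scale `ncp_scale = 30`
  converts a unit log-OR to an expected |Z|, derived from a 5000-case /
  5000-control design at common allele frequencies
  ($\sqrt{n_{eff} \cdot 2\bar f(1-\bar f)} \approx \sqrt{2500 \times 0.37}$).
* **Covariates** (5 realisations per study): A — iid U(0,1); B — p-values
  of a second GWAS sharing causal positions *and effect sizes* in exactly 4
  of 24 blocks (a genetically related trait shares causal architecture;
  sharing positions alone leaves the covariate uninformative), leveraged on
  the absolute-Z scale because a related trait's signal is concentrated
  below the covariate bandwidth on the p scale; C — iid
  $0.5N(-2,0.5^2)+0.5N(3,2^2)$, independent of p; D — per-SNP mixtures
  whose weights flip between functional SNPs (causal ± 10 kb) and the
  rest, with $(\mu_1, \mu_2, w)$ drawn per realisation without replacement
  from $\{2.5,3,4\} \times \{-1.5,-2,-3\} \times \{0.6,...,0.95\}$; E — the
  same two fixed distributions every realisation (the adversarial case).
* **Scoring**: sensitivity and specificity proxies at an FDR threshold of
  5e-6 on truth sets defined by $r^2 \ge 0.8$ (associated) and
  $r^2 \le 0.01$ (not associated), and an FDR proxy — the proportion of
  discoveries at threshold 0.05 that are truly not associated, 0/0
  counting as 0.

What the generator does **not** emulate: real haplotype LD (patchy,
long-range, MAF-dependent), linkage between blocks, genotyping artefacts,
or covariates with atoms and bounded support other than scenario B.
Consequently the desk-scale causal density is ~10× a real chromosome 22
(72 causal among 10,080 SNPs), which makes the functional covariate of
scenarios D/E several times more informative relative to a related trait's
p-values than on real data; comparisons *between* covariate types at this
scale inherit that distortion, while FDR-control conclusions do not depend
on it.

## Problem sizes and runtimes

The replicated studies use a 251 × 251 grid (at ~10,000 SNPs a finer grid
changes v-values negligibly while dominating runtime) and 100 replicates
for FDR-control quantities, 20 for calibration and trend checks; a single
iteration at this size takes well under a second. Direct calls to
`flexible_cfdr()` default to the 501 × 501 grid.

## Known limitations

* Binary or discrete covariates are out of scope (ties break the KDE
  machinery); so are covariates informative at both extremes.
* The KDE and local-fdr fits are shared between level construction and
  region integration without leave-one-out; the smoothness of the KDE
  justifies this, but at a few thousand SNPs the shared estimation noise is
  visible as a percent-level departure of v from exact uniformity.
* $\Pr(H_0) \approx 1$ is conservative by design; in very high-signal
  settings v-values will be correspondingly conservative.
* The AR(1) harness is a caricature of LD, adequate for error-rate
  properties, not for fine-mapping realism.
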