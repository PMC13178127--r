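---
title: "Surrogate minimal depth and co-occurrence mapping for SERS spectra: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate minimal depth and co-occurrence mapping for SERS spectra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectraforest)
```

## The problem

Surface-enhanced Raman scattering (SERS) probes the femtoliter volume
around a metal nanostructure — here, gold nanoparticles taken up into the
endolysosomes of living cells. Each acquired spectrum reports whichever
protein and lipid groups happened to sit near the particle at that moment,
so a dataset of thousands of single spectra shows strong spectrum-to-spectrum
intensity fluctuation and stochastic band occurrence: a band is present in
some fraction of spectra and absent in the rest. Classical averaging
discards exactly the information this structure carries.

`spectraforest` implements an analysis that embraces it. Two-class datasets
(treated vs control cells) are classified with a random forest whose nodes
additionally store *surrogate splits*; from that one fitted object the
package reads off

* **surrogate minimal depth (SMD)** — a per-wavenumber importance measure
  that credits a variable both for splitting well itself and for
  consistently mimicking the splits of other variables, which makes it
  robust when informative bands fluctuate; and
* **mean adjusted agreement (MAA)** — a variable-relation measure whose
  high values mark wavenumbers that route samples the same way, i.e. bands
  that co-occur in the same spectra. Restricted to the SMD-selected
  important bands, MAA yields a spectrally resolved co-occurrence map in
  which protein and lipid signals that share a local molecular environment
  appear as related columns.

## Forest and surrogate machinery

Trees are CART-style classification trees: Gini impurity
$G(t) = 1 - \sum_k p_k^2$, exhaustive midpoint threshold scans, primary
splits chosen among `mtry` randomly drawn candidate variables, bootstrap
resampling per tree, recursion stopping at class purity or
`min_node_size`. At every internal node the top `s` surrogate splits are
stored. For a surrogate on variable $j$ with routing agreement $A$
(fraction of node samples sent the same way as the primary split, under the
better of the two orientations) the *adjusted agreement* is

$$\mathrm{AA} = \max\!\left(0, \frac{A - p_{\text{maj}}}{1 - p_{\text{maj}}}\right),
\qquad p_{\text{maj}} = \max(p_L, 1 - p_L),$$

which is 0 for a surrogate no better than always guessing the primary's
majority side and 1 for an exact copy.

**SMD.** For variable $v$ and tree $t$, $d_t(v)$ is the depth of the
shallowest internal node where $v$ is the primary splitter or one of the
stored surrogates; if $v$ appears nowhere, $d_t(v)$ is the deepest internal
depth plus one. $\mathrm{SMD}(v)$ is the mean over trees. Trees with no
internal node carry no depth information and are excluded from the mean; a
forest of only such trees is an error.

**MAA.** $\mathrm{MAA}(i,j)$ averages the adjusted agreement of $j$'s best
surrogate over all nodes primarily split on $i$ (zero when $j$ is not among
the stored top-$s$); rows of variables that never split primarily are zero.
MAA is not symmetric and the package never assumes it is.

### Numerical conventions

Split decreases and adjusted agreements are compared with a $10^{-12}$
tolerance: genuine differences are rationals with denominators bounded by
$n^3$ and far exceed it, while mathematically tied candidates (e.g.
mirrored splits) can differ by one ulp depending on summation order.
Within a variable, ties resolve to the lowest threshold with the direct
orientation preferred.

Across variables, ties are broken by a **random per-tree priority** drawn
from the tree seed and stored with the tree. This was a genuinely open
design point with a wrong easy answer: breaking ties by column index looks
harmless but is strongly biased, because adjusted-agreement ties are common
at small, deep nodes — with an index rule, low-index columns hoard the
top-$s$ surrogate slots, and on null data the correlation between SMD and
column position reaches 0.95. With the per-tree random priority the
correlation is indistinguishable from zero, and fits remain bit-reproducible
because the priority is part of the serialized tree (so exhaustive
re-enumeration oracles can apply the identical rule).

Degenerate cases: nodes whose best decrease is not positive become leaves;
variables constant within a node are skipped; float-degenerate midpoints
(equal to a neighbouring value after rounding) are skipped.

## Variable selection against a shadow null

The selection threshold is data-driven. The feature table is augmented
with an independently permuted copy of every column (labels untouched) and
the forest is refit with the same parameters. Within that augmented forest,
real and shadow variables compete for the same primary and surrogate slots,
so their SMD values share one scale; selection compares each real
variable's null-scale SMD with a threshold over the shadow SMDs.

Two details matter and were measured during development on simulated data:

* SMD scale depends on the number of variables $p$: in a $2p$-variable
  forest every variable appears less often and sits deeper. Thresholds
  derived from the augmented fit therefore must not be applied to SMD from
  the $p$-variable main fit; the package compares within the augmented fit
  only, and reports main-forest SMD separately as the importance measure.
* Real irrelevant variables and shadows are exchangeable, so roughly half
  of the irrelevant variables fall below the *mean* shadow SMD. The mean
  is consequently a description of the null, not a control of false
  selection.

Hence two threshold modes:

* `"shadow_min"` (default): the minimum shadow SMD. A variable must outrank
  all $p$ permuted decoys — a family-wise guard in the spirit of Boruta,
  with expected null selection rate $\approx 1/(p+1)$. On the planted
  benchmark below this recovers all discriminative bands with a
  false-selection rate of a few percent.
* `"shadow_mean"`: the mean shadow SMD, retained for null-calibration
  studies; under label permutation the fraction of real variables below it
  is statistically indistinguishable from the fraction of shadows below it
  (about one half each).

With `n_shadow_repeats > 1` the augmented fit is repeated under fresh
permutations and both the per-variable null-scale SMD and the threshold are
averaged. The default of one repeat keeps the cost at two forest fits; the
repeats mainly reduce threshold variance and matter for small `num_trees`.

The augmented fit is also the source of the default *relation threshold*
for the co-occurrence map: the pool of MAA values between real primaries
and shadow surrogates is a null for "how much agreement an unrelated
variable shows", and the map marks relations above its mean plus two
standard deviations.

## The synthetic-data generator

No raw spectra are deposited with the study this package's analysis is
modelled on, so the generator stands in for them and doubles as the ground
truth for recovery tests. A dataset of $n$ spectra per class is drawn on a
wavenumber grid (default 450–1600 cm⁻¹ at 2 cm⁻¹, spanning the fingerprint
region and resolving bands printed 3 cm⁻¹ apart):

1. **Band presence.** Each band has class-specific occurrence
   probabilities; bands whose control and treated probabilities differ are
   the discriminative ground truth. Co-occurrence groups share a latent
   uniform $u$ per spectrum: a member with occurrence $p$ uses the
   indicator $\{u < p\}$ with probability $\rho$ and a fresh independent
   draw otherwise. This preserves every marginal exactly for heterogeneous
   $p$ (a single shared Bernoulli could not), makes equal-$p$ members
   identical at $\rho = 1$, and independent at $\rho = 0$.
2. **Amplitudes.** Present bands get i.i.d. log-normal amplitudes
   (default log-sd 0.6), emulating the strong SERS intensity fluctuation;
   the literature reports the fluctuation but no distribution, so the
   log-normal is a package choice.
3. **Lineshapes.** Lorentzian by default, FWHM 12 cm⁻¹ — typical SERS
   bandwidths; Gaussian available.
4. **Nuisance.** A degree-3 polynomial baseline with seeded random
   coefficients, i.i.d. Gaussian noise, and a configurable fraction of
   no-signal spectra (baseline + noise only), emulating empty
   acquisitions.

`default_band_library()` provides 51 bands at positions and protein/lipid
assignments standard for endolysosomal SERS (phenylalanine 1002 cm⁻¹,
phosphatidylinositol 787 cm⁻¹, amide III 1240–1288 cm⁻¹, lipid C–C
stretching 1054–1125 cm⁻¹, …); `planted_design()` builds the benchmark
used throughout the tests, with one band per 15 cm⁻¹ feature bin (Gaussian,
FWHM 7 cm⁻¹, centered on bin centers) so that ground truth maps one-to-one
onto feature columns.

What the generator does **not** emulate: correlated amplitude fluctuation
between bands (enhancement-driven), baseline shapes tied to aggregate
geometry, cosmic rays, wavelength-calibration drift, and spectral
interferents. Passing recovery tests therefore show the estimator works
under the stated stochastic-occurrence model, not that it is robust to
every artifact of measured SERS data.

A note on normalization: the recovery benchmarks feed the forest
*unnormalized* binned features. Vector normalization divides by the shared
per-spectrum norm; when one class carries more bands, that norm differs by
class and every variable — including planted "irrelevant" ones — becomes
weakly informative. That closure effect is real and worth knowing about
when interpreting selections from normalized data.

## Preprocessing

* `vector_normalize()` — unit Euclidean norm; the convention for average
  SERS spectra.
* `estimate_noise()` — $\mathrm{MAD}(\Delta x)/(\sqrt{2}\cdot 0.6745)$,
  robust to bands and smooth baselines.
* `detect_peaks()` — Savitzky–Golay smoothing (order 2, default window 9)
  then local maxima filtered by topographic prominence at
  `min_prominence_snr` (default 5) times the noise estimate. A tiny
  absolute prominence floor ($10^{-10}$ of the dynamic range) suppresses
  float ripple on analytically flat spectra.
* `filter_no_signal()` — drops spectra with fewer than `min_peaks`
  (default 1) detected peaks, the package's operational rule for
  eliminating no-signal acquisitions before averaging or classification
  (SERS studies state that such spectra are removed; a concrete rule is a
  package choice). Note that with the
  default settings a strong smooth baseline can register as signal;
  baseline-dominated datasets should raise `min_prominence_snr`.
* `band_occurrence()` — fraction of spectra with a detected peak within
  ±`tolerance` (default 4 cm⁻¹ — wide enough for grid offsets, narrow
  enough not to merge bands printed 3 cm⁻¹ apart) of each reference band.
  Two reference bands closer than twice the tolerance can both claim one
  peak; this is by definition, not an error. The occurrence reading
  implemented is "peak detected near the position"; an alternative reading
  (intensity above threshold at fixed positions) is not implemented.
* `bin_to_variables()` — contiguous mean-binning (default width = grid
  step, i.e. no coarsening) into the samples × variables feature table;
  baseline correction is deliberately **not** applied anywhere by default.

## PCA eigenspectra

`pca_eigenspectra()` is column-mean-centered PCA via SVD on the same
feature table the forest uses (one consistent representation; no scaling).
Loadings are returned as eigenspectra under a deterministic sign
convention — the element of largest magnitude is positive — so runs are
comparable. Orthonormality is tested to $10^{-8}$.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate/load → filter → bin → forest → SMD
selection → MAA → relation map → PCA, writing every intermediate artifact
as TSV/JSON plus a manifest with MD5 checksums of all outputs. Given the
same config and seed, every checksum reproduces exactly; all randomness in
the package flows from explicit seeds (R side) and per-tree `mt19937`
streams (C++ side).

Default forest parameters follow random-forest practice (`num_trees` 500,
`mtry` $\lceil\sqrt p\rceil$, `s` $\max(5, \lceil p/100\rceil)$,
`min_node_size` 5, bootstrap on). The packaged studies run at sizes chosen
to exercise the method honestly while staying desk-sized: recovery uses 80
bands × 600 spectra with 500-tree forests over ten seeds; oracle
equivalence checks enumerate every node of single trees on matrices up to
30 × 6 and forests of 50 trees on 200 × 80 data; the null calibration uses
twenty repeats of 30-variable tables. The test suite completes in a few
minutes on one core.

## Known limitations

* Binary (two-class) Gini trees only; no regression mode, and surrogates
  serve relation analysis, not missing-value imputation.
* SMD/MAA values depend on forest geometry (`p`, `min_node_size`, `s`);
  compare them only within a fit, and across fits only via the shadow
  machinery.
* The shadow-threshold defaults are a self-contained construction; they
  are not claimed to replicate thresholds from prior surrogate-depth
  literature, whose derivations live in works this package does not
  reimplement.
* Borderline selections near the threshold can differ when feature columns
  are reordered (candidate draws attach to positions); planted/strong
  variables are stable under reordering, and the tests assert exactly that.
* The relation map annotates columns by nearest library band within
  4 cm⁻¹; unmatched variables are "unassigned" rather than guessed.
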