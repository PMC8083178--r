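---
title: "Calling long-range Hi-C contacts: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling long-range Hi-C contacts: models, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicsig)
```

## The problem

A cis Hi-C contact map is a symmetric matrix of contact counts between
genomic bins of one chromosome. Its dominant feature is distance decay:
average contacts fall roughly as a power of genomic distance. A "long-range
contact" (a loop, or a domain–domain interaction) is a cell — or a block —
whose count is surprisingly large *for its distance*. This package scores
that surprise at two scales: single anchors of 1–3 bins (regions mode) and
externally called TADs (domains mode).

## Regions mode

### Model

Because the map is symmetric, the interaction profile of an anchor on the
diagonal is read horizontally: the value at signed offset $\delta$ is the
matrix entry between the anchor bin and the bin $\delta$ away (element-wise
mean of rows for 2–3 bin anchors; left offsets count from the anchor's
first bin, right offsets from its last, so the window never overlaps the
anchor). Positions off the chromosome are missing, never zero.

The null for distance $d$ is a two-parameter Weibull fitted by maximum
likelihood to the strictly positive entries of diagonal $d$ of the same
chromosome — so each test is matched by chromosome and distance. The shape
equation $\sum x^k\log x / \sum x^k - 1/k - \overline{\log x} = 0$ is
solved to $10^{-8}$ (at most 200 iterations), with a method-of-moments
fallback on the coefficient of variation if the root search fails. Sparse
maps contain structural zeros; they are excluded from the fit and their
fraction $z_d$ re-enters the p-value as a point mass:

$$p(x) = \begin{cases} 1 & x = 0\\
(1 - z_d)\,e^{-(x/\lambda_d)^{k_d}} & x > 0.\end{cases}$$

This is an upper-tail test only: depletion is never called.

### Multiple testing and replicates

All (anchor, offset) tests of one chromosome in one replicate are one
Benjamini–Hochberg family — the most conservative family consistent with a
background matched per chromosome (per-anchor correction would be far more
liberal). q-values use the step-up form $q_{(i)} = \min_{j \ge i}
p_{(j)}\,m/j$ with stable sorting, so tied p-values get tied q-values and
the result is permutation-consistent. Numerically the multiplier $m/j$ is
computed before the product so $q \ge p$ holds exactly in floating point.
A contact is reported only when $q \le \alpha$ in **every** replicate.

### Parameters that matter

| parameter | default | why |
|---|---|---|
| `alpha` | 0.01 | q-value threshold of both modes |
| `window_bins` | 30 | profile half-width in bins each way |
| `min_samples` | 50 | positive entries a diagonal needs before its Weibull is trusted; below it the distance is untested (p missing), never extrapolated |

Distance-weighted intensities (intensity $\times|\delta|$) appear **only**
in the profile plot, to keep distal signal visible against the decay;
statistics always use raw intensities.

## Domains mode

The bin map is aggregated over non-overlapping domains into
$M[i,j] = \sum_{a \in i, b \in j} \text{map}[a,b]$; bins outside every
domain count nowhere. Sums are rounded to integers for the discrete tests
(warning on normalized maps; raw sums are retained). The paper-level
methods name the tests but not the margins, so the null parameterization is
a stated design choice: total $T = \sum_{i\le j} M[i,j]$, marginals
$K_i = \sum_j M[i,j]$ (the intra-domain diagonal is counted in $K_i$ but
never tested — TAD interiors are enriched by definition), and expectation
$\mu_{ij} = K_iK_j/(2T)$, the standard contact-margin product. The three
one-sided tests of a pair with count $k$:

* hypergeometric — $X \sim \mathrm{Hyp}(T, K_i, K_j)$, $p = P(X \ge k)$.
  Note its expectation is $K_iK_j/T = 2\mu_{ij}$, so it is the most
  conservative of the three under this parameterization.
* Poisson — $X \sim \mathrm{Pois}(\mu_{ij})$.
* negative binomial — mean $\mu_{ij}$, variance $\mu + \varphi\mu^2$,
  $\varphi$ fitted once per matrix by method of moments,
  $\varphi = \max\!\big(0, \sum[(k_{ij}-\mu_{ij})^2 - \mu_{ij}] / \sum
  \mu_{ij}^2\big)$; $\varphi \le 0$ degenerates to Poisson.

BH correction runs over all tested $i<j$ pairs of the chromosome per test.
Adjacent pairs are tested by default; `min_separation` can exclude them,
because near-diagonal decay inflates adjacency.

**A caveat worth stating prominently:** the margin-product null ignores
distance. On maps with strong decay the NB dispersion absorbs the decay
itself (on synthetic maps with decay exponent 1 we measure
$\varphi \approx 0.5$), which costs the NB test most of its power, and the
hypergeometric expectation $K_iK_j/T$ likewise over-predicts distal pairs.
The Poisson test is the most sensitive but also anti-conservative under
decay. Users with strongly decaying maps should prefer larger
`min_separation` or interpret near-diagonal calls with care.

## Compartment analysis

PC1 follows the standard recipe made explicit: divide each entry by its
diagonal's mean (observed/expected), take the Pearson correlation matrix
over non-empty bins, extract the leading eigenvector. The eigenvector sign
is arbitrary, so it is oriented to correlate positively with bin coverage;
labels are reported as positive/negative, not A/B — anchoring to
activity needs external marks and is out of scope. Domains are labelled by
majority vote of their bins' PC1 signs; ties break to the sign of the
summed PC1 and are flagged. Among significant domain pairs, observed
(++/−−/+−) counts are compared to expected proportions
$p^2 : n^2 : 2pn$ (unordered pairs, normalized; the $2pn$ mixed share is a
stated interpretation of the garbled source text) by a 2-df chi-square
goodness of fit and a one-sided exact binomial for mixed-pair depletion.

## The synthetic generator: what a green test establishes

`generate_map()` draws the upper triangle independently per cell:
Weibull$(k, \lambda_0 d^{-\gamma} \cdot \text{fold})$, zeroed with
probability $z(d)$, mirrored. Defaults: $k = 1.5$ (right-skewed, CV
$\approx 0.68$, a plausible count-noise shape), $\lambda_0 = 100$
(comfortably above the `min_samples` fitting floor), $\gamma = 1$ (broadly
Hi-C-like decay), $z = 0$. Planted signals multiply the scale: loops
(pixels), domains (diagonal blocks), domain-pair blocks, and
same-compartment cells. A lognormal family with matched mean and CV exists
to probe misspecification.

Because the noise family equals the analysis model, calibration tests are
exact-model: a green type-I test says the fitting and FDR machinery are
correct, **not** that real Hi-C noise is Weibull. The generator has no
coverage bias, no restriction-fragment structure, no spatially correlated
noise; recovery results are upper bounds on real-data behaviour.

Three scenario choices deserve explanation:

* **Deterministic planted pixels for recall.** A loop planted by fold
  multiplies the Weibull *scale*; the drawn value is then stochastic, and
  at fold 10 it falls below any reasonable BH threshold in roughly a third
  of draws — 100% recall is impossible under that semantics. The recall
  tests therefore plant pixels at a deterministic intensity of ten times
  the diagonal scale $\lambda_d$ on a null map, which is what "planted at
  10× diagonal scale" can guarantee. Fixtures keep stochastic folds (at
  smoke-test strength 50) since they only exercise plumbing.
* **Exchangeable background for domain recall.** Under decay the
  margin-product null is misspecified (see the caveat above), so
  block-recovery under all three tests is stated on a flat background
  ($\gamma = 0$) with 40 domains, where the null holds by construction and
  the planted pair is a negligible fraction of the dispersion fit. The
  misspecified-decay behaviour is documented, not hidden.
* **Compartment fold 3 for exact label recovery.** At 2× within-compartment
  enrichment under $k=1.5$ noise, single-bin PC1 misassignments occur in a
  noticeable fraction of runs — realistic, but incompatible with an
  exact-recovery assertion; the exact-recovery scenario uses 3×. The
  noise-free checkerboard oracle test keeps 2×.

## Numerical and degenerate-input choices

* Maps are symmetrized as $(M + M^\top)/2$ with a warning past $10^{-9}$
  asymmetry; NaNs become zeros with a logged count.
* Constant (zero-variance) diagonals are flagged unusable rather than
  fitted; all-zero diagonals likewise — never an error.
* `hypergeom_pvalue` clips draws when $K_i + K_j > T$ (warned);
  $k > \min(K_i, K_j)$ is an invariant violation and errors.
* Zero expectation with a positive count yields $p = 0$ with a warning.
* Ties in BH and in tolerant matching are broken deterministically (stable
  sort; lower partner bin first).
* Liftover drops split or deleted intervals and reports the count;
  p/q-values are untouched.

## Known limitations

No spline-smoothed distance background (Fit-Hi-C style) and no local
neighbourhood enrichment (HiCCUPS style); trans contacts, sparse/.cool
containers and TAD calling itself are out of scope. The domain null's
distance blindness is the main modelling limitation, as discussed above.
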