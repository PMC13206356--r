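---
title: "Thermodynamics-inspired descriptors for dynamic graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics-inspired descriptors for dynamic graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermograph)
```

## The model

A time-varying network is an ordered sequence of graphs $G_1, \dots, G_K$
on a fixed node set of size $N$, here held in a `WindowedGraphSequence`.
For each window the package computes four descriptors.

**Internal energy.** $U = \sum_{i<j} w_{ij}$, the total edge mass; for a
binary graph this is the edge count.  $U$ tracks how much interaction the
network carries, irrespective of how it is arranged.

**Spectral Core Entropy (SCE).**  Let $\tilde L = D^{-1/2}(D-A)D^{-1/2}$
be the normalized Laplacian, with the convention that rows of isolated
nodes are zero.  Its eigenvalues $\tilde\lambda_1 \ge \dots \ge
\tilde\lambda_N$ lie in $[0,2]$ and sum to the number of non-isolated
nodes.  Treating the eigenmodes as micro-states with probabilities
$p_i = \tilde\lambda_i / N$, the SCE keeps only the top $\alpha$ modes:

$$S = -\sum_{i=1}^{\alpha} p_i \log p_i, \qquad 0 \log 0 := 0 .$$

With $\alpha = N$ this is the (full) von Neumann graph entropy; smaller
$\alpha$ retains the dominant spectral mass at reduced cost, and plain
SCE is non-decreasing in $\alpha$.  Because $\tilde L$ is invariant to a
global rescaling of the weights, $S$ responds to the *arrangement* of
edges, not their overall strength.  A renormalized variant
($p_i = \tilde\lambda_i / \sum_{\mathrm{top}\,\alpha}\tilde\lambda$)
measures dispersion *within* the retained core instead; on series where
spectral mass shifts into the leading modes the two variants move in
opposite directions, which is why plain SCE anti-aligns with
full-spectrum entropy dynamics (`diffAlignment()` quantifies this with a
Spearman correlation of first differences).

**Node energy.**  Each unit of edge weight is split between its
endpoints in proportion to their weighted degrees:
$U_i = \sum_j w_{ij}\, d_i / (d_i + d_j)$.  By construction
$\sum_i U_i = U$ exactly (each edge's two shares sum to its weight), so
node energy is a lossless local allocation of the internal energy —
useful for ranking which nodes carry group differences.

**Temperature index.**  Between consecutive windows,

$$T_n = \frac{U_n - U_{n-1}}{S_n - S_{n-1}}, \qquad T_1 = 0 .$$

$T$ is a dimensionless reconfiguration marker — energetic change per
unit of spectral change — not a physical temperature.  Large $|T|$
flags transitions where the edge mass moves a lot while the spectral
arrangement moves little, the signature of strength-dominated
reconfiguration.

### Degenerate entropy increments

If two consecutive windows have (numerically) equal entropy the ratio is
undefined.  The package keeps the unregularized definition and makes the
computation total: entries with $|\Delta S| <$ `dsEps` ($10^{-12}$ by
default) become `NaN`, are counted in the trajectory
(`@nDegenerate`), and are excluded pairwise from every downstream
metric.  No clipping or denominator regularization is applied anywhere.
Binary sequences from short, stable windows can repeat graphs exactly,
so real pipelines do hit this path; the descriptors and the evaluation
machinery treat those transitions as unscored rather than as zeros.

### Isolated nodes

The micro-state probabilities are normalized by $N$ even when isolated
nodes exist, so $\sum_i p_i < 1$ in that case (the deficit equals the
isolate fraction).  This keeps the definition of $S$ literal; the
alternative — renormalizing by the trace — would silently change the
entropy scale between windows with different isolate counts.

## From time series to graphs

`buildDynamicGraph()` composes three steps: sliding windows
(`segmentWindows()`, window length $w$, stride $s$, yielding
$\lfloor (T-w)/s \rfloor + 1$ windows), Pearson correlation per window
with zero diagonal (`correlationGraph()`; zero-variance columns are
disconnected for that window), and strict binarization at 0.5
(`binarizeGraph()`; a correlation of exactly 0.5 is *not* an edge, and
negative correlations never are).  Defaults $w = 5$, $s = 1$,
threshold $0.5$, $\alpha = 20$ suit short acquisitions at roughly
2-second resolution where fine temporal dynamics matter; $w$ trades
temporal resolution against correlation estimation noise, and the
binarization threshold trades edge stability against sensitivity.
Weighted mode (`keepWeighted = TRUE`) stores the raw correlations as-is;
the thermodynamic descriptors require non-negative weights, so weighted
correlation sequences are for SSIM/k-means style analyses, while the
descriptor pipeline runs on the binary graphs.

## Event labeling and lag-aware evaluation

Consecutive adjacency matrices are compared with the global (single
window) SSIM formula, treating the full matrix as a gray-scale image
with constants $C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$ and data range
$L$ (1 for binary pairs, max minus min otherwise).  A locally windowed
SSIM variant is available behind `windowed = TRUE` for sensitivity
checks; the global formula is the default because it is the printed
definition and adjacency matrices are not natural images.

Reconfiguration events are transitions whose SSIM falls strictly below
the subject's own empirical $q_S$ quantile ($q_S \in \{0.05, 0.07,
0.10\}$).  Scoring is threshold-free: the labels are dilated by a lag
tolerance $L$ (±2 windows on sliding-window data, ±1 on the synthetic
benchmark where boundaries are exact) and the continuous score is
evaluated against the dilated labels with rank-based (midrank) AUROC and
step-wise average precision.  Label dilation was chosen over score
pooling because it is monotone in the rule it implements ("a high score
within ±L of an event counts as a detection") and keeps the score
untouched.  One
consequence worth knowing: with $L = 1$, four of the six dilated
positives around two true boundaries are ordinary transitions carrying
noise scores, so even a perfect boundary detector is capped near
AUROC ≈ 2/3 under this protocol.  Comparisons *between* scores are
unaffected, which is why the benchmark's contracts are orderings.

For binary-vs-binary association, continuous scores are binarized at a
spike rate matched to the event rate (`spikeBinarize()`, removing the
free threshold that the Matthews correlation is sensitive to), and
significance comes from a permutation test (uniform shuffles by
default, 2000 permutations, add-one p-value
$p = (1 + \#\{\mathrm{MCC}^{perm} \ge \mathrm{MCC}\})/(n_{perm}+1)$; a
circular-shift scheme is available for autocorrelation-robust checks).

## Baselines and the surrogate null

The heat-trace (NetLSD-style) baseline summarizes each window by
$h(t) = \sum_i e^{-t \tilde\lambda_i}$ over 250 log-spaced diffusion
times in $[10^{-2}, 10^{2}]$ and scores transitions by the Euclidean
distance between consecutive signatures.  The k-means baseline clusters
vectorized upper triangles of the weighted correlation matrices
($k = 4$) and scores a transition 1 when the cluster switches.

The edge-count-preserving surrogate rewires each binary window to a
uniform random graph with the same edge count.  It preserves the $U$
series exactly (so any result that survives it is explained by density
alone) while destroying block and higher-order structure.

## The synthetic benchmark

`runBenchmark()` generates degree-corrected stochastic block model
series — 80 nodes, 4 equal blocks, three 15-window segments (change
points at windows 15 and 30, 0-based) — under three regimes:

* **R1, structure-only**: each segment uses a different wiring cell
  from the grid {(0.25, 0.05), (0.30, 0.05), (0.35, 0.08),
  (0.40, 0.10)} (a random ordered subset per series); every window is an
  independent redraw, rescaled so its edge mass equals the previous
  window's *exactly*.  $\Delta U = 0$ by construction, so $|T|$ carries
  no signal while $|\Delta S|$ does.
* **R2, strength-only**: one edge pattern frozen per series (wiring
  (0.30, 0.05)); segments differ only by a global gain drawn as a
  permutation of {1.2, 1.5, 2.0}.  Edge weights are redrawn every
  window, which keeps $\Delta S$ non-degenerate (with frozen weights
  every within-segment transition would repeat the graph exactly and
  $T$ would be undefined everywhere); the literal pure-gain variant is
  retained as `weightRedraw = FALSE`, under which SCE is exactly
  constant within segments — the scale-invariance property in its
  sharpest form.
* **R3, mixed**: a permuted contiguous triple of wiring cells plus
  per-segment gains, independent redraws per window.

Node propensities are Uniform(0.5, 1.5), renormalized to mean 1 within
blocks; present edges carry LogNormal(0, 0.25) weights.  Graphs are kept
weighted deliberately: hard binarization would suppress $\Delta U$ and
trivially disable $T$ in structure-only settings.  Five-ish repeats per
cell are swept to 500 series per regime in the full benchmark; the test
suite uses 100 per regime, which is enough to resolve the ordering
contracts (per-series AUROC has a standard deviation near 0.15, so
medians over 100 series are stable to about ±0.02).

The expected pattern, which the acceptance checks assert as orderings:
$|\Delta S| > |T|$ in R1 with $|T|$ at (or slightly below) chance;
$|T| > |\Delta S|$ in R2 with the spectral scores near chance;
$|\Delta S| \ge |T|$ in R3.  The sub-chance R1 $|T|$ is a real effect,
not noise: after exact mass rescaling the temperature is floating-point
noise divided by $\Delta S$, and $|\Delta S|$ is *larger* at boundaries,
pushing boundary $|T|$ *down* the ranking.

## The fixture subject

`makeFixtureSubject()` emulates the pipeline-relevant features of a
short regional acquisition: 176 time points, 40 regions, regions
loading a shared latent factor with ±1 signs carrying 98% of the
variance, and a planted switch that flips the sign of exactly half the
regions.  Under the default pipeline this produces a deep SSIM trough
in the five-transition zone mixing both regimes, centred at transition
`eventTime - floor(w/2)` (`expectedEventTransition()`).  The high
factor share is what makes 5-sample correlations stable enough for the
trough to be the global minimum in the large majority of seeds.

What the fixture does *not* emulate: temporal autocorrelation, drift,
motion artifacts, heavy-tailed noise, and spatially graded (rather than
sign-flip) connectivity changes.  Tests passing on fixtures therefore
validate the machinery — windowing, labeling, scoring, schemas — not
any claim about real recordings.  Note also that with a 0.98 factor
share many consecutive binary graphs repeat exactly, so a large
fraction of fixture transitions are degenerate for $T$; this is a
feature (it exercises the NaN path end-to-end), but it means fixture
$|T|$ AUROCs rest on the minority of valid transitions.

## Numerical choices

* Eigensolver: dense `eigen()` up to 512 nodes or when more than half
  the spectrum is requested; ARPACK Lanczos (via igraph) otherwise,
  with a dense fallback and a warning on non-convergence.  The two
  agree to $10^{-8}$ on graphs up to 200 nodes (asserted).
* Tiny negative eigenvalues from round-off are clipped to 0 before the
  entropy.
* Quantile labeling uses R's default type-7 empirical quantile with a
  strict inequality, so $n$ distinct values at rate $q$ yield
  $\lfloor q(n-1) \rfloor$-ish positives (exactly 5 of 100 at 0.05).
* Spike quotas round to the nearest integer with a floor of 1; ties
  beyond the quota break by series order.
* AUROC uses midranks (a constant score gives exactly 0.5); degenerate
  labels give `NA`, never a silent 0.5.
* All randomness flows through R's global RNG, so a single `set.seed`
  (or the `--seed` flag of the scripts) reproduces a run end-to-end.

## Known limitations

* The descriptors assume non-negative weights; signed correlation
  graphs must be binarized (or otherwise mapped) first.
* $T$ compares windows at lag 1 only; slow reconfigurations spread over
  many windows dilute into small increments.
* The ±L label dilation caps absolute AUROCs (see above); compare
  scores under the same protocol rather than reading absolute values.
* The benchmark's wiring grids and gain levels are package defaults
  chosen to realize the three regimes cleanly; absolute AUROC levels
  move with those choices even though the regime orderings are stable
  across them.
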