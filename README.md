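# thermograph

Thermodynamics-inspired descriptors for time-varying networks.

Dynamic connectivity analyses — resting-state fMRI being the motivating
case — produce long sequences of graphs and then face the question:
*when* does the network actually reorganize?  `thermograph` answers it
with a compact set of per-window descriptors and a complete
event-detection protocol around them, for researchers working on
change-point detection in evolving graphs (brain networks, financial
networks, any fixed-node-set dynamic system).

## The descriptors

For each graph window with weights `w_ij` and weighted degrees
`d_i = Σ_j w_ij`:

* **Internal energy** `U = Σ_{i<j} w_ij` — total edge mass (the edge
  count for binary graphs).
* **Spectral Core Entropy** `S = −Σ_{i≤α} p_i log p_i` with
  `p_i = λ̃_i/N`, the top-α eigenvalues of the normalized Laplacian
  `L̃ = D^{−1/2}(D−A)D^{−1/2}`.  At `α = N` this is the von Neumann
  graph entropy; `S` is invariant to global weight rescaling, so it
  sees the *arrangement* of edges, not their strength.
* **Node energy** `U_i = Σ_j w_ij · d_i/(d_i+d_j)` — a local
  allocation of edge mass with `Σ_i U_i = U` exactly.
* **Temperature index** `T_n = ΔU_n / ΔS_n` between consecutive
  windows (`T_1 = 0`) — a dimensionless reconfiguration marker, large
  when edge mass moves while the spectrum barely does.

The complementarity is the point: entropy change `|ΔS|` is sensitive to
rewiring, `|T|` to strength (gain) modulation.  The package ships the
full protocol for testing this: sliding-window Pearson graphs, SSIM
event labeling, lag-aware threshold-free AUROC/AP, matched-rate spike
MCC with permutation tests, heat-trace (NetLSD) and k-means baselines,
edge-count-preserving surrogate nulls, and a degree-corrected
stochastic-block-model benchmark with three controlled reconfiguration
regimes.

## Worked example

A synthetic "subject" with a planted connectivity switch at time point
88, pushed through the default pipeline (window 5, stride 1, threshold
0.5, α = 20):

```r
library(thermograph)
x  <- makeFixtureSubject(seed = 7)   # 176 x 40 time series
gs <- buildDynamicGraph(x)
gs
#> WindowedGraphSequence: 172 windows, 40 nodes, binary
#>   window length 5, stride 1
#>   binarization threshold 0.5 (strict >)

traj <- thermoTrajectory(gs, alpha = 20)
traj
#> ThermoTrajectory: 172 windows, 40 nodes (alpha = 20)
#>   U: [206, 416]  S: [1.925, 2.047]
#>   150 degenerate dS transition(s) set to NaN

ss <- ssimSeries(gs)
which.min(ss)                        # deepest structural break
#> [1] 86
expectedEventTransition(88, 5)       # where the planted switch should land
#> [1] 86

ev  <- dilateEvents(labelLowSsimEvents(ss, 0.05), 2L)
lagAwareDetection(abs(temperatureIndex(traj)[-1]), ev)
#> DetectionSummary
#>   AUROC 0.8611  AP 0.9105  MCC NA  p NA
#>   12 event(s), 21 valid transition(s)
```

The lowest-SSIM transition lands exactly where the planted switch
predicts, and the |T| score separates the labeled low-SSIM events from
ordinary transitions (AUROC 0.86).  Note the honest bookkeeping: most
transitions in this very stable fixture repeat the graph exactly, so
their temperature is undefined (`NaN`) and they are excluded from
scoring rather than imputed — 21 transitions remain valid here.

A command-line wrapper over the same functions lives at
`inst/cli/thermograph.R` with subcommands `trajectory`, `events`,
`benchmark`, `surrogate` and `fixtures`.

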