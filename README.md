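# eida

Exact two-eigenvector analysis of instantaneous phase alignment for
dynamic functional connectivity.

## The problem

Dynamic functional connectivity studies track how the coupling pattern of
N parcellated brain signals reconfigures over time. A standard frame-wise
object is the **instantaneous phase alignment (iPA) matrix**: after
bandpass filtering and extraction of instantaneous phases
θᵢ(t) via the analytic (Hilbert) signal,

    iPA_ij(t) = cos(θᵢ(t) − θⱼ(t)),

which is +1 for in-phase pairs, −1 for antiphase, 0 in quadrature.
Writing c = cos θ and s = sin θ elementwise, iPA = ccᵀ + ssᵀ: symmetric,
positive semidefinite, unit diagonal — and **rank ≤ 2**. Its eigensystem
is therefore closed-form. With γ = ‖c‖², σ = ‖s‖², ξ = cᵀs and
Δ = (σ−γ)² + 4ξ²,

    λ₁ = (N + √Δ)/2,   λ₂ = (N − √Δ)/2 = N − λ₁,
    v_k ∝ c + B_k s,   B_k = ((σ−γ) ± √Δ) / (2ξ),

so each frame is represented *losslessly* by 2N+2 numbers instead of
N(N−1)/2, at O(N) cost per frame instead of the O(N³) of a dense
eigensolver. λ₁ (the spectral radius, bounded in [N/2, N]) measures total
instantaneous order; its temporal standard deviation is the **spectral
metastability**; the fraction of frames with λ₁ below a stated fraction of
N is the **irreducibility index** (how often one eigenvector is not
enough).

On top of the decomposition the package provides:

* **Discrete pipeline** — k-means over the losslessly rebuilt matrices in
  strictly-upper-triangle space with cosine distance (recurrent brain
  "modes"), immune by construction to eigenvector sign flips; fractional
  occurrence, dwell times, per-mode metastability, elbow analysis.
* **Continuous pipeline** — reconfiguration speed
  s(t) = 1 − |R(iPA(t), iPA(t−1))|, kinematic speed–displacement (KSD)
  trajectories, the T×T functional connectivity dynamics (FCD) matrix with
  its mean and switching index, and Lempel–Ziv–Welch informational
  complexity of the quantised eigenvector stream.
* **Metric suite** — Kuramoto order parameter and metastability, static
  Pearson FC, FC index, time-averaged iPA.
* **Synthetic generators** — analytic limit cases, planted phase-locked
  mode sequences with known labels, narrowband noise, Kuramoto
  simulations; every pipeline stage is testable without external data.

Who it is for: anyone with a parcellated, ideally narrowband multivariate
time series (regions × timepoints CSV/TSV plus a TR) who wants frame-wise
phase-coupling analysis with exact spectra rather than numerical
eigendecompositions.

## Worked example

```r
library(eida)

# planted two-mode recording: 16 regions, 400 frames at TR = 2.75 s,
# switching between full synchrony and quadrature blocks (mean dwell 5
# frames, von Mises phase jitter kappa = 20)
templates <- list(in_phase   = gen_limit_case("all_in_phase", 16),
                  quadrature = gen_limit_case("quadrature_blocks", 16))
sim <- gen_planted_modes(templates, n_frames = 400, tr = 2.75,
                         dwell_mean = 5, jitter_kappa = 20, seed = 1)

dec <- ipa_decompose_series(sim$phases)
dec
#> <ipa_decomposition> N = 16, T = 400, TR = 2.75 s
#>   lambda1: mean 12.005, sd 3.3114, degenerate frames: 0

str(metrics_report(sim$phases, dec))
#> List of 5
#>  $ mean_lambda1          : num 12
#>  $ spectral_metastability: num 3.31
#>  $ kuramoto_metastability: num 0.145
#>  $ irreducibility        : Named num [1:4] 0.34 0.472 0.492 0.492
#>   ..- attr(*, "names")= chr [1:4] "0.55" "0.60" "0.65" "0.70"
#>  $ fc_index_mean_ipa     : num 147
```

Mean λ₁ ≈ 12 on 16 regions: the recording sits between full order
(λ₁ = 16, the in-phase mode) and maximal irreducibility (λ₁ = 8, the
quadrature mode), and the irreducibility profile says ~34–49% of frames
are not summarisable by one eigenvector, exactly as planted. Clustering
recovers the modes:

```r
cm <- discrete_eida(dec, k = 2, seed = 1)
cm
#> <eida_clusters> k = 2, T = 400, inertia = 0.693562, converged
round(fractional_occurrence(cm), 3)
#> [1] 0.507 0.492
round(dwell_time(cm), 2)      # seconds; ~5 frames x 2.75 s
#> [1] 12.98 12.90

str(fcd_summary(fcd(dec)))
#> List of 2
#>  $ mean    : num 0.74
#>  $ variance: num 0.107
lzw_complexity(dec)[1]
#> [1] 131516
```

There is also a command-line pipeline (installed at `exec/eida.R`) with
subcommands `decompose`, `metrics`, `discrete`, `continuous`, `simulate`,
`benchmark`; every run writes its resolved configuration to
`run_config.json` for exact reruns.

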