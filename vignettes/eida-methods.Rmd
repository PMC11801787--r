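---
title: "Exact two-eigenvector analysis of instantaneous phase alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact two-eigenvector analysis of instantaneous phase alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eida)
```

## The model

A parcellated recording is an N x T matrix of region signals sampled every
TR seconds. After bandpass filtering to a narrow band, each signal's
analytic representation $x(t) + i\,H\{x\}(t)$ yields an instantaneous phase
$\theta_i(t)$. At each frame the **instantaneous phase alignment (iPA)
matrix** collects all pairwise alignments,

$$\mathrm{iPA}_{ij}(t) = \cos\bigl(\theta_i(t) - \theta_j(t)\bigr),$$

which is $+1$ for in-phase pairs, $-1$ for antiphase pairs and $0$ in
quadrature. Writing $c = \cos\theta$ and $s = \sin\theta$ elementwise gives
$\mathrm{iPA} = cc^\top + ss^\top$: the matrix is symmetric, positive
semidefinite, has unit diagonal, trace $N$, and **rank at most 2**. Its full
eigensystem is therefore available in closed form. With

$$\gamma = \lVert c\rVert^2,\quad \sigma = \lVert s\rVert^2,\quad
  \xi = c^\top s,\quad \Delta = (\sigma-\gamma)^2 + 4\xi^2,$$

the two non-null eigenvalues are

$$\lambda_{1,2} = \frac{N \pm \sqrt{\Delta}}{2},$$

and the eigenvectors are unit-normalised $c + B_{1,2}\,s$ with
$B_{1,2} = \bigl((\sigma-\gamma) \pm \sqrt{\Delta}\bigr)/(2\xi)$. The pair
$(\lambda_1, v_1, \lambda_2, v_2)$ — $2N+2$ numbers — is a *lossless*
representation of the $N(N-1)/2$ distinct matrix entries, and the closed
form costs $O(N)$ per frame against the $O(N^3)$ of a dense eigensolver.

$\lambda_1$ is the spectral radius of the matrix and summarises the total
amount of instantaneous order: it is bounded in $[N/2, N]$, reaches $N$
exactly when all signals are pairwise in phase or antiphase (rank-1
collapse), and reaches $N/2$ exactly when $c \perp s$ with equal norms, the
maximally irreducible configuration in which both eigenvectors carry equal
information. Because $\lambda_2 = N - \lambda_1$, the single series
$\lambda_1(t)$ characterises the spectrum completely.

## Numerical choices in the decomposition

The textbook formulas above degrade numerically in three regimes, all of
which occur in practice (and exactly on the limit cases). `ipa_decompose`
resolves them explicitly rather than relying on generic fallbacks:

* **Quadratic-root cancellation.** $B_1$ is evaluated as
  $((\sigma-\gamma)+\sqrt{\Delta})/(2\xi)$ only when
  $\xi(\sigma-\gamma) \ge 0$; otherwise the algebraically equivalent
  $2\xi/((\gamma-\sigma)+\sqrt{\Delta})$ avoids subtractive cancellation.
  The second root uses the Vieta identity $B_1 B_2 = -1$.
* **Rank-1 collapse** ($\lambda_2 \approx 0$). Detected either through a
  vanishing $\lVert s\rVert^2$ or $\lVert c\rVert^2$, or — when both norms
  are finite but $c \parallel s$ — through a vanishing Gram determinant
  $\gamma\sigma - \xi^2$ (which equals $\lambda_1\lambda_2$). The frame is
  returned as $\lambda_1 = N$, $v_2 = 0$ and flagged `degenerate`; the
  naive formula would divide by a zero norm here.
* **Equal eigenvalues** ($\xi \approx 0$, $\sigma \approx \gamma$). Any
  rotation of $\{c, s\}$ is an eigenbasis; the orthonormalised pair is
  returned and flagged. When $\xi \approx 0$ with distinct norms, $c$ and
  $s$ themselves are the (unique) eigenvectors and no flag is set.

Degeneracy thresholds are $10^{-12} N$, proportional to the trace so the
branch choice is scale-free in N. Stored eigenvectors are sign-canonicalised
(largest-magnitude component positive, ties to the first index); every
downstream quantity operates on rebuilt matrices or absolute correlations
and is invariant to this choice — it only stabilises serialised output.

## Phase extraction

Signals are demeaned per region and transformed with the FFT analytic
signal (periodic assumption). Since boundary frames can be distorted by the
implicit periodicity, `analytic_phase` exposes an `edge_trim` parameter;
the default is 0 (no trimming), as the appropriate amount depends on the
band and the recording length, and all shipped analyses operate on interior
frames long enough for edge effects to be negligible. The bandpass
prefilter is a second-order Butterworth applied forward and backward
(`signal::filtfilt`, zero phase, effective order 4); the default band in
the generators, 0.01–0.08 Hz at TR = 2.75 s, is the standard
resting-state regime for which the narrowband assumption behind the
analytic phase is defensible.

## Discrete analysis: recurrent modes

`discrete_eida` clusters frames with k-means in the space of
strictly-upper triangles of the *rebuilt* matrices: assignment by cosine
distance, centroid update by the arithmetic mean of assigned upper
triangles. Because frames are rebuilt from both weighted eigenvectors, the
clustering uses the full matrix information (it is mathematically
equivalent to clustering the full iPA matrices) while storing only
$2N+2$ numbers per frame — and it is immune by construction to the
eigenvector sign-flip ambiguity and to $v_1/v_2$ swaps in near-degenerate
frames, both of which plague clustering in leading-eigenvector space.

Two consequences of this exact distance/update pair are documented rather
than "fixed": the mean is not the cosine-distance minimiser, so strict
monotone convergence is not guaranteed in theory; termination is by zero
reassignments with a `max_iter = 300` guard and a `converged` flag.
Centroids are initialised from k distinct random frames, with 10 restarts
by default and the lowest-inertia model kept; inertia is the sum of
*squared* cosine distances (the squared convention makes the k = T limit
vanish and matches the usual elbow-plot objective). Empty clusters are
repaired by promoting the frame farthest from its centroid. The diagonal is
excluded from the upper triangle: it is constantly 1 and would only add a
constant offset to every cosine similarity.

Mode statistics follow directly: fractional occurrence (share of frames per
mode), dwell time (mean maximal-run length times TR, in seconds; `NA`
rather than 0 for modes never visited), and per-mode spectral
metastability.

## Continuous analysis: flow, FCD and complexity

When modes are not well separated, the flow picture is used instead. The
reconfiguration speed is
$s(t) = 1 - \lvert R(\mathrm{iPA}(t), \mathrm{iPA}(t-1))\rvert$ with $R$
the Pearson correlation over strictly-upper triangles (centered
correlation, not cosine similarity; the diagonal is excluded because its
constant entries would distort the centering). The kinematic
speed-displacement (KSD) embedding pairs position $\lambda_1(t)$ with this
speed (or per-eigenvector positions $\lambda_k$ with eigenvector
correlation speeds). Speeds are undefined at the first frame; series have
length $T-1$. A frame whose upper triangle has zero variance (a perfectly
uniform alignment pattern) yields an `NA` marker at the affected steps
rather than an arbitrary 0 or an exception.

The FCD matrix extends the same distance to all frame pairs,
$\mathrm{FCD}_{ij} = 1 - \lvert R(\mathrm{iPA}(t_i), \mathrm{iPA}(t_j))\rvert$;
it is symmetric with zero diagonal and its superdiagonal equals the
reconfiguration speed identically. Its upper-triangle mean and (population)
variance — the switching index — summarise dynamical fluidity.

LZW complexity quantises a series into `n_levels` uniform bins over its
global range, concatenates frames in time order, and compresses with
Lempel–Ziv–Welch over an initial dictionary of the `n_levels` symbols,
reporting emitted-code-count times $\lceil \log_2 \rvert\text{dict}\lvert \rceil$
bits. The symbolisation (which series, how many levels, which binning) is
a genuine free choice: the default compresses the per-frame concatenation
of $\sqrt{\lambda_1}\,v_1$ and $\sqrt{\lambda_2}\,v_2$ with 256 levels, and
every result carries its symbolisation settings as attributes because bit
counts are only comparable between identical settings.

## Conventions

Both metastabilities (standard deviation of $\lambda_1$ over time; standard
deviation of the Kuramoto order parameter modulus
$r(t) = \lvert \tfrac1N \sum_j e^{i\theta_j(t)}\rvert$) use the
**population** standard deviation (divide by T). The sample convention
would differ by $O(1/T)$; one convention is used everywhere, including the
FCD variance, for internal comparability. Note the deliberate contrast
between the two order measures: two equal groups in antiphase give
$r = 0$ yet $\lambda_1 = N$ — the phasor sum cancels while the alignment
matrix is perfectly ordered.

The irreducibility index at threshold fraction $x$ is the fraction of
frames with $\lambda_1 < xN$; thresholds at or below $0.5$ are rejected
(the index would be identically 0 since $\lambda_1 \ge N/2$) to catch unit
mistakes. The default profile grid is $\{0.55, 0.60, 0.65, 0.70\}$. The FC
index is the plain sum of squared matrix entries, diagonal included — for
correlation-like matrices the diagonal contributes a constant $N$.

## What the synthetic generators emulate

The generators provide every regime the pipeline distinguishes, with known
ground truth:

* `gen_limit_case` — the analytic corner cases (all-in-phase, antiphase
  mixtures, quadrature blocks) whose decompositions are known exactly.
* `gen_planted_modes` — a mode sequence with geometric (memoryless) dwells
  of configurable mean, frames jittered around phase templates by von Mises
  noise of concentration $\kappa$ ($\kappa = \infty$ = none; the sampler is
  the Best–Fisher rejection method). Returns true labels for recovery
  scoring. Default study conditions for recovery tests: T = 500 frames,
  dwell mean 5 frames, $\kappa = 20$ (circular sd $\approx 0.22$ rad).
* `gen_narrowband` — independent white-noise rows filtered to 0.01–0.08 Hz
  at TR = 2.75 s: a stationary null with realistic spectral content.
* `gen_kuramoto` — mean-field Kuramoto oscillators, Euler-integrated at
  dt = TR/10 and subsampled, with Gaussian natural frequencies; coupling
  sweeps cover incoherence, near-critical metastability and full lock.

None of these emulate hemodynamics, spatial autocorrelation, motion or
physiological noise; passing recovery tests on them demonstrates the
correctness of the algorithms, not robustness to real acquisition
artifacts.

## Problem sizes used in the shipped analyses

Test fixtures use N between 6 and 200 regions and T between 10 and 600
frames; oracle-equivalence checks run 1000 random frames across
N in {2, 3, 10, 44, 200}; mode-recovery checks run 20 seeds of T = 500 at
N = 16 for 2 and 3 planted modes. These sizes make every distributional
claim cheap to recompute while covering the dimensionalities typical of
parcellated recordings.

## Known limitations

* The decomposition is specific to matrices of the form
  $cc^\top + ss^\top$; general dynamic-connectivity matrices of higher rank
  are out of scope.
* Assignment/update asymmetry in the discrete pipeline (cosine distance vs
  arithmetic mean) can in principle oscillate; this is inherited from the
  algorithm's definition and surfaced via `converged`.
* Absolute LZW bit counts depend on the symbolisation; only within-setting
  comparisons are meaningful.
* The analytic phase assumes narrowband signals; on broadband input the
  instantaneous phase is not physically interpretable, and the package
  deliberately does not guess a band — filtering is explicit.
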