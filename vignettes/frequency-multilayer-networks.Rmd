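---
title: "Frequency-based multiplex and multilayer functional networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-based multiplex and multilayer functional networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqlayer)
```

## The model

A multichannel oscillatory recording (the motivating case is resting-state
MEG: ~240 sensors at 508.63 Hz) is turned into a *frequency-based
multilayer network* in four steps:

1. **Band-pass filtering.** Each channel is filtered into the canonical
   bands theta [3, 8], alpha [8, 12], beta [12, 30] and gamma [30, 100] Hz
   (`bandpass()`), giving `l * N` node-layer series for `l` bands and `N`
   channels.
2. **Mutual information.** Coordination between every unordered pair of
   node-layers is quantified by histogram MI in nats,
   \(MI_{ij} = \sum_{u,v} p_{uv} \ln\left(p_{uv} / (p_u p_v)\right)\)
   (`mutual_information()`, `mi_matrix()`). Within-band pairs give
   intralayer edges; cross-band pairs give interlayer edges, including the
   "diagonal" edges linking one channel's bands to each other.
3. **Surrogate thresholding.** Each series is cut into blocks (default
   1018 samples, ~2 s) which are permuted uniformly at random,
   independently per channel; MI between surrogates (`MI^rand`) serves as
   a significance threshold: `W_ij = MI_ij - MI^rand_ij` where MI exceeds
   the surrogate, else 0 (`block_permutation_surrogate()`,
   `threshold_weights()`). Zeros are the *missing edges*.
4. **Normalization and assembly.** The whole `lN x lN` matrix is min-max
   normalized to [0, 1] in one shot (`normalize01()`) and sliced into
   layer blocks and interlayer coupling blocks (`supra_network`). The
   *multiplex* restriction keeps only the diagonal interlayer entries
   (`restrict_to_multiplex()`); the *aggregated* monolayer network is the
   componentwise sum of the layers (`aggregate_layers()`).

The spectral object of interest is the combinatorial supra-Laplacian
`L = diag(s) - M` of the supra-adjacency `M` (`combinatorial_laplacian()`),
in its weighted form — the unit-weight textbook definition is the special
case, and MI-weighted empirical networks require the weighted one. Its
second-smallest eigenvalue, the algebraic connectivity \(\lambda_2\),
measures how strongly the layers are structurally integrated: for small
uniform interlayer weight `p` a two-layer multiplex has
\(\lambda_2 = 2p\) exactly (the antisymmetric split vector is an exact
eigenvector), while for large `p` it saturates at the aggregated-network
value \(\lambda_{2,agg} = \tfrac12 \lambda_2(L^\alpha + L^\beta)\). A
full multilayer network with all-to-all coupling `P = pC` behaves as
\(\lambda_2 = 2p\langle c\rangle\) for small `p` (\(\langle c\rangle\) the
mean weighted degree of `C`, equal to `N` for all-ones `C`) and as
\(\lambda_{2,\min(\alpha,\beta)} + \lambda_2(pC)\) beyond the transition.
The *transition point* `p*` separating the regimes is located as the
intersection of the \(\lambda_2\) and \(\lambda_3\) branches
(`scan_transition()`, `transition_point()`).

## Transition-point detection

The gap \(\lambda_3 - \lambda_2\) along a log-spaced `p` grid is not
always a single V: for non-identical random layers the physical
transition appears as an *avoided crossing* (the branches pinch but do
not meet), and further, deeper dips occur at larger `p` where the two
aggregated-limit branches nearly touch. `transition_point()` therefore:

* takes the **first interior local minimum** of the gap (the smallest `p`
  at which the branches meet), not the global minimum;
* refines it by golden-section search;
* declares an exact crossing when the refined gap satisfies
  `gap <= atol + rtol * lambda3` (defaults `1e-6`, `1e-4`, echoed in the
  result); when the branches coincide over a whole interval (identical
  layers), it bisects for the *leftmost* crossing point;
* only accepts threshold crossings at or before the first gap minimum —
  in the large-`p` regime `rtol * lambda3` grows without bound and would
  otherwise spuriously "cross" the constant branch separation;
* for avoided crossings returns the gap-minimizing `p` flagged
  `crossed = FALSE`.

Eigenvalue branches are identified by value ordering only (\(\lambda_2\)
is always the second-smallest at each `p`); eigenvector-continuity branch
tracking is out of scope. Disconnected supra-graphs yield
\(\lambda_2 = 0\) with a warning rather than an error, because
edge-deletion sweeps legitimately produce them.

## The ensemble density calibration

The synthetic ensembles use two `G(N, p_con)` Erdős–Rényi layers with
`N = 250` and report the ensemble-mean `p*`. The source experiments print
`p_con = 0.25` together with `<p*> ~ 2.870` (multiplex) and
`p* ~ 0.013` (full multilayer) — but these three numbers are mutually
inconsistent: at `p_con = 0.25` the closed forms give
\(\lambda_{2,agg}/2 \approx 24\) and \(\lambda_{2,\min}/N \approx 0.16\),
an order of magnitude away. A density scan shows `p_con = 0.05`
reproduces *both* printed values through the closed forms
(\(\approx 2.74\) and \(\approx 0.012\)), so the package's ensembles
default to `p_con = 0.05` and `scripts/acceptance.R` prints the
self-consistency check before measuring anything.

One caveat is inherent in the avoided-crossing geometry: the measured
gap-minimum `p*` of the multiplex ensemble sits systematically below the
closed form (the pinch occurs while the \(\lambda_3\) branch is still
rising toward its aggregated asymptote), giving an ensemble mean near
2.3 rather than the printed 2.870, which matches the closed form. The
full-multilayer target is insensitive to this and reproduces 0.013
essentially exactly. No density/convention combination reproduces both
printed values via the measured crossing; the discrepancy is reported,
not tuned away.

At `p_con = 0.05` (`mean degree ~12.5`) a non-negligible fraction of ER
realizations is disconnected; since the scans assume connected layers,
`er_layer()` resamples disconnected draws with a warning and logs the
count (`attr(., "resamples")`).

## The synthetic signal generator

`generate_signals()` emulates the statistical features the pipeline needs
to be testable without any recorded data: band-limited channels
\(x_n(t) = \sum_b a_{n,b}(t)\cos(2\pi f_b t + \phi_{n,b}) + \varepsilon\)
with positive, slow, mean-1 amplitude envelopes and planted coupling.

* **Envelope process.** Low-pass-filtered (default cutoff 1 Hz) absolute
  value of a *stationary* Ornstein–Uhlenbeck (AR(1)) process whose
  correlation time matches the cutoff, clipped at zero and rescaled to
  mean 1. A random-walk driver was considered and rejected: it is
  non-ergodic, so independent envelopes share their \(\sqrt{t}\) growth
  shape and stay correlated (~0.6) no matter how long the series — the
  stationary driver makes the sample correlation of uncoupled envelopes
  vanish with series length, which the tests rely on.
* **Planted coupling** mixes a shared envelope component into a pair with
  weight \(\rho \in [0,1]\): \(a \leftarrow (1-\rho)a_{own} + \rho
  a_{shared}\), within a band (`intra_pairs`) or across bands
  (`cross_pairs`) — amplitude–amplitude coupling, the quantity the MI
  pipeline detects on band-passed signals. Optional phase–amplitude pairs
  modulate a gamma envelope by \(1 + \kappa\sin(\theta\text{-phase})\)
  and are off by default.
* **Determinism.** Every random stream is keyed by
  `(seed, purpose, channel, band)`, so outputs are bit-identical for a
  config and adding a channel does not perturb existing ones.
* **Scale.** Test default `n_samples = 20000` (~39 s at 508.63 Hz) keeps
  simulations fast; the full recording scale (149646 samples, ~240
  channels) is supported but not exercised in tests.

What a green test does *not* establish: the generator has no lead
fields, sensor noise spectra, volume conduction or source mixing, so
pipeline performance on it says nothing about artifact robustness on
real MEG — only that the construction recovers planted statistical
dependence and stays calibrated under the null.

## Numerical and convention choices

* **Bin-count rule.** The published rule `u = v = 5 * round(t/10)`
  (nearest integer, .5 up) is implemented verbatim as `"auto"`
  (`default_bin_count()`); at full scale it yields ~75k bins, which the
  sparse joint-histogram accumulator handles in `O(t log t)`. Because
  that regime makes nearly every sample unique, a documented `"sqrt"`
  alternative `5 * round(sqrt(t/10))` (`bin_count_sqrt()`) is provided
  and used by the pipeline tests; the rule in force is recorded in the
  network metadata.
* **MI details.** Equal-width bins span each series' own range; a
  constant series is an error, not a silent zero. Terms are summed in a
  canonical order so `MI(x, y)` and `MI(y, x)` are bit-identical.
* **Surrogates.** Permutations are drawn independently per channel
  (destroying cross-channel coupling); a same-permutation mode exists
  behind a flag. The trailing partial block stays in place. With the
  published single surrogate the null probability of retaining an edge is
  1/2 by exchangeability, so the threshold mainly removes the MI bias;
  `n_surrogates > 1` with `aggregate = "max"` gives a nominal per-edge
  false-positive rate of `1/(n_surrogates + 1)`, the mode used for the
  calibration tests.
* **Normalization.** `w_min`/`w_max` are the smallest/largest entries
  (the source text swaps the words; `M` must land in [0, 1]), applied to
  the whole matrix at once, zeros included.
* **Filtering.** Linear-phase windowed-sinc (Hamming) FIR applied
  forward and backward (zero net phase), transition width 10% of each
  band edge, reflection padding; the passband/stopband contract is pinned
  by spectral tests, the filter design itself is configuration.
* **Heterogeneous interlayer weights.** Uniform on
  `[1 - sigma*sqrt(3), 1 + sigma*sqrt(3)]`: mean exactly 1, population
  sd exactly `sigma`, non-negativity bounding `sigma <= 1/sqrt(3)`. No
  post-hoc rescaling of samples.
* **Strength percentages.** Layer `l` is credited
  `100 * ||M^l||_1 / ||M||_1` intralayer and the full weight of its
  interlayer row block, so intralayer plus interlayer percentages over
  all layers sum to exactly 100 (the published interlayer formula's
  extra factor 2 would break that; the published table's columns sum to
  ~100, so the row-block convention is taken as intended).
* **Missing-edge percentages** count zero off-diagonal entries among all
  off-diagonal entries for monolayer networks, zero diagonal slots among
  `N` for multiplex couplings, and zero entries among `N^2` for full
  couplings.
* **Eigensolver.** Dense LAPACK decomposition up to 1500 nodes; a block
  Krylov solver (Rayleigh–Ritz with full reorthogonalization on the
  spectral reflection `cI - L`, block width `k + 2` to tolerate
  multiplicities) beyond, growing its subspace until Ritz residuals
  converge — the two routes are cross-checked against each other in the
  tests at 1e-8.
* **Sweeps.** Per-realization seeds derive from the base seed and
  realization index; baselines (sigma = 0, no missing edges) share the
  same layer realizations as their treatments, so paired differences are
  exact and `delta_lambda2 = 0` identically for the baseline itself.

## Limitations

* MI is the only coordination measure (no phase-locking value, coherence
  or partial correlation) and no zero-lag/common-source correction is
  attempted.
* The generator's coupling parameterization is a stand-in: the source
  data's generative process is unknown, so recovery rates measured here
  do not transfer to any particular instrument.
* Branch identities near crossings are by value ordering; eigenvector
  continuity is not tracked.
* The multiplex ensemble transition point depends on the avoided-crossing
  convention (see above); values from different conventions can differ by
  ~20%.
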