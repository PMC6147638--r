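# freqlayer

Frequency-based multiplex and full multilayer functional networks from
multichannel oscillatory time series, and the spectral analysis of their
combinatorial supra-Laplacians.

## The problem

Brain activity recorded at many sensors (MEG/EEG) coordinates both
*within* classical frequency bands (theta, alpha, beta, gamma) and
*across* them (cross-frequency coupling). Encoding one recording as a
multilayer network — one layer per band, interlayer edges for cross-band
coordination — raises a structural question with real consequences for
biomarkers: should interlayer edges connect only each region to itself
across bands (a **multiplex** network) or any region to any region (a
**full multilayer** network)?

The discriminating quantity is the algebraic connectivity λ₂ (Fiedler
value) of the combinatorial supra-Laplacian `L = diag(s) − M`, where `M`
is the supra-adjacency matrix (layer blocks on the diagonal, interlayer
coupling blocks `P` off it) and `s` the node strengths. Scaling the
interlayer weights by `p`:

- multiplex, small p: `λ₂ = 2p` (exactly — the ±1 split vector is an
  eigenvector); large p: `λ₂ → λ₂,agg = ½ λ₂(L^α + L^β)`;
- full multilayer (`P = pC`), small p: `λ₂ = 2p⟨c⟩` with `⟨c⟩` the mean
  weighted degree of `C`; large p: `λ₂ → λ₂,min(α,β) + λ₂(pC)`.

The two regimes are separated by the transition point `p*`, located as
the intersection of the λ₂ and λ₃ branches. Heterogeneous interlayer
weights and (especially) missing interlayer edges — both unavoidable in
functional networks thresholded against surrogates — depress λ₂ most
strongly near `p*`. This package implements the full pipeline
(filtering → mutual information → block-permutation surrogate
thresholding → normalization → supra-network), the spectral machinery
(λ₂/λ₃ scans, `p*` detection, closed-form reference curves), the
Erdős–Rényi / Barabási–Albert ensemble experiments, and a deterministic
MEG-like signal generator with planted coupling so the whole pipeline is
testable without any data download.

## Worked example

```r
library(freqlayer)

# 4 synthetic channels, alpha + beta bands, one planted cross-band pair
cross <- data.frame(i = 1, band_i = "alpha", j = 2, band_j = "beta",
                    rho = 0.9)
cfg <- signal_config(4, sampling_rate = 120, n_samples = 8000,
                     bands = default_bands(c("alpha", "beta")),
                     cross_pairs = cross, noise_sd = 0.1, seed = 42)
sim <- generate_signals(cfg)

net <- build_frequency_network(sim$signals,
                               default_bands(c("alpha", "beta")),
                               mi_config(n_bins = "sqrt",
                                         block_length = 240, seed = 7))
net
#> <supra_network> 2 layers x 4 nodes (alpha, beta)
#>   coupling 1_2: [partial] 7 active, strength 1.313

# the planted (channel 1, alpha) - (channel 2, beta) edge survives
# surrogate thresholding and carries the largest normalized weight:
net$couplings[["1_2"]]$block[1, 2]
#> [1] 1

algebraic_connectivity(combinatorial_laplacian(net))
#> [1] 0.06844465

# transition point of an identical-layer multiplex: p* = lambda2(G) / 2
g <- er_layer(100, 0.1, seed = 3)
sc <- scan_transition(list(alpha = g, beta = g),
                      diagonal_coupling(100, 1), log_grid(0.05, 20, 30))
transition_point(sc)
#> <transition_point> p* = 0.397257 (gap 8.05e-05)
algebraic_connectivity(g) / 2
#> [1] 0.3972972
```

The supra-network's λ₂ (0.068) is far below the layers' internal
connectivity: with only a handful of significant interlayer edges the
two bands are still structurally independent — exactly the regime the
ensemble experiments (`run_heterogeneity_sweep()`,
`run_missing_edges_sweep()`, `run_densification_sweep()`) map out, and
the detected `p*` matches the closed form to four digits.

## Command line

```sh
exec/freqlayer simulate-signals --config sim.json --out sig --seed 7
exec/freqlayer build-network --signals sig --bands alpha,beta \
    --bins sqrt --block-length 1018 --out net --seed 7
exec/freqlayer spectral-scan --net net --p-min 0.01 --p-max 10 \
    --n-p 40 --out scan.tsv
exec/freqlayer make-ensemble --model er --n 250 --pcon 0.05 \
    --coupling diagonal --sigma 0.4 --out ens --seed 1
exec/freqlayer sweep --config sweep.json --kind missing --out out/
exec/freqlayer summarize --net net --out summary.json
```

All outputs are plain text (TSV matrices and edge lists with JSON
sidecars) and bit-identical across runs at a fixed seed.
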