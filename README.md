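# mammofuse

Contrast elevation for breast images — mammograms and digital breast
tomosynthesis slices — for researchers building computer-aided diagnosis
preprocessing chains. Low contrast, noise and acquisition artifacts hide
the regions of interest (lesions, microcalcifications) that radiological
interpretation depends on; `mammofuse` implements an optimized sigmoid
enhancement with wavelet-domain feature restoration and the quality
metrics to judge both.

## The method

**S-curve transform.** A normalized pixel r ∈ [0, 1] is remapped by the
sigmoid gray-level transform

    s(r) = α + (β − α) / (1 + exp(−(r − γ)/δ))

with asymptote constants α, β, center γ and width δ. The default
constants (α = 0.9642, β = 8.594·10⁻⁴, γ = 0.4962, δ = 0.07598) stretch
mid-tone contrast sharply; note they make the map *decreasing*
(intensity-inverting) — `scurve_invert()` swaps the asymptotes if that is
unwanted. The transform is applied globally, or locally on a k×k tile
grid with per-tile renormalization and bilinear blending between tile
mappings so no artificial tile boundaries appear.

**PSO tuning.** α and β are tuned per image by a particle swarm (default
30 particles, 10 iterations) maximizing the enhancement measure

    EME = mean over 3×3 blocks of 20·log10(I_max / I_min)

using the canonical velocity/position rules
v′ = w·v + c₁r₁(xBest − x) + c₂r₂(gBest − x), x′ = x + v′, with clipped
bounds and a monotone global-best trace. One elitist particle starts at
the default constants, so the tuned EME never falls below the fixed one.

**Wavelet fusion.** Enhancement can suppress diagnostic detail, so the
enhanced image is fused with the original: one-level DWT of both
(haar/db2/db4/sym4), coefficient-wise **maximum rule**
F(i,j) = max(A(i,j), B(i,j)) on approximate and detail sub-bands, then
IDWT. The filter bank is orthonormal with periodic extension, so
reconstruction is exact for any image size.

**Metrics.** Entropy (bits), EME, AMBE (|mean(ref) − mean(proc)|),
population SD, and the Wang–Bovik universal image quality index over 8×8
sliding windows.

## Worked example

No mammography database is needed: the phantom generator produces
reproducible mammogram-like scenes (smooth tissue background, faint
lesions, microcalcification specks, noise).

```r
library(mammofuse)

ph  <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 7,
                                     preset = "low_contrast"))
cfg <- pipeline_config(pso = pso_config(seed = 7))
res <- run_fuse(ph$image, cfg)
print(res$report, row.names = FALSE, digits = 4)
#>     stage     E    EME  AMBE    SD      IQI alpha beta seed
#>  original 4.533 0.7092    NA 5.931       NA     1    0    7
#>  enhanced 5.081 0.9365 4.376 8.523 -0.53768     1    0    7
#>     fused 4.985 0.8429 5.268 8.022 -0.02556     1    0    7
```

Reading the report: the swarm pushed the asymptotes to α = 1, β = 0
(maximum sigmoid amplitude), raising EME from 0.71 to 0.94 dB and
entropy from 4.53 to 5.08 bits on this narrow-band phantom. The fused
image sits between the stages — it keeps most of the contrast gain
(EME 0.84) and spread (SD 8.02 ≥ the original's 5.93) while moving back
toward the original's structure (IQI −0.03 against the original versus
−0.54 for the enhanced image alone, which is negative because the
default S-curve inverts intensity). AMBE stays within a few gray levels,
i.e. global brightness is roughly preserved.

### Command line

```sh
Rscript inst/cli/mammofuse.R phantom --size 128 --seed 3 --preset low_contrast --out-dir work
Rscript inst/cli/mammofuse.R fuse work/phantom_3.png --out-dir work/out --seed 3
Rscript inst/cli/mammofuse.R metrics work/out/phantom_3_fused.png work/phantom_3.png --out-dir work/out
```

Subcommands: `enhance`, `fuse`, `metrics`, `phantom`, `pipeline` (batch
enhance + fuse + combined report); reports in JSON or CSV; YAML config
via `--config` with flags taking precedence.

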