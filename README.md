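# organoidmech

Quantitative tools for the mechanics and structural organization of brain
organoids. Developing brain tissue is a soft, solid-like viscoelastic
material whose stiffness is set in large part by the amount and spatial
arrangement of its extracellular matrix (ECM); mutations that disturb ECM
deposition (such as *LIS1* haploinsufficiency, the most common genetic
cause of lissencephaly) stiffen the tissue and scatter the normally
ring-like collagen deposition. This package implements the four
computational procedures such a study runs, each exercised end to end on
seeded synthetic data:

1. **Micropipette-aspiration rheology** (`fit_sls`). Under constant
   suction ΔP through a pipette of radius Rp, the aspirated tongue length
   L(t) gives the creep compliance of the half-space model,

       J(t) = 2π L(t) / (3 φ Rp ΔP),        φ = 2.1,

   which is fitted by the standard linear solid (SLS) creep function

       J_SLS(t) = (1/k_st) (1 − ((k0 − k_st)/k0) e^(−t/τ)),

   yielding the instantaneous stiffness k0, steady-state stiffness k_st,
   and response time τ, plus the Maxwell elements k1 = k_st,
   k2 = k0 − k_st, µ = τ k1 k2/(k1 + k2).

2. **Microstructure stiffness model** (`build_lattice`, `dilute`,
   `place_cells`, `compute_stiffness`). The ECM is a diluted triangular
   lattice of semiflexible fibers with embedded area-elastic cell
   triangles, with energy

       E = (ks/2) Σ_⟨ij⟩ p_ij (l_ij − l0)²
         + (kb/2) Σ_⟨ijk⟩ p_ij p_jk (θ_ijk − π)²
         + Σ_n λ q_n (A_n − A0)².

   The system (periodic horizontally, clamped top and bottom) is
   compressed uniaxially, relaxed to a minimum-energy state, and the
   tissue stiffness K = (1/A_sys) d²E/dγ² extracted by finite
   differences. Removing edges at random (disorganized, mutant-like ECM)
   is compared with removing them from one central circular region
   (patterned, control-like ECM).

3. **Diffusion-MRI ADC distributions** (`fit_adc_map`, `adc_pipeline`).
   Multi-b diffusion-weighted stacks are reduced to per-voxel apparent
   diffusion coefficients by the mono-exponential log-linear fit
   ln S(b) = ln S0 − b·ADC; tissue voxels are segmented on the highest-b
   image; the masked ADC values are binned into a 100-bin normalized
   histogram, Fourier-denoised, and summarized by the 2/3·Imax
   maximal-likelihood position; groups are compared by per-scan relative
   deviation (which cancels scanner drift) with a matched t test.

4. **Radial collagen profiling** (`sholl_counts`, `compare_profiles`).
   Thresholded collagen signal is counted on concentric circles from the
   section center (Sholl analysis) at normalized radial increments, and
   conditions are compared with a Mann–Whitney U test (exact enumeration
   at small n, tie-corrected normal approximation otherwise).

Seeded generators (`gen_creep_traces`, `gen_dwi_phantom`,
`gen_collagen_image`, `gen_network_configs`) produce synthetic inputs with
the statistical structure each stage assumes, so everything here runs with
no external data.

## Worked example

Fit one synthetic aspiration trace and inspect the recovered parameters:

```r
library(organoidmech)
tr  <- gen_creep_traces(1, k0 = 400, k_st = 250, tau = 2, seed = 1)[[1]]
cc  <- compute_creep_compliance(tr)   # onset auto-detected at 2.0 s
fit <- fit_sls(cc)
fit
#> sls_fit 'synthetic_01': k0 = 399.8 Pa, k_st = 250.2 Pa, tau = 1.98 s (R2 = 0.9914, n = 201)
derive_maxwell_elements(fit)$mu
#> [1] 185.3782
```

The generating parameters (400 Pa, 250 Pa, 2 s) are recovered to a
fraction of a percent under 1% measurement noise, with the fit quality the
aspiration measurements themselves show (R² ≈ 0.99). The dashpot value
µ ≈ 185 Pa·s is the viscosity of the Maxwell arm equivalent to that creep
response.

The analysis scripts under `analysis/` run each study stage and write
their tables under `results/`:

```sh
Rscript analysis/01_rheology.R   # three-condition creep-test comparison
Rscript analysis/02_network.R    # K(p) sweep + patterned-vs-random contrast
Rscript analysis/03_adc.R        # five-scan, three-group ADC phantom
Rscript analysis/04_sholl.R      # ring vs scattered collagen profiling
```

`analysis/02_network.R`, for instance, prints

```
K(patterned, p = 0.85) = 8.40 +/- 0.03
K(random,    p = 0.95) = 11.97 +/- 0.39
Relative stiffness increase: 42.5%
```

— the same amount of ECM is substantially stiffer when its loss is
scattered at random than when it is cleared from one central weak spot —
and `analysis/03_adc.R` recovers a +8.6% ± 2.2% mutant ADC deviation from
a phantom with a 9% injected offset under Rician noise and scanner drift.

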