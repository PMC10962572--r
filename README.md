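# cardiodwi

Two-compartment biophysical modelling of cardiac diffusion-weighted MRI:
estimates the intracellular volume fraction (ICV) and the major and minor
diameters of cardiomyocytes from multi-diffusion-time, multi-b-value DWI
data, and provides the simulation machinery to characterise the estimator.

## Who this is for

Researchers quantifying myocardial microstructure ex vivo (e.g. in murine
hypertrophy models, where pressure overload thickens cardiomyocyte
cross-sections by ~30%) who have — or plan — acquisitions with several
diffusion times Δ and several diffusion weightings b, and want biophysical
parameters rather than DTI summary indices.

## The model

The normalised signal is a mixture of two non-exchanging pools sharing one
eigenvector frame (u₁, u₂, u₃):

    S = v_IC · S_cyl-ECS + (1 − v_IC) · S_tensor

* **Intracellular**: an impermeable cylinder with an elliptical
  cross-section — free diffusivity d along the cell axis u₁, restricted
  diffusion across it with major radius r₁ (along u₂) and minor radius r₂
  (along u₃). Perpendicular attenuation follows the Gaussian-phase
  (van Gelderen) series over the roots of J₁′; dividing by
  γ²δ²(Δ − δ/3) gives the apparent perpendicular diffusivity
  D⊥app(r, d; Δ, δ).
* **Extracellular**: an anisotropic Gaussian tensor
  (d_EC∥, d_EC⊥1, d_EC⊥2).

Because a cylinder at a *single* (Δ, δ) is indistinguishable from a tensor
with eigenvalues (d, D⊥app(r₁), D⊥app(r₂)), estimation proceeds in two
steps that disentangle b-dependence from Δ-dependence:

1. fit a bi-exponential **tensor–tensor** model per diffusion time
   (maximum likelihood ≡ least squares under Gaussian noise; the slow
   compartment is the intracellular one; d_EC∥ pinned at 2.1 μm²/ms, the
   buffer's free diffusivity);
2. extrapolate v_IC(Δ) and d_IC∥(Δ) linearly to Δ = 0, then recover r₁,
   r₂ by least squares of the measured d_IC⊥ᵢ(Δ) curves against
   D⊥app(rᵢ, d₀; Δ, δ).

## Worked example

```r
library(cardiodwi)

scheme <- build_protocol_scheme()   # 10 dirs x 6 b x 5 Delta + 5 b0 = 305
truth <- list(v_ic = 0.6, d = 0.9, r1 = 8.7, r2 = 5.1,
              d_ec_par = 2.1, d_ec_perp1 = 1.6, d_ec_perp2 = 1.0,
              theta = 0, phi = 0, alpha = 0)
mv <- generate_synthetic_dataset(truth, scheme,
                                 noise = noise_spec(60, seed = 3))
hierarchical_fit(mv, restarts = 4, seed = 1)
#> Hierarchical two-step fit (5 diffusion times)
#>   ICV (Delta -> 0):   0.598
#>   d0, c1:             0.895 um^2/ms, +0.0001 per ms
#>   major diameter 2r1: 17.44 um
#>   minor diameter 2r2: 10.20 um
```

The fit recovers the generating geometry: an ICV of 0.598 against a true
0.6, and diameters 17.44/10.20 μm against the true 2r₁ = 17.4 μm and
2r₂ = 10.2 μm — healthy-myocyte dimensions. `fit_volume()` applies the same
procedure voxel-wise to a NIfTI volume (`dwi_dataset()`, `normalize_to_b0()`,
optional `lowpass_filter()`), and `roi_statistics()` summarises maps per
region. A command-line front end lives at `inst/cli/cardiodwi.R`
(subcommands `scheme`, `simulate`, `fit`, `precision`, `degeneracy`).

Simulation tools: `precision_analysis()` (sampling distribution of the
step-1 estimator under Rician noise, normalised bias/SD per SNR),
`degeneracy_sweep()` (profile-objective sweeps per parameter), and
`mc_dperp_app()` (an independent random-walk check of the van Gelderen
series).

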