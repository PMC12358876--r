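# memtub

Energetics of membrane tubulation by bacterial ESCRT-III (PspA-family)
rods.

PspA forms helical protein rods that engulf and thin lipid membrane
tubules. Two opposing energies decide whether a membrane tube stays inside
a rod: the free energy gained when the amphipathic N-terminal helix α0 of
each subunit binds the outer membrane leaflet, and the Helfrich bending
cost of holding the bilayer at high curvature. `memtub` implements the
quantitative analysis layer of that problem for structural biologists and
simulators:

* **Leaflet surfaces** — split membrane marker point clouds into leaflets
  and fit a 2D Gaussian ("bell curve") height function
  `h(x, y) = z0 + A exp(-((x-x0)² + (y-y0)²) / 2σ²)` per leaflet,
  plus component density profiles along the membrane normal.
* **Helfrich bending energy** — exact Monge-gauge curvatures
  (H, K) from the fitted surface and the bending energy
  `E = ∫ [2κ(H - c0)² + κ̄K] dA`, decomposed into mean and Gauss terms,
  with cumulative radial profiles and height × width isoenergy maps.
* **Binding free energy** — WHAM estimation of the potential of mean
  force W(z) from umbrella-sampling windows, its integration to a 1 M
  standard-state binding free energy
  `ΔG⁰ = -k_BT ln[(A/V⁰)∫ e^(-W/k_BT) dz] + ΔG_entropy`, and
  Jarzynski work-average replica selection.
* **Helical lattice** — the constant-arc rod geometry model: with n
  subunits per rung (the Bessel order of the ~110 Å layer line) and
  diameter D, the subunit arc is s = πD/n and inserting one subunit
  widens the rod by D/n (≈ 20 Å for the narrowest 200 Å, n = 10 class).
* **Contacts and the energy balance** — per-residue peptide–headgroup
  contact counts with composition/area-per-lipid scaling, bound-helix
  counting against a fitted surface, and the binding-versus-bending
  verdict `n × |ΔG⁰| vs E_bend`.
* **Tomographic quantification** — vesicle attachment and
  internal-location fractions and per-rod tube/disc content histograms.
* **Synthetic data** — generators for every input above with known
  ground truth (Gaussian-bump leaflet clouds, Metropolis-sampled umbrella
  windows, ideal rods, contact frames, vesicle tables), so the whole
  pipeline is testable without MD trajectories or cryo-EM data.

## Worked example

```r
library(memtub)

# a membrane deformed by a 150 x 50 Angstrom Gaussian bump, 2 A marker noise
cloud <- gen_leaflet_cloud(amplitude = 150, sigma = 50, n_points = 10000,
                           noise_sd = 2, seed = 1)
fit <- fit_gaussian_surface(split_leaflets(cloud)$upper, leaflet = "upper")
fit
#> 2D Gaussian surface fit (upper leaflet)
#>   amplitude 150.1 A, sigma (49.97, 49.97) A, centre (213.3, 213.3), baseline 17 A
#>   rms residual 1.981 A over 10000 points

res <- helfrich_energy(fit, bending_moduli())   # kappa = 20 kT, kbar = -0.8 kappa
res
#> Helfrich bending energy (rho <= 249.8 A):
#>   E_total = 147.8 kcal/mol (mean 147.8, Gauss -9.387e-08)

round(radial_energy_profile(res)[seq(1, 65, by = 16), ], 2)
#>       rho E_total E_mean E_gauss
#> 1    0.00    0.00   0.00    0.00
#> 17  62.46   94.25 124.04  -29.80
#> 33 124.92  136.65 139.67   -3.02
#> 49 187.38  147.81 147.82    0.00
#> 65 249.84  147.84 147.84    0.00
```

Most of the bending cost accrues near the bump tip (94 of 148 kcal/mol
inside ρ = 62 Å); the Gauss term is locally favourable there but vanishes
over the full plane, as Gauss–Bonnet requires for an asymptotically flat
surface.

```r
lattice_from_rung(diameter = 200, n = 10)
#> Helical lattice: n = 10 subunits/rung, D = 200 A, rung spacing 110 A
#>   subunit arc s = 62.83 A, diameter step D/n = 20 A

energy_balance(n_bound = 30, dG_per_helix = -6.32,
               bending_energy = 160, tolerance = 35)
#> Energy balance: 30 helices x 6.32 kcal/mol = 189.6 kcal/mol binding
#>   vs bending cost 160 kcal/mol (tolerance 35): balanced
```

Thirty bound helices at −6.32 kcal/mol each supply 189.6 kcal/mol, within
the dead band around a 160 kcal/mol bending cost: binding and bending are
balanced, consistent with a membrane tubule that stays internalized
without being pulled deeper.

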