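# protacscreen

Ligand-centric ternary-complex screening and SPR cooperativity analysis
for PROTACs with rigid diyne linkers.

PROTAC degraders work by holding a target protein and an E3 ubiquitin
ligase together in a ternary complex. When the linker is a short, rigid
diyne (C≡C–C≡C), the ligand has essentially one conformational degree of
freedom — rotation about the linker axis — which makes the geometry of the
ternary complex unusually predictable. `protacscreen` implements the full
modelling and binding-analysis workflow that exploits this:

1. **Conformer enumeration** — systematic rotation of one warhead about
   the diyne axis in fixed increments (10° by default, giving 36
   conformers), warhead internal geometry held fixed.
2. **Warhead superposition** — each protein–ligand complex is posed onto
   its PROTAC warhead by least-squares rigid-body (Kabsch) superposition
   of an explicit atom map, moving the whole complex rigidly.
3. **Clash screening** — inter-protein steric clashes are counted at a
   2.4 Å heavy-atom cutoff; a pose is *viable* iff it has **no**
   backbone–backbone clashes and **at most 20** heavy-atom clash pairs.
4. **Staged relaxation bookkeeping** — the four-stage harmonic-restraint
   release schedule (restrain all heavy atoms → release sidechains →
   release backbone → release ligand, force constant
   10 kcal mol⁻¹ Å⁻²), trajectory frame accounting with a 10 ns
   equilibration discard, and representative-frame selection by lowest
   median RMSD (target-protein Cα RMSD after aligning the E3 backbone).
5. **SPR kinetics** — simulation and global fitting of 1:1 Langmuir
   binding for binary (small molecule vs immobilised protein) and
   pre-mixed ternary formats, with
   K_D = k_off / k_on, t₁/₂ = ln 2 / k_off, and the cooperativity factor
   **α = K_D(binary) / K_D(ternary)** (α > 1: positive cooperativity).

A synthetic-data module plants screening scenes and sensorgram datasets
with ground truth known by construction, so every stage is testable
without downloading structures.

The package is tidyverse-shaped: atom records, screens, and kinetic
summaries are tibbles; fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

```r
library(protacscreen)
library(dplyr)

# a planted scene whose clash-free dihedral angles are known by construction
scene      <- plant_ternary_scene(viable_angles = c(0, 10, 20, 30), seed = 1)
conformers <- enumerate_conformers(scene$ligand, step_deg = 10)
screen     <- screen_conformers(conformers,
                                scene$complex_a, scene$map_a,
                                scene$complex_b, scene$map_b)
screen |> filter(viable)
#> <ternary_screen> 4 viable of 4 conformers
#> # A tibble: 4 x 4
#>   angle backbone_pairs heavy_pairs viable
#>   <dbl>          <int>       <int> <lgl>
#> 1     0              0           0 TRUE
#> 2    10              0           0 TRUE
#> 3    20              0           0 TRUE
#> 4    30              0           0 TRUE
```

Only 4 of the 36 grid angles give a pose free of backbone clashes and
within the 20-heavy-clash tolerance — the planted analogue of a rigid
linker restricting the accessible protein–protein interfaces.

```r
# ternary-format SPR: simulate 5 cycles at 2 RU noise, then fit globally
truth <- kinetic_params(k_on = 1.47e5, k_off = 0.0085, rmax = 100)
data  <- make_sensorgram_dataset(truth, ternary_injection_series(),
                                 noise_sd = 2, seed = 1)
fit   <- fit_kinetics(data)
glance(fit)
#> # A tibble: 1 x 9
#>      k_on   k_off  rmax     K_D t_half residual_norm n_obs n_cycles converged
#>     <dbl>   <dbl> <dbl>   <dbl>  <dbl>         <dbl> <int>    <int> <lgl>
#> 1 146982. 0.00851 100.0 5.79e-8   81.4          139.  5005        5 TRUE

cooperativity(1810e-9, glance(fit)$K_D)
#> # A tibble: 1 x 4
#>    kd_binary   kd_ternary alpha classification
#> 1 0.00000181 0.0000000579  31.3 positive
```

The fitted ternary K_D of ~58 nM against a binary K_D of 1810 nM gives
α ≈ 31: strongly positive cooperativity, i.e. the pre-formed
PROTAC:target complex binds the ligase far more tightly than the free
ligand does.

A thin command-line wrapper over the same functions is installed at
`inst/cli/protacscreen.R` (subcommands `scan`, `represent`, `spr-sim`,
`spr-fit`, `coop`, `synth`).

## License

MIT
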