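# passivemotion

Classify micron-scale particles in a quiescent liquid as **cell-like** or
**mineral-like** from their passive 3D motion alone.

## The problem

Life-detection microscopy — in terrestrial field samples or on ocean worlds
such as Europa and Enceladus — must decide whether a barely resolved,
non-motile, micron-scale object is a cell or a mineral grain. At 0.2–2 µm
there is too little morphology to tell, and non-motile organisms offer no
behavioural cue. Density does discriminate: aquatic cells are almost always
lighter than 1.3 g/cm³ (cytoplasm is mostly water), nearly all minerals are
denser than 1.5 g/cm³, and no mineral floats. A particle's trajectory in a
volumetric recording (e.g. from a digital holographic microscope) encodes
both its size and its density, so passive motion alone can make the call.

## The model

For a sphere of radius *r* and density ρ<sub>p</sub> in a fluid
(T, η, ρ<sub>f</sub>) under gravity *g*:

- lateral Brownian motion has diffusivity **D = k<sub>B</sub>T/(6πηr)**
  (Einstein–Stokes), giving *r* from the measured mean squared
  displacement;
- axial drift follows Stokes' law,
  **v = 2(ρ<sub>p</sub> − ρ<sub>f</sub>)gr²/(9η)**, giving
  ρ<sub>p</sub> − ρ<sub>f</sub> from the measured settling/rising rate;
- their timescale ratio is the particle Strouhal number,
  **Sr<sub>p</sub> = 3k<sub>B</sub>T/(4π|ρ<sub>p</sub> − ρ<sub>f</sub>|gr⁴)**:
  Sr<sub>p</sub> ≫ 1 is diffusion-dominated motion, Sr<sub>p</sub> ≪ 1
  visible sinking/floating, with both effects competing near
  Sr<sub>p</sub> ~ 1.

The package implements this chain end to end: a ground-truthed Langevin
trajectory simulator emulating holographic-microscope recordings (tracks
and 4D intensity volumes), projection-based detection plus greedy
nearest-neighbour linking, per-track estimators with outlier filtering,
the density-gap classifier, and observation-time planning for arbitrary
gravity/temperature environments (`mission_plan()`). See the methods
vignette (`vignettes/passive-motion-classification.Rmd`) for assumptions,
estimator details and limitations.

## Worked example

Fifteen alumina grains (r = 0.75 µm, Δρ = 1932 kg/m³) recorded for 78 s at
15 frames/s in water at 20 °C, then estimated and classified:

```r
library(passivemotion)
fluid <- fluid_medium(293.15, 1.002e-3, 998)   # water at 20 °C
earth <- mission_environment("Earth", gravity = 9.81, fluid = fluid)

pop <- sample_population(
  population_spec("Alumina", 15, size_fixed(0.75), earth), seed = 1)
rec <- recording_spec(duration = 78)           # 15 fps, default noise
sim <- simulate_population(pop, rec, earth, seed = 1)
tracks <- apply_localization_noise(sim$tracks, rec, seed = 1)

est <- estimate_particles(tracks, earth,
                          radius_source = "fixed", fixed_radius_um = 0.75)
summarize_population(est, "vz_um_s")
#> mean sinking speed: 2.36 ± 0.04 µm/s (95% CI), median 2.36

cls <- classify_population(est, fluid, truth = sim$truth)
confusion_matrix(cls)
#>               call
#> truth          mineral-like
#>   mineral-like           15
```

The recovered mean sinking speed matches the Stokes prediction
(2.36 µm/s for this radius and density difference), and every grain is
called mineral-like because its estimated density (≈ 2930 kg/m³) lies far
above the 1.5 g/cm³ mineral threshold. Planning the same measurement for a
bacterium-like particle (Δρ = 100 kg/m³, r = 0.75 µm, 2 µm axial
resolution) across gravity environments:

```r
mission_plan(classes = tibble::tibble(label = "bacterium",
                                      delta_rho_kg_m3 = 100,
                                      radius_um = 0.75),
             fluid = fluid)[, c("environment", "g_m_s2",
                                "t_required_s", "regime")]
#>   environment g_m_s2 t_required_s regime
#> 1 Earth        9.81          16.3 mixed
#> 2 Enceladus    0.113       1419.  brownian
#> 3 Europa       1.32         122.  brownian
#> 4 Mars         3.71          43.2 mixed
```

i.e. ~16 s of recording suffices on Earth, minutes on Europa or Mars, and
~1400 s on Enceladus, where gravity is ~1% of Earth's.

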