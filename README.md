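# epidermsim

Agent-based simulation of epidermal homeostasis on structured basement
membranes.

Reconstructed human epidermis grown from passaged keratinocytes is usually
far thinner than native tissue, and a long-standing hypothesis is that the
missing ingredient is geometric: native epidermis sits on an undulating
papillary interface (rete ridges), while culture inserts are flat.
`epidermsim` is a three-dimensional *center-based* (off-lattice) model
built to explore that hypothesis in silico: keratinocytes generated by
stem cells anchored on a configurable substrate migrate under overdamped
contact mechanics, differentiate positionally through the spinous and
granular compartments, flatten into corneocytes that pack into a
stratum-corneum sheet, and desquamate from the free surface. The package
is aimed at skin biologists and tissue engineers who want to ask which
substrate undulation patterns (sinusoid amplitude/wavelength, textile
fiber thickness/spacing) favour a thick living layer and a thick stratum
corneum before committing to culture experiments.

## The model in brief

Each cell is a particle with position `x`, axisymmetric ellipsoid
semi-axes `(a, a, c)` and a lifecycle state. Dynamics are overdamped:

    gamma dx/dt = F_contact + F_membrane + F_anchor + noise

with linear repulsion below contact and linear adhesion in a short shell
beyond it; contact distances use direction-dependent ellipsoid radii so
flattened corneocytes (`c/a -> 0.2`, volume `a^2 c = r0^3` conserved
exactly) stack into sheets. The lifecycle is a stochastic state machine
`STEM -> PROLIF -> SPINOUS -> GRANULAR -> CORNEOCYTE -> shed`: stem
divisions are exponential clocks gated by a local crowding cap,
differentiation triggers at a fixed clearance above the membrane, and
desquamation removes only surface-exposed corneocytes. Homeostasis — a
stationary total cell count — emerges from the feedback between crowding
and shedding. Substrates are flat, product-sinusoidal
(`h = (A/2) sin(2 pi x / lambda) sin(2 pi y / lambda)`), or textile-like
orthogonal fiber grids; a packaged preset table carries ten measured
textile geometries plus the measured human papillary geometry
(51 um ridge height, 105 um interval). See the methods vignette
(`vignettes/epidermal-homeostasis-model.Rmd`) for the full account of the
laws, defaults and design choices.

## Worked example

Grow an epidermis on a sinusoidal membrane (amplitude 50 um, wavelength
100 um — the papillary-scale geometry) for 300 simulated hours on a
100 x 100 um domain:

```r
library(epidermsim)

membrane <- membrane_spec("sinusoidal", amplitude_um = 50, wavelength_um = 100,
                          domain_x_um = 100, domain_y_um = 100)
traj <- simulate_epidermis(membrane, T_total_h = 300, snapshot_every_h = 50,
                           seed = 42)
print(traj)
#> <epiderm_trajectory> sinusoidal membrane, 7 snapshots to t = 300 h
#>   final: 1914 cells (1300 cornified), births 2747, removals 953

tissue <- final_state(traj)
count_layers(tissue)
#> n_corneocytes      n_living
#>          1300           614

profile <- thickness_profiles(tissue, membrane, bins = 10)
cat(sprintf("living %.1f um, stratum corneum %.1f um, roughness %.1f um\n",
            profile$mean_living_thickness_um, profile$mean_sc_thickness_um,
            profile$interface_roughness_um))
#> living 55.7 um, stratum corneum 49.1 um, roughness 21.1 um

section_areas(tissue, membrane, y0 = 45, slab_um = 10)
#>     sc_area_per100um living_area_per100um
#>             8782.875             2229.562
```

The counts partition the tissue into cornified and living cells; the
thickness profile and the histology-like section areas (um^2 per 100 um of
section, substrate pixels masked out) are the readouts used to compare
substrate geometries. `render_section()` draws the same slab with the
conventional color code (membrane green, living cells purple, cornified
cells red), and `experiment_flat_vs_sinusoidal()`,
`experiment_amplitude_wavelength_sweep()` and `experiment_textile_panel()`
run the paired-seed comparisons; `compare_conditions()` applies one-way
ANOVA with Tukey HSD to replicate metrics. A thin CLI over the same
functions is at `inst/cli/epidermsim.R`
(`run`, `analyze`, `render`, `experiment` subcommands, YAML run configs).

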