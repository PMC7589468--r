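# evcapture

Design calculators and a Monte Carlo capture simulator for microfluidic
immunoaffinity beds that enrich extracellular vesicles (EVs) on
antibody-coated micropillar arrays.

## What it is for

Liquid-biopsy assays that profile EV cargo need the vesicles first: a
plasma sample is pumped through a bed of micropillars coated with a
monoclonal antibody (e.g. anti-CD8α to pull down T-cell-derived EVs).
A vesicle is recovered only if it diffuses across the 10–15 µm channel
between pillars and binds an antibody before the flow carries it out of
the bed. The designer's central question — how does **recovery** (the
fraction of entering particles captured) fall as the volumetric flow
rate rises — is what this package answers, together with the bookkeeping
arithmetic of device design (surface area, EV monolayer load capacity,
antibody coverage, throughput ratios, processing time).

## The model

Particles are tracked through the 2-D unit cell of the array: a channel
of gap *g* (the inter-pillar spacing) and length *L* (the bed), whose
walls are the capture surfaces. Per time step *dt*:

- convection with the plane-Poiseuille profile
  *u(y) = 6 ū (y/g)(1 − y/g)*, where *ū = Q / A_open* is the
  interstitial velocity through the pillar-row constriction;
- Brownian displacements of standard deviation √(2 D dt) in both axes,
  with *D = k_B T / (3π η d)* (Stokes–Einstein);
- within an encounter radius *a* of a wall, capture with probability
  *P = 1 − exp(−k_f ρ n_ag f dt)*, where ρ is the antibody areal
  density, *n_ag* the antigen copies per vesicle, *f* the fraction of
  the path lined by pillar faces, and
  *k_f = k_in / (1 + Pe)*, *Pe = a u(y)/D*, the motion-attenuated
  forward rate (intrinsic rate *k_in* in the reaction limit, decreasing
  with slip velocity).

Batches repeat until the 95% binomial CI on recovery is narrower than
±0.5 percentage points; runs are bit-identical under a fixed seed.
Serial beds chain survivors; parallel beds run at the per-bed flow.
An absorbing-wall plug-flow mode is benchmarked against the closed-form
eigenfunction series (`slab_survival()`).

Two device fixtures ship with the package (a 3-bed serial chip with
circular 100 µm pillars and a 7-bed parallel chip with diamond 10 µm
pillars), plus a kinetics fixture whose intrinsic on-rate is anchored to
the 3-bed device's characterized 41% recovery at 5 µL/min (see the
methods vignette for what that anchoring does and does not imply).

## Worked example

```r
library(evcapture)

d3  <- load_device_config(evcapture_fixture("evmap_3bed"))
d7  <- load_device_config(evcapture_fixture("evmap_7bed"))
kin <- load_kinetics_config(evcapture_fixture("chang_hammer_kinetics"))
cfg <- simulation_config(n_particles_per_batch = 5000, seed = 11)

geometry_report(d7, antibody_mass_ug = 23.1)
#>   name       n_beds arrangement n_pillars surface_area_cm2 internal_volume_ul
#> 1 evmap-7bed      7 parallel      1475712             38.2               21.6
#>   open_cross_section_m2   ev_capacity antibody_pmol antibody_pmol_cm2
#> 1            0.00000063 195810607009.           154              4.04

simulate_device(d3, transport_context(5), kin, cfg)
#> <recovery_result> recovery = 41.0% (95% CI 40.6-41.5%), 16419 bound / 23581 lost, 8 batch(es), converged

tidy(recovery_flow_sweep(d7, transport_context(5), kin, cfg, c(5, 10, 20)))
#>   flow_ul_min recovery ci_low ci_high n_bound n_lost batches converged
#> 1           5    0.998  0.997   0.999    9980     20       2 TRUE
#> 2          10    0.947  0.942   0.951    9469    531       2 TRUE
#> 3          20    0.737  0.732   0.742   22115   7885       6 TRUE

processing_time(100, 10)   # 100 uL at 10 uL/min -> 10 min
throughput_ratio(d7, d3)   # 8.24, i.e. ~8-fold at matched channel velocity
```

Reading the numbers: the 38.2 cm² of functionalizable surface holds
~2.0 × 10¹¹ close-packed 150 nm vesicles and carries 154 pmol (~4
pmol/cm²) of a 150 kDa antibody at 23.1 µg loading. The 3-bed chip
recovers 41% of entering EVs at 5 µL/min; the 7-bed chip holds ~100% at
the same flow, still 74% at 20 µL/min, and processes 100 µL in 10 min at
10 µL/min — the throughput/recovery trade the curve quantifies.

`autoplot()` on a sweep draws the recovery-vs-flow curve with its CI
ribbon. A thin CLI (`exec/evcapture`) exposes the same operations as
`geometry`, `simulate`, `plan`, `compare` and `fixtures` subcommands.

## Scope

The package models particle transport and capture only. Downstream assay
steps (vesicle release chemistry, RNA extraction, RT, ddPCR readout) and
any clinical interpretation are out of scope; `assay_timeline()` merely
totals user-supplied stage durations, and `capacity_guard()` flags
operating points that would saturate the capture surface.
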