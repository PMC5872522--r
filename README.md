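# melnest

Simulation and quantification of melanoma nest formation in a 3D skin
co-culture, using a lattice-based individual-based model (IBM).

When melanoma cells are seeded together with skin cells onto a
three-dimensional skin substitute, they aggregate into *nests* — compact
clusters that resemble the earliest stage of melanoma progression. `melnest`
simulates this process to ask which cell-level mechanisms (migration,
proliferation, cell–cell adhesion) drive nest growth, and to predict how
perturbing those mechanisms changes nest size. It is aimed at computational
biologists studying early tumour morphogenesis and at modellers who need a
well-tested 3D exclusion-process engine with cluster quantification.

## Model

Cells are agents on a 3D square lattice (default 150 × 150 × 100 sites at
Δ = 20 μm, i.e. a 3 mm × 3 mm × 2 mm block of tissue), with at most one
agent per site. Lateral boundaries are periodic; the top and bottom faces
are no-flux. Two species coexist: motile, proliferative *skin* agents and
motile, proliferative, mutually adhesive *melanoma* agents. Each time step
of duration τ runs two phases of random sequential updates. In each phase,
N(t) agents are selected one at a time with replacement:

* **Motility.** The selected agent moves with probability P_m^(s) (skin)
  or P_m^(m) (melanoma) to a uniformly chosen site of its six-site von
  Neumann neighbourhood. A melanoma agent first counts the melanoma
  occupants *a* of its 26-site Moore neighbourhood and passes an extra
  adhesion gate with probability (1 − q)^a, so q = 0 means no adhesion and
  q = 1 freezes any melanoma agent touching another. Moves onto occupied
  sites or through the horizontal boundaries are aborted.
* **Proliferation.** The selected agent divides with probability P_p^(s)
  or P_p^(m), placing a same-species daughter on a uniformly chosen vacant
  von Neumann site; the event is aborted only if all six sites are
  occupied.

The per-step probabilities map to continuum rates λ = P_p/τ (proliferation)
and D = P_m Δ²/(6τ) (diffusivity). The baseline parameter set
(τ = 0.01 h, P_m^(m) = 0.075, P_m^(s) = 0.3, P_p^(m) = 4×10⁻⁴,
P_p^(s) = 2.5×10⁻⁴, q = 0.7) corresponds to λ^(m) = 0.04 /h,
λ^(s) = 0.025 /h, D^(m) = 500 μm²/h and D^(s) = 2000 μm²/h.

Runs start from agents seeded uniformly on the top surface at densities
matched to experimental cell counts pipetted into a 3 mm disc
(`density_matched_count()`: 30 000 skin cells → 9549 agents; 1250 / 5000 /
8500 melanoma cells → 398 / 1592 / 2706 agents) and last four days (96 h).

Nests are quantified as connected components of melanoma agents
(wrap-aware 26-connectivity by default), clusters of fewer than four agents
are excluded, and nest area is agent count × Δ² = 400 μm² per agent, with
boxplot summaries (type-7 quartiles, 1.5·IQR whiskers). An optional
erosion/reconstruction splitter (`split_merged_nests()`) separates nests
fused by thin bridges.

## Worked example

A four-day baseline run on the reduced quarter-surface lattice
(75 × 75 × 60 ≙ 1.5 mm × 1.5 mm × 1.2 mm), seeded at the density matched to
30 000 skin and 5000 melanoma cells:

```r
library(melnest)

params <- model_parameters()
print(params)
#> IBM model parameters
#>   tau = 0.01 h, delta = 20 um, q = 0.7
#>   melanoma: Pm = 0.075, Pp = 0.0004
#>   skin:     Pm = 0.3, Pp = 0.00025
#>   rates: lambda_m = 0.04 /h, lambda_s = 0.025 /h, D_m = 500, D_s = 2000 um^2/h

geom <- lattice_geometry(75, 75, 60)
set.seed(7)
init <- seed_surface(scale_count(9549, geom),
                     scale_count(density_matched_count(5000), geom), geom)
res <- simulate_ibm(init, params, duration_h = 96, geom = geom)
print(res)
#> IBM run: 9600 steps (t = 96 h) on 75 x 75 x 60 lattice
#>   final agents: 11831 melanoma, 27084 skin
#>   moves: 27302754 / 133145774 selections succeeded
#>   births: 36130 / 133145774 selections

an <- analyze_nests(res$final, geom = geom)
print(an$summary)
#> nest summary: 78 nests
#>   median 3600 um^2 (0.0036 mm^2), IQR [2000, 8000] um^2
#>   whiskers [1600, 14800], 10 outlier(s)

head(an$nests[, 1:4])
#>   label n_agents area_um2 area_mm2
#> 1     1     8870  3548000   3.5480
#> 2     2      704   281600   0.2816
#> 3     3      292   116800   0.1168
#> 4     4      203    81200   0.0812
#> 5     5      100    40000   0.0400
#> 6     6       84    33600   0.0336
```

The initial 398 melanoma agents grow to ~12 000 over four days; after the
<4-agent filter, 78 nests remain. The largest component (8870 agents)
illustrates nest *merging*: neighbouring nests that grow into contact are
labelled as one connected component — see the methods vignette
(`vignettes/melnest-methods.Rmd`) for why this matters when comparing
median nest sizes across conditions.

Scenario runners reproduce the perturbation experiments: suppressed
melanoma proliferation (`no_melanoma_proliferation`, emulating irradiated
cells), halved proliferation (`half_proliferation`) and halved adhesion
(`half_adhesion`):

```r
base <- run_scenario(scenario_spec("baseline"))
half <- run_scenario(scenario_spec("half_proliferation"))
compare_scenarios(base, half)   # fold change of median nest area + bootstrap CI
```

A command-line interface wraps the same functions
(`inst/cli/melnest run|analyze|sweep|fixtures|convert-params`).

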