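# aerotraits

Most of what is known about the hypoxia tolerance of marine animals comes
from respirometry on a few dozen species. Yet the trait that matters for
biogeography — the minimum O₂ pressure at which an *ecologically active*
population remains viable, and how that threshold moves with
temperature — leaves a fingerprint in where species actually live.
`aerotraits` diagnoses these traits from occurrence records paired with
gridded ocean temperature and O₂ fields, and provides the downstream
analyses that turn per-species traits into macroecological and
evolutionary statements: aerobic habitat volumes over trait space,
range-edge temperature sensitivities, occupied metabolic-index headroom,
the temperature dependence of active versus resting metabolic costs, and
phylogenetic signal. A synthetic ocean and species generator with known
ground truth makes the whole pipeline testable offline.

It is written for quantitative marine ecologists and ecophysiologists
comfortable with R.

## The model

The Metabolic Index compares ambient O₂ supply potential with the demand
of sustained activity,

    Phi(pO2, T) = A_eco * pO2 / f(E(T), T),
    f(E, T)     = exp(-E/k_B * (1/T_K - 1/Tref_K)),
    E(T)        = E_eco_ref + dEdT * (T - T_ref),

with `T_ref = 15` °C. Water with `Phi >= 1` is metabolically viable; the
temperature-dependent lower threshold is `pO2_act(T) = f(E(T), T)/A_eco`.
Three traits per species — active hypoxia tolerance `A_eco` (atm⁻¹), its
temperature sensitivity `E_eco_ref` (eV), and the sensitivity slope `dEdT`
(eV/°C) — are fitted by maximising the F1-score of the `Phi >= 1`
habitability classifier over the species' presence/background samples in
binned temperature–pO₂ state space. The trait algebra connects to resting
physiology via `A_eco = A_o/Phi_crit` and
`E_eco = E_d − E_s + E_phicrit`.

## Worked example

Generate a synthetic ocean, sample occurrences for a species with known
traits, and diagnose the traits back:

```r
library(aerotraits)

env <- make_ocean(resolution_deg = 2, seed = 1)
truth <- species_truth(trait_set(9.75, 0.31, 0.034, species_id = "demo"),
                       n_presence = 500, noise_rate = 0.05, seed = 11)
occ <- simulate_species(env, truth)

ds  <- build_occupancy(occ, env)
fit <- fit_traits(ds)
print(fit)
```

```
Trait fit [demo]: F1 = 0.766 (ok)
  A_eco = 9.73 atm^-1, E_eco_ref = 0.355 eV, dEdT = 0.0358
  inhabited T: 0.9-15.3 degC; Phi_max = 1.85; 499 cells
```

The fitted tolerance `A_eco = 9.73` atm⁻¹ recovers the generating value
(9.75) to 0.2 %: this species needs about 0.10 atm O₂ at 15 °C to sustain
activity. `E_eco_ref = 0.355` eV (truth 0.31) means the threshold rises
steeply with warming, and `dEdT = 0.036` eV/°C (truth 0.034) says that
sensitivity itself strengthens toward the warm edge. `Phi_max = 1.85` is
the occupied headroom: the species' best waters supply ~1.9× its sustained
need. The F1 of 0.77 is the classification skill of the fitted threshold
against the (noisy) occupancy pattern.

Range-edge sensitivities follow directly:

```r
edge_sensitivities(fit)
```

```
E_eco at warm/cold edges: 0.37 / -0.15 eV (delta 0.51)
```

so hypoxia tolerance declines with warming at the warm range edge but
*improves* with warming at the cold edge — the signature of multi-step O₂
supply that `dEdT` parameterises.

## The analysis workflow

`analysis/` holds numbered drivers that run the full study on the
synthetic system and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | 2° ocean climatology, 20 ground-truth species, Grafen tree |
| `02_fit_traits.R` | per-species trait diagnosis + recovery summary |
| `03_diagnostics.R` | edge sensitivities, Phi_max headroom, habitat volumes, latitude bands, KS tests, E_phicrit |
| `04_phylo_signal.R` | Pagel's λ power check and demo-assemblage estimates |

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_traits.R
...
```

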