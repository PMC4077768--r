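# iltol

Mechanistic modelling of ionic-liquid (IL) tolerance in *E. coli*
engineered with the EilA efflux pump, under different promoter control
strategies.

Imidazolium ILs such as [C2mim]Cl are excellent solvents for
lignocellulose pretreatment, but the residue carried into the sugar
stream is toxic to fermentation hosts. Expressing an IL efflux pump
rescues growth — at a membrane-protein burden that is itself costly — so
the practical question is regulatory: is it better to express the pump
constitutively (an IPTG-induced promoter), not at all, or dynamically
from a native IL-responsive promoter? `iltol` is for strain engineers and
modellers who want to explore that trade-off quantitatively, and for
analysts who need the screening arithmetic (differential-expression
filtering, qPCR ΔΔCt, SRM protein ratios) that identifies candidate
promoters in the first place.

## The model

Biomass `N`, substrate `S`, pump protein `p` and intracellular IL `c_i`
evolve as

    dN/dt  = mu(S, c_i, p) * N
    mu     = mu_max * S/(K_s+S) * 1/(1+(c_i/K_c)^h) * 1/(1+p/K_p)
    dS/dt  = -(1/gamma) * mu * N
    dp/dt  = pi(c_i) - beta*p
    dc_i/dt = alpha_d * (V_e/V_i) * (c_e - c_i) - alpha_c * p * c_i

with the controller law `pi` being basal (`alpha_p0`), constitutive
(`alpha_p0 + alpha_p`) or IL-responsive
(`alpha_p0 + alpha_p * c_i/(gamma_c + c_i)`). The extracellular
concentration `c_e` is derived from a reactor-level IL mass balance
(total IL is constant), so conservation is structural. On top of the
simulator the package provides a serial-passage competition model,
nonlinear-least-squares calibration of every kinetic parameter,
measurement-based derivation of the promoter parameters, the
promoter-screening statistics, and seeded synthetic-data generators for
all of the above. See the vignette
(`vignettes/il-tolerance-model.Rmd`) for assumptions, parameter meanings
and numerical choices.

## Worked example

```r
library(iltol)
pp <- promoter_presets()          # the five constructs
g  <- run_controller_grid(pp[c("PmarR", "PlacUV5", "promoterless")],
                          c(0, 400), t_end = 20)
g$summary[, c("controller", "il_mM", "final_od", "doubling_h", "t_half_h")]
#>    controller il_mM final_od doubling_h t_half_h
#>         PmarR     0    1.035      0.788     5.00
#>         PmarR   400    1.035      0.788     9.33
#>       PlacUV5     0    1.035      0.817     5.33
#>       PlacUV5   400    1.035      0.817    10.67
#>  promoterless     0    1.035      0.737     4.67
#>  promoterless   400    0.128      0.737    10.33
```

Read: without IL every construct reaches the substrate-limited density
(OD 1.035), and the constitutive construct pays for pump expression with
a slower doubling time (0.82 h vs 0.74 h for promoterless). At 400 mM the
promoterless strain stalls at OD 0.13 within the 20-h assay, while the
IL-responsive PmarR construct still reaches full density, with a delayed
half-rise time (9.3 h vs 5.0 h).

```r
simulate_competition(pp, il_mM = 200, n_passages = 6)
#> Serial-passage competition at 200 mM IL
#>  passage       strain abundance
#>        6        PydfO 1.882e-06
#>        6        PydfA 7.119e-01
#>        6        PmarR 2.421e-01
#>        6      PlacUV5 4.607e-02
#>        6 promoterless 1.075e-06
```

After six pooled 1:100 subcultures at 200 mM, the weakly expressing
constructs have washed out and the IL-responsive PmarR strain outnumbers
the constitutive PlacUV5 strain about five-fold.

The `analysis/` directory holds numbered drivers that run the full study
(controller grid, competition, calibration recovery, promoter screen) and
write their tables under `results/`.

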