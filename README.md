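# wingplan

Estimating the total wing area and aspect ratio of birds from three
linear measurements of ordinary study skins — wingspan (*WS*), wing
length (*WL*, wrist joint to longest primary), and wing width (*S1*,
wrist joint to first secondary) — so that flight-efficiency proxies can
be computed for the thousands of museum specimens that have no
spread-wing preparation or photograph.

The aspect ratio, the wing trait most predictive of long-distance flight
efficiency and dispersal ability, is

```
AR = WS^2 / A
```

where *A* is the projected area of both wings plus the intervening body.
`wingplan` estimates *A* with closed-form geometric planform models: a
medial rectangle `(WS - 2*WL) * S1` flanked by two hand-wings whose
combined area depends on the assumed shape,

| model            | hand-wing area          | total area                         |
|------------------|-------------------------|------------------------------------|
| triangle         | `WL*S1`                 | `(WS - WL)*S1`                     |
| ellipse          | `(pi/2)*WL*S1`          | `(pi/2)*WL*S1 + (WS - 2*WL)*S1`    |
| ellipse-triangle | `((pi + 1)/3)*WL*S1`    | `((pi+1)/3)*WL*S1 + (WS - 2*WL)*S1`|

all three being members of the ellipse-fraction family
`h_f = WL*S1*(f*pi/2 + 1 - f)` at `f = 0, 2/3, 1`. The package also
re-implements the traditional spread-wing workflow (threshold → fill
holes → particle area → root-box reconstruction `2a + c*(WS - 2e)`),
the method-comparison statistics (log10 discrepancy, percent
differences, coefficients of variation), phylogenetic generalized least
squares with a Pagel's λ correlation structure (through-origin
regression, ML λ, AICc), and exact synthetic ground-truth generators
(planform polygons, rasters, paired cohorts, λ-Brownian traits).

## Worked example

```r
library(wingplan)

tab <- data.frame(specimen_id = c("ROM001", "ROM002"),
                  species = "Columba livia",
                  wingspan = c(66.0, 64.2), wing_length = c(22.4, 21.8),
                  s1 = c(11.1, 10.7))   # cm
out <- estimate_wing_areas(tab)
out[, c("specimen_id", "area_triangle", "area_ellipse",
        "area_ellipse_triangle", "aspect_ratio_ellipse")]
#>   specimen_id area_triangle area_ellipse area_ellipse_triangle
#> 1      ROM001         484.0        625.9                 578.6
#> 2      ROM002         453.7        586.8                 542.4
#>   aspect_ratio_ellipse
#> 1                6.960
#> 2                7.024
```

Areas are in cm²: for ROM001 the triangle model (pointed hand-wing)
gives 484 cm², the ellipse model (rounded hand-wing) 626 cm², and the
intermediate ellipse-triangle model 579 cm²; the corresponding pigeon
aspect ratio of ~7 sits in the mid-range typical of intermediate wing
shapes. Comparing a simulated paired cohort of 18 specimens against the
generating truth:

```r
sim <- make_paired_dataset(n = 18, WL = 22, S1 = 11, WS = 65, f = 2/3,
                           model = "ellipse-triangle", specimen_cv = 0.05,
                           measurement_cv = 0.02, seed = 42)
intraspecific_summary(sim$pairs, model = "ellipse-triangle")
#>              species  n mean_spread mean_folded sd_spread sd_folded cv_spread
#> 1 Synthetica exempli 18         555         555      51.8      49.7      9.34
#>   cv_folded pct_diff discrepancy            model
#> 1      8.95    0.159      0.0155 ellipse-triangle
```

A matched model recovers the cohort mean to 0.16 % with comparable CVs
— the agreement expected when the assumed hand-wing shape is correct
and only small measurement error is present.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/wingplan.R", package="wingplan"))')" \
    estimate --model ellipse-triangle --units mm in.csv -o out.csv
```

with subcommands `estimate`, `spreadarea`, `compare`, `pgls`, and
`simulate` (each exits non-zero on validation failure).

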