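# Output data dictionary

All CSV outputs written by `write_outputs()` and the forest / species /
microhabitat writers.

## summary.csv (one row per simulated year)
| column | unit | meaning |
|---|---|---|
| year | a | simulation year (0-based) |
| abundance_start | individuals | standing abundance at the start of the year |
| recruits | individuals | propagules that established this year |
| deaths_light_niche | individuals | deaths from light outside the species niche |
| deaths_competition | individuals | space-competition removals (smallest first) |
| deaths_oversize | individuals | lone individuals exceeding their voxel's substrate |
| deaths_dislodgement | individuals | falls with shed branches / fallen trees |
| deaths_metabolic | individuals | quarter-power mass-dependent mortality |
| abundance | individuals | end-of-year abundance |
| richness | species | species present at the end of the year |
| saturation | % | occupied / total substrate area x 100 |
| growth_rate | a-1 | abundance / abundance_start |

## mortality.csv
`cause` (one of the five channels, plus `competition_total` =
competition + oversize, and `total`), `rate` (% of start-of-year abundance
per year, mean over the pooling window).

## rank_abundance.csv
`rank` (descending), `ID_Sp`, `rel_abundance` (fraction of pooled
individuals).

## vertical.csv
`z` (1-m height bin, voxel index), `rel_abundance`.

## sizes.csv
`log10_mass_lo`, `log10_mass_hi` (quarter-decade log10 mass bin edges, g),
`count` (pooled individuals).

## stratification.csv
`ID_Sp`, `z_lo`, `z_med`, `z_hi` (2.5/50/97.5 % height quantiles, m, voxel
centres), `n` (pooled individuals); rows sorted by `z_med`.

## config.yaml
Fully resolved configuration echo of the run (seed, area, global
parameters, forest scenario config) sufficient to reproduce it.

## Forest CSV (`write_forest_csv`)
`year`, `id`, `x`, `y` (m), `dbh_cm`, `height_m`, `crown_radius_m`,
`crown_depth_m`, `alive` (only living trees are stored).

## Species CSV (`write_species_csv`)
One row per species with the trait symbols as columns: `ID_Sp`, `A_Mat`
(a), `M_Mat`, `M_Max` (g), `K` (a-1), `n_RPot`, `D_K` (1/m), `D_KAs`,
`I_Min`, `I_Opt`, `I_Max` (umol m-2 s-1), `I_A`, `I_B`, `I_C`.

## Microhabitat grids
NetCDF: dimensions `x`, `y`, `z` (m, voxel indices), `year`; variables `I`
(umol m-2 s-1), `S_B` (m2), `S_Loss` (%). CSV: long format
`year,x,y,z,I,S_B,S_Loss` with every voxel present.
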