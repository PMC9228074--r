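# kbafootprint

Trade-linked accounting of biodiversity loss from land use in key
biodiversity areas (KBAs).

KBAs are sites identified for their outsized contribution to the global
persistence of biodiversity — yet many carry cropland, pasture,
plantations, managed forest and built-up land, and in a globalized
economy that land use is often driven by final consumption elsewhere.
`kbafootprint` implements the full accounting chain for this problem,
aimed at industrial-ecology and conservation researchers who work with
multiregional input–output (MRIO) models and spatial biodiversity
impact assessment:

1. **Hybrid MRIO model** — a physical agriculture/food/forestry system
   (tonnes, heads, m³) coupled to a monetary economy-wide system (euros)
   through a biomass "other uses" link, as an upper-block-triangular
   coefficient matrix. The Leontief inverse factorizes into blocks,

   ```
   A = [[A_phys, A_link],        L = [[L_A, L_A·A_link·L_B],
        [0,      A_mon ]]             [0,   L_B           ]]
   ```

   with `L_A = (I − A_phys)⁻¹`, `L_B = (I − A_mon)⁻¹`. A consumer
   region's land footprint is `F^s = ê (L_A y_phys^s +
   L_A A_link L_B y_mon^s)`, with `ê` the land-use intensities (m² per
   unit output); food and nonfood demand stay separate provenance
   partitions.
2. **Spatial allocation** — national footprints downscaled onto grid
   cells of the producing country proportionally to observed production
   patterns, with an exact cellwise split inside/outside KBAs.
3. **Species loss** — cell-level land occupation times ecoregion-level
   characterization factors (potential global species lost per m², five
   taxa × five land-use types × three intensities), aggregated into
   production- vs consumption-based accounts, per-capita tables,
   embodied trade flows and final-product attribution.
4. **Decomposition & CTV** — country-level KBA loss factorized as
   `SL = A · (L/A) · (S/L) · (SL/S)` (KBA area, used share, richness
   per area, relative loss) with each factor's contribution to variance
   from normalized squared Spearman rank correlations.

A synthetic-world generator (`generate_world()`, `planted_scenario()`)
produces balanced toy economies, land rasters, characterization factors
and KBA masks with known ground truth, so the whole chain is testable
without external databases. See the vignette in `vignettes/` for the
model, assumptions and design choices.

## Worked example

```r
library(kbafootprint)

world     <- generate_world(world_config(seed = 1))
economy   <- world_economy(world)
footprint <- consumption_footprint(economy, world$extension,
                                   world$phys$y, world$mon$y)
shares    <- normalize_distribution(world$grid, world$extension)
grid      <- allocate_land(footprint, shares, world$masks)
account   <- species_loss(grid, world$cfs, world$masks,
                          footprint = footprint, shares = shares)

footprint
#> <footprint_tensor> 4 x 4 x 3 x 15 (consumer x producer x product x category);
#>   total 4.254e+09 m2 (food 77%)
account
#> <species_loss_account> species-equivalents lost (all land):
#>    mammals amphibians   reptiles      birds     plants
#>   0.005105   0.006949   0.006609   0.006741   0.058110

round(100 * trade_flows(account)$trade_share, 1)
#>    mammals amphibians   reptiles      birds     plants
#>       38.7       40.6       39.4       40.0       40.0

ctv(decompose_kba_loss(account, grid, world$masks, world$cfs))
#> <ctv_result> contributions to variance (%):
#>                      taxon
#> factor                mammals amphibians reptiles birds plants vertebrates
#>   area_of_kbas            0.0        0.0        0   0.0    0.0         0.0
#>   share_with_land_use    33.3       48.5        0  13.8   44.4        52.9
#>   richness_per_area      33.3        3.0       20  31.0   44.4        23.5
#>   relative_loss          33.3       48.5       80  55.2   11.1        23.5
```

Reading the output: the toy world's land footprint is 4.25 × 10⁹ m²,
77% of it driven by food consumption; about 0.058 plant
species-equivalents are committed to extinction, ~40% of that embodied
in international trade; and (on this draw, where every country has the
same KBA area) the variance of country-level KBA loss is explained by
the remaining three factors. The same chain runs file-to-file with
`run_pipeline(world_config(seed = 1), "out")`, which writes each stage's
outputs as CSV plus hash manifests and is byte-identical across reruns.

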