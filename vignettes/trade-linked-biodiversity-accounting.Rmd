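---
title: "Trade-linked accounting of biodiversity loss in key biodiversity areas"
author: "kbafootprint"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbafootprint)
```

## The problem

Key biodiversity areas (KBAs) are sites identified for their outsized
contribution to the global persistence of biodiversity. They are not
necessarily protected, and many carry cropland, pasture, plantations,
managed forest and built-up land. Because supply chains are global, the
land use inside a KBA in one country is often driven by final consumption
in another. This package implements the full accounting chain needed to
ask: *how much potential global species loss does land use cause, where
does it happen, who consumes the products that drive it, and which
country-level factors explain the differences?*

The chain has four stages:

1. a **hybrid multiregional input–output (MRIO) model** that traces land
   use from producing sectors to final consumers across borders,
2. **spatial allocation** of each consumer's land footprint onto grid
   cells of the producing country,
3. conversion of land occupation into **potential global species loss**
   via ecoregion-level characterization factors (CFs), split inside and
   outside KBAs, and
4. a **four-factor decomposition** of country-level KBA losses with a
   contribution-to-variance (CTV) analysis.

A synthetic-world generator supplies complete toy datasets with known
ground truth, so every stage is testable end to end without any external
database.

## The hybrid MRIO model

Real-world applications of this accounting couple a physical
agriculture/food/forestry table (product flows in tonnes, heads, m³) with
a monetary economy-wide table (euros), linked by an "other uses" matrix
giving biomass inputs per unit of monetary output. The package represents
this as an upper-block-triangular coefficient matrix

$$
A \;=\; \begin{bmatrix} A_{\mathrm{phys}} & A_{\mathrm{link}} \\
                        0 & A_{\mathrm{mon}} \end{bmatrix},
\qquad A_{\cdot} = Z_{\cdot}\,\hat{x}^{-1},
$$

where the zero block encodes the modelling assumption that monetary
sectors deliver no inputs back to the physical system. The Leontief
inverse then factorizes into blocks,

$$
L \;=\; (I - A)^{-1} \;=\;
\begin{bmatrix} L_A & L_A A_{\mathrm{link}} L_B \\ 0 & L_B \end{bmatrix},
\qquad L_A = (I - A_{\mathrm{phys}})^{-1},\;
L_B = (I - A_{\mathrm{mon}})^{-1},
$$

which `block_leontief()` exploits; the test suite checks the factorized
form against a dense inverse of the coupled matrix on random productive
economies. Food demand ($y_{\mathrm{phys}}$) and nonfood demand
($y_{\mathrm{mon}}$, routed through the link block) are kept as disjoint
provenance partitions throughout.

A consumer region's land footprint is

$$
F^s \;=\; \hat{e}\,\big(L_A\, y^s_{\mathrm{phys}}
        + L_A A_{\mathrm{link}} L_B\, y^s_{\mathrm{mon}}\big),
$$

with $\hat{e}$ the diagonal of land-use intensities (m² per tonne, head,
m³ — the intensities absorb the mixed units, and the pipeline never
converts units). Final demand carries a last-exporter origin on its rows,
so the first supply-chain link is attributed to the exporting region
while deeper links follow the Leontief structure. Monetary final demand
of composite rest-of-world regions is split across member physical
regions proportionally to population (equal per-capita consumption), the
standard treatment when the monetary system is spatially coarser.

**Zero-output sectors.** Physical IO tables have many empty
country–product cells. Coefficient columns of zero-output sectors are set
to zero rather than dropped, so indexing is preserved and inert sectors
can never produce division artifacts; a dedicated test drives worlds with
forced-inert sectors through the whole chain.

**Inversion strategy.** For small systems the explicit block inverses are
formed; above a configurable side (`solve_side_threshold`, default 2048)
the footprint solves one linear system per demand column instead. The two
paths agree to 1e-10 (relative) by contract and by test.

## Spatial allocation

National footprints are downscaled with the proportionality assumption:
the land use driven by consumer $s$ in producer $r$ is spread over $r$'s
grid cells in proportion to the observed production pattern of that
product and land-use category,

$$
R^s_m(n) \;=\; \sum_{r,i} F^s_{r,i,m}\,
  \frac{R^r_{i,m}(n)}{\sum_{n'} R^r_{i,m}(n')}.
$$

Shares are normalized per (producer, product, category) layer; a positive
land-extension entry whose raster layer is empty is an *allocation gap*
and raises an error naming the offending layers rather than silently
dropping land. Allocation conserves every (consumer, producer, category)
marginal of the footprint tensor, and is invariant to layer ordering and
to refining cells into halves — both properties are tested.

KBA membership is binary per cell (center-point rule); the KBA split is
an exact cellwise partition, so KBA plus non-KBA losses reproduce totals
for every slice. Country attribution comes solely from the country
raster; cross-border polygon effects are out of scope.

## From land to species loss

Characterization factors give the potential global species loss per m² of
a land-use category in an ecoregion: species-equivalents committed to
extinction over the long term (including extinction debt) if the land use
persists, for five taxa (mammals, amphibians, reptiles, birds, plants)
across five land-use types × three intensities = 15 categories. CFs are
consumed as data; *average* (not marginal) CFs are assumed, appropriate
for large departures from natural habitat. Every cell of an ecoregion
carries the ecoregion's CF. Cell-level loss is then

$$
SL^s_{g,m,n} \;=\; CF_{g,m,\mathrm{eco}(n)} \cdot F^s_{m,n},
$$

and all reported quantities — production- vs consumption-based country
accounts, per-capita values, embodied trade flows, final-product
attribution — are sums of this product over index subsets. The vectorized
computation is checked against an explicit per-cell, per-taxon loop.

Missing CFs for cells that carry land are an error by default
(`missing_cf = "strict"`); a permissive zero-fill mode reports the
coverage gap instead. Vertebrate results are the plain sum of the four
class-level losses (species-equivalents are additive); plants are
reported separately. Relative losses are computed against global species
numbers per taxon.

**Final-product attribution** follows the product the consumer buys:
physical products for food demand and monetary products for nonfood
demand (the consumer-facing category, not the biomass input). By
linearity this is computed exactly, one final product at a time, and the
group sums partition the total loss.

## Four-factor decomposition and CTV

For country $r$ and taxon $g$, species loss inside KBAs factorizes as

$$
SL_{r,g} = A_r \cdot \frac{L_r}{A_r} \cdot \frac{S_{r,g}}{L_r}
          \cdot \frac{SL_{r,g}}{S_{r,g}},
$$

with $A_r$ the KBA area, $L_r$ the anthropogenic land-use area within
KBAs and $S_{r,g}$ the species richness of the occupied land (richness
per unit area constant within an ecoregion; $S_{r,g}$ is accumulated
cell-by-cell as density × occupied area over the country's KBA cells).
The chain is an exact identity wherever all denominators are positive,
and the package verifies the reconstruction on every generated world.
Countries with any undefined factor (e.g. no land use inside KBAs) are
flagged and excluded listwise from the CTV step, because the
multiplicative chain breaks at zero denominators.

CTV is computed from Spearman rank correlations $R_d$ between each factor
and $SL$ across countries — rank-based because these variables are far
from normal — and reported as the normalized share
$\mathrm{CTV}_d = R_d^2 / \sum_{d'} R_{d'}^2 \times 100$. The
$R^2$-share normalization is one established reading of CTV and is
adopted here as the package's definition. Ties receive average ranks
(the standard Spearman convention).

Two numerical choices deserve note:

* **Near-constant factors.** A factor that is constant by construction
  accumulates relative spreads of order 1e-16 through the pipeline. Rank
  statistics would amplify that noise into an arbitrary correlation, so
  factors whose relative spread falls below `var_tol` (default 1e-9) are
  treated as constant: correlation undefined, contribution zero.
* **Zero-variance factors** contribute 0 with a warning rather than an
  error; only an all-undefined correlation set is an analysis error.

## The synthetic world

`generate_world()` draws a complete dataset whose structure mirrors the
coupled systems used in real applications — at full scale a 192 × 128
physical system and a 49 × 200 monetary system; here at toy sizes
(defaults: 4 countries × 3 products physical, 3 regions × 4 products
monetary with one rest-of-world composite, a 12 × 16 grid at nominal
5-arcmin resolution, 4 ecoregions, 30% KBA coverage).

Key construction choices:

* **Balance by residual closure.** Coefficient blocks are drawn first and
  rescaled to the target spectral radius (default 0.45; productive
  economies require < 1), total final demand is drawn, and total output
  solves the Leontief system — so the balance identity
  $x = Z\,\mathbf{1} + y\,\mathbf{1}$ holds exactly and the conservation
  invariants are meaningful rather than approximate.
* **Trade topology.** `random` (domestic-biased), `autarky` (no
  cross-country flows anywhere) and `single-exporter` are supported;
  cross-region coefficients are damped tenfold and final demand is
  domestic-biased, which yields food shares near 70% and embodied trade
  shares near 35–40% on default draws — the qualitative structure of
  real accounts, where food dominates land use and most consumption is
  domestic.
* **Land rasters before extensions.** Per-cell land use is drawn first
  (bounded by a configurable fraction of the cell area, so land inside
  KBAs can never exceed KBA area) and the land extension is its exact
  column sum; rasters and extension are consistent by construction and
  verified by `balance_check()`.
* **CFs.** Log-uniform within per-taxon ranges (plants an order of
  magnitude above vertebrates) and made intensity-monotone (intense ≥
  light ≥ minimal within a type and ecoregion) by sorting — the
  qualitative structure of intensity-dependent CFs without copying any
  external values.
* **One seed.** All randomness flows from a single seed; two calls with
  the same configuration are bit-identical, and the file-based pipeline
  is byte-identical across reruns.

Planted scenarios fix enough structure for closed-form expectations:
`single-chain` (one consumer, one producer, one product on all-KBA cells:
loss = land × CF exactly, trade share 100%), `no-trade` (trade share 0),
`uniform-cf` (loss ratios equal land ratios) and `one-driver-ctv` (30
countries whose KBA area is the only varying factor: CTV = 100/0/0/0).
The four-codriver scenario is planted at the decomposition level:
log-loss is standard normal across 200 countries and each log factor is
a quarter of it plus centered independent noise (scale 0.08), so the
factor product reconstructs the loss exactly and the four factors have
equal rank-correlation strength (≈ 0.96) by exchangeability — realizing
equal continuous co-drivers through boolean per-cell KBA masks would
quantize the factors, which is why this scenario does not pass through
the raster stage.

### What the generator does *not* emulate

Statistical realism of real IO marginals, realistic geography, partial
cell coverage of KBAs, price layers, supply-use transformations and
non-proportional (e.g. road-density based) export allocation are all out
of scope. Passing tests therefore demonstrate the *accounting machinery*
— conservation, attribution, decomposition, determinism — not the
empirical accuracy of any real-world number. Real applications would
substitute observed IO tables, land-use rasters, CF tables and KBA
boundaries for the generated ones.

## Worked example

```{r example, eval = FALSE}
world <- generate_world(world_config(seed = 1))
economy <- world_economy(world)
footprint <- consumption_footprint(economy, world$extension,
                                   world$phys$y, world$mon$y)
shares <- normalize_distribution(world$grid, world$extension)
grid <- allocate_land(footprint, shares, world$masks)
account <- species_loss(grid, world$cfs, world$masks,
                        footprint = footprint, shares = shares)
trade_flows(account)$trade_share
product_attribution(account)$food_share
dec <- decompose_kba_loss(account, grid, world$masks, world$cfs)
ctv(dec)
```

The same chain runs file-to-file via `run_pipeline(world_config(seed = 1),
"out")`, which writes every stage's inputs and outputs as CSV plus a
hash manifest.

## Problem sizes and tolerances

The test-suite and acceptance computations use worlds of up to 5 × 4
physical sectors, 50-cell-wide grids for the cell-loop oracle, 100
random economies (coupled side ≤ 50) for the inversion oracle and 200
countries for the co-driver CTV scenario; together they run in well
under a minute on one core, and the sizes exercise every code path
(composite regions, inert sectors, all trade topologies). Conservation
checks default to 1e-9 relative tolerance (configurable); exact
identities (KBA partition, factor reconstruction, planted single-chain
recovery) hold to 1e-12 relative or better in practice.

## Known limitations

* CFs and richness densities are inputs; nothing upstream of them
  (species–area relationships, vulnerability scoring) is modelled.
* The block-triangular reading forbids physical products re-entering the
  physical system through monetary sectors; if such feedback exists in a
  dataset it is ignored by construction.
* Grouping of final-demand categories (households vs capital etc.) is
  caller-defined; the package treats demand matrix columns as given.
* The CTV normalization is one defensible reading of
  contribution-to-variance; results should be reported together with the
  underlying rank correlations (`ctv()$rho`), which the package returns.
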