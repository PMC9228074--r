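# Synthetic-world generator: balanced toy economies, land-use rasters,
# ecoregion characterization factors, KBA masks and populations with known
# ground truth, so every pipeline stage is testable without external data.
#
# Construction order guarantees the balance identity x = Z 1 + y 1 exactly:
# coefficient blocks are drawn first and rescaled to the target spectral
# radius, total final demand is drawn, and total output is obtained by
# solving the Leontief system, after which Z = A diag(x). Final demand is
# then split over consumer columns (the split never affects balance).

#' Synthetic-world configuration
#'
#' Defaults describe the toy study conditions: a 4-country, 3-product
#' physical system coupled to a 3-region, 4-product monetary system (one
#' rest-of-world composite), a 12 x 16 grid at nominal 5-arcmin resolution,
#' 4 ecoregions, 30% KBA coverage and a productive economy with spectral
#' radius 0.45.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_phys_regions,n_phys_products physical system size.
#' @param n_mon_regions,n_mon_products monetary system size;
#'   `n_mon_regions <= n_phys_regions`, the last monetary region absorbs the
#'   remaining physical regions as a rest-of-world composite.
#' @param grid_nrow,grid_ncol raster dimensions; `grid_ncol` must be at
#'   least `n_phys_regions` (countries are contiguous column bands).
#' @param cell_area_m2 constant cell area.
#' @param n_ecoregions number of ecoregions (contiguous row bands).
#' @param kba_fraction fraction of each country's cells flagged KBA.
#' @param trade_topology `"random"`, `"autarky"` (no cross-country flows in
#'   Z, link or y) or `"single-exporter"` (only country 1 exports).
#' @param trade_density expected fraction of admissible coefficient entries
#'   that are nonzero.
#' @param target_rho target spectral radius of the coupled coefficient
#'   matrix, in (0, 1).
#' @param occupied_fraction fraction of each country's cells carrying
#'   anthropogenic land use.
#' @param max_cell_land_fraction upper bound on the used fraction of a
#'   cell's area.
#' @param population_range min/max regional population.
#' @param cf_range_plants,cf_range_vertebrates log-uniform CF ranges
#'   (species lost per m2).
#' @param zero_output_sectors number of physical sectors forced inert (zero
#'   output, zero flows) to exercise empty country-product cells.
#' @return An object of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_phys_regions = 4L, n_phys_products = 3L,
                         n_mon_regions = 3L, n_mon_products = 4L,
                         grid_nrow = 12L, grid_ncol = 16L,
                         cell_area_m2 = 8.6e7,
                         n_ecoregions = 4L,
                         kba_fraction = 0.3,
                         trade_topology = c("random", "autarky",
                                            "single-exporter"),
                         trade_density = 0.4,
                         target_rho = 0.45,
                         occupied_fraction = 0.6,
                         max_cell_land_fraction = 0.8,
                         population_range = c(1e6, 5e7),
                         cf_range_plants = c(1e-12, 1e-10),
                         cf_range_vertebrates = c(1e-13, 1e-11),
                         zero_output_sectors = 0L) {
  trade_topology <- match.arg(trade_topology)
  cfg <- list(seed = as.integer(seed),
              n_phys_regions = as.integer(n_phys_regions),
              n_phys_products = as.integer(n_phys_products),
              n_mon_regions = as.integer(n_mon_regions),
              n_mon_products = as.integer(n_mon_products),
              grid_nrow = as.integer(grid_nrow),
              grid_ncol = as.integer(grid_ncol),
              cell_area_m2 = cell_area_m2,
              n_ecoregions = as.integer(n_ecoregions),
              kba_fraction = kba_fraction,
              trade_topology = trade_topology,
              trade_density = trade_density,
              target_rho = target_rho,
              occupied_fraction = occupied_fraction,
              max_cell_land_fraction = max_cell_land_fraction,
              population_range = as.numeric(population_range),
              cf_range_plants = as.numeric(cf_range_plants),
              cf_range_vertebrates = as.numeric(cf_range_vertebrates),
              zero_output_sectors = as.integer(zero_output_sectors))
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  with(cfg, {
    if (n_phys_regions < 1 || n_phys_products < 1 ||
        n_mon_regions < 1 || n_mon_products < 1)
      abort_config("world_config: all counts must be >= 1")
    if (n_mon_regions > n_phys_regions)
      abort_config("world_config: n_mon_regions must not exceed n_phys_regions")
    if (target_rho <= 0 || target_rho >= 1)
      abort_config("world_config: target_rho must be in (0, 1)")
    if (kba_fraction < 0 || kba_fraction > 1)
      abort_config("world_config: kba_fraction must be in [0, 1]")
    if (grid_ncol < n_phys_regions)
      abort_config("world_config: grid_ncol must be >= n_phys_regions")
    if (n_ecoregions < 1 || n_ecoregions > grid_nrow)
      abort_config("world_config: n_ecoregions must be in 1..grid_nrow")
    if (occupied_fraction <= 0 || occupied_fraction > 1)
      abort_config("world_config: occupied_fraction must be in (0, 1]")
    if (zero_output_sectors >= n_phys_regions * n_phys_products)
      abort_config("world_config: cannot zero out every physical sector")
  })
  invisible(cfg)
}

# admissible cross-region pattern under a trade topology; rows/cols are
# region indices of the supplying and using sector
topology_allows <- function(topology, from_region, to_region) {
  switch(topology,
         "random" = rep_len(TRUE, max(length(from_region), length(to_region))),
         "autarky" = from_region == to_region,
         "single-exporter" = from_region == to_region | from_region == 1L)
}

# random non-negative coefficient block respecting topology, rescaled to the
# target spectral radius
random_coefficients <- function(n_regions, n_products, topology, density,
                                target_rho) {
  n <- n_regions * n_products
  region_of <- rep(seq_len(n_regions), each = n_products)
  A <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  keep <- matrix(stats::runif(n * n) < density, n, n)
  allowed <- outer(region_of, region_of,
                   function(f, t) topology_allows(topology, f, t))
  # keep the diagonal-block backbone so the matrix is not nilpotent and the
  # spectral radius can be scaled to the target
  diag(keep) <- TRUE
  # domestic supply chains dominate: damp cross-region coefficients
  cross <- outer(region_of, region_of, `!=`)
  A <- A * keep * allowed * ifelse(cross, 0.1, 1)
  r0 <- spectral_radius(A)
  if (r0 == 0) abort_config("random_coefficients(): degenerate draw")
  A * (target_rho / r0)
}

#' Generate a synthetic world
#'
#' Draws a complete dataset: physical and monetary IO tables (balanced by
#' construction), the biomass link table, land-use extension and rasters,
#' country/ecoregion/KBA masks, characterization factors and populations.
#' Deterministic for a fixed seed.
#'
#' @param config a [world_config()].
#' @return An object of class `synthetic_world` with fields `phys`, `mon`,
#'   `link`, `extension`, `grid`, `masks`, `cfs`, `population`,
#'   `concordance`, `config`.
#' @export
generate_world <- function(config) {
  if (!inherits(config, "world_config")) config <- do.call(world_config, config)
  set.seed(config$seed)
  n_r <- config$n_phys_regions; n_i <- config$n_phys_products
  n_u <- config$n_mon_regions; n_k <- config$n_mon_products
  regions <- sprintf("C%02d", seq_len(n_r))
  products <- sprintf("p%02d", seq_len(n_i))
  regions_mon <- c(sprintf("M%02d", seq_len(n_u - 1)),
                   if (n_u < n_r) "RoW" else sprintf("M%02d", n_u))
  products_mon <- sprintf("s%02d", seq_len(n_k))
  units <- stats::setNames(rep(c("tonnes", "heads", "m3"),
                               length.out = n_i), products)
  # concordance: 1:1 for the first n_u - 1 regions, remainder -> last
  concordance <- stats::setNames(
    regions_mon[pmin(seq_len(n_r), n_u)], regions)

  topo <- config$trade_topology
  A_phys <- random_coefficients(n_r, n_i, topo, config$trade_density,
                                config$target_rho)
  A_mon <- random_coefficients(n_u, n_k, topo, config$trade_density,
                               config$target_rho)

  # link block: physical inputs per unit monetary output, cross-region
  # pattern follows the topology through the concordance
  n_ps <- n_r * n_i; n_ms <- n_u * n_k
  region_of_phys <- rep(seq_len(n_r), each = n_i)
  monreg_of_phys <- match(concordance[regions[region_of_phys]], regions_mon)
  monreg_of_mon <- rep(seq_len(n_u), each = n_k)
  allowed <- outer(monreg_of_phys, monreg_of_mon,
                   function(f, t) topology_allows(topo, f, t))
  A_link <- matrix(stats::runif(n_ps * n_ms, 0.001, 0.01), n_ps, n_ms) *
    (matrix(stats::runif(n_ps * n_ms), n_ps, n_ms) < config$trade_density) *
    allowed * ifelse(outer(monreg_of_phys, monreg_of_mon, `!=`), 0.1, 1)

  # inert sectors: zero row and column in every block touching them
  zero_sectors <- integer(0)
  if (config$zero_output_sectors > 0) {
    zero_sectors <- sample(n_ps, config$zero_output_sectors)
    A_phys[zero_sectors, ] <- 0; A_phys[, zero_sectors] <- 0
    A_link[zero_sectors, ] <- 0
  }

  # totals first (residual closure), then flows
  y_mon_total <- stats::runif(n_ms, 2e2, 2e3)
  x_mon <- solve(diag(n_ms) - A_mon, y_mon_total)
  Z_mon <- A_mon * rep(x_mon, each = n_ms)
  Z_link <- A_link * rep(x_mon, each = n_ps)
  y_phys_total <- stats::runif(n_ps, 10, 100)
  y_phys_total[zero_sectors] <- 0
  x_phys <- solve(diag(n_ps) - A_phys,
                  as.vector(A_link %*% x_mon) + y_phys_total)
  Z_phys <- A_phys * rep(x_phys, each = n_ps)

  # split totals over consumer columns (domestic-biased random weights)
  split_demand <- function(total, n_cons, region_of_row, topology,
                           region_index_of_col = seq_len(n_cons)) {
    y <- matrix(0, length(total), n_cons)
    for (row in seq_along(total)) {
      if (total[row] == 0) next
      w <- stats::runif(n_cons, 0.1, 1)
      w <- w * (1 + 10 * (region_index_of_col == region_of_row[row]))
      ok <- vapply(region_index_of_col, function(t)
        topology_allows(topology, region_of_row[row], t), logical(1))
      w <- w * ok
      y[row, ] <- total[row] * w / sum(w)
    }
    y
  }
  y_phys <- split_demand(y_phys_total, n_r, region_of_phys, topo)
  y_mon <- split_demand(y_mon_total, n_u, monreg_of_mon, topo)

  phys <- physical_io(Z_phys, x_phys, y_phys, regions, products, units)
  mon <- monetary_io(Z_mon, x_mon, y_mon, regions_mon, products_mon)
  link <- link_table(Z_link, phys, mon)

  population <- stats::setNames(
    stats::runif(n_r, config$population_range[1], config$population_range[2]),
    regions)

  # --- grid, masks, land rasters -------------------------------------------
  geometry <- grid_geometry(config$grid_nrow, config$grid_ncol,
                            config$cell_area_m2)
  ncell <- geometry$ncell
  col_of <- rep(seq_len(config$grid_ncol), times = config$grid_nrow)
  row_of <- rep(seq_len(config$grid_nrow), each = config$grid_ncol)
  # countries: contiguous column bands; ecoregions: contiguous row bands
  country_id <- pmin(ceiling(col_of * n_r / config$grid_ncol), n_r)
  ecoregion_id <- pmin(ceiling(row_of * config$n_ecoregions / config$grid_nrow),
                       config$n_ecoregions)
  kba <- logical(ncell)
  for (r in seq_len(n_r)) {
    cells_r <- which(country_id == r)
    n_kba <- round(config$kba_fraction * length(cells_r))
    if (config$kba_fraction > 0 && length(cells_r) == 0)
      abort_config("generate_world(): kba_fraction set but country has no cells")
    if (n_kba > 0) kba[sample(cells_r, n_kba)] <- TRUE
  }
  ecoregions <- sprintf("E%02d", seq_len(config$n_ecoregions))
  masks <- cell_masks(country_id, ecoregion_id, kba, geometry,
                      regions, ecoregions)

  # land use per cell: each (region, product) with positive output uses 1-3
  # categories; occupied cells split a bounded fraction of their area
  categories <- land_use_categories()
  n_m <- length(categories)
  R <- array(0, c(ncell, n_r, n_i, n_m))
  x_ri <- t(matrix(x_phys, n_i, n_r))  # [region, product]
  for (r in seq_len(n_r)) {
    cells_r <- which(country_id == r)
    n_occ <- max(1L, round(config$occupied_fraction * length(cells_r)))
    occ <- sort(sample(cells_r, n_occ))
    active <- list()
    for (i in seq_len(n_i)) {
      if (x_ri[r, i] <= 0) next
      cats_i <- sample(n_m, sample(1:3, 1))
      for (m in cats_i) active[[length(active) + 1L]] <- c(i, m)
    }
    if (length(active) == 0) next
    for (n in occ) {
      frac <- stats::runif(1, 0.05, config$max_cell_land_fraction)
      w <- stats::runif(length(active), 0.1, 1)
      w <- w / sum(w)
      area <- frac * config$cell_area_m2
      for (a in seq_along(active))
        R[n, r, active[[a]][1], active[[a]][2]] <-
          R[n, r, active[[a]][1], active[[a]][2]] + area * w[a]
    }
  }
  d <- apply(R, c(2, 3, 4), sum)
  grid <- land_use_grid(R, geometry, regions, products, categories)
  extension <- land_extension(d, x_phys, regions, products, categories)

  # --- characterization factors --------------------------------------------
  cfs <- random_cf_table(config, ecoregions)

  structure(list(
    phys = phys, mon = mon, link = link, extension = extension,
    grid = grid, masks = masks, cfs = cfs, population = population,
    concordance = concordance, config = config
  ), class = "synthetic_world")
}

# CFs log-uniform within per-taxon ranges, made intensity-monotone (intense
# >= light >= minimal within a type and ecoregion) by sorting; richness
# densities log-uniform with plants an order of magnitude richer.
random_cf_table <- function(config, ecoregions) {
  taxa <- taxa_names()
  categories <- land_use_categories()
  n_eco <- length(ecoregions)
  cf <- array(0, c(length(taxa), length(categories), n_eco))
  log_unif <- function(n, range)
    exp(stats::runif(n, log(range[1]), log(range[2])))
  for (g in seq_along(taxa)) {
    range <- if (taxa[g] == "plants") config$cf_range_plants
             else config$cf_range_vertebrates
    for (e in seq_len(n_eco)) {
      for (ty in seq_along(land_use_types())) {
        idx <- (ty - 1L) * 3L + 1:3   # minimal, light, intense
        cf[g, idx, e] <- sort(log_unif(3, range))
      }
    }
  }
  rich <- matrix(0, length(taxa), n_eco)
  for (g in seq_along(taxa)) {
    scale <- if (taxa[g] == "plants") c(1e-9, 1e-8) else c(1e-10, 1e-9)
    rich[g, ] <- log_unif(n_eco, scale)
  }
  cf_table(cf, rich, taxa = taxa, categories = categories,
           ecoregions = ecoregions)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> seed ", x$config$seed, ": ",
      length(x$phys$regions), "x", length(x$phys$products), " physical + ",
      length(x$mon$regions), "x", length(x$mon$products), " monetary, grid ",
      x$masks$geometry$nrow, "x", x$masks$geometry$ncol, ", topology ",
      x$config$trade_topology, "\n", sep = "")
  invisible(x)
}

#' Balance and consistency report for a synthetic world
#'
#' Verifies sector balance (`x = Z 1 + y 1`, with the link flows on the
#' physical side), productiveness (spectral radius of the coupled
#' coefficient matrix below one), raster-extension consistency (every layer
#' sums to its extension entry and stays inside its country), and mask
#' consistency (every cell with land has a country and an ecoregion).
#'
#' @param world a [generate_world()] result.
#' @param tol relative tolerance for balance checks.
#' @return An object of class `balance_report`: data.frame `checks` with
#'   `name`, `pass`, `detail`, and overall `pass`.
#' @export
balance_check <- function(world, tol = 1e-9) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      name = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  phys <- world$phys; mon <- world$mon
  lhs <- phys$x
  rhs <- rowSums(phys$Z) + rowSums(world$link$Z) + rowSums(phys$y)
  bad <- which(rel_diff(lhs, rhs) > tol)
  add("physical_balance", length(bad) == 0,
      if (length(bad)) paste("unbalanced:", paste(phys$sectors[utils::head(bad, 5)],
                                                  collapse = ", ")) else "")
  lhs <- mon$x; rhs <- rowSums(mon$Z) + rowSums(mon$y)
  bad <- which(rel_diff(lhs, rhs) > tol)
  add("monetary_balance", length(bad) == 0,
      if (length(bad)) paste("unbalanced:", paste(mon$sectors[utils::head(bad, 5)],
                                                  collapse = ", ")) else "")
  A_phys <- technical_coefficients(phys$Z, phys$x)
  A_mon <- technical_coefficients(mon$Z, mon$x)
  rho <- max(spectral_radius(A_phys), spectral_radius(A_mon))
  add("productive", rho < 1, sprintf("spectral radius %.6f", rho))
  layer_sums <- apply(world$grid$R, c(2, 3, 4), sum)
  add("raster_extension_consistency",
      max(rel_diff(layer_sums, world$extension$d)) <= tol,
      sprintf("max rel diff %.3e", max(rel_diff(layer_sums, world$extension$d))))
  ok_support <- TRUE
  for (r in seq_along(phys$regions)) {
    if (any(world$grid$R[world$masks$country_id != r, r, , ] > 0)) {
      ok_support <- FALSE; break
    }
  }
  add("raster_country_support", ok_support,
      if (!ok_support) paste("layer support outside", phys$regions[r]) else "")
  land_cells <- apply(world$grid$R, 1, sum) > 0
  add("mask_coverage",
      all(world$masks$country_id[land_cells] > 0) &&
        all(world$masks$ecoregion_id[land_cells] > 0), "")
  checks <- do.call(rbind, checks)
  structure(list(checks = checks, pass = all(checks$pass)),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  status <- ifelse(x$checks$pass, "ok", "FAIL")
  cat(sprintf("%-30s %s %s\n", x$checks$name, status, x$checks$detail),
      sep = "")
  invisible(x)
}

#' Build the hybrid economy of a synthetic world
#'
#' Convenience wrapper: technical coefficients of all three blocks plus
#' [assemble_hybrid()].
#'
#' @param world a [generate_world()] result.
#' @return A `hybrid_economy`.
#' @export
world_economy <- function(world) {
  A_phys <- technical_coefficients(world$phys$Z, world$phys$x)
  A_mon <- technical_coefficients(world$mon$Z, world$mon$x)
  A_link <- technical_coefficients(world$link$Z, world$mon$x)
  assemble_hybrid(A_phys, A_link, A_mon, world$concordance,
                  world$population,
                  world$phys$regions, world$phys$products,
                  world$mon$regions, world$mon$products)
}
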