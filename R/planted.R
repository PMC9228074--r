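# Planted scenarios: worlds with closed-form expected results, used to test
# every pipeline stage against known ground truth.

#' Generate a planted scenario
#'
#' Each scenario fixes enough structure that key pipeline outputs have
#' closed-form expectations, returned alongside the world:
#'
#' * `"no-trade"`: autarky world with identity region concordance; expected
#'   trade share 0 for every taxon.
#' * `"single-chain"`: country A's sole demand is for country B's single
#'   product, grown only on B's KBA cells in one ecoregion with uniform CF
#'   `c`; expected species loss is exactly `land x CF`, attributed 100% to
#'   the single consumer and product, trade share 100%.
#' * `"uniform-cf"`: random world with CFs constant across categories and
#'   ecoregions per taxon; expected country loss ratios equal land-use
#'   ratios.
#' * `"one-driver-ctv"`: 30 autarkic countries whose KBA area increases
#'   strictly while the other three decomposition factors are constant;
#'   expected CTV (100, 0, 0, 0).
#'
#' @param name scenario name.
#' @param config optional [world_config()] overridden as the scenario
#'   requires; scenarios with hand-built structure ignore most of it.
#' @return List with `world`, `expected` (a named list of closed-form
#'   values) and `name`.
#' @export
planted_scenario <- function(name = c("no-trade", "single-chain",
                                      "uniform-cf", "one-driver-ctv"),
                             config = NULL) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort_config(
                     paste0("planted_scenario(): unknown scenario '",
                            name[1], "'")))
  switch(name,
         "no-trade" = scenario_no_trade(config),
         "single-chain" = scenario_single_chain(config),
         "uniform-cf" = scenario_uniform_cf(config),
         "one-driver-ctv" = scenario_one_driver(config))
}

scenario_no_trade <- function(config) {
  config <- config %||% world_config()
  cfg <- as.list(config)
  cfg$trade_topology <- "autarky"
  cfg$n_mon_regions <- cfg$n_phys_regions  # identity concordance: exact autarky
  world <- generate_world(do.call(world_config, cfg))
  list(world = world, name = "no-trade",
       expected = list(trade_share = stats::setNames(
         rep(0, length(taxa_names())), taxa_names())))
}

scenario_uniform_cf <- function(config) {
  config <- config %||% world_config()
  world <- generate_world(config)
  taxa <- world$cfs$taxa
  cf_levels <- stats::setNames(
    vapply(taxa, function(g)
      mean(world$cfs$cf[match(g, taxa), , ]), numeric(1)), taxa)
  cf <- world$cfs$cf
  for (g in seq_along(taxa)) cf[g, , ] <- cf_levels[g]
  world$cfs <- cf_table(cf, world$cfs$richness_per_m2,
                        world$cfs$taxon_totals, taxa,
                        world$cfs$categories, world$cfs$ecoregions)
  list(world = world, name = "uniform-cf",
       expected = list(cf_levels = cf_levels,
                       land_by_producer = apply(world$extension$d, 1, sum)))
}

scenario_single_chain <- function(config) {
  cell_area <- 8.6e7
  regions <- c("A", "B"); products <- "p01"
  geometry <- grid_geometry(2, 4, cell_area)
  # columns 1-2 belong to A, 3-4 to B; all of B's cells are KBA
  country_id <- rep(c(1L, 1L, 2L, 2L), times = 2)
  ecoregion_id <- rep(1L, geometry$ncell)
  kba <- country_id == 2L
  masks <- cell_masks(country_id, ecoregion_id, kba, geometry,
                      regions, "E01")
  q <- 50                      # tonnes of B's product, demanded only by A
  land <- 1.2e8                # m2 of cropland, minimal intensity
  category <- "cropland:minimal"
  categories <- land_use_categories()
  m0 <- match(category, categories)
  Z_phys <- matrix(0, 2, 2)
  x_phys <- c(0, q)            # sector order: A_p01, B_p01
  y_phys <- matrix(0, 2, 2); y_phys[2, 1] <- q
  phys <- physical_io(Z_phys, x_phys, y_phys, regions, products,
                      stats::setNames("tonnes", products))
  # trivial monetary side with no biomass link
  Z_mon <- matrix(0, 1, 1); x_mon <- 1
  y_mon <- matrix(1, 1, 1)
  mon <- monetary_io(Z_mon, x_mon, y_mon, "M01", "s01")
  link <- link_table(matrix(0, 2, 1), phys, mon)
  d <- array(0, c(2, 1, length(categories)))
  d[2, 1, m0] <- land
  extension <- land_extension(d, x_phys, regions, products, categories)
  R <- array(0, c(geometry$ncell, 2, 1, length(categories)))
  b_cells <- which(country_id == 2L)
  R[b_cells, 2, 1, m0] <- land / length(b_cells)
  grid <- land_use_grid(R, geometry, regions, products, categories)
  cf_value <- stats::setNames(c(2e-11, 3e-11, 4e-11, 5e-11, 1e-9),
                              taxa_names())
  cf <- array(rep(cf_value, length(categories)),
              c(5, length(categories), 1))
  rich <- matrix(1e-9, 5, 1)
  cfs <- cf_table(cf, rich, taxa = taxa_names(), categories = categories,
                  ecoregions = "E01")
  world <- structure(list(
    phys = phys, mon = mon, link = link, extension = extension,
    grid = grid, masks = masks, cfs = cfs,
    population = c(A = 1e6, B = 1e6),
    concordance = c(A = "M01", B = "M01"),
    config = NULL
  ), class = "synthetic_world")
  list(world = world, name = "single-chain",
       expected = list(
         species_loss = cf_value * land,
         consumer = "A", producer = "B", product = "p01",
         category = category,
         trade_share = stats::setNames(rep(1, 5), taxa_names()),
         kba_share = 1))
}

scenario_one_driver <- function(config) {
  n_c <- 30L
  regions <- sprintf("C%02d", seq_len(n_c))
  products <- "p01"
  categories <- land_use_categories()
  m0 <- match("pasture:light", categories)
  cell_area <- 8.6e7
  ncol <- n_c + 1L
  geometry <- grid_geometry(n_c, ncol, cell_area)
  # country r occupies grid row r; its first r cells are KBA
  country_id <- rep(seq_len(n_c), each = ncol)
  col_of <- rep(seq_len(ncol), times = n_c)
  kba <- col_of <= country_id
  ecoregion_id <- rep(1L, geometry$ncell)
  masks <- cell_masks(country_id, ecoregion_id, kba, geometry,
                      regions, "E01")
  land_per_cell <- 0.4 * cell_area   # constant -> constant share factor
  # autarkic economy with no intermediates: x = y, e = d / x
  x_phys <- rep(100, n_c)
  y_phys <- diag(100, n_c)
  phys <- physical_io(matrix(0, n_c, n_c), x_phys, y_phys, regions,
                      products, stats::setNames("tonnes", products))
  mon <- monetary_io(matrix(0, 1, 1), 1, matrix(1, 1, 1), "M01", "s01")
  link <- link_table(matrix(0, n_c, 1), phys, mon)
  R <- array(0, c(geometry$ncell, n_c, 1, length(categories)))
  for (r in seq_len(n_c)) {
    cells <- which(country_id == r & kba)
    R[cells, r, 1, m0] <- land_per_cell
  }
  d <- apply(R, c(2, 3, 4), sum)
  extension <- land_extension(d, x_phys, regions, products, categories)
  grid <- land_use_grid(R, geometry, regions, products, categories)
  cf_value <- stats::setNames(c(2e-11, 3e-11, 4e-11, 5e-11, 1e-9),
                              taxa_names())
  cf <- array(rep(cf_value, length(categories)),
              c(5, length(categories), 1))
  cfs <- cf_table(cf, matrix(1e-9, 5, 1), taxa = taxa_names(),
                  categories = categories, ecoregions = "E01")
  world <- structure(list(
    phys = phys, mon = mon, link = link, extension = extension,
    grid = grid, masks = masks, cfs = cfs,
    population = stats::setNames(rep(1e6, n_c), regions),
    concordance = stats::setNames(rep("M01", n_c), regions),
    config = NULL
  ), class = "synthetic_world")
  expected_ctv <- matrix(0, 4, 6)
  expected_ctv[1, ] <- 100
  list(world = world, name = "one-driver-ctv",
       expected = list(ctv = expected_ctv,
                       driver = "area_of_kbas"))
}

#' Planted four-codriver decomposition
#'
#' Constructs a country decomposition in which the four multiplicative
#' factors are independently planted monotone co-drivers of species loss
#' with equal rank-correlation strength: log SL is standard normal across
#' countries and each log factor is `log(SL)/4` plus centered independent
#' noise, so the factor product reconstructs SL exactly and each factor has
#' the same (strong) rank correlation with SL by exchangeability. The share
#' factor is rescaled into (0, 1] (a monotone transformation, invisible to
#' rank correlations) so the KBA-area bound holds.
#'
#' @param n_countries number of countries.
#' @param seed integer seed.
#' @param sigma noise scale on the log factors; the default keeps each
#'   factor's rank correlation with SL near 0.96, so the planted equal
#'   strengths dominate rank-sampling noise at a few hundred countries.
#' @return List with `decomposition` (single-taxon) and `expected` (CTV of
#'   25 per factor).
#' @export
planted_ctv_codrivers <- function(n_countries = 200L, seed = 1L,
                                  sigma = 0.08) {
  set.seed(seed)
  n <- as.integer(n_countries)
  log_sl <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * 4, sd = sigma), n, 4)
  eps <- eps - rowMeans(eps)            # noises sum to zero per country
  logf <- log_sl / 4 + eps              # product of factors == SL exactly
  f <- exp(logf)
  sl <- exp(log_sl)
  # rescale the share factor into (0, 1]; compensate in the relative-loss
  # factor to keep the product intact (both changes are monotone)
  scale_share <- 0.9 / max(f[, 2])
  f[, 2] <- f[, 2] * scale_share
  f[, 4] <- f[, 4] / scale_share
  A <- f[, 1]
  L <- A * f[, 2]
  S <- L * f[, 3]
  sl_chk <- S * f[, 4]
  stopifnot(max(abs(sl_chk - sl) / sl) < 1e-12)
  dec <- country_decomposition(
    kba_area = A, land_use = L,
    richness = matrix(S, ncol = 1), species_loss = matrix(sl, ncol = 1),
    regions = sprintf("C%03d", seq_len(n)), taxa = "plants")
  list(decomposition = dec,
       expected = list(ctv = rep(25, 4)))
}
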