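# Biodiversity accounting: characterization factors, species-loss accounts,
# production/consumption perspectives, per-capita values, embodied trade
# flows and final-product attribution.
#
# Characterization factors (CFs) give the potential global species loss per
# m2 of a land-use category in an ecoregion: species-equivalents committed to
# extinction in the long run if the land use persists. Every cell of an
# ecoregion carries that ecoregion's CF; species loss in a cell is
# CF[taxon, category, ecoregion(cell)] * allocated land[consumer, category,
# cell], and all reported quantities are sums of that product over index
# subsets.

#' Characterization-factor table
#'
#' @param cf numeric array `[taxon, category, ecoregion]`, potential global
#'   species lost per m2 of land occupation. Average (not marginal) CFs are
#'   assumed, appropriate for large departures from natural habitat.
#' @param richness_per_m2 numeric array `[taxon, ecoregion]`, species
#'   richness per m2 of occupied land (constant within an ecoregion); used by
#'   the country-level decomposition.
#' @param taxon_totals named numeric vector of global species numbers per
#'   taxon, for relative-loss reporting.
#' @param taxa,categories,ecoregions dimension labels.
#' @return An object of class `cf_table`.
#' @export
cf_table <- function(cf, richness_per_m2, taxon_totals = default_taxon_totals(),
                     taxa = taxa_names(),
                     categories = land_use_categories(),
                     ecoregions = NULL) {
  cf <- as.array(cf)
  if (is.null(ecoregions)) ecoregions <- dimnames(cf)[[3]] %||%
      paste0("E", seq_len(dim(cf)[3]))
  if (!all(dim(cf) == c(length(taxa), length(categories), length(ecoregions))))
    abort_structural("cf_table: cf must be [taxon, category, ecoregion]")
  if (any(cf < 0, na.rm = TRUE))
    abort_validation("cf_table: negative CFs not allowed")
  richness_per_m2 <- as.matrix(richness_per_m2)
  if (!all(dim(richness_per_m2) == c(length(taxa), length(ecoregions))))
    abort_structural("cf_table: richness_per_m2 must be [taxon, ecoregion]")
  if (!all(taxa %in% names(taxon_totals)))
    abort_validation("cf_table: taxon_totals missing some taxa")
  dimnames(cf) <- list(taxon = taxa, category = categories,
                       ecoregion = ecoregions)
  dimnames(richness_per_m2) <- list(taxon = taxa, ecoregion = ecoregions)
  structure(list(cf = cf, richness_per_m2 = richness_per_m2,
                 taxon_totals = taxon_totals[taxa], taxa = taxa,
                 categories = categories, ecoregions = ecoregions),
            class = "cf_table")
}

# CF per cell: [taxon, category, cell]; cells without an ecoregion get 0.
cf_raster <- function(cfs, masks) {
  n_g <- length(cfs$taxa); n_m <- length(cfs$categories)
  ncell <- masks$geometry$ncell
  out <- array(0, c(n_g, n_m, ncell),
               dimnames = list(taxon = cfs$taxa, category = cfs$categories,
                               cell = NULL))
  has_eco <- masks$ecoregion_id > 0
  out[, , has_eco] <- cfs$cf[, , masks$ecoregion_id[has_eco]]
  out
}

#' Species loss from allocated land use
#'
#' Multiplies the allocated land-use grid by the cellwise CF view and
#' aggregates to a species-loss account indexed by taxon, consumer, producer
#' (the cell's country), land-use category and KBA membership. Food and
#' nonfood provenance partitions are carried through. When the footprint and
#' share grids are supplied, losses are additionally attributed to the final
#' product purchased (food: physical products; nonfood: monetary products).
#'
#' @param grid an [allocate_land()] result.
#' @param cfs a [cf_table()].
#' @param masks a [cell_masks()] on the same geometry.
#' @param footprint,shares optional; enable final-product attribution.
#' @param missing_cf `"strict"` errors when a cell with allocated land lacks
#'   an ecoregion or has an undefined (NA) CF; `"zero"` treats such CFs as
#'   zero and reports the coverage gap.
#' @param retain_cells keep the cell-level loss array (taxon x consumer x
#'   category x cell) on the account.
#' @return An object of class `species_loss_account`.
#' @export
species_loss <- function(grid, cfs, masks, footprint = NULL, shares = NULL,
                         missing_cf = c("strict", "zero"),
                         retain_cells = FALSE) {
  missing_cf <- match.arg(missing_cf)
  if (!same_geometry(grid$geometry, masks$geometry))
    abort_structural("species_loss(): grid and masks geometry differ")
  if (!identical(grid$categories, cfs$categories))
    abort_structural("species_loss(): category labels differ")
  ncell <- grid$geometry$ncell
  land_in_cell <- apply(grid$total, 3, sum)
  cfc <- cf_raster(cfs, masks)
  gap_cells <- land_in_cell > 0 &
    (masks$ecoregion_id == 0 | apply(is.na(cfc), 3, any))
  if (any(gap_cells)) {
    if (missing_cf == "strict")
      abort_coverage(sprintf(
        "species_loss(): %d cells with land have no defined CF", sum(gap_cells)))
  }
  cfc[is.na(cfc)] <- 0
  n_g <- length(cfs$taxa); n_s <- length(grid$consumers)
  n_m <- length(grid$categories); n_r <- length(masks$regions)

  # cell-level loss per provenance source: SL[g, s, m, n]
  cell_loss <- function(G) {
    arr <- array(0, c(n_g, n_s, n_m, ncell),
                 dimnames = list(taxon = cfs$taxa, consumer = grid$consumers,
                                 category = grid$categories, cell = NULL))
    for (g in seq_len(n_g))
      arr[g, , , ] <- G * array(rep(cfc[g, , ], each = n_s),
                                dim = c(n_s, n_m, ncell))
    arr
  }
  # zonal aggregation to [g, s, r, m, kba]
  zonal <- function(SLc) {
    ind <- matrix(0, ncell, 2L * n_r)
    has <- masks$country_id > 0
    inside <- has & masks$kba
    outside <- has & !masks$kba
    ind[cbind(which(inside), masks$country_id[inside])] <- 1
    ind[cbind(which(outside), n_r + masks$country_id[outside])] <- 1
    flat <- matrix(SLc, nrow = n_g * n_s * n_m, ncol = ncell)
    z <- flat %*% ind
    arr <- array(z, c(n_g, n_s, n_m, n_r, 2L))
    arr <- aperm(arr, c(1L, 2L, 4L, 3L, 5L))
    dimnames(arr) <- list(taxon = cfs$taxa, consumer = grid$consumers,
                          producer = masks$regions,
                          category = grid$categories,
                          kba = c("inside", "outside"))
    arr
  }
  slc_food <- cell_loss(grid$food)
  slc_nonfood <- cell_loss(grid$nonfood)
  food <- zonal(slc_food)
  nonfood <- zonal(slc_nonfood)

  by_product <- NULL
  if (!is.null(footprint) && !is.null(shares)) {
    lf <- loss_factors(shares, cfs, masks)  # [g, r, i, m, kba]
    contract <- function(bp) {
      if (is.null(bp)) return(NULL)
      n_fp <- dim(bp)[1]
      bs <- apply(bp, c(1, 3, 4, 5), sum)  # [final_product, r, i, m]
      flat_b <- matrix(bs, nrow = n_fp)
      out <- array(0, c(n_g, n_fp, 2L),
                   dimnames = list(taxon = cfs$taxa,
                                   final_product = dimnames(bp)[[1]],
                                   kba = c("inside", "outside")))
      for (k in 1:2) {
        flat_l <- matrix(lf[, , , , k], nrow = n_g)
        out[, , k] <- flat_l %*% t(flat_b)
      }
      out
    }
    by_product <- list(food = contract(footprint$by_product_food),
                       nonfood = contract(footprint$by_product_nonfood))
  }

  structure(list(
    food = food, nonfood = nonfood, total = food + nonfood,
    by_product = by_product,
    taxa = cfs$taxa, taxon_totals = cfs$taxon_totals,
    consumers = grid$consumers, producers = masks$regions,
    categories = grid$categories,
    coverage_gap_cells = sum(gap_cells),
    cells = if (retain_cells) list(food = slc_food, nonfood = slc_nonfood)
            else NULL
  ), class = "species_loss_account")
}

# Per-unit-footprint loss factors: lf[g, r, i, m, kba] =
# sum_n share[n|r,i,m] * CF[g, m, eco(n)] * [kba status of n]. Footprint on
# layer (r,i,m) times lf gives the species loss of that slice, which is what
# final-product attribution contracts against.
loss_factors <- function(shares, cfs, masks) {
  cfc <- cf_raster(cfs, masks)
  cfc[is.na(cfc)] <- 0
  n_g <- length(cfs$taxa)
  n_r <- length(shares$regions); n_i <- length(shares$products)
  n_m <- length(shares$categories)
  ncell <- shares$geometry$ncell
  out <- array(0, c(n_g, n_r, n_i, n_m, 2L),
               dimnames = list(taxon = cfs$taxa, producer = shares$regions,
                               product = shares$products,
                               category = shares$categories,
                               kba = c("inside", "outside")))
  masks_list <- list(masks$kba, !masks$kba)
  for (k in 1:2) {
    w <- as.numeric(masks_list[[k]])
    for (m in seq_len(n_m)) {
      Sm <- matrix(shares$shares[, , , m], nrow = ncell, ncol = n_r * n_i)
      cfm <- cfc[, m, , drop = FALSE]
      dim(cfm) <- c(n_g, ncell)
      lfm <- (cfm * rep(w, each = n_g)) %*% Sm   # [g, r*i]
      out[, , , m, k] <- array(lfm, c(n_g, n_r, n_i))
    }
  }
  out
}

#' @export
print.species_loss_account <- function(x, ...) {
  tot <- apply(x$total, 1, sum)
  cat("<species_loss_account> species-equivalents lost (all land):\n")
  print(signif(tot, 4))
  invisible(x)
}

#' Aggregate an account over taxa groups
#'
#' Species-equivalents are additive, so the vertebrate group is the plain sum
#' of the mammal, bird, amphibian and reptile losses; plants stay separate.
#'
#' @param SL array whose first margin is taxon.
#' @return Array with first margin `c("plants", "vertebrates")`.
#' @export
taxon_group_sums <- function(SL) {
  dn <- dimnames(SL)
  dims <- dim(SL)
  flat <- matrix(SL, nrow = dims[1])
  pl <- flat[match("plants", dn[[1]]), ]
  vt <- colSums(flat[match(vertebrate_taxa(), dn[[1]]), , drop = FALSE])
  array(rbind(pl, vt), c(2L, dims[-1]),
        dimnames = c(list(group = c("plants", "vertebrates")), dn[-1]))
}

#' Production- versus consumption-based accounts
#'
#' The production-based account is the marginal of the species-loss account
#' over consumers (loss located in each producing country); the
#' consumption-based account is the marginal over producers (loss driven by
#' each country's final consumption). Both sum to the same global total.
#'
#' @param account a [species_loss()] result.
#' @param scope `"total"`, `"kba"` (inside KBAs only) or `"non_kba"`.
#' @param source `"total"`, `"food"` or `"nonfood"`.
#' @return List with matrices `production` and `consumption`
#'   (taxon x region) and a long-format `table` data.frame.
#' @export
production_vs_consumption <- function(account,
                                      scope = c("total", "kba", "non_kba"),
                                      source = c("total", "food", "nonfood")) {
  scope <- match.arg(scope); source <- match.arg(source)
  SL <- account_slice(account, scope, source)
  production <- apply(SL, c(1, 3), sum)
  consumption <- apply(SL, c(1, 2), sum)
  tab <- rbind(
    cbind(array_to_df(production), perspective = "production"),
    cbind(stats::setNames(array_to_df(consumption),
                          c("taxon", "producer", "value")),
          perspective = "consumption"))
  names(tab) <- c("taxon", "region", "species_lost", "perspective")
  list(production = production, consumption = consumption, table = tab)
}

account_slice <- function(account, scope, source) {
  SL <- account[[source]]
  m <- switch(scope,
              total = SL[, , , , "inside", drop = FALSE] +
                      SL[, , , , "outside", drop = FALSE],
              kba = SL[, , , , "inside", drop = FALSE],
              non_kba = SL[, , , , "outside", drop = FALSE])
  array(m, dim(SL)[1:4], dimnames(SL)[1:4])
}

#' Per-capita values
#'
#' Divides a taxon x region table elementwise by regional population;
#' resulting unit is species lost per person.
#'
#' @param table matrix taxon x region.
#' @param population named numeric vector covering every column.
#' @return Matrix of per-capita values.
#' @export
per_capita <- function(table, population) {
  regs <- colnames(table)
  if (!all(regs %in% names(population)))
    abort_validation("per_capita(): population missing for some regions")
  pop <- population[regs]
  if (any(pop <= 0))
    abort_validation("per_capita(): population must be positive")
  sweep(table, 2, pop, "/")
}

#' Embodied biodiversity-loss trade flows
#'
#' Aggregates the species-loss account to producer-group x consumer-group
#' flow matrices per taxon. The diagonal is domestic loss; the trade share is
#' one minus the diagonal share of the total.
#'
#' @param account a [species_loss()] result.
#' @param grouping named character vector mapping every region to a group;
#'   defaults to one group per region.
#' @param scope,source see [production_vs_consumption()].
#' @return An object of class `flow_matrix`: array
#'   `flows[taxon, producer_group, consumer_group]` and per-taxon
#'   `trade_share` (fraction in 0..1).
#' @export
trade_flows <- function(account, grouping = NULL,
                        scope = c("total", "kba", "non_kba"),
                        source = c("total", "food", "nonfood")) {
  scope <- match.arg(scope); source <- match.arg(source)
  regions <- account$producers
  if (is.null(grouping))
    grouping <- stats::setNames(regions, regions)
  if (!all(regions %in% names(grouping)))
    abort_validation("trade_flows(): grouping must cover every region")
  if (!all(account$consumers %in% names(grouping)))
    abort_validation("trade_flows(): grouping must cover every consumer region")
  groups <- sort(unique(unname(grouping)))
  SL <- account_slice(account, scope, source)  # [g, s, r, m]
  by_sr <- apply(SL, c(1, 2, 3), sum)          # [g, s, r]
  n_g <- dim(by_sr)[1]
  flows <- array(0, c(n_g, length(groups), length(groups)),
                 dimnames = list(taxon = dimnames(SL)[[1]],
                                 producer_group = groups,
                                 consumer_group = groups))
  gp_cons <- match(grouping[account$consumers], groups)
  gp_prod <- match(grouping[regions], groups)
  for (s in seq_along(account$consumers))
    for (r in seq_along(regions))
      flows[, gp_prod[r], gp_cons[s]] <-
        flows[, gp_prod[r], gp_cons[s]] + by_sr[, s, r]
  totals <- apply(flows, 1, sum)
  domestic <- vapply(seq_len(n_g), function(g) {
    M <- matrix(flows[g, , ], length(groups), length(groups))
    sum(M[cbind(seq_along(groups), seq_along(groups))])
  }, numeric(1))
  trade_share <- ifelse(totals > 0, 1 - domestic / totals, 0)
  names(trade_share) <- dimnames(flows)[[1]]
  structure(list(flows = flows, trade_share = trade_share,
                 grouping = grouping, scope = scope, source = source),
            class = "flow_matrix")
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat("<flow_matrix> ", dim(x$flows)[2], " region groups; trade share:\n",
      sep = "")
  print(signif(100 * x$trade_share, 3))
  invisible(x)
}

#' Attribute species loss to final products
#'
#' Losses follow the final product purchased: physical products for food
#' demand, monetary products for nonfood demand (the consumer-facing
#' category, not the biomass input). Group sums partition the total loss; the
#' food/nonfood split is reported alongside.
#'
#' @param account a [species_loss()] result computed with `footprint` and
#'   `shares` (so it carries by-product detail).
#' @param grouping_food,grouping_nonfood named character vectors mapping
#'   final products to report groups; default one group per product.
#' @param scope `"total"`, `"kba"` or `"non_kba"`.
#' @return An object of class `product_attribution`: long `table`
#'   data.frame, per-taxon `food_share`, and the per-(taxon, group) matrix.
#' @export
product_attribution <- function(account, grouping_food = NULL,
                                grouping_nonfood = NULL,
                                scope = c("total", "kba", "non_kba")) {
  scope <- match.arg(scope)
  if (is.null(account$by_product))
    abort_structural("product_attribution(): account lacks by-product detail")
  pick <- function(arr) {
    m <- switch(scope,
                total = arr[, , "inside", drop = FALSE] +
                        arr[, , "outside", drop = FALSE],
                kba = arr[, , "inside", drop = FALSE],
                non_kba = arr[, , "outside", drop = FALSE])
    matrix(m, nrow = dim(arr)[1], ncol = dim(arr)[2],
           dimnames = dimnames(arr)[1:2])
  }
  attr_one <- function(arr, grouping, source) {
    sl <- pick(arr)  # [taxon, final_product]
    prods <- colnames(sl)
    if (is.null(grouping)) grouping <- stats::setNames(prods, prods)
    if (!all(prods %in% names(grouping)))
      abort_validation("product_attribution(): grouping must cover every product")
    groups <- unique(unname(grouping[prods]))
    out <- sapply(groups, function(gp)
      rowSums(sl[, grouping[prods] == gp, drop = FALSE]))
    out <- matrix(out, nrow = nrow(sl),
                  dimnames = list(taxon = rownames(sl), group = groups))
    df <- array_to_df(out, value = "species_lost")
    df$source <- source
    df
  }
  tab <- rbind(attr_one(account$by_product$food, grouping_food, "food"),
               attr_one(account$by_product$nonfood, grouping_nonfood,
                        "nonfood"))
  by_taxon <- tapply(tab$species_lost, list(tab$taxon, tab$source), sum)
  totals <- rowSums(by_taxon)
  food_share <- ifelse(totals > 0, by_taxon[, "food"] / totals, 0)
  wide <- tapply(tab$species_lost, list(tab$taxon, paste(tab$source,
    tab$group, sep = ":")), sum)
  structure(list(table = tab, food_share = food_share, matrix = wide,
                 scope = scope),
            class = "product_attribution")
}

#' Relative species loss
#'
#' Loss as a share of each taxon's global species number.
#'
#' @param account a [species_loss()] result.
#' @param scope see [production_vs_consumption()].
#' @return Named numeric vector, fraction of global richness per taxon.
#' @export
relative_loss <- function(account, scope = c("total", "kba", "non_kba")) {
  scope <- match.arg(scope)
  SL <- account_slice(account, scope, "total")
  apply(SL, 1, sum) / account$taxon_totals
}
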