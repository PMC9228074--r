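# Spatial allocation: distribute national consumption-based land use onto a
# regular grid proportionally to observed production patterns, and split each
# cell's allocation by KBA membership.
#
# Grids are regular lat-lon rasters stored as vectors of length
# nrow * ncol (row-major, origin at the north-west corner); all layers and
# masks of one analysis share a single geometry.

#' Grid geometry
#'
#' @param nrow,ncol grid dimensions.
#' @param cell_area_m2 area of one cell in m2 (constant across the toy grid).
#' @param resolution_arcmin nominal resolution, metadata only.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(nrow, ncol, cell_area_m2,
                          resolution_arcmin = 5) {
  if (nrow < 1 || ncol < 1 || cell_area_m2 <= 0)
    abort_config("grid_geometry(): positive dimensions and cell area required")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 ncell = as.integer(nrow) * as.integer(ncol),
                 cell_area_m2 = cell_area_m2,
                 resolution_arcmin = resolution_arcmin),
            class = "grid_geometry")
}

same_geometry <- function(a, b) {
  identical(a$nrow, b$nrow) && identical(a$ncol, b$ncol) &&
    isTRUE(all.equal(a$cell_area_m2, b$cell_area_m2))
}

#' Land-use raster stack
#'
#' Absolute land-use area (m2) per cell, one layer per producer region x
#' product x land-use category. Cells outside the producing country are zero
#' in that country's layers, and each layer sums to the corresponding land
#' extension entry.
#'
#' @param R numeric array `[cell, region, product, category]`.
#' @param geometry a [grid_geometry()].
#' @param regions,products,categories layer labels.
#' @return An object of class `land_use_grid`.
#' @export
land_use_grid <- function(R, geometry, regions, products,
                          categories = land_use_categories()) {
  R <- as.array(R)
  if (!all(dim(R) == c(geometry$ncell, length(regions), length(products),
                       length(categories))))
    abort_structural("land_use_grid: R must be [cell, region, product, category]")
  if (any(R < 0))
    abort_validation("land_use_grid: negative cell areas not allowed")
  dimnames(R) <- list(cell = NULL, region = regions, product = products,
                      category = categories)
  structure(list(R = R, geometry = geometry, regions = regions,
                 products = products, categories = categories),
            class = "land_use_grid")
}

#' Cell masks
#'
#' Country identity, ecoregion identity and KBA membership per grid cell.
#' Country and ecoregion are integer indices (0 = none, e.g. sea); KBA
#' membership is binary per cell (center-point rule).
#'
#' @param country_id,ecoregion_id integer vectors, one entry per cell.
#' @param kba logical vector, one entry per cell.
#' @param geometry a [grid_geometry()].
#' @param regions,ecoregions labels the integer ids index into.
#' @return An object of class `cell_masks`.
#' @export
cell_masks <- function(country_id, ecoregion_id, kba, geometry,
                       regions, ecoregions) {
  n <- geometry$ncell
  if (length(country_id) != n || length(ecoregion_id) != n || length(kba) != n)
    abort_structural("cell_masks: masks must have one entry per cell")
  if (any(country_id < 0) || any(country_id > length(regions)))
    abort_validation("cell_masks: country ids out of range")
  if (any(ecoregion_id < 0) || any(ecoregion_id > length(ecoregions)))
    abort_validation("cell_masks: ecoregion ids out of range")
  structure(list(country_id = as.integer(country_id),
                 ecoregion_id = as.integer(ecoregion_id),
                 kba = as.logical(kba), geometry = geometry,
                 regions = regions, ecoregions = ecoregions),
            class = "cell_masks")
}

#' Normalize land-use rasters to allocation shares
#'
#' Converts each `(region, product, category)` layer of absolute land use to
#' within-layer shares, the proportional-allocation assumption: consumption
#' of country `s` is spread across all producing cells of country `r` in
#' proportion to observed production. A positive land-extension entry with an
#' all-zero raster layer is an allocation gap and raises an error naming the
#' offending layers.
#'
#' @param grid a [land_use_grid()].
#' @param extension a [land_extension()]; used only to detect gaps.
#' @return An object of class `share_grid`: array `shares` with layers
#'   summing to one (or all-zero where no land exists), and a logical
#'   `defined` array marking nonempty layers.
#' @export
normalize_distribution <- function(grid, extension) {
  R <- grid$R
  totals <- apply(R, c(2, 3, 4), sum)
  d <- extension$d
  if (!all(dim(totals) == dim(d)))
    abort_structural("normalize_distribution(): grid and extension dimensions differ")
  gap <- d > 0 & totals == 0
  if (any(gap)) {
    idx <- which(gap, arr.ind = TRUE)
    labs <- apply(idx, 1, function(k)
      paste(grid$regions[k[1]], grid$products[k[2]], grid$categories[k[3]],
            sep = "/"))
    abort_allocation_gap(paste0(
      "normalize_distribution(): land recorded but no raster support for: ",
      paste(utils::head(labs, 10), collapse = ", ")))
  }
  denom <- array(rep(totals, each = dim(R)[1]), dim = dim(R))
  shares <- ifelse(denom > 0, R / denom, 0)
  dimnames(shares) <- dimnames(R)
  structure(list(shares = shares, defined = totals > 0,
                 geometry = grid$geometry, regions = grid$regions,
                 products = grid$products, categories = grid$categories),
            class = "share_grid")
}

#' Allocate footprints to grid cells
#'
#' Spreads each consumer's footprint `F[s, r, i, m]` over the cells of the
#' producing country using the share layers:
#' `cell value = sum_{r,i} F[s,r,i,m] * share[n | r,i,m]`. Food and nonfood
#' partitions are allocated separately. Allocation conserves every
#' `(consumer, producer, category)` marginal of the footprint tensor.
#'
#' @param footprint a [consumption_footprint()] result.
#' @param shares a [normalize_distribution()] result.
#' @param masks a [cell_masks()] on the same geometry (used to verify layer
#'   support stays within the producing country).
#' @return An object of class `allocated_grid` with arrays
#'   `[consumer, category, cell]` for `food`, `nonfood`, `total`.
#' @export
allocate_land <- function(footprint, shares, masks) {
  if (!same_geometry(shares$geometry, masks$geometry))
    abort_structural("allocate_land(): shares and masks geometry differ")
  dn <- dimnames(footprint$total)
  regions <- dn$producer; products <- dn$product; cats <- dn$category
  if (!identical(regions, shares$regions) ||
      !identical(products, shares$products) ||
      !identical(cats, shares$categories))
    abort_structural("allocate_land(): footprint and share labels differ")
  used <- apply(footprint$total, c(2, 3, 4), sum) > 0
  if (any(used & !shares$defined)) {
    idx <- which(used & !shares$defined, arr.ind = TRUE)
    labs <- apply(idx, 1, function(k)
      paste(regions[k[1]], products[k[2]], cats[k[3]], sep = "/"))
    abort_allocation_gap(paste0(
      "allocate_land(): footprint on layers without raster support: ",
      paste(utils::head(labs, 10), collapse = ", ")))
  }
  # share support must lie inside the producing country
  for (r in seq_along(regions)) {
    outside <- masks$country_id != r
    if (any(shares$shares[outside, r, , ] > 0))
      abort_structural(sprintf(
        "allocate_land(): share layer of %s has support outside the country",
        regions[r]))
  }
  n_s <- length(dn$consumer); n_cat <- length(cats)
  ncell <- shares$geometry$ncell
  alloc_one <- function(FF) {
    G <- array(0, c(n_s, n_cat, ncell),
               dimnames = list(consumer = dn$consumer, category = cats,
                               cell = NULL))
    nri <- length(regions) * length(products)
    for (m in seq_len(n_cat)) {
      Sm <- matrix(shares$shares[, , , m], nrow = ncell, ncol = nri)
      Fm <- matrix(FF[, , , m], nrow = n_s, ncol = nri)
      G[, m, ] <- Fm %*% t(Sm)
    }
    G
  }
  structure(list(food = alloc_one(footprint$food),
                 nonfood = alloc_one(footprint$nonfood),
                 total = alloc_one(footprint$total),
                 geometry = shares$geometry,
                 consumers = dn$consumer, categories = cats),
            class = "allocated_grid")
}

#' @export
print.allocated_grid <- function(x, ...) {
  cat("<allocated_grid> ", length(x$consumers), " consumers x ",
      length(x$categories), " categories x ", x$geometry$ncell,
      " cells; total ", format(sum(x$total), digits = 4), " m2\n", sep = "")
  invisible(x)
}

#' Split an allocated grid by KBA membership
#'
#' Exact cellwise partition: `inside + outside` reproduces the input grid.
#'
#' @param grid an [allocate_land()] result.
#' @param masks a [cell_masks()] on the same geometry.
#' @return List with `inside` and `outside` `allocated_grid` objects.
#' @export
split_by_kba <- function(grid, masks) {
  if (!same_geometry(grid$geometry, masks$geometry))
    abort_structural("split_by_kba(): geometry mismatch")
  mask_grid <- function(g, keep) {
    w <- rep(as.numeric(keep), each = dim(g$total)[1] * dim(g$total)[2])
    out <- g
    for (f in c("food", "nonfood", "total")) {
      arr <- g[[f]] * array(w, dim = dim(g[[f]]))
      dimnames(arr) <- dimnames(g[[f]])
      out[[f]] <- arr
    }
    out
  }
  list(inside = mask_grid(grid, masks$kba),
       outside = mask_grid(grid, !masks$kba))
}

#' Allocation conservation report
#'
#' Verifies that, for every consumer, producing country and category, the
#' allocated cell values within the producing country sum back to the
#' footprint marginal over products.
#'
#' @param grid an [allocate_land()] result.
#' @param footprint the footprint it was allocated from.
#' @param masks a [cell_masks()].
#' @param tol relative tolerance.
#' @return List with `max_rel_diff` and `pass`.
#' @export
allocation_conservation <- function(grid, footprint, masks, tol = 1e-9) {
  dn <- dimnames(footprint$total)
  n_r <- length(dn$producer)
  # indicator: cell -> country
  ind <- matrix(0, grid$geometry$ncell, n_r)
  has_country <- masks$country_id > 0
  ind[cbind(which(has_country), masks$country_id[has_country])] <- 1
  # allocated sums per (s, m, r)
  smr <- array(0, c(length(grid$consumers), length(grid$categories), n_r))
  for (m in seq_along(grid$categories))
    smr[, m, ] <- grid$total[, m, ] %*% ind
  target <- aperm(apply(footprint$total, c(1, 2, 4), sum), c(1, 3, 2)) # s, m, r
  mrd <- max(rel_diff(smr, target))
  list(max_rel_diff = mrd, pass = mrd <= tol)
}
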