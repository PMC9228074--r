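# Plain-file serialization for pipeline stage handoff. Everything is long
# CSV plus one YAML metadata file, so stages are independently testable,
# resumable and diffable; zero entries are omitted from sparse tensors and
# restored on read.

write_long_csv <- function(arr, path, keep_zero = FALSE) {
  df <- array_to_df(arr)
  if (!keep_zero) df <- df[df$value != 0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_long_array <- function(path, dimnames) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rep("character",
                                           length(dimnames)), "numeric"))
  names(df) <- c(names(dimnames), "value")
  df_to_array(df, dimnames)
}

#' Write a synthetic world to a directory
#'
#' One CSV per table or tensor plus a `meta.yaml` carrying all labels,
#' units, the grid geometry, concordance and population. Cell tensors omit
#' zero entries.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  meta <- list(
    regions_phys = world$phys$regions, products_phys = world$phys$products,
    units = as.list(world$phys$units),
    regions_mon = world$mon$regions, products_mon = world$mon$products,
    categories = world$extension$categories,
    ecoregions = world$cfs$ecoregions, taxa = world$cfs$taxa,
    taxon_totals = as.list(world$cfs$taxon_totals),
    concordance = as.list(world$concordance),
    population = as.list(world$population),
    geometry = list(nrow = world$masks$geometry$nrow,
                    ncol = world$masks$geometry$ncol,
                    cell_area_m2 = world$masks$geometry$cell_area_m2),
    seed = if (!is.null(world$config)) world$config$seed else NA
  )
  yaml::write_yaml(meta, p("meta.yaml"), precision = 15)
  sec_p <- world$phys$sectors; sec_m <- world$mon$sectors
  mat_named <- function(M, rn, cn) {
    dimnames(M) <- stats::setNames(list(rn[[1]], rn[[2]]), cn)
    M
  }
  write_long_csv(mat_named(world$phys$Z, list(sec_p, sec_p),
                           c("from_sector", "to_sector")), p("z_phys.csv"))
  write_long_csv(mat_named(world$mon$Z, list(sec_m, sec_m),
                           c("from_sector", "to_sector")), p("z_mon.csv"))
  write_long_csv(mat_named(world$link$Z, list(sec_p, sec_m),
                           c("from_sector", "to_sector")), p("z_link.csv"))
  write_long_csv(mat_named(cbind(world$phys$x), list(sec_p, "x"),
                           c("sector", "col")), p("x_phys.csv"),
                 keep_zero = TRUE)
  write_long_csv(mat_named(cbind(world$mon$x), list(sec_m, "x"),
                           c("sector", "col")), p("x_mon.csv"),
                 keep_zero = TRUE)
  write_long_csv(mat_named(world$phys$y, list(sec_p, world$phys$regions),
                           c("sector", "consumer")), p("y_phys.csv"))
  write_long_csv(mat_named(world$mon$y, list(sec_m, world$mon$regions),
                           c("sector", "consumer")), p("y_mon.csv"))
  write_long_csv(world$extension$d, p("extension_d.csv"))
  Rt <- world$grid$R
  dimnames(Rt)[[1]] <- as.character(seq_len(dim(Rt)[1]))
  names(dimnames(Rt))[1] <- "cell"
  write_long_csv(Rt, p("grid_r.csv"))
  masks_df <- data.frame(cell = seq_len(world$masks$geometry$ncell),
                         country_id = world$masks$country_id,
                         ecoregion_id = world$masks$ecoregion_id,
                         kba = as.integer(world$masks$kba))
  utils::write.csv(masks_df, p("masks.csv"), row.names = FALSE, quote = FALSE)
  write_long_csv(world$cfs$cf, p("cf.csv"), keep_zero = TRUE)
  write_long_csv(world$cfs$richness_per_m2, p("richness.csv"),
                 keep_zero = TRUE)
  invisible(dir)
}

#' Read a synthetic world from a directory
#'
#' Inverse of [write_world()].
#'
#' @param dir directory written by [write_world()].
#' @return An object of class `synthetic_world`.
#' @export
read_world <- function(dir) {
  p <- function(f) file.path(dir, f)
  if (!file.exists(p("meta.yaml")))
    abort_dependency(paste0("read_world(): no world at ", dir))
  meta <- yaml::read_yaml(p("meta.yaml"))
  regions <- unlist(meta$regions_phys); products <- unlist(meta$products_phys)
  regions_mon <- unlist(meta$regions_mon)
  products_mon <- unlist(meta$products_mon)
  categories <- unlist(meta$categories)
  ecoregions <- unlist(meta$ecoregions); taxa <- unlist(meta$taxa)
  sec_p <- sector_names(regions, products)
  sec_m <- sector_names(regions_mon, products_mon)
  rd <- function(f, dn) read_long_array(p(f), dn)
  Z_phys <- rd("z_phys.csv", list(from_sector = sec_p, to_sector = sec_p))
  Z_mon <- rd("z_mon.csv", list(from_sector = sec_m, to_sector = sec_m))
  Z_link <- rd("z_link.csv", list(from_sector = sec_p, to_sector = sec_m))
  x_phys <- rd("x_phys.csv", list(sector = sec_p, col = "x"))[, 1]
  x_mon <- rd("x_mon.csv", list(sector = sec_m, col = "x"))[, 1]
  y_phys <- rd("y_phys.csv", list(sector = sec_p, consumer = regions))
  y_mon <- rd("y_mon.csv", list(sector = sec_m, consumer = regions_mon))
  d <- rd("extension_d.csv", list(region = regions, product = products,
                                  category = categories))
  geometry <- grid_geometry(meta$geometry$nrow, meta$geometry$ncol,
                            meta$geometry$cell_area_m2)
  Rt <- rd("grid_r.csv",
           list(cell = as.character(seq_len(geometry$ncell)),
                region = regions, product = products, category = categories))
  masks_df <- utils::read.csv(p("masks.csv"))
  masks <- cell_masks(masks_df$country_id, masks_df$ecoregion_id,
                      masks_df$kba == 1, geometry, regions, ecoregions)
  cf <- rd("cf.csv", list(taxon = taxa, category = categories,
                          ecoregion = ecoregions))
  rich <- rd("richness.csv", list(taxon = taxa, ecoregion = ecoregions))
  units <- stats::setNames(unlist(meta$units)[products], products)
  phys <- physical_io(Z_phys, x_phys, y_phys, regions, products, units)
  mon <- monetary_io(Z_mon, x_mon, y_mon, regions_mon, products_mon)
  structure(list(
    phys = phys, mon = mon, link = link_table(Z_link, phys, mon),
    extension = land_extension(d, x_phys, regions, products, categories),
    grid = land_use_grid(Rt, geometry, regions, products, categories),
    masks = masks,
    cfs = cf_table(cf, rich,
                   stats::setNames(unlist(meta$taxon_totals)[taxa], taxa),
                   taxa, categories, ecoregions),
    population = stats::setNames(unlist(meta$population)[regions], regions),
    concordance = stats::setNames(
      unlist(meta$concordance)[regions], regions),
    config = NULL
  ), class = "synthetic_world")
}

write_footprint <- function(footprint, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_long_csv(footprint$food, file.path(dir, "food.csv"))
  write_long_csv(footprint$nonfood, file.path(dir, "nonfood.csv"))
  if (!is.null(footprint$by_product_food)) {
    write_long_csv(footprint$by_product_food,
                   file.path(dir, "by_product_food.csv"))
    write_long_csv(footprint$by_product_nonfood,
                   file.path(dir, "by_product_nonfood.csv"))
  }
  invisible(dir)
}

read_footprint <- function(dir, world) {
  if (!file.exists(file.path(dir, "food.csv")))
    abort_dependency(paste0("read_footprint(): no footprint cache at ", dir))
  extension <- world$extension
  regions <- world$phys$regions; products <- world$phys$products
  dn <- list(consumer = regions, producer = regions, product = products,
             category = extension$categories)
  food <- read_long_array(file.path(dir, "food.csv"), dn)
  nonfood <- read_long_array(file.path(dir, "nonfood.csv"), dn)
  bp_f <- bp_n <- NULL
  if (file.exists(file.path(dir, "by_product_food.csv"))) {
    bp_f <- read_long_array(file.path(dir, "by_product_food.csv"),
                            c(list(final_product = products), dn))
    bp_n <- read_long_array(file.path(dir, "by_product_nonfood.csv"),
                            c(list(final_product = world$mon$products), dn))
  }
  structure(list(food = food, nonfood = nonfood, total = food + nonfood,
                 by_product_food = bp_f, by_product_nonfood = bp_n,
                 consumers = regions, extension = extension),
            class = "footprint_tensor")
}

write_allocated <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("food", "nonfood")) {
    arr <- grid[[f]]
    dimnames(arr)[[3]] <- as.character(seq_len(dim(arr)[3]))
    names(dimnames(arr))[3] <- "cell"
    write_long_csv(arr, file.path(dir, paste0(f, ".csv")))
  }
  invisible(dir)
}

read_allocated <- function(dir, world) {
  if (!file.exists(file.path(dir, "food.csv")))
    abort_dependency(paste0("read_allocated(): no allocation cache at ", dir))
  geometry <- world$masks$geometry
  dn <- list(consumer = world$phys$regions,
             category = world$extension$categories,
             cell = as.character(seq_len(geometry$ncell)))
  food <- read_long_array(file.path(dir, "food.csv"), dn)
  nonfood <- read_long_array(file.path(dir, "nonfood.csv"), dn)
  strip <- function(a) { dimnames(a)[[3]] <- NULL; a }
  structure(list(food = strip(food), nonfood = strip(nonfood),
                 total = strip(food + nonfood), geometry = geometry,
                 consumers = world$phys$regions,
                 categories = world$extension$categories),
            class = "allocated_grid")
}

write_account <- function(account, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("food", "nonfood"))
    write_long_csv(account[[f]], file.path(dir, paste0(f, ".csv")))
  if (!is.null(account$by_product)) {
    write_long_csv(account$by_product$food,
                   file.path(dir, "by_product_food.csv"))
    write_long_csv(account$by_product$nonfood,
                   file.path(dir, "by_product_nonfood.csv"))
  }
  invisible(dir)
}

read_account <- function(dir, world) {
  if (!file.exists(file.path(dir, "food.csv")))
    abort_dependency(paste0("read_account(): no loss cache at ", dir))
  dn <- list(taxon = world$cfs$taxa, consumer = world$phys$regions,
             producer = world$phys$regions,
             category = world$extension$categories,
             kba = c("inside", "outside"))
  food <- read_long_array(file.path(dir, "food.csv"), dn)
  nonfood <- read_long_array(file.path(dir, "nonfood.csv"), dn)
  by_product <- NULL
  if (file.exists(file.path(dir, "by_product_food.csv"))) {
    dnp <- function(prods) list(taxon = world$cfs$taxa,
                                final_product = prods,
                                kba = c("inside", "outside"))
    by_product <- list(
      food = read_long_array(file.path(dir, "by_product_food.csv"),
                             dnp(world$phys$products)),
      nonfood = read_long_array(file.path(dir, "by_product_nonfood.csv"),
                                dnp(world$mon$products)))
  }
  structure(list(food = food, nonfood = nonfood, total = food + nonfood,
                 by_product = by_product, taxa = world$cfs$taxa,
                 taxon_totals = world$cfs$taxon_totals,
                 consumers = world$phys$regions,
                 producers = world$phys$regions,
                 categories = world$extension$categories,
                 coverage_gap_cells = 0L, cells = NULL),
            class = "species_loss_account")
}
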