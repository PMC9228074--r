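# Input-output table containers. Sectors are region-product pairs ordered
# region-major (product fastest); final demand carries the last-exporter
# origin on its rows (the row sector's region) and the consuming region on
# its columns.

#' Physical input-output table
#'
#' Inter-industry flows of agriculture, food and forestry products in mixed
#' physical units (tonnes, heads, m3 depending on the product), with a total
#' output vector and an origin-resolved final-demand matrix.
#'
#' @param Z square inter-industry flow matrix (sector x sector), physical
#'   units per row product.
#' @param x total output vector, one entry per sector, same units as the
#'   corresponding `Z` rows.
#' @param y final-demand matrix, sectors x consuming regions; the row
#'   sector's region is the last exporter to the consuming region.
#' @param regions,products character vectors naming regions and products;
#'   sectors are their region-major combination.
#' @param units named character vector mapping each product to its unit
#'   label (e.g. `"tonnes"`, `"heads"`, `"m3"`).
#' @return An object of class `physical_io`.
#' @export
physical_io <- function(Z, x, y, regions, products, units = NULL) {
  obj <- new_io_table(Z, x, y, regions, products, "physical_io")
  if (is.null(units))
    units <- stats::setNames(rep("tonnes", length(products)), products)
  if (!all(products %in% names(units)))
    abort_validation("every product needs a unit label")
  obj$units <- units[products]
  obj
}

#' Monetary input-output table
#'
#' Economy-wide inter-industry flows in currency units, with total output and
#' origin-resolved final demand. Same layout as [physical_io()] but a single
#' unit (euros) for all products.
#'
#' @inheritParams physical_io
#' @return An object of class `monetary_io`.
#' @export
monetary_io <- function(Z, x, y, regions, products) {
  new_io_table(Z, x, y, regions, products, "monetary_io")
}

new_io_table <- function(Z, x, y, regions, products, class) {
  Z <- as.matrix(Z)
  y <- as.matrix(y)
  n <- length(regions) * length(products)
  if (nrow(Z) != n || ncol(Z) != n)
    abort_structural(sprintf("%s: Z must be %d x %d", class, n, n))
  if (length(x) != n)
    abort_structural(sprintf("%s: x must have %d entries", class, n))
  if (nrow(y) != n)
    abort_structural(sprintf("%s: y must have %d rows", class, n))
  if (any(Z < 0) || any(x < 0) || any(y < 0))
    abort_validation(sprintf("%s: negative entries not allowed", class))
  sec <- sector_names(regions, products)
  dimnames(Z) <- list(sec, sec)
  names(x) <- sec
  rownames(y) <- sec
  if (ncol(y) == length(regions)) colnames(y) <- regions
  names(dimnames(y)) <- c("sector", "consumer")
  structure(list(Z = Z, x = x, y = y, regions = regions,
                 products = products, sectors = sec),
            class = c(class, "io_table"))
}

#' Physical-to-monetary link table
#'
#' Biomass inputs (physical units of the physical system's products) consumed
#' by monetary sectors, the "other uses" bridge between the two systems.
#'
#' @param Z_link matrix with one row per physical sector and one column per
#'   monetary sector; units are those of the row product.
#' @param phys a [physical_io()] object.
#' @param mon a [monetary_io()] object.
#' @return An object of class `link_table`.
#' @export
link_table <- function(Z_link, phys, mon) {
  Z_link <- as.matrix(Z_link)
  if (nrow(Z_link) != length(phys$sectors))
    abort_structural("link_table: row count must match the physical system")
  if (ncol(Z_link) != length(mon$sectors))
    abort_structural("link_table: column count must match the monetary system")
  if (any(Z_link < 0))
    abort_validation("link_table: negative entries not allowed")
  dimnames(Z_link) <- list(phys$sectors, mon$sectors)
  structure(list(Z = Z_link), class = "link_table")
}

#' Land-use extension
#'
#' Land area occupied by each producer-region x product x land-use-category
#' cell, and the derived environmental intensity (area per unit output).
#' Intensities absorb the mixed units of the physical system: m2 per tonne,
#' per head or per m3 depending on the product.
#'
#' @param d numeric array `[region, product, category]` of land areas in m2.
#' @param x total output vector of the physical system (sector order), used
#'   to derive intensities; zero-output sectors get intensity zero and must
#'   carry no land.
#' @param regions,products,categories dimension labels; `categories` defaults
#'   to [land_use_categories()].
#' @return An object of class `land_extension` with fields `d` and `e`.
#' @export
land_extension <- function(d, x, regions, products,
                           categories = land_use_categories()) {
  d <- as.array(d)
  if (!all(dim(d) == c(length(regions), length(products), length(categories))))
    abort_structural("land_extension: d must be [region, product, category]")
  if (any(d < 0))
    abort_validation("land_extension: negative land areas not allowed")
  dimnames(d) <- list(region = regions, product = products,
                      category = categories)
  xm <- matrix(x, nrow = length(products), ncol = length(regions))
  x_ri <- t(xm)  # [region, product]
  e <- array(0, dim = dim(d), dimnames = dimnames(d))
  pos <- x_ri > 0
  for (m in seq_along(categories)) {
    slab <- d[, , m]
    if (length(regions) == 1L || length(products) == 1L)
      slab <- matrix(slab, nrow = length(regions), ncol = length(products))
    bad <- !pos & slab > 0
    if (any(bad))
      abort_validation("land_extension: land recorded for zero-output sectors")
    em <- matrix(0, length(regions), length(products))
    em[pos] <- slab[pos] / x_ri[pos]
    e[, , m] <- em
  }
  structure(list(d = d, e = e, regions = regions, products = products,
                 categories = categories),
            class = "land_extension")
}

#' @export
print.land_extension <- function(x, ...) {
  cat("<land_extension> ", length(x$regions), " regions x ",
      length(x$products), " products x ", length(x$categories),
      " categories; total land ", format(sum(x$d), digits = 4), " m2\n",
      sep = "")
  invisible(x)
}
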