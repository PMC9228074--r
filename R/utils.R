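# Shared helpers: condition classes, land-use vocabulary, array utilities.

#' Land-use vocabulary
#'
#' The accounting distinguishes five land-use types (managed forest,
#' plantation, pasture, cropland, urban), each at three use intensities
#' (minimal, light, intense), giving 15 land-use categories. Categories are
#' ordered type-major so the three intensities of one type are adjacent.
#'
#' @return Character vector of category labels, `"<type>:<intensity>"`.
#' @export
land_use_categories <- function() {
  as.vector(t(outer(land_use_types(), land_use_intensities(),
                    paste, sep = ":")))
}

#' @rdname land_use_categories
#' @export
land_use_types <- function() {
  c("managed_forest", "plantation", "pasture", "cropland", "urban")
}

#' @rdname land_use_categories
#' @export
land_use_intensities <- function() {
  c("minimal", "light", "intense")
}

#' Taxa covered by the characterization factors
#'
#' Five terrestrial taxa; the four non-plant classes aggregate to the
#' "vertebrates" group used in reporting.
#'
#' @return Character vector of taxon names.
#' @export
taxa_names <- function() {
  c("mammals", "amphibians", "reptiles", "birds", "plants")
}

#' @rdname taxa_names
#' @export
vertebrate_taxa <- function() {
  c("mammals", "amphibians", "reptiles", "birds")
}

# Approximate global species counts per taxon, used only for relative-loss
# reporting (share of global richness committed to extinction).
default_taxon_totals <- function() {
  c(mammals = 5490, amphibians = 6433, reptiles = 9084, birds = 10104,
    plants = 321212)
}

# --- condition helpers ------------------------------------------------------

abort_kba <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "kbafootprint_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_structural <- function(message) {
  abort_kba(message, "kbafootprint_structural_error")
}

abort_validation <- function(message) {
  abort_kba(message, "kbafootprint_validation_error")
}

abort_nonproductive <- function(message) {
  abort_kba(message, "kbafootprint_nonproductive_error")
}

abort_allocation_gap <- function(message) {
  abort_kba(message, "kbafootprint_allocation_gap_error")
}

abort_coverage <- function(message) {
  abort_kba(message, "kbafootprint_coverage_error")
}

abort_dependency <- function(message) {
  abort_kba(message, "kbafootprint_dependency_error")
}

abort_analysis <- function(message) {
  abort_kba(message, "kbafootprint_analysis_error")
}

abort_config <- function(message) {
  abort_kba(message, "kbafootprint_config_error")
}

# --- numeric helpers --------------------------------------------------------

#' Spectral radius of a matrix
#'
#' Largest eigenvalue modulus; a block-triangular coefficient matrix is
#' productive iff the spectral radius of each diagonal block is below one.
#'
#' @param M square numeric matrix.
#' @return Non-negative scalar.
#' @export
spectral_radius <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    abort_structural("spectral_radius() needs a square matrix")
  if (nrow(M) == 0L) return(0)
  if (all(M == 0)) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

# Names of combined region-product sectors, region-major with product fastest,
# matching the (product, region) unfolding used throughout.
sector_names <- function(regions, products) {
  as.vector(vapply(regions, function(r) paste(r, products, sep = "_"),
                   character(length(products))))
}

# Relative difference robust to zero denominators.
rel_diff <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s > 0, d / s, 0)
}

# Long data.frame from a named array: one column per margin plus `value`.
array_to_df <- function(arr, value = "value") {
  dn <- dimnames(arr)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    abort_structural("array_to_df() needs complete dimnames")
  nm <- names(dn)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("dim", seq_along(dn))
  df <- expand.grid(dn, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(df) <- nm
  df[[value]] <- as.vector(arr)
  df
}

# Inverse of array_to_df(): rebuild an array with the given dimnames from a
# long data.frame (missing combinations fill with 0).
df_to_array <- function(df, dimnames, value = "value") {
  dims <- unname(lengths(dimnames))
  arr <- array(0, dim = dims, dimnames = dimnames)
  idx <- mapply(function(col, dn) match(df[[col]], dn),
                names(dimnames), dimnames, SIMPLIFY = FALSE)
  if (any(vapply(idx, anyNA, logical(1))))
    abort_validation("df_to_array(): labels in file not present in schema")
  arr[as.matrix(as.data.frame(idx))] <- df[[value]]
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
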