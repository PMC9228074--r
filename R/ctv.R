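# Country-level decomposition of KBA species loss into four multiplicative
# factors and contribution-to-variance (CTV) analysis.
#
# For country r and taxon g, species loss inside KBAs factorizes as
#   SL_{r,g} = A_r * (L_r / A_r) * (S_{r,g} / L_r) * (SL_{r,g} / S_{r,g})
# with A_r the KBA area, L_r the anthropogenic land-use area within KBAs,
# and S_{r,g} the species richness of the occupied land within KBAs
# (richness per unit area is constant within an ecoregion). The chain is an
# exact identity wherever all denominators are positive; countries with any
# undefined factor are listwise-excluded from the CTV step.
#
# CTV uses Spearman rank correlations R_d between each factor and SL across
# countries (rank-based because the variables are far from normal) and
# reports the normalized squared-correlation share
#   CTV_d = R_d^2 / sum_d' R_d'^2 * 100.

#' Decompose country-level KBA species loss
#'
#' Aggregates KBA area, anthropogenic land use inside KBAs, occupied-land
#' species richness and species loss to the country level and forms the four
#' explanatory factors. The 5 taxa are carried individually plus the
#' vertebrate aggregate (loss and richness summed over the four classes).
#'
#' @param account a [species_loss()] result.
#' @param grid the [allocate_land()] result the account was computed from.
#' @param masks a [cell_masks()].
#' @param cfs a [cf_table()] (supplies richness per m2 by ecoregion).
#' @return An object of class `country_decomposition` with per-country
#'   vectors `kba_area` (A_r, m2), `land_use` (L_r, m2), matrices
#'   `richness` (S_rg, species) and `species_loss` (SL_rg), the factor
#'   matrices, and a logical `defined` matrix.
#' @export
decompose_kba_loss <- function(account, grid, masks, cfs) {
  if (!same_geometry(grid$geometry, masks$geometry))
    abort_structural("decompose_kba_loss(): geometry mismatch")
  regions <- masks$regions
  n_r <- length(regions)
  cell_area <- masks$geometry$cell_area_m2
  kba_cells <- masks$kba & masks$country_id > 0
  A <- vapply(seq_len(n_r), function(r)
    cell_area * sum(kba_cells & masks$country_id == r), numeric(1))
  land_per_cell <- apply(grid$total, 3, sum)  # all consumers, all categories
  L <- vapply(seq_len(n_r), function(r)
    sum(land_per_cell[kba_cells & masks$country_id == r]), numeric(1))
  # richness of occupied land: density of the cell's ecoregion times the
  # occupied area in the cell, summed over the country's KBA cells
  taxa5 <- cfs$taxa
  S5 <- matrix(0, n_r, length(taxa5), dimnames = list(regions, taxa5))
  has_eco <- masks$ecoregion_id > 0
  for (g in seq_along(taxa5)) {
    dens <- numeric(masks$geometry$ncell)
    dens[has_eco] <- cfs$richness_per_m2[g, masks$ecoregion_id[has_eco]]
    contrib <- dens * land_per_cell
    S5[, g] <- vapply(seq_len(n_r), function(r)
      sum(contrib[kba_cells & masks$country_id == r]), numeric(1))
  }
  SL_in <- account_slice(account, "kba", "total")
  SL5 <- t(apply(SL_in, c(1, 3), sum))  # [r, g]
  verts <- vertebrate_taxa()
  taxa <- c(taxa5, "vertebrates")
  S <- cbind(S5, vertebrates = rowSums(S5[, verts, drop = FALSE]))
  SL <- cbind(SL5, vertebrates = rowSums(SL5[, verts, drop = FALSE]))
  colnames(S) <- taxa; colnames(SL) <- taxa

  f_area <- A
  f_share <- ifelse(A > 0, L / A, NA_real_)
  f_rich <- sweep(S, 1, ifelse(L > 0, L, NA_real_), "/")
  f_rel <- SL / S; f_rel[S == 0] <- NA_real_
  defined <- (A > 0) & (L > 0) & (S > 0) & !is.na(f_rel)
  structure(list(
    regions = regions, taxa = taxa,
    kba_area = stats::setNames(A, regions),
    land_use = stats::setNames(L, regions),
    richness = S, species_loss = SL,
    f_area = stats::setNames(f_area, regions),
    f_share = stats::setNames(f_share, regions),
    f_richness = f_rich, f_relative_loss = f_rel,
    defined = defined
  ), class = "country_decomposition")
}

#' Construct a country decomposition from explicit factor values
#'
#' Used by planted scenarios and available for analyses that already hold
#' country-level aggregates: supply A, L, S and SL directly.
#'
#' @param kba_area,land_use numeric vectors per country.
#' @param richness,species_loss matrices country x taxon.
#' @param regions,taxa labels.
#' @return An object of class `country_decomposition`.
#' @export
country_decomposition <- function(kba_area, land_use, richness, species_loss,
                                  regions = NULL, taxa = NULL) {
  regions <- regions %||% names(kba_area) %||%
    sprintf("C%03d", seq_along(kba_area))
  richness <- as.matrix(richness); species_loss <- as.matrix(species_loss)
  taxa <- taxa %||% colnames(richness) %||%
    paste0("taxon", seq_len(ncol(richness)))
  if (any(kba_area < 0) || any(land_use < 0) ||
      any(richness < 0) || any(species_loss < 0))
    abort_validation("country_decomposition(): negative quantities not allowed")
  if (any(land_use > kba_area * (1 + 1e-12)))
    abort_validation("country_decomposition(): land use inside KBAs cannot exceed KBA area")
  A <- stats::setNames(as.numeric(kba_area), regions)
  L <- stats::setNames(as.numeric(land_use), regions)
  dimnames(richness) <- dimnames(species_loss) <- list(regions, taxa)
  f_share <- ifelse(A > 0, L / A, NA_real_)
  f_rich <- sweep(richness, 1, ifelse(L > 0, L, NA_real_), "/")
  f_rel <- species_loss / richness; f_rel[richness == 0] <- NA_real_
  defined <- (A > 0) & (L > 0) & (richness > 0)
  structure(list(
    regions = regions, taxa = taxa, kba_area = A, land_use = L,
    richness = richness, species_loss = species_loss,
    f_area = A, f_share = stats::setNames(f_share, regions),
    f_richness = f_rich, f_relative_loss = f_rel, defined = defined
  ), class = "country_decomposition")
}

#' Multiply the four factors back together
#'
#' The reconstruction identity: for every country with all factors defined,
#' the factor product equals the species loss exactly (up to floating
#' error). Returns the reconstructed matrix for comparison.
#'
#' @param decomposition a [decompose_kba_loss()] or
#'   [country_decomposition()] result.
#' @return Matrix country x taxon of factor products (NA where undefined).
#' @export
reconstruct_loss <- function(decomposition) {
  d <- decomposition
  out <- d$f_area * d$f_share * d$f_richness * d$f_relative_loss
  out[!d$defined] <- NA_real_
  out
}

#' @export
print.country_decomposition <- function(x, ...) {
  cat("<country_decomposition> ", length(x$regions), " countries x ",
      length(x$taxa), " taxa; ", sum(rowSums(!x$defined) == 0),
      " countries fully defined\n", sep = "")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (standard tie handling). A variable
#' with zero variance has no defined rank correlation; `NA` is returned with
#' a warning rather than an error so zero-variance factors can enter CTV
#' with contribution zero.
#'
#' @param x,y paired numeric samples, at least 3 pairs.
#' @return Scalar in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    abort_structural("spearman_rho(): x and y must have equal length")
  if (length(x) < 3)
    abort_validation("spearman_rho(): at least 3 pairs required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("spearman_rho(): zero variance, correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Contribution-to-variance analysis
#'
#' For each taxon, correlates the four factors with species loss across
#' countries (Spearman) and reports each factor's share of the summed squared
#' correlations as a percentage. Shares sum to 100 within rounding; factors
#' with undefined correlation (zero variance) contribute 0. Countries with
#' any undefined factor are excluded listwise; fewer than 3 usable countries
#' is an analysis error.
#'
#' Ranks are meaningless below floating-point noise, so a factor whose
#' relative spread across countries is below `var_tol` is treated as
#' constant (undefined correlation, contribution 0): a factor that is
#' constant by construction accumulates spreads of order 1e-16 on its way
#' through the pipeline, and rank statistics would otherwise amplify that
#' noise into an arbitrary correlation.
#'
#' @param decomposition a [decompose_kba_loss()] or
#'   [country_decomposition()] result.
#' @param var_tol relative spread below which a variable counts as
#'   constant.
#' @return An object of class `ctv_result`: matrices `ctv` and `rho`
#'   (factor x taxon), per-taxon sample size `n`.
#' @export
ctv <- function(decomposition, var_tol = 1e-9) {
  d <- decomposition
  factor_names <- c("area_of_kbas", "share_with_land_use",
                    "richness_per_area", "relative_loss")
  taxa <- d$taxa
  ctv_m <- rho_m <- matrix(NA_real_, 4, length(taxa),
                           dimnames = list(factor = factor_names,
                                           taxon = taxa))
  n <- stats::setNames(integer(length(taxa)), taxa)
  for (g in seq_along(taxa)) {
    ok <- d$defined[, g] & !is.na(d$f_share) & d$kba_area > 0
    n[g] <- sum(ok)
    if (n[g] < 3)
      abort_analysis(sprintf(
        "ctv(): fewer than 3 countries with defined factors for %s", taxa[g]))
    sl <- d$species_loss[ok, g]
    fac <- cbind(d$f_area[ok], d$f_share[ok], d$f_richness[ok, g],
                 d$f_relative_loss[ok, g])
    near_constant <- function(v) {
      r <- range(v)
      (r[2] - r[1]) <= var_tol * max(abs(v))
    }
    rho <- vapply(1:4, function(k) {
      if (near_constant(fac[, k]) || near_constant(sl)) NA_real_
      else stats::cor(fac[, k], sl, method = "spearman")
    }, numeric(1))
    if (all(is.na(rho)))
      abort_analysis(sprintf("ctv(): all correlations undefined for %s",
                             taxa[g]))
    r2 <- ifelse(is.na(rho), 0, rho^2)
    ctv_m[, g] <- 100 * r2 / sum(r2)
    rho_m[, g] <- rho
  }
  structure(list(ctv = ctv_m, rho = rho_m, n = n,
                 factors = factor_names),
            class = "ctv_result")
}

#' @export
print.ctv_result <- function(x, ...) {
  cat("<ctv_result> contributions to variance (%):\n")
  print(round(x$ctv, 1))
  invisible(x)
}
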