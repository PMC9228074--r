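# Hybrid MRIO core: technical coefficients, block assembly, block Leontief
# inverse, rest-of-world demand disaggregation, consumption footprints.
#
# The coupled system is upper block triangular,
#     A = [[A_phys, A_link], [0, A_mon]],
# monetary sectors deliver no inputs back to physical sectors. Its Leontief
# inverse therefore factorizes into
#     L = [[L_A, L_A A_link L_B], [0, L_B]]
# with L_A = (I - A_phys)^-1 and L_B = (I - A_mon)^-1, which is what
# block_leontief() computes and what the dense-inverse oracle in the test
# suite checks against.

#' Technical coefficient matrix
#'
#' Input requirements per unit of sector output, `A = Z %*% diag(1/x)`.
#' Columns of zero-output sectors are set to zero rather than dropped, so
#' sparse country-product tables keep their indexing and inert sectors never
#' produce division artifacts.
#'
#' @param Z non-negative flow matrix whose columns match `x` (square for an
#'   inter-industry table, rectangular for a link table).
#' @param x non-negative total output vector of the column sectors.
#' @return Matrix of coefficients with the dimensions of `Z`.
#' @export
technical_coefficients <- function(Z, x) {
  Z <- as.matrix(Z)
  if (!is.numeric(Z) || !is.numeric(x))
    abort_structural("technical_coefficients(): numeric inputs required")
  if (ncol(Z) != length(x))
    abort_structural("technical_coefficients(): ncol(Z) must equal length(x)")
  if (any(Z < 0) || any(x < 0))
    abort_validation("technical_coefficients(): negative entries not allowed")
  inv <- ifelse(x > 0, 1 / x, 0)
  A <- Z * rep(inv, each = nrow(Z))
  dimnames(A) <- dimnames(Z)
  A
}

#' Assemble the hybrid block economy
#'
#' Combines the physical-system, link and monetary-system coefficient blocks
#' into one upper-block-triangular economy and validates that it is
#' productive (spectral radius below one). For a block-triangular matrix the
#' spectral radius is the maximum over the diagonal blocks, which is how it
#' is computed here.
#'
#' @param A_phys,A_mon square coefficient blocks of the physical and monetary
#'   systems.
#' @param A_link physical-rows x monetary-columns coefficient block (biomass
#'   input per unit monetary output).
#' @param concordance named character vector mapping every physical region to
#'   its monetary region (many-to-one for rest-of-world composites).
#' @param population named numeric vector of persons per physical region.
#' @param regions_phys,products_phys,regions_mon,products_mon dimension
#'   labels of the two systems.
#' @return An object of class `hybrid_economy`.
#' @export
assemble_hybrid <- function(A_phys, A_link, A_mon, concordance, population,
                            regions_phys, products_phys,
                            regions_mon, products_mon) {
  n_p <- length(regions_phys) * length(products_phys)
  n_m <- length(regions_mon) * length(products_mon)
  A_phys <- as.matrix(A_phys); A_mon <- as.matrix(A_mon)
  A_link <- as.matrix(A_link)
  if (nrow(A_phys) != n_p || ncol(A_phys) != n_p)
    abort_structural("assemble_hybrid(): A_phys has wrong dimensions")
  if (nrow(A_mon) != n_m || ncol(A_mon) != n_m)
    abort_structural("assemble_hybrid(): A_mon has wrong dimensions")
  if (nrow(A_link) != n_p || ncol(A_link) != n_m)
    abort_structural("assemble_hybrid(): A_link has wrong dimensions")
  if (any(A_phys < 0) || any(A_mon < 0) || any(A_link < 0))
    abort_validation("assemble_hybrid(): negative coefficients not allowed")
  if (!all(regions_phys %in% names(concordance)))
    abort_validation("assemble_hybrid(): concordance must cover every physical region")
  if (!all(concordance[regions_phys] %in% regions_mon))
    abort_validation("assemble_hybrid(): concordance maps to unknown monetary regions")
  if (!all(regions_phys %in% names(population)) || any(population[regions_phys] <= 0))
    abort_validation("assemble_hybrid(): positive population needed for every physical region")
  rho <- max(spectral_radius(A_phys), spectral_radius(A_mon))
  if (rho >= 1)
    abort_nonproductive(sprintf(
      "assemble_hybrid(): economy not productive (spectral radius %.4f >= 1)", rho))
  sec_p <- sector_names(regions_phys, products_phys)
  sec_m <- sector_names(regions_mon, products_mon)
  dimnames(A_phys) <- list(sec_p, sec_p)
  dimnames(A_mon) <- list(sec_m, sec_m)
  dimnames(A_link) <- list(sec_p, sec_m)
  structure(list(
    A_phys = A_phys, A_link = A_link, A_mon = A_mon,
    concordance = concordance[regions_phys],
    population = population[regions_phys],
    regions_phys = regions_phys, products_phys = products_phys,
    regions_mon = regions_mon, products_mon = products_mon,
    sectors_phys = sec_p, sectors_mon = sec_m,
    spectral_radius = rho
  ), class = "hybrid_economy")
}

#' @export
print.hybrid_economy <- function(x, ...) {
  cat("<hybrid_economy> physical ", length(x$regions_phys), "x",
      length(x$products_phys), " + monetary ", length(x$regions_mon), "x",
      length(x$products_mon), "; spectral radius ",
      format(x$spectral_radius, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Full block coefficient matrix of a hybrid economy
#'
#' @param economy a [assemble_hybrid()] result.
#' @return Square matrix `[[A_phys, A_link], [0, A_mon]]`.
#' @export
block_matrix <- function(economy) {
  n_p <- nrow(economy$A_phys); n_m <- nrow(economy$A_mon)
  rbind(cbind(economy$A_phys, economy$A_link),
        cbind(matrix(0, n_m, n_p), economy$A_mon))
}

#' Block Leontief inverse
#'
#' Exploits the upper-block-triangular structure: the inverse of the coupled
#' system is assembled from the two small inverses `L_A`, `L_B` and the
#' cross block `L_A A_link L_B`, avoiding inversion of the full matrix.
#'
#' @param economy a [assemble_hybrid()] result.
#' @return An object of class `leontief_blocks` with fields `L_A`, `L_AB`
#'   (upper-right block) and `L_B`; the lower-left block is identically zero.
#' @export
block_leontief <- function(economy) {
  L_A <- leontief_inverse(economy$A_phys)
  L_B <- leontief_inverse(economy$A_mon)
  structure(list(L_A = L_A, L_AB = L_A %*% economy$A_link %*% L_B, L_B = L_B),
            class = "leontief_blocks")
}

leontief_inverse <- function(A) {
  out <- tryCatch(solve(diag(nrow(A)) - A),
                  error = function(e) abort_nonproductive(
                    paste0("Leontief inverse failed: ", conditionMessage(e))))
  dimnames(out) <- dimnames(A)
  out
}

# Solve (I - A) X = Y without forming the inverse.
leontief_solve <- function(A, Y) {
  out <- tryCatch(solve(diag(nrow(A)) - A, Y),
                  error = function(e) abort_nonproductive(
                    paste0("Leontief solve failed: ", conditionMessage(e))))
  out <- as.matrix(out)
  rownames(out) <- rownames(A)
  out
}

#' Disaggregate composite-region final demand
#'
#' The monetary system aggregates many physical regions into rest-of-world
#' composites. Composite-region demand is split across its member physical
#' regions proportionally to population (equal per-capita consumption within
#' a composite); totals are conserved exactly.
#'
#' @param y_mon matrix of monetary final demand with one column per monetary
#'   region.
#' @param concordance named character vector, physical region -> monetary
#'   region.
#' @param population named numeric vector of persons per physical region.
#' @return Matrix with one column per physical region (order of
#'   `names(concordance)`).
#' @export
disaggregate_rest_of_world <- function(y_mon, concordance, population) {
  y_mon <- as.matrix(y_mon)
  regions_phys <- names(concordance)
  if (is.null(regions_phys))
    abort_structural("disaggregate_rest_of_world(): concordance must be named")
  if (!all(concordance %in% colnames(y_mon)))
    abort_structural("disaggregate_rest_of_world(): y_mon lacks columns for some monetary regions")
  if (!all(regions_phys %in% names(population)))
    abort_validation("disaggregate_rest_of_world(): population missing for some regions")
  pop <- population[regions_phys]
  if (any(pop <= 0))
    abort_validation("disaggregate_rest_of_world(): population must be positive")
  totals <- tapply(pop, concordance, sum)
  if (any(totals[unique(concordance)] <= 0))
    abort_validation("disaggregate_rest_of_world(): composite region with zero population")
  share <- pop / totals[concordance]
  out <- y_mon[, concordance, drop = FALSE] *
    rep(share, each = nrow(y_mon))
  colnames(out) <- regions_phys
  out
}

#' Consumption-based land-use footprint
#'
#' Traces final demand through the hybrid Leontief system to the physical
#' sectors whose output occupies land, and scales their output requirements
#' by the land-use intensity of the producing sector. Food demand (physical
#' final demand) and nonfood demand (monetary final demand routed through the
#' link block) are kept as separate provenance partitions; they are disjoint
#' and sum to the total. When `by_product = TRUE` the footprint is also
#' resolved by the final product purchased, which is what final-product
#' attribution of species loss consumes.
#'
#' @param economy a [assemble_hybrid()] result.
#' @param extension a [land_extension()] for the physical system.
#' @param y_phys physical final demand, physical sectors x consuming physical
#'   regions.
#' @param y_mon monetary final demand, monetary sectors x consuming monetary
#'   regions (disaggregated internally via the concordance and population) or
#'   x physical regions if already disaggregated.
#' @param by_product also resolve footprints by final product.
#' @param method `"inverse"` forms the explicit block inverses, `"solve"`
#'   solves one linear system per demand column, `"auto"` picks by system
#'   side; both paths agree to numerical precision.
#' @param solve_side_threshold side above which `"auto"` switches to the
#'   solver path.
#' @return An object of class `footprint_tensor` with arrays
#'   `[consumer, producer, product, category]` for `food`, `nonfood` and
#'   `total`, optional by-product arrays, and the extension it was built
#'   from.
#' @export
consumption_footprint <- function(economy, extension, y_phys, y_mon,
                                  by_product = TRUE,
                                  method = c("auto", "inverse", "solve"),
                                  solve_side_threshold = 2048L) {
  method <- match.arg(method)
  y_phys <- as.matrix(y_phys); y_mon <- as.matrix(y_mon)
  n_p <- length(economy$sectors_phys)
  n_m <- length(economy$sectors_mon)
  regions <- economy$regions_phys
  products <- economy$products_phys
  n_r <- length(regions); n_i <- length(products)
  n_cat <- length(extension$categories)
  if (nrow(y_phys) != n_p)
    abort_structural("consumption_footprint(): y_phys rows must match physical sectors")
  if (nrow(y_mon) != n_m)
    abort_structural("consumption_footprint(): y_mon rows must match monetary sectors")
  if (any(y_phys < 0) || any(y_mon < 0))
    abort_validation("consumption_footprint(): negative final demand not allowed")
  if (!identical(extension$regions, regions) ||
      !identical(extension$products, products))
    abort_structural("consumption_footprint(): extension labels must match the economy")
  if (ncol(y_phys) != n_r)
    abort_structural("consumption_footprint(): y_phys needs one column per physical region")
  colnames(y_phys) <- colnames(y_phys) %||% regions

  # nonfood demand per physical consumer region
  if (ncol(y_mon) == length(economy$regions_mon)) {
    colnames(y_mon) <- colnames(y_mon) %||% economy$regions_mon
    y_mon_d <- disaggregate_rest_of_world(y_mon, economy$concordance,
                                          economy$population)
  } else if (ncol(y_mon) == n_r) {
    colnames(y_mon) <- colnames(y_mon) %||% regions
    y_mon_d <- y_mon
  } else {
    abort_structural("consumption_footprint(): y_mon needs one column per monetary or physical region")
  }

  side <- n_p + n_m
  use_inverse <- method == "inverse" ||
    (method == "auto" && side <= solve_side_threshold)
  if (use_inverse) {
    L <- block_leontief(economy)
    apply_LA <- function(Y) L$L_A %*% Y
    apply_LB <- function(Y) L$L_B %*% Y
  } else {
    apply_LA <- function(Y) leontief_solve(economy$A_phys, Y)
    apply_LB <- function(Y) leontief_solve(economy$A_mon, Y)
  }

  X_food <- apply_LA(y_phys)                                   # phys sectors x s
  X_nonfood <- apply_LA(economy$A_link %*% apply_LB(y_mon_d))  # phys sectors x s

  tensorize <- function(X) {
    # X: [sector(i fastest within r), consumer] -> F[s, r, i, m]
    Xsri <- aperm(array(X, c(n_i, n_r, n_r)), c(3L, 2L, 1L))   # s, r, i
    FF <- array(Xsri, c(n_r, n_r, n_i, n_cat)) *
      aperm(array(extension$e, c(n_r, n_i, n_cat, n_r)), c(4L, 1L, 2L, 3L))
    dimnames(FF) <- list(consumer = regions, producer = regions,
                         product = products, category = extension$categories)
    FF
  }

  F_food <- tensorize(X_food)
  F_nonfood <- tensorize(X_nonfood)

  bp_food <- bp_nonfood <- NULL
  if (by_product) {
    # food: split demand by the final physical product j (the product of the
    # demand row); linearity lets each product's demand run independently.
    prod_of_phys_row <- rep(seq_len(n_i), times = n_r)
    bp_food <- array(0, c(n_i, n_r, n_r, n_i, n_cat),
                     dimnames = c(list(final_product = products),
                                  dimnames(F_food)))
    for (j in seq_len(n_i)) {
      Yj <- y_phys * (prod_of_phys_row == j)
      bp_food[j, , , , ] <- tensorize(apply_LA(Yj))
    }
    # nonfood: split by the final monetary product k.
    n_k <- length(economy$products_mon)
    prod_of_mon_row <- rep(seq_len(n_k), times = length(economy$regions_mon))
    bp_nonfood <- array(0, c(n_k, n_r, n_r, n_i, n_cat),
                        dimnames = c(list(final_product = economy$products_mon),
                                     dimnames(F_food)))
    for (k in seq_len(n_k)) {
      Yk <- y_mon_d * (prod_of_mon_row == k)
      bp_nonfood[k, , , , ] <- tensorize(apply_LA(economy$A_link %*% apply_LB(Yk)))
    }
  }

  structure(list(
    food = F_food, nonfood = F_nonfood, total = F_food + F_nonfood,
    by_product_food = bp_food, by_product_nonfood = bp_nonfood,
    consumers = regions, extension = extension
  ), class = "footprint_tensor")
}

#' @export
print.footprint_tensor <- function(x, ...) {
  cat("<footprint_tensor> ", paste(dim(x$total), collapse = " x "),
      " (consumer x producer x product x category); total ",
      format(sum(x$total), digits = 4), " m2 (food ",
      format(100 * sum(x$food) / max(sum(x$total), .Machine$double.xmin),
             digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' Footprint conservation report
#'
#' Checks that summing the footprint over consumers reproduces the
#' production-based land extension per producer, product and category: global
#' consumption-based land use must equal production-based land use whenever
#' final demand closes the system.
#'
#' @param footprint a [consumption_footprint()] result.
#' @param tol relative tolerance.
#' @return List with `max_rel_diff`, `pass`, and the two compared arrays.
#' @export
footprint_conservation <- function(footprint, tol = 1e-9) {
  by_producer <- apply(footprint$total, c(2, 3, 4), sum)
  d <- footprint$extension$d
  mrd <- max(rel_diff(by_producer, d))
  list(max_rel_diff = mrd, pass = mrd <= tol,
       consumption_based = by_producer, production_based = d)
}
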