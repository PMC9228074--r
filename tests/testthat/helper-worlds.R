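# Shared fixtures and independent oracles, all built in code.

# Run the full analysis chain on a world; returns every intermediate.
run_chain <- function(world, by_product = TRUE) {
  eco <- world_economy(world)
  fp <- consumption_footprint(eco, world$extension, world$phys$y,
                              world$mon$y, by_product = by_product)
  sh <- normalize_distribution(world$grid, world$extension)
  g <- allocate_land(fp, sh, world$masks)
  acc <- species_loss(g, world$cfs, world$masks,
                      footprint = if (by_product) fp else NULL,
                      shares = if (by_product) sh else NULL)
  list(economy = eco, footprint = fp, shares = sh, grid = g, account = acc)
}

# Random productive hybrid economy of bounded side, for Leontief oracles.
random_hybrid_economy <- function(seed) {
  set.seed(seed)
  n_r <- sample(2:4, 1); n_i <- sample(2:4, 1)
  n_u <- sample(1:n_r, 1); n_k <- sample(2:4, 1)
  rho <- stats::runif(1, 0.2, 0.85)
  n_p <- n_r * n_i; n_m <- n_u * n_k
  rand_block <- function(n, target) {
    A <- matrix(stats::runif(n * n), n, n) *
      (matrix(stats::runif(n * n), n, n) < 0.5)
    diag(A) <- diag(A) + 0.1
    A * (target / max(Mod(eigen(A, only.values = TRUE)$values)))
  }
  A_phys <- rand_block(n_p, rho)
  A_mon <- rand_block(n_m, stats::runif(1, 0.2, 0.85))
  A_link <- matrix(stats::runif(n_p * n_m, 0, 0.3), n_p, n_m)
  regions <- sprintf("R%02d", seq_len(n_r))
  regions_mon <- sprintf("M%02d", seq_len(n_u))
  assemble_hybrid(A_phys, A_link, A_mon,
                  concordance = stats::setNames(
                    regions_mon[pmin(seq_len(n_r), n_u)], regions),
                  population = stats::setNames(stats::runif(n_r, 1, 10) * 1e6,
                                               regions),
                  regions, sprintf("p%02d", seq_len(n_i)),
                  regions_mon, sprintf("s%02d", seq_len(n_k)))
}

# Dense-inverse oracle: Leontief inverse of the full coupled matrix.
dense_leontief_oracle <- function(economy) {
  A <- block_matrix(economy)
  solve(diag(nrow(A)) - A)
}

# Assemble the block result into a full matrix for comparison.
blocks_as_matrix <- function(L) {
  n_p <- nrow(L$L_A); n_m <- nrow(L$L_B)
  rbind(cbind(L$L_A, L$L_AB), cbind(matrix(0, n_m, n_p), L$L_B))
}

# Brute-force species-loss oracle: explicit per-cell, per-taxon, per-category
# loop over the allocated grid (independent of the vectorized path).
brute_species_loss <- function(grid, cfs, masks) {
  n_g <- length(cfs$taxa); n_s <- length(grid$consumers)
  n_m <- length(grid$categories); n_r <- length(masks$regions)
  out <- array(0, c(n_g, n_s, n_r, n_m, 2),
               dimnames = list(taxon = cfs$taxa, consumer = grid$consumers,
                               producer = masks$regions,
                               category = grid$categories,
                               kba = c("inside", "outside")))
  for (n in seq_len(masks$geometry$ncell)) {
    r <- masks$country_id[n]
    if (r == 0) next
    e <- masks$ecoregion_id[n]
    k <- if (masks$kba[n]) 1L else 2L
    for (g in seq_len(n_g)) for (s in seq_len(n_s)) for (m in seq_len(n_m)) {
      land <- grid$total[s, m, n]
      if (land == 0) next
      cf <- if (e > 0) cfs$cf[g, m, e] else 0
      out[g, s, r, m, k] <- out[g, s, r, m, k] + cf * land
    }
  }
  out
}

# Brute-force Spearman oracle: Pearson correlation of average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
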