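test_that("the four factors form an exact multiplicative identity", {
  dec <- country_decomposition(
    kba_area = c(X = 100), land_use = c(X = 50),
    richness = matrix(10, 1, 1), species_loss = matrix(0.2, 1, 1),
    regions = "X", taxa = "plants")
  expect_equal(unname(dec$f_area), 100)
  expect_equal(unname(dec$f_share), 0.5)
  expect_equal(unname(dec$f_richness[1, 1]), 0.2)
  expect_equal(unname(dec$f_relative_loss[1, 1]), 0.02)
  expect_equal(unname(reconstruct_loss(dec)[1, 1]), 0.2)
})

test_that("zero land use leaves downstream factors undefined", {
  dec <- country_decomposition(
    kba_area = c(X = 100, Y = 80), land_use = c(X = 50, Y = 0),
    richness = matrix(c(10, 0), 2, 1), species_loss = matrix(c(0.2, 0), 2, 1),
    taxa = "plants")
  expect_true(dec$defined["X", "plants"])
  expect_false(dec$defined["Y", "plants"])
  expect_true(is.na(reconstruct_loss(dec)["Y", "plants"]))
})

test_that("decomposition reconstructs pipeline species loss on generated worlds", {
  for (seed in c(41, 42)) {
    world <- generate_world(world_config(seed = seed))
    ch <- run_chain(world, by_product = FALSE)
    dec <- decompose_kba_loss(ch$account, ch$grid, world$masks, world$cfs)
    rec <- reconstruct_loss(dec)
    ok <- dec$defined
    expect_true(any(ok))
    expect_lt(max(abs(rec[ok] - dec$species_loss[ok]) /
                    pmax(dec$species_loss[ok], 1e-300)), 1e-12)
    # land inside KBAs can never exceed the KBA area
    expect_true(all(dec$land_use <= dec$kba_area + 1e-9 * dec$kba_area))
  }
})

test_that("spearman correlation matches a direct rank-based oracle", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 7, 10)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  expect_equal(spearman_rho(x, y), spearman_oracle(x, y))
  expect_equal(spearman_rho(x, y), 0.6)

  set.seed(8)
  for (i in 1:10) {
    x <- sample(20, 12, replace = TRUE)  # replace=TRUE exercises ties
    y <- sample(20, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y),
                 tolerance = 1e-12)
  }

  expect_error(spearman_rho(1:2, 1:2),
               class = "kbafootprint_validation_error")
  expect_warning(out <- spearman_rho(c(1, 1, 1), 1:3), "zero variance")
  expect_true(is.na(out))
})

test_that("a single varying driver takes all contribution to variance", {
  n <- 12
  A <- seq(1, 12) * 1e6           # only varying factor
  share <- rep(0.5, n)
  richness <- matrix(A * share * 2e-9, ncol = 1)  # rich = L * const
  sl <- richness * 0.01
  dec <- country_decomposition(A, A * share, richness, sl, taxa = "plants")
  res <- ctv(dec)
  expect_equal(unname(res$ctv[, "plants"]), c(100, 0, 0, 0))
})

test_that("four equally correlated factors share CTV equally", {
  # factors all equal SL^(1/4): each has rank correlation 1 by symmetry
  sl <- seq(0.1, 0.9, length.out = 9)
  f <- sl^(1 / 4)
  dec <- country_decomposition(
    kba_area = f, land_use = f^2, richness = matrix(f^3, ncol = 1),
    species_loss = matrix(sl, ncol = 1), taxa = "plants")
  res <- ctv(dec)
  expect_equal(unname(res$ctv[, "plants"]), rep(25, 4))
})

test_that("planted co-driver decompositions recover near-equal CTV", {
  cd <- planted_ctv_codrivers(200, seed = 5)
  rec <- reconstruct_loss(cd$decomposition)
  expect_lt(max(abs(rec - cd$decomposition$species_loss) /
                  cd$decomposition$species_loss), 1e-12)
  res <- ctv(cd$decomposition)
  expect_lt(max(abs(res$ctv[, 1] - 25)), 2)
  expect_equal(sum(res$ctv[, 1]), 100, tolerance = 1e-9)
})

test_that("CTV is invariant to country order and factor-monotone rescaling", {
  cd <- planted_ctv_codrivers(60, seed = 9)
  res <- ctv(cd$decomposition)
  set.seed(1)
  perm <- sample(60)
  d <- cd$decomposition
  dp <- country_decomposition(
    kba_area = d$kba_area[perm], land_use = d$land_use[perm],
    richness = d$richness[perm, , drop = FALSE],
    species_loss = d$species_loss[perm, , drop = FALSE],
    regions = d$regions[perm], taxa = d$taxa)
  resp <- ctv(dp)
  expect_equal(unname(resp$ctv), unname(res$ctv), tolerance = 1e-12)

  # rank correlations see only order: rescaling a factor monotonically
  # (constant positive multiple) changes nothing
  ds <- country_decomposition(
    kba_area = d$kba_area * 10, land_use = d$land_use,
    richness = d$richness, species_loss = d$species_loss,
    regions = d$regions, taxa = d$taxa)
  ress <- ctv(ds)
  expect_equal(unname(ress$ctv), unname(res$ctv), tolerance = 1e-12)
})

test_that("CTV needs at least three usable countries and one defined factor", {
  dec <- country_decomposition(
    kba_area = c(1, 2), land_use = c(0.5, 1),
    richness = matrix(c(1, 2), 2, 1), species_loss = matrix(c(0.1, 0.2), 2, 1),
    taxa = "plants")
  expect_error(ctv(dec), class = "kbafootprint_analysis_error")
})
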