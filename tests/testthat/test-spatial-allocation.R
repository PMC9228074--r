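test_that("raster layers normalize to shares that sum to one", {
  geom <- grid_geometry(1, 4, 1e6)
  R <- array(0, c(4, 1, 1, 15))
  R[, 1, 1, 1] <- c(2, 2, 4, 2)
  grid <- land_use_grid(R, geom, "A", "p")
  d <- array(0, c(1, 1, 15)); d[1, 1, 1] <- 10
  ext <- land_extension(d, 10, "A", "p")
  sh <- normalize_distribution(grid, ext)
  expect_equal(sh$shares[, 1, 1, 1], c(0.2, 0.2, 0.4, 0.2))

  # single-cell layer gets share one
  geom1 <- grid_geometry(1, 1, 1e6)
  R1 <- array(0, c(1, 1, 1, 15)); R1[1, 1, 1, 1] <- 7
  sh1 <- normalize_distribution(land_use_grid(R1, geom1, "A", "p"),
                                land_extension(d, 10, "A", "p"))
  expect_equal(sh1$shares[1, 1, 1, 1], 1)

  # random layers: every nonempty layer sums to one
  world <- generate_world(world_config(seed = 21))
  sh <- normalize_distribution(world$grid, world$extension)
  sums <- apply(sh$shares, c(2, 3, 4), sum)
  expect_lt(max(abs(sums[sh$defined] - 1)), 1e-12)
  expect_true(all(sums[!sh$defined] == 0))
})

test_that("land recorded without raster support is an allocation gap", {
  geom <- grid_geometry(1, 2, 1e6)
  R <- array(0, c(2, 1, 1, 15))
  grid <- land_use_grid(R, geom, "A", "p")
  d <- array(0, c(1, 1, 15)); d[1, 1, 3] <- 5
  ext <- land_extension(d, 10, "A", "p")
  expect_error(normalize_distribution(grid, ext),
               class = "kbafootprint_allocation_gap_error")
})

test_that("allocation spreads footprints proportionally and conserves marginals", {
  world <- generate_world(world_config(seed = 22))
  ch <- run_chain(world, by_product = FALSE)
  cons <- allocation_conservation(ch$grid, ch$footprint, world$masks)
  expect_lt(cons$max_rel_diff, 1e-9)

  # hand-checked proportional split: a footprint of 10 m2 over shares
  # (0.25, 0.75) lands as (2.5, 7.5)
  geom <- grid_geometry(1, 2, 1e6)
  R <- array(0, c(2, 1, 1, 15)); R[, 1, 1, 1] <- c(1, 3)
  d <- array(0, c(1, 1, 15)); d[1, 1, 1] <- 10
  ext <- land_extension(d, 1, "A", "p")
  sh <- normalize_distribution(land_use_grid(R, geom, "A", "p"), ext)
  msk <- cell_masks(c(1L, 1L), c(1L, 1L), c(TRUE, FALSE), geom, "A", "E01")
  f_arr <- array(0, c(1, 1, 1, 15))
  f_arr[1, 1, 1, 1] <- 10
  dimnames(f_arr) <- list(consumer = "A", producer = "A", product = "p",
                          category = land_use_categories())
  fp <- structure(list(food = f_arr, nonfood = f_arr * 0, total = f_arr,
                       consumers = "A", extension = ext),
                  class = "footprint_tensor")
  g <- allocate_land(fp, sh, msk)
  expect_equal(as.numeric(g$total[1, 1, ]), c(2.5, 7.5))
})

test_that("two consumers with equal demand get identical spatial patterns", {
  world <- generate_world(world_config(seed = 23))
  eco <- world_economy(world)
  y <- world$phys$y
  y[, 2] <- y[, 1]
  ym <- world$mon$y * 0  # food only, to keep consumer columns comparable
  fp <- consumption_footprint(eco, world$extension, y, ym)
  sh <- normalize_distribution(world$grid, world$extension)
  g <- allocate_land(fp, sh, world$masks)
  expect_equal(g$total[1, , ], g$total[2, , ], tolerance = 1e-12)
})

test_that("KBA split is an exact cellwise partition", {
  world <- generate_world(world_config(seed = 24))
  ch <- run_chain(world, by_product = FALSE)
  parts <- split_by_kba(ch$grid, world$masks)
  expect_equal(parts$inside$total + parts$outside$total, ch$grid$total)

  all_in <- world$masks
  all_in$kba <- rep(TRUE, all_in$geometry$ncell)
  parts <- split_by_kba(ch$grid, all_in)
  expect_equal(sum(parts$outside$total), 0)
  none <- world$masks
  none$kba <- rep(FALSE, none$geometry$ncell)
  parts <- split_by_kba(ch$grid, none)
  expect_equal(sum(parts$inside$total), 0)
})

test_that("allocation is invariant to halving cells (refinement invariance)", {
  world <- generate_world(world_config(seed = 25))
  ch <- run_chain(world, by_product = FALSE)
  geom <- world$masks$geometry
  # split every cell into two horizontal halves with halved land
  idx <- rep(seq_len(geom$ncell), each = 2)
  geom2 <- grid_geometry(geom$nrow, geom$ncol * 2, geom$cell_area_m2 / 2)
  R2 <- world$grid$R[idx, , , , drop = FALSE] / 2
  grid2 <- land_use_grid(R2, geom2, world$phys$regions, world$phys$products)
  masks2 <- cell_masks(world$masks$country_id[idx],
                       world$masks$ecoregion_id[idx],
                       world$masks$kba[idx], geom2,
                       world$masks$regions, world$masks$ecoregions)
  sh2 <- normalize_distribution(grid2, world$extension)
  g2 <- allocate_land(ch$footprint, sh2, masks2)
  # country sums unchanged by the refinement
  for (r in seq_along(world$phys$regions)) {
    orig <- sum(ch$grid$total[, , world$masks$country_id == r])
    refined <- sum(g2$total[, , masks2$country_id == r])
    expect_equal(refined, orig, tolerance = 1e-12)
  }
})

test_that("allocation is invariant to product layer ordering", {
  world <- generate_world(world_config(seed = 26))
  ch <- run_chain(world, by_product = FALSE)
  perm <- rev(seq_along(world$phys$products))
  grid_p <- land_use_grid(world$grid$R[, , perm, , drop = FALSE],
                          world$masks$geometry, world$phys$regions,
                          world$phys$products[perm])
  ext_p <- world$extension
  ext_p$d <- ext_p$d[, perm, , drop = FALSE]
  ext_p$e <- ext_p$e[, perm, , drop = FALSE]
  ext_p$products <- world$phys$products[perm]
  sh_p <- normalize_distribution(grid_p, ext_p)
  fp_p <- ch$footprint
  for (f in c("food", "nonfood", "total"))
    fp_p[[f]] <- fp_p[[f]][, , perm, , drop = FALSE]
  g_p <- allocate_land(fp_p, sh_p, world$masks)
  expect_equal(g_p$total, ch$grid$total, tolerance = 1e-12)
})

test_that("geometry mismatches are structural errors", {
  world <- generate_world(world_config(seed = 27))
  ch <- run_chain(world, by_product = FALSE)
  other <- cell_masks(rep(1L, 4), rep(1L, 4), rep(TRUE, 4),
                      grid_geometry(2, 2, 1e6), world$phys$regions, "E01")
  expect_error(split_by_kba(ch$grid, other),
               class = "kbafootprint_structural_error")
  expect_error(allocate_land(ch$footprint, ch$shares, other),
               class = "kbafootprint_structural_error")
})
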