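# Minimal hand-built single-cell world for exact CF arithmetic.
one_cell_setup <- function(cf_value = 1e-3, land = 10) {
  geom <- grid_geometry(1, 1, 1e6)
  masks <- cell_masks(1L, 1L, TRUE, geom, "A", "E01")
  g_arr <- array(0, c(1, 15, 1),
                 dimnames = list(consumer = "A",
                                 category = land_use_categories(),
                                 cell = NULL))
  g_arr[1, 1, 1] <- land
  grid <- structure(list(food = g_arr, nonfood = g_arr * 0, total = g_arr,
                         geometry = geom, consumers = "A",
                         categories = land_use_categories()),
                    class = "allocated_grid")
  cf <- array(cf_value, c(5, 15, 1))
  cfs <- cf_table(cf, matrix(1e-9, 5, 1), ecoregions = "E01")
  list(grid = grid, masks = masks, cfs = cfs)
}

test_that("species loss multiplies land by the cell CF", {
  s <- one_cell_setup(cf_value = 1e-3, land = 10)
  acc <- species_loss(s$grid, s$cfs, s$masks)
  expect_equal(unname(acc$total["plants", "A", "A", 1, "inside"]), 0.01)
  expect_equal(sum(acc$total[, , , , "outside"]), 0)

  s0 <- one_cell_setup(cf_value = 0)
  acc0 <- species_loss(s0$grid, s0$cfs, s0$masks)
  expect_equal(sum(acc0$total), 0)
})

test_that("species loss is linear in CFs and in land use", {
  world <- generate_world(world_config(seed = 31))
  ch <- run_chain(world, by_product = FALSE)
  cfs3 <- world$cfs
  cfs3$cf <- cfs3$cf * 3
  acc3 <- species_loss(ch$grid, cfs3, world$masks)
  expect_equal(acc3$total, 3 * ch$account$total, tolerance = 1e-12)

  g2 <- ch$grid
  for (f in c("food", "nonfood", "total")) g2[[f]] <- g2[[f]] * 2
  acc2 <- species_loss(g2, world$cfs, world$masks)
  expect_equal(acc2$total, 2 * ch$account$total, tolerance = 1e-12)
})

test_that("vectorized species loss equals the brute-force cell loop", {
  world <- generate_world(world_config(seed = 32))
  ch <- run_chain(world, by_product = FALSE)
  oracle <- brute_species_loss(ch$grid, world$cfs, world$masks)
  expect_equal(ch$account$total, oracle, tolerance = 1e-12)
})

test_that("cells with land but no CF are a coverage error unless zero-filled", {
  s <- one_cell_setup()
  bad_masks <- s$masks
  bad_masks$ecoregion_id <- 0L  # land present, no ecoregion
  expect_error(species_loss(s$grid, s$cfs, bad_masks),
               class = "kbafootprint_coverage_error")
  acc <- species_loss(s$grid, s$cfs, bad_masks, missing_cf = "zero")
  expect_equal(sum(acc$total), 0)
  expect_equal(acc$coverage_gap_cells, 1L)
})

test_that("production and consumption perspectives share one global total", {
  world <- generate_world(world_config(seed = 33))
  ch <- run_chain(world, by_product = FALSE)
  pc <- production_vs_consumption(ch$account)
  expect_equal(sum(pc$production), sum(pc$consumption), tolerance = 1e-9)

  # autarky: the two perspectives coincide country by country
  nt <- planted_scenario("no-trade")
  chn <- run_chain(nt$world, by_product = FALSE)
  pcn <- production_vs_consumption(chn$account)
  expect_equal(pcn$production, pcn$consumption, tolerance = 1e-9,
               ignore_attr = TRUE)

  # single exporter: the exporter's production exceeds its consumption
  se <- generate_world(world_config(seed = 34,
                                    trade_topology = "single-exporter",
                                    n_mon_regions = 4))
  chs <- run_chain(se, by_product = FALSE)
  pcs <- production_vs_consumption(chs$account)
  expect_gt(sum(pcs$production[, 1]), sum(pcs$consumption[, 1]))
})

test_that("per-capita division is elementwise and validates population", {
  tab <- matrix(c(2e-4, 4e-4), 1, 2, dimnames = list("plants", c("A", "B")))
  out <- per_capita(tab, c(A = 100, B = 100))
  expect_equal(unname(out["plants", "A"]), 2e-6)
  # equal losses, tenfold population ratio -> tenth of the per-capita value
  out2 <- per_capita(matrix(c(1, 1), 1, 2,
                            dimnames = list("plants", c("A", "B"))),
                     c(A = 10, B = 100))
  expect_equal(unname(out2[1, "B"] / out2[1, "A"]), 0.1)
  expect_error(per_capita(tab, c(A = 100, B = 0)),
               class = "kbafootprint_validation_error")
  expect_error(per_capita(tab, c(A = 100)),
               class = "kbafootprint_validation_error")
})

test_that("trade flows conserve the account total and classify topologies", {
  world <- generate_world(world_config(seed = 35))
  ch <- run_chain(world, by_product = FALSE)
  fl <- trade_flows(ch$account)
  expect_equal(apply(fl$flows, 1, sum), apply(ch$account$total, 1, sum),
               tolerance = 1e-12)

  # grouped flows conserve too
  grouping <- c(C01 = "north", C02 = "north", C03 = "south", C04 = "south")
  flg <- trade_flows(ch$account, grouping)
  expect_equal(apply(flg$flows, 1, sum), apply(ch$account$total, 1, sum),
               tolerance = 1e-12)

  nt <- planted_scenario("no-trade")
  chn <- run_chain(nt$world, by_product = FALSE)
  fln <- trade_flows(chn$account)
  expect_equal(max(fln$trade_share), 0)
  off <- fln$flows
  for (g in seq_len(dim(off)[1])) diag(off[g, , ]) <- 0
  expect_equal(sum(off), 0)

  expect_error(trade_flows(ch$account, grouping[-1]),
               class = "kbafootprint_validation_error")
})

test_that("product attribution partitions the total loss", {
  world <- generate_world(world_config(seed = 36))
  ch <- run_chain(world)
  at <- product_attribution(ch$account)
  tot_by_taxon <- apply(ch$account$total, 1, sum)
  got <- tapply(at$table$species_lost, at$table$taxon, sum)
  expect_equal(got[names(tot_by_taxon)], tot_by_taxon, tolerance = 1e-9,
               ignore_attr = TRUE)

  # grouping products coarsely preserves the partition
  gf <- stats::setNames(rep("food", length(world$phys$products)),
                        world$phys$products)
  gn <- stats::setNames(rep("goods", length(world$mon$products)),
                        world$mon$products)
  at2 <- product_attribution(ch$account, gf, gn)
  got2 <- tapply(at2$table$species_lost, at2$table$taxon, sum)
  expect_equal(got2[names(tot_by_taxon)], tot_by_taxon, tolerance = 1e-9,
               ignore_attr = TRUE)

  # a single-product world attributes everything to that product
  sc <- planted_scenario("single-chain")
  chs <- run_chain(sc$world)
  ats <- product_attribution(chs$account)
  expect_equal(unname(ats$food_share), rep(1, 5), tolerance = 1e-12)
  one <- ats$table[ats$table$taxon == "plants" & ats$table$species_lost > 0, ]
  expect_equal(one$group, "p01")
})

test_that("uniform CFs make loss proportional to land across countries", {
  uc <- planted_scenario("uniform-cf")
  ch <- run_chain(uc$world, by_product = FALSE)
  prod_sl <- apply(ch$account$total, c(1, 3), sum)
  land <- uc$expected$land_by_producer
  ratio <- sweep(prod_sl, 2, land, "/")
  spread <- apply(ratio, 1, function(z) diff(range(z)) / mean(z))
  expect_lt(max(spread), 1e-12)
})

test_that("taxon group sums add the four vertebrate classes", {
  world <- generate_world(world_config(seed = 37))
  ch <- run_chain(world, by_product = FALSE)
  groups <- taxon_group_sums(ch$account$total)
  expect_equal(groups["plants", , , , ], ch$account$total["plants", , , , ])
  verts <- apply(ch$account$total[vertebrate_taxa(), , , , , drop = FALSE],
                 2:5, sum)
  expect_equal(groups["vertebrates", , , , ], verts, tolerance = 1e-12)
})

test_that("relative loss reports the share of global richness", {
  s <- one_cell_setup(cf_value = 1e-3, land = 10)
  acc <- species_loss(s$grid, s$cfs, s$masks)
  rel <- relative_loss(acc)
  expect_equal(unname(rel["plants"]), 0.01 / 321212)
})
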