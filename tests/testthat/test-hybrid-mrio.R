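test_that("technical coefficients divide flows by output and zero inert columns", {
  expect_equal(technical_coefficients(matrix(4), 8), matrix(0.5))
  A <- technical_coefficients(matrix(c(1, 0, 0, 2), 2), c(2, 0))
  expect_equal(A, matrix(c(0.5, 0, 0, 0), 2))

  set.seed(101)
  Z <- matrix(runif(36), 6)
  x <- runif(6, 1, 5)
  A <- technical_coefficients(Z, x)
  expect_lt(max(abs(A %*% diag(x) - Z)), 1e-12)

  expect_error(technical_coefficients(matrix(1, 2, 3), c(1, 2)),
               class = "kbafootprint_structural_error")
  expect_error(technical_coefficients(matrix(-1), 1),
               class = "kbafootprint_validation_error")
})

test_that("hybrid assembly validates block shapes, concordance and productiveness", {
  ok <- assemble_hybrid(matrix(0.2), matrix(0.1), matrix(0.5),
                        c(A = "M"), c(A = 10), "A", "p", "M", "s")
  expect_s3_class(ok, "hybrid_economy")
  expect_equal(ok$spectral_radius, 0.5)

  expect_error(
    assemble_hybrid(matrix(0.2), matrix(0.1, 2, 1), matrix(0.5),
                    c(A = "M"), c(A = 10), "A", "p", "M", "s"),
    class = "kbafootprint_structural_error")
  expect_error(
    assemble_hybrid(matrix(0.2), matrix(0.1), matrix(1.01),
                    c(A = "M"), c(A = 10), "A", "p", "M", "s"),
    class = "kbafootprint_nonproductive_error")
  expect_error(
    assemble_hybrid(matrix(0.2), matrix(0.1), matrix(0.5),
                    c(B = "M"), c(A = 10), "A", "p", "M", "s"),
    class = "kbafootprint_validation_error")
})

test_that("all-zero blocks give the identity Leontief inverse", {
  eco <- assemble_hybrid(matrix(0), matrix(0), matrix(0),
                         c(A = "M"), c(A = 1), "A", "p", "M", "s")
  L <- block_leontief(eco)
  expect_equal(unname(blocks_as_matrix(L)), diag(2))
})

test_that("block Leontief matches hand-derived 1x1-block values", {
  eco <- assemble_hybrid(matrix(0.2), matrix(0.1), matrix(0.5),
                         c(A = "M"), c(A = 1), "A", "p", "M", "s")
  L <- block_leontief(eco)
  expect_equal(unname(blocks_as_matrix(L)),
               matrix(c(1.25, 0, 0.25, 2), 2), tolerance = 1e-12)
})

test_that("block Leontief equals the dense inverse of the coupled system", {
  for (seed in 1:10) {
    eco <- random_hybrid_economy(seed)
    L <- blocks_as_matrix(block_leontief(eco))
    expect_lt(max(abs(L - dense_leontief_oracle(eco))), 1e-10)
  }
})

test_that("Leontief power series increases entrywise toward the inverse", {
  eco <- random_hybrid_economy(42)
  A <- block_matrix(eco)
  L <- dense_leontief_oracle(eco)
  S <- diag(nrow(A))
  P <- diag(nrow(A))
  prev_gap <- Inf
  for (k in 1:200) {
    P <- P %*% A
    S <- S + P
    gap <- max(L - S)
    expect_true(all(L - S >= -1e-10))  # partial sums never overshoot
    expect_lte(gap, prev_gap + 1e-12)  # monotone approach
    prev_gap <- gap
  }
  expect_lt(prev_gap, 1e-6)
})

test_that("rest-of-world demand splits by population and conserves totals", {
  y <- matrix(100, 1, 1, dimnames = list(NULL, "RoW"))
  out <- disaggregate_rest_of_world(y, c(a = "RoW", b = "RoW"),
                                    c(a = 1, b = 3))
  expect_equal(as.numeric(out), c(25, 75))

  out1 <- disaggregate_rest_of_world(y, c(a = "RoW"), c(a = 7))
  expect_equal(as.numeric(out1), 100)

  set.seed(7)
  y <- matrix(runif(12, 0, 50), 4, 3,
              dimnames = list(NULL, c("M1", "M2", "RoW")))
  conc <- c(r1 = "M1", r2 = "M2", r3 = "RoW", r4 = "RoW", r5 = "RoW")
  pop <- c(r1 = 2, r2 = 3, r3 = 5, r4 = 1, r5 = 9) * 1e6
  out <- disaggregate_rest_of_world(y, conc, pop)
  expect_equal(out[, "r3"] + out[, "r4"] + out[, "r5"], y[, "RoW"])
  expect_equal(out[, "r1"], y[, "M1"])
  expect_error(disaggregate_rest_of_world(y, conc, replace(pop, 3, 0)),
               class = "kbafootprint_validation_error")
})

test_that("a chain with no intermediates puts intensity times demand on the consumer", {
  # one unit of B's product demanded by A, intensity 5 m2/unit, no A matrix
  regions <- c("A", "B"); cats <- land_use_categories()
  eco <- assemble_hybrid(matrix(0, 2, 2), matrix(0, 2, 1), matrix(0),
                         c(A = "M", B = "M"), c(A = 1, B = 1),
                         regions, "p", "M", "s")
  d <- array(0, c(2, 1, 15)); d[2, 1, 4] <- 5
  ext <- land_extension(d, c(0, 1), regions, "p")
  y_phys <- matrix(0, 2, 2)
  y_phys[2, 1] <- 1  # B's product demanded by consumer A only
  y_mon <- matrix(0, 1, 1)
  fp <- consumption_footprint(eco, ext, y_phys, y_mon)
  expect_equal(fp$total["A", "B", "p", cats[4]], 5)
  expect_equal(sum(fp$total), 5)
  expect_equal(sum(fp$nonfood), 0)
})

test_that("monetary demand without a biomass link leaves no land footprint", {
  eco <- assemble_hybrid(matrix(0.2), matrix(0), matrix(0.4),
                         c(A = "M"), c(A = 1), "A", "p", "M", "s")
  d <- array(0, c(1, 1, 15)); d[1, 1, 1] <- 3
  ext <- land_extension(d, 1, "A", "p")
  fp <- consumption_footprint(eco, ext, matrix(0, 1, 1), matrix(10, 1, 1))
  expect_equal(sum(fp$total), 0)
})

test_that("footprints conserve land and respond linearly to demand", {
  world <- generate_world(world_config(seed = 5))
  ch <- run_chain(world, by_product = FALSE)
  expect_lt(footprint_conservation(ch$footprint)$max_rel_diff, 1e-9)

  # doubling one consumer's demand doubles its footprint, leaves others alone
  y2 <- world$phys$y
  y2[, 2] <- 2 * y2[, 2]
  ym2 <- world$mon$y  # monetary demand unchanged
  fp2 <- consumption_footprint(ch$economy, world$extension, y2, ym2)
  expect_equal(fp2$food[2, , , ], 2 * ch$footprint$food[2, , , ],
               tolerance = 1e-12)
  expect_equal(fp2$food[-2, , , ], ch$footprint$food[-2, , , ],
               tolerance = 1e-12)
})

test_that("solver and explicit-inverse footprint paths agree", {
  world <- generate_world(world_config(seed = 9))
  eco <- world_economy(world)
  fp_inv <- consumption_footprint(eco, world$extension, world$phys$y,
                                  world$mon$y, method = "inverse")
  fp_sol <- consumption_footprint(eco, world$extension, world$phys$y,
                                  world$mon$y, method = "solve")
  expect_lt(max(abs(fp_inv$total - fp_sol$total)) / max(fp_inv$total), 1e-10)
  expect_lt(max(abs(fp_inv$by_product_food - fp_sol$by_product_food)) /
              max(fp_inv$total), 1e-10)
})

test_that("zero-output sectors stay inert through the whole footprint", {
  world <- generate_world(world_config(seed = 13, zero_output_sectors = 2))
  expect_true(balance_check(world)$pass)
  ch <- run_chain(world, by_product = FALSE)
  expect_false(any(!is.finite(ch$footprint$total)))
  expect_lt(footprint_conservation(ch$footprint)$max_rel_diff, 1e-9)
  # inert sectors carry no land by construction, hence no footprint
  zero <- world$phys$x == 0
  xr <- matrix(world$phys$x, length(world$phys$products))
  for (r in seq_along(world$phys$regions))
    for (i in seq_along(world$phys$products))
      if (xr[i, r] == 0)
        expect_equal(sum(ch$footprint$total[, r, i, ]), 0)
})

test_that("negative final demand is rejected", {
  world <- generate_world(world_config(seed = 2))
  eco <- world_economy(world)
  y_bad <- world$phys$y; y_bad[1, 1] <- -1
  expect_error(consumption_footprint(eco, world$extension, y_bad, world$mon$y),
               class = "kbafootprint_validation_error")
})
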