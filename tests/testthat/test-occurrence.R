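test_that("occurrence tables read back from disk and validate their cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,sp1,sp2,sp3",
               "A,1,1,0",
               "B,0,1,0",
               "C,0,0,1"), path)
  occ <- suppressMessages(read_occurrence(path, "coarse"))
  expect_equal(sum(occ$incidence), 4)
  expect_equal(site_ids(occ), c("A", "B", "C"))
  expect_equal(species_ids(occ), c("sp1", "sp2", "sp3"))

  writeLines(c("site_id,sp1", "A,1", "A,0"), path)
  expect_error(suppressMessages(read_occurrence(path)), "duplicate site",
               class = "dsc_validation")

  writeLines(c("site_id,sp1,sp2", "A,1,0", "B,2,1"), path)
  err <- tryCatch(suppressMessages(read_occurrence(path)), error = identity)
  expect_s3_class(err, "dsc_validation")
  expect_match(conditionMessage(err), "row 'B'")
  expect_match(conditionMessage(err), "column 'sp1'")
})

test_that("write -> read round-trips a random matrix exactly", {
  occ <- random_occ(20, 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrence(occ, path)
  back <- suppressMessages(read_occurrence(path, "coarse"))
  expect_identical(back$incidence, occ$incidence)
})

test_that("block aggregation ORs presences and matches a per-block oracle", {
  grid <- grid_spec(20, 20, block_factor = 5)
  # one presence in one fine cell -> one coarse presence
  inc <- matrix(FALSE, 400, 2, dimnames = list(fine_site_ids(grid), c("a", "b")))
  inc[3, 1] <- TRUE          # inside block (0, 0)
  inc[, 2] <- TRUE           # saturated species
  occ <- occurrence_matrix(inc, "fine")
  coarse <- aggregate_to_coarse(occ, grid)
  expect_equal(unname(colSums(coarse$incidence)), c(1, 16))
  expect_equal(coarse$resolution, "coarse")

  # random fine matrix vs brute-force per-block OR
  occ_r <- random_occ(400, 8, seed = 2, density = 0.05, resolution = "fine")
  occ_r <- occurrence_matrix(occ_r$incidence, "fine",
                             sites = fine_site_ids(grid),
                             species = species_ids(occ_r))
  coarse_r <- aggregate_to_coarse(occ_r, grid)
  for (cr in 0:3) for (cc in 0:3) {
    rows <- as.vector(outer((cc * 5 + 1):(cc * 5 + 5),
                            (cr * 5 + 0:4) * 20, "+"))
    expected <- colSums(occ_r$incidence[rows, , drop = FALSE]) > 0
    got <- coarse_r$incidence[sprintf("r%dc%d", cr, cc), ]
    expect_equal(unname(got), unname(expected))
  }

  expect_error(aggregate_to_coarse(abc_occ(), grid), "fine grid",
               class = "dsc_validation")
})

test_that("aggregation with k = 1 is the identity and counts are ordered", {
  grid1 <- grid_spec(6, 7, block_factor = 1)
  occ <- random_occ(42, 5, seed = 7, resolution = "fine")
  occ <- occurrence_matrix(occ$incidence, "fine",
                           sites = fine_site_ids(grid1),
                           species = species_ids(occ))
  agg <- aggregate_to_coarse(occ, grid1)
  expect_identical(agg$incidence, occ$incidence)

  grid <- grid_spec(20, 20, block_factor = 5)
  occf <- occurrence_matrix(random_occ(400, 6, seed = 8, density = 0.2)$incidence,
                            "fine", sites = fine_site_ids(grid),
                            species = sprintf("sp%d", 1:6))
  occc <- aggregate_to_coarse(occf, grid)
  fine_counts <- colSums(occf$incidence)
  coarse_counts <- colSums(occc$incidence)
  expect_true(all(coarse_counts <= fine_counts))
  expect_true(all(fine_counts <= 25 * coarse_counts))
})

test_that("rasterized range masks match set membership and commute with aggregation", {
  grid <- grid_spec(30, 30, block_factor = 5)
  n <- n_fine_cells(grid)

  full <- range_map_set(list(all = seq_len(n)), n_fine = n)
  occ_full <- rasterize_ranges(full, grid, "fine")
  expect_true(all(occ_full$incidence))
  expect_true(all(rasterize_ranges(full, grid, "coarse")$incidence))

  single <- range_map_set(list(one = 17L), n_fine = n)
  expect_equal(sum(rasterize_ranges(single, grid, "fine")$incidence), 1)
  expect_equal(sum(rasterize_ranges(single, grid, "coarse")$incidence), 1)

  # 10 random rectangles: per-cell richness equals brute-force membership count
  set.seed(3)
  masks <- lapply(1:10, function(i) {
    r0 <- sample(0:25, 1); c0 <- sample(0:25, 1)
    h <- sample(1:5, 1); w <- sample(1:5, 1)
    cells <- as.vector(outer((c0:(c0 + w)) + 1, (r0:(r0 + h)) * 30, "+"))
    cells[cells <= n]
  })
  names(masks) <- sprintf("sp%02d", 1:10)
  ranges <- range_map_set(masks, n_fine = n)
  occ_fine <- rasterize_ranges(ranges, grid, "fine")
  richness <- rowSums(occ_fine$incidence)
  oracle <- vapply(seq_len(n), function(cell)
    sum(vapply(masks, function(m) cell %in% m, logical(1))), numeric(1))
  expect_equal(unname(richness), oracle)

  # commutation: rasterize-then-aggregate == rasterize at coarse
  via_fine <- aggregate_to_coarse(occ_fine, grid)
  direct <- rasterize_ranges(ranges, grid, "coarse")
  expect_identical(via_fine$incidence, direct$incidence)

  expect_error(rasterize_ranges(range_map_set(setNames(list(), character(0))),
                                grid), "empty", class = "dsc_validation")
})

test_that("partial edge blocks are valid coarse cells", {
  grid <- grid_spec(7, 7, block_factor = 5)  # 2 x 2 coarse incl. partial blocks
  expect_equal(n_coarse_cells(grid), 4)
  inc <- matrix(FALSE, 49, 1, dimnames = list(fine_site_ids(grid), "sp"))
  inc["r6c6", 1] <- TRUE  # bottom-right 2 x 2 partial block
  coarse <- aggregate_to_coarse(occurrence_matrix(inc, "fine"), grid)
  expect_true(coarse$incidence["r1c1", "sp"])
  expect_equal(sum(coarse$incidence), 1)
})
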