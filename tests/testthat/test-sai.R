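test_that("accumulation curves count newly represented species per prefix", {
  inc <- diag(4) == 1
  dimnames(inc) <- list(sprintf("s%d", 1:4), sprintf("sp%d", 1:4))
  occ <- occurrence_matrix(inc, "fine")
  rk <- selection_ranking(sprintf("s%d", c(3, 1, 4, 2)), occ)
  expect_equal(accumulation_curve(rk, occ)$count, as.numeric(0:4))

  occ3 <- abc_occ()
  rk3 <- selection_ranking(c("A", "C", "B"), occ3)
  expect_equal(accumulation_curve(rk3, occ3)$count, c(0, 2, 3, 3))

  occ_r <- random_occ(18, 9, seed = 17, density = 0.3)
  set.seed(17)
  rk_r <- selection_ranking(sample(site_ids(occ_r)), occ_r)
  expect_equal(accumulation_curve(rk_r, occ_r)$count,
               as.numeric(union_counts_oracle(rk_r$sites, occ_r)))

  expect_error(accumulation_curve(rk3, occ_r), "different site",
               class = "dsc_validation")
})

test_that("optimum curves from both methods track the exhaustive optimum", {
  inc <- diag(4) == 1
  dimnames(inc) <- list(sprintf("s%d", 1:4), sprintf("sp%d", 1:4))
  occ <- occurrence_matrix(inc, "fine")
  expect_equal(optimum_curve(occ, "zonation")$count, as.numeric(0:4))
  expect_equal(optimum_curve(occ, "rwr")$count, as.numeric(0:4))

  expect_equal(optimum_curve(abc_occ(), "zonation")$count[3], 3)

  for (seed in 18:20) {
    occ_r <- random_occ(10, 8, seed = seed, density = 0.5)
    for (method in c("zonation", "rwr")) {
      oc <- suppressMessages(optimum_curve(occ_r, method))
      for (m in 1:3)
        expect_gte(oc$count[m + 1], exhaustive_optimum(occ_r, m)$n_species - 1)
    }
  }
})

test_that("the mean random curve matches its expectation and stays below O", {
  inc <- matrix(TRUE, 1, 3, dimnames = list("only", c("a", "b", "c")))
  occ1 <- occurrence_matrix(inc, "fine")
  expect_equal(random_mean_curve(occ1, n_reps = 5, seed = 1)$count, c(0, 3))

  # diagonal: E[species at m] = m exactly
  incd <- diag(6) == 1
  dimnames(incd) <- list(sprintf("s%d", 1:6), sprintf("sp%d", 1:6))
  occd <- occurrence_matrix(incd, "fine")
  R <- random_mean_curve(occd, n_reps = 3000, seed = 2)
  se <- R$sd / sqrt(R$n_reps)
  expect_true(all(abs(R$count - R$m) <= 3 * pmax(se, 1e-9)))

  occ_r <- random_occ(15, 10, seed = 21, density = 0.3)
  R_r <- suppressMessages(random_mean_curve(occ_r, n_reps = 400, seed = 3))
  O_r <- suppressMessages(optimum_curve(occ_r, "zonation"))
  expect_true(all(R_r$count <= O_r$count + 3 * R_r$sd / sqrt(400) + 1e-9))
})

test_that("SAI applies its formula and flags undefined fractions", {
  S <- dscomp:::new_curve(c(0, 3, 7, 9, 10), "S:test")
  O <- dscomp:::new_curve(c(0, 5, 10, 10, 10), "O:test")
  R <- dscomp:::new_curve(c(0, 2, 4, 6, 10), "R:mean")
  res <- sai(S, O, R, fractions = c(0.5, 0.75))
  expect_equal(res$table$m, c(2, 3))
  expect_equal(res$table$SAI[1], (7 - 4) / (10 - 4))  # 0.5
  expect_equal(res$table$SAI[2], (9 - 6) / (10 - 6))

  # S = R -> SAI 0; S = O -> SAI 1
  res0 <- sai(R, O, R, fractions = c(0.5))
  expect_equal(res0$table$SAI, 0)
  res1 <- sai(O, O, R, fractions = c(0.5))
  expect_equal(res1$table$SAI, 1)

  # O = R at the last prefix -> flagged, excluded from the mean
  expect_warning(res_na <- sai(S, O, R, fractions = c(0.5, 1)), "undefined")
  expect_true(is.na(res_na$table$SAI[2]))
  expect_equal(res_na$mean_sai, 0.5)

  expect_error(sai(S, O, R, fractions = c(0.5, 0.4)), "fractions",
               class = "dsc_validation")
})

test_that("fraction-to-cell conversion rounds half up with a floor of one", {
  S <- dscomp:::new_curve(rep(0, 11), "S:test")
  O <- dscomp:::new_curve(c(0, seq_len(10)), "O:test")
  R <- dscomp:::new_curve(rep(0, 11), "R:mean")
  res <- suppressWarnings(sai(S, O, R, fractions = c(0.04, 0.15, 0.25)))
  expect_equal(res$table$m, c(1, 2, 3))  # 0.4 -> 1 (floor), 1.5 -> 2, 2.5 -> 3
})

test_that("a surrogate equal to true fine RWR scores SAI = 1 everywhere", {
  land <- gen_landscape(small_config(seed = 31))
  occ <- land$occ_fine
  true_scores <- rwr(occ)
  S <- accumulation_curve(ranking_from_scores(true_scores, occ), occ)
  O <- optimum_curve(occ, "rwr")
  R <- random_mean_curve(occ, n_reps = 200, seed = 31)
  res <- sai(S, O, R)
  expect_equal(res$table$SAI, rep(1, 5))
  expect_equal(res$mean_sai, 1)
})

test_that("the area-under-curve mode agrees with hand integration", {
  S <- dscomp:::new_curve(c(0, 3, 7, 9, 10), "S:test")
  O <- dscomp:::new_curve(c(0, 5, 10, 10, 10), "O:test")
  R <- dscomp:::new_curve(c(0, 2, 4, 6, 10), "R:mean")
  res <- sai(S, O, R, fractions = c(0.5), mode = "auc")
  expect_equal(res$mean_sai, (29 - 22) / (35 - 22))
})

test_that("SAI tables serialize with one row per fraction plus a mean row", {
  land <- gen_landscape(small_config(seed = 32))
  occ <- land$occ_fine
  S <- accumulation_curve(ranking_from_scores(rwr(occ), occ), occ)
  res <- sai(S, optimum_curve(occ, "zonation"),
             random_mean_curve(occ, 100, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sai_table(res, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$fraction, c("0.15", "0.2", "0.25", "0.3", "0.35", "Mean"))
  expect_equal(tab$SAI[6], res$mean_sai)
})
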