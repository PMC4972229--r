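test_that("varimax factor selection recovers block structure", {
  set.seed(14)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(f1, f1, f1, f2, f2, f2) + 0.05 * matrix(rnorm(6 * n), n)
  colnames(X) <- paste0("v", 1:6); rownames(X) <- paste0("s", 1:n)
  fm <- vrfa_select(env_table(X))
  expect_length(fm$eigenvalues, 2)
  expect_true(all(fm$eigenvalues > 1))
  expect_length(fm$selected, 2)
  expect_true(any(fm$selected %in% c("v1", "v2", "v3")))
  expect_true(any(fm$selected %in% c("v4", "v5", "v6")))

  # rotation is orthogonal and preserves communalities
  expect_equal(crossprod(fm$rotmat), diag(2), tolerance = 1e-10)
  C <- cor(X)
  eig <- eigen(C, symmetric = TRUE)
  L0 <- eig$vectors[, 1:2] %*% diag(sqrt(eig$values[1:2]))
  expect_equal(unname(rowSums(fm$loadings^2)), rowSums(L0^2), tolerance = 1e-8)
})

test_that("varimax selection handles degenerate inputs", {
  # exactly orthogonal columns -> sample correlation is the identity ->
  # no eigenvalue exceeds 1 and the Kaiser criterion retains nothing
  H <- cbind(c(1, 1, -1, -1, 1, 1, -1, -1),
             c(1, -1, 1, -1, 1, -1, 1, -1),
             c(1, -1, -1, 1, 1, -1, -1, 1))
  colnames(H) <- paste0("h", 1:3); rownames(H) <- paste0("s", 1:8)
  expect_error(vrfa_select(env_table(H)), "Kaiser", class = "dsc_validation")

  set.seed(15)
  X <- cbind(matrix(rnorm(40 * 3), 40), 7)
  colnames(X) <- c("a", "b", "c", "const"); rownames(X) <- paste0("s", 1:40)
  expect_warning(try(vrfa_select(env_table(X)), silent = TRUE), "constant")

  X2 <- X[, c("a", "b", "const"), drop = FALSE]
  expect_error(suppressWarnings(vrfa_select(env_table(X2))),
               "3 non-constant", class = "dsc_validation")
})

test_that("downscale fits are reproducible and recover a constructed gradient", {
  land <- gen_landscape(landscape_config(seed = 15, epsilon = 0.05,
                                         driver_vars = 1,
                                         optimum_quantiles = c(0.9, 0.98)))
  m1 <- fit_downscale_model(land$occ_coarse, land$env_coarse,
                            n_trees = 300, seed = 15)
  m2 <- fit_downscale_model(land$occ_coarse, land$env_coarse,
                            n_trees = 300, seed = 15)
  expect_identical(m1$importance, m2$importance)
  p1 <- predict_fine(m1, land$env_fine)
  p2 <- predict_fine(m2, land$env_fine)
  expect_identical(p1$score, p2$score)

  # the driving gradient dominates and OOB fit quality is high
  expect_equal(names(which.max(m1$importance)), "env01")
  expect_gt(m1$oob_r2, 0.7)
  truth <- rwr(land$occ_fine)
  expect_gt(cor(p1$score, truth$score, method = "spearman"), 0.8)
})

test_that("a constant response yields constant predictions and null importances", {
  set.seed(16)
  inc <- diag(30) == 1  # every species in exactly one site: RWR = 1 everywhere
  dimnames(inc) <- list(sprintf("s%02d", 1:30), sprintf("sp%02d", 1:30))
  occ <- occurrence_matrix(inc, "coarse")
  env <- env_table(matrix(rnorm(60), 30, 2,
                          dimnames = list(sprintf("s%02d", 1:30), c("a", "b"))))
  m <- suppressWarnings(fit_downscale_model(occ, env, n_trees = 200, seed = 1))
  pred <- predict_fine(m, env)
  expect_equal(pred$score, rep(1, 30), tolerance = 1e-12)
  expect_equal(unname(m$importance), c(0, 0), tolerance = 1e-12)
})

test_that("prediction on the training table returns the model's fitted values", {
  land <- gen_landscape(small_config(seed = 41))
  m <- fit_downscale_model(land$occ_coarse, land$env_coarse,
                           n_trees = 200, seed = 41)
  got <- predict_fine(m, land$env_coarse)
  fitted <- unname(predict(m$forest,
                           as.data.frame(land$env_coarse$values[, m$predictors])))
  expect_equal(got$score, pmax(fitted, 0))
  expect_equal(got$method, "SDC_a")
})

test_that("fit and prediction guards fire", {
  land <- gen_landscape(small_config(seed = 42))
  tiny <- occurrence_matrix(land$occ_coarse$incidence[1:6, , drop = FALSE],
                            "coarse")
  env6 <- env_table(land$env_coarse$values[1:6, , drop = FALSE])
  expect_error(suppressMessages(fit_downscale_model(tiny, env6, seed = 1)),
               "10 complete sites", class = "dsc_validation")

  expect_warning(fit_downscale_model(land$occ_coarse, land$env_coarse,
                                     n_trees = 50, seed = 1), "200 trees")

  m <- fit_downscale_model(land$occ_coarse, land$env_coarse,
                           predictors = c("env01", "env02"),
                           n_trees = 200, seed = 1)
  env_missing <- env_table(land$env_fine$values[, "env01", drop = FALSE])
  expect_error(predict_fine(m, env_missing), "missing predictor")

  expect_error(fit_downscale_model(land$occ_coarse, land$env_coarse,
                                   predictors = "nope", seed = 1),
               "unknown predictors", class = "dsc_validation")
})

test_that("sites with missing predictors are dropped from fits and flagged in predictions", {
  land <- gen_landscape(small_config(seed = 43))
  vals <- land$env_coarse$values
  vals[1:3, 1] <- NA
  env_na <- env_table(vals)
  m <- fit_downscale_model(land$occ_coarse, env_na, n_trees = 200, seed = 1)
  expect_equal(m$n_sites_fit, nrow(vals) - 3)
  expect_equal(m$dropped_sites, rownames(vals)[1:3])
  pred <- suppressMessages(predict_fine(m, env_na))
  expect_equal(attr(pred, "incomplete_sites"), rownames(vals)[1:3])
  expect_length(pred$score, nrow(vals) - 3)
})

test_that("direct downscaling equals RWR of the rasterized masks", {
  grid <- grid_spec(10, 10, 5)
  n <- n_fine_cells(grid)
  all_cells <- range_map_set(list(wide = seq_len(n)), n_fine = n)
  expect_equal(direct_downscale(all_cells, grid)$score, rep(1 / n, n))

  one <- range_map_set(list(sp = 55L), n_fine = n)
  sc <- direct_downscale(one, grid)
  expect_equal(sum(sc$score), 1)
  expect_equal(sc$score[55], 1)
  expect_equal(sc$method, "DDC_r")

  # independent per-cell double-loop oracle on random rectangles
  grid25 <- grid_spec(25, 25, 5)
  set.seed(16)
  masks <- lapply(1:15, function(i) {
    r0 <- sample(0:20, 1); c0 <- sample(0:20, 1)
    cells <- as.vector(outer((c0 + 1):(c0 + sample(2:5, 1)),
                             (r0:(r0 + sample(1:4, 1))) * 25, "+"))
    cells[cells <= 625]
  })
  names(masks) <- sprintf("sp%02d", 1:15)
  ranges <- range_map_set(masks, n_fine = 625)
  got <- direct_downscale(ranges, grid25)$score
  oracle <- vapply(seq_len(625), function(cell) {
    s <- 0
    for (m in masks) if (cell %in% m) s <- s + 1 / length(m)
    s
  }, numeric(1))
  expect_equal(got, oracle)
  expect_equal(sum(got), 15, tolerance = 1e-12)  # total mass
})
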