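#' Predictor selection by varimax-rotated factor analysis
#'
#' Identifies major environmental gradients and one representative variable
#' per gradient, so that the selected predictors have low multicollinearity.
#' Variables are standardized; principal factors are extracted from their
#' correlation matrix; factors with eigenvalue > 1 are retained (Kaiser
#' criterion) and varimax-rotated (Kaiser-normalized); for each rotated
#' factor the variable with the largest absolute loading (equivalently, the
#' variable most highly correlated with the factor scores) is selected.
#' Duplicate picks collapse to a unique set with a message.
#'
#' Sites with a missing value in any variable are dropped; constant
#' variables are dropped with a warning.
#'
#' @param env An `env_table` with at least 3 non-constant variables and more
#'   complete sites than variables.
#' @return An object of class `factor_model` with the rotated loading
#'   matrix, retained eigenvalues, and the selected variables.
#' @export
vrfa_select <- function(env) {
  X <- env$values
  const <- constant_variables(env)
  if (length(const)) {
    warning(sprintf("dropping constant variables: %s", paste(const, collapse = ", ")))
    X <- X[, setdiff(colnames(X), const), drop = FALSE]
  }
  if (ncol(X) < 3) stop_validation("need at least 3 non-constant variables")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < ncol(X) + 1)
    stop_validation("need at least variables + 1 complete sites for factor analysis")
  C <- stats::cor(X)
  eig <- eigen(C, symmetric = TRUE)
  retained <- which(eig$values > 1)
  if (!length(retained))
    stop_validation(paste("no factor passes the Kaiser criterion (all eigenvalues <= 1);",
                          "supply an explicit predictor list instead"))
  L <- eig$vectors[, retained, drop = FALSE] %*%
    diag(sqrt(eig$values[retained]), length(retained))
  rownames(L) <- colnames(X)
  rotmat <- diag(length(retained))
  if (length(retained) > 1) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- unclass(rot$loadings)
    rotmat <- rot$rotmat
  }
  picks <- colnames(X)[apply(abs(L), 2L, which.max)]
  selected <- unique(picks)
  if (length(selected) < length(picks))
    message("duplicate factor picks collapsed to a unique predictor set")
  structure(list(variables = colnames(X),
                 loadings = L,
                 rotmat = rotmat,
                 eigenvalues = eig$values[retained],
                 selected_by_factor = picks,
                 selected = selected,
                 dropped_constant = const),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d retained factors (eigenvalues %s) over %d variables\n",
              length(x$eigenvalues),
              paste(round(x$eigenvalues, 2), collapse = ", "),
              length(x$variables)))
  cat("selected predictors:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the statistical downscaling model
#'
#' Regresses the rarity-weighted richness of the coarse cells on
#' environmental predictors measured in those cells, using an ensemble of
#' regression trees (random forest): `n_trees` trees, each grown on a
#' bootstrap sample of about 66% of the sites drawn without replacement. The
#' held-out ~34% of sites per tree provide the out-of-bag (OOB) error, OOB
#' R-squared, and the permutation importance of each predictor (mean
#' increase in OOB error after permuting that predictor, unnormalized).
#'
#' @param occ_coarse Coarse `occurrence_matrix`; its RWR is the response.
#' @param env_coarse `env_table` over the same sites.
#' @param predictors Predictor names (default: all variables); typically the
#'   output of [vrfa_select()].
#' @param n_trees Number of trees (default 500; with fewer than ~200 trees
#'   the ensemble error has typically not yet plateaued, so a warning is
#'   emitted).
#' @param seed RNG seed; fits are reproducible given the seed.
#' @param sample_fraction Fraction of sites per tree (default 0.66).
#' @param method_tag `"SDC_a"` when the coarse source is atlas data,
#'   `"SDC_r"` when it is rasterized range maps.
#' @return An object of class `downscale_model`.
#' @export
fit_downscale_model <- function(occ_coarse, env_coarse,
                                predictors = colnames(env_coarse$values),
                                n_trees = 500, seed = 1,
                                sample_fraction = 0.66,
                                method_tag = "SDC_a") {
  if (!all(predictors %in% colnames(env_coarse$values)))
    stop_validation("unknown predictors: %s",
                    paste(setdiff(predictors, colnames(env_coarse$values)), collapse = ", "))
  idx <- match(site_ids(occ_coarse), rownames(env_coarse$values))
  if (anyNA(idx))
    stop_validation("env table is missing sites of the coarse occurrence matrix")
  if (!is_count(n_trees)) stop_validation("n_trees must be a positive integer")
  if (n_trees < 200)
    warning("fewer than 200 trees: ensemble error may not have plateaued")
  X <- env_coarse$values[idx, predictors, drop = FALSE]
  y <- rwr(occ_coarse)$score
  complete <- stats::complete.cases(X)
  if (sum(complete) < 10)
    stop_validation("fewer than 10 complete sites; refusing an unstable fit")
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = as.data.frame(X[complete, , drop = FALSE]),
    y = y[complete],
    ntree = n_trees,
    replace = FALSE,
    sampsize = max(2L, ceiling(sample_fraction * sum(complete))),
    importance = TRUE,
    keep.forest = TRUE)
  imp <- randomForest::importance(forest, type = 1, scale = FALSE)[, 1]
  structure(list(forest = forest,
                 predictors = predictors,
                 n_trees = as.integer(n_trees),
                 sample_fraction = sample_fraction,
                 seed = seed,
                 oob_mse = forest$mse[n_trees],
                 oob_r2 = forest$rsq[n_trees],
                 importance = imp,
                 n_sites_fit = sum(complete),
                 dropped_sites = site_ids(occ_coarse)[!complete],
                 method_tag = method_tag),
            class = "downscale_model")
}

#' @export
print.downscale_model <- function(x, ...) {
  cat(sprintf("downscale_model [%s]: %d trees on %d sites, OOB MSE %.4g, OOB R2 %.3f\n",
              x$method_tag, x$n_trees, x$n_sites_fit, x$oob_mse, x$oob_r2))
  imp <- sort(x$importance, decreasing = TRUE)
  cat("permutation importance:",
      paste(sprintf("%s=%.3g", names(imp), imp), collapse = ", "), "\n")
  invisible(x)
}

#' Predict downscaled complementarity at fine resolution
#'
#' Applies a fitted downscaling model to environmental predictors measured
#' in the fine cells, yielding downscaled RWR (DRWR) per fine cell.
#' Predictions are clamped at 0 (with a message) in the rare case a tree
#' average dips below; sites with missing predictor values are excluded from
#' the result and flagged in the `incomplete_sites` attribute.
#'
#' @param model A `downscale_model`.
#' @param env_fine `env_table` containing all model predictors.
#' @return A `complementarity_vector` tagged with the model's method.
#' @export
predict_fine <- function(model, env_fine) {
  missing_vars <- setdiff(model$predictors, colnames(env_fine$values))
  if (length(missing_vars))
    stop(sprintf("missing predictor column(s): %s", paste(missing_vars, collapse = ", ")))
  X <- env_fine$values[, model$predictors, drop = FALSE]
  complete <- stats::complete.cases(X)
  if (any(!complete))
    message(sprintf("flagging %d sites with missing predictor values", sum(!complete)))
  pred <- stats::predict(model$forest,
                         newdata = as.data.frame(X[complete, , drop = FALSE]))
  if (any(pred < 0)) {
    message(sprintf("clamping %d negative predictions to 0", sum(pred < 0)))
    pred <- pmax(pred, 0)
  }
  out <- complementarity_vector(rownames(env_fine$values)[complete], pred,
                                method = model$method_tag)
  attr(out, "incomplete_sites") <- rownames(env_fine$values)[!complete]
  out
}

#' Directly downscaled complementarity from range maps
#'
#' Overlays the species range masks on the fine grid, counts the fine cells
#' overlapped by each species' range, and computes rarity-weighted richness
#' for every fine cell from those overlap patterns. Equivalent to
#' `rwr(rasterize_ranges(ranges, grid, "fine"))`.
#'
#' @param ranges A nonempty `range_map_set`.
#' @param grid A `grid_spec`.
#' @return A `complementarity_vector` with method `"DDC_r"`.
#' @export
direct_downscale <- function(ranges, grid) {
  out <- rwr(rasterize_ranges(ranges, grid, "fine"))
  out$method <- "DDC_r"
  out
}

#' Persist / restore a downscaling model manifest
#'
#' Writes a plain-text key-value manifest of a fitted model (predictors,
#' tree count, seed, OOB statistics, importances). The manifest documents a
#' run; the forest itself is refit from data and seed when needed.
#' @param model A `downscale_model`.
#' @param path Output file.
#' @export
write_model_manifest <- function(model, path) {
  lines <- c(
    sprintf("method_tag = %s", model$method_tag),
    sprintf("predictors = %s", paste(model$predictors, collapse = ",")),
    sprintf("n_trees = %d", model$n_trees),
    sprintf("sample_fraction = %g", model$sample_fraction),
    sprintf("seed = %s", format(model$seed)),
    sprintf("n_sites_fit = %d", model$n_sites_fit),
    sprintf("oob_mse = %.10g", model$oob_mse),
    sprintf("oob_r2 = %.10g", model$oob_r2),
    sprintf("importance_%s = %.10g", names(model$importance), model$importance))
  writeLines(lines, path)
  invisible(path)
}
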