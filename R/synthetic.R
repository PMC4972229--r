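#' Synthetic nested-grid landscape configuration
#'
#' Parameters of the synthetic landscape generator used to exercise the
#' whole downscaling pipeline without external data. The default
#' configuration is a desk-scale analog of a national atlas setting: a
#' 50 x 50 fine grid nested in 10 x 10 coarse blocks (k = 5), 60 species,
#' and 10 environmental variables.
#'
#' @param n_rows_fine,n_cols_fine,block_factor Grid geometry (see
#'   [grid_spec()]).
#' @param n_species Number of species.
#' @param n_env_vars Number of environmental variables.
#' @param smoothness Gaussian kernel standard deviation (in fine cells) used
#'   to smooth each environmental field; 0 gives white noise.
#' @param beta Environment-to-occupancy effect size: the weight of the
#'   species' environmental suitability in its occupancy score.
#' @param epsilon Occupancy noise level: standard deviation of the
#'   independent per-cell perturbation added to the suitability, which makes
#'   the coarse-to-fine transfer imperfect by construction.
#' @param rarity_skew Skew of the occupied-area distribution (>= 0). Larger
#'   values produce more narrow-ranged species and fewer widespread ones
#'   (log-series-like).
#' @param dilation_radius Range-map dilation radius in fine cells: each
#'   species' "drawn" range is its occupied cell set dilated by a disc of
#'   this radius, so range masks over-cover true occupancy.
#' @param driver_vars Optional indices of the environmental variables
#'   species' niches may depend on (default: all).
#' @param optimum_quantiles Quantile window of the driving variable from
#'   which species optima are drawn (default the full 5-95% range).
#'   Narrowing the window toward one end concentrates all species at that
#'   end of the gradient and makes rarity-weighted richness monotone in it -
#'   the constructed-signal setting used to verify parameter recovery.
#' @param seed RNG seed.
#' @export
landscape_config <- function(n_rows_fine = 50, n_cols_fine = 50,
                             block_factor = 5, n_species = 60,
                             n_env_vars = 10, smoothness = 6,
                             beta = 1, epsilon = 0.25,
                             rarity_skew = 1.5, dilation_radius = 1,
                             driver_vars = NULL,
                             optimum_quantiles = c(0.05, 0.95), seed = 1) {
  if (!is_count(n_species) || !is_count(n_env_vars))
    stop_validation("n_species and n_env_vars must be positive integers")
  if (epsilon < 0) stop_validation("epsilon must be >= 0")
  if (dilation_radius < 0) stop_validation("dilation_radius must be >= 0")
  if (smoothness < 0) stop_validation("smoothness must be >= 0")
  if (rarity_skew < 0) stop_validation("rarity_skew must be >= 0")
  if (!is.null(driver_vars) &&
      (!all(driver_vars %in% seq_len(n_env_vars))))
    stop_validation("driver_vars must index the environmental variables")
  if (length(optimum_quantiles) != 2 || any(optimum_quantiles < 0) ||
      any(optimum_quantiles > 1) || optimum_quantiles[1] > optimum_quantiles[2])
    stop_validation("optimum_quantiles must be an ordered pair in [0, 1]")
  structure(list(n_rows_fine = n_rows_fine, n_cols_fine = n_cols_fine,
                 block_factor = block_factor, n_species = n_species,
                 n_env_vars = n_env_vars, smoothness = smoothness,
                 beta = beta, epsilon = epsilon, rarity_skew = rarity_skew,
                 dilation_radius = dilation_radius,
                 driver_vars = driver_vars,
                 optimum_quantiles = optimum_quantiles,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# separable Gaussian smoothing of a matrix field, edge-normalized
smooth_field <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  smoother <- function(n) {
    S <- stats::dnorm(abs(outer(seq_len(n), seq_len(n), "-")), sd = sd_cells)
    S / rowSums(S)
  }
  smoother(nrow(m)) %*% m %*% t(smoother(ncol(m)))
}

#' Generate synthetic environmental tables
#'
#' Each variable is a smoothed Gaussian random field over the fine grid
#' (kernel standard deviation = `smoothness` cells), standardized and
#' perturbed by a small independent nugget. The coarse table holds the
#' block mean of each variable, mirroring how per-cell environmental
#' summaries are computed at both grains.
#'
#' @param config A `landscape_config`.
#' @return A list with elements `fine` and `coarse` (`env_table`s) and
#'   `grid` (the `grid_spec`).
#' @export
gen_environment <- function(config) {
  grid <- grid_spec(config$n_rows_fine, config$n_cols_fine, config$block_factor)
  set.seed(config$seed)
  n <- n_fine_cells(grid)
  vals <- matrix(NA_real_, n, config$n_env_vars)
  for (v in seq_len(config$n_env_vars)) {
    field <- matrix(stats::rnorm(n), grid$n_rows_fine, grid$n_cols_fine)
    field <- smooth_field(field, config$smoothness)
    # fine cells are laid out row-major: row index varies slowest
    x <- as.numeric(t(field))
    x <- (x - mean(x)) / stats::sd(x)
    vals[, v] <- x + 0.1 * stats::rnorm(n)
  }
  vars <- sprintf("env%02d", seq_len(config$n_env_vars))
  fine <- env_table(vals, sites = fine_site_ids(grid), variables = vars)
  block <- fine_block_index(grid)
  agg <- rowsum(vals, group = block)
  blocks <- as.integer(rownames(agg))
  sizes <- tabulate(block, nbins = max(block))[blocks]
  coarse <- env_table(agg / sizes, sites = coarse_site_ids(grid)[blocks],
                      variables = vars)
  list(fine = fine, coarse = coarse, grid = grid)
}

#' Generate environment-driven species occupancy
#'
#' Each species responds to 1-2 randomly chosen environmental variables
#' through a Gaussian suitability kernel with a species-specific optimum
#' (drawn from the variable's 5-95% quantile range) and tolerance. Its
#' occupancy score is `beta * suitability + epsilon * noise`; the species
#' occupies exactly its target number of cells - the cells with the highest
#' scores - so every species occupies at least one cell by construction.
#' Target occupied-cell counts are drawn from a skewed (log-series-like)
#' distribution controlled by `rarity_skew`, yielding both range-restricted
#' and widespread species.
#'
#' @param env_fine Fine `env_table` from [gen_environment()].
#' @param config The same `landscape_config`.
#' @return A fine `occurrence_matrix` covering every fine cell.
#' @export
gen_species_occupancy <- function(env_fine, config) {
  set.seed(derive_seed(config$seed, 1))
  X <- env_fine$values
  n <- nrow(X)
  candidates <- config$driver_vars %||% seq_len(ncol(X))
  f_min <- 1 / n
  f_max <- 0.5
  inc <- matrix(FALSE, n, config$n_species)
  for (s in seq_len(config$n_species)) {
    nd <- sample(1:2, 1)
    vars <- sample(candidates, min(nd, length(candidates)))
    suit <- rep(1, n)
    for (v in vars) {
      x <- X[, v]
      oq <- config$optimum_quantiles %||% c(0.05, 0.95)
      opt <- stats::quantile(x, stats::runif(1, oq[1], oq[2]), names = FALSE)
      tol <- stats::runif(1, 0.5, 1.5) * stats::sd(x)
      suit <- suit * exp(-0.5 * ((x - opt) / tol)^2)
    }
    z <- config$beta * suit + config$epsilon * stats::rnorm(n)
    u <- stats::runif(1)
    frac <- f_min * (f_max / f_min)^(u^config$rarity_skew)
    k <- max(1L, as.integer(round(frac * n)))
    inc[order(z, decreasing = TRUE)[seq_len(k)], s] <- TRUE
  }
  occurrence_matrix(inc, "fine", sites = rownames(X),
                    species = sprintf("sp%03d", seq_len(config$n_species)))
}

#' Generate over-covering range maps from true occupancy
#'
#' Each species' range mask is the morphological dilation of its occupied
#' cell set by a disc of `dilation_radius` fine cells, approximating a
#' drawn range polygon. True occupancy is always a subset of the mask
#' (range maps over-cover, never under-cover); with the default radius the
#' per-cell richness implied by the masks exceeds true richness by roughly
#' 50-200%.
#'
#' @param occ_fine Fine `occurrence_matrix` over all cells of the grid.
#' @param config The same `landscape_config`.
#' @return A `range_map_set`.
#' @export
gen_range_maps <- function(occ_fine, config) {
  grid <- grid_spec(config$n_rows_fine, config$n_cols_fine, config$block_factor)
  if (nrow(occ_fine$incidence) != n_fine_cells(grid))
    stop_validation("occupancy matrix does not cover the configured fine grid")
  r <- config$dilation_radius
  ri <- floor(r)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off <- off[off$dr^2 + off$dc^2 <= r^2 + 1e-9, ]
  nc <- grid$n_cols_fine
  nr <- grid$n_rows_fine
  masks <- lapply(seq_len(ncol(occ_fine$incidence)), function(j) {
    idx <- which(occ_fine$incidence[, j]) - 1L
    row <- rep(idx %/% nc, each = nrow(off)) + off$dr
    col <- rep(idx %% nc, each = nrow(off)) + off$dc
    ok <- row >= 0 & row < nr & col >= 0 & col < nc
    sort(unique(row[ok] * nc + col[ok] + 1L))
  })
  names(masks) <- species_ids(occ_fine)
  range_map_set(masks, n_fine = n_fine_cells(grid))
}

#' Per-cell richness inflation of range masks over true occupancy
#'
#' Ratio of the mean per-cell species richness implied by the range masks to
#' the mean richness of the true occupancy; drawn range maps typically
#' inflate richness by a factor of about 1.5-3.
#' @param ranges A `range_map_set`.
#' @param occ_fine The true fine `occurrence_matrix`.
#' @export
richness_inflation <- function(ranges, occ_fine) {
  sum(lengths(ranges$masks)) / sum(occ_fine$incidence)
}

#' Generate a complete synthetic landscape
#'
#' Bundles [gen_environment()], [gen_species_occupancy()],
#' [aggregate_to_coarse()], and [gen_range_maps()] into the full fixture
#' set: fine and coarse environmental tables, fine and coarse occurrence
#' atlases, and range masks.
#'
#' @param config A `landscape_config`.
#' @return An object of class `landscape`.
#' @export
gen_landscape <- function(config = landscape_config()) {
  env <- gen_environment(config)
  occ_fine <- gen_species_occupancy(env$fine, config)
  structure(list(config = config,
                 grid = env$grid,
                 env_fine = env$fine,
                 env_coarse = env$coarse,
                 occ_fine = occ_fine,
                 occ_coarse = aggregate_to_coarse(occ_fine, env$grid),
                 ranges = gen_range_maps(occ_fine, config)),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d x %d fine grid (k = %d), %d species, %d env vars, seed %d\n",
              x$config$n_rows_fine, x$config$n_cols_fine,
              x$config$block_factor, x$config$n_species,
              x$config$n_env_vars, x$config$seed))
  invisible(x)
}
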