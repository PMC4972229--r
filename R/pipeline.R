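#' Run configuration for the pipeline commands
#'
#' Flat key-value configuration shared by the pipeline commands
#' ([run_simulate()], [run_downscale()], [run_evaluate()]) and the
#' command-line wrapper. A configuration file holds `key = value` lines
#' (`#` starts a comment); list values are comma-separated. Any value can
#' be overridden programmatically or by a CLI flag.
#'
#' @param path Path to a configuration file.
#' @return A named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop_validation("malformed config line: %s", lines[bad][1])
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, function(m) trimws(m[2]), character(1)))
}

config_num <- function(config, key, default) {
  v <- config[[key]]
  if (is.null(v)) return(default)
  out <- suppressWarnings(as.numeric(strsplit(as.character(v), ",")[[1]]))
  if (anyNA(out)) stop_validation("config field '%s' is not numeric", key)
  out
}

config_chr <- function(config, key, default) {
  v <- config[[key]]
  if (is.null(v)) return(default)
  trimws(strsplit(as.character(v), ",")[[1]])
}

validate_fractions <- function(fractions) {
  if (any(fractions <= 0 | fractions > 1) ||
      is.unsorted(fractions, strictly = TRUE))
    stop_validation("fractions must lie in (0, 1] and be strictly increasing")
  fractions
}

log_line <- function(log_path, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS1"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
  invisible(NULL)
}

log_inputs <- function(log_path, paths) {
  for (p in paths)
    log_line(log_path, "input %s md5=%s", p, unname(tools::md5sum(p)))
}

landscape_config_from <- function(config) {
  landscape_config(
    n_rows_fine = config_num(config, "n_rows_fine", 50),
    n_cols_fine = config_num(config, "n_cols_fine", 50),
    block_factor = config_num(config, "block_factor", 5),
    n_species = config_num(config, "n_species", 60),
    n_env_vars = config_num(config, "n_env_vars", 10),
    smoothness = config_num(config, "smoothness", 6),
    beta = config_num(config, "beta", 1),
    epsilon = config_num(config, "epsilon", 0.25),
    rarity_skew = config_num(config, "rarity_skew", 1.5),
    dilation_radius = config_num(config, "dilation_radius", 1),
    seed = config_num(config, "seed", 1))
}

#' Simulate a synthetic fixture directory
#'
#' Generates a full synthetic landscape and writes the fixture set (fine and
#' coarse atlases, fine and coarse environmental tables, range masks) plus a
#' key-value manifest into `out_dir`. Re-running with the same configuration
#' overwrites the files with identical content.
#'
#' @param config Named list (see [read_run_config()]); recognized keys are
#'   the [landscape_config()] fields plus `out_dir` and `fractions`.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config = list(), out_dir = config[["out_dir"]]) {
  if (is.null(out_dir)) stop_validation("out_dir is required")
  if (!is.null(config[["fractions"]]))
    validate_fractions(config_num(config, "fractions", NULL))
  cfg <- landscape_config_from(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("# simulate, seed %d\n", cfg$seed), file = log_path)
  t0 <- proc.time()[3]
  land <- gen_landscape(cfg)
  write_occurrence(land$occ_fine, file.path(out_dir, "fine_atlas.csv"))
  write_occurrence(land$occ_coarse, file.path(out_dir, "coarse_atlas.csv"))
  write_env_table(land$env_fine, file.path(out_dir, "env_fine.csv"))
  write_env_table(land$env_coarse, file.path(out_dir, "env_coarse.csv"))
  write_range_maps(land$ranges, land$grid, file.path(out_dir, "range_masks.csv"))
  manifest <- c(
    sprintf("n_rows_fine = %d", cfg$n_rows_fine),
    sprintf("n_cols_fine = %d", cfg$n_cols_fine),
    sprintf("block_factor = %d", cfg$block_factor),
    sprintf("n_species = %d", cfg$n_species),
    sprintf("n_env_vars = %d", cfg$n_env_vars),
    sprintf("smoothness = %g", cfg$smoothness),
    sprintf("beta = %g", cfg$beta),
    sprintf("epsilon = %g", cfg$epsilon),
    sprintf("rarity_skew = %g", cfg$rarity_skew),
    sprintf("dilation_radius = %g", cfg$dilation_radius),
    sprintf("seed = %d", cfg$seed))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  log_line(log_path, "simulate done in %.1f s", proc.time()[3] - t0)
  invisible(out_dir)
}

resolve_grid <- function(config, dir = NULL) {
  manifest <- config[["manifest"]]
  if (is.null(manifest) && !is.null(dir) &&
      file.exists(file.path(dir, "manifest.txt")))
    manifest <- file.path(dir, "manifest.txt")
  if (!is.null(manifest)) {
    m <- read_run_config(manifest)
    for (k in c("n_rows_fine", "n_cols_fine", "block_factor"))
      if (is.null(config[[k]])) config[[k]] <- m[[k]]
  }
  for (k in c("n_rows_fine", "n_cols_fine", "block_factor"))
    if (is.null(config[[k]]))
      stop_validation("grid field '%s' is required (directly or via a manifest)", k)
  grid_spec(config_num(config, "n_rows_fine", NULL),
            config_num(config, "n_cols_fine", NULL),
            config_num(config, "block_factor", NULL))
}

#' Build downscaled complementarity surrogates
#'
#' For each requested method, writes a per-fine-cell score file
#' (`site_id, score, method`) into `out_dir`; statistical downscaling also
#' writes a plain-text model manifest with OOB statistics and permutation
#' importances. Recognized config keys: `out_dir`, input paths
#' (`coarse_atlas`, `env_coarse`, `env_fine`, `range_masks`, `manifest`),
#' `methods` (subset of `SDC_a,SDC_r,DDC_r`), `predictor_mode`
#' (`vrfa`/`explicit`), `predictors`, `n_trees`, `seed`, and the grid
#' fields.
#'
#' @param config Named list of configuration values.
#' @return Named character vector of written score files, invisibly.
#' @export
run_downscale <- function(config = list()) {
  out_dir <- config[["out_dir"]] %||% stop_validation("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "downscale.log")
  cat("# downscale\n", file = log_path)
  methods <- config_chr(config, "methods", c("SDC_a", "SDC_r", "DDC_r"))
  if (!all(methods %in% c("SDC_a", "SDC_r", "DDC_r")))
    stop_validation("methods must be a subset of SDC_a, SDC_r, DDC_r")
  n_trees <- config_num(config, "n_trees", 500)
  seed <- config_num(config, "seed", 1)
  need_ranges <- any(methods %in% c("SDC_r", "DDC_r"))
  if (need_ranges && is.null(config[["range_masks"]]))
    stop_validation("range_masks input is required for SDC_r / DDC_r")
  if ("SDC_a" %in% methods && is.null(config[["coarse_atlas"]]))
    stop_validation("coarse_atlas input is required for SDC_a")
  sdc <- any(methods %in% c("SDC_a", "SDC_r"))
  if (sdc && (is.null(config[["env_coarse"]]) || is.null(config[["env_fine"]])))
    stop_validation("env_coarse and env_fine inputs are required for statistical downscaling")
  grid <- resolve_grid(config, dir = dirname(config[["coarse_atlas"]] %||%
                                               config[["range_masks"]] %||% "."))
  log_inputs(log_path, unlist(config[c("coarse_atlas", "env_coarse",
                                       "env_fine", "range_masks")]))
  env_coarse <- if (sdc) read_env_table(config[["env_coarse"]])
  env_fine <- if (sdc) read_env_table(config[["env_fine"]])
  ranges <- if (need_ranges) read_range_maps(config[["range_masks"]], grid)
  out <- character(0)

  pick_predictors <- function() {
    mode <- config_chr(config, "predictor_mode", "vrfa")[1]
    if (mode == "explicit") {
      config_chr(config, "predictors", NULL) %||%
        stop_validation("predictor_mode=explicit requires a predictors list")
    } else {
      fm <- vrfa_select(env_coarse)
      log_line(log_path, "vrfa selected: %s", paste(fm$selected, collapse = ", "))
      fm$selected
    }
  }

  fit_and_predict <- function(occ_coarse, tag) {
    t0 <- proc.time()[3]
    model <- fit_downscale_model(occ_coarse, env_coarse,
                                 predictors = pick_predictors(),
                                 n_trees = n_trees, seed = seed,
                                 method_tag = tag)
    write_model_manifest(model, file.path(out_dir, sprintf("model_%s.txt", tag)))
    scores <- predict_fine(model, env_fine)
    path <- file.path(out_dir, sprintf("scores_%s.csv", tag))
    write_scores(scores, path)
    log_line(log_path, "%s: OOB R2 %.3f, %d fine cells scored, %.1f s",
             tag, model$oob_r2, length(scores$sites), proc.time()[3] - t0)
    path
  }

  if ("SDC_a" %in% methods) {
    occ_coarse <- read_occurrence(config[["coarse_atlas"]], "coarse")
    out["SDC_a"] <- fit_and_predict(occ_coarse, "SDC_a")
  }
  if ("SDC_r" %in% methods) {
    occ_coarse_r <- rasterize_ranges(ranges, grid, "coarse")
    out["SDC_r"] <- fit_and_predict(occ_coarse_r, "SDC_r")
  }
  if ("DDC_r" %in% methods) {
    t0 <- proc.time()[3]
    scores <- direct_downscale(ranges, grid)
    path <- file.path(out_dir, "scores_DDC_r.csv")
    write_scores(scores, path)
    log_line(log_path, "DDC_r: %d fine cells scored, %.1f s",
             length(scores$sites), proc.time()[3] - t0)
    out["DDC_r"] <- path
  }
  invisible(out)
}

#' Evaluate surrogates against a fine-grid atlas
#'
#' For each surrogate score file, computes the accumulation curve S on the
#' independent fine evaluation atlas, the optimum curves O from both the
#' Zonation-style ranking and RWR, the mean random curve R, and the Species
#' Accumulation Index at the configured protection fractions; writes one SAI
#' table per method plus a correlation report (Pearson r with Dutilleul-
#' corrected significance) among the surrogates and true fine-scale RWR.
#' Recognized config keys: `out_dir`, `fine_atlas`, `scores` (comma list of
#' score files), `fractions`, `n_random_reps`, `o_method`
#' (`zonation`/`rwr`), `seed`, grid fields / `manifest`.
#'
#' @param config Named list of configuration values.
#' @return A named list of `sai_result` objects plus the correlation table,
#'   invisibly.
#' @export
run_evaluate <- function(config = list()) {
  out_dir <- config[["out_dir"]] %||% stop_validation("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "evaluate.log")
  cat("# evaluate\n", file = log_path)
  fractions <- validate_fractions(
    config_num(config, "fractions", c(0.15, 0.20, 0.25, 0.30, 0.35)))
  n_reps <- config_num(config, "n_random_reps", 1000)
  seed <- config_num(config, "seed", 1)
  o_method <- match.arg(config_chr(config, "o_method", "zonation")[1],
                        c("zonation", "rwr"))
  atlas_path <- config[["fine_atlas"]] %||%
    stop_validation("fine_atlas input is required")
  score_paths <- config_chr(config, "scores", NULL) %||%
    stop_validation("scores input list is required")
  missing <- score_paths[!file.exists(score_paths)]
  if (length(missing))
    stop_validation("missing surrogate file(s): %s", paste(missing, collapse = ", "))
  log_inputs(log_path, c(atlas_path, score_paths))
  occ_eval <- read_occurrence(atlas_path, "fine")
  grid <- resolve_grid(config, dir = dirname(atlas_path))

  t0 <- proc.time()[3]
  O_zon <- optimum_curve(occ_eval, "zonation")
  O_rwr <- optimum_curve(occ_eval, "rwr")
  R <- random_mean_curve(occ_eval, n_reps = n_reps, seed = seed)
  log_line(log_path, "O and R curves in %.1f s (n_reps = %d, seed = %d)",
           proc.time()[3] - t0, n_reps, seed)
  O_main <- if (o_method == "zonation") O_zon else O_rwr
  O_alt <- if (o_method == "zonation") O_rwr else O_zon

  true_scores <- rwr(occ_eval)
  results <- list()
  score_list <- list(true = true_scores$score[id_order(true_scores$sites)])
  for (path in score_paths) {
    sc <- read_scores(path)
    rk <- ranking_from_scores(sc, occ_eval)
    S <- accumulation_curve(rk, occ_eval)
    res <- sai(S, O_main, R, fractions = fractions)
    m <- res$table$m
    write_sai_table(res, file.path(out_dir, sprintf("sai_%s.csv", sc$method)),
                    extra = stats::setNames(list(O_alt$count[m + 1L]),
                                            paste0("O_", sub(".*:", "", O_alt$source))))
    log_line(log_path, "%s: mean SAI %.3f", sc$method, res$mean_sai)
    results[[sc$method]] <- res
    score_list[[sc$method]] <- sc$score[id_order(sc$sites)]
  }
  ord_ids <- sort(true_scores$sites, method = "radix")
  stopifnot(identical(sort(site_ids(occ_eval), method = "radix"), ord_ids))
  coords <- fine_coords(grid)[match(ord_ids, fine_site_ids(grid)), , drop = FALSE]
  corr <- correlation_report(score_list, coords)
  utils::write.csv(corr, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE, quote = FALSE)
  log_line(log_path, "correlation report written (%d pairs)", nrow(corr))
  invisible(c(results, list(correlations = corr)))
}

#' Standalone RWR and ranking commands
#'
#' `run_rwr()` computes rarity-weighted richness for any occurrence file;
#' `run_rank()` writes the full site ranking (`zonation` or `rwr`) with rank
#' values and prefix species counts.
#' @param occ_path Path to an occurrence CSV.
#' @param out Output file.
#' @export
run_rwr <- function(occ_path, out) {
  occ <- read_occurrence(occ_path)
  write_scores(rwr(occ), out)
  invisible(out)
}

#' @rdname run_rwr
#' @param method `"zonation"` or `"rwr"`.
#' @export
run_rank <- function(occ_path, method = c("zonation", "rwr"), out) {
  method <- match.arg(method)
  occ <- read_occurrence(occ_path)
  rk <- if (method == "zonation") zonation_ranking(occ)
        else ranking_from_scores(rwr(occ), occ)
  df <- data.frame(site_id = rk$sites,
                   score = rk$rank_value %||% rep(NA_real_, length(rk$sites)),
                   rank = seq_along(rk$sites),
                   species_represented = rk$prefix_counts[-1])
  utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}
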