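#' Species accumulation curve of a ranking
#'
#' As cells are accumulated in ranking order, counts the number of species
#' represented in at least one accumulated cell, for every prefix size
#' 0..n. The curve starts at 0, is nondecreasing, and ends at the number of
#' occurring species.
#'
#' @param ranking A `selection_ranking` covering exactly the sites of
#'   `occ_eval`.
#' @param occ_eval The evaluation `occurrence_matrix` (typically the
#'   independent fine-grid atlas).
#' @return An object of class `accumulation_curve` with fields `m`
#'   (0..n), `count`, and `source`.
#' @export
accumulation_curve <- function(ranking, occ_eval) {
  if (!setequal(ranking$sites, site_ids(occ_eval)) ||
      length(ranking$sites) != nrow(occ_eval$incidence))
    stop_validation("ranking and evaluation matrix cover different site sets")
  new_curve(prefix_species_counts(ranking$sites, occ_eval),
            source = paste0("S:", ranking$method))
}

new_curve <- function(counts, source, sd = NULL, n_reps = NULL) {
  structure(list(m = seq_along(counts) - 1L, count = as.numeric(counts),
                 sd = sd, n_reps = n_reps, source = source),
            class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("accumulation_curve [%s]: %d sites, %g species at full prefix\n",
              x$source, max(x$m), x$count[length(x$count)]))
  invisible(x)
}

#' Optimal accumulation curve
#'
#' The accumulation curve of a near-optimal ranking of the evaluation matrix
#' itself, estimated either by the Zonation-style reverse-greedy ranking or
#' by rarity-weighted richness. The two estimates coincide on many data sets
#' but are not guaranteed equal, so both can be computed and compared.
#'
#' @param occ_eval An `occurrence_matrix`.
#' @param method `"zonation"` or `"rwr"`.
#' @export
optimum_curve <- function(occ_eval, method = c("zonation", "rwr")) {
  method <- match.arg(method)
  rk <- if (method == "zonation") zonation_ranking(occ_eval)
        else ranking_from_scores(rwr(occ_eval), occ_eval)
  cv <- accumulation_curve(rk, occ_eval)
  cv$source <- paste0("O:", method)
  cv
}

#' Mean random accumulation curve
#'
#' Pointwise mean (and standard deviation) of the accumulation curves of
#' `n_reps` uniformly random site orderings; the baseline R of the Species
#' Accumulation Index.
#'
#' @param occ_eval An `occurrence_matrix`.
#' @param n_reps Number of random orderings (the reference analysis uses
#'   1000).
#' @param seed RNG seed.
#' @export
random_mean_curve <- function(occ_eval, n_reps = 1000, seed = 1) {
  if (!is_count(n_reps) || n_reps < 2)
    stop_validation("n_reps must be an integer >= 2")
  set.seed(seed)
  inc <- occ_eval$incidence
  n <- nrow(inc)
  sp_sites <- lapply(seq_len(ncol(inc)), function(j) which(inc[, j]))
  sp_sites <- sp_sites[lengths(sp_sites) > 0]
  s1 <- s2 <- numeric(n + 1L)
  pos <- integer(n)
  for (rep in seq_len(n_reps)) {
    pos[sample.int(n)] <- seq_len(n)
    fc <- vapply(sp_sites, function(ix) min(pos[ix]), numeric(1))
    curve <- c(0, cumsum(tabulate(fc, nbins = n)))
    s1 <- s1 + curve
    s2 <- s2 + curve^2
  }
  mean_curve <- s1 / n_reps
  sd_curve <- sqrt(pmax(0, s2 / n_reps - mean_curve^2) * n_reps / (n_reps - 1))
  new_curve(mean_curve, source = "R:mean", sd = sd_curve, n_reps = n_reps)
}

#' Species Accumulation Index
#'
#' SAI = (S - R)/(O - R), where S is the species count accumulated by the
#' surrogate ranking, O by the (near-)optimal ranking, and R the mean count
#' over random orderings, all evaluated at the same number of cells. SAI is
#' scaled -Inf to 1: 1 means the surrogate matches the optimum, 0 random
#' performance, negative worse than random. By default SAI is evaluated with
#' 15, 20, 25, 30, and 35 percent of the landscape hypothetically reserved
#' and summarized by the mean over those five levels; `mode = "auc"` instead
#' uses the areas under the entire S, O, and R curves.
#'
#' Fractions are converted to cell counts by rounding half up, with a
#' minimum of one cell. Fractions where O = R carry no signal; they are
#' flagged `NA`, excluded from the mean, and a warning is emitted.
#'
#' @param surrogate_curve,optimum,random_mean `accumulation_curve` objects
#'   over the same site set.
#' @param fractions Protection fractions in (0, 1].
#' @param mode `"fractions"` (default) or `"auc"`.
#' @return An object of class `sai_result`: a per-fraction table
#'   (fraction, m, S, O, R, R_sd, SAI) plus `mean_sai`.
#' @export
sai <- function(surrogate_curve, optimum, random_mean,
                fractions = c(0.15, 0.20, 0.25, 0.30, 0.35),
                mode = c("fractions", "auc")) {
  mode <- match.arg(mode)
  n <- max(surrogate_curve$m)
  if (max(optimum$m) != n || max(random_mean$m) != n)
    stop_validation("accumulation curves do not share a prefix domain")
  if (any(fractions <= 0 | fractions > 1) || is.unsorted(fractions, strictly = TRUE))
    stop_validation("fractions must lie in (0, 1] and be strictly increasing")
  m <- pmax(1L, as.integer(floor(fractions * n + 0.5)))
  S <- surrogate_curve$count[m + 1L]
  O <- optimum$count[m + 1L]
  R <- random_mean$count[m + 1L]
  R_sd <- if (!is.null(random_mean$sd)) random_mean$sd[m + 1L] else rep(NA_real_, length(m))
  sai_f <- ifelse(O == R, NA_real_, (S - R) / (O - R))
  if (anyNA(sai_f))
    warning(sprintf("SAI undefined (O = R) at fraction(s) %s; excluded from the mean",
                    paste(fractions[is.na(sai_f)], collapse = ", ")))
  tab <- data.frame(fraction = fractions, m = m, S = S, O = O, R = R,
                    R_sd = R_sd, SAI = sai_f)
  mean_sai <- if (mode == "auc") {
    idx <- 2:(n + 1L)
    denom <- sum(optimum$count[idx] - random_mean$count[idx])
    if (denom == 0) NA_real_
    else sum(surrogate_curve$count[idx] - random_mean$count[idx]) / denom
  } else mean(sai_f, na.rm = TRUE)
  structure(list(table = tab, mean_sai = mean_sai, mode = mode,
                 surrogate = surrogate_curve$source,
                 optimum = optimum$source,
                 n_random_reps = random_mean$n_reps),
            class = "sai_result")
}

#' @export
print.sai_result <- function(x, digits = 3, ...) {
  cat(sprintf("Species Accumulation Index  (surrogate %s vs %s, R over %s reps)\n",
              x$surrogate, x$optimum, x$n_random_reps %||% "?"))
  print(cbind(x$table[, c("fraction", "m", "S", "O")],
              round(x$table[, c("R", "SAI")], digits)), row.names = FALSE)
  cat(sprintf("Mean SAI (%s): %.3f\n", x$mode, x$mean_sai))
  invisible(x)
}

#' Serialize an SAI result table
#'
#' One row per protection fraction plus a `Mean` row, delimited text.
#' @param result An `sai_result`.
#' @param path Output file.
#' @param extra Optional named list of extra per-fraction columns (e.g. the
#'   alternative optimum estimate).
#' @export
write_sai_table <- function(result, path, extra = NULL) {
  tab <- result$table
  if (!is.null(extra)) for (nm in names(extra)) tab[[nm]] <- extra[[nm]]
  tab$fraction <- as.character(tab$fraction)
  mean_row <- tab[1, ]
  mean_row[1, ] <- NA
  mean_row$fraction <- "Mean"
  mean_row$SAI <- result$mean_sai
  utils::write.csv(rbind(tab, mean_row), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
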