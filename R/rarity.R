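#' Per-species rarity scores
#'
#' The rarity of a species is the inverse of the number of cells in which it
#' occurs: a species found in a single cell scores 1/1 = 1, one found in 20
#' cells scores 1/20 = 0.05. Species with zero presences are excluded (their
#' rarity is undefined) and reported in the `excluded_species` field.
#'
#' @param occ An `occurrence_matrix`.
#' @return An object of class `species_rarity` with fields `species`,
#'   `count` (occupied-cell counts c), `rarity` (1/c), and
#'   `excluded_species`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "C"), c("sp1", "sp2", "sp3")))
#' rarity_scores(occurrence_matrix(m, "coarse"))
#' @export
rarity_scores <- function(occ) {
  counts <- colSums(occ$incidence)
  keep <- counts >= 1
  if (!any(keep)) stop_validation("no scorable species (all occupied-cell counts are zero)")
  if (any(!keep))
    message(sprintf("excluding %d zero-occurrence species: %s", sum(!keep),
                    paste(utils::head(species_ids(occ)[!keep], 5), collapse = ", ")))
  structure(list(species = species_ids(occ)[keep],
                 count = unname(counts[keep]),
                 rarity = unname(1 / counts[keep]),
                 excluded_species = species_ids(occ)[!keep]),
            class = "species_rarity")
}

#' @export
print.species_rarity <- function(x, ...) {
  cat(sprintf("species_rarity: %d species (rarity %.4g-%.4g), %d excluded\n",
              length(x$species), min(x$rarity), max(x$rarity),
              length(x$excluded_species)))
  invisible(x)
}

#' Per-site complementarity scores
#'
#' Container for any per-site priority score: rarity-weighted richness,
#' downscaled complementarity (SDC_a, SDC_r, DDC_r), or a Zonation-style
#' rank value. Scores must be finite and nonnegative.
#'
#' @param sites Site IDs.
#' @param score Numeric scores, same length.
#' @param method Method tag, e.g. `"RWR"`, `"SDC_a"`, `"SDC_r"`, `"DDC_r"`,
#'   `"zonation"`.
#' @export
complementarity_vector <- function(sites, score, method = "RWR") {
  sites <- as.character(sites)
  if (anyDuplicated(sites)) stop_validation("duplicate site IDs in score vector")
  if (length(sites) != length(score))
    stop_validation("sites and score lengths differ")
  if (any(!is.finite(score)) || any(score < 0))
    stop_validation("scores must be finite and nonnegative")
  structure(list(sites = sites, score = as.numeric(score), method = method),
            class = "complementarity_vector")
}

#' @export
print.complementarity_vector <- function(x, ...) {
  cat(sprintf("complementarity_vector [%s]: %d sites, scores %.4g-%.4g\n",
              x$method, length(x$sites), min(x$score), max(x$score)))
  invisible(x)
}

#' Rarity-weighted richness
#'
#' The RWR of a cell is the sum of the rarity scores (1/c) of all species
#' present in it; a cell with no species scores 0. Summed over all cells,
#' RWR equals the number of occurring species, since each species contributes
#' c * (1/c) = 1 in total.
#'
#' @param occ An `occurrence_matrix`.
#' @return A `complementarity_vector` with method `"RWR"`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "C"), c("sp1", "sp2", "sp3")))
#' rwr(occurrence_matrix(m, "coarse"))$score  # 1.5, 0.5, 1.0
#' @export
rwr <- function(occ) {
  sr <- rarity_scores(occ)
  score <- as.numeric(occ$incidence[, sr$species, drop = FALSE] %*% sr$rarity)
  complementarity_vector(site_ids(occ), score, "RWR")
}

#' Read / write complementarity score vectors
#'
#' Delimited text with columns `site_id, score, method`.
#' @param path File path.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  complementarity_vector(df$site_id, df$score, method = df$method[1])
}

#' @rdname read_scores
#' @param scores A `complementarity_vector`.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(site_id = scores$sites, score = scores$score,
                   method = scores$method)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
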