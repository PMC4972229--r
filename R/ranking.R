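#' Site selection rankings
#'
#' A `selection_ranking` is a permutation of the sites of an occurrence
#' matrix, best site first, together with the number of species represented
#' by every prefix of the ranking (computed against that matrix). Prefix
#' counts are nondecreasing and end at the number of occurring species, so
#' the top-m set of any ranking is nested within the top-m' set for m < m'.
#'
#' @param sites_ordered Site IDs, highest priority first; must be a
#'   permutation of the sites of `occ`.
#' @param occ The `occurrence_matrix` prefix counts are computed against.
#' @param method Method tag.
#' @param rank_value Optional per-site numeric value in ranking order (e.g.
#'   the Zonation removal score in `[0, 1]`).
#' @export
selection_ranking <- function(sites_ordered, occ, method = "custom",
                              rank_value = NULL) {
  sites_ordered <- as.character(sites_ordered)
  if (length(sites_ordered) != nrow(occ$incidence) ||
      anyDuplicated(sites_ordered) ||
      !all(sites_ordered %in% site_ids(occ)))
    stop_validation("ranking is not a permutation of the occurrence matrix sites")
  structure(list(sites = sites_ordered,
                 prefix_counts = prefix_species_counts(sites_ordered, occ),
                 method = method,
                 rank_value = rank_value),
            class = "selection_ranking")
}

#' @export
print.selection_ranking <- function(x, ...) {
  n <- length(x$sites)
  cat(sprintf("selection_ranking [%s]: %d sites, %d species at full prefix\n",
              x$method, n, x$prefix_counts[n + 1L]))
  invisible(x)
}

# species represented by each prefix of a site ordering (length n+1, from 0)
prefix_species_counts <- function(sites_ordered, occ) {
  n <- nrow(occ$incidence)
  pos <- match(site_ids(occ), sites_ordered)   # rank position of each row
  inc <- occ$incidence
  first_cover <- vapply(seq_len(ncol(inc)), function(j) {
    p <- pos[inc[, j]]
    if (length(p)) min(p) else NA_integer_
  }, numeric(1))
  counts <- cumsum(tabulate(first_cover[!is.na(first_cover)], nbins = n))
  c(0L, counts)
}

#' Zonation-style reverse-greedy core-area ranking
#'
#' Starts with all cells hypothetically reserved and iteratively removes the
#' cell that is least needed: at each step the marginal loss of cell i is
#' `delta_i = max` over species present in i of 1/(remaining occupied-cell
#' count of that species), and the cell with minimal `delta` is removed.
#' This minimizes the proportional range loss of the worst-off species.
#' With presence-absence data `delta` takes few distinct values (reciprocals
#' of integers) and ties are pervasive, so ties are broken by removing the
#' cell with the smallest remaining rarity-weighted richness (the cell
#' contributing least complementarity among the equally expendable ones),
#' and remaining ties by ascending site ID. The ranking is the removal
#' order reversed (last removed = highest priority), and each site carries a
#' rank value (removal position)/(number of sites) in (0, 1]: values near 1
#' mark cells removed last.
#'
#' This is the basic core-area formulation for presence-absence data with
#' unit species weights, no boundary-length penalty, and single-cell removal.
#' Zero-occurrence species are excluded from all `delta` computations.
#'
#' @param occ An `occurrence_matrix` with at least one occurring species.
#' @return A `selection_ranking` with method `"zonation"`.
#' @export
zonation_ranking <- function(occ) {
  ord <- id_order(site_ids(occ))
  inc <- occ$incidence[ord, , drop = FALSE]
  sites <- site_ids(occ)[ord]
  n <- nrow(inc)
  counts <- colSums(inc)
  keep <- which(counts >= 1)
  if (!length(keep)) stop_validation("no occurring species to rank on")
  inc <- inc[, keep, drop = FALSE]
  cnt <- as.integer(counts[keep])
  sp_sites <- lapply(seq_along(keep), function(j) which(inc[, j]))
  site_sp <- apply(inc, 1L, which, simplify = FALSE)

  delta <- rep(0, n)   # sites with no species are least needed
  rwr_rem <- rep(0, n) # remaining rarity-weighted richness, tie-break key
  for (j in seq_along(cnt)) {
    delta[sp_sites[[j]]] <- pmax(delta[sp_sites[[j]]], 1 / cnt[j])
    rwr_rem[sp_sites[[j]]] <- rwr_rem[sp_sites[[j]]] + 1 / cnt[j]
  }

  removal <- integer(n)
  for (step in seq_len(n)) {
    cand <- which(delta == min(delta))  # removed sites hold delta = Inf
    if (length(cand) > 1L) {
      cand <- cand[rwr_rem[cand] == min(rwr_rem[cand])]
      # which() is ascending, so cand[1] is the lexicographically first site
    }
    p <- cand[1L]
    removal[step] <- p
    delta[p] <- Inf
    for (j in site_sp[[p]]) {
      cnt[j] <- cnt[j] - 1L
      if (cnt[j] > 0L) {
        mem <- sp_sites[[j]]
        # removed sites keep delta = Inf, so no aliveness filter is needed
        delta[mem] <- pmax(delta[mem], 1 / cnt[j])
        rwr_rem[mem] <- rwr_rem[mem] + 1 / cnt[j] - 1 / (cnt[j] + 1L)
      }
    }
  }
  ranking <- rev(removal)
  # site at ranking position i was removed at step n - i + 1, so its
  # removal score is (n - i + 1)/n: 1 for the last-removed (best) site
  selection_ranking(sites[ranking], occ, method = "zonation",
                    rank_value = rev(seq_len(n)) / n)
}

#' Rank sites by a complementarity score vector
#'
#' Sorts sites by descending score, ties broken by ascending site ID, and
#' computes prefix species counts against the stated occurrence matrix.
#'
#' @param scores A `complementarity_vector` covering exactly the sites of
#'   `occ`.
#' @param occ The evaluation `occurrence_matrix`.
#' @export
ranking_from_scores <- function(scores, occ) {
  if (!setequal(scores$sites, site_ids(occ)) ||
      length(scores$sites) != nrow(occ$incidence))
    stop_validation("score vector and occurrence matrix cover different site sets")
  ord <- id_order(scores$sites, scores$score)
  selection_ranking(scores$sites[ord], occ, method = scores$method,
                    rank_value = scores$score[ord])
}

#' Random site rankings
#'
#' Independent uniform permutations of the sites, reproducible given the
#' seed. Used for the random baseline R of the Species Accumulation Index.
#'
#' @param occ An `occurrence_matrix`.
#' @param n_reps Number of permutations.
#' @param seed RNG seed.
#' @return A list of `selection_ranking` objects with method `"random"`.
#' @export
random_rankings <- function(occ, n_reps, seed = 1) {
  if (!is_count(n_reps)) stop_validation("n_reps must be a positive integer")
  set.seed(seed)
  sites <- site_ids(occ)
  lapply(seq_len(n_reps), function(i)
    selection_ranking(sample(sites), occ, method = "random"))
}

#' Exhaustively optimal m-site subset
#'
#' Enumerates all m-subsets of sites and returns one maximizing the number
#' of represented species (ties broken lexicographically by site ID). A test
#' oracle for the greedy optimum; refuses instances with more than 1e6
#' candidate subsets.
#'
#' @param occ An `occurrence_matrix`.
#' @param m Subset size.
#' @return A list with `sites` (the best subset) and `n_species`.
#' @export
exhaustive_optimum <- function(occ, m) {
  n <- nrow(occ$incidence)
  if (!is_count(m) || m > n) stop_validation("m must be an integer in 1..n_sites")
  if (choose(n, m) > 1e6)
    stop(sprintf("refusing exhaustive enumeration: choose(%d, %d) exceeds 1e6", n, m))
  ord <- id_order(site_ids(occ))
  inc <- occ$incidence[ord, , drop = FALSE]
  combos <- utils::combn(n, m)
  covered <- apply(combos, 2L, function(ix)
    sum(colSums(inc[ix, , drop = FALSE]) > 0))
  best <- which.max(covered)  # combn enumerates in lexicographic order
  list(sites = rownames(inc)[combos[, best]],
       n_species = as.integer(covered[best]))
}
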