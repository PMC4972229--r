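# Shared fixtures, all built in code.

# worked three-site example: c = (1, 2, 1), RWR = (1.5, 0.5, 1.0)
abc_occ <- function() {
  m <- matrix(c(1, 1, 0,
                0, 1, 0,
                0, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("sp1", "sp2", "sp3")))
  occurrence_matrix(m, "coarse")
}

random_occ <- function(n_sites, n_species, seed, density = 0.5,
                       resolution = "coarse") {
  set.seed(seed)
  inc <- matrix(stats::runif(n_sites * n_species) < density, n_sites, n_species,
                dimnames = list(sprintf("s%03d", seq_len(n_sites)),
                                sprintf("sp%03d", seq_len(n_species))))
  if (all(colSums(inc) == 0)) inc[1, 1] <- TRUE
  occurrence_matrix(inc, resolution)
}

# small landscape for module-level tests (fast to generate)
small_config <- function(seed = 1, ...) {
  landscape_config(n_rows_fine = 20, n_cols_fine = 20, block_factor = 4,
                   n_species = 15, n_env_vars = 4, smoothness = 3,
                   seed = seed, ...)
}

# independent set-union oracle for prefix species counts
union_counts_oracle <- function(sites_ordered, occ) {
  inc <- occ$incidence[sites_ordered, , drop = FALSE]
  counts <- integer(length(sites_ordered) + 1L)
  seen <- rep(FALSE, ncol(inc))
  for (i in seq_along(sites_ordered)) {
    seen <- seen | inc[i, ]
    counts[i + 1L] <- sum(seen)
  }
  counts
}
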