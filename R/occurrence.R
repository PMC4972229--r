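#' Presence-absence occurrence matrix
#'
#' A sites x species incidence matrix tagged with its grid resolution.
#' Species with zero presences are representable (they are excluded from
#' rarity computations downstream, with a report).
#'
#' @param incidence Logical or 0/1 numeric matrix, sites as rows. Row and
#'   column names supply site and species identifiers unless `sites` /
#'   `species` are given.
#' @param resolution `"fine"` or `"coarse"`.
#' @param sites,species Identifier vectors; must be free of duplicates.
#' @return An object of class `occurrence_matrix`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "C"), c("sp1", "sp2", "sp3")))
#' occurrence_matrix(m, "coarse")
#' @export
occurrence_matrix <- function(incidence, resolution = c("fine", "coarse"),
                              sites = rownames(incidence),
                              species = colnames(incidence)) {
  resolution <- match.arg(resolution)
  if (!is.matrix(incidence)) stop_validation("incidence must be a matrix")
  if (is.numeric(incidence)) {
    bad <- which(!(incidence %in% c(0, 1)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(incidence))
      stop_validation("incidence values must be 0/1 (offending entry at row %d, column %d)",
                      rc[1], rc[2])
    }
    incidence <- incidence > 0
  }
  if (!is.logical(incidence)) stop_validation("incidence must be logical or 0/1")
  if (is.null(sites) || is.null(species))
    stop_validation("site and species identifiers are required")
  sites <- as.character(sites)
  species <- as.character(species)
  if (anyDuplicated(sites))
    stop_validation("duplicate site IDs: %s",
                    paste(unique(sites[duplicated(sites)]), collapse = ", "))
  if (anyDuplicated(species))
    stop_validation("duplicate species IDs: %s",
                    paste(unique(species[duplicated(species)]), collapse = ", "))
  if (length(sites) != nrow(incidence) || length(species) != ncol(incidence))
    stop_validation("identifier lengths do not match incidence dimensions")
  dimnames(incidence) <- list(sites, species)
  structure(list(incidence = incidence, resolution = resolution),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("occurrence_matrix (%s): %d sites x %d species, %d presences\n",
              x$resolution, nrow(x$incidence), ncol(x$incidence),
              sum(x$incidence)))
  invisible(x)
}

#' @export
dim.occurrence_matrix <- function(x) dim(x$incidence)

#' Accessors for occurrence matrices
#' @param occ An `occurrence_matrix`.
#' @export
site_ids <- function(occ) rownames(occ$incidence)

#' @rdname site_ids
#' @export
species_ids <- function(occ) colnames(occ$incidence)

#' Read / write occurrence tables
#'
#' Comma-delimited text, sites as rows: first column holds site IDs, the
#' header row species IDs, and cells are 0/1.
#'
#' @param path File path.
#' @param resolution Resolution tag to attach on read.
#' @return `read_occurrence()` returns an `occurrence_matrix`.
#' @export
read_occurrence <- function(path, resolution = c("fine", "coarse")) {
  resolution <- match.arg(resolution)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_validation("occurrence table needs a site column plus species columns")
  sites <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
  }
  bad <- which(is.na(vals) | !(vals %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(vals))
    stop_validation("malformed cell at row '%s', column '%s' of %s (must be 0 or 1)",
                    sites[rc[1]], colnames(vals)[rc[2]], path)
  }
  occ <- occurrence_matrix(vals, resolution, sites = sites,
                           species = colnames(vals))
  message(sprintf("read %s: %d sites, %d species, %d presences",
                  path, nrow(vals), ncol(vals), sum(vals)))
  occ
}

#' @rdname read_occurrence
#' @param occ An `occurrence_matrix` to serialize.
#' @export
write_occurrence <- function(occ, path) {
  df <- data.frame(site_id = site_ids(occ),
                   occ$incidence * 1L, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate a fine-grid occurrence matrix to the coarse grid
#'
#' A species is present in a coarse cell if it is present in any member fine
#' cell (block-wise logical OR), mirroring how range maps and atlases record
#' presence for any partially overlapped coarse cell.
#'
#' @param occ_fine `occurrence_matrix` whose site IDs are fine cells of `grid`.
#' @param grid A `grid_spec`.
#' @return A coarse `occurrence_matrix` covering every block that contains at
#'   least one site of `occ_fine`, in row-major coarse order.
#' @export
aggregate_to_coarse <- function(occ_fine, grid) {
  fid <- fine_site_ids(grid)
  pos <- match(site_ids(occ_fine), fid)
  if (anyNA(pos))
    stop_validation("site IDs not on the fine grid: %s",
                    paste(utils::head(site_ids(occ_fine)[is.na(pos)], 5), collapse = ", "))
  block <- fine_block_index(grid)[pos]
  agg <- rowsum(occ_fine$incidence * 1L, group = block)
  blocks <- as.integer(rownames(agg))
  ord <- order(blocks)
  occurrence_matrix(agg[ord, , drop = FALSE] > 0, "coarse",
                    sites = coarse_site_ids(grid)[blocks[ord]],
                    species = species_ids(occ_fine))
}

#' Environmental predictor table
#'
#' Numeric site x variable values; `NA` marks missing measurements. Sites
#' with a missing value in any selected predictor are dropped from model
#' fitting and flagged in prediction output, never imputed.
#'
#' @param values Numeric matrix (sites x variables).
#' @param sites,variables Identifier vectors (default dimnames).
#' @export
env_table <- function(values, sites = rownames(values),
                      variables = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("env values must be a numeric matrix")
  if (is.null(sites) || is.null(variables))
    stop_validation("site and variable identifiers are required")
  sites <- as.character(sites); variables <- as.character(variables)
  if (anyDuplicated(sites)) stop_validation("duplicate site IDs in env table")
  if (anyDuplicated(variables)) stop_validation("duplicate variable names in env table")
  dimnames(values) <- list(sites, variables)
  structure(list(values = values), class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: %d sites x %d variables (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

# variables with no finite variance over non-missing sites
constant_variables <- function(env) {
  v <- apply(env$values, 2, function(col) stats::var(col[!is.na(col)]))
  colnames(env$values)[!is.finite(v) | v == 0]
}

#' @rdname env_table
#' @param path File path (CSV: site_id column, one column per variable).
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  env_table(vals, sites = as.character(df[[1]]), variables = colnames(vals))
}

#' @rdname env_table
#' @param env An `env_table` to serialize.
#' @export
write_env_table <- function(env, path) {
  df <- data.frame(site_id = rownames(env$values), env$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Species range-map masks on the fine grid
#'
#' Each species' range map is represented by the set of fine cells its range
#' overlaps (1-based positions in row-major fine order). A species' mask may
#' be empty (range outside the grid); such species are excluded downstream.
#'
#' @param masks Named list of integer vectors of fine-cell positions.
#' @param n_fine Optional number of fine cells, for index validation.
#' @export
range_map_set <- function(masks, n_fine = NULL) {
  if (!is.list(masks) || is.null(names(masks)) || anyDuplicated(names(masks)))
    stop_validation("masks must be a named list with unique species IDs")
  masks <- lapply(masks, function(m) sort(unique(as.integer(m))))
  bad <- vapply(masks, function(m) length(m) && (anyNA(m) || min(m) < 1L ||
                  (!is.null(n_fine) && max(m) > n_fine)), logical(1))
  if (any(bad))
    stop_validation("invalid fine-cell indices in masks for: %s",
                    paste(names(masks)[bad], collapse = ", "))
  structure(list(masks = masks), class = "range_map_set")
}

#' @export
print.range_map_set <- function(x, ...) {
  cat(sprintf("range_map_set: %d species, mask sizes %s\n",
              length(x$masks),
              paste(range(lengths(x$masks)), collapse = "-")))
  invisible(x)
}

#' Read / write range-map masks
#'
#' Two-column delimited text: `species_id, cell_id`, where `cell_id` is a
#' fine-grid site ID of the accompanying grid.
#' @param path File path.
#' @param grid A `grid_spec` giving the fine grid the cell IDs refer to.
#' @export
read_range_maps <- function(path, grid) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_validation("range-mask table needs species_id and cell_id columns")
  pos <- match(as.character(df[[2]]), fine_site_ids(grid))
  if (anyNA(pos))
    stop_validation("unknown fine cell IDs in %s: %s", path,
                    paste(utils::head(df[[2]][is.na(pos)], 5), collapse = ", "))
  range_map_set(split(pos, as.character(df[[1]])), n_fine = n_fine_cells(grid))
}

#' @rdname read_range_maps
#' @param ranges A `range_map_set` to serialize.
#' @export
write_range_maps <- function(ranges, grid, path) {
  fid <- fine_site_ids(grid)
  sp <- rep(names(ranges$masks), lengths(ranges$masks))
  df <- data.frame(species_id = sp, cell_id = fid[unlist(ranges$masks)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rasterize range-map masks to an occurrence matrix
#'
#' At fine resolution, a species is present in exactly the cells of its mask;
#' at coarse resolution the fine rasterization is aggregated block-wise (any
#' partial overlap counts).
#'
#' @param ranges A `range_map_set`.
#' @param grid A `grid_spec`.
#' @param resolution Target resolution.
#' @export
rasterize_ranges <- function(ranges, grid, resolution = c("fine", "coarse")) {
  resolution <- match.arg(resolution)
  if (!length(ranges$masks)) stop_validation("empty range_map_set")
  n <- n_fine_cells(grid)
  bad <- vapply(ranges$masks,
                function(m) length(m) && max(m) > n, logical(1))
  if (any(bad))
    stop_validation("masks reference cells outside the grid: %s",
                    paste(names(ranges$masks)[bad], collapse = ", "))
  inc <- matrix(FALSE, n, length(ranges$masks))
  for (j in seq_along(ranges$masks)) inc[ranges$masks[[j]], j] <- TRUE
  occ <- occurrence_matrix(inc, "fine", sites = fine_site_ids(grid),
                           species = names(ranges$masks))
  if (resolution == "coarse") aggregate_to_coarse(occ, grid) else occ
}
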