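## Range refinement and presence-stack assembly.

#' Refine a range extent by elevational limits
#'
#' Keeps exactly the extent cells whose (cell-mean) elevation lies
#' within the species' reported elevational limits, inclusive at both
#' bounds.  An empty result is legal (the species is later kept in the
#' stack as an all-zero row).
#'
#' @param extent_cells Integer vector of cell indices (unrefined
#'   extent).
#' @param elevation Elevation layer: matrix or vector indexed by cell.
#' @param elev_min,elev_max Elevational limits in m, `elev_min <=
#'   elev_max`; use `-Inf`/`Inf` to disable a bound.
#' @return Integer vector of retained cell indices.
#' @export
refine_by_elevation <- function(extent_cells, elevation, elev_min, elev_max) {
  if (elev_min > elev_max) stop("elev_min must be <= elev_max")
  e <- as.vector(elevation)[extent_cells]
  out <- extent_cells[e >= elev_min & e <= elev_max]
  if (!length(out) && length(extent_cells)) {
    message("refine_by_elevation: refined range is empty")
  }
  out
}

#' Build a presence stack from per-species cell sets
#'
#' @param refined_ranges Named list (names are species ids) of integer
#'   cell-index vectors; empty vectors give all-zero rows.
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_km Nominal cell edge in km (metadata).
#' @return Object of class `ts_stack`: list with `species_ids`,
#'   `occupancy` (species x cell 0/1 matrix), `n_rows`, `n_cols`,
#'   `cell_km`.
#' @export
build_stack <- function(refined_ranges, n_rows, n_cols, cell_km = 20) {
  ids <- names(refined_ranges)
  if (is.null(ids) || any(ids == "")) stop("refined_ranges must be named")
  if (anyDuplicated(ids)) stop("duplicate species_id in refined_ranges")
  n_cells <- n_rows * n_cols
  occ <- matrix(0L, length(ids), n_cells, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    cells <- refined_ranges[[i]]
    if (!length(cells)) {
      message("build_stack: species ", ids[i], " has an empty refined range")
      next
    }
    if (any(cells < 1L | cells > n_cells)) {
      stop("cell index outside grid for species ", ids[i])
    }
    occ[i, cells] <- 1L
  }
  structure(list(species_ids = ids, occupancy = occ,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_km = cell_km),
            class = "ts_stack")
}

#' @export
print.ts_stack <- function(x, ...) {
  cat(sprintf("Presence stack: %d species on a %d x %d grid (%g km cells)\n",
              length(x$species_ids), x$n_rows, x$n_cols, x$cell_km))
  cat(sprintf("  occupied species-cells: %d; empty-range species: %d\n",
              sum(x$occupancy), sum(rowSums(x$occupancy) == 0)))
  invisible(x)
}

#' Recover per-species cell sets from a stack
#'
#' Inverse of [build_stack()].
#'
#' @param stack A `ts_stack`.
#' @return Named list of integer cell-index vectors.
#' @export
stack_to_ranges <- function(stack) {
  out <- lapply(seq_along(stack$species_ids),
                function(i) which(stack$occupancy[i, ] == 1L))
  names(out) <- stack$species_ids
  out
}

#' Species-richness map
#'
#' Per-cell count of species present in the stack.
#'
#' @param stack A `ts_stack`.
#' @return Integer matrix of dimension `n_rows` x `n_cols`.
#' @export
species_richness_map <- function(stack) {
  matrix(as.integer(colSums(stack$occupancy)), stack$n_rows, stack$n_cols)
}
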