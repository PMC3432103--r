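## Trait distances and community-composition metrics: Gower distance,
## principal-coordinates trait space, community-weighted means,
## functional richness (per-trait and convex-hull), and functional
## divergence (Rao quadratic entropy with its Jost numbers
## equivalent).

## Trait scopes and the columns they address.
trait_scopes <- c("mass", "genlength", "migration", "diet")
trait_columns <- c(mass = "log_mass", genlength = "log_genlength",
                   migration = "migratory_class", diet = "diet_class")
continuous_scopes <- c("mass", "genlength")
categorical_scopes <- c("migration", "diet")

#' Gower trait distance matrix
#'
#' Pairwise Gower distances among species in trait space.  Continuous
#' traits (log body mass, log generation length) contribute
#' `|x_s - x_s'|` divided by the trait's range across the *global*
#' species pool (so distances are comparable across communities);
#' categorical traits contribute 0 for a shared class and 1 otherwise.
#' The distance is the unweighted mean of the per-trait contributions
#' in `scope`.
#'
#' @param traits Data frame with `species_id`, `log_mass`,
#'   `log_genlength`, `migratory_class`, `diet_class`; complete cases
#'   required (species with missing trait values must be excluded
#'   upstream, and are rejected here).
#' @param species Optional character vector restricting the matrix to
#'   a subset of species; pool ranges are still taken from the full
#'   `traits` table.
#' @param scope `"all"` (all four traits) or one of `"mass"`,
#'   `"genlength"`, `"migration"`, `"diet"`.
#' @return Symmetric species x species matrix with values in
#'   \[0, 1\], zero diagonal, dimnames = species ids.
#' @export
gower_distance <- function(traits, species = NULL, scope = "all") {
  cols <- unname(trait_columns)
  if (any(is.na(traits[, cols]))) {
    stop("species with missing trait values must be excluded")
  }
  scope <- match.arg(scope, c("all", trait_scopes))
  use <- if (scope == "all") trait_scopes else scope
  sub <- if (is.null(species)) traits else {
    if (!all(species %in% traits$species_id)) stop("unknown species_id")
    traits[match(species, traits$species_id), ]
  }
  if (nrow(sub) < 2) stop("need at least 2 species")
  n <- nrow(sub)
  acc <- matrix(0, n, n)
  for (sc in use) {
    col <- trait_columns[[sc]]
    if (sc %in% continuous_scopes) {
      rng <- diff(range(traits[[col]]))
      ## a zero-range trait carries no discriminating information
      contrib <- if (rng == 0) matrix(0, n, n) else {
        abs(outer(sub[[col]], sub[[col]], "-")) / rng
      }
    } else {
      contrib <- 1 - outer(sub[[col]], sub[[col]], "==")
    }
    acc <- acc + contrib
  }
  d <- acc / length(use)
  dimnames(d) <- list(sub$species_id, sub$species_id)
  d
}

#' Principal coordinates analysis of a trait distance matrix
#'
#' Classical metric scaling (double-centred eigendecomposition) of a
#' distance matrix; axes with non-positive eigenvalues are dropped.
#' For Euclidean-embeddable distance matrices the retained coordinates
#' reproduce the input distances.
#'
#' @param d Symmetric distance matrix with species ids as dimnames.
#' @return Object of class `ts_pcoa`: list with `coords` (species x
#'   axis matrix, axes ordered by decreasing eigenvalue) and
#'   `eigenvalues` (positive eigenvalues, one per retained axis).
#'   All-zero distances yield zero retained axes.
#' @export
trait_pcoa <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  n <- nrow(d)
  if (all(d == 0)) {
    message("trait_pcoa: all distances are zero; no axes retained")
    return(structure(list(coords = matrix(0, n, 0,
                                          dimnames = list(rownames(d), NULL)),
                          eigenvalues = numeric(0)),
                     class = "ts_pcoa"))
  }
  ## cmdscale warns when fewer than k eigenvalues are positive; the
  ## non-positive axes are dropped below by design
  mds <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  tol <- 1e-8 * max(abs(mds$eig))
  keep <- which(mds$eig > tol)
  coords <- mds$points[, keep, drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("axis", seq_along(keep))
  structure(list(coords = coords, eigenvalues = mds$eig[keep]),
            class = "ts_pcoa")
}

#' @export
print.ts_pcoa <- function(x, ...) {
  cat(sprintf("PCoA trait space: %d species, %d positive axes\n",
              nrow(x$coords), ncol(x$coords)))
  if (length(x$eigenvalues)) {
    cat("  relative eigenvalues:",
        paste(sprintf("%.3f", x$eigenvalues / sum(x$eigenvalues)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Select leading PCoA axes for the hull
#'
#' Keeps the smallest number of leading axes whose eigenvalues explain
#' at least `var_target` of the retained (positive) eigenvalue mass,
#' capped at `max_axes` so that most communities have more species
#' than axes and hull volumes stay non-degenerate.
#'
#' @param pcoa A `ts_pcoa`.
#' @param var_target Fraction of eigenvalue mass to cover (default
#'   0.95).
#' @param max_axes Hard cap on the number of axes (default 3).
#' @return Species x axis coordinate matrix.
#' @export
select_axes <- function(pcoa, var_target = 0.95, max_axes = 3) {
  ev <- pcoa$eigenvalues
  if (!length(ev)) return(pcoa$coords)
  k <- which(cumsum(ev) / sum(ev) >= var_target)[1]
  k <- min(k, max_axes, length(ev))
  pcoa$coords[, seq_len(k), drop = FALSE]
}

#' Community-weighted mean of a continuous trait
#'
#' `sum(A_s * x_s) / A`: the mean trait value among individuals, with
#' species values weighted by abundance.  Continuous traits enter on
#' the log scale throughout.
#'
#' @param abund Positive abundances of the species present.
#' @param values Trait values matched to `abund`.
#' @return Weighted mean.
#' @export
cwm_continuous <- function(abund, values) {
  stopifnot(length(abund) == length(values))
  if (!length(abund)) stop("empty community")
  if (any(abund <= 0)) stop("abundances must be positive")
  sum(abund * values) / sum(abund)
}

#' Community-weighted mean of a categorical trait class
#'
#' The proportion of individuals in class `class`:
#' `sum(A_s for s in class) / A`.
#'
#' @param abund Positive abundances of the species present.
#' @param classes Class labels matched to `abund`.
#' @param class The class whose proportion is wanted.
#' @param levels Known class labels; `class` must be one of them
#'   (defaults to the labels present in `classes`).
#' @return Proportion in \[0, 1\].
#' @export
cwm_categorical <- function(abund, classes, class,
                            levels = sort(unique(classes))) {
  stopifnot(length(abund) == length(classes))
  if (!length(abund)) stop("empty community")
  if (!class %in% levels) stop("unknown class: ", class)
  sum(abund[classes == class]) / sum(abund)
}

#' Single-trait functional richness
#'
#' The range of values present (continuous trait) or the number of
#' distinct classes present (categorical trait).  Abundance is
#' ignored by construction.
#'
#' @param x Trait values of the species present: numeric for a
#'   continuous trait, character/factor for a categorical one.
#' @return Range or class count.
#' @export
frich_single <- function(x) {
  if (!length(x)) stop("empty community")
  if (is.numeric(x)) max(x) - min(x) else length(unique(as.character(x)))
}

#' Convex-hull functional richness in trait space
#'
#' Volume of the convex hull enclosing the principal-coordinate
#' positions of the species present.  Degenerate communities (no more
#' species than axes, or affinely dependent points) return 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param coords Species x axis coordinate matrix for the community
#'   (see [select_axes()]).
#' @return Hull volume with attribute `degenerate`.
#' @export
frich_hull <- function(coords) {
  convex_hull_volume(coords)
}

#' Rao quadratic entropy of a community
#'
#' `Q = sum_s sum_s' d(s, s') (A_s / A)(A_s' / A)` over the species
#' present: the expected trait distance between two individuals drawn
#' at random (with replacement) from the community.  With distances in
#' \[0, 1\], `Q` lies in \[0, 1); a single-species community has
#' `Q = 0`.
#'
#' @param abund Named positive abundances (names are species ids), or
#'   unnamed if `d` rows align with `abund`.
#' @param d Trait distance matrix containing the community's species.
#' @return Rao's Q.
#' @export
rao_q <- function(abund, d) {
  if (!length(abund)) stop("empty community")
  if (any(abund <= 0)) stop("abundances must be positive")
  if (!is.null(names(abund))) {
    if (!all(names(abund) %in% rownames(d))) {
      stop("community species missing from distance matrix")
    }
    d <- d[names(abund), names(abund), drop = FALSE]
  } else {
    stopifnot(nrow(d) == length(abund))
  }
  p <- abund / sum(abund)
  as.numeric(t(p) %*% d %*% p)
}

#' Jost numbers equivalent of Rao's Q
#'
#' Converts Rao's quadratic entropy to an effective number of
#' (maximally distinct, equally abundant) species: `1 / (1 - Q)`.
#' For `S` equally abundant species at mutual distance 1,
#' `Q = (S - 1) / S` and the numbers equivalent is exactly `S`.
#'
#' @param q Rao's Q in \[0, 1).
#' @return Numbers equivalent, `>= 1`.
#' @export
numbers_equivalent <- function(q) {
  if (any(q < 0 | q >= 1)) stop("Q must lie in [0, 1)")
  1 / (1 - q)
}

#' All community-composition metrics for one community
#'
#' Emits, for a single community (a grid cell or a survey site):
#' community-weighted means for each continuous trait, CWM proportions
#' for every class of each categorical trait, single-trait functional
#' richness per trait, optionally the multivariate convex-hull
#' functional richness (only meaningful for abundance-ignoring,
#' presence-based communities), and functional divergence (the Jost
#' numbers equivalent of Rao's Q) per trait and for all traits
#' together.
#'
#' @param species Character vector of species present.
#' @param abund Positive abundances matched to `species`.
#' @param traits Full trait table (defines class levels and pool
#'   ranges).
#' @param dist_list Named list of distance matrices with elements
#'   `mass`, `genlength`, `migration`, `diet`, `all` (full-pool
#'   matrices from [gower_distance()]).
#' @param coords Optional coordinate matrix from [select_axes()]
#'   (full pool); required when `include_hull = TRUE`.
#' @param include_hull Compute the convex-hull FRICH over all traits
#'   (use only for abundance-ignoring communities).
#' @param include_frich Compute FRICH metrics at all (FRICH ignores
#'   abundance, so it is emitted only for presence-based method runs).
#' @return Data frame with columns `metric`, `trait_scope`, `value`,
#'   `flag` (`""`, `"single_species"` or `"degenerate_hull"`).
#' @export
community_metrics <- function(species, abund, traits, dist_list,
                              coords = NULL, include_hull = FALSE,
                              include_frich = TRUE) {
  stopifnot(length(species) == length(abund))
  if (!length(species)) stop("empty community")
  tr <- traits[match(species, traits$species_id), ]
  if (any(is.na(tr$species_id))) stop("unknown species in community")
  single <- length(species) < 2
  rows <- list()
  add <- function(metric, scope, value, flag = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, trait_scope = scope, value = as.numeric(value),
      flag = flag, stringsAsFactors = FALSE)
  }
  for (sc in continuous_scopes) {
    add("CWM", sc, cwm_continuous(abund, tr[[trait_columns[[sc]]]]))
  }
  class_levels <- list(migration = migratory_classes, diet = diet_classes)
  for (sc in categorical_scopes) {
    for (cl in class_levels[[sc]]) {
      add("CWM", paste(sc, cl, sep = "."),
          cwm_categorical(abund, tr[[trait_columns[[sc]]]], cl,
                          levels = class_levels[[sc]]))
    }
  }
  if (include_frich) {
    for (sc in trait_scopes) {
      add("FRICH", sc, frich_single(tr[[trait_columns[[sc]]]]))
    }
    if (include_hull) {
      if (is.null(coords)) stop("coords required when include_hull = TRUE")
      v <- frich_hull(coords[species, , drop = FALSE])
      add("FRICH", "all", v,
          flag = if (isTRUE(attr(v, "degenerate"))) "degenerate_hull" else "")
    }
  }
  for (sc in c(trait_scopes, "all")) {
    q <- if (single) 0 else rao_q(stats::setNames(abund, species),
                                  dist_list[[sc]])
    add("FDIV", sc, numbers_equivalent(q),
        flag = if (single) "single_species" else "")
  }
  do.call(rbind, rows)
}

#' Trait distance matrices for every scope
#'
#' Convenience wrapper building the five distance matrices
#' (`mass`, `genlength`, `migration`, `diet`, `all`) used by
#' [community_metrics()].
#'
#' @param traits Full trait table.
#' @return Named list of distance matrices.
#' @export
trait_distances <- function(traits) {
  out <- lapply(c(trait_scopes, all = "all"), function(sc) {
    gower_distance(traits, scope = sc)
  })
  names(out) <- c(trait_scopes, "all")
  out
}

#' Community metric maps for an abundance field
#'
#' Applies [community_metrics()] to the community of every grid cell
#' (or a subset of cells) of an abundance field.  Cells with no
#' eligible species are skipped.
#'
#' @param field A `ts_abundance`.
#' @param traits Full trait table.
#' @param dist_list From [trait_distances()].
#' @param coords From [select_axes()]; needed when
#'   `include_hull = TRUE`.
#' @param include_hull,include_frich Passed to [community_metrics()];
#'   FRICH metrics default to the presence-based field only
#'   (`method_tag == "uniform"`).
#' @param cells Optional integer vector of cell indices to evaluate
#'   (default: all occupied cells).
#' @return Long data frame: `cell`, `metric`, `trait_scope`, `value`,
#'   `flag`.
#' @export
community_metric_maps <- function(field, traits, dist_list, coords = NULL,
                                  include_hull = NULL, include_frich = NULL,
                                  cells = NULL) {
  presence_based <- identical(field$method_tag, "uniform")
  if (is.null(include_frich)) include_frich <- presence_based
  if (is.null(include_hull)) include_hull <- presence_based
  rows <- field$species_ids %in% field$eligible_species
  vals <- field$values[rows, , drop = FALSE]
  if (is.null(cells)) cells <- which(colSums(vals) > 0)
  out <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    a <- vals[, cells[k]]
    present <- which(a > 0)
    if (!length(present)) next
    m <- community_metrics(rownames(vals)[present], a[present], traits,
                           dist_list, coords, include_hull = include_hull,
                           include_frich = include_frich)
    m$cell <- cells[k]
    out[[k]] <- m
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(metric = character(), trait_scope = character(),
                      value = numeric(), flag = character(),
                      cell = integer(), stringsAsFactors = FALSE)
  }
  res[, c("cell", "metric", "trait_scope", "value", "flag")]
}

#' Rasterise one metric from a long metric table
#'
#' @param metric_df Output of [community_metric_maps()].
#' @param metric,trait_scope The metric/scope pair to extract.
#' @param n_rows,n_cols Grid dimensions.
#' @return Matrix with `NA` at cells without a value.
#' @export
metric_map_matrix <- function(metric_df, metric, trait_scope,
                              n_rows, n_cols) {
  sel <- metric_df$metric == metric & metric_df$trait_scope == trait_scope
  m <- matrix(NA_real_, n_rows, n_cols)
  m[metric_df$cell[sel]] <- metric_df$value[sel]
  m
}
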