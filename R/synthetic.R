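## Synthetic worlds: landscapes, species pools, ranges, abundance
## surfaces and survey records with the statistical structure the
## mapping pipeline assumes, so everything downstream is testable
## without external range, trait or count data.

#' Migratory and diet classes recognised by the package
#'
#' Canonical categorical trait levels: four migratory classes and six
#' diet classes.
#'
#' @name trait_classes
#' @aliases migratory_classes diet_classes
#' @export
migratory_classes <- c("non-migrant", "nomad", "altitudinal", "latitudinal")

#' @rdname trait_classes
#' @export
diet_classes <- c("fruit", "nectar", "plant", "invertebrate", "vertebrate",
                  "mixed")

#' Generate a synthetic landscape
#'
#' Builds an equal-area grid carrying an elevation layer and three
#' smooth environmental covariates (a temperature-like gradient, a
#' precipitation-like field, and a minimum-temperature-like field).
#' Each layer is a low-order spatial trend plus Gaussian-smoothed
#' noise, so neighbouring cells are positively autocorrelated.
#'
#' @param n_rows,n_cols Grid dimensions in cells; both must be >= 4.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param cell_km Nominal cell edge length in km (metadata only).
#' @return An object of class `ts_landscape`: a list with `n_rows`,
#'   `n_cols`, `cell_km` and matrices `elevation` (m), `env1`, `env2`,
#'   `env3`.
#' @examples
#' land <- generate_landscape(12, 12, seed = 1)
#' range(land$elevation)
#' @export
generate_landscape <- function(n_rows, n_cols, seed = 1L, cell_km = 20) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 4 || n_cols < 4) {
    stop("n_rows and n_cols must both be >= 4")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  rg <- matrix(rep(seq(0, 1, length.out = n_rows), n_cols), n_rows, n_cols)
  cg <- matrix(rep(seq(0, 1, length.out = n_cols), each = n_rows),
               n_rows, n_cols)
  sigma <- max(1, min(n_rows, n_cols) / 10)
  noise <- function(sd) {
    gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols, 0, sd),
                           n_rows, n_cols), sigma)
  }
  with_seed(derive_seed(seed, "landscape"), {
    ridge <- exp(-(cg - 0.5)^2 / (2 * 0.18^2))
    elevation <- pmax(300 + 1700 * ridge + 8 * noise(120), 0)
    env1 <- 26 - 20 * rg - 0.004 * elevation + 3 * noise(1.5)
    env2 <- pmax(900 + 500 * sin(pi * cg) - 350 * rg + 30 * noise(15), 0)
    env3 <- env1 - 12 + 2 * noise(1.5)
    structure(
      list(n_rows = n_rows, n_cols = n_cols, cell_km = cell_km,
           elevation = elevation, env1 = env1, env2 = env2, env3 = env3),
      class = "ts_landscape"
    )
  })
}

#' @export
print.ts_landscape <- function(x, ...) {
  cat(sprintf("Synthetic landscape: %d x %d cells (%g km edge)\n",
              x$n_rows, x$n_cols, x$cell_km))
  cat(sprintf("  elevation: %.0f-%.0f m; env1: %.1f-%.1f; env2: %.0f-%.0f; env3: %.1f-%.1f\n",
              min(x$elevation), max(x$elevation), min(x$env1), max(x$env1),
              min(x$env2), max(x$env2), min(x$env3), max(x$env3)))
  invisible(x)
}

#' Default configuration for a synthetic species pool
#'
#' Distributions emulate a hemispheric bird fauna: log-normal body mass
#' (median ~50 g) and generation length (median ~4 yr), four migratory
#' and six diet classes at realistic frequencies, wide elevational
#' tolerances, log-normal range sizes, and a log-linear abundance model
#' in three environmental covariates.  `trait_coupling` adds a multiple
#' of centred log-mass to each species' log-abundance intercept; at the
#' default 0 the abundance surfaces are independent of traits (the null
#' regime in which presence-only mapping is unbiased).
#'
#' @param ... Named overrides of any default element.
#' @return A named list of pool parameters.
#' @export
default_trait_config <- function(...) {
  cfg <- list(
    mass_log_mean = log(50), mass_log_sd = 1.1,
    genlength_log_mean = log(4), genlength_log_sd = 0.45,
    migratory_probs = c("non-migrant" = 0.55, "nomad" = 0.05,
                        "altitudinal" = 0.10, "latitudinal" = 0.30),
    diet_probs = c(fruit = 0.10, nectar = 0.07, plant = 0.13,
                   invertebrate = 0.42, vertebrate = 0.10, mixed = 0.18),
    elev_breadth_log_mean = log(2200), elev_breadth_log_sd = 0.4,
    range_frac_log_mean = log(0.35), range_frac_log_sd = 0.5,
    abund_intercept_log_mean = log(4), abund_intercept_log_sd = 0.5,
    env_coef_sd = 0.4,
    trait_coupling = 0,
    pop_missing_prob = 0.3,
    pop_noise_log_sd = 0.3,
    area_fraction_shape = c(5, 2)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown trait_config fields: ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Generate a synthetic species pool
#'
#' Draws `n_species` species with continuous traits (stored
#' log-transformed, as used in all analyses), categorical traits,
#' elevational limits, range seeds and sizes, per-species abundance
#' coefficients linking expected local abundance to the three
#' environmental covariates, and global population bounds with the
#' fraction of the occupied area falling inside the study region.
#'
#' @param n_species Number of species (>= 2).
#' @param landscape A `ts_landscape`.
#' @param trait_config List from [default_trait_config()].
#' @param seed Integer seed.
#' @return A data frame of class `ts_pool`, one row per species.
#' @export
generate_species_pool <- function(n_species, landscape,
                                  trait_config = default_trait_config(),
                                  seed = 1L) {
  if (n_species < 2) stop("n_species must be >= 2")
  stopifnot(inherits(landscape, "ts_landscape"))
  cfg <- trait_config
  if (!all(names(cfg$migratory_probs) %in% migratory_classes)) {
    stop("unknown migratory class labels in trait_config")
  }
  if (!all(names(cfg$diet_probs) %in% diet_classes)) {
    stop("unknown diet class labels in trait_config")
  }
  n_cells <- landscape$n_rows * landscape$n_cols
  with_seed(derive_seed(seed, "pool"), {
    log_mass <- stats::rnorm(n_species, cfg$mass_log_mean, cfg$mass_log_sd)
    log_genlength <- stats::rnorm(n_species, cfg$genlength_log_mean,
                                  cfg$genlength_log_sd)
    migratory_class <- sample(names(cfg$migratory_probs), n_species,
                              replace = TRUE, prob = cfg$migratory_probs)
    diet_class <- sample(names(cfg$diet_probs), n_species, replace = TRUE,
                         prob = cfg$diet_probs)
    elev_centre <- sample(as.vector(landscape$elevation), n_species,
                          replace = TRUE)
    breadth <- stats::rlnorm(n_species, cfg$elev_breadth_log_mean,
                             cfg$elev_breadth_log_sd)
    elev_min <- pmax(0, elev_centre - breadth / 2)
    elev_max <- elev_centre + breadth / 2
    range_size <- pmin(n_cells, pmax(1L, round(
      n_cells * stats::rlnorm(n_species, cfg$range_frac_log_mean,
                              cfg$range_frac_log_sd))))
    range_seed_cell <- sample.int(n_cells, n_species, replace = TRUE)
    b0 <- stats::rnorm(n_species, cfg$abund_intercept_log_mean,
                       cfg$abund_intercept_log_sd) +
      cfg$trait_coupling * (log_mass - mean(log_mass))
    b1 <- stats::rnorm(n_species, 0, cfg$env_coef_sd)
    b2 <- stats::rnorm(n_species, 0, cfg$env_coef_sd)
    b3 <- stats::rnorm(n_species, 0, cfg$env_coef_sd)
    ## Population bounds consistent with the species' own abundance
    ## scale and range size, with log-normal survey error.
    regional_mid <- exp(b0) * range_size *
      stats::rlnorm(n_species, 0, cfg$pop_noise_log_sd)
    area_fraction <- stats::rbeta(n_species, cfg$area_fraction_shape[1],
                                  cfg$area_fraction_shape[2])
    global_mid <- regional_mid / area_fraction
    half_width <- stats::runif(n_species, 0.1, 0.5)
    global_pop_min <- global_mid * (1 - half_width)
    global_pop_max <- global_mid * (1 + half_width)
    missing_pop <- stats::runif(n_species) < cfg$pop_missing_prob
    global_pop_min[missing_pop] <- NA_real_
    global_pop_max[missing_pop] <- NA_real_
    pool <- data.frame(
      species_id = sprintf("sp%04d", seq_len(n_species)),
      log_mass = log_mass,
      log_genlength = log_genlength,
      migratory_class = migratory_class,
      diet_class = diet_class,
      elev_min = elev_min,
      elev_max = elev_max,
      range_seed_cell = as.integer(range_seed_cell),
      range_size = as.integer(range_size),
      b0 = b0, b1 = b1, b2 = b2, b3 = b3,
      global_pop_min = global_pop_min,
      global_pop_max = global_pop_max,
      area_fraction = area_fraction,
      stringsAsFactors = FALSE
    )
    class(pool) <- c("ts_pool", "data.frame")
    pool
  })
}

#' Grow a contiguous species range
#'
#' Grows a 4-connected set of exactly `range_size` cells from the
#' species' seed cell by uniform-random neighbour accretion.  This is
#' the unrefined extent of occurrence; elevational refinement is
#' applied downstream by [refine_by_elevation()].
#'
#' @param species A one-row `ts_pool` subset (or list) with
#'   `range_seed_cell` and `range_size`.
#' @param landscape A `ts_landscape`.
#' @param seed Integer seed.
#' @return Sorted integer vector of occupied cell indices
#'   (column-major linear indices into the grid).
#' @export
grow_range <- function(species, landscape, seed = 1L) {
  n_rows <- landscape$n_rows; n_cols <- landscape$n_cols
  n_cells <- n_rows * n_cols
  seed_cell <- as.integer(species$range_seed_cell)
  size <- as.integer(species$range_size)
  if (is.na(seed_cell) || seed_cell < 1L || seed_cell > n_cells) {
    stop("range_seed_cell outside the grid")
  }
  if (size < 1L || size > n_cells) {
    stop("range_size must be between 1 and the number of grid cells")
  }
  with_seed(seed, {
    in_set <- logical(n_cells)
    in_set[seed_cell] <- TRUE
    frontier <- setdiff(cell_neighbours(seed_cell, n_rows, n_cols), seed_cell)
    n_in <- 1L
    while (n_in < size && length(frontier)) {
      pick <- frontier[sample.int(length(frontier), 1L)]
      in_set[pick] <- TRUE
      n_in <- n_in + 1L
      frontier <- frontier[frontier != pick]
      nb <- cell_neighbours(pick, n_rows, n_cols)
      frontier <- union(frontier, nb[!in_set[nb]])
    }
    which(in_set)
  })
}

#' Grow ranges for a whole pool
#'
#' @param pool A `ts_pool`.
#' @param landscape A `ts_landscape`.
#' @param seed Master seed; each species gets a derived stream.
#' @return Named list of cell-index vectors, one per species.
#' @export
grow_ranges <- function(pool, landscape, seed = 1L) {
  out <- lapply(seq_len(nrow(pool)), function(i) {
    grow_range(pool[i, ], landscape, derive_seed(seed, pool$species_id[i]))
  })
  names(out) <- pool$species_id
  out
}

#' True abundance surfaces for a pool
#'
#' Expected local abundance for species `s` in cell `c` is
#' `exp(b0_s + b1_s z1(c) + b2_s z2(c) + b3_s z3(c))` inside the
#' species' (refined) range and 0 outside, where `z1..z3` are the
#' standardised environmental covariates.
#'
#' @param pool A `ts_pool`.
#' @param ranges Named list of cell sets (typically refined ranges).
#' @param landscape A `ts_landscape`.
#' @return Species x cell matrix of expected abundances.
#' @export
abundance_truth <- function(pool, ranges, landscape) {
  stopifnot(all(pool$species_id %in% names(ranges)))
  z1 <- standardise(as.vector(landscape$env1))
  z2 <- standardise(as.vector(landscape$env2))
  z3 <- standardise(as.vector(landscape$env3))
  n_cells <- landscape$n_rows * landscape$n_cols
  lambda <- matrix(0, nrow(pool), n_cells,
                   dimnames = list(pool$species_id, NULL))
  for (i in seq_len(nrow(pool))) {
    cells <- ranges[[pool$species_id[i]]]
    if (!length(cells)) next
    lambda[i, cells] <- exp(pool$b0[i] + pool$b1[i] * z1[cells] +
                              pool$b2[i] * z2[cells] + pool$b3[i] * z3[cells])
  }
  lambda
}

#' Place survey sites on a landscape
#'
#' Samples distinct grid cells for survey-site centroids.
#'
#' @param n_sites Number of sites.
#' @param landscape A `ts_landscape`.
#' @param seed Integer seed.
#' @return Data frame with `site_id`, `row`, `col`, `cell`.
#' @export
place_sites <- function(n_sites, landscape, seed = 1L) {
  n_cells <- landscape$n_rows * landscape$n_cols
  if (n_sites > n_cells) stop("more sites than grid cells")
  with_seed(derive_seed(seed, "sites"), {
    cells <- sample.int(n_cells, n_sites)
    rc <- cell_rowcol(cells, landscape$n_rows)
    data.frame(site_id = sprintf("site%04d", seq_len(n_sites)),
               row = rc[, "row"], col = rc[, "col"], cell = cells,
               stringsAsFactors = FALSE)
  })
}

#' Simulate effort-dependent, detectability-biased survey counts
#'
#' For every site, every species with positive true abundance at the
#' site's cell, and every year, draws
#' `count ~ Poisson(lambda * effort * p)`, where `p` is a logistic
#' function of centred log body mass, migratory class and centred log
#' range size.  With `detectability = NULL` detection is perfect
#' (`p = 1`).  Detection acts only on the recorded counts, never on the
#' truth surfaces.
#'
#' @param pool A `ts_pool`.
#' @param truth Species x cell abundance matrix from
#'   [abundance_truth()].
#' @param sites Data frame from [place_sites()].
#' @param years Integer vector of survey years (non-empty).
#' @param effort Either a single positive number (constant
#'   observer-hours) or a list `list(log_mean=, log_sd=)` for
#'   log-normal per-site-year effort.
#' @param detectability `NULL` for perfect detection, or a list with
#'   elements `intercept` (logit scale), `mass`, `range` (slopes on
#'   centred log mass / log range size) and `class_effects` (named
#'   numeric, one entry per migratory class; missing classes get 0).
#' @param seed Integer seed.
#' @return Data frame of survey records: `site_id`, `species_id`,
#'   `year`, `count`, `effort`.  Rows are emitted for all
#'   site x species x year combinations with positive true abundance,
#'   including sampling zeros; downstream effort correction treats a
#'   species with no positive count at a site as unrecorded there.
#' @export
simulate_surveys <- function(pool, truth, sites, years,
                             effort = list(log_mean = log(10), log_sd = 0.3),
                             detectability = NULL, seed = 1L) {
  if (nrow(sites) == 0L) stop("site list is empty")
  if (length(years) == 0L) stop("years is empty")
  stopifnot(all(pool$species_id == rownames(truth)))
  p_det <- detection_probability(pool, detectability)
  with_seed(derive_seed(seed, "surveys"), {
    recs <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
      lam <- truth[, sites$cell[i]]
      present <- which(lam > 0)
      if (!length(present)) next
      eff <- if (is.numeric(effort)) {
        rep(effort, length(years))
      } else {
        stats::rlnorm(length(years), effort$log_mean, effort$log_sd)
      }
      n_sp <- length(present)
      n_yr <- length(years)
      mu <- outer(lam[present] * p_det[present], eff)
      counts <- matrix(stats::rpois(n_sp * n_yr, mu), n_sp, n_yr)
      recs[[i]] <- data.frame(
        site_id = sites$site_id[i],
        species_id = rep(pool$species_id[present], times = n_yr),
        year = rep(years, each = n_sp),
        count = as.integer(counts),
        effort = rep(eff, each = n_sp),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, recs)
    if (is.null(out)) {
      out <- data.frame(site_id = character(), species_id = character(),
                        year = integer(), count = integer(),
                        effort = numeric(), stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}

## Per-species detection probability under the logistic model.
detection_probability <- function(pool, detectability) {
  if (is.null(detectability)) return(rep(1, nrow(pool)))
  d <- detectability
  ce <- d$class_effects
  if (is.null(ce)) ce <- numeric(0)
  class_term <- ifelse(pool$migratory_class %in% names(ce),
                       ce[pool$migratory_class], 0)
  lp <- d$intercept +
    (if (is.null(d$mass)) 0 else d$mass * (pool$log_mass - mean(pool$log_mass))) +
    (if (is.null(d$range)) 0 else
      d$range * (log(pool$range_size) - mean(log(pool$range_size)))) +
    class_term
  stats::plogis(lp)
}
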