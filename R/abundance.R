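## The four abundance-estimation methods that turn a presence stack
## into species x cell abundance fields:
##   a) uniform: every species equally abundant everywhere in range;
##   b) regional population size divided by range area;
##   c) mean survey abundance across training sites, constant in range;
##   d) per-species environmental abundance models (additive smooths),
##      varying both among species and within ranges.

new_abundance_field <- function(stack, values, method_tag, eligible) {
  stopifnot(identical(dim(values), dim(stack$occupancy)))
  values[stack$occupancy == 0L] <- 0
  structure(list(species_ids = stack$species_ids, values = values,
                 method_tag = method_tag,
                 eligible_species = eligible,
                 n_rows = stack$n_rows, n_cols = stack$n_cols),
            class = "ts_abundance")
}

#' @export
print.ts_abundance <- function(x, ...) {
  cat(sprintf("Abundance field (method: %s): %d/%d eligible species\n",
              x$method_tag, length(x$eligible_species),
              length(x$species_ids)))
  invisible(x)
}

#' Method (a): uniform presence-absence abundance
#'
#' Assigns every species the same abundance (1) everywhere within its
#' range — the range-overlay assumption.
#'
#' @param stack A `ts_stack`.
#' @return A `ts_abundance` with `method_tag = "uniform"`.
#' @export
method_a_uniform <- function(stack) {
  new_abundance_field(stack, stack$occupancy + 0, "uniform",
                      stack$species_ids)
}

#' Regional population size from global bounds
#'
#' The regional total is the mid-point of the global minimum and
#' maximum population estimates, rescaled by the fraction of the
#' species' occupied area falling inside the study region.
#'
#' @param global_min,global_max Global population bounds
#'   (individuals); `0 <= global_min <= global_max`.
#' @param area_fraction Fraction in \[0, 1\].
#' @return Regional population estimate (individuals); vectorised.
#' @examples
#' regional_population(2000, 6000, 0.5)  # 2000
#' @export
regional_population <- function(global_min, global_max, area_fraction) {
  if (any(global_min < 0, na.rm = TRUE) || any(global_max < 0, na.rm = TRUE) ||
      any(area_fraction < 0 | area_fraction > 1, na.rm = TRUE)) {
    stop("negative population bounds or area_fraction outside [0, 1]")
  }
  if (any(global_min > global_max, na.rm = TRUE)) {
    stop("global_min must be <= global_max")
  }
  (global_min + global_max) / 2 * area_fraction
}

#' Method (b): regional population divided by range area
#'
#' Each species with population data gets a constant per-cell
#' abundance equal to its regional population total divided by its
#' range size in cells; row sums therefore conserve the regional
#' totals exactly.  Species without population data, or with a
#' positive population but an empty refined range, are excluded from
#' `eligible_species`.
#'
#' @param stack A `ts_stack`.
#' @param populations Data frame with `species_id`, `global_pop_min`,
#'   `global_pop_max`, `area_fraction` (a `ts_pool` works directly;
#'   `NA` bounds mean no estimate).
#' @return A `ts_abundance` with `method_tag = "pop_over_range"`.
#' @export
method_b_pop_over_range <- function(stack, populations) {
  pops <- populations[match(stack$species_ids, populations$species_id), ]
  regional <- rep(NA_real_, length(stack$species_ids))
  have <- !is.na(pops$global_pop_min) & !is.na(pops$global_pop_max)
  regional[have] <- regional_population(pops$global_pop_min[have],
                                        pops$global_pop_max[have],
                                        pops$area_fraction[have])
  range_cells <- rowSums(stack$occupancy)
  values <- matrix(0, nrow(stack$occupancy), ncol(stack$occupancy),
                   dimnames = dimnames(stack$occupancy))
  eligible <- character(0)
  for (i in seq_along(stack$species_ids)) {
    if (is.na(regional[i])) next
    if (range_cells[i] == 0L) {
      if (regional[i] > 0) {
        warning("species ", stack$species_ids[i],
                " has population data but an empty range; excluded")
      }
      next
    }
    values[i, ] <- stack$occupancy[i, ] * regional[i] / range_cells[i]
    eligible <- c(eligible, stack$species_ids[i])
  }
  new_abundance_field(stack, values, "pop_over_range", eligible)
}

#' Effort-corrected, year-averaged site abundance
#'
#' Applies the survey correction rule: each count is divided by the
#' effort of its count (observer-hours), the corrected values are
#' averaged across the years in which the species was recorded
#' (count > 0) at the site, and the mean is rounded up to the nearest
#' integer.  Years with zero counts do not enter the average; if all
#' counts are zero the species is treated as unrecorded (`NA`).
#'
#' @param counts Non-negative integer counts, one per year.
#' @param efforts Positive efforts, matched to `counts`.
#' @return Integer-valued abundance, or `NA_real_` if never recorded.
#' @examples
#' effort_corrected_abundance(c(4, 7), c(2, 2))  # ceiling(2.75) = 3
#' @export
effort_corrected_abundance <- function(counts, efforts) {
  stopifnot(length(counts) == length(efforts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(efforts <= 0)) stop("efforts must be positive")
  rec <- counts > 0
  if (!any(rec)) return(NA_real_)
  ceiling(mean(counts[rec] / efforts[rec]))
}

#' Per-site, per-species observed abundance table
#'
#' Applies [effort_corrected_abundance()] to every (site, species)
#' pair in a record table, dropping pairs never recorded.
#'
#' @param records Data frame with `site_id`, `species_id`, `year`,
#'   `count`, `effort`.
#' @return Data frame `site_id`, `species_id`, `abundance` (positive
#'   integers).
#' @export
site_species_abundance <- function(records) {
  if (!nrow(records)) {
    return(data.frame(site_id = character(), species_id = character(),
                      abundance = numeric(), stringsAsFactors = FALSE))
  }
  pos <- records[records$count > 0, , drop = FALSE]
  if (!nrow(pos)) {
    return(data.frame(site_id = character(), species_id = character(),
                      abundance = numeric(), stringsAsFactors = FALSE))
  }
  key <- interaction(pos$site_id, pos$species_id, drop = TRUE)
  agg <- tapply(pos$count / pos$effort, key, mean)
  first <- !duplicated(key)
  data.frame(site_id = pos$site_id[first],
             species_id = pos$species_id[first],
             abundance = as.numeric(ceiling(agg[as.character(key[first])])),
             stringsAsFactors = FALSE)
}

#' Method (c): mean survey abundance, constant within range
#'
#' Each species recorded at one or more training sites gets a constant
#' abundance — the mean of its per-site effort-corrected abundances
#' over the training sites where it was recorded — applied to every
#' occupied cell.  Species never recorded are excluded.
#'
#' @param stack A `ts_stack`.
#' @param records Survey record table (see
#'   [site_species_abundance()]).
#' @param training_sites Character vector of training `site_id`s
#'   (must be disjoint from any evaluation sites).
#' @return A `ts_abundance` with `method_tag = "survey_mean"`.
#' @export
method_c_survey_mean <- function(stack, records, training_sites) {
  ssa <- site_species_abundance(
    records[records$site_id %in% training_sites, , drop = FALSE])
  mean_ab <- tapply(ssa$abundance, ssa$species_id, mean)
  values <- matrix(0, nrow(stack$occupancy), ncol(stack$occupancy),
                   dimnames = dimnames(stack$occupancy))
  eligible <- intersect(stack$species_ids, names(mean_ab))
  for (sp in eligible) {
    values[sp, ] <- stack$occupancy[sp, ] * mean_ab[[sp]]
  }
  new_abundance_field(stack, values, "survey_mean", eligible)
}

#' Fit an environmental abundance model for one species
#'
#' Fits an additive model of per-site observed abundance against the
#' three environmental covariates, one fixed-degrees-of-freedom
#' regression-spline smooth (5 df) per covariate, with a log link on a
#' continuous positive response (Gamma errors by default).  Species
#' with fewer than `min_records` site records are skipped.
#'
#' @param abund Data frame `site_id`, `abundance` for one species
#'   (positive effort-corrected values).
#' @param site_env Data frame `site_id`, `env1`, `env2`, `env3`.
#' @param min_records Minimum number of site records (default 30).
#' @param smooth_df Effective degrees of freedom per smooth (fixed,
#'   default 5).
#' @param family One of `"gamma"` (log link, default), `"lognormal"`
#'   (Gaussian smooths on the log response, predictions
#'   exponentiated; numerically the most robust log-scale option) or
#'   `"gaussian"` (identity link).
#' @return Object of class `ts_envmodel` (with `dev_expl`, the
#'   explained-deviance fraction), or `NULL` if skipped.
#' @export
fit_env_abundance_model <- function(abund, site_env, min_records = 30,
                                    smooth_df = 5, family = "gamma") {
  d <- merge(abund, site_env, by = "site_id")
  if (nrow(d) < min_records) {
    message("fit_env_abundance_model: ", nrow(d), " records < ",
            min_records, "; skipped")
    return(NULL)
  }
  env_range <- list(env1 = range(d$env1), env2 = range(d$env2),
                    env3 = range(d$env3))
  resp_max <- max(d$abundance)
  if (stats::sd(d$abundance) == 0) {
    return(structure(list(constant = d$abundance[1], dev_expl = 1,
                          env_range = env_range, resp_max = resp_max,
                          n = nrow(d)),
                     class = "ts_envmodel"))
  }
  family <- match.arg(family, c("gamma", "lognormal", "gaussian"))
  log_response <- family == "lognormal"
  fam <- switch(family,
                gamma = stats::Gamma(link = "log"),
                lognormal = stats::gaussian(),
                gaussian = stats::gaussian())
  if (log_response) d$abundance <- log(d$abundance)
  k <- smooth_df + 1
  k1 <- min(k, length(unique(d$env1)))
  k2 <- min(k, length(unique(d$env2)))
  k3 <- min(k, length(unique(d$env3)))
  form <- stats::as.formula(sprintf(
    "abundance ~ s(env1, k = %d, fx = TRUE) + s(env2, k = %d, fx = TRUE) + s(env3, k = %d, fx = TRUE)",
    k1, k2, k3))
  fit <- mgcv::gam(form, data = d, family = fam)
  dev_expl <- (fit$null.deviance - fit$deviance) / fit$null.deviance
  structure(list(fit = fit, dev_expl = dev_expl,
                 log_response = log_response,
                 env_range = env_range, resp_max = resp_max, n = nrow(d)),
            class = "ts_envmodel")
}

#' @export
print.ts_envmodel <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("Constant abundance model: %g (n = %d)\n", x$constant, x$n))
  } else {
    cat(sprintf("Environmental abundance model: n = %d, deviance explained = %.1f%%\n",
                x$n, 100 * x$dev_expl))
  }
  invisible(x)
}

#' Predict from an environmental abundance model
#'
#' Covariates are clamped to the training range of each variable
#' before prediction (spline extrapolation beyond the observed
#' covariate range is not trusted); clamping is reported via a
#' message.  Predictions are floored at 0.
#'
#' @param object A `ts_envmodel`.
#' @param newdata Data frame with `env1`, `env2`, `env3`.
#' @param clamp Clamp covariates to the training range (default TRUE).
#' @param cap Cap predictions at `cap` times the species' maximum
#'   training abundance (default 2); fixed-df log-link smooths can
#'   otherwise produce implausible abundances in sparsely sampled
#'   covariate corners.  `NULL` disables the cap.
#' @param ... Unused.
#' @return Numeric vector of predicted abundances.
#' @export
predict.ts_envmodel <- function(object, newdata, clamp = TRUE, cap = 2, ...) {
  if (!is.null(object$constant)) return(rep(object$constant, nrow(newdata)))
  if (clamp) {
    n_out <- 0L
    for (v in c("env1", "env2", "env3")) {
      r <- object$env_range[[v]]
      out <- newdata[[v]] < r[1] | newdata[[v]] > r[2]
      n_out <- n_out + sum(out)
      newdata[[v]] <- pmin(pmax(newdata[[v]], r[1]), r[2])
    }
    if (n_out > 0) {
      message("predict.ts_envmodel: ", n_out,
              " covariate values outside the training range were clamped")
    }
  }
  p <- as.numeric(mgcv::predict.gam(object$fit, newdata = newdata,
                                    type = "response"))
  if (isTRUE(object$log_response)) p <- exp(p)
  p <- pmax(0, p)
  if (!is.null(cap)) p <- pmin(p, cap * object$resp_max)
  p
}

#' Fit environmental abundance models for all recorded species
#'
#' @param records Survey record table.
#' @param training_sites Character vector of training site ids.
#' @param sites Site table (`site_id`, `cell`).
#' @param landscape A `ts_landscape`.
#' @inheritParams fit_env_abundance_model
#' @return Named list of `ts_envmodel` objects (species below the
#'   record threshold are absent).
#' @export
fit_env_abundance_models <- function(records, training_sites, sites,
                                     landscape, min_records = 30,
                                     smooth_df = 5, family = "gamma") {
  site_env <- site_covariates(sites, landscape)
  ssa <- site_species_abundance(
    records[records$site_id %in% training_sites, , drop = FALSE])
  out <- list()
  ## species whose fit fails numerically under the requested family
  ## are refitted with the robust log-normal family before giving up
  failed <- character(0)
  fit_one <- function(sp, fam) {
    suppressWarnings(suppressMessages(fit_env_abundance_model(
      ssa[ssa$species_id == sp, c("site_id", "abundance")],
      site_env, min_records = min_records, smooth_df = smooth_df,
      family = fam)))
  }
  for (sp in unique(ssa$species_id)) {
    m <- tryCatch(fit_one(sp, family), error = function(e) NULL)
    if (is.null(m) && family != "lognormal" &&
        sum(ssa$species_id == sp) >= min_records) {
      m <- tryCatch(fit_one(sp, "lognormal"),
                    error = function(e) { failed <<- c(failed, sp); NULL })
    }
    if (!is.null(m)) out[[sp]] <- m
  }
  if (length(failed)) {
    message("fit_env_abundance_models: fits failed for ",
            length(failed), " species (skipped)")
  }
  message("fit_env_abundance_models: ", length(out), " of ",
          length(unique(ssa$species_id)), " recorded species had >= ",
          min_records, " records")
  out
}

#' Environmental covariates at site cells
#'
#' @param sites Site table with `site_id` and `cell`.
#' @param landscape A `ts_landscape`.
#' @return Data frame `site_id`, `env1`, `env2`, `env3`.
#' @export
site_covariates <- function(sites, landscape) {
  data.frame(site_id = sites$site_id,
             env1 = as.vector(landscape$env1)[sites$cell],
             env2 = as.vector(landscape$env2)[sites$cell],
             env3 = as.vector(landscape$env3)[sites$cell],
             stringsAsFactors = FALSE)
}

#' Method (d): environmentally modelled abundance
#'
#' For each species with a fitted environmental model, predicts
#' abundance at every occupied cell from the cell's covariates, so
#' abundance varies both among species and within each range.
#'
#' @param stack A `ts_stack`.
#' @param models Named list from [fit_env_abundance_models()].
#' @param landscape A `ts_landscape`.
#' @return A `ts_abundance` with `method_tag = "env_model"`.
#' @export
method_d_env_model <- function(stack, models, landscape) {
  if (!length(models)) stop("no fitted environmental models supplied")
  values <- matrix(0, nrow(stack$occupancy), ncol(stack$occupancy),
                   dimnames = dimnames(stack$occupancy))
  eligible <- intersect(stack$species_ids, names(models))
  e1 <- as.vector(landscape$env1); e2 <- as.vector(landscape$env2)
  e3 <- as.vector(landscape$env3)
  for (sp in eligible) {
    cells <- which(stack$occupancy[sp, ] == 1L)
    if (!length(cells)) next
    nd <- data.frame(env1 = e1[cells], env2 = e2[cells], env3 = e3[cells])
    values[sp, cells] <- suppressMessages(predict(models[[sp]], nd))
  }
  new_abundance_field(stack, values, "env_model", eligible)
}

#' Total-abundance map of a field
#'
#' Per-cell sum of abundance over the field's eligible species.
#'
#' @param field A `ts_abundance`.
#' @return Numeric matrix of dimension `n_rows` x `n_cols`.
#' @export
total_abundance_map <- function(field) {
  rows <- field$species_ids %in% field$eligible_species
  matrix(colSums(field$values[rows, , drop = FALSE]),
         field$n_rows, field$n_cols)
}
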