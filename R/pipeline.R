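## Pipeline orchestration: simulate -> ranges -> abundance -> metrics
## -> evaluate, driven by a single validated configuration with one
## master seed fanned out to per-stage streams.

#' Default pipeline configuration
#'
#' A small self-contained world: 20 x 20 grid, 40 species, 80 survey
#' sites (20 held out for evaluation), five survey years, log-normal
#' effort, perfect detection, all four abundance methods.  Any nested
#' element can be overridden via `...` using top-level names (e.g.
#' `pool = list(n_species = 60)` replaces only the fields given).
#'
#' @param ... Named overrides merged into the default sections.
#' @return Nested configuration list of class `ts_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    landscape = list(n_rows = 20L, n_cols = 20L, cell_km = 20),
    pool = list(n_species = 40L, trait_config = list()),
    survey = list(n_sites = 80L, n_eval = 20L, first_year = 2000L,
                  n_years = 5L, effort = list(log_mean = log(10),
                                              log_sd = 0.3),
                  detectability = NULL),
    abundance = list(methods = c("a", "b", "c", "d"), min_records = 30L,
                     smooth_df = 5L, family = "gamma"),
    metrics = list(hull_var_target = 0.95, hull_max_axes = 3L),
    evaluation = list(sided = "two", run_sar = TRUE,
                      map_cells = "all", stratify_quadrants = TRUE)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config sections: ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("ts_config", "list"))
}

#' Validate a pipeline configuration
#'
#' Checks every section and reports all violations (with field
#' paths) rather than stopping at the first.
#'
#' @param config A configuration list (see [default_config()]).
#' @return Character vector of error messages; `character(0)` if the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    add("seed: must be an explicit integer")
  }
  ls <- config$landscape
  if (is.null(ls$n_rows) || ls$n_rows < 4) add("landscape.n_rows: must be >= 4")
  if (is.null(ls$n_cols) || ls$n_cols < 4) add("landscape.n_cols: must be >= 4")
  if (is.null(config$pool$n_species) || config$pool$n_species < 2) {
    add("pool.n_species: must be >= 2")
  }
  sv <- config$survey
  if (is.null(sv$n_sites) || sv$n_sites < 2) add("survey.n_sites: must be >= 2")
  if (is.null(sv$n_eval) || sv$n_eval < 1) add("survey.n_eval: must be >= 1")
  if (!is.null(sv$n_sites) && !is.null(sv$n_eval) && sv$n_eval >= sv$n_sites) {
    add("survey.n_eval: must be smaller than survey.n_sites")
  }
  if (is.null(sv$n_years) || sv$n_years < 1) add("survey.n_years: must be >= 1")
  if (is.numeric(sv$effort) && any(sv$effort <= 0)) {
    add("survey.effort: must be positive")
  }
  ab <- config$abundance
  if (!length(ab$methods)) {
    add("abundance.methods: must be non-empty")
  } else if (!all(ab$methods %in% c("a", "b", "c", "d"))) {
    add("abundance.methods: must be a subset of a, b, c, d")
  }
  if (!is.null(ab$min_records) && ab$min_records < 1) {
    add("abundance.min_records: must be >= 1")
  }
  mt <- config$metrics
  if (!is.null(mt$hull_max_axes) &&
      (mt$hull_max_axes < 1 || mt$hull_max_axes > 3)) {
    add("metrics.hull_max_axes: must be in 1..3")
  }
  if (!is.null(config$evaluation$sided) &&
      !config$evaluation$sided %in% c("two", "one")) {
    add("evaluation.sided: must be 'two' or 'one'")
  }
  errs
}

#' Read / write a pipeline configuration
#'
#' YAML serialisation; a configuration round-trips losslessly through
#' [write_config()] and [read_config()].
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `read_config` returns the configuration; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$abundance$methods)) {
    cfg$abundance$methods <- as.character(cfg$abundance$methods)
  }
  structure(cfg, class = c("ts_config", "list"))
}

method_tags <- c(a = "uniform", b = "pop_over_range", c = "survey_mean",
                 d = "env_model")

#' Run the full mapping-and-evaluation pipeline
#'
#' Generates a synthetic world from the configuration, refines and
#' stacks ranges, builds abundance fields for the configured methods,
#' computes community metric maps, simulates surveys, computes
#' observed site metrics at the evaluation sites, and evaluates every
#' metric x method pair (OLS fit, slope-departure test, optional
#' spatial-error model), plus Jaccard composition similarity,
#' per-site trait-abundance screens and the detectability model.
#' Deterministic given the configuration (all randomness derives from
#' `config$seed`).
#'
#' @param config Configuration from [default_config()] (validated
#'   first; invalid configurations abort with the full error list).
#' @param outdir Optional directory: tables (traits, sites, surveys,
#'   report, Jaccard) are written as CSV together with the
#'   configuration and a manifest (config hash, versions).
#' @param quiet Suppress stage messages.
#' @return List of class `ts_pipeline` with elements `landscape`,
#'   `pool`, `stack`, `sites`, `split`, `records`, `fields`,
#'   `metric_maps`, `observed`, `report`, `jaccard`, `screen`,
#'   `detectability`, `config`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         quiet = FALSE) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed

  ## --- synthetic world ------------------------------------------------
  land <- generate_landscape(config$landscape$n_rows, config$landscape$n_cols,
                             seed = seed, cell_km = config$landscape$cell_km)
  tc <- do.call(default_trait_config, config$pool$trait_config)
  pool <- generate_species_pool(config$pool$n_species, land, tc, seed = seed)
  say("pipeline: pool of ", nrow(pool), " species (",
      sum(!is.na(pool$global_pop_min)), " with population data)")
  extents <- grow_ranges(pool, land, seed = seed)
  refined <- lapply(seq_len(nrow(pool)), function(i) {
    suppressMessages(refine_by_elevation(extents[[i]], land$elevation,
                                         pool$elev_min[i], pool$elev_max[i]))
  })
  names(refined) <- pool$species_id
  stack <- suppressMessages(build_stack(refined, land$n_rows, land$n_cols,
                                        land$cell_km))
  say("pipeline: stack built; ", sum(rowSums(stack$occupancy) > 0),
      " species with non-empty refined ranges")

  ## --- surveys --------------------------------------------------------
  sites <- place_sites(config$survey$n_sites, land, seed = seed)
  strat <- if (isTRUE(config$evaluation$stratify_quadrants)) {
    paste(sites$row > land$n_rows / 2, sites$col > land$n_cols / 2)
  } else NULL
  split <- split_sites(sites, config$survey$n_eval, stratify = strat,
                       seed = seed)
  truth <- abundance_truth(pool, refined, land)
  years <- seq(config$survey$first_year,
               length.out = config$survey$n_years)
  records <- simulate_surveys(pool, truth, sites, years,
                              effort = config$survey$effort,
                              detectability = config$survey$detectability,
                              seed = seed)
  say("pipeline: ", nrow(records), " survey records at ",
      nrow(sites), " sites (", length(split$evaluation), " evaluation)")

  ## --- abundance fields -----------------------------------------------
  methods <- config$abundance$methods
  fields <- list()
  if ("a" %in% methods) fields$a <- method_a_uniform(stack)
  if ("b" %in% methods) {
    fields$b <- suppressWarnings(method_b_pop_over_range(stack, pool))
  }
  train_rec <- records[records$site_id %in% split$training, , drop = FALSE]
  if ("c" %in% methods) {
    fields$c <- method_c_survey_mean(stack, train_rec, split$training)
  }
  models <- NULL
  if ("d" %in% methods) {
    models <- suppressMessages(fit_env_abundance_models(
      train_rec, split$training, sites, land,
      min_records = config$abundance$min_records,
      smooth_df = config$abundance$smooth_df,
      family = config$abundance$family))
    say("pipeline: environmental models fitted for ", length(models),
        " species")
    if (length(models)) {
      fields$d <- method_d_env_model(stack, models, land)
    } else {
      say("pipeline: no species reached the record threshold; method d skipped")
    }
  }
  for (m in names(fields)) {
    say("pipeline: method ", m, " (", fields[[m]]$method_tag, "): ",
        length(fields[[m]]$eligible_species), " eligible species")
  }

  ## --- trait space and metric maps ------------------------------------
  traits <- pool[, c("species_id", "log_mass", "log_genlength",
                     "migratory_class", "diet_class")]
  dist_list <- trait_distances(traits)
  coords <- select_axes(trait_pcoa(dist_list$all),
                        var_target = config$metrics$hull_var_target,
                        max_axes = config$metrics$hull_max_axes)
  eval_cells <- sites$cell[match(split$evaluation, sites$site_id)]
  map_cells <- if (identical(config$evaluation$map_cells, "eval")) {
    eval_cells
  } else NULL
  metric_maps <- lapply(fields, community_metric_maps, traits = traits,
                        dist_list = dist_list, coords = coords,
                        cells = map_cells)

  ## --- observed metrics at evaluation sites ---------------------------
  eval_rec <- records[records$site_id %in% split$evaluation, , drop = FALSE]
  observed <- suppressMessages(
    observed_site_metrics(eval_rec, traits, dist_list, coords))

  ## --- evaluation ------------------------------------------------------
  eval_sites <- data.frame(site_id = split$evaluation,
                           cell = eval_cells,
                           row = sites$row[match(split$evaluation,
                                                 sites$site_id)],
                           col = sites$col[match(split$evaluation,
                                                 sites$site_id)],
                           stringsAsFactors = FALSE)
  report <- evaluate_maps(metric_maps, fields, stack, observed, eval_sites,
                          sided = config$evaluation$sided,
                          run_sar = isTRUE(config$evaluation$run_sar))
  jac <- jaccard_by_site(stack, eval_rec, eval_sites)
  screen <- trait_abundance_screen(records, traits)
  det_data <- detectability_data(records, pool, stack)
  detect <- if (nrow(det_data) >= 20) detectability_glm(det_data) else NULL
  res <- structure(
    list(landscape = land, pool = pool, stack = stack, sites = sites,
         split = split, records = records, truth = truth, fields = fields,
         env_models = models, traits = traits, dist_list = dist_list,
         coords = coords, metric_maps = metric_maps, observed = observed,
         report = report, jaccard = jac, screen = screen,
         detectability = detect, config = config),
    class = "ts_pipeline")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' @export
print.ts_pipeline <- function(x, ...) {
  cat(sprintf("traitscape pipeline run: %d species, %d x %d grid, %d sites\n",
              nrow(x$pool), x$landscape$n_rows, x$landscape$n_cols,
              nrow(x$sites)))
  cat(sprintf("  methods: %s; evaluation sites: %d; report rows: %d\n",
              paste(names(x$fields), collapse = ", "),
              length(x$split$evaluation), nrow(x$report)))
  cat(sprintf("  mean Jaccard similarity at evaluation sites: %.2f\n",
              mean(x$jaccard$jaccard, na.rm = TRUE)))
  invisible(x)
}

## Join estimated metric values (at evaluation-site cells) with
## observed site metrics and regress, metric pair by metric pair.
evaluate_maps <- function(metric_maps, fields, stack, observed, eval_sites,
                          sided = "two", run_sar = TRUE) {
  rows <- list()
  coords <- as.matrix(eval_sites[, c("col", "row")])
  obs_wide <- function(metric, scope) {
    sel <- observed$metric == metric & observed$trait_scope == scope
    stats::setNames(observed$value[sel], observed$site_id[sel])
  }
  add_comparison <- function(metric, scope, method_key, est_by_site) {
    obs <- obs_wide(metric, scope)
    sites_both <- intersect(names(obs), names(est_by_site))
    x <- obs[sites_both]; y <- est_by_site[sites_both]
    r <- regress_estimate_on_observed(x, y, sided = sided)
    sar_sig <- "not_run"
    if (run_sar && sum(is.finite(x) & is.finite(y)) >= 10 &&
        is.finite(r$slope)) {
      cc <- coords[match(sites_both, eval_sites$site_id), , drop = FALSE]
      sar <- tryCatch(suppressMessages(sar_error_model(x, y, cc)),
                      error = function(e) NULL)
      if (!is.null(sar)) sar_sig <- if (sar$significant) "yes" else "no"
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      trait_scope = scope, metric = metric,
      method = method_tags[[method_key]],
      r2 = r$r2, p_corr = r$p_corr, slope = r$slope,
      t_unity = r$t_unity, p_unity = r$p_unity,
      sar_significant = sar_sig, n_sites = r$n,
      stringsAsFactors = FALSE)
  }
  for (mk in names(metric_maps)) {
    md <- metric_maps[[mk]]
    md <- md[md$cell %in% eval_sites$cell, , drop = FALSE]
    md$site_id <- eval_sites$site_id[match(md$cell, eval_sites$cell)]
    for (grp in split(md, paste(md$metric, md$trait_scope, sep = "|"))) {
      metric <- grp$metric[1]; scope <- grp$trait_scope[1]
      add_comparison(metric, scope, mk,
                     stats::setNames(grp$value, grp$site_id))
    }
  }
  ## species richness (presence-based) and total abundance (methods
  ## with abundance data) use the same regression machinery
  if ("a" %in% names(fields)) {
    rich <- species_richness_map(stack)
    est <- stats::setNames(rich[eval_sites$cell], eval_sites$site_id)
    add_comparison("richness", "all", "a", est)
  }
  for (mk in intersect(c("b", "c", "d"), names(fields))) {
    tot <- total_abundance_map(fields[[mk]])
    est <- stats::setNames(tot[eval_sites$cell], eval_sites$site_id)
    add_comparison("total_abundance", "all", mk, est)
  }
  evaluation_report(do.call(rbind, rows))
}

## Jaccard similarity between stack-predicted and observed species
## composition at each evaluation site.
jaccard_by_site <- function(stack, eval_records, eval_sites) {
  ssa <- site_species_abundance(eval_records)
  out <- data.frame(site_id = eval_sites$site_id, jaccard = NA_real_,
                    n_predicted = NA_integer_, n_observed = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(eval_sites))) {
    pred <- stack$species_ids[stack$occupancy[, eval_sites$cell[i]] == 1L]
    obs <- ssa$species_id[ssa$site_id == eval_sites$site_id[i]]
    out$jaccard[i] <- jaccard(pred, obs)
    out$n_predicted[i] <- length(pred)
    out$n_observed[i] <- length(obs)
  }
  out
}

## CSV + manifest outputs for a pipeline run.
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$pool, file.path(outdir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(res$sites, file.path(outdir, "sites.csv"),
                   row.names = FALSE)
  utils::write.csv(res$records, file.path(outdir, "surveys.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$report),
                   file.path(outdir, "report.csv"), row.names = FALSE)
  utils::write.csv(res$jaccard, file.path(outdir, "jaccard.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_config(res$config, cfg_path)
  manifest <- list(
    package = "traitscape",
    package_version = as.character(utils::packageVersion("traitscape")),
    r_version = as.character(getRversion()),
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_species = nrow(res$pool),
    n_sites = nrow(res$sites),
    methods = names(res$fields)
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
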