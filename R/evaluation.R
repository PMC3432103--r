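## Comparing distribution-based metric estimates against
## survey-observed community metrics: training/evaluation splits,
## regression and slope-departure tests, Jaccard composition
## similarity, spatial-error models, per-site trait-abundance screens
## and the detectability model.

#' Split sites into training and evaluation subsets
#'
#' Disjoint, exhaustive split, optionally stratified (each stratum
#' contributes a share of evaluation sites proportional to its size,
#' allocated by largest remainder, so every stratum's evaluation count
#' is within 1 of exact proportionality).
#'
#' @param sites Site table with `site_id`.
#' @param n_eval Number of evaluation sites (`< nrow(sites)`).
#' @param stratify Optional vector of stratum labels, one per site.
#' @param seed Integer seed.
#' @return List with character vectors `training` and `evaluation`.
#' @export
split_sites <- function(sites, n_eval, stratify = NULL, seed = 1L) {
  n <- nrow(sites)
  if (n_eval >= n) stop("n_eval must be smaller than the number of sites")
  if (n_eval < 1) stop("n_eval must be >= 1")
  with_seed(derive_seed(seed, "split"), {
    if (is.null(stratify)) {
      ev <- sample(sites$site_id, n_eval)
    } else {
      stopifnot(length(stratify) == n)
      strata <- split(sites$site_id, stratify)
      ideal <- n_eval * vapply(strata, length, 1L) / n
      take <- floor(ideal)
      rem <- n_eval - sum(take)
      if (rem > 0) {
        extra <- order(ideal - take, decreasing = TRUE)[seq_len(rem)]
        take[extra] <- take[extra] + 1L
      }
      ev <- unlist(mapply(function(ids, k) {
        if (k == 0) character(0) else sample(ids, min(k, length(ids)))
      }, strata, take, SIMPLIFY = FALSE), use.names = FALSE)
    }
    list(training = setdiff(sites$site_id, ev), evaluation = sort(ev))
  })
}

#' Observed community metrics at survey sites
#'
#' Builds each site's observed community (effort-corrected,
#' year-averaged, rounded-up abundances) and runs it through exactly
#' the same metric code path as the map cells
#' ([community_metrics()]).
#'
#' @param records Survey record table.
#' @param traits Full trait table.
#' @param dist_list From [trait_distances()].
#' @param coords From [select_axes()].
#' @param include_hull Compute the multivariate hull FRICH (default
#'   TRUE; observed FRICH ignores the abundances by construction).
#' @return Long data frame: `site_id`, `metric`, `trait_scope`,
#'   `value`, `flag`; plus observed `richness` and
#'   `total_abundance` rows.  Sites with no recorded species are
#'   skipped with a message.
#' @export
observed_site_metrics <- function(records, traits, dist_list, coords = NULL,
                                  include_hull = TRUE) {
  ssa <- site_species_abundance(records)
  out <- list()
  for (sid in unique(ssa$site_id)) {
    s <- ssa[ssa$site_id == sid, ]
    m <- community_metrics(s$species_id, s$abundance, traits, dist_list,
                           coords, include_hull = include_hull,
                           include_frich = TRUE)
    m <- rbind(m, data.frame(
      metric = c("richness", "total_abundance"),
      trait_scope = "all",
      value = c(nrow(s), sum(s$abundance)),
      flag = "", stringsAsFactors = FALSE))
    m$site_id <- sid
    out[[sid]] <- m
  }
  skipped <- setdiff(unique(records$site_id), unique(ssa$site_id))
  if (length(skipped)) {
    message("observed_site_metrics: ", length(skipped),
            " sites with no recorded species skipped")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("site_id", "metric", "trait_scope", "value", "flag")]
}

#' Regression of distribution-based estimates on observations
#'
#' Ordinary least squares of estimate (`y`) on observation (`x`).
#' Precision is the regression R-squared (identical to squared
#' Pearson correlation in simple regression) with the correlation
#' test's p-value; accuracy is the departure of the fitted slope from
#' the 1:1 line, tested with `t = (slope - 1) / SE(slope)`
#' (two-sided by default; `sided = "one"` tests slope < 1).
#'
#' @param observed Observed metric values (x).
#' @param estimated Distribution-based estimates (y).
#' @param sided `"two"` (default) or `"one"` for the slope-departure
#'   test.
#' @return One-row data frame: `r2`, `p_corr`, `slope`, `se_slope`,
#'   `t_unity`, `p_unity`, `n`.  Zero variance in `observed` (or
#'   fewer than 3 pairs) refuses the fit and returns `NA`s.
#' @export
regress_estimate_on_observed <- function(observed, estimated,
                                         sided = c("two", "one")) {
  sided <- match.arg(sided)
  ok <- is.finite(observed) & is.finite(estimated)
  x <- observed[ok]; y <- estimated[ok]
  empty <- data.frame(r2 = NA_real_, p_corr = NA_real_, slope = NA_real_,
                      se_slope = NA_real_, t_unity = NA_real_,
                      p_unity = NA_real_, n = length(x))
  if (length(x) < 3 || stats::sd(x) == 0) return(empty)
  n <- length(x)
  if (stats::sd(y) == 0) {
    empty$r2 <- 0; empty$p_corr <- 1; empty$slope <- 0
    return(empty)
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  sxx <- sum((x - mean(x))^2)
  df <- n - 2L
  ## a numerically perfect fit has no sampling variance: report the
  ## slope test against 1 directly rather than dividing by a ~0 SE
  if (rss <= 1e-12 * tss) {
    exact_unity <- abs(slope - 1) < 1e-8
    return(data.frame(r2 = 1, p_corr = 0, slope = slope, se_slope = 0,
                      t_unity = if (exact_unity) 0 else sign(slope - 1) * Inf,
                      p_unity = if (exact_unity) 1 else 0, n = n))
  }
  se <- sqrt(rss / df / sxx)
  t_unity <- (slope - 1) / se
  p_unity <- if (sided == "two") {
    2 * stats::pt(abs(t_unity), df, lower.tail = FALSE)
  } else {
    stats::pt(t_unity, df)               # H1: slope < 1
  }
  p_corr <- stats::cor.test(x, y)$p.value
  data.frame(r2 = 1 - rss / tss, p_corr = p_corr, slope = slope,
             se_slope = se, t_unity = t_unity, p_unity = p_unity,
             n = n)
}

#' Jaccard similarity of two species sets
#'
#' `|intersection| / |union|`: 1 for identical sets, 0 for disjoint
#' sets.  Undefined (NA) when both sets are empty.
#'
#' @param set_a,set_b Character vectors of species ids.
#' @return Value in \[0, 1\], or `NA` if both sets are empty.
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(NA_real_)
  length(intersect(set_a, set_b)) / u
}

#' Delaunay neighbour pairs of a point set
#'
#' Brute-force Delaunay triangulation by the empty-circumcircle
#' property: a triangle belongs to the triangulation iff no other
#' point lies strictly inside its circumcircle.  Duplicate
#' coordinates are jittered (with a message).  Intended for site
#' networks of up to a few hundred points.
#'
#' @param coords Two-column matrix of point coordinates.
#' @return Two-column integer matrix of neighbour index pairs
#'   (`i < j`).
#' @export
delaunay_neighbours <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3) return(cbind(seq_len(max(n - 1, 0)), seq_len(max(n - 1, 0)) + 1L))
  if (anyDuplicated(round(coords, 10))) {
    message("delaunay_neighbours: duplicate coordinates jittered")
    jit <- diff(range(coords)) * 1e-6
    dup <- duplicated(round(coords, 10))
    coords[dup, ] <- coords[dup, ] + stats::runif(2 * sum(dup), -jit, jit)
  }
  x <- coords[, 1]; y <- coords[, 2]
  tri <- utils::combn(n, 3)
  edges <- matrix(integer(0), 0, 2)
  for (t in seq_len(ncol(tri))) {
    i <- tri[1, t]; j <- tri[2, t]; k <- tri[3, t]
    ## circumcentre by perpendicular-bisector solve
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-12 * max(abs(c(ax, ay, bx, by, cx, cy)), 1)) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / dd
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (x - ux)^2 + (y - uy)^2
    d2[c(i, j, k)] <- Inf
    if (all(d2 > r2 * (1 - 1e-10))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  if (!nrow(edges)) {
    ## collinear configuration: chain nearest neighbours
    o <- order(x, y)
    edges <- cbind(o[-n], o[-1])
  }
  edges <- t(apply(edges, 1, sort))
  unique(edges)
}

#' Spatial-error (SAR) regression
#'
#' Simultaneous autoregressive error model
#' `y = b0 + b1 x + u`, `u = lambda W u + e`, with row-standardised
#' neighbour weights `W` from a Delaunay triangulation of the site
#' coordinates.  `lambda` is estimated by profile maximum likelihood
#' (log-determinant via the eigenvalues of `W`); the slope and its
#' standard error come from the generalised least squares fit at the
#' estimated `lambda`, and `lambda`'s significance from a likelihood
#' ratio test against the non-spatial model.
#'
#' @param x Observed values (predictor).
#' @param y Estimated values (response).
#' @param coords Two-column matrix of site coordinates.
#' @param alpha Significance level used for the `significant` flag on
#'   the slope (default 0.05).
#' @return List with `slope`, `se_slope`, `p_slope`, `lambda`,
#'   `p_lambda`, `loglik`, `significant` (logical: slope significant
#'   at `alpha` under the SAR model).
#' @export
sar_error_model <- function(x, y, coords, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; coords <- as.matrix(coords)[ok, , drop = FALSE]
  n <- length(y)
  if (n < 10) stop("need at least 10 sites with coordinates")
  edges <- delaunay_neighbours(coords)
  A <- matrix(0, n, n)
  A[edges] <- 1
  A <- A + t(A)
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  W <- A / rs
  ev <- Re(eigen(W, only.values = TRUE)$values)
  lo <- 1 / min(ev) + 1e-6
  hi <- 1 / max(ev) - 1e-6
  X <- cbind(1, x)
  prof <- function(lambda) {
    M <- diag(n) - lambda * W
    yt <- M %*% y
    Xt <- M %*% X
    b <- stats::lm.fit(Xt, yt)
    s2 <- sum(b$residuals^2) / n
    ll <- sum(log(abs(1 - lambda * ev))) - n / 2 * (log(2 * pi * s2) + 1)
    if (!is.finite(ll)) -1e300 else ll
  }
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE)
  lambda <- opt$maximum
  M <- diag(n) - lambda * W
  yt <- M %*% y; Xt <- M %*% X
  b <- stats::lm.fit(Xt, yt)
  s2 <- sum(b$residuals^2) / n
  vcov_b <- s2 * n / (n - 2) * solve(crossprod(Xt))
  slope <- unname(b$coefficients[2])
  se <- sqrt(vcov_b[2, 2])
  p_slope <- 2 * stats::pt(abs(slope / se), n - 2, lower.tail = FALSE)
  lr <- 2 * (opt$objective - prof(0))
  p_lambda <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  list(slope = slope, se_slope = se, p_slope = p_slope,
       lambda = lambda, p_lambda = p_lambda, loglik = opt$objective,
       significant = is.finite(p_slope) && p_slope < alpha)
}

#' Per-site trait-abundance screens
#'
#' For every site with enough data: Pearson correlations of
#' log-transformed observed abundance with log body mass and log
#' generation length (>= 3 species with variation required), and
#' one-way analyses of variance of log abundance with respect to
#' migratory class and diet class (>= 2 classes present required).
#' If local abundance is unrelated to traits, the mean correlation
#' across sites is ~0 and ANOVAs are rarely significant — the regime
#' in which presence-only trait maps are unbiased.
#'
#' @param records Survey record table.
#' @param traits Full trait table.
#' @param alpha Significance level for counting significant ANOVAs.
#' @return List with `per_site` (data frame of per-site statistics)
#'   and `summary` (mean r with standard error per continuous trait;
#'   site counts, significant counts and mean F per categorical
#'   trait).
#' @export
trait_abundance_screen <- function(records, traits, alpha = 0.05) {
  ssa <- site_species_abundance(records)
  d <- merge(ssa, traits, by = "species_id")
  d$log_ab <- log(d$abundance)
  per_site <- lapply(split(d, d$site_id), function(s) {
    out <- data.frame(site_id = s$site_id[1],
                      r_mass = NA_real_, r_genlength = NA_real_,
                      F_migration = NA_real_, p_migration = NA_real_,
                      F_diet = NA_real_, p_diet = NA_real_,
                      n_species = nrow(s), stringsAsFactors = FALSE)
    if (nrow(s) >= 3 && stats::sd(s$log_ab) > 0) {
      if (stats::sd(s$log_mass) > 0) {
        out$r_mass <- stats::cor(s$log_ab, s$log_mass)
      }
      if (stats::sd(s$log_genlength) > 0) {
        out$r_genlength <- stats::cor(s$log_ab, s$log_genlength)
      }
    }
    for (tr in c("migration", "diet")) {
      col <- trait_columns[[tr]]
      if (length(unique(s[[col]])) >= 2 && stats::sd(s$log_ab) > 0) {
        a <- suppressWarnings(stats::anova(stats::aov(
          log_ab ~ factor(cls),
          data = data.frame(log_ab = s$log_ab, cls = s[[col]]))))
        out[[paste0("F_", tr)]] <- a$`F value`[1]
        out[[paste0("p_", tr)]] <- a$`Pr(>F)`[1]
      }
    }
    out
  })
  per_site <- do.call(rbind, per_site)
  rownames(per_site) <- NULL
  mean_se <- function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
  }
  summary <- list(
    r_mass = mean_se(per_site$r_mass),
    r_genlength = mean_se(per_site$r_genlength),
    migration = c(n_tested = sum(is.finite(per_site$p_migration)),
                  n_significant = sum(per_site$p_migration < alpha,
                                      na.rm = TRUE),
                  mean_F = mean(per_site$F_migration, na.rm = TRUE)),
    diet = c(n_tested = sum(is.finite(per_site$p_diet)),
             n_significant = sum(per_site$p_diet < alpha, na.rm = TRUE),
             mean_F = mean(per_site$F_diet, na.rm = TRUE))
  )
  list(per_site = per_site, summary = summary)
}

#' Per-species recording summary for the detectability model
#'
#' @param records Survey record table.
#' @param pool Trait/pool table with `species_id`, `log_mass`,
#'   `migratory_class`.
#' @param stack A `ts_stack` (supplies refined range sizes); species
#'   with empty refined ranges are dropped.
#' @return Data frame `species_id`, `n_sites_recorded`, `range_size`,
#'   `log_mass`, `migratory_class`.
#' @export
detectability_data <- function(records, pool, stack) {
  ssa <- site_species_abundance(records)
  n_rec <- table(ssa$species_id)
  range_size <- rowSums(stack$occupancy)
  keep <- stack$species_ids[range_size > 0]
  d <- data.frame(species_id = keep,
                  n_sites_recorded = as.integer(n_rec[keep]),
                  range_size = as.integer(range_size[keep]),
                  stringsAsFactors = FALSE)
  d$n_sites_recorded[is.na(d$n_sites_recorded)] <- 0L
  d$log_mass <- pool$log_mass[match(d$species_id, pool$species_id)]
  d$migratory_class <- pool$migratory_class[match(d$species_id,
                                                  pool$species_id)]
  d
}

#' Detectability model: sites recorded vs range size and traits
#'
#' Quasi-Poisson generalised linear model relating the number of sites
#' at which each species was recorded to its log-transformed refined
#' range size, log body mass and migratory class.  Reports the
#' coefficient table and a sequential partition of explained deviance
#' (percent of the null deviance captured by each term, and overall).
#'
#' @param data Data frame from [detectability_data()] (or equivalent
#'   columns).
#' @return List with `fit` (the `glm`), `coefficients` (summary
#'   table) and `deviance_explained` (named percentages: `overall`,
#'   `range_size`, `mass`, `migratory_class`).
#' @export
detectability_glm <- function(data) {
  if (nrow(data) < 20) stop("need at least 20 species")
  terms <- c("log(range_size)", "log_mass")
  if (length(unique(data$migratory_class)) >= 2) {
    terms <- c(terms, "migratory_class")
  } else {
    message("detectability_glm: single migratory class; term dropped")
  }
  form <- stats::as.formula(paste("n_sites_recorded ~",
                                  paste(terms, collapse = " + ")))
  fit <- stats::glm(form, data = data, family = stats::quasipoisson())
  an <- stats::anova(fit)
  null_dev <- fit$null.deviance
  dev_terms <- an$Deviance[-1]
  names(dev_terms) <- rownames(an)[-1]
  ## a (numerically) constant response has nothing to explain
  degenerate <- null_dev <= 1e-8 * max(1, sum(data$n_sites_recorded))
  pct <- if (degenerate) dev_terms * 0 else 100 * dev_terms / null_dev
  overall_pct <- if (degenerate) 0 else {
    100 * (null_dev - fit$deviance) / null_dev
  }
  out <- c(overall = overall_pct,
           range_size = unname(pct["log(range_size)"]),
           mass = unname(pct["log_mass"]),
           migratory_class = if ("migratory_class" %in% names(pct)) {
             unname(pct["migratory_class"])
           } else NA_real_)
  list(fit = fit, coefficients = summary(fit)$coefficients,
       deviance_explained = out)
}

#' Assemble the evaluation report
#'
#' Binds per-(trait scope, metric, method) regression rows into one
#' long table, flagging within each (trait scope, metric) group the
#' method with the highest R-squared and the method whose slope is
#' closest to 1.
#'
#' @param rows Data frame with columns `trait_scope`, `metric`,
#'   `method`, `r2`, `p_corr`, `slope`, `t_unity`, `p_unity`,
#'   `sar_significant`, `n_sites` (extra columns are kept).
#' @return The same table with logical columns `best_r2` and
#'   `best_slope` added; class `ts_report`.
#' @export
evaluation_report <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  rows$best_r2 <- FALSE
  rows$best_slope <- FALSE
  grp <- interaction(rows$trait_scope, rows$metric, drop = TRUE)
  for (g in levels(grp)) {
    i <- which(grp == g)
    r2 <- rows$r2[i]
    if (any(is.finite(r2))) {
      rows$best_r2[i[which.max(replace(r2, !is.finite(r2), -Inf))]] <- TRUE
    }
    dev <- abs(rows$slope[i] - 1)
    if (any(is.finite(dev))) {
      rows$best_slope[i[which.min(replace(dev, !is.finite(dev), Inf))]] <- TRUE
    }
  }
  class(rows) <- c("ts_report", "data.frame")
  rows
}

#' @export
print.ts_report <- function(x, digits = 3, ...) {
  cat(sprintf("Evaluation report: %d metric x method comparisons\n", nrow(x)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
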