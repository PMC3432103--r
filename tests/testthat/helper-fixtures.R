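# Shared fixtures and independent oracles, all built in code.

## ---- fixtures -------------------------------------------------------

tiny_traits <- function() {
  data.frame(
    species_id = c("sp_a", "sp_b", "sp_c", "sp_d", "sp_e"),
    log_mass = c(2.0, 3.5, 5.0, 2.8, 4.1),
    log_genlength = c(0.7, 1.1, 2.0, 1.5, 0.9),
    migratory_class = c("non-migrant", "latitudinal", "non-migrant",
                        "nomad", "altitudinal"),
    diet_class = c("fruit", "invertebrate", "vertebrate", "fruit", "mixed"),
    stringsAsFactors = FALSE
  )
}

random_traits <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    species_id = sprintf("rsp%03d", seq_len(n)),
    log_mass = rnorm(n, 4, 1),
    log_genlength = rnorm(n, 1.3, 0.4),
    migratory_class = sample(migratory_classes, n, replace = TRUE),
    diet_class = sample(diet_classes, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

## A small complete world (landscape, pool, refined stack, truth,
## sites, survey records) for integration-level tests.
make_world <- function(seed = 1, n = 10, n_species = 15, n_sites = 20,
                       n_years = 3, effort = 10,
                       trait_config = default_trait_config(),
                       detectability = NULL) {
  land <- generate_landscape(n, n, seed = seed)
  pool <- generate_species_pool(n_species, land, trait_config, seed = seed)
  extents <- grow_ranges(pool, land, seed = seed)
  refined <- lapply(seq_len(nrow(pool)), function(i) {
    suppressMessages(refine_by_elevation(extents[[i]], land$elevation,
                                         pool$elev_min[i], pool$elev_max[i]))
  })
  names(refined) <- pool$species_id
  stack <- suppressMessages(build_stack(refined, n, n))
  truth <- abundance_truth(pool, refined, land)
  sites <- place_sites(n_sites, land, seed = seed)
  records <- simulate_surveys(pool, truth, sites, seq_len(n_years) + 1999,
                              effort = effort,
                              detectability = detectability, seed = seed)
  list(land = land, pool = pool, refined = refined, stack = stack,
       truth = truth, sites = sites, records = records)
}

## ---- independent oracles -------------------------------------------

## Rao's Q by explicit nested double sum.
oracle_rao <- function(abund, d) {
  A <- sum(abund)
  total <- 0
  for (s in seq_along(abund)) {
    for (t in seq_along(abund)) {
      total <- total + d[s, t] * (abund[s] / A) * (abund[t] / A)
    }
  }
  total
}

## Gower distance by per-element, per-trait recomputation.
oracle_gower <- function(traits, i, j) {
  rng_m <- max(traits$log_mass) - min(traits$log_mass)
  rng_g <- max(traits$log_genlength) - min(traits$log_genlength)
  c_mass <- if (rng_m == 0) 0 else abs(traits$log_mass[i] - traits$log_mass[j]) / rng_m
  c_gen <- if (rng_g == 0) 0 else abs(traits$log_genlength[i] - traits$log_genlength[j]) / rng_g
  c_mig <- as.numeric(traits$migratory_class[i] != traits$migratory_class[j])
  c_diet <- as.numeric(traits$diet_class[i] != traits$diet_class[j])
  mean(c(c_mass, c_gen, c_mig, c_diet))
}

## PCoA by explicit double-centring and eigendecomposition.
oracle_pcoa <- function(d) {
  n <- nrow(d)
  B <- -0.5 * d^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  e <- eigen(B, symmetric = TRUE)
  keep <- e$values > 1e-8 * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep), sum(keep))
}

## 2-D hull area by directed-edge enumeration (a pair is a hull edge
## iff every other point lies on its left), then the shoelace formula
## on the recovered cycle.  Independent of grDevices::chull.
oracle_hull_area_2d <- function(p) {
  n <- nrow(p)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cross <- (p[j, 1] - p[i, 1]) * (p[, 2] - p[i, 2]) -
        (p[j, 2] - p[i, 2]) * (p[, 1] - p[i, 1])
      if (all(cross[-c(i, j)] > 1e-12)) edges[[length(edges) + 1]] <- c(i, j)
    }
  }
  if (!length(edges)) return(0)
  em <- do.call(rbind, edges)
  cyc <- em[1, ]
  while (cyc[length(cyc)] != cyc[1]) {
    nxt <- em[em[, 1] == cyc[length(cyc)], 2][1]
    cyc <- c(cyc, nxt)
  }
  cyc <- cyc[-length(cyc)]
  x <- p[cyc, 1]; y <- p[cyc, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## 3-D hull volumes via an external qhull implementation
## (scipy.spatial.ConvexHull), batched through JSON.
oracle_hull_volumes_scipy <- function(point_sets) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(point_sets, unname), infile, digits = NA)
  script <- paste(
    "import json, sys",
    "from scipy.spatial import ConvexHull, QhullError",
    sprintf("sets = json.load(open(%s))", deparse(infile)),
    "out = []",
    "for pts in sets:",
    "    try:",
    "        out.append(ConvexHull(pts).volume)",
    "    except QhullError:",
    "        out.append(0.0)",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(outfile)),
    sep = "\n")
  status <- system2("python", c("-c", shQuote(script)))
  stopifnot(status == 0)
  unlist(jsonlite::read_json(outfile))
}

## Flood fill under 4-adjacency: is a cell set connected?
is_connected_4 <- function(cells, n_rows, n_cols) {
  if (length(cells) <= 1) return(TRUE)
  inset <- logical(n_rows * n_cols)
  inset[cells] <- TRUE
  seen <- logical(n_rows * n_cols)
  queue <- cells[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    r <- ((cur - 1) %% n_rows) + 1
    cl <- ((cur - 1) %/% n_rows) + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- cl + d[2]
      if (rr < 1 || rr > n_rows || cc < 1 || cc > n_cols) next
      idx <- (cc - 1) * n_rows + rr
      if (inset[idx] && !seen[idx]) {
        seen[idx] <- TRUE
        queue <- c(queue, idx)
      }
    }
  }
  all(seen[cells])
}
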