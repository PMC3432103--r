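test_that("Gower distances match the per-trait formula and daisy", {
  tr <- tiny_traits()
  d <- gower_distance(tr)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d[i, j], oracle_gower(tr, i, j), tolerance = 1e-12)
  }
  ## cross-check against an established mixed-type implementation
  skip_if_not_installed("cluster")
  dd <- as.matrix(cluster::daisy(
    data.frame(tr$log_mass, tr$log_genlength,
               factor(tr$migratory_class), factor(tr$diet_class)),
    metric = "gower"))
  expect_equal(unname(d), unname(dd), tolerance = 1e-10)
})

test_that("Gower extremes, subsets, invariances and errors", {
  tr <- tiny_traits()
  ## identical species are at distance zero
  tr2 <- rbind(tr, tr[1, ]); tr2$species_id[6] <- "sp_a2"
  expect_equal(gower_distance(tr2)["sp_a", "sp_a2"], 0)
  ## pool-extreme, fully mismatched pair is at distance one
  extreme <- data.frame(
    species_id = c("lo", "hi"), log_mass = c(0, 5), log_genlength = c(0, 2),
    migratory_class = c("nomad", "latitudinal"),
    diet_class = c("fruit", "nectar"))
  expect_equal(gower_distance(extreme)["lo", "hi"], 1)
  ## species subset uses global pool ranges
  sub <- gower_distance(tr, species = c("sp_a", "sp_c"))
  expect_equal(sub["sp_a", "sp_c"], gower_distance(tr)["sp_a", "sp_c"])
  ## invariant to species ordering and affine rescaling of mass
  perm <- tr[c(3, 1, 5, 2, 4), ]
  expect_equal(gower_distance(perm)[tr$species_id, tr$species_id],
               gower_distance(tr))
  resc <- tr; resc$log_mass <- 7 + 3 * resc$log_mass
  expect_equal(gower_distance(resc), gower_distance(tr))
  ## zero-range continuous trait contributes 0 rather than 0/0
  flat <- tr; flat$log_genlength <- 1
  expect_true(all(is.finite(gower_distance(flat))))
  ## missing trait data is rejected (excluded-species rule)
  miss <- tr; miss$log_mass[2] <- NA
  expect_error(gower_distance(miss), "missing trait values")
  expect_error(gower_distance(tr[1, , drop = FALSE]), "at least 2")
})

test_that("PCoA embeds distances: equilateral, linear and random cases", {
  ## three points at mutual distance 1: the embedding preserves it
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- trait_pcoa(d3)
  expect_equal(as.matrix(dist(p3$coords)), d3, tolerance = 1e-8,
               ignore_attr = TRUE)
  ## points on a line: one dominant axis recovers the spacing
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x))
  pl <- trait_pcoa(dl)
  expect_equal(length(pl$eigenvalues), 1)
  expect_equal(as.matrix(dist(pl$coords[, 1])), dl, tolerance = 1e-8)
  ## random Euclidean configurations round-trip within 1e-6, and the
  ## coordinates agree with a hand-rolled double-centred eigendecomposition
  set.seed(41)
  for (rep in 1:5) {
    pts <- matrix(rnorm(8 * 3), 8, 3)
    dmat <- as.matrix(dist(pts))
    emb <- trait_pcoa(dmat)
    expect_lt(max(abs(as.matrix(dist(emb$coords)) - dmat)), 1e-6)
    manual <- oracle_pcoa(dmat)
    expect_equal(dim(emb$coords), dim(manual))
    expect_lt(max(abs(as.matrix(dist(manual)) - dmat)), 1e-6)
  }
  ## eigenvalues ordered, axes positive only
  expect_true(all(diff(trait_pcoa(as.matrix(dist(matrix(rnorm(20), 10))))$eigenvalues) <= 0))
  ## degenerate all-zero distances
  z <- matrix(0, 4, 4)
  expect_message(pz <- trait_pcoa(z), "all distances are zero")
  expect_identical(ncol(pz$coords), 0L)
})

test_that("axis selection honours the variance target and cap", {
  ev_pcoa <- structure(list(coords = matrix(rnorm(40), 10, 4),
                            eigenvalues = c(10, 5, 1, 0.5)),
                       class = "ts_pcoa")
  expect_identical(ncol(select_axes(ev_pcoa, 0.9, 3)), 2L)
  expect_identical(ncol(select_axes(ev_pcoa, 0.99, 3)), 3L)
  expect_identical(ncol(select_axes(ev_pcoa, 0.5, 3)), 1L)
})

test_that("community-weighted means are abundance-weighted and bounded", {
  expect_equal(cwm_continuous(c(1, 1), c(2, 4)), 3)
  expect_equal(cwm_continuous(5, 7.3), 7.3)
  expect_equal(cwm_continuous(c(1, 3), c(2, 4)), 3.5)
  set.seed(42)
  for (rep in 1:20) {
    a <- runif(6, 0.1, 5); x <- rnorm(6)
    v <- cwm_continuous(a, x)
    expect_gte(v, min(x)); expect_lte(v, max(x))
  }
  expect_error(cwm_continuous(numeric(0), numeric(0)), "empty community")
  expect_error(cwm_continuous(c(1, 0), c(1, 2)), "positive")

  expect_equal(cwm_categorical(c(2, 3), c("k", "k"), "k"), 1)
  expect_equal(cwm_categorical(c(1, 1, 2), c("k", "j", "k"), "k"), 3 / 4)
  ## proportions over all classes sum to one
  cls <- c("a", "b", "a", "c")
  ab <- c(1, 2, 3, 4)
  expect_equal(sum(vapply(unique(cls), function(k) {
    cwm_categorical(ab, cls, k)
  }, numeric(1))), 1)
  expect_error(cwm_categorical(1, "a", "zzz"), "unknown class")
})

test_that("single-trait functional richness is range or class count", {
  expect_equal(frich_single(3.2), 0)
  expect_equal(frich_single(c(1.0, 2.5, 2.0)), 1.5)
  expect_equal(frich_single(c("fruit", "fruit", "nectar")), 2)
  expect_error(frich_single(character(0)), "empty community")
})

test_that("convex hull volumes: canonical shapes and degeneracies", {
  ## right triangle, area 1/2
  expect_equal(as.numeric(convex_hull_volume(rbind(c(0, 0), c(1, 0), c(0, 1)))),
               0.5)
  ## interior points do not change the hull
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(1, 1), c(0.5, 0.3))
  expect_equal(as.numeric(convex_hull_volume(sq)), 4)
  ## collinear points are degenerate
  col3 <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(as.numeric(convex_hull_volume(col3)), 0)
  expect_true(attr(convex_hull_volume(col3), "degenerate"))
  ## unit tetrahedron, volume 1/6
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(as.numeric(convex_hull_volume(tet)), 1 / 6, tolerance = 1e-12)
  ## unit cube, volume 1 (coplanar facets must not be double-counted)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(as.numeric(convex_hull_volume(cube)), 1, tolerance = 1e-10)
  ## coplanar 3-D points are degenerate
  flat <- cbind(matrix(runif(12), 6, 2), 0.7)
  expect_true(attr(convex_hull_volume(flat), "degenerate"))
  ## 1-D: range
  expect_equal(as.numeric(convex_hull_volume(cbind(c(1, 5, 2)))), 4)
  expect_error(convex_hull_volume(matrix(1, 2, 4)), "1-3 dimensional")
  expect_error(convex_hull_volume(matrix(c(1, NA), 1)), "finite")
})

test_that("2-D hull areas match an independent edge-enumeration oracle", {
  set.seed(51)
  for (rep in 1:30) {
    p <- matrix(runif(2 * sample(4:15, 1)), ncol = 2)
    expect_equal(as.numeric(convex_hull_volume(p)), oracle_hull_area_2d(p),
                 tolerance = 1e-9)
  }
})

test_that("hull volume is monotone under adding species", {
  set.seed(52)
  for (dims in 2:3) {
    pts <- matrix(rnorm(12 * dims), ncol = dims)
    v_part <- as.numeric(convex_hull_volume(pts[1:6, , drop = FALSE]))
    v_full <- as.numeric(convex_hull_volume(pts))
    expect_gte(v_full, v_part)
  }
})

test_that("Rao's Q matches the nested-loop double sum", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(rao_q(c(x = 1, y = 1), d2), 0.5)
  expect_equal(rao_q(c(x = 3), d2[1, 1, drop = FALSE]), 0)
  set.seed(61)
  tr <- random_traits(12)
  d <- gower_distance(tr)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    sp <- sample(tr$species_id, k)
    a <- stats::setNames(runif(k, 0.2, 9), sp)
    expect_equal(rao_q(a, d), oracle_rao(unname(a), d[sp, sp]),
                 tolerance = 1e-12)
  }
  expect_error(rao_q(c(zz = 1), d), "missing from distance matrix")
  expect_error(rao_q(numeric(0), d), "empty community")
})

test_that("the numbers equivalent behaves as an effective species count", {
  expect_equal(numbers_equivalent(0), 1)
  expect_equal(numbers_equivalent(0.5), 2)
  expect_error(numbers_equivalent(1), "\\[0, 1\\)")
  expect_error(numbers_equivalent(-0.1), "\\[0, 1\\)")
  ## strictly increasing in Q
  q <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(numbers_equivalent(q)) > 0))
  ## S equally abundant, maximally distinct species give exactly S
  for (S in 2:10) {
    d <- matrix(1, S, S) - diag(S)
    ids <- sprintf("s%d", 1:S)
    dimnames(d) <- list(ids, ids)
    q <- rao_q(stats::setNames(rep(2, S), ids), d)
    expect_equal(numbers_equivalent(q), S, tolerance = 1e-12)
  }
})

test_that("community_metrics composes the standalone operations", {
  tr <- tiny_traits()
  dl <- trait_distances(tr)
  coords <- select_axes(trait_pcoa(dl$all))
  ab <- c(2, 1, 4, 1, 3)
  m <- community_metrics(tr$species_id, ab, tr, dl, coords,
                         include_hull = TRUE)
  pick <- function(metric, scope) m$value[m$metric == metric &
                                            m$trait_scope == scope]
  expect_equal(pick("CWM", "mass"), cwm_continuous(ab, tr$log_mass))
  expect_equal(pick("CWM", "genlength"), cwm_continuous(ab, tr$log_genlength))
  expect_equal(pick("CWM", "diet.fruit"),
               cwm_categorical(ab, tr$diet_class, "fruit", diet_classes))
  expect_equal(pick("FRICH", "mass"), frich_single(tr$log_mass))
  expect_equal(pick("FRICH", "diet"), frich_single(tr$diet_class))
  expect_equal(pick("FRICH", "all"),
               as.numeric(frich_hull(coords[tr$species_id, ])))
  expect_equal(pick("FDIV", "all"),
               numbers_equivalent(rao_q(stats::setNames(ab, tr$species_id),
                                        dl$all)))
  expect_equal(pick("FDIV", "mass"),
               numbers_equivalent(rao_q(stats::setNames(ab, tr$species_id),
                                        dl$mass)))
  ## class-proportion CWMs sum to one within each categorical trait
  diet_rows <- grepl("^diet\\.", m$trait_scope) & m$metric == "CWM"
  expect_equal(sum(m$value[diet_rows]), 1)
  mig_rows <- grepl("^migration\\.", m$trait_scope) & m$metric == "CWM"
  expect_equal(sum(m$value[mig_rows]), 1)
})

test_that("presence-based FDIV equals the equal-abundance computation", {
  tr <- tiny_traits()
  dl <- trait_distances(tr)
  m1 <- community_metrics(tr$species_id, rep(1, 5), tr, dl)
  m7 <- community_metrics(tr$species_id, rep(7, 5), tr, dl)
  f1 <- m1[m1$metric == "FDIV", "value"]
  f7 <- m7[m7$metric == "FDIV", "value"]
  expect_equal(f1, f7)
  ## and is invariant to permuting species labels
  perm <- sample(5)
  mp <- community_metrics(tr$species_id[perm], rep(1, 5), tr, dl)
  expect_equal(mp[mp$metric == "FDIV", "value"], f1)
})

test_that("single-species communities are flagged but computable", {
  tr <- tiny_traits()
  dl <- trait_distances(tr)
  m <- community_metrics("sp_b", 4, tr, dl)
  expect_equal(m$value[m$metric == "CWM" & m$trait_scope == "mass"],
               tr$log_mass[2])
  fdiv <- m[m$metric == "FDIV", ]
  expect_true(all(fdiv$value == 1))
  expect_true(all(fdiv$flag == "single_species"))
})

test_that("metric maps agree with direct per-cell computation", {
  w <- make_world(seed = 14, n_species = 12)
  tr <- w$pool[, c("species_id", "log_mass", "log_genlength",
                   "migratory_class", "diet_class")]
  dl <- trait_distances(tr)
  coords <- select_axes(trait_pcoa(dl$all))
  f <- method_a_uniform(w$stack)
  maps <- community_metric_maps(f, tr, dl, coords)
  cells <- sample(unique(maps$cell), 5)
  for (cell in cells) {
    sp <- w$stack$species_ids[w$stack$occupancy[, cell] == 1L]
    direct <- community_metrics(sp, rep(1, length(sp)), tr, dl, coords,
                                include_hull = TRUE)
    sub <- maps[maps$cell == cell, c("metric", "trait_scope", "value")]
    expect_equal(sub$value, direct$value)
  }
  ## rasterisation picks the right cells
  mm <- metric_map_matrix(maps, "CWM", "mass", 10, 10)
  expect_equal(mm[cells[1]],
               maps$value[maps$cell == cells[1] & maps$metric == "CWM" &
                            maps$trait_scope == "mass"])
})
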