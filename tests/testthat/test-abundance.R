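test_that("method (a) reproduces occupancy and richness", {
  w <- make_world(seed = 2)
  f <- method_a_uniform(w$stack)
  expect_identical(f$values, w$stack$occupancy + 0)
  expect_equal(total_abundance_map(f),
               species_richness_map(w$stack) + 0)
  one <- build_stack(list(solo = c(2L, 5L, 9L)), 4, 4)
  expect_identical(sum(method_a_uniform(one)$values), 3)
})

test_that("regional population is the area-rescaled mid-point", {
  expect_identical(regional_population(2000, 6000, 0.5), 2000)
  expect_identical(regional_population(1000, 1000, 1.0), 1000)
  expect_identical(regional_population(0, 0, 0.3), 0)
  expect_error(regional_population(-1, 5, 0.5), "negative")
  expect_error(regional_population(0, 5, 1.5), "negative|outside")
  expect_error(regional_population(10, 5, 0.5), "must be <=")
})

test_that("method (b) spreads regional totals evenly and conserves them", {
  stack <- build_stack(list(sp1 = 1:100), 10, 10)
  pops <- data.frame(species_id = "sp1", global_pop_min = 500,
                     global_pop_max = 1500, area_fraction = 1)
  f <- method_b_pop_over_range(stack, pops)
  expect_true(all(f$values[1, ] == 10))

  w <- make_world(seed = 4, n_species = 20)
  f <- suppressWarnings(method_b_pop_over_range(w$stack, w$pool))
  ## row sums equal the regional populations exactly (conservation)
  for (sp in f$eligible_species) {
    i <- match(sp, w$pool$species_id)
    expect_equal(sum(f$values[sp, ]),
                 regional_population(w$pool$global_pop_min[i],
                                     w$pool$global_pop_max[i],
                                     w$pool$area_fraction[i]))
  }
  ## species without population data are not eligible and stay zero
  no_pop <- setdiff(w$pool$species_id[is.na(w$pool$global_pop_min)],
                    f$eligible_species)
  expect_identical(no_pop, w$pool$species_id[is.na(w$pool$global_pop_min)])
  expect_true(all(f$values[no_pop, ] == 0))
  ## per-cell values match an independent loop
  for (sp in sample(f$eligible_species, min(3, length(f$eligible_species)))) {
    i <- match(sp, w$pool$species_id)
    reg <- (w$pool$global_pop_min[i] + w$pool$global_pop_max[i]) / 2 *
      w$pool$area_fraction[i]
    cells <- which(w$stack$occupancy[sp, ] == 1L)
    for (cell in cells) {
      expect_equal(unname(f$values[sp, cell]), reg / length(cells))
    }
  }
})

test_that("effort correction follows the recorded-years round-up rule", {
  expect_identical(effort_corrected_abundance(6, 3), 2)
  expect_identical(effort_corrected_abundance(c(4, 7), c(2, 2)), 3)
  ## any recorded species gets at least 1
  expect_identical(effort_corrected_abundance(1, 10), 1)
  ## zero-count years are excluded from the average
  expect_identical(effort_corrected_abundance(c(0, 6), c(1, 3)), 2)
  expect_true(is.na(effort_corrected_abundance(c(0, 0), c(1, 1))))
  expect_error(effort_corrected_abundance(-1, 1), "non-negative")
  expect_error(effort_corrected_abundance(1, 0), "positive")
})

test_that("site-species abundances match a direct two-pass recomputation", {
  set.seed(21)
  rec <- data.frame(
    site_id = sample(sprintf("s%d", 1:6), 200, replace = TRUE),
    species_id = sample(sprintf("sp%d", 1:8), 200, replace = TRUE),
    year = sample(2000:2009, 200, replace = TRUE),
    count = rpois(200, 2),
    effort = runif(200, 0.5, 8)
  )
  rec <- rec[!duplicated(rec[, c("site_id", "species_id", "year")]), ]
  got <- site_species_abundance(rec)
  for (k in seq_len(nrow(got))) {
    sub <- rec[rec$site_id == got$site_id[k] &
                 rec$species_id == got$species_id[k] & rec$count > 0, ]
    expect_equal(got$abundance[k], ceiling(mean(sub$count / sub$effort)))
  }
  ## pairs never recorded are absent
  all_zero <- aggregate(count ~ site_id + species_id, rec, sum)
  zero_pairs <- all_zero[all_zero$count == 0, ]
  if (nrow(zero_pairs)) {
    expect_false(any(paste(zero_pairs$site_id, zero_pairs$species_id) %in%
                       paste(got$site_id, got$species_id)))
  }
})

test_that("method (c) applies the training-site mean within the range", {
  stack <- build_stack(list(sp1 = 1:10, sp2 = 5:20), 5, 5)
  rec <- data.frame(
    site_id = c("t1", "t2", "e1"),
    species_id = "sp1",
    year = 2000L,
    count = c(4, 9, 100),
    effort = c(2, 3, 1)
  )
  f <- method_c_survey_mean(stack, rec, training_sites = c("t1", "t2"))
  ## per-site values ceiling(2)=2 and ceiling(3)=3, mean 2.5; the
  ## evaluation site is excluded by the split
  expect_true(all(f$values["sp1", 1:10] == 2.5))
  expect_true(all(f$values["sp1", 11:25] == 0))
  ## never-recorded species are not eligible
  expect_identical(f$eligible_species, "sp1")
  expect_true(all(f$values["sp2", ] == 0))
})

test_that("method (c) matches an independent recomputation on random records", {
  w <- make_world(seed = 6, n_sites = 15)
  train <- w$sites$site_id[1:10]
  f <- method_c_survey_mean(w$stack, w$records, train)
  ssa <- site_species_abundance(w$records[w$records$site_id %in% train, ])
  for (sp in f$eligible_species) {
    want <- mean(ssa$abundance[ssa$species_id == sp])
    cells <- which(w$stack$occupancy[sp, ] == 1L)
    expect_true(all(f$values[sp, cells] == want))
  }
})

test_that("environmental models recover a noiseless single-covariate response", {
  set.seed(31)
  n <- 200
  site_env <- data.frame(site_id = sprintf("s%d", 1:n),
                         env1 = runif(n, -2, 2), env2 = runif(n, -2, 2),
                         env3 = runif(n, -2, 2))
  abund <- data.frame(site_id = site_env$site_id,
                      abundance = exp(1 + 0.8 * site_env$env1))
  m <- fit_env_abundance_model(abund, site_env)
  expect_gt(m$dev_expl, 0.95)
  pred <- predict(m, site_env)
  expect_gt(cor(pred, abund$abundance), 0.97)
})

test_that("constant abundance, record thresholds and clamping behave", {
  set.seed(32)
  site_env <- data.frame(site_id = sprintf("s%d", 1:50),
                         env1 = runif(50), env2 = runif(50), env3 = runif(50))
  const <- data.frame(site_id = site_env$site_id, abundance = 3)
  m <- fit_env_abundance_model(const, site_env)
  expect_equal(predict(m, site_env), rep(3, 50), tolerance = 1e-6)
  ## 29 records with threshold 30 are skipped
  expect_message(
    m29 <- fit_env_abundance_model(const[1:29, ], site_env, min_records = 30),
    "skipped")
  expect_null(m29)
  ## predictions outside the training covariate box are clamped
  vary <- data.frame(site_id = site_env$site_id,
                     abundance = exp(site_env$env1) + 1)
  mv <- fit_env_abundance_model(vary, site_env)
  far <- data.frame(env1 = 50, env2 = 0.5, env3 = 0.5)
  expect_message(p_far <- predict(mv, far), "clamped")
  edge <- data.frame(env1 = max(site_env$env1), env2 = 0.5, env3 = 0.5)
  expect_equal(p_far, suppressMessages(predict(mv, edge)))
})

test_that("method (d) respects the range mask and floors at zero", {
  w <- make_world(seed = 8, n_sites = 40)
  models <- suppressMessages(fit_env_abundance_models(
    w$records, w$sites$site_id, w$sites, w$land, min_records = 10))
  skip_if(length(models) == 0)
  f <- method_d_env_model(w$stack, models, w$land)
  expect_true(all(f$values >= 0))
  expect_true(all(f$values[w$stack$occupancy == 0L] == 0))
  expect_error(method_d_env_model(w$stack, list(), w$land),
               "no fitted environmental models")
})

test_that("all methods stay inside the refined ranges", {
  w <- make_world(seed = 12, n_sites = 30)
  train <- w$sites$site_id[1:25]
  fields <- list(
    method_a_uniform(w$stack),
    suppressWarnings(method_b_pop_over_range(w$stack, w$pool)),
    method_c_survey_mean(w$stack, w$records, train)
  )
  for (f in fields) {
    expect_true(all(f$values[w$stack$occupancy == 0L] == 0))
    expect_true(all(f$values >= 0))
  }
})

test_that("total-abundance map equals an independent per-cell loop", {
  w <- make_world(seed = 13)
  f <- suppressWarnings(method_b_pop_over_range(w$stack, w$pool))
  tot <- total_abundance_map(f)
  for (cell in sample.int(100, 10)) {
    s <- 0
    for (sp in f$eligible_species) s <- s + unname(f$values[sp, cell])
    expect_equal(tot[cell], s)
  }
  zero <- new_field <- method_a_uniform(
    suppressMessages(build_stack(list(sp1 = integer(0)), 4, 4)))
  expect_true(all(total_abundance_map(zero) == 0))
})

test_that("the environmental method recovers truth better than the flat methods", {
  ## when the world truly follows a smooth abundance-environment
  ## response, method (d)'s total-abundance map should beat the
  ## spatially flat methods (b) and (c) in most replicates
  wins <- logical(25)
  for (s in seq_len(25)) {
    w <- make_world(seed = 100 + s, n = 10, n_species = 25, n_sites = 80,
                    n_years = 3, effort = 10)
    train <- w$sites$site_id[1:70]
    train_rec <- w$records[w$records$site_id %in% train, ]
    fb <- suppressWarnings(method_b_pop_over_range(w$stack, w$pool))
    fc <- method_c_survey_mean(w$stack, train_rec, train)
    models <- suppressMessages(fit_env_abundance_models(
      train_rec, train, w$sites, w$land, min_records = 10))
    if (length(models) < 5) next
    fd <- method_d_env_model(w$stack, models, w$land)
    common <- Reduce(intersect, list(fb$eligible_species,
                                     fc$eligible_species,
                                     fd$eligible_species))
    if (length(common) < 5) next
    tot_truth <- colSums(w$truth[common, , drop = FALSE])
    occ <- tot_truth > 0
    r_of <- function(f) {
      cor(colSums(f$values[common, , drop = FALSE])[occ], tot_truth[occ])
    }
    wins[s] <- r_of(fd) > r_of(fb) && r_of(fd) > r_of(fc)
  }
  expect_gte(mean(wins), 0.8)
})
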