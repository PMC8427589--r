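test_that("habitat map honours degenerate and target rocky fractions", {
  expect_equal(generate_habitat_map(100, 1, 20, seed = 1)$rocky, rep(1L, 100))
  expect_equal(generate_habitat_map(100, 0, 20, seed = 1)$rocky, rep(0L, 100))
  for (s in 1:20) {
    frac <- mean(generate_habitat_map(3190, 0.5, 20, seed = s)$rocky)
    expect_true(frac >= 0.4 && frac <= 0.6)
  }
  expect_error(generate_habitat_map(0, 0.5), "positive integer")
  expect_error(generate_habitat_map(100, 1.2), "\\[0, 1\\]")
})

test_that("habitat map is reproducible and has patchiness near the patch scale", {
  m1 <- generate_habitat_map(2000, 0.5, 20, seed = 3)
  m2 <- generate_habitat_map(2000, 0.5, 20, seed = 3)
  expect_identical(m1$rocky, m2$rocky)
  runs <- rle(m1$rocky)
  mean_run <- mean(runs$lengths[runs$values == 1])
  expect_true(mean_run > 20 / 4 && mean_run < 20 * 4)
  # current divide flips the upstream sign only below the boundary
  mb <- generate_habitat_map(100, 0.5, 10, boundary_km = 40,
                             flip_below_boundary = TRUE, seed = 1)
  expect_equal(mb$upstream_sign, c(rep(-1L, 40), rep(1L, 60)))
})

test_that("species fields follow the configured structure", {
  map <- generate_habitat_map(1000, 1, 20, seed = 2)  # all rocky
  flat <- species_field_config("a", c(200, 700), 0.5)
  f <- generate_species_fields(map, list(flat))
  inside <- f$positions_km >= 200 & f$positions_km <= 700
  expect_true(all(f$mu[inside, 1] == 0.5))
  expect_true(all(f$mu[!inside, 1] == 0))
  # coupling on an all-rocky map only rescales by a constant
  coup <- species_field_config("a", c(200, 700), 0.5, habitat_coupling = 2,
                               dispersal_window_km = 50)
  fc <- generate_species_fields(map, list(coup))
  interior <- f$positions_km >= 260 & f$positions_km <= 640  # away from edges
  ratio <- fc$mu[interior, 1] / f$mu[interior, 1]
  expect_true(diff(range(ratio)) < 1e-12)
  expect_equal(ratio[1], 1 + 2 * 1)  # all-rocky: normalised amount = 1
})

test_that("a planted periodic component dominates the field's spectrum", {
  map <- generate_habitat_map(3000, 1, 20, seed = 2)
  cfg <- species_field_config("a", c(0, 3000), 1,
                              periodic_components = list(c(150, 0.8, 0.3)))
  f <- generate_species_fields(map, list(cfg))
  v <- f$mu[, 1]
  spec <- Mod(stats::fft(v - mean(v)))[2:100]
  k_hat <- which.max(spec)
  expect_equal(3000 / k_hat, 150, tolerance = 3000 / (3000 / 150)^2)
})

test_that("survey counts respect the expected-CPUE surface", {
  map <- generate_habitat_map(500, 1, 20, seed = 4)
  zero <- generate_species_fields(map, list(
    species_field_config("a", c(0, 500), 0)))
  v <- generate_survey(map, zero, list(observer_config("o", 1)),
                       n_sites = 30, seed = 5)
  expect_true(all(v$count_a == 0))
  expect_true(all(v$count_a == round(v$count_a)))
  # doubling detection efficiency roughly doubles mean counts
  f <- generate_species_fields(map, list(
    species_field_config("a", c(0, 500), 0.5, overdispersion = 2)))
  tot <- sapply(c(1, 2), function(eff) {
    s <- sapply(1:25, function(i) {
      vv <- generate_survey(map, f, list(observer_config("o", eff)),
                            n_sites = 40, seed = 100 + i)
      mean(vv$count_a / vv$search_minutes)
    })
    mean(s)
  })
  expect_true(tot[2] / tot[1] > 1.8 && tot[2] / tot[1] < 2.2)
})

test_that("survey regeneration is bit-identical and flags are exercised", {
  w1 <- make_test_world(seed = 9, n_sites = 60)
  w2 <- make_test_world(seed = 9, n_sites = 60)
  expect_identical(w1$visits, w2$visits)
  # the default short-visit fraction plants removable visits
  expect_true(any(w1$visits$search_minutes < 15))
  expect_error(
    generate_survey(w1$map, w1$fields, list(observer_config("o", 1)),
                    n_sites = 1e6, seed = 1),
    "exceeds")
})

test_that("counts approach the Poisson limit as overdispersion grows", {
  map <- generate_habitat_map(200, 1, 20, seed = 6)
  f <- generate_species_fields(map, list(
    species_field_config("a", c(0, 200), 0.5, overdispersion = 1e9)))
  # fixed expectation: single site surveyed many times
  counts <- unlist(lapply(1:250, function(i) {
    v <- generate_survey(map, f, list(observer_config("o", 1)), n_sites = 40,
                         effort_cfg = list(meanlog = log(45), sdlog = 0,
                                           min_minutes = 45, max_minutes = 45,
                                           short_fraction = 0),
                         seed = 1000 + i)
    v$count_a
  }))
  mu <- 0.5 * 45
  ratio <- stats::var(counts) / mean(counts)
  expect_true(ratio > 0.9 && ratio < 1.1)
  expect_equal(mean(counts), mu, tolerance = 0.05)
})

test_that("habitat and visits CSV dialects round-trip", {
  tmp <- withr::local_tempdir()
  map <- generate_habitat_map(300, 0.4, 15, seed = 8)
  p1 <- file.path(tmp, "habitat.csv")
  write_habitat_csv(map, p1)
  back <- read_habitat_csv(p1)
  expect_equal(back$rocky, map$rocky)
  expect_equal(back$upstream_sign, map$upstream_sign)
  w <- make_test_world(seed = 10, n_sites = 20)
  p2 <- file.path(tmp, "visits.csv")
  write_visits_csv(w$visits, p2)
  vr <- read_visits_csv(p2)
  expect_equal(vr$search_minutes, w$visits$search_minutes)
  expect_equal(vr$count_urchin, w$visits$count_urchin)
  # missing required column is a schema error naming the column
  bad <- w$visits; bad$tide_start_m <- NULL
  p3 <- file.path(tmp, "bad.csv")
  utils::write.csv(bad, p3, row.names = FALSE)
  expect_error(read_visits_csv(p3), "tide_start_m")
})
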