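toy_map <- function(length_km = 50, rocky_cells = NULL, sign = 1L) {
  rocky <- integer(length_km)
  if (!is.null(rocky_cells)) rocky[rocky_cells + 1L] <- 1L  # 0-based cells
  structure(list(length_km = as.integer(length_km), rocky = rocky,
                 upstream_sign = rep(as.integer(sign), length_km),
                 meta = list()),
            class = "coast_map")
}

test_that("window ladder enumerates 5-140 km in 5-km steps", {
  w <- window_sizes()
  expect_length(w, 28)
  expect_equal(range(w), c(5, 140))
  expect_equal(window_sizes(5, 5, 5), 5)
  expect_error(window_sizes(10, 9, 5), "min_km <= max_km")
  expect_error(window_sizes(5, 140, 0), "positive")
})

test_that("habitat amount counts rocky km in the directional window", {
  all_rocky <- toy_map(200, 0:199)
  expect_equal(as.numeric(habitat_amount(all_rocky, 100.5, "upstream", 40)), 40)
  all_sand <- toy_map(200)
  expect_equal(as.numeric(habitat_amount(all_sand, 100.5, "upstream", 40)), 0)
  # rocky cells {10-19, 30-34}, site at 25, upstream sign +1, window 10:
  # cells 26-35 contain rocky 30-34 -> 5 km
  tm <- toy_map(50, c(10:19, 30:34))
  expect_equal(as.numeric(habitat_amount(tm, 25, "upstream", 10)), 5)
  # downstream window covers cells 15-24 -> rocky 15-19 -> 5 km
  expect_equal(as.numeric(habitat_amount(tm, 25, "downstream", 10)), 5)
  expect_error(habitat_amount(tm, 60, "upstream", 10), "outside")
})

test_that("edge windows are truncated and audited", {
  tm <- toy_map(30, 0:29)
  a <- habitat_amount(tm, 25.5, "upstream", 10)  # cells 26-35, map ends at 29
  expect_equal(as.numeric(a), 4)
  expect_equal(attr(a, "truncated_km"), 6)
  a2 <- habitat_amount(tm, 15.5, "upstream", 10)
  expect_equal(attr(a2, "truncated_km"), 0)
})

test_that("habitat amount matches a cell-walking oracle and its invariants", {
  set.seed(31)
  for (i in 1:100) {
    L <- sample(20:50, 1)
    m <- toy_map(L, which(runif(L) < 0.5) - 1L,
                 sign = sample(c(-1L, 1L), 1))
    site <- runif(1, 0, L - 1e-9)
    w <- sample(1:20, 1)
    dir <- sample(c("upstream", "downstream"), 1)
    expect_equal(as.numeric(habitat_amount(m, site, dir, w)),
                 oracle_habitat(m, site, dir, w), tolerance = 1e-12)
    # monotone in window size and bounded by it
    w2 <- w + sample(1:10, 1)
    a1 <- as.numeric(habitat_amount(m, site, dir, w))
    a2 <- as.numeric(habitat_amount(m, site, dir, w2))
    expect_true(a2 >= a1 && a1 <= w && a2 <= w2)
  }
})

test_that("flipping every upstream sign swaps upstream and downstream exactly", {
  set.seed(32)
  m <- toy_map(100, which(runif(100) < 0.4) - 1L, sign = 1L)
  m_fl <- m; m_fl$upstream_sign <- -m$upstream_sign
  sites <- runif(10, 0, 99)
  for (w in c(5, 20, 60)) {
    expect_equal(as.numeric(habitat_amount(m, sites, "upstream", w)),
                 as.numeric(habitat_amount(m_fl, sites, "downstream", w)))
    expect_equal(as.numeric(habitat_amount(m, sites, "downstream", w)),
                 as.numeric(habitat_amount(m_fl, sites, "upstream", w)))
  }
})

scan_table <- function(map, km, cpue, obs = "o1") {
  data.frame(species = "u", observer_id = obs,
             site_id = sprintf("S%03d", seq_along(km)),
             alongshore_km = km, n_visits = 1, total_count = 1,
             total_minutes = 1, cpue = cpue, stringsAsFactors = FALSE)
}

test_that("the scan emits 28 rows per direction and finds planted proportionality", {
  set.seed(33)
  m <- generate_habitat_map(800, 0.5, 15, seed = 33)
  km <- sort(sample(which(m$rocky == 1), 40)) - 0.5
  amt <- as.numeric(habitat_amount(m, km, "upstream", 50))
  tab <- scan_table(m, km, cpue = 0.01 * amt)  # proportional to 50-km window
  scan <- suppressMessages(window_correlation_scan(tab, m))
  expect_equal(nrow(scan), 2 * 28)
  expect_equal(sum(scan$direction == "upstream"), 28)
  row50 <- scan[scan$direction == "upstream" & scan$window_km == 50, ]
  expect_equal(row50$rho, 1)
  expect_true(row50$significant)
})

test_that("families with too few in-range sites are skipped with a message", {
  m <- generate_habitat_map(200, 1, 10, seed = 34)
  tab <- scan_table(m, c(10, 50), cpue = c(1, 2))
  expect_message(out <- window_correlation_scan(tab, m), "skipped")
  expect_equal(nrow(out), 0)
})
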