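test_that("compute_cpue standardises counts by search time", {
  expect_equal(compute_cpue(30, 60), 0.5)
  expect_equal(compute_cpue(0, 45), 0)
  # 22 individuals over 219 observer-minutes of effort
  expect_equal(compute_cpue(22, 219), 22 / 219)
  expect_equal(round(compute_cpue(22, 219), 2), 0.10)
  expect_error(compute_cpue(5, 0), "positive")
  expect_error(compute_cpue(-1, 10), "nonnegative")
})

make_visit <- function(minutes, tide_start, tide_end = tide_start,
                       site = "S001", count = 5) {
  data.frame(visit_id = NA, site_id = site, alongshore_km = 10,
             observer_id = "obs1", search_minutes = minutes,
             tide_start_m = tide_start, tide_end_m = tide_end,
             count_urchin = count, stringsAsFactors = FALSE)
}

test_that("exclusion thresholds are strict inequalities on the worst reading", {
  v <- rbind(make_visit(14, 0.3),          # duration fail
             make_visit(15, 0.83),         # exactly at both thresholds: kept
             make_visit(60, 0.5, 0.9),     # tide fail via the end reading
             make_visit(60, 0.9, 0.5))     # tide fail via the start reading
  out <- apply_exclusion_filters(v)
  expect_equal(nrow(out$kept), 1)
  expect_equal(out$kept$search_minutes, 15)
  fl <- out$removal_log$flags
  expect_true(fl$duration_fail[1] && !fl$tide_fail[1])
  expect_true(fl$tide_fail[3] && fl$tide_fail[4])
})

test_that("the 164-visit fixture reproduces the survey's removal bookkeeping", {
  v <- filter_demo_visits()
  expect_equal(nrow(v), 164)
  expect_equal(length(unique(v$site_id)), 116)
  out <- apply_exclusion_filters(v)
  log <- out$removal_log
  expect_equal(log$n_duration_only, 6)
  expect_equal(log$n_tide_only, 3)
  expect_equal(log$n_both, 5)
  expect_equal(log$n_visits_removed, 14)
  expect_equal(log$n_sites_removed, 11)
  expect_equal(log$n_sites_kept, 105)
})

test_that("the shipped fixture CSV matches its generator", {
  path <- system.file("extdata", "filter_demo_visits.csv",
                      package = "alongshore")
  shipped <- read_visits_csv(path)
  gen <- filter_demo_visits()
  expect_equal(shipped$search_minutes, gen$search_minutes)
  expect_equal(shipped$tide_start_m, gen$tide_start_m)
  expect_equal(shipped$site_id, gen$site_id)
})

test_that("filtering is idempotent, monotone, and partitions the visits", {
  set.seed(5)
  w <- make_test_world(seed = 5)
  out1 <- apply_exclusion_filters(w$visits)
  out2 <- apply_exclusion_filters(out1$kept)
  expect_equal(nrow(out2$kept), nrow(out1$kept))
  expect_equal(out2$removal_log$n_visits_removed, 0)
  # tightening min_duration never enlarges the kept set
  strict <- apply_exclusion_filters(w$visits, min_duration = 30)
  expect_true(all(strict$kept$visit_id %in% out1$kept$visit_id))
  # partition: kept + removed = all
  log <- out1$removal_log
  expect_equal(nrow(out1$kept) + log$n_visits_removed, nrow(w$visits))
  expect_true(all(log$removed_sites %in%
                    log$flags$site_id[log$flags$removed]))
})

test_that("site abundance pools counts and minutes within observer x site", {
  v <- rbind(make_visit(20, 0.3, count = 10),
             make_visit(30, 0.3, count = 0))
  tab <- site_abundance_table(v)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$cpue, 10 / 50)  # ratio of sums, not mean of ratios
  # CPUE invariant to splitting a visit into sub-visits
  v_split <- rbind(make_visit(10, 0.3, count = 4),
                   make_visit(10, 0.3, count = 6),
                   make_visit(30, 0.3, count = 0))
  expect_equal(site_abundance_table(v_split)$cpue, 10 / 50)
})

test_that("site mean CPUE averages across observers", {
  v <- rbind(make_visit(10, 0.3, count = 2),   # obs1: cpue 0.2
             {
               x <- make_visit(10, 0.3, count = 6)  # obs2: cpue 0.6
               x$observer_id <- "obs2"; x
             })
  tab <- site_abundance_table(v)
  m <- site_mean_cpue(tab)
  expect_equal(m$mean_cpue, 0.4)
  expect_equal(m$n_observers, 2L)
})

test_that("observer concordance evaluates pairs with enough shared shores", {
  mk <- function(obs, sites, cpue) {
    data.frame(species = "u", observer_id = obs, site_id = sites,
               alongshore_km = seq_along(sites), n_visits = 1,
               total_count = cpue * 10, total_minutes = 10, cpue = cpue,
               stringsAsFactors = FALSE)
  }
  sites5 <- sprintf("S%02d", 1:5)
  # identical CPUE vectors over 5 shared sites -> rho = 1
  tab <- rbind(mk("a", sites5, c(1, 2, 3, 4, 5)), mk("b", sites5, c(1, 2, 3, 4, 5)))
  out <- observer_concordance(tab)
  expect_equal(out$rho, 1)
  expect_equal(out$n_shared, 5L)
  # observers sharing only 2 sites emit no row (with a message)
  tab2 <- rbind(mk("a", sites5[1:2], c(1, 2)), mk("b", sites5[1:2], c(2, 1)))
  expect_message(out2 <- observer_concordance(tab2), "skipped")
  expect_equal(nrow(out2), 0)
  # 4 observers all mutually sharing sites -> choose(4, 2) = 6 rows
  tab4 <- do.call(rbind, lapply(letters[1:4], function(o) {
    mk(o, sites5, rank(rnorm(5)))
  }))
  out4 <- observer_concordance(tab4)
  expect_equal(nrow(out4), 6)
})
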