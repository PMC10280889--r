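# Frequency tables, per-100k normalization, prediction intervals, ranking
# and rank stability.

test_that("tabulation counts categories per year exactly", {
  rec <- make_records(c("I21", "I21", "I63"), rep(2015, 3))
  pre <- preprocess_records(rec)
  tab <- tabulate_admissions(pre$records, population = 100000)
  expect_equal(tab$counts["I21", "2015"], 2L)
  expect_equal(tab$counts["I63", "2015"], 1L)
  expect_equal(sum(tab$counts), nrow(pre$records))
})

test_that("tabulation flags record years missing from the population map", {
  rec <- preprocess_records(make_records(c("I21", "I63"), c(2015, 2016)))$records
  expect_error(
    tabulate_admissions(rec, population = c("2015" = 1e5), years = 2015L),
    "not covered")
})

test_that("scoped tables conserve the scope's record count", {
  codes <- c("I21", "I48", "G40", "S72", "A09", "B15")
  rec <- preprocess_records(make_records(rep(codes, 4), rep(2015:2018, each = 6)),
                            roster_mapping = read_roster_mapping())$records
  tab_all <- tabulate_admissions(rec, scope = "all")
  tab_i <- tabulate_admissions(rec, scope = "chapter:I")
  tab_ab <- tabulate_admissions(rec, scope = "chapter:A/B")
  tab_surg <- tabulate_admissions(rec, scope = "roster:surgical")
  expect_equal(sum(tab_all$counts), 24L)
  expect_equal(sum(tab_i$counts), 8L)   # I21, I48
  expect_equal(sum(tab_ab$counts), 8L)  # A09, B15 merged
  expect_equal(sum(tab_surg$counts), 4L)  # S72
})

test_that("noiseless synthetic stream reproduces the rounded expected counts", {
  law <- exponential_law(500, 0.3, n_categories = 8)
  cfg <- simulation_config(law, years = 2015:2017, z_fraction = 0)
  pre <- preprocess_records(generate_admissions(cfg))
  tab <- tabulate_admissions(pre$records, years = cfg$years)
  want <- pmax(1L, as.integer(round(expected_counts(law))))
  for (y in colnames(tab$counts))
    expect_equal(unname(tab$counts[synthetic_icd_codes(8), y]), want)
})

test_that("per-100k normalization is exact and scale-equivariant", {
  expect_equal(normalize_per_100k(315, 315000), 100)
  expect_equal(normalize_per_100k(0, 315000), 0)
  expect_error(normalize_per_100k(10, 0), "population")

  counts <- c(40, 20, 10)
  r1 <- normalize_per_100k(counts, 1e5)
  r2 <- normalize_per_100k(counts, 2e5)
  expect_equal(r1 / 2, r2)
  expect_equal(order(r1), order(r2))
})

test_that("prediction interval matches the t formula and its edge cases", {
  expect_equal(prediction_interval(c(10, 10, 10)), c(lower = 10, upper = 10))
  # hand computation: mean 10, s = 2, t(0.975, 2) = 4.3026527,
  # half-width = 4.3026527 * 2 * sqrt(1 + 1/3) = 9.9365509
  pi <- prediction_interval(c(8, 10, 12), clip = FALSE)
  expect_equal(unname(pi), c(0.0634491, 19.9365509), tolerance = 1e-6)
  expect_true(pi["lower"] <= 10 && 10 <= pi["upper"])
  # clipping respects non-negativity
  expect_equal(unname(prediction_interval(c(8, 10, 12))["lower"]), 0.0634491,
               tolerance = 1e-6)
  expect_gte(prediction_interval(c(0, 1, 0))["lower"], 0)
  expect_error(prediction_interval(10), "fewer than 2")
})

test_that("ranking sorts by mean rate with lexicographic tie-break", {
  counts <- matrix(c(5, 10, 5, 5, 10, 5), nrow = 3,
                   dimnames = list(c("I63", "I21", "A09"), c("2015", "2016")))
  tab <- make_table(counts)
  prof <- rank_by_mean(tab)
  expect_equal(prof$category, c("I21", "A09", "I63"))  # ties: A09 < I63
  expect_equal(prof$rank, 1:3)
  expect_true(all(diff(prof$mean_per_100k) <= 0))
  expect_true(all(prof$pi_lower <= prof$mean_per_100k + 1e-12 &
                    prof$mean_per_100k <= prof$pi_upper + 1e-12))
})

test_that("coverage truncation keeps the minimal prefix reaching the share", {
  counts <- matrix(c(10, 5, 3, 2), ncol = 1,
                   dimnames = list(c("A00", "B00", "C00", "D00"), "2015"))
  tab <- make_table(counts)
  prof80 <- rank_by_mean(tab, coverage_truncation = 0.8)
  expect_equal(nrow(prof80), 3L)  # shares 50%, 75%, 90%
  expect_equal(nrow(rank_by_mean(tab, coverage_truncation = 1)), 4L)
  expect_error(rank_by_mean(tab, coverage_truncation = 0), "coverage_truncation")
})

test_that("population rescaling divides rates but leaves ranks unchanged", {
  law <- exponential_law(100, 0.25, 10)
  rec <- preprocess_records(generate_admissions(
    simulation_config(law, z_fraction = 0)))$records
  p1 <- rank_by_mean(tabulate_admissions(rec, population = 1e5))
  p3 <- rank_by_mean(tabulate_admissions(rec, population = 3e5))
  expect_equal(p1$category, p3$category)
  expect_equal(p1$mean_per_100k / 3, p3$mean_per_100k)
  expect_equal(p1$mean_count, p3$mean_count)
})

test_that("rank stability is 1 for identical years and -1 for reversed ones", {
  same <- matrix(c(9, 5, 2, 9, 5, 2), nrow = 3,
                 dimnames = list(c("A00", "B00", "C00"), c("2015", "2016")))
  expect_equal(rank_stability(make_table(same))$mean, 1.0)

  rev <- matrix(c(9, 5, 2, 2, 5, 9), nrow = 3,
                dimnames = list(c("A00", "B00", "C00"), c("2015", "2016")))
  expect_equal(rank_stability(make_table(rev))$pairs$spearman, -1.0)
})

test_that("a Poisson-noised exponential cohort keeps a stable rank order", {
  cfg <- simulation_config(exponential_law(1000, 0.1, 50), years = 2015:2020,
                           z_fraction = 0, noise = "poisson", seed = 17L)
  rec <- preprocess_records(generate_admissions(cfg))$records
  st <- rank_stability(tabulate_admissions(rec, years = cfg$years))
  expect_gt(st$mean, 0.9)
})
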