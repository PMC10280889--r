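# Synthetic admission-stream generator: expected counts under both law
# families, record generation, Z contamination, determinism, Poisson
# convergence.

test_that("exponential expected counts follow b0*exp(-b1*rank)", {
  law <- exponential_law(b0 = 1000, b1 = 0.1, n_categories = 5)
  mu <- expected_counts(law)
  expect_equal(mu[1], 1000 * exp(-0.1), tolerance = 1e-12)
  expect_equal(mu, 1000 * exp(-0.1 * (1:5)), tolerance = 1e-12)

  flat <- expected_counts(exponential_law(1000, 0, 4))
  expect_equal(flat, rep(1000, 4))
})

test_that("pareto expected counts match the hand-evaluated rank-size grid", {
  # alpha = 2, k = 1, n = 5: x_r = k*(n/r)^(1/alpha), evaluated by hand
  mu <- expected_counts(pareto_law(alpha = 2, k = 1, n_categories = 5))
  expect_equal(mu, c(sqrt(5), sqrt(5 / 2), sqrt(5 / 3), sqrt(5 / 4), 1),
               tolerance = 1e-12)
  expect_equal(min(mu), 1)  # smallest category sits exactly at k
})

test_that("expected counts are strictly positive and non-increasing", {
  laws <- list(
    exponential_law(1000, 0.1, 50), exponential_law(3, 0.5, 10),
    pareto_law(0.7, 2, 30), pareto_law(2.5, 1, 100), pareto_law(1, 15, 12)
  )
  for (law in laws) {
    mu <- expected_counts(law)
    expect_length(mu, law$n_categories)
    expect_true(all(mu > 0))
    expect_true(all(diff(mu) <= 0))
  }
})

test_that("invalid law parameters name the offending field", {
  expect_error(exponential_law(b0 = -1), "b0")
  expect_error(exponential_law(b1 = -0.1), "b1")
  expect_error(pareto_law(alpha = 0), "alpha")
  expect_error(pareto_law(k = -2), "k")
  expect_error(pareto_law(n_categories = 1), "n_categories")
})

test_that("flat noiseless law yields exactly the expected record counts", {
  cfg <- simulation_config(exponential_law(10, 0, n_categories = 3),
                           years = 2015L, z_fraction = 0)
  adm <- generate_admissions(cfg)
  expect_equal(nrow(adm), 30L)
  tab <- table(adm$icd10_code)
  expect_length(tab, 3L)
  expect_true(all(tab == 10L))
  expect_true(all(adm$year == 2015L))
})

test_that("Z contamination hits the configured share of the whole stream", {
  # 900 non-Z per year, z = round(900*0.1/0.9) = 100 -> Z share exactly 10%
  cfg <- simulation_config(exponential_law(90, 0, n_categories = 10),
                           years = 2015:2016, z_fraction = 0.1)
  adm <- generate_admissions(cfg)
  is_z <- substr(adm$icd10_code, 1, 1) == "Z"
  expect_equal(sum(is_z), 200L)
  expect_equal(mean(is_z), 0.1)
})

test_that("the generator is deterministic given config and seed", {
  cfg <- simulation_config(exponential_law(50, 0.2, 15), noise = "poisson",
                           z_fraction = 0.05, seed = 99L)
  a <- generate_admissions(cfg)
  b <- generate_admissions(cfg)
  expect_identical(a, b)

  cfg2 <- simulation_config(exponential_law(50, 0.2, 15), noise = "poisson",
                            z_fraction = 0.05, seed = 100L)
  expect_false(identical(generate_admissions(cfg2)$icd10_code, a$icd10_code))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(7)
  before <- runif(1)
  set.seed(7)
  invisible(generate_admissions(simulation_config(seed = 3L, noise = "poisson")))
  expect_identical(runif(1), before)
})

test_that("Poisson per-category means converge to the expected counts", {
  law <- exponential_law(200, 0.2, n_categories = 10)
  cfg <- simulation_config(law, years = 1501:2000, z_fraction = 0,
                           noise = "poisson", seed = 11L)
  adm <- generate_admissions(cfg)
  mu <- expected_counts(law)
  codes <- synthetic_icd_codes(10)
  mean_count <- as.numeric(table(factor(adm$icd10_code, levels = codes))) / 500
  rel_err <- abs(mean_count - mu) / mu
  expect_true(all(rel_err[mu >= 10] < 0.05))
})

test_that("noiseless empirical rank order matches ground truth", {
  law <- exponential_law(400, 0.35, n_categories = 12)
  adm <- generate_admissions(simulation_config(law, z_fraction = 0))
  counts <- table(adm$icd10_code)
  expect_equal(names(sort(counts, decreasing = TRUE)), synthetic_icd_codes(12))
})

test_that("per-year factors scale expected counts multiplicatively", {
  cfg <- simulation_config(exponential_law(100, 0, 4), years = 2015:2016,
                           z_fraction = 0, year_factors = c(1, 2))
  adm <- generate_admissions(cfg)
  expect_equal(sum(adm$year == 2015), 400L)
  expect_equal(sum(adm$year == 2016), 800L)
})

test_that("admission CSV round-trips with its metadata sidecar", {
  cfg <- simulation_config(exponential_law(20, 0.1, 5), z_fraction = 0.1,
                           seed = 5L)
  adm <- generate_admissions(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_admissions(adm, path)
  back <- read_admissions(path)
  expect_equal(back$icd10_code, adm$icd10_code)
  expect_equal(back$year, adm$year)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 5L)
  expect_equal(meta$family, "exponential")
})
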