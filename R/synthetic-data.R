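# Synthetic admission-stream generator with a known ground-truth
# rank-frequency law. Every downstream stage (ICD processing, tabulation,
# fitting, vital-few extraction) is testable against this generator without
# access to a hospital registry.

#' Ground-truth rank-frequency law for the synthetic generator
#'
#' Defines the expected annual admission count per diagnosis rank. Two
#' families are supported:
#' * `exponential`: expected count of rank \eqn{r} is
#'   \eqn{b_0 e^{-b_1 r}} (1-based rank), the exponential decay commonly
#'   seen in whole-cohort emergency diagnosis histograms;
#' * `pareto`: the per-category annual frequencies are an exact discrete
#'   Pareto(\eqn{\alpha}, \eqn{k}) rank-size profile,
#'   \eqn{x_r = k (n/r)^{1/\alpha}}, the heavy-tailed alternative. The
#'   smallest category has frequency exactly \eqn{k}, so the minimum-based
#'   estimator \eqn{\hat{k} = \min(x_i)} recovers \eqn{k}.
#'
#' @param family `"exponential"` or `"pareto"`.
#' @param b0 Expected annual count of the rank-1 category (exponential
#'   family). Must be > 0.
#' @param b1 Decay rate per rank, dimensionless (exponential family).
#'   Must be > 0 (use `b1 = 0` only for degenerate flat test profiles).
#' @param alpha Pareto tail exponent, > 0.
#' @param k Minimum annual frequency scale (admissions/year), > 0.
#' @param n_categories Number of distinct diagnosis categories, >= 2.
#' @return An object of class `gt_law`.
#' @examples
#' exponential_law(b0 = 1000, b1 = 0.1, n_categories = 50)
#' pareto_law(alpha = 2, k = 10, n_categories = 40)
#' @export
exponential_law <- function(b0 = 1000, b1 = 0.1, n_categories = 100) {
  check_scalar_num(b0, "b0", positive = TRUE)
  check_scalar_num(b1, "b1", nonneg = TRUE)
  check_n_categories(n_categories)
  structure(list(family = "exponential", b0 = b0, b1 = b1,
                 n_categories = as.integer(n_categories)),
            class = "gt_law")
}

#' @rdname exponential_law
#' @export
pareto_law <- function(alpha = 1, k = 10, n_categories = 100) {
  check_scalar_num(alpha, "alpha", positive = TRUE)
  check_scalar_num(k, "k", positive = TRUE)
  check_n_categories(n_categories)
  structure(list(family = "pareto", alpha = alpha, k = k,
                 n_categories = as.integer(n_categories)),
            class = "gt_law")
}

check_n_categories <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop_config("n_categories", "must be an integer >= 2")
  invisible(n)
}

#' @export
print.gt_law <- function(x, ...) {
  if (x$family == "exponential")
    cat(sprintf("Ground-truth law: exponential decay, b0 = %g, b1 = %g, %d categories\n",
                x$b0, x$b1, x$n_categories))
  else
    cat(sprintf("Ground-truth law: Pareto rank-size, alpha = %g, k = %g, %d categories\n",
                x$alpha, x$k, x$n_categories))
  invisible(x)
}

#' Expected annual admission counts per rank under a ground-truth law
#'
#' @param law A [exponential_law()] or [pareto_law()] object.
#' @return Numeric vector of length `n_categories`, strictly positive and
#'   non-increasing with rank.
#' @examples
#' expected_counts(exponential_law(1000, 0.1, 5))
#' @export
expected_counts <- function(law) {
  if (!inherits(law, "gt_law")) stop_config("law", "must be a gt_law object")
  n <- law$n_categories
  r <- seq_len(n)
  if (law$family == "exponential") {
    law$b0 * exp(-law$b1 * r)
  } else {
    law$k * (n / r)^(1 / law$alpha)
  }
}

#' Simulation configuration for the synthetic admission stream
#'
#' Emulates a multi-year emergency-admission cohort: per-category annual
#' counts follow the ground-truth law, a configurable fraction of the whole
#' stream carries Z-chapter (non-emergency) codes to exercise the exclusion
#' filter, and annual totals can drift through per-year multiplicative
#' factors (emulating a secular increase in admissions).
#'
#' @param law Ground-truth law, see [exponential_law()].
#' @param years Strictly increasing integer vector of calendar years.
#'   Default 2015:2020, a six-year window.
#' @param population Catchment population per year: a single number
#'   (recycled) or a vector named by year. Default 315000 inhabitants.
#' @param z_fraction Proportion in \[0, 1) of the *whole* generated stream
#'   assigned a Z-chapter code. Default 0.027 (roughly the share of
#'   non-emergency Z-coded discharges seen in practice).
#' @param noise `"none"` (deterministic rounded expected counts) or
#'   `"poisson"` (independent Poisson draws with those means).
#' @param year_factors Optional multiplicative factor per year applied to
#'   all expected counts (default 1 for every year).
#' @param seed Integer random seed; the generator is fully deterministic
#'   given the configuration and seed.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(law = exponential_law(),
                              years = 2015:2020,
                              population = 315000,
                              z_fraction = 0.027,
                              noise = c("none", "poisson"),
                              year_factors = NULL,
                              seed = 1L) {
  if (!inherits(law, "gt_law")) stop_config("law", "must be a gt_law object")
  if (length(years) < 1L || any(years != round(years)) || is.unsorted(years, strictly = TRUE))
    stop_config("years", "must be a non-empty strictly increasing integer vector")
  years <- as.integer(years)
  pop <- resolve_populations(population, years)
  if (any(pop <= 0)) stop_config("population", "must be > 0 for every year")
  check_scalar_num(z_fraction, "z_fraction", nonneg = TRUE)
  if (z_fraction >= 1) stop_config("z_fraction", "must be < 1")
  noise <- match.arg(noise)
  if (is.null(year_factors)) year_factors <- rep(1, length(years))
  if (length(year_factors) != length(years) || any(year_factors <= 0))
    stop_config("year_factors", "must be positive, one per year")
  check_scalar_num(seed, "seed")
  structure(list(law = law, years = years, population = pop,
                 z_fraction = z_fraction, noise = noise,
                 year_factors = as.numeric(year_factors),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Normalize a population spec (scalar or year-named vector) to a vector
# named by year.
resolve_populations <- function(population, years) {
  if (length(population) == 1L && is.null(names(population)))
    return(setNames(rep(as.numeric(population), length(years)), years))
  if (!is.null(names(population))) {
    missing <- setdiff(as.character(years), names(population))
    if (length(missing))
      stop_config("population", paste("missing years:", paste(missing, collapse = ", ")))
    return(setNames(as.numeric(population[as.character(years)]), years))
  }
  if (length(population) == length(years))
    return(setNames(as.numeric(population), years))
  stop_config("population", "must be a scalar, a year-named vector, or one value per year")
}

#' Deterministic synthetic ICD-10 category labels
#'
#' Rank `i` maps to a real-format 3-character category: the chapter letter
#' cycles through A..Y (Z is reserved for the contaminating non-emergency
#' codes) and the two-digit part increments each time the alphabet wraps,
#' so labels are unique, lexically valid, and exercise the A/B chapter
#' merge. The scheme is fixed, so identical configurations always yield
#' identical code sets.
#'
#' @param n Number of category labels.
#' @return Character vector of length `n` (e.g. `"A00"`, `"B00"`, ...).
#' @export
synthetic_icd_codes <- function(n) {
  pool <- setdiff(LETTERS, "Z")
  i <- seq_len(n) - 1L
  paste0(pool[i %% length(pool) + 1L], sprintf("%02d", i %/% length(pool)))
}

# Z-chapter codes cycled over the contaminating records; dotted 4-character
# detail codes so truncation is exercised too.
z_code_pool <- function() c("Z03.8", "Z76.5", "Z09.9", "Z47.0", "Z51.1")

#' Generate a synthetic multi-year admission stream
#'
#' For each year, per-category counts are the law's expected counts times
#' the year factor, either rounded half-to-even with a floor of 1
#' (`noise = "none"`, keeping every category present so the category set is
#' stable across runs) or drawn from independent Poisson distributions with
#' those means (`noise = "poisson"`). Z-chapter records are appended so that
#' their share of the whole stream equals `z_fraction`:
#' `round(N_nonZ * z/(1-z))` records per year. Patient ids are synthetic
#' sequential tokens. Identical configuration implies byte-identical output.
#'
#' @param config A [simulation_config()].
#' @return A `data.frame` with columns `patient_id`, `icd10_code`, `year`,
#'   with the configuration attached as attribute `"config"`.
#' @examples
#' adm <- generate_admissions(simulation_config(
#'   exponential_law(10, 0, n_categories = 3),
#'   years = 2015L, z_fraction = 0))
#' nrow(adm)  # 30: 10 per category
#' @export
generate_admissions <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("config", "must be a sim_config object")
  mu <- expected_counts(config$law)
  codes <- synthetic_icd_codes(config$law$n_categories)
  zpool <- z_code_pool()
  zf <- config$z_fraction

  with_seed(config$seed, {
    year_codes <- lapply(seq_along(config$years), function(j) {
      m <- mu * config$year_factors[j]
      counts <- if (config$noise == "none") pmax(1L, as.integer(round(m)))
                else rpois(length(m), m)
      non_z <- rep(codes, counts)
      n_z <- if (zf > 0) as.integer(round(sum(counts) * zf / (1 - zf))) else 0L
      z <- if (n_z > 0) zpool[(seq_len(n_z) - 1L) %% length(zpool) + 1L] else character(0)
      c(non_z, z)
    })
    all_codes <- unlist(year_codes)
    out <- data.frame(
      patient_id = sprintf("P%07d", seq_along(all_codes)),
      icd10_code = all_codes,
      year = rep(config$years, lengths(year_codes)),
      stringsAsFactors = FALSE
    )
    attr(out, "config") <- config
    out
  })
}

#' Write / read an admission stream as CSV
#'
#' The CSV contract is `patient_id,icd10_code,year[,roster]` with a header,
#' UTF-8. `write_admissions()` also writes a JSON sidecar
#' (`<path>.meta.json`) recording the generator seed and configuration when
#' the stream came from [generate_admissions()].
#'
#' @param records Admission `data.frame`.
#' @param path Output CSV path.
#' @return `write_admissions()` returns `path` invisibly;
#'   `read_admissions()` returns the records `data.frame`.
#' @export
write_admissions <- function(records, path) {
  keep <- intersect(c("patient_id", "icd10_code", "year", "roster"), names(records))
  write.csv(records[, keep, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  cfg <- attr(records, "config")
  if (!is.null(cfg)) {
    meta <- list(seed = cfg$seed, family = cfg$law$family,
                 n_categories = cfg$law$n_categories,
                 years = cfg$years, z_fraction = cfg$z_fraction,
                 noise = cfg$noise)
    write_json_file(meta, paste0(path, ".meta.json"))
  }
  invisible(path)
}

#' @rdname write_admissions
#' @export
read_admissions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("patient_id", "icd10_code", "year")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_config("input", paste("CSV missing columns:", paste(missing, collapse = ", ")))
  df$year <- as.integer(df$year)
  df
}
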