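# Per-year frequency tables, per-100k normalization, ranked profiles with
# t-based 95% prediction intervals, and year-to-year rank stability.

#' Tabulate admissions into a category-by-year count table
#'
#' Counts admissions per (diagnosis category, year) for a chosen scope:
#' the whole cohort, one chapter group, or one roster arm. Records are
#' expected to be preprocessed ([preprocess_records()]): parsed, truncated,
#' Z-excluded.
#'
#' @param records Preprocessed admission `data.frame` with `category`,
#'   `chapter_group` and `year` columns (and `roster` for roster scopes).
#' @param population Catchment population: a single number applied to all
#'   years or a vector named by year. Denominator for per-100k rates.
#' @param scope `"all"`, `"chapter:<label>"` (e.g. `"chapter:I"`), or
#'   `"roster:<label>"` (e.g. `"roster:surgical"`).
#' @param years Optional integer vector of years the table must cover
#'   (columns for years with no admissions in scope are kept as zeros);
#'   defaults to the years present in `records`.
#' @return An object of class `yearly_freq_table`: a list with `counts`
#'   (integer matrix, categories x years), `population` (named by year),
#'   `scope`, and `chapter_group` (named by category).
#' @export
tabulate_admissions <- function(records, population = 315000, scope = "all",
                                years = NULL) {
  sub <- filter_scope(records, scope)
  if (is.null(years)) years <- sort(unique(records$year))
  if (length(years) == 0L) stop_config("years", "no years present")
  pop <- resolve_populations(population, years)
  bad_years <- setdiff(unique(sub$year), years)
  if (length(bad_years))
    stop_config("population", paste("record year(s) not covered:",
                                    paste(bad_years, collapse = ", ")))
  cats <- sort(unique(sub$category))
  counts <- table(factor(sub$category, levels = cats),
                  factor(sub$year, levels = years))
  counts <- matrix(as.integer(counts), nrow = length(cats),
                   dimnames = list(cats, years))
  cg <- setNames(chapter_group(cats), cats)
  structure(list(counts = counts, population = pop, scope = scope,
                 chapter_group = cg),
            class = "yearly_freq_table")
}

filter_scope <- function(records, scope) {
  if (identical(scope, "all")) return(records)
  if (grepl("^chapter:", scope)) {
    lab <- sub("^chapter:", "", scope)
    return(records[records$chapter_group == lab, , drop = FALSE])
  }
  if (grepl("^roster:", scope)) {
    if (is.null(records$roster))
      stop_config("scope", "roster scope requested but records have no roster column")
    lab <- sub("^roster:", "", scope)
    return(records[records$roster == lab, , drop = FALSE])
  }
  stop_config("scope", "must be 'all', 'chapter:<label>' or 'roster:<label>'")
}

#' @export
print.yearly_freq_table <- function(x, ...) {
  cat(sprintf("Yearly frequency table [%s]: %d categories x %d years, %d admissions\n",
              x$scope, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Normalize a count to a rate per 100,000 inhabitants
#'
#' @param count Admission count(s).
#' @param population Catchment population (> 0).
#' @return `count * 100000 / population`.
#' @examples
#' normalize_per_100k(315, 315000)  # 100
#' @export
normalize_per_100k <- function(count, population) {
  if (any(!is.finite(population)) || any(population <= 0))
    stop_config("population", "must be > 0")
  count * 1e5 / population
}

#' Two-sided t prediction interval for one future annual value
#'
#' Given the observed annual values of one diagnosis category, computes the
#' frequentist prediction interval for a single future year's value:
#' \deqn{\bar{x} \pm t_{1-(1-level)/2,\,n-1}\; s \sqrt{1 + 1/n}}
#' where \eqn{s} is the sample standard deviation. The lower bound may be
#' clipped at 0, since frequencies are non-negative.
#'
#' @param values Numeric vector of per-year values (length >= 2).
#' @param level Coverage level, default 0.95.
#' @param clip Clip the lower bound at 0 (default `TRUE`).
#' @return Named numeric vector `c(lower, upper)`; always contains the mean.
#' @examples
#' prediction_interval(c(8, 10, 12), clip = FALSE)  # approx (0.064, 19.936)
#' @export
prediction_interval <- function(values, level = 0.95, clip = TRUE) {
  n <- length(values)
  if (n < 2L) stop("prediction interval undefined for fewer than 2 values", call. = FALSE)
  if (level <= 0 || level >= 1) stop_config("level", "must be in (0, 1)")
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) * sqrt(1 + 1 / n)
  lower <- m - half
  if (clip) lower <- max(0, lower)
  c(lower = lower, upper = m + half)
}

#' Rank diagnosis categories by mean normalized frequency
#'
#' Builds the ranked rank-frequency profile: one global order by the
#' across-year mean of per-100k normalized frequencies (ties broken
#' lexicographically by category code), each entry carrying its 95%
#' prediction interval. Optionally truncates the display to the smallest
#' top-rank prefix whose cumulative share of mean admissions reaches
#' `coverage_truncation` (e.g. 0.8 drops the long tail of rare diagnoses).
#'
#' @param table A [tabulate_admissions()] result.
#' @param coverage_truncation Fraction in (0, 1]; 1 keeps all categories.
#' @param scale `"per100k"` (default) computes means and prediction
#'   intervals on normalized rates; `"count"` on raw counts.
#' @param level Prediction-interval level, default 0.95.
#' @return A `ranked_profile`: a `data.frame` with columns `category`,
#'   `chapter_group`, `rank`, `mean_per_100k`, `pi_lower`, `pi_upper`,
#'   `mean_count`, with attributes `n_years`, `coverage_truncation`,
#'   `scale` and `total_mean_count` (pre-truncation).
#' @export
rank_by_mean <- function(table, coverage_truncation = 1, scale = c("per100k", "count"),
                         level = 0.95) {
  stopifnot(inherits(table, "yearly_freq_table"))
  scale <- match.arg(scale)
  if (coverage_truncation <= 0 || coverage_truncation > 1)
    stop_config("coverage_truncation", "must be in (0, 1]")
  if (nrow(table$counts) == 0L) stop("empty frequency table", call. = FALSE)
  counts <- table$counts
  rates <- sweep(counts, 2L, table$population, function(cnt, pop) normalize_per_100k(cnt, pop))
  display <- if (scale == "per100k") rates else counts
  mean_disp <- rowMeans(display)
  mean_count <- rowMeans(counts)
  n_years <- ncol(counts)
  pis <- if (n_years >= 2L) t(apply(display, 1L, prediction_interval, level = level))
         else cbind(lower = mean_disp, upper = mean_disp)

  ord <- order(-mean_disp, rownames(counts))
  prof <- data.frame(
    category = rownames(counts)[ord],
    chapter_group = unname(table$chapter_group[rownames(counts)[ord]]),
    rank = seq_along(ord),
    mean_per_100k = unname(if (scale == "per100k") mean_disp[ord]
                           else normalize_per_100k(mean_count[ord], mean(table$population))),
    pi_lower = unname(pis[ord, 1L]),
    pi_upper = unname(pis[ord, 2L]),
    mean_count = unname(mean_count[ord]),
    stringsAsFactors = FALSE
  )
  total <- sum(prof$mean_count)
  if (coverage_truncation < 1) {
    share <- cumsum(prof$mean_count) / total
    keep <- seq_len(match(TRUE, share >= coverage_truncation, nomatch = nrow(prof)))
    prof <- prof[keep, , drop = FALSE]
  }
  structure(prof,
            n_years = n_years,
            coverage_truncation = coverage_truncation,
            scale = scale,
            total_mean_count = total,
            scope = table$scope,
            class = c("ranked_profile", "data.frame"))
}

#' Year-to-year stability of the diagnosis rank order
#'
#' Spearman rank correlation of per-category counts between every pair of
#' years — a quantitative check that the diagnosis mix is reproducible
#' across years rather than randomly variable.
#'
#' @param table A [tabulate_admissions()] result with >= 2 years.
#' @return A list with `pairs` (data.frame: year_a, year_b, spearman),
#'   `min` and `mean` across pairs.
#' @export
rank_stability <- function(table) {
  stopifnot(inherits(table, "yearly_freq_table"))
  yrs <- colnames(table$counts)
  if (length(yrs) < 2L) stop("rank stability needs at least 2 years", call. = FALSE)
  combs <- utils::combn(seq_along(yrs), 2L)
  rho <- apply(combs, 2L, function(ij)
    cor(table$counts[, ij[1L]], table$counts[, ij[2L]], method = "spearman"))
  list(pairs = data.frame(year_a = yrs[combs[1L, ]], year_b = yrs[combs[2L, ]],
                          spearman = rho, stringsAsFactors = FALSE),
       min = min(rho), mean = mean(rho))
}
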