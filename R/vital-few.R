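# Cumulative coverage curves and "vital few" extraction: the minimal set of
# most frequent diagnoses covering a target share (80/20 analysis) of the
# admission load, the basis of duty-roster competence lists.

#' Cumulative coverage curve of a ranked profile
#'
#' Share of total admissions covered by the top-r diagnosis categories, for
#' every rank r. Exact rational shares: share at rank r is the sum of the
#' top-r mean counts divided by the total; the last share is 1.
#'
#' @param profile A [rank_by_mean()] profile (untruncated, or accept that
#'   shares are relative to the truncated display), or a numeric count
#'   vector in rank order.
#' @return A `cumulative_profile` `data.frame` with columns `rank`,
#'   `category`, `count`, `share`, `cumulative_share` and attribute
#'   `total`.
#' @examples
#' cc <- cumulative_curve(c(10, 5, 3, 2))
#' cc$cumulative_share  # 0.50 0.75 0.90 1.00
#' @export
cumulative_curve <- function(profile) {
  if (inherits(profile, "ranked_profile")) {
    counts <- profile$mean_count
    cats <- profile$category
  } else {
    counts <- sort(as.numeric(profile), decreasing = TRUE)
    cats <- sprintf("rank%03d", seq_along(counts))
  }
  total <- sum(counts)
  if (length(counts) == 0L || total <= 0)
    stop("empty scope: no admissions to accumulate", call. = FALSE)
  out <- data.frame(rank = seq_along(counts), category = cats, count = counts,
                    share = counts / total,
                    cumulative_share = cumsum(counts) / total,
                    stringsAsFactors = FALSE)
  structure(out, total = total, class = c("cumulative_profile", "data.frame"))
}

#' Extract the "vital few" diagnosis set at a coverage threshold
#'
#' The minimal top-rank prefix whose cumulative share of admissions reaches
#' the threshold (default 0.8, the 80/20 rule). The report also carries the
#' share covered by the ten most frequent categories and whether that share
#' reaches 80% — the community-diagnosis criterion that the ten most common
#' conditions cover more than 80% of the case load.
#'
#' @param curve A [cumulative_curve()] result.
#' @param threshold Coverage fraction in (0, 1], default 0.8. Attainment
#'   uses `>=`: the category whose cumulative share first reaches the
#'   threshold is included.
#' @return A `vital_few_report` list: `threshold`, `categories` (character
#'   vector, the competence list), `n_vital`, `coverage` (achieved share),
#'   `top10_share`, `pareto_principle_met` (`top10_share >= 0.8`).
#' @examples
#' vf <- vital_few_set(cumulative_curve(c(10, 5, 3, 2)), threshold = 0.8)
#' vf$n_vital  # 3
#' @export
vital_few_set <- function(curve, threshold = 0.8) {
  stopifnot(inherits(curve, "cumulative_profile"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  idx <- match(TRUE, curve$cumulative_share >= threshold - 1e-12,
               nomatch = nrow(curve))
  t10 <- top_k_share(curve, 10L)
  structure(list(threshold = threshold,
                 categories = curve$category[seq_len(idx)],
                 n_vital = idx,
                 coverage = curve$cumulative_share[idx],
                 top10_share = t10,
                 pareto_principle_met = t10 >= 0.8),
            class = "vital_few_report")
}

#' Share of admissions covered by the top k categories
#'
#' @param curve A [cumulative_curve()] result.
#' @param k Number of top categories (>= 1); `k >= n` gives 1.
#' @return Fraction in (0, 1].
#' @examples
#' top_k_share(cumulative_curve(c(10, 5, 3, 2)), k = 2)  # 0.75
#' @export
top_k_share <- function(curve, k = 10L) {
  stopifnot(inherits(curve, "cumulative_profile"))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be >= 1", call. = FALSE)
  curve$cumulative_share[min(as.integer(k), nrow(curve))]
}

#' @export
print.vital_few_report <- function(x, ...) {
  cat(sprintf("Vital few at %.0f%% coverage: %d categories (achieved %.1f%%)\n",
              100 * x$threshold, x$n_vital, 100 * x$coverage))
  cat(sprintf("Top-10 share: %.1f%%%s\n", 100 * x$top10_share,
              if (x$pareto_principle_met) " (>= 80%: community-diagnosis criterion met)"
              else " (< 80%)"))
  invisible(x)
}
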