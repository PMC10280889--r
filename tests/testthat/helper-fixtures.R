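# Shared fixture builders. Everything is generated in code; no stored data
# beyond the small handwritten CSV under inst/extdata.

# Admission records data.frame from parallel vectors.
make_records <- function(codes, years, ids = NULL) {
  data.frame(
    patient_id = ids %||% sprintf("T%04d", seq_along(codes)),
    icd10_code = codes,
    year = as.integer(years),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A yearly_freq_table built from explicit per-year counts: `counts` is a
# category x year matrix (dimnames required).
make_table <- function(counts, population = 100000, scope = "all") {
  records <- do.call(rbind, lapply(colnames(counts), function(y) {
    n <- counts[, y]
    make_records(rep(rownames(counts), n), rep(as.integer(y), sum(n)))
  }))
  pre <- preprocess_records(records)
  tabulate_admissions(pre$records, population = population, scope = scope,
                      years = as.integer(colnames(counts)))
}

# Inverse-CDF sampler for Pareto(alpha, k) — the independent draw generator
# used by the MLE oracles.
rpareto <- function(n, alpha, k) k * runif(n)^(-1 / alpha)

# Pareto log-likelihood in alpha, with the threshold fixed at min(x); used
# as the numerical-maximization oracle for the closed-form estimator.
pareto_loglik_alpha <- function(alpha, x) {
  k <- min(x)
  length(x) * log(alpha) + length(x) * alpha * log(k) - (alpha + 1) * sum(log(x))
}
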