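# Competing models for the rank-frequency profile: exponential decay fitted
# by nonlinear least squares on frequency-vs-rank, and a Pareto (power-law)
# density fitted by closed-form maximum likelihood on the frequency values.

#' Fit an exponential decay to a ranked profile
#'
#' Nonlinear least squares of \eqn{f(x) = b_0 e^{-b_1 x}} against mean
#' frequency versus 1-based rank \eqn{x}, via Levenberg-Marquardt with
#' \eqn{b_1} bounded below at 0. Default initial values are
#' \eqn{b_0 = 1000}, \eqn{b_1 = 0.1}.
#'
#' @param profile A [rank_by_mean()] profile (>= 3 entries with positive
#'   frequencies), or a bare numeric vector of frequencies in rank order.
#' @param init Named initial values `c(b0 = ..., b1 = ...)`.
#' @param scale Which profile column to fit: `"per100k"` (default, the
#'   displayed scale) or `"count"`.
#' @param weights `"none"` (default) for ordinary least squares, or
#'   `"poisson"` for iteratively reweighted least squares with weights
#'   `1/fitted` — the variance-correct scheme when the frequencies are
#'   Poisson counts, giving calibrated standard errors.
#' @return An `exponential_fit` list: `b0`, `b1`, `sse`, `converged`,
#'   `se` (least-squares standard errors), `init`, `n`, `scale`, `control`
#'   (optimizer tolerances), `fitted`.
#' @examples
#' y <- 1000 * exp(-0.1 * (1:50))
#' fit_exponential(y)
#' @export
fit_exponential <- function(profile, init = c(b0 = 1000, b1 = 0.1),
                            scale = c("per100k", "count"),
                            weights = c("none", "poisson")) {
  scale <- match.arg(scale)
  weights <- match.arg(weights)
  y <- profile_values(profile, scale)
  if (any(y < 0)) stop("exponential fit needs non-negative frequencies", call. = FALSE)
  if (sum(y > 0) < 3L)
    stop("exponential fit needs at least 3 positive frequencies", call. = FALSE)
  x <- seq_along(y)
  if (sd(y) == 0) {
    # perfectly flat profile: zero decay, amplitude = the common value
    return(structure(list(b0 = y[1], b1 = 0, sse = 0, converged = TRUE,
                          se = c(b0 = 0, b1 = 0), init = init, n = length(y),
                          scale = scale,
                          control = list(ftol = 1e-8, ptol = 1e-8, maxfev = 10000),
                          fitted = y),
                     class = "exponential_fit"))
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8, maxiter = 1024,
                                     maxfev = 10000)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch({
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ b0 * exp(-b1 * x), data = dat,
                        start = as.list(init),
                        lower = c(b0 = 0, b1 = 0), control = ctrl),
      error = function(e) {
        # retry from a log-linear least-squares start on the positive part
        pos <- y > 0
        ll <- stats::lm(log(y[pos]) ~ x[pos])
        start2 <- list(b0 = exp(unname(coef(ll)[1])),
                       b1 = max(0, -unname(coef(ll)[2])))
        minpack.lm::nlsLM(y ~ b0 * exp(-b1 * x), data = dat, start = start2,
                          lower = c(b0 = 0, b1 = 0), control = ctrl)
      })
    if (weights == "poisson") {
      for (i in 1:3) {
        w <- 1 / pmax(fitted(f), 1e-8)
        f <- minpack.lm::nlsLM(y ~ b0 * exp(-b1 * x), data = dat,
                               start = as.list(coef(f)), weights = w,
                               lower = c(b0 = 0, b1 = 0), control = ctrl)
      }
    }
    f
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(b0 = NA_real_, b1 = NA_real_, sse = NA_real_,
                          converged = FALSE, se = c(b0 = NA_real_, b1 = NA_real_),
                          init = init, n = length(y), scale = scale,
                          control = list(ftol = 1e-8, ptol = 1e-8, maxfev = 10000),
                          fitted = rep(NA_real_, length(y)),
                          message = conditionMessage(fit)),
                     class = "exponential_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(b0 = NA_real_, b1 = NA_real_))
  structure(list(b0 = unname(cf["b0"]), b1 = unname(cf["b1"]),
                 sse = sum((y - fitted(fit))^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 se = se, init = init, n = length(y), scale = scale,
                 control = list(ftol = 1e-8, ptol = 1e-8, maxfev = 10000),
                 fitted = unname(fitted(fit))),
            class = "exponential_fit")
}

profile_values <- function(profile, scale = "per100k") {
  if (inherits(profile, "ranked_profile"))
    return(if (scale == "per100k") profile$mean_per_100k else profile$mean_count)
  as.numeric(profile)
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit: b0 = %.6g, b1 = %.6g (SSE %.6g, %s, scale %s)\n",
              x$b0, x$b1, x$sse, if (x$converged) "converged" else "NOT converged",
              x$scale))
  invisible(x)
}

#' Pareto power-law density
#'
#' \deqn{f(x \mid \alpha, k, C) = C\,\alpha k^\alpha / x^{\alpha+1},\quad
#'   k \le x < \infty;\ \alpha, k > 0,} and 0 below the support (`x < k`).
#'
#' @param x Evaluation points.
#' @param alpha Tail exponent (> 0).
#' @param k Minimum scale (> 0).
#' @param C Scale constant (default 1 gives the normalized density).
#' @return Density values.
#' @examples
#' pareto_density(2, alpha = 2, k = 1)  # 0.25
#' @export
pareto_density <- function(x, alpha, k, C = 1) {
  check_scalar_num(alpha, "alpha", positive = TRUE)
  check_scalar_num(k, "k", positive = TRUE)
  ifelse(x < k, 0, C * alpha * k^alpha / x^(alpha + 1))
}

#' Closed-form maximum-likelihood Pareto fit
#'
#' For sample frequencies \eqn{x_i} (\eqn{i = 1..n}), the minimum-based
#' threshold is \eqn{\hat{k} = \min(x_i)} — the data can never lie below the
#' support — and the tail exponent has the closed MLE form
#' \deqn{\hat\alpha = n \Big/ \sum_{i=1}^n \log(x_i / \hat{k}).}
#' The scale constant \eqn{C} is chosen so that the fitted rank-size curve
#' \eqn{\hat{k}(n/r)^{1/\hat\alpha}} sums to the observed total over the
#' observed support, which lets the fit be overlaid on the rank axis.
#'
#' @param x Positive frequency sample, length >= 2.
#' @return A `pareto_fit` list: `alpha_hat`, `k_hat`, `C`, `loglik`, `n`,
#'   `fitted` (rank-size curve on ranks 1..n).
#' @examples
#' pareto_mle(c(1, exp(1), exp(2)))  # alpha_hat = 1
#' @export
pareto_mle <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("Pareto MLE needs at least 2 values", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("Pareto MLE needs positive finite frequencies", call. = FALSE)
  k_hat <- min(x)
  slog <- sum(log(x / k_hat))
  if (slog == 0)
    stop("degenerate sample: all values equal, Pareto exponent undefined", call. = FALSE)
  alpha_hat <- n / slog
  loglik <- n * log(alpha_hat) + n * alpha_hat * log(k_hat) -
    (alpha_hat + 1) * sum(log(x))
  fitted <- pareto_rank_curve(alpha_hat, k_hat, n)
  C <- sum(sort(x, decreasing = TRUE)) / sum(fitted)
  structure(list(alpha_hat = alpha_hat, k_hat = k_hat, C = C,
                 loglik = loglik, n = n, fitted = C * fitted),
            class = "pareto_fit")
}

# Rank-size curve of a Pareto(alpha, k) sample of size n: expected frequency
# at rank r via the quantile mapping x_r = k * (n/r)^(1/alpha).
pareto_rank_curve <- function(alpha, k, n) {
  k * (n / seq_len(n))^(1 / alpha)
}

#' @export
print.pareto_fit <- function(x, ...) {
  cat(sprintf("Pareto MLE fit: alpha = %.6g, k = %.6g, C = %.6g (loglik %.6g, n = %d)\n",
              x$alpha_hat, x$k_hat, x$C, x$loglik, x$n))
  invisible(x)
}

#' Compare the exponential and Pareto fits on a ranked profile
#'
#' Both fitted curves are evaluated on the profile's 1-based rank grid (the
#' Pareto fit via its rank-size curve scaled by `C`) and scored by residual
#' sum of squares (`criterion = "sse"`, default) or by Gaussian-error AIC
#' (`criterion = "aic"`; both models carry 2 counted parameters — b0, b1
#' for the exponential; the tail exponent plus the scale constant for the
#' Pareto, whose threshold is the sample minimum, an order statistic).
#' Lower score wins; an exact tie prefers the exponential with a note.
#'
#' @param profile Ranked profile (or numeric frequency vector in rank
#'   order) on which both fits were produced.
#' @param exp_fit An [fit_exponential()] result.
#' @param pareto_fit A [pareto_mle()] result.
#' @param criterion `"sse"` or `"aic"`.
#' @param scale Profile column both fits used; must match `exp_fit$scale`.
#' @return A `model_comparison` list: `preferred`, `criterion`,
#'   `exponential_score`, `pareto_score`, `n_params`, `note`.
#' @export
compare_models <- function(profile, exp_fit, pareto_fit, criterion = c("sse", "aic"),
                           scale = c("per100k", "count")) {
  criterion <- match.arg(criterion)
  scale <- match.arg(scale)
  stopifnot(inherits(exp_fit, "exponential_fit"), inherits(pareto_fit, "pareto_fit"))
  if (!identical(exp_fit$scale, scale))
    stop("scale mismatch: exponential fit was produced on scale '", exp_fit$scale,
         "' but comparison requested '", scale, "'", call. = FALSE)
  y <- sort(profile_values(profile, scale), decreasing = TRUE)
  n <- length(y)
  if (pareto_fit$n != n || exp_fit$n != n)
    stop("fits and profile disagree on the number of ranks", call. = FALSE)
  r <- seq_len(n)
  exp_curve <- exp_fit$b0 * exp(-exp_fit$b1 * r)
  par_curve <- pareto_fit$C * pareto_rank_curve(pareto_fit$alpha_hat, pareto_fit$k_hat, n)
  sse_exp <- sum((y - exp_curve)^2)
  sse_par <- sum((y - par_curve)^2)
  n_params <- c(exponential = 2L, pareto = 2L)
  if (criterion == "sse") {
    score_exp <- sse_exp
    score_par <- sse_par
  } else {
    score_exp <- n * log(sse_exp / n) + 2 * n_params[["exponential"]]
    score_par <- n * log(sse_par / n) + 2 * n_params[["pareto"]]
  }
  note <- NULL
  if (score_exp == score_par) note <- "exact tie; exponential preferred by convention"
  structure(list(preferred = if (score_exp <= score_par) "exponential" else "pareto",
                 criterion = criterion,
                 exponential_score = score_exp, pareto_score = score_par,
                 n_params = n_params, note = note),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%s): exponential %.6g vs pareto %.6g -> %s preferred\n",
              x$criterion, x$exponential_score, x$pareto_score, x$preferred))
  if (!is.null(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}
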