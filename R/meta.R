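#' Per-period estimates feeding the meta-analysis
#'
#' A small data frame holding, for each observation period, the
#' weighted-kappa estimate and its variance.  This is the input to the
#' pooling functions [pool_fixed()], [pool_random()] and
#' [pool_average()].
#'
#' @param period Period identifiers.
#' @param kappa Per-period weighted-kappa estimates.
#' @param v Per-period variances (squared standard errors), all >= 0.
#' @param n Optional per-period numbers of interactions.
#' @return A data frame of class `"period_estimates"` with columns
#'   `period`, `kappa`, `v`, `n`.
#' @export
period_estimates <- function(period, kappa, v, n = NA_integer_) {
  stopifnot(length(kappa) == length(period), length(v) == length(kappa))
  if (any(v < 0)) stop("variances must be non-negative", call. = FALSE)
  out <- data.frame(period = period, kappa = as.numeric(kappa),
                    v = as.numeric(v), n = n)
  class(out) <- c("period_estimates", "data.frame")
  out
}

check_pool_input <- function(est, min_g = 2L) {
  if (!is.data.frame(est) || !all(c("kappa", "v") %in% names(est)))
    stop("estimates must be a data frame with columns 'kappa' and 'v'",
         call. = FALSE)
  g <- nrow(est)
  if (g < min_g)
    stop("pooling needs at least ", min_g, " observation periods (got ", g,
         "); periods with undefined kappa must be excluded upstream",
         call. = FALSE)
  if (min_g >= 2L && any(est$v <= 0))
    stop("zero-variance period(s): ",
         paste(est$period[est$v <= 0], collapse = ", "),
         "; inverse-variance pooling requires V_wm > 0 (exclude upstream ",
         "with a logged warning)", call. = FALSE)
  est
}

pool_result <- function(method, estimate, se, alpha, weights = NULL,
                        chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                        tau2 = NA_real_, tau2_truncated = FALSE, g = NA_integer_) {
  ci <- wald_ci(estimate, se, alpha, clip = FALSE)
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = max(ci[1], -1), ci_high = min(ci[2], 1),
                 ci_unclipped = ci, alpha = alpha, g = g,
                 chi2_het = chi2, df = df, het_p = p,
                 tau2 = tau2, tau2_truncated = tau2_truncated,
                 meta_weights = weights),
            class = "kappa_pool")
}

#' Pool per-period kappa estimates
#'
#' Combines \eqn{g \ge 2} observation-period estimates
#' \eqn{\hat\kappa_{wm}} with variances \eqn{V_{wm}} into one summary.
#'
#' `pool_fixed()` is the inverse-variance fixed-effects estimate: with
#' weights \eqn{\omega_m = 1/V_{wm}},
#' \deqn{\hat\kappa_{w\,fixed} = \sum_m \omega_m \hat\kappa_{wm} /
#'       \sum_m \omega_m, \qquad
#'       SE = \sqrt{1/\sum_m \omega_m}.}
#' It assumes a single common true kappa across periods; equality is
#' tested by [heterogeneity()].
#'
#' `pool_random()` allows the true kappa to vary across periods with
#' variance \eqn{\tau^2}, estimated by the DerSimonian-Laird moment
#' estimator (see [dl_tau2()]) unless supplied via `tau2`.  Weights are
#' \eqn{\Omega_m = 1/(V_{wm} + \tau^2)}; the pooled value estimates the
#' mean of the distribution of kappa across periods.  With
#' \eqn{\tau^2 = 0} it coincides with the fixed-effects estimate; as
#' \eqn{\tau^2 \to \infty} it tends to the simple average.
#'
#' `pool_average()` is the simple average \eqn{\sum_m \hat\kappa_{wm}/g}
#' with \eqn{SE = \sqrt{\sum_m V_{wm}/g^2}}.  It ignores period
#' precision and so over-weights sparse periods.
#'
#' @param est A `"period_estimates"` data frame (columns `kappa`, `v`).
#' @param alpha Confidence level parameter in (0, 1).
#' @param tau2 For `pool_random()`: between-period variance; `NULL`
#'   (default) estimates it by DerSimonian-Laird.
#' @return An object of class `"kappa_pool"`: method tag, estimate,
#'   `se`, clipped CI, heterogeneity `chi2_het`/`df`/`het_p`, `tau2`
#'   (random effects), and per-period `meta_weights` in percent.
#' @examples
#' est <- period_estimates(1:2, c(0.5, 0.7), c(0.01, 0.01))
#' pool_fixed(est)
#' pool_random(est)
#' @export
pool_fixed <- function(est, alpha = 0.05) {
  est <- check_pool_input(est)
  w <- 1 / est$v
  estimate <- sum(w * est$kappa) / sum(w)
  se <- sqrt(1 / sum(w))
  het <- heterogeneity(est)
  pool_result("fixed", estimate, se, alpha,
              weights = stats::setNames(100 * w / sum(w), est$period),
              chi2 = het$chi2, df = het$df, p = het$p, g = nrow(est))
}

#' @rdname pool_fixed
#' @export
pool_random <- function(est, alpha = 0.05, tau2 = NULL) {
  est <- check_pool_input(est)
  truncated <- FALSE
  if (is.null(tau2)) {
    tau2 <- dl_tau2(est)
    truncated <- attr(tau2, "truncated")
    tau2 <- as.numeric(tau2)
  }
  W <- 1 / (est$v + tau2)
  estimate <- sum(W * est$kappa) / sum(W)
  se <- sqrt(1 / sum(W))
  het <- heterogeneity(est)
  pool_result("random", estimate, se, alpha,
              weights = stats::setNames(100 * W / sum(W), est$period),
              chi2 = het$chi2, df = het$df, p = het$p,
              tau2 = tau2, tau2_truncated = truncated, g = nrow(est))
}

#' @rdname pool_fixed
#' @export
pool_average <- function(est, alpha = 0.05) {
  est <- check_pool_input(est, min_g = 1L)
  g <- nrow(est)
  estimate <- mean(est$kappa)
  se <- sqrt(sum(est$v) / g^2)
  het <- if (g >= 2 && all(est$v > 0)) heterogeneity(est)
         else list(chi2 = NA_real_, df = NA_integer_, p = NA_real_)
  pool_result("averaged", estimate, se, alpha,
              weights = stats::setNames(rep(100 / g, g), est$period),
              chi2 = het$chi2, df = het$df, p = het$p, g = g)
}

#' Heterogeneity of per-period estimates
#'
#' Cochran's chi-square test of equality of the g underlying
#' period-specific kappas:
#' \deqn{\chi^2 = \sum_m \omega_m (\hat\kappa_{wm} -
#'       \hat\kappa_{w\,fixed})^2, \quad \omega_m = 1/V_{wm},}
#' referred to the chi-square distribution with g - 1 degrees of
#' freedom; equality is conventionally rejected when the statistic
#' exceeds the 0.95 percentile.
#'
#' @inheritParams pool_fixed
#' @return A list with `chi2`, `df`, `p` (upper-tail p-value).
#' @export
heterogeneity <- function(est) {
  est <- check_pool_input(est)
  w <- 1 / est$v
  fixed <- sum(w * est$kappa) / sum(w)
  chi2 <- sum(w * (est$kappa - fixed)^2)
  df <- nrow(est) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' DerSimonian-Laird between-period variance
#'
#' Moment estimator of the between-period variance \eqn{\tau^2}:
#' \deqn{\hat\tau^2 = \frac{\chi^2_{het} - (g - 1)}
#'   {\sum_m \omega_m - (\sum_m \omega_m^2)/(\sum_m \omega_m)},}
#' truncated at 0 when the heterogeneity statistic falls below its
#' degrees of freedom.
#'
#' @inheritParams pool_fixed
#' @return The estimate \eqn{\hat\tau^2 \ge 0}, with attribute
#'   `"truncated"` indicating whether truncation at 0 was applied.
#' @examples
#' dl_tau2(period_estimates(1:2, c(0.5, 0.7), c(0.01, 0.01)))
#' @export
dl_tau2 <- function(est) {
  est <- check_pool_input(est)
  w <- 1 / est$v
  het <- heterogeneity(est)
  num <- het$chi2 - het$df
  den <- sum(w) - sum(w^2) / sum(w)
  tau2 <- num / den
  truncated <- tau2 < 0
  structure(max(tau2, 0), truncated = truncated)
}

#' @export
print.kappa_pool <- function(x, digits = 2, ...) {
  lvl <- 100 * (1 - x$alpha)
  cat(sprintf("Pooled weighted kappa (%s effects%s): %s (%g%% CI %s to %s)\n",
              x$method,
              if (x$method == "averaged") ", simple average" else "",
              fmt2(x$estimate, digits), lvl,
              fmt2(x$ci_low, digits), fmt2(x$ci_high, digits)))
  if (!is.na(x$chi2_het))
    cat(sprintf("  heterogeneity chi-square = %.2f on %d df (p = %.4g)\n",
                x$chi2_het, x$df, x$het_p))
  if (x$method == "random")
    cat(sprintf("  tau^2 (DerSimonian-Laird) = %.4f%s\n", x$tau2,
                if (isTRUE(x$tau2_truncated)) " (truncated at 0)" else ""))
  invisible(x)
}
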