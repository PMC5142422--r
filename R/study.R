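#' Fit a pooled inter-rater reliability analysis
#'
#' The central fitting function of the package.  Takes paired ratings
#' grouped into observation periods, cross-tabulates each period,
#' computes the per-period weighted kappa with its Fleiss standard
#' error, and combines the periods into overall summaries by all four
#' strategies: collapsing the tables into one, inverse-variance
#' fixed-effects pooling, DerSimonian-Laird random-effects pooling, and
#' simple averaging.
#'
#' Periods whose kappa or standard error is undefined (no jointly
#' observed interactions, or all probability mass in full-agreement
#' cells so that expected weighted agreement is 1, or zero estimated
#' variance) are excluded from the inverse-variance and averaged
#' pooling with a warning, but their counts still enter the collapsed
#' table.  Pooling requires at least two usable periods; with fewer,
#' the pooled components are `NULL` and only the collapsed estimate is
#' reported.
#'
#' @param data Data frame with columns `period`, `rater1`, `rater2`,
#'   one row per jointly observed interaction (the CSV dialect read by
#'   [read_pairs()]).
#' @param scheme Weighting-scheme name (see [scheme_names()]) or a
#'   `"kappa_weights"` matrix.
#' @param alpha Confidence level parameter in (0, 1).
#' @param scale Category scale of the ratings.
#' @return An object of class `"kappa_study"` with components:
#'   \describe{
#'     \item{periods}{data frame of per-period results: `period`, `n`,
#'       `kappa`, `se`, `v`, `used`, `reason`.}
#'     \item{tables}{named list of per-period cross-tabulations.}
#'     \item{collapsed}{`"kappa_estimate"` on the collapsed table.}
#'     \item{fixed, random, averaged}{`"kappa_pool"` objects (or
#'       `NULL` when fewer than two usable periods).}
#'     \item{scheme, alpha, scale}{the analysis settings.}
#'   }
#' @seealso [weighted_kappa()], [pool_fixed()], [forest_data()],
#'   [write_report()]
#' @examples
#' sim <- simulate_study(g = 6, n_m = 30, kappa_mean = 0.6, tau = 0.1,
#'                       seed = 1)
#' fit <- kappa_study(sim$data, scheme = "A4")
#' fit
#' coef(fit)
#' @export
kappa_study <- function(data, scheme = "A4", alpha = 0.05,
                        scale = quis_scale()) {
  scale <- category_scale(scale)
  req <- c("period", "rater1", "rater2")
  if (!is.data.frame(data) || !all(req %in% names(data)))
    stop("'data' must be a data frame with columns period, rater1, rater2",
         call. = FALSE)
  if (!nrow(data)) stop("empty study: no interactions", call. = FALSE)
  W <- resolve_weights(scheme, scale)
  periods <- unique(data$period)
  tables <- lapply(periods, function(pd) {
    rows <- data$period == pd
    tabulate_pairs(data$rater1[rows], data$rater2[rows], scale)
  })
  names(tables) <- as.character(periods)

  per <- data.frame(period = periods, n = vapply(tables, sum, 0L),
                    kappa = NA_real_, se = NA_real_, v = NA_real_,
                    used = FALSE, reason = "", stringsAsFactors = FALSE)
  ests <- vector("list", length(periods))
  for (i in seq_along(tables)) {
    e <- tryCatch(weighted_kappa(tables[[i]], W, alpha),
                  error = function(err) conditionMessage(err))
    if (is.character(e)) {
      per$reason[i] <- e
    } else {
      ests[[i]] <- e
      per$kappa[i] <- e$kappa
      per$se[i] <- e$se
      per$v[i] <- e$se^2
      if (e$se > 0) per$used[i] <- TRUE
      else per$reason[i] <- "zero estimated variance"
    }
  }
  if (any(!per$used))
    warning("excluded from pooling: ",
            paste(sprintf("period %s (%s)", per$period[!per$used],
                          per$reason[!per$used]), collapse = "; "),
            call. = FALSE)

  collapsed <- weighted_kappa(collapse_tables(tables), W, alpha)
  est <- period_estimates(per$period[per$used], per$kappa[per$used],
                          per$v[per$used], per$n[per$used])
  fixed <- random <- averaged <- NULL
  if (nrow(est) >= 2L) {
    fixed <- pool_fixed(est, alpha)
    random <- pool_random(est, alpha)
    averaged <- pool_average(est, alpha)
  }
  structure(list(periods = per, tables = tables, estimates = ests,
                 collapsed = collapsed, fixed = fixed, random = random,
                 averaged = averaged, scheme = W, alpha = alpha,
                 scale = scale),
            class = "kappa_study")
}

#' @export
print.kappa_study <- function(x, digits = 2, ...) {
  g <- sum(x$periods$used)
  cat(sprintf("Inter-rater reliability study: %d period(s), %d interactions, scheme %s\n",
              nrow(x$periods), sum(x$periods$n),
              attr(x$scheme, "scheme") %||% "custom"))
  cat(sprintf("  collapsed: %s (%s to %s)\n", fmt2(x$collapsed$kappa, digits),
              fmt2(x$collapsed$ci_low, digits), fmt2(x$collapsed$ci_high, digits)))
  if (!is.null(x$fixed)) {
    for (m in c("fixed", "random", "averaged")) {
      p <- x[[m]]
      cat(sprintf("  %-9s %s (%s to %s)\n", paste0(m, ":"),
                  fmt2(p$estimate, digits), fmt2(p$ci_low, digits),
                  fmt2(p$ci_high, digits)))
    }
    cat(sprintf("  heterogeneity chi-square %.2f on %d df (p = %.4g), tau^2 = %.4f\n",
                x$fixed$chi2_het, x$fixed$df, x$fixed$het_p, x$random$tau2))
  } else {
    cat("  fewer than two usable periods: inverse-variance and averaged\n",
        "  pooling not available (collapsed estimate only)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.kappa_study <- function(object, ...) {
  structure(list(fit = object), class = "summary.kappa_study")
}

#' @export
print.summary.kappa_study <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPer-period estimates:\n")
  per <- fit$periods
  out <- data.frame(period = per$period, n = per$n,
                    kappa = round_half_away(per$kappa, 2),
                    se = round(per$se, 4),
                    used = per$used,
                    reason = per$reason)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.kappa_study <- function(object, ...) {
  c(collapsed = object$collapsed$kappa,
    fixed = if (!is.null(object$fixed)) object$fixed$estimate else NA_real_,
    random = if (!is.null(object$random)) object$random$estimate else NA_real_,
    averaged = if (!is.null(object$averaged)) object$averaged$estimate else NA_real_)
}

#' @export
confint.kappa_study <- function(object, parm, level = 1 - object$alpha, ...) {
  comp <- list(collapsed = object$collapsed, fixed = object$fixed,
               random = object$random, averaged = object$averaged)
  if (!missing(parm)) comp <- comp[parm]
  a <- 1 - level
  out <- t(vapply(comp, function(p) {
    if (is.null(p)) return(c(NA_real_, NA_real_))
    est <- if (inherits(p, "kappa_estimate")) p$kappa else p$estimate
    wald_ci(est, p$se, a)
  }, numeric(2)))
  colnames(out) <- sprintf("%g %%", 100 * c(a / 2, 1 - a / 2))
  out
}

#' Simulate replicate studies from a fitted analysis
#'
#' Draws new studies from the generative model of [simulate_study()]
#' with parameters taken from the fit: mean agreement equal to the
#' random-effects pooled estimate (the collapsed estimate when pooling
#' was unavailable), between-period SD equal to
#' \eqn{\sqrt{\hat\tau^2}}, the margin profile taken as the average of
#' the two raters' margins of the collapsed table, and the observed
#' per-period sample sizes.
#'
#' @param object A `"kappa_study"` fit.
#' @param nsim Number of replicate studies.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` simulated studies (see [simulate_study()]).
#' @export
simulate.kappa_study <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  km <- if (!is.null(object$random)) object$random$estimate
        else object$collapsed$kappa
  tau <- if (!is.null(object$random)) sqrt(object$random$tau2) else 0
  tab <- collapse_tables(object$tables)
  pr <- crosstab_props(tab)
  pi <- (pr$pi. + pr$p.j) / 2
  lapply(seq_len(nsim), function(r)
    simulate_study(g = nrow(object$periods), n_m = object$periods$n,
                   pi = pi, kappa_mean = min(max(km, 0), 1), tau = tau,
                   seed = seed + r - 1L, scale = object$scale))
}

#' Forest-plot data
#'
#' Per-period estimates with confidence limits and normalised
#' meta-analytic weights, plus pooled rows, in a layout suitable for
#' external forest plotting (no graphics are produced).
#'
#' @param fit A `"kappa_study"` object.
#' @return Data frame with columns `row` (`"period"`, `"fixed"`,
#'   `"random"`, `"averaged"`), `period`, `n`, `kappa`, `se`,
#'   `ci_low`, `ci_high`, `weight_fixed_pct`, `weight_random_pct`.
#' @export
forest_data <- function(fit) {
  stopifnot(inherits(fit, "kappa_study"))
  per <- fit$periods
  wf <- wr <- rep(NA_real_, nrow(per))
  if (!is.null(fit$fixed)) {
    wf[per$used] <- fit$fixed$meta_weights
    wr[per$used] <- fit$random$meta_weights
  }
  rows <- data.frame(row = "period", period = as.character(per$period),
                     n = per$n, kappa = per$kappa, se = per$se,
                     ci_low = NA_real_, ci_high = NA_real_,
                     weight_fixed_pct = wf, weight_random_pct = wr,
                     stringsAsFactors = FALSE)
  ok <- !is.na(per$kappa)
  ci <- t(mapply(function(k, s) wald_ci(k, s, fit$alpha),
                 per$kappa[ok], per$se[ok]))
  rows$ci_low[ok] <- ci[, 1]
  rows$ci_high[ok] <- ci[, 2]
  pooled <- lapply(c("fixed", "random", "averaged"), function(m) {
    p <- fit[[m]]
    if (is.null(p)) return(NULL)
    data.frame(row = m, period = NA_character_, n = sum(per$n[per$used]),
               kappa = p$estimate, se = p$se,
               ci_low = p$ci_low, ci_high = p$ci_high,
               weight_fixed_pct = if (m == "averaged") NA_real_ else 100,
               weight_random_pct = if (m == "averaged") NA_real_ else 100,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(list(rows), pooled))
}

#' Combined estimates across weighting schemes
#'
#' Runs [kappa_study()] under several weighting schemes and tabulates
#' the four combined estimates per scheme, mirroring the standard
#' presentation grid of such studies (collapsed, fixed, heterogeneity
#' chi-square, random, averaged, each with its confidence interval).
#'
#' @inheritParams kappa_study
#' @param schemes Character vector of scheme names.
#' @return Data frame with one row per scheme.
#' @export
kappa_grid <- function(data, schemes = scheme_names(), alpha = 0.05,
                       scale = quis_scale()) {
  rows <- lapply(schemes, function(s) {
    fit <- kappa_study(data, scheme = s, alpha = alpha, scale = scale)
    ex <- function(p, what = "estimate")
      if (is.null(p)) NA_real_ else p[[what]]
    data.frame(scheme = s,
               collapsed = fit$collapsed$kappa,
               collapsed_lo = fit$collapsed$ci_low,
               collapsed_hi = fit$collapsed$ci_high,
               fixed = ex(fit$fixed), fixed_lo = ex(fit$fixed, "ci_low"),
               fixed_hi = ex(fit$fixed, "ci_high"),
               chi2_het = ex(fit$fixed, "chi2_het"),
               df = if (is.null(fit$fixed)) NA_integer_ else fit$fixed$df,
               het_p = ex(fit$fixed, "het_p"),
               tau2 = ex(fit$random, "tau2"),
               random = ex(fit$random), random_lo = ex(fit$random, "ci_low"),
               random_hi = ex(fit$random, "ci_high"),
               averaged = ex(fit$averaged),
               averaged_lo = ex(fit$averaged, "ci_low"),
               averaged_hi = ex(fit$averaged, "ci_high"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
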