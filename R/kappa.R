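#' Weighted kappa for a single cross-tabulation
#'
#' Chance-corrected, severity-weighted agreement between two raters.
#' With cell proportions \eqn{p_{ij}}, margins \eqn{p_{i.}, p_{.j}} and
#' agreement weights \eqn{w_{ij} \in [0,1]}, the observed and expected
#' weighted agreement are
#' \deqn{p_{o(w)} = \sum_i \sum_j w_{ij} p_{ij}, \qquad
#'       p_{e(w)} = \sum_i \sum_j w_{ij} p_{i.} p_{.j},}
#' and weighted kappa is
#' \deqn{\hat\kappa_w = (p_{o(w)} - p_{e(w)}) / (1 - p_{e(w)}).}
#' With identity weights this reduces to Cohen's unweighted kappa.  The
#' standard error is the Fleiss large-sample estimate
#' \deqn{\widehat{SE} = \frac{1}{(1-p_{e(w)})\sqrt n}
#'   \sqrt{\sum_i\sum_j p_{i.}p_{.j}
#'   [w_{ij} - (\bar w_{i.} + \bar w_{.j})]^2 - p_{e(w)}^2},}
#' where \eqn{\bar w_{i.} = \sum_j p_{.j} w_{ij}} and
#' \eqn{\bar w_{.j} = \sum_i p_{i.} w_{ij}}, and the confidence
#' interval is the Wald interval \eqn{\hat\kappa_w \pm z_{\alpha/2} SE}
#' (clipped to [-1, 1] for display; unclipped bounds are kept in the
#' returned object).
#'
#' @param tab A `"kappa_crosstab"` (or square count matrix) with at
#'   least one observation.
#' @param weights A scheme name (see [scheme_names()]) or a
#'   `"kappa_weights"` matrix on the same scale as `tab`.
#' @param alpha Two-sided confidence level parameter in (0, 1);
#'   `alpha = 0.05` gives a 95\% interval.
#' @return An object of class `"kappa_estimate"`: a list with elements
#'   `kappa`, `po_w`, `pe_w`, `se`, `ci_low`, `ci_high` (clipped),
#'   `ci_unclipped`, `alpha`, `n`, `scheme`.
#' @references Fleiss JL, Levin B, Paik MC. Statistical Methods for
#'   Rates and Proportions, 3rd ed., section 13.1.
#' @examples
#' tab <- tabulate_pairs(c("+s", "+c", "+c", "N"), c("+s", "+c", "N", "N"))
#' weighted_kappa(tab, "A4")
#' @export
weighted_kappa <- function(tab, weights = "A4", alpha = 0.05) {
  tab <- as_crosstab(tab)
  W <- resolve_weights(weights, rownames(tab))
  pr <- crosstab_props(tab)
  po <- sum(W * pr$p)
  pe <- sum(W * outer(pr$pi., pr$p.j))
  if (pe >= 1 - 1e-14)
    stop("expected weighted agreement is 1; kappa is undefined ",
         "(all probability mass in cells with weight 1)", call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  se <- kappa_se(tab, W)
  ci <- wald_ci(kappa, se, alpha, clip = FALSE)
  structure(list(kappa = kappa, po_w = po, pe_w = pe, se = se,
                 ci_low = max(ci[1], -1), ci_high = min(ci[2], 1),
                 ci_unclipped = ci, alpha = alpha, n = pr$n,
                 scheme = attr(W, "scheme")),
            class = "kappa_estimate")
}

#' @rdname weighted_kappa
#' @return `observed_agreement()` and `expected_agreement()` return the
#'   proportions \eqn{p_{o(w)}} and \eqn{p_{e(w)}}.
#' @export
observed_agreement <- function(tab, weights = "A4") {
  tab <- as_crosstab(tab)
  W <- resolve_weights(weights, rownames(tab))
  pr <- crosstab_props(tab)
  sum(W * pr$p)
}

#' @rdname weighted_kappa
#' @export
expected_agreement <- function(tab, weights = "A4") {
  tab <- as_crosstab(tab)
  W <- resolve_weights(weights, rownames(tab))
  pr <- crosstab_props(tab)
  sum(W * outer(pr$pi., pr$p.j))
}

#' @rdname weighted_kappa
#' @return `kappa_se()` returns the Fleiss standard error (a
#'   non-negative scalar scaling as \eqn{1/\sqrt n}).
#' @export
kappa_se <- function(tab, weights = "A4") {
  tab <- as_crosstab(tab)
  W <- resolve_weights(weights, rownames(tab))
  pr <- crosstab_props(tab)
  pe <- sum(W * outer(pr$pi., pr$p.j))
  if (pe >= 1 - 1e-14)
    stop("expected weighted agreement is 1; standard error is undefined",
         call. = FALSE)
  wbar_i <- c(W %*% pr$p.j)        # row weighted means, sum_j p_.j w_ij
  wbar_j <- c(crossprod(pr$pi., W))  # column weighted means, sum_i p_i. w_ij
  dev <- W - outer(wbar_i, wbar_j, `+`)
  s <- sum(outer(pr$pi., pr$p.j) * dev^2) - pe^2
  # guard against tiny negative values from floating-point cancellation
  sqrt(max(s, 0)) / ((1 - pe) * sqrt(pr$n))
}

#' Wald confidence interval
#'
#' Normal-approximation interval `estimate +/- z * se` with
#' `z = qnorm(1 - alpha/2)`.  Kappa is bounded in [-1, 1], so bounds
#' are clipped to that range for reporting when `clip = TRUE`.
#'
#' @param estimate Point estimate.
#' @param se Non-negative standard error.
#' @param alpha Level parameter in (0, 1).
#' @param clip Clip the interval to [-1, 1]?
#' @return Numeric vector `c(low, high)`.
#' @examples
#' wald_ci(0.5, 0.1)
#' @export
wald_ci <- function(estimate, se, alpha = 0.05, clip = TRUE) {
  stopifnot(alpha > 0, alpha < 1, se >= 0)
  z <- stats::qnorm(1 - alpha / 2)
  ci <- c(estimate - z * se, estimate + z * se)
  if (clip) ci <- pmin(pmax(ci, -1), 1)
  ci
}

#' @export
print.kappa_estimate <- function(x, digits = 2, ...) {
  lvl <- 100 * (1 - x$alpha)
  cat(sprintf("Weighted kappa%s: %s (%g%% CI %s to %s), n = %d\n",
              if (!is.null(x$scheme)) paste0(" [", x$scheme, "]") else "",
              fmt2(x$kappa, digits), lvl, fmt2(x$ci_low, digits),
              fmt2(x$ci_high, digits), x$n))
  cat(sprintf("  p_o(w) = %.4f, p_e(w) = %.4f, SE = %.4f\n",
              x$po_w, x$pe_w, x$se))
  invisible(x)
}

# round half away from zero (display convention; R's round() is
# round-half-even)
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fmt2 <- function(x, digits = 2) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}
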