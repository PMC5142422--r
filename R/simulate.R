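#' Simulate an inter-rater reliability study
#'
#' Generates paired ordinal ratings for g observation periods under a
#' random-effects model with analytically known ground truth.  For
#' period m a true agreement level \eqn{\lambda_m} is drawn as
#' \eqn{\lambda_m = \mathrm{clip}(\kappa_{mean} + \delta_m,\ 0,\ 1)}
#' with \eqn{\delta_m \sim N(0, \tau^2)}, and the joint rating
#' distribution is the mixture
#' \deqn{P_m = \lambda_m\, \mathrm{diag}(\pi) +
#'       (1 - \lambda_m)\, \pi\pi^\top,}
#' i.e. with probability \eqn{\lambda_m} both raters give the same
#' category drawn from \eqn{\pi}, otherwise the two ratings are
#' independent draws from \eqn{\pi}.  This family is chosen because its
#' population weighted kappa equals \eqn{\lambda_m} exactly for every
#' unit-diagonal weighting scheme (see [true_kappa()]), giving
#' closed-form ground truth for parameter-recovery tests.  Both raters
#' share the margin \eqn{\pi}; true kappa below 0 is not generatable.
#' The `n_m` cell counts of each period are drawn multinomially from
#' \eqn{P_m}.
#'
#' Per-period random substreams are derived deterministically from the
#' master seed, so changing `g` does not reshuffle earlier periods, and
#' identical seeds reproduce identical studies bit for bit.
#'
#' @param g Number of observation periods (>= 1).
#' @param n_m Interactions per period: a single count or a length-g
#'   vector.
#' @param pi Marginal category distribution (length k, sums to 1).
#'   Defaults to the first rater's margins of the collapsed QuIS
#'   reliability-study table, (59, 201, 70, 14, 10)/354.
#' @param kappa_mean Mean true agreement in [0, 1].
#' @param tau Between-period SD of true agreement (>= 0).
#' @param seed Integer master seed.
#' @param pair_lambda_n `"random"` leaves the drawn agreement levels in
#'   period order; `"inverse"` sorts them so the largest
#'   \eqn{\lambda_m} is paired with the smallest `n_m`, emulating
#'   studies where sparse periods show the highest agreement (the
#'   pattern that biases the simple-average summary upwards).
#' @param scale Category scale (length k).
#' @return An object of class `"simulated_study"`: a list with
#'   \describe{
#'     \item{data}{data frame `period`, `rater1`, `rater2`, one row per
#'       interaction, in the dialect read by [read_pairs()].}
#'     \item{lambda}{length-g vector of true per-period agreement.}
#'     \item{P}{list of g true joint probability matrices.}
#'     \item{config}{the generating parameters.}
#'   }
#' @examples
#' sim <- simulate_study(g = 3, n_m = 10, kappa_mean = 0.6, tau = 0,
#'                       seed = 42)
#' head(sim$data)
#' true_kappa(sim$P[[1]], weight_scheme("A4"))
#' @export
simulate_study <- function(g = 18, n_m = 20,
                           pi = c(59, 201, 70, 14, 10) / 354,
                           kappa_mean = 0.6, tau = 0.1, seed = 1,
                           pair_lambda_n = c("random", "inverse"),
                           scale = quis_scale()) {
  pair_lambda_n <- match.arg(pair_lambda_n)
  scale <- category_scale(scale)
  k <- length(scale)
  if (length(pi) != k)
    stop("'pi' must have one probability per category (", k, ")",
         call. = FALSE)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-12)
    stop("'pi' must be non-negative and sum to 1", call. = FALSE)
  if (g < 1) stop("'g' must be at least 1", call. = FALSE)
  if (kappa_mean < 0 || kappa_mean > 1)
    stop("'kappa_mean' must lie in [0, 1]", call. = FALSE)
  if (tau < 0) stop("'tau' must be non-negative", call. = FALSE)
  n_m <- rep_len(as.integer(n_m), g)
  if (any(n_m < 1)) stop("per-period sizes must be positive", call. = FALSE)

  # deterministic per-period substream, independent of g
  delta <- vapply(seq_len(g), function(m) {
    set_substream(seed, m, 1L)
    stats::rnorm(1, 0, tau)
  }, 0)
  lambda <- pmin(pmax(kappa_mean + delta, 0), 1)
  if (pair_lambda_n == "inverse")
    lambda <- sort(lambda, decreasing = TRUE)[order(order(n_m))]

  P <- lapply(lambda, function(l) {
    M <- l * diag(pi, nrow = k) + (1 - l) * outer(pi, pi)
    dimnames(M) <- list(scale, scale)
    M
  })
  pieces <- lapply(seq_len(g), function(m) {
    set_substream(seed, m, 2L)
    cells <- stats::rmultinom(1, n_m[m], c(P[[m]]))
    idx <- rep.int(seq_len(k * k), cells)
    data.frame(period = m,
               rater1 = scale[(idx - 1L) %% k + 1L],
               rater2 = scale[(idx - 1L) %/% k + 1L],
               stringsAsFactors = FALSE)
  })
  structure(list(data = do.call(rbind, pieces), lambda = lambda, P = P,
                 config = list(g = g, n_m = n_m, pi = pi,
                               kappa_mean = kappa_mean, tau = tau,
                               seed = seed, pair_lambda_n = pair_lambda_n,
                               scale = scale)),
            class = "simulated_study")
}

# seed the RNG for (master seed, period, stream) reproducibly; kept
# below 2^31 - 1
set_substream <- function(seed, m, stream) {
  s <- (as.numeric(seed) * 48271 + m * 69621 + stream * 16807) %%
    2147483647
  set.seed(as.integer(s))
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated inter-rater study: g = %d periods, %d interactions\n",
              cfg$g, nrow(x$data)))
  cat(sprintf("  kappa_mean = %g, tau = %g, seed = %d\n",
              cfg$kappa_mean, cfg$tau, cfg$seed))
  cat("  true per-period agreement: ",
      paste(sprintf("%.3f", x$lambda), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Population weighted kappa of a joint rating distribution
#'
#' Applies the weighted-kappa definition to a known joint probability
#' matrix P rather than sampled counts: observed agreement is
#' \eqn{\sum w_{ij} P_{ij}}, expected agreement uses the margins of P.
#' For the mixture family of [simulate_study()] and any unit-diagonal
#' weight matrix this returns exactly the mixing parameter
#' \eqn{\lambda}.
#'
#' @param P Joint probability matrix (non-negative, sums to 1).
#' @param weights Scheme name or `"kappa_weights"` matrix.
#' @return The population weighted kappa.
#' @export
true_kappa <- function(P, weights = "A4") {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || any(P < 0) || abs(sum(P) - 1) > 1e-9)
    stop("'P' must be a square probability matrix summing to 1",
         call. = FALSE)
  scale <- if (!is.null(rownames(P))) category_scale(rownames(P))
           else if (nrow(P) == 5L) quis_scale()
           else as.character(seq_len(nrow(P)))
  dimnames(P) <- list(scale, scale)
  W <- resolve_weights(weights, scale)
  po <- sum(W * P)
  pe <- sum(W * outer(rowSums(P), colSums(P)))
  if (pe >= 1 - 1e-14)
    stop("expected weighted agreement is 1; kappa is undefined",
         call. = FALSE)
  (po - pe) / (1 - pe)
}
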