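#' Agreement-weight matrices
#'
#' A weight matrix assigns each pair of rating categories (i, j) a
#' weight in [0, 1] expressing the degree to which a rating of i by
#' one rater and j by the other is counted as agreement: 1 is perfect
#' agreement, 0 complete disagreement.  Weight matrices are symmetric
#' with a unit diagonal.  `weight_matrix()` builds one from a square
#' numeric matrix and validates it; `validate_weights()` returns the
#' list of violated constraints (empty for a valid matrix).
#'
#' @param w Square numeric matrix of weights, rows and columns in scale
#'   order.
#' @param scale Category scale (see [category_scale()]); defaults to
#'   the column names of `w`, or [quis_scale()] for bare 5x5 matrices.
#' @param name Optional scheme label carried along for reporting.
#' @param validate If `TRUE` (default), reject invalid matrices.
#' @return An object of class `"kappa_weights"`: a k x k numeric matrix
#'   with the scale as dimnames and the scheme name in
#'   `attr(, "scheme")`.
#' @examples
#' weight_scheme("A4")
#' linear_weights(category_scale(c("low", "mid", "high")))
#' @export
weight_matrix <- function(w, scale = NULL, name = NULL, validate = TRUE) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w))
    stop("weight matrix must be square", call. = FALSE)
  if (is.null(scale)) {
    scale <- if (!is.null(colnames(w))) colnames(w)
             else if (nrow(w) == 5L) quis_scale()
             else as.character(seq_len(nrow(w)))
  }
  scale <- category_scale(scale)
  if (length(scale) != nrow(w))
    stop("scale has ", length(scale), " categories but weight matrix is ",
         nrow(w), "x", ncol(w), call. = FALSE)
  storage.mode(w) <- "double"
  dimnames(w) <- list(scale, scale)
  out <- structure(w, scheme = name,
                   class = c("kappa_weights", "matrix", "array"))
  if (validate) {
    bad <- validate_weights(out)
    if (length(bad))
      stop("invalid weight matrix:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
  }
  out
}

#' @rdname weight_matrix
#' @param W A weight matrix (any square numeric matrix is accepted so
#'   that broken candidates can be diagnosed).
#' @return `validate_weights()` returns a character vector of violation
#'   messages, `character(0)` when the matrix is valid.
#' @export
validate_weights <- function(W) {
  W <- as.matrix(W)
  out <- character(0)
  if (nrow(W) != ncol(W))
    return(sprintf("matrix is not square (%d x %d)", nrow(W), ncol(W)))
  bad <- which(abs(W - t(W)) > 1e-12, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad))
    out <- c(out, sprintf("symmetry violated at (%d,%d): w_ij=%g, w_ji=%g",
                          bad[, 1], bad[, 2], W[bad], W[bad[, c(2, 1), drop = FALSE]]))
  dg <- which(abs(diag(W) - 1) > 1e-12)
  if (length(dg))
    out <- c(out, sprintf("diagonal not 1 at category %d (w=%g)", dg, diag(W)[dg]))
  rng <- which(W < 0 | W > 1, arr.ind = TRUE)
  if (nrow(rng))
    out <- c(out, sprintf("weight out of [0,1] range at (%d,%d): %g",
                          rng[, 1], rng[, 2], W[rng]))
  out
}

#' @rdname weight_matrix
#' @export
identity_weights <- function(scale = quis_scale()) {
  scale <- category_scale(scale)
  weight_matrix(diag(length(scale)), scale, name = "unweighted")
}

#' @rdname weight_matrix
#' @details Linear weights are `1 - |i - j| / (k - 1)` and quadratic
#'   weights `1 - ((i - j) / (k - 1))^2`, with i, j the 1-based ordinal
#'   indices of the categories.  Both give weight 1 on the diagonal and
#'   0 at the maximal distance of k - 1 categories; quadratic weights
#'   penalise small disagreements less.
#' @export
linear_weights <- function(scale = quis_scale()) {
  scale <- category_scale(scale)
  k <- length(scale)
  w <- outer(seq_len(k), seq_len(k), function(i, j) 1 - abs(i - j) / (k - 1))
  weight_matrix(w, scale, name = "linear")
}

#' @rdname weight_matrix
#' @export
quadratic_weights <- function(scale = quis_scale()) {
  scale <- category_scale(scale)
  k <- length(scale)
  w <- outer(seq_len(k), seq_len(k), function(i, j) 1 - ((i - j) / (k - 1))^2)
  weight_matrix(w, scale, name = "quadratic")
}

# QuIS block-scheme parameters: a = weight within the two positive
# categories, b = weight between neutral and any positive or negative
# category, c = weight within the two negative categories.  All
# positive-negative cross weights are 0.
.quis_scheme_params <- list(
  A1 = c(a = 1.00, b = 0.50, c = 1.00),
  A2 = c(a = 0.90, b = 0.50, c = 0.90),
  A3 = c(a = 0.80, b = 0.50, c = 0.80),
  A4 = c(a = 0.75, b = 0.50, c = 0.75),
  A5 = c(a = 0.70, b = 0.50, c = 0.70),
  A6 = c(a = 0.60, b = 0.50, c = 0.60),
  B1 = c(a = 0.66, b = 0.33, c = 0.66),
  B2 = c(a = 0.50, b = 0.25, c = 0.50),
  B3 = c(a = 0.50, b = 0.00, c = 0.50),
  C1 = c(a = 0.50, b = 0.25, c = 0.75),
  C2 = c(a = 0.60, b = 0.40, c = 0.80),
  C3 = c(a = 0.66, b = 0.50, c = 0.83)
)

#' Named weighting schemes
#'
#' Weighting schemes addressable by name.  `"unweighted"`, `"linear"`
#' and `"quadratic"` are formula-based and work for any scale; the
#' lettered QuIS schemes `A1`-`A6`, `B1`-`B3` and `C1`-`C3` are defined
#' on the five-category QuIS scale only.  Each lettered scheme is
#' determined by three parameters: the weight `a` between the two
#' positive categories, the weight `b` between neutral and any positive
#' or negative category, and the weight `c` between the two negative
#' categories; all weights between a positive and a negative category
#' are 0.  Scheme A4 (`a = c = 0.75`, `b = 0.5`) is the recommended
#' representation of misclassification severity between QuIS
#' categories: crossing the positive/negative divide carries no credit,
#' confusing neutral with an adjacent block carries half credit, and
#' within-block confusion is mild.
#'
#' @param name Scheme name, one of `scheme_names()`.
#' @param scale Category scale; lettered schemes require the default
#'   five-category QuIS scale (or any other scale of exactly five
#'   categories, interpreted as positive, positive, neutral, negative,
#'   negative in rank order).
#' @return A `"kappa_weights"` matrix.
#' @seealso [weight_matrix()], [read_weights()]
#' @examples
#' weight_scheme("A4")
#' scheme_names()
#' @export
weight_scheme <- function(name, scale = quis_scale()) {
  if (inherits(name, "kappa_weights")) return(name)
  name <- as.character(name)
  if (length(name) != 1L)
    stop("'name' must be a single scheme name", call. = FALSE)
  scale <- category_scale(scale)
  if (name == "unweighted") return(identity_weights(scale))
  if (name == "linear") return(linear_weights(scale))
  if (name == "quadratic") return(quadratic_weights(scale))
  if (!name %in% names(.quis_scheme_params))
    stop("unknown weighting scheme '", name, "'; available: ",
         paste(scheme_names(), collapse = ", "), call. = FALSE)
  if (length(scale) != 5L)
    stop("scheme '", name, "' is defined for the 5-category QuIS scale only",
         call. = FALSE)
  p <- .quis_scheme_params[[name]]
  w <- diag(5)
  w[1, 2] <- p[["a"]]                     # within the positive block
  w[1, 3] <- w[2, 3] <- p[["b"]]          # neutral vs positives
  w[3, 4] <- w[3, 5] <- p[["b"]]          # neutral vs negatives
  w[4, 5] <- p[["c"]]                     # within the negative block
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  weight_matrix(w, scale, name = name)
}

#' @rdname weight_scheme
#' @export
scheme_names <- function() {
  c("unweighted", "linear", "quadratic", names(.quis_scheme_params))
}

#' Read a custom weight matrix from CSV
#'
#' Reads a k x k weight matrix from a CSV file whose header row gives
#' the category labels (in scale order); row order must match the
#' header.  The matrix is validated on construction.
#'
#' @param path Path to the CSV file.
#' @param name Optional scheme label; defaults to the file name.
#' @return A `"kappa_weights"` matrix.
#' @export
read_weights <- function(path, name = NULL) {
  x <- utils::read.csv(path, check.names = FALSE)
  w <- as.matrix(x)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  W <- weight_matrix(w, scale = colnames(x), name = name, validate = FALSE)
  bad <- validate_weights(W)
  if (length(bad))
    stop("invalid weight matrix in '", path, "':\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  W
}

#' @export
print.kappa_weights <- function(x, digits = 3, ...) {
  nm <- attr(x, "scheme")
  cat("Agreement-weight matrix",
      if (!is.null(nm)) paste0(" (scheme ", nm, ")"), "\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

# resolve a scheme name or matrix against a scale, with scale check
resolve_weights <- function(weights, scale) {
  W <- if (inherits(weights, "kappa_weights")) weights
       else weight_scheme(weights, scale)
  if (!identical(rownames(W), scale))
    stop("weight matrix scale (", paste(rownames(W), collapse = ","),
         ") does not match data scale (", paste(scale, collapse = ","), ")",
         call. = FALSE)
  W
}
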