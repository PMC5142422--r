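#' Cross-tabulate paired ratings
#'
#' Builds the k x k contingency table of paired ratings: rows index the
#' first rater's category, columns the second rater's.  All categories
#' of the scale are retained even when never used, so that expected
#' agreement is computed on the same scale in every observation period.
#'
#' @param rater1,rater2 Character vectors of category labels, one entry
#'   per jointly observed interaction.
#' @param scale Category scale the labels must come from.
#' @return An object of class `"kappa_crosstab"`: a k x k integer
#'   matrix of counts with the scale as dimnames.
#' @examples
#' tab <- tabulate_pairs(c("+s", "+c", "+c"), c("+s", "+c", "N"))
#' sum(tab)
#' @export
tabulate_pairs <- function(rater1, rater2, scale = quis_scale()) {
  scale <- category_scale(scale)
  rater1 <- as.character(rater1)
  rater2 <- as.character(rater2)
  if (length(rater1) != length(rater2))
    stop("rater1 and rater2 must have the same length", call. = FALSE)
  bad <- which(!(rater1 %in% scale) | !(rater2 %in% scale))
  if (length(bad))
    stop("unknown category label(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5),
         ": labels must be one of ", paste(scale, collapse = ", "),
         call. = FALSE)
  f1 <- factor(rater1, levels = scale)
  f2 <- factor(rater2, levels = scale)
  counts <- table(f1, f2, dnn = NULL)
  as_crosstab(unclass(counts), scale)
}

#' @rdname tabulate_pairs
#' @param counts Square matrix of non-negative integer counts (rows =
#'   first rater, columns = second rater), e.g. a published
#'   cross-tabulation.
#' @export
as_crosstab <- function(counts, scale = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("a cross-tabulation must be square", call. = FALSE)
  if (is.null(scale)) {
    scale <- if (!is.null(colnames(counts))) colnames(counts)
             else if (nrow(counts) == 5L) quis_scale()
             else as.character(seq_len(nrow(counts)))
  }
  scale <- category_scale(scale)
  if (length(scale) != nrow(counts))
    stop("scale length does not match table dimension", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(scale, scale)
  structure(counts, class = c("kappa_crosstab", "matrix", "array"))
}

#' Collapse cross-tabulations over observation periods
#'
#' Cellwise sum of several cross-tabulations on the same scale, as used
#' for the collapsed (naive) overall kappa.  Collapsing ignores period
#' structure and risks confounding agreement with between-period
#' differences in the rating mix.
#'
#' @param tables List of `"kappa_crosstab"` objects on identical
#'   scales.
#' @return A single `"kappa_crosstab"` with `n` equal to the total
#'   count.
#' @export
collapse_tables <- function(tables) {
  if (!length(tables)) stop("no tables to collapse", call. = FALSE)
  tables <- lapply(tables, function(t) as_crosstab(t))
  scale <- rownames(tables[[1]])
  same <- vapply(tables, function(t) identical(rownames(t), scale), logical(1))
  if (!all(same))
    stop("cannot collapse tables built on different scales", call. = FALSE)
  out <- Reduce(`+`, lapply(tables, unclass))
  as_crosstab(out, scale)
}

#' @export
print.kappa_crosstab <- function(x, ...) {
  n <- sum(x)
  cat("Paired-rating cross-tabulation (rows = rater 1, cols = rater 2), n = ",
      n, "\n", sep = "")
  m <- unclass(x)
  m <- cbind(m, Total = rowSums(m))
  m <- rbind(m, Total = colSums(m))
  print(m)
  invisible(x)
}

# cell and margin proportions of a crosstab
crosstab_props <- function(tab) {
  n <- sum(tab)
  if (n == 0L) stop("empty cross-tabulation (n = 0)", call. = FALSE)
  p <- unclass(tab) / n
  list(n = n, p = p, pi. = rowSums(p), p.j = colSums(p))
}
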