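#' Ordinal category scales
#'
#' A category scale is an ordered character vector of unique category
#' labels, highest-ranked first.  All cross-tabulations and weight
#' matrices in this package carry their scale as dimnames, and
#' operations refuse to mix objects built on different scales.
#'
#' `quis_scale()` returns the five-category Quality of Interactions
#' Schedule (QuIS) scale used to rate staff-inpatient interactions:
#' positive social (`+s`), positive care (`+c`), neutral (`N`),
#' negative protective (`-p`) and negative restrictive (`-r`), in
#' decreasing rank order.
#'
#' @param labels Character vector of unique category labels, ordered
#'   from highest- to lowest-ranked category.
#' @return A validated character vector of category labels.
#' @examples
#' quis_scale()
#' category_scale(c("good", "fair", "poor"))
#' @export
category_scale <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("a category scale needs at least 2 categories", call. = FALSE)
  if (anyDuplicated(labels))
    stop("category labels must be unique", call. = FALSE)
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("category labels must be non-missing and non-empty", call. = FALSE)
  labels
}

#' @rdname category_scale
#' @export
quis_scale <- function() {
  category_scale(c("+s", "+c", "N", "-p", "-r"))
}
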