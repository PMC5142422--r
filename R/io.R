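#' Read paired ratings from CSV
#'
#' Reads a UTF-8 comma-separated file with header
#' `period,rater1,rater2`, one row per jointly observed interaction.
#' Rows with missing fields or labels outside the scale are reported
#' with their file line numbers (header = line 1).
#'
#' @param path Path to the CSV file.
#' @param scale Category scale the rating labels must come from.
#' @return Data frame with columns `period`, `rater1`, `rater2`,
#'   suitable for [kappa_study()].
#' @export
read_pairs <- function(path, scale = quis_scale()) {
  scale <- category_scale(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = TRUE)
  req <- c("period", "rater1", "rater2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("'", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(df)) stop("'", path, "' contains no interactions", call. = FALSE)
  df <- df[req]
  line <- seq_len(nrow(df)) + 1L  # header occupies line 1
  blank <- !nzchar(df$period) | !nzchar(df$rater1) | !nzchar(df$rater2)
  bad <- !blank & (!(df$rater1 %in% scale) | !(df$rater2 %in% scale))
  if (any(blank | bad)) {
    msg <- c(
      if (any(blank)) sprintf("line %d: missing field", line[blank]),
      if (any(bad)) sprintf("line %d: unknown label '%s'/'%s'",
                            line[bad], df$rater1[bad], df$rater2[bad]))
    stop("malformed rows in '", path, "':\n  ",
         paste(utils::head(msg, 10), collapse = "\n  "),
         if (length(msg) > 10) sprintf("\n  (and %d more)", length(msg) - 10),
         call. = FALSE)
  }
  df
}

#' Write paired ratings to CSV
#'
#' Inverse of [read_pairs()]: writes the `period,rater1,rater2` CSV
#' dialect.  Accepts a data frame or a `"simulated_study"`.
#'
#' @param data Data frame with columns `period`, `rater1`, `rater2`,
#'   or a `"simulated_study"` object.
#' @param path Output path.
#' @export
write_pairs <- function(data, path) {
  if (inherits(data, "simulated_study")) data <- data$data
  stopifnot(all(c("period", "rater1", "rater2") %in% names(data)))
  utils::write.csv(data[c("period", "rater1", "rater2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_list <- function(fit) {
  stopifnot(inherits(fit, "kappa_study"))
  per <- fit$periods
  est <- function(p) {
    if (is.null(p)) return(NULL)
    if (inherits(p, "kappa_estimate"))
      list(estimate = p$kappa, estimate_2dp = fmt2(p$kappa),
           se = p$se, ci_low = p$ci_low, ci_high = p$ci_high,
           po_w = p$po_w, pe_w = p$pe_w, n = p$n)
    else
      list(estimate = p$estimate, estimate_2dp = fmt2(p$estimate),
           se = p$se, ci_low = p$ci_low, ci_high = p$ci_high,
           chi2_het = p$chi2_het, df = p$df, het_p = p$het_p,
           tau2 = p$tau2, g = p$g)
  }
  list(
    scheme = attr(fit$scheme, "scheme") %||% "custom",
    alpha = fit$alpha,
    scale = fit$scale,
    n_total = sum(per$n),
    periods = lapply(seq_len(nrow(per)), function(i)
      list(period = as.character(per$period[i]), n = per$n[i],
           kappa = per$kappa[i], se = per$se[i], used = per$used[i],
           reason = per$reason[i])),
    excluded = as.character(per$period[!per$used]),
    collapsed = est(fit$collapsed),
    fixed = est(fit$fixed),
    random = est(fit$random),
    averaged = est(fit$averaged))
}

#' Export an analysis report
#'
#' Writes the full study report (per-period estimates, exclusions, and
#' the four combined estimates with confidence intervals and
#' heterogeneity results) as JSON or TSV.  Machine fields are written
#' at full precision alongside 2-decimal display values; key order is
#' fixed, so identical inputs give byte-identical output.
#'
#' @param fit A `"kappa_study"` object, or a data frame from
#'   [kappa_grid()] for the multi-scheme grid.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_report <- function(fit, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (is.data.frame(fit)) {           # kappa_grid output
    if (format == "tsv")
      utils::write.table(fit, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    else
      jsonlite::write_json(fit, path, dataframe = "rows",
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  rep <- report_list(fit)
  if (format == "json") {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    rows <- lapply(c("collapsed", "fixed", "random", "averaged"),
                   function(m) {
      p <- rep[[m]]
      data.frame(method = m,
                 estimate = if (is.null(p)) NA_real_ else p$estimate,
                 se = if (is.null(p)) NA_real_ else p$se,
                 ci_low = if (is.null(p)) NA_real_ else p$ci_low,
                 ci_high = if (is.null(p)) NA_real_ else p$ci_high,
                 chi2_het = if (is.null(p$chi2_het)) NA_real_ else p$chi2_het,
                 df = if (is.null(p$df)) NA_integer_ else p$df,
                 tau2 = if (is.null(p$tau2)) NA_real_ else p$tau2)
    })
    utils::write.table(do.call(rbind, rows), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @details `write_forest()` writes the [forest_data()] table as TSV:
#'   one row per observation period plus pooled rows, with confidence
#'   limits and percent meta-analytic weights.
#' @export
write_forest <- function(fit, path) {
  utils::write.table(forest_data(fit), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
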