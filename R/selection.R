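#' Practical-significance cutoffs on the log-survival scale
#'
#' A coefficient corresponds to a delta-fold or larger change in survival per
#' unit increase in the predictor when it falls outside
#' `(log(1 - delta), log(1 + delta))`. Note the region is only approximately
#' symmetric: `|log(1 - delta)| > log(1 + delta)`.
#'
#' @param delta minimum practically relevant fractional change in survival
#'   time, in (0, 1); 0.05 means a 5% change.
#' @return Numeric vector `c(lower, upper)` = `(log(1 - delta),
#'   log(1 + delta))`.
#' @export
effect_cutoffs <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1) {
    stop("delta must be a single value in (0, 1)")
  }
  c(lower = log(1 - delta), upper = log(1 + delta))
}

#' Posterior exceedance probabilities and significance flags
#'
#' For each coefficient, computes the fraction of stored posterior draws
#' strictly above the upper cutoff (`p_plus`) and strictly below the lower
#' cutoff (`p_minus`) from [effect_cutoffs()], then flags the marker as a
#' positive (negative) prognostic marker when `p_plus` (`p_minus`) is
#' strictly greater than 0.5. At most one flag can hold since
#' `p_plus + p_minus <= 1`.
#'
#' Coefficients are reported on the standardized-predictor scale; when the
#' chain carries the design's standardization constants, the posterior mean
#' per original component unit is also reported (`estimate_raw`).
#'
#' @param chain an `ng_chain` with at least one stored draw.
#' @param delta practical effect-size threshold (default 0.05).
#' @return A `selection_report` tibble: one row per column with `term`,
#'   `gene_id`/`platform` (when annotated), `estimate`, `estimate_raw`,
#'   `p_plus`, `p_minus`, `flag` (`"positive"`, `"negative"` or `"none"`),
#'   and attributes `delta`, `cutoffs`, `n_draws`.
#' @export
exceedance_probabilities <- function(chain, delta = 0.05) {
  stopifnot(inherits(chain, "ng_chain"), nrow(chain$beta) >= 1)
  cuts <- effect_cutoffs(delta)
  S <- nrow(chain$beta)
  p_plus <- unname(colMeans(chain$beta > cuts["upper"]))
  p_minus <- unname(colMeans(chain$beta < cuts["lower"]))
  est <- unname(colMeans(chain$beta))
  out <- tibble::tibble(
    term = colnames(chain$beta) %||% paste0("b", seq_along(est)),
    estimate = est,
    estimate_raw = if (!is.null(chain$scale)) est / unname(chain$scale)
                   else NA_real_,
    p_plus = p_plus,
    p_minus = p_minus,
    flag = dplyr::case_when(
      p_plus > 0.5 ~ "positive",
      p_minus > 0.5 ~ "negative",
      TRUE ~ "none"
    )
  )
  if (!is.null(chain$annotation)) {
    out <- dplyr::left_join(dplyr::rename(out, column = "term"),
                            chain$annotation, by = "column")
    out <- dplyr::relocate(dplyr::rename(out, term = "column"),
                           "gene_id", "platform", .after = "term")
  }
  structure(out, class = c("selection_report", class(out)),
            delta = delta, cutoffs = cuts, n_draws = S)
}

#' Aggregate a marker-level selection report to genes
#'
#' Collapses flagged markers to one row per gene, listing the platforms on
#' which the gene is flagged and the flag directions. Genes with no flagged
#' marker are omitted.
#'
#' @param report a `selection_report` from [exceedance_probabilities()] with
#'   gene annotation.
#' @return Tibble with `gene_id`, `n_flagged`, `platforms` (comma-separated),
#'   `directions`, `n_positive`, `n_negative`.
#' @export
gene_level_report <- function(report) {
  stopifnot(inherits(report, "selection_report"))
  if (!"gene_id" %in% names(report)) {
    stop("report has no gene annotation; fit the chain through run_ng_mcmc()")
  }
  flagged <- dplyr::filter(report, .data$flag != "none")
  if (nrow(flagged) == 0) {
    return(tibble::tibble(gene_id = character(0), n_flagged = integer(0),
                          platforms = character(0), directions = character(0),
                          n_positive = integer(0), n_negative = integer(0)))
  }
  dplyr::summarise(
    dplyr::group_by(flagged, .data$gene_id),
    n_flagged = dplyr::n(),
    platforms = paste(.data$platform, collapse = ","),
    directions = paste(.data$flag, collapse = ","),
    n_positive = sum(.data$flag == "positive"),
    n_negative = sum(.data$flag == "negative"),
    .groups = "drop"
  )
}

#' Write a selection report as delimited text
#'
#' @param report a `selection_report`.
#' @param path output path.
#' @param delim delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path, delim = "\t") {
  readr::write_delim(as.data.frame(report), path, delim = delim)
  invisible(path)
}

#' Plot a selection report
#'
#' Exceedance probabilities (or posterior means) per marker, coloured by
#' platform, with flagged markers drawn solid — the style of the
#' marker-selection figures this model is usually summarized with.
#'
#' @param object a `selection_report`.
#' @param type `"p_plus"`, `"p_minus"` or `"estimate"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object,
                                      type = c("p_plus", "p_minus",
                                               "estimate"), ...) {
  type <- match.arg(type)
  df <- tibble::as_tibble(object)
  df$idx <- seq_len(nrow(df))
  df$flagged <- df$flag != "none"
  if (!"platform" %in% names(df)) df$platform <- "all"
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data[[type]],
                                         colour = .data$platform,
                                         shape = .data$flagged)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(x = "marker", y = switch(
      type,
      p_plus = "P(beta > log(1 + delta))",
      p_minus = "P(beta < log(1 - delta))",
      estimate = "posterior mean"
    )) +
    ggplot2::theme_bw()
  if (type %in% c("p_plus", "p_minus")) {
    gg <- gg + ggplot2::geom_hline(yintercept = 0.5, linetype = 2)
  }
  gg
}
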