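#' Overnight percentage change in an affect score
#'
#' `100 * (morning - evening) / evening`. A higher value indicates a larger
#' positive overnight increase. Undefined (NA) when the evening score is
#' zero or missing.
#'
#' @param evening,morning numeric vectors of pre- and post-sleep scores.
#' @return numeric vector of percentage changes.
#' @examples
#' overnight_change(20, 30)   # +50
#' overnight_change(40, 30)   # -25
#' @export
overnight_change <- function(evening, morning) {
  stopifnot(is.numeric(evening), is.numeric(morning),
            length(evening) == length(morning))
  out <- 100 * (morning - evening) / evening
  bad <- !is.na(evening) & evening == 0
  if (any(bad)) {
    warn(sprintf("%d evening score(s) of 0: overnight change undefined, set NA.",
                 sum(bad)))
    out[bad] <- NA_real_
  }
  out
}

#' Tie-aware correlation of one variable pair
#'
#' Implements the tie-fallback protocol: Spearman's rho is used provided
#' there are no ties present in the data (ties distort its ranks); where
#' ties are present, Pearson's r is used as an alternative. Missing values
#' are removed pairwise (listwise within the pair) before testing, and
#' p-values are not corrected for multiple comparisons here.
#'
#' @param x,y paired numeric vectors.
#' @param tie_policy `"either"` (default): ties in either vector trigger the
#'   Pearson fallback; `"both"`: only when both vectors contain ties.
#' @return one-row tibble: `coefficient`, `method` (`"spearman"` or
#'   `"pearson"`), `p_value`, `n` (complete pairs used), `ties_present`.
#'   A constant vector yields an NA coefficient with a warning.
#' @examples
#' correlate_pair(1:4, c(10, 20, 30, 40))      # spearman, rho = 1
#' correlate_pair(c(1, 2, 2, 4), c(5, 1, 4, 2)) # tie in x -> pearson
#' @export
correlate_pair <- function(x, y, tie_policy = c("either", "both")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs to correlate.")
  tx <- anyDuplicated(x) > 0L
  ty <- anyDuplicated(y) > 0L
  ties <- if (tie_policy == "either") tx || ty else tx && ty
  method <- if (ties) "pearson" else "spearman"
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant vector: correlation undefined.")
    return(tibble::tibble(coefficient = NA_real_, method = method,
                          p_value = NA_real_, n = n, ties_present = ties))
  }
  # under the within-both policy Spearman can run on tied data; the exact
  # permutation p is unavailable there, so fall back to the t approximation
  ct <- if (method == "spearman" && (tx || ty)) {
    cor.test(x, y, method = "spearman", exact = FALSE)
  } else {
    cor.test(x, y, method = method)
  }
  tibble::tibble(
    coefficient = unname(ct$estimate),
    method = method,
    p_value = ct$p.value,
    n = n,
    ties_present = ties
  )
}

#' Correlate emotion indicators with external variables
#'
#' Runs [correlate_pair()] for every (indicator, external variable) pair,
#' producing the long-format validation table and, implicitly, the edge
#' list of significant relationships for network-style rendering. p-values
#' are uncorrected by default, matching the protocol's explicit choice for
#' exploratory pilot data; Holm or Benjamini-Hochberg adjustment is
#' available via `adjust`.
#'
#' @param indicators tibble from [dream_indicators()] (or any table with a
#'   `report_id` column and numeric indicator columns).
#' @param externals data frame with a `report_id` column and numeric
#'   external-variable columns (sleep, state, trait measures).
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @param tie_policy passed to [correlate_pair()].
#' @param adjust multiple-testing adjustment applied across all pairs:
#'   `"none"` (default), `"holm"`, or `"BH"`; the `significant` flag uses
#'   the adjusted p-value when one is requested.
#' @return tibble with one row per pair: `indicator`, `variable`,
#'   `coefficient`, `method`, `p_value`, `n`, `ties_present`,
#'   `significant`.
#' @export
correlate_indicators <- function(indicators, externals, alpha = 0.05,
                                 tie_policy = c("either", "both"),
                                 adjust = c("none", "holm", "BH")) {
  tie_policy <- match.arg(tie_policy)
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(indicators), is.data.frame(externals),
            "report_id" %in% names(indicators),
            "report_id" %in% names(externals))
  joined <- dplyr::inner_join(indicators, externals, by = "report_id",
                              suffix = c("", ".ext"))
  if (nrow(joined) == 0L) abort("no report_ids shared between the two tables.")
  ind_cols <- setdiff(names(indicators)[vapply(indicators, is.numeric, logical(1))],
                      "report_id")
  ext_cols <- setdiff(names(externals)[vapply(externals, is.numeric, logical(1))],
                      "report_id")
  ext_cols_joined <- ifelse(ext_cols %in% ind_cols, paste0(ext_cols, ".ext"), ext_cols)
  if (length(ind_cols) == 0L || length(ext_cols) == 0L) {
    abort("both tables need at least one numeric column besides report_id.")
  }
  grid <- tidyr::expand_grid(indicator = ind_cols, variable = ext_cols)
  res <- purrr::pmap(grid, function(indicator, variable) {
    vcol <- ext_cols_joined[match(variable, ext_cols)]
    correlate_pair(joined[[indicator]], joined[[vcol]], tie_policy = tie_policy)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  p_for_flag <- out$p_value
  if (adjust != "none") {
    out$p_adjusted <- p.adjust(out$p_value, method = adjust)
    p_for_flag <- out$p_adjusted
  }
  out$significant <- !is.na(p_for_flag) & p_for_flag < alpha
  out
}

#' Significant-edge list for network rendering
#'
#' Filters a correlation table to the significant pairs and attaches the
#' relationship sign (positive or negative), the information an
#' indicator-variable network diagram encodes with its colored edges.
#'
#' @param correlations tibble from [correlate_indicators()].
#' @return tibble `indicator`, `variable`, `coefficient`, `p_value`, `sign`
#'   (`"positive"`/`"negative"`).
#' @export
significant_edges <- function(correlations) {
  correlations |>
    dplyr::filter(.data$significant) |>
    dplyr::transmute(
      .data$indicator, .data$variable, .data$coefficient, .data$p_value,
      sign = ifelse(.data$coefficient >= 0, "positive", "negative")
    )
}
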