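#' Post-search PSM score thresholds
#'
#' Spectrum Mill-style acceptance thresholds applied to peptide-spectrum
#' matches after the database search. All comparisons in [filter_psms()] are
#' inclusive (a record exactly at a threshold is kept), matching the search
#' engine's convention.
#'
#' @param fwd_rev_min minimum forward-minus-reverse score (default 1.2).
#' @param rank12_min minimum rank 1-2 score difference (default 2).
#' @param score_min minimum identification score (default 3).
#' @param spi_min_percent minimum scored peak intensity, percent (default 30).
#' @return an object of class `psm_thresholds`.
#' @export
psm_thresholds <- function(fwd_rev_min = 1.2, rank12_min = 2,
                           score_min = 3, spi_min_percent = 30) {
  vals <- c(fwd_rev_min = fwd_rev_min, rank12_min = rank12_min,
            score_min = score_min, spi_min_percent = spi_min_percent)
  if (!all(is.finite(vals))) {
    stop("psm_thresholds: all thresholds must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "psm_thresholds")
}

.psm_columns <- c("protein_id", "sequence", "score", "fwd_rev_score",
                  "rank12_score", "spi_percent", "intensity", "sample_id")

validate_psms <- function(records) {
  if (!is.data.frame(records)) stop("PSM records must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(.psm_columns, names(records))
  if (length(missing_cols)) {
    stop("PSM table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$spi_percent < 0 | records$spi_percent > 100, na.rm = TRUE)) {
    stop("PSM spi_percent must lie in [0, 100]", call. = FALSE)
  }
  if (any(records$intensity < 0, na.rm = TRUE)) {
    stop("PSM intensity must be non-negative", call. = FALSE)
  }
  records
}

#' Filter PSM records on post-search score thresholds
#'
#' Keeps exactly the records satisfying all four inclusive criteria:
#' `fwd_rev_score >= fwd_rev_min`, `rank12_score >= rank12_min`,
#' `score >= score_min` and `spi_percent >= spi_min_percent`. Input order is
#' preserved; an empty input yields an empty output.
#'
#' @param records data.frame with columns `protein_id`, `sequence`, `score`,
#'   `fwd_rev_score`, `rank12_score`, `spi_percent`, `intensity`, `sample_id`.
#' @param thresholds a [psm_thresholds()] object.
#' @return the surviving subset of `records`.
#' @export
filter_psms <- function(records, thresholds = psm_thresholds()) {
  records <- validate_psms(records)
  if (!inherits(thresholds, "psm_thresholds")) {
    stop("`thresholds` must come from psm_thresholds()", call. = FALSE)
  }
  keep <- records$fwd_rev_score >= thresholds$fwd_rev_min &
    records$rank12_score >= thresholds$rank12_min &
    records$score >= thresholds$score_min &
    records$spi_percent >= thresholds$spi_min_percent
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Roll filtered PSMs up to a protein-by-sample table
#'
#' Protein-level intensity is the sum of member PSM intensities per sample
#' (mean and median are available alternatives). Proteins and samples appear
#' in order of first appearance in `records`.
#'
#' @param records a (filtered) PSM data.frame; see [filter_psms()].
#' @param fun aggregation rule, one of `"sum"`, `"mean"`, `"median"`.
#' @return a [quant_table()]; protein/sample pairs with no PSM are `NA`.
#' @export
aggregate_psms <- function(records, fun = c("sum", "mean", "median")) {
  records <- validate_psms(records)
  fun <- match.arg(fun)
  f <- switch(fun, sum = sum, mean = mean, median = stats::median)
  proteins <- unique(records$protein_id)
  samples <- unique(records$sample_id)
  m <- matrix(NA_real_, length(proteins), length(samples),
              dimnames = list(proteins, samples))
  if (nrow(records)) {
    agg <- tapply(records$intensity,
                  list(factor(records$protein_id, levels = proteins),
                       factor(records$sample_id, levels = samples)),
                  f)
    m[] <- agg
  }
  quant_table(m)
}
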