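#' Normalize a quantification table to a spiked-in standard
#'
#' Each sample is rescaled by the ratio of the reference sample's total
#' spike-in intensity (e.g. externally spiked BSA) to that sample's total
#' spike-in intensity, correcting unequal loading. The spike-in rows are
#' removed from the returned table; the reference sample itself is unchanged.
#' Missing intensities stay missing (no imputation).
#'
#' The operation is invariant under a global rescaling of the input and is
#' idempotent once the spike rows carry equal totals.
#'
#' @param table a [quant_table()] containing the spike-in rows.
#' @param spike_ids character vector of spike-in protein row ids (non-empty,
#'   all present in `table`).
#' @param reference sample id used as the scaling reference, or `"first"`
#'   (default) for the first column.
#' @return a [quant_table()] without the spike rows, rescaled per sample.
#' @export
normalize_to_spike <- function(table, spike_ids, reference = "first") {
  table <- quant_table(as.matrix(table))
  if (length(spike_ids) < 1L) {
    stop("normalize_to_spike: `spike_ids` must be non-empty", call. = FALSE)
  }
  absent <- setdiff(spike_ids, rownames(table))
  if (length(absent)) {
    stop("normalize_to_spike: spike id(s) not in table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (identical(reference, "first")) reference <- colnames(table)[1L]
  if (!reference %in% colnames(table)) {
    stop("normalize_to_spike: reference sample not in table: ", reference,
         call. = FALSE)
  }
  spike <- unclass(table)[spike_ids, , drop = FALSE]
  totals <- colSums(spike, na.rm = TRUE)
  n_obs <- colSums(!is.na(spike))
  bad <- colnames(table)[n_obs == 0L | totals <= 0]
  if (length(bad)) {
    stop("normalize_to_spike: zero or missing spike total in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factors <- totals[reference] / totals
  out <- sweep(unclass(table), 2L, factors, `*`)
  out <- out[setdiff(rownames(table), spike_ids), , drop = FALSE]
  quant_table(out)
}

#' Relative qPCR expression by the comparative Ct method
#'
#' Computes the fold change `2^(-ddCt)` where
#' `ddCt = (Ct_target - Ct_reference)_treated - (Ct_target - Ct_reference)_vehicle`,
#' i.e. target gene expression normalized to a reference gene (e.g. GAPDH)
#' and expressed relative to the vehicle-treated condition. One PCR cycle
#' corresponds to a doubling, so a treated delta-Ct smaller by one cycle
#' yields a fold change of 2.
#'
#' @param treated,vehicle one-row data.frames (or named lists) with fields
#'   `gene`, `condition`, `ct_target`, `ct_reference`; both records must
#'   describe the same gene, with finite positive Ct values.
#' @return the fold change, a single positive number.
#' @export
ddct_fold_change <- function(treated, vehicle) {
  rec <- function(x, which) {
    need <- c("gene", "ct_target", "ct_reference")
    if (!all(need %in% names(x))) {
      stop("ddct_fold_change: `", which, "` needs fields ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    ct <- c(x$ct_target, x$ct_reference)
    if (!all(is.finite(ct)) || any(ct <= 0)) {
      stop("ddct_fold_change: Ct values in `", which,
           "` must be finite and > 0", call. = FALSE)
    }
    x
  }
  treated <- rec(treated, "treated")
  vehicle <- rec(vehicle, "vehicle")
  if (!identical(as.character(treated$gene), as.character(vehicle$gene))) {
    stop("ddct_fold_change: gene mismatch (", treated$gene, " vs ",
         vehicle$gene, ")", call. = FALSE)
  }
  ddct <- (treated$ct_target - treated$ct_reference) -
    (vehicle$ct_target - vehicle$ct_reference)
  2^(-ddct)
}
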