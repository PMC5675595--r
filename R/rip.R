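#' Input-normalized delta-Ct for a RIP fraction
#'
#' Normalizes a RIP (or IgG control) Ct to the input fraction, correcting for
#' the fraction of the input RNA that was saved:
#' \deqn{\Delta Ct = Ct_{target} - (Ct_{input} - \log_2(fraction))}
#'
#' @param ct_target Ct of the immunoprecipitated fraction.
#' @param ct_input Ct of the input fraction for the same assay.
#' @param fraction_input_saved Fraction of input RNA saved, in (0, 1].
#' @return Normalized delta-Ct; vectorized.
#' @export
normalized_delta_ct <- function(ct_target, ct_input, fraction_input_saved) {
  if (any(fraction_input_saved <= 0) || any(fraction_input_saved > 1)) {
    stop("fraction_input_saved must be in (0, 1]")
  }
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_input))) {
    stop("Ct values must be finite")
  }
  ct_target - (ct_input - log2(fraction_input_saved))
}

#' RIP fold enrichment over the non-specific control
#'
#' \deqn{\Delta\Delta Ct = \Delta Ct_{RIP} - \Delta Ct_{NS};\quad
#'       FoldEnrichment = 2^{-\Delta\Delta Ct}}
#'
#' @param dct_rip Normalized delta-Ct of the specific antibody.
#' @param dct_ns Normalized delta-Ct of the IgG (non-specific) control.
#' @return Fold enrichment (>= 0); vectorized.
#' @export
fold_enrichment <- function(dct_rip, dct_ns) {
  2^(-(dct_rip - dct_ns))
}

#' Compute RIP-qPCR fold enrichment from a Ct table
#'
#' Expects one row per (target, antibody) with antibody \code{"specific"} or
#' \code{"IgG"}; replicate Cts may be given as a comma-separated list and are
#' averaged before normalization. Input Ct and saved fraction are shared per
#' row.
#'
#' @param table data.frame with columns \code{target_id, antibody, ct,
#'   ct_input, fraction_input_saved}, or a path to such a TSV.
#' @return data.frame with columns \code{target_id, dct_rip, dct_ns, ddct,
#'   fold_enrichment}.
#' @export
rip_analysis <- function(table) {
  if (is.character(table)) table <- read_tsv(table)
  req <- c("target_id", "antibody", "ct", "ct_input", "fraction_input_saved")
  if (!all(req %in% names(table))) {
    stop("RIP table must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(table$antibody %in% c("specific", "IgG"))) {
    stop("antibody must be 'specific' or 'IgG'")
  }
  mean_ct <- vapply(strsplit(as.character(table$ct), ","), function(v) {
    mean(as.numeric(v))
  }, numeric(1))
  dct <- normalized_delta_ct(mean_ct, table$ct_input,
                             table$fraction_input_saved)
  targets <- unique(table$target_id)
  rows <- lapply(targets, function(tg) {
    sel <- table$target_id == tg
    rip <- dct[sel & table$antibody == "specific"]
    ns <- dct[sel & table$antibody == "IgG"]
    if (length(rip) != 1L || length(ns) != 1L) {
      stop("target ", tg, " needs exactly one specific and one IgG row")
    }
    data.frame(target_id = tg, dct_rip = rip, dct_ns = ns,
               ddct = rip - ns, fold_enrichment = fold_enrichment(rip, ns),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
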