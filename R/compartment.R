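#' Construct a compartment-resolved expression matrix
#'
#' Couples a transcripts x samples abundance matrix (linear scale, >= 0) with
#' per-sample metadata: genotype (\code{WT}/\code{KO}), compartment
#' (\code{nuclear}/\code{cytoplasmic}), timepoint label and replicate index.
#'
#' @param values Numeric matrix, rows = transcripts (rownames required),
#'   columns = samples (colnames required).
#' @param samples data.frame with columns \code{sample_id, genotype,
#'   compartment, timepoint, replicate}; \code{sample_id} must match the
#'   matrix column names.
#' @return An object of class \code{compartment_expression}.
#' @export
expression_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("abundances must be non-negative")
  if (anyDuplicated(rownames(values))) stop("transcript ids must be unique")
  req <- c("sample_id", "genotype", "compartment", "timepoint", "replicate")
  if (!all(req %in% names(samples))) {
    stop("sample metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (!setequal(samples$sample_id, colnames(values)) ||
      nrow(samples) != ncol(values)) {
    stop("sample_id must match matrix column names one-to-one")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  if (!all(samples$genotype %in% c("WT", "KO"))) {
    stop("genotype must be WT or KO")
  }
  if (!all(samples$compartment %in% c("nuclear", "cytoplasmic"))) {
    stop("compartment must be nuclear or cytoplasmic")
  }
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples),
            class = "compartment_expression")
}

#' Read an expression matrix and sample metadata from TSV files
#'
#' @param values_path TSV whose first column is \code{transcript_id}, remaining
#'   columns one per sample.
#' @param samples_path TSV with the metadata columns of [expression_matrix()].
#' @return A \code{compartment_expression} object.
#' @export
read_expression <- function(values_path, samples_path) {
  tab <- read_tsv(values_path)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  expression_matrix(values, read_tsv(samples_path))
}

#' Write an expression matrix and its metadata to TSV files
#' @param x A \code{compartment_expression} object.
#' @param values_path,samples_path Output paths.
#' @export
write_expression <- function(x, values_path, samples_path) {
  tab <- data.frame(transcript_id = rownames(x$values), x$values,
                    check.names = FALSE)
  write_tsv(tab, values_path)
  write_tsv(x$samples, samples_path)
  invisible(c(values_path, samples_path))
}

# Column indices for one (genotype, compartment, timepoint) cell.
sample_cell <- function(x, genotype, compartment, timepoint) {
  s <- x$samples
  idx <- which(s$genotype == genotype & s$compartment == compartment &
                 s$timepoint == timepoint)
  if (!length(idx)) {
    stop(sprintf("no samples for (%s, %s, %s)", genotype, compartment,
                 timepoint))
  }
  idx
}

#' Summarize replicate abundance for one experimental cell
#'
#' Replicates of the requested (genotype, compartment, timepoint) cell are
#' combined per transcript; the default is the arithmetic mean on the linear
#' abundance scale, with a geometric mean available for log-symmetric noise.
#'
#' @param x \code{compartment_expression}.
#' @param genotype,compartment,timepoint Cell selector.
#' @param method \code{"mean"} (default) or \code{"geometric"}.
#' @return Named numeric vector, one value per transcript.
#' @export
summarize_abundance <- function(x, genotype, compartment, timepoint,
                                method = c("mean", "geometric")) {
  method <- match.arg(method)
  v <- x$values[, sample_cell(x, genotype, compartment, timepoint),
                drop = FALSE]
  if (method == "mean") rowMeans(v) else exp(rowMeans(log(v + 1e-12)))
}

#' Call LPS-induced transcripts
#'
#' A transcript is induced when its whole-cell (nuclear + cytoplasmic) WT
#' abundance rises at least \code{fc_threshold}-fold from baseline to the LPS
#' timepoint; a pseudocount stabilizes the ratio for weakly expressed
#' transcripts.
#'
#' @param x \code{compartment_expression}.
#' @param baseline_timepoint,lps_timepoint Timepoint labels.
#' @param fc_threshold Fold-change cutoff (default 2).
#' @param genotype Genotype to assess induction in (default \code{"WT"}).
#' @param eps Pseudocount on the relative-abundance scale (default 1).
#' @param method Replicate summary, see [summarize_abundance()].
#' @return Character vector of induced transcript ids.
#' @export
call_induced <- function(x, baseline_timepoint, lps_timepoint,
                         fc_threshold = 2, genotype = "WT", eps = 1,
                         method = "mean") {
  if (fc_threshold <= 0) stop("fc_threshold must be positive")
  total <- function(tp) {
    summarize_abundance(x, genotype, "nuclear", tp, method) +
      summarize_abundance(x, genotype, "cytoplasmic", tp, method)
  }
  fc <- (total(lps_timepoint) + eps) / (total(baseline_timepoint) + eps)
  names(fc)[fc >= fc_threshold]
}

#' Nuclear-retention ratio R = N / C
#'
#' @param N,C Nuclear and cytoplasmic abundance (>= 0); vectorized.
#' @param eps Pseudocount added to both compartments before the ratio
#'   (default 1); with both abundances zero the ratio is 1.
#' @return R = (N + eps) / (C + eps).
#' @export
retention_ratio <- function(N, C, eps = 1) {
  stopifnot(all(N >= 0), all(C >= 0), eps >= 0)
  (N + eps) / (C + eps)
}

#' Retention index I = R_KO / R_WT
#'
#' Measures how much the knockout shifts a transcript toward the nucleus:
#' I > 1 means loss of the factor increases nuclear retention.
#'
#' @param R_KO,R_WT Retention ratios (> 0); vectorized.
#' @return I = R_KO / R_WT.
#' @export
retention_index <- function(R_KO, R_WT) {
  if (any(!is.finite(R_KO)) || any(!is.finite(R_WT)) ||
      any(R_KO <= 0) || any(R_WT <= 0)) {
    stop("retention ratios must be positive and finite")
  }
  R_KO / R_WT
}

#' Build the per-transcript retention table
#'
#' Summarizes each compartment/genotype at the chosen LPS timepoint, computes
#' retention ratios and the retention index, calls induction against the
#' baseline timepoint, and ranks induced transcripts by decreasing index
#' (ties by transcript id).
#'
#' @param x \code{compartment_expression}.
#' @param baseline_timepoint Baseline label; default the lexicographically
#'   first timepoint.
#' @param lps_timepoint Stimulated label used for R and I; default the last
#'   timepoint in the metadata.
#' @param fc_threshold Induction fold-change cutoff (default 2).
#' @param eps Pseudocount (default 1).
#' @param method Replicate summary, see [summarize_abundance()].
#' @return data.frame with columns \code{transcript_id, N_WT, C_WT, N_KO,
#'   C_KO, R_WT, R_KO, I, induced, rank} (rank NA for non-induced).
#' @export
retention_table <- function(x, baseline_timepoint = NULL, lps_timepoint = NULL,
                            fc_threshold = 2, eps = 1, method = "mean") {
  tps <- unique(x$samples$timepoint)
  baseline_timepoint <- baseline_timepoint %||% sort(tps)[1]
  lps_timepoint <- lps_timepoint %||% tps[length(tps)]
  N_WT <- summarize_abundance(x, "WT", "nuclear", lps_timepoint, method)
  C_WT <- summarize_abundance(x, "WT", "cytoplasmic", lps_timepoint, method)
  N_KO <- summarize_abundance(x, "KO", "nuclear", lps_timepoint, method)
  C_KO <- summarize_abundance(x, "KO", "cytoplasmic", lps_timepoint, method)
  R_WT <- retention_ratio(N_WT, C_WT, eps)
  R_KO <- retention_ratio(N_KO, C_KO, eps)
  I <- retention_index(R_KO, R_WT)
  induced <- rownames(x$values) %in%
    call_induced(x, baseline_timepoint, lps_timepoint, fc_threshold,
                 eps = eps, method = method)
  tab <- data.frame(transcript_id = rownames(x$values),
                    N_WT = N_WT, C_WT = C_WT, N_KO = N_KO, C_KO = C_KO,
                    R_WT = R_WT, R_KO = R_KO, I = I, induced = induced,
                    rank = NA_integer_, stringsAsFactors = FALSE)
  ind <- which(tab$induced)
  ord <- ind[order(-tab$I[ind], tab$transcript_id[ind])]
  tab$rank[ord] <- seq_along(ord)
  rownames(tab) <- NULL
  attr(tab, "baseline_timepoint") <- baseline_timepoint
  attr(tab, "lps_timepoint") <- lps_timepoint
  tab
}

#' Partition induced transcripts into positive and negative sets
#'
#' Induced transcripts sorted by decreasing retention index form the ranking;
#' the top \code{positive_size} are the positive set (knockout-retained). The
#' negative set is the remaining induced transcripts whose index is at most
#' \code{negative_threshold}, i.e. whose nuclear/cytoplasmic distribution is
#' essentially unaffected by the knockout.
#'
#' @param table Output of [retention_table()].
#' @param positive_size Requested positive-set size (default 70); clamped with
#'   a warning when fewer transcripts are induced.
#' @param negative_threshold Index ceiling for the negative set (default 1.1).
#' @return List of class \code{gene_set_partition} with \code{positive_ids}
#'   (ordered by rank), \code{negative_ids}, and \code{parameters}.
#' @export
rank_and_partition <- function(table, positive_size = 70,
                               negative_threshold = 1.1) {
  ind <- table[table$induced, , drop = FALSE]
  if (nrow(ind) < 2) stop("need at least 2 induced transcripts to partition")
  ind <- ind[order(ind$rank), , drop = FALSE]
  if (nrow(ind) < positive_size) {
    warning("only ", nrow(ind), " induced transcripts; positive set clamped ",
            "from ", positive_size)
  }
  n_pos <- min(positive_size, nrow(ind))
  pos <- ind$transcript_id[seq_len(n_pos)]
  rest <- ind[-seq_len(n_pos), , drop = FALSE]
  neg <- rest$transcript_id[rest$I <= negative_threshold]
  structure(list(positive_ids = pos, negative_ids = neg,
                 parameters = list(positive_size = positive_size,
                                   negative_threshold = negative_threshold)),
            class = "gene_set_partition")
}

#' Write a partition as a TSV plus two plain id lists
#' @param partition \code{gene_set_partition}.
#' @param path Output TSV (columns transcript_id, set, rank_in_set); two
#'   sibling files \code{<path>.positive.txt} / \code{<path>.negative.txt}
#'   hold bare id lists.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(
    transcript_id = c(partition$positive_ids, partition$negative_ids),
    set = rep(c("positive", "negative"),
              c(length(partition$positive_ids),
                length(partition$negative_ids))),
    rank_in_set = c(seq_along(partition$positive_ids),
                    seq_along(partition$negative_ids)),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
  writeLines(partition$positive_ids, paste0(path, ".positive.txt"))
  writeLines(partition$negative_ids, paste0(path, ".negative.txt"))
  invisible(path)
}

#' Read a partition written by [write_partition()]
#' @param path Partition TSV path.
#' @return \code{gene_set_partition}.
#' @export
read_partition <- function(path) {
  df <- read_tsv(path)
  df <- df[order(df$set, df$rank_in_set), , drop = FALSE]
  structure(list(positive_ids = df$transcript_id[df$set == "positive"],
                 negative_ids = df$transcript_id[df$set == "negative"],
                 parameters = list()),
            class = "gene_set_partition")
}
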