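#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases the sequence, maps T to U, and replaces any character outside
#' \code{A,C,G,U} with \code{N}. An \code{N} in a transcript never matches any
#' motif position, so unknown characters silently fail to match rather than
#' aborting a scan.
#'
#' @param raw_sequence Character scalar (DNA or RNA, any case).
#' @return Character scalar over \code{{A,C,G,U,N}}.
#' @examples
#' normalize_alphabet("acgt")  # "ACGU"
#' @export
normalize_alphabet <- function(raw_sequence) {
  if (!is.character(raw_sequence) || length(raw_sequence) != 1L ||
      is.na(raw_sequence) || nchar(raw_sequence) == 0L) {
    stop("normalize_alphabet: sequence must be a non-empty character scalar")
  }
  s <- chartr("T", "U", toupper(raw_sequence))
  gsub("[^ACGU]", "N", s)
}

#' Read transcript records from FASTA plus a CDS annotation table
#'
#' Builds one transcript record per annotated FASTA sequence. Sequences are
#' normalized to the RNA alphabet ([normalize_alphabet()]). CDS coordinates are
#' 0-based half-open on the mature mRNA; the three regions are
#' 5'UTR = \[0, cds_start), CDS = \[cds_start, cds_end),
#' 3'UTR = \[cds_end, length). Sequences without an annotation row are skipped
#' with a warning.
#'
#' @param fasta_source Path to a FASTA file; the first whitespace-delimited
#'   token of each header is the transcript id.
#' @param annotation_source Path to a TSV with columns
#'   \code{transcript_id, gene_id, cds_start, cds_end}, or a data.frame with
#'   those columns.
#' @return A data.frame of class \code{transcript_records} with columns
#'   \code{transcript_id, gene_id, sequence, cds_start, cds_end}.
#' @export
read_transcripts <- function(fasta_source, annotation_source) {
  seqs <- Biostrings::readBStringSet(fasta_source)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate transcript_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  annot <- if (is.data.frame(annotation_source)) annotation_source else
    read_tsv(annotation_source)
  req <- c("transcript_id", "gene_id", "cds_start", "cds_end")
  if (!all(req %in% names(annot))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(annot$transcript_id)) {
    stop("duplicate transcript_id in annotation: ",
         paste(unique(annot$transcript_id[duplicated(annot$transcript_id)]),
               collapse = ", "))
  }
  missing_annot <- setdiff(ids, annot$transcript_id)
  if (length(missing_annot)) {
    warning(length(missing_annot), " transcript(s) lack annotation and were ",
            "skipped: ", paste(missing_annot, collapse = ", "))
  }
  keep <- intersect(ids, annot$transcript_id)
  annot <- annot[match(keep, annot$transcript_id), , drop = FALSE]
  seq_chr <- vapply(as.character(seqs)[match(keep, ids)],
                    normalize_alphabet, character(1), USE.NAMES = FALSE)
  rec <- data.frame(transcript_id = keep,
                    gene_id = annot$gene_id,
                    sequence = seq_chr,
                    cds_start = as.integer(annot$cds_start),
                    cds_end = as.integer(annot$cds_end),
                    stringsAsFactors = FALSE)
  validate_transcripts(rec)
}

#' @keywords internal
validate_transcripts <- function(rec) {
  len <- nchar(rec$sequence)
  bad <- !(rec$cds_start >= 0L & rec$cds_start < rec$cds_end &
             rec$cds_end <= len)
  if (any(bad)) {
    stop("invalid CDS coordinates for transcript(s): ",
         paste(rec$transcript_id[bad], collapse = ", "))
  }
  rownames(rec) <- NULL
  class(rec) <- c("transcript_records", "data.frame")
  rec
}

#' Keep the longest isoform per gene
#'
#' When a gene has several isoforms, the mature mRNA used downstream is the
#' longest one; length ties go to the lexicographically smallest transcript id
#' so the selection is deterministic.
#'
#' @param records A \code{transcript_records} data.frame.
#' @return A \code{transcript_records} data.frame with one row per gene,
#'   ordered by \code{gene_id}.
#' @export
select_longest_isoform <- function(records) {
  ord <- order(records$gene_id, -nchar(records$sequence),
               records$transcript_id)
  rec <- records[ord, , drop = FALSE]
  rec <- rec[!duplicated(rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("transcript_records", "data.frame")
  rec
}

#' Extract a regulatory region from a transcript record
#'
#' @param record One row of a \code{transcript_records} data.frame (or a list
#'   with the same fields).
#' @param kind One of \code{"five_prime_utr"}, \code{"cds"},
#'   \code{"three_prime_utr"}, \code{"whole_transcript"}.
#' @return List with \code{offset} (0-based start of the region within the
#'   transcript) and \code{sequence} (possibly empty).
#' @export
extract_region <- function(record,
                           kind = c("three_prime_utr", "five_prime_utr",
                                    "cds", "whole_transcript")) {
  kind <- match.arg(kind)
  len <- nchar(record$sequence)
  bounds <- switch(kind,
    five_prime_utr   = c(0L, record$cds_start),
    cds              = c(record$cds_start, record$cds_end),
    three_prime_utr  = c(record$cds_end, len),
    whole_transcript = c(0L, len))
  list(offset = as.integer(bounds[1]),
       sequence = substr(record$sequence, bounds[1] + 1L, bounds[2]))
}
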