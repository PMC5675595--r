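# IUPAC ambiguity codes over the RNA alphabet. N in a *sequence* matches no
# motif position; N in a *pattern* matches any of the four bases.
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

#' Construct an IUPAC motif
#'
#' @param motif_id Identifier (e.g. \code{"SRSF1_1"}).
#' @param rbp_name RNA-binding protein name.
#' @param pattern IUPAC RNA pattern, length >= 2 (e.g. \code{"KGRWGSM"},
#'   the SRSF1 site: K=G/U, R=G/A, W=A/U, S=G/C, M=A/C).
#' @return Object of class \code{iupac_motif}.
#' @export
iupac_motif <- function(motif_id, rbp_name, pattern) {
  pattern <- toupper(chartr("T", "U", pattern))
  chars <- strsplit(pattern, "")[[1]]
  if (length(chars) < 2) stop("motif pattern must have length >= 2")
  bad <- setdiff(chars, names(IUPAC_RNA))
  if (length(bad)) {
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(motif_id = motif_id, rbp_name = rbp_name, pattern = pattern),
            class = "iupac_motif")
}

#' Read a motif collection TSV (motif_id, rbp_name, iupac_pattern)
#' @param path TSV path.
#' @return List of \code{iupac_motif}.
#' @export
read_motifs <- function(path) {
  tab <- read_tsv(path)
  req <- c("motif_id", "rbp_name", "iupac_pattern")
  if (!all(req %in% names(tab))) {
    stop("motif collection must have columns: ", paste(req, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    iupac_motif(tab$motif_id[i], tab$rbp_name[i], tab$iupac_pattern[i])
  })
}

#' Expand an IUPAC motif into its concrete k-mers
#'
#' Cartesian product of the per-position base sets, e.g. \code{"KGRWGSM"}
#' expands to 2*1*2*2*1*2*2 = 32 heptamers.
#'
#' @param motif \code{iupac_motif}.
#' @return Character vector of k-mers over \code{{A,C,G,U}}, sorted.
#' @export
expand_motif <- function(motif) {
  sets <- IUPAC_RNA[strsplit(motif$pattern, "")[[1]]]
  grid <- do.call(expand.grid,
                  c(rev(sets), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(grid)))
}

#' All concrete dinucleotides contained in a motif
#'
#' Union over adjacent pattern positions of the expansions of each two-code
#' window; these are the control features paired with a motif in the
#' enrichment regression.
#'
#' @param motif \code{iupac_motif}.
#' @return Sorted character vector of dinucleotides.
#' @export
motif_dinucleotides <- function(motif) {
  chars <- strsplit(motif$pattern, "")[[1]]
  k <- length(chars)
  dins <- unlist(lapply(seq_len(k - 1L), function(j) {
    as.vector(outer(IUPAC_RNA[[chars[j]]], IUPAC_RNA[[chars[j + 1L]]],
                    paste0))
  }))
  sort(unique(dins))
}

#' Scan a region for perfect IUPAC motif matches
#'
#' Reports every position (overlaps included) where the region matches the
#' motif at all pattern positions. A sequence \code{N} matches no pattern
#' position. Hit coordinates are reported in transcript coordinates by adding
#' the region offset.
#'
#' @param sequence Normalized RNA region sequence.
#' @param motif \code{iupac_motif}.
#' @param region_offset 0-based start of the region within the transcript.
#' @return data.frame with columns \code{start, end} (0-based half-open,
#'   transcript coordinates) and \code{kmer}; zero rows when there is no hit.
#' @export
scan_region <- function(sequence, motif, region_offset = 0L) {
  k <- nchar(motif$pattern)
  L <- nchar(sequence)
  empty <- data.frame(start = integer(), end = integer(),
                      kmer = character(), stringsAsFactors = FALSE)
  if (L < k) return(empty)
  chars <- strsplit(sequence, "")[[1]]
  pat <- strsplit(motif$pattern, "")[[1]]
  ok <- lapply(pat, function(code) chars %in% IUPAC_RNA[[code]])
  m <- rep(TRUE, L - k + 1L)
  for (j in seq_len(k)) m <- m & ok[[j]][j:(L - k + j)]
  starts <- which(m) - 1L
  if (!length(starts)) return(empty)
  data.frame(start = region_offset + starts,
             end = region_offset + starts + k,
             kmer = substring(sequence, starts + 1L, starts + k),
             stringsAsFactors = FALSE)
}

#' Accessibility-weighted motif score of a region
#'
#' The region score is the sum over motif hits of the site accessibility (mean
#' unpaired probability of the site's bases); a region with no hit scores 0.
#' With a uniform track the score equals the raw hit count.
#'
#' @param hits Hit table from [scan_region()] (transcript coordinates).
#' @param track \code{accessibility_track} covering the transcript.
#' @return Scalar >= 0.
#' @export
region_score <- function(hits, track) {
  if (nrow(hits) == 0) return(0)
  if (any(hits$start < 0) || any(hits$end > length(track$p))) {
    stop("motif hit outside accessibility track for ", track$transcript_id)
  }
  sum(vapply(seq_len(nrow(hits)), function(i) {
    site_accessibility(track, hits$start[i], hits$end[i])
  }, numeric(1)))
}

# Overlapping occurrence count of a fixed dinucleotide in a sequence.
count_dinucleotide <- function(sequence, din) {
  L <- nchar(sequence)
  if (L < 2) return(0L)
  chars <- strsplit(sequence, "")[[1]]
  sum(chars[-L] == substr(din, 1, 1) & chars[-1] == substr(din, 2, 2))
}
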