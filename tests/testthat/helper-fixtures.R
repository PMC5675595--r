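# Shared fixtures and independent oracles, built in code at test time.

srsf1_motif <- function() iupac_motif("SRSF1_1", "SRSF1", "KGRWGSM")

# Independent brute-force scanner oracle: expand the motif to its concrete
# k-mers and test every offset by substring membership. Stays deliberately
# separate from the position-set matcher in scan_region().
oracle_scan <- function(sequence, motif, region_offset = 0L) {
  kmers <- expand_motif(motif)
  k <- nchar(motif$pattern)
  L <- nchar(sequence)
  if (L < k) return(integer())
  starts <- which(substring(sequence, seq_len(L - k + 1L),
                            seq_len(L - k + 1L) + k - 1L) %in% kmers) - 1L
  region_offset + starts
}

# Independent dinucleotide oracle via expansion of adjacent code pairs.
oracle_dinucleotides <- function(pattern) {
  m <- iupac_motif("x", "x", pattern)
  full <- expand_motif(m)
  k <- nchar(pattern)
  sort(unique(unlist(lapply(seq_len(k - 1L), function(j) {
    unique(substring(full, j, j + 1L))
  }))))
}

# Random IUPAC pattern; N kept rare so expansions stay small.
random_pattern <- function(len) {
  codes <- c("A", "C", "G", "U", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  w <- c(rep(8, 4), rep(2, 6), rep(1, 4), 0.5)
  paste(sample(codes, len, replace = TRUE, prob = w), collapse = "")
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# A small deterministic transcript set: one gene each, known CDS bounds.
toy_records <- function() {
  validate <- getFromNamespace("validate_transcripts", "retmotif")
  validate(data.frame(
    transcript_id = c("TX1", "TX2"),
    gene_id = c("G1", "G2"),
    sequence = c("AACCCGGGUU", "GGAAGGACCC"),
    cds_start = c(3L, 0L),
    cds_end = c(7L, 7L),
    stringsAsFactors = FALSE))
}

toy_partition <- function(positive, negative) {
  structure(list(positive_ids = positive, negative_ids = negative,
                 parameters = list()),
            class = "gene_set_partition")
}

# Planted-enrichment fixture shared by enrichment and acceptance tests:
# 70 positive 3'UTRs with 4 planted SRSF1 sites, 200 negative backgrounds.
planted_fixture <- function(seed = 1, n_pos = 70, n_neg = 200,
                            sites = 4) {
  motif <- srsf1_motif()
  pos <- sprintf("T%04d", seq_len(n_pos))
  tx <- generate_transcripts(n_pos + n_neg, motif = motif, positive_ids = pos,
                             sites_per_positive = sites, seed = seed)
  list(motif = motif, records = tx$records, truth = tx$truth,
       partition = toy_partition(pos,
                                 sprintf("T%04d", (n_pos + 1):(n_pos + n_neg))))
}

write_fasta_lines <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}
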