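#' Synthetic transcripts with planted motif sites
#'
#' Generates i.i.d. uniform-composition transcripts (fixed-length 5'UTR and
#' CDS, variable 3'UTR) and plants, in the 3'UTR of each positive transcript,
#' \code{sites_per_positive} non-overlapping k-mers drawn uniformly from the
#' motif expansion. All transcripts additionally receive rare background
#' plantings at \code{background_rate} sites/kb of 3'UTR (Poisson), on top of
#' the chance matches implied by uniform composition. The returned truth
#' records every planted position.
#'
#' @param n Number of transcripts (ids \code{T0001...}; one isoform per gene).
#' @param mean_utr3_len Mean 3'UTR length in nt (default 300; lengths are
#'   normal with sd 10% of the mean, floored at twice the motif length plus
#'   the planted span).
#' @param motif \code{iupac_motif} to plant.
#' @param positive_ids Ids (subset of the generated ids) receiving planted
#'   sites.
#' @param sites_per_positive Planted sites per positive 3'UTR (default 4).
#' @param background_rate Background planting rate, sites per kb of 3'UTR
#'   (default 0.2).
#' @param utr5_len,cds_len Fixed 5'UTR and CDS lengths (defaults 50, 300).
#' @param seed RNG seed (required).
#' @return List with \code{records} (\code{transcript_records}) and
#'   \code{truth} (list: planted_sites data.frame, parameters).
#' @export
generate_transcripts <- function(n, mean_utr3_len = 300, motif, positive_ids,
                                 sites_per_positive = 4,
                                 background_rate = 0.2,
                                 utr5_len = 50, cds_len = 300, seed) {
  ids <- sprintf("T%04d", seq_len(n))
  if (!all(positive_ids %in% ids)) {
    stop("positive_ids must be a subset of the generated ids T0001..T",
         sprintf("%04d", n))
  }
  kmers <- expand_motif(motif)
  k <- nchar(motif$pattern)
  with_seed(seed, {
    utr3_len <- pmax(round(stats::rnorm(n, mean_utr3_len,
                                        0.1 * mean_utr3_len)),
                     2L * k + sites_per_positive * k)
    planted <- list()
    seqs <- character(n)
    for (i in seq_len(n)) {
      len <- utr5_len + cds_len + utr3_len[i]
      s <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
      n_plant <- stats::rpois(1, background_rate * utr3_len[i] / 1000)
      type <- rep("background", n_plant)
      if (ids[i] %in% positive_ids) {
        n_plant <- n_plant + sites_per_positive
        type <- c(type, rep("positive", sites_per_positive))
      }
      if (n_plant > 0) {
        starts <- place_sites(utr3_len[i], k, n_plant)
        if (is.null(starts)) {
          stop("3'UTR of ", ids[i], " too short for ", n_plant,
               " non-overlapping sites")
        }
        site_kmers <- sample(kmers, n_plant, replace = TRUE)
        for (j in seq_len(n_plant)) {
          at <- utr5_len + cds_len + starts[j]          # 0-based, transcript
          s[(at + 1L):(at + k)] <- strsplit(site_kmers[j], "")[[1]]
        }
        planted[[ids[i]]] <- data.frame(
          transcript_id = ids[i],
          start = utr5_len + cds_len + starts,
          end = utr5_len + cds_len + starts + k,
          kmer = site_kmers, type = type, stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    records <- validate_transcripts(data.frame(
      transcript_id = ids,
      gene_id = sub("^T", "G", ids),
      sequence = seqs,
      cds_start = utr5_len,
      cds_end = utr5_len + cds_len,
      stringsAsFactors = FALSE))
    planted_sites <- if (length(planted)) do.call(rbind, c(planted,
                                                           make.row.names = FALSE))
      else data.frame(transcript_id = character(), start = integer(),
                      end = integer(), kmer = character(), type = character(),
                      stringsAsFactors = FALSE)
    truth <- list(planted_sites = planted_sites,
                  parameters = list(n = n, mean_utr3_len = mean_utr3_len,
                                    motif = motif$pattern,
                                    positive_ids = positive_ids,
                                    sites_per_positive = sites_per_positive,
                                    background_rate = background_rate,
                                    utr5_len = utr5_len, cds_len = cds_len,
                                    seed = seed))
    list(records = records, truth = truth)
  })
}

# Sample n_sites non-overlapping 0-based start positions for sites of width k
# in a region of the given length; NULL when it cannot be done.
place_sites <- function(region_len, k, n_sites) {
  if (n_sites * k > region_len) return(NULL)
  for (attempt in 1:200) {
    starts <- sort(sample.int(region_len - k + 1L, n_sites) - 1L)
    if (n_sites == 1L || all(diff(starts) >= k)) return(starts)
  }
  # rejection failed (crowded region): deterministic even spacing
  gap <- (region_len - n_sites * k) %/% (n_sites + 1L)
  starts <- cumsum(c(gap, rep(k + gap, n_sites - 1L)))
  if (all(starts + k <= region_len)) starts else NULL
}

#' Synthetic compartment-resolved expression with planted retention
#'
#' Emulates the statistical structure of an LPS time course measured in
#' nuclear and cytoplasmic fractions of WT and KO cells. Baseline abundance is
#' log-normal; LPS multiplies the whole-cell abundance of induced transcripts
#' by \code{induction_fc}; every transcript splits nuclear:cytoplasmic at
#' \code{baseline_nuclear_share}:(1 - share); for planted targets under
#' KO + LPS the nuclear share is rescaled so the noiseless retention index
#' equals \code{retention_multiplier}. Each replicate gets independent
#' multiplicative log-normal noise.
#'
#' @param n Number of transcripts (ids \code{T0001...}).
#' @param frac_induced Fraction of transcripts induced by LPS (default 0.4).
#' @param induction_fc Whole-cell induction fold change (default 8).
#' @param targets Ids with planted KO-specific retention (must be induced;
#'   default: the first \code{min(70, n_induced)} induced ids).
#' @param retention_multiplier Planted index I = R_KO/R_WT (default 3).
#' @param replicates Replicates per condition (default 3).
#' @param log2_noise_sd Replicate noise sd on the log2 scale (default 0.3).
#' @param baseline_abundance Median baseline abundance (default 100).
#' @param baseline_nuclear_share Nuclear fraction of each transcript's
#'   abundance outside the planted effect (default 0.3).
#' @param timepoints Labels, baseline first (default \code{c("0h","LPS_2h")}).
#' @param seed RNG seed (required).
#' @return List with \code{matrix} (\code{compartment_expression}) and
#'   \code{truth} (induced_ids, target_ids, retention_multiplier, parameters).
#' @export
generate_expression <- function(n, frac_induced = 0.4, induction_fc = 8,
                                targets = NULL, retention_multiplier = 3,
                                replicates = 3, log2_noise_sd = 0.3,
                                baseline_abundance = 100,
                                baseline_nuclear_share = 0.3,
                                timepoints = c("0h", "LPS_2h"), seed) {
  stopifnot(n >= 1, frac_induced >= 0, frac_induced <= 1, induction_fc > 0,
            retention_multiplier > 0, replicates >= 1,
            baseline_nuclear_share > 0, baseline_nuclear_share < 1,
            length(timepoints) >= 2)
  ids <- sprintf("T%04d", seq_len(n))
  n_induced <- round(frac_induced * n)
  induced_ids <- ids[seq_len(n_induced)]
  targets <- targets %||% induced_ids[seq_len(min(70L, n_induced))]
  if (!all(targets %in% induced_ids)) {
    stop("planted retention targets must be induced transcripts")
  }
  b <- baseline_nuclear_share
  m <- retention_multiplier
  ko_share <- m * b / (1 - b + m * b)
  if (!is.finite(ko_share) || ko_share >= 1) {
    stop("retention multiplier yields nuclear share >= 1")
  }
  with_seed(seed, {
    base <- stats::rlnorm(n, meanlog = log(baseline_abundance), sdlog = 1)
    grid <- expand.grid(replicate = seq_len(replicates),
                        compartment = c("nuclear", "cytoplasmic"),
                        genotype = c("WT", "KO"),
                        timepoint = timepoints,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("genotype", "compartment", "timepoint", "replicate")]
    grid$sample_id <- sprintf("%s_%s_%s_r%d", grid$genotype,
                              substr(grid$compartment, 1, 3), grid$timepoint,
                              grid$replicate)
    values <- matrix(0, n, nrow(grid), dimnames = list(ids, grid$sample_id))
    lps <- grid$timepoint != timepoints[1]
    for (j in seq_len(nrow(grid))) {
      total <- base
      if (lps[j]) total[ids %in% induced_ids] <-
          total[ids %in% induced_ids] * induction_fc
      share <- rep(b, n)
      if (lps[j] && grid$genotype[j] == "KO") share[ids %in% targets] <- ko_share
      frac <- if (grid$compartment[j] == "nuclear") share else 1 - share
      noise <- 2^stats::rnorm(n, 0, log2_noise_sd)
      values[, j] <- total * frac * noise
    }
    truth <- list(induced_ids = induced_ids, target_ids = targets,
                  retention_multiplier = m, induction_fc = induction_fc,
                  parameters = list(n = n, frac_induced = frac_induced,
                                    replicates = replicates,
                                    log2_noise_sd = log2_noise_sd,
                                    baseline_abundance = baseline_abundance,
                                    baseline_nuclear_share = b,
                                    timepoints = timepoints, seed = seed))
    list(matrix = expression_matrix(values, grid), truth = truth)
  })
}

#' Synthetic RIP-qPCR Ct table with known enrichment
#'
#' Builds, per target, one specific-antibody and one IgG row sharing input Ct
#' and saved fraction, constructed so the noiseless fold enrichment equals
#' \code{true_enrichment}; Gaussian noise (sd \code{ct_noise_sd}) is then
#' added to every Ct independently.
#'
#' @param targets Character vector of target ids.
#' @param true_enrichment True fold enrichment per target (recycled).
#' @param ct_noise_sd Gaussian Ct noise sd (default 0.2).
#' @param ct_input Input Ct (default 20).
#' @param fraction_input_saved Saved input fraction (default 0.1).
#' @param igg_dct Normalized delta-Ct of the IgG control (default 8).
#' @param seed RNG seed (required).
#' @return List with \code{table} (RIP input data.frame) and \code{truth}.
#' @export
generate_rip_table <- function(targets, true_enrichment, ct_noise_sd = 0.2,
                               ct_input = 20, fraction_input_saved = 0.1,
                               igg_dct = 8, seed) {
  if (any(true_enrichment <= 0)) stop("true enrichment must be positive")
  nt <- length(targets)
  enr <- rep_len(true_enrichment, nt)
  with_seed(seed, {
    offset <- ct_input - log2(fraction_input_saved)
    ct_ns <- offset + igg_dct
    ct_rip <- offset + igg_dct - log2(enr)
    table <- data.frame(
      target_id = rep(targets, each = 2L),
      antibody = rep(c("specific", "IgG"), nt),
      ct = as.vector(rbind(ct_rip, ct_ns)) + stats::rnorm(2L * nt, 0,
                                                          ct_noise_sd),
      ct_input = ct_input,
      fraction_input_saved = fraction_input_saved,
      stringsAsFactors = FALSE)
    list(table = table,
         truth = list(true_enrichment = stats::setNames(enr, targets),
                      parameters = list(ct_noise_sd = ct_noise_sd,
                                        ct_input = ct_input,
                                        fraction_input_saved =
                                          fraction_input_saved,
                                        igg_dct = igg_dct, seed = seed)))
  })
}

#' Write a full synthetic dataset to disk
#'
#' Generates linked transcripts, expression, and RIP tables with consistent
#' planted structure (the expression targets are the motif-planted positive
#' transcripts) and writes FASTA, annotation TSV, expression + metadata TSVs,
#' RIP TSV and a truth JSON into \code{dir}.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of transcripts (default 500).
#' @param n_positive Number of planted retention/motif targets (default 70).
#' @param motif \code{iupac_motif} (default the SRSF1 site KGRWGSM).
#' @param seed RNG seed (required).
#' @param ... Passed on to [generate_expression()].
#' @return Invisible named vector of written paths.
#' @export
simulate_dataset <- function(dir, n = 500, n_positive = 70,
                             motif = iupac_motif("SRSF1_1", "SRSF1",
                                                 "KGRWGSM"),
                             seed, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frac_induced <- list(...)$frac_induced %||% 0.4
  n_induced <- round(frac_induced * n)
  if (n_positive > n_induced) {
    warning("only ", n_induced, " induced transcripts; clamping n_positive ",
            "from ", n_positive)
    n_positive <- n_induced
  }
  # the planted retention targets and the motif-planted positives coincide
  targets <- sprintf("T%04d", seq_len(n_positive))
  expr <- generate_expression(n, targets = targets, seed = seed, ...)
  tx <- generate_transcripts(n, motif = motif, positive_ids = targets,
                             seed = seed + 1L)
  rip <- generate_rip_table(targets[seq_len(min(10L, length(targets)))],
                            true_enrichment = 8, seed = seed + 2L)
  paths <- c(fasta = file.path(dir, "transcripts.fa"),
             annotation = file.path(dir, "annotation.tsv"),
             expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             rip = file.path(dir, "rip.tsv"),
             truth = file.path(dir, "truth.json"))
  write_transcripts_fasta(tx$records, paths["fasta"])
  write_tsv(tx$records[, c("transcript_id", "gene_id", "cds_start",
                           "cds_end")], paths["annotation"])
  write_expression(expr$matrix, paths["expression"], paths["samples"])
  write_tsv(rip$table, paths["rip"])
  jsonlite::write_json(list(transcripts = tx$truth, expression = expr$truth,
                            rip = rip$truth),
                       paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Write transcript records as FASTA
#' @param records \code{transcript_records}.
#' @param path Output path.
#' @export
write_transcripts_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(records$sequence)
  names(seqs) <- records$transcript_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
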