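#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form \code{key = value} (or \code{key: value}); blank lines
#' and \code{#} comments ignored. Values are returned as character and
#' coerced where the pipeline expects numbers.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("unparseable config line(s): ",
                     paste(lines[bad], collapse = " | "))
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, `[`, character(1), 2L))
}

pipeline_defaults <- function() {
  list(region = "three_prime_utr", positive_size = 70,
       induction_fc_threshold = 2, negative_threshold = 1.1, eps = 1,
       accessibility = "uniform", folds = 5,
       baseline_timepoint = NULL, lps_timepoint = NULL)
}

#' Run the end-to-end retention + motif-enrichment pipeline
#'
#' Stages: read transcripts (FASTA + annotation, longest isoform per gene);
#' read compartment expression; build the retention table; partition into
#' positive/negative sets; test every motif in the collection; write the
#' retention table, partition (TSV + id lists), enrichment report and a run
#' manifest (parameters, seed, package version, input checksums). Outputs are
#' deterministic for a fixed (config, seed); on any stage failure the files
#' written so far are removed and the error names the stage.
#'
#' @param config Named list (or path to a key = value file, see
#'   [read_pipeline_config()]) with keys: \code{fasta, annotation,
#'   expression, samples, motifs, out_dir} and optionally \code{region,
#'   positive_size, induction_fc_threshold, negative_threshold, eps,
#'   accessibility} (\code{"uniform"} or \code{"dir:<path>"}),
#'   \code{folds, baseline_timepoint, lps_timepoint, rip}.
#' @param seed RNG seed (required; recorded in the manifest).
#' @return Invisible named vector of output paths.
#' @export
run_pipeline <- function(config, seed) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  for (key in c("fasta", "annotation", "expression", "samples", "motifs",
                "out_dir")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  }
  for (key in c("positive_size", "induction_fc_threshold",
                "negative_threshold", "eps", "folds")) {
    cfg[[key]] <- as.numeric(cfg[[key]])
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- c(retention = file.path(cfg$out_dir, "retention_table.tsv"),
           partition = file.path(cfg$out_dir, "partition.tsv"),
           enrichment = file.path(cfg$out_dir, "enrichment.tsv"),
           manifest = file.path(cfg$out_dir, "manifest.json"))
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(c(written, paste0(out["partition"], c(".positive.txt",
                                                   ".negative.txt"))))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("gene_models", {
    select_longest_isoform(read_transcripts(cfg$fasta, cfg$annotation))
  })
  expr <- stage("compartment_analysis", {
    read_expression(cfg$expression, cfg$samples)
  })
  ret <- stage("compartment_analysis", {
    retention_table(expr, baseline_timepoint = cfg$baseline_timepoint,
                    lps_timepoint = cfg$lps_timepoint,
                    fc_threshold = cfg$induction_fc_threshold, eps = cfg$eps)
  })
  part <- stage("compartment_analysis", {
    rank_and_partition(ret, positive_size = cfg$positive_size,
                       negative_threshold = cfg$negative_threshold)
  })
  provider <- stage("accessibility", {
    if (identical(cfg$accessibility, "uniform")) {
      accessibility_provider("uniform")
    } else if (startsWith(cfg$accessibility, "dir:")) {
      accessibility_provider("file", dir = sub("^dir:", "",
                                               cfg$accessibility))
    } else stop("accessibility must be 'uniform' or 'dir:<path>'")
  })
  motifs <- stage("motif_enrichment", read_motifs(cfg$motifs))
  report <- stage("motif_enrichment", {
    scan_collection(motifs, part, records, region = cfg$region,
                    provider = provider, folds = cfg$folds, seed = seed)
  })

  stage("report", {
    write_tsv(ret, out["retention"]); written <- c(written, out["retention"])
    write_partition(part, out["partition"])
    written <- c(written, out["partition"])
    write_tsv(report, out["enrichment"])
    written <- c(written, out["enrichment"])
    if (!is.null(cfg$rip)) {
      rip_out <- file.path(cfg$out_dir, "rip_enrichment.tsv")
      write_tsv(rip_analysis(cfg$rip), rip_out)
      out <- c(out, rip = rip_out)
      written <- c(written, rip_out)
    }
    inputs <- unlist(cfg[c("fasta", "annotation", "expression", "samples",
                           "motifs", "rip")])
    manifest <- list(
      package = "retmotif",
      version = as.character(utils::packageVersion("retmotif")),
      seed = seed,
      parameters = cfg[setdiff(names(cfg), "out_dir")],
      input_md5 = as.list(tools::md5sum(inputs)),
      n_transcripts = nrow(records),
      n_induced = sum(ret$induced),
      n_positive = length(part$positive_ids),
      n_negative = length(part$negative_ids))
    jsonlite::write_json(manifest, out["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    written <- c(written, out["manifest"])
  })
  invisible(out)
}
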