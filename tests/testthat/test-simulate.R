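test_that("planted motif sites are present and recorded in the truth", {
  m <- srsf1_motif()
  pos <- sprintf("T%04d", 1:10)
  g <- generate_transcripts(30, motif = m, positive_ids = pos,
                            sites_per_positive = 4, seed = 5)
  kmers <- expand_motif(m)
  planted <- g$truth$planted_sites
  expect_true(all(planted$kmer %in% kmers))
  for (id in pos) {
    rec <- g$records[g$records$transcript_id == id, ]
    reg <- extract_region(rec, "three_prime_utr")
    hits <- scan_region(reg$sequence, m, reg$offset)
    expect_gte(nrow(hits), 4)
    # every recorded planted position really carries its k-mer
    ps <- planted[planted$transcript_id == id, ]
    expect_identical(substring(rec$sequence, ps$start + 1, ps$end), ps$kmer)
    # planted sites do not overlap
    ps <- ps[order(ps$start), ]
    if (nrow(ps) > 1) expect_true(all(diff(ps$start) >= 7))
  }
  expect_error(generate_transcripts(5, motif = m, positive_ids = "T0099",
                                    seed = 1), "subset")
})

test_that("unplanted hit counts are consistent with the binomial background", {
  m <- srsf1_motif()                      # 32 / 4^7 ~ 0.195% per position
  g <- generate_transcripts(500, motif = m, positive_ids = character(),
                            sites_per_positive = 0, background_rate = 0,
                            seed = 11)
  hits <- vapply(seq_len(nrow(g$records)), function(i) {
    reg <- extract_region(g$records[i, ], "three_prime_utr")
    nrow(scan_region(reg$sequence, m, reg$offset))
  }, numeric(1))
  positions <- sum(nchar(g$records$sequence) - g$records$cds_end - 6)
  p0 <- length(expand_motif(m)) / 4^7
  # total hit count within 4 sd of the binomial expectation
  expect_lt(abs(sum(hits) - positions * p0),
            4 * sqrt(positions * p0 * (1 - p0)))
  expect_equal(nrow(g$truth$planted_sites), 0L)
})

test_that("generators are pure functions of parameters and seed", {
  m <- srsf1_motif()
  a <- generate_transcripts(20, motif = m, positive_ids = "T0001", seed = 3)
  b <- generate_transcripts(20, motif = m, positive_ids = "T0001", seed = 3)
  expect_identical(a$records$sequence, b$records$sequence)
  c <- generate_transcripts(20, motif = m, positive_ids = "T0001", seed = 4)
  expect_false(identical(a$records$sequence, c$records$sequence))

  e1 <- generate_expression(30, seed = 6)
  e2 <- generate_expression(30, seed = 6)
  expect_identical(e1$matrix$values, e2$matrix$values)

  r1 <- generate_rip_table("t", 8, seed = 2)
  r2 <- generate_rip_table("t", 8, seed = 2)
  expect_identical(r1$table$ct, r2$table$ct)

  # the global RNG stream is left untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_expression(10, seed = 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("simulate_dataset writes a coherent, re-readable bundle", {
  d <- file.path(tempdir(), "simbundle")
  paths <- simulate_dataset(d, n = 120, n_positive = 20, seed = 2)
  expect_true(all(file.exists(paths)))
  rec <- read_transcripts(paths["fasta"], paths["annotation"])
  expect_equal(nrow(rec), 120)
  x <- read_expression(paths["expression"], paths["samples"])
  expect_equal(nrow(x$values), 120)
  rip <- rip_analysis(paths[["rip"]])
  expect_gt(median(rip$fold_enrichment), 1)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_length(truth$expression$target_ids, 20)
  expect_length(truth$rip$true_enrichment, 10)
  unlink(d, recursive = TRUE)
})
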