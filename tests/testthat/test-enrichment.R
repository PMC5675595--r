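test_that("feature tables carry motif score, controls and length", {
  fx <- planted_fixture(seed = 1, n_pos = 8, n_neg = 12)
  tab <- build_feature_table(fx$partition, fx$records, fx$motif)
  expect_identical(names(tab)[1:3], c("transcript_id", "label", "motif_score"))
  expect_true("region_length" %in% names(tab))
  expect_length(grep("^din_", names(tab)), 10)
  expect_false(anyNA(tab))
  expect_true(all(tab$motif_score >= 0))
  expect_identical(tab$label, rep(c(1L, 0L), c(8, 12)))
  # planted signal shows in the mean motif score
  expect_gt(mean(tab$motif_score[tab$label == 1]),
            mean(tab$motif_score[tab$label == 0]))
  # with the uniform provider the score is the raw hit count
  for (i in sample(nrow(tab), 5)) {
    rec <- fx$records[fx$records$transcript_id == tab$transcript_id[i], ]
    reg <- extract_region(rec, "three_prime_utr")
    expect_equal(tab$motif_score[i],
                 nrow(scan_region(reg$sequence, fx$motif, reg$offset)))
  }
  # overlapping dinucleotide counting convention
  expect_equal(getFromNamespace("count_dinucleotide", "retmotif")("GGGG",
                                                                  "GG"), 3L)
  expect_error(build_feature_table(toy_partition("NOPE", "TX1"),
                                   fx$records, fx$motif), "NOPE")
})

test_that("empty regions are retained with zero features and a warning", {
  validate <- getFromNamespace("validate_transcripts", "retmotif")
  rec <- validate(data.frame(
    transcript_id = c("TA", "TB"), gene_id = c("GA", "GB"),
    sequence = c("GGAAGGAGGG", "AAGGAAGGAA"),
    cds_start = c(0L, 0L), cds_end = c(10L, 5L), stringsAsFactors = FALSE))
  expect_warning(
    tab <- build_feature_table(toy_partition("TA", "TB"), rec, srsf1_motif()),
    "empty")
  ta <- tab[tab$transcript_id == "TA", ]
  expect_true(all(ta[, -(1:2)] == 0))
})

test_that("lasso CV selects the separating score and handles degenerate input", {
  # all-zero features: nothing to select
  zero <- data.frame(transcript_id = paste0("t", 1:20),
                     label = rep(c(1L, 0L), 10),
                     motif_score = 0, din_AA = 0, region_length = 0,
                     check.names = FALSE)
  sel0 <- fit_lasso_cv(zero, seed = 1)
  expect_length(sel0$selected_features, 0)
  expect_error(fit_lasso_cv(zero[zero$label == 1, ], seed = 1),
               "single-class")

  # a perfectly separating motif_score with noise controls is found
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    tab <- data.frame(transcript_id = paste0("t", 1:n),
                      label = rep(c(1L, 0L), each = n / 2),
                      motif_score = rep(c(3, 0), each = n / 2) + runif(n, 0, 0.5),
                      din_AA = rnorm(n), din_GG = rnorm(n),
                      region_length = rnorm(n, 300, 20), check.names = FALSE)
    sel <- fit_lasso_cv(tab, seed = s)
    hits <- hits + ("motif_score" %in% sel$selected_features)
  }
  expect_gte(hits, 19)
})

test_that("lasso rarely selects the motif under permuted labels", {
  fx <- planted_fixture(seed = 1)
  tab <- build_feature_table(fx$partition, fx$records, fx$motif)
  picked <- 0L
  for (s in 1:50) {
    ptab <- tab
    set.seed(1000 + s)
    ptab$label <- sample(ptab$label)
    sel <- fit_lasso_cv(ptab, seed = s)
    picked <- picked + ("motif_score" %in% sel$selected_features)
  }
  expect_lte(picked, 10)   # <= 20% of 50 null permutations
})

test_that("the nested LRT follows its conventions and the chi-square tail", {
  fx <- planted_fixture(seed = 1, n_pos = 10, n_neg = 15)
  tab <- build_feature_table(fx$partition, fx$records, fx$motif)
  # motif not selected -> p = 1 by convention
  r0 <- nested_lrt(tab, c("din_GG", "region_length"))
  expect_false(r0$motif_selected)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$lrt_statistic, 0)
  expect_equal(r0$df, 0L)
  # chi-square(1) upper tail oracle
  expect_equal(stats::pchisq(10.83, 1, lower.tail = FALSE), 0.000998,
               tolerance = 1e-3)
  # full vs reduced computed by independent glm fits
  r1 <- nested_lrt(tab, c("motif_score", "region_length"))
  f_full <- suppressWarnings(
    stats::glm(label ~ motif_score + region_length, data = tab,
               family = binomial()))
  f_red <- suppressWarnings(
    stats::glm(label ~ region_length, data = tab, family = binomial()))
  stat <- 2 * as.numeric(logLik(f_full) - logLik(f_red))
  expect_equal(r1$lrt_statistic, stat, tolerance = 1e-6)
  expect_equal(r1$df, 1L)
  expect_equal(r1$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_gte(r1$lrt_statistic, 0)
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
})

test_that("identical classes give no signal; planted motif ranks first", {
  # all-identical sequences in both classes -> every motif p = 1
  validate <- getFromNamespace("validate_transcripts", "retmotif")
  same <- validate(data.frame(
    transcript_id = sprintf("S%02d", 1:12),
    gene_id = sprintf("g%02d", 1:12),
    sequence = strrep("ACGU", 30),
    cds_start = 10L, cds_end = 60L, stringsAsFactors = FALSE))
  part <- toy_partition(sprintf("S%02d", 1:6), sprintf("S%02d", 7:12))
  motifs <- list(srsf1_motif(), iupac_motif("d1", "d1", "ACGU"))
  rep_same <- scan_collection(motifs, part, same, seed = 1)
  expect_true(all(rep_same$p_value == 1))

  # planted enrichment + decoys: the planted motif wins
  fx <- planted_fixture(seed = 1)
  decoys <- list(iupac_motif("d1", "RBFOX", "UGCAUG"),
                 iupac_motif("d2", "PUM", "UGUANAUA"),
                 iupac_motif("d3", "ELAVL", "UUUUUUU"),
                 iupac_motif("d4", "NOVA", "YCAY"))
  rep <- scan_collection(c(list(fx$motif), decoys), fx$partition, fx$records,
                         seed = 1)
  expect_identical(rep$motif_id[1], "SRSF1_1")
  expect_lt(rep$p_value[1], 0.0004)
  expect_true(all(diff(rep$p_value) >= 0))
  expect_true(all(rep$q_value >= rep$p_value - 1e-12))
  # single-motif collection equals the single-motif run
  one <- scan_collection(list(fx$motif), fx$partition, fx$records, seed = 1)
  single <- test_motif_enrichment(fx$partition, fx$records, fx$motif,
                                  seed = 1)
  expect_equal(one$p_value, single$p_value, tolerance = 1e-12)
  expect_equal(one$lrt_stat, single$lrt_statistic, tolerance = 1e-9)

  # a failing motif yields an error row, not a crash
  bad <- fx$partition
  bad$positive_ids <- c(bad$positive_ids, "MISSING")
  rep_bad <- scan_collection(list(fx$motif), bad, fx$records, seed = 1)
  expect_match(rep_bad$flags[1], "error:")
  expect_true(is.na(rep_bad$p_value[1]))
})

test_that("enrichment results are deterministic for fixed inputs and seed", {
  fx <- planted_fixture(seed = 2, n_pos = 15, n_neg = 30)
  r1 <- test_motif_enrichment(fx$partition, fx$records, fx$motif, seed = 7)
  r2 <- test_motif_enrichment(fx$partition, fx$records, fx$motif, seed = 7)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})
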