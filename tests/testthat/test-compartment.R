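test_that("replicate summaries and missing cells behave as documented", {
  values <- matrix(c(10, 14, 7, 7), nrow = 1,
                   dimnames = list("TX1", paste0("s", 1:4)))
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        genotype = "WT",
                        compartment = c("nuclear", "nuclear", "cytoplasmic",
                                        "cytoplasmic"),
                        timepoint = c("0h", "0h", "0h", "LPS_2h"),
                        replicate = c(1, 2, 1, 1))
  x <- expression_matrix(values, samples)
  expect_equal(unname(summarize_abundance(x, "WT", "nuclear", "0h")), 12)
  expect_equal(unname(summarize_abundance(x, "WT", "cytoplasmic", "LPS_2h")), 7)
  expect_error(summarize_abundance(x, "WT", "nuclear", "LPS_9h"),
               "LPS_9h")
})

test_that("retention ratio and index follow the N/C and KO/WT formulas", {
  expect_equal(retention_ratio(10, 5, eps = 0), 2)
  expect_equal(retention_ratio(37, 37, eps = 3), 1)
  expect_equal(retention_ratio(0, 0, eps = 1), 1)
  expect_equal(retention_index(4, 2), 2)
  expect_equal(retention_index(0.7, 0.7), 1)
  expect_error(retention_index(-1, 2), "positive")
  expect_error(retention_index(1, 0), "positive")
})

test_that("induction calls recover planted induced transcripts", {
  expect_error(call_induced(generate_expression(20, seed = 1)$matrix,
                            "0h", "LPS_2h", fc_threshold = -1), "positive")
  g <- generate_expression(200, log2_noise_sd = 0.1, seed = 1)
  ind <- call_induced(g$matrix, "0h", "LPS_2h", fc_threshold = 2)
  expect_gte(sum(g$truth$induced_ids %in% ind), 78)
  expect_length(setdiff(ind, g$truth$induced_ids), 0)
})

test_that("index recovers the planted retention multiplier (5 seeds)", {
  med <- vapply(1:5, function(s) {
    g <- generate_expression(500, seed = s)
    rt <- retention_table(g$matrix)
    median(rt$I[rt$transcript_id %in% g$truth$target_ids])
  }, numeric(1))
  expect_true(all(med >= 2.7 & med <= 3.3))
})

test_that("index is scale-invariant per genotype and 1 under no effect", {
  g <- generate_expression(60, retention_multiplier = 2, seed = 3)
  x <- g$matrix
  rt1 <- retention_table(x, eps = 0)
  ko <- x$samples$genotype == "KO"
  x2 <- x
  x2$values[, ko] <- x2$values[, ko] * 7.3
  rt2 <- retention_table(x2, eps = 0)
  expect_equal(rt2$I, rt1$I, tolerance = 1e-12)

  g0 <- generate_expression(40, retention_multiplier = 1, log2_noise_sd = 0,
                            seed = 4)
  rt0 <- retention_table(g0$matrix, eps = 0)
  expect_equal(rt0$I, rep(1, 40), tolerance = 1e-12)
  # noiseless planted effect is exact
  g3 <- generate_expression(40, retention_multiplier = 3, log2_noise_sd = 0,
                            seed = 4)
  rt3 <- retention_table(g3$matrix, eps = 0)
  on_target <- rt3$transcript_id %in% g3$truth$target_ids
  expect_equal(rt3$I[on_target], rep(3, sum(on_target)), tolerance = 1e-12)
  expect_equal(rt3$I[!on_target], rep(1, sum(!on_target)), tolerance = 1e-12)
})

test_that("ranking and partitioning clamp, break ties, and stay disjoint", {
  g <- generate_expression(500, seed = 1)          # 200 induced, 70 targets
  rt <- retention_table(g$matrix)
  part <- rank_and_partition(rt)
  expect_length(part$positive_ids, 70)
  expect_length(intersect(part$positive_ids, part$negative_ids), 0)
  expect_true(all(c(part$positive_ids, part$negative_ids) %in%
                    rt$transcript_id[rt$induced]))
  expect_gte(sum(g$truth$target_ids %in% part$positive_ids), 60)
  # deterministic
  part2 <- rank_and_partition(retention_table(g$matrix))
  expect_identical(part2$positive_ids, part$positive_ids)

  g2 <- generate_expression(120, seed = 2)          # 48 induced < 70
  expect_warning(p2 <- rank_and_partition(retention_table(g2$matrix)),
                 "clamped")
  expect_length(p2$positive_ids, 48)

  # boundary tie goes to the lexicographically smaller id
  tab <- data.frame(transcript_id = c("TB", "TA", "TC"),
                    N_WT = 1, C_WT = 1, N_KO = 1, C_KO = 1,
                    R_WT = 1, R_KO = 1, I = c(2, 2, 3), induced = TRUE,
                    rank = NA_integer_)
  ind <- which(tab$induced)
  ord <- ind[order(-tab$I[ind], tab$transcript_id[ind])]
  tab$rank[ord] <- seq_along(ord)
  p3 <- rank_and_partition(tab, positive_size = 2, negative_threshold = 5)
  expect_identical(p3$positive_ids, c("TC", "TA"))
  expect_identical(p3$negative_ids, "TB")
})

test_that("expression matrices round-trip through TSV", {
  g <- generate_expression(25, seed = 9)
  vp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_expression(g$matrix, vp, sp)
  back <- read_expression(vp, sp)
  expect_equal(back$values, g$matrix$values, tolerance = 1e-12)
  expect_identical(back$samples$sample_id, g$matrix$samples$sample_id)
})
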