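#' Build the per-motif feature table for enrichment testing
#'
#' For every transcript of the positive and negative sets, computes in the
#' chosen regulatory region: the accessibility-weighted motif score
#' ([region_score()]), the overlapping occurrence count of every dinucleotide
#' contained in the motif (the control features), and the region length in nt.
#' Labels are 1 for the positive set, 0 for the negative set. Empty regions
#' are retained (all features 0) with a warning.
#'
#' @param partition \code{gene_set_partition}.
#' @param records \code{transcript_records} covering every partition member.
#' @param motif \code{iupac_motif}.
#' @param region Region kind, see [extract_region()].
#' @param provider Accessibility provider from [accessibility_provider()]
#'   (default uniform).
#' @param dinucleotide_mode \code{"count"} (default) or \code{"frequency"}
#'   (count / region length).
#' @return data.frame with columns \code{transcript_id, label, motif_score,
#'   din_<XY>..., region_length}; attribute \code{motif} carries the motif.
#' @export
build_feature_table <- function(partition, records, motif,
                                region = "three_prime_utr",
                                provider = accessibility_provider("uniform"),
                                dinucleotide_mode = c("count", "frequency")) {
  dinucleotide_mode <- match.arg(dinucleotide_mode)
  ids <- c(partition$positive_ids, partition$negative_ids)
  missing <- setdiff(ids, records$transcript_id)
  if (length(missing)) {
    stop("no sequence for partition member(s): ",
         paste(missing, collapse = ", "))
  }
  dins <- motif_dinucleotides(motif)
  rows <- lapply(ids, function(id) {
    rec <- records[records$transcript_id == id, , drop = FALSE]
    reg <- extract_region(rec, region)
    len <- nchar(reg$sequence)
    if (len == 0L) {
      score <- 0
      counts <- rep(0, length(dins))
    } else {
      track <- provider(id, nchar(rec$sequence))
      hits <- scan_region(reg$sequence, motif, reg$offset)
      score <- region_score(hits, track)
      counts <- vapply(dins, count_dinucleotide, integer(1),
                       sequence = reg$sequence)
      if (dinucleotide_mode == "frequency") counts <- counts / len
    }
    c(score, counts, len)
  })
  n_empty <- sum(vapply(rows, function(r) r[length(r)] == 0, logical(1)))
  if (n_empty > 0) {
    warning(n_empty, " transcript(s) have an empty ", region,
            "; their features are all zero")
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("motif_score", paste0("din_", dins), "region_length")
  tab <- data.frame(transcript_id = ids,
                    label = rep(c(1L, 0L),
                                c(length(partition$positive_ids),
                                  length(partition$negative_ids))),
                    mat, stringsAsFactors = FALSE, check.names = FALSE)
  attr(tab, "motif") <- motif
  tab
}

# Feature matrix (numeric columns only) and labels from a feature table.
feature_matrix <- function(table) {
  cols <- setdiff(names(table), c("transcript_id", "label"))
  list(x = as.matrix(table[, cols, drop = FALSE]), y = table$label)
}

# Stratified fold assignment: within each class, folds are dealt round-robin
# over a seeded permutation so both classes appear in every fold.
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    foldid <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      foldid[idx] <- rep_len(seq_len(folds), length(idx))
    }
    foldid
  })
}

# Mean binomial deviance of predicted probabilities against 0/1 labels.
binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Lasso-penalized logistic regression with cross-validated penalty
#'
#' Features are standardized to zero mean and unit variance, then fit on the
#' default penalty path of the L1-penalized logistic model (100 values,
#' geometric from the smallest all-zero penalty down to
#' \code{lambda_max * r}, r = 0.01 when rows < columns else 1e-4). The penalty
#' is chosen by stratified k-fold cross-validation minimizing mean binomial
#' deviance across folds; ties go to the stronger penalty. The final model is
#' refit on all rows at the selected penalty and features with non-zero
#' coefficients (|w| > 1e-9, standardized scale) are reported.
#'
#' @param table Feature table from [build_feature_table()].
#' @param folds Number of CV folds (default 5).
#' @param seed RNG seed for the fold assignment (required).
#' @return List with \code{lambda_selected}, \code{selected_features},
#'   \code{weights} (named, standardized scale, intercept included),
#'   \code{lambda_path}, \code{cv_deviance}, \code{foldid}.
#' @export
fit_lasso_cv <- function(table, folds = 5, seed) {
  fm <- feature_matrix(table)
  x <- fm$x; y <- fm$y
  if (length(unique(y)) < 2) stop("labels are single-class; cannot fit")
  if (min(table(y)) < 2) stop("need >= 2 rows per class")
  if (nrow(x) < folds) stop("fewer rows than folds")
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  keep <- scale_ > 0
  if (!any(keep)) {
    return(list(lambda_selected = NA_real_, selected_features = character(),
                weights = c(`(Intercept)` = stats::qlogis(mean(y))),
                lambda_path = numeric(), cv_deviance = numeric(),
                foldid = stratified_folds(y, folds, seed)))
  }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2,
              scale_[keep], `/`)
  if (ncol(xs) == 1L) {
    # glmnet requires >= 2 columns; pad with a zero column that can never be
    # selected (penalized, no variance in signal direction).
    xs <- cbind(xs, .pad = 0)
  }
  lmr <- if (nrow(xs) < ncol(xs)) 0.01 else 1e-4
  full <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                         standardize = FALSE, nlambda = 100,
                         lambda.min.ratio = lmr)
  lambda_path <- full$lambda
  foldid <- stratified_folds(y, folds, seed)
  dev <- matrix(NA_real_, folds, length(lambda_path))
  for (f in seq_len(folds)) {
    train <- foldid != f
    fit_f <- glmnet::glmnet(xs[train, , drop = FALSE], y[train],
                            family = "binomial", alpha = 1,
                            standardize = FALSE, lambda = lambda_path)
    p <- stats::predict(fit_f, xs[!train, , drop = FALSE], type = "response")
    dev[f, ] <- apply(p, 2, binomial_deviance, y = y[!train])
  }
  mean_dev <- colMeans(dev)
  # lambda_path is decreasing, so the first index among ties is the
  # strongest penalty.
  best <- which(mean_dev <= min(mean_dev) + 1e-12)[1]
  lambda_selected <- lambda_path[best]
  w <- as.numeric(stats::coef(full, s = lambda_selected, exact = FALSE))
  names(w) <- rownames(stats::coef(full))
  w <- w[names(w) != ".pad"]
  feat <- setdiff(names(w), "(Intercept)")
  selected <- feat[abs(w[feat]) > 1e-9]
  list(lambda_selected = lambda_selected, selected_features = selected,
       weights = w, lambda_path = lambda_path, cv_deviance = mean_dev,
       foldid = foldid)
}

# Unpenalized logistic fit returning log-likelihood and diagnostics.
# Separation shows up as the "fitted probabilities numerically 0 or 1"
# warning; the fit is kept at the iteration cap and flagged.
logistic_loglik <- function(x, y, features) {
  df <- data.frame(y = y)
  if (length(features)) df <- cbind(df, as.data.frame(x[, features,
                                                        drop = FALSE]))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    # fallback: damp with a tiny ridge via one-step refit on jittered start
    fit2 <- try(stats::glm(y ~ ., data = df, family = stats::binomial(),
                           control = stats::glm.control(maxit = 1000,
                                                        epsilon = 1e-6)),
                silent = TRUE)
    if (inherits(fit2, "try-error") || !fit2$converged) {
      stop("logistic model failed to converge for features: ",
           paste(features, collapse = ", "))
    }
    fit <- fit2
  }
  list(loglik = as.numeric(stats::logLik(fit)), separation = sep,
       converged = fit$converged)
}

#' Nested-model likelihood-ratio test for a motif
#'
#' Given the Lasso-selected feature set, fits two unpenalized logistic
#' regressions on the raw features: the full model on all selected features
#' and the reduced model on the selected control features only (intercept
#' always included). The statistic is twice the log-likelihood difference,
#' referred to a chi-square with 1 degree of freedom (each motif contributes
#' exactly one score feature). If the motif score was not selected, the motif
#' is reported as not enriched with p = 1. Under perfect separation the
#' statistic comes from the iteration-capped fit and the p-value is flagged as
#' an upper bound.
#'
#' @param table Feature table from [build_feature_table()].
#' @param selected_features Character vector from [fit_lasso_cv()].
#' @param lambda_selected Optional penalty to record in the result.
#' @return List of class \code{enrichment_result} with \code{motif_id,
#'   rbp_name, lambda_selected, selected_features, motif_selected,
#'   lrt_statistic, df, p_value, separation, p_is_upper_bound, converged}.
#' @export
nested_lrt <- function(table, selected_features, lambda_selected = NA_real_) {
  motif <- attr(table, "motif")
  fm <- feature_matrix(table)
  motif_selected <- "motif_score" %in% selected_features
  if (!motif_selected) {
    res <- list(lrt_statistic = 0, df = 0L, p_value = 1,
                separation = FALSE, converged = TRUE)
  } else {
    controls <- setdiff(selected_features, "motif_score")
    full <- logistic_loglik(fm$x, fm$y, selected_features)
    reduced <- logistic_loglik(fm$x, fm$y, controls)
    stat <- max(0, 2 * (full$loglik - reduced$loglik))
    res <- list(lrt_statistic = stat, df = 1L,
                p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                separation = full$separation || reduced$separation,
                converged = full$converged && reduced$converged)
  }
  structure(list(motif_id = motif$motif_id %||% NA_character_,
                 rbp_name = motif$rbp_name %||% NA_character_,
                 lambda_selected = lambda_selected,
                 selected_features = selected_features,
                 motif_selected = motif_selected,
                 lrt_statistic = res$lrt_statistic, df = res$df,
                 p_value = res$p_value, separation = res$separation,
                 p_is_upper_bound = res$separation, converged = res$converged),
            class = "enrichment_result")
}

#' Test one motif for enrichment in the positive set
#'
#' Convenience wrapper: feature table, Lasso feature selection, nested LRT.
#'
#' @inheritParams build_feature_table
#' @inheritParams fit_lasso_cv
#' @return \code{enrichment_result}.
#' @export
test_motif_enrichment <- function(partition, records, motif,
                                  region = "three_prime_utr",
                                  provider = accessibility_provider("uniform"),
                                  folds = 5, seed = 1) {
  table <- build_feature_table(partition, records, motif, region, provider)
  sel <- fit_lasso_cv(table, folds = folds, seed = seed)
  nested_lrt(table, sel$selected_features, sel$lambda_selected)
}

#' Run the enrichment test over a motif collection
#'
#' Each motif is tested independently with its own control features. Results
#' are sorted by increasing p-value; Benjamini-Hochberg q-values across the
#' collection are reported alongside the raw p-values. A motif whose test
#' errors yields an error entry rather than aborting the collection.
#'
#' @param motifs List of \code{iupac_motif}.
#' @inheritParams test_motif_enrichment
#' @return data.frame with one row per motif: \code{motif_id, rbp_name,
#'   n_pos, n_neg, lambda, motif_selected, selected_features, lrt_stat, df,
#'   p_value, q_value, flags}.
#' @export
scan_collection <- function(motifs, partition, records,
                            region = "three_prime_utr",
                            provider = accessibility_provider("uniform"),
                            folds = 5, seed = 1) {
  if (!length(motifs)) stop("motif collection is empty")
  rows <- lapply(motifs, function(m) {
    r <- tryCatch(
      test_motif_enrichment(partition, records, m, region, provider,
                            folds, seed),
      error = function(e) e)
    if (inherits(r, "error")) {
      data.frame(motif_id = m$motif_id, rbp_name = m$rbp_name,
                 n_pos = length(partition$positive_ids),
                 n_neg = length(partition$negative_ids),
                 lambda = NA_real_, motif_selected = NA,
                 selected_features = "", lrt_stat = NA_real_,
                 df = NA_integer_, p_value = NA_real_,
                 flags = paste0("error:", conditionMessage(r)),
                 stringsAsFactors = FALSE)
    } else {
      flags <- c(if (r$separation) "separation;p_upper_bound",
                 if (!r$converged) "nonconverged")
      data.frame(motif_id = r$motif_id, rbp_name = r$rbp_name,
                 n_pos = length(partition$positive_ids),
                 n_neg = length(partition$negative_ids),
                 lambda = r$lambda_selected, motif_selected = r$motif_selected,
                 selected_features = paste(r$selected_features,
                                           collapse = ";"),
                 lrt_stat = r$lrt_statistic, df = r$df, p_value = r$p_value,
                 flags = paste(flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$motif_id), , drop = FALSE]
  out <- out[, c("motif_id", "rbp_name", "n_pos", "n_neg", "lambda",
                 "motif_selected", "selected_features", "lrt_stat", "df",
                 "p_value", "q_value", "flags")]
  rownames(out) <- NULL
  out
}
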