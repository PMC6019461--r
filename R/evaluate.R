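# Spike-in based accuracy metrics and repertoire-feature statistics.

#' Classify a spike-in record against its matched standard
#'
#' `exact`: CDR3 a.a. and the full VDJ nucleotide sequence both match the
#' standard. `vdj_nt_error_variant`: correct CDR3 a.a. but >= 1 nt
#' difference across the VDJ. `cdr3_error_variant`: >= 1 a.a. difference
#' in the CDR3.
#'
#' @param records annotated spike-in records (need `matched_standard_id`,
#'   `junction_aa`, `sequence`)
#' @param standards a `spikein_set`
#' @return character vector of classes
#' @export
assign_error_class <- function(records, standards) {
  st <- standards$standards
  i <- match(records$matched_standard_id, st$standard_id)
  ifelse(records$junction_aa != st$cdr3_aa[i], "cdr3_error_variant",
         ifelse(records$sequence != st$full_sequence[i],
                "vdj_nt_error_variant", "exact"))
}

#' Erroneous-variant report for a spike-in dataset
#'
#' Counts, per standard, the distinct CDR3 a.a. error variants and the
#' distinct VDJ nt error variants (correct CDR3, mutated VDJ), both raw
#' and normalized per 100,000 aligned spike-in reads, plus dataset medians
#' and the Pearson correlation of per-standard error counts with pool
#' concentration.
#'
#' @param records annotated spike-in records (one row per distinct
#'   sequence)
#' @param standards a `spikein_set`
#' @param aligned_read_total total aligned spike-in reads in the dataset
#' @return list of class `error_variant_report`
#' @export
error_variant_report <- function(records, standards, aligned_read_total) {
  st <- standards$standards
  cls <- assign_error_class(records, standards)
  per <- data.frame(standard_id = st$standard_id,
                    relative_concentration = st$relative_concentration,
                    stringsAsFactors = FALSE)
  tab <- function(klass) {
    t0 <- table(factor(records$matched_standard_id[cls == klass],
                       levels = st$standard_id))
    as.integer(t0)
  }
  per$n_cdr3_aa_error_variants <- tab("cdr3_error_variant")
  per$n_vdj_nt_error_variants <- tab("vdj_nt_error_variant")
  per$cdr3_errors_per_100k <- per$n_cdr3_aa_error_variants * 1e5 /
    aligned_read_total
  per$vdj_errors_per_100k <- per$n_vdj_nt_error_variants * 1e5 /
    aligned_read_total
  cor_or_na <- function(x) {
    if (stats::sd(x) == 0 || stats::sd(per$relative_concentration) == 0) {
      NA_real_
    } else cor(x, per$relative_concentration)
  }
  structure(list(
    per_standard = per,
    median_cdr3_errors = median(per$n_cdr3_aa_error_variants),
    median_vdj_errors = median(per$n_vdj_nt_error_variants),
    median_cdr3_errors_per_100k = median(per$cdr3_errors_per_100k),
    median_vdj_errors_per_100k = median(per$vdj_errors_per_100k),
    cor_cdr3_vs_concentration = cor_or_na(per$n_cdr3_aa_error_variants),
    cor_vdj_vs_concentration = cor_or_na(per$n_vdj_nt_error_variants),
    aligned_read_total = aligned_read_total,
    total_cdr3_errors = sum(per$n_cdr3_aa_error_variants),
    total_vdj_errors = sum(per$n_vdj_nt_error_variants)),
    class = "error_variant_report")
}

#' Percentage of erroneous distinct variants removed by correction
#' @param raw_report,corrected_report `error_variant_report`s over the
#'   same dataset before and after MAF correction
#' @return list: pct_cdr3_removed, pct_vdj_removed (NA when the raw count
#'   is zero)
#' @export
correction_efficacy <- function(raw_report, corrected_report) {
  pct <- function(raw, corr) {
    if (raw == 0) NA_real_ else 100 * (1 - corr / raw)
  }
  list(pct_cdr3_removed = pct(raw_report$total_cdr3_errors,
                              corrected_report$total_cdr3_errors),
       pct_vdj_removed = pct(raw_report$total_vdj_errors,
                             corrected_report$total_vdj_errors))
}

#' Frequency recovery of the spike-in pool
#'
#' Compares observed standard frequencies (by raw reads, by RIDs, or by
#' FID:RID bias-corrected counts) against expected frequencies. R^2 is
#' computed against the identity line (1 - SS_res/SS_tot with residuals to
#' y = x and SS_tot about the mean expected frequency); the ordinary
#' regression R^2 is also reported. MSE is in percentage-point^2 units.
#'
#' @param records annotated spike-in records with counts
#' @param expected named vector standard_id -> expected frequency (the
#'   manifest, or realized ground-truth frequencies)
#' @param mode "reads", "rids" or "corrected"
#' @return list of class `frequency_recovery`: per_standard, r_squared
#'   (identity-line), r_squared_regression, mse_pp2
#' @export
frequency_recovery <- function(records, expected,
                               mode = c("reads", "rids", "corrected")) {
  mode <- match.arg(mode)
  ids <- names(expected)
  sub <- records[!is.na(records$matched_standard_id), , drop = FALSE]
  agg <- function(col) {
    v <- tapply(sub[[col]], factor(sub$matched_standard_id, levels = ids),
                sum, default = 0)
    as.numeric(v)
  }
  obs <- switch(mode,
    reads = agg("read_count"),
    rids = agg("rid_count"),
    corrected = {
      df <- data.frame(key = ids, rid_count = agg("rid_count"),
                       fid_count = agg("fid_count"))
      present <- df$rid_count > 0
      out <- numeric(length(ids))
      out[present] <- bias_correct(df[present, ])$corrected_count
      out
    })
  obs <- if (sum(obs) > 0) obs / sum(obs) else obs
  exp_ <- as.numeric(expected)
  ss_res <- sum((obs - exp_)^2)
  ss_tot <- sum((exp_ - mean(exp_))^2)
  structure(list(
    per_standard = data.frame(standard_id = ids, expected = exp_,
                              observed = obs, stringsAsFactors = FALSE),
    mode = mode,
    r_squared = 1 - ss_res / ss_tot,
    r_squared_regression = suppressWarnings(cor(obs, exp_)^2),
    mse_pp2 = mean((100 * (obs - exp_))^2)),
    class = "frequency_recovery")
}

#' Normalized feature distributions
#'
#' @param x an annotated-record or clonotype data.frame
#' @param feature one of "v_family_usage", "cdr3_length_dist", "shm_dist",
#'   "subclass_usage"
#' @return data.frame: category, count, fraction (fractions sum to 1;
#'   ambiguous subclass is its own category)
#' @export
feature_summary <- function(x, feature = c("v_family_usage",
                                           "cdr3_length_dist", "shm_dist",
                                           "subclass_usage")) {
  feature <- match.arg(feature)
  df <- as.data.frame(x)
  if (nrow(df) == 0) stop_maf("empty input", "mafseq_validation_error")
  vals <- switch(feature,
    v_family_usage = family_of(df$v_gene %||% df$v_call),
    cdr3_length_dist = if ("cdr3_length" %in% names(df)) df$cdr3_length
                       else nchar(df$junction_aa),
    shm_dist = if ("mean_shm_per_variant" %in% names(df))
                 df$mean_shm_per_variant else df$shm_count,
    subclass_usage = ifelse(is.na(df$subclass), "ambiguous", df$subclass))
  t0 <- table(vals, useNA = "no")
  data.frame(category = names(t0), count = as.integer(t0),
             fraction = as.numeric(t0) / sum(t0), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Centered log-ratio transform
#'
#' Rows are composition vectors; zeros are replaced by `pseudocount`
#' before transforming. Each output row sums to zero.
#' @param x numeric matrix (samples x components) or vector
#' @param pseudocount replacement for zero components
#' @return matrix of the same shape
#' @export
clr_transform <- function(x, pseudocount = 1e-6) {
  v <- is.null(dim(x))
  m <- if (v) matrix(x, nrow = 1) else as.matrix(x)
  m[m == 0] <- pseudocount
  if (any(m <= 0)) {
    stop_maf("components must be positive after pseudocount",
             "mafseq_validation_error")
  }
  lm_ <- log(m)
  out <- lm_ - rowMeans(lm_)
  if (v) out[1, ] else out
}

#' Two-class Fisher linear discriminant axis with grouped holdout
#'
#' Fits w = (S_w + eps I)^-1 (mu_1 - mu_0) on the pooled within-class
#' covariance (ridge-regularized for stability) and classifies by the
#' nearest projected class mean. When `groups` is given, a
#' leave-one-group-out cross-validation is run (e.g. leave one donor out).
#'
#' @param x numeric matrix (samples x features), e.g. CLR-transformed
#'   usage frequencies
#' @param labels two-class factor/vector
#' @param groups optional grouping for leave-one-group-out holdout
#' @param eps ridge regularization (default 1e-6)
#' @return list of class `lda_axis`: loadings, projections, class_means,
#'   cv (data.frame with holdout predictions) and holdout_accuracy
#' @export
lda_axis <- function(x, labels, groups = NULL, eps = 1e-6) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop_maf("need exactly two classes",
                                     "mafseq_validation_error")
  fit <- function(xt, lt) {
    if (min(table(lt)) < 2) {
      stop_maf("need >= 2 samples per class in the training split",
               "mafseq_validation_error")
    }
    mus <- lapply(levels(lt), function(l) colMeans(xt[lt == l, , drop = FALSE]))
    sw <- matrix(0, ncol(xt), ncol(xt))
    for (l in levels(lt)) {
      xc <- scale(xt[lt == l, , drop = FALSE], center = TRUE, scale = FALSE)
      sw <- sw + crossprod(xc)
    }
    sw <- sw / (nrow(xt) - 2)
    w <- solve(sw + diag(eps, ncol(xt)), mus[[2]] - mus[[1]])
    w <- w / sqrt(sum(w^2))
    list(w = w, centers = c(sum(mus[[1]] * w), sum(mus[[2]] * w)))
  }
  full <- fit(x, labels)
  proj <- as.numeric(x %*% full$w)
  predict_ <- function(model, xn) {
    p <- as.numeric(xn %*% model$w)
    levels(labels)[apply(abs(outer(p, model$centers, "-")), 1, which.min)]
  }
  cv <- NULL
  acc <- NA_real_
  if (!is.null(groups)) {
    rows <- list()
    for (g in unique(groups)) {
      te <- which(groups == g)
      model <- fit(x[-te, , drop = FALSE], droplevels(labels[-te]))
      pred <- predict_(model, x[te, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        sample = te, group = g, truth = as.character(labels[te]),
        predicted = pred, stringsAsFactors = FALSE)
    }
    cv <- do.call(rbind, rows)
    acc <- mean(cv$truth == cv$predicted)
  }
  structure(list(loadings = as.numeric(full$w), projections = proj,
                 class_means = full$centers, classes = levels(labels),
                 cv = cv, holdout_accuracy = acc),
            class = "lda_axis")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities not exceeding
#' the observed table's probability (the classic conditional test).
#' @param table 2x2 matrix of non-negative integer counts
#' @return p-value
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) ||
      any(table != round(table))) {
    stop_maf("need a 2x2 table of non-negative integers",
             "mafseq_validation_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}
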