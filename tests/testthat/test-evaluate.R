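test_that("error classes follow the CDR3/VDJ rules", {
  set <- fixture_set()
  st <- set$standards[1, ]
  mk <- function(seq, aa) data.frame(sequence = seq, junction_aa = aa,
                                     matched_standard_id = st$standard_id,
                                     stringsAsFactors = FALSE)
  expect_equal(assign_error_class(mk(st$full_sequence, st$cdr3_aa), set),
               "exact")
  # one framework substitution, intact CDR3 -> VDJ nt error variant
  s <- st$full_sequence
  substr(s, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(s, 30, 30))[1]
  expect_equal(assign_error_class(mk(s, st$cdr3_aa), set),
               "vdj_nt_error_variant")
  # CDR3 amino-acid change -> CDR3 error variant
  aa <- st$cdr3_aa
  substr(aa, 3, 3) <- "P"
  expect_equal(assign_error_class(mk(s, aa), set), "cdr3_error_variant")
})

test_that("zero-noise datasets report zero errors everywhere", {
  db <- fixture_db(); layout <- fixture_layout(); set <- fixture_set()
  params <- simulator_params(n_transcripts = 120, seed = 61)
  mols <- transcribe_and_tag(params, spikeins = set)
  sim <- amplify_and_sequence(mols, params)
  parsed <- parse_layout(sim$reads, layout)
  rec <- correct_dataset(group_by_rid(parsed))
  ann <- annotate_rearrangements(rec, db, layout, set)
  rep_ <- error_variant_report(ann, set, sum(ann$read_count))
  expect_equal(rep_$total_cdr3_errors, 0L)
  expect_equal(rep_$total_vdj_errors, 0L)
  expect_equal(rep_$median_cdr3_errors, 0)
})

test_that("uncorrected error counts correlate with clone abundance", {
  db <- fixture_db(); layout <- fixture_layout()
  set <- fixture_set85()
  params <- simulator_params(n_transcripts = 4000, seq_error_rate = 0.003,
                             reads_per_molecule_mean = 4, seed = 67)
  mols <- suppressWarnings(transcribe_and_tag(params, spikeins = set))
  sim <- amplify_and_sequence(mols, params)
  parsed <- parse_layout(sim$reads, layout)
  # raw (uncorrected) distinct variants
  raw <- unique(parsed$reads[, c("insert"), drop = FALSE])
  names(raw) <- "sequence"
  raw$read_count <- as.integer(table(parsed$reads$insert)[raw$sequence])
  raw$rid_count <- 1L; raw$fid_count <- 1L
  ann <- annotate_rearrangements(raw, db, layout, set)
  rep_ <- error_variant_report(ann[ann$is_spikein, ], set,
                               nrow(parsed$reads))
  expect_gt(rep_$cor_cdr3_vs_concentration, 0.5)
  expect_gt(rep_$total_cdr3_errors, 0)
})

test_that("correction efficacy arithmetic and the n/a path", {
  mk <- function(cdr3, vdj) structure(list(total_cdr3_errors = cdr3,
                                           total_vdj_errors = vdj),
                                      class = "error_variant_report")
  e <- correction_efficacy(mk(100, 40), mk(0, 1))
  expect_equal(e$pct_cdr3_removed, 100)
  expect_equal(e$pct_vdj_removed, 97.5)
  expect_true(is.na(correction_efficacy(mk(0, 0), mk(0, 0))$pct_cdr3_removed))
})

test_that("frequency recovery matches an independent recomputation", {
  exp_ <- c(S1 = 0.4, S2 = 0.3, S3 = 0.15, S4 = 0.1, S5 = 0.05)
  obs_counts <- c(35, 30, 20, 10, 5)
  rec <- data.frame(matched_standard_id = names(exp_),
                    read_count = obs_counts, rid_count = obs_counts,
                    fid_count = obs_counts)
  fr <- frequency_recovery(rec, exp_, "reads")
  o <- obs_counts / 100
  r2_hand <- 1 - sum((o - exp_)^2) / sum((exp_ - mean(exp_))^2)
  mse_hand <- mean((100 * (o - exp_))^2)
  expect_equal(fr$r_squared, r2_hand)
  expect_equal(fr$mse_pp2, mse_hand)
  expect_equal(fr$r_squared_regression, cor(o, exp_)^2)
  # identical observed and expected -> perfect recovery
  perfect <- frequency_recovery(
    data.frame(matched_standard_id = names(exp_), read_count = exp_ * 1000,
               rid_count = 1, fid_count = 1), exp_, "reads")
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$mse_pp2, 0)
  # absent standard contributes observed frequency zero
  missing <- frequency_recovery(rec[1:4, ], exp_, "reads")
  expect_equal(missing$per_standard$observed[5], 0)
})

test_that("feature summaries normalize to one", {
  cl <- data.frame(v_gene = rep(c("IGHV1-2", "IGHV4-4"), c(4, 6)),
                   cdr3_length = c(rep(12, 7), rep(15, 3)),
                   mean_shm_per_variant = rpois(10, 3),
                   subclass = c(rep("IgG1", 5), rep("IgG2", 3), NA, NA))
  fam <- feature_summary(cl, "v_family_usage")
  expect_equal(fam$fraction[fam$category == "IGHV1"], 0.4)
  expect_equal(sum(fam$fraction), 1)
  sub <- feature_summary(cl, "subclass_usage")
  expect_equal(sub$fraction[sub$category == "ambiguous"], 0.2)
  expect_equal(sum(feature_summary(cl, "cdr3_length_dist")$fraction), 1)
})

test_that("clr transform matches hand values and centers rows", {
  got <- clr_transform(c(0.25, 0.25, 0.5))
  expect_equal(round(got, 4), c(-0.2310, -0.2310, 0.4621))
  expect_equal(sum(got), 0, tolerance = 1e-9)
  expect_equal(clr_transform(rep(0.2, 5)), rep(0, 5))
  z <- clr_transform(c(0.5, 0.5, 0), pseudocount = 1e-6)
  expect_true(all(is.finite(z)))
  expect_equal(sum(z), 0, tolerance = 1e-9)
  expect_error(clr_transform(c(-1, 2)), class = "mafseq_validation_error")
})

test_that("the discriminant axis separates planted structure", {
  set.seed(44)
  n <- 12
  x <- matrix(rnorm(2 * n * 6, sd = 0.3), 2 * n, 6)
  x[(n + 1):(2 * n), 3] <- x[(n + 1):(2 * n), 3] + 4  # planted component
  labels <- rep(c("naive", "memory"), each = n)
  groups <- rep(rep(c("D1", "D2", "D3"), each = 4), 2)
  fit <- lda_axis(x, labels, groups)
  expect_equal(fit$holdout_accuracy, 1)
  expect_equal(which.max(abs(fit$loadings)), 3L)
  # permuted labels lose the signal
  accs <- replicate(10, {
    lda_axis(x, sample(labels), groups)$holdout_accuracy
  })
  expect_lt(mean(accs), 0.8)
  expect_gt(mean(accs), 0.2)
  expect_error(lda_axis(x[1:3, ], labels[c(1, 1, 2)]),
               class = "mafseq_validation_error")
})

test_that("the discriminant direction agrees with MASS::lda", {
  skip_if_not_installed("MASS")
  set.seed(9)
  x <- rbind(matrix(rnorm(60, 0), 15), matrix(rnorm(60, 1.5), 15))
  labels <- rep(c("a", "b"), each = 15)
  w <- lda_axis(x, labels)$loadings
  m <- as.numeric(MASS::lda(x, grouping = labels)$scaling)
  m <- m / sqrt(sum(m^2))
  expect_gt(abs(sum(w * m)), 0.99)  # same axis up to sign
})

test_that("fisher p-values match enumeration across table space", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2)),
               fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)))
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1)
  # exhaustive over all tables with total <= 12
  for (n in 0:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      tab <- matrix(c(a, b, c, n - a - b - c), 2)
      expect_equal(fisher_exact_2x2(tab), fisher_enum(tab),
                   tolerance = 1e-9)
    }
  }
})
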