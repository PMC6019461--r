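mk_parsed <- function(rids, inserts = "ACGT", fids = "AAAAAAAAAA",
                      quals = NULL) {
  n <- length(rids)
  inserts <- rep_len(inserts, n)
  data.frame(read_id = sprintf("r%03d", seq_len(n)),
             fid = rep_len(fids, n), rid = rids, insert = inserts,
             insert_qual = quals %||%
               vapply(nchar(inserts), function(k) strrep("F", k), ""),
             mean_q = 37, stringsAsFactors = FALSE)
}

test_that("exact RID grouping recovers group sizes", {
  df <- mk_parsed(rep(c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG"),
                      c(4, 3, 2)))
  g <- group_by_rid(df)
  expect_equal(sort(g$groups$n_reads), c(2, 3, 4))
  expect_equal(nrow(g$groups), 3)
  empty <- group_by_rid(df[0, ])
  expect_equal(nrow(empty$groups), 0)
})

test_that("near-RID merging absorbs 1-mismatch singletons into big groups", {
  big <- rep("AAAAAAAAAAAA", 5)
  near <- "AAAAAAAAAAAT"   # Hamming 1
  far <- "AAAAAAAATTTT"    # Hamming 4
  df <- mk_parsed(c(big, near, far))
  g_off <- group_by_rid(df, merge_near_rids = FALSE)
  expect_equal(sort(g_off$groups$n_reads), c(1, 1, 5))
  g_on <- group_by_rid(df, merge_near_rids = TRUE)
  expect_equal(sort(g_on$groups$n_reads), c(1, 6))
  expect_equal(g_on$n_absorbed, 1L)
})

test_that("consensus follows majority vote with quality tie-breaks", {
  g1 <- mk_parsed(rep("A", 3), inserts = "ACGT")
  expect_equal(build_consensus(g1)$sequence, "ACGT")
  expect_equal(build_consensus(g1)$provenance, "corrected")

  g2 <- mk_parsed(rep("A", 3), inserts = c("ACGT", "ACGA", "ACGT"))
  expect_equal(build_consensus(g2)$sequence, "ACGT")

  # two reads only: passthrough of the higher-mean-quality member
  g3 <- mk_parsed(rep("A", 2), inserts = c("ACGT", "AGGT"),
                  quals = c("FF!F", "FFFF"))
  r3 <- build_consensus(g3)
  expect_equal(r3$provenance, "passthrough")
  expect_equal(r3$sequence, "AGGT")

  # 2/2 position split: Phred sums 74 (F+F) vs 52 (;+;) -> base with 74 wins
  g4 <- mk_parsed(rep("A", 4), inserts = c("ACGT", "ACGT", "ACCT", "ACCT"),
                  quals = c("FFFF", "FFFF", "FF;F", "FF;F"))
  expect_equal(build_consensus(g4)$sequence, "ACGT")
})

test_that("consensus is invariant under read permutation", {
  set.seed(5)
  ins <- c("ACGTACGT", "ACGTACGT", "ACCTACGT", "ACGTACGA", "ACGTACGT")
  df <- mk_parsed(rep("A", 5), inserts = ins)
  base <- build_consensus(df)$sequence
  for (i in 1:5) {
    expect_equal(build_consensus(df[sample(5), ])$sequence, base)
  }
})

test_that("correct_dataset aggregates by sequence and conserves groups", {
  df <- mk_parsed(rep(c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG"),
                      each = 3), inserts = "TTTT")
  g <- group_by_rid(df)
  rec <- correct_dataset(g)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$rid_count, 3L)
  expect_equal(rec$read_count, 9L)
  expect_equal(sum(rec$rid_count), nrow(g$groups))
})

test_that("zero-noise correction returns exactly the true molecule set", {
  set <- fixture_set()
  params <- simulator_params(n_transcripts = 200, seed = 21)
  mols <- suppressWarnings(transcribe_and_tag(params, spikeins = set))
  sim <- amplify_and_sequence(mols, params)
  parsed <- parse_layout(sim$reads, fixture_layout())
  rec <- correct_dataset(group_by_rid(parsed))
  expect_setequal(rec$sequence, unique(mols$insert))
  expect_equal(sum(rec$rid_count), 200)
})

test_that("correction shrinks the variant set but never below truth", {
  set <- fixture_set()
  params <- simulator_params(n_transcripts = 400, seq_error_rate = 0.005,
                             reads_per_molecule_mean = 6, seed = 23)
  mols <- suppressWarnings(transcribe_and_tag(params, spikeins = set))
  sim <- amplify_and_sequence(mols, params)
  parsed <- parse_layout(sim$reads, fixture_layout())
  rec <- correct_dataset(group_by_rid(parsed, merge_near_rids = TRUE))
  n_before <- length(unique(parsed$reads$insert))
  expect_lte(nrow(rec), n_before)
  expect_gte(nrow(rec), length(unique(mols$insert)))
})

test_that("high-coverage consensus reproduces every true sequence", {
  set <- fixture_set()
  params <- simulator_params(n_transcripts = 150, seq_error_rate = 0.005,
                             reads_per_molecule_mean = 8,
                             min_reads_per_molecule = 5, seed = 29)
  mols <- suppressWarnings(transcribe_and_tag(params, spikeins = set))
  sim <- amplify_and_sequence(mols, params)
  parsed <- parse_layout(sim$reads, fixture_layout())
  grp <- group_by_rid(parsed, merge_near_rids = TRUE)
  rec <- correct_dataset(grp)
  gs <- attr(rec, "group_sequences")
  built <- gs[gs$provenance == "corrected", ]
  truth <- stats::setNames(mols$insert, mols$rid)[built$rid]
  expect_true(all(built$sequence == truth))
})

test_that("FID:RID rescaling matches hand-evaluated cases", {
  # two clones, equal RID counts, ratios 4 and 2 -> 75 / 150, 1/3 vs 2/3
  ab <- data.frame(key = c("c1", "c2"), rid_count = c(100, 100),
                   fid_count = c(400, 200))
  out <- bias_correct(ab)
  expect_equal(out$amplification_ratio, c(4, 2))
  expect_equal(out$corrected_count, c(75, 150))
  expect_equal(out$corrected_frequency, c(1, 2) / 3)

  # equal ratios: a no-op on frequencies
  flat <- bias_correct(data.frame(key = c("a", "b"), rid_count = c(30, 70),
                                  fid_count = c(90, 210)))
  expect_equal(flat$corrected_frequency, c(0.3, 0.7))

  single <- bias_correct(data.frame(key = "a", rid_count = 10,
                                    fid_count = 55))
  expect_equal(single$corrected_frequency, 1)
  expect_error(bias_correct(data.frame(key = "a", rid_count = 0,
                                       fid_count = 1)),
               class = "mafseq_validation_error")
})

test_that("bias correction reduces frequency MSE under heterogeneous bias", {
  set <- fixture_set()
  genes <- unique(gene_of(set$standards$v_name))
  for (s in 1:5) {
    set.seed(100 + s)
    eff <- stats::setNames(runif(length(genes), 0.6, 1.0), genes)
    params <- simulator_params(n_transcripts = 1500, efficiency = eff,
                               reads_per_molecule_mean = 2,
                               min_reads_per_molecule = 0, seed = s)
    mols <- suppressWarnings(transcribe_and_tag(params, spikeins = set))
    sim <- amplify_and_sequence(mols, params)
    parsed <- parse_layout(sim$reads, fixture_layout())
    rec <- correct_dataset(group_by_rid(parsed))
    ann <- annotate_rearrangements(rec, fixture_db(), fixture_layout(), set)
    tf <- table(factor(mols$source_id, levels = set$standards$standard_id))
    tf <- stats::setNames(as.numeric(tf) / sum(tf),
                          set$standards$standard_id)
    mse <- vapply(c("rids", "corrected"), function(m)
      frequency_recovery(ann, tf, m)$mse_pp2, numeric(1))
    expect_lt(mse[["corrected"]], mse[["rids"]])
  }
})
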