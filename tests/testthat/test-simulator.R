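test_that("naive repertoires are single-variant, single-replicate clones", {
  db <- fixture_db()
  rp <- repertoire_params("naive", n_clones = 10, n_replicates = 2, seed = 4)
  rep_ <- generate_repertoire(db, rp, fixture_layout())
  expect_equal(nrow(rep_$variants), 10)
  expect_true(all(rep_$clones$n_variants == 1))
  per_clone_reps <- tapply(rep_$occupancy$replicate_id,
                           sub("\\.v.*", "", rep_$occupancy$variant_id),
                           function(x) length(unique(x)))
  expect_true(all(per_clone_reps == 1))
  expect_true(all(rep_$variants$subclass == "IgM"))
})

test_that("memory SHM load concentrates around its Poisson mean", {
  db <- fixture_db()
  rp <- repertoire_params("memory", n_clones = 200, shm_per_variant = 22,
                          n_replicates = 2, seed = 7)
  rep_ <- generate_repertoire(db, rp, fixture_layout())
  n <- nrow(rep_$variants)
  expect_lt(abs(mean(rep_$variants$n_shm) - 22), 3 * sqrt(22 / n))
  # planted mutations respect the allowed span: variants still translate,
  # junction untouched
  expect_true(all(rep_$variants$cdr3_aa ==
                    translate_nt(rep_$variants$cdr3_nt)))
})

test_that("subclass draws follow the 5:3:1:0 IgG weights", {
  db <- fixture_db()
  rp <- repertoire_params("memory", n_clones = 300, variants_lambda = 0,
                          subclass_weights = c(IgG1 = 5, IgG2 = 3,
                                               IgG3 = 1, IgG4 = 0),
                          n_replicates = 1, seed = 12)
  rep_ <- generate_repertoire(db, rp, fixture_layout())
  n <- nrow(rep_$variants)
  obs <- table(factor(rep_$variants$subclass,
                      levels = c("IgG1", "IgG2", "IgG3", "IgG4")))
  for (k in seq_along(obs)) {
    p <- c(5, 3, 1, 0)[k] / 9
    bounds <- stats::qbinom(c(0.005, 0.995), n, p)
    expect_gte(obs[[k]], bounds[1])
    expect_lte(obs[[k]], bounds[2])
  }
})

test_that("transcription samples the manifest multinomially", {
  set <- fixture_set()
  two <- set
  two$standards <- two$standards[1:2, ]
  two$standards$relative_concentration <- c(0.9, 0.1)
  params <- simulator_params(n_transcripts = 10000, seed = 3)
  mols <- suppressWarnings(transcribe_and_tag(params, spikeins = two))
  expect_equal(nrow(mols), 10000)
  n1 <- sum(mols$source_id == two$standards$standard_id[1])
  bounds <- stats::qbinom(c(0.005, 0.995), 10000, 0.9)
  expect_gte(n1, bounds[1])
  expect_lte(n1, bounds[2])
  expect_error(transcribe_and_tag(simulator_params(n_transcripts = 0)),
               class = "mafseq_validation_error")
})

test_that("RIDs are unique at scale and the collision path reports", {
  set <- fixture_set()
  params <- simulator_params(n_transcripts = 100, seed = 8)
  mols <- transcribe_and_tag(params, spikeins = set)
  expect_equal(attr(mols, "rid_collisions"), 0L)
  expect_equal(length(unique(mols$rid)), 100)
  # rid_length 6 forces the collision warning (100^2/4^6 >> 1e-3)
  short <- simulator_params(n_transcripts = 100, rid_length = 6, seed = 8)
  expect_warning(transcribe_and_tag(short, spikeins = set), "collision")
})

test_that("zero-noise reads reproduce the molecule inserts exactly", {
  set <- fixture_set()
  params <- simulator_params(n_transcripts = 50, seed = 2)
  mols <- transcribe_and_tag(params, spikeins = set)
  sim <- amplify_and_sequence(mols, params)
  i <- match(sim$truth$molecule_id, mols$molecule_id)
  ins <- substr(sim$reads$sequence, params$fid_length + 1,
                nchar(sim$reads$sequence) - params$rid_length)
  expect_true(all(ins == mols$insert[i]))
  expect_true(all(substr(sim$reads$sequence, 1, params$fid_length) ==
                    sim$truth$fid))
})

test_that("uniform efficiency gives balanced FID:RID ratios across genes", {
  set <- fixture_set()
  params <- simulator_params(n_transcripts = 4000, seed = 6)
  mols <- suppressWarnings(transcribe_and_tag(params, spikeins = set))
  sim <- amplify_and_sequence(mols, params)
  # distinct FIDs observed per molecule, averaged per V gene
  obs <- tapply(sim$truth$fid, sim$truth$molecule_id,
                function(x) length(unique(x)))
  gene <- gene_of(mols$v_name[match(names(obs), mols$molecule_id)])
  per_gene <- tapply(as.numeric(obs), gene, mean)
  counts <- table(gene)
  big <- counts >= 100
  expect_gt(sum(big), 2)
  grand <- mean(as.numeric(obs))
  se <- stats::sd(as.numeric(obs)) / sqrt(as.numeric(counts[big]))
  expect_true(all(abs(per_gene[big] - grand) < 4 * se))
})

test_that("the simulator is byte-deterministic under a fixed seed", {
  set <- fixture_set()
  params <- simulator_params(n_transcripts = 60, seq_error_rate = 0.005,
                             pcr_error_rate = 1e-4, seed = 9)
  run <- function() {
    mols <- transcribe_and_tag(params, spikeins = set)
    d <- tempfile()
    amplify_and_sequence(mols, params, out_prefix = d)
    readLines(paste0(d, ".fastq"))
  }
  expect_identical(run(), run())
})

test_that("observed read depth converges to its configured mean", {
  lambda <- rep(10, 1e5)
  set.seed(31)
  k <- mafseq:::draw_read_counts(lambda, 1L)
  expect_true(all(k >= 1))
  expect_lt(abs(mean(k) - 10) / 10, 0.01)
})

test_that("molecule count is conserved through amplification", {
  set <- fixture_set()
  params <- simulator_params(n_transcripts = 300, seed = 13)
  mols <- suppressWarnings(transcribe_and_tag(params, spikeins = set))
  sim <- amplify_and_sequence(mols, params)
  expect_equal(length(unique(sim$truth$rid)) +
                 attr(mols, "rid_collisions"), 300)
})

test_that("unknown efficiency names are rejected", {
  set <- fixture_set()
  params <- simulator_params(n_transcripts = 20,
                             efficiency = c(IGHVX = 0.5), seed = 1)
  mols <- transcribe_and_tag(simulator_params(n_transcripts = 20, seed = 1),
                             spikeins = set)
  expect_error(amplify_and_sequence(mols, params),
               class = "mafseq_validation_error")
})
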