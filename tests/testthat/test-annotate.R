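test_that("zero-noise annotation matches ground truth on every field", {
  db <- fixture_db(); layout <- fixture_layout(); set <- fixture_set()
  params <- simulator_params(n_transcripts = 150, seed = 41)
  mols <- suppressWarnings(transcribe_and_tag(params, spikeins = set))
  sim <- amplify_and_sequence(mols, params)
  parsed <- parse_layout(sim$reads, layout)
  rec <- correct_dataset(group_by_rid(parsed))
  ann <- annotate_rearrangements(rec, db, layout, set)
  st <- set$standards
  k <- match(ann$matched_standard_id, st$standard_id)
  expect_true(all(ann$is_spikein))
  expect_equal(ann$v_call, st$v_name[k])
  expect_equal(ann$j_call, st$j_name[k])
  expect_equal(ann$junction_aa, st$cdr3_aa[k])
  expect_equal(ann$shm_count, st$n_designed_mutations[k])
  expect_equal(ann$subclass, st$subclass[k])
  expect_true(all(ann$productive))
})

test_that("annotation is order-invariant", {
  db <- fixture_db(); layout <- fixture_layout(); set <- fixture_set()
  rec <- data.frame(sequence = set$standards$full_sequence,
                    read_count = 1L, rid_count = 1L, fid_count = 1L)
  a1 <- annotate_rearrangements(rec, db, layout, set)
  perm <- c(7, 3, 11, 1, 12, 5, 9, 2, 8, 4, 10, 6)
  a2 <- annotate_rearrangements(rec[perm, , drop = FALSE], db, layout, set)
  o1 <- a1[order(a1$sequence), c("v_call", "j_call", "junction_aa",
                                 "shm_count", "subclass")]
  o2 <- a2[order(a2$sequence), c("v_call", "j_call", "junction_aa",
                                 "shm_count", "subclass")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("planted V substitutions are located exactly", {
  db <- fixture_db(); layout <- fixture_layout()
  v <- db$v[5, ]
  lead <- nchar(layout$leader)
  seq0 <- paste0(layout$leader, v$sequence, strrep("G", 30))
  planted <- c(40L, 90L, 200L)  # 0-based V positions
  s <- seq0
  for (p in planted) {
    at <- lead + p + 1L
    old <- substr(s, at, at)
    substr(s, at, at) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  aln <- assign_v(s, db$v)
  expect_equal(aln$call, v$name)
  expect_equal(aln$mismatch_ref_pos[[1]], planted)
  clean <- assign_v(seq0, db$v)
  expect_equal(clean$mismatches, 0L)
})

test_that("random sequences get no V call", {
  db <- fixture_db()
  set.seed(55)
  rand <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = ""),
    "")
  aln <- assign_v(rand, db$v)
  expect_true(all(is.na(aln$call)))
})

test_that("stop-containing junctions are flagged nonproductive", {
  db <- fixture_db(); layout <- fixture_layout()
  v <- db$v[1, ]; j <- db$j[1, ]
  v_cys <- substr(v$sequence, v$anchor_offset + 1, v$anchor_offset + 3)
  cdr3 <- paste0(v_cys, "GCTTAGGCA", "TGG")  # internal TAG stop
  ins <- paste0(layout$leader, substr(v$sequence, 1, v$anchor_offset), cdr3,
                substr(j$sequence, j$anchor_offset + 4, nchar(j$sequence)),
                db$c$sequence[db$c$subclass_label == "IgG1"])
  ann <- annotate_rearrangements(data.frame(sequence = ins), db, layout)
  expect_false(ann$productive)
  expect_equal(ann$flag, "nonproductive")
  expect_true(grepl("\\*", ann$junction_aa))
})

test_that("SHM counting excludes the primer footprint", {
  db <- fixture_db(); layout <- fixture_layout()
  v <- db$v[8, ]; j <- db$j[2, ]
  v_cys <- substr(v$sequence, v$anchor_offset + 1, v$anchor_offset + 3)
  cdr3 <- paste0(v_cys, "GCAGGTACC", "TGG")
  ins0 <- paste0(layout$leader, substr(v$sequence, 1, v$anchor_offset), cdr3,
                 substr(j$sequence, j$anchor_offset + 4, nchar(j$sequence)),
                 db$c$sequence[db$c$subclass_label == "IgG2"])
  lead <- nchar(layout$leader)
  s <- ins0
  inside <- c(5L, 12L)                       # within the 21-nt footprint
  outside <- c(40L, 100L, 150L, 200L, 250L)  # observable V positions
  for (p in c(inside, outside)) {
    at <- lead + p + 1L
    old <- substr(s, at, at)
    substr(s, at, at) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  ann <- annotate_rearrangements(data.frame(sequence = c(ins0, s)), db,
                                 layout)
  expect_equal(ann$shm_count, c(0L, 5L))
})

test_that("memory-repertoire SHM counts equal the planted loads", {
  db <- fixture_db(); layout <- fixture_layout()
  rp <- repertoire_params("memory", n_clones = 60, variants_lambda = 1,
                          n_replicates = 1, seed = 44)
  rep_ <- generate_repertoire(db, rp, layout)
  ann <- annotate_rearrangements(
    data.frame(sequence = rep_$variants$insert), db, layout)
  i <- match(ann$sequence, rep_$variants$insert)
  same_v <- ann$v_call == rep_$variants$v_name[i]
  expect_gt(mean(same_v), 0.95)  # heavy SHM can shift the nearest germline
  expect_equal(ann$shm_count[same_v], rep_$variants$n_shm[i][same_v])
  expect_equal(ann$junction_aa[same_v], rep_$variants$cdr3_aa[i][same_v])
})

test_that("isotype calls are exact and degrade to ambiguous", {
  db <- fixture_db()
  ig1 <- db$c$sequence[db$c$subclass_label == "IgG1"]
  ig2 <- db$c$sequence[db$c$subclass_label == "IgG2"]
  pad <- strrep("A", 100)
  expect_equal(assign_isotype(paste0(pad, ig1), db$c), "IgG1")
  # equidistant chimera of IgG1/IgG2 private sites -> ambiguous
  d12 <- which(strsplit(ig1, "")[[1]] != strsplit(ig2, "")[[1]])
  half <- strsplit(ig1, "")[[1]]
  take <- d12[seq(1, length(d12), by = 2)]
  half[take] <- strsplit(ig2, "")[[1]][take]
  expect_equal(assign_isotype(paste0(pad, paste(half, collapse = "")), db$c),
               "ambiguous")
})

test_that("spike-in separation tolerates one identifier mismatch", {
  layout <- fixture_layout(); set <- fixture_set()
  spike <- set$standards$full_sequence[1]
  bio <- paste0(strrep("ACGT", 80))
  rec <- data.frame(sequence = c(spike, bio),
                    junction_aa = c(set$standards$cdr3_aa[1], "CARW"))
  out <- separate_spikeins(rec, layout, set)
  expect_equal(out$is_spikein, c(TRUE, FALSE))
  expect_equal(out$matched_standard_id[1], set$standards$standard_id[1])
  # one mismatch inside the identifier still separates
  at <- regexpr(layout$synthetic_identifier, spike, fixed = TRUE) + 5L
  old <- substr(spike, at, at)
  substr(spike, at, at) <- setdiff(c("A", "C", "G", "T"), old)[1]
  out2 <- separate_spikeins(data.frame(sequence = spike,
                                       junction_aa = set$standards$cdr3_aa[1]),
                            layout, set)
  expect_true(out2$is_spikein)
})
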