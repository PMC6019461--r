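test_that("cdr3 similarity is Hamming-based and length-strict", {
  expect_equal(cdr3_similarity("CARWGGS", "CARWGGS"), 1.0)
  expect_equal(cdr3_similarity("AAAAAAAAAA", "AAAAAAAACC"), 0.8)
  expect_error(cdr3_similarity("CARW", "CARWS"),
               class = "mafseq_contract_error")
})

test_that("complete vs single linkage split the hand-worked triple", {
  # pairwise distances d(1,2)=0.1, d(2,3)=0.2, d(1,3)=0.3 at threshold 0.8:
  # complete linkage merges {1,2} then stops (max to 3 is 0.3 > 0.2);
  # single linkage chains all three at 0.2
  aa <- c("AAAAAAAAAA", "CAAAAAAAAA", "CDDAAAAAAA")
  rec <- make_records(aa)
  comp <- cluster_clonotypes(rec, 0.8, "complete")
  expect_equal(nrow(comp$clonotypes), 2)
  expect_equal(sort(comp$clonotypes$n_members), c(1, 2))
  sing <- cluster_clonotypes(rec, 0.8, "single")
  expect_equal(nrow(sing$clonotypes), 1)
  expect_equal(sing$clonotypes$n_members, 3)
})

test_that("records differing in keys or CDR3 length never co-cluster", {
  rec <- rbind(make_records("CARWWGGS", v_gene = "IGHV1-1"),
               make_records("CARWWGGS", v_gene = "IGHV1-2"),
               make_records("CARWWGGSA", v_gene = "IGHV1-1"))
  rec$sequence_id <- sprintf("S%03d", 1:3)
  cl <- cluster_clonotypes(rec)
  expect_equal(nrow(cl$clonotypes), 3)
})

test_that("clustering matches the independent O(n^3) oracle", {
  set.seed(91)
  hamming_mat <- function(x) {
    m <- do.call(rbind, strsplit(x, ""))
    n <- length(x)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ]) / ncol(m)
    }
    d
  }
  for (rep_i in 1:25) {
    n <- sample(2:12, 1)
    len <- sample(c(8, 10), 1)
    aa <- random_aa(n, len, alphabet = c("A", "C", "D"))
    rec <- make_records(aa)
    rec$sequence <- sprintf("NT%02d", seq_len(n))
    # the implementation orders group members canonically before
    # agglomeration; feed the oracle the same order so index tie-breaks
    # coincide
    ord <- order(aa, rec$sequence)
    d <- hamming_mat(aa[ord])
    for (linkage in c("complete", "single")) {
      cl <- cluster_clonotypes(rec, 0.75, linkage)
      got <- stats::setNames(cl$members$clonotype_id,
                             cl$members$sequence_id)[rec$sequence_id[ord]]
      want <- agglom_oracle(d, 0.25, linkage)
      expect_equal(canon_partition(match(got, unique(got))),
                   canon_partition(want))
      if (!anyDuplicated(d[upper.tri(d)])) {
        hc <- stats::cutree(stats::hclust(stats::as.dist(d),
                                          method = linkage),
                            h = 0.25 + 1e-9)
        expect_equal(canon_partition(match(got, unique(got))),
                     canon_partition(hc))
      }
    }
  }
})

test_that("every within-clonotype pair meets the similarity floor", {
  set.seed(17)
  aa <- random_aa(40, 10, alphabet = c("A", "C"))
  rec <- make_records(aa)
  rec$sequence <- paste0("NT", 1:40)
  cl <- cluster_clonotypes(rec, 0.8, "complete")
  expect_gt(sum(cl$clonotypes$n_members > 1), 0)
  for (id in cl$clonotypes$clonotype_id) {
    mem <- aa[match(cl$members$sequence_id[cl$members$clonotype_id == id],
                    rec$sequence_id)]
    if (length(mem) > 1) {
      sims <- outer(mem, mem, Vectorize(function(x, y)
        cdr3_similarity(x, y)))
      expect_gte(min(sims), 0.8)
    }
  }
})

test_that("cluster assignment is invariant under record permutation", {
  set.seed(33)
  aa <- random_aa(15, 8, alphabet = c("A", "C"))
  rec <- make_records(aa)
  rec$sequence <- paste0("NT", 1:15)
  cl1 <- cluster_clonotypes(rec)
  perm <- sample(15)
  cl2 <- cluster_clonotypes(rec[perm, ])
  p1 <- stats::setNames(cl1$members$clonotype_id, cl1$members$sequence_id)
  p2 <- stats::setNames(cl2$members$clonotype_id, cl2$members$sequence_id)
  ids <- rec$sequence_id
  expect_equal(canon_partition(match(p1[ids], unique(p1[ids]))),
               canon_partition(match(p2[ids], unique(p2[ids]))))
})

test_that("replicate overlap separates naive from shared structure", {
  # clones confined to one replicate -> nothing shared
  rec <- rbind(make_records(c("AAAAAAAA", "CCCCCCCC"), replicate_id = 1),
               make_records(c("DDDDDDDD", "EEEEEEEE"), replicate_id = 2))
  rec$sequence_id <- sprintf("S%03d", 1:4)
  rec$sequence <- paste0("NT", 1:4)
  cl <- cluster_clonotypes(rec)
  ov <- clonotype_overlap(cl, rec)
  expect_equal(ov$n_shared, 0)
  expect_equal(ov$n_unique, 4)

  # identical replicates -> everything shared
  rec2 <- rbind(make_records(c("AAAAAAAA", "CCCCCCCC"), replicate_id = 1),
                make_records(c("AAAAAAAA", "CCCCCCCC"), replicate_id = 2))
  rec2$sequence_id <- sprintf("S%03d", 1:4)
  rec2$sequence <- paste0("NT", c(1, 2, 1, 2))
  cl2 <- cluster_clonotypes(rec2)
  ov2 <- clonotype_overlap(cl2, rec2)
  expect_equal(ov2$n_shared, nrow(cl2$clonotypes))
  expect_equal(unname(ov2$pairwise["1", "2"]), 2)
})

test_that("planted multi-replicate fraction is recovered", {
  set.seed(71)
  n <- 200
  shared <- runif(n) < 0.3
  rows <- list()
  aa <- random_aa(n, 12, alphabet = LETTERS[1:12])
  for (i in seq_len(n)) {
    reps <- if (shared[i]) c(1, 2) else sample(1:2, 1)
    for (r in reps) {
      rows[[length(rows) + 1]] <- make_records(aa[i], replicate_id = r)
    }
  }
  rec <- do.call(rbind, rows)
  rec$sequence_id <- sprintf("S%04d", seq_len(nrow(rec)))
  rec$sequence <- paste0("NT", rec$junction_aa)
  cl <- cluster_clonotypes(rec)
  ov <- clonotype_overlap(cl, rec)
  frac <- ov$n_shared / (ov$n_shared + ov$n_unique)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.3) / n
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("intraclonal summaries count variants and subclass mix", {
  # planted lineage: 6 CDR3 a.a. variants over 15 nt variants
  aa6 <- c("CARAAGSQYYYW", "CARAAGSQYYFW", "CARAAGSQYFYW", "CARAAGSQFYYW",
           "CARAAGSFYYYW", "CARAAGFQYYYW")
  nt <- sprintf("NT%02d", 1:15)
  aa15 <- rep(aa6, c(3, 3, 3, 2, 2, 2))
  rec <- make_records(aa15, subclass = rep(c("IgG1", "IgG2"), c(10, 5)))
  rec$sequence <- nt
  rec$sequence_id <- sprintf("S%03d", 1:15)
  cl <- cluster_clonotypes(rec, 0.8, "complete")
  expect_equal(nrow(cl$clonotypes), 1)
  s <- intraclonal_summary(cl, cl$clonotypes$clonotype_id[1], rec)
  expect_equal(s$n_aa_variants, 6)
  expect_equal(s$n_nt_variants, 15)
  expect_equal(unname(s$simplex), c(10, 5, 0) / 15)

  one <- make_records("CARWGGSW", shm = 7)
  one$sequence_id <- "S001"
  cl1 <- cluster_clonotypes(one)
  s1 <- intraclonal_summary(cl1, cl1$clonotypes$clonotype_id[1], one)
  expect_equal(s1$n_aa_variants, 1)
  expect_equal(s1$mean_shm_per_variant, 7)
  expect_equal(unname(s1$simplex), c(1, 0, 0))
})
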