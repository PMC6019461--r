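# Clonotype clustering and intraclonal structure.
#
# A clonotype is a cluster of productive rearrangements sharing V gene,
# J gene and CDR3 amino-acid length, with CDR3 a.a. similarity of at least
# the threshold (default 80%) under the chosen linkage. Clustering is a
# deterministic agglomerative implementation: at each step the pair of
# clusters at minimal linkage distance is merged, ties broken by the
# smaller first cluster index, then the second.

#' CDR3 amino-acid similarity
#'
#' Fraction of identical positions between two equal-length strings
#' (1 - normalized Hamming distance).
#' @param a,b amino-acid strings of equal length (vectors recycled)
#' @return numeric vector in \[0, 1\]
#' @export
cdr3_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop_maf("cdr3_similarity requires equal-length strings",
             "mafseq_contract_error")
  }
  vapply(seq_len(n), function(i) {
    1 - hamming(a[i], b[i]) / nchar(a[i])
  }, numeric(1))
}

# deterministic agglomerative clustering; d is a distance matrix,
# returns integer cluster assignment after cutting at height h (inclusive)
agglomerate <- function(d, h, linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dd <- if (linkage == "complete") max(cross) else min(cross)
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    if (best_d > h + 1e-12) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}

hamming_dist_matrix <- function(x) {
  n <- length(x)
  m <- do.call(rbind, strsplit(x, ""))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ]) / ncol(m)
    }
  }
  d
}

#' Cluster annotated rearrangements into clonotypes
#'
#' Records are first grouped by (v_gene, j_gene, CDR3 length); within each
#' group, agglomerative clustering on 1 - CDR3 a.a. similarity is cut at
#' 1 - `similarity_threshold` (inclusive). Non-productive records are
#' dropped.
#'
#' @param records `annotated_rearrangements`
#' @param similarity_threshold minimum within-clonotype CDR3 similarity
#'   (default 0.80, inclusive)
#' @param linkage "complete" (default) or "single"
#' @return list of class `clonotypes`: `clonotypes` (summary data.frame)
#'   and `members` (sequence_id -> clonotype_id)
#' @export
cluster_clonotypes <- function(records, similarity_threshold = 0.8,
                               linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  if (similarity_threshold <= 0 || similarity_threshold > 1) {
    stop_maf("similarity threshold must be in (0, 1]", "mafseq_validation_error")
  }
  df <- as.data.frame(records)
  df <- df[df$productive & !is.na(df$junction_aa), , drop = FALSE]
  df$cdr3_length <- nchar(df$junction_aa)
  key <- paste(df$v_gene, df$j_gene, df$cdr3_length, sep = "|")
  # stable group order: sort keys so ids are permutation-invariant
  groups <- split(seq_len(nrow(df)), key)
  groups <- groups[order(names(groups))]
  h <- 1 - similarity_threshold
  clone_rows <- list()
  member_rows <- list()
  cid <- 0L
  for (g in groups) {
    # order members deterministically within the group
    g <- g[order(df$junction_aa[g], df$sequence[g])]
    assign_ <- if (length(g) == 1) 1L else {
      agglomerate(hamming_dist_matrix(df$junction_aa[g]), h, linkage)
    }
    for (cl in sort(unique(assign_))) {
      cid <- cid + 1L
      idx <- g[assign_ == cl]
      mem <- df[idx, , drop = FALSE]
      wt <- if ("rid_count" %in% names(mem) && !all(is.na(mem$rid_count))) {
        mem$rid_count
      } else rep(1, nrow(mem))
      cons <- mem$junction_aa[order(-wt, mem$junction_aa)][1]
      clone_rows[[cid]] <- data.frame(
        clonotype_id = NA_character_,
        v_gene = mem$v_gene[1], j_gene = mem$j_gene[1],
        cdr3_length = mem$cdr3_length[1], consensus_cdr3_aa = cons,
        n_members = nrow(mem),
        n_aa_variants = length(unique(mem$junction_aa)),
        n_nt_variants = length(unique(mem$sequence)),
        mean_shm_per_variant = mean(mem$shm_count),
        rid_count = sum(wt),
        replicate_set = if ("replicate_id" %in% names(mem)) {
          paste(sort(unique(mem$replicate_id)), collapse = ",")
        } else NA_character_,
        stringsAsFactors = FALSE)
      member_rows[[cid]] <- data.frame(sequence_id = mem$sequence_id,
                                       clonotype_index = cid,
                                       stringsAsFactors = FALSE)
    }
  }
  clonotypes <- do.call(rbind, clone_rows)
  clonotypes$clonotype_id <- sprintf("CT%05d", seq_len(nrow(clonotypes)))
  members <- do.call(rbind, member_rows)
  members$clonotype_id <- clonotypes$clonotype_id[members$clonotype_index]
  members$clonotype_index <- NULL
  structure(list(clonotypes = clonotypes, members = members,
                 similarity_threshold = similarity_threshold,
                 linkage = linkage),
            class = "clonotypes")
}

#' @export
print.clonotypes <- function(x, ...) {
  cat("clonotypes:", nrow(x$clonotypes), "clusters over",
      nrow(x$members), "rearrangements (", x$linkage, "linkage, >=",
      x$similarity_threshold, "similarity )\n")
  invisible(x)
}

#' Clonotype presence across replicates or subsets
#'
#' @param clons a `clonotypes` object (clustered on the pooled records)
#' @param records the annotated records that were clustered
#' @param label_col column of `records` giving the partition label
#'   (e.g. `replicate_id` or a subset label)
#' @return list: `membership` (logical clonotype x label matrix),
#'   `pairwise` (shared clonotype counts), `venn` (cell counts, labels
#'   <= 8 only), `n_shared`, `n_unique`
#' @export
clonotype_overlap <- function(clons, records, label_col = "replicate_id") {
  df <- as.data.frame(records)
  mm <- merge(clons$members, df[, c("sequence_id", label_col)],
              by = "sequence_id")
  labs <- sort(unique(mm[[label_col]]))
  ids <- clons$clonotypes$clonotype_id
  membership <- matrix(FALSE, length(ids), length(labs),
                       dimnames = list(ids, as.character(labs)))
  for (r in seq_len(nrow(mm))) {
    membership[mm$clonotype_id[r], as.character(mm[[label_col]][r])] <- TRUE
  }
  k <- rowSums(membership)
  pairwise <- crossprod(membership)
  venn <- NULL
  if (length(labs) <= 8) {
    pat <- apply(membership, 1, function(x) paste(as.integer(x), collapse = ""))
    venn <- as.data.frame(table(pattern = pat), stringsAsFactors = FALSE)
    names(venn) <- c("pattern", "count")
  }
  list(membership = membership, pairwise = pairwise, venn = venn,
       n_shared = sum(k >= 2), n_unique = sum(k == 1))
}

#' Summarize the intraclonal structure of one clonotype
#'
#' @param clons a `clonotypes` object
#' @param clonotype_id the clonotype to summarize
#' @param records the annotated records
#' @return list: n_aa_variants, n_nt_variants, mean_shm_per_variant,
#'   subclass_counts, and `simplex` — the relative IgG1/IgG2/IgG3
#'   composition of the clonotype's variants
#' @export
intraclonal_summary <- function(clons, clonotype_id, records) {
  ids <- clons$members$sequence_id[clons$members$clonotype_id == clonotype_id]
  mem <- as.data.frame(records)
  mem <- mem[mem$sequence_id %in% ids, , drop = FALSE]
  if (nrow(mem) == 0) stop_maf("unknown clonotype", "mafseq_validation_error")
  sub_counts <- table(mem$subclass)
  g3 <- c("IgG1", "IgG2", "IgG3")
  gg <- vapply(g3, function(s) sum(mem$subclass == s, na.rm = TRUE), numeric(1))
  simplex <- if (sum(gg) > 0) gg / sum(gg) else setNames(rep(NA_real_, 3), g3)
  list(n_aa_variants = length(unique(mem$junction_aa)),
       n_nt_variants = length(unique(mem$sequence)),
       mean_shm_per_variant = mean(mem$shm_count),
       subclass_counts = sub_counts, simplex = simplex)
}

#' Incidence matrix of clonotypes across replicates
#' @param clons a `clonotypes` object
#' @param records annotated records with a replicate label column
#' @param label_col label column name
#' @return logical clonotype x replicate matrix (rows seen nowhere are
#'   dropped)
#' @export
clonotype_incidence <- function(clons, records, label_col = "replicate_id") {
  m <- clonotype_overlap(clons, records, label_col)$membership
  m[rowSums(m) > 0, , drop = FALSE]
}
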