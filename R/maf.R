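# MAF error and bias correction: RID grouping, majority-vote consensus,
# molecule counting by RIDs, and FID:RID amplification-ratio normalization.

#' Group parsed reads by RID
#'
#' Exact-match grouping on the reverse UID. With `merge_near_rids`,
#' singleton groups whose RID lies within Hamming distance 1 of the RID of
#' a group with at least three reads are absorbed into that group (ties go
#' to the largest group, then the lexicographically smallest RID).
#'
#' @param parsed a `parsed_reads` object or its `reads` data.frame
#' @param merge_near_rids absorb 1-mismatch singletons (default FALSE)
#' @return list of class `uid_groups`: `reads` (parsed reads plus
#'   `group_id`), `groups` (group_id, rid, n_reads, n_fids) and
#'   `size_histogram`
#' @export
group_by_rid <- function(parsed, merge_near_rids = FALSE) {
  df <- if (inherits(parsed, "parsed_reads")) parsed$reads else parsed
  if (nrow(df) == 0) {
    return(structure(list(reads = df, groups = data.frame(
      group_id = integer(0), rid = character(0), n_reads = integer(0),
      n_fids = integer(0)), size_histogram = table(integer(0))),
      class = "uid_groups"))
  }
  rid_f <- factor(df$rid)
  gid <- as.integer(rid_f)
  rids <- levels(rid_f)
  sizes <- tabulate(gid, nbins = length(rids))
  n_absorbed <- 0L
  if (merge_near_rids) {
    single <- which(sizes == 1L)
    big <- which(sizes >= 3L)
    if (length(single) && length(big)) {
      ord <- big[order(-sizes[big], rids[big])]
      mh <- cpp_min_hamming(rids[single], rids[ord])
      hit <- which(mh$d1 == 1L)
      if (length(hit)) {
        remap <- seq_along(rids)
        remap[single[hit]] <- ord[mh$best[hit]]
        gid <- remap[gid]
        n_absorbed <- length(hit)
      }
    }
  }
  # compact group ids
  gf <- factor(gid)
  gid <- as.integer(gf)
  grid <- rids[as.integer(levels(gf))]
  df$group_id <- gid
  n_reads <- tabulate(gid, nbins = length(grid))
  n_fids <- vapply(split(df$fid, gid), function(x) length(unique(x)),
                   integer(1))
  groups <- data.frame(group_id = seq_along(grid), rid = grid,
                       n_reads = n_reads, n_fids = as.integer(n_fids),
                       stringsAsFactors = FALSE)
  structure(list(reads = df, groups = groups,
                 size_histogram = table(n_reads), n_absorbed = n_absorbed),
            class = "uid_groups")
}

#' @export
print.uid_groups <- function(x, ...) {
  cat("uid_groups:", nrow(x$groups), "RID groups over", nrow(x$reads),
      "reads\n")
  invisible(x)
}

#' Build the consensus of one UID group
#'
#' Groups with at least `min_reads_for_consensus` members are restricted to
#' reads of the modal insert length (ties go to the longer length) and
#' resolved by per-position majority vote; position ties are broken by the
#' larger summed Phred score for the tied base. Smaller groups pass through
#' the member with the highest mean Phred.
#'
#' @param group_reads data.frame with `insert` and `insert_qual` columns
#'   (the members of one RID group)
#' @param min_reads_for_consensus read threshold (default 3)
#' @return list: sequence, provenance ("corrected"/"passthrough"),
#'   read_count
#' @export
build_consensus <- function(group_reads, min_reads_for_consensus = 3L) {
  if (nrow(group_reads) == 0) stop_maf("empty group", "mafseq_validation_error")
  res <- cpp_consensus(group_reads$insert, group_reads$insert_qual,
                       rep(1L, nrow(group_reads)), 1L,
                       as.integer(min_reads_for_consensus))
  list(sequence = res$sequence[1], provenance = res$provenance[1],
       read_count = res$read_count[1])
}

#' Correct a dataset of UID groups
#'
#' Builds per-group consensus/passthrough sequences and aggregates records
#' with identical sequence, summing read, RID and FID counts. The total
#' `rid_count` over all records equals the number of UID groups (or of
#' consensus-built groups in strict mode).
#'
#' @param groups a `uid_groups` object
#' @param min_reads_for_consensus read threshold for consensus building
#' @param strict drop groups below the threshold instead of passing them
#'   through
#' @param min_rid_per_sequence post-filter: keep only sequences supported
#'   by at least this many RID groups (default 1 = keep all)
#' @return data.frame of class `corrected_records`: sequence, read_count,
#'   rid_count, fid_count, provenance; attribute `group_sequences` maps
#'   group_id -> consensus sequence
#' @export
correct_dataset <- function(groups, min_reads_for_consensus = 3L,
                            strict = FALSE, min_rid_per_sequence = 1L) {
  df <- groups$reads
  g <- groups$groups
  if (nrow(df) == 0) {
    out <- data.frame(sequence = character(0), read_count = integer(0),
                      rid_count = integer(0), fid_count = integer(0),
                      provenance = character(0))
    class(out) <- c("corrected_records", "data.frame")
    return(out)
  }
  res <- cpp_consensus(df$insert, df$insert_qual, df$group_id, nrow(g),
                       as.integer(min_reads_for_consensus))
  keep <- rep(TRUE, nrow(g))
  if (strict) keep <- res$provenance == "corrected"
  agg <- data.frame(sequence = res$sequence[keep],
                    read_count = g$n_reads[keep], rid = g$rid[keep],
                    fid_count = g$n_fids[keep],
                    provenance = res$provenance[keep],
                    stringsAsFactors = FALSE)
  sp <- split(seq_len(nrow(agg)), agg$sequence)
  out <- data.frame(
    sequence = names(sp),
    read_count = vapply(sp, function(i) sum(agg$read_count[i]), integer(1)),
    rid_count = lengths(sp),
    fid_count = vapply(sp, function(i) sum(agg$fid_count[i]), integer(1)),
    provenance = vapply(sp, function(i)
      if (any(agg$provenance[i] == "corrected")) "corrected" else "passthrough",
      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (min_rid_per_sequence > 1L) {
    out <- out[out$rid_count >= min_rid_per_sequence, , drop = FALSE]
  }
  attr(out, "group_sequences") <- data.frame(
    group_id = g$group_id, rid = g$rid, sequence = res$sequence,
    provenance = res$provenance, stringsAsFactors = FALSE)
  class(out) <- c("corrected_records", "data.frame")
  out
}

#' FID:RID amplification-bias correction
#'
#' Per clone c with RID count R_c and FID-RID pair count F_c, the
#' amplification ratio is a_c = F_c / R_c. With the pool-wide mean ratio
#' a-bar = sum(F) / sum(R), the corrected molecule count is
#' R_c * (a-bar / a_c): clones amplified more than average (high FID:RID)
#' are down-weighted, and uniform amplification leaves frequencies
#' unchanged.
#'
#' @param abundances data.frame with a clone key column (first column or
#'   `key`), `rid_count` and `fid_count`
#' @return the input plus `amplification_ratio`, `corrected_count` and
#'   `corrected_frequency` (summing to 1)
#' @export
bias_correct <- function(abundances) {
  df <- as.data.frame(abundances)
  if (any(df$rid_count < 1)) {
    stop_maf("every clone needs rid_count >= 1", "mafseq_validation_error")
  }
  a <- df$fid_count / df$rid_count
  abar <- sum(df$fid_count) / sum(df$rid_count)
  corrected <- df$rid_count * (abar / a)
  df$amplification_ratio <- a
  df$corrected_count <- corrected
  df$corrected_frequency <- corrected / sum(corrected)
  df
}
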