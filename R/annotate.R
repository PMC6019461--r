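# Germline V/J assignment, CDR3 extraction, SHM counting, isotype calls
# and spike-in separation.
#
# Alignment is gapless seed-and-extend: exact k-mer seeds nominate
# diagonals, the best diagonal is scored match +1 / mismatch -1 over the
# reference/read overlap, and the best-scoring segment wins (ties: fewer
# mismatches, then lexicographic name). Calls below the score floor
# (fraction of aligned length) are rejected. This is exact for
# substitution-type errors, the error model of this protocol.

align_to_segments <- function(seqs, segments, score_floor = 0.6,
                              seed_len = 12L, seed_step = 4L) {
  res <- cpp_seed_align(seqs, segments$sequence, seed_len, seed_step, 3L)
  ok <- !is.na(res$ref_index) &
    res$score >= score_floor * res$aligned_length
  data.frame(call = ifelse(ok, segments$name[res$ref_index], NA_character_),
             score = res$score, mismatches = res$mismatches,
             ref_start = res$ref_start, ref_end = res$ref_end,
             read_start = res$read_start,
             aligned_length = res$aligned_length,
             stringsAsFactors = FALSE) -> out
  out$mismatch_ref_pos <- res$mismatch_ref_pos
  out$mismatch_read_pos <- res$mismatch_read_pos
  out$anchor_offset <- segments$anchor_offset[res$ref_index]
  out$call[!ok] <- NA_character_
  out
}

#' Assign the best germline V segment
#' @param seqs character vector of sequences (5' to 3', plus strand)
#' @param v_segments `germline_segments` of kind V (name-sorted)
#' @param score_floor minimum score as a fraction of aligned length
#' @return data.frame with call, score, mismatches, aligned interval,
#'   mismatch positions (list columns) and the segment anchor offset
#' @export
assign_v <- function(seqs, v_segments, score_floor = 0.6) {
  if (nrow(v_segments) == 0) stop_maf("no V segments", "mafseq_validation_error")
  align_to_segments(seqs, v_segments, score_floor)
}

#' Assign the best germline J segment
#' @inheritParams assign_v
#' @param j_segments `germline_segments` of kind J
#' @export
assign_j <- function(seqs, j_segments, score_floor = 0.6) {
  if (nrow(j_segments) == 0) stop_maf("no J segments", "mafseq_validation_error")
  align_to_segments(seqs, j_segments, score_floor, seed_len = 10L,
                    seed_step = 2L)
}

#' Extract the anchor-inclusive CDR3 from V and J alignments
#'
#' The CDR3 spans the read position aligned to the V Cys codon through the
#' end of the J Trp codon, both included. Junctions whose anchors are not
#' covered by the alignments are flagged `cdr3_fail`; out-of-frame or
#' stop-containing junctions are flagged non-productive.
#'
#' @param seqs sequences
#' @param v_aln,j_aln rows from [assign_v()] / [assign_j()]
#' @return data.frame: cdr3_nt, cdr3_aa, cdr3_start (0-based), cdr3_end
#'   (exclusive), productive, flag
#' @export
extract_cdr3 <- function(seqs, v_aln, j_aln) {
  n <- length(seqs)
  start <- v_aln$read_start - v_aln$ref_start + v_aln$anchor_offset
  end <- j_aln$read_start - j_aln$ref_start + j_aln$anchor_offset + 3L
  ok <- !is.na(v_aln$call) & !is.na(j_aln$call) &
    v_aln$anchor_offset >= v_aln$ref_start &
    v_aln$anchor_offset < v_aln$ref_end &
    j_aln$anchor_offset >= j_aln$ref_start &
    j_aln$anchor_offset + 3L <= j_aln$ref_end &
    end > start & end <= nchar(seqs)
  cdr3_nt <- rep(NA_character_, n)
  cdr3_nt[ok] <- substr(seqs[ok], start[ok] + 1L, end[ok])
  cdr3_aa <- translate_nt(cdr3_nt)
  productive <- !is.na(cdr3_aa) & !grepl("*", cdr3_aa, fixed = TRUE)
  flag <- ifelse(ok, ifelse(productive, "ok", "nonproductive"), "cdr3_fail")
  data.frame(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
             cdr3_start = ifelse(ok, start, NA_integer_),
             cdr3_end = ifelse(ok, end, NA_integer_),
             productive = productive, flag = flag, stringsAsFactors = FALSE)
}

#' Count somatic hypermutations against the germline V and J
#'
#' Counts nucleotide mismatches within the aligned V and J regions,
#' excluding the junction interval and the multiplex-primer footprint
#' (template bases under the primer are overwritten, so mutations there
#' are unobservable). Substitutions only; the gapless aligner records no
#' indels, reported as `indels = 0`.
#'
#' @param v_aln,j_aln alignment rows
#' @param cdr3 result of [extract_cdr3()]
#' @param primer_footprint nt at the V 5' end to exclude
#' @return data.frame: shm_count, indels
#' @export
count_shm <- function(v_aln, j_aln, cdr3, primer_footprint = 21L) {
  n <- nrow(v_aln)
  shm <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is.na(v_aln$call[i]) || is.na(j_aln$call[i])) next
    vm <- v_aln$mismatch_ref_pos[[i]]
    vr <- v_aln$mismatch_read_pos[[i]]
    keep_v <- vm >= primer_footprint
    if (!is.na(cdr3$cdr3_start[i])) {
      keep_v <- keep_v & vr < cdr3$cdr3_start[i]
    }
    jm <- j_aln$mismatch_read_pos[[i]]
    keep_j <- if (!is.na(cdr3$cdr3_end[i])) jm >= cdr3$cdr3_end[i] else
      rep(TRUE, length(jm))
    shm[i] <- sum(keep_v) + sum(keep_j)
  }
  data.frame(shm_count = shm, indels = ifelse(is.na(shm), NA_integer_, 0L))
}

#' Assign the isotype/subclass from the constant-region prefix
#'
#' Best Hamming match of the observed 3' constant prefix against the
#' subclass references; calls closer than 2 mismatches apart are
#' "ambiguous".
#'
#' @param seqs sequences (insert ending in the constant prefix)
#' @param c_segments `germline_segments` of kind C
#' @param min_margin required margin between best and second best
#' @return character vector of subclass labels or "ambiguous"
#' @export
assign_isotype <- function(seqs, c_segments, min_margin = 2L) {
  if (is.null(c_segments) || nrow(c_segments) == 0) {
    return(rep(NA_character_, length(seqs)))
  }
  cl <- nchar(c_segments$sequence)[1]
  tail_ <- substr(seqs, pmax(1L, nchar(seqs) - cl + 1L), nchar(seqs))
  mh <- cpp_min_hamming(tail_, c_segments$sequence)
  lab <- c_segments$subclass_label[mh$best]
  amb <- !is.na(mh$d2) & (mh$d2 - mh$d1) < min_margin
  lab[amb] <- "ambiguous"
  lab
}

#' Separate spike-in records from biological records
#'
#' A record is a spike-in iff the layout's synthetic identifier occurs in
#' its sequence within one mismatch. Spike-ins are matched to the standard
#' with the nearest CDR3 amino-acid Levenshtein distance.
#'
#' @param records annotated data.frame (needs `sequence`, `cdr3_aa`)
#' @param layout a `maf_layout`
#' @param standards optional `spikein_set` for nearest-standard matching
#' @return the records with `is_spikein` and `matched_standard_id` columns
#' @export
separate_spikeins <- function(records, layout, standards = NULL) {
  idf <- Biostrings::DNAString(layout$synthetic_identifier)
  hits <- Biostrings::vcountPattern(idf,
                                    Biostrings::DNAStringSet(records$sequence),
                                    max.mismatch = 1) > 0
  records$is_spikein <- as.vector(hits)
  records$matched_standard_id <- NA_character_
  if (!is.null(standards) && any(hits)) {
    aa <- records$junction_aa %||% records$cdr3_aa
    aa <- ifelse(is.na(aa), "", aa)
    d <- adist(aa[hits], standards$standards$cdr3_aa)
    best <- max.col(-d, ties.method = "first")
    records$matched_standard_id[hits] <- standards$standards$standard_id[best]
  }
  records
}

#' Annotate corrected records into AIRR-style rearrangements
#'
#' Runs V and J assignment, CDR3 extraction, SHM counting, isotype calls
#' and spike-in separation over a table of (typically MAF-corrected)
#' sequences. Column names follow the AIRR Rearrangement conventions where
#' they apply (`sequence_id`, `v_call`, `junction`, `junction_aa`,
#' `productive`, `duplicate_count`) with toolkit-specific additions.
#'
#' @param records data.frame with `sequence` plus optional `read_count`,
#'   `rid_count`, `fid_count`, `replicate_id`
#' @param db a `germline_db`
#' @param layout a `maf_layout`
#' @param standards optional `spikein_set`
#' @param score_floor alignment call floor
#' @return data.frame of class `annotated_rearrangements`; records without
#'   a V or J call are excluded and reported in the `unannotated`
#'   attribute
#' @export
annotate_rearrangements <- function(records, db, layout, standards = NULL,
                                    score_floor = 0.6) {
  if (nrow(db$v) == 0 || nrow(db$j) == 0) {
    stop_maf("annotation requires at least one V and one J segment",
             "mafseq_validation_error")
  }
  seqs <- records$sequence
  v_aln <- assign_v(seqs, db$v, score_floor)
  j_aln <- assign_j(seqs, db$j, score_floor)
  cdr3 <- extract_cdr3(seqs, v_aln, j_aln)
  shm <- count_shm(v_aln, j_aln, cdr3, layout$primer_footprint)
  out <- data.frame(
    sequence_id = if ("sequence_id" %in% names(records)) records$sequence_id
                  else sprintf("S%06d", seq_along(seqs)),
    sequence = seqs,
    v_call = v_aln$call, j_call = j_aln$call,
    v_gene = ifelse(is.na(v_aln$call), NA, gene_of(v_aln$call)),
    j_gene = ifelse(is.na(j_aln$call), NA, gene_of(j_aln$call)),
    junction = cdr3$cdr3_nt, junction_aa = cdr3$cdr3_aa,
    productive = cdr3$productive, flag = cdr3$flag,
    shm_count = shm$shm_count, indels = shm$indels,
    v_mismatches = v_aln$mismatches,
    stringsAsFactors = FALSE, row.names = NULL)
  out$subclass <- assign_isotype(seqs, db$c)
  for (col in c("read_count", "rid_count", "fid_count", "provenance",
                "replicate_id")) {
    if (col %in% names(records)) out[[col]] <- records[[col]]
  }
  if ("read_count" %in% names(out)) out$duplicate_count <- out$read_count
  out <- separate_spikeins(out, layout, standards)
  keep <- !is.na(out$v_call) & !is.na(out$j_call)
  unann <- out[!keep, , drop = FALSE]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unannotated") <- unann
  class(out) <- c("annotated_rearrangements", "data.frame")
  out
}

#' Write an annotated rearrangement table as TSV
#' @param records `annotated_rearrangements`
#' @param path file path
#' @export
write_airr_tsv <- function(records, path) {
  df <- as.data.frame(records)
  df$v_mismatches <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_airr_tsv
#' @export
read_airr_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("annotated_rearrangements", "data.frame")
  df
}
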