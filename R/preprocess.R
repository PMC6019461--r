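# Read preprocessing: FASTQ I/O, pair merging, quality/length filtering,
# and parsing of the MAF read layout (FID | insert | revcomp(RID)).

#' Read a FASTQ file into a data.frame
#' @param path FASTQ file (Sanger Phred+33)
#' @return data.frame with read_id, sequence, quality
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a data.frame of reads as FASTQ
#' @param reads data.frame with read_id, sequence, quality
#' @param path output file
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

# best overlap merge of one pair (r2 already reverse-complemented)
merge_one_pair <- function(s1, q1, s2, q2, min_overlap, max_mismatch_fraction) {
  l1 <- nchar(s1); l2 <- nchar(s2)
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  p1 <- utf8ToInt(q1) - 33L; p2 <- utf8ToInt(q2) - 33L
  best <- NULL; best_score <- -Inf
  for (o in seq(min(l1, l2), min_overlap)) {
    a <- c1[(l1 - o + 1):l1]; b <- c2[1:o]
    mm <- sum(a != b)
    if (mm / o > max_mismatch_fraction) next
    score <- o - 2 * mm
    if (score > best_score) { best_score <- score; best <- o }
  }
  if (is.null(best)) return(NULL)
  o <- best
  ia <- (l1 - o + 1):l1; ib <- 1:o
  ov_base <- ifelse(p1[ia] >= p2[ib], c1[ia], c2[ib])
  ov_qual <- pmax(p1[ia], p2[ib])
  list(sequence = paste(c(c1[seq_len(l1 - o)], ov_base,
                          if (o < l2) c2[(o + 1):l2]), collapse = ""),
       quality = qual_string(c(p1[seq_len(l1 - o)], ov_qual,
                               if (o < l2) p2[(o + 1):l2])))
}

#' Merge paired-end reads
#'
#' R2 is reverse-complemented, the best-scoring overlap of at least
#' `min_overlap` bases with mismatch fraction below the threshold is taken,
#' and the higher-quality base wins at overlap mismatches. Unmergeable
#' pairs are dropped and counted.
#'
#' @param r1,r2 data.frames from [read_fastq()] (record order must match)
#' @param min_overlap minimum acceptable overlap (nt)
#' @param max_mismatch_fraction maximum mismatch fraction in the overlap
#' @return list with `reads` (merged data.frame) and `stats`
#'   (merged/dropped counts)
#' @export
merge_pairs <- function(r1, r2, min_overlap = 15L, max_mismatch_fraction = 0.1) {
  ids1 <- sub("/[12]$", "", r1$read_id)
  ids2 <- sub("/[12]$", "", r2$read_id)
  if (nrow(r1) != nrow(r2) || any(ids1 != ids2)) {
    stop_maf("R1/R2 streams are desynchronized", "mafseq_input_error")
  }
  s2 <- revcomp(r2$sequence)
  q2 <- vapply(strsplit(r2$quality, ""), function(x)
    paste(rev(x), collapse = ""), "")
  out <- vector("list", nrow(r1))
  dropped <- 0L
  for (i in seq_len(nrow(r1))) {
    m <- merge_one_pair(r1$sequence[i], r1$quality[i], s2[i], q2[i],
                        min_overlap, max_mismatch_fraction)
    if (is.null(m)) { dropped <- dropped + 1L; next }
    out[[i]] <- data.frame(read_id = ids1[i], sequence = m$sequence,
                           quality = m$quality, stringsAsFactors = FALSE)
  }
  merged <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(merged)) {
    merged <- data.frame(read_id = character(0), sequence = character(0),
                         quality = character(0))
  }
  list(reads = merged,
       stats = c(input = nrow(r1), merged = nrow(merged), dropped = dropped))
}

#' Filter reads by mean quality and length
#'
#' Length is checked before quality; each rejected read is counted under
#' one reason.
#' @param reads data.frame with sequence and quality columns
#' @param min_mean_q minimum mean Phred score (default 25)
#' @param length_range allowed read length interval (default 300-600 nt)
#' @return list with `reads` (kept) and `counts` (kept/length/quality)
#' @export
quality_length_filter <- function(reads, min_mean_q = 25,
                                  length_range = c(300L, 600L)) {
  len <- nchar(reads$sequence)
  bad_len <- len < length_range[1] | len > length_range[2]
  mq <- mean_phred(reads$quality)
  bad_q <- !bad_len & mq < min_mean_q
  keep <- !bad_len & !bad_q
  list(reads = reads[keep, , drop = FALSE],
       counts = c(kept = sum(keep), length = sum(bad_len),
                  quality = sum(bad_q)))
}

#' Parse the MAF read layout
#'
#' FID = first `fid_length` bases, RID = reverse complement of the last
#' `rid_length` bases, insert = the remainder. A read is accepted only if
#' one of the layout's constant-region prefixes matches the 3' end of the
#' insert within `max_anchor_mismatch` substitutions; reads with `N` inside
#' either UID are rejected (`ambiguous_uid`), and reads too short to
#' contain the minimum insert are rejected (`too_short`).
#'
#' @param reads data.frame with read_id, sequence, quality (and optionally
#'   replicate_id, carried through)
#' @param layout a `maf_layout`
#' @param fid_length,rid_length UID lengths in nt
#' @param min_insert minimum insert length
#' @param max_anchor_mismatch allowed mismatches in the constant anchor
#' @return list of class `parsed_reads`: `reads` (read_id, fid, rid,
#'   insert, insert_qual, mean_q, replicate_id), `rejects` (read_id,
#'   reason) and `counts`
#' @export
parse_layout <- function(reads, layout, fid_length = 10L, rid_length = 12L,
                         min_insert = 50L, max_anchor_mismatch = 2L) {
  n <- nrow(reads)
  len <- nchar(reads$sequence)
  reason <- rep(NA_character_, n)
  too_short <- len < fid_length + rid_length + min_insert
  reason[too_short] <- "too_short"
  fid <- substr(reads$sequence, 1L, fid_length)
  rid_raw <- substr(reads$sequence, len - rid_length + 1L, len)
  insert <- substr(reads$sequence, fid_length + 1L, len - rid_length)
  iqual <- substr(reads$quality, fid_length + 1L, len - rid_length)
  amb <- !too_short & grepl("N", paste0(fid, rid_raw), fixed = TRUE)
  reason[amb] <- "ambiguous_uid"
  open <- is.na(reason)
  if (any(open)) {
    prefixes <- unname(layout$constant_prefixes)
    cl <- nchar(prefixes)
    if (length(unique(cl)) != 1) {
      stop_maf("constant prefixes must share one length", "mafseq_validation_error")
    }
    tail_ <- substr(insert[open], nchar(insert[open]) - cl[1] + 1L,
                    nchar(insert[open]))
    mh <- cpp_min_hamming(tail_, prefixes)
    no_anchor <- mh$d1 > max_anchor_mismatch
    reason[open][no_anchor] <- "no_anchor"
  }
  keep <- is.na(reason)
  parsed <- data.frame(read_id = reads$read_id[keep], fid = fid[keep],
                       rid = revcomp(rid_raw[keep]), insert = insert[keep],
                       insert_qual = iqual[keep],
                       mean_q = mean_phred(iqual[keep]),
                       stringsAsFactors = FALSE, row.names = NULL)
  if ("replicate_id" %in% names(reads)) {
    parsed$replicate_id <- reads$replicate_id[keep]
  }
  rejects <- data.frame(read_id = reads$read_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  counts <- c(parsed = nrow(parsed),
              too_short = sum(reason == "too_short", na.rm = TRUE),
              ambiguous_uid = sum(reason == "ambiguous_uid", na.rm = TRUE),
              no_anchor = sum(reason == "no_anchor", na.rm = TRUE))
  structure(list(reads = parsed, rejects = rejects, counts = counts),
            class = "parsed_reads")
}

#' Write / read a parsed-read table (TSV)
#' @param parsed a `parsed_reads` object or its `reads` data.frame
#' @param path file path
#' @export
write_parsed_tsv <- function(parsed, path) {
  df <- if (inherits(parsed, "parsed_reads")) parsed$reads else parsed
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parsed_tsv
#' @export
read_parsed_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(read_id = "character", fid = "character",
                            rid = "character", insert = "character",
                            insert_qual = "character"))
}
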