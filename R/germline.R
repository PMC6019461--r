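# Germline V/J/constant segment references: loading, validation, anchors.
#
# Coordinates are 0-based, intervals half-open, plus strand only.
# V anchor: first nt of the conserved Cys-104 codon (TGT/TGC).
# J anchor: first nt of the Trp-118 codon (the TGG of the W-G-x-G motif).

#' Derive the gene family from a V or J segment name
#'
#' The family is the locus prefix plus the leading group number, i.e. the
#' name up to the first `-` with any `*allele` suffix removed:
#' `"IGHV1-8*01" -> "IGHV1"`, `"IGHJ6*03" -> "IGHJ6"`.
#'
#' @param name character vector of segment identifiers matching
#'   `IGH[VJ]<digits>[-...][*allele]`
#' @return character vector of family names
#' @export
family_of <- function(name) {
  ok <- grepl("^IGH[VJ][0-9]+([-*].*)?$", name)
  if (!all(ok)) {
    stop_maf(paste0("malformed segment name(s): ",
                    paste(name[!ok], collapse = ", ")),
             "mafseq_validation_error")
  }
  sub("-.*$", "", sub("\\*.*$", "", name))
}

#' Strip the allele suffix from a segment name
#' @param name character vector, e.g. `"IGHV1-8*01"`
#' @return gene-level name, e.g. `"IGHV1-8"`
#' @export
gene_of <- function(name) sub("\\*.*$", "", name)

# scan for the last in-frame Cys codon (frame 0)
scan_v_anchor <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return(NA_integer_)
  starts <- seq.int(0L, n - 3L, by = 3L)
  codons <- substring(seq, starts + 1L, starts + 3L)
  hits <- starts[codons %in% c("TGT", "TGC")]
  if (length(hits) == 0) NA_integer_ else hits[length(hits)]
}

# scan for the first TGG opening a W-G-x-G motif (any frame)
scan_j_anchor <- function(seq) {
  n <- nchar(seq)
  if (n < 12) return(NA_integer_)
  for (i in 0:(n - 12L)) {
    if (substr(seq, i + 1L, i + 3L) == "TGG" &&
        substr(seq, i + 4L, i + 5L) == "GG" &&
        substr(seq, i + 10L, i + 11L) == "GG") {
      return(i)
    }
  }
  NA_integer_
}

#' Read an anchor specification TSV
#'
#' Two columns: segment `name` and 0-based `offset` of the anchor codon.
#' @param path file path
#' @return named integer vector
#' @export
read_anchor_spec <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_maf("anchor spec needs two columns (name, offset)",
                             "mafseq_parse_error")
  setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Load germline segments from FASTA
#'
#' Parses an IMGT-style FASTA of V, J or constant (C) segments. Anchor
#' offsets are taken from `anchor_spec` when provided for a record,
#' otherwise found by motif scan (V: last in-frame Cys codon; J: first TGG
#' of the W-G-x-G motif). Records whose anchor cannot be resolved, or whose
#' stated anchor codon is not Cys (V) / Trp (J), are excluded and listed in
#' the `excluded` attribute of the result.
#'
#' For C segments the subclass label is taken from `subclass_map` or from a
#' `subclass=<label>` token in the FASTA description.
#'
#' @param path FASTA file path
#' @param kind one of "V", "J", "C"
#' @param anchor_spec optional named integer vector (or TSV path, see
#'   [read_anchor_spec()]) of explicit 0-based anchor offsets
#' @param subclass_map optional named character vector, segment name ->
#'   subclass label (IgM, IgG1..IgG4, IgA)
#' @return data.frame of class `germline_segments` with columns `name`,
#'   `family`, `kind`, `sequence`, `anchor_offset`, `subclass_label`;
#'   attribute `excluded` is a data.frame (name, reason)
#' @export
load_germline_fasta <- function(path, kind = c("V", "J", "C"),
                                anchor_spec = NULL, subclass_map = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop_maf(paste0("cannot read germline FASTA: ", path), "mafseq_io_error")
  }
  fa <- Biostrings::readDNAStringSet(path)
  if (length(fa) == 0) stop_maf("empty germline FASTA", "mafseq_validation_error")
  headers <- names(fa)
  names_ <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- toupper(as.character(fa))
  if (anyDuplicated(names_)) {
    stop_maf(paste0("duplicate segment name(s): ",
                    paste(unique(names_[duplicated(names_)]), collapse = ", ")),
             "mafseq_validation_error")
  }
  bad_alpha <- grepl("[^ACGT]", seqs) | nchar(seqs) == 0
  if (any(bad_alpha)) {
    stop_maf(paste0("non-ACGT or empty sequence(s): ",
                    paste(names_[bad_alpha], collapse = ", ")),
             "mafseq_validation_error")
  }
  if (is.character(anchor_spec) && length(anchor_spec) == 1 &&
      file.exists(anchor_spec)) {
    anchor_spec <- read_anchor_spec(anchor_spec)
  }
  subclass <- rep(NA_character_, length(seqs))
  if (kind == "C") {
    m <- regmatches(desc, regexpr("subclass=\\S+", desc))
    has <- grepl("subclass=", desc)
    subclass[has] <- sub("subclass=", "", m)
    if (!is.null(subclass_map)) {
      hit <- names_ %in% names(subclass_map)
      subclass[hit] <- unname(subclass_map[names_[hit]])
    }
  }
  anchor <- rep(NA_integer_, length(seqs))
  reason <- rep(NA_character_, length(seqs))
  if (kind != "C") {
    for (i in seq_along(seqs)) {
      off <- if (!is.null(anchor_spec) && names_[i] %in% names(anchor_spec)) {
        as.integer(anchor_spec[[names_[i]]])
      } else if (kind == "V") scan_v_anchor(seqs[i]) else scan_j_anchor(seqs[i])
      if (is.na(off) || off < 0 || off + 3 > nchar(seqs[i])) {
        reason[i] <- "anchor_unresolved"
        next
      }
      codon <- substr(seqs[i], off + 1, off + 3)
      if (kind == "V" && !codon %in% c("TGT", "TGC")) {
        reason[i] <- "anchor_not_cys"
      } else if (kind == "J" && codon != "TGG") {
        reason[i] <- "anchor_not_trp"
      } else {
        anchor[i] <- off
      }
    }
  }
  keep <- is.na(reason)
  fam <- rep(NA_character_, length(seqs))
  if (kind != "C") fam[keep] <- family_of(names_[keep])
  out <- data.frame(name = names_[keep], family = fam[keep], kind = kind,
                    sequence = seqs[keep],
                    anchor_offset = anchor[keep],
                    subclass_label = subclass[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("germline_segments", "data.frame")
  attr(out, "excluded") <- data.frame(name = names_[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Write germline segments back to FASTA
#' @param segments a `germline_segments` data.frame
#' @param path output file
#' @export
write_germline_fasta <- function(segments, path) {
  x <- Biostrings::DNAStringSet(segments$sequence)
  desc <- ifelse(is.na(segments$subclass_label), "",
                 paste0(" subclass=", segments$subclass_label))
  names(x) <- paste0(segments$name, desc)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Assemble a germline database
#'
#' @param v,j,c `germline_segments` data.frames (c may be NULL)
#' @return object of class `germline_db` with elements `v`, `j`, `c`
#' @export
germline_database <- function(v, j, c = NULL) {
  for (seg in list(v, j)) {
    if (is.null(seg) || nrow(seg) == 0) {
      stop_maf("germline database needs at least one V and one J segment",
               "mafseq_validation_error")
    }
  }
  # keep name-sorted so alignment tie-breaking is lexicographic
  v <- v[order(v$name), , drop = FALSE]
  j <- j[order(j$name), , drop = FALSE]
  if (!is.null(c)) c <- c[order(c$name), , drop = FALSE]
  structure(list(v = v, j = j, c = c), class = "germline_db")
}

#' @export
print.germline_db <- function(x, ...) {
  cat("germline_db:", nrow(x$v), "V,", nrow(x$j), "J,",
      if (is.null(x$c)) 0 else nrow(x$c), "C segments\n")
  invisible(x)
}

#' Simulate a synthetic germline reference database
#'
#' Generates an entirely synthetic stand-in for an IMGT-style human heavy
#' chain reference: `n_v` IGHV genes spread over families IGHV1-IGHV7 with
#' realistic within-family similarity, `n_j` IGHJ genes opening with the
#' W-G-x-G motif, and constant-region 5' fragments for IgM, IgG1-IgG4 and
#' IgA (the IgG subclasses differ from a common ancestor at three private
#' positions each). V genes are open reading frames ending in the Cys-104
#' codon; families share an ancestor mutated at ~6% of codons per gene.
#' No real IMGT sequence is included; the database emulates layout and
#' anchor conventions only.
#'
#' @param n_v number of V genes (default 48)
#' @param n_j number of J genes (default 6)
#' @param v_codons codons per V segment before the Cys anchor (default 94)
#' @param c_length length of each constant 5' fragment (default 60)
#' @param seed RNG seed
#' @return a `germline_db`
#' @export
simulate_germline_db <- function(n_v = 48, n_j = 6, v_codons = 94,
                                 c_length = 60, seed = 101) {
  with_seed(seed, {
    fam_quota <- c(9, 4, 17, 11, 3, 2, 2)  # IGHV1..IGHV7, echoes IMGT skew
    fam_quota <- round(fam_quota * n_v / sum(fam_quota))
    while (sum(fam_quota) < n_v) fam_quota[3] <- fam_quota[3] + 1
    while (sum(fam_quota) > n_v) {
      i <- which.max(fam_quota)
      fam_quota[i] <- fam_quota[i] - 1
    }
    v_list <- list()
    for (f in seq_along(fam_quota)) {
      if (fam_quota[f] == 0) next
      ancestor <- strsplit(random_sense_codons(v_codons), "")[[1]]
      for (g in seq_len(fam_quota[f])) {
        codons <- matrix(ancestor, nrow = 3)
        nmut <- rbinom(1, v_codons, 0.06) + 2L
        at <- sample(v_codons, nmut)
        for (a in at) {
          codons[, a] <- strsplit(sample(SENSE_CODONS, 1), "")[[1]]
        }
        seqv <- paste0(paste(as.vector(codons), collapse = ""),
                       sample(c("TGT", "TGC"), 1))
        v_list[[length(v_list) + 1]] <- data.frame(
          name = sprintf("IGHV%d-%d*01", f, g),
          family = sprintf("IGHV%d", f), kind = "V", sequence = seqv,
          anchor_offset = 3L * v_codons, subclass_label = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    v <- do.call(rbind, v_list)

    j_list <- lapply(seq_len(n_j), function(k) {
      seqj <- paste0("TGG", "GG", substr(random_sense_codons(1), 3, 3),
                     random_sense_codons(1), "GG",
                     substr(random_sense_codons(1), 3, 3),
                     random_sense_codons(11))
      data.frame(name = sprintf("IGHJ%d*01", k), family = sprintf("IGHJ%d", k),
                 kind = "J", sequence = seqj, anchor_offset = 0L,
                 subclass_label = NA_character_, stringsAsFactors = FALSE)
    })
    j <- do.call(rbind, j_list)

    igg_anc <- strsplit(random_nt(1, c_length), "")[[1]]
    subclasses <- c("IgG1", "IgG2", "IgG3", "IgG4")
    mut_pos <- matrix(sample(c_length, 12), nrow = 4)  # 3 private sites each
    c_list <- lapply(seq_along(subclasses), function(s) {
      x <- igg_anc
      for (p in mut_pos[s, ]) x[p] <- sample(setdiff(DNA_BASES, x[p]), 1)
      data.frame(name = paste0("IGHG", s), family = NA_character_, kind = "C",
                 sequence = paste(x, collapse = ""), anchor_offset = NA_integer_,
                 subclass_label = subclasses[s], stringsAsFactors = FALSE)
    })
    c_list[[length(c_list) + 1]] <- data.frame(
      name = "IGHM", family = NA_character_, kind = "C",
      sequence = random_nt(1, c_length), anchor_offset = NA_integer_,
      subclass_label = "IgM", stringsAsFactors = FALSE)
    c_list[[length(c_list) + 1]] <- data.frame(
      name = "IGHA", family = NA_character_, kind = "C",
      sequence = random_nt(1, c_length), anchor_offset = NA_integer_,
      subclass_label = "IgA", stringsAsFactors = FALSE)
    cc <- do.call(rbind, c_list)
    for (df in list(v, j, cc)) class(df) <- c("germline_segments", "data.frame")
    class(v) <- class(j) <- class(cc) <- c("germline_segments", "data.frame")
    germline_database(v, j, cc)
  })
}
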