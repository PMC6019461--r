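# Design and validation of synthetic spike-in standard sets.
#
# Each standard is a complete VDJ open reading frame assembled as
#   conserved_5p | leader | V (optionally with designed point mutations,
#   up to but excluding the Cys anchor codon) | CDR3 | J (from after the
#   Trp codon) | synthetic identifier | constant-region prefix
# CDR3s are anchor-inclusive (start with Cys, end with Trp) and any two
# CDR3s in a set are separated by a minimum nucleotide Levenshtein
# distance so sequencing/PCR errors cannot turn one standard into another.

#' Define the structural layout shared by all standards
#'
#' @param conserved_5p singleplex forward-primer target (non-coding)
#' @param leader leader peptide sequence beginning with ATG
#' @param synthetic_identifier non-coding spike-in identifier; must not
#'   occur in any germline segment of the working database
#' @param constant_prefixes named character vector, subclass label ->
#'   constant-region 5' fragment
#' @param primer_footprint nt count at the V 5' end covered by the
#'   multiplex forward primer (mutations there are unobservable)
#' @return object of class `maf_layout`
#' @export
standard_layout <- function(conserved_5p, leader, synthetic_identifier,
                            constant_prefixes, primer_footprint = 21L) {
  fields <- list(conserved_5p = conserved_5p, leader = leader,
                 synthetic_identifier = synthetic_identifier)
  for (nm in names(fields)) {
    x <- fields[[nm]]
    if (!is.character(x) || length(x) != 1 || nchar(x) == 0 ||
        grepl("[^ACGT]", x)) {
      stop_maf(paste0("layout field '", nm, "' must be a non-empty ACGT string"),
               "mafseq_validation_error")
    }
  }
  if (is.null(names(constant_prefixes)) || any(names(constant_prefixes) == "")) {
    stop_maf("constant_prefixes must be named by subclass", "mafseq_validation_error")
  }
  structure(list(conserved_5p = conserved_5p, leader = leader,
                 synthetic_identifier = synthetic_identifier,
                 constant_prefixes = constant_prefixes,
                 primer_footprint = as.integer(primer_footprint)),
            class = "maf_layout")
}

#' Default layout used throughout the package
#'
#' Fixed non-coding elements plus the constant prefixes of `db` (or of the
#' default synthetic germline database). When `db` is given, the identifier
#' is checked for absence from every germline sequence.
#' @param db optional `germline_db` supplying constant prefixes
#' @return a `maf_layout`
#' @export
default_layout <- function(db = NULL) {
  cps <- if (!is.null(db) && !is.null(db$c)) {
    setNames(db$c$sequence, db$c$subclass_label)
  } else {
    stop_maf("default_layout needs a database with constant segments",
             "mafseq_validation_error")
  }
  layout <- standard_layout(
    conserved_5p = "GGTACCTCAGCGAAGTCTGCA",
    leader = "ATGGAGTTTGGACTGAGCTGGGTT",
    synthetic_identifier = "CATGTCGCAACGGACTTCGCA",
    constant_prefixes = cps)
  check_identifier_absent(layout, db)
  layout
}

check_identifier_absent <- function(layout, db) {
  all_germ <- c(db$v$sequence, db$j$sequence,
                if (!is.null(db$c)) db$c$sequence)
  hit <- vapply(all_germ, function(s)
    grepl(layout$synthetic_identifier, s, fixed = TRUE), logical(1))
  if (any(hit)) {
    stop_maf("synthetic identifier occurs in a germline sequence",
             "mafseq_validation_error")
  }
  invisible(TRUE)
}

#' Levenshtein edit distance
#'
#' Minimal number of insertions, deletions and substitutions turning `a`
#' into `b` (computed by base R's C implementation).
#' @param a,b character vectors (recycled)
#' @return integer vector of distances
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1))
}

#' Pairwise CDR3 distance matrix of a spike-in set
#' @param set a `spikein_set`
#' @param level "nt" or "aa"
#' @return symmetric integer matrix with zero diagonal, dimnames =
#'   standard ids
#' @export
pairwise_cdr3_distances <- function(set, level = c("nt", "aa")) {
  level <- match.arg(level)
  x <- if (level == "nt") set$standards$cdr3_nt else set$standards$cdr3_aa
  d <- adist(x)
  dimnames(d) <- list(set$standards$standard_id, set$standards$standard_id)
  d
}

# assemble one standard's full sequence (mutations: data.frame v_position/new)
assemble_standard <- function(layout, v_seq, v_anchor, j_seq, j_anchor,
                              cdr3_nt, c_prefix, mutations = NULL) {
  v_body <- substr(v_seq, 1, v_anchor)  # excludes the anchor codon
  if (!is.null(mutations) && nrow(mutations) > 0) {
    chars <- strsplit(v_body, "")[[1]]
    chars[mutations$v_position + 1L] <- mutations$new
    v_body <- paste(chars, collapse = "")
  }
  paste0(layout$conserved_5p, layout$leader, v_body, cdr3_nt,
         substr(j_seq, j_anchor + 4L, nchar(j_seq)),
         layout$synthetic_identifier, c_prefix)
}

default_v_usage_plan <- function(db, n_clones) {
  vs <- db$v$name
  plan <- setNames(rep(1L, length(vs)), vs)
  extra <- n_clones - length(vs)
  if (extra < 0) {
    plan <- plan[seq_len(n_clones)]
  } else if (extra > 0) {
    # concentrate re-use on the large families, echoing skewed usage
    ord <- order(match(db$v$family, names(sort(table(db$v$family),
                                               decreasing = TRUE))))
    idx <- rep_len(vs[ord], extra)
    for (v in idx) plan[v] <- plan[v] + 1L
  }
  plan
}

#' Design a spike-in standard set
#'
#' CDR3s are generated by rejection sampling: random in-frame junctions
#' that begin with the V segment's Cys anchor codon and end with the J
#' Trp codon, accepted only if the nucleotide Levenshtein distance to every
#' already accepted CDR3 is at least `min_cdr3_nt_distance` (and the
#' translated CDR3 is new). Designed somatic-hypermutation-like point
#' substitutions are placed in the V segment outside the multiplex-primer
#' footprint and the anchor codon.
#'
#' @param db a `germline_db`
#' @param layout a `maf_layout` (default built from `db`)
#' @param n_clones number of standards (default 85)
#' @param v_usage_plan named integer vector v_name -> clone count; sums to
#'   `n_clones`. Default: every V gene once, re-using large families for
#'   the remainder.
#' @param cdr3_length_range amino-acid length interval, anchors included
#' @param min_cdr3_nt_distance minimum pairwise CDR3 nt edit distance
#' @param n_shm_standards how many standards carry designed V mutations
#' @param shm_range range of designed mutation counts per mutated standard
#' @param concentrations optional vector of relative concentrations; default
#'   is a log-uniform draw spanning two orders of magnitude, normalized
#' @param seed RNG seed (design is deterministic per seed)
#' @param max_rejections rejection budget per clone before a capacity error
#' @return object of class `spikein_set`: list with `standards` (data.frame),
#'   `mutations` (data.frame standard_id/v_position/original/new), `layout`,
#'   `min_cdr3_nt_distance`
#' @export
design_standard_set <- function(db, layout = default_layout(db),
                                n_clones = 85, v_usage_plan = NULL,
                                cdr3_length_range = c(10, 20),
                                min_cdr3_nt_distance = 9,
                                n_shm_standards = 39,
                                shm_range = c(2, 15),
                                concentrations = NULL, seed = 1,
                                max_rejections = 1e5) {
  if (is.null(v_usage_plan)) v_usage_plan <- default_v_usage_plan(db, n_clones)
  if (sum(v_usage_plan) != n_clones) {
    stop_maf("v_usage_plan counts must sum to n_clones", "mafseq_validation_error")
  }
  if (!all(names(v_usage_plan) %in% db$v$name)) {
    stop_maf("v_usage_plan names absent from database", "mafseq_validation_error")
  }
  check_identifier_absent(layout, db)
  with_seed(seed, {
    v_names <- rep(names(v_usage_plan), v_usage_plan)
    j_names <- sample(db$j$name, n_clones, replace = TRUE)
    subcl <- rep_len(names(layout$constant_prefixes), n_clones)
    shm_standards <- sample(n_clones, min(n_shm_standards, n_clones))
    accepted_nt <- character(0)
    accepted_aa <- character(0)
    std_rows <- vector("list", n_clones)
    mut_rows <- list()
    for (i in seq_len(n_clones)) {
      v <- db$v[db$v$name == v_names[i], ]
      j <- db$j[db$j$name == j_names[i], ]
      v_cys <- substr(v$sequence, v$anchor_offset + 1, v$anchor_offset + 3)
      la <- if (length(cdr3_length_range) == 1) cdr3_length_range else
        sample(seq(cdr3_length_range[1], cdr3_length_range[2]), 1)
      ok <- FALSE
      for (att in seq_len(max_rejections)) {
        mid <- if (la > 2) random_sense_codons(la - 2) else ""
        cdr3 <- paste0(v_cys, mid, "TGG")
        if (length(accepted_nt) == 0 ||
            min(adist(cdr3, accepted_nt)) >= min_cdr3_nt_distance) {
          aa <- translate_nt(cdr3)
          if (!aa %in% accepted_aa) { ok <- TRUE; break }
        }
        # redraw the length too, otherwise short-CDR3 clones can wedge
        la <- if (length(cdr3_length_range) == 1) cdr3_length_range else
          sample(seq(cdr3_length_range[1], cdr3_length_range[2]), 1)
      }
      if (!ok) {
        stop_maf(paste0("CDR3 distance constraint unsatisfiable at clone ", i),
                 "mafseq_capacity_error")
      }
      accepted_nt <- c(accepted_nt, cdr3)
      accepted_aa <- c(accepted_aa, translate_nt(cdr3))
      sid <- sprintf("STD%03d", i)
      muts <- NULL
      if (i %in% shm_standards) {
        k <- sample(seq(shm_range[1], shm_range[2]), 1)
        span <- seq(layout$primer_footprint, v$anchor_offset - 1L)
        pos <- sort(sample(span, min(k, length(span))))
        orig <- substring(v$sequence, pos + 1, pos + 1)
        new <- vapply(orig, function(b) sample(setdiff(DNA_BASES, b), 1), "")
        muts <- data.frame(standard_id = sid, v_position = pos,
                           original = orig, new = unname(new),
                           stringsAsFactors = FALSE, row.names = NULL)
        mut_rows[[length(mut_rows) + 1]] <- muts
      }
      full <- assemble_standard(layout, v$sequence, v$anchor_offset,
                                j$sequence, j$anchor_offset, cdr3,
                                layout$constant_prefixes[[subcl[i]]], muts)
      std_rows[[i]] <- data.frame(
        standard_id = sid, v_name = v_names[i], j_name = j_names[i],
        cdr3_nt = cdr3, cdr3_aa = accepted_aa[length(accepted_aa)],
        subclass = subcl[i], n_designed_mutations = if (is.null(muts)) 0L else nrow(muts),
        full_sequence = full, stringsAsFactors = FALSE)
    }
    standards <- do.call(rbind, std_rows)
    standards$relative_concentration <- if (is.null(concentrations)) {
      w <- 10^runif(n_clones, -2, 0)
      w / sum(w)
    } else {
      if (abs(sum(concentrations) - 1) > 1e-9) {
        stop_maf("concentrations must sum to 1", "mafseq_validation_error")
      }
      concentrations
    }
    structure(list(standards = standards,
                   mutations = if (length(mut_rows)) do.call(rbind, mut_rows)
                               else data.frame(standard_id = character(0),
                                               v_position = integer(0),
                                               original = character(0),
                                               new = character(0)),
                   layout = layout,
                   min_cdr3_nt_distance = min_cdr3_nt_distance),
              class = "spikein_set")
  })
}

#' @export
print.spikein_set <- function(x, ...) {
  cat("spikein_set:", nrow(x$standards), "standards,",
      sum(x$standards$n_designed_mutations > 0), "with designed SHM,",
      "min CDR3 nt distance", x$min_cdr3_nt_distance, "\n")
  invisible(x)
}

#' Validate a spike-in standard set
#'
#' Re-checks every structural invariant: CDR3 translation and anchors,
#' amino-acid uniqueness, the pairwise nucleotide distance floor,
#' concentration normalization, identifier absence from germlines, unique
#' in-range mutation positions, and byte-level agreement of each
#' `full_sequence` with a fresh assembly from the named germline segments
#' and declared mutations (so undeclared mutations are caught).
#'
#' @param set a `spikein_set`
#' @param db the `germline_db` the set was designed against
#' @return list of class `maf_validation` with elements `pass` (flag) and
#'   `violations` (data.frame standard_id/rule/detail)
#' @export
validate_standard_set <- function(set, db) {
  v <- list()
  add <- function(id, rule, detail = "") {
    v[[length(v) + 1]] <<- data.frame(standard_id = id, rule = rule,
                                      detail = detail, stringsAsFactors = FALSE)
  }
  st <- set$standards
  aa <- translate_nt(st$cdr3_nt)
  bad <- which(is.na(aa) | aa != st$cdr3_aa)
  for (i in bad) add(st$standard_id[i], "cdr3_translation")
  bad <- which(substr(st$cdr3_aa, 1, 1) != "C" |
               substr(st$cdr3_aa, nchar(st$cdr3_aa), nchar(st$cdr3_aa)) != "W")
  for (i in bad) add(st$standard_id[i], "cdr3_anchors")
  dup <- st$standard_id[duplicated(st$cdr3_aa) |
                        duplicated(st$cdr3_aa, fromLast = TRUE)]
  for (id in unique(dup)) add(id, "cdr3_aa_uniqueness")
  if (nrow(st) > 1) {
    d <- adist(st$cdr3_nt)
    diag(d) <- NA
    if (min(d, na.rm = TRUE) < set$min_cdr3_nt_distance) {
      idx <- which(d < set$min_cdr3_nt_distance, arr.ind = TRUE)
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      for (r in seq_len(nrow(idx))) {
        add(st$standard_id[idx[r, 1]], "cdr3_nt_min_distance",
            paste0("vs ", st$standard_id[idx[r, 2]], " d=",
                   d[idx[r, 1], idx[r, 2]]))
      }
    }
  }
  if (abs(sum(st$relative_concentration) - 1) > 1e-9) {
    add("*", "concentration_sum")
  }
  if (any(st$relative_concentration <= 0 | st$relative_concentration > 1)) {
    add("*", "concentration_range")
  }
  id_ok <- tryCatch({ check_identifier_absent(set$layout, db); TRUE },
                    error = function(e) FALSE)
  if (!id_ok) add("*", "identifier_in_germline")
  for (i in seq_len(nrow(st))) {
    vv <- db$v[db$v$name == st$v_name[i], ]
    jj <- db$j[db$j$name == st$j_name[i], ]
    if (nrow(vv) != 1 || nrow(jj) != 1) {
      add(st$standard_id[i], "unknown_germline")
      next
    }
    muts <- set$mutations[set$mutations$standard_id == st$standard_id[i], ]
    if (nrow(muts) > 0) {
      if (anyDuplicated(muts$v_position) ||
          any(muts$v_position < 0 | muts$v_position >= vv$anchor_offset)) {
        add(st$standard_id[i], "mutation_positions")
      }
      orig_ok <- substring(vv$sequence, muts$v_position + 1,
                           muts$v_position + 1) == muts$original
      if (!all(orig_ok)) add(st$standard_id[i], "mutation_reference_base")
    }
    expected <- assemble_standard(set$layout, vv$sequence, vv$anchor_offset,
                                  jj$sequence, jj$anchor_offset,
                                  st$cdr3_nt[i],
                                  set$layout$constant_prefixes[[st$subclass[i]]],
                                  muts)
    if (expected != st$full_sequence[i]) {
      add(st$standard_id[i], "sequence_mismatch",
          "full_sequence differs from assembly of germline + declared mutations")
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(standard_id = character(0), rule = character(0),
               detail = character(0))
  structure(list(pass = nrow(violations) == 0, violations = violations),
            class = "maf_validation")
}

#' @export
print.maf_validation <- function(x, ...) {
  if (x$pass) cat("validation: PASS\n")
  else {
    cat("validation: FAIL,", nrow(x$violations), "violation(s)\n")
    print(utils::head(x$violations, 20))
  }
  invisible(x)
}

#' Write / read a pool concentration manifest (TSV)
#'
#' Two tab-separated columns, `standard_id` and `relative_concentration`
#' (12 significant digits; round trips losslessly at that precision).
#' @param set a `spikein_set` or a data.frame with the two columns
#' @param path output path
#' @export
write_pool_manifest <- function(set, path) {
  df <- if (inherits(set, "spikein_set")) set$standards else set
  if (abs(sum(df$relative_concentration) - 1) > 1e-9) {
    stop_maf("manifest concentrations must sum to 1", "mafseq_validation_error")
  }
  lines <- c("standard_id\trelative_concentration",
             sprintf("%s\t%.12g", df$standard_id, df$relative_concentration))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pool_manifest
#' @param tol tolerance on the concentration sum
#' @return `read_pool_manifest`: named numeric vector standard_id ->
#'   relative concentration
#' @export
read_pool_manifest <- function(path, tol = 1e-6) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_maf("empty manifest", "mafseq_parse_error")
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop_maf(paste0("malformed manifest line ", bad[1] + 1L), "mafseq_parse_error")
  }
  ids <- vapply(parts, `[`, "", 1)
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (any(is.na(val))) {
    stop_maf(paste0("malformed manifest line ",
                    which(is.na(val))[1] + 1L), "mafseq_parse_error")
  }
  if (abs(sum(val) - 1) > tol) {
    stop_maf("manifest concentrations do not sum to 1", "mafseq_validation_error")
  }
  setNames(val, ids)
}

#' Write standards as FASTA
#' @param set a `spikein_set`
#' @param path output file
#' @export
write_standards_fasta <- function(set, path) {
  x <- Biostrings::DNAStringSet(set$standards$full_sequence)
  names(x) <- sprintf("%s v_name=%s j_name=%s subclass=%s",
                      set$standards$standard_id, set$standards$v_name,
                      set$standards$j_name, set$standards$subclass)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write standards as a GenBank-flavored flat file with feature annotations
#' @param set a `spikein_set`
#' @param db the germline database (for segment lengths)
#' @param path output file
#' @export
write_standards_genbank <- function(set, db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lay <- set$layout
  for (i in seq_len(nrow(set$standards))) {
    st <- set$standards[i, ]
    vv <- db$v[db$v$name == st$v_name, ]
    full <- st$full_sequence
    n <- nchar(full)
    p0 <- 1L
    feat <- function(name, start, end)
      sprintf("     misc_feature    %d..%d\n                     /label=\"%s\"",
              start, end, name)
    v_len <- vv$anchor_offset
    segs <- c(nchar(lay$conserved_5p), nchar(lay$leader), v_len,
              nchar(st$cdr3_nt))
    starts <- cumsum(c(1L, segs))
    writeLines(sprintf("LOCUS       %s %d bp DNA linear SYN", st$standard_id, n), con)
    writeLines(sprintf("DEFINITION  synthetic spike-in standard %s (%s / %s, %s)",
                       st$standard_id, st$v_name, st$j_name, st$subclass), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(feat("conserved_5p", starts[1], starts[2] - 1L), con)
    writeLines(feat("leader", starts[2], starts[3] - 1L), con)
    writeLines(feat(paste0("V:", st$v_name), starts[3], starts[4] - 1L), con)
    writeLines(feat("CDR3", starts[4], starts[5] - 1L), con)
    id_at <- regexpr(lay$synthetic_identifier, full, fixed = TRUE)
    writeLines(feat("identifier", id_at,
                    id_at + nchar(lay$synthetic_identifier) - 1L), con)
    writeLines(feat(paste0("C:", st$subclass), id_at +
                    nchar(lay$synthetic_identifier), n), con)
    writeLines("ORIGIN", con)
    for (s in seq(1, n, by = 60)) {
      writeLines(sprintf("%9d %s", s, substr(full, s, min(n, s + 59))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
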